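# Genome assembly: places planted snoRNA blocks, host genes, decoy ncRNAs
# and the repeat family on chromosomes separated by random spacers.

.TRUTH_COLS <- c("locus_id", "start", "end", "strand", "sno_class",
                 "guide_kind", "target_molecule_id", "target_position",
                 "guide_box", "target2_molecule_id", "target2_position",
                 "guide_box2", "host_gene_id", "intron_index", "cluster_id",
                 "capped", "pol3_terminator")

.fill_truth_cols <- function(df) {
  if (is.null(df)) return(NULL)
  for (cn in .TRUTH_COLS) {
    if (!cn %in% names(df)) {
      df[[cn]] <- switch(cn,
                         intron_index = NA_integer_,
                         capped = FALSE, pol3_terminator = FALSE,
                         NA_character_)
    }
  }
  df[, .TRUTH_COLS]
}

#' Build a synthetic genome with planted snoRNAs
#'
#' Generates chromosome sequences carrying protein-coding genes (with
#' introns), annotated decoy ncRNAs (tRNA/snRNA/rRNA/known-snoRNA-like), a
#' repeat family of near-identical truncated snoRNA copies, and planted C/D
#' and H/ACA box snoRNAs in intronic, clustered (polycistronic) and
#' intergenic contexts per the configured organization mix.  Each planted
#' structure is validated against the package's own scanners at construction
#' time, and planted guides are validated to recover exactly their planted
#' target residue (orphans to recover nothing).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sno_simulation`: a list with `genome` (a
#'   genome bundle: `$seq` named chromosome sequences, `$features` annotation
#'   data.frame), `truth` (one row per planted locus), `targets` (bundled
#'   rRNA/snRNA target molecules), `decoys` (expression parameters of decoy
#'   and repeat transcripts) and `config`.
#' @export
build_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  targets <- .make_targets()

  n <- config$n_cd + config$n_haca
  classes <- c(rep("CD", config$n_cd), rep("HACA", config$n_haca))
  ids <- ifelse(classes == "CD",
                sprintf("CD_%03d", seq_len(n)),
                sprintf("HA_%03d", seq_len(n)))
  org_counts <- .apportion(n, config$organization_mix[
    c("intronic", "clustered", "intergenic")])
  org <- sample(rep(c("intronic", "clustered", "intergenic"), org_counts))
  if (sum(org == "clustered") == 1L) org[org == "clustered"] <- "intergenic"
  kinds <- sample(rep(names(config$target_mix),
                      .apportion(n, config$target_mix)))

  ## intergenic loci draw cap / Pol III status
  capped <- rep(FALSE, n)
  pol3 <- rep(FALSE, n)
  inter <- which(org == "intergenic")
  capped[inter] <- runif(length(inter)) < config$capped_fraction_intergenic
  pol3[inter] <- runif(length(inter)) < config$pol3_fraction_intergenic

  loci <- vector("list", n)
  for (i in seq_len(n)) {
    loci[[i]] <- if (classes[i] == "CD") {
      .make_cd_locus(targets, kinds[i])
    } else {
      .make_haca_locus(targets, kinds[i])
    }
    if (pol3[i]) loci[[i]] <- .add_pol3_pad(loci[[i]])
  }

  ## ---- blocks ------------------------------------------------------------
  blocks <- list()
  add_block <- function(b, strand) {
    b$truth <- .fill_truth_cols(b$truth)
    if (strand == "-") b <- .flip_block(b)
    blocks[[length(blocks) + 1L]] <<- b
  }

  ## clusters
  cl_idx <- which(org == "clustered")
  n_cl <- if (length(cl_idx) >= 2L) {
    max(1L, min(config$n_clusters, length(cl_idx) %/% 2L))
  } else 0L
  if (n_cl > 0L) {
    sizes <- rep(2L, n_cl)
    rem <- length(cl_idx) - sum(sizes)
    if (rem > 0L) {
      extra <- sample(n_cl, rem, replace = TRUE)
      for (e in extra) sizes[e] <- sizes[e] + 1L
    }
    cl_members <- split(sample(cl_idx), rep(seq_len(n_cl), sizes))
    for (ci in seq_len(n_cl)) {
      mem <- cl_members[[ci]]
      mblocks <- lapply(mem, function(i) .sno_block(loci[[i]], ids[i]))
      gaps <- sample(20:80, max(1L, length(mem) - 1L), replace = TRUE)
      cb <- .cluster_block(mblocks, gaps)
      cb$truth$cluster_id <- sprintf("cluster_%02d", ci)
      intronic_cluster <- (ci == 1L && n_cl >= 3L)
      if (intronic_cluster) {
        ni <- .rand_len(2L, 3L)
        cb <- .gene_block(sprintf("gene_cl%02d", ci), hosted = cb,
                          host_intron = sample(ni, 1), n_introns = ni)
      }
      add_block(cb, sample(c("+", "-"), 1))
    }
  }

  ## intronic single loci, each hosted in its own gene
  for (i in which(org == "intronic")) {
    ni <- .rand_len(2L, 4L)
    gb <- .gene_block(sprintf("gene_%s", ids[i]),
                      hosted = .sno_block(loci[[i]], ids[i]),
                      host_intron = sample(ni, 1), n_introns = ni)
    add_block(gb, sample(c("+", "-"), 1))
  }

  ## intergenic single loci
  for (i in which(org == "intergenic")) {
    add_block(.sno_block(loci[[i]], ids[i]), sample(c("+", "-"), 1))
  }

  ## decoy annotated ncRNAs
  decoy_meta <- NULL
  if (config$n_decoys > 0L) {
    dtypes <- rep(c("tRNA", "snRNA", "tRNA", "rRNA", "tRNA", "snoRNA"),
                  length.out = config$n_decoys)
    for (d in seq_len(config$n_decoys)) {
      id <- sprintf("decoy_%02d", d)
      add_block(.decoy_block(id, dtypes[d]), sample(c("+", "-"), 1))
      decoy_meta <- rbind(decoy_meta,
                          data.frame(locus_id = id, type = dtypes[d],
                                     stringsAsFactors = FALSE))
    }
  }

  ## repeat family (truncated "dead" snoRNA copies)
  if (config$n_repeat_copies > 0L) {
    master <- .repeat_master()
    for (r in seq_len(config$n_repeat_copies)) {
      id <- sprintf("repeat_%02d", r)
      cp <- .repeat_copy(master)
      add_block(list(seq = cp,
                     feats = .feat_row(id, "repeat_region", 1L, nchar(cp)),
                     truth = NULL),
                sample(c("+", "-"), 1))
      decoy_meta <- rbind(decoy_meta,
                          data.frame(locus_id = id, type = "repeat_region",
                                     stringsAsFactors = FALSE))
    }
  }

  ## extra genes without snoRNAs
  if (config$n_extra_genes > 0L) {
    for (g in seq_len(config$n_extra_genes)) {
      add_block(.gene_block(sprintf("gene_x%02d", g)), sample(c("+", "-"), 1))
    }
  }

  ## ---- chromosome assembly ------------------------------------------------
  n_chr <- config$n_chromosomes
  sizes <- rep(floor(config$genome_length / n_chr), n_chr)
  sizes[n_chr] <- config$genome_length - sum(sizes[-n_chr])
  ord <- sample(length(blocks))
  chrom_of <- rep(seq_len(n_chr), length.out = length(blocks))

  seqs <- character(n_chr)
  names(seqs) <- sprintf("chr%d", seq_len(n_chr))
  feats <- NULL
  truth <- NULL
  min_spacer <- 60L
  for (k in seq_len(n_chr)) {
    bk <- blocks[ord[chrom_of == k]]
    lens <- vapply(bk, function(b) nchar(b$seq), numeric(1))
    n_slots <- length(bk) + 1L
    free <- sizes[k] - sum(lens) - n_slots * min_spacer
    if (free < 0) {
      stop("genome_length too small to place the requested loci without ",
           "overlap: chromosome ", k, " needs at least ",
           sum(lens) + n_slots * min_spacer, " nt but has ", sizes[k])
    }
    extra <- as.vector(rmultinom(1, free, rep(1, n_slots)))
    spacer_lens <- min_spacer + extra
    parts <- character(2L * length(bk) + 1L)
    off <- 0L
    for (j in seq_along(bk)) {
      parts[2L * j - 1L] <- .random_dna(spacer_lens[j])
      off <- off + spacer_lens[j]
      b <- bk[[j]]
      if (nrow(b$feats) > 0L) {
        b$feats$start <- b$feats$start + off
        b$feats$end <- b$feats$end + off
        b$feats$chrom <- names(seqs)[k]
        feats <- rbind(feats, b$feats)
      }
      if (!is.null(b$truth) && nrow(b$truth) > 0L) {
        b$truth$start <- b$truth$start + off
        b$truth$end <- b$truth$end + off
        b$truth$chrom <- names(seqs)[k]
        truth <- rbind(truth, b$truth)
      }
      parts[2L * j] <- b$seq
      off <- off + nchar(b$seq)
    }
    parts[2L * length(bk) + 1L] <- .random_dna(spacer_lens[n_slots])
    seqs[k] <- paste(parts, collapse = "")
  }

  ## ---- truth bookkeeping ---------------------------------------------------
  truth$organization <- org[match(truth$locus_id, ids)]
  truth$capped <- capped[match(truth$locus_id, ids)]
  truth$pol3_terminator <- pol3[match(truth$locus_id, ids)]
  truth <- truth[order(truth$locus_id), ]
  rownames(truth) <- NULL

  ## accumulated abundance and stability, Gaussian-copula coupled
  rho_z <- 2 * sin(pi * config$stability_abundance_rho / 6)
  z1 <- rnorm(n)
  z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * rnorm(n)
  abundance <- 10^(config$abundance_log10_mean +
                     config$abundance_log10_sd * z1)
  lo <- config$stability_range[1]
  hi <- config$stability_range[2]
  stability <- lo + (hi - lo) * pnorm(z2)
  truth$stability <- stability
  truth$abundance_weight <- abundance / stability   # molar weight: w = a / s

  ## decoy / repeat expression parameters
  decoys <- NULL
  if (!is.null(decoy_meta)) {
    m <- match(decoy_meta$locus_id, feats$feature_id)
    decoys <- data.frame(
      locus_id = decoy_meta$locus_id, type = decoy_meta$type,
      chrom = feats$chrom[m], strand = feats$strand[m],
      start = feats$start[m], end = feats$end[m],
      stringsAsFactors = FALSE)
    is_rep <- decoys$type == "repeat_region"
    decoys$abundance_weight <-
      ifelse(is_rep, 10^rnorm(nrow(decoys), 0.8, 0.2),
             10^rnorm(nrow(decoys), 1.2, 0.5))
    decoys$stability <- ifelse(is_rep, runif(nrow(decoys), 0.7, 0.95),
                               runif(nrow(decoys), 0.6, 0.95))
    decoys$capped <- decoys$type == "snoRNA"
  }

  feats <- feats[, c("feature_id", "type", "chrom", "start", "end",
                     "strand", "parent", "class", "idx")]
  rownames(feats) <- NULL
  truth <- truth[, c("locus_id", "chrom", "strand", "start", "end",
                     setdiff(.TRUTH_COLS,
                             c("locus_id", "chrom", "strand", "start", "end")),
                     "organization", "abundance_weight", "stability")]

  structure(list(
    genome = structure(list(seq = seqs, features = feats),
                       class = "genome_bundle"),
    truth = truth, targets = targets, decoys = decoys, config = config
  ), class = "sno_simulation")
}

#' Extract a locus sequence from a genome bundle
#'
#' Strand-aware: minus-strand loci are returned reverse-complemented so the
#' result always reads 5' to 3' on the transcribed (sense) strand, with
#' `flank` nt of genomic context on each side.
#'
#' @param genome a genome bundle (`$seq`, `$features`).
#' @param chrom,start,end,strand locus coordinates (1-based closed).
#' @param flank nt of genomic flanking sequence to include on both sides.
#' @return a character string.
#' @export
locus_sequence <- function(genome, chrom, start, end, strand = "+",
                           flank = 0L) {
  seq <- genome$seq[[chrom]]
  lo <- max(1L, start - flank)
  hi <- min(nchar(seq), end + flank)
  s <- substr(seq, lo, hi)
  if (strand == "-") s <- revcomp(s)
  s
}
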