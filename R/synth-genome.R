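# Synthetic genome with planted snoRNAs.
#
# Every planted locus is built in sense orientation as a "block" (terminal IR
# arms + mature sequence for C/D loci; mature sequence for H/ACA loci), then
# embedded into host-gene introns, polycistronic clusters or intergenic
# space, possibly on the minus strand.  Construction is validated against the
# package's own scanners: planted structures must be recognized and planted
# guides must recover their planted target residue (orphans must recover
# nothing) -- loci are resampled until they satisfy their own definition.

.mutate_base <- function(chars, pos) {
  chars[pos] <- sample(setdiff(.BASES, chars[pos]), 1)
  chars
}

## One divergence from the strict C box consensus (for internal C' boxes).
.divergent_box <- function(box) {
  ch <- .chars(box)
  paste(.mutate_base(ch, sample(seq_along(ch), 1)), collapse = "")
}

.rand_len <- function(lo, hi) {
  if (lo == hi) return(as.integer(lo))   # sample(n, 1) would draw from 1:n
  sample(lo:hi, 1)
}

## sample() treats a length-1 vector as 1:x; this always picks from `x`.
.sample1 <- function(x) x[[sample.int(length(x), 1L)]]

## -------------------------------------------------------------------------
## Target molecules (bundled synthetic rRNA / snRNA the guides point at).

.make_targets <- function() {
  data.frame(
    molecule_id = c("SSU_rRNA", "U2_snRNA"),
    kind = c("rRNA", "snRNA"),
    sequence = c(.random_dna(1800), .random_dna(190)),
    stringsAsFactors = FALSE)
}

## Antisense element against target positions [u-4, u-5+len]; the guide base
## 5 nt upstream of the box then pairs the target residue u (D+5 rule).
.cd_ase <- function(target_seq, u, len) {
  revcomp(substr(target_seq, u - 4L, u - 5L + len))
}

## Pocket strands pairing the target around the unpaired U-N at u:
## right strand pairs target[u-1], target[u-2], ...; left strand (read
## 3'->5') pairs target[u+2], target[u+3], ...
.haca_pockets <- function(target_seq, u, side = 7L) {
  tch <- .chars(target_seq)
  pr <- paste(.comp1[tch[u - seq_len(side)]], collapse = "")
  pl <- paste(.comp1[tch[u + 1L + rev(seq_len(side))]], collapse = "")
  list(left = pl, right = pr)
}

## Pick a guided residue: any base for 2'-O-methylation, a U (T) for
## pseudouridylation.
.pick_residue <- function(target_seq, psi = FALSE) {
  lo <- 12L
  hi <- nchar(target_seq) - 20L
  if (psi) {
    pos <- which(.chars(target_seq) == "T")
    .sample1(pos[pos >= lo & pos <= hi])
  } else {
    .sample1(lo:hi)
  }
}

## -------------------------------------------------------------------------
## C/D box locus construction + closure validation.

## guide_kind: "rRNA", "snRNA", "dual", "orphan".  arm_range: terminal IR
## stem length (paper-typical 4-7 bp by default; polycistronic-unit fixtures
## use strong stems so that unit boundaries are IR-dominated).
.make_cd_locus <- function(targets, guide_kind, max_tries = 60L,
                           arm_range = c(4L, 7L)) {
  rr <- targets[targets$kind == "rRNA", ][1, ]
  sn <- targets[targets$kind == "snRNA", ][1, ]
  for (try in seq_len(max_tries)) {
    s <- .rand_len(arm_range[1], arm_range[2])
    arm5 <- .random_dna(s)
    arm3 <- revcomp(arm5)
    cbox <- sample(c("ATGATGA", "GTGATGA"), 1)
    cprime <- .divergent_box("ATGATGA")

    t1 <- if (guide_kind %in% c("rRNA", "dual")) rr else
      if (guide_kind == "snRNA") sn else NULL
    u1 <- if (!is.null(t1)) .pick_residue(t1$sequence) else NA_integer_
    ase1 <- if (!is.null(t1)) .cd_ase(t1$sequence, u1, .rand_len(11L, 14L))
            else .random_dna(12L)
    dual <- identical(guide_kind, "dual")
    u2 <- if (dual) .pick_residue(sn$sequence) else NA_integer_
    mid <- if (dual) .cd_ase(sn$sequence, u2, .rand_len(11L, 13L))
           else .random_dna(.rand_len(8L, 12L))

    parts <- c(.random_dna(4L), cbox, .random_dna(.rand_len(8L, 14L)),
               cprime, .random_dna(.rand_len(4L, 8L)),
               mid, "CTGA",
               .random_dna(.rand_len(6L, 10L)), ase1, "CTGA",
               .random_dna(3L))
    mature <- paste(parts, collapse = "")
    lm <- nchar(mature)
    d_rel <- lm - 6L                                   # terminal D box start
    dp_rel <- lm - 6L - nchar(ase1) -
      .nch(parts[8]) - 4L                              # D' box start
    seqf <- paste0(arm5, mature, arm3)

    ann <- scan_cd(seqf, flank = s)
    if (is.null(ann)) next
    if (ann$d_box[1] != s + d_rel) next
    if (classify_locus(ann, scan_haca(mature)) != "CD") next
    if (dual && (is.null(ann$d_prime_box) ||
                 ann$d_prime_box[1] != s + dp_rel)) next
    hits <- find_cd_targets(ann, seqf, targets)
    if (guide_kind == "orphan") {
      if (nrow(hits) > 0L) next
    } else {
      ok1 <- any(hits$guide_box == "D" &
                 hits$target_molecule_id == t1$molecule_id &
                 hits$predicted_residue == u1)
      if (!ok1) next
      if (dual) {
        ok2 <- any(hits$guide_box == "Dprime" &
                   hits$target_molecule_id == sn$molecule_id &
                   hits$predicted_residue == u2)
        if (!ok2) next
      }
    }
    return(list(sno_class = "CD", block = seqf, arm_len = s,
                mature_rel = c(s + 1L, s + lm),
                guide_kind = guide_kind,
                target_molecule_id = if (is.null(t1)) NA_character_
                                     else t1$molecule_id,
                target_position = u1, guide_box = if (is.null(t1)) NA else "D",
                target2_molecule_id = if (dual) sn$molecule_id
                                      else NA_character_,
                target2_position = u2,
                guide_box2 = if (dual) "Dprime" else NA_character_))
  }
  stop("failed to construct a valid C/D locus after ", max_tries, " tries")
}

.nch <- function(x) nchar(x)

## -------------------------------------------------------------------------
## H/ACA locus construction + closure validation.

## One hairpin: outer arm, pocket internal loop (the bipartite ASE), inner
## arm, 4 nt apical loop.  16 pairs per hairpin.
.haca_stem <- function(pockets) {
  outer <- .random_dna(8L)
  inner <- .random_dna(8L)
  paste0(outer, pockets$left, inner, .random_dna(4L),
         revcomp(inner), pockets$right, revcomp(outer))
}

.make_haca_locus <- function(targets, guide_kind, max_tries = 60L) {
  rr <- targets[targets$kind == "rRNA", ][1, ]
  sn <- targets[targets$kind == "snRNA", ][1, ]
  for (try in seq_len(max_tries)) {
    t1 <- if (guide_kind %in% c("rRNA", "dual")) rr else
      if (guide_kind == "snRNA") sn else NULL
    u1 <- if (!is.null(t1)) .pick_residue(t1$sequence, psi = TRUE)
          else NA_integer_
    p1 <- if (!is.null(t1)) .haca_pockets(t1$sequence, u1) else
      list(left = .random_dna(7L), right = .random_dna(7L))
    dual <- identical(guide_kind, "dual")
    u2 <- if (dual) .pick_residue(sn$sequence, psi = TRUE) else NA_integer_
    p2 <- if (dual) .haca_pockets(sn$sequence, u2) else
      list(left = .random_dna(7L), right = .random_dna(7L))

    hbox <- paste0("A", .random_dna(1L), "A", .random_dna(2L), "A")
    mature <- paste0(.random_dna(3L), .haca_stem(p1), .random_dna(2L),
                     hbox, .random_dna(2L), .haca_stem(p2), .random_dna(2L),
                     "ACA", .random_dna(3L))
    ann <- scan_haca(mature)
    if (is.null(ann)) next
    if (classify_locus(scan_cd(paste0(.random_dna(15L), mature,
                                      .random_dna(15L))), ann) != "HACA") next
    hits <- find_haca_targets(ann, mature, targets)
    if (guide_kind == "orphan") {
      if (nrow(hits) > 0L) next
    } else {
      ok1 <- any(hits$guide_box == "pocket1" &
                 hits$target_molecule_id == t1$molecule_id &
                 hits$predicted_residue == u1)
      if (!ok1) next
      if (dual) {
        ok2 <- any(hits$guide_box == "pocket2" &
                   hits$target_molecule_id == sn$molecule_id &
                   hits$predicted_residue == u2)
        if (!ok2) next
      }
    }
    lm <- nchar(mature)
    return(list(sno_class = "HACA", block = mature, arm_len = 0L,
                mature_rel = c(1L, lm),
                guide_kind = guide_kind,
                target_molecule_id = if (is.null(t1)) NA_character_
                                     else t1$molecule_id,
                target_position = u1,
                guide_box = if (is.null(t1)) NA_character_ else "pocket1",
                target2_molecule_id = if (dual) sn$molecule_id
                                      else NA_character_,
                target2_position = u2,
                guide_box2 = if (dual) "pocket2" else NA_character_))
  }
  stop("failed to construct a valid H/ACA locus after ", max_tries, " tries")
}

## Append an RNA polymerase III terminator: a 6 nt T-stretch starting 2 nt
## past the downstream end of the block (well within 15 nt of the 3' end).
.add_pol3_pad <- function(locus) {
  locus$block <- paste0(locus$block, .random_dna(2L), "TTTTTT", .random_dna(2L))
  locus
}

## -------------------------------------------------------------------------
## Blocks: seq + relative features + relative truth spans, sense-built,
## flipped as a whole for minus-strand placement.

.empty_feats <- function() {
  data.frame(feature_id = character(0), type = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             parent = character(0), class = character(0),
             idx = integer(0), stringsAsFactors = FALSE)
}

.feat_row <- function(id, type, start, end, parent = NA_character_,
                      class = NA_character_, idx = NA_integer_) {
  data.frame(feature_id = id, type = type, start = as.integer(start),
             end = as.integer(end), strand = "+", parent = parent,
             class = class, idx = as.integer(idx), stringsAsFactors = FALSE)
}

.flip_block <- function(block) {
  L <- nchar(block$seq)
  block$seq <- revcomp(block$seq)
  flip <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    s <- df$start
    df$start <- L - df$end + 1L
    df$end <- L - s + 1L
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  block$feats <- flip(block$feats)
  block$truth <- flip(block$truth)
  block
}

## Truth rows carried inside blocks before genomic placement.
.truth_row <- function(locus, locus_id) {
  data.frame(locus_id = locus_id,
             start = locus$mature_rel[1], end = locus$mature_rel[2],
             strand = "+", sno_class = locus$sno_class,
             guide_kind = locus$guide_kind,
             target_molecule_id = locus$target_molecule_id,
             target_position = locus$target_position,
             guide_box = locus$guide_box,
             target2_molecule_id = locus$target2_molecule_id,
             target2_position = locus$target2_position,
             guide_box2 = locus$guide_box2,
             stringsAsFactors = FALSE)
}

## A standalone snoRNA block (intergenic locus / cluster member).
.sno_block <- function(locus, locus_id) {
  tr <- .truth_row(locus, locus_id)
  feats <- .feat_row(locus_id, "ncRNA", tr$start, tr$end,
                     class = locus$sno_class)
  list(seq = locus$block, feats = feats, truth = tr)
}

## Several member blocks chained with short spacers (a polycistronic
## cluster transcribed as one precursor).
.cluster_block <- function(member_blocks, gaps) {
  seq <- ""
  feats <- .empty_feats()
  truth <- NULL
  off <- 0L
  for (i in seq_along(member_blocks)) {
    b <- member_blocks[[i]]
    seq <- paste0(seq, b$seq)
    b$feats$start <- b$feats$start + off
    b$feats$end <- b$feats$end + off
    b$truth$start <- b$truth$start + off
    b$truth$end <- b$truth$end + off
    feats <- rbind(feats, b$feats)
    truth <- rbind(truth, b$truth)
    off <- off + nchar(b$seq)
    if (i < length(member_blocks)) {
      seq <- paste0(seq, .random_dna(gaps[i]))
      off <- off + gaps[i]
    }
  }
  list(seq = seq, feats = feats, truth = truth)
}

## A protein-coding gene; `hosted` (optional) is a block embedded in intron
## `host_intron` with 25 nt margins on both sides.
.gene_block <- function(gene_id, hosted = NULL, host_intron = 1L,
                        n_introns = NULL) {
  if (is.null(n_introns)) n_introns <- .rand_len(2L, 4L)
  margin <- 25L
  exon_lens <- sample(130:260, n_introns + 1L, replace = TRUE)
  seq <- ""
  feats <- .empty_feats()
  truth <- NULL
  off <- 0L
  mrna_id <- paste0(gene_id, ".t1")
  for (k in seq_len(n_introns + 1L)) {
    ex <- .random_dna(exon_lens[k])
    feats <- rbind(feats,
                   .feat_row(paste0(mrna_id, ".exon", k), "exon",
                             off + 1L, off + exon_lens[k], parent = mrna_id,
                             idx = k),
                   .feat_row(paste0(mrna_id, ".cds", k), "CDS",
                             off + 1L, off + exon_lens[k], parent = mrna_id))
    seq <- paste0(seq, ex)
    off <- off + exon_lens[k]
    if (k <= n_introns) {
      if (!is.null(hosted) && k == host_intron) {
        intron_seq <- paste0(.random_dna(margin), hosted$seq,
                             .random_dna(margin))
        hosted$feats$start <- hosted$feats$start + off + margin
        hosted$feats$end <- hosted$feats$end + off + margin
        hosted$truth$start <- hosted$truth$start + off + margin
        hosted$truth$end <- hosted$truth$end + off + margin
        feats <- rbind(feats, hosted$feats)
        truth <- rbind(truth, hosted$truth)
      } else {
        intron_seq <- .random_dna(.rand_len(80L, 140L))
      }
      feats <- rbind(feats,
                     .feat_row(paste0(mrna_id, ".intron", k), "intron",
                               off + 1L, off + nchar(intron_seq),
                               parent = mrna_id, idx = k))
      seq <- paste0(seq, intron_seq)
      off <- off + nchar(intron_seq)
    }
  }
  feats <- rbind(.feat_row(gene_id, "gene", 1L, off),
                 .feat_row(mrna_id, "mRNA", 1L, off, parent = gene_id),
                 feats)
  if (!is.null(truth)) {
    truth$host_gene_id <- gene_id
    truth$intron_index <- host_intron
  }
  list(seq = seq, feats = feats, truth = truth)
}

## Decoy annotated ncRNAs (the discard list: rRNA, tRNA, snRNA, known
## snoRNA) and the repeat family of truncated "dead" snoRNA copies.
.decoy_block <- function(id, type) {
  len <- switch(type, tRNA = .rand_len(70L, 80L), snRNA = .rand_len(150L, 170L),
                rRNA = 120L, snoRNA = 215L)
  list(seq = .random_dna(len),
       feats = .feat_row(id, type, 1L, len, class = type), truth = NULL)
}

.repeat_master <- function() {
  paste0(.random_dna(4L), "ATGATGA", .random_dna(45L), "CTGA", .random_dna(3L))
}

.repeat_copy <- function(master, per_base_mut = 0.02) {
  ch <- .chars(master)
  hit <- which(runif(length(ch)) < per_base_mut)
  for (p in hit) ch <- .mutate_base(ch, p)
  paste(ch, collapse = "")
}
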