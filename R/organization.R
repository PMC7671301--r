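# Genomic-organization taxonomy: intronic (hosted in a protein-coding gene's
# intron, sense strand), clustered (polycistronic: same-strand neighbours
# within max_gap with nothing annotated in between), or intergenic
# (monocistronic).  Clustering takes precedence; a cluster inside an intron
# keeps org_class "clustered" with intronic_cluster = TRUE.

#' Classify the genomic organization of snoRNA loci
#'
#' @param loci data.frame with `locus_id`, `chrom`, `strand`, `start`, `end`.
#' @param genome a genome bundle whose features include `gene`, `exon`,
#'   `CDS` and `intron` rows.
#' @param max_gap maximum gap (nt) chaining same-strand loci into a cluster.
#' @return a data.frame of organization calls: `org_class` (`intronic`,
#'   `clustered`, `intergenic`, or `ambiguous` for exon-straddling or
#'   antisense-intronic loci), `host_gene_id`, `intron_index`, `cluster_id`,
#'   `cluster_size`, `intronic_cluster`.
#' @export
classify_organization <- function(loci, genome, max_gap = 500L) {
  f <- genome$features
  n <- nrow(loci)
  out <- data.frame(locus_id = loci$locus_id,
                    org_class = rep(NA_character_, n),
                    host_gene_id = rep(NA_character_, n),
                    intron_index = rep(NA_integer_, n),
                    cluster_id = rep(NA_character_, n),
                    cluster_size = rep(NA_integer_, n),
                    intronic_cluster = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  ## --- clusters first: chain same-strand loci with small, empty gaps ------
  blockers <- f[f$type %in% c("exon", "CDS", "rRNA", "tRNA", "snRNA",
                              "snoRNA", "repeat_region"), , drop = FALSE]
  ord <- order(loci$chrom, loci$strand, loci$start)
  comp <- integer(n)            # cluster component per locus (input order)
  comp[ord[1]] <- 1L
  n_comp <- 1L
  if (n > 1L) {
    for (k in 2:n) {
      i_prev <- ord[k - 1L]
      i <- ord[k]
      chained <- FALSE
      if (loci$chrom[i] == loci$chrom[i_prev] &&
          loci$strand[i] == loci$strand[i_prev]) {
        gap_lo <- loci$end[i_prev] + 1L
        gap_hi <- loci$start[i] - 1L
        gap <- gap_hi - gap_lo + 1L
        if (gap <= max_gap) {
          blocked <- gap >= 1L &&
            any(blockers$chrom == loci$chrom[i] &
                  blockers$start <= gap_hi & blockers$end >= gap_lo)
          chained <- !blocked
        }
      }
      if (!chained) n_comp <- n_comp + 1L
      comp[i] <- n_comp
    }
  }
  sizes <- table(comp)
  is_clustered <- as.integer(sizes[as.character(comp)]) >= 2L
  cl_ids <- match(comp, sort(unique(comp[is_clustered])))
  out$cluster_id[is_clustered] <-
    sprintf("cluster_%02d", cl_ids[is_clustered])
  out$cluster_size[is_clustered] <-
    as.integer(sizes[as.character(comp)])[is_clustered]

  ## --- intronic / intergenic / ambiguous ----------------------------------
  introns <- f[f$type == "intron", , drop = FALSE]
  genes <- f[f$type == "gene", , drop = FALSE]
  mrna <- f[f$type == "mRNA", , drop = FALSE]
  for (i in seq_len(n)) {
    contains <- introns$chrom == loci$chrom[i] &
      introns$start <= loci$start[i] & introns$end >= loci$end[i]
    sense <- contains & introns$strand == loci$strand[i]
    gene_ov <- genes$chrom == loci$chrom[i] &
      genes$start <= loci$end[i] & genes$end >= loci$start[i]
    host <- function(j) {
      tx <- introns$parent[j]
      g <- mrna$parent[match(tx, mrna$feature_id)]
      if (is.na(g)) tx else g
    }
    if (any(sense)) {
      j <- which(sense)[1]
      out$host_gene_id[i] <- host(j)
      out$intron_index[i] <- introns$idx[j]
      if (is_clustered[i]) {
        out$org_class[i] <- "clustered"
        out$intronic_cluster[i] <- TRUE
      } else {
        out$org_class[i] <- "intronic"
      }
    } else if (is_clustered[i]) {
      out$org_class[i] <- "clustered"
      if (any(contains)) {          # antisense-intronic cluster member
        out$intronic_cluster[i] <- TRUE
      }
    } else if (any(contains)) {     # antisense-intronic: flagged, unclassified
      out$org_class[i] <- "ambiguous"
      out$host_gene_id[i] <- host(which(contains)[1])
    } else if (any(gene_ov)) {      # straddles exon-intron boundary / exon
      out$org_class[i] <- "ambiguous"
      out$host_gene_id[i] <- genes$feature_id[which(gene_ov)[1]]
    } else {
      out$org_class[i] <- "intergenic"
    }
  }
  out
}

#' Tally organization classes
#'
#' @param calls output of [classify_organization()].
#' @return named integer vector over intronic / clustered / intergenic /
#'   ambiguous plus `total`; classes partition the loci, so the counts sum
#'   to `nrow(calls)`.
#' @export
summarize_organization <- function(calls) {
  classes <- c("intronic", "clustered", "intergenic", "ambiguous")
  counts <- vapply(classes, function(cl) sum(calls$org_class == cl,
                                             na.rm = TRUE), integer(1))
  c(counts, total = nrow(calls))
}
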