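# Abundance quantification: read counting (50% overlap rule), TPM
# normalization, snoRNA/sdRNA stability ratios, and the abundance-stability
# rank correlation.

#' Count reads per locus
#'
#' A read is assigned to a locus iff at least half of the read overlaps the
#' locus on the same strand; each read counts at most once per (library,
#' replicate), toward the locus of maximal overlap (ties toward the 5'-most,
#' i.e. leftmost-start, locus).
#'
#' @param loci data.frame with `locus_id`, `chrom`, `strand`, `start`, `end`.
#' @param reads aligned-read data.frame.
#' @return integer matrix, loci x (library.replicate) columns.
#' @export
count_reads <- function(loci, reads) {
  combos <- unique(reads[, c("library", "replicate")])
  combos <- combos[order(match(combos$library, .LIBRARIES),
                         combos$replicate), , drop = FALSE]
  cols <- if (nrow(combos)) paste(combos$library, combos$replicate, sep = ".")
          else character(0)
  counts <- matrix(0L, nrow = nrow(loci), ncol = length(cols),
                   dimnames = list(loci$locus_id, cols))
  if (nrow(loci) == 0L || nrow(reads) == 0L) return(counts)

  gl <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start, loci$end),
                               strand = loci$strand)
  gr <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start, reads$end),
                               strand = reads$strand)
  ov <- GenomicRanges::findOverlaps(gr, gl, ignore.strand = FALSE)
  if (length(ov) == 0L) return(counts)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  ow <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr)[qh],
                                           IRanges::ranges(gl)[sh]))
  rw <- IRanges::width(gr)[qh]
  keep <- ow >= rw / 2                       # >= 50% of the read
  qh <- qh[keep]; sh <- sh[keep]; ow <- ow[keep]
  if (length(qh) == 0L) return(counts)
  ## per read: maximal overlap, ties -> leftmost locus start
  o <- order(qh, -ow, loci$start[sh])
  qh <- qh[o]; sh <- sh[o]
  first <- !duplicated(qh)
  qh <- qh[first]; sh <- sh[first]
  col_of <- match(paste(reads$library[qh], reads$replicate[qh], sep = "."),
                  cols)
  for (i in seq_along(qh)) {
    counts[sh[i], col_of[i]] <- counts[sh[i], col_of[i]] + 1L
  }
  counts
}

#' Transcripts-per-million normalization
#'
#' `tpm_i = 1e6 * (c_i / L_i) / sum_j(c_j / L_j)`.  An all-zero count vector
#' returns all-zero TPM.
#'
#' @param counts non-negative numeric vector of raw counts.
#' @param lengths positive numeric vector of locus lengths (nt).
#' @return numeric TPM vector (sums to 1e6 whenever any count is nonzero).
#' @export
compute_tpm <- function(counts, lengths) {
  if (any(counts < 0)) stop("negative read count")
  if (any(lengths <= 0)) stop("locus lengths must be positive")
  rate <- counts / lengths
  s <- sum(rate)
  if (s == 0) return(rep(0, length(counts)))
  1e6 * rate / s
}

#' Per-locus abundance records
#'
#' Raw counts and TPM per (library, replicate); replicate TPM are averaged
#' per library after normalization.  The stability ratio is mean +TAP TPM
#' over mean small-RNA TPM computed on the same locus universe; a zero
#' sdRNA TPM yields an infinite ratio with `ratio_infinite = TRUE`.
#'
#' @param loci data.frame with `locus_id`, `chrom`, `strand`, `start`, `end`.
#' @param reads aligned-read data.frame (all libraries).
#' @return a data.frame with one row per locus: counts and TPM columns per
#'   (library, replicate), `tpm_plus_mean`, `sdrna_tpm_mean`,
#'   `stability_ratio`, `ratio_infinite`.
#' @export
abundance_table <- function(loci, reads) {
  counts <- count_reads(loci, reads)
  lengths <- loci$end - loci$start + 1L
  tpm <- apply(counts, 2, compute_tpm, lengths = lengths)
  if (is.null(dim(tpm))) tpm <- matrix(tpm, nrow = nrow(loci),
                                       dimnames = dimnames(counts))
  plus_cols <- grepl("^mnc_tap_plus", colnames(tpm))
  srna_cols <- grepl("^srna", colnames(tpm))
  out <- data.frame(locus_id = loci$locus_id,
                    length = lengths, stringsAsFactors = FALSE)
  for (cn in colnames(counts)) {
    out[[paste0("count.", cn)]] <- counts[, cn]
    out[[paste0("tpm.", cn)]] <- tpm[, cn]
  }
  out$tpm_plus_mean <- if (any(plus_cols))
    rowMeans(tpm[, plus_cols, drop = FALSE]) else 0
  out$sdrna_tpm_mean <- if (any(srna_cols))
    rowMeans(tpm[, srna_cols, drop = FALSE]) else 0
  sr <- stability_ratio(out$tpm_plus_mean, out$sdrna_tpm_mean)
  out$stability_ratio <- sr$ratio
  out$ratio_infinite <- sr$infinite
  out
}

#' snoRNA / sdRNA stability ratio
#'
#' The ratio of full-length (mncRNA +TAP) TPM to sno-derived small RNA TPM is
#' a relative measure of a locus's susceptibility to degradation: stable
#' snoRNAs have high ratios, unstable ones low.  A zero denominator is
#' reported as `Inf` with an explicit flag rather than dropped.
#'
#' @param tpm_plus_mean numeric vector of mean +TAP TPM.
#' @param sdrna_tpm_mean numeric vector of mean small-RNA TPM over the same
#'   loci.
#' @return list with `ratio` and logical `infinite`.
#' @export
stability_ratio <- function(tpm_plus_mean, sdrna_tpm_mean) {
  ratio <- ifelse(sdrna_tpm_mean == 0,
                  ifelse(tpm_plus_mean > 0, Inf, NA_real_),
                  tpm_plus_mean / sdrna_tpm_mean)
  list(ratio = ratio, infinite = is.infinite(ratio))
}

#' Spearman correlation between abundance and stability ratio
#'
#' Rank correlation between mean +TAP TPM and the snoRNA/sdRNA ratio over
#' loci above `min_tpm` with finite ratios (infinite-ratio loci are excluded
#' and counted).  Ties get average ranks.  The p-value is two-sided: by
#' permutation (fixed internal seed, `n_perm` shuffles) when n < 50, else by
#' the asymptotic t approximation.
#'
#' @param records an [abundance_table()] data.frame (needs `tpm_plus_mean`,
#'   `stability_ratio`).
#' @param min_tpm minimum mean +TAP TPM for inclusion.
#' @param n_perm permutation count for the small-n p-value.
#' @param perm_seed fixed seed of the permutation stream (documented for
#'   reproducibility; does not touch the caller's RNG state).
#' @return list with `rho`, `p_value`, `n`, `n_excluded_infinite`, `method`.
#' @export
abundance_stability_correlation <- function(records, min_tpm = 0,
                                            n_perm = 10000L,
                                            perm_seed = 20201009L) {
  usable <- records$tpm_plus_mean > min_tpm &
    is.finite(records$stability_ratio)
  n_inf <- sum(records$tpm_plus_mean > min_tpm &
                 is.infinite(records$stability_ratio))
  x <- records$tpm_plus_mean[usable]
  y <- records$stability_ratio[usable]
  n <- length(x)
  if (n < 5L) stop("fewer than 5 usable records above min_tpm")
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n < 50L) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(perm_seed)
    perm <- replicate(n_perm, abs(cor(rx, sample(ry))))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    p <- (1 + sum(perm >= abs(rho))) / (n_perm + 1)
    method <- "permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "asymptotic_t"
  }
  list(rho = rho, p_value = p, n = n, n_excluded_infinite = n_inf,
       method = method)
}
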