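# Simulated sequencing of the three libraries.
#
# Full-length molecules are sampled in proportion to molar abundance x
# stability into both medium-size libraries; capped loci are depleted by
# `cap_depletion` in the -TAP library (the 5' cap blocks adaptor ligation
# unless removed by TAP treatment).  Degraded molecules (proportional to
# molar abundance x (1 - stability)) appear as 19-50 nt fragments in the
# small-RNA library, biased 2:1 toward the locus 3' half.  Read extremities
# get truncated Gaussian jitter, with the first two reads of every locus
# kept exact so that mature extremities stay identifiable; the first read of
# every expressed locus is mismatch-free.

.trunc_jitter <- function(n, sd) {
  if (n == 0L || sd <= 0) return(integer(n))
  cap <- as.integer(ceiling(3 * sd))
  pmin(pmax(as.integer(round(rnorm(n, 0, sd))), -cap), cap)
}

## Expand per-entity read counts into jittered full-length read intervals.
.fulllength_reads <- function(ent, counts, sd, mismatch_rate, chrom_len) {
  idx <- rep(seq_along(counts), counts)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  nth <- sequence(counts[counts > 0L])
  exact <- nth <= 2L
  n <- length(idx)
  j5 <- .trunc_jitter(n, sd) * !exact
  j3 <- .trunc_jitter(n, sd) * !exact
  start <- ent$start[idx] + j5
  end <- ent$end[idx] + j3
  start <- pmax(1L, start)
  end <- pmin(chrom_len[ent$chrom[idx]], end)
  bad <- end <= start
  if (any(bad)) { start[bad] <- ent$start[idx][bad]; end[bad] <- ent$end[idx][bad] }
  mm <- rbinom(n, end - start + 1L, mismatch_rate)
  mm[nth == 1L] <- 0L
  data.frame(chrom = ent$chrom[idx], strand = ent$strand[idx],
             start = start, end = end, mismatches = mm,
             stringsAsFactors = FALSE)
}

## Degradation fragments for the small-RNA library, 3'-biased 2:1.
.srna_reads <- function(ent, counts, len_range, mismatch_rate) {
  idx <- rep(seq_along(counts), counts)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  nth <- sequence(counts[counts > 0L])
  n <- length(idx)
  w <- ent$end[idx] - ent$start[idx] + 1L
  len <- pmin(sample(len_range[1]:len_range[2], n, replace = TRUE), w)
  d_size <- w - len + 1L                       # start positions available
  half <- pmax(1L, d_size %/% 2L)
  in3 <- runif(n) < 2 / 3                      # fragment from the 3' half
  off3 <- half + as.integer(floor(runif(n) * pmax(1L, d_size - half)))
  off5 <- as.integer(floor(runif(n) * half))
  offset <- ifelse(in3, pmin(off3, d_size - 1L), off5)
  ## 3' side is the right end on "+", the left end on "-"
  minus <- ent$strand[idx] == "-"
  offset[minus] <- d_size[minus] - 1L - offset[minus]
  start <- ent$start[idx] + offset
  end <- start + len - 1L
  mm <- rbinom(n, len, mismatch_rate)
  mm[nth == 1L] <- 0L
  data.frame(chrom = ent$chrom[idx], strand = ent$strand[idx],
             start = start, end = end, mismatches = mm,
             stringsAsFactors = FALSE)
}

#' Simulate the three read libraries
#'
#' @param sim a `sno_simulation` from [build_genome()], or a genome bundle
#'   (then `truth` must be supplied).
#' @param truth optional truth table overriding `sim$truth` (may be any
#'   data.frame with `locus_id`, `chrom`, `strand`, `start`, `end`,
#'   `abundance_weight`, `stability`, `capped`).
#' @param config optional [sim_config()] overriding `sim$config`.
#' @param seed integer seed for the read sampler (defaults to a fixed offset
#'   of the configured `rng_seed` so that genome construction and sequencing
#'   draw from independent streams).
#' @param include_decoys also express the decoy/repeat transcripts (default
#'   `TRUE`; they are what the screening filters are there to remove).
#' @return a data.frame of aligned reads: `library` (one of `mnc_tap_plus`,
#'   `mnc_tap_minus`, `srna`), `replicate`, `read_id`, `chrom`, `strand`,
#'   `start`, `end` (1-based closed), `mismatches`.
#' @export
simulate_libraries <- function(sim, truth = NULL, config = NULL, seed = NULL,
                               include_decoys = TRUE) {
  config <- config %||% sim$config
  truth <- truth %||% sim$truth
  if (is.null(seed)) seed <- config$rng_seed + 499979L
  set.seed(seed)
  chrom_len <- vapply(sim$genome$seq, nchar, integer(1))

  ent <- data.frame(locus_id = truth$locus_id, chrom = truth$chrom,
                    strand = truth$strand, start = truth$start,
                    end = truth$end, w = truth$abundance_weight,
                    s = truth$stability, capped = truth$capped,
                    stringsAsFactors = FALSE)
  if (include_decoys && !is.null(sim$decoys) && nrow(sim$decoys) > 0L) {
    d <- sim$decoys
    ent <- rbind(ent, data.frame(locus_id = d$locus_id, chrom = d$chrom,
                                 strand = d$strand, start = d$start,
                                 end = d$end, w = d$abundance_weight,
                                 s = d$stability, capped = d$capped,
                                 stringsAsFactors = FALSE))
  }

  probs <- list(
    mnc_tap_plus = ent$w * ent$s,
    mnc_tap_minus = ent$w * ent$s *
      ifelse(ent$capped, config$cap_depletion, 1),
    srna = ent$w * (1 - ent$s))

  depth_rep <- round(config$read_depth_total / config$n_replicates)
  out <- vector("list", 3L * config$n_replicates)
  k <- 0L
  for (lib in .LIBRARIES) {
    p <- probs[[lib]]
    for (r in seq_len(config$n_replicates)) {
      k <- k + 1L
      if (sum(p) <= 0 || depth_rep == 0L) {
        counts <- integer(nrow(ent))
      } else {
        counts <- as.vector(rmultinom(1, depth_rep, p))
      }
      reads <- if (lib == "srna") {
        .srna_reads(ent, counts, config$srna_read_length_range,
                    config$mismatch_rate)
      } else {
        .fulllength_reads(ent, counts, config$end_jitter_sd,
                          config$mismatch_rate, chrom_len)
      }
      if (nrow(reads) > 0L) {
        reads$library <- lib
        reads$replicate <- r
        reads$read_id <- sprintf("%s_r%d_%07d", lib, r, seq_len(nrow(reads)))
      } else {
        reads$library <- character(0)
        reads$replicate <- integer(0)
        reads$read_id <- character(0)
      }
      out[[k]] <- reads
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("library", "replicate", "read_id", "chrom", "strand",
          "start", "end", "mismatches")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
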