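# Strand-aware coverage / end profiles and rule-based candidate calling.
#
# Retention rules: at least two reads sharing a clear-cut common extremity,
# at least one read matching the genome perfectly, and accumulation above
# 0.1 TPM.  Candidates are discarded when they map on annotated ncRNAs
# (rRNA/tRNA/snRNA/known snoRNA), on CDS, or on a repeated-sequence family
# (>= 10 near-identical copies).

#' Screening parameters
#'
#' @param min_depth minimum read depth defining a candidate interval.
#' @param min_shared_ends reads required at the modal extremity.
#' @param min_tpm minimum mean TPM in the +TAP library.
#' @param size_window allowed mature locus length (mncRNA window with slack).
#' @param exclude_types annotated ncRNA feature types that discard a
#'   candidate.
#' @param repeat_identity,repeat_min_members sequence-identity threshold and
#'   family size defining the repeat exclusion.
#' @param cap_max_ratio,uncap_min_ratio,cap_min_support cap-status thresholds
#'   (see [classify_cap()]).
#' @param t_run,t_window Pol III terminator rule: a run of >= `t_run` T
#'   starting within `t_window` nt downstream of the 3' end.
#' @param end_slack nt around a depth interval searched for modal read
#'   extremities.
#' @return a list of screening parameters.
#' @export
screen_params <- function(min_depth = 2L, min_shared_ends = 2L, min_tpm = 0.1,
                          size_window = c(60L, 320L),
                          exclude_types = c("rRNA", "tRNA", "snRNA", "snoRNA"),
                          repeat_identity = 0.90, repeat_min_members = 10L,
                          cap_max_ratio = 0.2, uncap_min_ratio = 0.5,
                          cap_min_support = 10L, t_run = 5L, t_window = 15L,
                          end_slack = 10L) {
  list(min_depth = as.integer(min_depth),
       min_shared_ends = as.integer(min_shared_ends), min_tpm = min_tpm,
       size_window = as.integer(size_window), exclude_types = exclude_types,
       repeat_identity = repeat_identity,
       repeat_min_members = as.integer(repeat_min_members),
       cap_max_ratio = cap_max_ratio, uncap_min_ratio = uncap_min_ratio,
       cap_min_support = as.integer(cap_min_support),
       t_run = as.integer(t_run), t_window = as.integer(t_window),
       end_slack = as.integer(end_slack))
}

#' Build per-library, per-strand coverage and end-count profiles
#'
#' @param reads aligned-read data.frame (replicates are pooled per library).
#' @param genome a genome bundle (for chromosome lengths).
#' @return a `coverage_profiles` object: `profiles[[library]][[chrom]][[strand]]`
#'   holds `depth` (integer Rle), `p5` and `p3` (integer vectors of 5' / 3'
#'   read-end counts per position; strand-aware, so on `-` the 5' end is the
#'   right coordinate).
#' @export
build_profiles <- function(reads, genome) {
  chrom_len <- vapply(genome$seq, nchar, integer(1))
  out <- list()
  for (lib in .LIBRARIES) {
    out[[lib]] <- list()
    for (chrom in names(chrom_len)) {
      out[[lib]][[chrom]] <- list()
      for (strand in c("+", "-")) {
        sel <- reads$library == lib & reads$chrom == chrom &
          reads$strand == strand
        r <- reads[sel, , drop = FALSE]
        L <- chrom_len[[chrom]]
        if (nrow(r) == 0L) {
          prof <- list(depth = S4Vectors::Rle(0L, L),
                       p5 = integer(L), p3 = integer(L))
        } else {
          ir <- IRanges::IRanges(r$start, r$end)
          depth <- IRanges::coverage(ir, width = L)
          if (strand == "+") {
            p5 <- tabulate(r$start, nbins = L)
            p3 <- tabulate(r$end, nbins = L)
          } else {
            p5 <- tabulate(r$end, nbins = L)
            p3 <- tabulate(r$start, nbins = L)
          }
          prof <- list(depth = depth, p5 = p5, p3 = p3)
        }
        out[[lib]][[chrom]][[strand]] <- prof
      }
    }
  }
  structure(out, class = "coverage_profiles")
}

## Modal position in counts[window]; ties broken toward the longer locus
## (`prefer` = "low" keeps the smallest position, "high" the largest).
.modal_pos <- function(counts, lo, hi, prefer) {
  w <- counts[lo:hi]
  if (all(w == 0L)) return(NA_integer_)
  mx <- max(w)
  pos <- which(w == mx) + lo - 1L
  if (prefer == "low") min(pos) else max(pos)
}

## Single-linkage clustering of candidate sequences at >= identity; returns
## integer family sizes per row.  Pairs are prefiltered by length ratio and
## shared 8-mer content (near-identical copies share most of their 8-mers,
## unrelated loci almost none), so the quadratic alignment step only runs on
## plausible family members.
.repeat_family_sizes <- function(seqs, identity) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  lens <- nchar(seqs)
  k <- 8L
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      if (lens[i] > 1.25 * lens[j] || lens[j] > 1.25 * lens[i]) next
      shared <- length(intersect(kmers[[i]], kmers[[j]]))
      if (shared < 0.3 * min(length(kmers[[i]]), length(kmers[[j]]))) next
      al <- Biostrings::pairwiseAlignment(seqs[i], seqs[j], type = "global")
      if (Biostrings::pid(al, type = "PID1") / 100 >= identity) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(table(roots)[as.character(roots)])
}

#' Call candidate mncRNA loci from read profiles
#'
#' Maximal intervals of +TAP depth >= `min_depth` define candidate regions;
#' mature extremities are the modal 5' and 3' read ends (ties toward the
#' longer locus).  Each candidate is annotated with its exclusion reason
#' (annotated ncRNA overlap, CDS overlap, repeat family) or `"none"`, and
#' retained when unexcluded, supported by >= `min_shared_ends` reads at a
#' common extremity, covered by at least one perfect read, and above
#' `min_tpm` mean TPM (+TAP replicates, TPM universe = candidate set).
#' Cap status and Pol III terminator are classified on retained loci.
#'
#' @param profiles a `coverage_profiles` object (from the same reads).
#' @param genome a genome bundle.
#' @param reads the aligned reads (for perfect-read evidence and counting).
#' @param params screening parameters from [screen_params()].
#' @return a data.frame of candidate loci (one per row) with retention and
#'   classification columns.
#' @export
call_candidates <- function(profiles, genome, reads, params = screen_params()) {
  plus <- reads[reads$library == "mnc_tap_plus", , drop = FALSE]
  cand <- NULL
  for (chrom in names(genome$seq)) {
    for (strand in c("+", "-")) {
      prof <- profiles[["mnc_tap_plus"]][[chrom]][[strand]]
      hits <- S4Vectors::runValue(prof$depth) >= params$min_depth
      rr <- IRanges::IRanges(S4Vectors::start(prof$depth)[hits],
                             S4Vectors::end(prof$depth)[hits])
      runs <- IRanges::reduce(rr)
      if (length(runs) == 0L) next
      L <- length(prof$p5)
      for (k in seq_along(runs)) {
        lo <- max(1L, IRanges::start(runs)[k] - params$end_slack)
        hi <- min(L, IRanges::end(runs)[k] + params$end_slack)
        if (strand == "+") {
          m5 <- .modal_pos(prof$p5, lo, hi, prefer = "low")
          m3 <- .modal_pos(prof$p3, lo, hi, prefer = "high")
        } else {
          m5 <- .modal_pos(prof$p5, lo, hi, prefer = "high")
          m3 <- .modal_pos(prof$p3, lo, hi, prefer = "low")
        }
        if (is.na(m5) || is.na(m3)) next
        start <- min(m5, m3)
        end <- max(m5, m3)
        width <- end - start + 1L
        if (width < params$size_window[1] || width > params$size_window[2]) next
        sel <- plus$chrom == chrom & plus$strand == strand &
          plus$start <= end & plus$end >= start
        rsub <- plus[sel, , drop = FALSE]
        cand <- rbind(cand, data.frame(
          chrom = chrom, strand = strand, start = start, end = end,
          length = width,
          n_reads_mnc = nrow(rsub),
          shared_5p_reads = prof$p5[m5],
          shared_3p_reads = prof$p3[m3],
          has_perfect_read = any(rsub$mismatches == 0L),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(cand)) {
    return(data.frame(locus_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_reads_mnc = integer(0), shared_5p_reads = integer(0),
                      shared_3p_reads = integer(0),
                      has_perfect_read = logical(0), tpm_plus = numeric(0),
                      exclusion = character(0), retained = logical(0),
                      cap_status = character(0), cap_support_plus = numeric(0),
                      pol3_terminator = logical(0),
                      stringsAsFactors = FALSE))
  }
  cand <- cand[order(cand$chrom, cand$start, cand$strand), , drop = FALSE]
  cand$locus_id <- sprintf("cand_%04d", seq_len(nrow(cand)))

  ## TPM over the candidate universe, +TAP replicates averaged
  counts <- count_reads(cand, plus)
  plus_cols <- grepl("^mnc_tap_plus", colnames(counts))
  tpm <- apply(counts[, plus_cols, drop = FALSE], 2, compute_tpm,
               lengths = cand$length)
  cand$tpm_plus <- rowMeans(tpm)

  ## exclusions
  f <- genome$features
  excl <- rep("none", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- f$chrom == cand$chrom[i] & f$start <= cand$end[i] &
      f$end >= cand$start[i]
    if (any(ov & f$type %in% params$exclude_types)) {
      excl[i] <- "annotated_ncRNA"
    } else if (any(ov & f$type == "CDS")) {
      excl[i] <- "cds_overlap"
    }
  }
  seqs <- vapply(seq_len(nrow(cand)), function(i) {
    locus_sequence(genome, cand$chrom[i], cand$start[i], cand$end[i],
                   cand$strand[i])
  }, character(1))
  fam <- .repeat_family_sizes(seqs, params$repeat_identity)
  excl[excl == "none" & fam >= params$repeat_min_members] <- "repeat_family"
  cand$exclusion <- excl

  cand$retained <- cand$exclusion == "none" &
    (cand$shared_5p_reads >= params$min_shared_ends |
       cand$shared_3p_reads >= params$min_shared_ends) &
    cand$has_perfect_read & cand$tpm_plus > params$min_tpm

  cand$cap_status <- classify_cap(cand, profiles, params)
  cand$cap_support_plus <- .cap_support(cand, profiles, "mnc_tap_plus")
  cand$pol3_terminator <- detect_pol3_terminator(cand, genome, params)
  rownames(cand) <- NULL
  cand[, c("locus_id", "chrom", "strand", "start", "end", "length",
           "n_reads_mnc", "shared_5p_reads", "shared_3p_reads",
           "has_perfect_read", "tpm_plus", "exclusion", "retained",
           "cap_status", "cap_support_plus", "pol3_terminator")]
}

## Raw 5'-end support (reads ending within +/-3 nt of the locus 5' end).
.cap_support <- function(loci, profiles, lib) {
  vapply(seq_len(nrow(loci)), function(i) {
    p5 <- profiles[[lib]][[loci$chrom[i]]][[loci$strand[i]]]$p5
    p5pos <- if (loci$strand[i] == "+") loci$start[i] else loci$end[i]
    lo <- max(1L, p5pos - 3L)
    hi <- min(length(p5), p5pos + 3L)
    sum(p5[lo:hi])
  }, numeric(1))
}

#' Classify cap status from +TAP versus -TAP 5'-end support
#'
#' Capped RNAs ligate adaptors only after TAP treatment, so their 5' ends are
#' depleted in the -TAP library.  Support is the number of 5' read ends
#' within +/-3 nt of the locus 5' end, normalized by library size;
#' `capped` when the -TAP/+TAP ratio is <= `cap_max_ratio` with raw +TAP
#' support >= `cap_min_support`; `uncapped` when the ratio is >=
#' `uncap_min_ratio` at the same support; otherwise `undetermined`.
#'
#' @param loci data.frame with `chrom`, `strand`, `start`, `end`.
#' @param profiles a `coverage_profiles` object.
#' @param params screening parameters.
#' @return character vector of `"capped"` / `"uncapped"` / `"undetermined"`.
#' @export
classify_cap <- function(loci, profiles, params = screen_params()) {
  tot <- function(lib) {
    sum(vapply(profiles[[lib]], function(ch) {
      sum(vapply(ch, function(pr) sum(pr$p5), numeric(1)))
    }, numeric(1)))
  }
  n_plus <- max(1, tot("mnc_tap_plus"))
  n_minus <- max(1, tot("mnc_tap_minus"))
  vapply(seq_len(nrow(loci)), function(i) {
    chrom <- loci$chrom[i]; strand <- loci$strand[i]
    p5pos <- if (strand == "+") loci$start[i] else loci$end[i]
    sup <- function(lib) {
      p5 <- profiles[[lib]][[chrom]][[strand]]$p5
      lo <- max(1L, p5pos - 3L)
      hi <- min(length(p5), p5pos + 3L)
      sum(p5[lo:hi])
    }
    s_plus <- sup("mnc_tap_plus")
    s_minus <- sup("mnc_tap_minus")
    if (s_plus < params$cap_min_support) return("undetermined")
    ratio <- (s_minus / n_minus) / (s_plus / n_plus)
    if (ratio <= params$cap_max_ratio) "capped"
    else if (ratio >= params$uncap_min_ratio) "uncapped"
    else "undetermined"
  }, character(1))
}

#' Detect an RNA polymerase III terminator downstream of a locus
#'
#' TRUE iff a run of >= `t_run` consecutive T (coding strand) starts within
#' `t_window` nt downstream of the locus 3' end.
#'
#' @param loci data.frame with `chrom`, `strand`, `start`, `end`.
#' @param genome a genome bundle.
#' @param params screening parameters.
#' @return logical vector.
#' @export
detect_pol3_terminator <- function(loci, genome, params = screen_params()) {
  pat <- strrep("T", params$t_run)
  span <- params$t_window + params$t_run - 1L
  vapply(seq_len(nrow(loci)), function(i) {
    chrom_seq <- genome$seq[[loci$chrom[i]]]
    L <- nchar(chrom_seq)
    if (loci$strand[i] == "+") {
      lo <- loci$end[i] + 1L
      hi <- min(L, loci$end[i] + span)
      if (lo > hi) return(FALSE)
      down <- substr(chrom_seq, lo, hi)
    } else {
      hi <- loci$start[i] - 1L
      lo <- max(1L, loci$start[i] - span)
      if (lo > hi) return(FALSE)
      down <- revcomp(substr(chrom_seq, lo, hi))
    }
    grepl(pat, down, fixed = TRUE)
  }, logical(1))
}
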