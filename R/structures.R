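# Rule-based C/D box and H/ACA box snoRNA scanners.
#
# C/D box snoRNAs carry a terminal C box (RUGAUGA, one divergence tolerated)
# near the 5' mature end and an exact terminal D box (CUGA) near the 3' end,
# flanked by a short terminal inverted repeat (IR) that is usually truncated
# by maturation and therefore searched in the genomic flanks.  H/ACA box
# snoRNAs fold into two hairpins separated by an H box (ANANNA), each hairpin
# carrying an internal-loop pocket that holds a bipartite antisense element,
# and end with an ACA box exactly 3 nt upstream of the mature 3' end.

#' Default parameters for the C/D box scanner
#'
#' @param c_box IUPAC consensus of the C box (RNA R = A/G; T stands for U).
#' @param d_box exact D box consensus.
#' @param max_c_mm maximum substitutions tolerated in the C box.
#' @param box_window boxes must start within this many nt of the mature ends.
#' @param min_stem,max_stem terminal-stem length bounds (base pairs, counting
#'   Watson-Crick and G:U).
#' @param stem_window the IR arms are searched within this many nt outside
#'   each box (10 nt of mature sequence plus the 15 nt genomic flank).
#' @return a list of scanner parameters.
#' @export
cd_params <- function(c_box = "RTGATGA", d_box = "CTGA", max_c_mm = 1L,
                      box_window = 25L, min_stem = 2L, max_stem = 10L,
                      stem_window = 25L) {
  list(c_box = c_box, d_box = d_box, max_c_mm = as.integer(max_c_mm),
       box_window = as.integer(box_window), min_stem = as.integer(min_stem),
       max_stem = as.integer(max_stem), stem_window = as.integer(stem_window))
}

#' Default parameters for the H/ACA box scanner
#'
#' @param h_box IUPAC consensus of the hinge box.
#' @param aca_offset required distance (nt) between the end of the ACA box
#'   and the mature 3' end.
#' @param min_stem_pairs minimum base pairs per hairpin (outer + inner arm).
#' @param min_arm minimum contiguous pairs per arm segment.
#' @param min_pocket minimum unpaired nt on each strand of the ASE pocket.
#' @param min_loop minimum apical loop length (nt).
#' @return a list of scanner parameters.
#' @export
haca_params <- function(h_box = "ANANNA", aca_offset = 3L,
                        min_stem_pairs = 8L, min_arm = 2L, min_pocket = 4L,
                        min_loop = 3L) {
  list(h_box = h_box, aca_offset = as.integer(aca_offset),
       min_stem_pairs = as.integer(min_stem_pairs),
       min_arm = as.integer(min_arm), min_pocket = as.integer(min_pocket),
       min_loop = as.integer(min_loop))
}

## Best terminal stem for a (C box, D box) placement.  Arms pair
## seq[i + k] : seq[j - k] (WC or G:U), arm5 inside [lw_from, cg - 1],
## arm3 inside [dg_end + 1, rw_to].  Returns list(len, i, j) with the
## outermost pair at (i, j); len = 0 when nothing pairs.
.best_stem <- function(chars, lw_from, cg, dg_end, rw_to, min_stem, max_stem) {
  best <- list(len = 0L, i = NA_integer_, j = NA_integer_)
  if (lw_from > cg - 1L || dg_end + 1L > rw_to) return(best)
  for (i in lw_from:(cg - 1L)) {
    for (j in rw_to:(dg_end + 1L)) {
      s_cap <- min(max_stem, cg - i, j - dg_end)
      if (s_cap < min_stem || s_cap <= best$len) next
      s <- 0L
      while (s < s_cap && .can_pair(chars[i + s], chars[j - s])) s <- s + 1L
      if (s >= min_stem &&
          (s > best$len ||
           (s == best$len && (i < best$i || (i == best$i && j > best$j))))) {
        best <- list(len = s, i = i, j = j)
      }
    }
  }
  best
}

## Core C/D placement search over explicit C-box / D-box candidate sets.
## Returns the best-scoring placement or NULL.  Score = 2 * stem + (2 - c_mm);
## ties: longer stem, 5'-most C box, 3'-most D box, 5'-most arm5, 3'-most arm3.
.cd_place <- function(chars, c_cand, d_starts, left_bound, right_bound, p) {
  best <- NULL
  if (nrow(c_cand) == 0L || length(d_starts) == 0L) return(NULL)
  for (k in seq_len(nrow(c_cand))) {
    cg <- c_cand$start[k]
    c_mm <- c_cand$mm[k]
    for (dg in d_starts) {
      if (dg < cg + 7L) next
      dg_end <- dg + 3L
      stem <- .best_stem(chars,
                         lw_from = max(left_bound, cg - p$stem_window),
                         cg = cg, dg_end = dg_end,
                         rw_to = min(right_bound, dg_end + p$stem_window),
                         min_stem = p$min_stem, max_stem = p$max_stem)
      if (stem$len < p$min_stem) next
      score <- 2L * stem$len + (2L - c_mm)
      better <- is.null(best) ||
        score > best$score ||
        (score == best$score && (
          stem$len > best$stem_len ||
          (stem$len == best$stem_len && (
            cg < best$c_start ||
            (cg == best$c_start && (
              dg > best$d_start ||
              (dg == best$d_start && (
                stem$i < best$arm5[1] ||
                (stem$i == best$arm5[1] && stem$j > best$arm3[2])))))))))
      if (better) {
        best <- list(c_start = cg, c_mm = c_mm, d_start = dg,
                     stem_len = stem$len,
                     arm5 = c(stem$i, stem$i + stem$len - 1L),
                     arm3 = c(stem$j - stem$len + 1L, stem$j),
                     score = score)
      }
    }
  }
  best
}

## Optional internal C'/D' boxes in the middle 40-80% of the mature span.
## Purely annotative: fewest mismatches first, then 5'-most.
.cd_internal_boxes <- function(chars, mat_from, mat_to, c_end, d_start, p) {
  m <- mat_to - mat_from + 1L
  lo <- max(mat_from + as.integer(ceiling(0.4 * m)) - 1L, c_end + 2L)
  hi <- min(mat_from + as.integer(floor(0.8 * m)) - 1L, d_start - 5L)
  out <- list(d_prime = NULL, d_prime_mm = NA_integer_,
              c_prime = NULL, c_prime_mm = NA_integer_)
  if (lo > hi) return(out)
  dp <- .match_box(chars, p$d_box, max_mm = 1L, from = lo, to = hi - 3L + 1L)
  dp <- dp[dp$start + 3L <= hi, , drop = FALSE]
  if (nrow(dp) > 0L) {
    dp <- dp[order(dp$mm, dp$start), , drop = FALSE]
    out$d_prime <- c(dp$start[1], dp$start[1] + 3L)
    out$d_prime_mm <- dp$mm[1]
  }
  cp_hi <- if (!is.null(out$d_prime)) out$d_prime[1] - 1L else hi
  cp <- .match_box(chars, p$c_box, max_mm = 1L, from = lo, to = cp_hi - 6L)
  if (nrow(cp) > 0L) {
    cp <- cp[order(cp$mm, cp$start), , drop = FALSE]
    out$c_prime <- c(cp$start[1], cp$start[1] + 6L)
    out$c_prime_mm <- cp$mm[1]
  }
  out
}

#' Scan a candidate sequence for a C/D box snoRNA structure
#'
#' The input is the mature candidate sequence plus `flank` nt of genomic
#' context on each side: terminal inverted repeats are usually truncated from
#' the mature RNA and only fully visible in the genomic sequence.  The scanner
#' requires a C box (at most one divergence from RUGAUGA) starting within
#' 25 nt of the mature 5' end, an exact D box (CUGA) within 25 nt of the
#' mature 3' end, and a terminal stem of at least `min_stem` pairs (WC or G:U)
#' between the regions just outside the two boxes.  The highest-scoring
#' placement wins (score = 2 x stem length + (2 - C box mismatches)); ties go
#' to the longer stem, then the 5'-most C box, then the 3'-most (terminal)
#' D box.
#'
#' @param seq candidate sequence (character, sense strand) including `flank`
#'   nt of genomic sequence on both sides.
#' @param flank width of the genomic flanks included in `seq`.
#' @param params scanner parameters from [cd_params()].
#' @return a list describing the annotation (box spans and mismatch counts,
#'   terminal stem arms and length, mature span, score; all coordinates
#'   1-based in `seq`), or `NULL` when no placement satisfies the rules.
#' @export
scan_cd <- function(seq, flank = 15L, params = cd_params()) {
  seq <- toupper(chartr("U", "T", seq))
  n <- nchar(seq)
  mat_from <- flank + 1L
  mat_to <- n - flank
  m <- mat_to - mat_from + 1L
  if (m < 50L) return(NULL)
  chars <- .chars(seq)
  p <- params
  c_cand <- .match_box(chars, p$c_box, max_mm = p$max_c_mm,
                       from = mat_from,
                       to = mat_from + (p$box_window - 7L))
  d_lo <- max(mat_from, mat_to - p$box_window + 1L)
  d_cand <- .match_box(chars, p$d_box, max_mm = 0L,
                       from = d_lo, to = mat_to - 3L)
  best <- .cd_place(chars, c_cand, d_cand$start,
                    left_bound = 1L, right_bound = n, p = p)
  if (is.null(best)) return(NULL)
  internal <- .cd_internal_boxes(chars, mat_from, mat_to,
                                 c_end = best$c_start + 6L,
                                 d_start = best$d_start, p = p)
  structure(list(
    c_box = c(best$c_start, best$c_start + 6L), c_mm = best$c_mm,
    d_box = c(best$d_start, best$d_start + 3L),
    c_prime_box = internal$c_prime, c_prime_mm = internal$c_prime_mm,
    d_prime_box = internal$d_prime, d_prime_mm = internal$d_prime_mm,
    terminal_stem = best$stem_len, arm5 = best$arm5, arm3 = best$arm3,
    mature_span = c(mat_from, mat_to), flank = flank,
    score = best$score
  ), class = "cd_annotation")
}

#' Scan a candidate sequence for an H/ACA box snoRNA structure
#'
#' Requires an ACA box ending exactly `aca_offset` nt upstream of the 3' end,
#' an H box (ANANNA) strictly between two hairpins, and for each hairpin a
#' two-segment stem (outer arm, ASE pocket internal loop with at least
#' `min_pocket` unpaired nt per strand, inner arm, apical loop of at least
#' `min_loop` nt) with at least `min_stem_pairs` pairs in total.  H box
#' placements are tried 5' to 3'; the first placement for which both regions
#' fold is returned.
#'
#' @param seq candidate mature sequence (character, sense strand; no flanks).
#' @param params scanner parameters from [haca_params()].
#' @return a list describing the annotation (H and ACA box spans, per-stem
#'   spans, pair counts and pocket spans; 1-based in `seq`), or `NULL`.
#' @export
scan_haca <- function(seq, params = haca_params()) {
  seq <- toupper(chartr("U", "T", seq))
  n <- nchar(seq)
  if (n < 60L) return(NULL)
  p <- params
  aca_start <- n - p$aca_offset - 2L
  if (substr(seq, aca_start, aca_start + 2L) != "ACA") return(NULL)
  chars <- .chars(seq)
  h_cand <- .match_box(chars, p$h_box, max_mm = 0L,
                       from = 2L, to = aca_start - 7L)
  if (nrow(h_cand) == 0L) return(NULL)
  for (h in h_cand$start) {
    if (h - 1L < 20L || (aca_start - 1L) - (h + 6L) + 1L < 20L) next
    hp1 <- cpp_hairpin_search(seq, 1L, h - 1L, p$min_arm, p$min_stem_pairs,
                              p$min_pocket, p$min_loop, TRUE)
    if (length(hp1) == 0L) next
    hp2 <- cpp_hairpin_search(seq, h + 6L, aca_start - 1L, p$min_arm,
                              p$min_stem_pairs, p$min_pocket, p$min_loop, TRUE)
    if (length(hp2) == 0L) next
    stem <- function(hp) list(
      span = c(hp[["i1"]], hp[["j1"]]),
      pairs = hp[["s1"]] + hp[["s2"]],
      pocket_left = c(hp[["i1"]] + hp[["s1"]], hp[["i2"]] - 1L),
      pocket_right = c(hp[["j2"]] + 1L, hp[["j1"]] - hp[["s1"]]))
    s1 <- stem(hp1); s2 <- stem(hp2)
    return(structure(list(
      h_box = c(h, h + 5L), aca_box = c(aca_start, aca_start + 2L),
      aca_offset_from_3p = p$aca_offset,
      stem1_span = s1$span, stem1_pairs = s1$pairs,
      pocket1_left = s1$pocket_left, pocket1_right = s1$pocket_right,
      stem2_span = s2$span, stem2_pairs = s2$pairs,
      pocket2_left = s2$pocket_left, pocket2_right = s2$pocket_right,
      score = s1$pairs + s2$pairs
    ), class = "haca_annotation"))
  }
  NULL
}

#' Find nested C/D box snoRNA units inside a long candidate
#'
#' Polycistronic precursors can accumulate as stable long RNAs that are
#' further processed into shorter C/D box units delimited by their own boxes
#' and inverted repeats.  This scans the interior of a long candidate
#' (between the parent's terminal boxes) for complete internal units
#' (C box, D box 40-140 nt downstream, flanking IR stem) and returns them
#' non-overlapping, 5' to 3'.  The parent annotation is retained alongside.
#'
#' @param seq the parent candidate sequence (with flanks, as given to
#'   [scan_cd()]).
#' @param parent the parent's [scan_cd()] annotation.
#' @param min_parent_len minimum parent mature length for nested search.
#' @param params scanner parameters from [cd_params()].
#' @return a list of child annotations (each with `unit_span`, the IR-to-IR
#'   span in `seq` coordinates); empty when the parent is short or no
#'   internal unit is found.
#' @export
scan_nested <- function(seq, parent, min_parent_len = 150L,
                        params = cd_params()) {
  seq <- toupper(chartr("U", "T", seq))
  if (is.null(parent)) return(list())
  m <- parent$mature_span[2] - parent$mature_span[1] + 1L
  if (m <= min_parent_len) return(list())
  chars <- .chars(seq)
  out <- list()
  find_units <- function(win_from, win_to) {
    if (win_to - win_from + 1L < 50L) return()
    c_cand <- .match_box(chars, params$c_box, max_mm = params$max_c_mm,
                         from = win_from, to = win_to - 6L)
    d_cand <- .match_box(chars, params$d_box, max_mm = 0L,
                         from = win_from, to = win_to - 3L)
    if (nrow(c_cand) == 0L || nrow(d_cand) == 0L) return()
    best <- NULL
    for (k in seq_len(nrow(c_cand))) {
      cg <- c_cand$start[k]
      ds <- d_cand$start[d_cand$start >= cg + 40L & d_cand$start <= cg + 140L]
      cand <- .cd_place(chars, c_cand[k, , drop = FALSE], ds,
                        left_bound = win_from, right_bound = win_to,
                        p = params)
      if (!is.null(cand) &&
          (is.null(best) || cand$score > best$score ||
           (cand$score == best$score && cand$c_start < best$c_start))) {
        best <- cand
      }
    }
    if (is.null(best)) return()
    unit <- c(best$arm5[1], best$arm3[2])
    ann <- list(c_box = c(best$c_start, best$c_start + 6L), c_mm = best$c_mm,
                d_box = c(best$d_start, best$d_start + 3L),
                terminal_stem = best$stem_len,
                arm5 = best$arm5, arm3 = best$arm3,
                unit_span = unit, score = best$score)
    out[[length(out) + 1L]] <<- ann
    find_units(win_from, unit[1] - 1L)
    find_units(unit[2] + 1L, win_to)
  }
  find_units(parent$c_box[2] + 1L, parent$d_box[1] - 1L)
  out[order(vapply(out, function(a) a$unit_span[1], numeric(1)))]
}

#' Classify a locus from its structural annotations
#'
#' @param cd a [scan_cd()] annotation or `NULL`.
#' @param haca a [scan_haca()] annotation or `NULL`.
#' @return one of `"CD"`, `"HACA"`, `"unclassified"`.  When both scanners
#'   match, the higher normalized score wins (C/D score over its maximum
#'   2 x max_stem + 2; H/ACA total pairs over 32); an exact tie is reported
#'   as `"unclassified"`.
#' @export
classify_locus <- function(cd, haca) {
  if (is.null(cd) && is.null(haca)) return("unclassified")
  if (is.null(haca)) return("CD")
  if (is.null(cd)) return("HACA")
  cd_norm <- cd$score / 22
  haca_norm <- min(1, haca$score / 32)
  if (cd_norm > haca_norm) "CD"
  else if (haca_norm > cd_norm) "HACA"
  else "unclassified"
}
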