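# Antisense-element target prediction.
#
# C/D box guides: the antisense element (ASE) lies immediately upstream of
# the D or D' box and forms a contiguous duplex of >= 10 nt with the target;
# the 2'-O-methylated residue is the target nucleotide paired with the guide
# base 5 nt upstream of the box (the D+5 rule).  H/ACA guides: each hairpin
# pocket holds a bipartite ASE whose two segments pair with the target on
# either side of an unpaired U-N dinucleotide; the U is pseudouridylated.

#' Default parameters for ASE target prediction
#'
#' @param min_duplex minimum contiguous C/D guide duplex length (nt).
#' @param max_wobble maximum G:U pairs in a C/D duplex.
#' @param guide_window ASE search window upstream of the D/D' box (nt).
#' @param max_gap maximum distance between the duplex 3' end and the box.
#' @param haca_min_side minimum paired nt per bipartite segment.
#' @param haca_min_total minimum total paired nt over both segments.
#' @param haca_allow_gu allow G:U pairs in bipartite duplexes (strict
#'   Watson-Crick by default).
#' @param pocket_pad nt of slack around annotated pocket strands when
#'   searching bipartite segments.
#' @return a list of target-prediction parameters.
#' @export
target_params <- function(min_duplex = 10L, max_wobble = 2L,
                          guide_window = 20L, max_gap = 2L,
                          haca_min_side = 4L, haca_min_total = 9L,
                          haca_allow_gu = FALSE, pocket_pad = 3L) {
  list(min_duplex = as.integer(min_duplex), max_wobble = as.integer(max_wobble),
       guide_window = as.integer(guide_window), max_gap = as.integer(max_gap),
       haca_min_side = as.integer(haca_min_side),
       haca_min_total = as.integer(haca_min_total),
       haca_allow_gu = haca_allow_gu, pocket_pad = as.integer(pocket_pad))
}

.empty_matches <- function() {
  data.frame(locus_id = character(0), guide_box = character(0),
             guide_start = integer(0), guide_end = integer(0),
             target_molecule_id = character(0),
             target_start = integer(0), target_end = integer(0),
             duplex_length = integer(0), wobble_count = integer(0),
             predicted_residue = integer(0), modification = character(0),
             stringsAsFactors = FALSE)
}

## Resolve overlapping hits for one box and one target molecule: hits whose
## guide spans overlap form a group; keep the longest, then fewest wobbles,
## then 5'-most target position, then smallest gap.
.resolve_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits[, "guide_start"]), , drop = FALSE]
  grp <- integer(nrow(hits))
  g <- 1L
  grp[1] <- g
  hi <- hits[1, "guide_end"]
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits[i, "guide_start"] > hi) g <- g + 1L
    grp[i] <- g
    hi <- max(hi, hits[i, "guide_end"])
  }
  keep <- vapply(split(seq_len(nrow(hits)), grp), function(idx) {
    sub <- hits[idx, , drop = FALSE]
    o <- order(-sub[, "length"], sub[, "wobbles"],
               sub[, "target_start"], sub[, "gap"])
    idx[o[1]]
  }, integer(1))
  hits[sort(keep), , drop = FALSE]
}

#' Predict C/D box snoRNA targets from antisense elements
#'
#' @param cd a [scan_cd()] annotation (coordinates in `locus_seq`).
#' @param locus_seq the sequence the annotation refers to (mature candidate
#'   plus flanks, sense strand).
#' @param targets a data.frame of target molecules with columns
#'   `molecule_id`, `kind` (`"rRNA"` or `"snRNA"`) and `sequence`.
#' @param locus_id identifier copied into the result.
#' @param params parameters from [target_params()].
#' @return a data.frame of ASE matches (one row per predicted duplex) with
#'   guide box, guide and target spans, duplex length, wobble count, the
#'   predicted 2'-O-methylated residue (1-based on the target) and
#'   `modification = "Nm"`.
#' @export
find_cd_targets <- function(cd, locus_seq, targets, locus_id = NA_character_,
                            params = target_params()) {
  locus_seq <- toupper(chartr("U", "T", locus_seq))
  out <- .empty_matches()
  if (is.null(cd)) return(out)
  boxes <- list(D = cd$d_box[1])
  if (!is.null(cd$d_prime_box)) boxes$Dprime <- cd$d_prime_box[1]
  for (box_name in names(boxes)) {
    b <- boxes[[box_name]]
    for (t in seq_len(nrow(targets))) {
      tseq <- toupper(chartr("U", "T", targets$sequence[t]))
      hits <- cpp_cd_duplex_scan(locus_seq, b, params$guide_window,
                                 params$max_gap, tseq, params$min_duplex,
                                 params$max_wobble)
      hits <- .resolve_hits(hits)
      if (nrow(hits) == 0L) next
      for (i in seq_len(nrow(hits))) {
        gap <- hits[i, "gap"]
        residue <- hits[i, "target_start"] + 4L - gap
        if (residue < hits[i, "target_start"] ||
            residue > hits[i, "target_end"]) next
        out <- rbind(out, data.frame(
          locus_id = locus_id, guide_box = box_name,
          guide_start = hits[i, "guide_start"],
          guide_end = hits[i, "guide_end"],
          target_molecule_id = targets$molecule_id[t],
          target_start = hits[i, "target_start"],
          target_end = hits[i, "target_end"],
          duplex_length = hits[i, "length"],
          wobble_count = hits[i, "wobbles"],
          predicted_residue = residue, modification = "Nm",
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Predict H/ACA box snoRNA targets from bipartite pocket elements
#'
#' For each hairpin pocket, searches every target uridine `u` for a bipartite
#' duplex: the pocket's 3' strand pairs the target bases immediately 5' of
#' `u` and the pocket's 5' strand pairs the bases immediately 3' of the U-N
#' dinucleotide, which itself stays unpaired.  Segment search windows are the
#' annotated pocket strands padded by `pocket_pad` nt.
#'
#' @inheritParams find_cd_targets
#' @param haca a [scan_haca()] annotation (coordinates in `locus_seq`).
#' @return a data.frame of ASE matches with `modification = "Psi"` and the
#'   predicted pseudouridylated residue.
#' @export
find_haca_targets <- function(haca, locus_seq, targets,
                              locus_id = NA_character_,
                              params = target_params()) {
  locus_seq <- toupper(chartr("U", "T", locus_seq))
  out <- .empty_matches()
  if (is.null(haca)) return(out)
  n <- nchar(locus_seq)
  pockets <- list(
    pocket1 = list(left = haca$pocket1_left, right = haca$pocket1_right),
    pocket2 = list(left = haca$pocket2_left, right = haca$pocket2_right))
  pad <- params$pocket_pad
  for (pk in names(pockets)) {
    pl <- pockets[[pk]]$left
    pr <- pockets[[pk]]$right
    for (t in seq_len(nrow(targets))) {
      tseq <- toupper(chartr("U", "T", targets$sequence[t]))
      hits <- cpp_bipartite_scan(locus_seq,
                                 max(1L, pl[1] - pad), min(n, pl[2] + pad),
                                 max(1L, pr[1] - pad), min(n, pr[2] + pad),
                                 tseq, params$haca_min_side,
                                 params$haca_min_total, params$haca_allow_gu)
      if (nrow(hits) == 0L) next
      for (i in seq_len(nrow(hits))) {
        u <- hits[i, "u"]
        out <- rbind(out, data.frame(
          locus_id = locus_id, guide_box = pk,
          guide_start = hits[i, "left_end"] - hits[i, "b"] + 1L,
          guide_end = hits[i, "right_start"] + hits[i, "a"] - 1L,
          target_molecule_id = targets$molecule_id[t],
          target_start = u - hits[i, "a"],
          target_end = u + 1L + hits[i, "b"],
          duplex_length = hits[i, "a"] + hits[i, "b"],
          wobble_count = 0L,
          predicted_residue = u, modification = "Psi",
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Classify snoRNA function from its predicted targets
#'
#' @param matches a data.frame of ASE matches for one locus (as returned by
#'   [find_cd_targets()] / [find_haca_targets()]).
#' @param targets the target-molecule data.frame (for the `kind` lookup).
#' @return one of `"rRNA_guide"`, `"snRNA_guide"` (scaRNA-like), `"dual"`,
#'   `"orphan"`.
#' @export
classify_function <- function(matches, targets) {
  if (is.null(matches) || nrow(matches) == 0L) return("orphan")
  kinds <- unique(targets$kind[match(matches$target_molecule_id,
                                     targets$molecule_id)])
  if (all(kinds == "rRNA")) "rRNA_guide"
  else if (all(kinds == "snRNA")) "snRNA_guide"
  else "dual"
}
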