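# Independent brute-force oracles used to cross-check the scanners and
# quantification.  These share no code with the package: pairing, box
# matching and search are re-implemented from the rule definitions with
# naive loops / matrix scans.

o_pair <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
  if (wc) return(TRUE)
  allow_gu && ((a == "G" && b == "T") || (a == "T" && b == "G"))
}

o_chars <- function(seq) strsplit(toupper(chartr("U", "T", seq)), "")[[1]]

## mismatches of chars[start..] vs an IUPAC pattern (R = A/G, N = any)
o_box_mm <- function(chars, start, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  mm <- 0L
  for (k in seq_along(pat)) {
    ch <- chars[start + k - 1L]
    ok <- switch(pat[k], R = ch %in% c("A", "G"), N = TRUE, ch == pat[k])
    if (!ok) mm <- mm + 1L
  }
  mm
}

## ---------------------------------------------------------------------------
## C/D scanner oracle: full enumeration of (C box, D box, IR stem) placements
## under the frozen rule; comparator = score desc, stem desc, C 5'-most,
## D 3'-most, arm5 5'-most, arm3 3'-most.

oracle_scan_cd <- function(seq, flank = 15L, max_c_mm = 1L, box_window = 25L,
                           min_stem = 2L, max_stem = 10L, stem_window = 25L) {
  chars <- o_chars(seq)
  n <- length(chars)
  mat_from <- flank + 1L
  mat_to <- n - flank
  if (mat_to - mat_from + 1L < 50L) return(NULL)
  best <- NULL
  for (cg in mat_from:(mat_from + box_window - 7L)) {
    if (cg + 6L > mat_to) next
    mm <- o_box_mm(chars, cg, "RTGATGA")
    if (mm > max_c_mm) next
    for (dg in max(mat_from, mat_to - box_window + 1L):(mat_to - 3L)) {
      if (dg < cg + 7L) next
      if (o_box_mm(chars, dg, "CTGA") > 0L) next
      dg_end <- dg + 3L
      ## best stem for this (C, D): maximal anchored run, ties i asc, j desc
      bs <- NULL
      for (i in max(1L, cg - stem_window):(cg - 1L)) {
        for (j in min(n, dg_end + stem_window):(dg_end + 1L)) {
          cap <- min(max_stem, cg - i, j - dg_end)
          if (cap < min_stem) next
          s <- 0L
          while (s < cap && o_pair(chars[i + s], chars[j - s])) s <- s + 1L
          if (s < min_stem) next
          if (is.null(bs) || s > bs$s ||
              (s == bs$s && (i < bs$i || (i == bs$i && j > bs$j)))) {
            bs <- list(s = s, i = i, j = j)
          }
        }
      }
      if (is.null(bs)) next
      score <- 2L * bs$s + (2L - mm)
      cand <- list(c = cg, mm = mm, d = dg, s = bs$s, i = bs$i, j = bs$j,
                   score = score)
      if (is.null(best)) { best <- cand; next }
      better <- cand$score > best$score ||
        (cand$score == best$score && (cand$s > best$s ||
          (cand$s == best$s && (cand$c < best$c ||
            (cand$c == best$c && (cand$d > best$d ||
              (cand$d == best$d && (cand$i < best$i ||
                (cand$i == best$i && cand$j > best$j)))))))))
      if (better) best <- cand
    }
  }
  best
}

## ---------------------------------------------------------------------------
## H/ACA scanner oracle: anchored-run matrix built per anti-diagonal, then a
## full scan over (outer anchor, s1, inner anchor) with the same comparator
## chain as the scanner (total desc, s1 desc, i1 asc, j1 desc, i2 asc,
## j2 desc).  Returns NULL or list(h, per-stem anchors/arms).

oracle_hairpin <- function(chars, from, to, min_arm = 2L, min_total = 8L,
                           min_pocket = 4L, min_loop = 3L) {
  n <- to - from + 1L
  if (n < 2L * min_total + 2L * min_pocket + min_loop) return(NULL)
  s <- chars[from:to]
  run <- matrix(0L, n, n)
  for (i1 in seq_len(n - 1L)) {           # extend each anchor inwards
    for (j1 in (i1 + 1L):n) {
      k <- 0L
      while (i1 + k < j1 - k && o_pair(s[i1 + k], s[j1 - k])) k <- k + 1L
      run[i1, j1] <- k
    }
  }
  cap <- outer(seq_len(n), seq_len(n),
               function(i, j) pmax(0L, (j - i + 1L - min_loop) %/% 2L))
  s2cap <- pmin(run, cap)
  s2cap[s2cap < min_arm] <- 0L
  ## best[a, b] = max s2cap over i2 >= a, j2 <= b
  S <- s2cap
  for (a in (n - 1L):1L) S[a, ] <- pmax(S[a, ], S[a + 1L, ])
  best <- t(apply(S, 1, cummax))

  anchors <- which(run >= min_arm, arr.ind = TRUE)
  best_total <- 0L
  if (nrow(anchors)) {
    for (r in seq_len(nrow(anchors))) {
      i1 <- anchors[r, 1]; j1 <- anchors[r, 2]
      for (s1 in min_arm:run[i1, j1]) {
        a <- i1 + s1 + min_pocket
        b <- j1 - s1 - min_pocket
        if (a > n || b < 1L || a > b) next
        s2 <- best[a, b]
        if (s2 >= min_arm && s1 + s2 > best_total) best_total <- s1 + s2
      }
    }
  }
  if (best_total < min_total) return(NULL)
  for (s1 in (best_total - min_arm):min_arm) {
    s2 <- best_total - s1
    if (s2 < min_arm) next
    for (i1 in seq_len(n - 1L)) {
      for (j1 in n:(i1 + 1L)) {
        if (run[i1, j1] < s1) next
        a <- i1 + s1 + min_pocket
        b <- j1 - s1 - min_pocket
        if (a > n || b < 1L || a > b || best[a, b] < s2) next
        for (i2 in a:n) {
          if (b <= i2) break
          for (j2 in b:(i2 + 1L)) {
            if (s2cap[i2, j2] >= s2) {
              off <- from - 1L
              return(list(i1 = i1 + off, j1 = j1 + off, s1 = s1,
                          i2 = i2 + off, j2 = j2 + off, s2 = s2))
            }
          }
        }
      }
    }
  }
  NULL
}

oracle_scan_haca <- function(seq, aca_offset = 3L, min_arm = 2L,
                             min_total = 8L, min_pocket = 4L, min_loop = 3L) {
  chars <- o_chars(seq)
  n <- length(chars)
  if (n < 60L) return(NULL)
  aca <- n - aca_offset - 2L
  if (paste(chars[aca:(aca + 2L)], collapse = "") != "ACA") return(NULL)
  for (h in 2L:(aca - 7L)) {
    if (o_box_mm(chars, h, "ANANNA") > 0L) next
    if (h - 1L < 20L || (aca - 1L) - (h + 6L) + 1L < 20L) next
    hp1 <- oracle_hairpin(chars, 1L, h - 1L, min_arm, min_total, min_pocket,
                          min_loop)
    if (is.null(hp1)) next
    hp2 <- oracle_hairpin(chars, h + 6L, aca - 1L, min_arm, min_total,
                          min_pocket, min_loop)
    if (is.null(hp2)) next
    return(list(h = h, hp1 = hp1, hp2 = hp2))
  }
  NULL
}

## Compare a scan_haca() annotation with the oracle result field by field.
haca_agrees <- function(ann, orc) {
  if (is.null(ann) || is.null(orc)) return(is.null(ann) && is.null(orc))
  stems_equal <- function(sp, pairs, pl, pr, hp) {
    all(sp == c(hp$i1, hp$j1)) && pairs == hp$s1 + hp$s2 &&
      all(pl == c(hp$i1 + hp$s1, hp$i2 - 1L)) &&
      all(pr == c(hp$j2 + 1L, hp$j1 - hp$s1))
  }
  ann$h_box[1] == orc$h &&
    stems_equal(ann$stem1_span, ann$stem1_pairs, ann$pocket1_left,
                ann$pocket1_right, orc$hp1) &&
    stems_equal(ann$stem2_span, ann$stem2_pairs, ann$pocket2_left,
                ann$pocket2_right, orc$hp2)
}

## Compare a scan_cd() annotation with the oracle result.
cd_agrees <- function(ann, orc) {
  if (is.null(ann) || is.null(orc)) return(is.null(ann) && is.null(orc))
  ann$c_box[1] == orc$c && ann$c_mm == orc$mm && ann$d_box[1] == orc$d &&
    ann$terminal_stem == orc$s && ann$arm5[1] == orc$i && ann$arm3[2] == orc$j
}

## ---------------------------------------------------------------------------
## ASE duplex oracles.

## All anchored C/D guide duplexes (gap 0..max_gap upstream of the box),
## resolved per overlapping guide-span group exactly like the scanner.
oracle_cd_duplexes <- function(seq, box_start, target, window = 20L,
                               max_gap = 2L, min_len = 10L, max_wobble = 2L) {
  g <- o_chars(seq)
  t <- o_chars(target)
  hits <- NULL
  for (gap in 0L:max_gap) {
    e <- box_start - 1L - gap
    if (e < 1L) next
    lo <- max(1L, box_start - window)
    for (p in seq_along(t)) {
      len <- 0L; wob <- 0L
      repeat {
        gp <- e - len; tp <- p + len
        if (gp < lo || tp > length(t)) break
        if (o_pair(g[gp], t[tp], allow_gu = FALSE)) { len <- len + 1L; next }
        if (o_pair(g[gp], t[tp]) && wob < max_wobble) {
          wob <- wob + 1L; len <- len + 1L; next
        }
        break
      }
      if (len >= min_len) {
        hits <- rbind(hits, data.frame(
          guide_start = e - len + 1L, guide_end = e, target_start = p,
          target_end = p + len - 1L, length = len, wobbles = wob, gap = gap))
      }
    }
  }
  if (is.null(hits)) return(hits)
  ## group overlapping guide spans; keep longest, fewest wobbles, 5'-most
  ## target, smallest gap
  hits <- hits[order(hits$guide_start), , drop = FALSE]
  grp <- integer(nrow(hits))
  grp[1] <- 1L
  running_end <- hits$guide_end[1]
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$guide_start[i] > running_end) grp[i] <- grp[i - 1L] + 1L
    else grp[i] <- grp[i - 1L]
    running_end <- max(running_end, hits$guide_end[i])
  }
  keep <- unlist(lapply(split(seq_len(nrow(hits)), grp), function(idx) {
    sub <- hits[idx, ]
    idx[order(-sub$length, sub$wobbles, sub$target_start, sub$gap)[1]]
  }))
  hits[sort(keep), , drop = FALSE]
}

## Bipartite pocket duplexes around an unpaired U-N dinucleotide.
oracle_bipartite <- function(seq, pl, pr, target, min_side = 4L,
                             min_total = 9L, allow_gu = FALSE) {
  g <- o_chars(seq)
  t <- o_chars(target)
  out <- NULL
  for (u in 2L:(length(t) - 1L)) {
    if (t[u] != "T") next
    a_best <- 0L; qa <- 0L
    for (q in pr[1]:pr[2]) {
      a <- 0L
      while (q + a <= pr[2] && u - 1L - a >= 1L &&
             o_pair(g[q + a], t[u - 1L - a], allow_gu)) a <- a + 1L
      if (a > a_best) { a_best <- a; qa <- q }
    }
    b_best <- 0L; qb <- 0L
    for (q in pl[2]:pl[1]) {
      b <- 0L
      while (q - b >= pl[1] && u + 2L + b <= length(t) &&
             o_pair(g[q - b], t[u + 2L + b], allow_gu)) b <- b + 1L
      if (b > b_best) { b_best <- b; qb <- q }
    }
    if (a_best >= min_side && b_best >= min_side &&
        a_best + b_best >= min_total) {
      out <- rbind(out, data.frame(u = u, a = a_best, b = b_best,
                                   right_start = qa, left_end = qb))
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Quantification oracles.

oracle_depth <- function(reads, pos) {
  vapply(pos, function(p) sum(reads$start <= p & reads$end >= p), integer(1))
}

oracle_count_reads <- function(loci, reads) {
  counts <- setNames(integer(nrow(loci)), loci$locus_id)
  for (r in seq_len(nrow(reads))) {
    best <- NA_integer_; best_ov <- -1L
    rw <- reads$end[r] - reads$start[r] + 1L
    for (l in seq_len(nrow(loci))) {
      if (loci$chrom[l] != reads$chrom[r] ||
          loci$strand[l] != reads$strand[r]) next
      ov <- min(loci$end[l], reads$end[r]) - max(loci$start[l], reads$start[r]) + 1L
      if (ov < rw / 2) next
      if (ov > best_ov ||
          (ov == best_ov && loci$start[l] < loci$start[best])) {
        best <- l; best_ov <- ov
      }
    }
    if (!is.na(best)) counts[best] <- counts[best] + 1L
  }
  counts
}

oracle_tpm <- function(counts, lengths) {
  denom <- 0
  for (j in seq_along(counts)) denom <- denom + counts[j] / lengths[j]
  if (denom == 0) return(rep(0, length(counts)))
  vapply(seq_along(counts),
         function(i) 1e6 * (counts[i] / lengths[i]) / denom, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

## Exact probability that a window of `span` iid uniform ACGT bases contains
## a run of >= t_run consecutive T (transfer-matrix DP over run length).
oracle_t_run_prob <- function(span = 19L, t_run = 5L) {
  state <- c(1, rep(0, t_run - 1))   # P(current T-run length = 0..t_run-1)
  hit <- 0
  for (pos in seq_len(span)) {
    new <- rep(0, t_run)
    for (k in seq_len(t_run)) {
      p <- state[k]
      if (p == 0) next
      new[1] <- new[1] + p * 3 / 4          # non-T resets the run
      if (k == t_run) hit <- hit + p / 4    # T completes a run of t_run
      else new[k + 1] <- new[k + 1] + p / 4
    }
    state <- new
  }
  hit
}
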