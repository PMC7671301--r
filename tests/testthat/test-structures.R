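# C/D and H/ACA structure scanners: planted-sequence closure, rule gates,
# oracle equivalence, nested units, classification.

test_that("planted C/D sequences are annotated with boxes, stem and class", {
  set.seed(101)
  targets <- test_targets()
  for (kind in c("rRNA", "snRNA", "dual", "orphan")) {
    p <- planted_cd(targets, kind)
    ann <- scan_cd(p$seq, flank = 15L)
    expect_false(is.null(ann))
    expect_lte(ann$c_mm, 1L)
    expect_identical(substr(p$seq, ann$d_box[1], ann$d_box[2]), "CTGA")
    expect_gte(ann$terminal_stem, 2L)
    expect_identical(classify_locus(ann, scan_haca(p$mature)), "CD")
  }
})

test_that("no terminal D box means no C/D call", {
  set.seed(102)
  s <- paste0(rand_dna(175), strrep("A", 25))   # CUGA cannot occur in 3' 25 nt
  expect_null(scan_cd(s, flank = 0L))
})

test_that("scan_cd equals the exhaustive placement oracle", {
  set.seed(103)
  targets <- test_targets()
  seqs <- c(replicate(60, rand_dna(300)),
            replicate(10, planted_cd(targets, "rRNA")$seq),
            replicate(10, planted_haca(targets, "rRNA")$seq))
  for (s in seqs) {
    expect_true(cd_agrees(scan_cd(s, flank = 15L),
                          oracle_scan_cd(s, flank = 15L)))
  }
})

test_that("planted H/ACA sequences are annotated with ACA at offset 3", {
  set.seed(104)
  targets <- test_targets()
  for (kind in c("rRNA", "snRNA", "dual", "orphan")) {
    p <- planted_haca(targets, kind)
    ann <- scan_haca(p$mature)
    expect_false(is.null(ann))
    expect_identical(ann$aca_offset_from_3p, 3L)
    n <- nchar(p$mature)
    expect_identical(substr(p$mature, n - 5L, n - 3L), "ACA")
    expect_gte(ann$stem1_pairs, 8L)
    expect_gte(ann$stem2_pairs, 8L)
    expect_true(ann$h_box[1] > ann$stem1_span[2] &&
                  ann$h_box[2] < ann$stem2_span[1])
  }
})

test_that("an ACA at the wrong offset is rejected", {
  set.seed(105)
  p <- planted_haca(test_targets())
  shifted <- substr(p$mature, 1, nchar(p$mature) - 1L)  # ACA now at offset 2
  expect_null(scan_haca(shifted))
})

test_that("scan_haca equals the exhaustive hairpin oracle", {
  set.seed(106)
  targets <- test_targets()
  seqs <- character(0)
  for (k in 1:40) {
    s <- rand_dna(250)
    if (k %% 2 == 0) substr(s, 245, 247) <- "ACA"   # exercise the fold stage
    seqs <- c(seqs, s)
  }
  seqs <- c(seqs, replicate(10, planted_haca(targets, "rRNA")$mature),
            replicate(5, planted_cd(targets, "rRNA")$mature))
  for (s in seqs) {
    expect_true(haca_agrees(scan_haca(s), oracle_scan_haca(s)))
  }
})

## Tandem fixture: a long parent C/D candidate carrying complete internal
## units (its own boxes and IR flank the whole cluster).
make_tandem <- function(targets, n_units = 3L) {
  ## Unit IR arms at the scanner's stem cap: no chance pairing can outscore
  ## a planted arm, so the rule's optimum is the planted decomposition.
  units <- replicate(n_units,
                     snoforge:::.make_cd_locus(targets, "rRNA",
                                               arm_range = c(10L, 10L)),
                     simplify = FALSE)
  armP <- rand_dna(6)
  ## spacers between units start and end with AAA: A:A cannot pair, so
  ## chance stems cannot extend across the IR-delimited unit boundaries.
  parts <- c(rand_dna(4), "ATGATGA", rand_dna(3), "AAA")
  spans <- matrix(0L, n_units, 2)
  off <- 6L + sum(nchar(parts))                  # after armP + lead + C + sp
  seq <- paste(parts, collapse = "")
  for (i in seq_len(n_units)) {
    spans[i, ] <- c(off + 1L, off + nchar(units[[i]]$block))
    seq <- paste0(seq, units[[i]]$block)
    off <- off + nchar(units[[i]]$block)
    gap <- if (i < n_units) paste0("AAA", rand_dna(6), "AAA") else ""
    seq <- paste0(seq, gap)
    off <- off + nchar(gap)
  }
  tail_sp <- paste0("AAA", gsub("CTGA", "GGGG", rand_dna(12), fixed = TRUE))
  seq <- paste0(armP, seq, tail_sp, "CTGA", rand_dna(3))
  seq <- paste0(seq, snoforge:::revcomp(armP))
  list(seq = seq, spans = spans, flank = 6L)
}

test_that("nested C/D units inside a long parent are recovered exactly", {
  set.seed(107)
  targets <- test_targets()
  td <- make_tandem(targets, 3L)
  parent <- scan_cd(td$seq, flank = td$flank)
  expect_false(is.null(parent))
  kids <- scan_nested(td$seq, parent)
  expect_length(kids, 3L)
  got <- t(vapply(kids, function(k) k$unit_span, integer(2)))
  expect_equal(got[order(got[, 1]), ], td$spans, ignore_attr = TRUE)
})

test_that("short candidates yield no nested units", {
  set.seed(108)
  p <- planted_cd(test_targets())
  ann <- scan_cd(p$seq, flank = 15L)
  expect_length(scan_nested(p$seq, ann), 0L)
})

test_that("locus classification is total and deterministic", {
  set.seed(109)
  targets <- test_targets()
  cd <- scan_cd(planted_cd(targets)$seq, flank = 15L)
  haca <- scan_haca(planted_haca(targets)$mature)
  expect_identical(classify_locus(cd, NULL), "CD")
  expect_identical(classify_locus(NULL, haca), "HACA")
  expect_identical(classify_locus(NULL, NULL), "unclassified")
  both <- replicate(100, classify_locus(cd, haca))
  expect_length(unique(both), 1L)   # adversarial double match: stable outcome
})

test_that("minus-strand extraction yields the same annotation", {
  set.seed(110)
  p <- planted_cd(test_targets())
  n <- nchar(p$seq)
  chrom_plus <- paste0(rand_dna(40), p$seq, rand_dna(40))
  genome_minus <- list(seq = list(chr1 = snoforge:::revcomp(chrom_plus)))
  L <- nchar(chrom_plus)
  ## the locus [40+16, 40+n-15] on + becomes [L-(40+n-15)+1, L-(40+16)+1] on -
  s_minus <- locus_sequence(genome_minus, "chr1",
                            L - (40L + n - 15L) + 1L, L - (40L + 16L) + 1L,
                            strand = "-", flank = 15L)
  expect_identical(s_minus, p$seq)
  expect_equal(scan_cd(s_minus, flank = 15L), scan_cd(p$seq, flank = 15L))
})
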