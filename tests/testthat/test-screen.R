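# Coverage profiles, candidate calling, retention/exclusion rules, cap and
# Pol III classification.

.mini_genome <- function(len = 2000L, seed = 501) {
  set.seed(seed)
  genome_bundle(c(chr1 = rand_dna(len)),
                data.frame(feature_id = character(0), type = character(0),
                           chrom = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           parent = character(0), class = character(0),
                           idx = integer(0), stringsAsFactors = FALSE))
}

test_that("profiles count depth and strand-aware read ends", {
  gb <- .mini_genome()
  reads <- make_reads("chr1", start = rep(100L, 3), end = rep(179L, 3))
  prof <- build_profiles(reads, gb)
  p <- prof$mnc_tap_plus$chr1[["+"]]
  expect_identical(as.integer(p$depth[99:181]),
                   c(0L, rep(3L, 80), 0L, 0L))
  expect_identical(p$p5[100], 3L)
  expect_identical(p$p3[179], 3L)
  expect_identical(sum(p$p5), nrow(reads))
  ## minus strand: the 5' end is the right coordinate
  mreads <- make_reads("chr1", 300L, 360L, strand = "-")
  pm <- build_profiles(mreads, gb)$mnc_tap_plus$chr1[["-"]]
  expect_identical(pm$p5[360], 1L)
  expect_identical(pm$p3[300], 1L)
})

test_that("empty read sets give all-zero profiles", {
  gb <- .mini_genome()
  prof <- build_profiles(make_reads("chr1", integer(0), integer(0)), gb)
  p <- prof$srna$chr1[["+"]]
  expect_identical(sum(p$depth), 0L)
  expect_identical(sum(p$p5) + sum(p$p3), 0L)
})

test_that("depth equals the brute-force interval-stabbing count", {
  gb <- .mini_genome(seed = 502)
  set.seed(502)
  n <- 1000L
  start <- sample(1:1900, n, replace = TRUE)
  reads <- make_reads("chr1", start, pmin(2000L, start + sample(20:90, n,
                                                                replace = TRUE)))
  p <- build_profiles(reads, gb)$mnc_tap_plus$chr1[["+"]]
  pos <- sample(1:2000, 60)
  expect_identical(as.integer(p$depth[pos]), oracle_depth(reads, pos))
})

test_that("retention and exclusion rules work on the simulated run", {
  run <- small_run()
  cand <- run$candidates
  sim <- run$sim
  ## all 12 planted repeat copies are called and excluded as a family
  expect_identical(sum(cand$exclusion == "repeat_family"), 12L)
  ## candidates over decoy ncRNAs are excluded with the annotated_ncRNA reason
  expect_gte(sum(cand$exclusion == "annotated_ncRNA"), 1L)
  ## retained loci: all retention rules hold
  ret <- cand[cand$retained, ]
  expect_true(all(ret$shared_5p_reads >= 2L | ret$shared_3p_reads >= 2L))
  expect_true(all(ret$has_perfect_read))
  expect_true(all(ret$tpm_plus > 0.1))
  expect_true(all(ret$length >= 60L & ret$length <= 320L))
  ## no retained locus overlaps an annotated ncRNA or CDS
  f <- sim$genome$features
  bad <- f[f$type %in% c("rRNA", "tRNA", "snRNA", "snoRNA", "CDS"), ]
  for (i in seq_len(nrow(ret))) {
    expect_false(any(bad$chrom == ret$chrom[i] &
                       bad$start <= ret$end[i] & bad$end >= ret$start[i]))
  }
})

test_that("cap classification follows the support-ratio thresholds", {
  gb <- .mini_genome(seed = 503)
  locus <- data.frame(locus_id = "L1", chrom = "chr1", strand = "+",
                      start = 500L, end = 580L, stringsAsFactors = FALSE)
  bg_plus <- make_reads("chr1", 1000L, 1090L, library = "mnc_tap_plus")
  bg_minus <- make_reads("chr1", 1000L, 1090L, library = "mnc_tap_minus")
  mk <- function(n_plus, n_minus) {
    ## equal-depth background keeps library totals comparable
    rbind(make_reads("chr1", rep(500L, n_plus), rep(580L, n_plus),
                     library = "mnc_tap_plus"),
          if (n_minus > 0)
            make_reads("chr1", rep(500L, n_minus), rep(580L, n_minus),
                       library = "mnc_tap_minus"),
          bg_plus[rep(1, 1000), ], bg_minus[rep(1, 1000), ])
  }
  expect_identical(
    classify_cap(locus, build_profiles(mk(100L, 3L), gb)), "capped")
  expect_identical(
    classify_cap(locus, build_profiles(mk(100L, 95L), gb)), "uncapped")
  expect_identical(
    classify_cap(locus, build_profiles(mk(4L, 0L), gb)), "undetermined")
  expect_identical(
    classify_cap(locus, build_profiles(mk(100L, 35L), gb)), "undetermined")
})

test_that("Pol III terminator detection applies the T-stretch rule", {
  base <- strrep("G", 100)
  mk <- function(downstream) {
    genome_bundle(c(chr1 = paste0(base, "GC", downstream, strrep("G", 50))),
                  .mini_genome()$features)
  }
  locus <- data.frame(chrom = "chr1", strand = "+", start = 20L, end = 100L)
  expect_true(detect_pol3_terminator(locus, mk("TTTTTA")))
  expect_false(detect_pol3_terminator(locus, mk("TTTA")))
  ## run starting beyond the 15 nt window does not count
  far <- genome_bundle(c(chr1 = paste0(base, strrep("G", 16), "TTTTT",
                                       strrep("G", 30))),
                       .mini_genome()$features)
  expect_false(detect_pol3_terminator(locus, far))
  ## minus strand: the T-stretch is upstream in genome coordinates
  gm <- genome_bundle(c(chr1 = paste0(strrep("G", 30), "AAAAA",
                                      strrep("G", 2), strrep("C", 100))),
                      .mini_genome()$features)
  lm <- data.frame(chrom = "chr1", strand = "-", start = 38L, end = 120L)
  expect_true(detect_pol3_terminator(lm, gm))
})

test_that("raising the TPM threshold monotonically shrinks the retained set", {
  cfg <- small_config(seed = 504, read_depth_total = 4e4)
  sim <- build_genome(cfg)
  reads <- simulate_libraries(sim)
  prof <- build_profiles(reads, sim$genome)
  prev <- NULL
  for (thr in c(0.1, 50, 2000)) {
    cand <- call_candidates(prof, sim$genome, reads,
                            params = screen_params(min_tpm = thr))
    ids <- cand$locus_id[cand$retained]
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
  expect_lt(length(prev), nrow(sim$truth))   # the top threshold really bites
})

test_that("noise-free simulation is recovered with exact extremities", {
  cfg <- small_config(seed = 505, end_jitter_sd = 0, mismatch_rate = 0,
                      abundance_log10_sd = 0.4)
  sim <- build_genome(cfg)
  reads <- simulate_libraries(sim)
  prof <- build_profiles(reads, sim$genome)
  cand <- call_candidates(prof, sim$genome, reads)
  ret <- cand[cand$retained, ]
  tr <- sim$truth
  key <- function(df) paste(df$chrom, df$strand, df$start, df$end)
  expect_setequal(key(ret), key(tr))
})
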