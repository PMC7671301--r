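# Read counting, TPM normalization, stability ratios, rank correlation.

test_that("the 50 percent overlap rule governs read assignment", {
  loci <- data.frame(locus_id = c("A", "B"), chrom = "chr1", strand = "+",
                     start = c(100L, 500L), end = c(199L, 599L),
                     stringsAsFactors = FALSE)
  inside <- make_reads("chr1", 120L, 160L)
  expect_identical(count_reads(loci, inside)["A", 1], 1L)
  edge <- make_reads("chr1", 110L, 209L)   # 90/100 overlap with A
  expect_identical(count_reads(loci, edge)["A", 1], 1L)
  out <- make_reads("chr1", 190L, 289L)    # only 10/100 overlap
  expect_identical(sum(count_reads(loci, out)), 0L)
  anti <- make_reads("chr1", 120L, 160L, strand = "-")
  expect_identical(sum(count_reads(loci, anti)), 0L)
})

test_that("counting matches the exhaustive assignment oracle", {
  set.seed(701)
  loci <- data.frame(locus_id = sprintf("L%02d", 1:20), chrom = "chr1",
                     strand = sample(c("+", "-"), 20, replace = TRUE),
                     start = seq(100L, by = 250L, length.out = 20),
                     stringsAsFactors = FALSE)
  loci$end <- loci$start + sample(60:160, 20, replace = TRUE)
  start <- sample(1:5200, 500, replace = TRUE)
  reads <- make_reads("chr1", start, start + sample(19:120, 500, TRUE),
                      strand = sample(c("+", "-"), 500, TRUE))
  got <- count_reads(loci, reads)[, 1]
  expect_identical(got, oracle_count_reads(loci, reads))
})

test_that("TPM follows its defining equation", {
  expect_identical(compute_tpm(5, 80), 1e6)
  expect_equal(compute_tpm(c(10, 10), c(100, 200)),
               c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-12)
  set.seed(702)
  counts <- rpois(50, 40)
  lengths <- sample(60:300, 50, replace = TRUE)
  tpm <- compute_tpm(counts, lengths)
  expect_equal(tpm, oracle_tpm(counts, lengths), tolerance = 1e-12)
  expect_lt(abs(sum(tpm) - 1e6) / 1e6, 1e-6)
  ## scale invariance and degenerate cases
  expect_equal(compute_tpm(7 * counts, lengths), tpm, tolerance = 1e-12)
  expect_identical(compute_tpm(c(0, 0), c(100, 200)), c(0, 0))
  expect_error(compute_tpm(c(-1, 2), c(10, 10)), "negative")
})

test_that("stability ratios report degradation susceptibility", {
  sr <- stability_ratio(c(100, 100, 0), c(100, 0, 0))
  expect_identical(sr$ratio[1], 1)
  expect_identical(sr$ratio[2], Inf)
  expect_identical(sr$infinite, c(FALSE, TRUE, FALSE))
  expect_true(is.na(sr$ratio[3]))
})

test_that("high-stability loci get higher ratios than low-stability ones", {
  sim <- build_genome(small_config(seed = 703))
  tr <- sim$truth[1:6, ]
  tr$abundance_weight <- 20
  tr$stability <- rep(c(0.95, 0.2), 3)
  tr$capped <- FALSE
  loci <- loci_from_truth(tr)
  ok <- 0L
  for (s in 1:25) {
    reads <- simulate_libraries(sim, truth = tr, include_decoys = FALSE,
                                seed = 7000 + s)
    ab <- abundance_table(loci, reads)
    hi <- ab$stability_ratio[tr$stability == 0.95]
    lo <- ab$stability_ratio[tr$stability == 0.2]
    if (min(hi) > max(lo)) ok <- ok + 1L
  }
  expect_gte(ok, 24L)
})

test_that("Spearman correlation matches rank-formula and library oracles", {
  expect_identical(
    abundance_stability_correlation(
      data.frame(tpm_plus_mean = 1:20, stability_ratio = (1:20)^2))$rho, 1)
  expect_identical(
    abundance_stability_correlation(
      data.frame(tpm_plus_mean = 1:20, stability_ratio = rev(1:20)))$rho, -1)
  set.seed(704)
  x <- rlnorm(30, 3, 1)
  y <- 0.5 * rank(x) + rnorm(30, 0, 4)
  rec <- data.frame(tpm_plus_mean = x, stability_ratio = y)
  got <- abundance_stability_correlation(rec)
  expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)
  expect_identical(got$method, "permutation")
  ## permutation p agrees with an independent permutation estimate
  set.seed(705)
  perm <- replicate(4000, abs(oracle_spearman(x, sample(y))))
  p_orc <- (1 + sum(perm >= abs(got$rho))) / 4001
  expect_lt(abs(got$p_value - p_orc), 0.02)
  ## n >= 50 takes the asymptotic route; cross-check against cor.test
  x2 <- rlnorm(60, 3, 1); y2 <- 0.4 * rank(x2) + rnorm(60, 0, 8)
  got2 <- abundance_stability_correlation(
    data.frame(tpm_plus_mean = x2, stability_ratio = y2))
  ct <- suppressWarnings(stats::cor.test(x2, y2, method = "spearman",
                                         exact = FALSE))
  expect_identical(got2$method, "asymptotic_t")
  expect_equal(got2$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got2$p_value, ct$p.value, tolerance = 1e-8)
})

test_that("infinite ratios are excluded and counted; small n errors", {
  rec <- data.frame(tpm_plus_mean = c(1:6, 10),
                    stability_ratio = c(1, 2, 3, 4, 5, 6, Inf))
  got <- abundance_stability_correlation(rec)
  expect_identical(got$n, 6L)
  expect_identical(got$n_excluded_infinite, 1L)
  expect_error(abundance_stability_correlation(
    data.frame(tpm_plus_mean = 1:4, stability_ratio = 1:4)), "fewer than 5")
})

test_that("abundance table sums TPM to a million per replicate", {
  run <- small_run()
  ab <- run$abundance
  tpm_cols <- grep("^tpm\\.", names(ab), value = TRUE)
  for (cn in tpm_cols) {
    s <- sum(ab[[cn]])
    if (s > 0) expect_lt(abs(s - 1e6) / 1e6, 1e-6)
  }
  expect_identical(ab$length,
                   run$candidates$end[run$candidates$retained] -
                     run$candidates$start[run$candidates$retained] + 1L)
})
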