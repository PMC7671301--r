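# Synthetic-data generator: bookkeeping, determinism, placement, sequence
# closure, and the statistical contracts of the three libraries.

test_that("class and organization tallies equal the requested counts", {
  cfg <- small_config(seed = 301)
  sim <- build_genome(cfg)
  expect_identical(sum(sim$truth$sno_class == "CD"), cfg$n_cd)
  expect_identical(sum(sim$truth$sno_class == "HACA"), cfg$n_haca)
  n <- cfg$n_cd + cfg$n_haca
  expected <- snoforge:::.apportion(
    n, cfg$organization_mix[c("intronic", "clustered", "intergenic")])
  got <- c(sum(sim$truth$organization == "intronic"),
           sum(sim$truth$organization == "clustered"),
           sum(sim$truth$organization == "intergenic"))
  expect_identical(got, expected)
})

test_that("a single intergenic C/D locus is built to rule", {
  cfg <- sim_config(genome_length = 6000, n_chromosomes = 1L, rng_seed = 302,
                    n_cd = 1L, n_haca = 0L,
                    organization_mix = c(intronic = 0, clustered = 0,
                                         intergenic = 1),
                    n_clusters = 0L, n_decoys = 0L, n_repeat_copies = 0L,
                    n_extra_genes = 0L, read_depth_total = 0)
  sim <- build_genome(cfg)
  expect_identical(nrow(sim$truth), 1L)
  tr <- sim$truth[1, ]
  mat <- locus_sequence(sim$genome, tr$chrom, tr$start, tr$end, tr$strand)
  expect_true(grepl("^....[AG]TGATGA", mat))          # C box near the 5' end
  expect_identical(substr(mat, nchar(mat) - 6L, nchar(mat) - 3L), "CTGA")
  ## terminal IR stem sits in the genomic flanks
  ann <- scan_cd(locus_sequence(sim$genome, tr$chrom, tr$start, tr$end,
                                tr$strand, flank = 15L), flank = 15L)
  expect_gte(ann$terminal_stem, 2L)
  expect_true(ann$arm5[2] <= 15L || ann$arm5[1] <= 15L)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(genome_length = 8e4, n_cd = 5L, n_haca = 3L,
                    n_clusters = 1L, n_decoys = 3L, n_repeat_copies = 0L,
                    n_extra_genes = 2L, read_depth_total = 2e4,
                    rng_seed = 303)
  sim1 <- build_genome(cfg)
  sim2 <- build_genome(cfg)
  expect_identical(sim1$genome$seq, sim2$genome$seq)
  expect_identical(sim1$truth, sim2$truth)
  r1 <- simulate_libraries(sim1)
  r2 <- simulate_libraries(sim2)
  expect_identical(r1, r2)
  d <- tempfile(); dir.create(d)
  f1 <- file.path(d, "g1.fa"); f2 <- file.path(d, "g2.fa")
  write_genome_fasta(sim1$genome$seq, f1)
  write_genome_fasta(sim2$genome$seq, f2)
  expect_identical(readLines(f1), readLines(f2))
  b1 <- file.path(d, "r1.bed"); b2 <- file.path(d, "r2.bed")
  write_alignments_bed(r1[r1$library == "srna", ], b1)
  write_alignments_bed(r2[r2$library == "srna", ], b2)
  expect_identical(readLines(b1), readLines(b2))
})

test_that("truth records satisfy their declared invariants", {
  sim <- build_genome(small_config(seed = 304))
  tr <- sim$truth
  len <- tr$end - tr$start + 1L
  expect_true(all(len >= 60L & len <= 300L))
  expect_true(all(tr$stability > 0 & tr$stability <= 1))
  f <- sim$genome$features
  introns <- f[f$type == "intron", ]
  genes <- f[f$type == "gene", ]
  for (i in seq_len(nrow(tr))) {
    if (tr$organization[i] == "intronic") {
      inside <- any(introns$chrom == tr$chrom[i] &
                      introns$strand == tr$strand[i] &
                      introns$start < tr$start[i] & introns$end > tr$end[i])
      expect_true(inside)
    }
    if (tr$organization[i] == "clustered") {
      expect_false(is.na(tr$cluster_id[i]))
      expect_gte(sum(tr$cluster_id == tr$cluster_id[i], na.rm = TRUE), 2L)
    }
    if (tr$organization[i] == "intergenic") {
      expect_false(any(genes$chrom == tr$chrom[i] &
                         genes$start <= tr$end[i] & genes$end >= tr$start[i]))
    }
  }
  ## capped / Pol III status only arises on intergenic loci
  expect_true(all(!tr$capped[tr$organization != "intergenic"]))
  expect_true(all(!tr$pol3_terminator[tr$organization != "intergenic"]))
})

test_that("an undersized genome triggers a placement error", {
  cfg <- small_config(seed = 305)
  cfg$genome_length <- 2e4
  expect_error(build_genome(cfg), "too small")
})

test_that("fully stable loci emit no small-RNA reads", {
  sim <- build_genome(small_config(seed = 306))
  tr <- sim$truth
  tr$stability <- 1
  reads <- simulate_libraries(sim, truth = tr, include_decoys = FALSE)
  expect_identical(sum(reads$library == "srna"), 0L)
  expect_gt(sum(reads$library == "mnc_tap_plus"), 0L)
})

test_that("capped loci are depleted at least 10-fold in the -TAP library", {
  sim <- build_genome(small_config(seed = 307))
  ## one capped locus in a background of uncapped ones, so that depleting it
  ## barely perturbs the fixed library depth (as in the full simulation)
  tr <- sim$truth
  tr$abundance_weight <- 10
  tr$stability <- 0.9
  tr$capped <- c(TRUE, rep(FALSE, nrow(tr) - 1L))
  plus_cap <- minus_cap <- plus_unc <- minus_unc <- 0
  for (s in 1:5) {
    reads <- simulate_libraries(sim, truth = tr, include_decoys = FALSE,
                                seed = 5000 + s)
    cnt <- function(lib, i) {
      sum(reads$library == lib & reads$chrom == tr$chrom[i] &
            reads$start <= tr$end[i] & reads$end >= tr$start[i])
    }
    plus_cap <- plus_cap + cnt("mnc_tap_plus", 1)
    minus_cap <- minus_cap + cnt("mnc_tap_minus", 1)
    plus_unc <- plus_unc + cnt("mnc_tap_plus", 2)
    minus_unc <- minus_unc + cnt("mnc_tap_minus", 2)
  }
  expect_lte(minus_cap / plus_cap, 0.1)       # configured depletion is 0.05
  ## uncapped locus: +TAP and -TAP counts agree within binomial error
  p <- plus_unc / (plus_unc + minus_unc)
  se <- sqrt(0.25 / (plus_unc + minus_unc))
  expect_lt(abs(p - 0.5), 4 * se)
})

test_that("per-locus read shares follow abundance x stability", {
  cfg <- small_config(seed = 308, read_depth_total = 2e5, n_replicates = 1L)
  sim <- build_genome(cfg)
  reads <- simulate_libraries(sim, include_decoys = FALSE)
  plus <- reads[reads$library == "mnc_tap_plus", ]
  counts <- count_reads(loci_from_truth(sim$truth), plus)[, 1]
  expected <- sim$truth$abundance_weight * sim$truth$stability
  expected <- sum(counts) * expected / sum(expected)
  keep <- expected >= 5
  chi2 <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  p <- stats::pchisq(chi2, df = sum(keep) - 1L, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("every emitted read overlaps its source locus universe", {
  sim <- build_genome(small_config(seed = 309))
  reads <- simulate_libraries(sim)
  src <- rbind(loci_from_truth(sim$truth),
               sim$decoys[, c("locus_id", "chrom", "strand", "start", "end")])
  gr <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start, reads$end),
                               strand = reads$strand)
  gl <- GenomicRanges::GRanges(src$chrom,
                               IRanges::IRanges(src$start - 10L, src$end + 10L),
                               strand = src$strand)
  ov <- GenomicRanges::countOverlaps(gr, gl)
  expect_true(all(ov >= 1L))
})

test_that("planted loci pass their own scanners noise-free (closure)", {
  sim <- build_genome(small_config(seed = 310))
  st <- annotate_structures(loci_from_truth(sim$truth), sim$genome)
  expect_identical(st$table$called_class, sim$truth$sno_class)
})
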