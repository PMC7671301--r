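# Small fixture builders shared across test files.  Planted sequences come
# from the package's own generator (internal constructors) so that closure
# properties test the real construction path.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_targets <- function() snoforge:::.make_targets()

## A planted C/D locus padded so the scanner sees standard 15 nt flanks.
planted_cd <- function(targets, kind = "rRNA", flank = 15L) {
  loc <- snoforge:::.make_cd_locus(targets, kind)
  pad <- flank - loc$arm_len
  seq <- paste0(rand_dna(pad), loc$block, rand_dna(pad))
  list(seq = seq, mature = substr(seq, flank + 1L, nchar(seq) - flank),
       loc = loc)
}

## A planted H/ACA locus (mature sequence; no terminal IR arms).
planted_haca <- function(targets, kind = "rRNA", flank = 15L) {
  loc <- snoforge:::.make_haca_locus(targets, kind)
  seq <- paste0(rand_dna(flank), loc$block, rand_dna(flank))
  list(seq = seq, mature = loc$block, loc = loc)
}

## Random guide kind with the rough proportions of the default target mix.
sample_kind <- function() {
  sample(c("rRNA", "snRNA", "dual", "orphan"), 1,
         prob = c(0.6, 0.1, 0.1, 0.2))
}

## Aligned-read rows built by hand.
make_reads <- function(chrom, start, end, strand = "+",
                       library = "mnc_tap_plus", replicate = 1L,
                       mismatches = 0L) {
  n <- length(start)
  data.frame(library = rep(library, length.out = n),
             replicate = rep(as.integer(replicate), length.out = n),
             read_id = sprintf("t_%04d", seq_len(n)),
             chrom = rep(chrom, length.out = n),
             strand = rep(strand, length.out = n),
             start = rep(as.integer(start), length.out = n),
             end = rep(as.integer(end), length.out = n),
             mismatches = rep(as.integer(mismatches), length.out = n),
             stringsAsFactors = FALSE)
}

## A small, fast study configuration used by most pipeline-level tests.
small_config <- function(seed = 7L, ...) {
  args <- list(genome_length = 2e5, n_cd = 12L, n_haca = 8L, n_clusters = 3L,
               read_depth_total = 1e5, rng_seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

## Cached small simulation + pipeline run (built once per test session).
.fixture_env <- new.env(parent = emptyenv())

small_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- run_pipeline(small_config())
  }
  .fixture_env$run
}
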