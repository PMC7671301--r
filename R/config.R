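#' Simulation configuration
#'
#' Study conditions for the synthetic genome and read libraries.  Defaults
#' emulate the statistical structure of a compact algal mncRNA transcriptome:
#' a ~1 Mb genome slice carrying 100 snoRNAs (60 C/D box, 40 H/ACA box) split
#' 0.55/0.37/0.08 across intronic, clustered and intergenic organization,
#' abundances spread over more than four orders of magnitude, locus-specific
#' stability (the fraction of molecules surviving as full-length rather than
#' degrading into sno-derived small RNAs), capped versus uncapped 5' ends
#' differentially visible in the +TAP versus -TAP medium-size libraries, and
#' a small-RNA fraction of 19-50 nt degradation fragments.
#'
#' @param genome_length total genome length (nt) across chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param rng_seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @param n_cd,n_haca number of planted C/D and H/ACA box snoRNAs.
#' @param organization_mix named proportions over intronic / clustered /
#'   intergenic (must sum to 1).
#' @param n_clusters number of polycistronic clusters (each gets >= 2 loci).
#' @param abundance_log10_mean,abundance_log10_sd log10-normal parameters of
#'   the accumulated (full-length) abundance.
#' @param stability_range range of per-locus stability fractions (0, 1].
#' @param stability_abundance_rho true Spearman correlation between
#'   accumulated abundance and stability (Gaussian copula).
#' @param capped_fraction_intergenic fraction of intergenic loci with a 5'
#'   cap.
#' @param pol3_fraction_intergenic fraction of intergenic loci given an RNA
#'   polymerase III T-stretch terminator.
#' @param cap_depletion factor by which capped loci are depleted in the -TAP
#'   library (0.05 = 95 percent loss; the cap blocks adaptor ligation unless
#'   removed by TAP treatment).
#' @param read_depth_total reads per library (split across replicates).
#' @param n_replicates biological replicates per library.
#' @param mnc_read_length_range,srna_read_length_range size-fraction windows
#'   (nt) of the medium-size and small-RNA libraries.
#' @param end_jitter_sd Gaussian jitter (nt, sd) on read extremities.
#' @param mismatch_rate per-base substitution probability on reads.
#' @param target_mix named proportions of loci guiding rRNA only, snRNA only
#'   (scaRNA-like), both (dual), or nothing (orphan).
#' @param n_decoys annotated non-snoRNA ncRNA decoys (tRNA/snRNA/rRNA-like).
#' @param n_repeat_copies copies in the planted repeat family of truncated
#'   "dead" snoRNAs.
#' @param n_extra_genes protein-coding genes without hosted snoRNAs.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6,
                       n_chromosomes = 2L,
                       rng_seed = 1L,
                       n_cd = 60L,
                       n_haca = 40L,
                       organization_mix = c(intronic = 0.55, clustered = 0.37,
                                            intergenic = 0.08),
                       n_clusters = 9L,
                       abundance_log10_mean = 1,
                       abundance_log10_sd = 1.1,
                       stability_range = c(0.05, 0.98),
                       stability_abundance_rho = 0.6,
                       capped_fraction_intergenic = 0.2,
                       pol3_fraction_intergenic = 0.5,
                       cap_depletion = 0.05,
                       read_depth_total = 1e6,
                       n_replicates = 2L,
                       mnc_read_length_range = c(50L, 300L),
                       srna_read_length_range = c(19L, 50L),
                       end_jitter_sd = 1,
                       mismatch_rate = 0.002,
                       target_mix = c(rRNA = 0.80, snRNA = 0.04,
                                      dual = 0.04, orphan = 0.12),
                       n_decoys = 10L,
                       n_repeat_copies = 12L,
                       n_extra_genes = 8L) {
  cfg <- list(genome_length = genome_length,
              n_chromosomes = as.integer(n_chromosomes),
              rng_seed = as.integer(rng_seed),
              n_cd = as.integer(n_cd), n_haca = as.integer(n_haca),
              organization_mix = organization_mix,
              n_clusters = as.integer(n_clusters),
              abundance_log10_mean = abundance_log10_mean,
              abundance_log10_sd = abundance_log10_sd,
              stability_range = stability_range,
              stability_abundance_rho = stability_abundance_rho,
              capped_fraction_intergenic = capped_fraction_intergenic,
              pol3_fraction_intergenic = pol3_fraction_intergenic,
              cap_depletion = cap_depletion,
              read_depth_total = read_depth_total,
              n_replicates = as.integer(n_replicates),
              mnc_read_length_range = as.integer(mnc_read_length_range),
              srna_read_length_range = as.integer(srna_read_length_range),
              end_jitter_sd = end_jitter_sd,
              mismatch_rate = mismatch_rate,
              target_mix = target_mix,
              n_decoys = as.integer(n_decoys),
              n_repeat_copies = as.integer(n_repeat_copies),
              n_extra_genes = as.integer(n_extra_genes))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param config a `sim_config` list.
#' @export
validate_sim_config <- function(config) {
  stopifnot(
    config$genome_length > 0,
    config$n_chromosomes >= 1L,
    config$n_cd >= 0L, config$n_haca >= 0L,
    all(c("intronic", "clustered", "intergenic") %in%
          names(config$organization_mix)),
    all(config$organization_mix >= 0)
  )
  if (abs(sum(config$organization_mix) - 1) > 1e-9) {
    stop("organization_mix must sum to 1")
  }
  if (config$srna_read_length_range[2] > config$mnc_read_length_range[1]) {
    stop("sRNA and mncRNA size-fraction windows must not overlap")
  }
  if (config$stability_range[1] <= 0 || config$stability_range[2] > 1 ||
      config$stability_range[1] > config$stability_range[2]) {
    stop("stability_range must lie in (0, 1]")
  }
  if (abs(sum(config$target_mix) - 1) > 1e-9) {
    stop("target_mix must sum to 1")
  }
  if (config$cap_depletion < 0 || config$cap_depletion > 1) {
    stop("cap_depletion must lie in [0, 1]")
  }
  invisible(config)
}

## Deterministic FNV-1a hash of any R object (used to stamp outputs).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

## Largest-remainder apportionment of n over proportions p (sums to n).
.apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}
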