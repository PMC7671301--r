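# End-to-end orchestration: simulate -> screen -> annotate -> targets ->
# organize -> quantify -> correlate -> benchmark, deterministic under a
# fixed config + seed.

#' Coerce a truth table to a plain locus table
#'
#' Lets downstream stages (annotation, targets, organization, quantification)
#' run directly on simulation truth, bypassing screening.
#'
#' @param truth a truth data.frame from [build_genome()].
#' @return data.frame with `locus_id`, `chrom`, `strand`, `start`, `end`.
#' @export
loci_from_truth <- function(truth) {
  data.frame(locus_id = truth$locus_id, chrom = truth$chrom,
             strand = truth$strand, start = truth$start, end = truth$end,
             stringsAsFactors = FALSE)
}

#' Annotate loci with snoRNA structures
#'
#' Runs [scan_cd()] (on the locus plus genomic flanks) and [scan_haca()] (on
#' the mature sequence) for every locus and classifies each as CD / HACA /
#' unclassified.
#'
#' @param loci locus data.frame (`locus_id`, `chrom`, `strand`, `start`,
#'   `end`).
#' @param genome a genome bundle.
#' @param flank genomic flank width for the IR search.
#' @param cd_p,haca_p scanner parameters.
#' @return list with `table` (one row per locus: called class, scores, box
#'   positions in locus coordinates) and `annotations` (per-locus scanner
#'   results and sequences, keyed by locus id).
#' @export
annotate_structures <- function(loci, genome, flank = 15L,
                                cd_p = cd_params(), haca_p = haca_params()) {
  anns <- list()
  rows <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    seqf <- locus_sequence(genome, loci$chrom[i], loci$start[i], loci$end[i],
                           loci$strand[i], flank = flank)
    mat <- substr(seqf, flank + 1L, nchar(seqf) - flank)
    cd <- scan_cd(seqf, flank = flank, params = cd_p)
    haca <- scan_haca(mat, params = haca_p)
    cls <- classify_locus(cd, haca)
    anns[[loci$locus_id[i]]] <- list(cd = cd, haca = haca, class = cls,
                                     seq_flanked = seqf, seq_mature = mat,
                                     flank = flank)
    rows[[i]] <- data.frame(
      locus_id = loci$locus_id[i], called_class = cls,
      cd_score = if (is.null(cd)) NA_integer_ else cd$score,
      haca_score = if (is.null(haca)) NA_integer_ else haca$score,
      c_box_start = if (is.null(cd)) NA_integer_ else cd$c_box[1] - flank,
      c_box_mm = if (is.null(cd)) NA_integer_ else cd$c_mm,
      d_box_start = if (is.null(cd)) NA_integer_ else cd$d_box[1] - flank,
      terminal_stem = if (is.null(cd)) NA_integer_ else cd$terminal_stem,
      h_box_start = if (is.null(haca)) NA_integer_ else haca$h_box[1],
      stem1_pairs = if (is.null(haca)) NA_integer_ else haca$stem1_pairs,
      stem2_pairs = if (is.null(haca)) NA_integer_ else haca$stem2_pairs,
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), annotations = anns)
}

#' Predict targets for annotated loci
#'
#' @param structures output of [annotate_structures()].
#' @param targets target-molecule data.frame (`molecule_id`, `kind`,
#'   `sequence`).
#' @param params parameters from [target_params()].
#' @return list with `matches` (all ASE matches) and `functions` (data.frame
#'   locus_id / function_class over rRNA_guide, snRNA_guide, dual, orphan).
#' @export
predict_targets <- function(structures, targets, params = target_params()) {
  matches <- .empty_matches()
  fun <- character(0)
  ids <- names(structures$annotations)
  for (id in ids) {
    a <- structures$annotations[[id]]
    m <- .empty_matches()
    if (a$class == "CD" && !is.null(a$cd)) {
      m <- find_cd_targets(a$cd, a$seq_flanked, targets, locus_id = id,
                           params = params)
    } else if (a$class == "HACA" && !is.null(a$haca)) {
      m <- find_haca_targets(a$haca, a$seq_mature, targets, locus_id = id,
                             params = params)
    }
    matches <- rbind(matches, m)
    fun <- c(fun, classify_function(m, targets))
  }
  list(matches = matches,
       functions = data.frame(locus_id = ids, function_class = fun,
                              stringsAsFactors = FALSE))
}

## Reciprocal-overlap matching of predicted loci to truth loci.
## Returns integer vector: for each truth row, the matching predicted row
## index or NA.  Match: same chrom and strand, reciprocal overlap >= min_ro,
## both extremities within +/- end_tol nt.
.match_loci <- function(truth, pred, min_ro = 0.8, end_tol = 5L) {
  m <- rep(NA_integer_, nrow(truth))
  if (nrow(pred) == 0L) return(m)
  for (i in seq_len(nrow(truth))) {
    cand <- which(pred$chrom == truth$chrom[i] &
                    pred$strand == truth$strand[i] &
                    pred$start <= truth$end[i] & pred$end >= truth$start[i])
    if (length(cand) == 0L) next
    ov <- pmin(pred$end[cand], truth$end[i]) -
      pmax(pred$start[cand], truth$start[i]) + 1L
    wt <- truth$end[i] - truth$start[i] + 1L
    wp <- pred$end[cand] - pred$start[cand] + 1L
    ok <- ov >= min_ro * wt & ov >= min_ro * wp &
      abs(pred$start[cand] - truth$start[i]) <= end_tol &
      abs(pred$end[cand] - truth$end[i]) <= end_tol
    if (any(ok)) m[i] <- cand[ok][which.max(ov[ok])]
  }
  m
}

#' Benchmark pipeline output against simulation truth
#'
#' Loci are matched by reciprocal overlap >= 80% with both extremities
#' within +/-5 nt.  Sensitivity is reported both over all planted loci and
#' conditioned on loci with expected +TAP read support >= 2 (loci below that
#' depth are legitimately unrecoverable).  Precision over an empty prediction
#' set is reported as 1.0 with an explicit flag.
#'
#' @param result a [run_pipeline()] result (or a list with `candidates`,
#'   `structures`, `targets`, `organization` components).
#' @param sim the `sno_simulation` the pipeline ran on.
#' @param min_ro,end_tol matching thresholds.
#' @return a list of per-stage metrics and the class-confusion table.
#' @export
benchmark_against_truth <- function(result, sim, min_ro = 0.8, end_tol = 5L) {
  truth <- sim$truth
  cand <- result$candidates
  pred <- cand[cand$retained, , drop = FALSE]
  m <- .match_loci(truth, pred, min_ro = min_ro, end_tol = end_tol)
  matched <- !is.na(m)

  ## expected +TAP read support per truth locus
  w_all <- truth$abundance_weight * truth$stability
  denom <- sum(w_all)
  if (!is.null(sim$decoys) && nrow(sim$decoys) > 0L) {
    denom <- denom + sum(sim$decoys$abundance_weight * sim$decoys$stability)
  }
  exp_reads <- sim$config$read_depth_total * w_all / denom
  recoverable <- exp_reads >= 2

  sensitivity_all <- mean(matched)
  sensitivity <- if (any(recoverable)) mean(matched[recoverable]) else NA_real_
  precision_flag <- nrow(pred) == 0L
  precision <- if (precision_flag) 1.0 else {
    sum(!is.na(m)) / nrow(pred)
  }

  ## class confusion among recovered loci
  called <- result$structures$table
  truth_class <- truth$sno_class[matched]
  pred_class <- called$called_class[match(pred$locus_id[m[matched]],
                                          called$locus_id)]
  confusion <- table(truth = factor(truth_class, c("CD", "HACA")),
                     called = factor(pred_class,
                                     c("CD", "HACA", "unclassified")))
  class_accuracy <- if (length(truth_class) > 0L) {
    mean(truth_class == pred_class)
  } else NA_real_

  ## target-residue recovery over matched guided loci
  tm <- result$targets$matches
  fn <- result$targets$functions
  guided <- which(matched & !is.na(truth$target_molecule_id))
  hit1 <- vapply(guided, function(i) {
    cid <- pred$locus_id[m[i]]
    any(tm$locus_id == cid &
          tm$target_molecule_id == truth$target_molecule_id[i] &
          tm$predicted_residue == truth$target_position[i])
  }, logical(1))
  dual <- which(matched & !is.na(truth$target2_molecule_id))
  hit2 <- vapply(dual, function(i) {
    cid <- pred$locus_id[m[i]]
    any(tm$locus_id == cid &
          tm$target_molecule_id == truth$target2_molecule_id[i] &
          tm$predicted_residue == truth$target2_position[i])
  }, logical(1))
  target_exact <- if (length(guided) + length(dual) > 0L) {
    (sum(hit1) + sum(hit2)) / (length(guided) + length(dual))
  } else NA_real_
  orphans <- which(matched & truth$guide_kind == "orphan")
  orphan_ok <- vapply(orphans, function(i) {
    cid <- pred$locus_id[m[i]]
    identical(fn$function_class[fn$locus_id == cid], "orphan")
  }, logical(1))
  orphan_rate <- if (length(orphans) > 0L) mean(orphan_ok) else NA_real_

  ## cap status (on matched loci with adequate +TAP 5' support)
  sup_ok <- matched & pred$cap_support_plus[m] >= 10L
  cap_truth <- ifelse(truth$capped, "capped", "uncapped")[sup_ok]
  cap_pred <- pred$cap_status[m[sup_ok]]
  cap_accuracy <- if (length(cap_truth) > 0L) {
    mean(cap_truth == cap_pred)
  } else NA_real_

  ## Pol III terminator
  p3t <- which(matched & truth$pol3_terminator)
  p3f <- which(matched & !truth$pol3_terminator)
  pol3_sensitivity <- if (length(p3t) > 0L) {
    mean(pred$pol3_terminator[m[p3t]])
  } else NA_real_
  pol3_false_rate <- if (length(p3f) > 0L) {
    mean(pred$pol3_terminator[m[p3f]])
  } else NA_real_

  ## organization
  org <- result$organization
  org_pred <- org$org_class[match(pred$locus_id[m[matched]], org$locus_id)]
  org_accuracy <- if (any(matched)) {
    mean(truth$organization[matched] == org_pred)
  } else NA_real_

  list(n_truth = nrow(truth), n_predicted = nrow(pred),
       n_matched = sum(matched),
       n_recoverable = sum(recoverable),
       sensitivity = sensitivity, sensitivity_all = sensitivity_all,
       precision = precision, precision_on_empty = precision_flag,
       class_confusion = confusion, class_accuracy = class_accuracy,
       target_exact_match_rate = target_exact,
       orphan_rate = orphan_rate,
       n_guided = length(guided) + length(dual), n_orphans = length(orphans),
       cap_accuracy = cap_accuracy, n_cap_informative = sum(sup_ok),
       pol3_sensitivity = pol3_sensitivity,
       pol3_false_rate = pol3_false_rate,
       n_pol3 = length(p3t), n_non_pol3 = length(p3f),
       organization_accuracy = org_accuracy)
}

#' Run the full discovery pipeline on a simulation
#'
#' simulate -> screen -> annotate -> predict targets -> organize -> quantify
#' -> correlate -> benchmark.  Deterministic given config + seed; when
#' `outdir` is set, all stage outputs are written (FASTA, GFF3, BED, TSV)
#' with the config hash and seed stamped in each TSV header.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @param screen_p,cd_p,haca_p,target_p,max_gap stage parameters.
#' @param min_cor_tpm TPM floor of the abundance-stability correlation.
#' @param sim optionally reuse an existing [build_genome()] result.
#' @param reads optionally reuse existing simulated reads.
#' @return a list with `sim`, `candidates`, `structures`, `targets`,
#'   `organization`, `abundance`, `correlation`, `benchmark`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         screen_p = screen_params(), cd_p = cd_params(),
                         haca_p = haca_params(), target_p = target_params(),
                         max_gap = 500L, min_cor_tpm = 0,
                         sim = NULL, reads = NULL) {
  if (is.null(sim)) sim <- build_genome(config)
  if (is.null(reads)) reads <- simulate_libraries(sim)
  profiles <- build_profiles(reads, sim$genome)
  candidates <- call_candidates(profiles, sim$genome, reads, params = screen_p)
  retained <- candidates[candidates$retained, , drop = FALSE]
  structures <- annotate_structures(retained, sim$genome,
                                    cd_p = cd_p, haca_p = haca_p)
  targets <- predict_targets(structures, sim$targets, params = target_p)
  organization <- classify_organization(retained, sim$genome,
                                        max_gap = max_gap)
  abundance <- abundance_table(retained, reads)
  correlation <- tryCatch(
    abundance_stability_correlation(abundance, min_tpm = min_cor_tpm),
    error = function(e) list(rho = NA_real_, p_value = NA_real_,
                             n = 0L, n_excluded_infinite = NA_integer_,
                             method = "unavailable"))
  result <- list(sim = sim, candidates = candidates, structures = structures,
                 targets = targets, organization = organization,
                 abundance = abundance, correlation = correlation)
  result$benchmark <- benchmark_against_truth(result, sim)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    note <- sprintf("snoforge run: config_hash=%s seed=%d",
                    config_hash(sim$config), sim$config$rng_seed)
    write_genome_fasta(sim$genome$seq, file.path(outdir, "genome.fa"))
    write_annotation_gff3(sim$genome$features,
                          file.path(outdir, "annotations.gff3"))
    write_tsv(sim$truth, file.path(outdir, "truth.tsv"), note)
    write_tsv(data.frame(molecule_id = sim$targets$molecule_id,
                         kind = sim$targets$kind,
                         sequence = sim$targets$sequence),
              file.path(outdir, "target_molecules.tsv"), note)
    for (lib in unique(reads$library)) {
      for (r in unique(reads$replicate)) {
        sel <- reads$library == lib & reads$replicate == r
        if (any(sel)) {
          write_alignments_bed(reads[sel, ],
                               file.path(outdir,
                                         sprintf("reads_%s_r%d.bed", lib, r)))
        }
      }
    }
    write_tsv(candidates, file.path(outdir, "candidates.tsv"), note)
    write_tsv(structures$table, file.path(outdir, "snostructures.tsv"), note)
    write_tsv(targets$matches, file.path(outdir, "targets.tsv"), note)
    write_tsv(targets$functions, file.path(outdir, "target_functions.tsv"),
              note)
    write_tsv(organization, file.path(outdir, "organization.tsv"), note)
    write_tsv(abundance, file.path(outdir, "abundance.tsv"), note)
    co <- result$correlation
    write_tsv(data.frame(rho = co$rho, p_value = co$p_value, n = co$n,
                         n_excluded_infinite = co$n_excluded_infinite,
                         method = co$method),
              file.path(outdir, "stats_summary.tsv"), note)
    b <- result$benchmark
    scalars <- b[!vapply(b, is.table, logical(1))]
    write_tsv(data.frame(metric = names(scalars),
                         value = vapply(scalars, function(v)
                           as.character(v[1]), character(1))),
              file.path(outdir, "benchmark.tsv"), note)
  }
  result
}
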