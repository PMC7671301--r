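---
title: "Methods: rule-based snoRNA discovery from size-fractionated libraries"
author: "snoforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based snoRNA discovery from size-fractionated libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

snoforge re-implements, as a tested and reusable pipeline, a transcriptomic
workflow for discovering small nucleolar RNAs (snoRNAs) in a compact
eukaryotic genome from three size-fractionated sequencing libraries:

* **mncRNA+TAP** — the 50–300 nt (medium-size ncRNA) fraction treated with a
  pyrophosphatase that removes 5' caps, so both capped and uncapped RNAs
  ligate adaptors and are sequenced;
* **mncRNA−TAP** — the same fraction untreated, in which capped RNAs are
  strongly depleted (the cap blocks 5' adaptor ligation);
* **sRNA** — the 19–50 nt fraction, capturing degradation and processing
  fragments, including snoRNA-derived small RNAs (sdRNAs).

The pipeline calls candidate loci from strand-aware read profiles, annotates
them as C/D box or H/ACA box snoRNAs with rule-based scanners, predicts the
rRNA/snRNA residues they modify from their antisense elements, classifies
their genomic organization (intronic, polycistronic cluster, intergenic) and
their 5'-cap / RNA polymerase III status, and quantifies abundance and
stability.  A synthetic-data generator plants ground-truth snoRNAs in a
simulated genome so that every stage can be benchmarked without any external
download.

# The synthetic-data generator

`sim_config()` fixes the study conditions; `build_genome()` and
`simulate_libraries()` realize them.  Defaults were chosen once to emulate
the statistical structure of a compact algal mncRNA transcriptome:

* **Genome**: 1 Mb over 2 chromosomes.  Real compact genomes run to ~13 Mb
  over 20 chromosomes; a 1 Mb slice keeps desk-scale runs fast while leaving
  the locus density (1 snoRNA per ~10 kb) comparable.
* **Loci**: 60 C/D box and 40 H/ACA box snoRNAs — the roughly 3:1
  class imbalance observed in such genomes, at a size that gives stable
  benchmark denominators.
* **Organization mix** 0.55/0.37/0.08 over intronic/clustered/intergenic,
  matching the observed 72/49/10 split over 131 loci, with 9 polycistronic
  clusters of ≥2 members each; one cluster is hosted inside an intron when
  at least three clusters are requested (intronic clusters exist but are the
  minority).
* **Abundance**: accumulated (full-length) abundance is log10-normal with
  sd 1.1, spreading loci over more than four orders of magnitude as observed
  in TPM distributions of real snoRNA families.
* **Stability**: each locus has a stability `s` in (0.05, 0.98] — the
  fraction of its molecules surviving full-length rather than degrading into
  19–50 nt sdRNA fragments.  Stability is coupled to accumulated abundance
  by a Gaussian copula at Spearman rho = 0.6 by default, reflecting the
  finding that differential stability, not host-gene expression, is the main
  determinant of differential snoRNA accumulation.  The molar transcription
  weight is back-computed as `abundance / stability`, so the mncRNA
  libraries sample loci proportionally to accumulated abundance and the
  sRNA library proportionally to `weight × (1 − stability)`.
* **Cap status**: a fraction (0.2) of intergenic loci are capped; capped
  loci keep full +TAP representation but are depleted to 5% in −TAP
  (`cap_depletion = 0.05`).  The real comparison is qualitative
  presence/absence; a strong factor keeps classification testable under
  sampling noise.  Intronic and clustered loci are always uncapped, as
  products of intron processing or polycistronic precursors.
* **Pol III terminators**: half of the intergenic loci receive a 6 nt
  T-stretch starting 2 nt downstream of the 3' end, modelling RNA
  polymerase III termination.
* **Reads**: 1e6 reads per library split over 2 replicates; read extremities
  get Gaussian jitter (sd 1 nt) truncated at ±3 sd, with the first two reads
  of every locus kept exact (mature extremities of real snoRNAs are sharply
  defined by snoRNP-protected ends); per-base mismatches at 0.2% with the
  first read of every locus mismatch-free.  sRNA fragments are drawn 2:1
  from the 3' half of their locus, reflecting the observed accumulation of
  3'-end fragments.

**What the generator does not emulate:** PCR over-amplification (observed
for one extreme real locus, with no stated model), paired-end read
structure (screening operates on mapped intervals), sequencing-error
structure beyond uniform substitutions, adapter artifacts, and
alignment/multimapping ambiguity (reads are emitted as unique placements —
alignment is out of scope).  Benchmarks passed on synthetic data therefore
validate the *rules and their implementation*, not robustness to mapping
artifacts or library-preparation biases.

**Construction is validated, not hoped for.**  Planted C/D sequences are
resampled until the package's own scanner recognizes the planted terminal
D box (the terminal D box of a C/D snoRNA is by definition the 3'-most one)
and, for guided loci, until the planted target residue is recovered exactly;
planted orphans are resampled until no qualifying duplex against the bundled
targets exists — an "orphan" *means* a locus without target
complementarity.  This closure guarantee is what makes recovery benchmarks
interpretable.

# Candidate screening

`build_profiles()` accumulates, per (chromosome, strand, library), the read
depth and the counts of 5' and 3' read extremities per position (replicates
pooled).  `call_candidates()` then:

1. takes maximal intervals of +TAP depth ≥ 2;
2. sets mature extremities to the modal 5' and 3' read ends near the
   interval (ties broken toward the longer locus), mirroring how mature ends
   are delimited from read-profile edges;
3. keeps loci of 60–320 nt (the mncRNA window with slack);
4. applies the retention rules: ≥ 2 reads sharing a common extremity, ≥ 1
   read with a perfect genome match, and > 0.1 TPM in the +TAP library (TPM
   universe = the candidate set, replicates averaged after normalization);
5. applies the exclusion rules: overlap with annotated ncRNAs
   (rRNA/tRNA/snRNA/known snoRNA), overlap with CDS, or membership in a
   repeated-sequence family.

"On or close to CDS" is operationalized as strict overlap; curated
exceptions on mis-annotated genes are a matter for an explicit allowlist,
not heuristics.  The repeat rule — families of ≥ 10 members at ≥ 90%
identity (global alignment, single linkage, with an 8-mer prefilter) — makes
the identity threshold explicit where the source analysis only counts
"10–15 copies" of truncated snoRNA pseudogenes.

**Cap classification** compares 5'-end support (reads ending within ±3 nt of
the locus 5' end) between the two mncRNA libraries, normalized by library
size (equivalent to the raw ratio at equal depths): capped when −TAP/+TAP ≤
0.2 with +TAP support ≥ 10, uncapped when ≥ 0.5 at the same support floor,
undetermined otherwise.  The thresholds are config-exposed defaults standing
in for what was originally a visual comparison.

**Pol III terminators** are flagged when a run of ≥ 5 consecutive T on the
coding strand starts within 15 nt downstream of the 3' end.  On random
(i.i.d.) sequence this rule fires with an exactly computable background
probability (~1.1%), which the test suite verifies against a transfer-matrix
calculation.

# Structure scanners

`scan_cd()` requires a C box (RUGAUGA, one divergence tolerated — R = A/G,
matching on T ≡ U) starting within 25 nt of the mature 5' end, an exact
terminal D box (CUGA) within 25 nt of the 3' end, and a terminal inverted
repeat of ≥ 2 bp (Watson–Crick and G:U counted) between the windows just
outside the boxes — 10 nt of mature sequence plus the 15 nt genomic flank on
each side, because mature ends are usually trimmed into the IR and the
repeat is fully visible only in genomic sequence.  The highest-scoring
placement wins, with score = 2 × stem length + (2 − C-box mismatches); ties
prefer the longer stem, then the 5'-most C box, then the **3'-most** D box
(the terminal D box is the 3' one; preferring 5'-most D would systematically
pick chance upstream CUGAs).  Internal C'/D' boxes are annotated in the
middle 40–80% of the mature span (≤ 1 divergence each, fewest mismatches
then 5'-most) and never affect acceptance.

`scan_haca()` requires an ACA box ending exactly 3 nt upstream of the 3'
end, an ANANNA hinge box strictly between two hairpins, and each hairpin to
fold with ≥ 8 base pairs.  The hairpin model is an explicit two-segment
stem: an outer arm, an internal loop with ≥ 4 unpaired nt per strand (the
pocket that holds the bipartite antisense element), an inner arm, and an
apical loop of ≥ 3 nt, searched exhaustively in compiled code.  A
maximum-pairing dynamic program was considered and rejected: maximizing pair
count has no incentive to leave the ASE pocket open, so the planted pocket
is routinely paired away and the internal-loop requirement becomes
uncheckable on the traceback.  The explicit two-segment model *is* the
structure the rule describes.  Thermodynamic folding (an external server in
the original workflow) is deliberately not used; the pair-count threshold is
config-exposed.

`scan_nested()` decomposes long candidates (> 150 nt) into internal C/D
units — complete (C box, D box 40–140 nt downstream, flanking IR) units
found greedily by score and masked recursively, returned 5'→3' with the
parent retained alongside, as polycistronic precursors can accumulate as
stable RNAs.  A caveat documented by the tests: when an internal unit's
planted stem is weak (2–5 bp), chance G:U-permissive pairings elsewhere can
legitimately outscore it under this scoring rule, so exact unit boundaries
are only guaranteed for IR-dominated units.

`classify_locus()` compares normalized scores when both scanners match
(C/D score over its maximum 22; H/ACA total pairs over 32) and reports an
exact tie as unclassified.  MRP-like snoRNAs (found via covariance models in
the original analysis) are out of scope and surface as unclassified.

# Target prediction

For C/D loci, `find_cd_targets()` scans the ≤ 20 nt upstream of the D and
D' boxes for a contiguous antisense duplex of ≥ 10 nt against any bundled
target molecule, allowing ≤ 2 G:U wobbles, with the duplex 3' end at most
2 nt from the box.  The 2'-O-methylated residue is the target base paired
with the guide base 5 nt upstream of the box (the canonical D+5 rule, stated
explicitly and config-exposed).  Overlapping hits on one box resolve to the
longest, then fewest wobbles, then 5'-most target position;
non-overlapping hits are all reported.

For H/ACA loci, `find_haca_targets()` searches each hairpin pocket for a
bipartite duplex: two segments of ≥ 4 nt each pairing the target on either
side of an unpaired U-N dinucleotide, ≥ 9 paired nt in total; the U is the
predicted pseudouridine.  Segments float within the annotated pocket strands
padded by 3 nt, so small shifts in the folded pocket do not lose planted
targets.  Bipartite duplexes are strict Watson–Crick by default
(config-exposed): the pocket rule stays sharp and matches what the generator
plants, while C/D duplexes keep the ≤ 2 wobble allowance.

`classify_function()` maps per-locus matches to rRNA-guide, snRNA-guide
(scaRNA-like), dual, or orphan.  With a ≥ 10 nt duplex threshold and ~2 kb
of target sequence, chance duplexes are expected at a non-trivial rate
(~0.1 per box and target); guided loci may therefore carry additional
predictions beyond their planted residue — as in real data, where manual
searches at "≥ 10 complementary bases" also need curation — and the
benchmark accordingly scores *recovery of the planted residue*, not
uniqueness.

# Organization, abundance, stability

`classify_organization()` clusters first (same-strand neighbours with gaps ≤
`max_gap` and no annotated feature in the gap), then classifies intronic
(strictly inside an annotated intron, sense strand; the host gene and intron
index are recorded), else intergenic.  A clustered locus inside an intron
keeps class "clustered" with `intronic_cluster = TRUE`.  Antisense-intronic
and exon-straddling loci are flagged "ambiguous" rather than forced into a
class.  `max_gap` defaults to 500 nt: no inter-snoRNA distance is stated in
the source analysis, and in a very compact genome a tight default is
appropriate; it is config-exposed.  Exons block chaining so that two
snoRNAs in consecutive introns of one host gene do not fuse into a spurious
cluster.

`count_reads()` assigns a read to a locus iff ≥ 50% of the read overlaps it
on the same strand, each read once per (library, replicate), to the locus of
maximal overlap (ties to the 5'-most locus).  `compute_tpm()` implements
TPM = 1e6 × (c/L) / Σ(c/L); all-zero counts give all-zero TPM.  Replicates
are averaged after normalization, and per-replicate values are always
retained in the output.

The **stability ratio** is mean +TAP TPM over mean sRNA-library TPM computed
on the same locus universe (the universes must match for ratios to be
comparable; the original analysis does not state its choice).  A zero sdRNA
TPM yields an `Inf` sentinel with an explicit flag rather than a dropped
locus.  `abundance_stability_correlation()` is a Spearman rank correlation
over loci above a TPM floor with finite ratios (infinite-ratio loci are
excluded and counted — whether the original correlation included them is
unstated, so the exclusion count is always reported); ties get average
ranks; the two-sided p-value is by permutation (10^4 shuffles under a fixed,
documented seed that does not disturb the caller's RNG) for n < 50 and by
the asymptotic t approximation otherwise.

# Benchmarking and reproducibility

`benchmark_against_truth()` matches retained loci to planted loci by
reciprocal overlap ≥ 80% with both extremities within ±5 nt.  Sensitivity is
reported over all planted loci and conditioned on loci with expected +TAP
support ≥ 2 reads — loci below that depth are legitimately unrecoverable
under the retention rules, and the log-normal abundance spread deliberately
places a small tail of loci there.  Precision over an empty prediction set
is 1.0 with an explicit flag (stable machine-readable reports).  Class
confusion, exact target-residue recovery, orphan recovery, cap accuracy (on
loci with +TAP 5'-end support ≥ 10), Pol III sensitivity and false-flag
rate, and organization accuracy are computed per matched locus.

Every run is deterministic given the configuration and seed; the genome
builder and the read sampler draw from separate streams derived from
`rng_seed`, and all TSV outputs carry the configuration hash and seed in a
header comment.  The problem sizes used by the bundled checks — a 1 Mb
genome with 100 loci at 1e6 reads/library for recovery, 500 random 300-mers
plus 100 planted sequences per class for scanner–oracle equivalence, and
5 × 200 loci for correlation recovery — were chosen as the smallest scales
at which the benchmarked quantities have stable denominators.

# Known limitations

* Alignment, multimapping policy and read QC are consumed, not modelled.
* MRP RNA and covariance-model homology are out of scope (such loci surface
  as unclassified/orphan).
* Nested-unit boundaries are only exact for IR-dominated internal units
  (see above).
* Cap thresholds, hairpin pair counts, pocket geometry and `max_gap` are
  explicit stand-ins for judgements that were manual or visual in the
  original workflow; all are config-exposed and their defaults documented
  here.
* The ~1% chance C/D-duplex rate against ~2 kb of targets means function
  classes beyond the planted residue (e.g. dual vs rRNA-guide) are not
  benchmarked; only exact residue recovery and orphanhood are.
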