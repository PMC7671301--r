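# snoforge

Rule-based discovery and annotation of small nucleolar RNAs (snoRNAs) from
size-fractionated noncoding RNA sequencing libraries, with a synthetic-data
generator that makes the whole analysis verifiable against planted ground
truth.

## The problem

snoRNAs guide two chemical modifications of rRNA and snRNA: **C/D box**
snoRNAs direct 2′-O-ribose methylation and **H/ACA box** snoRNAs direct
pseudouridylation. In compact eukaryotic genomes they are discovered from a
medium-size ncRNA (mncRNA, 50–300 nt) transcriptome by comparing three
libraries: the mncRNA fraction treated with a cap-removing pyrophosphatase
(**+TAP**), the untreated fraction (**−TAP**, in which capped RNAs are
depleted because the cap blocks adaptor ligation), and the small-RNA
fraction (**sRNA**, 19–50 nt) that captures snoRNA-derived degradation
fragments (sdRNAs).

snoforge implements that workflow end to end for anyone who wants to run,
stress-test, or adapt it: candidate loci are called from strand-aware read
profiles under explicit retention rules (≥ 2 reads sharing a common
extremity, ≥ 1 perfect-match read, > 0.1 TPM) and exclusion rules (annotated
ncRNAs, CDS overlap, repeat families); candidates are classified by
structure scanners built on the canonical motifs — C box RUGAUGA (one
divergence allowed) and terminal D box CUGA flanked by a terminal inverted
repeat searched in the genomic flanks; H box ANANNA between two ≥ 8 bp
hairpins and an ACA box exactly 3 nt from the 3′ end. Target residues follow
from antisense elements: a ≥ 10 nt duplex upstream of the D/D′ box with the
methylated residue at the **D+5** position, or a bipartite pocket duplex
around an unpaired U-N dinucleotide for pseudouridylation. Loci are further
classified as intronic / clustered (polycistronic) / intergenic, capped or
uncapped, and Pol III-terminated (≥ 5 T within 15 nt downstream), and
quantified as TPM = 10⁶·(c/L)/Σ(c/L) with a snoRNA/sdRNA **stability ratio**
and the Spearman correlation between abundance and stability.

Because the headline numbers of any real study derive from deep sequencing
plus manual curation, snoforge ships a first-class simulator:
`build_genome()` plants snoRNAs (with their boxes, stems, guides, hosts,
clusters, decoy ncRNAs and a repeat family) in a synthetic genome and
`simulate_libraries()` emits the three libraries with configurable depth,
jitter, mismatch rate, cap depletion and an abundance–stability coupling.
Every pipeline stage is benchmarked against this truth.

## Worked example

```r
library(snoforge)

cfg <- sim_config(genome_length = 2e5, n_cd = 12, n_haca = 8, n_clusters = 3,
                  read_depth_total = 1e5, rng_seed = 42)
res <- run_pipeline(cfg)   # simulate -> screen -> annotate -> targets ->
                           # organize -> quantify -> correlate -> benchmark

table(res$candidates$exclusion)
#> annotated_ncRNA            none   repeat_family
#>              10              20              12
```

42 read-supported loci were called; the 10 decoy ncRNAs (tRNA/snRNA/rRNA/
known-snoRNA-like) were discarded by the annotated-ncRNA rule and all 12
copies of the planted repeat family by the ≥ 10-member / ≥ 90%-identity
rule, leaving the 20 planted snoRNAs:

```r
head(subset(res$candidates, retained), 4)[, c(1:5, 11, 14, 16)]
#>   locus_id chrom strand start   end  tpm_plus cap_status pol3_terminator
#>  cand_0001  chr1      -  3578  3654  2631.369   uncapped           FALSE
#>  cand_0003  chr1      + 12052 12172 53202.389   uncapped           FALSE
#>  cand_0004  chr1      - 20755 20875 13380.647   uncapped           FALSE
#>  cand_0005  chr1      - 20906 20983  1063.471   uncapped           FALSE

table(res$structures$table$called_class)
#>   CD HACA
#>   12    8
table(res$targets$functions$function_class)
#>        dual      orphan  rRNA_guide snRNA_guide
#>           2           2          15           1
summarize_organization(res$organization)
#>   intronic  clustered intergenic  ambiguous      total
#>         11          7          2          0         20
```

Abundance spans orders of magnitude and stable loci show high
snoRNA/sdRNA ratios:

```r
head(res$abundance[order(-res$abundance$tpm_plus_mean),
                   c("locus_id", "tpm_plus_mean", "sdrna_tpm_mean",
                     "stability_ratio")], 3)
#>   locus_id tpm_plus_mean sdrna_tpm_mean stability_ratio
#>  cand_0019        552278          50116          11.020
#>  cand_0032        131589           8656          15.203
#>  cand_0003         84137          28329           2.970

res$correlation$rho           # abundance-stability rank correlation
#> [1] 0.5039
unlist(res$benchmark[c("sensitivity", "precision", "class_accuracy")])
#>    sensitivity      precision class_accuracy
#>              1              1              1
```

At this small scale every planted locus is recovered with its exact mature
extremities, class, organization and (for guided loci) target residue; the
jittered full-scale conditions are exercised by the test suite and the
acceptance script.

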