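# mapas

Nucleotide-resolution discovery of RNA-binding-protein binding sites from
CRAC/CLIP alignments, using cross-link-induced deletions.

## Who this is for

When an RNA-binding protein is UV cross-linked to its targets and the
protected RNA is sequenced (CRAC, iCLIP and relatives), reverse
transcription skips the cross-linked nucleotide and leaves a micro-deletion
in the read at the exact protein–RNA contact. `mapas` is for analysts who
have such aligned reads (two or more cross-linked replicates plus a mock
control) and want single-nucleotide binding-site calls with a
sequence-model filter, plus the standard downstream quantifications:
per-RNA interaction weights, an affinity-weighted motif logo, transcript
metaprofiles, polyadenylation-site usage, translation-efficiency (TE)
statistics from polysome profiling, and calibration-curve molecule
stoichiometry.

## The method

Stage 1 localizes candidates: every position with at least one replicate
deletion is a candidate; control deletions are subtracted (library-size
scaled) and control-dominated positions removed; each candidate gets
empirical right-tail p-values for its summed coverage and summed deletions
against the genome-wide distributions over coverage-positive positions,
combined by Fisher's method:

    X = -2 (ln p_cov + ln p_del) ~ chi-square(4)
    p_comb = exp(-X/2) (1 + X/2)

Stage 2 builds a 4x7 seed positional weight matrix from the 7-nt windows of
unique candidates with p_comb < 0.05, scores every candidate with log2-odds
sums, and thresholds at the 95th percentile of the scores of all 4^7 =
16,384 heptamers (exhaustive, deterministic). High-confidence sites also
need >= 3 deletions (>= 1 per replicate) and >= 6 spanning reads (>= 2 per
replicate).

A fully synthetic data generator (FASTA + GTF + SAM + expression + truth
BED + TE count matrices + absorbance traces) provides planted ground truth
so the whole pipeline is testable offline.

## Worked example

```r
library(mapas)

cfg <- sim_config(seed = 42)                 # the default synthetic world
tx  <- make_transcriptome(cfg)               # 60 mRNAs + 1 sponge ncRNA
sim <- simulate_crac_reads(cfg, tx, dir = "crac_demo")
res <- run_mapas(sim$sam_paths, sim$sample_sheet, tx$genome,
                 models = tx$models, expression = tx$fpkm)
res$pwm
#> seed PWM: 7 nt, 1079 seed sequences
#> consensus: UCUUUUU
#> score threshold (null percentile): 1.8011

hc <- high_confidence_sites(res)
ev <- evaluate_calls(hc, tx$truth)
nrow(hc)                                     # 461 high-confidence sites
ev$recovery; ev$fdp                          # 0.910 recovery, 0.009 FDP

head(interaction_weights(hc, group_by = "rna"), 3)
#>      key intensity weight_pct
#> 1   ncY1 7033.8655  55.936077
#> 2 TX0012  301.9937   2.401574
#> 3 TX0036  220.0000   1.749527

coding <- hc[hc$biotype %in% "protein_coding", ]
mean(coding$region == "3UTR")                # 0.90

logo <- weighted_logo(affinity_weights(hc, tx$fpkm))
round(logo[, 2:5], 2)
#>   [,1] [,2] [,3] [,4]
#> A 0.33 0.01 0.03 0.01
#> C 0.39 0.01 0.01 0.00
#> G 0.29 0.01 0.00 0.01
#> U 0.02 1.00 0.99 1.00
```

Reading the numbers: 461 of the calls pass all filters, 91% of the 502
planted truth positions are recovered with a false-discovery proportion
under 1%; the sponge ncRNA dominates the interaction weights; 90% of the
coding-transcript sites sit in 3'UTRs (the planted fraction); and the
affinity-weighted logo shows the planted CU-rich element — a U triplet at
full weight preceded by C > A > G — the hallmark of ELAV-family binding.

TE and stoichiometry, in brief:

```r
te  <- simulate_te_counts(sim_config(seed = 42))
tbl <- delta_te_table(te$pol, te$tot, class_threshold = 0.5)
target_enrichment(te$target_set,
                  tbl$gene_id[tbl$class == "up"], te$gene_ids)
molecule_ratio(213000, 109000)               # 1.95
```

## Package layout

* `R/alignment_ingest.R` — SAM/BAM loading, barcode duplicate collapse,
  CIGAR-aware pileups, pileup TSV dialect
* `R/site_detection.R` — replicate merge, control penalization, empirical
  p-values, Fisher combination, seed selection
* `R/motif_model.R` — window extraction, seed PWM, exhaustive null
  threshold, high-confidence filter, affinity weights, weighted logo
* `R/site_annotation.R` — GTF models, region assignment, interaction
  weights, metaprofile, pA-site usage
* `R/translation_metrics.R` — global/gene TE, delta-TE tables,
  hypergeometric target enrichment, stoichiometry
* `R/synthetic_data.R` — the generator for every input above
* `vignettes/binding-site-discovery.Rmd` — model, parameter rationale,
  calibration caveats, known limitations
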