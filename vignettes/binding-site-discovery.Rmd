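---
title: "Deletion-and-PWM binding-site discovery: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deletion-and-PWM binding-site discovery: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapas)
```

## The problem and the signal

UV cross-linking of an RNA-binding protein to its targets, followed by
tandem-affinity purification and sequencing of the bound RNA (CRAC, and the
related CLIP family), leaves a covalent protein–RNA adduct at the contact
nucleotide. Reverse transcriptase stalls there and frequently skips the
cross-linked base, so the cDNA — and the aligned read — carries a
micro-deletion at the exact contact position. Deletions are therefore a
nucleotide-resolution localizer of binding, sharper than read coverage
alone, which spreads over the whole protected fragment.

`mapas` turns this signal into binding-site calls in two stages.

**Stage 1 — candidate localization and significance.** Per-sample pileups
record, at every position, the number of spanning reads (`coverage`; a
deleted base counts as spanning via its D operation) and the number of
reads deleting the position. Replicate tracks are merged, and every
position with at least one deletion becomes a candidate. Control (mock)
libraries penalize candidates twice: the summed deletion count is reduced
by the library-size-scaled control deletions (floored at zero), and
candidates whose raw control deletions reach the case deletions are
removed. Each surviving candidate receives two empirical right-tail
p-values — of its summed coverage and of its summed deletions — computed
against the genome-wide distributions over all coverage-positive positions,
and the two are combined with Fisher's method,

$$X = -2(\ln p_{\mathrm{cov}} + \ln p_{\mathrm{del}}) \sim \chi^2_4,
\qquad p_{\mathrm{comb}} = e^{-X/2}\,(1 + X/2).$$

Because the observed position is a member of its own null universe, the
minimum attainable p-value is $1/N$ and the log transform is always finite.

**Stage 2 — sequence model and filters.** Unique candidate locations with
$p_{\mathrm{comb}} < 0.05$ (strict) seed a positional weight matrix over
the 7-nt window centred on the deletion (three nucleotides each side; the
footprint of tandem RRM domains on AU-rich elements). Column frequencies
use a pseudocount:
$f_{b,j} = (n_{b,j} + c)\,/\,(n + 4c)$ with $c = 1$, and scores are
log-odds sums $\sum_j \log_2 (f_{s_j,j}/b_{s_j})$ against an explicit
background (uniform by default), so a uniform PWM scores every sequence
exactly 0. The score threshold $\tau$ is the 95th percentile of the scores
of **all** $4^7 = 16{,}384$ heptamers, each weighted by its background
probability — an exhaustive enumeration, so $\tau$ is deterministic, with
no sampling and no RNG. A candidate is a high-confidence site when all of:

* score strictly above $\tau$;
* summed deletions $\ge 3$, with $\ge 1$ in every replicate;
* summed spanning reads $\ge 6$, with $\ge 2$ in every replicate.

Site *intensity* is the control-adjusted deletion total. *Affinity* is
intensity divided by the host transcript's expression (FPKM, floored at
0.1), and the affinity-weighted logo sums each site's letters weighted by
its affinity, rescaled so the global maximum entry is 1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | strict seed-site threshold on the combined p-value |
| `percentile` | 95 | heptamer-null percentile defining $\tau$ |
| `pseudocount` | 1 | per letter per PWM column; avoids $-\infty$ log-odds |
| `background` | uniform | scoring background and null heptamer weighting |
| `min_del_total`, `min_del_rep` | 3, 1 | deletion evidence filters |
| `min_cov_total`, `min_cov_rep` | 6, 2 | spanning-read evidence filters |
| `floor` | 0.1 FPKM | expression floor for affinity |
| APA `window` | 10 nt | closed, direction-agnostic distance to a pA site |
| TE `min_cpm` | 1 | CPM floor in all four libraries |
| TE `class_threshold` | 1 | \|log2 delta-TE\| for the up/down classes |

## Numerical and convention choices

* **Coordinates** are 0-based half-open internally; 1-based only at SAM
  ingest; BED output is 0-based. Deleted bases live in a separate
  `deletions` track and are *not* counted in `coverage`; "aligned reads"
  in the evidence filters means spanning reads, i.e. coverage + deletions.
* **Percentile convention** for $\tau$: lower nearest-rank on the
  background-weighted, sorted exhaustive score multiset — deterministic,
  bit-identical across runs, and guaranteeing that at most 5% of heptamer
  probability mass scores strictly above $\tau$.
* **Ties**: seed selection is strictly `<` alpha and the score filter is
  strictly `>` tau. Duplicate-collapse keeps the lexicographically smallest
  read id. Multi-transcript overlaps resolve by FPKM, then lexicographic
  transcript id. Multi-base deletions are centred on their 5'-most base.
  A read start equidistant from two pA sites credits the 5'-most.
* **Degenerate inputs**: empty alignment files load to empty record sets;
  an empty seed set is a hard error (the PWM cannot be built); windows
  containing `N` or running off a contig are dropped with logged counts;
  zero total intensity and zero 80S area are hard errors.
* **Empirical p-value universe**: coverage-positive positions of the merged
  case pileup, separately for the coverage and deletion distributions. The
  universe choice matters; see the calibration caveat below.

## The synthetic world

The generator emulates, at desk scale, the statistical structure the
caller assumes. Values the analysis design fixes: 2 cross-linked
replicates of 50,000 reads plus a 50,000-read control; 500 planted mRNA
sites, 90% in 3'UTRs; a cross-link deletion probability of 0.3 per
covering read; a background deletion probability of 0.001 per covered
internal base; and one designated ~100-nt small ncRNA "sponge" that is
expected to carry 70% of the planted deletion intensity, emulating the
dominant small-RNA partner seen in real interactomes.

Values left open, chosen once and frozen:

* **60 coding transcripts** (5'UTR 50–150, CDS 300–600, 3'UTR 200–450 nt)
  and **40-nt reads**, giving roughly 20x per-replicate coverage at mRNA
  sites once the sponge has taken its read share. This is the depth regime
  the evidence filters (3 deletions, 6 reads) were designed for.
* **Expression** lognormal(meanlog 1, sdlog 0.4). Real FPKM distributions
  are far heavier-tailed; the moderate spread keeps planted sites on
  detectably expressed transcripts, so a green recovery test says the
  caller works at adequate depth — it does **not** establish recall on
  weakly expressed transcripts, where the per-replicate deletion filter is
  the binding constraint.
* **Planted PWM**: a near-deterministic U-triplet core (0.95 per base)
  with a C-biased preceding column and U-biased downstream columns —
  the CU-rich element family. About 95% of draws from this PWM score above
  the exhaustive 95th-percentile threshold of their own recovered PWM.
* **Barcodes are 5-nt random sequences** and PCR duplicates are injected at
  rate 0.1. The sponge is short and extremely abundant, so its
  (start, barcode) key space saturates under duplicate collapse; the
  sponge-expression solver models this saturation explicitly
  ($B(1-(1-1/B)^m)$ surviving molecules per start at $m$ molecules and $B$
  barcode variants). Three-nucleotide barcodes would cap the sponge at
  64x64 unique molecules and make the 70% share unattainable at this depth.
* **Site placement** keeps truth sites at least `read_length + 10` nt from
  transcript ends so every site can be covered by a full window of read
  starts: recovery then measures the caller, not end geometry.
* **TE counts**: negative-binomial with dispersion 0.002
  (technical-replicate scale, one lysate split across libraries) and
  expression sdlog 0.4 at 1M reads per library. The planted log2 effect of
  1 multiplies the polysomal-case means of the 50 target genes only.

What the generator does **not** emulate: splicing (each transcript is its
own contig), sequencing errors, paired ends, substitution-type cross-link
mutations, position-dependent coverage biases other than end ramps, and
biological replicate dispersion in the TE experiment.

## Calibration of the combined p-value — a known limit

Fisher's method assumes the two p-values are independent under the null.
In read-generated data they are not: deletions arise per covered base, so
a position's deletion count is mechanically proportional to its coverage,
and the fraction of null candidates with $p_{\mathrm{comb}} < 0.05$
inflates (we measure ~0.075 on a read-level null at 2% background
deletions). The calibration test therefore builds the null at the pileup
level — deletions uniform across positions, independent of coverage, which
is also what "uniform background deletions" means literally — at an
intensity of 1.2 deletions/position across replicates at 20x each. The
intensity matters because rank p-values on discrete counts are exactly
uniform only in the limit of rich support: far sparser nulls are
anti-conservative *among candidates* (every candidate is automatically in
the deletion tail), and moderately sparse ones are conservative (the
staircase effect). Practical reading: the combined p-value orders
candidates well and feeds a threshold that is then followed by much
stricter evidence filters, but it is not a calibrated genome-wide FDR —
the original analysis applied no multiple-testing correction at this stage
either, and neither do we.

## Translation-efficiency module

Global TE is the trapezoidal area ratio of the polysomal portion of a
sucrose-gradient A254 trace over the 80S monosome peak. Gene-level TE is
polysomal CPM over total CPM per condition; delta-TE is its log2 change.
Normalization is plain CPM — the original analysis used edgeR's TMM, which
is out of scope here; with CPM, a change that shifts library composition
(e.g. 50 genes doubling) moves every gene's delta-TE by the same
$-\log_2$(mass ratio) offset, ~0.14 at the default synthetic effect. This
is why the synthetic recovery test classifies at half the planted effect
(threshold 0.5): the realized target delta-TE is ~0.86, and half-effect is
the natural detection boundary. Enrichment of a target set among a
delta-TE class is a one-sided hypergeometric tail, checked in the tests
against an explicit point-mass summation.

Molecule stoichiometry inverts a least-squares calibration line
(OD against ng of recombinant protein standards), converts nanograms to
molecules through the molecular mass, divides by cell count, and reports
ratios to two decimals.

## Known limitations

* Single-position sites: adjacent deletion positions are separate
  candidates; no region merging is performed.
* The empirical p-value universe is a package choice (coverage-positive
  positions); other universes change the p-values.
* Antisense reads are dropped with a count, not analyzed.
* Post-alignment duplicate collapse on (position, barcode) approximates
  the original pre-alignment sequence+barcode collapse.
* The realized sponge intensity share fluctuates around its expectation
  (~0.5–0.73 across seeds at defaults) because the sponge carries only two
  sites, each subject to the strict score filter.
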