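---
title: "Models and methods behind strainvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind strainvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`strainvar` analyses multi-strain transcriptome panels: a few rat
strains and crossbred lines, a few replicate animals each, one
log2-normalized expression matrix. This vignette records the models, the
tunable parameters, the numerical choices, and the places where the
design was genuinely open — and what the synthetic-data generator does
and does not emulate.

## The design being modelled

Five populations: three parental strains (LE, HW, SD) and two lines
derived from LE×HW crosses (LnA, LnC), four animals each, twenty arrays
in total. Two populations (HW and LnA) carry a variant AHR allele; the
other three are wildtype. Every analysis in the package is written for
the general k-population, n-replicate case but is exercised and tested
at this 5×4 scale.

## Variance partition

For gene $g$ with strain index $i$ and replicate $j$,
$y_{ij} = \mu + a_i + e_{ij}$, $a_i \sim (0, \sigma_b^2)$,
$e_{ij} \sim (0, \sigma_w^2)$. We estimate by the ANOVA method of
moments: $W = \mathrm{MS}_\text{within}$,
$B = \max(0, (\mathrm{MS}_\text{between} - W)/n_0)$ with
$n_0 = (N - \sum n_i^2/N)/(k-1)$ (equal to the replicate count for a
balanced design), and report the ratio $W/T$, $T = W + B$. The
method-of-moments form was chosen over REML because it is exact and
closed-form for the balanced design and, importantly, reproduces the
observed point mass at $W/T = 1$: whenever the between-group mean square
falls below the within-group mean square, truncation fires and the gene
is reported as all-within-variance. A constant gene is flagged and
reported as ratio 1. Intensity bins are left-closed at 4, 8 and 12
(`<4` unexpressed, `[4,8)` low, `[8,12)` medium, `>=12` high); W/T
deciles are left-closed tenths of $[0,1]$ with the last closed at 1.
The strain-only one-way model is used for W/B even when an AHR effect
exists; the AHR term is handled by the linear models below.

## Moderated linear models

Both models are fit gene-wise by ordinary least squares against a shared
design. The *simple* model uses cell-means coding (one indicator per
population, no intercept) so that contrasts are direct differences of
population means; all ten pairwise contrasts are extracted and the
overall moderated F over the contrast space (rank 4) summarizes
inter-strain variability. The *ancestry + AHR* model replaces strain
indicators by parental-ancestry proportions (LnA and LnC rows carry
0.5/0.5 for LE and HW) plus a 0/1 AHR-variant column; with the five
populations present this design has full column rank, and the AHR
coefficient is identified chiefly by the LnA–LnC contrast and the
HW-vs-midparent deviation. Rank deficiency (e.g. dropping the cross
lines, which confounds AHR with HW) is a hard error rather than silent
aliasing.

Empirical-Bayes moderation assumes $s_g^2 \mid \sigma_g^2 \sim
\sigma_g^2 \chi^2_d/d$ and $1/\sigma_g^2 \sim \chi^2_{d_0}/(d_0 s_0^2)$.
Matching the first two moments of $\log s_g^2$ gives
$\mathrm{trigamma}(d_0/2) = \mathrm{Var}(e) - \mathrm{trigamma}(d/2)$
with $e = \log s^2 - \psi(d/2) + \log(d/2)$, solved by Newton iteration
on the trigamma inverse to relative tolerance 1e-8, and then
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. The posterior
variance $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ feeds
moderated t (df $d_0 + d$) and F statistics. When the observed
log-variance dispersion does not exceed the chi-square baseline
($\mathrm{Var}(e) \le \mathrm{trigamma}(d/2)$), the prior degrees of
freedom are infinite and every gene is assigned $s_0^2$ — the normal /
chi-square limit of the t/F reference distributions. No
intensity-dependent trend or robustification is applied. Multiple
testing uses Benjamini–Hochberg step-up throughout; threshold
sensitivity curves are exported on both the adjusted and the raw scale
because published threshold plots are ambiguous about which is on the
axis.

## Heritability

For genes passing the parental gate (LE vs HW adjusted p < 0.05), each
line's position on the parental interval is
$d = (Y_\text{line} - Y_\text{low})/(Y_\text{high} - Y_\text{low})$
computed from strain mean intensities — means of four animals being the
natural per-strain summary. $d$ is affine-invariant; $d \notin [0,1]$
means the line is more extreme than both parents. The gate direction
(which parent is higher) is decided from the observed means. Gaussian
kernel densities use Silverman's rule-of-thumb bandwidth
(`stats::bw.nrd0`), overridable. Interacting loci are called from the
simple model: a gene×line pair is reported when the line differs from
*both* parents at adjusted p < 0.05 with the same sign; genes called in
both lines are flagged. Transgressive segregation is not classified —
with only two cross lines it is not assessable. When the two parents are
exactly equal, the distance is undefined and the gene is flagged not
tested rather than given an arbitrary value.

## Clustering

The workflow mirrors the standard unsupervised check on such panels:
keep genes with across-sample variance strictly above 0.25 (or overall-F
p below 0.001), mean-center and RMS-scale each gene, and cluster the
*animals* with DIANA on $1 - r$ Pearson correlation distance (range
$[0,2]$; the cited implementation's convention, not $(1-r)/2$). DIANA is
implemented in-package: repeatedly split the cluster of largest
diameter, seeding a splinter with the item of maximal average
dissimilarity and migrating items while their average dissimilarity to
the splinter is smaller than to the remainder; all argmax ties break to
the lowest item index, making the tree deterministic and
permutation-equivariant. Cutting for k clusters proceeds divisively in
decreasing diameter order. Genes can be clustered instead of samples via
a flag; sample clustering is primary because the reference figures show
animals as rows.

## Enrichment

Term enrichment is the one-sided hypergeometric upper tail of the 2×2
overlap table; terms are treated as flat sets (ontology propagation
belongs to the annotation builder, not the engine). Depletion is
available behind a flag. The permutation FDR draws random gene sets of
the target's size, builds the null p distribution per term, and reports
terms at the largest p cut whose estimated FDR (mean null discoveries /
observed discoveries) stays at or below 10%, with 1,000 randomizations
by default. The set-randomization null is a documented choice — the
reference tool's exact null construction is not described. Per-column
set sizes are attached to every enrichment matrix since unequal set
sizes mean unequal power. The contrast matrix has eleven columns (ten
pairs at adjusted p < 0.05, plus the AHR gene set from the
ancestry model); term selection keeps rows whose summed log10 p is at or
below −10 (−5, −7.5, −20, −30 supported), and the reduced matrix is
clustered with DIANA.

## Motif analysis

The scorer is a deliberately simplified average-likelihood-ratio
statistic, not the full Clover recursion: per sequence, the likelihood
ratio of the pseudocount-smoothed PWM (0.375 per cell, configurable)
against the background composition is averaged over every window on both
strands and logged; the set score is the mean over sequences; windows
touching non-ACGT characters contribute likelihood 0. The five-null
architecture is the methodological core and is preserved exactly:
per-sequence mononucleotide shuffles; dinucleotide-preserving shuffles
(random last-exit-edge arborescence plus edge permutation — an Euler-path
shuffle whose dinucleotide counts are asserted exactly in the tests);
PWM column permutation; and random same-size sets from two background
pools (all promoters, and promoters of genes with mean intensity ≥ 4).
Enrichment p uses the add-one estimator $(1 + \#\{null \ge obs\})/(B+1)$
so p is never exactly 0; depletion is the mirror count, and both are
reported since the two published conventions (lower tail vs one minus
upper tail) cannot be distinguished. The enriched call requires at least
four of the five tests below p = 0.05 *and* a raw score of at least 5
(threshold read as ≥). Column permutation of a repetitive motif
reproduces the observed score and is therefore powerless — a documented
bias of that test, visible in the tests. A background pool smaller than
the target set skips that pool's test with a warning and the 4-of-n rule
applies to the tests actually run.

Promoters are extracted on 1-based inclusive coordinates as
tss−upstream … tss+downstream, so the default −1000..+1000 window is
2,001 bp — the inclusive reading is forced by that printed length.
Minus-strand genes return the reverse complement; windows truncated at
chromosome ends are returned short with a warning.

## Genome mapping

Published "islands" of strain-dependent genes are identified by eye; to
make the claim testable the package adds an explicit scan statistic:
5 Mb windows stepped by half a window, observed set counts compared
against random same-size gene sets from the universe, add-one empirical
p, BH across windows. The statistic is the package's own extension, not
attributed to the source analyses.

## Concordance

ΔΔCt uses NE = 2^−ΔΔCt with the calibrator defaulting to the mean ΔCt of
a designated reference strain per gene — published qPCR workflows rarely
name the calibrator, so it is configurable. Platform concordance is
Pearson on log2 fold changes computed between strain means on both
platforms. Cross-species comparison aggregates multi-matching probesets
by none/mean/min/max before Spearman correlation; cross-tissue
comparison summarizes log2 F per gene group and Welch-tests each group
against all genes.

## The synthetic-data generator

The generator is the package's study stand-in, with defaults fixed to
the motivating design's published proportions rather than to any test
outcome: 5 populations × 4 replicates; baseline intensities from a
four-component mixture spanning the <4 / 4–8 / 8–12 / >12 bins (weights
0.35/0.35/0.25/0.05); 10% of genes with parental strain effects of
1.5–3 log2 units (each parental strain affected independently with
probability 2/3); 0.7% of genes with an AHR effect of 0.5–3.5 log2 units
added to both variant-carrier populations (matching ~105/15,923
probesets at 5% FDR, with observed effect sets dominated by small
effects); 0.25% interacting genes (≈41/15,923), one line pushed
1.5× the parental span (at least 1.5 log2 units) beyond the nearer
parent; within-strain SD 0.3 log2 units — typical replicate noise of
normalized arrays, and required for the 0.25-variance clustering filter
to be selective the way the published filter evidently was. A per-gene
variance option draws σ²_w from a scaled inverse chi-square (d0 = 4,
s0² = 0.25), and a pure random-effects mode (`sigma_b`) serves the W/T
calibration analyses. Noise is Gaussian on the log2 scale.

Cross-line means are convex combinations of the LE and HW means with a
per-gene mixing weight $d$ shared by both lines. $d$ is drawn
Beta(0.5, 0.5): U-shaped, supported on $[0,1]$, i.e. cross-line
expression sits near one parental level at most genes while remaining
inside the parental interval. This models differences driven by fixed
cis-acting parental alleles — a line inherits one parent's regulatory
variant — and it is what makes the two lines each other's nearest
neighbours in correlation space. A uniform mixing weight (available via
`d_mix_shape = 1`) gives the lines no more shared deviation than each
shares with a parent, and the observed sister topology of the cross
lines then becomes unstable. The U-shape has a cost made explicit below.

What the generator does *not* emulate: probe-level effects and
normalization artifacts, intensity-dependent variance trends, circadian
or husbandry covariates, correlated gene modules (genes are independent
given the design), and real ontologies or genomes (annotations,
promoters, loci and homolog maps are simulated with planted structure).
Passing tests therefore demonstrate correctness and calibration of the
statistics under the stated generative model, not robustness to
real-array artifacts.

## Known limitations and open trade-offs

* With four replicates, the strain-mean noise gives the heritability
  distance an sd of roughly 0.1 near the significance gate. Any mixing
  distribution heavy enough at the interval ends to reproduce the
  cross-line sister topology therefore spills 10–15% of distance
  estimates outside $[0,1]$; interior-heavy mixing contains the
  distances but destabilizes the sister topology. The defaults favour
  the clustering structure: about 85% of gated distance values (and
  75–90% of the fitted kernel-density mass, which the bandwidth smears
  further) fall inside $[0,1]$, and ~95% inside $[-0.1, 1.1]$.
* The moment-matched prior assumes a single variance population; no
  intensity trend is fitted.
* The permutation FDR and hotspot scans are exchangeable-null tests;
  correlated annotations or clustered gene positions under the null
  would require a different null model.
* Problem sizes in the tests and the acceptance script (5,000–10,000
  genes, 1,000 motif permutations, 300–500 background promoters) were
  chosen as the smallest sizes at which the calibration statements are
  stable.
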