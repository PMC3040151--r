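---
title: "Quantifying dosage compensation in ZZ/ZW systems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dosage compensation in ZZ/ZW systems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdosage)
```

## The scientific question

In birds and other female-heterogametic species, males are ZZ and females
ZW. A Z-linked gene therefore has two template copies in males and one in
females. If nothing compensates for this, its expression should be twice as
high in males: a male-to-female (m:f) expression ratio of 2, against 1 for
autosomal genes. Complete dosage compensation — as seen on the mammalian X —
would push the Z ratio back to 1. The empirical picture in birds is neither:
Z-linked m:f ratios sit between 1 and 2, indicating partial compensation,
apparently achieved by up-regulating the single female Z rather than
silencing one male copy.

`zdosage` packages the full analysis used to measure this from shallow
RNA-seq of a non-model species: qPCR verification that orthology predicts
chromosomal location, RPKM quantification, a core gene-set filter,
GC-bias removal, chromosome-wise inference on log2(m:f), Z:autosome ratios
per sex, sex-bias classification, and cross-species comparison — plus a
ground-truthed simulator so every stage can be validated end to end.

## The expression pipeline

### RPKM and chromosome assignment

Counts are normalised as
\[
\mathrm{RPKM}_{gs} = \frac{10^9 \, C_{gs}}{N_s \, L_g},
\]
with $C_{gs}$ the read count of gene $g$ in sample $s$, $N_s$ the sample's
library size (taken from the sample sheet) and $L_g$ the exon length in bp.
Chromosome labels are transferred from an annotated reference species over
one-to-one orthologues only (`assign_chromosomes()`); genes without a
one-to-one orthologue are dropped and counted. Avian karyotypes are
conserved enough that this transfer is reliable at the chromosome scale,
which the qPCR module verifies independently (below).

### The core gene-set filter

At a few reads per gene and individual, per-gene ratios are extremely
noisy, and weakly expressed Z genes may yield zero female reads under
incomplete compensation. `filter_core_gene_set()` therefore retains a gene
only if

1. its expression exceeds a per-individual reference level in at least
   `min_samples_per_sex` (default 2) males *and* as many females, and
2. $|\log_2(\text{m:f})| \le 4$ (computed from the per-sex means of RPKM).

The reference level is, by default, the individual's **mean log2
expression** over its expressed genes — the geometric mean, which sits near
the median of a right-skewed expression distribution and so retains roughly
half the genes of each individual and, after the two-per-sex rule, close to
half the gene set. An arithmetic-mean variant
(`threshold = "per_individual"`) is a far higher bar on skewed data (it
retains roughly a quarter), and a matrix-wide `"global"` variant is also
available. We made the geometric reading the default because it is the one
consistent with the retention fraction such shallow-coverage studies report
when they describe this exact filter, and because it needs no cross-sample
normalisation.

Requiring the gene to clear the threshold *in both sexes* has an important
side effect discussed under *Known limitations*.

### GC-bias removal

Library PCR is not equally efficient across GC contexts, so digital
expression estimates carry a GC component; because avian
micro-chromosomes are GC-rich and the Z is relatively GC-poor, an
uncorrected GC effect distorts *between-chromosome* m:f comparisons
specifically. `remove_gc_effect()` regresses per-gene log2(m:f) on GC
fraction (ordinary least squares, linear in GC — no functional form beyond
linearity is assumed) and replaces each value by its residual plus the
grand mean. Consequences, each tested:

* adjusted values are exactly uncorrelated with GC (OLS residual property);
* the grand mean of log2(m:f) is preserved to machine precision;
* the operation is idempotent.

Reference-species GC is used as a proxy for focal-species GC, which is
defensible because GC content is strongly conserved between related
genomes. Sex-specific fits of expression level on GC
(`gc_effect_by_sex()`) are reported as diagnostics only; the chromosome
inference consumes m:f, so the correction is applied there.

### Chromosome-level inference

Per-gene log2(m:f) values are regressed on chromosome identity **without an
intercept**: each coefficient is then that chromosome's mean log2(m:f), and
the global F statistic tests the joint null that every chromosome mean is 0
(full compensation everywhere). Per-chromosome confidence intervals are
computed at level $1-\alpha/k$ for $k$ chromosomes (Bonferroni), formed on
the log2 scale and exponentiated, so they are symmetric on the log scale
like the estimates themselves. Fitting per gene is algebraically identical,
in point estimates, to regressing per-chromosome means weighted by gene
counts (the tests verify the equivalence to 1e-10); per-gene residual
variance is used for inference, which treats genes, not chromosomes, as
the unit of replication. Chromosomes with fewer than two genes are
excluded with a warning.

Z:A ratios per sex (`za_ratio()`) are computed as the difference of mean
per-gene log2 expression between Z and autosomes, exponentiated; this is
the scale on which such ratios are conventionally reported (a mean log2
difference of −0.35 corresponds to a ratio of 0.78). Gene-level bootstrap
percentile intervals are attached, resampling Z and autosomal genes
independently. An arithmetic-mean mode exists behind `log_scale = FALSE`.

`mean_ratio_ci()` provides nonparametric percentile bootstrap intervals
for either the mean of per-gene ratios or the ratio of per-sex means
(`mode` flag); the bootstrap resamples genes, so it captures both
gene-level heterogeneity and counting noise. Intervals are labelled as
bootstrap intervals in outputs because an analytic construction is not
prescribed for these quantities.

### Density, bias classes, positional profile

`density_log2mf()` wraps `stats::density()` with a Gaussian kernel and
Silverman's rule-of-thumb bandwidth (`bw.nrd0`); on Z genes a bimodal curve
(modes near 0 and near 1 on the log2 scale) suggests discrete classes of
compensated and uncompensated genes. `classify_sex_bias()` uses the
conventional thresholds m:f > 2 (male-biased), 0.8 < m:f < 1.2 (unbiased),
m:f < 0.5 (female-biased) and deliberately leaves the gaps [0.5, 0.8] and
[1.2, 2] unclassified rather than forcing genes into a class.
`bias_expression_anova()` is a one-way ANOVA of per-sex log2 expression
level on class, with Bonferroni-adjusted pairwise t-tests as the post hoc;
with the conventional three classes and 101 classified genes this is an
$F_{2,98}$ test. `positional_mf_profile()` orders a chromosome's genes by
reference position and reports sliding-window means (default 10 genes,
step 1) of GC-adjusted log2(m:f) — a coarse screen for regionally
restricted compensation, only as good as the assumption of conserved gene
order.

## The qPCR Z-linkage module

Genomic qPCR measures template copy number. Relative to an autosomal
control gene, the ΔCt method gives
$\text{conc} = 2^{-(Ct_\text{target} - Ct_\text{control})}$; a Z-linked
locus is expected at relative concentration ~1 in ZZ males and ~0.5 in ZW
females. Because amplification-efficiency differences shift both sexes
equally, the decisive quantity is the male-to-female ratio of mean
concentrations: 2 for Z-linked loci, 1 for autosomal ones.

Design choices:

* **Replicates** (triplicate by default) are averaged per (sample, gene,
  locus) before ΔCt; replicate-level scatter is reported as QC and not
  propagated, matching standard ΔCt practice.
* **Per-locus test**: pooled-variance two-sample Student t with
  $df = n_m + n_f - 2$ and a one-sided p-value for male > female — the
  direction Z-linkage predicts. With 4 + 4 individuals this gives the
  familiar df = 6 tail. If both groups are constant and equal, t = 0 and
  p = 0.5.
* **Gene-level call** (`call_z_linkage()`): Z-linked iff *every* locus has
  p < α and m:f ≥ 1.5; autosomal iff every locus has m:f < 1.5 and p ≥ α;
  anything mixed is ambiguous. The boundary 1.5 is the linear midpoint of
  the two expectations; the log-scale midpoint √2 can be supplied via
  `ratio_boundary`.
* **Control-gene choice** (`choose_control_gene()`): candidates are ranked
  by |mean m:f − 1| with Ct standard deviation across samples as the
  tie-break, both criteria reported.
* **Efficiency** (`efficiency_from_dilution()`): slope of Ct against log10
  template over a ≥ 2-log dilution series; efficiency $=10^{-1/\text{slope}}-1$
  (slope −3.32 ⇔ perfect doubling). Efficiencies are QC output only; ΔCt
  concentrations are *not* efficiency-corrected, since normalisation to a
  matched control absorbs most of the effect.
* **Synteny disruption** (`synteny_disruption_test()`): Fisher exact test
  of moved/stayed counts in the tested set against a background rate (e.g.
  the fraction of one-to-one orthologues that moved between two reference
  genomes). Both sidedness variants are returned; the directional question
  ("more movement than expected?") uses the one-sided greater tail. The
  2×2 counts are inputs, not constants, because the appropriate background
  depends on divergence times.
* **Intron-length check** (`intron_length_check()`): when a candidate gene
  appears autosomal, regressing observed exon–exon amplicon lengths on the
  reference intron lengths distinguishes whole-gene movement (slope ≈ 1,
  high R²) from retrotransposition (no relationship).

## The synthetic-data generator

`simulate_expression()` emulates the data regime this pipeline targets —
a shallow shotgun transcriptome of a wild bird — with known ground truth:

* **Doses.** Autosomal genes are diploid in both sexes. Z genes carry male
  dose 2 and female dose $2^d$, where $d \in [0,1]$ is the compensation
  degree: the true m:f ratio is $2^{1-d}$. Compensation is parameterised as
  female up-regulation, the mechanism supported in birds. `d` may be a
  per-Z-gene vector to emulate regional compensation.
* **Baselines.** Per-gene baseline log2 expression is Normal(3, 1.5) on
  the log2 RPKM scale — roughly three orders of magnitude of dynamic range,
  typical of a brain transcriptome.
* **GC.** GC fractions are uniform on [0.35, 0.65], shifted by −0.05 for
  Z genes (the avian Z is relatively GC-poor); sex-specific GC slopes act
  on log2 expression around the central GC of 0.5, so injecting a slope
  adds GC-correlated bias without moving the mean.
* **Counts.** A gene's expected read yield is proportional to its
  expression times its exon length (shotgun sampling is per nucleotide),
  scaled by one global factor so the overall mean is `mean_reads_per_gene`
  (default 10 reads/gene/individual — squarely in the shallow-coverage
  regime of early pyrosequencing studies). Counts are negative binomial
  with dispersion 0.2 (biological CV ≈ 0.45, appropriate for wild, outbred,
  mixed-age individuals). At `dispersion = 0` the generator returns the
  expected counts themselves — a deterministic limit, chosen so that
  noise-free runs realise their ground truth *exactly* and exactness tests
  are meaningful.
* **Library sizes.** The sample sheet carries the nominal common depth
  (`n_genes × mean_reads_per_gene`) for every sample. Using the nominal
  rather than the realised column sum keeps RPKM free of the small
  composition artefact that arises because female libraries contain fewer
  Z reads, and makes noise-free ratios exact.

`simulate_qpcr()` draws per-gene base Ct from Uniform(22, 28) and sets
replicate Ct to $base - \log_{1+E}(\text{copies}) + N(0, \sigma)$ with
copies 2 except for female Z genes (1), efficiency $E$ (default 1) and
Ct noise σ = 0.15 cycles. With perfect efficiency the single female copy
costs exactly one cycle. `simulate_orthology()` flips a gene's reference
chromosome to a random different one with a configurable disruption
probability.

What the generator does **not** emulate: read mapping and assembly errors,
multi-mapping, per-individual random effects beyond the NB dispersion,
correlated expression along chromosomes, and sequence-level artefacts.
Passing tests therefore demonstrate the statistical machinery under the
stated sampling model, not robustness to upstream bioinformatic error.

## Numerical choices and degenerate inputs

* Identical seeds give bit-identical outputs everywhere; all randomness
  flows through R's RNG seeded once per generator or bootstrap call.
* Bootstrap intervals are percentile intervals; `n_boot < 100` is refused.
* `fit_gc_effect()` requires ≥ 3 finite pairs and non-constant GC;
  `density_log2mf()` refuses all-identical input (degenerate bandwidth);
  `chromosome_mf_regression()` needs ≥ 2 chromosomes with ≥ 2 genes.
* Control-gene ranking breaks exact ratio ties by Ct stability.
* In `locus_mf_test()`, zero pooled variance with equal means yields
  t = 0, p = 0.5; with unequal means, ±∞ and p ∈ {0, 1}.
* Gene tables are sorted deterministically (by gene id) wherever order
  would otherwise depend on hash/user order.

## Validation strategy and problem sizes

The test-suite checks fall into three groups. Exact oracles: closed-form
RPKM values, one-cycle ΔCt arithmetic, a from-scratch hypergeometric
enumeration against the Fisher test (1e-12), the weighted/per-gene
regression equivalence (1e-10), OLS residual orthogonality (1e-8).
Published worked examples: the 21-candidate qPCR locus table with its
printed t and p values, reproduced by the pooled one-sided t at df = 6 to
1e-3 and called 20 Z-linked / 1 autosomal. Simulation studies at the
package's default study conditions (150 Z and 3400 autosomal genes, 4 + 4
individuals): parameter recovery across $d \in \{0, .25, .5, .75, 1\}$
with 50 seeds, family-wise type-I control over 200 null seeds, bootstrap
coverage over 200 replicates, and ≥ 95% end-to-end qPCR call recovery over
40 plates. These sizes were chosen to give stable Monte-Carlo estimates at
interactive runtimes.

## Known limitations

**The core filter is selection-biased at low compensation.** Requiring a
gene to exceed the expression threshold in ≥ 2 *females* preferentially
retains, among Z genes whose female expression is marginal, exactly those
whose female counts fluctuated upward. Conditioning on that event inflates
the female mean and attenuates the estimated Z m:f ratio. In our
simulations at default noise the full pipeline estimates ≈ 1.85 when the
truth is 2.0 (no compensation), ≈ 1.36 when the truth is 1.41, and is
essentially unbiased at full compensation (truth 1.0) where the filter
acts symmetrically on the sexes. The bias is a property of the published
filtering rule itself, not of this implementation — any analysis applying
this filter to low-coverage data will understate the Z ratio, and
real-data estimates near 1.4 should be read with that attenuation in mind.
We deliberately did not "fix" the filter, because reproducing the method
includes reproducing its bias; the simulator makes the bias measurable.

**Z:A ratios inherit the same selection.** On the filtered core set,
retained Z genes are drawn from higher baseline expression than retained
autosomal genes (they had to clear the female threshold at reduced dose),
which can inflate both sexes' Z:A ratios. Comparisons of Z:A *between*
sexes are more trustworthy than their absolute values.

**Positional inference assumes conserved gene order**, which holds only
approximately even within birds; the positional profile is a screen, not a
map.

**Coverage.** At ~10 reads/gene/individual, per-gene ratios are dominated
by sampling noise; all inference here is chromosome- or class-level.
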