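---
title: "Methods: differential GWAS with sample-overlap correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential GWAS with sample-overlap correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Two related complex traits — here the motivating case is a pair of
psychiatric disorders such as schizophrenia and PTSD — can share much of
their polygenic architecture yet differ at individual loci, including
*antagonistic* loci where the same allele raises risk for one disorder
and lowers it for the other. Genetic-correlation methods summarize the
shared component; they do not point at the variants where the two
architectures disagree. This package tests, SNP by SNP, whether the two
studies' effect sizes differ, using nothing but publicly released
summary statistics.

## The model

For a SNP harmonized to a shared effect allele, with effect estimates
$\hat\beta_1, \hat\beta_2$ and standard errors $se_1, se_2$, the
differential statistic is

$$Z = \frac{\hat\beta_1 - \hat\beta_2}
          {\sqrt{se_1^2 + se_2^2 - 2\rho\, se_1 se_2}}.$$

Under large-sample theory the reported standard errors already encode
sample size and sampling variability, so with no shared samples the
classical two-sample form ($\rho = 0$) suffices. When the two studies
overlap, their effect-estimate errors are correlated and the naive
variance is too large: the test becomes conservative. The covariance
term is not published, but for null SNPs
$\mathrm{Cov}(z_1, z_2) \approx \rho$, the correlation of z-scores, so a
genome-wide empirical $\rho$ estimated from quasi-independent SNPs can
be plugged in. For two studies of sizes $n_1, n_2$ sharing $n_o$
samples (and phenotype noise), theory gives
$\rho = n_o / \sqrt{n_1 n_2}$; the estimator targets exactly this
quantity, which is how the synthetic generator validates it.

### Estimating rho

`estimate_rho()` takes the Pearson correlation of $z_1 = \beta_1/se_1$
and $z_2 = \beta_2/se_2$ over a pruned SNP subset, with a Fisher
z-transform 95% interval. Two pruning routes (`pruning_config()`):

* **distance thinning** (default): keep the lowest-position SNP per
  250 kb window per chromosome. Deterministic and data-independent — in
  particular not enriched for significant SNPs, which would bias $\rho$
  upward — and self-contained, requiring no genotype reference panel.
* **ld_file**: greedy removal of SNPs with pairwise $R^2 \ge 0.1$
  against any retained SNP, scanning by position, from an externally
  computed LD table. This is the route to use when a reference panel is
  available; 0.1 is the conventional low-LD cutoff.

$\rho$ is a single genome-wide scalar, not per-chromosome: the overlap
fraction that generates it is a property of the cohorts, not of any
locus.

An optional restriction (`null_zmax`, default 2.0) drops SNPs with
$\max(|z_1|, |z_2|) \ge 2$ before the correlation. The motivation: the
correction targets the *null* sampling covariance, and strongly
associated SNPs contribute true shared polygenic signal that inflates
the estimate. The cost: truncating a bivariate normal at $|z| < 2$
biases the correlation toward zero when the input really is null, so
analyses of data known to be null (as in the package's own recovery
tests) pass `null_zmax = NULL`. On real psychiatric GWAS, where
thousands of SNPs carry shared signal, the restriction is the safer
default; both behaviours are exposed because neither dominates
universally.

### Genome-wide standardization

Raw differential z-scores are rescaled to sample mean 0 and standard
deviation 1 across all retained SNPs before p-values are assigned —
analogous in spirit to genomic control. This absorbs residual
miscalibration that the empirical $\rho$ cannot fix, e.g. when either
GWAS carries many genome-wide significant SNPs. Convention: plain
mean/SD over all SNPs, computed once (not leave-one-out, not
per-chromosome). A `robust = TRUE` option uses median/MAD instead,
because heavy polygenic tails inflate the plain SD and cost power; the
plain version is the default since it matches the mean-0/variance-1
restriction exactly.

Standardization makes the test remarkably forgiving of a misspecified
$\rho$: if the ratio $se_1/se_2$ is constant across SNPs (exactly true
in the synthetic generator, nearly true in real data where both SEs are
driven by the same allele frequency), using the wrong $\rho$ rescales
all z-scores by a common factor that standardization undoes. The
package therefore also emits the *unstandardized* p-value (`p_raw`),
which is where omitting the correction visibly deflates the test — the
acceptance checks demonstrate calibration on `p_diff` and deflation on
`p_raw` at $\rho^\* = 0.5$. Conversely this means the ranking of SNPs,
not only their calibration, is what the $\rho$ correction and
standardization jointly protect.

One caveat is checked rather than assumed: standardization shifts by
the genome-wide mean, so a near-zero raw z-score can change sign. Rows
where that happens are flagged (`sign_consistent = FALSE`) and counted,
never silently passed.

### Selection, clumping, replication

A SNP becomes a candidate only if (i) $P_\mathrm{diff} < 5\times10^{-8}$,
(ii) $P < 0.05$ in *both* original GWAS, and (iii) the two betas have
opposite signs. The composite rule deliberately discards SNPs that are
extreme in one study and flat in the other — those produce significant
differences without any cross-trait biology.

Candidates are clumped into loci greedily: best remaining
$P_\mathrm{diff}$ becomes a lead (ties broken by chromosome, then
position), absorbing all candidates within 1 Mb on the same chromosome.
Distance-based clumping is the package's own rule — published analyses
report "independent loci" without one — and 1 Mb is the field's common
locus radius.

Replication triage aligns each lead to a replication GWAS (rsid first,
then position; z negated on swapped alleles; allele-incompatible
matches treated as absent) and partitions by replication p-value:
`replicated` below $5\times10^{-8}$, `attenuated` at or above $10^{-3}$,
`intermediate` between. The boundary is deliberate: published
narratives use "retained genome-wide significance" and "all P > 0.001"
as the two implicit cutoffs, and the bundled worked example has a locus
at $P = 0.00126$ — just above the attenuation cutoff, hence attenuated
under the $\ge$ convention, in line with the published reading. The
three-way partition keeps genuinely intermediate evidence visible
instead of forcing it into either bin. Direction consistency compares
the sign of the aligned z with the candidate's trait-2 beta, since
replication tables often publish z and p only.

## Harmonization choices

* Join key is (chromosome, position) with an allele-compatibility
  check, **not** rsid: rsid vintages differ across releases. Trait-1
  rsids are carried for display. Duplicate position keys are an error
  naming the position.
* Swapped-allele pairs are merged onto trait-2's orientation with the
  trait-1 beta negated and frequency complemented, `flipped = TRUE`.
* Strand-ambiguous (palindromic A/T, C/G) SNPs are excluded by default:
  without frequencies a strand flip is indistinguishable from an allele
  swap. With `ambiguous = "freq"` orientation is read off the allele
  frequencies, but only when both frequencies sit further than
  `freq_margin` (default 0.10) from 0.5.
* Indels and non-ACGT alleles are rejected at read time by default
  (`allow_indels = FALSE`); the analysis is SNP-focused.
* The MAF $\ge 0.05$ filter applies to the trait-2 table by default
  (mirroring a preprocessing convention in which only the second
  study's frequencies are trusted for filtering), extendable to both
  with `maf_both = TRUE`. MAF is $\min(f, 1-f)$.
* Positions are 1-based; "chr" prefixes are stripped; only autosomes
  1–22 are analyzed.

## Numerical choices

* Two-sided p-values are $2\,\Phi(-|z|)$ via the normal survival
  function (`lower.tail = FALSE`), preserving relative accuracy in the
  extreme tail instead of computing $1 - \mathrm{CDF}$; values underflow
  only below ~1e-308.
* `delta_variance()` raises a degenerate-variance error when
  $se_1^2 + se_2^2 - 2\rho se_1 se_2 \le 0$ (attainable only at
  $|\rho| = 1$ with equal SEs); `run_diff_gwas()` drops such rows with a
  logged count rather than aborting a genome-wide run.
* A constant raw z-score vector (e.g. a table harmonized against
  itself) is a standardization error, surfaced as such.
* All simulation is seeded; identical configurations give byte-identical
  outputs.

## The synthetic generator

`simulate_pair()` emulates the statistical structure the test assumes:
per-SNP estimates $\hat\beta_k \sim N(\beta_k, se_k^2)$ with
$se_k = 1/\sqrt{2 n_k f (1-f)}$ (the quantitative-trait large-sample
formula, chosen for analytic transparency over a case-control
effective-N variant) and cross-study noise correlation
$\rho^\* = n_o/\sqrt{n_1 n_2}$ imposed analytically through a bivariate
normal. Frequencies are uniform on [0.05, 0.5]; causal SNPs are a small
minority, `shared` (equal true effects) or `opposite` (equal
standardized magnitude $|\beta|/se$ drawn from `effect_scale`, opposite
signs); flags inject allele swaps and palindromic SNPs so harmonization
is exercised, and a companion `simulate_replication()` draws a
replication study from the trait-2 true effects.

In the full-overlap limit $n_1 = n_2 = n_o$ the generator produces
$\rho^\* = 1$, which corresponds to shared phenotype noise as well as
shared samples — i.e. literally the same study twice.

What the generator does **not** emulate, and what passing tests
therefore do not establish about real data: LD between SNPs (all SNPs
are independent; real clumps span many correlated SNPs, and distance
thinning is only a proxy for LD pruning), realistic allele-frequency
spectra, population stratification or other confounding inflation,
case-control ascertainment effects on SEs, cross-SNP heterogeneity in
overlap, and indels/multi-allelic sites. The published four-locus
worked example bundled in `inst/extdata` covers the arithmetic on real
statistics, but the full-scale discovery requires the original
summary-statistics releases.

## Problem sizes used in validation

The test-suite and acceptance checks use 50,000 SNPs × 10 seeds per
grid point for $\rho$ recovery ($\rho^\* \in \{0, 0.25, 0.5\}$, mean
within ±0.02), 100,000 null SNPs for type-I calibration at
$\alpha = 0.05$ (binomial 99% band) with deflation of the uncorrected
classical test below 0.04 at $\rho^\* = 0.5$, and 10 seeds × 20,000
SNPs with 20 antagonistic + 20 shared causal SNPs at $|\beta|/se = 6$
for selection power (≥ 18/20 recovered, zero shared-class false
selections). The `analysis/` drivers use a 100,000-SNP pair at
$n_1 = 30{,}000$, $n_2 = 120{,}000$, 15,000 shared samples
($\rho^\* = 0.25$) — sizes that put the per-SNP SEs in the
0.003–0.019 range typical of large psychiatric GWAS while keeping every
script re-runnable in seconds.

## Limitations

The method inherits every bias of its inputs: technical artifacts that
inflate one GWAS masquerade as differential signal, which is why
replication triage is part of the pipeline rather than an afterthought.
$\rho$ is assumed homogeneous genome-wide. The composite rule's nominal
thresholds are conventions, not optimized quantities. And the
differential z-scores printed in published lead-SNP tables are not
exactly recoverable from betas and SEs alone — they depend on the
unpublished $\rho$ and standardization constants — so the reproducible
surface on real statistics is the z→p consistency and the triage
partition, not the z values themselves.
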