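---
title: "Fine-mapping and cumulative risk modeling in admixed case-control studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping and cumulative risk modeling in admixed case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixfine)
```

## The problem

Genome-wide association studies are run predominantly in cohorts of
European ancestry, and the "index" variant reported at each risk locus is
rarely the functional allele itself — it is a marker correlated with it in
the discovery population. In an admixed population such as African
Americans (roughly 80% African / 20% European ancestry on average), that
correlation can be much weaker: the index marker may fail to replicate even
where the underlying biology is shared. Fine-mapping in the admixed sample
— testing every genotyped and imputed variant around each index signal,
with ancestry carefully adjusted for — can recover a better marker of the
functional allele and, aggregated over loci, a better polygenic risk-allele
score.

`admixfine` implements that workflow end to end for case-control data:

1. **QC**: call-rate/MAF/replicate-concordance filters; method-of-moments
   identity-by-descent (IBD) relatedness inference with a within-1-SD
   classification rule; degree-based pruning of related samples.
2. **Ancestry**: genotype PCA for global ancestry with a 4-SD outlier
   rule on the first two eigenvectors; region-averaged local ancestry
   (expected European-chromosome count in [0, 2]) consumed as a covariate.
3. **Association**: per-variant logistic trend tests (1-df Wald) with
   age/study/eigenvector/local-ancestry adjustment; genotype-class ORs;
   Cochran's Q heterogeneity by study.
4. **LD and tagging**: composite-LD r², EM-based D′, ±250 kb windows with
   D′-block extension, greedy tag-SNP selection, and the two-tier
   significance thresholds derived from tag counts.
5. **Fine-mapping**: stepwise selection under the two-tier thresholds, a
   dense-region multi-signal mode, conditional tests, and
   variance-explained diagnostics.
6. **Risk score**: the unweighted risk-allele count, per-allele and
   control-quartile ORs with family-history stratification, a case-only
   severity test, and the closed-form fraction of familial relative risk
   explained.

Because no individual-level study data can ship with a package, every
stage is exercised against a synthetic admixed-cohort generator whose
study conditions (sample sizes, effect sizes, divergence, LD geometry) are
fixed once, in code, and used identically by the test suite and the
reproduction script.

## The synthetic admixed cohort

The generator composes, per individual, two mosaic haplotypes over a pair
of ancestral panels:

* **Ancestral panels.** Two populations share a variant map and a block
  partition. Per-population allele frequencies follow a Balding–Nichols
  model around common ancestral frequencies: for divergence $F$ the
  population frequency is Beta-distributed with mean $p$ and variance
  $F\,p(1-p)$. The default $F = 0.15$ is a realistic European–West
  African divergence. Within a block, haplotypes are drawn from a small
  founder set (2–8 founders), which gives high, controllable within-block
  LD; blocks are independent. This founder construction — rather than a
  coalescent simulation — is deliberate: the fine-mapping tests need exact
  control of the r² between designated index and causal variants, and of
  how that r² differs between the two panels. Single-variant blocks use
  two founders with weights $(1-p, p)$, making the declared frequency
  exact.
* **Admixture.** Each haplotype switches ancestry along the variant-index
  coordinate as a Poisson process (default 6 expected switches per
  chromosome-scale map; 0.05 for sub-megabase regional simulations), with
  each tract's ancestry drawn Bernoulli($\theta$); the default
  $\theta = 0.2$ European fraction matches the admixed population being
  emulated. The emitted local-ancestry track is the *true* per-variant
  count of population-1 chromosomes, so local-ancestry adjustment can be
  tested without re-implementing an inference tool (local ancestry is an
  input contract here, not an inference).
* **Observed data.** Typed variants emit integer genotypes with a
  missing-call rate; a configurable fraction of variants is emitted as
  "imputed" continuous dosages: true dosage plus Gaussian noise, clipped
  to [0, 2], with the noise scale calibrated by bisection so the squared
  correlation with the true dosage hits the target Rsq (clipping would
  otherwise push the realized quality above the closed-form solution).
  The per-variant Rsq metadata carries that target, playing the role of
  an imputation tool's quality estimate.
* **Phenotypes.** Case status follows a logistic model in the causal
  dosages plus age and study effects, with the intercept solved
  numerically so the pre-ascertainment prevalence matches the configured
  value (default 0.1). Case-control ascertainment is by rejection
  sampling in batches. Family history is linked to case status with a
  default odds ratio of 1.55 — the familial relative risk the risk-score
  analysis decomposes — and a severity label (advanced vs non-advanced)
  is assigned to cases only.
* **Relatives.** Injected pairs (duplicate/MZ, parent-offspring, full and
  half siblings) are built by copying or transmitting parental
  haplotypes. Transmission applies Poisson crossovers (default 3 per
  meiosis) along the variant index rather than whole-haplotype passing,
  so full siblings' genome-averaged IBD concentrates near 0.5 and the Z
  vectors of each relationship class are canonical — which is what the
  classification rule needs ground truth for.

What the generator does **not** emulate: coalescent/demographic realism,
recombination-map-aware tract lengths, genotyping batch effects,
population-specific imputation error structure, or X-chromosome data.
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery under a controlled admixture model, not performance
on any particular real cohort.

## Statistical procedures and their parameters

**IBD relatedness.** For each pair, identity-by-state counts over typed,
jointly non-missing, polymorphic variants are inverted through the
expected IBS-given-IBD distribution (a function of allele frequencies) to
give $(Z_0, Z_1, Z_2)$, clipped to $[0,1]$ and renormalized. Allele
frequencies default to the full post-filter sample, cases included; this
matches common practice but, in an admixed sample, ancestry-induced
frequency stratification biases pairs toward apparent relatedness — the
package therefore exposes the frequencies as an argument, and the demo
workflow LD-prunes markers (r² < 0.2) before screening. The
classification rule "within 1 SD of the expected Z" needs a definition
of that SD; it is
a single configurable per-component tolerance, default 0.1. A pair is
labelled with a relationship only if *every* component matches; multiple
matches resolve by Euclidean distance. Pruning removes the
maximum-degree sample repeatedly (ties and isolated pairs by a seeded,
self-contained random stream, so results are reproducible and do not
disturb the session RNG).

**PCA.** Dosages are standardized by $2\hat p$ and
$\sqrt{2\hat p(1-\hat p)}$, missing values mean-imputed for the
decomposition only, and the sample eigenvectors computed by SVD. Sign is
fixed by making each eigenvector's first-sample coordinate non-negative.
Ten eigenvectors are the default adjustment in single-variant models; the
stepwise models default to the first eigenvector only. These two defaults
are deliberately independent settings: the procedures being reproduced
used both conventions in different places, and the package does not
silently reconcile them.

**Association.** `trend_test()` is a maximum-likelihood logistic fit with
a 1-df Wald chi-square on the per-allele log OR; imputed variants enter
as continuous dosages (standard dosage practice), and variants with
imputation Rsq < 0.3 are excluded before testing. Single-variant models
use complete cases for that variant; the stepwise machinery instead
preserves the sample size by mean-filling no-calls, each matching the
procedure it reproduces. Constant dosages are skipped with a reason,
quasi-separation is flagged rather than silently reported.
Heterogeneity by study is Cochran's Q over per-stratum fits with
inverse-variance weights — the underlying test is not named in the
source material, and Q over stratified fits is the reproducible,
stratification-safe choice.

**Windows, correlated sets, tags, thresholds.** Fine-mapping windows are
$(pos - 250\,\mathrm{kb},\ pos + 250\,\mathrm{kb}]$ around each index
variant (exactly 500,000 positions, 1-based closed), extended to cover
any containing D′-defined LD block and merged when overlapping. The
index-correlated set is every window variant with r² ≥ 0.2 to an index
variant; r² is the squared Pearson correlation of dosages (composite LD,
valid for unphased/imputed data), while D′ uses EM haplotype frequencies
from the 3×3 genotype table. Thresholds at the stated cutoffs are
inclusive (the source mixes strict and non-strict inequalities; one
convention had to be fixed and it is configurable). Greedy tagging picks
the variant covering the most uncovered members (r² ≥ 0.8; a variant
covers itself; ties toward the lower position). The lenient threshold is
$\alpha_a = 0.05/(\text{tag count})$ — by default the cross-region
average count, matching a single global threshold of the ~0.004 scale,
with a per-region mode available — and the stringent threshold for novel
signals is $\alpha_b = 0.05/(\text{total tags across regions})$, about
$5.6\times10^{-6}$ at the emulated study's scale of ~8,900 tags.

**Stepwise selection.** Forward selection with backward elimination after
each entry (entry = retention threshold): each step adds the candidate
with the smallest Wald p in the current joint model if below its
applicable threshold ($\alpha_a$ for index-correlated candidates,
$\alpha_b$ for novel ones), then drops any selected variant whose p has
risen above its own threshold. Whether the procedure being reproduced
also eliminated backward is unknown; `backward = FALSE` switches to
forward-only. Exactly collinear candidates are skipped with a reason;
ties break toward the smaller p, then the lower position, so reruns are
byte-identical. The dense-region mode restricts the candidate pool to
variants with single-variant p < 0.05 and applies a single retention
threshold of 0.001 — the convention for a region known to harbor
multiple independent signals.

**Risk score.** The score is the unweighted sum of risk-allele dosages
over the score variants, with missing genotypes contributing twice the
control risk-allele frequency. Quartile cutpoints are control-sample
quantiles with linear interpolation (`stats::quantile` type 7 — the
printed cutpoints of the study being emulated, e.g. 37.5/40.0/42.7, show
interpolation was used). Stratified quartile ORs use
family-history-negative Q1 as the common reference. The familial
decomposition is exact algebra: with first-degree-relative correlation
$r = 0.5$, the expected count in relatives of cases is
$m_{rel} = m_0(1-r^2) + m_1 r^2$; the score-implied familial relative
risk is $\rho_{score} = \exp(\log \lambda \cdot (m_{rel}-m_0))$, and the
fraction explained is $(\rho_{score}-1)/(\rho_{obs}-1)$. Note the
formula weights the mixture by $r^2 = 0.25$ even though the relative
correlation is stated as $r = 0.5$; it is implemented exactly as
printed, with $r$ exposed as a parameter, because the statistical
justification of the $(1-r^2)/r^2$ weighting versus a $\rho$-weighted
conditional mean is not given in the source and guessing intent would be
worse than documenting the ambiguity. Both a full-precision path and a
2-decimal display path (rounding $m_{rel}$, $\Delta$ and $\rho_{score}$
before each subsequent step) are returned, the latter reproducing the
canonical worked example digit for digit:

```{r familial}
familial_risk_explained(m0 = 30.66, m1 = 32.13, lambda = 1.17,
                        rho_obs = 1.55, r = 0.5)
```

## Numerical choices and degenerate inputs

* Logistic fits are `stats::glm` ML fits; coefficients beyond ±30 or
  non-convergence raise a separation error rather than returning a
  misleading Wald interval. A Firth-style fallback is deliberately not
  the default.
* Wald CIs are $\exp(\beta \pm 1.96\,se)$ and the trend p is the 1-df
  chi-square of $(\beta/se)^2$ (identical to the two-sided normal p).
* The EM for haplotype frequencies iterates only the double-heterozygote
  split (the one ambiguous class), to $10^{-10}$; monomorphic input gives
  `NA` D′.
* `variance_explained_by_others()` uses an SVD pseudo-inverse, so exact
  collinearity among the explanatory dosages is handled, and clips to
  [0, 1].
* Conditioning on an exact proxy (r² = 1) of the tested variant returns
  $\beta = 0$, $p = 1$ with a `collinear` flag: there is no residual
  information, and an aliased fit would otherwise silently drop the
  wrong column.
* PCA on constant data, windows with no local-ancestry estimates, empty
  dosage matrices, unreachable prevalence in the simulator, and unknown
  relationship labels are all errors with named subjects, not warnings.

## Problem sizes used by the tests and the reproduction script

The calibration experiment uses 1,000 null variants in 1,000 cases /
1,000 controls; the fine-mapping recovery experiment runs 100 replicates
of a 30-variant region in 3,000/3,000 admixed samples (index–causal
r² of 0.9 in the European-like panel versus 0.05 in the African-like
panel, causal per-allele OR 1.3, the scale at which the emulated study
had ~80% power); the score experiment runs 100 replicates of 27 unlinked
variants at a true per-allele OR of 1.17 in ~3,400/~3,300 samples. The
demonstration workflow under `analysis/` uses a deliberately smaller
cohort (600/600, 800 variants) so the whole sequence runs in about a
minute. These sizes are the package's own choices: large enough that the
stated coverage and recovery rates are meaningful, small enough that a
full run is routine on a laptop.

## Known limitations

* IBD estimation uses global allele frequencies; in admixed samples this
  overstates relatedness for pairs sharing ancestry (the demo mitigates
  with LD pruning, and unrelated-pair tests assert only $Z_0 > 0.8$).
  Ancestry-conditional frequencies would remove the bias but are not in
  scope.
* Single-marker tagging only; multi-marker (haplotype) tagging is
  deliberately out of scope, so derived tag counts are conservative.
* The simulator's ancestry switches are memoryless along the variant
  index; tract-length distributions are not calibrated to generations
  since admixture.
* Power calculations, sex checks from array intensities, projection onto
  external reference panels, and Bayesian fine-mapping (credible sets,
  colocalization) are out of scope.
* The score analysis assumes unlinked variants with independent,
  same-scale effects — the `independence_check()` diagnostic quantifies,
  but cannot repair, departures from that assumption. Selecting score
  variants by their observed effects in the same sample (as the demo
  does) inflates the apparent fraction of familial risk explained
  (winner's curse); the headline familial-risk numbers reproduced by the
  package come from fixed, externally printed inputs instead.
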