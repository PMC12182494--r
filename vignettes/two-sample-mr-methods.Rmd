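---
title: "Two-sample Mendelian randomization with microMR: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with microMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microMR)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for an exposure (here, the abundance of a gut-bacterial taxon)
against an outcome (childhood neuroblastoma status) measured in a different
sample. For variant $j$, let $\hat\gamma_j$ (SE $\sigma_{xj}$) be its
estimated per-allele effect on the exposure and $\hat\Gamma_j$ (SE
$\sigma_{yj}$) its effect on the outcome, both taken from published GWAS
summary statistics. Under the three instrumental-variable assumptions —
the variant is (1) associated with the exposure, (2) independent of
confounders of the exposure–outcome relation, and (3) affects the outcome
only through the exposure — each Wald ratio

$$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j, \qquad
  \widehat{se}(\hat\beta_j) = \sigma_{yj} / |\hat\gamma_j|$$

estimates the same causal effect $\theta$ (a log odds ratio for a binary
outcome), and the inverse-variance-weighted (IVW) combination
$\hat\theta = \sum_j w_j \hat\beta_j / \sum_j w_j$, $w_j = 1/\widehat{se}_j^2$,
is the efficient meta-analytic estimate. The companion estimators trade
efficiency for robustness to assumption (3): MR-Egger regresses
$\hat\Gamma_j$ on $\hat\gamma_j$ with a free intercept (consistent under
InSIDE — instrument strength independent of direct effects — with the
intercept estimating average directional pleiotropy); the weighted median is
consistent while valid instruments carry more than half the weight; and the
weighted mode is consistent when the largest homogeneous cluster of ratios
is valid.

## Pipeline stages and their parameters

**Instrument selection.** Variants pass a strict p-value threshold
(default $10^{-5}$, the conventional relaxed cutoff for microbiome GWAS,
where genome-wide significant hits are scarce) and are then thinned by
greedy LD clumping: process variants in ascending p-value order, retain the
current index variant and remove all others on the same chromosome within
10,000 kb whose $r^2$ with it is $\ge 0.001$. Ties on p-value break by
chromosome, position, then identifier, so the output is invariant to input
row order. A variant missing from the LD matrix is an error, not an implied
independence — silent assumptions corrupt instrument sets. The LD matrix is
an input here; the package does not compute LD from genotype panels.

**Harmonization.** Outcome effects are re-expressed on the exposure's
effect allele. Allele-order swaps negate the outcome beta and reflect its
allele frequency; allele pairs that only match after complementing are
treated as strand flips and re-checked. Palindromic variants (A/T, C/G)
carry no orientation information in their labels, so orientation is
inferred from allele frequencies: both frequencies must lie outside
$0.5 \pm w$ (default window $w = 0.08$, a conservative standard choice);
same-side frequencies mean agreement, opposite sides mean a flip, and
anything else — including a missing frequency — drops the variant with a
recorded reason. Dropping ambiguous palindromic variants loses a little
power but cannot inject sign errors, which would be far more damaging to a
ratio estimator.

**Estimation.** The IVW default is multiplicative random effects: the
fixed-effect SE is inflated by $\sqrt{\max(1, Q/(k-1))}$, which reduces
exactly to the fixed-effect analysis when instruments are homogeneous
(as they are for the built-in worked example, where $Q = 1.14 < 4$).
MR-Egger orients pairs so exposure effects are non-negative (the estimator
is not invariant to allele re-coding otherwise), weights by
$1/\sigma_{yj}^2$, and rescales coefficient SEs to a residual dispersion of
$\max(1, \hat\sigma^2)$ so under-dispersion never shrinks them below the
fixed-effect scale; its p-values use the $t$ distribution with $k-2$ df.
IVW, median and mode p-values use the normal reference, which together with
the CI multiplier 1.959964 reproduces the worked example's printed p-value
0.010775 and CI bounds to printed precision. The weighted median
interpolates the ordered ratios at standardized cumulative weight
$p_j = (S_j - w_j/2)/S_k = 0.5$; the weighted mode maximizes the weighted
Gaussian kernel density with bandwidth `bandwidth_factor` times a modified
Silverman scale $0.9\,\min(\mathrm{sd}_w, \mathrm{mad}_w)\,k^{-1/5}$,
located on a 512-point grid over the ratio range $\pm 3$ bandwidths and
refined by golden-section search; identical ratios are a degenerate case
returning the common value. Both bootstrap SEs (default 5000 resamples,
seed required) redraw each ratio from $N(\hat\beta_j, \widehat{se}_j)$
with weights held fixed.

**Sensitivity.** Cochran's $Q = \sum_j w_j(\hat\beta_j - \hat\theta)^2$
against the fixed-effect estimate, $\chi^2_{k-1}$ upper tail; leave-one-out
always re-fits fixed-effect IVW regardless of the headline mode so rows are
comparable across subsets; funnel and single-SNP outputs are emitted as
data tables rather than plots, keeping them bit-exactly testable.

**Annotation.** Nearest gene on the variant's chromosome within a window
(default 10 kb), distance measured to the nearer interval endpoint and
reported in floor-kilobases, `GENE(0)` when inside. Functional-consequence
calls (missense and the like) require a variant-effect database and are out
of scope. The bundled gene intervals (`inst/extdata/genes_synthetic.bed`)
are a synthetic fixture: MUC4 follows its reference span, the PELI2
interval is a stand-in constructed to contain the worked example's
position.

## The synthetic GWAS generator

`simulateGWASPair()` emulates exactly what two-sample MR consumes — paired
summary statistics — without individual-level genotypes. True instrument
effects $\gamma_j$ are drawn from $N(0, 0.08^2)$ truncated at
$|\gamma| \ge 0.02$, so that at the default sample sizes (20,000 per
sample) instruments can realistically clear the $10^{-5}$ selection
threshold; observed effects add Gaussian noise with the standard GWAS
standard error $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$, and outcome
effects are $\theta\gamma_j + \alpha_j$ plus noise, with direct effects
$\alpha_j$ nonzero only for a configured fraction of invalid instruments.
Directional pleiotropy is defined on the exposure-increasing allele coding
(the sign of $\gamma_j$): the arbitrary choice of effect allele otherwise
makes "directional" meaningless, and with symmetric $\gamma$ a
naively-coded directional effect would cancel out of both the IVW bias and
the Egger intercept. InSIDE violation is implemented as
$\alpha_j = \kappa\gamma_j + \text{noise}$, a simple explicit mechanism
coupling strength and direct effect. LD is block-diagonal with constant
within-block correlation; blocks sharing a chromosome are placed 20 Mb
apart so clumping windows never straddle blocks. Binary-outcome effects are
simulated directly on the log-odds scale with Gaussian noise.

What the generator does *not* model — and what passing tests therefore do
not establish about real data: realistic human LD maps, case/control
ascertainment, sample overlap between the two GWAS, winner's-curse bias
from selecting instruments in the same sample they were estimated in,
taxonomic nesting of microbiome traits across ranks, and non-Gaussian
effect-size distributions. Tests against the generator validate the
estimators' algebra and their robustness properties under the stated model,
not the epidemiological validity of any particular application.

## Numerical and design choices

- **Estimands at finite precision.** With noisy ratios the weighted median
  converges to the mixture quantile at cumulative weight 0.5, which sits
  roughly $0.97\,se_j$ from $\theta$ when 40% of weight is invalid and
  shifted upward; consistency claims are therefore demonstrated at small
  per-ratio SEs, where that offset is within tolerance. Similarly the Egger
  intercept's estimand is the mean direct effect across *all* instruments
  ($\text{prop}_{\text{invalid}} \times$ the pleiotropy mean), which the
  Monte-Carlo tests target.
- **Wald-ratio SE** uses the first-order delta method only (no
  $\sigma_{xj}$ term); this matches how the worked example's printed per-SNP
  SEs combine into the printed summary row, and is a documented limitation
  (it understates uncertainty for weak instruments).
- **P-value floors.** Simulated p-values are floored at `1e-300` to keep
  them in $(0,1]$ at large sample sizes, as real GWAS tables print tiny
  nonzero values.
- **Validation is total.** File readers reject malformed rows with a
  per-row report (`rejected()`), never silently; LD matrices must be
  symmetric to $10^{-8}$ and are clamped to $[0,1]$; degenerate pipeline
  states (zero instruments after selection, all pairs dropped) raise typed
  conditions that the command-line wrapper maps to distinct exit codes.
- **Reproducibility.** Every stochastic component (the generator, both
  bootstraps) takes an explicit seed; `mrEstimate()` derives per-method
  seeds from one master seed so adding a method never perturbs another's
  draws, and library code restores the caller's RNG state.
- **Problem sizes.** The shipped test suite and acceptance script use 200
  replicates for parameter recovery (50 instruments, $n = 20{,}000$ per
  sample), 100 replicates for the pleiotropy scenarios, 2000 replicates for
  the Q-test calibration check, and exhaustive (all-subset) clumping oracles
  at 10–12 variants — sizes at which Monte-Carlo error is small relative to
  the tested tolerances while the whole suite runs in well under a minute.

## Known limitations

No proxy-SNP lookup for variants absent from the outcome GWAS; no LD
computation from reference panels; no MR-PRESSO outlier removal, Steiger
filtering, or multivariable MR; no variant-effect prediction. With three
instruments MR-Egger has a single residual degree of freedom and its
estimates are reported but essentially uninformative.
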