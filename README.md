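# microMR

Two-sample Mendelian randomization (MR) for GWAS summary statistics, built
around the question of whether gut-microbiota abundance causally affects
childhood neuroblastoma risk. MR uses genetic variants as instrumental
variables: if variants that shift the abundance of a bacterial taxon also
shift disease risk, and the usual instrumental-variable assumptions hold
(association with the exposure, independence from confounders, no direct
path to the outcome), the per-variant effect ratios estimate a causal
effect — without individual-level data, using only published per-SNP
association statistics from two non-overlapping samples.

The package implements the full pipeline:

- **Instrument selection** — p-value threshold filtering (default
  p < 1e-5) followed by greedy LD clumping (retain the lowest-p variant,
  remove neighbours with r² ≥ 0.001 within a 10,000 kb window).
- **Harmonization** — align the outcome sample's effects to the exposure's
  effect allele, resolving allele-order swaps, strand flips, and palindromic
  (A/T, C/G) variants via allele frequencies.
- **Four estimators** over the per-SNP Wald ratios
  `b_j = beta_out_j / beta_exp_j`, `se_j = se_out_j / |beta_exp_j|`:
  - *IVW*: inverse-variance weighted mean, `b = Σ w_j b_j / Σ w_j` with
    `w_j = 1/se_j²` (fixed or multiplicative random effects);
  - *MR-Egger*: weighted regression of outcome on exposure effects with a
    free intercept estimating average directional pleiotropy;
  - *weighted median*: consistent while ≥ 50 % of the weight comes from
    valid instruments;
  - *weighted mode*: maximizer of the weighted kernel density of the
    ratios.
- **Sensitivity analyses** — Cochran's Q heterogeneity test, leave-one-out
  re-estimation, single-SNP tables, funnel-plot data.
- **Annotation** — nearest-gene lookup for instrument SNPs from BED-like
  gene intervals.
- **Synthetic GWAS generator** — paired exposure/outcome summary statistics
  with known causal effect, configurable pleiotropy (directional, InSIDE-
  violating), LD blocks, palindromic variants and allele-order scrambling,
  so every stage is testable against ground truth.

## Worked example

The package ships the five per-SNP estimates for the *Erysipelotrichia*
instruments against neuroblastoma as a built-in fixture:

```r
library(microMR)
fx <- erysipelotrichiaFixture()
mrIVW(fx, mode = "fixed", exposure = "Erysipelotrichia")
#> MRResult [IVW] Erysipelotrichia
#>   nsnp = 5, b = -0.990768 (se 0.388551), p = 0.0107752
#>   OR = 0.371291 (95% CI 0.173372 - 0.795152)

cochranQ(fx)
#>   method        Q df         p
#> 1    IVW 1.135302  4 0.8886315

leaveOneOut(fx)
#>   omitted_snp nsnp          b        se           p
#> 1   rs1074800    4 -0.9338950 0.4329299 0.030993925
#> 2   rs2300774    4 -1.0652961 0.4405745 0.015607351
#> 3  rs35161940    4 -0.8199279 0.4377231 0.061045485
#> 4   rs4078432    4 -1.1168836 0.4298587 0.009369819
#> 5   rs8003149    4 -1.0146867 0.4312602 0.018630594
```

The IVW odds ratio of 0.37 (95 % CI 0.17–0.80, p = 0.011) indicates a
protective association; Cochran's Q (p = 0.89) shows no heterogeneity among
the five instruments, and every leave-one-out estimate stays negative, so no
single SNP drives the result.

An end-to-end run on simulated data:

```r
sim <- simulateGWASPair(simulationConfig(n_snps = 60, theta = 0.3, seed = 7))
res <- runPipeline(sim$exposure, sim$outcome, sim$ld,
                   p_threshold = 1e-3, n_boot = 1000, seed = 7)
estimate(res$results$ivw)   # close to the simulated causal effect 0.3
```

A thin command-line front end (`inst/scripts/mr.R`) exposes `run`,
`simulate` and `fixture` subcommands over the same functions.

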