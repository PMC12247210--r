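---
title: "Two-step Mendelian randomization mediation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step Mendelian randomization mediation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization treats genetic variants as
instruments for a modifiable exposure. For instrument $j$ the exposure
study supplies $\hat\beta_{Xj}$ (with $se_{Xj}$) and an independent
outcome study supplies $\hat\beta_{Yj}$ (with $se_{Yj}$); under the
instrumental-variable assumptions (relevance, independence from
confounders, no direct path to the outcome) each Wald ratio
$\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same causal effect, and
the estimators in this package are different ways of combining those
ratios that trade efficiency against robustness to assumption
violations:

* **IVW** — inverse-variance weighted mean of the ratios, equivalently
  weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through the
  origin with weights $1/se_Y^2$. Efficient when all instruments are
  valid; biased if any pleiotropy is directional.
* **MR-Egger** — the same regression with a free intercept. The slope
  remains consistent under directional pleiotropy if instrument
  strength is independent of the direct effects (InSIDE); the
  intercept estimates the average direct effect and its test is the
  pleiotropy diagnostic. Inference uses $t_{k-2}$ with a residual
  scale bounded below by 1.
* **Weighted median** — the ratio at which cumulative inverse-variance
  weight crosses one half; consistent while valid instruments carry
  more than half the weight.
* **Mode-based estimators** — the normal-kernel density mode of the
  ratios (simple: equal weights; weighted: inverse-variance weights),
  consistent when the largest homogeneous cluster is valid.

For a binary outcome all effects are log-odds; `beta_to_or()` maps
them to odds ratios as $e^\beta$ with bounds $e^{\beta \pm 1.96\,se}$.

Two-step mediation composes three such analyses. With
$\beta_1$ (exposure → mediator), $\beta_2$ (mediator → outcome) and
$\beta_{all}$ (total exposure → outcome), the mediated (indirect)
effect is the product $\beta_1\beta_2$ and the mediated proportion is
$\beta_1\beta_2/\beta_{all}$. The approach assumes linear, additive
effects without exposure–mediator interaction; a mediated effect whose
sign opposes the total effect produces a negative proportion, which
the package reports as-is with a suppression flag rather than
truncating.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 5e-8 | genome-wide significance for instrument selection |
| `r2_max`, `window_kb` | 0.001, 10000 | LD clumping: maximum squared correlation inside the window (kb) |
| `f_min` | 10 | weak-instrument cutoff on the single-SNP F statistic |
| `palindrome_policy` | `"remove"` | A/T & C/G handling; `"infer_by_eaf"` keeps them when both allele frequencies are > 0.08 from 0.5 on the same side |
| IVW `mode` | multiplicative random | fixed-effect se inflated by $\max(1,\sqrt{Q/(k-1)})$ |
| `phi` | 1.0 | mode-estimator bandwidth multiplier on $0.9\min(sd, mad)k^{-1/5}$ |
| `n_boot` | 1000 | bootstrap draws for median/mode standard errors (seeded) |
| PRESSO `n_sim` | 1000 | simulated null datasets; per-SNP outlier p is Bonferroni-corrected, so resolving outliers at level $\alpha$ requires `n_sim` well above $k/\alpha$ |
| `p_screen_1`, `p_screen_2` | 0.05, 0.01 | the two IVW screening passes of the mediator cascade |
| `fdr_level` | 0.05 | level at which BH q-values are reported (reported, not gating) |

Defaults mirror the conventions of current two-sample MR practice:
multiplicative random effects is the dominant IVW flavour when
heterogeneity cannot be excluded, and the fixed-effect estimate is
always reported alongside. The robustness verdict requires Cochran's
Q, the Egger intercept and the PRESSO global test all at $p \ge 0.05$
(inclusive); leave-one-out flags and the PRESSO distortion test are
computed but advisory, since they are qualitative checks rather than
accept/reject rules.

## Numerical choices

* Wald-ratio standard errors are first order, $|se_Y/\hat\beta_X|$,
  ignoring exposure-side error (the no-measurement-error
  approximation); the F > 10 gate upstream is what licenses it.
* Confidence bounds use the literal 1.96 multiplier (and published
  CIs are inverted as width/3.92), matching how such tables are
  printed; MR-Egger uses the $t_{k-2}$ quantile instead, an honesty
  adjustment at small $k$.
* The mediated-effect CI defaults to the standard product delta
  method, $se^2 = \beta_2^2 se_1^2 + \beta_1^2 se_2^2$. A second
  pairing, `paper_compat` ($\beta_1^2 se_1^2 + \beta_2^2 se_2^2$), is
  provided because published mediation tables are sometimes computed
  with each coefficient paired to its own standard error; the two
  coincide when $|\beta_1| \approx |\beta_2|$. The default remains the
  delta method; the replay reader uses `paper_compat` so bundled
  published tables reproduce exactly.
* The mediated-proportion CI divides the mediated-effect bounds by
  $\beta_{all}$, holding the total effect fixed; dividing by a
  negative total reverses bound order, and both the raw orientation
  and a sorted form are reported.
* Clumping is greedy on ascending p with ties broken on SNP id, so the
  result is invariant to input row order; a SNP is excluded only when
  both the r² and the same-chromosome window condition hold.
* Mode estimation maximizes the kernel density with a 512-point grid
  refined by local optimization; when all ratios coincide the common
  ratio is returned directly (zero bandwidth).
* Weighted-median and mode bootstraps draw over pairs in canonical
  SNP-id order, so the seeded standard error does not depend on row
  order.
* Degenerate inputs fail loudly and specifically: zero exposure betas,
  fewer than 3 (Egger/median/modes) or 4 (PRESSO) instruments, empty
  allele intersections, and zero surviving instruments all raise
  errors that name the stage (selection attaches a per-stage attrition
  table).

## The synthetic-data generator

`simulate_study()` emulates the statistical structure of a three-study
summary-data design: an exposure GWAS, a mediator GWAS with its *own*
genome-wide-significant loci (as real metabolite GWAS have —
`n_snps_mediator` variants acting on the mediator directly), and a
binary-outcome GWAS, in three mutually independent samples. Summary
statistics are generated analytically — observed effect = true
marginal effect + normal noise at the single-SNP regression standard
error $1/\sqrt{2f(1-f)\,n}$, scaled by $1/\sqrt{\varphi(1-\varphi)}$
for a binary trait of prevalence $\varphi$ — rather than via
individual-level genotypes; `simulate_study_individual()` is the slow
genotype-level companion used to validate those moments.

Defaults are the package's reference study: 50 exposure instruments
(and 50 mediator instruments) jointly explaining 5% of trait variance,
100,000 participants per study, $\alpha = 0.5$, $\gamma = 0.4$,
$\theta = 0.1$ (total 0.30, proportion 2/3), outcome prevalence 0.017
— the case fraction of a typical end-stage renal-failure GWAS.
Pleiotropic direct effects are planted in the *oriented* frame
(relative to the allele that raises the exposure): a constant offset
in raw outcome-effect space would cancel across randomly signed
exposure effects and act as balanced, not directional, pleiotropy.

Two fixture scenarios were designed with explicit power calculations:

* *directional-pleiotropy* uses pervasive oriented pleiotropy (98% of
  instruments, mean 0.08, sd 0.01). A 30%-mixture scenario gives the
  Egger intercept test almost no power, because the residual scale
  inflates with the same planted effects that create the intercept —
  a known property of the test; the pervasive scenario is its proper
  positive control (measured power ≈ 84%).
* the weighted-median robustness scenario contaminates 30% of
  instruments with mean direct effect 0.3 — "large" is relative to the
  per-SNP ratio noise (≈ 0.8 here, driven by the low-prevalence binary
  outcome), and smaller contamination is simply absorbed into that
  noise for every estimator.

What passing these simulations does **not** show: the generator has
independent (or simple block-LD) instruments, exact normal sampling
noise, no sample overlap, no winner's curse, and no allele-frequency
mismatch between studies. Real GWAS data violate all of these to some
degree, so green tests certify the arithmetic and the operating
characteristics under the stated model, not robustness to every
real-data pathology.

## Simulation summaries for ratio estimands

Replicate-level mediated proportions are ratios of noisy estimates;
their per-replicate mean is biased upward by roughly
$(se_{all}/\beta_{all})^2$ (≈ 13% under the reference design) even
when every input is unbiased. The recovery checks therefore summarize
the proportion as the ratio of *mean* recovered effects across
replicates, with a delta-method Monte-Carlo standard error — the
standard stable summary for ratio estimands — while the total effect,
being linear, is summarized by its plain replicate mean. Problem sizes
used by the recovery checks (500 replicates of the reference design;
200 null replicates for the PRESSO type-I calibration) were chosen as
the smallest sizes at which the Monte-Carlo bands are meaningfully
narrower than the tolerances they certify.

## Known limitations

* No reference-panel LD: clumping requires an explicit LD matrix (an
  identity matrix is assumed for pre-pruned inputs).
* No multivariable MR, Steiger direction filtering, or
  multiple-simultaneous-mediator decomposition; one mediator per
  pathway.
* Mediated-proportion CIs do not propagate uncertainty in
  $\beta_{all}$ (deliberately, to match how such tables are printed);
  a fully propagated interval would be wider.
* VCF input, liftover and multi-allelic variants are out of scope;
  inputs are delimited text with a header.

## A compact run

```{r example, eval = FALSE}
sim <- simulate_study(sim_config(seed = 42))
iv  <- select_instruments(sim$exposure, ld = sim$ld)
hs  <- harmonize(iv, sim$outcome)
mr_all(hs, seed = 1)                    # all five estimators
sensitivity_report(hs, seed = 1)        # Q, Egger intercept, PRESSO, LOO, verdict
assemble_mediation(sim$exposure, list(m = sim$mediator), sim$outcome)
```
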