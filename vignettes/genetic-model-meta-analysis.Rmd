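---
title: "Pooling case-control SNP studies: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling case-control SNP studies: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The problem and the model

A biallelic SNP with alleles G and A yields three genotypes per subject. A
case-control study reports genotype counts for diseased cases and healthy
controls; `snpmeta` pools several such studies into a single association
estimate per *genetic contrast*:

* codominant **AA vs GG** and **GA vs GG** (the excluded genotype is dropped
  from the 2x2 table entirely),
* **dominant** (AA+GA vs GG),
* **recessive** (AA vs GA+GG).

The A-carrying category is always treated as "exposed", so an odds ratio
above 1 means the variant allele increases disease odds under that contrast.

Each study contributes a 2x2 table with cells $a, b, c, d$ (exposed cases,
exposed controls, unexposed cases, unexposed controls). The per-study effect
is the log odds ratio $\hat\theta_i = \ln(a_i d_i / b_i c_i)$ with Woolf
variance $v_i = 1/a_i + 1/b_i + 1/c_i + 1/d_i$.

**Heterogeneity.** With fixed inverse-variance weights $w_i = 1/v_i$ and
$\hat\theta = \sum w_i\hat\theta_i / \sum w_i$, Cochran's
$Q = \sum w_i(\hat\theta_i - \hat\theta)^2$ is $\chi^2_{k-1}$ under
homogeneity. The DerSimonian-Laird moment estimator is
$\hat\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i)\}$,
and $I^2 = \max\{0, (Q - df)/Q\} \cdot 100$ is reported as the standard
companion even where source tables omit it.

**Model selection.** The pipeline follows the heterogeneity-gated rule common
in genetic-association meta-analyses: if the Q-test p-value is *strictly
greater* than `alpha_het` (default 0.05), pool with Mantel-Haenszel fixed
effects,
$\widehat{OR}_{MH} = \sum(a_i d_i/n_i) \big/ \sum(b_i c_i/n_i)$,
with the Robins-Breslow-Greenland variance for $\ln \widehat{OR}_{MH}$;
otherwise pool with DerSimonian-Laird random effects,
weights $w_i^* = 1/(v_i + \hat\tau^2)$ and CI
$\exp(\hat\theta^* \pm 1.96/\sqrt{\sum w_i^*})$. The selection is re-made
independently in every stratum and in every leave-one-out subset, because
each reduced pool is a complete meta-analysis in its own right. The method
actually used is recorded on every result and in the pipeline log.

**Hardy-Weinberg QC.** Control arms are tested against HWE with the 3-cell
Pearson chi-square on 1 df (allele frequency estimated from the data). The
chi-square form, rather than the exact test, reproduces the HWE column of
the bundled dataset on reconstructed counts to the printed precision.
Studies failing HWE are flagged, never dropped: the bundled seven-study
analysis retains its one HWE-deviant control series, and so does this
implementation.

**Publication bias.** `egger_test()` is the original unweighted OLS of the
standardized effect $\hat\theta_i/\sqrt{v_i}$ on precision $1/\sqrt{v_i}$;
the intercept's t statistic on $k-2$ df is the asymmetry test. This variant
(rather than the weighted one) was chosen because it is the classical
formulation and the default in the meta-analysis software generation the
bundled results came from. `begg_rank_test()` (Kendall correlation between
standardized deviates and variances, normal approximation with continuity
correction) is supplementary output; the bundled analysis only draws Begg
funnels. `funnel_data()` exports plottable points and pseudo-CI guide lines
rather than rendering figures.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha_het` | 0.05 | Q-test threshold gating fixed vs random pooling; fixed iff p > threshold, mirroring the source rule |
| `correction` | `"none"` | Haldane-Anscombe +0.5 on all four cells, applied only when a zero cell occurs; off by default because the bundled data have no zero cells, and silently correcting would change nothing there while masking sparse-data problems elsewhere. With `"none"` a zero cell is a named error |
| `tol` (reconstruction) | 0.02 | allowed drift of printed genotype proportions from 1; accommodates rows whose 3-decimal proportions sum to 0.999-1.001 |
| z quantile | `qnorm(0.975)` = 1.959964 | all intervals 95%, all tests two-sided |

## Count reconstruction

Published tables often print per-arm genotype *proportions*; integer counts
are rebuilt as `round(n * freq)` with a largest-remainder repair whenever the
rounded cells miss `n`. On the bundled dataset plain rounding already
balances all 14 arms (verified by test), and the repair path is exercised on
synthetic rows. A property test checks the result against an enumeration
oracle: the reconstruction attains the minimal possible maximum deviation
from `n * freq` over all integer triples summing to `n`.

## What the simulator emulates — and what it does not

`simulate_collection()` draws, per study: a control A-allele frequency `q`
uniform in `allele_freq_A_range`; control genotype probabilities from HWE
$(p^2, 2pq, q^2)$; a study-level shift $\delta \sim N(0, \tau^2)$ applied
multiplicatively (on the OR scale) to *both* non-reference genotypes; case
probabilities proportional to control probabilities times
$(1, OR_{GA}e^\delta, OR_{AA}e^\delta)$; and multinomial genotype counts per
arm. Truth records carry the generating probabilities and the analytic OR of
every contrast — for the codominant contrasts these equal
$OR_{AA}e^\delta$ and $OR_{GA}e^\delta$ exactly, while dominant/recessive
truths also depend on `q`.

Defaults state a world resembling the bundled studies: `k = 7`, case arms
40-700 and control arms 75-700 subjects, `q` in 0.27-0.60 (the observed
span of the seven control series), a 3:4 Asian:Caucasian mix, mostly
hospital-based controls, and no true effect (`OR = 1`, `tau = 0`). A single
global seed drives deterministic per-study substreams, so increasing `k`
extends a collection without reshuffling earlier studies.

Not emulated: linkage/LD structure, genotyping error, covariates,
selection/publication mechanisms, and non-HWE control populations. A green
calibration test therefore establishes correct statistical behaviour under
clean multinomial sampling — not robustness to genotyping artefacts, which
is precisely what the HWE QC flag is for on real data.

In calibration summaries (`run_simulation_study()`), CI coverage is scored
against the analytic per-study contrast OR, geometric-mean-averaged over
studies; for codominant contrasts with `tau = 0` that is exactly the
configured per-genotype OR, whereas for dominant/recessive it is a summary
of study-varying truths and should be read as approximate.

## Numerical choices and degenerate inputs

* Q-test calibration runs on the dominant contrast, whose cells are the
  largest, so the chi-square approximation of Q is cleanest at
  fixture-like arm sizes; the Egger null uses effect SEs 0.1-0.5, the range
  typical of the per-study Woolf SEs in this setting.
* `tau^2` is truncated at 0; when `Q <= k - 1`, DerSimonian-Laird pooling
  coincides with the fixed inverse-variance pool (tested).
* MH pooling itself uses raw cells (zeros tolerated inside the sums); a
  wholly degenerate set of tables (all `a*d` or all `b*c` products zero) is
  a named undefined-effect error.
* A monomorphic control arm returns HWE chi-square 0, p 1 — there is no
  polymorphism to test.
* Egger's regression refuses identical SEs (degenerate design matrix) with
  a named error; `simulate_null_funnel()` with an equal-SE grid exercises
  that path.
* Strata are closed enumerations ({Asian, Caucasian} x {Hospital,
  Population}), parsed case-insensitively; an unknown value is an error
  rather than a silent third stratum, because subgroup pooling over an
  open-ended label set would silently change the analysis.
* Presentation rounding (2 decimals for ORs/CIs, 3 for p-values) happens
  only in the human-readable `summary.txt`; all TSV outputs carry full
  precision.

## Known limitations

* Only the four genotype contrasts are implemented; no allele-count (G vs
  A) contrast, no meta-regression, no Hartung-Knapp adjustment, no REML or
  Paule-Mandel `tau^2`, no trim-and-fill.
* The heterogeneity-gated model switch is implemented because it is the
  rule stated by the source analysis; statistically it is known to distort
  conditional inference slightly, and users wanting a single prespecified
  model can call `pool_mantel_haenszel()` / `pool_dersimonian_laird()`
  directly.
* One published subgroup cell (population-based controls, GA vs GG) is not
  reproduced by the stated selection rule; the implementation follows the
  rule, not that cell. The bundled-data tests pin only the cells that the
  rule reproduces.
* Reconstruction from 3-decimal proportions is exact-to-rounding, not
  exact: counts are guaranteed to sum to the arm size and to reproduce the
  printed proportions to within `0.0005 + 0.5/n`, which is sharp for data
  printed at that precision.
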