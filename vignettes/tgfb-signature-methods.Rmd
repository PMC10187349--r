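---
title: "Methods: deriving and evaluating a prostate cancer-specific TGF-beta activity signature"
author: "tgfbsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and evaluating a prostate cancer-specific TGF-beta activity signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgfbsig)
```

## Scope and rationale

`tgfbsig` implements a complete radiogenomic analysis pipeline for localized
prostate cancer treated with external beam radiotherapy (EBRT) and androgen
deprivation: derivation of a tumor-cell-specific TGF-beta activity gene
signature from an *in vitro* epithelial/stromal co-culture contrast,
single-sample scoring of patient biopsies, patient-blocked differential
expression for cohorts with repeated biopsies, a PTEN/TP53 allele-dosage
classifier of biochemical recurrence (BCR), and Phoenix-rule BCR calling
from PSA follow-up. Because the patient cohorts such an analysis would
normally consume are controlled-access, the package ships synthetic-data
generators that reproduce the statistical structure of the study design;
every stage of the pipeline is exercised and tested against those
generators and against independent oracles.

## The co-culture derivation contrast

The signature is derived from a six-condition experiment: LNCaP prostate
cancer epithelial cells co-cultured with HPS-19I stromal cells and
stimulated with TGF-beta (`cocult_tgfb`, the positive arm), and five
negative arms — vehicle co-culture, co-culture with the TGF-beta receptor
inhibitor SD-208 with and without stimulation, and stroma alone with and
without stimulation. The derivation contrast weights the positive arm +1
and each negative arm −1/5 (`coculture_contrast()`), so the estimated
effect is the log2 fold-change of the stimulated co-culture over the
equally weighted average of the five negatives. Restricting the positive
signal to the stimulated co-culture selects genes induced in the
epithelial compartment specifically under active TGF-beta receptor
signaling.

Per-gene inference uses an ordinary least-squares fit of a group-means
design followed by empirical-Bayes variance moderation. Writing $s_g^2$
for the gene's residual variance on $d_g$ degrees of freedom, the prior
$(d_0, s_0^2)$ is estimated by moment matching on $\log s_g^2$ using the
digamma/trigamma equations, and each gene's variance is shrunk to the
posterior

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

with the moderated $t = \widehat{\beta}_c / (\tilde s_g \sqrt{c^\top (X^\top
X)^{-1} c})$ referred to a $t$ distribution on $d_0 + d_g$ degrees of
freedom. The moment estimator is closed-form and deterministic; when the
observed spread of $\log s_g^2$ does not exceed what chi-square sampling
alone would produce, the prior is degenerate ($d_0 = \infty$) and every
posterior variance equals $s_0^2$ — this is a defined branch, not a
failure. The implementation is cross-checked in the test suite against
`limma::eBayes` on shared inputs, but the package's own fit is what the
pipeline runs.

Candidate genes are those with Benjamini–Hochberg adjusted $P < 0.1$,
ranked by descending log2 fold-change (ties broken lexicographically by
gene identifier so the ranking is deterministic). The BH step-up
adjustment is delegated to `stats::p.adjust(method = "BH")` behind
`benjamini_hochberg()`, which adds domain validation; tests compare it to
a brute-force transcription of the step-up definition.

## ssGSEA scoring

Samples are scored one at a time by the running-sum enrichment statistic.
Within a sample the $N$ genes are ranked by expression (average ranks on
ties; the most expressed gene has rank $N$) and walked in descending rank
order, breaking rank ties by gene identifier. With $r_g$ the rank of gene
$g$, $G$ the signature and $\tau$ the weighting exponent, the score is

$$ES = \sum_{i=1}^{N} \left[ \frac{\sum_{g \in G,\, \mathrm{pos}(g) \le i}
r_g^{\tau}}{\sum_{g \in G} r_g^{\tau}} - \frac{\#\{g \notin G,\,
\mathrm{pos}(g) \le i\}}{N - |G|} \right].$$

Two design choices deserve note. First, the weights are the rank
magnitudes themselves raised to $\tau$, matching the GSVA realization of
ssGSEA rather than the original ssGSEA publication's normalized-intensity
weights; with the pipeline default $\tau = 0.25$ the two differ, and the
README flags this divergence risk for anyone comparing against other
implementations. Second, `normalize = TRUE` (the default) divides all
scores by the cohort's score range, mirroring GSVA's default
normalization; scores are then comparable across cohorts only in rank
terms. Single-sample scoring should set `normalize = FALSE` (a degenerate
zero range triggers a warning and returns unnormalized scores).

Scoring is rank-based, hence invariant to any strictly monotone transform
of a sample's expression values, and the score is bounded by $|ES| \le N -
1$. Both properties, the two hand-derived three-gene cases ($ES = \pm
1.5$), and agreement with a naive double-loop oracle to $10^{-9}$ are
enforced by tests. Missing signature genes are an error by default
(`allow_missing = TRUE` downgrades to a warning and drops them): silently
scoring a partial signature is exactly the failure mode that made the
original study decline to validate on an array lacking signature genes.

## Signature size selection

`select_signature()` scores the top-$N$ candidates for $N = 3, 4, \ldots,
n_\mathrm{max}$ (default $n_\mathrm{max} = \min(30, \text{candidates})$),
computes the ROC AUC of the scores against the discovery outcome labels,
and returns the smallest $N$ that is a local maximum of the AUC trace
($AUC(N) \ge AUC(N-1)$ where defined and $AUC(N) \ge AUC(N+1)$). An AUC
trace still strictly increasing at $n_\mathrm{max}$ returns
$n_\mathrm{max}$ with a warning. Equal neighbours resolve to the smaller
$N$ (parsimony). The returned signature is locked — field assignment on a
locked signature is an error — and carries the full AUC trace in its
provenance. Because selection maximizes in-sample AUC, the discovery AUC
is optimistic; the test suite quantifies this on null cohorts (no planted
effect), where the median selected-signature AUC over seeds must stay
within [0.45, 0.65].

## Patient-blocked differential expression

Cohorts with repeated biopsies per patient violate the independence
assumption of the ordinary linear model. `fit_mixed_model()` fits, per
gene,

$$y_{gij} = \beta_0 + \beta_1\,\mathrm{BCR}_i + u_{gi} + \varepsilon_{gij},
\qquad u_{gi} \sim N(0, \sigma_u^2),\ \varepsilon_{gij} \sim N(0,
\sigma_e^2),$$

by REML with the patient as a random intercept, using `lmerTest`/`lme4`,
and reports the Wald $t$ test of $\beta_1$ with Satterthwaite degrees of
freedom. Satterthwaite (rather than a normal-reference Wald $z$) was
chosen because it is exact for balanced random-intercept designs and keeps
null p-values uniform at the small patient counts this design targets —
the test suite checks uniformity by Kolmogorov–Smirnov. Outcome is a
patient-level label; a patient appearing in both outcome groups is an
error. Boundary fits ($\widehat\sigma_u^2 = 0$, detected via
`lme4::isSingular`) and single-biopsy-per-patient designs fall back to the
ordinary least-squares two-group fit, which the mixed model then equals
exactly — tested to $10^{-8}$.

## PTEN/TP53 allele dosage

Each tumor suppressor contributes $\min(2,\ \text{copies lost} +
\text{oncogenic mutations})$ altered alleles, so the per-sample count is
$A \in \{0, \ldots, 4\}$ over PTEN and TP53, and $A \ge 3$ (configurable
threshold) defines the high-risk class. Only mutations flagged oncogenic
or likely oncogenic upstream are counted; two mutations in a gene without
copy loss count as two altered alleles (compound heterozygosity is
assumed; phasing is out of scope). Patient-level classification uses one
representative core per patient, chosen by highest Gleason grade group,
then greatest percentage of tumor at the highest-grade pattern, then
lexicographically smallest biopsy ID — the residual tie-break is an
artifact convention chosen for determinism.

## Outcome statistics

* **ROC/AUC** — computed by the Mann–Whitney rank identity (ties counted
  one half), which equals the trapezoid area under the threshold-swept
  curve; cross-checked against `pROC` and a concordant-pair oracle.
* **Mann–Whitney U** — exact p-value (via `stats::wilcox.test`'s exact
  path) when the combined sample size is at most 12 with no ties, else
  the normal approximation with tie and continuity correction; tests
  compare against full enumeration and a $10^5$-permutation oracle.
* **Spearman vs volume** — volumes receive a pseudocount (default
  0.1 cm³; the value is a plotting convention, as any positive
  pseudocount yields identical ranks and hence identical $\rho$) and a
  log10 transform; $P$ uses the $t$ approximation.
* **Phoenix BCR calling** — the nadir is the *running* minimum of the PSA
  series, and BCR is called at the first time PSA reaches nadir +
  2 ng/mL, inclusively. Using the running rather than global minimum
  means later declines cannot retroactively un-call a recurrence,
  matching sequential clinical assessment.

## The synthetic study conditions

The generators default to the design of the motivating study and are not
meant to be tuned per analysis:

* **Co-culture** (`coculture_config`): 200 genes, 3 replicates per
  condition (the replicate count of the source arrays is unstated; 3 is a
  typical microarray design and is configurable), 6 planted
  TGF-beta-responsive genes at +2 log2 units (4-fold) in the stimulated
  co-culture only, residual SD 0.5 on the log2 scale. Gene baselines are
  drawn once from $N(8, 2)$ on the log2 scale, matching RMA-normalized
  intensity ranges.
* **Cohort** (`cohort_config`): 29 patients, 1–4 biopsies each (about 60
  biopsies in expectation), per-patient BCR probability 0.17 (about 5 BCR
  patients in expectation), planted signature effect +1 log2 unit in BCR
  samples, $\sigma_u = \sigma_e = 0.5$. Outcome is assigned at the
  patient level so all biopsies of a patient share it. Lesion volumes are
  lognormal with a higher median for BCR patients (meanlog 1.8 vs 0.7,
  sdlog 0.8, in cm³), so volume-outcome comparisons are rehearsable.
* **Allele calls** (`allele_config`): the intended altered-allele count is
  drawn from outcome-conditional distributions; the default places no NED
  mass at $A \ge 3$ — making the 3-allele rule perfectly specific by
  construction, which is the regime the rule is meant to demonstrate —
  and 70% BCR mass at 3–4. Setting both distributions equal switches the
  association off for null checks.
* **PSA** (`psa_config`): log-linear decline from a lognormal baseline
  (median 13.5 ng/mL) to a uniform nadir in [0.05, 0.5] ng/mL by month
  12; NED series stay at the nadir with noise clipped at ±0.5 ng/mL so
  they can never cross the Phoenix threshold; BCR series regrow
  exponentially (doubling time 6 months) calibrated to cross nadir + 2
  exactly at a planted measurement time, so the zero-noise crossing is
  recovered exactly by the caller.

A single global seed expands to fixed per-stream seeds (genes, patients,
volumes, alleles, PSA, ...), so adding a stream never perturbs draws of
earlier streams, and identical configurations reproduce outputs
bit for bit. A binomial outcome draw can yield zero BCR patients; the
generator rejects such configurations with an instructive error rather
than silently producing a degenerate cohort, and replicated analyses scan
forward to the next valid seed.

What the generators do **not** emulate: probe-level microarray structure,
RNA-seq counts and their mean–variance relationship, correlated gene–gene
expression modules, tumor purity variation, or MRI measurement error.
Passing tests therefore demonstrate that the statistical machinery is
correct under the stated model, not that the biological signature would
replicate on real arrays.

## Numerical choices

* REML fitting, singularity detection (`tol = 1e-5`) and the OLS fallback
  are delegated to `lme4`; the trigamma inverse in the variance-prior fit
  uses Newton iteration to relative tolerance $10^{-10}$.
* All rank computations use average ranks for ties; ordering ties resolve
  by gene identifier.
* The problem sizes used by the test suite and the acceptance script
  (200-gene co-cultures, 29-patient cohorts, 2,000-gene null
  calibrations, 10–20 seed replicates) were chosen as the smallest sizes
  at which the distributional checks are stable; they mirror the scale of
  the motivating study design rather than cohort-scale expression
  compendia.

## Limitations

* The discovery AUC is in-sample and optimistic by construction; an
  external validation cohort is required for honest effect estimates.
* The Wald test of the mixed model can be anticonservative for severely
  unbalanced designs with very few patients per group; a likelihood-ratio
  or parametric-bootstrap test would be the conservative alternative.
* The allele-dosage classifier consumes gene-level allele calls; deriving
  those calls from sequencing (alignment, variant calling, allele-specific
  copy number) is upstream of this package.
* Precision weights for mean–variance trends (voom-style) are not
  implemented; the random-intercept model is this package's realization of
  patient blocking, and rank-based scoring is insensitive to modest
  mean–variance effects.
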