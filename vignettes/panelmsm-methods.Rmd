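---
title: "Methods: multistate Markov modelling of cognitive ageing panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multistate Markov modelling of cognitive ageing panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`panelmsm` fits a continuous-time Markov multistate model to
panel-observed cognitive state data.  The default state space is

1. **NOCI** — no cognitive impairment,
2. **CIND** — cognitive impairment, no dementia,
3. **Dementia**,
4. **Death** (absorbing),

with seven allowed instantaneous transitions: `1-2`, `2-1` (recovery from
CIND back to NOCI is explicitly allowed), `1-3`, `2-3`, `1-4`, `2-4`,
`3-4`.  The process is governed by a generator matrix $Q$ whose
off-diagonal entries are transition intensities

$$ q_{rs}(z, a) \;=\; q^0_{rs}\,
   \exp\!\bigl(\beta_{rs}^\top z + \alpha_{rs}[\,b(a)\,]\bigr), $$

where $z$ are subject-level covariates, $\exp(\beta)$ is the hazard ratio
of a covariate level versus its reference, and $\alpha_{rs}[b]$ are
additive log-intensity offsets that are piecewise constant on age bands
$b(a) \in \{[50,60), [60,70), [70,80), [80,\infty)\}$ (first band =
reference).  Analysis time is years since baseline; age enters only
through the band offsets, so intensities are step functions of age.  The
transition probability matrix over an interval that crosses band
cut-points is the ordered product of per-segment matrix exponentials
$\prod_j \exp(Q_{b_j}\,\delta_j)$.

Covariate conventions follow the socioeconomic-gradient literature: the
reference level of each indicator (education low, occupation
routine/manual, wealth lowest tertile) is the most disadvantaged group,
so published-style hazard ratios read as effects of *advantage*.  Sex
(ref. male), marital status (ref. married) and the age bands adjust all
transitions **except** the two dementia-onset transitions `1-3` and
`2-3`, matching the convergence-driven adjustment strategy used in
analyses of cohorts of this kind.  One socioeconomic indicator is
modelled at a time for the same reason; `elsa_covariate_spec("all")`
exists but joint fits are harder to identify.

## The panel likelihood

States are observed only at interview waves, so each consecutive pair of
observations $(r \to s, \Delta t)$ contributes $\log P_{rs}(\Delta t)$.
Two refinements:

* **Exact death times** (`death_exact = TRUE`, the default): a final
  interval ending in death at $\Delta t$ contributes the density
  $\log \sum_{s'} P_{r s'}(\Delta t^{-})\, q_{s'4}$, summing over
  transient states with an allowed transition to death.  A
  `--death-panel` switch treats death like any other panel observation.
* **Age-band crossings** split each interval, with covariates held at
  their interval-left values.

Observation pairs that are impossible under the structure (e.g. dementia
followed by NOCI) yield $-\infty$ with a diagnostic naming the record.
Subjects with a single observation cannot contribute and are dropped with
a logged count.

Internally the dataset is collapsed to *weighted terms*: unique
combinations of covariate pattern, band segmentation, interval length and
observed pair.  Baseline ages are whole years and waves are scheduled, so
panels collapse to a few hundred terms regardless of cohort size; only
exactly observed death times stay subject-specific.  Each likelihood
evaluation computes one 4×4 matrix exponential (scaling-and-squaring with
a [6/6] Padé approximant) per unique (generator, interval) pair, in
compiled code.  This is what keeps the 4 000-subject acceptance fits in
the tens of seconds.

## Estimation and numerics

* Maximisation: BFGS (`stats::optim`) on the unconstrained scale (log
  baseline intensities, raw coefficients) with central finite-difference
  gradients (relative step `1e-5`), objective relative tolerance
  `1e-10`, at most 500 iterations.  A gradient-norm stopping rule of
  `1e-7` is below finite-difference noise at log-likelihoods of order
  $10^4$, so the objective-based rule is used instead and the honest
  `optim` convergence code is reported.
* Initial values: crude rates — observed pair counts over person-time in
  the source state, floored at `1e-4`/year for unobserved transitions;
  coefficients start at 0.
* Standard errors: inverse of the central finite-difference Hessian at
  the optimum (4-point cross differences).  If the condition number
  exceeds `1e10` an eigenvalue pseudo-inverse is used with a warning.
* Guard rails: transition-probability entries are clamped to $[0,1]$
  inside the likelihood (extreme intensities proposed during line search
  can otherwise push Padé round-off above 1 and create spurious positive
  log-likelihoods); non-finite rate proposals score $-\infty$.
* Identifiability: the fit reports, per coefficient, the number of
  observed direct transition pairs informing it.  The direct
  NOCI→dementia rate `1-3` is intrinsically weakly identified in panels
  of this design — most observed 1→3 pairs arise via the 1→2→3 pathway —
  and its baseline rate routinely hits the zero boundary (flagged by a
  warning), exactly the behaviour reported for the real analyses this
  package emulates.

## Derived quantities

* **Hazard ratios**: $\exp(\hat\beta)$ with delta-method CIs
  $\exp(\hat\beta \pm z_{0.975}\,\mathrm{SE})$; never re-estimated.
* **Occupancy / stacked transition probabilities**: rows of $P(t)$ from a
  start state over a grid, composing across age bands.
* **Total length of stay**: $\int_0^T P_{rs}(u)\,du$ evaluated in closed
  form per band segment via the Van Loan augmented-matrix identity
  ($\exp$ of $\bigl[\begin{smallmatrix} Q & I \\ 0 & 0
  \end{smallmatrix}\bigr]\delta$ contains the integral in its upper-right
  block).  The original design sketch called for adaptive quadrature at
  tolerance `1e-8`; the closed form has no quadrature error at all and is
  verified against Simpson's rule (step 0.01 y, tolerance `1e-6`) in the
  tests.  The horizon-restricted reading of "years spent in each state"
  is used throughout (at age 80 a 10-year window is *not* remaining
  lifetime; the distinction matters and is deliberate).
* **Sojourn times**: $-1/q_{rr}$ per transient state with a log-scale
  delta-method CI.
* **Prevalence goodness-of-fit**: observed prevalence assigns each
  subject the state of their nearest observation within a window (default
  half the median inter-observation gap; an exactly observed death
  carries forward), and expected prevalence averages model occupancy from
  each risk-set subject's baseline state/covariates/age.  With dropout,
  subjects who died remain assignable at late times while surviving
  dropouts do not, which tilts *observed* late prevalence toward death —
  a known artifact of this construction, shared with standard
  implementations.  The self-consistency test therefore runs without
  dropout; applied users should read late-time discrepancies with this in
  mind.

## The synthetic cohort: a stated world

`generate_cohort()` emulates the *structure* of an English ageing panel
(waves 4–9 of ELSA-style follow-up) without any access to restricted
data: n = 8 442 by default, six biennial waves over 10 years, baseline
age ~ round(TruncNormal(67, 9.5², ≥50)) in whole years (real studies
record age in years; integer ages also make band-crossing offsets
discrete, enabling the term grouping above), female 55.74 %, married
65.30 %, education 27.81/54.11/18.07 %, occupation 31.02/35.24/33.73 %,
wealth tertiles 32.80/33.74/33.45 % (vectors normalised to 1; the
published female share 55.74 % slightly disagrees with its own
numerator/denominator 4663/8442 = 55.24 % — the printed value is used).
Covariates are sampled independently; real socioeconomic indicators
correlate, so a documented hook exists (post-process the cohort table),
but no default or test depends on it.

Exact trajectories use the Gillespie scheme with exponential holding
times re-drawn at age-band boundaries (valid by memorylessness), then
`observe_panel()` degrades them: states recorded at attended waves;
per-wave dropout probability 0.08; deaths are *discovered at the first
scheduled wave after the event, and only if that wave precedes dropout*,
then recorded at the exact event time (or at the discovery wave under
`--death-panel`).  Discovery-based ascertainment was chosen after an
earlier registry-style rule (deaths always observed, even after dropout)
produced informative censoring — dead dropouts kept follow-up while
surviving dropouts lost it — and biased mortality intensities upward by
several standard errors at n = 20 000.  Under the discovery rule the
unattended tail of follow-up yields no record whether or not the subject
survived it, so the panel likelihood is exactly the density of the
generated records; the large-n bias check is part of the development
history, and parameter recovery is the central acceptance property.

Generating parameters: baseline rates (per year) q₁₂ = 0.25, q₂₁ = 0.15,
q₁₃ = 0.002, q₂₃ = 0.05, q₁₄ = 0.02, q₂₄ = 0.06, q₃₄ = 0.30 — repo
fixtures reproducing the qualitative abundance ordering of such cohorts
(NOCI↔CIND common, CIND→dementia moderate, direct NOCI→dementia rare,
dementia→death high).  Socioeconomic log hazard ratios are fixed at the
published point estimates carried by `reference_hazard_ratios()` (e.g.
wealth highest-vs-lowest on CIND→NOCI: 1.56).  Demographic effects and
age offsets are not published anywhere, so field-plausible values were
chosen once and frozen: female mortality HR 0.75, single-vs-married
mortality HR 1.25, mortality ×1.5 per age decade, progression ×1.2,
recovery ×0.9, dementia mortality ×1.2; initial state split
0.65/0.33/0.02 over NOCI/CIND/dementia.

What a green test does *not* establish: absolute transition counts and
probabilities are **not** reproduced (the real study's baseline
intensities are unpublished; with the fixture rates and an aged cohort
the synthetic 10-year mortality ≈ 50 % exceeds the real ≈ 20 %), there
are no sampling weights, household clustering, refreshment samples,
state-dependent dropout, or diagnostic misclassification.  Recovery of
the *generating* hazard ratios — which the acceptance suite verifies to
within 10 % over 5 seeds at n = 4 000 for every adequately populated
transition — is evidence about the estimator, not about the real cohort.

## Known limitations

* The `1-3` cells cannot be recovered at desk scale (published CIs for
  that column span 0.11–8.49; the synthetic design reproduces that
  non-identifiability) — the identifiability diagnostics expose this
  rather than the fit failing opaquely.
* Hidden-Markov misclassification layers, frailty and sampling weights
  are out of scope by design.
* The coverage (100 × n = 250) and SE-scaling (n up to 16 000) suites use
  a reduced single-covariate model with panel-censored death so the whole
  test run stays within its compute budget; scaling behaviour, not
  absolute precision, is what they certify.
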