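---
title: "Methods: from roulette histograms to offset benefit distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from roulette histograms to offset benefit distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offsetElicit)
```

## The problem and the model

A biodiversity offset promises future gains in exchange for present losses.
Whether the promise is credible depends on two counterfactual trajectories
for the offset site over a fixed horizon (here 20 years): what happens under
business as usual (BAU), and what happens under conservation management.
The benefit model splits the offset's contribution into

* management gain, `MG = future value with offset − current value`,
* averted loss, `AL = current value − future value without offset`,
* total benefit, `TB = AL + MG`.

Negative values are meaningful throughout: an attribute may be expected to
decline even under management (negative MG), or to improve under BAU
(negative AL).

`offsetElicit` estimates these quantities from structured expert judgement
along two pathways.

**Aggregate pathway.** Experts give each site a single vegetation-condition
score out of 100, now and 20 years ahead under offset management (a subset
of the panel also scores a BAU future). Benefit arithmetic is applied
directly on the 0–100 scale (`aggregate_point_benefit()`), and a boosted
regression tree decomposes the variation in scores and in MG/AL/TB over
site covariates and expert identity (`fit_brt()`, `relative_influence()`).

**Attribute pathway.** For 13 vegetation attributes (native foliage cover
and richness of five growth forms; large trees, litter cover, log length),
experts provide trial-roulette histograms: a plausible interval
`[θ_min, θ_max]`, split into 10 equal bins, over which they distribute 100
chips. The share of chips in a bin is the subjective probability of that
outcome. Histograms are elicited for a *reference* state — the
best-attainable condition in the contemporary landscape — and for the
future states of each scenario.

## Reference standardisation

Experts differ in their frames of reference: the same absolute change can
be large or small relative to what each expert believes is attainable. All
attribute values are therefore standardised by the expert's own elicited
reference value before benefit accounting:

`BC = min(V / R, 1)`

(`condition_score()`). The cap at 1 encodes the common assessment
assumption that accrual above the benchmark is not additional biodiversity
value. The cap matters for interpretation: where an attribute starts at or
above its reference, MG is 0 by construction for at least half the draws,
and standardisation can hide changes on the raw measurement scale.

## Fitting subjective distributions

Histograms elicited on different intervals cannot be pooled directly, so
each is summarised parametrically (`fit_distribution()`):

* **Family.** Percentage attributes (foliage covers, litter cover) use a
  beta distribution rescaled from (0, 1) to (0, 100); all remaining
  attributes (richness counts, large-tree counts, log length) use a normal
  distribution. These two families were sufficient in practice; log-normal
  and mixture alternatives are deliberately not offered.
* **Objective.** Parameters minimise the sum of squared differences between
  the parametric CDF and the elicited cumulative probabilities at the nine
  interior bin edges — the convention of standard elicitation-fitting
  toolkits. The optimiser is Nelder–Mead on (location, log scale) or
  (log α, log β), started from moment-matched values, relative tolerance
  1e-12, with a coarse grid fallback; the achieved SSE is reported as
  `fit_sse`.
* **Degenerate histograms.** All chips in one bin would imply zero
  variance, which would collapse the Monte-Carlo pooling; instead the
  location is fixed at the bin midpoint and the spread floored at a quarter
  of the bin width (≈ the resolution the expert actually expressed).
* **Boundary handling.** For beta fits, interior edges that rescale to
  exactly 0 or 1 are nudged inward by 1e-9 before CDF evaluation.
* **Multimodality.** Histograms with two or more strict local maxima
  separated by a strictly lower bin are flagged (`detect_multimodality()`)
  but still fitted with the unimodal family; the flag is carried into the
  fits table for review. No mixture is fitted.

Sampling from a fitted distribution clips draws to the attribute support
(counts floored at 0, covers capped at 100) rather than rejection-sampling;
clipping is simpler, and the clipped fraction is attached to every draw
vector so truncation is never silent.

## Monte-Carlo pooling

For each scenario, attribute and expert, `pooled_benefit()` draws
`draws_per_expert` triples (reference R, offset future V_off, BAU future
V_bau where elicited). Within a draw the *same* reference sample
standardises the start value and both futures. The alternative — drawing an
independent reference per state — would break the internal coherence of
`TB = AL + MG` at the draw level; sharing R keeps the identity exact, and it
is asserted for every emitted sample. The default of 84 draws per expert
with a panel of 25 gives 2100 pooled samples per attribute, enough for
stable medians and quartiles while keeping within- and among-expert
variation visible.

Two numerical guards: reference draws below 1% of the reference
distribution's mean are floored there (ratio blow-up protection; floor
events are counted and logged), and fern attributes are excluded from
pooling by default because their reference distributions sit near zero,
making the standardised ratio unstable. Quantiles everywhere use linear
interpolation between order statistics (`type = 7`), stated so results are
bit-reproducible.

## Expert diagnostics

Averaging each expert's draws per attribute places them in the
(mean AL, mean MG) plane (`expert_means()`). Quadrants read as opinions:
high MG with low AL is optimism under both regimes; high AL with low MG is
pessimism regardless of management; high AL with high MG is pessimism about
BAU but belief in the offset. A tolerance band of 0.01 condition units
around both axes provides a tie rule near the origin
(`classify_quadrant()`); the classification is exhaustive and mutually
exclusive. `al_mg_fit()` regresses mean MG on mean AL across experts — a
negative slope is the signature of a shared "temporal" disposition.
`systematic_bias()` flags an expert as optimist/pessimist when the sign of
their mean MG is consistent for at least 80% of their attributes (with at
least 5 attributes assessed); the threshold is a design choice — no
standard numeric rule exists — set high enough that unbiased panels are
flagged in under 10% of simulated cases (property-tested).

## Boosted regression trees

`fit_brt()` performs stagewise squared-error gradient boosting (via
xgboost) with interaction depth = tree complexity 5, learning rate 0.005
and per-tree row subsampling at bag fraction 0.75. The tree count is chosen
by 10-fold cross-validation, stopping once the cross-validated deviance has
failed to improve for `tree_step` (50) rounds, then refitting on all rows
at the selected size. Expert identity is one-hot encoded for the tree
builder and the encoded columns' influences are summed back into a single
expert-identity entry — otherwise the categorical covariate's influence
would be fragmented and incomparable with the numeric covariates.
Influence is the standard gain measure: squared-error improvement credited
to each covariate's splits, accumulated over trees and normalised to sum
to 100.

Two reproducibility choices: fits are deterministic given the
configuration seed (single-threaded), and `build_design()` sorts rows by
(expert, site) so the pipeline is invariant to input row order. Partial
dependence (`fitted_function()`) fixes one covariate on a grid and averages
predictions over the training rows. `predict_condition()` averages member
predictions over all expert levels (a prediction for the average expert),
clips to [0, 100], and reports the between-member standard deviation as
spread.

## The synthetic generator

No elicitation dataset of this kind is publicly deposited, so the package
ships a generator (`simulate_site_pool()`, `simulate_point_scores()`,
`simulate_roulette_elicitations()`) that emulates the *statistical
structure* the analysis assumes, with known ground truth:

* **Sites.** 64 sites on a latent condition gradient `u ~ Uniform(0, 1)`;
  each attribute is a monotone fraction of its reference mean at `u` with
  multiplicative log-normal noise (CV 0.15); alien covers decrease in `u`.
  The true aggregate score is a weighted mean of capped condition ratios,
  discounted by invasive cover.
* **Point scores.** 29 experts, 15 sites each of which 5 are common to the
  panel (chosen a priori to span the condition range); 16 experts also
  score a BAU future. Scores are truth plus a per-expert intercept
  (sd 8 points — some experts are consistently generous or harsh) plus
  noise (sd 5 points), clipped to [0, 100].
* **True benefit.** `MG* = 0.125 (1 − BC_start)` and
  `AL* = 0.08 BC_start + 0.01` on the condition scale: gains concentrate
  where starting condition is low, losses where there is something to lose.
  At moderate starting condition these place median MG and AL at a handful
  of points per 100 — the order of magnitude practitioners report for
  20-year horizons.
* **Roulette panels.** 25 experts; each expert's subjective distribution is
  centred on the true state mean shifted by a per-expert temporal-optimism
  term (sd 0.05 condition units) applied *jointly* to the BAU and offset
  futures — which is what induces the negative AL–MG association across
  experts — with spread equal to the benchmark sd times an overconfidence
  factor of 0.8. Elicitation bounds are the subjective mean ± 3 sd clipped
  to the support (a conventional near-total-probability interval), and bin
  masses are converted to exactly 100 chips by largest-remainder rounding,
  so every generated record passes validation by construction.
* **Oracle mode** zeroes every noise, bias and change term and makes the
  subjective distributions effectively point masses, giving each downstream
  operation an exact expected output (zero benefit end to end, up to the
  ~1e-9 width of the degenerate distributions).

What the generator does **not** emulate: real floristic covariance among
attributes, skewed or heavy-tailed expert opinion, correlation between an
expert's point-score intercept and their roulette bias, and genuinely
multimodal judgements. Passing tests therefore demonstrate that the
machinery is correct and that known structure is recovered — not that any
particular real panel would produce these numbers.

## Problem sizes and determinism

The shipped analysis uses the full design (64 sites, 29/25 experts, 84
draws per expert, 2275 fitted histograms); the test suite exercises the
same code on smaller panels (3–25 experts, 2–6 attributes, tree budgets of
a few hundred) chosen so the whole suite completes in about a minute while
still covering every operation, and the end-to-end recovery check runs 20
independent seeds against a 400-panel Monte-Carlo oracle interval. Every
stochastic function takes an explicit seed; the pipeline driver derives
per-stage seeds from one master seed, and two runs with the same seed are
asserted identical down to the CSV outputs.

## Known limitations

* The beta/normal family choice is fixed by attribute category; a
  heavy-tailed or skewed judgement on a count attribute is forced into a
  normal shape.
* Clipping at supports slightly biases means of distributions with
  substantial mass outside the support (the clipped fraction is logged).
* The condition-score cap makes MG distributions atomic at 0 for
  near-reference starts; summaries report the zero fraction explicitly
  rather than pretending continuity.
* Relative influence inherits the known biases of split-gain importance
  measures (preference for high-cardinality covariates); expert identity,
  as a many-level factor, benefits from this, which is worth remembering
  when reading its NRI.
* Opinion pooling is unweighted; there is no calibration scoring against
  realised outcomes, because no outcome data exist at these horizons.
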