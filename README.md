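# offsetElicit

Biodiversity offsetting trades certain, immediate habitat losses against
uncertain future conservation gains. Deciding whether an offset can deliver
requires predicting two counterfactual quantities for the offset site:
the **averted loss** (AL), the decline expected under business as usual (BAU)
that conservation management would prevent, and the **management gain** (MG),
the improvement above today's value that management would add. Their sum is
the **total benefit** of the offset:

    MG = future value with offset − current value
    AL = current value − future value without offset
    TB = AL + MG

Empirical data on such trajectories are scarce, so these predictions usually
come from expert judgement. `offsetElicit` is an R package for doing that
judgement elicitation *structurally* and propagating its uncertainty, aimed
at conservation ecologists and offset-policy analysts. It implements:

- **Trial-roulette elicitation records** — an expert states a plausible
  interval for a quantity, the interval is split into 10 equal bins, and the
  expert spreads 100 chips over the bins as a subjective probability
  histogram. The package validates, reads and writes these records.
- **Subjective distribution fitting** — each histogram is summarised by a
  beta distribution rescaled to (0, 100) (percentage attributes) or a normal
  distribution (counts, lengths), by least-squares matching of the CDF at
  the interior bin edges. Parametric fits let experts who chose different
  intervals be pooled.
- **Reference-standardised benefit accounting** — attribute values are
  scored against a reference benchmark, `BC = min(V/R, 1)`, and AL, MG and
  TB are computed per Monte-Carlo draw on that 0–1 condition scale, pooling
  draws across the expert panel (25 experts × 84 draws = 2100 samples per
  attribute) so results carry both within- and among-expert uncertainty.
- **Expert diagnostics** — per-expert mean AL vs mean MG, optimism/pessimism
  quadrants, the AL–MG regression, and flags for systematically biased
  experts.
- **Boosted-regression-tree analysis** of aggregate 0–100 condition scores:
  normalised relative influence of site covariates and expert identity,
  partial dependence, and ensemble condition predictions for new sites.
- **A synthetic generator** for site pools and expert panels with known
  ground truth, so the whole pipeline is testable end to end.

## Worked example

Simulate a small panel for the moderate-condition woodland scenario, fit the
elicited histograms and pool the benefit draws:

```r
library(offsetElicit)

sc   <- wsgw_scenarios()[[1]]                    # moderate condition, has a BAU future
sim  <- simulate_roulette_elicitations(sc, generator_config(), seed = 1)
fits <- fit_elicitations(sim$elicitations)
s    <- pooled_benefit(fits[fits$scenario_id == sc$id, ], sc$start_values,
                       exclude = c("fern_cover", "fern_richness"), seed = 2)
nrow(s) / length(unique(s$attribute))            # 2100 pooled draws per attribute
head(summarize_benefit(s)[, c("attribute", "AL_median", "MG_median", "TB_median")], 4)
```

```
[1] 2100
                    attribute  AL_median   MG_median  TB_median
forb_cover         forb_cover 0.06425805 0.009026184 0.07924071
forb_richness   forb_richness 0.03721409 0.055100191 0.09436539
grass_cover       grass_cover 0.04804682 0.056454440 0.10631521
grass_richness grass_richness 0.05542926 0.040037126 0.08949347
```

Read: for forb richness the panel's median expectation is that BAU would
lose ~4% of the reference condition over 20 years (averted loss 0.037),
management would add ~6% above today (gain 0.055), for a median total
benefit of ~0.09 on the 0–1 condition scale. Forb *cover* starts near its
reference benchmark, so the condition-score cap leaves little headroom and
its median gain is close to 0 — accrual above the benchmark does not count
as benefit.

The full analysis is the numbered scripts in `analysis/` (run in order from
the repository root): `01_simulate.R` writes the synthetic study inputs,
`02_fit_distributions.R` fits all 2275 histograms, `03_benefit.R` pools
benefit distributions for the three scenarios, `04_expert_diagnostics.R`
produces the optimism/pessimism diagnostics, and `05_relative_influence.R`
fits the boosted regression trees (tree complexity 5, learning rate 0.005,
bag fraction 0.75) and writes influence, partial-dependence and
scenario-prediction tables. All outputs land under `results/`.

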