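# fracCEA

Markov cohort cost-effectiveness analysis of radiotherapy fractionation
schedules for early-stage glottic cancer, from the perspective of the
Brazilian public (SUS) and private (CBHPM) health systems.

Definitive radiotherapy for early glottic cancer can be delivered
conventionally fractionated (CFRT, 2 Gy × 30–33) or moderately
hypofractionated (HYPOFRT, 2.25 Gy × 25–28); hypofractionation achieves
better five-year local control, and Brazilian payers reimburse both
schedules identically. `fracCEA` is for health-economics analysts and
methodologists who want that comparison — or any structurally similar
state-transition model — as code: a declarative JSON model format, a
tunnel-state cohort engine, incremental cost-effectiveness analysis, and
deterministic plus probabilistic sensitivity analysis, all tidyverse-native
(tibbles in and out, `tidy()`/`glance()`/`autoplot()` methods).

## The model in brief

A cohort of 65-year-old men starts in *controlled disease* and moves
yearly among {controlled disease, local failure, distant failure, dead}
over a 15-year horizon, discounted at 5%/yr. Transition probabilities and
state costs are year-specific for five years (duration dependence via
tunnel states) and constant thereafter. For strategies A (reference) and
B (comparator) the package reports discounted totals and

```
ICER = (Cost_B − Cost_A) / (Effect_B − Effect_A),   NMB(λ) = λ·Effect − Cost
```

with dominance classification, tornado one-way sensitivity analysis
(costs ±40%, probabilities/utilities ±1.96 SD), and a 10,000-iteration
Monte Carlo PSA (method-of-moments beta/gamma distributions) yielding the
cost-effectiveness plane, acceptability curves (CEAC) and NMB-vs-λ curves.

## Worked example

```r
library(fracCEA)

hyp  <- esgc_model("HYPOFRT", "public")   # embedded canonical inputs
cfrt <- esgc_model("CFRT",    "public")

cmp <- incremental_analysis(run_model(hyp), run_model(cfrt))
cmp
#> <cea_comparison> CFRT vs HYPOFRT (public)
#>   dCost 934.32  dQALY -1.1637  dLYG -0.6119
#>   ICER -802.90/QALY, -1527.01/LYG  [comparator_dominated]
```

Conventional fractionation costs R$934 more per patient and yields 1.16
fewer QALYs, so it is dominated: hypofractionation is cheaper *and* more
effective, and the negative ICER is reported only for presentation, with
the dominance class carrying the conclusion. The probabilistic analysis
quantifies how certain that is:

```r
psa <- run_psa(hyp, cfrt, n = 10000, seed = 1)
ceac_at(psa, 2000)      # P(HYPOFRT has the higher NMB at R$2,000/QALY)
#> [1] 0.9694
autoplot(psa, "ceac")   # acceptability curves over the full WTP grid
```

A note on fidelity to the source analysis: the embedded inputs reproduce
the direction and robustness of the published conclusion (dominance of
hypofractionation, in every sensitivity analysis), but not the published
base-case magnitudes — the published input table is mutually inconsistent
with the published totals, as worked through in the methods vignette
(`vignettes/markov-cea-methods.Rmd`).

Other entry points: `read_model()`/`write_model()` (JSON round-trip),
`run_cohort()` + `tidy()` (occupancy traces), `run_tornado()` +
`autoplot()` (tornado diagram), `random_model()` and `microsimulate()`
(synthetic models and the individual-level validation oracle), and a thin
CLI at `inst/cli/fraccea` (`run | dsa | psa | fixture | synth | microsim |
validate`) writing CSV/JSON outputs with a manifest.

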