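# camshield

Camera-trap analysis of predator–prey–human co-occurrence: does human
activity create spatial refugia for prey ("human-shield" dynamics)?

Camera-trap surveys record timestamped detections of species at fixed
stations. Testing whether prey associate with humans while predators avoid
them requires three complementary analyses, all implemented here on tidy
tables:

1. **Co-occurrence occupancy.** Latent presence of the prey, predator and
   human "guilds" at each site follows a multinomial-logit distribution,
   `P(z) ∝ exp(Σ f_s z_s + Σ f_jk z_j z_k)`, with first-order natural
   parameters `f_s` and pairwise interaction terms `f_jk`; detection is
   imperfect (occasion-wise Bernoulli with per-guild probability `p_s`).
   The package fits the model by maximum likelihood, compares
   interaction vs no-interaction models by AIC, and derives marginal,
   pairwise and conditional occupancy (e.g. prey occupancy given human
   presence) with confidence intervals.
2. **Diel activity overlap.** Detection times on the 24-h circle are
   smoothed with von Mises kernels (plug-in concentration rule) and
   pairwise overlap is the coefficient `Δ = ∫ min(f, g)`, estimated by
   `Δ̂1`, `Δ̂4` or `Δ̂5` depending on sample size, with smoothed-bootstrap
   confidence intervals and a low / moderate / high classification at
   0.5 and 0.75.
3. **Spatiotemporal overlap.** Detections are binned into grid × hour
   cells; exclusive, pairwise (Jaccard) and triple overlap proportions of
   the guilds' active-cell sets are reported with grid-bootstrap intervals
   and Venn region counts.

A seeded synthetic survey generator (`sim_preset()`, `simulate_survey()`)
with known occupancy, detection and diel structure backs every stage with
ground truth, and `run_pipeline()` orchestrates the whole analysis from a
config (or YAML file) into a directory of CSV/JSON reports.

## Worked example

Simulate a survey under the default study conditions (88 one-km² grids,
20 days, guild marginal occupancies 0.78 / 0.42 / 0.38, positive
human–prey co-occurrence), then run the three analyses:

```r
library(camshield)

cfg <- sim_preset(seed = 42)
sv  <- simulate_survey(cfg)
rec <- filter_independent(sv$records)   # 15-min independence rule

summarize_effort(sv$design, rec)
#> <effort_summary> 1760 trap-nights, 1930 independent captures
#> # A tibble: 7 × 3
#>   species      n_captures naive_occupancy
#> 1 human               966           0.364
#> 2 spotted deer        465           0.75
#> ...
```

1760 trap-nights is 88 stations × 20 nights; naive occupancy is the
uncorrected fraction of stations with at least one detection.

```r
gm <- guild_map()
h  <- sapply(c("prey", "predator", "human"),
             function(g) build_detection_history(rec, sv$design, gm, g),
             simplify = FALSE)
fit2 <- fit_msom(h, interaction_order = 2, seed = 1)
fit1 <- fit_msom(h, interaction_order = 1, seed = 1)
compare_models(pairwise = fit2, independent = fit1)
#>   model           k logLik   AIC delta_aic best
#> 1 independent     6 -1715. 3442.      0    TRUE
#> 2 pairwise        9 -1713. 3444.      1.97 FALSE

conditional_occupancy(fit2, "prey", "human", present = TRUE)$estimate
#> 0.844
conditional_occupancy(fit2, "prey", "human", present = FALSE)$estimate
#> 0.696
```

Prey occupancy is higher where humans are present (0.84 vs 0.70) — the
human-shield signature — though at a single 88-grid survey AIC may not
separate the two models (here the simpler model wins by ΔAIC ≈ 2; power
arrives at larger site counts, as the test suite demonstrates at 300).

```r
x <- time_to_radians(rec$timestamp[rec$species == "human"])
y <- time_to_radians(rec$timestamp[rec$species == "tiger"])
bootstrap_overlap(x, y, B = 1000, seed = 1, labels = c("human", "tiger"))
#>   label_a label_b n_a n_b estimator  delta ci_low ci_high classification
#> 1   human   tiger 966  84     dhat4 0.0510 0.0168  0.0922            low

bootstrap_spatiotemporal(rec, sv$design, gm, B = 1000, seed = 1)
#>   statistic         guilds numerator denominator proportion ci_low ci_high
#>   pairwise  human:predator         2         437    0.00458 0.0000  0.0123
#>   pairwise      human:prey       152         777    0.19562 0.1385  0.2493
#>   pairwise   predator:prey        21         699    0.03004 0.0159  0.0440
#>   triple    human:pred:prey        1         870    0.00115 0.0000  0.0036
```

Diurnal humans and nocturnal tigers barely overlap in time (Δ̂4 = 0.05),
and humans share grid-hours with prey an order of magnitude more than with
predators (0.196 vs 0.005). Every proportion names its numerator and
denominator so alternative overlap conventions can be recomputed.

`run_pipeline(pipeline_config(simulate = cfg, seed = 42), "out/")` writes
all of the above (plus density grids for plotting and Venn region counts)
as CSV/JSON under `out/` with a seeded manifest; `autoplot()` methods and
`plot_density_pair()` draw the standard figures.

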