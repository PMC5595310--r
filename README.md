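# cticorrect

Model-based correction of the community temperature index (CTI) for
confounding by non-climate drivers.

## The problem

The CTI is a community-weighted mean of species' temperature preferences,

```
CTI_t = sum_s  T_s * w_{s,t},     w_{s,t} = N_{s,t} / sum_s' N_{s',t}
```

with `T_s` the temperature preference of species `s` (°C) and `N_{s,t}`
its abundance index in year `t`.  A rising CTI ("thermophilization") is
widely used as an indicator that warming is restructuring communities.
But temperature preference covaries with other species attributes —
habitat preference in birds, commercial exploitation and body size in
fish — and those attributes respond to land-use change and fishing, not
climate.  Unchecked, that covariation biases CTI trends.

`cticorrect` is for ecologists analysing long-term community census data
who want to test how robust a CTI trend is to such confounding.  It fits a
panel regression of log abundance indices on year-by-attribute
interactions,

```
log N_{s,t} = a + b_t fYear_t + b_T T_s + b_A A_s
            + c_t fYear_t:T_s + d_t fYear_t:A_s
            + Sp_s + cYear_s * t + e_{s,t},     e ~ AR(1) within species
```

with sum-to-zero species random intercepts `Sp` and random year slopes
`cYear`, and then recomputes the index from predicted abundances in which
the year interactions `d_t fYear_t:A_s` of every confounding attribute are
removed (the **modelled CTI**).  Predictions retaining all effects give the
**modelled-uncorrected CTI**, the model-adequacy check against the original
index.  A seeded community simulator with controllable trait covariation
and four observation-error models quantifies the bias of the original
index and how much of it the correction removes; diagnostics cover
attribute-trend screening, trait covariation tests, warm/cool-quartile
mechanism analysis, and loess trend smoothing.

## Worked example

A bundled generator emulates the structure of a national breeding-bird
survey (36 species, 33 annual censuses, farmland/forest/urban habitat
classes whose mean temperature preferences differ):

```r
library(cticorrect)
fx     <- generate_fixture("birds_like", seed = 42, dir = tempdir())
comm   <- read_community(fx$community)
traits <- read_traits(fx$traits)

covariation_test(traits, other = "habitat")
#> Covariation test: F(2,33) = 12.57, p = 8.75e-05
#>           n     mean
#> farmland 13 13.59043
#> forest   16 11.68887
#> urban     7 13.76206
```

Habitat and temperature preference covary (forest birds are the
cool-preferring group), so a CTI trend could reflect land-use change as
much as climate.  Screen which attributes explain long-term trends, then
fit the correction:

```r
idx <- standardize_to_index(comm)            # index = 100 in year 1
al  <- align_community_traits(idx, traits)

trend_test(al$panel, c("temp_pref", "habitat"))
#> Attribute effects on long-term abundance trends (AR(1) rho = 0.919):
#>                 term estimate       se       lo      hi
#>      cyear:temp_pref  0.01271 0.002072 0.008647 0.01677
#>  cyear:habitatforest  0.04436 0.006521 0.031582 0.05714
#>   cyear:habitaturban  0.03477 0.006532 0.021971 0.04758

fit <- fit_attribute_year_model(al$panel, model_spec(confounders = "habitat"))
fit
#> Attribute-by-year abundance model
#>   36 species, 33 years, n = 1188
#>   focal: temp_pref; confounders: habitat
#>   rho = 0.885, sigma2 = 0.0589, var(Sp) = 0.108, var(cYear) = 0.00041
#>   logLik = 813.56, AIC = -1355.12
```

Both the per-degree trend effect (0.013/yr) and the habitat effects are
supported, so both drivers shape this community.  Compare the index
variants:

```r
series <- bind_cti_series(
  cti_series(al$panel, al$traits, variant = "original"),
  modelled_uncorrected_cti(fit, al$panel, al$traits),
  modelled_cti(fit, al$panel, al$traits))
#> original               year1 12.779  final 13.150  change +0.371
#> modelled_uncorrected   year1 12.770  final 13.218  change +0.448
#> modelled               year1 12.770  final 13.566  change +0.797
```

The modelled-uncorrected series tracks the original (the model captures
the dynamics), and the corrected trend is *steeper* (+0.80 °C vs
+0.37 °C): here the declining farmland birds are warm-preferring, so
land-use change was masking part of the climate signal.
`loess_trend(series[series$variant == "modelled", ])` smooths any variant
with a pointwise 95% band, and `quartile_mechanism(al$panel)` shows
whether the trend comes from warm-adapted gains or cool-adapted losses.

A command-line wrapper exposes the same pipeline
(`Rscript $(Rscript -e 'cat(system.file("cli","cti.R",package="cticorrect"))') --help`):
subcommands `compute`, `model`, `simulate`, `simulate-grid`, `trends`,
`mechanism`, `smooth`, `fixture`, each writing CSV outputs plus a JSON
manifest recording the full configuration and seed.

## Validating the correction by simulation

```r
cfg <- sim_config(trait_correlation = -0.6, error_model = "poisson",
                  n_reps = 100, seed = 1)
run_scenario(cfg)       # true / original / modelled CTI per replicate
```

When temperature preference and habitat breadth covary negatively, the
original CTI underestimates the true (temperature-only) index by about
half a degree after 20 years, while the modelled CTI stays within a few
hundredths; `bias_grid()` sweeps correlation, effect size and community
size, and `robustness_suite()` checks superfluous analyst-model terms.

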