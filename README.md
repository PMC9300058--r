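# branta

Growth analysis for barnacle goose (*Branta leucopsis*) goslings
across breeding colonies spanning the Arctic to the temperate zone.

Arctic-breeding geese raise their young under continuous summer
daylight and a sharp peak in food quality; recently established
Baltic and North Sea colonies of the same species do not. `branta`
provides the statistical machinery to ask how much faster Arctic
goslings grow, whether day length accounts for the difference, how
hatching late in the season penalizes growth, and whether
between-colony differences are small enough to be evolutionary or
must be phenotypic plasticity.

## The model

Growth of body mass, head length and tarsus length is described by a
fixed-endpoint Gompertz curve,

    size(t) = A · exp( log(I/A) · e^(−k·t) ),

pinned to the measured hatch size *I* at *t* = 0 and the measured
adult asymptote *A*, so the growth coefficient *k* is the only
estimated curve parameter. The time axis *t* is either age in days or
the daylight hours accumulated between hatch and capture (computed
from colony coordinates with a built-in solar module, civil-twilight
convention). Random effects on *k* for cohort (year) and for nest
nested within cohort capture shared genetics, rearing environment and
annual conditions; the model is fitted by Laplace-approximated maximum
likelihood. Population differences are dummy-coded offsets to *k*
fitted jointly with Wald t tests. Residuals from the fixed-effects
fits feed a linear mixed model of hatch-date effects with backward
AIC selection, and haldane rates
`h = (X2/Sp − X1/Sp) / g` express between-colony differences in
pooled phenotypic SDs per generation.

Because the field data are not bundled, the package ships a
synthetic-data generator (`generate_scenario()`) with presets for the
three study colonies (Barents Sea 68°35′N, Baltic 57°25′N, North Sea
51°40′N; n = 392/933/116) whose generating coefficients are the
published estimates; all methods are validated by parameter recovery
against it.

## Worked example

```r
library(branta)

cfg <- scenario_preset("barents")      # Arctic colony preset
d <- generate_scenario(cfg, seed = 1)  # 392 synthetic goslings
fit_random_gompertz(d, "mass_g", "male", A = 2100, I = 65)
#> Fixed-endpoint Gompertz fit (mass_g, male, age_days axis)
#>   A = 2100, I = 65 (fixed); n = 192 goslings, 86 nests, 6 cohorts
#>   k      0.056257 +/- 0.00104
#>   sd_cohort = 0.00186, sd_nest = 0.00548, sd_residual = 86.39
#>   logLik = -1188.294, AIC = 2384.589, converged = TRUE
```

The fitted growth coefficient (0.0563/day) recovers the preset's
generating value of 0.056/day for Arctic male body mass; `sd_cohort`
and `sd_nest` are the between-year and between-brood SDs of *k*, and
`sd_residual` the within-gosling measurement scatter in grams.

The whole analysis — three colonies, both sexes, three traits, both
time axes, contrasts, residual hatch-date models and haldane rates —
runs with:

```r
report <- run_growth_pipeline(seed = 1)
report$contrasts$male.mass_g.age_days   # e.g. Barents vs North Sea k
report$hatchdate_slopes$mass_g          # slope per population, g/day
report$haldanes                         # SD units per generation
```

Daylight utilities stand alone:

```r
daylight_profile(68.583, 52.333, "2010-07-10", "2010-08-10")  # 24 h/day
accumulated_daylight(51.667, 4.233, as.Date("2010-05-25"),
                     as.Date("2010-06-24"))                   # ~541 h
```

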