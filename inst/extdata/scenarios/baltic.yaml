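# Short-distance migratory colony, Gotland, Baltic Sea.
population: baltic
latitude_deg: 57.417
longitude_deg: 18.883
n_cohorts: 15
cohort_years: [1986, 1987, 1988, 1989, 1990, 1991, 1992, 1993, 1994,
               1995, 1996, 1997, 1998, 1999, 2000]
nests_per_cohort: 15
brood_size_mean: 4
n_goslings_target: 933
mean_hatch_doy: 156        # ~5 June
hatch_sd_days: 5
cohort_hatch_shift_sd: 3
capture_age_median: 46
capture_age_min: 28
capture_age_max: 63
true_k:
  age:
    mass_g:   {male: 0.040, female: 0.042}
    head_mm:  {male: 0.037, female: 0.038}
    tarsus_mm: {male: 0.078, female: 0.074}
  daylight:
    mass_g:   {male: 0.0020, female: 0.0021}
    head_mm:  {male: 0.0019, female: 0.0019}
    tarsus_mm: {male: 0.0044, female: 0.0041}
sd_cohort:   {mass_g: 0.004, head_mm: 0.004, tarsus_mm: 0.012}
sd_nest:     {mass_g: 0.005, head_mm: 0.004, tarsus_mm: 0.012}
sd_residual: {mass_g: 80,    head_mm: 2.5,   tarsus_mm: 2.0}
hatchdate_slope: {mass_g: -3.91, head_mm: -0.15, tarsus_mm: -0.08}
year_trend:  {mass_g: 0, head_mm: 0, tarsus_mm: 0}
adult_A:
  mass_g:   {male: 2100, female: 1900}
  head_mm:  {male: 98,   female: 94}
  tarsus_mm: {male: 78,  female: 74}
hatch_I: {mass_g: 65, head_mm: 42, tarsus_mm: 28}
seed: 104
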