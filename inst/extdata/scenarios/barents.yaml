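# Arctic colony, Kolokolkova Bay, Barents Sea coast.
# true_k values are the published growth-coefficient estimates used as
# generating truth; variance components, A, I and hatch dates are
# package calibrations, not published values.
population: barents
latitude_deg: 68.583
longitude_deg: 52.333
n_cohorts: 6
cohort_years: [2003, 2004, 2006, 2008, 2013, 2015]
nests_per_cohort: 16
brood_size_mean: 4
n_goslings_target: 392
mean_hatch_doy: 191        # ~10 July
hatch_sd_days: 4
cohort_hatch_shift_sd: 3
capture_age_median: 29
capture_age_min: 5
capture_age_max: 42
true_k:
  age:
    mass_g:   {male: 0.056, female: 0.059}
    head_mm:  {male: 0.044, female: 0.045}
    tarsus_mm: {male: 0.087, female: 0.089}
  daylight:
    mass_g:   {male: 0.0023, female: 0.0025}
    head_mm:  {male: 0.0019, female: 0.0019}
    tarsus_mm: {male: 0.0036, female: 0.0037}
sd_cohort:   {mass_g: 0.004, head_mm: 0.004, tarsus_mm: 0.012}
sd_nest:     {mass_g: 0.005, head_mm: 0.004, tarsus_mm: 0.012}
sd_residual: {mass_g: 80,    head_mm: 2.5,   tarsus_mm: 2.0}
hatchdate_slope: {mass_g: -8.85, head_mm: -0.4, tarsus_mm: -0.08}
year_trend:  {mass_g: 0, head_mm: 0, tarsus_mm: 0}
adult_A:
  mass_g:   {male: 2100, female: 1900}
  head_mm:  {male: 98,   female: 94}
  tarsus_mm: {male: 78,  female: 74}
hatch_I: {mass_g: 65, head_mm: 42, tarsus_mm: 28}
seed: 103
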