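# Sedentary colony, Dutch delta, North Sea coast.
population: northsea
latitude_deg: 51.667
longitude_deg: 4.233
n_cohorts: 5
cohort_years: [2004, 2008, 2012, 2015, 2018]
nests_per_cohort: 6
brood_size_mean: 4
n_goslings_target: 116
mean_hatch_doy: 145        # ~25 May
hatch_sd_days: 11
cohort_hatch_shift_sd: 3
capture_age_median: 44
capture_age_min: 10
capture_age_max: 86
true_k:
  age:
    mass_g:   {male: 0.036, female: 0.035}
    head_mm:  {male: 0.036, female: 0.035}
    tarsus_mm: {male: 0.064, female: 0.059}
  daylight:
    mass_g:   {male: 0.0020, female: 0.0019}
    head_mm:  {male: 0.0020, female: 0.0020}
    tarsus_mm: {male: 0.0035, female: 0.0031}
sd_cohort:   {mass_g: 0.004, head_mm: 0.004, tarsus_mm: 0.012}
sd_nest:     {mass_g: 0.005, head_mm: 0.004, tarsus_mm: 0.012}
sd_residual: {mass_g: 80,    head_mm: 2.5,   tarsus_mm: 2.0}
hatchdate_slope: {mass_g: 5.39, head_mm: 0.1, tarsus_mm: -0.08}
year_trend:  {mass_g: 0, head_mm: 0, tarsus_mm: 0}
adult_A:
  mass_g:   {male: 2100, female: 1900}
  head_mm:  {male: 98,   female: 94}
  tarsus_mm: {male: 78,  female: 74}
hatch_I: {mass_g: 65, head_mm: 42, tarsus_mm: 28}
seed: 105
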