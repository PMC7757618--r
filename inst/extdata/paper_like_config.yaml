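# "Paper-like" synthetic-world configuration.
#
# Calibrated analytically so the generated world reproduces the magnitudes of
# the published 1993-2019 USI accounting:
#   - 139 countries, endpoint population ~7.0 billion (baseline ~5.1 billion)
#   - baseline TGR ~ N(13, 4) truncated to [1, 40]  -> global baseline ~13.1%
#   - endpoint MUIC ~ logN(5.217, 0.5): population-mean modeled TGR
#     alpha*exp(beta*mu + beta^2*sigma^2/2) = 3.12%, so the constructed global
#     prevented-case fraction is 1 - 3.12/13 ~= 0.76, and ~11% of countries
#     fall below MUIC 100 (iodine deficient) at endpoint.
n_countries: 139
n_survey_points: 24
seed: 1
alpha_true: 11049
beta_true: -1.63
log_noise_sd: 0.3
muic_log_mean: 5.217
muic_log_sd: 0.5
baseline_tgr_mean: 13.0
baseline_tgr_sd: 4.0
baseline_tgr_range: [1.0, 40.0]
baseline_population_scale: 0.72
population_range_thousands: [1000, 100000]
crude_birth_rate_range: [8, 35]
gni_range_usd: [1000, 60000]
wage_share_range: [0.35, 0.75]
participation_range: [0.5, 0.8]
hale_range: [50, 70]
region_weights:
  Africa: 29
  Americas: 22
  Eastern Mediterranean: 19
  Europe: 43
  South Asia: 11
  East Asia and Pacific: 15
baseline_year: 1993
endpoint_year: 2019
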