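# Small smoke-test configuration: 2 cities, 1 ensemble member, 50 draws,
# one-year periods on a 2x2 coarse domain. Completes in well under a minute.
seed: 1
n_draws: 50
K: 19
scenarios: [high, moderate]
truth:
  n_sites: 8
  n_cities: 2
  n_ensemble: 1
  coarse_grid: [28, 110, 2.0, 2.5, 2, 2]
  fine_grid: [28, 110, 0.25, 0.25, 16, 20]
  historical_period: ["2013-04-27", "2014-04-26"]
  future_period: ["2053-04-27", "2054-04-26"]
  missing_rate: 0.106
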