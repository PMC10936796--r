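# Example all-in-one pipeline configuration: simulate a small two-season
# survey and run every analysis. Use with
#   Rscript inst/cli/trawlniche.R run --config example-run.yaml
# or  run_pipeline("example-run.yaml") from R.
seed: 42
output: "trawlniche-out"
simulate:
  n_stations:
    spring: 500
    autumn: 500
  n_stomachs: 27
analyses: [validate, niche, ogive, lw, diet, envelope, abundance]
niche:
  variables: [temperature, depth]
  probs: [0.05, 0.95]
  season: both
ogive:
  sex: female
  mature_stages: [3, 4, 5, 6, 7]
  n_boot: 200
  level: 0.95
envelope:
  juvenile_max_tl: 20
  mature_stages: [5, 6]
abundance:
  trend: true
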