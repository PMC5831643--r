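# Example CLI config: simulate the rupture/repair probe with an aware dyad.
# Run from an installed package:
#   Rscript $(Rscript -e 'cat(system.file("cli/trustgame", package="trustgame"))') \
#     simulate --config example_simulate.yaml --out out/ --seed 1
investor:
  alpha: 0.4
  plan: 4
  tom: 2
  beta: 1/3
  omega: 1.0
  zeta: 0.5
  awareness: 2
trustee:
  alpha: 0.4
  plan: 4
  tom: 1
  beta: 1/3
  omega: 1.0
  zeta: 0
  awareness: 2
# path to a scenario JSON/YAML; omit for free play
# scenario: scenario_rupture.json
n_runs: 10
seed: 1
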