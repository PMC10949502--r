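# Reaction essentiality and regulation modes for the leucine producer
# (the strategy-figure workflow): growth vs production states, FVA at the
# production optimum, U/D/KO recommendation.
model:
  source: core
config:
  substrate_uptake_max: 4.67
  biomass_fraction: 0.2
product_exchange: EX_leu
stages: [gfba, classify, recommend]
seed: 1
output_dir: cgflux_essentiality
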