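# Aconitase attenuation sweep for the leucine producer (relative flux
# 1.0 down to 0.1; the 1.0 row is the control production state).
model:
  source: core
config:
  substrate_uptake_max: 4.67
  biomass_fraction: 0.2
product_exchange: EX_leu
stages: [sweep]
sweep_target: ACONT
seed: 1
output_dir: cgflux_acn_sweep
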