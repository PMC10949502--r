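# Acetyl-CoA ceiling with and without the phosphoketolase (bifido shunt)
# pathway: the acetate export ceiling rises from 2 to 3 mol per mol
# glucose after augmentation.
model:
  source: core
config:
  substrate_uptake_max: 4.67
product_exchange: EX_ac
stages: [yield]
yield_products: [EX_ac]
compare_bifido: true
seed: 1
output_dir: cgflux_bifido_yields
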