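# cgflux

Constraint-based flux analysis and in-silico strain design for the
central carbon metabolism of *Corynebacterium glutamicum*.

Pyruvate-derived products — L-alanine, L-valine, L-leucine — compete
with biomass formation for carbon, and rational producer design asks
which reactions to delete, attenuate, or upregulate. `cgflux`
implements the computational workflow behind that question on a bundled,
elementally balanced central-carbon core network:

* **Flux solvers** on the steady state *S v* = 0, *l* ≤ *v* ≤ *u*:
  flux balance analysis (FBA), flux variability analysis (FVA), and
  geometric FBA (the unique central distribution among alternate
  optima), on top of a built-in deterministic bounded-variable simplex.
* **Strain-design analytics**: reaction essentiality classification
  (*essential* — FVA interval excludes zero; *substitutable* — spans or
  touches zero; *blocked* — identically zero), U/D/KO regulation
  recommendations from growth-vs-production comparison, theoretical
  product yield ceilings, biomass-constrained production simulation
  (biomass ≥ 20 % of maximum by default), and relative-flux attenuation
  sweeps (e.g. aconitase from 1.0 down to 0.1 of its native flux).
* **A curated core model** of *C. glutamicum* (61 reactions, 50
  metabolites): glycolysis, PPP, PDH, full TCA, glyoxylate shunt,
  pyc/ppc anaplerosis, malic enzyme, lactate/alanine drains, the
  valine/leucine pathways, acetate metabolism, lumped respiration, and
  genotype presets — `LEU-28` (Δpyc Δppc, growth on glucose abolished)
  and `LEU-29` (icd attenuated to 20 % capacity, glyoxylate shunt
  active, growth restored).
* **Bifido-shunt augmentation**: the bifunctional phosphoketolase
  (FxpK) reactions F6P + Pi → E4P + AcP and X5P + Pi → G3P + AcP,
  raising the acetyl-CoA ceiling from 2 to exactly 3 per glucose with
  no carbon loss.
* **Antisense sRNA design**: 24-nt target-binding sequences antisense
  to the translation-initiation region (A of the start codon = +1, no
  position 0), assembled with scaffold and terminator into a cassette.
* **Model I/O**: SBML Level 3 + FBC, a native JSON dialect, and a TSV
  reaction table, all with exact round-trip; plus a declarative YAML
  pipeline (`run_pipeline()`) and a thin command-line front end
  (`inst/scripts/cgflux`).

## Worked example

```r
library(cgflux)

m   <- build_core_model()      # wild type, glucose medium
cfg <- sim_config()            # glucose uptake <= 4.67 mmol/gCDW/h

m
#> Metabolic model 'cg_core': 50 metabolites, 61 reactions (11 exchanges, 2 pseudo)
#> Objective: max BIOMASS

fba(m, cfg)
#> FBA fit (cg_core): status optimal; max BIOMASS = 0.90307647

max_theoretical_yield(m, cfg, "EX_val")
#> Theoretical yield: EX_val / EX_glc = 1 mol/mol (status optimal)

ess <- essentiality_analysis(m, cfg, "EX_leu")
table(ess$class)
#>       blocked     essential substitutable
#>            16            30            15
```

The biomass flux (0.903, arbitrary biomass units — the lumped
composition is a documented convention, so growth magnitudes are not
comparison targets) is carbon- and ATP-limited under the 4.67 glucose
cap. The valine ceiling of 1 mol/mol is exact pathway stoichiometry:
two pyruvate per valine, two pyruvate per glucose, with NADPH supplied
carbon-neutrally through the pyruvate-carboxylase/malic-enzyme cycle.
Under leucine production the classifier marks the lactate and alanine
drains substitutable (deletion candidates), and
`recommend_regulation()` marks the TCA entries (aceE, gltA, acn, icd)
for downregulation; `sweep_relative_flux(m, cfg, "ACONT")` then shows
leucine export rising monotonically as the aconitase cap falls.

The same analyses run from the shell:

```sh
Rscript inst/scripts/cgflux run \
  --config inst/extdata/pipeline_essentiality.yaml --out out/
```

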