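# sprshell

Modelling of angle-interrogated surface plasmon resonance (SPR) biosensors
whose sensing layer is loaded with gold-coated magnetite (Fe₃O₄@Au)
core-shell nanoparticles.

SPR refractometry reads out the angle of minimum p-polarized reflectivity
of a prism/metal-film/analyte stack (Kretschmann attenuated total
reflection). `sprshell` computes that readout end to end for a four-layer
sensor — BK7 prism / silver film / nanoparticle-biomaterial-water
composite / air — at 632.8 nm, for biomaterial analytes (blood plasma,
haemoglobin cytoplasm, lecithin) whose adsorption the nanoparticles are
meant to amplify.

The chain of models:

* **Core-shell homogenization.** A sphere with core permittivity ε_c,
  shell ε_s and fill fraction f = (b/a)³ gets the quasi-static effective
  permittivity
  ε_eff = ε_s[(ε_c+2ε_s) + 2f(ε_c−ε_s)] / [(ε_c+2ε_s) − f(ε_c−ε_s)].
* **Constituent calibration.** ε_c and ε_s are not taken from literature
  tables but back-solved from two published effective-permittivity rows;
  the two-row inverse problem reduces to a quadratic (two exact algebraic
  solutions), and the solver enumerates both, selects by residual,
  passivity and an extrapolation heuristic, and reports the alternate.
* **Composite mixing.** Biomaterial-coated grains in water are homogenized
  by a Maxwell-Garnett-type relation
  (1−F)(ε−ε_m)/(2ε+ε_m) + F(ε−ε_n)/(ε+ε_n) = 0, solved as a quadratic
  with continuity-in-F root tracking (a textbook-variant switch is
  provided).
* **Multilayer reflectivity.** Recursive N-media Fresnel recursion with
  phase factors e^{2i k_z d}, cross-checked against an independent 2×2
  characteristic-matrix route; dip localization by parabolic refinement;
  sensitivity S = Δθ_SPR/Δn (deg/RIU) and percentage enhancement metrics.

## Worked example

```r
library(sprshell)

# calibrate the unprinted core/shell constituents from two published rows
cal <- calibrated_constituents()
cal$eps_core    #> 3.286465+3.145988i   (magnetite-like)
cal$eps_shell   #> -10.56157+1.27695i   (gold-like at 632.8 nm)

# nanoparticle grain at fill fraction 0.73, then the sensing composite
mats <- default_materials()
e2 <- coreshell_eps(core_shell_geometry(f = 0.73), cal$eps_core, cal$eps_shell)
e2              #> 0.78887+3.19903i
spec <- composite_spec(e2, mats$hb_cytoplasm$eps, mats$water$eps,
                       alpha = 0.73, F = 0.1)
composite_eps(spec)   #> 1.894953+0.297938i

# dip angles: bare sensor vs haemoglobin sensing, with and without particles
fx <- make_fixtures()
run_scenario(fx$conventional)$dip
#> <dip_result> theta_SPR = 45.1060 deg, R_min = 0.057171
run_scenario(fx$no_coreshell_hb_cytoplasm)$dip
#> <dip_result> theta_SPR = 45.1404 deg, R_min = 0.057232
run_scenario(fx$with_coreshell_hb_cytoplasm_a2.5_F0.1)$dip
#> <dip_result> theta_SPR = 45.3958 deg, R_min = 0.088031
```

The bare sensor dips at 45.106°. Dissolved haemoglobin alone moves the dip
by 0.034°; with the core-shell nanoparticles in the layer the same analyte
moves it by 0.290° — the nanoparticle loading amplifies the refractometric
response by almost an order of magnitude for this configuration (α = 0.73
assumed for the biomaterial coat; see the vignette for why this parameter
is an assumption and how it is exposed).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/spr-sim.R effmed coreshell --b 10 --a 15
Rscript inst/cli/spr-sim.R calibrate
Rscript inst/cli/spr-sim.R fixtures --outdir fixtures
Rscript inst/cli/spr-sim.R dip --config fixtures/conventional.yaml --json
```

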