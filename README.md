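# promec

Process simulator for a coupled **pressure-retarded osmosis (PRO) /
microbial electrolysis cell (MEC)** system: a batch PRO unit extracts clean
water and osmotic energy from the salinity gradient between a dilute organic
feed (synthetic wastewater) and a concentrated NaCl draw; the concentrated
feed effluent then becomes the anolyte and the diluted draw the catholyte of
a two-chamber MEC, whose electrical consumption for hydrogen evolution is
capped by the osmotic energy the PRO unit harvested. The package is for
researchers in bioelectrochemical systems and osmotic processes who want to
explore the water–energy coupling: how influent volume, draw salinity and
applied voltage trade off water recovery, organic removal and H₂ yield.

## Models

**PRO.** The water flux solves the implicit internal/external
concentration-polarization equation

J = A { [π_D e^(−J/k) − π_F e^(J·S/D)] / [1 + (B/J)(e^(J·S/D) − e^(−J/k))] − P },

with feed/draw volumes and salt amounts advanced in time (reverse salt flux
J_S = B·J/(A·i·R·T)), either a constant applied pressure or the
maximum-power schedule P = (π_D − π_F)/2, and harvested energy
Q_PRO = a ∫ P·J dt. Osmotic pressures follow van't Hoff, π = i·R·T·C, with
the multi-solute feed carried as an equivalent NaCl molarity from its
conductivity (0.64 g/L per mS/cm).

**MEC.** A batch two-population anode model: exoelectrogens oxidise acetate
through an intracellular mediator pool (double Monod in substrate and
oxidised mediator) and feed electrons to the circuit; acetoclastic
methanogens consume acetate without current. Nernst anode/cathode
potentials, a mediator/substrate concentration overpotential, and a
biomass-dependent internal resistance close the circuit algebraically:

I = [(E_C − E_A) + E_ext − η_con] / (R_ext + R_in) · (M_T − M_OX)/(ε + M_T − M_OX),

with Q_MEC = E_ext ∫ I dt and V_H2 = Y_H2 · (∫ I dt)/(2F) · RT/P.

Membrane and kinetic defaults are calibrated to the published bench
validation runs; `vignettes/promec-methods.Rmd` documents every equation,
parameter, calibration decision and limitation.

## Worked example

The reference feasibility scenario — 600 mL of feed (193 mg/L acetate,
3.51 mS/cm) against 600 mL of 0.8 M NaCl at the maximum-power pressure
schedule, stopped at 0.5 L m⁻² h⁻¹, with the MEC at 0.8 V running on the
harvested energy:

```r
library(promec)
res <- run_system(system_scenario())
res
#> Coupled PRO-MEC run
#>   PRO:  494 mL water, 578 J in 14.8 h
#>   MEC:  99.9 % removal, 35.6 mL H2, 473 J in 46.0 h (substrate_removed)
#>   energy surplus: 105 J
```

The PRO side recovers 494 mL of clean water and 578 J of osmotic energy in
14.8 h; coupling concentrates the feed ~5.7-fold into a 106 mL anolyte. The
MEC then removes 99.9% of the acetate and evolves 35.6 mL of hydrogen while
consuming 473 J — inside the 578 J budget, leaving a 105 J surplus (one PRO
unit could drive more than one MEC). Sweeping the external voltage shows the
study's optimum near 0.9 V:

```r
sw <- sweep_system(system_scenario(), "voltage", seq(0.5, 1.1, 0.1))
sw[, c("value", "Q_MEC_J", "V_H2_mL", "removal_pct", "mec_hrt_h")]
#>   value Q_MEC_J V_H2_mL removal_pct mec_hrt_h
#> 1   0.5    84.9    10.2        99.9      82.8
#> 2   0.6   221.3    22.2        99.9      75.1
#> 3   0.7   359.2    30.9        99.9      56.3
#> 4   0.8   473.2    35.6        99.9      46.0
#> 5   0.9   571.0    38.2        99.9      39.2
#> 6   1.0   577.9    34.8        88.2      29.2
#> 7   1.1   577.9    31.6        79.4      25.5
```

Hydrogen peaks (38.2 mL) at 0.9 V; above it the energy budget binds and both
removal and H₂ fall. Scenario YAML presets for the five study designs ship
under `inst/extdata/presets/` (`list_presets()`), and a thin command-line
front end lives at `inst/cli/promec`:

```sh
Rscript inst/cli/promec preset --name exp2_feasibility --out results/
Rscript inst/cli/promec run --config my_scenario.yaml --out results/
```

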