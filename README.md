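# fentonsim

Kinetic simulation and calibration of Fenton and photo-Fenton degradation
of organic contaminants in a recirculating pilot plant.

Advanced oxidation processes degrade pharmaceuticals and other
contaminants of emerging concern with hydroxyl radicals (HO•) generated by
the iron/peroxide couple. Fully mechanistic models of these systems must
be rebuilt for every new contaminant; regression models do not transfer.
`fentonsim` implements a middle road for process-engineering use: a small
target-independent radical core plus a degradation mechanism *generated
from the contaminant's carbon number alone*, so that describing a new
compound takes exactly two new rate constants. The model tracks the
contaminant, H₂O₂ **and total organic carbon (TOC)** — the lumped quantity
used to judge water quality — in a four-compartment model of a 15-L
recirculating photo-reactor plant.

## The model in brief

Radical core (one well-mixed volume, concentrations in mol/L):

    Fe³⁺ + H₂O₂ → Fe²⁺ + H⁺ + HO₂•      r₁ = k₁[Fe³⁺][H₂O₂]
    Fe²⁺ + H₂O₂ → Fe³⁺ + OH⁻ + HO•      r₂ = k₂[Fe²⁺][H₂O₂]
    Fe³⁺ —light→ Fe²⁺ + HO•             r₀ = k₀[Fe³⁺]   (irradiated volume)
    HO• → (lost)                        r_elim = k_elim[HO•]

Degradation cascade, generated from the carbon number NC: fictitious
fragments FR_b with carbon weights FNC_b = NC/2^b,

    FR_{b-1} + HO• → 2 FR_b   (b = 1..F,  F = ⌈log₂ NC⌉)
    FR_F + HO• → mineralized carbon

with rate constant `k_target` for the first attack and `k_fragment` for
all later steps, and TOC = Σ_b FNC_b·c_b over **all** organic species.
Reactions competing for HO• are damped by the rate-weighted share
`r_i → r_i²/Σr_j` (elimination included), which keeps the explicit
fixed-step plant integration stable; a per-step availability clamp
guarantees non-negative concentrations. Calibration is staged: core
constants from organics-free blank assays, then the two target constants
per compound with weights encoding the TOC > target > H₂O₂ priority.

## Worked example

Simulate the paracetamol training assay (0.26 mmol/L PCT, 0.09 mmol/L
Fe²⁺, the stoichiometric 5.56 mmol/L H₂O₂ dose) under irradiation, at the
package's reference constants:

```r
library(fentonsim)
m <- fenton_model("PCT")
tr <- simulate_experiment(m, "EXP13_PCT")
tr
#> Simulated run EXP13_PCT (PCT, irradiated): 120 min, dt = 0.05 s
#>   [target]0 = 0.26, [Fe2+]0 = 0.09, [H2O2]0 = 5.56 mmol/L
#>   TOC conversion: 32.1% at 30 min, 49.6% final
#>   H2O2 consumed: 42.2% at 10 min
```

A third of the organic carbon is gone after 30 minutes and about half by
the end of the run, while the same assay in the dark reaches only ~13% and
~23% — the photo-reduction of Fe³⁺ in the 1.5-L irradiated compartment
keeps the catalytic cycle running. The fragment concentrations approach
asymptotes as the oxidant runs out:

```r
tail(tr$states[, 1, c("f1", "f2", "f3")], 1)  # tank, mmol/L, 120 min
#>        f1        f2        f3
#> 0.0935064 0.1820417 0.3007154
```

Stoichiometric dosing for any supported formula:

```r
stoichiometric_dose(fenton_compounds("PCT"), 40.00)  # mg/L -> mmol/L H2O2
#> [1] 5.556664
```

And a full synthetic calibration round trip (no measured data required):

```r
blanks <- generate_synthetic(c("BLANK_3", "BLANK_4"), sigma = 0, seed = 1)
core <- fit_fenton_core(blanks)
coef(core)
#>     k0     k1     k2
#>  0.056  5.000 63.000
```

A command-line workflow (`simulate`, `synth`, `fit`, `evaluate`) is
available as a thin Rscript:

```sh
Rscript inst/cli/fenton.R simulate --experiment EXP13_PCT --out out/
```

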