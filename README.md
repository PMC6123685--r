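# cicrfit

Quantitative analysis of ryanodine receptor (RyR1/RyR2) Ca²⁺
sensitivity for channel physiologists and structural biologists working
on Ca²⁺-induced Ca²⁺ release (CICR).

Equilibrium [³H]ryanodine binding reads out the average activity of a
channel population because ryanodine binds only open channels. Its
Ca²⁺ dependence is biphasic, and `cicrfit` models it as

    A([Ca²⁺]) = Amax · fA · (1 − fI),   fX = [Ca²⁺]^nX / ([Ca²⁺]^nX + KX^nX)

where the A-site (KA, nA) activates the channel and the I-site (KI, nI)
inactivates it; the sensitivity readout is pCa₅₀ = −log₁₀ KA. Around
this core the package provides:

* **Curve fitting** — multi-start Levenberg–Marquardt fits of replicate
  binding curves with fixed Hill coefficients, Scatchard Bmax
  normalization, panel-wide Hill-coefficient selection by summed R²,
  and per-genotype caffeine-sensitization tables (ΔpCa₅₀, resting-activity
  fold-change vs wild type at pCa 7).
* **Free-Ca²⁺ speciation** — an EGTA/BAPTA-style calculator solving the
  chelator mass balance (forward and inverse) to design pCa ladders.
* **Trace analysis** — min–max normalization of dual cytoplasmic/ER
  fluorescence recordings, deterministic oscillation detection, ER
  upper-level estimation, and caffeine dose–response EC₅₀ fitting.
* **Structure comparison** — Kabsch superposition of PDB/mmCIF models,
  domain-displacement measurement between ligand states (e.g. CTD and
  core-solenoid shifts), residue-pair distances and a planar
  pocket-size proxy.
* **Synthetic data** — seeded generators for every input above, so the
  whole pipeline is testable without laboratory data.

## Worked example

```r
library(cicrfit)

## wild type and a disease-class mutant with eightfold lower KA
wt  <- binding_params(Amax = 0.4, KA = 10^(-4.79), KI = 1e-3, nA = 2, nI = 1)
mut <- binding_params(Amax = 0.4, KA = 10^(-4.79)/8, KI = 1e-3, nA = 2, nI = 1)

## simulate a replicate binding curve and fit it back
curve <- gen_binding_curve(wt, noise_sd = 0.02, replicates = 4, seed = 42,
                           genotype = "WT", condition = "control")
fit <- fit_binding_curve(curve, nA = 2, nI = 1)
fit
#> binding fit [WT/control]: status=ok, pCa50=4.819 (SE 0.026), R2=0.9798

## extrapolate to resting cytoplasmic Ca2+ (pCa 7)
resting_activity(wt)                  # 1.52e-05
resting_activity(mut)                 # 0.000971
fold_change_at_rest(wt, mut)          # 63.8

## design a pCa ladder with 10 mM EGTA (apparent Kd 150 nM)
sys <- buffer_system(chelator_spec("EGTA", 10e-3, Kd_Ca = 1.5e-7))
pca_ladder(sys, c(8, 7, 6, 5))
#>   pCa  total_Ca_M status
#> 1   8 0.000625010     ok
#> 2   7 0.004000100     ok
#> 3   6 0.008696652     ok
#> 4   5 0.009862217     ok
```

The fitted pCa₅₀ (4.82 ± 0.03) recovers the generating truth of 4.79
within the assay's SEM scale. The fold-change shows why a modest
sensitivity shift matters: with nA = 2, an eightfold KA gain produces a
~64-fold higher modelled open probability at resting Ca²⁺ — a
constitutively leaky channel. The ladder column `total_Ca_M` is the
total Ca²⁺ to add per target pCa; at pCa 7 the 10 mM chelator is
nearly half-saturated, hence ~4 mM.

End-to-end, `run_pipeline(list(seed = 1, out_dir = "run1"))` simulates
a four-genotype panel, fits every genotype × condition, and writes
`binding.csv`, `fits.json`, `summary.tsv` and a hash-bearing
`manifest.json`; identical seeds reproduce byte-identical tables.

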