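# dissolkin

Dissolution-profile comparison, drug-release kinetics and liquisolid
formulation arithmetic for sustained-release tablet development.

Developing a sustained-release oral dosage form produces three kinds of
numbers: in-vitro dissolution curves (cumulative % of the dose released
over a two-stage gastric/intestinal pH protocol), the composition
arithmetic of the dosage form itself, and the powder/tablet quality
metrics that decide whether it can be manufactured. dissolkin implements
the full computational layer over all three, for formulation scientists
and for anyone who needs to reproduce or audit a release-kinetics table:

* **Profile comparison** — the model-independent difference and
  similarity factors

  f1 = 100 · Σ|R_t − T_t| / ΣR_t,  f2 = 50·log10(100·[1 + (1/n)Σ(R_t − T_t)²]^(−1/2)),

  with FDA-style point selection (truncation after the reference passes
  85% release) and the equivalence rule f1 ∈ [0, 15] and f2 ∈ [50, 100]
  (`compare_profiles()`).
* **Release kinetics** — least-squares fits of the zero-order
  (Q = k₀t + c), first-order (log10(100 − Q) linear in t), Higuchi
  (Q = k_H√t + c) and Korsmeyer–Peppas (Q = k·tⁿ) models on their
  linearizing transforms, scored by R² and mean percentage error,
  best-model selection, and mechanism classification from the
  diffusional exponent n (`analyze_profile()`, `kinetic_report()`).
* **Formulation arithmetic** — liquid load factor
  Lf = (m_API + m_vehicle)/m_carrier, percent-by-weight quantities and
  the carrier:coating ratio for liquisolid / Liqui-Mass dosage forms
  (`formulation_report()`), with a built-in ten-formulation propranolol
  development series (`propranolol_formulations()`).
* **Powder & tablet QC** — Carr's compressibility index, angle of
  repose, flow rate and friability, with compendial classification bands
  (`qc_report()`, `friability()`).
* **Synthetic experiments** — a seeded generator of noisy two-stage
  dissolution runs and powder measurements so the entire pipeline is
  testable without laboratory data (`simulate_profile()`), plus a study
  orchestrator that turns one YAML/JSON config into the full report set
  (`run_study()`).

## Worked example

Simulate a sustained-release formulation (Higuchi kinetics, 1% assay
noise, triplicate) on the standard 19-point schedule, identify its
release model, and compare a fast-releasing formulation against it:

```r
library(dissolkin)

sim <- simulate_profile("higuchi", list(k = 2.2), noise_sd = 1,
                        n_replicates = 3, seed = 42, formulation_id = "F-8")
sim[[1]]
#> <dissolution_profile> F-8 (replicate R1): 19 points, t = 15..1440 min, release 8.4..83.6%
#>   stages: pH 1.2 from 0 min; pH 7.4 from 120 min

analyze_profile(mean_profile(sim))
#> <model_selection_report> F-8
#>   <kinetic_fit> zero_order on F-8: k = 0.05142, R² = 0.9590, MPE = 17.91% (19 points)
#>   <kinetic_fit> first_order on F-8: k = 0.001114, R² = 0.9967, MPE = 7.33% (19 points)
#>   <kinetic_fit> higuchi on F-8: k = 2.247, R² = 0.9993, MPE = 1.72% (13 points, truncated at 60%)
#>   <kinetic_fit> korsmeyer_peppas on F-8: k = 2.072, n = 0.513, R² = 0.9984, MPE = 1.78% (13 points, truncated at 60%)
#>   best model: higuchi; mechanism: anomalous

fast <- simulate_profile("first_order", list(k = 0.02), noise_sd = 1,
                        seed = 42, formulation_id = "PMT-1")[[1]]
compare_profiles(fast, mean_profile(sim), rule = "fda85")
#> <comparison_result> PMT-1 vs F-8 (rule fda85)
#>   f1 = 74.75, f2 = 14.58 over 7 points: NOT equivalent
```

Reading the output: the fit recovers the generating Higuchi constant
(k̂_H = 2.247 %/√min against a true 2.2) with the highest R² on its own
transformed scale, and only the 13 points at ≤ 60% release enter the
Higuchi/Korsmeyer–Peppas fits; the power-law exponent n ≈ 0.51 sits in
the anomalous-transport band, as expected for square-root kinetics. The
comparison truncates after the fast formulation's reference curve passes
85% (7 points kept) and the factor pair (f1 = 74.75, f2 = 14.58) is far
outside the equivalence bands.

The derived composition table of the built-in development series:

```r
head(formulation_report(), 4)
#> # A tibble: 4 × 8
#>   formulation_id vehicle_name vehicle_mass_mg total_mass_mg liquid_load_factor
#> 1 PMT-1          ""                         0           269               0.44
#> 2 PMT-2          ""                         0           269               0.44
#> 3 F-1            "Tween 80"                40           309               0.67
#> 4 F-2            "Tween 20"                40           309               0.67
#> # ℹ 3 more variables: vehicle_pct_ww, eudragit_pct_ww, carrier_coating_ratio
```

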