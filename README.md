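# ligandflow

ligandflow is an R package for the computational workflow around
small-molecule inhibitors of protein–protein interactions — built for the
campaign style in which a known tetramerization-domain inhibitor (here, an
NHR2-binding benzodioxole–carboxylate template and its analogs M23, M27,
M10) is followed up by shape-based analog screening, orthogonal
biophysical assays, molecular-dynamics epitope mapping, and
membrane-permeability prediction. It is written tidyverse-style: data
frames in, tibbles out, `tidy()`/`glance()` for fitted objects,
`autoplot()` for every result type.

The package covers five stages:

1. **Ligand-based virtual screening** — Gaussian shape overlap
   (first-order Grant–Pickup spheres) plus pharmacophore "color" features
   (donor, acceptor, anion, cation, hydrophobe, ring), combined into the
   Tanimoto-Combo score
   `combo = V_AB/(V_AA+V_BB−V_AB) + color analog ∈ [0, 2]`,
   with rigid-overlay optimization, library ranking, threshold censuses,
   and programmatic pharmacophore-anchor checks.
2. **Assay fitting** — 4-parameter logistic dose-response (IC50), the
   exact quadratic 1:1 binding isotherm for MST titrations (K_D,app),
   nanoDSF F350/F330 melting curves (Tm, ΔTm via the first-derivative
   method refined by a two-state fit), STD-NMR epitope effects
   (I_sat/I_0 relative to a reference proton), and Henderson–Hasselbalch
   pKa fits with `protonated_fraction()`.
3. **Binding-epitope detection** — residue contact fingerprints
   (heavy-atom pairs < 4 Å), bound-frame filtering (≥ 5 residues),
   symmetry-aware ligand density grids (OpenDX output), Jaccard/average-
   linkage fingerprint clustering, and occupancy-ranked epitope reports
   with hot-spot flagging.
4. **Permeability prediction** — the solubility–diffusion resistance
   integral `1/P_eff = ∫ exp(ΔG(z)/kBT)/D(z) dz` over a PMF, calibrated
   against PAMPA reference data by OLS on the log10 scale, with the
   published high / low-to-medium classification bands.
5. **Synthetic data** — seeded generators for every input above, with
   planted truths recorded in manifests, so the whole pipeline is
   testable offline.

## Worked example

Screen a noisy synthetic analog library against the built-in template,
fit an MST titration, and calibrate a permeability prediction:

```r
library(ligandflow)

tmpl <- toy_template()
lib  <- gen_molecule_library(tmpl, n = 6, noise_levels = c(0, 0.2, 0.5),
                             n_decoys = 2, seed = 1)
rep  <- screen_library(tmpl, lib, thresholds = c(1.5, 1.4, 1.3),
                       n_starts = 5, seed = 2)
rep
#> # A tibble: 8 × 5
#>   id         shape_tanimoto color_tanimoto combo  rank
#> 1 analog_001          1.00           1     2.00      1
#> 2 analog_004          1              1     2         2
#> 3 analog_002          0.964          0.954 1.92      3
#> 4 analog_005          0.966          0.882 1.85      4
#> 5 analog_003          0.901          0.774 1.68      5
#> 6 analog_006          0.864          0.600 1.46      6
#> 7 decoy_002           0.410          0.118 0.528     7
#> 8 decoy_001           0.377          0.112 0.489     8
screen_census(rep)
#> 1.5 1.4 1.3
#>   5   6   6
```

The zero-noise analogs recover the maximal combo of 2 (identical shape
and features after overlay), jittered analogs degrade monotonically, and
random decoy scaffolds fall far below every census threshold: 5 library
members score above 1.5, 6 above 1.4.

```r
mst <- gen_mst_titration(kd = 39, target_conc_nM = 100, noise_sd = 0.2,
                         seed = 7)
fit <- fit_mst_kd(mst, target_conc_nM = 100)
tidy(fit)
#> # A tibble: 3 × 3
#>   term    estimate std.error
#> 1 kd_app   39.8       1.56
#> 2 f_free    0.0958    0.0444
#> 3 f_bound  10.00      0.0882
```

A 16-point 1:1 dilution from 1 mM with 100 nM labeled target, planted at
K_D = 39 µM, is recovered as 39.8 ± 1.6 µM by the exact isotherm fit.

```r
cal <- fit_calibration(reference_calibration_pairs())
cal
#> <lf_calibration> log Peff/PAMPA = 0.2705 x log Peff/PMF + -5.3059
#>                  (n = 5, sd 0.00462)
apply_calibration(cal, c(0.56, -2.95), compound = c("M23", "M27_H"))
#> # A tibble: 2 × 6
#>   compound log_peff_pmf log_peff_pampa  peff        class
#> 1 M23              0.56          -5.15  7.01e-6     high
#> 2 M27_H           -2.95          -6.10  7.87e-7     low_to_medium
```

The five shipped reference pairs give the calibration line
`y = 0.27 x − 5.31`; mapping the computed log permeabilities of the
neutral and protonated species through it classifies M23 as highly
permeable (> 4.7 × 10⁻⁶ cm/s) and its protonated form's congener M27_H as
low-to-medium — the protonation-state dependence that makes the measured
pKa values pharmacologically meaningful.

Every fitted object also has an `autoplot()` method, and
`run_pipeline(list(seed = 1), out_dir = "run1")` executes all stages on
synthetic data and writes per-stage CSV/JSON plus a collated
`summary.json`.

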