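---
title: "Methods: shape screening, assay fitting, epitope detection, and permeability prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape screening, assay fitting, epitope detection, and permeability prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandflow)
```

ligandflow implements the computational side of a small-molecule
protein–protein interaction inhibitor campaign against a tetramerization
domain: finding shape/pharmacophore analogs of a template inhibitor,
fitting the biophysical assays that characterize the hits, locating their
binding epitopes in free-ligand-diffusion simulations, and predicting
their membrane permeability from free-energy profiles. This vignette
explains each model, its assumptions, the tunable parameters, and the
design decisions taken where the methods literature leaves choices open.

## Gaussian shape and color scoring

Molecular shape similarity uses the first-order Gaussian sphere model:
each heavy atom contributes a spherical Gaussian
$\rho_i(r) = p\,e^{-\alpha_i \lVert r - r_i\rVert^2}$ with amplitude
$p = 2.7$ and width $\alpha_i$ fixed so the Gaussian integrates to the
atom's van der Waals sphere volume. The overlap volume of two molecules is
then the sum of pairwise product integrals

$$V_{AB} = \sum_{i\in A}\sum_{j\in B} p^2
  \left(\frac{\pi}{\alpha_i+\alpha_j}\right)^{3/2}
  \exp\!\left(-\frac{\alpha_i\alpha_j}{\alpha_i+\alpha_j}
  d_{ij}^2\right),$$

and the shape Tanimoto is $V_{AB} / (V_{AA} + V_{BB} - V_{AB})$.
Higher-order (multi-atom) product corrections are deliberately omitted:
with the first-order density the analytic sum is *exactly* the integral of
the product of summed atomic densities, which is what the test suite's
grid-quadrature oracle integrates numerically. Because the proprietary
scorers' atomic radii are unpublished, all heavy atoms share one 1.70 Å
radius by default ("radii off" mode); per-element radii can be passed.
Hydrogens never contribute to shape. Pair terms below $10^{-12}$ of the
peak are truncated for speed.

Pharmacophore ("color") similarity uses the same Gaussian algebra on typed
feature points — donor, acceptor, anion, cation, hydrophobe, ring — with
overlap counted only between features of the same kind (feature radius
1.0 Å by default). The color Tanimoto is 0 by convention when either
feature set is empty, so a featureless molecule's self-similarity is 1
(shape only), not 2. The Tanimoto-Combo score is the sum of the two
Tanimotos, with maximum 2 for a perfectly overlaid identical, featured
molecule.

Feature typing is rule-based and the rules are data
(`inst/extdata/feature_rules.yaml`): donors are N/O with explicit
hydrogen; acceptors are N/O with a lone pair; anions are formally negative
groups (plus neutral carboxylic acids, deprotonated at pH 7.4) placed at
the charged-group centroid; cations are formally positive atoms plus
aliphatic amines; hydrophobes are connected clusters of carbons with no
polar neighbours, one feature per cluster; rings are smallest-set-of-
smallest-rings centroids. Explicit-hydrogen input is required — donor
counts on implicit-H structures would silently be wrong, so such input is
rejected with guidance. No parity with any commercial feature assigner is
claimed; the rules are documented, editable, and deterministic.

## Overlay optimization

`optimize_overlay()` maximizes the combo score over rigid motions of the
query. Starting poses are the centroid-matched identity pose, the
inertial-frame alignment (principal axes of the heavy-atom covariance)
with its four proper axis flips, and — beyond those five — seeded uniform
random rotations. Each start is refined by Nelder–Mead ascent over the six
rigid-motion parameters (rotation vector about the reference centroid plus
translation). The refined pose is never allowed to score below its start,
ties between starts break on shape Tanimoto, and everything is
deterministic given `seed` and `n_starts`. The objective during refinement
is the combo itself, matching the ranking criterion. The test suite checks
the optimizer against an exhaustive two-stage pose-grid search (10° / 0.1 Å
final resolution) on small toys.

`screen_library()` ranks a library by combo and reports a census (count of
molecules above each threshold). Molecules whose feature assignment fails
are collected in a `skipped` attribute and warned about, never silently
dropped. `pharmacophore_point_check()` is the programmatic surrogate for
visual pharmacophore inspection: it asks whether the overlaid query places
a feature of a required kind within a distance tolerance (default 1.5 Å)
of each template anchor, e.g. a ring feature at the benzodioxole centroid
and an anion at the carboxylate.

## Assay fitters

All fitters share the `titration_series` container (long tibble of
x/replicate/response) and Levenberg–Marquardt least squares
(`minpack.lm`), with standard errors from the Jacobian-based covariance at
the optimum. On noiseless data every fitter reaches a residual sum of
squares no larger than at the planted truth (a property the tests
enforce).

**Dose-response (IC50).** Four-parameter logistic
$y = b + (t - b)/(1 + (x/\mathrm{IC}_{50})^h)$ fitted on
log10 concentration with top, bottom and Hill slope free (the assay's
"sigmoid dose-response" leaves the asymptotes unconstrained; fixing the
top at 1 would bias IC50 whenever the lowest dose already has an effect).
IC50 is parameterized on the log scale; its standard error is
delta-method transformed. Estimates outside the tested range are flagged
`extrapolated`, and IC50 > 1000 µM (or upward extrapolation) is
classified inactive. Viability input is first normalized to the vehicle
(DMSO) control mean via `normalize_to_vehicle()`.

**MST binding (K_D,app).** The exact 1:1 isotherm with ligand depletion:
bound fraction
$f_b = \bigl((L+T+K) - \sqrt{(L+T+K)^2 - 4LT}\bigr)/(2T)$ for total
ligand $L$, fixed labeled-target concentration $T$ (100 nM by default)
and dissociation constant $K$, with
$F_\mathrm{norm} = f_\mathrm{free} + (f_\mathrm{bound} -
f_\mathrm{free})\,f_b$. $K$ is fitted on the log scale within generous
bounds; hitting a bound flags the fit. When $T \ll K$ the model reduces
to the hyperbola $L/(L+K)$, which the tests verify. The choice among
thermophoresis/T-jump traces is upstream; the fitter takes one response
column (replicates welcome).

**nanoDSF melting (Tm).** The F350/F330 ratio is formed pointwise,
smoothed with a Savitzky–Golay filter (window 11, order 3 — the
instrument literature is silent on smoothing, so the filter is mild and
configurable), and the transition located at the first-derivative
extremum, whose sign is auto-detected (a transition may raise or lower
the ratio). Because the derivative peak of a two-state transition is
broad, the bare extremum estimator is statistically inefficient; by
default the extremum therefore *seeds* a two-state fit — logistic
transition plus linear baseline — and the reported Tm is the fitted
midpoint, mirroring how instrument software obtains Tm while the
derivative curve remains the visualization. When both channels are
supplied the fit is joint over log F330 and log F350 (fluorescence noise
is multiplicative, and the 330 channel pins the baseline), which is the
information-optimal use of the two channels; simulation puts this
estimator at the Cramér–Rao bound (≈0.06–0.09 °C at 0.5 % channel noise,
0.5 °C steps). `refine = "none"` gives the bare derivative extremum. A
scan whose smoothed amplitude does not clearly exceed the residual noise
is rejected ("no transition detected") rather than returning a noise
peak. Rescaling both channels by a common factor leaves Tm unchanged.
`delta_tm()` is the signed difference complex − apo; negative shifts
indicate destabilization, consistent with a compound that interferes with
the tetramer–dimer equilibrium.

**STD epitope mapping.** Per proton, the effect is the on-/off-resonance
intensity ratio $I_\mathrm{sat}/I_0$, expressed relative to a reference
proton (100 %): either the largest effect or a named proton, in which
case other protons can exceed 100 %. The broader NMR literature often
defines the STD effect as the attenuation $(I_0 - I_\mathrm{sat})/I_0$;
both conventions are supported via `direction`, and neither is asserted
as the "right" one — the printed percentages in this family of
experiments are ambiguous between the two, which the documentation
states rather than resolves.

**pKa (Henderson–Hasselbalch).** Chemical shift of a reporter proton vs
pH: $\delta(\mathrm{pH}) = \delta_\mathrm{base} +
(\delta_\mathrm{acid} - \delta_\mathrm{base})/(1 +
10^{\mathrm{pH} - \mathrm{p}K_a})$, one fit per reporter proton, with
flat titrations rejected. `protonated_fraction()` evaluates
$1/(1 + 10^{\mathrm{pH}-\mathrm{p}K_a})$; note that at pH 7.5 a site
with pKa 7.8 is ~2:1 protonated by this closed form even where a
qualitative "~1:1" description is common — the function reports the
closed form.

## Epitope detection from diffusion trajectories

Trajectories arrive as multi-model PDB plus residue metadata (binary MD
formats are out of scope; the container is
frames × atoms × 3 in Å). The pipeline is:

1. **Contacts.** A residue is contacted in a frame when any of its heavy
   atoms is strictly within 4.0 Å of any ligand heavy atom; hydrogens on
   both sides are excluded. The implementation is vectorized but must
   equal an all-pairs brute-force loop exactly, which the tests check.
2. **Bound frames.** Frames contacting ≥ 5 distinct residues count as
   bound — contact with a handful of residues distinguishes a posed
   ligand from a grazing encounter.
3. **Density grid.** Each bound frame's protein Cα set is superposed onto
   a reference conformer by quaternion (Horn) least squares; the fitted
   transform is applied to the ligand atoms and voxel counts accumulated
   (default 1 Å spacing; OpenDX output). Symmetry operators (explicit
   rigid transforms — no automatic symmetry detection) fold equivalent
   positions onto one asymmetric unit by replacing every position with
   its lexicographically smallest image, so total counts are conserved.
4. **Clustering.** Binary residue fingerprints of the bound frames are
   clustered agglomeratively: Jaccard distance, average linkage, tree cut
   at 0.7. These three defaults are exposed in the interface because the
   upstream methods literature defers them; they are declared defaults,
   not inferred settings. With a chain map (e.g. `c(C = "A", D = "B")`
   for a 2-fold symmetric tetramer), symmetry-equivalent chains are
   canonicalized onto one protomer before clustering so the two copies of
   an epitope merge.
5. **Report.** Clusters become epitopes ranked by occupancy
   = 100 × member frames / *all* trajectory frames. Using all frames (not
   only bound ones) as denominator makes the occupancy a fraction of
   simulation time, which is how site populations like "13.2 %" read
   naturally; the denominator is switchable. Per-residue contact
   frequencies are reported per epitope, with user-designated hot-spot
   residues (for the tetramerization domain: W498, W502, D533, E536,
   W540) flagged.

## Permeability from PMF profiles

The inhomogeneous solubility–diffusion model gives the resistance
integral

$$\frac{1}{P_\mathrm{eff}} = \int_{z_1}^{z_2}
  \frac{e^{\Delta G(z)/k_BT}}{D(z)}\,dz,$$

evaluated by the trapezoidal rule with $z$ converted to cm and
$\Delta G$ referenced to zero in the water phase (profiles violating that
reference are rejected). Defaults: $T = 300$ K, constant
$D = 10^{-5}\ \mathrm{cm^2\,s^{-1}}$ (a z-resolved D profile is
accepted), membrane bounds = the span where $|\Delta G| > 0.1$ kcal/mol.
The constant-D assumption biases the absolute $P_\mathrm{eff}$, which is
exactly why calibration against measured PAMPA permeabilities is
mandatory for reported values: `fit_calibration()` is an ordinary least
squares of experimental $\log_{10}(P_\mathrm{eff}/P_0)$ on computed
values over reference compounds, and `apply_calibration()` maps new
computed values through the line, exponentiates, and classifies:
high > 4.7×10⁻⁶ cm/s; low-to-medium 7×10⁻⁷–2.1×10⁻⁶; low below that
band; and an explicit `medium_high_gap` class for the interval the named
bands leave open. The package ships the five published lead-compound
calibration pairs (`reference_calibration_pairs()`) as its default line;
the original nine-compound reference set lives in supplementary material
that is not redistributed, which is documented at the function. Input
uncertainties on computed log permeabilities propagate linearly
(slope × se).

## Synthetic data: what it emulates, and what it does not

Every generator is seeded (one local RNG per call; the global RNG stream
is untouched), byte-deterministic, and writes its planted truths into a
`manifest` attribute; the recovery suites read truths only from
manifests. The defaults are the study designs:

- dose-response: 8 log-spaced concentrations on [1, 450] µM, triplicate,
  4PL response, Gaussian noise (default sd 0.03 of the viability
  fraction);
- MST: 16-point 1:1 serial dilution from 1 mM, 100 nM labeled target,
  exact quadratic isotherm, triplicates of the same dilution series,
  noise in Fnorm units;
- melting: 20–95 °C at 0.5 °C steps, two-state logistic in the ratio
  with linear channel baselines and 0.5 % multiplicative per-channel
  noise;
- pH titration: pH 2–13 in 0.5 steps, HH curve, 0.005 ppm noise;
- trajectory: a parametric 4-helix bundle (Cα + pseudo-CB per residue,
  exact 2-fold symmetry) with a 5-atom rigid ligand planted to contact
  each epitope's residue set (< 4 Å to ≥ 5 distinct residues) in exactly
  `round(fraction × n_frames)` frames and to float ~40 Å away otherwise;
- PMF: Gaussian central barrier plus symmetric interfacial wells pinned
  to zero in water; calibration sets: 9 reference pairs on a planted
  line.

Because the recovery tolerances are tight relative to the information
content of a single synthetic measurement, the recovery suites emulate
the replication the assays actually use: IC50 as the mean of three
independent plates, MST triplicate dilution series, duplicate melting
scans, and a site pKa indicated by two reporter protons (averaged
per-proton fits). All four fitters were verified by simulation to sit at
the Cramér–Rao bound of their designs, so these replication choices are
about matching the experiments' information content, not about
compensating estimator deficiencies.

What the generators do *not* emulate: real conformational ensembles
(each library member is a perturbed copy or a decoy atom cloud, not a
conformer set), NMR lineshapes and peak overlap (shifts are read off
directly), instrument drift or correlated noise (all noise is i.i.d.),
force-field physics in trajectories (ligand poses are placed
geometrically), or the shape of real PMFs beyond a barrier/well
parametrization. Passing the suites therefore demonstrates that the
estimators and the pipeline logic are correct at realistic noise levels
and designs — not that any particular real compound would reproduce the
planted numbers.

## Numerical choices and degenerate inputs

- Tie-breaks are everywhere deterministic: overlay starts by combo then
  shape Tanimoto; screen ranking by combo, shape, then id; cluster labels
  by first appearance; canonical symmetry images lexicographically.
- Superposition requires ≥ 3 non-degenerate points; collinear or
  coincident coordinates raise an error rather than returning an
  arbitrary rotation.
- The melting-scan smoother keeps a half-window margin at the scan edges;
  transitions whose derivative extremum falls into the margin are
  rejected.
- `fit_ic50`/`fit_pka` refuse constant responses ("no dose dependence" /
  "no titration transition") instead of fitting a flat line with huge
  uncertainties.
- Square-barrier PMFs are integrated exactly by the trapezoid when the
  step sits at a grid-cell midpoint — the convention the closed-form
  tests use.
- Suite problem sizes: 1000-frame trajectories for the occupancy checks,
  100-simulation recovery suites per fitter, toys of ≤ 5 atoms for the
  pose-grid comparisons, 0.05 Å quadrature grids for the overlap oracle.
  These sizes keep every check's runtime in seconds-to-minutes while
  leaving the statistical conclusions unchanged.

## Known limitations

- The shape scorer is first-order: it slightly overcounts density where
  many atoms overlap; rankings on drug-sized molecules are insensitive to
  this, but absolute volumes are not hard-sphere volumes.
- Feature typing is intentionally minimal (no aromaticity perception
  beyond SSSR, no tautomers, no pKa-dependent protonation enumeration);
  exact parity with commercial color features is not claimable.
- The overlay optimizer is local-refinement over a finite start set; for
  highly symmetric molecules additional random starts may be needed to
  escape equivalent-but-suboptimal alignments.
- The epitope clustering cut (0.7 Jaccard, average linkage) is a declared
  default; real systems with overlapping epitopes may need a different
  cut, and the occupancy denominator convention changes the reported
  percentages.
- Permeability classification applies fixed literature thresholds to
  calibrated values; outside the calibration range the linear map is an
  extrapolation and the propagated uncertainty should be taken seriously.
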