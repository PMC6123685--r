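---
title: "Quantifying ryanodine receptor Ca2+ sensitivity with cicrfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ryanodine receptor Ca2+ sensitivity with cicrfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicrfit)
```

## The biphasic CICR model

Ryanodine receptors (RyR1 in skeletal muscle, RyR2 in heart) are
sarcoplasmic-reticulum Ca2+-release channels activated by cytoplasmic
Ca2+ — Ca2+-induced Ca2+ release (CICR). Because the plant alkaloid
ryanodine binds only open channels, equilibrium [3H]ryanodine binding
over a ladder of buffered free-Ca2+ concentrations reads out the
channel population's average activity. The Ca2+ dependence is biphasic:
activity rises as a high-affinity activating site (A-site) fills and
falls again as a low-affinity inactivating site (I-site) fills. cicrfit
models this as

$$A([\mathrm{Ca}^{2+}]) = A_{max} \cdot f_A \cdot (1 - f_I), \qquad
  f_X = \frac{[\mathrm{Ca}^{2+}]^{n_X}}{[\mathrm{Ca}^{2+}]^{n_X} + K_X^{n_X}}$$

with five parameters: the gain $A_{max}$ (on the $B/B_{max}$ scale),
dissociation constants $K_A$, $K_I$ (mol/L) and Hill coefficients
$n_A$, $n_I$. The Ca2+-sensitivity readout is
$\mathrm{pCa}_{50} = -\log_{10} K_A$.

Site occupancies are evaluated in log space
(`plogis(n * (log(ca) - log(K)))`), which is algebraically identical to
the naive ratio but neither overflows nor underflows at extreme pCa;
agreement with naive arithmetic is property-tested to $10^{-10}$
relative wherever the naive form is representable.

Two conventions exist for reading off pCa50: the half-point of $f_A$
(exactly $-\log_{10} K_A$ under fixed Hill forms) or the half-maximum of
the composite biphasic curve. `pca50()` uses the $K_A$ definition by
default — the quantity called "pCa for 50% activation" when curves are
fitted with fixed Hill coefficients — and exposes the composite variant
via `method = "composite"`; the two differ measurably only when
inactivation encroaches on the activation limb.

## Fitting binding curves

`fit_binding_curve()` performs equal-weight nonlinear least squares
(Levenberg–Marquardt via minpack.lm) over $A_{max}$, $K_A$ and $K_I$,
with $n_A$ and $n_I$ held fixed. Design choices:

* **All replicates are fitted**, not the per-point means, so the
  replicate structure (n = 4 by default) carries its weight; a
  means-only mode (`use_means = TRUE`) is available for emulating
  published-figure fits.
* **Multi-start initialization.** Biphasic least squares is multimodal,
  so $K_A$ is started at every observed pCa grid point, $A_{max}$ at
  the maximum observed mean activity and $K_I$ at $10 K_A$; the start
  with the lowest residual sum of squares wins. This is deterministic,
  so fits are invariant to row order.
* **Lost-binding rule.** If the largest per-point mean activity is
  below 0.01 (or three times the replicate noise estimate), the fit is
  reported `not_determined` rather than inventing parameters for a dead
  channel.
* **Monophasic mode** (`inactivation = FALSE`) forces $f_I \equiv 0$
  for high-salt, Mg2+-free media in which inactivation through the
  low-affinity site is removed experimentally.

The Hill coefficients themselves are chosen once for a whole panel by
`select_hill_coefficients()`: every curve is fitted at every candidate
$(n_A, n_I)$ pair and the pair maximizing the summed $R^2$ is kept, with
ties broken toward the smaller (coarser) coefficients. On synthetic
panels generated at $(2, 1)$ the search returns $(2, 1)$; fitting then
proceeds with one shared pair, the convention used for comparing wild
type against mutant panels.

Raw bound counts are normalized to the maximal number of functional
channels, $B_{max}$, determined separately by `scatchard_bmax()`:
ordinary least squares on the Scatchard transform ($B/F$ against $B$),
whose slope is $-1/K_d$ and x-intercept is $B_{max}$. On noiseless
single-site data the recovery is exact because the transform is
an identity of the isotherm.

Standard errors of pCa50 are reported from the fit covariance
(`se_pCa50`). An SEM across replicate fits can equally be formed by
fitting seeded replicate panels; both routes are exercised in the test
suite, and at the default noise (SD 0.02, n = 4, 12 pCa points) the
per-fit recovery error has SD ≈ 0.025 pCa units — the same scale as the
±0.03 SEM typical of this assay. The synthetic-panel round-trip test
therefore asserts a median recovery error below 0.03 and every fit
within 0.1 (≈ 4 SD).

## Resting activity and disease phenotyping

Disease-associated gain-of-function mutations shift pCa50 upward.
`resting_activity()` extrapolates the fitted model to resting
cytoplasmic Ca2+ (pCa 7, 100 nM) and `fold_change_at_rest()` forms the
mutant/wild-type ratio. In the low-Ca limit the ratio approaches
$(K_{A,wt}/K_{A,mut})^{n_A}$; with $n_A = 2$, an eightfold affinity
gain therefore predicts roughly a 64-fold higher resting activity —
the quantitative link between a modest-looking sensitivity shift and a
constitutively leaky channel.

## Free-Ca2+ speciation

`free_ca()` solves the chelator mass balance (total = free + bound,
with competitive Ca2+/Mg2+ binding on every chelator) by bracketed
monotone root finding plus a Newton polish, driving the relative
mass-balance residual below $10^{-12}$; agreement with the closed-form
quadratic for a single 1:1 chelator is property-tested to $10^{-9}$
relative. `total_ca_for_target()` is the closed-form inverse used to
design pCa ladders (`pca_ladder()`).

The package deliberately ships **no chelator constant database**: the
apparent Kd of EGTA or BAPTA depends strongly on pH, ionic strength and
temperature, so the constants file supplied by the user at assay
conditions is the package boundary. `apparent_kd()` applies the
cumulative proton-binding polynomial when absolute constants plus
stepwise pKa values are supplied; ionic-strength and temperature
corrections are out of scope. The example constants in
`inst/extdata/buffer_example.json` are labelled illustrative.

## Fluorescence trace analysis

Dual-indicator recordings (cytoplasmic G-GECO1.1-like, ER-luminal
R-CEPIA1er-like) are normalized as $(F - F_{min})/(F_{max} - F_{min})$
from end-of-experiment calibration anchors. When a per-cell $F_{min}$
is missing, channel defaults apply: 7.655% of $F_{max}$ for the
ER-luminal indicator and 0 for the cytoplasmic one.

Oscillation detection (`detect_oscillations()`) is intentionally
simple and fully deterministic: a rolling-median baseline (15 s window)
plus a threshold of 5 MAD units, hysteresis at 50% of the threshold and
a 2 s refractory period. Any labelled calibration window is excluded
automatically. The "upper level" of the ER sawtooth
(`upper_er_level()`) is defined here as the 95th percentile of the
normalized signal within a window — a noise-robust envelope estimator
chosen over the maximum; both the quantile and the window are
configurable since the plateau convention is not standardized.

Caffeine dose-response data are fitted with a four-parameter monotone
Hill curve (`caffeine_dose_response()`), reporting the EC50 in mM and
flagging extrapolated EC50s outside the tested dose range. Box-plot
summaries (`summarize_cells()`) use linear-interpolation quartiles
(type 7) so the quoted five numbers are exactly reproducible.

## Structure comparison

`load_structure()` reads PDB and mmCIF coordinate models through bio3d,
keeps one protomer chain (first alphabetically by convention — the
channel is a homotetramer) and resolves altlocs to the
highest-occupancy conformer. Superposition is classical Kabsch least
squares on shared Cα atoms, with residues missing from either model
dropped pairwise, as cryo-EM models have gaps.

`domain_displacement()` measures conformational change between two
ligand states: superpose on a reference frame — by default the
transmembrane region plus S6c (residues 4540–4956 in RyR1 numbering),
the least mobile part of the channel — then report the mean per-Cα
displacement and centroid shift of a target domain such as the CTD
(4957–5037) or core solenoid (3667–4253). The frame is configurable
because published overlays rarely state theirs.

`pocket_gauge()` is explicitly a **proxy**: it projects designated
gauge atoms (side-chain oxygens of the Ca2+-coordinating residues by
default) onto their best-fit plane and returns the polygon area plus
all pairwise distances. It is rotation/translation invariant and scales
quadratically under uniform scaling, which makes relative comparisons
between states meaningful; it is not a cavity-volume algorithm, and
absolute areas from pictorial "dotted-circle" measurements are not
comparable to it.

## The synthetic-data generator

Every analysis stage is exercised against `gen_*` generators whose
truths are recoverable by construction:

* `gen_binding_curve()` runs the biphasic model forward and adds
  Gaussian replicate noise (SD 0.02 on the $B/B_{max}$ scale, n = 4 by
  default — the error-bar scale of this assay), truncated at zero.
  The truncation biases points whose mean activity is within ~2 SD of
  zero; bias checks therefore sit on high-activity points.
* `gen_saturation()` draws from the single-site isotherm over 3–20 nM.
* `gen_dual_trace()` builds antiphase cytoplasmic spike / ER sawtooth
  pairs with optional caffeine windows (massive release with ER
  depletion, or no response for caffeine-insensitive channels) and
  appends calibration segments that realize the anchors exactly.
* `gen_two_domain_fixture()` writes synthetic two-domain coordinate
  files (both PDB and mmCIF) with a known rigid shift of one domain,
  the exact ground truth for displacement measurements.
* `gen_paper_panel()` assembles a four-genotype study: wild type
  (activating-site pCa50 4.79, a literature-anchored truth), a
  caffeine-insensitive mutant, a constitutively sensitized mutant, and
  a disease-class mutant with an eightfold lower $K_A$. The manifest
  tags every truth `anchored` or `illustrative`; illustrative values
  are never asserted against published numbers.

All generators take an integer seed, restore the caller's RNG state,
and are bit-reproducible; the pipeline derives per-stage seeds from one
master seed so stages can be toggled without reshuffling the stream.

What the generators do **not** emulate: pipetting/batch effects and
non-Gaussian outliers in binding data, photobleaching and indicator
saturation in traces, and real side-chain heterogeneity in coordinate
models. Passing round-trip tests demonstrates the estimators are
correct and calibrated under the stated noise model, not that real
recordings are free of these artifacts.

## Orchestration

`run_pipeline()` runs simulate → fit → summarize on the synthetic
panel, writing the binding CSV, per-fit JSON, the sensitization summary
TSV (6 significant digits; full precision in JSON) and a manifest with
MD5 hashes; identical config and seed reproduce byte-identical tables,
and a failed stage skips its downstream stages with a recorded status.
The package's interface is its functions — the pipeline entry point,
the readers/writers and the stage functions — rather than a shell
executable, which suits an analysis library; all orchestration options
are plain function arguments validated up front with exhaustive error
listings.

## Problem sizes and numerical conventions

Default problem sizes used throughout the examples and tests — 12-point
pCa grids with 4 replicates, 6-curve selection panels over a 5 × 4
Hill grid, 120 s traces at 10 Hz, 1000-draw speciation property checks
— are the package's own choices, matched to the assay designs they
emulate. Convergence uses relative SSE change below $10^{-12}$ within
500 Levenberg–Marquardt iterations; grid ties break toward smaller Hill
coefficients; quartiles are type 7; zero total Ca2+ reports a
below-resolution flag rather than a root-finding failure.

## Known limitations

* Caffeine is treated empirically as a separate condition with its own
  fit, not as a mechanistic shift of binding constants.
* No global shared-parameter fitting across genotypes, no Bayesian
  posteriors, and no significance testing — descriptive summaries only.
* The speciation module does not model ATP/AMP metal binding or
  ionic-strength/temperature corrections.
* The pocket gauge orders atoms by angle about the centroid, which is
  well-defined for the near-planar, near-convex arrangements of
  coordination-site oxygens it is meant for, but not for arbitrary
  point sets.
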