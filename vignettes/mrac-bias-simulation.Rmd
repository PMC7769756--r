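---
title: "Propagating attenuation-map errors through dynamic brain PET quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating attenuation-map errors through dynamic brain PET quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative brain PET needs a map of linear attenuation coefficients at
511 keV (a mu-map, cm^-1) to correct emission data for photon attenuation.
On combined PET/MR systems no transmission or CT measurement is available,
so the mu-map must be derived from MR — and MR cannot see bone directly.
Errors in MR-based attenuation correction (MRAC) propagate into
reconstructed activity, and from there into the outcome parameters of
kinetic modelling: the non-displaceable binding potential `BP_ND` and the
relative delivery `R1` obtained with the simplified reference tissue model
(SRTM). Because those parameters are ratios against a reference region,
attenuation errors can partly cancel — or fail to cancel when their bias is
inhomogeneous in space or time.

`petmrac` reproduces this whole causal chain on synthetic data, end to end
and fully seeded, so that the behaviour of competing MRAC strategies —
multi-atlas majority voting (MaxProb), its single-atlas degenerate case,
zero-echo-time-like (ZTE) histogram segmentation with continuous bone
coefficients, and a degraded transmission-like reference — can be studied
with known ground truth.

## The phantom and what it emulates

`make_phantom()` builds a digital head: a closed ellipsoidal bone shell
around soft tissue, two frontal sinus air pockets, and ellipsoidal
anatomical regions (caudate, putamen, cerebellar grey matter,
anterior/posterior cortical bands, a limbic cluster, central white matter).
CT values are drawn per tissue class from truncated normals — soft tissue
N(30, 20) HU on [-500, 300], bone N(900, 150) HU above 300 HU, air at
-1000 HU — so the class/threshold consistency used by the segmentation
stages is exact by construction and assertable voxel-wise. The closed-shell
property (no 6-connected path from the volume border to any labelled region
through non-bone voxels) is verified by flood fill at construction time.

The proton-density-like (ZTE) channel models bone intensity as a linear
function of CT number (`zte = 0.55 - 1e-4 * HU`, normalized units), soft
tissue as the main histogram peak at 1.0 and air near zero, plus Gaussian
noise (SD 0.02 by default). The linear bone model is a deliberate design
choice: it makes the two-anchor intensity-to-HU calibration line able to
represent the true relationship exactly, so the noise-free recovery test
(voxel-wise error below 5% outside a one-voxel boundary band) probes the
segmentation logic rather than an arbitrary intensity model.

What the phantom does *not* emulate: realistic MR contrast or bias fields,
atrophy beyond the deformation amplitude of the atlas stage, patient
anatomy, or template-space normalization. Passing tests therefore show that
the algorithms behave correctly under their stated assumptions, not that
any particular clinical accuracy is attained on real data.

## Attenuation-map generation

Four map families share one interface (`mu_map`, cm^-1 at 511 keV):

* **MaxProb** (`maxprob_pseudo_ct()`): each atlas CT is registered to the
  target, classified into air/soft/bone by the thresholds above, each voxel
  takes the majority class across the database, and the pseudo-CT value is
  the mean HU of the majority-class atlases. Vote ties resolve by the fixed
  priority soft > bone > air — soft tissue being the least harmful
  misassignment for brain quantification. A single atlas degenerates to
  that atlas's registered CT, which is how the vendor-style single-atlas
  method is emulated.
* **Registration**: the atlas database is built by warping the template
  with random smooth displacement fields (control-point amplitude in mm,
  rejection of folding fields by a Jacobian check), and the true inverse
  transforms are stored. The default "oracle" registration mode uses those
  stored transforms, isolating the voting/averaging algorithm from
  registration quality; a centre-of-mass translation estimate is available
  as a crude alternative. Full affine + non-rigid mutual-information
  registration is out of scope.
* **ZTE-like** (`zte_like_segment()`): intensities are normalized to the
  soft-tissue histogram mode, log-rescaled, and a Gaussian is fitted to the
  main peak. Voxels in the sub-peak band `[mode - 4 sigma, mode - 1.5 sigma]`
  become bone with continuous coefficients via the calibration line and the
  bilinear HU conversion; in-mask voxels below the band are internal air.
  Because the fitted peak width collapses in the noise-free limit, the band
  uses `sigma_eff = max(sigma, 0.35)` on the log scale — the floor is the
  package's own choice, sized so the bone band of the default phantom falls
  inside it.
* **Transmission-like reference** (`degrade_to_reference()`): Gaussian
  smoothing (6 mm FWHM) plus additive noise (0.004 cm^-1), clipped at zero —
  an emulation of the resolution/noise character of a measured reference
  map, not a transmission reconstruction.

The bilinear HU conversion passes through (-1000 HU, 0) and (0 HU,
0.096 cm^-1) and maps 1000 HU to 0.130 cm^-1 by default; all four
parameters are configurable. Segmentation-based maps assign soft tissue the
fixed coefficient 0.100 cm^-1.

## PET simulation and reconstruction

The acquisition is a 2D slice-wise parallel-beam emulation (120 angles, 96
radial bins by default): three-dimensional time-of-flight modelling adds
nothing to the attenuation-error question at phantom scale. Expected counts
per sinogram bin are

    counts_scale x frame_duration x decay_factor x ACF x P(activity)

with `P` the ray-driven forward projector (bilinear sampling, step half a
pixel), `ACF = exp(-integral mu dl)`, and the frame-averaged decay factor
of carbon-11 (half-life 20.36 min). Poisson noise is sampled per bin;
`counts_scale` defaults to 0.001 counts per (kBq/mL x mm x s), which makes
the whole 80-min study of the default 64^3 phantom collect about 5 x 10^6
expected counts per slice — the studied acquisition reports no count
levels, so this is a package choice.

Reconstruction is OSEM with the *candidate* attenuation map inside the
system model (20 iterations, 16 subsets by default), while the counts were
generated with the *true* map — exactly how AC errors enter clinical
reconstructions. The backprojector is the exact adjoint of the projector
(verified to rounding error), which makes the EM update correct;
reconstructed activity is decay-corrected to injection time. One Poisson
realization per frame is reconstructed once per candidate map, so method
comparisons see identical counts, mirroring a within-subject design.

Numerical choices worth knowing: the ray step is half a pixel (chord-length
accuracy about 1% at 64 x 64, 3 mm pixels); 20 x 16 OSEM leaves the VOI
mean of a small hot striatal region within about 1% of its converged value
on the default phantom (6 x 8 leaves roughly -6%, which is why the default
is higher); slices outside the head can be skipped (`slices =`) — a pure
speedup with no effect on VOI quantities, since all regions lie inside the
head.

## Kinetic quantification

The SRTM target curve is

    C_T(t) = R1 C_R(t) + (k2 - R1 k2a) (C_R * exp(-k2a t))(t)

with `BP_ND = k2 / k2a - 1`. `srtm_forward()` evaluates the convolution on
a dense grid (0.25 s step; per-segment closed form, exact for
piecewise-linear `C_R`) and averages over the 22-frame, 80-min schedule
(4 x 60 s, 2 x 120 s, 4 x 180 s, 12 x 300 s). Basis-function fitting
(`rpm_fit()`, receptor parametric mapping) linearizes the model over a
log-spaced grid of 100 washout rates in [0.01, 0.6] min^-1 — the studied
analysis reports no grid, so the range was chosen to bracket plausible
striatal and cortical washout for a dopamine-transporter ligand, and it is
configurable. For each candidate rate a two-parameter linear least squares
is solved in closed form from cached normal-equation terms; ties in
residual sum of squares resolve toward the smaller rate; fits with a
negative `k2` are refit on the boundary (`k2 = 0`), so `BP_ND` never falls
below -1. Frame weighting is uniform (optional duration-decay weights were
considered and left out as the studied analysis states none).

The simulated reference input is a biexponential bolus,
`C_R(t) = 30 (exp(-0.03 t) - exp(-0.6 t))` kBq/mL with t in minutes — it
starts at zero, admits closed-form convolutions for the test oracles, and
its exact shape is immaterial to the bias questions because all outcome
parameters are normalized to the measured reference TAC. When parametric
maps are fitted (`fit_parametric_maps()`), the measured cerebellar TAC
itself is the first design column, and its linear interpolant (anchored at
zero) feeds the basis convolutions.

A consequence the package tests end to end: a constant-in-time
multiplicative error applied to every tissue shifts SUV uniformly but
leaves `BP_ND` and `R1` unchanged, because both are normalized to the
reference region. Time-varying or regionally inhomogeneous errors do
propagate — which is precisely why the TAC bias curves are part of the
evaluation.

## Evaluation framework

* `bias_map()` — voxel-wise candidate-minus-reference difference (cm^-1),
  inside a head mask (the studied bias images are head-masked; the exact
  mask is unstated there, so the union of head labels is used), summarized
  over a soft-tissue window of the reference map and over a bone mask from
  simple thresholding of the ZTE map followed by two passes of 6-connected
  erosion (connectivity unstated in the source material; 6-connected is the
  conservative choice).
* `relative_bias()` — `100 (candidate - reference) / reference`; its mean
  across subjects is accuracy, its SD precision.
* `deming_regression()` — closed-form errors-in-both-variables fit;
  the error-variance ratio defaults to 1 (orthogonal regression) as the
  ratio is not stated in the source analysis.
* `friedman_dunn()` — within-subject mid-ranks with tie correction; exact
  permutation p-value when the design is small enough to enumerate (at most
  5000 rank permutations), chi-squared approximation otherwise; Dunn's
  post-hoc z against the reference column with Bonferroni-style scaling
  over the k-1 comparisons, the scheme implemented by the statistics
  software used in the source analysis.
* `tac_bias_curves()` — per-frame SUV bias (dose 5 MBq/kg) per subject,
  mean and SD across subjects.
* `build_report()` — the region x method table of % bias, SD, Spearman r,
  Deming slope/intercept and significance flags; whole-striatum rows are
  volume-weighted averages of caudate and putamen.

## Orchestration and problem sizes

`run_experiment()` chains all stages per subject with seeds derived
deterministically from the master seed, so a fixed configuration is
bit-reproducible. The default configuration follows the study design this
framework emulates: 9 subjects, 4 methods with the transmission-like map as
reference, 64^3 voxels of 3 mm, 10 atlases. The shipped tests and the
acceptance script run scaled-down instances — 32^3 grids, 2-3 subjects and
a shortened schedule for the pipeline tests; the full 22-frame schedule on
a 48^3 phantom for the matched-map and directional-error checks — sizes
chosen to keep a complete run on a single desktop core while leaving every
algorithmic path identical. The command-line surface is the exported
function set plus `scripts/acceptance.R`; a shell subcommand wrapper was
deliberately not added, since the package's users drive it from R.

## Known limitations

* Scatter, randoms and detector normalization are not simulated; incorrect
  attenuation is reported to dominate these effects for the question at
  hand, and including them would blur the attribution of observed bias.
* Registration quality is idealized (oracle transforms); the multi-atlas
  results therefore isolate voting/averaging behaviour rather than the
  full registration pipeline.
* The phantom's anatomy is schematic; absolute bias magnitudes on real
  patients are outside what this synthetic design can establish.
* 2D slice-wise projection ignores axial attenuation paths; relative
  method comparisons are unaffected, absolute sensitivity is not modelled.
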