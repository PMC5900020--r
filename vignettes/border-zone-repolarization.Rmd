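---
title: "Modeling repolarization gradients around an infarct border zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling repolarization gradients around an infarct border zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

A healed myocardial infarct consists of a dense collagenous scar core
surrounded by a thin rim of surviving but remodeled myocardium, the
*border zone* (BZ). Experimental reports of BZ remodeling disagree —
depending on species, infarct age and region, the BZ has been described
with shorter, normal or longer action-potential duration (APD), with
reduced transverse conduction due to interstitial fibrosis, with slow
isotropic conduction, and with myofiber disarray. Models that simulate
arrhythmia risk must pick one of these *computational representations*,
and the choice matters: spatial gradients of repolarization time near
the scar are a recognized substrate for unidirectional block and
re-entry (experimentally, gradients above roughly 3.2 ms/mm support
block).

`bzep` implements an idealized 2D test bench that isolates this choice
from all anatomical confounders. A 30 x 30 mm sheet of human
ventricular tissue carries a central 10 mm-diameter insulating hole
(the scar core) surrounded by a 2 mm annulus (the BZ). Twelve
representations of the BZ — three APD variants x four
conductivity/fiber settings — are simulated under steady pacing, and
the activation-time (AT), repolarization-time (RT) and
|grad RT| maps are compared.

## Model

### Membrane kinetics

Each node carries the ten Tusscher–Panfilov (2006) human ventricular
membrane model, epicardial parameter set: 19 states (voltage, 12 gates,
intracellular Na+/K+/Ca2+ and SR/subspace Ca2+), with all constants at
their published values. The only parameter ever modified is the maximal
conductance of the slow delayed-rectifier current, `gKs`:

* `control` — `gks_scale = 1`;
* `longer_apd` — `gks_scale = 0.5` (less repolarizing current,
  longer APD);
* `shorter_apd` — `gks_scale = 2` (shorter APD).

`gKs` is used because APD of this model responds to it more strongly
than to any other single maximal conductance. At a 500 ms cycle length,
after 100 pre-pacing beats, the implementation gives APD90 = 284 ms for
control and shifts of roughly +38 ms and -42 ms for the two variants —
the intended "about 40 ms either way" separation. (At a 1000 ms cycle
length the control APD90 is 307 ms, within a few ms of the published
value for this model.)

```{r}
library(bzep)
st <- pace_to_steady_state(make_variant("control"), cycle_length = 500,
                           n_beats = 100)
measure_apd(simulate_ap(make_variant("control"), st, 500, 1))
```

APD is measured from the instant of maximum upstroke velocity to the
interpolated downward crossing of `V_peak - f (V_peak - V_rest)` with
`f = 0.9` (APD90) by default; an absolute-threshold convention
(`threshold = -70`, matching the tissue repolarization threshold) is
also supported and agrees with APD90 to within a few ms for these
cells. The repolarization-fraction convention for the "40 ms" statement
is not uniquely determined by the study design; APD90 is used because
both alternatives agree here.

### Tissue model

Propagation follows the monodomain equation

&beta; C_m dV/dt = div( &sigma; grad V ) − &beta; C_m (I_ion − I_stim),

with surface-to-volume ratio &beta; = 0.14 /µm and C_m = 1 µF/cm², so
the effective diffusivity is D = &sigma;/(&beta; C_m) (0.135 mm²/ms for
the normal longitudinal bulk conductivity; internal units are
mm–ms–mV). Per element, the 2x2 conductivity tensor is
R(&theta;) diag(&sigma;_l, &sigma;_t) R(&theta;)ᵀ where &theta; is the
fiber angle. Three presets are shipped:

| preset | &sigma;_l (S/m) | &sigma;_t (S/m) | models |
|---|---|---|---|
| `normal_anisotropic` | 0.1890 | 0.0690 | healthy myocardium |
| `decreased_transverse` | 0.1890 | 0.0069 | interstitial fibrosis |
| `decreased_isotropic` | 0.0689 | 0.0689 | slow isotropic conduction |

Healthy tissue always uses `normal_anisotropic` with fibers along x;
only the BZ annulus changes between configurations.

### What the printed conductivities mean

A caveat that matters when comparing against published velocity values:
a bulk monodomain conductivity is not a solver-independent quantity.
Different codes derive the monodomain tensor differently (some
harmonically combine separate intracellular and extracellular tensors),
so the same printed number can correspond to different effective
diffusivities. With the literal bulk-tensor reading used here, the
shipped presets yield strip velocities of about 0.71, 0.42 and
0.13 m/s (longitudinal/transverse/decreased-transverse) rather than the
0.6 / 0.4 / 0.12 m/s that motivated them; the ratios, and therefore all
qualitative study conclusions, are preserved. When a particular
velocity is required, `calibrate_conductivity()` adjusts &sigma; by
fixed-point iteration on the measured strip velocity
(&sigma; <- &sigma; (CV_target/CV)², converging in 2–3 strips at the
default 1% tolerance) — this is also how the decreased-isotropic preset
value was originally derived from the 0.4 m/s target in the source
study. Calibrating this package to 0.4 m/s isotropic returns
&sigma; = 0.063 S/m, 9% below the shipped preset, consistent with the
velocity offsets above.

## Numerics

* **Mesh.** Structured criss-cross triangulation (parity-alternating
  diagonals) of the square, carved by an element-centroid test: elements
  inside the scar circle are deleted (their absence makes the hole a
  no-flux insulator under the natural boundary conditions), elements
  with centroid radius in (5, 7] mm are labeled BZ (the half-open
  interval resolves the boundary-ownership ambiguity). The cell count
  per side is forced odd so the triangulation — not just the node set —
  is exactly mirror-symmetric about the vertical midline, which makes
  map symmetry a machine-precision property rather than a statistical
  one. The target resolution is the mean edge length (the criss-cross
  mean edge is (2+sqrt(2))/3 times the cell size).
* **Spatial discretization.** Linear-triangle FEM; per-element constant
  tensors; lumped mass. Stiffness rows sum to zero by construction
  (no-flux conservation), and the discrete gradient used for the maps is
  exact on linear fields.
* **Time stepping.** First-order operator splitting with dt = 0.02 ms
  by default: Rush-Larsen exponential gate updates (rates evaluated
  from lookup tables on a 0.05 mV grid, sampled from the same inline
  rate functions the 0D integrator uses exactly), forward Euler for
  concentrations, then a backward-Euler diffusion solve by
  Jacobi-preconditioned conjugate gradients warm-started from the
  previous field (relative residual 1e-6; about 2 iterations/step).
  Reversal potentials are refreshed every 25 steps (0.5 ms), over which
  the slow intracellular concentrations move by well under 1e-3 mM.
* **Stimulus.** 2 ms rectangular transmembrane current over a 0.5 mm
  half-disc at the center of the bottom edge, at twice the diastolic
  threshold found by bisection (once per study, on the
  normal-conductivity sheet; single-cell pacing likewise uses twice the
  single-cell threshold).
* **Pacing protocol.** Cells are pre-paced 100 beats at CL 500 ms in
  0D; the end-diastolic state seeds every node; the tissue is then
  paced 5 beats at CL 500 ms and all maps are taken from the final
  beat. Activation is the first upward crossing of -20 mV,
  repolarization the first downward crossing of -70 mV after
  activation, both linearly interpolated (the solver also tracks these
  crossings at full step resolution for each beat, which is how the
  beat-4-versus-beat-5 periodicity check is made; by beat 4 the maps
  repeat to well under 1 ms).
* **Gradient maps.** |grad RT| is constant per linear triangle; node
  values are the area-weighted mean over incident elements; masked
  nodes (no activation or no repolarization) mask their incident
  elements. Exceedance areas (the summary statistic) are computed from
  the per-element values directly.

### Problem sizes

The production ("paper-scale") resolution is 0.05 mm (about 466k nodes
for the sheet), which is what the geometry defaults document. All
shipped checks run at declared desk scales chosen once:

* strip velocity measurements: 20 x 1 mm strip at 0.1 mm (0.05 mm for
  the decreased-transverse case, whose wavefront is only ~0.1 mm wide,
  and for the refinement comparison);
* the acceptance script's sheet runs: 0.15 mm, dt = 0.025 ms, full
  5-beat protocol;
* the test suite's 12-configuration panel: 0.35 mm, dt = 0.025 ms,
  3 beats (plus one dedicated 5-beat run for the periodicity check).

Refinement checks bound the influence of these choices: longitudinal
strip velocity moves by ~1% between 0.1 and 0.05 mm and <3% between
0.05 and 0.025 mm; the extreme BZ-edge gradient changes by only a few
percent between 0.35 and 0.2 mm sheets.

## The twelve representations

`enumerate_configurations()` crosses the three APD variants with four
conductivity/fiber columns — normal anisotropic; decreased transverse
with horizontal fibers; decreased transverse with random fibers (one
independent uniform angle on [0, &pi;) per element, seeded; disarray
has no stated correlation length, so none is imposed); decreased
isotropic. Random fibers pair only with decreased transverse
conductivity, where fibrosis and disarray co-occur. A supplementary
variant replaces the abrupt healthy/BZ conductivity jump with a linear
radial ramp of &sigma;_t (`apply_smooth_transition()`).

```{r}
study <- run_study(enumerate_configurations(resolution = 0.15),
                   output_dir = "study_out")
print(study)
```

What the shipped panel shows (all of it asserted by the test suite or
recomputed by `scripts/acceptance.R`):

* APD heterogeneity dominates: within every conductivity column the
  normal-APD configuration has the smallest maximum |grad RT|, and the
  extreme values (~20–25 ms/mm at the BZ edge, far above the
  3.2 ms/mm block threshold) occur for altered APD combined with
  decreased transverse conductivity.
* Electrotonic smoothing: reducing transverse conductivity decouples
  the BZ from its neighbors and sharpens gradients at fixed APD
  contrast; normal and decreased-isotropic columns smooth the same
  contrast far more effectively.
* Fibrosis plus disarray mimics slow isotropic conduction: the
  activation maps of decreased-transverse-with-random-fibers and
  decreased-isotropic are closer to each other (nodewise RMS) than
  either is to decreased-transverse-with-horizontal-fibers.
* The smooth transition only smooths: the ramp never increases the
  maximum gradient.
* Figure-level patterns (inspected, not asserted numerically):
  activation isolines crowd below the BZ when transverse conductivity
  is decreased with horizontal fibers; RT isolines accumulate at the
  bottom/top BZ edges for longer/shorter BZ APD. Band statistics for
  these patterns can be computed from the maps, e.g.:

```{r}
res <- study$results[["longer+decreased_transverse+horizontal"]]
mesh <- build_mesh(geometry_config(resolution = 0.15))
cc <- element_centroids(mesh)
band <- function(lo, hi, side) {
  r <- sqrt((cc[, 1] - 15)^2 + (cc[, 2] - 15)^2)
  sel <- r > lo & r <= hi & (if (side == "bottom") cc[, 2] < 15 else cc[, 2] >= 15)
  mean(res$gradient$element_values[sel], na.rm = TRUE)
}
c(bottom = band(5, 9, "bottom"), top = band(5, 9, "top"))
```

## What the generator does and does not emulate

The geometry module is a synthetic-data generator in the strict sense:
its defaults *are* the study conditions (30 mm sheet, 10 mm scar, 2 mm
BZ, homogeneous regions, stimulus site fixed for every run). It
deliberately omits everything a patient-specific model would add —
wall curvature and thickness, transmural fiber rotation, scar-shape
irregularity, islands of surviving tissue and isthmuses, graded
("gray-zone") remodeling. Passing the shipped checks therefore
demonstrates the mechanism — how each BZ representation shapes
repolarization gradients — not a prediction for any real anatomy.

## Known limitations

* Sodium-channel remodeling (reduced excitability,
  post-repolarization refractoriness) is not modeled; the membrane
  variants alter `gKs` only.
* No arrhythmia-induction protocols: the package characterizes the
  substrate (gradients), it does not attempt re-entry.
* Monodomain only — no extracellular potentials or electrograms; and
  the printed-conductivity caveat above applies when comparing absolute
  velocities across solvers.
* Myofibroblast-myocyte coupling is not represented.
* 2D sheet; no transmural dimension.
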