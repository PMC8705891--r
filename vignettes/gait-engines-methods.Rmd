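---
title: "Methods: two kinematics engines, the Gait Profile Score, and synthetic gait data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two kinematics engines, the Gait Profile Score, and synthetic gait data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Clinical gait analysis summarises a child's walking pattern from
three-dimensional marker trajectories. Two families of methods turn markers
into joint angles:

* **Direct kinematics** (the conventional gait model, Plug-in-Gait style):
  each body segment's anatomical frame is built independently per frame from
  the markers attached to it, joint centres come from regression equations
  and the chord construction, and joint angles are Cardan decompositions of
  relative frame rotations. Soft-tissue artefact on any marker propagates
  directly into the segment frame.
* **Multibody-optimisation inverse kinematics**: a constrained articulated
  skeletal model is fitted to *all* markers simultaneously, per frame, by
  weighted least squares. Joint constraints spread marker error over the
  whole chain, which damps soft-tissue artefact.

This package implements both engines over one shared lower-limb model,
summarises their outputs with the Gait Variable Score (GVS) and Gait Profile
Score (GPS), classifies surgical outcome against the GPS minimal clinically
important difference (MCID), and provides a synthetic gait-laboratory
generator so that every step of the chain can be tested against a known
ground truth.

# The skeletal model

The chain is the classic lower-limb multibody layout: a 6-degree-of-freedom
pelvis root (3 translations + tilt/obliquity/rotation), and per leg a
3-DoF ball hip, a knee flexion hinge, a tibiotalar (ankle dorsiflexion)
hinge and a subtalar hinge; the metatarsophalangeal joint exists but is
permanently locked, and the subtalar joint can be locked by configuration
(its default is unlocked; none of the nine reported variables depends on
it).  With the subtalar hinges unlocked the model has
`6 + 2*(3+1+1+1) = 18` free coordinates.

**Laboratory frame.** X is the direction of walking progression, Y points
left, Z up (right-handed). All internal lengths are metres and internal
angles radians; degrees appear only at user-facing boundaries. Positive
angles are the clinical positives: flexion, adduction, internal rotation,
dorsiflexion, anterior pelvic tilt. The `hip_abduction` variable follows the
conventional gait-chart convention (ab/adduction axis, adduction positive).
For the left side, pelvic obliquity/rotation and the foot progression angle
are mirrored so both limbs' waveforms are directly comparable.

**Geometry is parametric, not a mesh.** Segment lengths and marker
placements are documented constants driven by anthropometry: femur length
0.46 x leg length, tibia 0.42, foot length 0.25, ankle height 0.05, pelvic
depth 0.625 x ASIS breadth; knee/ankle markers sit laterally at half joint
width + 5 mm marker radius; heel and toe markers sit on the foot midline
(calcaneus and second metatarsal head) at equal height, which keeps the foot
long axis stable under transverse-plane projection. Hip joint centres are
placed by the Harrington (2007) pelvic regression. Because the same
regression is used by the direct-kinematics engine and by scaling, the model
is exactly self-consistent: noise-free data round-trip through either engine
to machine precision. Muscle geometry, inertia and kinetics are out of
scope.

**Knee-axis (KAD) correction.** The knee flexion axis can be rotated in the
femur's transverse plane by a signed angle (positive = internal/medial
rotation of the axis), mimicking the knee-alignment-device personalisation
applied before scaling. The angle is accepted as a scalar input per side;
the KAD hardware geometry itself is not modelled.

**Scaling.** Scale factors come from surface markers and calculated joint
centres in a static pose: femur = subject hip-to-knee-centre distance over
the generic one, tibia analogously, foot from heel-to-toe marker distance;
the pelvis is scaled anisotropically (width from the inter-ASIS distance,
depth from ASIS-midpoint-to-sacrum, height as the geometric mean of the
two). Hip centres are re-derived from the regression. After geometric
scaling, the static pose is fitted once by inverse kinematics using the
anatomical markers only and every marker's model-fixed position is
re-registered in its segment frame — wand markers, whose placement is
arbitrary, are calibrated purely by this registration, and the lateral
stand-offs of the knee/ankle markers and the height of the foot markers are
treated as measured hardware constants rather than scaled quantities. This
is the same division of labour as standard marker-adjustment workflows, and
it makes scaled models exactly consistent with subjects generated at
different body sizes.

# The direct-kinematics engine

Pelvis frame from LASI/RASI/SACR (anteroposterior axis in the marker
plane); hip centres from the Harrington regression in the pelvis frame; knee
and ankle centres from the chord construction (the joint centre lies in the
plane of proximal centre, lateral marker and wand, at the half-width +
marker-radius offset from the lateral marker, perpendicular to the segment
axis; of the two in-plane solutions the one on the wand's side is taken).
A per-side thigh rotation offset can rotate the wand about the
hip-centre-to-knee-marker axis before the chord, the usual post-hoc
knee-axis alignment adjustment; it is never applied silently. Marker gaps
raise an error naming frame and label — silent gap-filling would corrupt the
engine-comparison statistics (optional interpolation is deliberately not a
default).

Joint angles are Cardan decompositions in the clinical sequence
flexion → ab/adduction → internal-external rotation (the same sequence for
the pelvis against the laboratory). The decomposition accepts arbitrary
orthogonal axis triads; left-handed triads (the mirrored left side) are
handled by flipping the third axis and negating its angle. Poses with the
middle angle within 0.5 degrees of ±90 are flagged as gimbal-adjacent.

# The multibody-optimisation engine

Per frame, the engine minimises the weighted sum of squared distances
between observed and model markers over the free coordinates. The
minimiser is a damped Gauss–Newton iteration with the analytic chain
Jacobian (for a rotational degree of freedom with instantaneous global axis
*w* through joint position *p*, the marker velocity is *w* x (*x* − *p*));
steps that fail to reduce the objective inflate the damping, so the
objective is non-increasing across accepted iterations. Iteration stops
when the coordinate update norm falls below the tolerance (default 1e-6
radians) or after 100 iterations (flagged). Bounds (hip rotations ±60°,
knee −10°–140°, ankle ±50°) are enforced by projection. Default marker
weights are 1, with wand markers down-weighted to 0.5 since they carry the
largest soft-tissue artefact. Frames are solved sequentially with warm
starts; frame one uses a neutral-pose cold start with the pelvis translation
initialised from the observed ASIS midpoint. No global search is attempted —
gait poses are far from the chain's ambiguous configurations.

Per-marker root-mean-square residuals are reported as a quality-control
table against the conventional 2 cm rule of thumb; the limit annotates, it
never gates.

# Gait metrics

Waveforms are time-normalised to T = 101 points (0–100% of the gait cycle,
endpoints interpolated at the heel-strike times; T is configurable and the
scores are grid-converged well below their tolerances at 101). The GVS of
variable *i* is the root-mean-square over the cycle of the deviation from
the reference mean waveform; the GPS is the root-mean-square of the nine
GVS values. The foot progression angle uses the transverse-plane angle
between the foot axis (ankle centre to toe marker) and the direction of
progression (pelvis-centre displacement from initial heel strike to the end
of the cycle), in-toeing positive. The Symmetry Index is Robinson's form,
`100 * (left - right) / (0.5 * (left + right))`; the formula is isolated in
one function so an alternative form is a one-line change. Reference
profiles pool limb-level mean waveforms of typically-developing subjects in
three age groups (children < 10 y, teenagers < 16 y, young adults ≥ 16 y).

# Outcome statistics

A limb is a **responder** when its change in GPS (post − pre) is ≤ −1.6°,
the published MCID for the GPS; the boundary is inclusive. Engine
agreement is summarised by per-variable RMSD and linear-fit R² of the
waveforms, Spearman correlation and a Wilcoxon signed-rank test of the GPS
values, Pearson correlation of the Symmetry Index, Bland–Altman limits of
agreement of the GPS changes (bias ± 1.96 sample SD), and a paired t test.
Knee-axis corrections are compared across groups with Kruskal–Wallis plus
Dunn's post hoc z tests (average ranks, tie-corrected; unadjusted and
Bonferroni-adjusted p-values both reported, since conventions differ).

**Pointwise waveform comparison.** Instead of random-field-theory
statistical parametric mapping, paired waveform conditions are compared
with a permutation test on the maximum absolute paired t statistic over the
cycle: sign-flip patterns of the paired differences (enumerated
exhaustively for n ≤ 12, sampled otherwise, identity always included) give
the null distribution of the max statistic, which controls the family-wise
error over time within each variable; a Bonferroni factor of 9 across
variables sets the per-variable level at 0.05/9 = 0.0056. This
self-contained construction is testable for calibration (its type-I rate is
checked against binomial bounds in the test suite) and needs no external
dependency. Wilcoxon zero differences are dropped; ties get average ranks.

# The synthetic cohort generator

The generator defines the study conditions under which every end-to-end
property is evaluated.

* **Templates.** The nine waveforms are truncated Fourier series (three
  harmonics) with stylised paediatric amplitudes and timing. They are
  plausibility constants, not digitised from any published figure, and no
  acceptance property compares to published curves numerically.
* **Cohorts.** The typically-developing cohort has three age subgroups with
  default sizes 12/10/12. Each cerebral-palsy subject carries paired
  pre/post-surgery sessions; surgery is modelled as bilateral, so 13
  subjects give the 26 operated limbs used in the classification checks.
  Per limb, zero-mean constant + first-harmonic deviation offsets are drawn
  for all nine variables (SDs 1–5° by variable); CP limbs additionally draw
  an elevated hip internal-rotation deviation (mean 18°, SD 6°, floored at
  8°) and an in-toeing foot-progression deviation (mean 10°, SD 4°, floored
  at 4°) — the floors reflect that derotation surgery is only indicated for
  substantial deviation. The chain has no tibial-torsion degree of freedom,
  so foot-progression deviations are realised through the hip-rotation
  coordinate, as femoral anteversion produces both in reality.
* **Surgery.** A responding limb has a fraction (default 0.9) of its
  pathological deviation removed post-surgery — a derotation osteotomy
  corrects the measured deviation, so the programmed correction scales with
  it; this guarantees the programmed GPS improvement of responders exceeds
  3° while non-responders change by 0. Constant per-variable effects can be
  layered on top by configuration. Subject-level deviations are otherwise
  held fixed across sessions. Ground-truth responder labels are drawn per
  limb (default fraction 0.6), and a simulated clinical label flips the
  truth independently per limb with probability 0.3 — a configuration knob
  reflecting that clinical judgement and instrumented analysis are partly
  independent sources, not an estimate of any real rate.
* **Soft-tissue artefact.** Each marker's displacement from its bone-fixed
  position is a gait-cycle-locked sinusoid plus an Ornstein–Uhlenbeck random
  walk (correlation time 0.12 s), scaled so the total RMS equals the
  configured amplitude: 19 mm for thigh wands (the largest, matching
  reported thigh tracking errors of about 1.9 cm), 12 mm for shank wands,
  8 mm elsewhere. The systematic (sinusoidal) component's direction and
  phase are drawn per subject and held fixed across that subject's sessions,
  since the artefact is anatomy-driven; the random component is redrawn per
  trial.
* **KAD angles.** Drawn per limb: near zero for TD (SD 3°), elevated for CP
  (mean 12°, SD 6°) and unchanged by surgery.
* **What is not emulated.** Event-detection error (heel strikes are exact
  cycle boundaries), marker occlusion, camera noise spectra, crouch or other
  sagittal-plane pathology, and real anatomical frame offsets between
  engines (both engines share one geometry here, so inter-engine offsets in
  pelvic tilt/hip flexion seen on real data appear only through the
  artefact). Passing tests therefore demonstrate correctness of the
  computational chain under known ground truth, not clinical equivalence on
  real patients.

# Problem sizes and numerical choices

Trials are sampled at 100 Hz (a typical clinical capture rate) with two
gait cycles per walking trial and three trials per session; the
classification cohort uses 13 CP subjects and a 10-subject TD reference
(4/3/3 across subgroups); the permutation-calibration study uses 200 null
replicates of 10 pairs on a 51-point grid. These sizes are chosen so the
full suite runs comfortably on a laptop while leaving the statistical
margins (90% recovery thresholds, binomial calibration bounds) far from
their failure points. Degenerate inputs fail loudly: collinear pelvis
markers, chord offsets no smaller than the proximal distance, zero ASIS
breadth, zero net progression, under-determined or collinear marker sets,
non-finite GPS deltas all raise errors rather than propagate.

# Known limitations

Single-axis knee and locked metatarsophalangeal joints understate real
joint coupling; the proportional-surgery model has no relapse or
compensation dynamics; clinical labels are simulated by independent flips;
and the generator's normative curves are stylised. The package's claims are
therefore about the measurement and analysis chain, for which it provides
exact oracles, not about reproducing any specific clinical cohort.
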