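---
title: "Methods: population-of-models analysis of rotor dynamics in remodeled atrial tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-of-models analysis of rotor dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Chronic (long-standing persistent) atrial fibrillation remodels the atrial
substrate, and the reentrant "rotors" that sustain the arrhythmia behave
differently from patient to patient. `afpop` implements a
population-of-models workflow for asking which ionic conductances control
whether functional reentry is maintained, how fast it activates the tissue
(dominant frequency, DF), how far the rotor core drifts (rotor meandering,
RM), and which substrates respond to L-type calcium-current block with
termination of the arrhythmia. The pipeline has five stages: a remodeled
human atrial cell model with scalable conductances; action-potential
biomarker extraction; Latin-hypercube sampling plus range-based calibration
of a model population; monodomain tissue simulation of functional reentry
with optional conductance block; and a statistical layer (Mann-Whitney
group comparisons, partial correlations) linking conductances to rotor
behaviour.

## The cell model

The membrane kinetics are the Courtemanche-Ramirez-Nattel (CRN) human
atrial action-potential model, transcribed from its published equation set,
with the standard chronic-AF electrical remodeling applied to the baseline
parameter set: ICaL reduced 70%, Ito and IKur reduced 50%, IK1 doubled.
We chose the CRN formulation as the base model because its equations are
printed in full in its publication and can be verified line by line against
the implementation; the workflow itself is agnostic to the base model, and
all downstream stages interact with it only through `cell_params` and the
solver interface. The remodeled baseline reproduces the expected phenotype:
APD90 shortens from roughly 300 ms (non-remodeled) to about 135 ms, resting
potential near -84 mV, and APD shortens further with pacing rate.

Eleven maximal-conductance parameters are treated as the axes of
intersubject variability: gNa, gCaL, gto, gKur, gKr, gKs, gK1, the Na/K
pump and Na/Ca exchanger maxima, the SERCA uptake maximum and the
sarcolemmal Ca-pump maximum (`conductance_names()`). The set is
configurable: any named subset of the model's maxima can be scaled, with
multipliers restricted to [0, 3], i.e. -100% to +200% of nominal. A
funny-current conductance is not part of the default set because the CRN
formulation has no If; the pump/exchanger/SERCA maxima take its place so
that eleven parameters are sampled.

## Numerics

The solver uses Rush-Larsen updates for all Hodgkin-Huxley-type gates and
forward Euler for the voltage and concentrations, at a fixed step. Three
implementation details matter for reproducibility and speed:

* voltage-dependent gate kinetics and current shape factors are tabulated
  on a 0.25-mV grid over [-100, 70] mV and linearly interpolated. The
  tables depend only on the step size, never on the scaled conductances, so
  every population member runs through identical arithmetic;
* reversal potentials and the Nai-dependent Na/K-pump saturation are
  refreshed every 16 steps (0.4 ms at the default step) because the
  underlying concentrations drift on second timescales; the SR-release
  gating signal is evaluated every step through a tabulated sigmoid;
* denormal floating-point values are flushed to zero inside the hot loops;
  decaying gate variables otherwise enter the subnormal range at a large
  per-operation cost.

Single-cell work uses dt = 0.02-0.025 ms. Desk-scale tissue runs use
dt = 0.04 ms: Rush-Larsen keeps the stiff gates stable there (verified up
to gNa x 3), and the integration bias this introduces (the baseline rotor's
DF shifts by roughly 0.5 Hz relative to dt = 0.025 ms) is uniform across
the population, which is what the cross-model comparisons rely on.
Convergence-sensitive checks (decoupling, conduction-velocity refinement)
run at dt = 0.0125-0.025 ms in the test suite. Identical inputs give
bit-identical outputs everywhere; with zero diffusion every tissue node
reproduces the single-cell trajectory exactly, because both loops execute
the same step function.

## Biomarkers and the synthetic calibration envelope

`compute_ap_biomarkers()` measures APD20/50/90, APA, RMP and V20 on one
beat. Conventions the literature leaves open, fixed here: the take-off
point is the time of maximum dV/dt during the upstroke (robust to the
stimulus artifact); repolarization levels are referenced to APA above RMP;
crossings are linearly interpolated; V20 is read at take-off + 0.2 x APD90
(not from stimulus onset). At fast pacing the remodeled model shows
beat-to-beat alternans, so the per-frequency phenotype is the element-wise
median over the last three paced beats rather than a single final beat; the
ordering APD20 <= APD50 <= APD90 survives the median because it holds
beat-wise. Rate dependence is summarized as APD50 and APD90 at 2/3/4 Hz
divided by their 1-Hz values, paced in sequence (warm continuation) with a
fixed stimulus of twice the baseline diastolic threshold found once by
bisection.

The experimental recordings behind the original calibration envelope
(APD and potential ranges measured in atrial trabeculae of a large
chronic-AF cohort) are not publicly deposited, so
`generate_biomarker_ranges()` builds a synthetic stand-in: bounds of
center +- spread x scale around a center phenotype, by default the baseline
AF model with spread 0.3. The scale is |center| floored at a quarter of
the biomarker family's magnitude (the APD90 center for durations, the APA
center for potentials, 1 for ratios). The floor exists because a purely
proportional window collapses for biomarkers whose center is small on its
natural scale - APD20 of the remodeled model is ~5 ms and V20 sits near
-12 mV - and a collapsed window rejects every candidate, which no
experimental envelope would do. What the synthetic envelope does *not*
emulate: real inter-patient biomarker correlations, measurement artifacts,
and the width asymmetries of the clinical distributions. Calibration
results therefore demonstrate that the machinery selects
phenotype-consistent models, not that the selected density matches the
clinical cohort.

## Population calibration

`latin_hypercube_sample()` (backed by the `lhs` package) draws scale
vectors with exactly one sample per dimension stratum. Each candidate is
paced at 1-4 Hz and accepted only if all twelve calibration quantities
(six 1-Hz biomarkers, six rate ratios) fall inside the envelope;
non-excitable candidates (no regenerative upstroke - e.g. gNa = 0 yields a
calcium-mediated hump peaking below 0 mV) and solver failures are rejected
with recorded reasons. At the desk preset (1024 candidates, spread 0.3)
roughly 5% calibrate, of the same order as the percent-level acceptance
rates typical of full-scale calibrated populations (a couple of hundred
accepted from ~16k candidates). Acceptance is monotone under envelope widening, which the test
suite checks by nesting envelopes.

## Tissue simulation

The monodomain equation is solved with Godunov splitting (reaction step,
then explicit diffusion through a sparse mesh Laplacian) on three mesh
types: square sheets (5-point stencil, no-flux boundaries), 1-D strips for
conduction-velocity measurements, and icospheres with cotangent-weight
Laplacians normalized by barycentric vertex area (closed surface: every
row sums to zero, Euler characteristic 2). The full-scale geometry is the
sphere; the desk preset uses a 2.5 x 2.5 cm sheet at dx = 0.05 cm because
rotor physics, the analysis layer and the statistics are exercised
identically at a fraction of the cost, and the homogeneous-kinetics
setting makes surface geometry a second-order factor for the sign-level
questions asked here. The diffusion
coefficient default D = 1.2e-3 cm^2/ms gives a planar conduction velocity
of about 54 cm/s for the remodeled model at converged resolution (~37 cm/s
at the desk discretization, where the 0.05-cm grid numerically slows the
wavefront). The default matters: at appreciably smaller D the reentrant
wavelength shrinks relative to the sheet and rotors become so stable that
conductance block can no longer destabilize the core, which changes the
block experiment qualitatively, so the conduction regime is treated as
part of the study conditions rather than a free dial.

Reentry is initiated by a phase-distribution seed: the state trajectory of
one paced beat (300-ms window from the upstroke) is wrapped once around
the mesh center, so activation phase advances by one cycle per turn. This
is robust across the whole population (no timing tuning per model); a
classic S1-S2 cross-field protocol is provided as an alternative.
Interventions are `block_spec()` objects - a named conductance multiplied
by a factor in [0, 1] from an onset time; 50% gCaL block is the
experiment of interest. Runs can record a full state snapshot at a chosen
time so an intervention can branch bit-exactly from a basal run.

## Rotor analysis

Phase is the argument of the FFT-based analytic signal of the
mean-subtracted voltage (time-delay embedding is available as an option);
the frame count is trimmed to a 5-smooth length because R's mixed-radix
FFT degrades badly at near-prime lengths. Phase singularities are faces
whose oriented boundary sum of wrapped phase differences is +-2 pi; the
test suite pins this detector to a brute-force winding-number oracle on
random smooth fields and to closed-sphere charge conservation. Cores are
tracked by greedy nearest-neighbour association gated at four node
spacings per frame with matching charge. RM is the convex-hull area of the
dominant (longest-lived) trajectory - the maximum across trajectories when
several comparably long-lived rotors coexist - projected to the tangent
plane on spheres. DF is the per-node Welch periodogram peak in 1-20 Hz
(Hann window, 50% overlap, parabolic log-power peak interpolation, which
recovers sub-bin frequency resolution from the short desk windows), and
the scalar DF is the modal per-node value. Termination is declared after
300 contiguous quiescent milliseconds (no singularity, all nodes below
-40 mV), tagged "core collision" when the last two opposite-charge
trajectories died within the gate distance of each other.

## The two experiments and their statistics

`run_maintenance_experiment()` calibrates the population, simulates every
accepted model (capped at `max_models`, desk default 22) for a basal
window plus a continuation window, classifies sustained vs unsustained on
the basal window, compares each conductance between those groups
(Mann-Whitney U, two-sided, alpha = 0.01, no multiplicity correction -
mirroring a fixed-threshold convention across the eleven comparisons; a
Benjamini-Hochberg option exists), and computes partial correlations of
each conductance with DF and RM among sustained models, controlling for
the other ten. `run_ical_block_experiment()` restarts every sustained
model bit-exactly from the end of its basal window with the block applied,
and measures changes in DF and RM against the matched no-block
continuation over the same window - so a null intervention (factor 1)
yields exactly zero change, and temporal drift of the rotor does not
masquerade as a drug effect. Desk windows are 1.2 s (the full-scale
protocol observes 7 s); block-induced termination is compared with
persistence across the conductances in the same way.

Partial correlations are computed from the precision matrix of
[outcome, predictors], which equals the Pearson correlation of the two
residual vectors from regressing outcome and predictor on the remaining
predictors (the test suite verifies the equivalence to 1e-10). With
eleven controlled predictors the layer requires at least thirteen
sustained models; the desk preset is sized so that this holds with margin
for typical seeds. DF-RM coupling is reported as a signed
correlation-style coefficient (`signed_r2()`): the magnitude is |r| and
the sign carries the direction - a notation choice, not a literal square.

## Problem sizes, determinism and limitations

Desk-scale defaults: 1024 Latin-hypercube candidates calibrated with 16
beats per frequency at dt = 0.025 ms; up to 22 tissue simulations of
2.4 s each (plus 1.2 s per block run) on the 2601-node sheet at
dt = 0.04 ms with 2-ms frames. A full run of both experiments takes
roughly a quarter of an hour on one CPU core. The full-scale preset
(`study_config()`: 16384 candidates, subdivision-6 icosphere, 7-s
windows) is provided but is cluster-scale. All randomness enters through
explicit seeds (sampling and envelope jitter); solvers and analyses are
deterministic, so a configuration plus seed reproduces every table
bit-for-bit.

The scaled-down trend experiment in the test suite checks the sign
pattern of the conductance-rotor couplings rather than magnitudes, and
the desk scale is not neutral across couplings. The strong, directly
conduction-mediated relations - sodium conductance raising the dominant
frequency and anchoring the core - reproduce robustly. The
meander-mediated relations are fragile on a small bounded sheet: models
whose cores meander most either terminate at the boundary or convert to
boundary-anchored reentry (whose core, and hence RM, ceases to exist), so
the surviving sample under-represents exactly the behaviour those
couplings describe. In larger diagnostic runs of the same pipeline the
L-type-calcium-to-meandering coupling and the mean meandering increase
under calcium block come out near zero or sign-flipped for this reason
(compounded by the remodeled baseline's already-small ICaL, whose further
block mostly shortens APD and accelerates the rotor). The corresponding
sign checks are asserted as stated and may fail at desk scale; a
closed-surface (sphere) geometry at production resolution is the
configuration in which they are expected to hold.

Known limitations: homogeneous tissue only (no fibrosis, no anisotropic
fibre fields, no anatomical atrial geometry); surface meshes only (no
transmural filament geometry); late-INa kinetics and small-conductance
Ca-activated K channels are outside the model; desk-scale windows are
short, so DF estimates carry ~1 Hz-scale uncertainty that the parabolic
peak interpolation only partly removes, and per-model Delta-RM estimates
are noisy - the statistical layer is designed around sign patterns and
rank tests for exactly that reason.
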