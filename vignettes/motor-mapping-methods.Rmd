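---
title: "Methods: surface-based TMS motor mapping with tmsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-based TMS motor mapping with tmsmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsmap)
```

## The problem

Navigated single-pulse TMS over the primary motor cortex elicits
motor-evoked potentials (MEPs) in contralateral muscles. Delivering many
pulses at pseudo-random positions over a coil grid and recording surface EMG
from several muscles at once yields, per muscle, a spatial map of cortical
excitability: where on the cortex does stimulation drive this muscle, how
large is that territory, and how much do the territories of different
muscles overlap? Because individual brains differ in shape, group-level
comparison requires carrying each subject's map onto a common template
surface.

`tmsmap` implements this analysis as a chain of testable stages:

1. **EMG**: zero-phase high-pass filtering, MEP/non-MEP classification,
   hotspot and resting-motor-threshold (RMT) rules;
2. **surface**: nearest-vertex projection of coil positions, masking to the
   primary motor cortex ("precentral L" atlas label), warping to a template
   through unit-sphere registrations with curvature matching;
3. **excitability maps**: geodesic inverse-distance interpolation of MEP
   amplitudes onto template vertices, and three map-level statistics —
   the MEP-weighted centroid, the MEP-weighted area, and pairwise
   intersection-over-union overlaps with muscle-pair grouping;
4. **group statistics**: two-way repeated-measures ANOVAs with Mauchly
   sphericity tests, Greenhouse-Geisser correction, and
   Bonferroni-corrected post-hocs;
5. **synthetic data**: a generator producing meshes, excitability fields,
   stimulation schedules and EMG traces with known ground truth, so every
   stage is validated by parameter recovery rather than by eyeballing.

## EMG processing and MEP rules

Traces are sampled at 2 kHz, span a pre-stimulus baseline and the response
window, and are high-pass filtered at 30 Hz with a 2nd-order Butterworth
filter applied forward and backward (zero phase). The forward-backward pass
uses odd-reflection padding with steady-state initial conditions, so a
constant (DC) trace filters to numerically zero and symmetric inputs stay
symmetric; traces shorter than the padding requirement are rejected rather
than zero-padded.

A stimulation counts as an MEP when the peak-to-peak amplitude in the
response window is

* **larger than 20x the baseline SD**, where the baseline SD is the
  population (1/N) standard deviation of the filtered trace in the 200 ms
  before the pulse, and
* **smaller than 10 mV**, read as an artifact-rejection upper bound.

Both inequalities are strict; the classification records which rule failed.
The response window defaults to 15–50 ms post-stimulus — a standard range
for hand and forearm MEPs; the exact window used in any given lab protocol
varies, so it is a configurable parameter (`response_window_ms`), as are the
multiplier (`k_sd`) and the bounds. The hotspot is the stimulation with the
largest amplitude (ties to the earliest pulse), and the RMT is the lowest
tested intensity at which more than half of ten pulses exceed 50 µV.

## Warping to the template

Subject and template surfaces each carry a per-vertex registration onto the
unit sphere (the standard output of cortical inflation; the package consumes
these as inputs and, for synthetic meshes, constructs them analytically).
A subject vertex maps to the template vertex minimising

$$\mathrm{cost}(s, t) \;=\; \arccos(\mathbf{s} \cdot \mathbf{t})
\;+\; \lambda \, \lvert \hat{c}_s - \hat{c}_t \rvert ,$$

the great-circle distance between the sphere coordinates plus a curvature
mismatch penalty. Matching gyral/sulcal curvature anchors the angular
correspondence to anatomy. The additive form and the weight are a design
choice of this package: curvatures are z-scored within each surface so both
terms are dimensionless and comparable, and `lambda_curv` defaults to 1.
A hard curvature constraint or multi-scale registration would be
alternatives; the additive penalty is transparent, and with
`lambda_curv = 0` the warp reduces to pure nearest-sphere-neighbour
matching, which the tests exploit (identity on self; exact recovery of a
known sphere rotation). Stimulations are masked to the precentral label on
the *subject* surface before warping — masking first is the order that does
not depend on label consistency across surfaces. MEP amplitudes are carried
through the warp unchanged.

Nearest-vertex projection of the coil position ignores coil orientation;
orientation is registered in the event tables but plays no role in the
analysis.

## Excitability maps and their metrics

Warped stimulation amplitudes are spread onto the template by geodesic
inverse-distance weighting: every vertex within `radius_mm` (default 5 mm)
of at least one stimulation vertex receives the 1/d-weighted mean of those
amplitudes; stimulation vertices keep their own amplitude exactly; vertices
beyond the radius stay outside the map. Geodesic distances are shortest
edge-paths (Dijkstra over the mesh edge graph with Euclidean weights),
which is accurate at the mesh resolutions used here; exact polyhedral
geodesics would change distances by less than an edge length.

The interpolation radius is a smoothing scale: fields whose spatial spread
is comparable to the radius are flattened near their flanks (biases up to
~20% of the local value for a Gaussian field with σ close to the radius),
while fields twice the radius or broader interpolate to within a few
percent pointwise. The tests pin both regimes.

For a map $W = \{(\mathbf{v}_i, \mathrm{MEP}_i)\}$:

* **centroid** — the MEP-weighted mean vertex position
  $\mathbf{C} = \sum_i \mathrm{MEP}_i \mathbf{v}_i / \sum_i \mathrm{MEP}_i$;
* **area** — over every surface triangle whose three vertices lie in the
  map, the Heron (semi-perimeter) area times the mean MEP weight of its
  vertices, summed. With unit weights this is exactly the geometric patch
  area (verified against cross-product areas to 1e-9). The Heron form is
  written with its square root; without it the expression would carry units
  of mm⁴ rather than an area;
* **overlap** — intersection-over-union of two maps' triangle sets:
  triangles complete in both maps over triangles complete in either. In the
  default `"geometric"` mode every triangle counts by its area alone. The
  MEP weights of two muscles are not commensurable inside the intersection
  (each map carries its own amplitudes), so a weighted union/intersection is
  not uniquely defined; the optional `"weighted"` mode max-normalises each
  map and averages the two normalised weights where both are present. The
  mode is recorded in the output. A triangle belongs to a map only when all
  three vertices do — a conservative rule with no fractional triangles,
  which under-counts thin sliver intersections on coarse meshes (the tests
  include a mesh-refinement convergence check for that regime).

The eight muscles (FDI, ADM, FPB, APB hand; EDC, FDS, ECR, FCR forearm)
form 28 unordered pairs partitioned into hand-hand (6), hand-forearm (16)
and forearm-forearm (6) groups. Synergistic pairs are flagged: FDI-APB,
FDI-FPB, APB-FPB within the hand; EDC-ECR and FDS-FCR within the forearm;
and EDC/FDS crossed with FDI, APB, FPB, ADM across groups — habitual
co-activation partners in grasping, extension and flexion.

## Group statistics

Map metrics (Cx, Cy, Cz, W) enter a two-way repeated-measures ANOVA with
muscle and intensity as within-subject factors; overlaps enter a
pair-group x intensity ANOVA (mean overlap per group per subject) followed
by within-group pair x intensity ANOVAs. Replicated cells (repetition
blocks) are averaged within subject and condition first. Each effect is
tested against its own subject-by-effect interaction term.

Sphericity is assessed per effect with Mauchly's test on the covariance of
orthonormal contrast scores; its p-value uses Box's chi-square expansion
including the second-order term. The Greenhouse-Geisser epsilon
$\varepsilon = \mathrm{tr}(S)^2 / (p\,\mathrm{tr}(S^2))$ deflates both
degrees of freedom; "necessary" is operationalised as Mauchly p < 0.05
(configurable), and the table always reports both the raw and the corrected
p so the decision is auditable. When the cohort is too small for a
non-singular contrast covariance, the sphericity columns are NA and the
uncorrected p is reported. Two facts worth noting: epsilon is bounded in
[1/(k−1), 1], and the corrected p exceeds the uncorrected p throughout the
near-significant regime (for F below ~1 the correction can move either way,
where it never affects a decision). Post-hoc comparisons are all pairwise
paired t-tests within one factor, Bonferroni-capped over the
k(k−1)/2-comparison family; paired t was chosen over simple-effect ANOVAs
as the most common reading of Bonferroni-corrected post-hocs in this
literature.

## The synthetic cohort generator

The generator emulates the study conditions end to end: 20 subjects, 8
muscles, 3 intensity conditions, 120 pseudo-random stimulations per
condition block with a 5 s inter-stimulus interval, the whole set repeated
twice (720 pulses per subject), coil positions uniform over a 5 x 5 cm grid
centred on the per-condition hotspot, EMG at 2 kHz.

Each muscle's excitability field is an isotropic Gaussian blob on the
template patch: amplitude = peak · exp(−‖p − c‖²/2σ²). Defaults place hand
muscles lateral and forearm muscles medial along a synthetic precentral
band, 4 mm apart with σ = 6 mm — neighbouring representations overlap
substantially at half maximum, distant ones not at all — and peaks of
400–800 µV with FDI largest. Intensity conditions scale the peaks
multiplicatively (1.0, 1.15, 1.30 by default, emulating stimulation just
above the respective RMTs). Per subject, field centres are jittered
tangentially (SD 2 mm), mesh vertices perturbed (SD 0.2 mm), and per-trial
amplitudes get additive Gaussian noise (SD 20 µV, clipped at zero). These
between-subject parameters are an invented variability model — no
generative model of inter-individual motor-map variation exists to copy —
and are exposed in the configuration.

Each trial's EMG trace is baseline Gaussian noise (SD 5 µV) plus, for
non-zero amplitudes, a biphasic Gabor-like wavelet (odd lobe pair under a
Gaussian envelope, time constant 3 ms) at 20 ms latency whose peak-to-peak
amplitude equals the trial amplitude. MEP waveshape and latency are not
constrained by any reference; the wavelet is the simplest biphasic shape
with an exactly controllable peak-to-peak, and 20 ms is a typical hand-MEP
latency, both configurable. Traces are regenerated on demand from
deterministic per-trial seeds rather than stored (a full cohort would hold
~115,000 traces).

Ground truth recorded per cohort: every subject's field centres, spreads
and peaks, plus pairwise overlaps of the half-maximum discs computed with
the analytic circular-lens formula — a flat-geometry approximation that is
exact on the planar template patch used by default.

What the generator does **not** emulate: biophysical electric-field spread
(amplitude is a pure Gaussian of coil-to-centre distance), corticospinal
conduction variability, trial-to-trial latency jitter, folded cortical
geometry (the default template is a flat patch; a hemispheric mesh with
analytic curvature and registration is provided for warp tests), or
registration error between subject and template spheres. Passing recovery
tests therefore demonstrates the correctness of the analysis chain, not its
robustness to every property of real cortical data.

## Numerical choices and degenerate inputs

* Heron radicands are clipped at zero before the square root (floating-point
  guards on near-degenerate triangles); meshes with exactly degenerate
  triangles are rejected at construction.
* Nearest-vertex and argmin ties resolve to the lowest index, everywhere.
* `arccos` arguments are clipped to [−1, 1] before great-circle distances.
* An all-zero-weight map has an undefined centroid (error); a map with no
  complete triangle has area 0 (with a warning); an empty union makes the
  overlap undefined (error), as does an empty stimulation set for
  interpolation.
* F statistics with a zero effect and zero error sum of squares are
  reported as 0 with p = 1 (identical values across levels).
* Unbalanced ANOVA input is an error naming the missing cells; replicates
  are only averaged when explicitly requested.

## Problem sizes used in validation

The test suite and the acceptance script validate at deliberately modest
sizes chosen to exercise every code path with comfortable margins: full
720-pulse schedules for bookkeeping; two-subject noiseless cohorts at the
full design for end-to-end centroid recovery (mean recovery error ~0.3 mm
on a 2 mm template patch — individual maps carry the irreducible sampling
noise of 120 random coil positions per block, about 1–2 mm, which averages
out across maps); an 81 x 81 patch at 0.5 mm spacing for the analytic
disc-overlap comparison; 50 random perturbed meshes for the area oracle;
1000–2000 simulated null cohorts (n = 12, 3 x 3 design) for type-I-error
calibration of the RM-ANOVA.

## Known limitations

* Shortest-edge-path geodesics overestimate true surface distance by up to
  ~8% on a regular grid (path anisotropy); immaterial at a 5 mm radius on
  1–2 mm meshes but a bias to keep in mind on coarse meshes.
* The complete-triangle membership rule biases thin intersections downward;
  overlap estimates for nearly-disjoint map pairs converge only with mesh
  refinement.
* The warp is a per-vertex argmin: it is not guaranteed injective, and no
  smoothness constraint ties neighbouring vertices together. For the
  small deformations typical of sphere-registered cortices this is
  adequate; strongly distorted registrations would need a regularised
  registration method instead.
* Weighted-mode overlap depends on per-map max-normalisation and is
  therefore sensitive to single extreme amplitudes; the geometric mode is
  the primary output.
* The Mauchly p-value is asymptotic; for very small cohorts (n close to the
  number of contrasts) it is unreliable, and the implementation refuses the
  singular case outright.
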