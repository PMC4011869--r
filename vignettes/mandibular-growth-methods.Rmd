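---
title: "Measuring longitudinal mandibular growth from surface meshes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring longitudinal mandibular growth from surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mandigrow)
```

mandigrow quantifies long-term three-dimensional growth of the mandible from
serial triangle surface meshes, as produced by segmenting cone-beam CT scans
taken at regular intervals (the timepoint vocabulary is T1..T12 with a
4-week interval, so a "month" here always means four weeks). Each scan is
measured independently — there is no inter-timepoint registration — which
mirrors how serial cephalometric data are analysed in practice and avoids
the confounding of registration error with growth.

## The measurement model

Seventeen anatomical landmarks are tracked: the lateral and medial condylar
poles (LP, MP), the coronoid process (CP), the gonion (GO), the anterior,
middle and posterior mental-foramen edges (AMF, MMF, PMF), the notch of the
groove for the external maxillary artery (NO) — all bilateral — and the
midline genial tubercle (GT). Five codes are detected automatically from
the mesh geometry; AMF, MMF, PMF and NO are ingested from a manually placed
landmark table, validated and snapped to the surface (snap tolerance 1.0 mm
— roughly four CT voxels — so voxel-scale placement error does not abort a
run, while grossly off-surface rows are rejected with a per-row report).
Repeatability of manual placement is quantified with the intraclass
correlation coefficient in its two-way random-effects, absolute-agreement,
single-measurement form, ICC(2,1); the form had to be fixed by us since
reliability is conventionally reported without one.

From one landmark set the package measures 25 inter-marker distances in
four orientation groups — anteroposterior (AP, 9 pairs, with nested
Mandible / Anterior (Body) / Posterior (Ramus) subgroups), superoinferior
(SI, 3), anteroinferior (AI, 6) and mediolateral (ML, 7 bilateral pairs) —
plus two inter-segmental angles (LP-GO-AMF at the gonion per side, and the
bilateral angle at GT between the rays to left and right GO) and the bone
volume of the watertight mesh. Distances are reported in cm, angles in
degrees, volume in cm³. Unilateral distances are computed per side and as
the side mean; the default longitudinal report uses the left side, matching
the side convention of per-side growth plots, and the side-mean reading
remains available (`side_select`) because summary tables in this field do
not always say which was printed.

## Automatic landmark rules

All detectors operate inside coarse regions of interest (ROIs). In the
original workflow a human marks the gross position of each structure before
the precise rule runs; here the ROIs are procedural — axis-aligned boxes in
the canonical anatomical frame (+x anterior, +y subject-left, +z superior,
origin at the centroid), expressed as fractions of the mesh bounding box so
they scale with the growing bone — and can be overridden in configuration.

* **LP / MP** are the extremal vertices along the lateral (+y on the left,
  −y on the right) and medial directions inside the condylar ROI.
* **CP** is the vertex of maximal discrete Gaussian curvature in the
  coronoid ROI. Curvature is the angle deficit normalized by the Meyer
  mixed area (Voronoi area for non-obtuse triangles, area/2 resp. area/4
  splits for obtuse ones); this estimator is parameter-free and
  sign-stable on protruding tips, which is exactly what a coronoid apex
  is. If the coronoid were a ridge of near-constant curvature the argmax
  would be weakly determined; ties are broken by lowest vertex index, and
  this limitation is accepted and documented rather than patched with
  smoothing heuristics.
* **GT** is the most posterior (−x extremal) vertex in the lingual
  anterior midline ROI. The alternative reading "most prominent point"
  appears in landmark glossaries; we implement the operational
  posterior-extremal rule because it is the one stated as the automated
  procedure, and flag the discrepancy here.
* **GO** uses the three-plane construction: a supporting plane tangent to
  the posterior ramus border (outward ≈ posterior), a second tangent to
  the inferior corpus border (outward ≈ inferior), and the plane bisecting
  the wedge into which both outward normals point (the exterior, obtuse
  wedge behind and below the mandibular angle). The bisector is
  intersected with the surface; among intersection-curve points within a
  neighborhood of the two border ROIs (default 18% of the bounding-box
  diagonal, large enough to cover the whole rounded corner between the
  two tangent bands), GO is the point closest to the two planes'
  intersection line, minimized continuously along the curve segments with
  ties broken by the lowest curve parameter.

**Supporting planes.** "Tangent to the borders" is a supporting-plane
statement, not a regression, so no least-squares fitting is used. The
implementation analyses the contact shell — ROI vertices within a band
(default 1% of the ROI diameter; an anatomical border is a rounded ridge,
not a mathematical edge, and the band operationalizes finite sharpness) of
the extreme along the outward direction. A planar contact patch contributes
its own normal; a line-like contact (a border ridge) is completed with the
outward direction (normal = outward minus its component along the ridge); a
point contact uses the outward direction itself. The plane is then placed
on the outermost ROI vertex along that normal, so the supporting property
holds by construction. A naive rule — take the convex-hull facet most
aligned with the outward direction — is unstable when the contact set is a
nearly straight chain: hull facets pivot freely about the chain and the
selected facet can tilt by tenths of a radian depending on incidental
secondary contacts. The test suite keeps the hull as an independent oracle:
the returned plane must be supporting and at least as aligned as every
enumerated hull facet.

**The gonion migrates.** GO is a *constructed* landmark: it is defined by
the tangent-plane geometry of each scan, not by a material point of bone.
Under non-homogeneous growth (ramus and body growing at different rates)
the construction re-applied at a later timepoint does not coincide with the
material transport of the earlier gonion — the corpus tangent plane's
offset grows with the body while the corner grows with the ramus, so the
constructed point slides along the border (several millimetres over a year
at realistic anisotropy, by direct computation with this package). This is
the classical behaviour of gonion in cephalometry. The synthetic generator
therefore records GO ground truth per timepoint by evaluating the
construction on the noise-free surface, while the sixteen anatomically
fixed landmarks are transported exactly by the growth deformation.
Correctness of the construction itself is validated against a closed form:
on an extruded quarter-cylinder fillet of radius r joining two orthogonal
planes, the construction must return a point on the fillet at 45°, at
distance r(√2 − 1) from the planes' intersection line.

## Growth statistics

For each parameter series v₁..v_T: total change Δ = v_T − v₁; *normalized
total change* N = Δ / v₁ (scale-free, so growth of small and large
dimensions is comparable); monthly changes d_t = v_t − v_{t−1} (which
telescope to Δ exactly); *percent-of-change* p_t = 100 (v_t − v₁)/Δ; and
the half-growth month, the first measured timepoint with p_t ≥ 50 — no
interpolation, since "reaching half of the growth around month m" is a
statement about measured visits, and interpolation would manufacture
sub-visit precision. A constant series returns N = 0 with the percent
series flagged undefined rather than dividing by zero.

Orientation-group summaries are unweighted means over member parameters of
per-subject values (mean of per-subject ratios, since normalization is to
each subject's own initial value); the across-subject mean and SD are then
reported. The orientation effect is tested with a one-way repeated-measures
ANOVA on the subject-level group means (the F statistic is checked in the
tests against a from-scratch sums-of-squares computation). Because
sphericity of the four-level within-subject factor is unverifiable in small
samples, the Greenhouse–Geisser epsilon and corrected p are always reported
alongside the uncorrected test. When the omnibus effect is significant at
α = 0.05, all six pairwise paired t-tests are run against the
Bonferroni-corrected threshold α/6 = 0.008333…; the threshold is stored at
full precision (printed summaries in this literature round it to 0.0082).

A bundled reference summary table from a year-long serial-CBCT miniature-pig
study (8 animals, 12 four-week timepoints; initial value, final value and
normalized total change per marker pair, with orientation-group means) is
used for internal-consistency checks: recomputing (final − initial)/initial
from the printed columns reproduces the printed normalized value within
table rounding (±0.01) for 19 of the 25 pairs, and every printed group and
subgroup mean is the unweighted mean of its printed member values within
±0.01. The six discrepant pairs are exactly those with large printed SDs —
the expected signature of a mean of per-subject ratios differing from the
ratio of printed means (Jensen-type inequality), not of a transcription
error. The table's "final value" column is read as v_T12: with that reading
the normalized column equals (v₁₂ − v₁)/v₁ throughout, which is the only
internally consistent interpretation. A small dose-budget utility completes
the reporting: per-scan dose × number of scans, µSv to mSv (e.g. 263 µSv ×
12 = 3.156 mSv equivalent; 182.1 µSv × 12 = 2.1852 mSv effective).

## The synthetic growing mandible

No public serial mandible meshes exist at this design, so validation rests
on a synthetic study generator whose defaults emulate the study conditions:
8 subjects × 12 four-week timepoints of an anisotropically growing,
bilaterally near-symmetric mandible-like closed surface with known
ground-truth landmark trajectories.

The template is a swept tube: a midline-symmetric path runs from the right
condylar top down the ramus, around the gonial bend, through the horseshoe
body and chin, and up to the left condyle; elliptical cross-sections (broad
axis ~11 mm in the ramus, ~7 mm tall in the body; thin axis 3.5–5 mm) are
swept along it and closed with rounded caps — a watertight genus-0 surface
of ~1900 vertices at the default resolution. Condylar knobs come from
inflating the terminal sections (mediolaterally widest, so the pole rules
are well-posed); the coronoid processes and the genial tubercle are smooth
Gaussian displacement bumps whose centres snap to surface vertices, making
each apex a single unambiguous vertex and the curvature/extremal argmax
stable under deformation. The posterior ramus border is a straight vertical
ridge and the mid-body inferior border is planar, so the two tangent planes
of the gonion construction have stable, anatomically sensible contacts.
Template dimensions approximate a one-month-old miniature-pig mandible
(bounding box ≈ 71 × 76 × 43 mm, volume ≈ 22 cm³).

Growth is a region- and direction-weighted coordinate scaling
p′ = p ⊙ (1 + τ(t) s(p)) about the centroid, where s blends per-region
rate triples (fractional total growth along AP/SI/ML) through smooth
logistic weight fields over bounding-box fractions — soft masks keep the
field crack-free, so meshes stay watertight. With all rates equal the map
reduces to an exact global similarity, which the tests exploit (angles must
be conserved to numerical precision). Default rates (anterior body
1.30/1.05/0.45 for AP/SI/ML, body 1.20/1.05/0.55, ramus 1.45/1.42/0.80,
condyle 1.42/1.40/0.75, coronoid 1.46/1.44/0.75) encode the qualitative
pattern the generator must emulate: ramus faster than body, superoinferior
and anteroposterior faster than mediolateral; they were chosen once from
the reference table's group structure and produce the orientation ordering
SI > AP > AI > ML with the pairwise significance pattern in which only
AP–SI is non-significant. The time curve is an exponential saturation
τ(t) = (1 − e^{−k(t−1)})/(1 − e^{−k(T−1)}) with k = 0.2/month, putting
~50.7% of total change before month 4 — fastest growth in the first
months, a measured half-growth month of 4. Per-subject variation is a
multiplicative size factor (SD 3%), lognormal jitter on the per-axis rates
(SD 4% by default), and an optional small shear for left-right asymmetry;
measurement noise is applied to the manual-landmark table only, not to the
mesh, so detector error and biological variation stay separable.

What the generator does **not** emulate: CT physics (no beam hardening or
intensity calibration), teeth and alveolar remodelling, soft tissue, local
surface texture of real bone, and condylar cartilage growth mechanics. A
pipeline that is exact on these meshes is therefore validated for its
geometry and statistics, not certified for segmentation-quality effects on
real scans; the voxelization round trip below is the bridge toward the
latter.

## Voxelization and reconstruction

`voxelize_and_reconstruct()` emulates the segment-then-mesh path: occupancy
is sampled per voxel centre by z-column ray parity (0.25 mm emulates the
CBCT protocol), diagonal checkerboard voxel pairs are filled to keep the
boundary edge-manifold, the block-boundary isosurface at occupancy 0.5 is
extracted on the voxel-corner lattice, and Taubin smoothing (λ = 0.5,
μ = −0.53, 15 passes) removes the staircase with negligible shrinkage —
the smoothing every practical segmentation-to-surface pipeline applies.
Voxel-count volume (count × h³) is also the independent oracle for the
divergence-theorem mesh volume (agreement within 2% at 0.1 mm on random
blobs), and volume error shrinks monotonically through 1.0/0.5/0.25 mm. At
1 mm voxels all 17 landmarks re-detected on the reconstructed mandible lie
within two voxel sizes of the clean-mesh detections; localization error of
extremal points on rounded features scales as √(voxel · feature radius),
so proportionally tighter bounds at much finer voxels should not be
expected.

## Numerical conventions

Geometric tolerance 1e-6 mm and angular tolerance 1e-9 rad, centralized in
`mg_tolerances()`. Tie-breaks are everywhere "lowest vertex index" (or
lowest curve parameter) for reproducibility. Meshes are re-oriented on read
by edge-consistency region growing plus a signed-volume sign fix; volume
refuses non-watertight input rather than estimating silently. The PLY
interchange format stores double-precision coordinates so write/read round
trips preserve vertices to 1e-6 mm. All randomness flows from a single
integer seed; a study is bit-reproducible given its model object.

Problem sizes in the shipped tests and acceptance script — template
resolutions of 1200–2600 vertices, studies of 1–8 subjects × 2–12
timepoints, 2000-replicate null calibration of the repeated-measures
ANOVA — were chosen as the smallest designs that exercise every code path
at the study's own dimensions.

## Known limitations

* The gonion's neighborhood gate and contact band are heuristics with
  scale-aware defaults; pathological geometries (a second corner inside
  the gate) would need explicit ROIs.
* Curvature-based CP detection assumes a protruding apex; flat or
  ridge-like coronoids degrade to a tie-break decision.
* The growth field is diagonal in the anatomical axes; real condylar
  growth has a rotational component that the generator does not model.
* Manual landmarks are trusted after snapping; no outlier test beyond the
  1 mm surface-distance gate is applied.
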