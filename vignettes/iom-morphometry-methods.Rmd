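---
title: "Methods: 3D morphometry and tensile analysis of the interosseous membrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry and tensile analysis of the interosseous membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iomorph)
```

## The measurement problem

The interosseous membrane (IOM) is the ligamentous sheet connecting the
radius and ulna along the forearm diaphysis. Its individual structures --
from distal to proximal the distal oblique bundle (DOB), the accessory
band (AB), the central band (CB) and the dorsal oblique accessory cord
(DOAC) -- stabilise pro-supination, and forearm simulation models need
per-ligament morphometric and tensile parameters that are tedious or
impossible to obtain with 2D calliper methods. `iomorph` implements the 3D
measurement chain on triangulated surface meshes of the two bones and the
membrane, plus the analysis of ramp-to-failure force-displacement curves,
and ships a parametric phantom generator so that every operator can be
validated against analytic ground truth.

## Geometry model and operators

All coordinates are millimetres in a single shared frame; no unit
autodetection is attempted. Meshes are plain triangle soups
(`surface_mesh`); STL is read and written natively (binary and ASCII, with
vertex merging at 1e-6 mm, well below micro-CT voxel size).

**Bone axes.** The longitudinal axis is the principal axis of the bone's
vertex cloud, oriented distal-to-proximal by a caller-supplied distal hint
point; the distal reference point is the extremal vertex against the axis
and the length is the extent of the vertex projections. PCA is used as the
reproducible surrogate for anatomical axis definitions that are specified
only by reference to surgical convention. Meshes whose two largest
principal spreads differ by less than a factor 1.5 are rejected as
degenerate.

**Fibre vectors and fan-out angles.** Each ligament is annotated by its
insertion landmarks: proximal/distal pairs on each bone for CB, AB and DOB
(`R_p`, `R_d`, `U_p`, `U_d`), a single mid-fibre pair (`R_m`, `U_m`) for
the narrow DOAC. A fibre vector is the ulnar minus the radial point. The
fan-out angle against the radius axis is reported with the acute magnitude
and a signed convention: positive when the radial-to-ulnar vector runs
distally along the axis (CB/AB course), negative when it runs proximally
(DOAC/DOB course). The raw arccosine of the dot product alone would report
obtuse angles for CB-type fibres; folding to the acute angle with the sign
taken from the axial component reproduces the signed values reported for
cadaveric forearms. A fibre perpendicular to the axis maps to +90, a
parallel one to exactly 0.

**Ligament separation.** The membrane is cut between two half-space clips.
For four-landmark ligaments each plane contains one boundary fibre line
and has its normal equal to the component of the radius axis orthogonal to
that fibre, so the planes fan with the fibres; for the DOAC two parallel
planes with the same normal construction straddle the mid-fibre at
`clip_half_width` (half the surgical-clip length in the original
annotation). Triangles crossing a plane are cut exactly at the plane
(per-triangle Sutherland-Hodgman), never dropped, so clipping conserves
area -- a property the tests check against the phantom's closed-form patch
areas at 2%.

**Thickness profiles.** Thickness is measured in a cross-sectional slab of
total width 0.2 mm centred on the plane containing a fibre line, sampled
at 0.05 mm stations along the fibre (both defaults in
`pipeline_config()`). The local "vertical" is the unit vector orthogonal
to the fibre and to the slab-plane normal, i.e. the dorso-palmar direction
of the sheet; per station, thickness is the maximum vertical separation of
the collected surface points. Point collection combines the exact
triangle-plane section (interpolated at each station; coplanar triangles
contribute their edges) with all mesh vertices inside the slab: the exact
section makes the profile independent of mesh resolution, while the slab
vertices preserve the original point-binning reading of the measurement.
Stations with fewer than two points are reported missing, never zero --
zeros would bias pooled means. The pooled per-ligament summary
(`average_thickness`) joins the fibre-direction profiles and an
axial-direction profile, mirroring how reported average thicknesses pool
both directions.

**Attachments.** Attachment location is the projection of a landmark on
the owning bone's axis, as a percentage of bone length from the distal
end. Attachment width is read literally as the longitudinal distance --
the axial projection of the proximal-distal chord; since the alternative
(3D Euclidean chord) is defensible, it is exposed as
`attachment_width_mode = "euclidean"` in the configuration rather than
decided silently. Each bone's own axis is used for projections of its
attachments.

## The forearm phantom

The phantom makes every operator's ground truth analytic. Bones are capped
cylinders (defaults: radius 254.4 mm, ulna 271.5 mm, shaft radius 7.5 mm)
with parallel axes separated by an 18 mm interosseous gap -- straight
cylinders rather than anatomical shapes precisely so that axes, landmarks,
angles, widths and areas have closed forms. The membrane is one thin ruled
solid per ligament: a planar mid-surface trapezoid spanning the gap
between the two attachment edges, offset by half the thickness field on
each side (dorso-palmar), closed by four walls, watertight. The thickness
field is constant or a linear ramp from the radial to the ulnar edge, so
profile slopes are known exactly. Landmarks sit exactly at the analytic
span endpoints.

Ligaments are declared either by both spans (the fan-out angles then
follow from the geometry) or, for the DOAC, by radial mid-position plus
signed angle and width (the ulnar position then follows). The default
layout uses the cadaveric table magnitudes: CB spans 51.7-65.1% (radius)
and 32.9-46.4% (ulna), DOB 10.0-17.5% / 11.0-19.1%, DOAC at -18.7 degrees
with 9.2 mm width. Because the phantom sheet is single-layered while real
neighbouring ligaments overlap axially at different dorso-palmar depths,
the AB is placed just distal of the CB (39.3-48.6%, the reported range
endpoints) and the DOAC mid-fibre at 70.5%, inside the reported ranges.
Overlapping spans are rejected as a configuration error.

Because the phantom's bones are parallel cylinders with a uniform gap,
span-derived fan-out angles differ somewhat from the cadaveric means for
ligaments whose real geometry involves converging bones (the DOB
especially); the recovery tests always compare against the generator's own
echoed truth, not against the cadaveric angles.

A note on one degenerate case: a fibre that crosses a positive
interosseous gap cannot make 0 degrees with the bone axis, so "no
obliquity" is the perpendicular-fibre case (+90 degrees, both edges at
equal axial height); that is the flat-slab configuration used to validate
constant-thickness recovery.

## Synthetic tensile curves

`make_tensile_curve()` builds the biphasic ramp-to-failure shape observed
in IOM ligament testing from declared parameters: starting at the 0.5 N
preload, a quadratic toe over `toe_span` joining the linear region with
continuous slope; a linear segment of slope `stiffness`; a linear drop of
`drop_fraction` (default 15%, at least 10%) after the first fibre-failure
peak; a concave parabolic rise with apex exactly at
(`gauge_length x ultimate_strain / 100`, `ultimate_force`); and a terminal
linear decay to 88% of the ultimate so the 95% stopping criterion falls
inside the tail. The rise is deliberately curved: a piecewise-linear rise
would itself be a perfect line and could win the linear-region search.
Noise is i.i.d. Gaussian on force only (displacement is
machine-controlled), drawn under the truth's seed without disturbing the
caller's RNG stream. Setting the first peak equal to the ultimate yields a
monophasic curve with the drop and rise omitted. The toe is modelled as a
quadratic because only the qualitative toe behaviour is described in the
testing literature; any smooth concave ramp with matched end slope would
serve.

## Curve analysis choices

**Preprocessing** zero-offsets displacement at the first sample reaching
the 0.5 N preload and truncates after the last sample before force first
falls below 95% of the maximum past the global peak -- the machine's
stopping criterion applied in software. A utility trims leading
pre-conditioning cycles by keeping the final monotone displacement run.

**Linear region.** The search considers every contiguous pre-peak window
whose strain span is at least `linear_fit_min_span` (default 0.15) of the
pre-peak strain range and returns the window maximising the r-squared of a
first-order fit; ties within 1e-9 go to the widest window, then the
earliest. Prefix sums make each window's fit O(1). Two guards bound the
search: the window must end at or before the global force maximum (the
linear section always precedes the ultimate force), and, when a first
fibre-failure peak exists, at or before that peak -- the first peak occurs
directly after the linear behaviour, so a window spanning the failure drop
cannot be a linear region even if its pooled r-squared is high. The
failure-peak bound is found on a lightly smoothed curve and requires the
drop to exceed both the 5% relative threshold and five standard errors of
the smoothed noise (noise estimated from first differences), so
measurement noise cannot fake a failure event; if the bound leaves no
admissible window it is ignored. Pure max-r-squared without the second
bound is measurably biased under noise: wide windows spanning drop and
rise accumulate enough y-variance to beat the true linear window. The
search is automatic rather than using published per-ligament strain
ranges, which are results of the original analysis, not inputs; recovering
those ranges is instead a test. A best window below r-squared 0.9 is
returned with a warning rather than an error -- robustness over silent
failure. The default `linear_fit_min_span = 0.15` keeps the window
comfortably inside the shortest reported linear ranges (1-1.5% strain of a
4-6% pre-peak span).

**Peaks and strain.** The ultimate force is the global maximum; ultimate
strain is grip-to-grip displacement at the maximum over the gauge length
(strain is reported without optical tracking, so gauge-length strain is
the operative definition). The first peak is the earliest local maximum
followed by a relative drop of at least `first_peak_drop` (default 5% --
large enough to separate fibre-failure events from noise at the
generator's noise scale) before the global maximum; monophasic curves
report the ultimate as their first peak.

**CSA and stress.** The cross-section is the trapezoid of the two
attachment widths and the mean thickness; nominal stress is force over the
initial CSA. Elastic moduli are deliberately not reported: with a single
constant CSA per ligament the modulus would be an artefact of that
approximation, while stiffness is read directly off the curve.

## Summary conventions

Tables report mean, population SD (divisor n) and range. The population
convention is not a stylistic choice: it exactly reproduces the published
per-ligament SDs computable from the per-forearm values (CB stiffness SD 18.61, against 20.80 under the n-1
convention), which is asserted as a unit test. Single-specimen groups (the DOB) report SD and range as
missing. Printed-table comparisons round half away from zero at the
printed precision (strain means print at one decimal); JSON outputs keep
full precision.

## Reproducibility and problem sizes

All randomness flows through explicit seeds: phantom poses, noise streams
and the pipeline's per-stage seeds are deterministic functions of one
top-level seed, and reruns of `run_pipeline()` produce byte-identical
result JSONs (manifest timestamp aside). The validation suites use 20
seeded phantoms at the tabulated morphometric magnitudes under random
rigid poses and 50 seeded tensile truths spanning the tabulated tensile
magnitudes (noise-free, plus 50 at 2% force noise), with default mesh
resolution of about 2,500 faces per bone and 1,800 per membrane patch and
a 0.01 mm curve sampling step; these sizes give recovery errors at or near
machine precision while keeping a full run in seconds.

## What the phantom does and does not show

Passing recovery on the phantom demonstrates that the operators are
mutually consistent and exact on geometry satisfying their assumptions:
cylindrical bones, planar ruled patches, noise-free meshes. Real
segmented meshes add curvature of the bone shafts, membrane folding,
segmentation noise, non-parallel bone axes and axially overlapping
ligaments at different depths -- none of which the phantom emulates. In
particular, PCA axes of curved bones differ from surgical axis
definitions; thickness of a folded membrane can exceed the true fibre
thickness (an effect reported for the DOB scanned in supination); and
clipping a real continuous sheet assigns inter-ligament tissue to
whichever side of the plane it falls. The tensile generator likewise omits
viscoelasticity, rate dependence and multi-fibre cascades beyond one
first-failure event. Results on real data therefore inherit these caveats
even though every computational step is validated.

## Known limitations

- Attachment widths beyond the axial-projection reading require the
  explicit `euclidean` switch; no attempt is made to decide which the
  original calliper protocol corresponds to.
- The DOAC separation needs an externally supplied `clip_half_width`; on
  real data this is the surgical-clip length, which is not recoverable
  from the mesh.
- `thickness_profile()` requires a reference direction that is not
  parallel to the fibre to orient the slab; profiles along the bone axis
  pass the mean fibre direction instead.
- The linear-region bound assumes at most one pre-ultimate failure drop;
  curves with several large intermediate drops will be bounded at the
  first one.
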