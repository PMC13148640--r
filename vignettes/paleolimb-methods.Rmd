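---
title: "Methods: musculoskeletal modelling and stance inference for extinct archosaurs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: musculoskeletal modelling and stance inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleolimb)
```

## The problem

Small Triassic pseudosuchians sit near the base of the great archosaur
locomotor radiation, and the classic questions about them — were they
bipeds or quadrupeds, sprawlers or erect walkers, plantigrade or
digitigrade — cannot be answered by eyeballing bones. They require a
quantitative chain: a fleshed-out body model with segment masses and a
whole-body centre of mass (COM); joints with anatomically meaningful
coordinate systems and ranges of motion (ROM); muscles reconstructed
from extant relatives and routed over the skeleton so their leverage
(moment arms) can be measured; and the animal's proportions placed in a
comparative morphometric context. `paleolimb` implements that chain as
a tested, offline pipeline.

## Body segment parameters

Body segments are watertight triangle meshes built by lofting series of
octagonal cross-sectional hoops along each segment's long axis (the
standard "hoop" reconstruction used for extinct archosaurs). Given a
closed mesh, volume, COM and the inertia tensor are computed by exact
signed-tetrahedron integration: each surface triangle spans a
tetrahedron with the origin, and volumes, first moments and second
moments accumulate in closed form (for the second moment of a
tetrahedron with vertices $p_1..p_4$,
$\int x x^T dV = \tfrac{V}{20}\left(\sum_i p_i p_i^T + s s^T\right)$
with $s=\sum_i p_i$). Orientation is repaired globally by the sign of
the signed volume; watertightness (every edge shared by exactly two
consistently oriented faces) is a hard precondition.

Air-filled spaces (pharynx, trachea, lungs) are separate watertight
meshes subtracted at zero density, so a segment's mass is
$\rho\,(V_\text{solid}-\sum V_\text{cavity})$ with the tissue density
default $\rho = 1060$ kg m$^{-3}$. This bookkeeping is what produces
net segment densities below tissue density (a 5.47% cavity fraction
gives a net density of ~1002 kg m$^{-3}$, i.e. 95% of base).

Hoop inflation multipliers — the correction for "shrink-wrapped"
initial hoops — are data, not code: the published values derive from
extant-animal studies and are not printed in the source material, so
the package defaults them to 1 and accepts per-hoop values. Loft
correspondence joins vertex $i$ of one octagon to vertex $i$ of the
next (no twist minimisation); lofts are validated watertight after
capping.

Incomplete caudal series are reconstructed by ordinary least squares of
centrum length and height against vertebra number, predicting the
missing distal vertebrae as cylinders (height is the dorsoventral
extent, hence used as the cylinder diameter) out to an assumed total of
30, with 10% of each length inserted as inter-cylinder gaps for missing
soft tissue. Negative extrapolations are clamped to the smallest
measured value with a warning.

The whole-body summary reports total mass, mass-weighted COM,
per-segment mass fractions, the COM's cranial offset from the hip
midpoint (projection on the craniocaudal axis, conventionally defined
by the sacrum) and the bipedality ratio — offset over femur length,
as a percentage.

## Joints: coordinate systems, posing, range of motion

Anatomical coordinate systems come from least-squares primitive fits to
isolated articular surfaces: total-least-squares planes, spheres
(algebraic solve then geometric Gauss–Newton refinement), cylinders
(Levenberg–Marquardt refinement of axis, axis point and radius, seeded
from all three covariance eigenvectors because a partial articular
patch does not reliably expose the axis), and algebraic 9-parameter
ellipsoids. Fits recover exact synthetic primitives to numerical
tolerance and report RMS orthogonal residuals.

Joint coordinate systems (JCS) pair parent and child primitives: hinge
z along the cylinder axis, ball-joint origin at the socket sphere
centre with z chosen so flexion/extension sweeps the sagittal plane.
Axis signs are canonicalised so a flipped fitted axis yields the same
frame; right-handedness is enforced at construction and left-handed
frames are rejected, not repaired.

Joints rotate in the fixed order z (flexion/extension), then y
(ab/adduction), then x (long-axis rotation). The per-joint meaning of a
positive angle differs between joints (hip/shoulder/MTP3/MCP3 versus
knee, ankle, elbow, wrist) and is therefore encoded as a data table in
the packaged configuration, not in code. Missing articular cartilage is
compensated by translating segments (and their whole distal subtree,
JCS origins included) distally — 5% of humerus length for the forearm,
10% of femur length for the crus.

ROM scanning sweeps one DOF at a time outward from the reference pose
in 5° steps, stopping at bone collision or articular disarticulation.
The published protocol was visual and manual; the package's automated
proxy is: collision when any mesh edge of one bone pierces a face of
the other (Möller–Trumbore segment–triangle tests, both directions) or
a vertex lies inside the other mesh deeper than a 0.1 mm tolerance
(containment by generalized winding number, penetration depth by exact
point-to-triangle distance); disarticulation when the minimum distance
between the two articular point sets exceeds 150% of the rest gap by
default. The winding-number containment was chosen over ray-parity
testing because parity rays grazing mesh edges produce unstable votes;
the winding number is exact for closed oriented meshes. A true
mechanical stop is recovered to within one scan step, which is the
honest resolution of a 5°-stepped protocol.

## Muscles: paths, wrapping, moment arms

Muscles are single lines of action from origin to insertion through
optional via points, deflected by analytic wrapping surfaces. A
cylinder wrap replaces the chord by the shortest tangent–arc–tangent
detour in the cross-section plane whenever the chord penetrates the
surface, distributing axial travel proportionally to unrolled in-plane
arclength (exact in the planar case, the standard obstacle-set
treatment otherwise); a sphere wrap uses the single geodesic in the
plane through both endpoints and the centre. The wrap side for
cylinders is an explicit per-surface datum (`active_side`) and is never
flipped automatically — automatic side flips are a classic silent error
source, so disengagement/engagement is logged instead. Path length is
continuous across engagement: a grazing chord equals its detour.

Moment arms use the tendon-excursion method,
$r = -\,dL/d\theta$, by central finite difference with half-width
0.25° (chosen to match the export behaviour of standard
musculoskeletal software while remaining self-contained). The sign
follows each joint's angle convention. Curves are evaluated on the 5°
ROM grid inclusive of both endpoints; the mean dimensionless moment
arm is the unweighted grid mean divided by a normalising bone length
(femur for the hip, tibia for the knee, metatarsal III for the ankle;
averaging grid and weighting are unstated in the source material, so
grid-mean is the package's documented choice). Dimensionless means are
invariant under uniform geometric scaling, which the tests verify at
×2.

Verification is dual-route throughout: finite-difference moment arms
are checked against perpendicular-distance closed forms on hinges,
against the wrap radius for paths fully wrapped on a hinge-coaxial
cylinder, against a boundary-graph numeric geodesic oracle for wrapped
lengths, and against an independent virtual-work computation (unit
tension, insertion-point velocity projected on the line of action).

## Muscle reconstruction by the extant phylogenetic bracket

Attachment characters scored across saurians are optimised on a rooted
phylogeny by unordered maximum parsimony. The implementation is a
unit-cost dynamic program (Sankoff down-pass for subtree costs, up-pass
for outside costs), which yields the exact minimum change count and the
full most-parsimonious-reconstruction (MPR) state set per node,
including on polytomies. Ambiguity is preserved as sets — only
singleton reconstructions are read as firm ancestral states. Missing
("?") entries allow any state; inapplicable ("−") entries are treated
as missing for optimisation but flagged separately.

Witmer inference levels are a pure function of two bits: singleton
versus ambiguous reconstruction (I versus II) and presence versus
absence of an osteological correlate on the fossil (plain versus
prime). The packaged 37-muscle pelvic-limb dictionary carries the
published levels and renders them in bracketed table style.

Correctness is anchored to an exhaustive-enumeration oracle that scores
every internal-node assignment on trees of up to 8 tips; the dynamic
program matches it on 100 seeded random trees, including MPR sets.

## Stance inference

Three independent lines:

* **Allometric mass.** The published quadrupedal stylopodial equation,
  $\log_{10}(\text{mass in g}) = 2.749\,\log_{10}(C_h + C_f) - 1.104$
  with circumferences in mm. The coefficient set reproduces the printed
  worked example (14 + 13 mm → 0.68 kg) exactly.
* **Repeated LDA.** Two-class linear discriminants (pooled covariance)
  over a battery of 22 test specifications. The canonical 22 test
  definitions are not printed in the source material, so the battery is
  explicit configuration; the shipped default (15 non-empty predictor
  subsets of the four features plus 7 seeded 75% subsamples) is clearly
  labelled non-canonical and is used for synthetic work. Failed tests
  (singular pooled covariance, one-class subsamples) are reported as
  failed, never silently dropped. The prior (proportional vs equal) is
  exposed as an option because the original choice is unstated.
* **Static COM criterion.** Bipedal standing requires the COM less than
  one femur length cranial to the hips; ratios in [0.6, 1.0) are
  flagged as "pushing the limits". The printed example (0.053 m /
  0.080 m = 66%) lands in the marginal band.

## The synthetic-data generator

`make_toy_skeleton`, `make_toy_muscles`, `make_toy_characters` and
`make_toy_morphometrics` generate every input the pipeline needs, each
carrying its own independent reference answer: octagonal-prism segments
with closed-form volumes ($2\sqrt2\,r^2 L$) at realistic scale (segment
lengths 0.05–0.3 m, body mass ≈ 1.3 kg, femur 0.080 m — so tolerances
transfer to real-model work); muscles with analytic moment arms
(perpendicular offsets, a hinge-coaxial wrap, an axis-parallel zero
case); trees and character matrices with brute-force parsimony
solutions; and two-class Gaussian morphometric datasets with stated
means and covariance (default 3σ class separation, 40 per class).
All randomness flows from a single integer seed and regeneration is
byte-identical.

What the fixtures do *not* emulate: real articular geometry (fits are
exact by construction, real surfaces are noisy and partial), mesh
pathology (holes, slivers), taphonomic deformation, and the real
48×107 character matrix (a format-identical synthetic stand-in is
used). Passing tests therefore demonstrate correctness of the
machinery, not the accuracy of any particular fossil reconstruction.

## Numerical choices

* Units: metres, kilograms, radians internally; ROM tables and grids in
  degrees.
* Collision penetration tolerance 0.1 mm; disarticulation threshold
  150% of the rest articular gap; ROM step 5°; sweep bound ±180°.
* Moment-arm finite difference h = 0.25°; convergence is second order
  (halving h from 0.125° changes results < 1e-8 m on smooth paths).
* Watertightness is enforced at mesh construction; global orientation
  repaired by volume sign; left-handed frames rejected.
* Gimbal handling: z-y-x decomposition clamps |y| at 89.999° with a
  warning.
* Near-parallel JCS axis ambiguity is tie-broken by the convention's
  long-axis flag, with a warning.
* Negative caudal-series extrapolations clamp to the smallest measured
  value, with a warning.
* Problem sizes in the shipped tests: icospheres at 3–4 subdivisions
  (1 280–5 120 faces), ROM fixtures with tens of triangles, parsimony
  trees of 4–8 tips, LDA at 40–4 000 samples per class — sizes chosen
  so the whole suite runs in minutes on one CPU while every oracle
  comparison stays exact or near-exact.

## Known limitations

* Single-DOF ROM sweeps, not 6-DOF mobility envelopes; translation at
  joints is not modelled.
* One wrap surface per path span; no automatic wrap side selection.
* The osim-style XML reader covers the subset the package writes
  (bodies, custom joints with rotation axes, path points, wrap
  cylinders/spheres); everything else lands in an explicit manifest of
  skipped elements rather than being silently dropped.
* Muscle force, architecture and activation are out of scope; moment
  arms are purely geometric.
* The LDA battery and the character matrix shipped for testing are
  synthetic stand-ins; published verdict tallies additionally require
  the corresponding published datasets.
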