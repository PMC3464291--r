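---
title: "A two-morphogen model of cercal filiform hair patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-morphogen model of cercal filiform hair patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cercalarray)
```

## The system and the model

Each cercus of a cricket carries hundreds of filiform hairs, thread-like
mechanoreceptors that deflect in air currents. Every hair moves along a
single plane set by its cuticular hinge, and one direction along that plane
excites the receptor neuron while the opposite direction inhibits it. Two
global regularities of the array call for a developmental explanation: the
hairs keep a characteristic distance from one another (denser at the cercus
base than at the tip, and about 1.22 times denser on the ventral hemi-cone
than the dorsal), and their movement axes are organized into longitudinal
bands — hairs near the two lineage restriction lines (one medial, one
lateral) move along the cercus axis, hairs midway between them move
transversely, with graded orientations in between.

`cercalarray` models the basal segment of a cercus as a cone frustum
(5.2 mm long, radius 0.27 mm tapering to 0.13 mm; the flattened "filet"
sheet tapers from 1.7 mm to 0.8 mm) and asks whether two diffusible
signals, acting through a single scalar cost function minimized by a greedy
Monte Carlo search, suffice to reproduce those regularities.

**Morphogen S (spacing).** Each hair socket releases an inhibitor that
decays exponentially with first-order kinetics, so its normalized
concentration at geodesic distance $r$ is $e^{-r/\lambda}$. The decay
length grows linearly from 0.2 mm at the base to 0.4 mm at the tip end,
matching the measured axial density gradient (roughly half the local
inter-hair distance). The inhibition a hair feels is summed over its
neighbours within one decay length — a finite interaction range that puts
each hair in contact with its first neighbour shell, about six hairs, so a
typical per-hair spacing cost sits near $6e^{-0.3} \approx 4.4$. For a
pair, $\lambda$ is evaluated at the mean axial coordinate so the term is
symmetric.

**Morphogen M (movement direction).** Both restriction lines release a
second signal with decay constant `lambda_m` (in units of the fractional
distance $x$ between the lines, $x = 0$ medial, $x = 1$ lateral). The
two-source profile
$\mathrm{raw}(x) = e^{-x/\lambda_m} + e^{-(1-x)/\lambda_m}$ is rescaled to
1 on the lines and 0 midway, and the cells' angular response saturates at
high concentration: $m(x) = \min(1, \mathrm{norm}(x)/m_\mathrm{sat})$.
The saturated plateau around each line is what produces the wide bands of
longitudinally moving hairs seen in mapped arrays; without it an
exponential profile makes the longitudinal bands vanishingly thin.

**The cost function.** Hair $i$ at position with response $m$ and movement
direction $\theta_i$ contributes

$$E_i \;=\; (1 - a^* W_i)\sum_{j \ne i, \; r_{ij} < \lambda_{ij}}
e^{-r_{ij}/\lambda_{ij}}
\;+\; c_1 (1 - a^* V_i)\left[\, m\,\lvert\sin\theta_i\rvert +
(1 - m)\,\lvert\cos\theta_i\rvert \,\right],$$

and the total cost is $E = \sum_i E_i$ (each pair counted once from each
side). Both angular terms are sines of an angle difference — from the
longitudinal axis and from the transverse axis — so a 180° flip of the
movement direction is never penalized (the morphogen sets the movement
axis, not the excitatory direction along it) and the bracket never exceeds
1. Where $m$ is saturated the optimum is the longitudinal axis; in the
transverse band it is $\pm 90°$; in the transition zones the minimum over
$\theta$ is $c_1\min(m, 1-m) > 0$, an irreducible residue. $c_1 = 10$
balances the two terms so that an alignment error above roughly 5° costs
more than a typical nearest-neighbour rearrangement gains.

**The ventral correction.** $W_i$ is 1 for hairs in the ventral
circumferential half, and lowering their spacing cost by the fraction
$a^* = 0.1$ lets the ventral hemi-cone pack hairs slightly denser; at the
default settings this reproduces the observed ventral/dorsal density ratio
of about 1.22. $V_i$ additionally requires a positive movement angle
($\theta \in (0°, 180°)$), tying the angular discount to positively moving
hairs. Keeping the positional condition alone on the spacing term matters:
if the whole per-hair cost is discounted only for positive angles, every
ventral transverse hair flips onto the $+90°$ branch, which empties one of
the four body-frame direction peaks. With the split form both the density
ratio and the four peaks reproduce simultaneously.

**The search.** All `n_hairs = 300` hairs are seeded uniformly per unit
area of the flattened trapezoid with uniform random directions. Each of
`p_iterations` proposals relocates one uniformly chosen hair to a fresh
global position (the same sampler as the initialization — no locality
kernel) and rotates it by a uniform increment; the proposal is accepted if
and only if the total cost strictly decreases (ties rejected). P counts
proposals, accepted or not. P regulates how much initial randomness
survives: at $P = 10^3$ the array is still essentially random, at
$P = 10^5$ (the default) the banded structure is in place but retains
seed-to-seed variability comparable to animal-to-animal variability, and by
$P \gtrsim 10^6$ the configurations are nearly deterministic given the
field.

## Geometry

All distances are geodesics on the cone frustum. Because the frustum is
developable, unrolling it into a planar annular sector is an isometry and
the geodesic is the chord between the unrolled images, minimized over the
two winding directions; the default domain unrolls to under 10° of sector,
so chords never leave the sector and the closed form is exact. This is the
distance kernel used everywhere. `geodesic_numeric()` reproduces the
stepwise evaluation (a straight segment in (axial, unwrapped-fraction)
parameter space, mapped to 3-D and summed over 100 chords) and agrees with
the closed form to well under 1% — it exists to document and validate the
discretized method, not to power the optimizer, which needs millions of
distances.

```{r geodesic}
dom <- cone_domain()
geodesic_analytic(dom, 1, 0, 2, 0)      # a generator line: the slant length
geodesic_numeric(dom, 0, -0.5, 0, 0.5)  # half-way around the base circle
```

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `n_hairs` | 300 | count | array size, fixed during the search |
| `c1` | 10 | — | alignment weight relative to spacing |
| `a_star` | 0.1 | — | ventral cost reduction |
| `p_iterations` | 1e5 | count | Monte Carlo proposals (accepted or not) |
| `lambda_base`, `lambda_tip` | 0.2, 0.4 | mm | spacing decay length at the two ends |
| `spacing_range` | 1 | decay lengths | interaction cutoff of the inhibitor |
| `lambda_m` | 0.2 | fractional | decay constant of the direction signal |
| `m_saturation` | 0.4 | — | response saturation level |
| `ventral_sign` | +1 | — | which circumferential half is ventral |

`lambda_m`, `m_saturation` and `spacing_range` parameterize the parts of
the model whose published functional forms are not fully specified; their
defaults were fixed once so that the default model reproduces the three
published summary outcomes together — the dominance of longitudinal
movement in the flattened histogram, the four body-centric direction
peaks, and the 1.22 ventral/dorsal ratio — and are exposed in the
configuration rather than hard-coded.

## Assessment suite

```{r run}
rec <- run_model(model_params(seed = 1))
rec
ventral_dorsal_ratio(rec$final_config)
count_peaks(to_body_frame(rec$final_config))
```

**Ripley's L.** $\hat K(s) = A \sum_i \sum_{j\ne i} \mathbf 1[r_{ij} < s] /
(N(N-1))$ with $A$ the flattened trapezoid area (6.5 mm²), and
$L = \sqrt{\hat K/\pi}$. Distances are geodesics, so the circumferential
direction has no edge at all; no edge correction is applied at the two
axial ends, which biases $L$ below the diagonal by a few percent at the
largest windows — the same bias affects the uniform reference pattern, so
comparisons against simulated references are unaffected, and against the
plain diagonal the bias stays inside the 10% band over window diameters of
0.3–1.5 mm (the assessed range). Published curves plot the window
*diameter*; the `ripley_curve` object carries both columns.

**Angle histograms.** 5° bins over (−180°, 180°], in the flattened frame
or transformed to body-centric coordinates: the movement axis is embedded
as a tangent vector (axial component along the cone axis, azimuthal
component around it), projected onto the horizontal plane — the cercus
axis is horizontal with the lateral line in the horizontal plane — and
expressed as an azimuth with 0° pointing directly anterior, minus the 30°
outward rotation of the cercus. Hairs on the lateral line moving at 0° or
180° in the flattened frame map to −30° and 150°; transverse hairs map to
exactly ±90° before the offset, i.e. 60° and −120° after it. A hair whose
movement axis projects to (numerically) zero horizontal length is excluded
with a warning.

**Peak counting.** Counts are smoothed with a centered circular moving
average (3 bins) and peaks are circular local maxima with prominence at
least 5% of the hair count. A maximal run of tied smoothed bins standing
above both neighbours counts as one peak — without this, a sharp two-bin
peak smooths into two exactly tied bins and would have no strict maximum
at all. Perfectly uniform counts have zero peaks.

## What the simulations do and do not establish

The synthetic fixtures (`poisson_hairs()`, `clustered_hairs()`,
`vonmises_mixture_hairs()`) emulate only the null and positive controls
the statistics need: complete spatial randomness on the trapezoid,
parent–offspring clumping, and a known number of angular modes. They do
not emulate measurement error in socket positions, hair-length-dependent
detection, the clavate-hair patch near the baso-medial base (a region the
model deliberately treats as ordinary cuticle), or left–right asymmetries
of real animals. Tests passing on these fixtures validate the statistics
and the simulator's internal consistency, not the biological fidelity of
any particular cercus.

Two scale effects of the reconstruction are worth knowing:

* The axially growing decay length makes low-cost territory of the cercus
  base; when spacing dominates ($c_1 = 1$) the equilibrium density
  gradient is fully developed (base:tip ≈ 4:1, the measured gradient) and
  raw nearest-neighbour distances are *smallest* there. Clustering
  comparisons across $c_1$ are therefore scale-resolved: at window
  diameters below ~0.3 mm the gradient's crowding dominates (strongest at
  low $c_1$), while at the 0.5–1.5 mm windows of the published analysis
  clustering increases with $c_1$, matching the published ordering. The
  package exposes `mean_nn_distance()` and `ripley_l()` so either scale
  can be inspected.
* Seed-to-seed variability of the movement-angle histogram shrinks
  monotonically with P (measured as total-variation distance to the mean
  histogram); the default $P = 10^5$ deliberately preserves part of it.

## Numerical choices

* Greedy acceptance is strict (`delta E < 0`); ties are rejected, so the
  cost trace is non-increasing and a zero-cost proposal never churns the
  state.
* The engine maintains the running cost incrementally (one O(N) pass per
  proposal, with an axial-slant prune that skips pairs that cannot be
  within range) and its final value is cross-checked against a full
  recomputation and against the independent R implementation to 1e-9
  relative tolerance in the tests.
* All randomness flows through R's RNG (also inside the C++ loop), so a
  run is bit-reproducible from its seed, and `p_iterations = 0` returns
  the initialization unchanged.
* Coordinates are canonicalized to circumferential fractions in (−1, 1]
  (−1 and +1 are the same medial seam) and angles in (−180°, 180°]; hairs
  exactly on a restriction line belong to neither circumferential half and
  are excluded from ventral/dorsal counts.
* Axial sampling inverts the trapezoid CDF in closed form; degenerate
  (rectangular) sheets fall back to uniform sampling.
* Simulation sizes in the test-suite follow the study conditions
  (N = 300, P = 1e5, 10–20 seeds per stochastic summary; the P-regime
  sweep uses P up to 2e6 with 5 seeds).

## Known limitations

* The reaction–diffusion origin of the two signals is outside the model:
  fields are steady-state exponentials, not solved PDEs, and the chemical
  identities are unspecified.
* Only first-order degradation is implemented; second-order (power-law)
  decay variants are not.
* The clavate patch, hair lengths, biomechanics and viscous coupling
  between neighbouring hairs are not modeled.
* Ripley's L uses circular windows only; anisotropic (elliptical-window)
  analysis is not implemented.
* The greedy rule has no temperature schedule; it is not simulated
  annealing, by design.
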