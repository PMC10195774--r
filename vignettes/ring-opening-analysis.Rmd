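---
title: "Modelling ultrafast electron diffraction of an electrocyclic ring-opening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ultrafast electron diffraction of an electrocyclic ring-opening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uedring)
```

## The system and the observable

α-Terpinene is a 1,3-cyclohexadiene carrying an isopropyl group (C2,
with methyls C7/C8) on C1 and a methyl reporter (C10) on C5.  On
photoexcitation to S₁ the molecule relaxes into the *pericyclic
minimum*: the C3 and C4 CH₂ carbons rehybridize from sp³ toward sp²
while the C3–C4 σ bond is still intact (we build this anchor with
C3–C4 = 1.6 Å), and only after internal conversion to S₀ does the σ
bond rupture, branching between open-chain triene products and return
to the reactant.

Gas-phase ultrafast electron diffraction measures, after rotational
averaging, the modified molecular scattering intensity

$$sM(s) = \frac{s\sum_{i\neq j} f_i(s) f_j(s)\,
  \mathrm{sinc}(s r_{ij})}{\sum_i f_i(s)^2},$$

whose damped sine transform
$\mathrm{PDF}(r) = \int sM(s)\sin(sr)e^{-\alpha s^2}\,ds$ peaks at the
interatomic distances.  The analysis presented here works entirely in
this forward-model space: geometries in, sM(s)/PDF/ΔPDF out.  The
elastic scattering amplitudes $f(s)$ are a standard five-Gaussian
parameterization for C and H, shipped as coefficients; the independent
atom model ignores inelastic, multiple-scattering and anisotropy
corrections, matching standard simulation practice for MeV-UED.

## Coordinates

All geometric analysis is referred to the **fixed reactant bond
topology** (ten C–C bonds).  Coordination spheres are shortest
bond-path lengths in that graph; they are never re-derived from
distances during the dynamics, so "the C3–C4 distance" remains
meaningful after rupture.  Third-sphere pairs a–x–y–b are labelled
*cis* (|dihedral| < 90°) or *trans* about their central bond, assigned
once on the reference reactant geometry and propagated — the label is
a reactant-frame conformation, not a per-frame quantity.

Rehybridization is tracked by two conrotatory angle coordinates:

* **φ (planarization)** — signed angle between the C3 CH₂ plane and
  the C1–C2–C3 plane, plus the analogous C4 angle against the
  C4–C5–C10 plane;
* **ψ (deplanarization)** — signed angles of those substituent planes
  against the least-squares plane through the diene carbons
  C1, C6, C9, C5.

For each side the magnitude is the full angle between the plane
normals (canonicalized to [0°, 90°]); the sign is the rotation sense
about the side axes C3→C1 and C4→C5, with reference normals oriented
by a consistent ring-traversal normal.  Under this convention a
conrotatory motion adds and a disrotatory motion cancels in the sums.
We chose the ring-traversal orientation over orienting toward the
isopropyl side because the isopropyl carbon lies essentially in the
diene plane, which would make that orientation numerically unstable.
Both coordinates are rigid-motion invariant (tested to 10⁻⁶ degrees);
the least-squares reference plane is the smallest principal component
of the centered diene coordinates, since four atoms are generically
non-coplanar.

Conrotatory sums could be formed from signed or unsigned component
angles; we implement the signed convention because it is the one under
which disrotatory motion cancels, which is the point of a
"conrotatory" coordinate.

## Built anchor geometries

Quantum-chemical stationary points are not redistributable inside this
package, so the anchors are **idealized built geometries** (shipped as
`inst/extdata/*_synthetic.xyz`): standard bond lengths (C=C 1.34,
conjugated C–C 1.45–1.47, sp³ C–C 1.53, C–H 1.09 Å), sp²/sp³ angles,
and half-chair ring torsions solved once so the emergent C3–C4 closure
hits its target — 1.537 Å for the reactant, 1.60 Å for the pericyclic
minimum, 2.2 Å for the ring-open conical-intersection (MECI) anchor.
The pericyclic anchor keeps π-bond alternation conservative (±0.015 Å)
— its stated structural content is the σ-bond elongation and the
out-of-plane bending — and its methyl out-of-plane torsion (26.85°,
isopropyl following conrotatorily at 0.4×) is solved so the C3–C10
reporter distance is 3.55 Å.  The four open-chain triene products
(cZc/cZt/tZc/tZt) use skewed-cis (~40–55°) and twisted-trans (~120°)
single-bond conformations selected by a nonbonded-clearance scan; the
fully planar forms would clash across the Z-triene bay.  All anchors
exist for the three isopropyl rotamers.

## The surrogate wavepacket generator

The generator emulates the *statistical structure* of ab initio
multiple spawning results without forces or energies.  Its defaults
define the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_traj` | 400 | trajectories, equally weighted |
| `p_open` | 0.58 | ring-opening branching fraction |
| `hop_latency` | 60 fs | no internal conversion before this |
| `hop_tau` | 120 fs | exponential hop-time scale past the latency |
| `dip_time` | 100 fs | time of the C3–C10 reporter minimum |
| `open_ramp` | 100 fs | post-hop morph timescale |
| `thermal_sigma` | 0.03 / 0.06 Å | Cartesian thermal sigma (C / H) |
| `t_max`, `dt` | 1000, 5 fs | native time grid |

Each trajectory starts from a thermally displaced reactant (a cheap
stand-in for harmonic Wigner sampling — independent Gaussian Cartesian
displacements, no mode structure).  The S₁ segment morphs
reactant → pericyclic anchor along a cosine ramp peaking exactly at
`dip_time`, then relaxes 30% back — so the C3–C10 minimum is a clear,
strict feature at `dip_time` even against the noise of the shrinking
S₁ population at late times.  Hops occur at
`hop_latency` + Exp(`hop_tau`); the latency and scale are free
parameters shaping a plausible S₀ rise, not measured lifetimes.  After
the hop, with probability `p_open` the trajectory morphs to a
uniformly chosen product isomer; otherwise it relaxes back to its own
thermal start.

All morphing is done in **internal coordinates** (the fixed Z-matrix
whose tree follows the open-chain connectivity, so the C3–C4 closure
distance is emergent): Cartesian interpolation would collapse CH₂/CH₃
groups while the ring torsions swing through ~150°.  Torsions
interpolate along the shorter arc; the thermal displacement persists
as an internal-coordinate offset for the whole trajectory, so the
ensemble never collapses onto the anchors.  By construction the S₁
C3–C4 distance stays within [1.45, 1.9] Å (σ bond intact before the
hop), and the post-hop C3–C4 growth is monotone once past 2 Å — the
cZt path dips transiently by ~0.14 Å before opening, a consequence of
the torsional pathway, which is why the open/closed classification
uses the final-time distance (threshold 2.0 Å) rather than first
crossing.

What the surrogate does *not* emulate: anharmonic mode structure and
mode-specific Wigner widths, spawning (population transfer is a single
stochastic hop per trajectory), coherent oscillations along individual
normal modes, and rotamer interconversion.  Passing tests therefore
validate the analysis chain and its statistical behaviour, not the
quantum dynamics of the real molecule.

## Analysis pipeline and numerical choices

* **Transform window** — s ∈ [0.5, 10] Å⁻¹, Δs = 0.02 Å⁻¹, zero-filled
  below s_min; damping α = ln(10)/s_max² so the damping factor is 0.1
  at the window edge; r ∈ [0, 8] Å, Δr = 0.01 Å.  The finite window
  produces truncation sidelobes of a few percent of a feature's
  amplitude; in particular, strong third-sphere changes leak a smooth
  negative lobe into r ≲ 1.2 Å, *below* the shortest physical
  interatomic distance.  Analysis regions are therefore kept at
  r ≥ 1.2 Å.
* **ΔPDF** — difference of the damped transforms of the delay and
  reference (t = 0 thermal reactant) ensembles, scaled by the
  excitation fraction (default 1.56%, the experimental excitation
  level; it scales amplitudes only).
* **Regions** — α = [1.2, 1.9], β = [2.2, 3.0], γ = [3.2, 3.7] Å.
  The bounds are not printed in the source figures; these are read
  structurally from the coordination spheres (α: bonds; β: geminal
  pairs; γ: the gap between the cis and trans third-sphere modes at
  3.4 Å).  Each named region carries its canonical signal direction
  (α, β depletions; γ gain), known from the late-time ΔPDF.
* **Onset fits** — region traces over the window −250…+300 fs around
  time zero (onset fitting concerns the rise, not the late plateau
  and partial recovery, which a single erf cannot represent),
  convolved with a 150 fs FWHM Gaussian instrument response, then fit
  with B + (A/2)[1 + erf((t−t₀)/(√2 w))] by Levenberg–Marquardt with
  the step direction constrained to the region's canonical sign —
  this stabilizes centers when a weak opposite-sign precursor (e.g.
  the left tail of the broadened γ feature) leaks into a shifted β
  window.  A fit whose |A| does not exceed twice the residual noise
  is flagged (`step_detected = FALSE`): no onset occurred inside the
  window, which downstream ordering comparisons treat as "later than
  anything detected".  The onset width is reported both as the
  Gaussian σ (`w`) and as FWHM = 2.355 σ.
* **Bootstrap** — resampling units are whole trajectories (or scans),
  never frames, which are serially correlated; 68% intervals are the
  16th–84th percentiles of the resampled statistic; seeds are
  mandatory and the global RNG stream is left untouched.
* **Degenerate inputs** — zero filtered weight masks an expectation
  value (NA) rather than erroring; an all-equal bootstrap statistic
  warns and returns a zero-width interval; erf fits fall back to a
  coarse grid search with sign-constrained linear least squares when
  Levenberg–Marquardt cannot start.

## What the desk-scale experiments show

With the defaults above, the pipeline recovers the study's structure:
the static PDF peaks at 1.4 Å (bonds) and 2.5 Å (geminal pairs); the
third-sphere ccDDF is bimodal (cis ≈ 2.9, trans ≈ 3.8 Å) with its
interior minimum at 3.4 Å; the surrogate branching fraction recovers
`p_open` within binomial error; the S₁ C3–C10 expectation dips to
3.55 Å at `dip_time`; and the fitted γ-region onset precedes the α and
β onsets — the diffraction signature that out-of-plane bending
(rehybridization) happens on S₁ before the σ bond breaks — robustly
under ±0.2 Å region-boundary shifts across seeded runs.  Problem sizes
used in the shipped tests and acceptance script (60-geometry thermal
ensembles, 150–400 trajectories, 20 seeded onset runs) were chosen as
the smallest at which the binomial/bootstrap error bands in those
checks are decisively narrower than the effects being tested.

## Known limitations

* The anchors are idealized constructions; absolute PDF peak shapes
  differ in detail from quantum-chemical geometries (peak positions
  agree to ~0.05 Å).
* The IAM neglects inelastic and multiple scattering; experimental
  sM(s) extraction (detector images, backgrounds) is out of scope —
  the pipeline starts from geometries or precomputed curves.
* H-containing pair distributions are retained in sM/PDF but not
  resolved in the ccDDF bookkeeping (their diffraction signatures are
  weak; removing all H moves the static PDF peaks by < 0.1 Å).
* The hop-time distribution is phenomenological; onset *times* from
  the surrogate are meaningful relative to each other, not as
  absolute predictions.
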