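---
title: "Models and methods: rule-based secondary-cell-wall assembly and its ssNMR-facing metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The lignified secondary cell wall (SCW) of hardwoods is a composite of
three polymers — crystalline cellulose fibrils, acetylated glucuronoxylan,
and syringyl/guaiacyl (S/G) lignin — whose relative placement cannot be
read off any single experiment. Solid-state 13C-13C spin-diffusion NMR
constrains that placement statistically: after selectively inverting one
carbon pool (the *source*), magnetization spreads to nearby carbons
(*sinks*) with a rate set by internuclear distance, so the asymptotic
fraction of each sink pool that is reached within a ~1 nm radius, and the
time constant T~SD~ of the transfer, are geometric observables.

`scwforge` implements the computational side of that program:

1. **builders** that realize cellulose fibrils, decorated xylan and lignin
   20-mers from composition rules;
2. **scenario assembly** of periodic whole-wall models under named packing
   hypotheses, with compression to a target density and solvation to a
   target moisture;
3. the **proximity statistic** (percentage of sink carbons within a cutoff
   of source carbons, minimum image) that makes a model comparable to the
   spin-diffusion asymptotes;
4. **conformation metrics** for xylan (glycosidic φ+ψ sums and the
   acetate-orientation dihedral θ²ᶠ);
5. a **spin-diffusion quantification** stack (pseudo-Voigt deconvolution,
   recovery fractions, T~SD~ fits, distance classes) and **synthetic
   generators** with serialized ground truth for end-to-end validation.

Internally everything is in Ångström; nanometers appear only at the CLI
boundary (`--cutoff-nm 1.0` = 10 Å).

# Polymer builders

## Cellulose elementary fibril

The default fibril is the consensus 18-chain model: chains in a 2-3-4-4-3-2
row profile of the Iβ lattice, each a β(1→4) glucan of DP 40. The builders
use an idealized, orthogonalized version of the Iβ cell (a = 7.784,
b = 8.201, c = 10.380 Å, γ = 96.5°): per-residue rise c/2 = 5.19 Å under a
twofold screw, in-sheet chain spacing b ≈ 8.2 Å, sheet stacking 3.9 Å
(the (200) d-spacing), and a c/4 stagger of alternate sheets. Rows are
centered, so rows of unequal parity interdigitate into the diamond
cross-section that exposes the (100), (200), (110) and (1-10) faces.

Residue internal coordinates are an idealized "ribbon" projection of the
pyranose chair (C–C 1.45–1.55 Å, C–O 1.36–1.43 Å) rather than
crystallographic coordinates. Five template constants — the screw-axis
offset, two ring tilts, the direction of the bridging glycosidic oxygen,
and the O3 azimuth — were calibrated **once** against independently stated
geometric anchors and then frozen:

* the twofold (2₁) screw must reproduce the canonical β(1→4) anchor
  φ+ψ ≈ +120° (we land at 123.4°);
* the threefold (3₁) screw must land in its torsion regime (≈ 50° or
  190°; we land at 190.1°);
* consecutive acetates on a twofold chain must sit on one face
  (θ²ᶠ ≈ 0°);
* no two non-bonded heavy atoms closer than 1.8 Å, within chains or
  between the chains of a fibril.

These are geometry constants of the model, not fitting parameters; no
acceptance threshold fed back into them.

A DP-*n* chain spans exactly *n* × 5.19 Å, which the assembly step uses as
the periodic box length along the fiber axis, so fibril chains bond to
their own periodic images — the standard "infinite fibril" construction
for crystalline cellulose.

## Decorated xylan

Xylan chains carry an acetyl on O2 of every other xylose and a
glucuronosyl (GlcA) unit on O2 every eighth residue (first at residue 2,
4, 6 or 8 — the four decoration phases are cycled across chains in
assemblies); a residue whose O2 is occupied by GlcA carries its acetyl on
O3 instead. All decorations sit on even residues counted from the reducing
end, so a twofold chain presents them all on one face. Three backbone
conformations are available: `twofold` (2₁, the cellulose-commensurate
ribbon), `threefold` (3₁, rise 4.95 Å), and `disordered` — per-linkage
uniform random screw twists, a deliberately synthetic stand-in for the
unbound, conformationally disordered state (it randomizes acetate
orientation without sampling any physical torsional free-energy surface).

## Lignin 20-mers

Lignin chains are 20-mers of 13 syringyl + 7 guaiacyl units (S:G = 65:35,
following the construction protocol's counts; the source text also quotes
S/G = 1.8 ≈ 12.9:7.1 — the integer counts win, the mismatch is noted).
Each chain has 19 inter-unit linkages; linkage types are drawn so that
β-O-4 is 80% of the ensemble total, with the remainder split
β-β 10%, β-5 6%, 5-5 2%, 4-O-5 2% of all linkages (a configurable default
standing in for the unpublished details of the hardwood 20-mer scheme).
`build_lignin_ensemble()` balances integer β-O-4 counts across chains by
largest remainder, so any ensemble whose chain count is a multiple of 5
realizes 80.000% exactly.

Geometry: monomers are rigid heavy-atom templates (planar ring, phenoxy
O4, propanoid Cα/Cβ/Cγ sidechain, methoxyls) chained through an idealized
Cβ(i)–O4(i+1) bond shared by **all** linkage types; the type list is
composition bookkeeping, not stereochemistry. This is a documented
fidelity limitation: the metrics the package computes (ring-carbon
proximities, shapes, masses) do not depend on linkage stereochemistry.
`extended` chains are straight rods (end-to-end = contour length);
`globular` chains grow with seeded random bends under a 1.8 Å
self-avoidance check (reject-and-retry, biased back toward the centroid),
giving gyration radii of ~0.1–0.2 × the extended end-to-end distance.

# Scenario assembly

`assemble_scenario()` realizes ten named packing hypotheses (letters a–h
plus the eight- and ten-fibril b.8/b.10; the letter ↔ roman-numeral
protocol mapping lives in one table, `SCENARIO_TABLE`). The common
skeleton:

1. fibrils first, in a clustered core (2×2 for four fibrils; two 2×2
   bundles separated by a 30 Å gap for b.8; a 2×5 grid for b.10) with
   ~25 Å center-to-center spacing along the sheet-stacking direction;
2. *trapped* xylan (b.8/b.10/g/h) on deterministic sites between bundles
   or fibrils;
3. *bound* xylan laid on the exterior cellulose surface in twofold
   conformation, decorated face outward. Surface slots drape over the
   actual surface-height profile of the placed cellulose (the
   cross-sections are diamonds, so flat-face slots would float); each
   chain starts just inside contact and is nudged outward until no
   heavy-atom pair is closer than 1.8 Å, leaving van-der-Waals-like
   contact. Scenario d lays lignin on the surface instead and exiles
   xylan (threefold) to an outer shell;
4. remaining xylan and all lignin placed at seeded random positions and
   orientations about the fiber axis, rejecting placements with contacts
   < 1.8 Å (scenario e restricts xylan to the top and lignin to the
   bottom half of the box).

All chains are axis-aligned with the fiber direction and the box z edge
equals the glycan repeat, which makes the periodic model a quasi-2D
packing problem — a deliberate idealization of the strongly anisotropic
wall. Same seed ⇒ bit-identical assembly.

## Compression

The construction protocol this emulates compressed its models with
molecular dynamics. MD is out of scope here, so `compress_to_density()`
substitutes a deterministic seeded scale-and-relax loop: the box
**cross-section** shrinks by 1% per step (the final step lands exactly on
the target), chain centroids scale with it (chains stay rigid), and after
each step overlapping chains are pushed apart — in all three directions;
sliding along the periodic fiber axis is what lets decorated rods
interdigitate — until no cross-chain heavy-atom pair is closer than
1.8 Å, with capped per-chain displacements and a random kick on
stagnation. The fiber-axis box edge is **not** scaled: the chains are
built commensurate with it, and shrinking it would break the periodic
bonding of the fibrils. (This replaces the isotropic shrink that a
free-standing model would use; for periodic-bonded fibrils isotropic
scaling is not well defined.) An unreachable target raises an error
reporting the best density achieved. Density is mass/volume with
residue-wise formula masses (implicit hydrogens included — builders emit
heavy atoms only), so 1.5 g/cm³ means the same thing it does in the
experimental protocol.

## Solvation and neutralization

`solvate_and_neutralize()` chooses the water count n~w~ so that
n~w~·18.015 / (dry mass + n~w~·18.015) is within one water of the target
mass %, places water oxygens on interstitial grid sites at least 2.4 Å
from any heavy atom (seeded order; too few sites is an explicit error),
and adds one Na⁺ per GlcA carboxylate so the net charge is zero. Waters
are single-site (oxygen only) but weigh 18.015 Da in all bookkeeping.

# The proximity statistic

`percent_within()` counts a sink atom once if **any** source atom lies
within the cutoff (default 10 Å) under the minimum-image convention, via a
cell list that is exactly equivalent to the O(N²) scan (the test suite
checks equality, not approximation, on randomized systems). Sinks default
to carbons of the sink polymer — the NMR observable is ¹³C magnetization —
with `carbon_only = FALSE` available since the underlying figure-of-merit
is stated in terms of "atoms". Sources are the two experimental source
pools: xylan acetyl methyl carbons (22 ppm) and lignin S3/S5/G3/G4 ring
carbons (~150 ppm).

`proximity_profile()` reports the four canonical metrics
(xylan→lignin, xylan→cellulose, lignin→xylan, lignin→cellulose) next to
the experimental reference percentages (~80/40/60/20%), and
`scorecard()` ranks models by mean absolute mismatch, ties broken by the
lignin→cellulose mismatch (the most diagnostic metric for misplaced
lignin). The references are ensemble-averaged experimental estimates and
are overridable.

A caveat the tests make explicit: on sparse, un-relaxed toy models the two
cross-polymer metrics are dominated by sink-pool size (lignin carbon pools
are ~3× larger than xylan's), so the toy-level inequality
xylan→lignin < lignin→xylan is *not* the experimental asymmetry
(which is 80% > 60%). The architectural mechanism — trapped xylan isolated
from lignin — is therefore also tested directly: trapped chains must show
strictly less lignin contact than their matrix siblings.

# Xylan conformation metrics

* `phi_psi_sum()`: φ = O5(i+1)–C1(i+1)–O4(i)–C4(i),
  ψ = C1(i+1)–O4(i)–C4(i)–C5(i), heavy atoms only, sums folded into
  (−180°, 180°]. The twofold builder sits at +123°, inside the ±15° band
  around the 2₁ anchor of 120°; the threefold at 190°.
* `theta_2f()`: the dihedral through (acetate-bound O, C5) of one
  acetylated xylose and (C5, acetate-bound O) of the next acetylated
  xylose (normally i and i+2; the acetate-bound oxygen is O3 on
  GlcA-bearing residues). Near 0° ⇒ acetates on one face (2₁-like);
  disordered chains spread over the circle (circular SD > 60° vs < 20°
  for built twofold chains — the bound/unbound contrast).
* `classify_bound()`: a xylan chain is cellulose-bound when ≥ 50% of its
  backbone residues have any heavy atom within 4.5 Å of cellulose. The
  threshold pair (4.5 Å, 50%) is not stated anywhere authoritative; both
  are arguments.

# Spin-diffusion quantification

* **Deconvolution** (`deconvolve`): non-negative amplitudes, centers
  constrained to ±`shift_tol` (default 0.5 ppm), fixed widths and
  pseudo-Voigt shapes (default Gaussian fraction 0.7). L-BFGS-B with an
  analytic gradient; areas by the closed-form pseudo-Voigt area; area
  uncertainties from the linearized amplitude covariance with noise
  estimated from a signal-free window (default 230–210 ppm, falling back
  to post-fit residual scatter when the axis does not reach it). The
  defaults stand in for unpublished deconvolution details and are flagged
  as assumptions.
* **Recovery fractions** (`recovery_fraction`): selective/nonselective
  area ratios per assignment; polymer-level fractions are ratios of summed
  areas (the cumulative, signal-unbiased estimate); first-order ratio
  error propagation; reference areas consistent with zero are flagged NA
  rather than divided.
* **T~SD~ fits** (`fit_tsd`): weighted least squares of
  f(τ) = A(1 − e^(−τ/T~SD~)) or a two-component sum, model selection by
  AICc when `model = "auto"`. The fit initializes from a profiled grid
  search over T (the amplitude is linear given T) and polishes with
  `nls(algorithm = "port")`; asymptotes are constrained to [0, 1.05] by
  default (a free mode exists, since whether the original analysis
  constrained them is unknown). On the seeded validation grid
  (T ∈ {100, 300, 1000, 3000} ms, noise 2–10% of the asymptote, the
  16-point mixing-time series) median bias is < 2.5% per cell and 68%
  intervals cover 62–68%.
* **Distance classes** (`distance_class`): T~SD~ ≤ 500 ms → "3–5 Å",
  ≤ 2.5 s → "5–10 Å", above → "5 to >10 Å"; boundaries half-open (a value
  on the boundary takes the lower bin) and configurable. The anchors are
  the experimental interpretation of ~300 ms (lignin↔xylan, 3–5 Å) and
  3–4 s (lignin→cellulose, 5 to >10 Å).

# Synthetic data: the stated world

The generators emulate, with known ground truth serialized beside every
dataset:

* 1D ¹³C spectra as pseudo-Voigt sums on a 200–0 ppm, 2048-point grid with
  seeded Gaussian noise (default 2% of the maximum peak height); the
  default 13-peak table covers the cellulose C1/C4/C6 domain-1/domain-2
  split, xylan backbone + acetyl (22/170 ppm) and lignin aromatic/methoxy
  signals;
* selective/nonselective mixing-time series on the experimental 16-point
  τ grid (0.001–5000 ms), sinks building up as A(1 − e^(−τ/T));
* pseudo-equilibrated snapshots by per-atom Gaussian jitter (frame 1 is
  the input).

What a green test does **not** establish: the generators contain no spin
physics (no rate matrix, no proton-driven transfer), no baseline/phase
artifacts, and the jittered "snapshots" have no relaxational correlation
structure. Green tests establish that the estimators recover the
parameters of this stated world at its stated noise — not that the
experimental values themselves are reproduced (those require the original
spectra and 100-ns MD, and enter the package only as scorecard reference
constants and distance-class anchors).

# Numerical choices and degenerate inputs

* Cutoffs above half the smallest box edge are refused (minimum image
  undefined), empty selections warn rather than silently scoring zero,
  flat recovery curves raise "no transfer detected", and dp-1 chains /
  single-acetyl chains yield empty torsion series.
* The steric floor everywhere is 1.8 Å between non-bonded heavy atoms.
* All stochastic steps (lignin shapes, placement, compression relaxation,
  noise) consume seeds derived from the user seed; same seed ⇒
  bit-identical output.

# Known limitations

* Compression is rigid-body scale-and-relax, not MD: densified models are
  sterically valid but not thermodynamically relaxed, and the proximity
  profiles of un-relaxed models underestimate the dense-wall contact
  percentages (the scorecard is used for *ranking* scenarios, which the
  negative-control orderings show is preserved).
* Lignin linkage stereochemistry, ring puckering, hydrogens and
  protonation states are not modeled.
* Solvation after full compression to 1.5 g/cm³ can legitimately fail for
  lack of 2.4 Å voids; the experimental protocol solvated an MD-relaxed
  system. The error is explicit.
* The disordered xylan generator randomizes screw twists uniformly; it is
  a contrast class for θ²ᶠ, not a Boltzmann ensemble.
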