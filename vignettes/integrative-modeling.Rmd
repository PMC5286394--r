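---
title: "Integrative rigid-body modeling into low-resolution EM maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative rigid-body modeling into low-resolution EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large multi-subunit protein complexes often resist high-resolution
structure determination as a whole, while their individual subunits or
domains are known at atomic detail. Negative-stain electron microscopy
of such complexes yields envelope maps at 25--60 Å — enough to see
lobes, arches, and rings, but not to place domains unambiguously: at
these resolutions several alternative placements of a compact domain
score almost equally against the density. Crosslinking mass
spectrometry (XL-MS) provides the complementary information: identified
lysine--lysine crosslinks bound the Cα--Cα distance between specific
residues (≤ ~30 Å for DSS/DSG linkers), which restrains which of the
near-degenerate placements are mutually consistent.

`rigidem` implements the resulting integrative protocol as a
desk-scale, fully scriptable pipeline:

1. **Per-domain fitting** — each rigid domain is fitted globally into
   the map by random restarts plus local optimization, scored by
   normalized cross-correlation (NCC), and the fits are clustered and
   assigned empirical-null P-values.
2. **Assembly by recombination** — full-complex configurations are
   sampled by simulated-annealing Monte Carlo over the precomputed fit
   libraries, scored by a linear combination of the EM term, the
   crosslink restraint, a domain-connectivity restraint, and an
   excluded-volume (clash) term.
3. **Continuous refinement** — the best configuration is refined with
   small rigid-body moves in continuous space, recomputing the EM
   correlation at every step.
4. **Reporting** — crosslink satisfaction ("k out of n (p%)" at the
   30 Å threshold), map coverage, difference maps, FSC curves,
   handedness tests, and superposition RMSDs.

A synthetic-data module generates ground-truth assemblies, simulated
noisy maps, and crosslink tables with a controlled decoy fraction, so
that the entire pipeline is testable end to end without any external
downloads.

## Representations

Structures are carried at two resolutions, as is standard in
integrative modeling:

* **Cα representation** — used for crosslink distances and domain
  connectivity (author residue numbering is preserved verbatim, since
  crosslink tables cite author positions).
* **10-residue beads** — each consecutive 10-residue stretch becomes a
  bead at the stretch's Cα centroid; the bead radius is that of a
  sphere of volume `span × 135 Å³` (the mean amino-acid volume).
  This representation drives the clash score, where all-pairs distance
  sums over atoms would be needlessly expensive.
* **3-residue beads** for density scoring — the density simulated from
  10-residue beads visibly deviates from the atomic density even at
  28 Å (self-fit NCC drops from ~1.00 to ~0.94), while 3-residue beads
  track it to better than 0.999 at a third of the cost of per-residue
  scoring. The scoring representation is configurable
  (`representation = "calpha"` gives the exact Cα density).

Simulated density places an isotropic Gaussian on every atom or bead,
weighted by its mass (one residue mass per Cα, `span` masses per
bead), with `σ = resolution / (π√2)` so that the kernel's Fourier
amplitude falls to 1/e at spatial frequency `1/resolution`. Kernels
are truncated at 4σ for map simulation (quadrature error < 0.2%) and
at 3σ inside the fitting inner loop.

Maps follow one unambiguous grid convention: voxel indices are 0-based
and voxel-centered, the physical position of voxel `(i,j,k)` is
`origin + (i,j,k) × voxel` in Å, and the values array is x-fastest.
MRC/CCP4-2014 I/O normalizes axis order on read and writes mode-2
(float32) files; non-cubic voxels are rejected.

## Global fitting

`global_fit()` draws `n_starts` random poses — rotations uniform on
SO(3) via normalized 4-vectors of Gaussians, centroid positions
uniform over the map region above 10% of the map maximum — and
optimizes each with a derivative-free coordinate hill climb:
translation and rotation axis moves whose steps start at 2 voxels /
30° and are halved whenever a full sweep of moves fails, down to
floors of 0.05 voxel / 0.5°. Two choices here deserve comment:

* *Support-restricted starts.* Uniform starts over the whole box waste
  nearly all restarts on empty stain; restricting the start region to
  the density support keeps the desk-scale budget (hundreds of
  restarts) effective. The whole-box behavior remains available
  (`start_region = "box"`).
* *Multiscale steps with sub-voxel floors.* A fixed sub-voxel step
  cannot migrate a pose across the map, and a coarse floor stalls on
  diagonal sub-voxel offsets (a 0.25-voxel floor leaves ~0.7 Å of
  residual error, costing ~0.01 NCC at the optimum). Halving from
  coarse to fine gives both global reach and sub-voxel convergence.

The score of a pose is the Pearson correlation between the map and the
body's simulated density over the body's own support mask — voxels
where the simulated body density exceeds `mask_frac` (default 0.3) of
its maximum. The core-weighted default discriminates between a body on
its own density and the same body buried in a larger neighboring blob
about twice as well as a looser mask; *wider* masks (support down to
1% of the maximum) were tested and rejected, because in a contact
assembly the surround of a correctly placed body contains its
neighbors' density, which the isolated-body simulation cannot explain.

Fits are clustered greedily in descending score order with the
conventional thresholds of 1° and 1 Å: a fit joins a cluster if it is
within *both* thresholds of the representative (rotation distance
`2·arccos |q₁·q₂|`; shift distance between transformed centroids).
When the map has a known cyclic symmetry, a fit also joins through any
of its symmetry images, so that symmetry-equivalent placements do not
inflate the library. Ties in score are broken by input order, which
keeps clustering deterministic.

### Fit significance

Because NCC values at low resolution crowd into a narrow range,
significance is judged against an empirical null: all optimized scores
are Fisher z-transformed (`atanh r`), the null location and scale are
estimated robustly from the bulk (median and 1.4826 × MAD), and
two-sided Gaussian-tail P-values are computed from the centered,
scaled z-scores. P-values are invariant under recentering, uniform
when the scores are pure null draws (verified by a Kolmogorov--Smirnov
check at n = 10,000), and an outlier five null SDs above the bulk
receives the minimum P-value, far below 10⁻³. All-equal scores yield
P = 1 everywhere. The handedness (mirror) test fits the same body into
the map and its mirror image with identical budgets and seeds and
compares the best fits' P-values; the verdict is "inconclusive" unless
they differ by at least one order of magnitude. The significance of a
hand preference is meaningful because each search is compared against
*its own* null — a chiral solenoid-like body prefers its native hand
by many orders of magnitude, while a planar (achiral) body cannot
prefer either.

## The composite score

A configuration assigns one pose to every body. Its score (lower is
better) is

```
total = w_em · (−Σ_b NCC_b) + w_xl · XL + w_conn · CONN + w_clash · CLASH
```

* **Crosslink restraint** — per link, the ambiguity-resolved Cα--Cα
  distance: for subunits present in two copies, the minimum over all
  copy-pair combinations consistent with the link; dimeric links (the
  same residue crosslinked to itself) are forced to cross copies.
  Links whose residues fall outside every modeled domain are flagged
  unmappable and counted, never silently dropped. The penalty is 0 up
  to the 30 Å threshold, then `((d − 30)/σ_xl)²` with σ_xl = 3 Å,
  **capped at 9** (flat beyond 39 Å). The cap is essential:
  identification tables carry an expected ~5% false-positive rate, and
  with an unbounded quadratic a single decoy link spanning 100 Å
  contributes hundreds of score units — enough to pull a whole subunit
  copy off its density, because the min-over-copies rule lets the
  remaining copy keep every true link satisfied. A bounded ("robust")
  penalty removes the decoy's gradient while still reporting it as
  violated.
* **Connectivity** — for consecutive domains of one chain, the gap
  between terminal Cα atoms must not exceed the linker's maximum
  extension (`n_linker × 3.8 Å + 5 Å` slack); quadratic beyond, with
  the same 3 Å softness.
* **Clash** — `Σ max(0, rᵢ + rⱼ − dᵢⱼ)²` over inter-body bead pairs on
  the 10-residue representation; exactly zero when no beads of
  different bodies overlap.
* **Weights** — defaults `w_em = 60, w_xl = 1, w_conn = 1,
  w_clash = 0.1`, calibrated on the standard synthetic fixture. The
  calibration target is not equal magnitudes but *decision margins*:
  the EM term's discrimination between a body on the right site and
  the best wrong-site placement (~0.03--0.09 NCC per body at 28 Å)
  must outweigh the capped gain of satisfying one false-positive link
  (9 units). With `w_em = 60` the best-scoring configuration is the
  ground-truth arrangement across every tested seed; with `w_em = 1`
  the sampler discovers size-compatible site swaps that trade a small
  EM loss for decoy satisfaction. All four weights are exposed.

## Sampling and refinement

`sample_configurations()` runs independent simulated-annealing Monte
Carlo optimizations (desk preset: 200 runs × 5,000 steps; the
paper-scale preset of 10,000 × 60,000 is available where time
permits). Each run starts from a random assignment, re-draws one
body's fit index uniformly per step, applies the Metropolis criterion
under a geometric schedule from T = 5 down to 0.05 (in score units;
the annealing parameters of the reference workflow are not published,
so these were chosen to accept freely at the start and freeze at the
end, and are configurable), and keeps its best-visited configuration.
Runs are independent across the run index and bit-reproducible given
the master seed, from which per-run seeds are derived.

`refine_continuous()` then perturbs one random body per step with
moves of up to one voxel / 2° — below the cluster thresholds, so the
basin found by recombination is preserved — recomputing that body's
NCC by direct splatting at each step. The best visited state includes
the input, so refinement never worsens the reported total under the
same scoring.

For two-state problems where lobes of a fitted model move relative to
each other, `hinge_split_refit()` cuts one chain at a hinge (the
hinge residues become the flexible linker), assigns every other chain
to the nearer lobe, refits the two super-bodies independently, and
refines. `rebuild_full_model()` converts a configuration back to full
coordinates, re-joining flexible linkers by straight-line Cα
interpolation — linker conformations are representational, not
physical claims.

## The synthetic ground truth

`generate_assembly()` builds compact domains as 3.8 Å-step
self-avoiding random walks with a compactness bias (steps that
increase the radius of gyration are accepted with probability 0.3),
packs them into a lobe with strict no-bead-overlap placement,
duplicates the lobe by a 180° rotation about z for C2 assemblies, and
optionally attaches extra bodies asymmetrically to one lobe. Every 8th
residue is link-eligible, standing in for the typical lysine density.
`simulate_crosslinks()` draws true links uniformly from eligible pairs
within the linker reach (30 Å) and decoys uniformly from *intra-body*
pairs beyond it, with ld confidence scores drawn above the cutoff of
30 for both classes (true links centered at 40, decoys at 33) so that
decoys survive filtering and exercise the satisfaction accounting.
Restricting decoys to intra-body pairs is deliberate: their violation
is pose-independent (a rigid body cannot shorten its own internal
distances), whereas an inter-body decoy in a 9-body fixture with
duplicated subunits creates a score degeneracy — a spare copy can
relocate to satisfy the decoy at near-zero EM cost while the
min-over-copies rule keeps every true link satisfied through the other
copy. That degeneracy is an artifact of the reduced fixture (a real
complex has many more domains and chain connectivity anchoring them),
not a property of the method under test.

The standard end-to-end fixture (`elongator_like_fixture()`) is a
two-lobed C2 scaffold of three subunits in two copies with a
three-body ring bound asymmetrically to one lobe, imaged at 28 Å with
5% relative Gaussian voxel noise, plus a 60-link crosslink table at 5%
decoys. Two geometric choices matter and were made deliberately:

* **All six body types have clearly distinct sizes** (170/130/95
  residues in the scaffold, 145/110/75 in the ring). At 28 Å two
  compact domains of similar size are interchangeable under NCC — the
  motivating experimental study reports exactly this, with several
  subunits fitting "various locations with similar scores". Distinct
  sizes reflect real hetero-complexes (whose subunits typically differ
  substantially in mass) and make each domain individually resolvable,
  which the per-domain recovery checks require.
* **Domains are packed with visible separation** (8 Å placement gap).
  Negative-stain envelopes of lobed complexes show separated lobes,
  wings, and rings; tightly interpenetrating blobs at this resolution
  are neither realistic for a stain envelope nor resolvable.

What the generator deliberately does **not** emulate: stain
flattening, the missing wedge, CTF effects, heterogeneity between
particles, and sequence-dependent crosslink reactivity. Passing the
recovery tests therefore demonstrates that the sampling and scoring
machinery is correct and well-calibrated under the stated noise model
— not that any real negative-stain dataset of comparable quality would
yield a unique model.

## Numerical choices and degenerate inputs

* Resampling between grids is trilinear — adequate far below Nyquist
  at 25--60 Å. C2 symmetrization about a grid axis uses an exact index
  rotation (no interpolation; the mean is preserved exactly); other
  orders interpolate.
* Low-pass filtering multiplies by `exp(−(f·R)²)` in Fourier space
  (amplitude 1/e at `1/R`, mean preserved); two filters compose as
  Gaussians, which the tests exploit.
* Difference maps filter both inputs to a common resolution (35 Å by
  default) and normalize each to zero mean and unit variance before
  subtracting, since stain intensity scales are arbitrary.
* FSC uses shells one Fourier voxel wide; `resolution_at()` linearly
  interpolates the first downward crossing and returns Nyquist with a
  `crossed = FALSE` attribute for never-crossing curves.
* Volume coverage picks its contour so the enclosed volume matches the
  expected molecular volume (1.21 Å³/Da at 110 Da/residue) unless a
  contour is given, and reports the fraction of supra-contour voxels
  inside the model's bead envelope.
* Degenerate inputs fail loudly: empty models, constant maps, empty
  correlation masks, scores at ±1 (clipped with a warning), overlap in
  body definitions, thresholds ≤ 0, and configurations referencing
  empty fit libraries all raise errors naming the offender.

## Problem sizes

The package's own test suite and the acceptance script run everything
at desk scale: ~1,100-residue assemblies in ~65³-voxel maps, 400
restarts × 220 optimization steps per domain fit, and 200 × 5,000-step
recombination runs, which completes the full pipeline in about two
minutes on one CPU. The paper-scale preset (10,000 restarts; 10,000 ×
60,000-step runs) reproduces the reference workflow's budgets when
more time is available.

## Known limitations

* The EM term scores each body against the map independently; there is
  no occupancy term rewarding explained density, so configurations
  that permute similar-sized bodies across sites are penalized only
  through the per-body NCC differences (hence the weight calibration
  above).
* Crosslink confidence (ld score) is used only for filtering, not for
  per-link weighting.
* No flexible fitting: domains are strictly rigid between the hinge
  split and the linker interpolation.
* The empirical-null P-values assume the bulk of restarts are
  incorrect placements; for very small maps where most restarts find
  the same optimum, the null is not meaningful (the all-equal guard
  returns P = 1).
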