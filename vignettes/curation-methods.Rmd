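---
title: "Curating periodic particle lattices on decorated microtubule filaments"
author: "ODAcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating periodic particle lattices on decorated microtubule filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ODAcurate)
```

# The model

Outer dynein arms (ODAs) decorate doublet microtubules in a linear array
with a 24-nm axial repeat, and on splayed axonemes they are retained in
clusters of consecutive repeat sites. Single-particle processing of such
filaments works on "8-nm particles": boxes extracted every 82 Å (one
tubulin α/β-heterodimer) along a picked filament axis. This package curates
the *coordinates* of those particles; it performs no image-domain
operation. Its geometric model has three layers:

* **A filament axis** is a polyline in micrograph-plane Å coordinates with
  an exact arc-length parameterization `s ∈ [0, L]`. A two-point pick gives
  a straight chord axis; curved filaments use more support points.
  Polylines were preferred over splines because their arc length is exact,
  which lets every lattice statement downstream be checked with integer
  arithmetic on site indices.
* **A lattice** (`LatticeSpec`) places binding sites at `s = i · step` with
  a functional repeat every `r` steps. The defaults are `step = 82` Å and
  `r = 3`, so the repeat is *defined* as `r · step = 246` Å and never
  stored as an independent 240 Å: the literature uses "8 nm" and "24 nm"
  interchangeably with 82 Å and 246 Å, and keeping the identity
  `repeat = r · step` exact avoids drift between the two conventions. All
  phase arithmetic (`site mod r`) inherits this exactness.
* **Occupancy** lives on repeat sites: a site is occupied when an ODA is
  bound there. A maximal run of consecutive occupied sites is a cluster.

# The curation procedure

Stage order is fixed: segment/assign → unify → iterative recovery
(expand → verify → snap → deduplicate) → QC. Unification precedes recovery
because candidate positions are meaningful only once all seeds share one
register.

**Register unification.** 3D classification of 8-nm particles yields three
classes corresponding to the three possible registers within the 24-nm
repeat. `unifyRegisters` shifts a particle of phase *k* along its own axis
by the minimum-magnitude integer Δ with `(k + Δ) ≡ k_ref (mod r)` — for
`r = 3` the unique Δ ∈ {−1, 0, +1}, i.e. the off-center classes move one
step (8 nm). For even `r`, exact ties break toward the negative shift for
determinism. Which class is the reference is a config input
(`reference_phase`, default 0): the choice only relabels the common phase
and does not affect any distance or count. Records mapped to
"non-particle" classes are dropped and counted; records whose shifted `s`
leaves `[0, L]` are clipped and counted.

**Neighbor recovery.** Because occupancy is clustered with a 24-nm repeat,
an occupied site predicts its neighbors. `expandSeeds` proposes candidates
at `s ± m · repeat` for `m ∈ {1, 2}` (±24 and ±48 nm) on the seed's own
filament axis — never across filaments. A *verifier* predicate accepts or
rejects candidates; in production that role belongs to mask-focused
classification plus inspection of particle positions, which is out of
scope here, so the verifier is an injected contract. `iterateRecovery`
repeats expand/verify/snap/deduplicate until a round adds no record, or
`max_rounds` (default 10) is reached — non-convergence is reported, not an
error. The deduplication priority (picked before expanded, then lower
record index) makes the procedure monotone: seeds and previously accepted
records always survive later rounds.

With a perfect verifier the recovered set equals breadth-first
reachability over occupied sites with edges ±1 and ±2 — every cluster
containing at least one seed is recovered completely. Note one subtlety:
a ±2 hop crosses a gap of exactly one unoccupied site, so two clusters
separated by a single empty site behave as one reachable component. The
test suite asserts equivalence with an independent BFS oracle rather than
with a run-based description, because the BFS is the exact semantics of
the expansion.

**Snapping and deduplication.** `snapToLattice` replaces `s` by the
nearest multiple of the step, enforcing the 8-nm register the way
re-extraction does; exact half-way ties go to the smaller `s` (the minus
end), the same tie rule used everywhere (`siteIndex`, projections, modal
bins). `deduplicate` is a greedy sweep in priority order keeping a record
iff it is ≥ `d_min` from every already-kept record in scope. The defaults
are `d_min = step/2 = 41` Å — large enough to merge same-site duplicates,
small enough never to merge adjacent lattice sites — and same-filament
scope, because duplicates arise from re-extraction and neighbor expansion
on the same microtubule while crossing filaments hold distinct complexes
even where boxes overlap in the image.

# Quality control

`spacingStats` reports per-filament nearest-neighbor arc spacings and
their histogram (default bin 10 Å, which separates the 82 Å and 246 Å
peaks cleanly). The modal spacing is reported as the *data mean within the
highest-count bin*, ties toward the smaller bin. A geometric bin center
anchored at 0 would report 245 Å for a perfect 246 Å lattice; the
center-of-mass definition returns the repeat exactly on noiseless data and
is insensitive to the bin anchor otherwise. `detectClusters` maps
particles to repeat sites (tolerance `step/2`, consistent with
deduplication) and tabulates maximal runs. `evaluateRecovery` matches
curated particles to occupied truth sites greedily by distance,
one-to-one; greedy matching is deterministic and adequate at these
densities (optimal assignment would differ only in pathological ties).

# The synthetic generator

`simulateField` emulates the coordinate-level structure of splayed-axoneme
micrographs:

* **Geometry** — filaments as circular arcs (one curvature parameter,
  radius 2–10 µm by default; `Inf` gives chords) sampled as 20 Å polyline
  steps, clipped to a square field of 4096 px at 1.36 Å/px. Circular arcs
  were chosen over splines because a single parameter controls curvature
  and the closed form makes oracle tests exact.
* **Occupancy** — a two-state Markov chain over repeat sites: occupied
  after unoccupied with `p_start` (default 0.3), occupied after occupied
  with `p_stay` (default 0.8), giving geometric cluster lengths with mean
  `1/(1 − p_stay)` = 5 repeats. This is the simplest process producing
  clustered retention with a tunable cluster scale; no quantitative
  occupancy model for splayed axonemes is available, so these defaults are
  sensitivity-sweep placeholders, not measured values.
* **Observation** — an occupied site is detected with
  `seed_detection_rate` (default 0.6, emulating the substantial miss rate
  of initial classification). Each detected particle is displaced a whole
  step by a uniformly drawn register offset c ∈ {−1, 0, +1} and labeled
  with the corresponding phase, so all three register classes are
  populated the way classification output is; with
  `register_offsets = FALSE` particles sit directly on their sites
  instead. Labels are wrong with probability `register_label_error`
  (default 0.05, uniform over the other phases). Isotropic Gaussian
  localization noise (`loc_noise_ang`, default 2 Å) is added in the image
  plane. Unoccupied sites can emit spurious seeds at `false_site_rate`
  (default 0 — spurious detections are an option, not part of the default
  study condition).
* **Determinism** — one RNG stream consumed in (micrograph, filament,
  site) order; identical configs give byte-identical outputs, and earlier
  micrographs are unchanged when more are appended.

What the simulator does *not* model: image formation (CTF, dose, ice),
the nine-fold 3-D arrangement of the axoneme, picking errors on the
filament ends, correlated mislabeling along a filament, and filament
crossings. Passing tests therefore demonstrate the correctness of the
geometric curation logic under the stated noise model, not performance on
real micrographs — in particular the verifier in tests is ground truth
(optionally corrupted with independent per-site false-accept/false-reject
draws), whereas a real verifier's errors correlate with local density.

# Numerical choices and degenerate inputs

* Segmentation includes the endpoint when `L` is an exact multiple of the
  step (`floor(L/step + 1e-9)` guards float error on curved axes); a short
  axis yields the single center `s = 0`.
* Projections onto a polyline break distance ties toward smaller `s`
  (segments are scanned in order and the first minimum wins).
* The lateral gate for attaching an external particle to an axis defaults
  to one box half-width (256 px · 1.36 Å/px ≈ 348 Å): anything farther
  than its own box cannot belong to the filament. Gated records are
  dropped and counted, not errors, at the table level.
* Coordinates are written with `%.17g`, so STAR/CSV round-trips are exact
  for IEEE doubles.
* Empty tables are legal everywhere and propagate to empty reports with
  zero counters; a single-particle filament contributes no spacings but is
  counted.

# Problem sizes

The test suite and acceptance script run at desk scale, chosen so the full
suite completes in well under a minute of compute per file: pipelines on
2–12 micrographs (10–60 filaments, tens of repeat sites each), rescue
oracle equivalence on 100 random single-filament instances of 15–40 sites,
deduplication oracle equivalence on 200 instances of up to 200 records,
simulator calibration on 10⁴ sites / 10⁴ particles, and STAR round-trips
on 1000 small random tables. These sizes exercise every code path of the
curation logic; the statistics (3 SE, 99% binomial CI) are sized to their
sample counts.

# Known limitations

* Chord axes under-measure arc length on strongly curved filaments; for
  the gentle curvatures simulated here the sagitta stays well inside the
  lateral gate, but real, strongly bent filaments should be traced with
  polyline support points.
* The register of a particle is trusted from its class label; the package
  cannot detect a mislabeled register except indirectly through the QC
  spacing spectrum (mislabeled seeds appear as 82/164 Å spacings).
* Cross-filament duplicates (two picks tracing the same microtubule) are
  only removed under `scope = "same_micrograph"`, which also risks merging
  genuinely crossing filaments; reconciling picks is upstream work.
* `evaluateRecovery` credits a curated particle to at most one truth site
  within the tolerance; systematic axis mis-calibration larger than
  `step/2` scores as total failure rather than as a shift.
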