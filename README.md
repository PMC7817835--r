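# ODAcurate

Coordinate-level curation of periodically decorated filament particles in
single-particle cryo-EM, built for outer dynein arms (ODAs) on the doublet
microtubules of splayed axonemes.

## The problem

ODAs bind doublet microtubules in a linear array with a 24-nm repeat, and
when axonemes are splayed the complexes are retained in *clusters* of
consecutive repeat sites. Filaments are picked by their start and end
coordinates and divided into boxed "8-nm particles" at an 82 Å step (the
tubulin α/β-heterodimer length), so an ODA-bearing particle can sit in any
of the **three registers** of the 8-nm lattice within the 24-nm repeat.
3D classification labels those registers, but it also misses many genuinely
bound complexes. This package implements the coordinate-space half of the
curation workflow:

1. **Segment** each picked filament axis into particles at
   `s_i = i · 82 Å` (`segmentAxis`).
2. **Unify registers**: a particle of phase *k* is shifted along its axis by
   the minimum-magnitude Δ with `(k + Δ) ≡ k_ref (mod 3)` — the two
   off-center classes move one step (8 nm) onto the reference register
   (`unifyRegisters`).
3. **Recover neighbors**: because occupancy is clustered with a 24-nm
   repeat, candidates are proposed at `s ± m · 246 Å`, m ∈ {1, 2} (±24 and
   ±48 nm) from every curated particle, verified by an injected predicate
   (standing in for mask-focused classification), and the cycle is iterated
   to a fixed point (`expandSeeds`, `iterateRecovery`).
4. **Snap and deduplicate**: positions are re-set on the exact 8-nm lattice
   (`snapToLattice`) and records closer than 41 Å on the same filament are
   collapsed with picked-before-expanded priority (`deduplicate`).
5. **QC**: nearest-neighbor spacing histograms (the 24-nm periodicity
   check), cluster run-length distributions, occupancy fractions, and —
   on synthetic data — precision/recall against ground truth
   (`spacingStats`, `detectClusters`, `evaluateRecovery`).

With a perfect verifier and multiples {1, 2}, the recovered set provably
equals breadth-first reachability over occupied repeat sites with edges
±1/±2 — i.e. every occupied cluster containing at least one seed is
recovered completely, and nothing else. The test suite checks this
equivalence against an independent graph oracle.

A synthetic splayed-axoneme generator (`simulateField`) provides ground
truth: curved filaments on micrograph fields, two-state Markov cluster
occupancy over repeat sites, localization noise, register
displacement/mislabeling, and partial initial detection. Particle tables
read and write the RELION-dialect STAR format losslessly (`readParticles`,
`writeParticles`).

## Worked example

```r
library(ODAcurate)

cfg <- PipelineConfig(
  sim = SimConfig(n_micrographs = 4, seed_detection_rate = 0.5, rng_seed = 42),
  rng_seed = 42)
report <- runPipeline(cfg)
report
#> RunReport (ODAcurate 0.1.0 )
#>   input : 68
#>   gated_out : 0
#>   after_assign : 68
#>   after_unify : 68
#>   final : 122
#>   precision: 0.9672131  recall: 0.921875

report@qc
#> QCReport
#>   spacings: 104  modal spacing: 246 A
#>   cluster runs: 28  mean length: 4.21 repeats
#>   occupancy fraction: 0.494
```

Half of the occupied sites were detected initially (68 seeds); neighbor
recovery grows the set to 122 curated particles, recovering 92% of all
bound sites (the misses are clusters that contained no seed at all). The
modal nearest-neighbor spacing of 246 Å is the 24-nm ODA repeat, and the
mean cluster run length (4.21 repeats) reflects the configured occupancy
persistence. Precision below 1 traces to the 5% register-mislabeling rate:
a mislabeled seed is shifted onto the wrong lattice phase.

A thin command-line front end over the same functions lives at
`inst/scripts/oda-pipeline.R` (subcommands `simulate`, `run`, `qc`,
`show-config`).

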