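test_that("phaseShift picks the minimum-magnitude congruent correction", {
  # exhaustive integer oracle for r = 3: the unique delta in {-1, 0, 1}
  for (ref in 0:2) for (k in 0:2) {
    d <- phaseShift(k, ref, 3L)
    expect_true(d %in% -1:1)
    expect_identical((k + d) %% 3L, ref)
  }
  # even r: ties break toward the negative shift
  expect_identical(phaseShift(0L, 2L, 4L), -2L)
  expect_identical(phaseShift(2L, 0L, 4L), -2L)
})

test_that("unifyRegisters shifts off-center registers one step onto the reference", {
  axes <- FilamentAxisList(list(makeStraightAxis(2000)))
  lat <- LatticeSpec()
  rm0 <- RegisterMap(reference_phase = 0L)
  # phase-congruence oracle: (s/step) mod 3 must equal the reference after
  # shifting a record whose position phase matches its label
  p1 <- makeParticles(246, register_class = 1L)
  out1 <- unifyRegisters(p1, axes, rm0, lat)
  expect_equal(particleData(out1)$s_ang, 164)    # delta = -1
  p2 <- makeParticles(164, register_class = 2L)
  out2 <- unifyRegisters(p2, axes, rm0, lat)
  expect_equal(particleData(out2)$s_ang, 246)    # delta = +1
  p0 <- makeParticles(492, register_class = 0L)
  expect_equal(particleData(unifyRegisters(p0, axes, rm0, lat))$s_ang, 492)
  # x recomputed from the shifted arc position
  expect_equal(particleData(out1)$x_px * 1.36, 164)
})

test_that("unifyRegisters drops non-particle classes and clipped records, with counts", {
  axes <- FilamentAxisList(list(makeStraightAxis(500)))
  rm <- RegisterMap(c("0" = 0L, "1" = 1L, "2" = 2L, "9" = NA),
                    reference_phase = 0L)
  ps <- makeParticles(c(82, 164, 480), register_class = c(9L, 1L, 1L))
  # 164 with phase 1 -> 82; 480 with phase 1 -> 398; class 9 dropped
  out <- unifyRegisters(ps, axes, rm)
  expect_equal(particleData(out)$s_ang, c(82, 398))
  log <- metadata(out)$unify_log
  expect_identical(log$dropped_nonparticle, 1L)
  expect_identical(log$dropped_clipped, 0L)
  # record shifted past the axis end is clipped and counted
  clip <- makeParticles(480, register_class = 2L)  # +82 -> 562 > 500
  outClip <- unifyRegisters(clip, axes, rm)
  expect_length(outClip, 0)
  expect_identical(metadata(outClip)$unify_log$dropped_clipped, 1L)
  # unmapped class errors, naming the class
  expect_error(unifyRegisters(makeParticles(82, register_class = 7L),
                              axes, rm), "7")
})

test_that("unify never changes filament or micrograph identity and conserves counts", {
  set.seed(11)
  lat <- LatticeSpec()
  axes <- FilamentAxisList(list(makeStraightAxis(8200, filament_id = 1L),
                                makeStraightAxis(8200, filament_id = 2L)))
  for (rep in 1:10) {
    n <- 40
    site <- sample(0:100, n, TRUE)
    phase <- site %% 3L
    df <- data.frame(micrograph_id = "mg1",
                     x_px = site * 82 / 1.36, y_px = 0,
                     filament_id = sample(1:2, n, TRUE),
                     s_ang = site * 82, register_class = phase,
                     stringsAsFactors = FALSE)
    ps <- ParticleSet(df)
    out <- unifyRegisters(ps, axes, RegisterMap(), lat)
    log <- metadata(out)$unify_log
    expect_identical(length(out) + log$dropped_nonparticle +
                     log$dropped_clipped, length(ps))
    odf <- particleData(out)
    idf <- particleData(ps)
    m <- match(odf$record_index, idf$record_index)
    expect_identical(odf$filament_id, idf$filament_id[m])
    expect_identical(odf$micrograph_id, idf$micrograph_id[m])
  }
})

test_that("snapToLattice snaps to the nearest site with ties toward the minus end", {
  lat <- LatticeSpec()
  expect_equal(particleData(snapToLattice(makeParticles(85), lattice = lat))$s_ang,
               82)
  expect_equal(particleData(snapToLattice(makeParticles(41), lattice = lat))$s_ang,
               0)   # exact half-way tie
  set.seed(5)
  s <- runif(500, 0, 8200)
  snapped <- particleData(snapToLattice(makeParticles(s), lattice = lat))$s_ang
  expect_true(all(snapped %% 82 == 0))             # exhaustive check
  expect_true(all(abs(snapped - s) <= 41))
})

test_that("unify followed by snap leaves every record on the reference phase", {
  # integer-arithmetic invariant on site indices, random tables
  set.seed(23)
  lat <- LatticeSpec()
  axes <- FilamentAxisList(list(makeStraightAxis(82 * 101)))
  for (rep in 1:10) {
    site <- sample(1:99, 30, TRUE)
    noise <- runif(30, -20, 20)
    df <- data.frame(micrograph_id = "mg1", x_px = (site * 82 + noise) / 1.36,
                     y_px = 0, filament_id = 1L, s_ang = site * 82 + noise,
                     register_class = site %% 3L, stringsAsFactors = FALSE)
    out <- snapToLattice(unifyRegisters(ParticleSet(df), axes, RegisterMap(),
                                        lat), axes, lat)
    idx <- siteIndex(particleData(out)$s_ang, 82)
    expect_true(all(idx %% 3L == 0L))
  }
})

test_that("deduplicate keeps picked over expanded and respects the distance rule", {
  pol <- DedupPolicy(d_min_ang = 41)
  # exact duplicate: the picked one survives
  df <- data.frame(micrograph_id = "mg1", x_px = c(100, 100), y_px = 0,
                   filament_id = 1L, s_ang = 136,
                   provenance = c("expanded", "picked"),
                   record_index = 0:1, stringsAsFactors = FALSE)
  out <- deduplicate(ParticleSet(df), pol)
  expect_length(out, 1)
  expect_identical(particleData(out)$provenance, "picked")
  # chain A-B-C at 0.6 * d_min: A kept, B removed, C kept (brute oracle)
  chain <- data.frame(micrograph_id = "mg1",
                      x_px = c(0, 0.6 * 41, 1.2 * 41) / 1.36, y_px = 0,
                      filament_id = 1L, s_ang = 0, stringsAsFactors = FALSE)
  outChain <- deduplicate(ParticleSet(chain), pol)
  expect_identical(particleData(outChain)$record_index, c(0L, 2L))
  expect_identical(metadata(outChain)$dedup_log$removed, 1L)
  # empty table
  empty <- deduplicate(ParticleSet(), pol)
  expect_length(empty, 0)
  expect_identical(metadata(empty)$dedup_log$removed, 0L)
})

test_that("deduplicate matches the O(n^2) brute-force oracle and is idempotent", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:120, 1)
    scope <- sample(c("same_filament", "same_micrograph"), 1)
    df <- randomParticleTable(n)
    # cluster some points tightly so duplicates actually occur
    dup <- sample(n, ceiling(n / 3))
    df$x_px[dup] <- df$x_px[sample(n, length(dup), TRUE)] + runif(length(dup), 0, 20)
    ps <- ParticleSet(df)
    pol <- DedupPolicy(d_min_ang = 41, scope = scope)
    out <- deduplicate(ps, pol)
    oracle <- bruteDedup(particleData(ps), 41, scope)
    expect_identical(particleData(out)$record_index,
                     particleData(ps)$record_index[oracle])
    # idempotent
    again <- deduplicate(out, pol)
    expect_identical(particleData(again), particleData(out))
    # all pairwise in-scope distances >= d_min
    odf <- particleData(out)
    key <- if (scope == "same_filament")
      paste(odf$micrograph_id, odf$filament_id) else odf$micrograph_id
    for (g in unique(key)) {
      sub <- odf[key == g, , drop = FALSE]
      if (nrow(sub) > 1) {
        d <- as.matrix(dist(cbind(sub$x_px, sub$y_px))) * 1.36
        expect_true(all(d[upper.tri(d)] >= 41))
      }
    }
  }
})
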