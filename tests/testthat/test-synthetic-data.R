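test_that("noiseless saturated occupancy puts every observed particle on a repeat site", {
  cfg <- SimConfig(n_micrographs = 2, p_start = 1, p_stay = 1,
                   loc_noise_ang = 0, register_label_error = 0,
                   seed_detection_rate = 1, register_offsets = FALSE,
                   rng_seed = 3L)
  sim <- simulateField(cfg)
  sites <- truthSites(sim$truth)
  expect_true(all(sites$occupied))
  obs <- assignArcCoordinates(sim$particles, truthAxes(sim$truth))
  expect_identical(length(obs), sum(sites$occupied))
  # every record sits exactly on s = j * repeat (up to projection round-off)
  resid <- particleData(obs)$s_ang %% 246
  expect_true(all(pmin(resid, 246 - resid) < 1e-6))
  expect_true(all(particleData(obs)$register_class == 0L))
})

test_that("identical SimConfigs generate byte-identical tables", {
  cfg <- SimConfig(n_micrographs = 2, rng_seed = 99L)
  a <- simulateField(cfg)
  b <- simulateField(cfg)
  expect_identical(particleData(a$particles), particleData(b$particles))
  expect_identical(truthSites(a$truth), truthSites(b$truth))
  expect_identical(a$picks, b$picks)
})

test_that("occupied-run lengths follow the geometric law of the Markov chain", {
  set.seed(1234)
  occ <- simulateOccupancy(1e4, p_start = 0.3, p_stay = 0.8)
  r <- rle(occ)
  runs <- r$lengths[r$values]
  se <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - 1 / (1 - 0.8)), 3 * se)   # mean 5.0
})

test_that("register labels are mislabeled at the configured rate", {
  cfg <- SimConfig(n_micrographs = 6, filaments_per_micrograph = 5L,
                   p_start = 1, p_stay = 1, loc_noise_ang = 0,
                   register_label_error = 0.1, seed_detection_rate = 1,
                   rng_seed = 21L)
  sim <- simulateField(cfg)
  obs <- assignArcCoordinates(sim$particles, truthAxes(sim$truth))
  df <- particleData(obs)
  truePhase <- siteIndex(df$s_ang, 82) %% 3L
  frac <- mean(df$register_class != truePhase)
  n <- nrow(df)
  ci <- qbinom(c(0.005, 0.995), n, 0.1) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("register offsets populate all three classes consistent with positions", {
  cfg <- SimConfig(n_micrographs = 3, p_start = 1, p_stay = 1,
                   loc_noise_ang = 0, register_label_error = 0,
                   seed_detection_rate = 1, rng_seed = 8L)
  sim <- simulateField(cfg)
  obs <- assignArcCoordinates(sim$particles, truthAxes(sim$truth))
  df <- particleData(obs)
  phase <- siteIndex(df$s_ang, 82) %% 3L
  expect_identical(sort(unique(df$register_class)), 0:2)
  # with no mislabeling the label always equals the position phase
  expect_true(all(df$register_class == phase))
})

test_that("the truth verifier accepts exactly near-occupied candidates when uncorrupted", {
  truth <- makeTruth(list(c(0, 1, 5)), n_sites = 8L)
  ver <- truthVerifier(truth, fp = 0, fn = 0, tol_ang = 41)
  cand <- data.frame(micrograph_id = "mg1", filament_id = 1L,
                     s_ang = c(0, 246, 5 * 246, 3 * 246, 5 * 246 + 60))
  expect_identical(ver(cand), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # fn = 1 rejects everything on occupied sites
  verFN <- truthVerifier(truth, fn = 1)
  expect_identical(verFN(cand), rep(FALSE, 5))
})

test_that("false accepts occur at the configured rate on unoccupied sites", {
  nSites <- 1000L
  truth <- makeTruth(list(integer(0)), n_sites = nSites)
  ver <- truthVerifier(truth, fp = 0.1, fn = 0, tol_ang = 41, rng_seed = 5L)
  cand <- data.frame(micrograph_id = "mg1", filament_id = 1L,
                     s_ang = (0:(nSites - 1L)) * 246)
  frac <- mean(ver(cand))
  se <- sqrt(0.1 * 0.9 / nSites)
  expect_lt(abs(frac - 0.1), 3 * se)
  # deterministic: same candidate, same answer
  expect_identical(ver(cand), ver(cand))
})

test_that("SimConfig survives a YAML round-trip", {
  cfg <- SimConfig(n_micrographs = 4, p_stay = 0.75, rng_seed = 12L,
                   curvature_range = c(3e4, 5e4))
  path <- tempfile(fileext = ".yaml")
  writeSimConfig(cfg, path)
  back <- readSimConfig(path)
  for (sl in slotNames(cfg))
    expect_equal(slot(back, sl), slot(cfg, sl), info = sl)
})

test_that("TruthTable serializes to CSV + JSON", {
  truth <- makeTruth(list(0:3), n_sites = 6L)
  dir <- tempfile()
  paths <- writeTruthTable(truth, dir)
  expect_true(all(file.exists(paths)))
  sites <- read.csv(file.path(dir, "truth_sites.csv"))
  expect_identical(nrow(sites), 6L)
  expect_identical(sum(sites$occupied), 4L)
})

test_that("degenerate fields are rejected", {
  expect_error(SimConfig(field_px = 100L), "repeat")
})
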