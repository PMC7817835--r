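test_that("STAR and CSV round-trips are the identity on all supported fields", {
  df <- data.frame(
    micrograph_id = c("mg01.mrc", "mg01.mrc", "mg02.mrc"),
    x_px = c(101.25, 2048.5, 17.125), y_px = c(3.5, 99.75, 4000.0),
    filament_id = c(1L, 1L, 2L), s_ang = c(0, 82, NA),
    register_class = c(0L, 2L, NA), provenance = c("picked", "expanded",
                                                   "picked"),
    stringsAsFactors = FALSE)
  ps <- ParticleSet(df)
  for (fmt in c("star", "csv", "tsv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    writeParticles(ps, path)
    back <- readParticles(path)
    expect_identical(particleData(back), particleData(ps), info = fmt)
  }
})

test_that("random tables round-trip exactly, preserving order and record_index", {
  set.seed(42)
  path <- tempfile(fileext = ".star")
  for (i in 1:25) {
    n <- sample(0:40, 1)
    ps <- ParticleSet(randomParticleTable(n))
    writeParticles(ps, path)
    back <- readParticles(path)
    expect_identical(particleData(back), particleData(ps))
  }
})

test_that("a 1000-record table round-trips with zero coordinate error", {
  set.seed(7)
  df <- randomParticleTable(1000)
  df$x_px <- stats::runif(1000, 0, 4096)  # full-precision doubles
  df$y_px <- stats::runif(1000, 0, 4096)
  ps <- ParticleSet(df)
  path <- tempfile(fileext = ".star")
  writeParticles(ps, path)
  back <- readParticles(path)
  expect_identical(particleData(back)$x_px, particleData(ps)$x_px)
  expect_identical(particleData(back)$y_px, particleData(ps)$y_px)
})

test_that("unknown STAR columns are preserved verbatim on round-trip", {
  df <- randomParticleTable(5)
  df[["_rlnAnglePsi"]] <- sprintf("%.4f", runif(5, -180, 180))
  ps <- ParticleSet(df)
  path <- tempfile(fileext = ".star")
  writeParticles(ps, path)
  back <- readParticles(path)
  expect_identical(particleData(back)[["_rlnAnglePsi"]], df[["_rlnAnglePsi"]])
})

test_that("an empty table writes a header-only file that re-reads as empty", {
  path <- tempfile(fileext = ".star")
  writeParticles(ParticleSet(), path)
  back <- readParticles(path)
  expect_s4_class(back, "ParticleSet")
  expect_length(back, 0)
})

test_that("a file lacking the x-coordinate column raises a format error naming it", {
  path <- tempfile(fileext = ".star")
  writeLines(c("data_particles", "", "loop_", "_rlnMicrographName #1",
               "_rlnCoordinateY #2", "mg01.mrc\t12.5"), path)
  expect_error(readParticles(path), "_rlnCoordinateX")
})

test_that("an unparsable numeric cell raises a row-level error", {
  path <- tempfile(fileext = ".star")
  writeLines(c("data_particles", "", "loop_", "_rlnMicrographName #1",
               "_rlnCoordinateX #2", "_rlnCoordinateY #3",
               "mg01.mrc\t10.0\t20.0", "mg01.mrc\toops\t21.0"), path)
  expect_error(readParticles(path), "row 2")
})

test_that("a missing filament_id column defaults per micrograph and is flagged", {
  path <- tempfile(fileext = ".star")
  writeLines(c("data_particles", "", "loop_", "_rlnMicrographName #1",
               "_rlnCoordinateX #2", "_rlnCoordinateY #3",
               "mg01.mrc\t10\t20", "mg02.mrc\t30\t40"), path)
  ps <- readParticles(path)
  expected <- ParticleSet(data.frame(
    micrograph_id = c("mg01.mrc", "mg02.mrc"), x_px = c(10, 30),
    y_px = c(20, 40), stringsAsFactors = FALSE))
  expect_identical(particleData(ps)$filament_id,
                   particleData(expected)$filament_id)
  expect_true(metadata(ps)$filament_id_defaulted)
  expect_identical(particleData(ps)$provenance, c("picked", "picked"))
  expect_identical(particleData(ps)$record_index, 0:1)
})

test_that("pick tables round-trip and validate", {
  picks <- data.frame(
    micrograph_id = c("mg01.mrc", "mg01.mrc", "mg02.mrc"),
    filament_id = c(1L, 2L, 1L),
    start_x_px = c(0, 100, 5.5), start_y_px = c(0, 200, 6.25),
    end_x_px = c(1000, 900, 800.75), end_y_px = c(0, 800, 900),
    stringsAsFactors = FALSE)
  for (fmt in c("star", "csv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    writePicks(picks, path)
    back <- readPicks(path)
    expect_identical(back, picks, info = fmt)
  }
  # grouping per micrograph
  expect_identical(as.integer(table(readPicks(writePicks(
    picks, tempfile(fileext = ".csv")))$micrograph_id)), c(2L, 1L))
})

test_that("degenerate picks are rejected with informative errors", {
  bad <- data.frame(micrograph_id = "mg01.mrc", filament_id = 1L,
                    start_x_px = 5, start_y_px = 5, end_x_px = 5,
                    end_y_px = 5, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  expect_error(writePicks(bad, path), "coincident")
  dup <- data.frame(micrograph_id = "mg01.mrc", filament_id = c(1L, 1L),
                    start_x_px = c(0, 1), start_y_px = c(0, 1),
                    end_x_px = c(10, 11), end_y_px = c(0, 1),
                    stringsAsFactors = FALSE)
  expect_error(writePicks(dup, path), "duplicate filament_id")
})
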