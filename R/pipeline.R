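#' @include AllClasses.R coords-io.R filament-geometry.R register-curation.R
#' @include neighbor-recovery.R periodicity-qc.R synthetic-data.R
NULL

#' Run the full curation workflow
#'
#' Executes the stages in fixed order: obtain particles and axes (synthetic
#' simulation, or STAR/CSV inputs with chord axes from the picks), assign
#' arc-length coordinates, unify register classes onto the reference phase,
#' iteratively recover neighbors at +/-1 and +/-2 repeats with verification,
#' snapping and duplicate elimination, then compute periodicity/cluster QC
#' (and, in synthetic mode, precision/recall against ground truth).
#' Register unification precedes recovery because seeds must share one phase
#' before their neighbors are proposed.
#'
#' @param config a [PipelineConfig-class].
#' @param verifier optional acceptance predicate for candidate particles
#'   (see [iterateRecovery()]).  Default: in synthetic mode, a
#'   [truthVerifier()] built from the simulated ground truth with the
#'   configured `verifier_fp`/`verifier_fn`; in real-input mode, a
#'   reject-all verifier (no recovery without an external classifier).
#' @return a [RunReport-class].  When `config@out_dir` is non-empty, the
#'   curated table (`curated.star`), intermediate tables, QC report and run
#'   report JSON are written there.
#' @export
runPipeline <- function(config, verifier = NULL) {
  validObject(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- numeric(0)
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }
  counts <- list()
  synthetic <- !is.null(config@sim)
  truth <- NULL
  if (synthetic) {
    sim <- simulateField(config@sim)
    truth <- sim$truth
    particles <- sim$particles
    picks <- sim$picks
    axes <- truthAxes(truth)
    px <- config@sim@pixel_size_ang
  } else {
    particles <- readParticles(config@particles_path)
    if (!nzchar(config@picks_path))
      stop("real-input mode requires picks_path (filament axes)",
           call. = FALSE)
    picks <- readPicks(config@picks_path)
    axes <- buildAxes(picks, config@pixel_size_ang)
    px <- config@pixel_size_ang
  }
  tick("input")
  counts$input <- length(particles)

  particles <- assignArcCoordinates(particles, axes, pixel_size_ang = px)
  counts$gated_out <- metadata(particles)$gated_out
  counts$after_assign <- length(particles)
  tick("assign")

  particles <- unifyRegisters(particles, axes, config@regmap,
                              config@lattice, pixel_size_ang = px)
  ulog <- metadata(particles)$unify_log
  counts$unify <- ulog
  counts$after_unify <- length(particles)
  tick("unify")

  if (is.null(verifier)) {
    verifier <- if (synthetic)
      truthVerifier(truth, fp = config@verifier_fp, fn = config@verifier_fn,
                    tol_ang = config@qc_tol_ang, rng_seed = config@rng_seed)
    else function(candidates) logical(nrow(candidates))
  }
  curated <- iterateRecovery(particles, axes, config@lattice,
                             config@expansion, config@dedup, verifier,
                             pixel_size_ang = px)
  rlog <- metadata(curated)$recovery_log
  counts$recovery <- rlog
  counts$final <- length(curated)
  tick("recover")

  qc <- qcReport(curated, axes, config@lattice, config@qc_bin_ang,
                 config@qc_tol_ang)
  evaluation <- list()
  if (synthetic)
    evaluation <- evaluateRecovery(curated, truth,
                                   tol_ang = config@qc_tol_ang)
  tick("qc")

  report <- new("RunReport", stage_counts = counts, qc = qc,
                evaluation = evaluation, config = config,
                timings = unlist(timings),
                version = as.character(utils::packageVersion("ODAcurate")))
  if (nzchar(config@out_dir)) {
    dir <- config@out_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeParticles(curated, file.path(dir, "curated.star"))
    writeParticles(curated, file.path(dir, "curated.csv"))
    writePicks(picks, file.path(dir, "picks.star"))
    if (synthetic) writeTruthTable(truth, dir)
    writeQCReport(qc, dir)
    writeRunReport(report, file.path(dir, "run_report.json"))
  }
  attr(report, "curated") <- curated
  if (synthetic) attr(report, "truth") <- truth
  report
}

#' Write a RunReport as JSON
#'
#' @param report a [RunReport-class].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeRunReport <- function(report, path) {
  qc <- report@qc
  jsonlite::write_json(list(
    version = report@version,
    stage_counts = report@stage_counts,
    evaluation = report@evaluation,
    timings_sec = as.list(report@timings),
    qc = if (is.null(qc)) NULL else list(
      modal_spacing_ang = qc@modal_spacing_ang,
      occupancy_fraction = qc@occupancy_fraction,
      run_lengths = qc@run_lengths,
      counters = qc@counters)),
    path, auto_unbox = TRUE, digits = NA, na = "null", force = TRUE)
  invisible(path)
}

#' Curated particles of a pipeline run
#'
#' @param report a [RunReport-class] returned by [runPipeline()].
#' @return the curated [ParticleSet-class].
#' @export
curatedParticles <- function(report) attr(report, "curated")
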