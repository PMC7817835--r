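#' @import methods
#' @importFrom S4Vectors SimpleList metadata
NULL

## Canonical particle-table columns, in storage order.  Internal lengths are
## Angstroms; x_px/y_px stay in pixels of the micrograph the record came from.
.PARTICLE_COLUMNS <- c("micrograph_id", "x_px", "y_px", "filament_id",
                       "s_ang", "register_class", "provenance", "record_index")

.PROVENANCE_LEVELS <- c("picked", "expanded")

#' LatticeSpec: the axial particle lattice
#'
#' Describes the one-dimensional lattice along a filament axis: binding sites
#' every `step_ang` (the tubulin-dimer length, 82 Angstroms by default) with a
#' functional repeat every `repeat_multiplier` steps (3 by default, giving the
#' 24-nm dynein repeat).  The repeat length is *defined* as
#' `repeat_multiplier * step_ang` and is never stored independently.
#'
#' @slot step_ang axial step between adjacent sites, Angstroms (> 0).
#' @slot repeat_multiplier integer number of steps per functional repeat
#'   (>= 1); equals the number of distinct registers a particle can occupy
#'   within the repeat.
#' @slot box_px box side length in pixels used at extraction time; carried as
#'   metadata only, no image operation is performed.
#'
#' @seealso [LatticeSpec()], [repeatAng()]
#' @export
setClass("LatticeSpec",
  slots = c(step_ang = "numeric", repeat_multiplier = "integer",
            box_px = "integer"))

setValidity("LatticeSpec", function(object) {
  msg <- character()
  if (length(object@step_ang) != 1L || !is.finite(object@step_ang) ||
      object@step_ang <= 0)
    msg <- c(msg, "step_ang must be a single positive finite number")
  if (length(object@repeat_multiplier) != 1L || is.na(object@repeat_multiplier) ||
      object@repeat_multiplier < 1L)
    msg <- c(msg, "repeat_multiplier must be a single integer >= 1")
  if (length(object@box_px) != 1L || is.na(object@box_px) || object@box_px < 1L)
    msg <- c(msg, "box_px must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a LatticeSpec
#'
#' @param step_ang axial step in Angstroms (default 82, the tubulin
#'   alpha/beta-heterodimer length).
#' @param repeat_multiplier steps per functional repeat (default 3).
#' @param box_px extraction box side in pixels (default 512; metadata only).
#' @return a [LatticeSpec-class] object.
#' @examples
#' lat <- LatticeSpec()
#' repeatAng(lat)  # 246
#' @export
LatticeSpec <- function(step_ang = 82, repeat_multiplier = 3L, box_px = 512L) {
  new("LatticeSpec", step_ang = as.numeric(step_ang),
      repeat_multiplier = as.integer(repeat_multiplier),
      box_px = as.integer(box_px))
}

#' ParticleSet: an ordered table of boxed particles
#'
#' Container for particle records: micrograph position in pixels, filament
#' identity, arc-length coordinate along the filament axis in Angstroms,
#' register-class label, and provenance (`picked` for records that entered
#' through picking/segmentation, `expanded` for records proposed by neighbor
#' recovery).  `record_index` is a stable per-record identifier preserved by
#' file round-trips.
#'
#' @slot records data.frame with the canonical columns (see
#'   [particleData()]).
#' @slot metadata list of curation logs and free-form annotations.
#' @export
setClass("ParticleSet", slots = c(records = "data.frame", metadata = "list"))

setValidity("ParticleSet", function(object) {
  df <- object@records
  missing <- setdiff(.PARTICLE_COLUMNS, names(df))
  if (length(missing))
    return(paste("missing particle columns:", paste(missing, collapse = ", ")))
  msg <- character()
  if (nrow(df)) {
    if (!all(is.finite(df$x_px)) || !all(is.finite(df$y_px)))
      msg <- c(msg, "x_px and y_px must be finite")
    if (anyNA(df$filament_id) || any(df$filament_id < 1L))
      msg <- c(msg, "filament_id must be >= 1")
    if (anyDuplicated(df$record_index))
      msg <- c(msg, "record_index must be unique")
    if (!all(df$provenance %in% .PROVENANCE_LEVELS))
      msg <- c(msg, "provenance must be 'picked' or 'expanded'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ParticleSet from a data.frame
#'
#' Missing optional columns are filled: `s_ang` and `register_class` with
#' `NA`, `provenance` with `"picked"`, `record_index` with `0:(n-1)`.
#' A missing `filament_id` column is filled with a per-micrograph
#' single-filament default (id 1) and the fill is flagged in
#' `metadata(x)$filament_id_defaulted`.
#'
#' @param records data.frame with at least `micrograph_id`, `x_px`, `y_px`.
#' @param metadata optional list of annotations.
#' @return a [ParticleSet-class].
#' @export
ParticleSet <- function(records = NULL, metadata = list()) {
  if (is.null(records))
    records <- data.frame(micrograph_id = character(), x_px = numeric(),
                          y_px = numeric())
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  req <- c("micrograph_id", "x_px", "y_px")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("particle table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- nrow(records)
  if (!"filament_id" %in% names(records)) {
    records$filament_id <- rep(1L, n)
    metadata$filament_id_defaulted <- TRUE
  }
  if (!"s_ang" %in% names(records)) records$s_ang <- rep(NA_real_, n)
  if (!"register_class" %in% names(records))
    records$register_class <- rep(NA_integer_, n)
  if (!"provenance" %in% names(records))
    records$provenance <- rep("picked", n)
  if (!"record_index" %in% names(records))
    records$record_index <- if (n) 0:(n - 1L) else integer()
  records$micrograph_id <- as.character(records$micrograph_id)
  records$x_px <- as.numeric(records$x_px)
  records$y_px <- as.numeric(records$y_px)
  records$filament_id <- as.integer(records$filament_id)
  records$s_ang <- as.numeric(records$s_ang)
  records$register_class <- as.integer(records$register_class)
  records$provenance <- as.character(records$provenance)
  records$record_index <- as.integer(records$record_index)
  extra <- setdiff(names(records), .PARTICLE_COLUMNS)
  records <- records[, c(.PARTICLE_COLUMNS, extra), drop = FALSE]
  rownames(records) <- NULL
  new("ParticleSet", records = records, metadata = metadata)
}

#' FilamentAxis: a parameterized filament axis
#'
#' A filament axis is a polyline in micrograph-plane Angstrom coordinates,
#' parameterized by arc length `s` in `[0, totalLength(axis)]`.  A two-point
#' (chord) pick yields a straight axis; curved filaments use more support
#' points.  The arc-length parameterization of a polyline is exact.
#'
#' @slot micrograph_id character micrograph identifier.
#' @slot filament_id integer filament identifier, unique per micrograph.
#' @slot support n x 2 numeric matrix of support points in Angstroms.
#' @slot cumlen cumulative arc length at each support point, starting at 0.
#' @export
setClass("FilamentAxis",
  slots = c(micrograph_id = "character", filament_id = "integer",
            support = "matrix", cumlen = "numeric"))

setValidity("FilamentAxis", function(object) {
  p <- object@support
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 2L)
    return("support must be a numeric matrix with >= 2 rows and 2 columns")
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg == 0))
    return("axis has zero-length segments (coincident support points)")
  cl <- object@cumlen
  if (length(cl) != nrow(p) || cl[1L] != 0 ||
      max(abs(cl - cumsum(c(0, seg)))) > 1e-6)
    return("cumlen inconsistent with support point segment lengths")
  TRUE
})

#' Construct a FilamentAxis from support points
#'
#' @param micrograph_id micrograph identifier.
#' @param filament_id integer filament identifier.
#' @param support n x 2 matrix of points in Angstroms (n >= 2).
#' @return a [FilamentAxis-class].
#' @export
FilamentAxis <- function(micrograph_id, filament_id, support) {
  support <- as.matrix(support)
  storage.mode(support) <- "double"
  dimnames(support) <- NULL
  ## drop consecutive duplicate points (zero-length segments)
  if (nrow(support) > 2L) {
    seg <- sqrt(rowSums((support[-1L, , drop = FALSE] -
                         support[-nrow(support), , drop = FALSE])^2))
    support <- support[c(TRUE, seg > 0), , drop = FALSE]
  }
  seg <- sqrt(rowSums((support[-1L, , drop = FALSE] -
                       support[-nrow(support), , drop = FALSE])^2))
  new("FilamentAxis", micrograph_id = as.character(micrograph_id),
      filament_id = as.integer(filament_id),
      support = support, cumlen = cumsum(c(0, seg)))
}

#' A list of FilamentAxis objects
#'
#' Named list (names are `"<micrograph_id>::<filament_id>"` keys) holding one
#' [FilamentAxis-class] per filament.
#' @export
setClass("FilamentAxisList", contains = "SimpleList",
         prototype = prototype(elementType = "FilamentAxis"))

#' @rdname FilamentAxisList-class
#' @param ... FilamentAxis objects, or a single list of them.
#' @export
FilamentAxisList <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !is(args[[1L]], "FilamentAxis"))
    args <- args[[1L]]
  if (length(args) && is.null(names(args)))
    names(args) <- vapply(args, function(a)
      axisKey(a@micrograph_id, a@filament_id), character(1))
  new("FilamentAxisList", S4Vectors::SimpleList(args))
}

#' Key used to index axes by micrograph and filament
#' @param micrograph_id,filament_id identifiers.
#' @return character key `"<micrograph>::<filament>"`.
#' @export
axisKey <- function(micrograph_id, filament_id) {
  paste0(micrograph_id, "::", as.integer(filament_id))
}

#' RegisterMap: external class labels to lattice phases
#'
#' Maps 3D-classification class labels to phase indices `0 .. r-1` within the
#' functional repeat (or `NA` for "non-particle" classes, whose records are
#' dropped).  `reference_phase` is the phase all particles are shifted onto.
#'
#' @slot class_to_phase named integer vector; names are external class labels
#'   (as character), values are phases or `NA` (non-particle).
#' @slot reference_phase the target phase.
#' @export
setClass("RegisterMap",
  slots = c(class_to_phase = "integer", reference_phase = "integer"))

setValidity("RegisterMap", function(object) {
  ph <- object@class_to_phase
  if (is.null(names(ph)) || anyDuplicated(names(ph)))
    return("class_to_phase must have unique names (external class labels)")
  assigned <- ph[!is.na(ph)]
  if (anyDuplicated(assigned))
    return("assigned phases must be distinct")
  if (!(object@reference_phase %in% assigned))
    return("reference_phase must be among the assigned phases")
  TRUE
})

#' Construct a RegisterMap
#'
#' @param class_to_phase named integer vector mapping external class labels to
#'   phases (`NA` marks non-particle classes).  Default: identity map for
#'   classes 0, 1, 2.
#' @param reference_phase phase to unify onto (default 0).
#' @return a [RegisterMap-class].
#' @export
RegisterMap <- function(class_to_phase = c("0" = 0L, "1" = 1L, "2" = 2L),
                        reference_phase = 0L) {
  ph <- as.integer(class_to_phase)
  names(ph) <- names(class_to_phase)
  new("RegisterMap", class_to_phase = ph,
      reference_phase = as.integer(reference_phase))
}

#' DedupPolicy: duplicate-elimination policy
#'
#' Records closer than `d_min_ang` in the micrograph plane (within scope:
#' same filament by default, or whole micrograph) are duplicates; a greedy
#' sweep keeps the highest-priority record of each clump (`picked` before
#' `expanded`, then lower `record_index`).
#'
#' @slot d_min_ang minimum allowed inter-particle distance, Angstroms.
#' @slot scope `"same_filament"` or `"same_micrograph"`.
#' @export
setClass("DedupPolicy", slots = c(d_min_ang = "numeric", scope = "character"))

setValidity("DedupPolicy", function(object) {
  if (length(object@d_min_ang) != 1L || !is.finite(object@d_min_ang) ||
      object@d_min_ang <= 0)
    return("d_min_ang must be a single positive number")
  if (!object@scope %in% c("same_filament", "same_micrograph"))
    return("scope must be 'same_filament' or 'same_micrograph'")
  TRUE
})

#' Construct a DedupPolicy
#'
#' @param d_min_ang distance threshold in Angstroms.  Default 41 (half the
#'   82-Angstrom step): merges same-site duplicates, never adjacent sites.
#' @param scope duplicate search scope (default `"same_filament"`).
#' @return a [DedupPolicy-class].
#' @export
DedupPolicy <- function(d_min_ang = 41, scope = "same_filament") {
  new("DedupPolicy", d_min_ang = as.numeric(d_min_ang),
      scope = match.arg(scope, c("same_filament", "same_micrograph")))
}

#' ExpansionSpec: neighbor-recovery settings
#'
#' Candidates are proposed at `s +/- m * repeatAng(lattice)` for each `m` in
#' `multiples` (default `{1, 2}`, i.e. +/-24 and +/-48 nm at the default
#' lattice), verified, merged, and the cycle repeated until no candidate is
#' accepted or `max_rounds` is reached.
#'
#' @slot multiples positive integers: repeat multiples to propose.
#' @slot max_rounds maximum expand/verify rounds.
#' @slot tol_ang position tolerance handed to the verifier, Angstroms.
#' @export
setClass("ExpansionSpec",
  slots = c(multiples = "integer", max_rounds = "integer", tol_ang = "numeric"))

setValidity("ExpansionSpec", function(object) {
  if (!length(object@multiples) || any(object@multiples < 1L))
    return("multiples must be a non-empty set of integers >= 1")
  if (object@max_rounds < 1L) return("max_rounds must be >= 1")
  if (object@tol_ang <= 0) return("tol_ang must be positive")
  TRUE
})

#' Construct an ExpansionSpec
#' @param multiples repeat multiples (default `c(1, 2)`).
#' @param max_rounds maximum rounds (default 10).
#' @param tol_ang verifier position tolerance in Angstroms (default 41).
#' @return an [ExpansionSpec-class].
#' @export
ExpansionSpec <- function(multiples = c(1L, 2L), max_rounds = 10L,
                          tol_ang = 41) {
  new("ExpansionSpec", multiples = sort(unique(as.integer(multiples))),
      max_rounds = as.integer(max_rounds), tol_ang = as.numeric(tol_ang))
}

#' SimConfig: synthetic splayed-axoneme dataset parameters
#'
#' Generative parameters for coordinate-level synthetic data: micrograph
#' fields of curved filaments carrying a site lattice with a functional repeat
#' whose sites are occupied in clusters (two-state Markov chain), observed
#' through localization noise, register displacement/labeling errors, and
#' partial initial detection.
#'
#' @slot n_micrographs number of micrograph fields.
#' @slot field_px field width/height in pixels (square field).
#' @slot pixel_size_ang Angstroms per pixel (default 1.36).
#' @slot filaments_per_micrograph length-2 integer range (min, max).
#' @slot filament_length_range length-2 range of target filament lengths, Angstroms.
#' @slot curvature_range length-2 range of arc radii in Angstroms
#'   (`Inf` = straight chords).
#' @slot lattice a [LatticeSpec-class].
#' @slot p_start probability the occupancy chain starts/restarts a cluster.
#' @slot p_stay probability an occupied repeat site is followed by another.
#' @slot loc_noise_ang isotropic localization noise sigma, Angstroms.
#' @slot register_label_error probability a register label is wrong
#'   (uniform over the other phases).
#' @slot seed_detection_rate probability an occupied site enters the seed set.
#' @slot false_site_rate probability an unoccupied repeat site yields a
#'   spurious seed record.
#' @slot register_offsets if `TRUE` (default) each detected particle is
#'   displaced a whole step from its site according to its register, so all
#'   three register classes are populated as in classification output; if
#'   `FALSE` particles sit at their sites and labels are reference-phase.
#' @slot rng_seed integer RNG seed; identical configs give identical output.
#' @export
setClass("SimConfig",
  slots = c(n_micrographs = "integer", field_px = "integer",
            pixel_size_ang = "numeric", filaments_per_micrograph = "integer",
            filament_length_range = "numeric", curvature_range = "numeric",
            lattice = "LatticeSpec", p_start = "numeric", p_stay = "numeric",
            loc_noise_ang = "numeric", register_label_error = "numeric",
            seed_detection_rate = "numeric", false_site_rate = "numeric",
            register_offsets = "logical", rng_seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  probs <- c(p_start = object@p_start, p_stay = object@p_stay,
             register_label_error = object@register_label_error,
             seed_detection_rate = object@seed_detection_rate,
             false_site_rate = object@false_site_rate)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    msg <- c(msg, paste("probabilities outside [0, 1]:",
                        paste(bad, collapse = ", ")))
  if (object@loc_noise_ang < 0) msg <- c(msg, "loc_noise_ang must be >= 0")
  if (object@n_micrographs < 1L) msg <- c(msg, "n_micrographs must be >= 1")
  if (length(object@filaments_per_micrograph) != 2L ||
      any(object@filaments_per_micrograph < 1L))
    msg <- c(msg, "filaments_per_micrograph must be a length-2 range >= 1")
  fieldAng <- object@field_px * object@pixel_size_ang
  if (fieldAng < repeatAng(object@lattice))
    msg <- c(msg, "field too small to hold one functional repeat")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults describe a splayed-axoneme-like field: gently curved filaments of
#' 0.4-0.9 micrometres on a 4096-pixel field at 1.36 Angstrom/pixel, an
#' 82-Angstrom step with a 3-step (24-nm) repeat, clustered occupancy, 2
#' Angstrom localization noise, 5% register mislabeling and 60% initial
#' detection.
#'
#' @param n_micrographs,field_px,pixel_size_ang see [SimConfig-class].
#' @param filaments_per_micrograph scalar or length-2 range.
#' @param filament_length_range,curvature_range length-2 numeric ranges (Angstroms).
#' @param lattice a [LatticeSpec-class].
#' @param p_start,p_stay two-state Markov occupancy parameters.
#' @param loc_noise_ang,register_label_error,seed_detection_rate,false_site_rate
#'   observation-model parameters.
#' @param register_offsets see [SimConfig-class].
#' @param rng_seed integer seed.
#' @return a [SimConfig-class].
#' @export
SimConfig <- function(n_micrographs = 10L, field_px = 4096L,
                      pixel_size_ang = 1.36,
                      filaments_per_micrograph = 5L,
                      filament_length_range = c(4000, 9000),
                      curvature_range = c(2e4, 1e5),
                      lattice = LatticeSpec(),
                      p_start = 0.3, p_stay = 0.8,
                      loc_noise_ang = 2,
                      register_label_error = 0.05,
                      seed_detection_rate = 0.6,
                      false_site_rate = 0,
                      register_offsets = TRUE,
                      rng_seed = 1L) {
  fpm <- as.integer(filaments_per_micrograph)
  if (length(fpm) == 1L) fpm <- c(fpm, fpm)
  new("SimConfig", n_micrographs = as.integer(n_micrographs),
      field_px = as.integer(field_px), pixel_size_ang = as.numeric(pixel_size_ang),
      filaments_per_micrograph = fpm,
      filament_length_range = as.numeric(filament_length_range),
      curvature_range = as.numeric(curvature_range), lattice = lattice,
      p_start = as.numeric(p_start), p_stay = as.numeric(p_stay),
      loc_noise_ang = as.numeric(loc_noise_ang),
      register_label_error = as.numeric(register_label_error),
      seed_detection_rate = as.numeric(seed_detection_rate),
      false_site_rate = as.numeric(false_site_rate),
      register_offsets = isTRUE(register_offsets),
      rng_seed = as.integer(rng_seed))
}

#' TruthTable: ground truth for a synthetic dataset
#'
#' Per-repeat-site occupancy with exact on-axis positions, the true filament
#' axes, and micrograph metadata.  Every occupied site lies on its filament
#' axis at `s = site_index * repeatAng(lattice)` exactly.
#'
#' @slot sites data.frame: `micrograph_id`, `filament_id`, `site_index`,
#'   `occupied` (logical), `s_ang`, `x_px`, `y_px`.
#' @slot axes a [FilamentAxisList-class] of true (polyline) axes.
#' @slot meta data.frame of micrograph metadata (`micrograph_id`, `width_px`,
#'   `height_px`, `pixel_size_ang`).
#' @slot lattice the [LatticeSpec-class] used to generate the data.
#' @export
setClass("TruthTable",
  slots = c(sites = "data.frame", axes = "FilamentAxisList",
            meta = "data.frame", lattice = "LatticeSpec"))

#' QCReport: periodicity and clustering statistics
#'
#' @slot spacings data.frame of per-filament nearest-neighbor arc spacings:
#'   `micrograph_id`, `filament_id`, `spacing_ang`.
#' @slot histogram data.frame `bin_lo`, `bin_hi`, `bin_center`, `count`.
#' @slot modal_spacing_ang center of mass of the highest-count bin (ties
#'   toward the smaller spacing); `NA` when no spacings exist.
#' @slot run_lengths data.frame `run_length` (repeat units), `count`.
#' @slot occupancy_fraction occupied repeat sites / total repeat sites
#'   (`NA` when site totals are unknown).
#' @slot counters list of counts carried from curation (drops, duplicates,
#'   excluded particles, single-particle filaments).
#' @export
setClass("QCReport",
  slots = c(spacings = "data.frame", histogram = "data.frame",
            modal_spacing_ang = "numeric", run_lengths = "data.frame",
            occupancy_fraction = "numeric", counters = "list"))

#' PipelineConfig: one config object for the full workflow
#'
#' Exactly one of synthetic mode (`sim` set) or real-input mode
#' (`particles_path` set, optionally `picks_path`) is active.
#'
#' @slot sim a [SimConfig-class] or `NULL`.
#' @slot particles_path,picks_path input files for real-input mode.
#' @slot pixel_size_ang Angstroms per pixel for real inputs.
#' @slot lattice,regmap,dedup,expansion stage parameter objects.
#' @slot verifier_fp,verifier_fn synthetic-mode verifier corruption rates.
#' @slot qc_bin_ang spacing histogram bin width, Angstroms.
#' @slot qc_tol_ang cluster/recovery matching tolerance, Angstroms.
#' @slot out_dir output directory ("" = write nothing).
#' @slot rng_seed integer seed for the run.
#' @export
setClass("PipelineConfig",
  slots = c(sim = "ANY", particles_path = "character",
            picks_path = "character", pixel_size_ang = "numeric",
            lattice = "LatticeSpec", regmap = "RegisterMap",
            dedup = "DedupPolicy", expansion = "ExpansionSpec",
            verifier_fp = "numeric", verifier_fn = "numeric",
            qc_bin_ang = "numeric", qc_tol_ang = "numeric",
            out_dir = "character", rng_seed = "integer"))

setValidity("PipelineConfig", function(object) {
  synthetic <- !is.null(object@sim)
  real <- nzchar(object@particles_path)
  if (synthetic == real)
    return("exactly one of synthetic mode (sim) or real-input mode (particles_path) must be active")
  if (synthetic && !is(object@sim, "SimConfig"))
    return("sim must be a SimConfig or NULL")
  TRUE
})

#' Construct a PipelineConfig
#'
#' @param sim a [SimConfig-class] for synthetic mode, or `NULL`.
#' @param particles_path,picks_path input tables for real-input mode.
#' @param pixel_size_ang pixel size for real inputs (default 1.36).
#' @param lattice,regmap,dedup,expansion stage parameters.
#' @param verifier_fp,verifier_fn synthetic verifier corruption (default 0).
#' @param qc_bin_ang histogram bin (default 10).
#' @param qc_tol_ang matching tolerance (default 41).
#' @param out_dir output directory, or "" to keep results in memory.
#' @param rng_seed integer seed.
#' @return a [PipelineConfig-class].
#' @export
PipelineConfig <- function(sim = NULL, particles_path = "", picks_path = "",
                           pixel_size_ang = 1.36,
                           lattice = LatticeSpec(), regmap = RegisterMap(),
                           dedup = DedupPolicy(), expansion = ExpansionSpec(),
                           verifier_fp = 0, verifier_fn = 0,
                           qc_bin_ang = 10, qc_tol_ang = 41,
                           out_dir = "", rng_seed = 1L) {
  new("PipelineConfig", sim = sim, particles_path = particles_path,
      picks_path = picks_path, pixel_size_ang = as.numeric(pixel_size_ang),
      lattice = lattice, regmap = regmap, dedup = dedup,
      expansion = expansion, verifier_fp = as.numeric(verifier_fp),
      verifier_fn = as.numeric(verifier_fn), qc_bin_ang = as.numeric(qc_bin_ang),
      qc_tol_ang = as.numeric(qc_tol_ang), out_dir = out_dir,
      rng_seed = as.integer(rng_seed))
}

#' RunReport: bookkeeping for one pipeline run
#'
#' @slot stage_counts named list of per-stage record counts and logs.
#' @slot qc a [QCReport-class] or `NULL`.
#' @slot evaluation list with `precision`/`recall` (synthetic mode).
#' @slot config the [PipelineConfig-class] echo.
#' @slot timings named numeric, wall-clock seconds per stage.
#' @slot version package version string.
#' @export
setClass("RunReport",
  slots = c(stage_counts = "list", qc = "ANY", evaluation = "list",
            config = "ANY", timings = "numeric", version = "character"))
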