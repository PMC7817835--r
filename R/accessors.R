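#' @include AllClasses.R
NULL

#' Accessors for lattice geometry
#'
#' `stepAng` is the axial site step, `repeatAng` the functional repeat,
#' defined as `registerCount(x) * stepAng(x)` exactly.  `registerCount` is the
#' number of distinct registers an axial particle can occupy within one
#' repeat.
#'
#' @param x a [LatticeSpec-class].
#' @return a single numeric (Angstroms) or integer.
#' @examples
#' registerCount(LatticeSpec())  # 3
#' @export
setGeneric("stepAng", function(x) standardGeneric("stepAng"))

#' @rdname stepAng
#' @export
setGeneric("repeatAng", function(x) standardGeneric("repeatAng"))

#' @rdname stepAng
#' @export
setGeneric("registerCount", function(x) standardGeneric("registerCount"))

#' @rdname stepAng
setMethod("stepAng", "LatticeSpec", function(x) x@step_ang)

#' @rdname stepAng
setMethod("repeatAng", "LatticeSpec",
          function(x) x@repeat_multiplier * x@step_ang)

#' @rdname stepAng
setMethod("registerCount", "LatticeSpec", function(x) x@repeat_multiplier)

#' Extract the particle records of a ParticleSet
#'
#' @param x a [ParticleSet-class].
#' @return the records as a `data.frame` (canonical columns first).
#' @export
setGeneric("particleData", function(x) standardGeneric("particleData"))

#' @rdname particleData
setMethod("particleData", "ParticleSet", function(x) x@records)

#' @describeIn particleData number of particle records.
#' @export
setMethod("length", "ParticleSet", function(x) nrow(x@records))

#' Metadata of a ParticleSet (curation logs, flags)
#' @param x a [ParticleSet-class].
#' @param ... ignored.
#' @return a list.
#' @export
setMethod("metadata", "ParticleSet", function(x, ...) x@metadata)

#' Total arc length of a filament axis
#' @param x a [FilamentAxis-class].
#' @return length in Angstroms.
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname totalLength
setMethod("totalLength", "FilamentAxis",
          function(x) x@cumlen[length(x@cumlen)])

#' Ground-truth site table of a TruthTable
#' @param x a [TruthTable-class].
#' @return data.frame of repeat sites with occupancy flags and positions.
#' @export
setGeneric("truthSites", function(x) standardGeneric("truthSites"))

#' @rdname truthSites
setMethod("truthSites", "TruthTable", function(x) x@sites)

#' True filament axes of a TruthTable
#' @param x a [TruthTable-class].
#' @return a [FilamentAxisList-class].
#' @export
setGeneric("truthAxes", function(x) standardGeneric("truthAxes"))

#' @rdname truthAxes
setMethod("truthAxes", "TruthTable", function(x) x@axes)

#' Modal nearest-neighbor spacing of a QC report
#' @param x a [QCReport-class].
#' @return spacing in Angstroms (`NA` when undefined).
#' @export
setGeneric("modalSpacing", function(x) standardGeneric("modalSpacing"))

#' @rdname modalSpacing
setMethod("modalSpacing", "QCReport", function(x) x@modal_spacing_ang)

#' Occupancy-run-length distribution of a QC report
#' @param x a [QCReport-class].
#' @return data.frame with `run_length` and `count`.
#' @export
setGeneric("runLengths", function(x) standardGeneric("runLengths"))

#' @rdname runLengths
setMethod("runLengths", "QCReport", function(x) x@run_lengths)

setMethod("show", "LatticeSpec", function(object) {
  cat("LatticeSpec: step", object@step_ang, "A x", object@repeat_multiplier,
      "registers = repeat", repeatAng(object), "A (box",
      object@box_px, "px)\n")
})

setMethod("show", "ParticleSet", function(object) {
  df <- object@records
  cat("ParticleSet with", nrow(df), "records on",
      length(unique(df$micrograph_id)), "micrograph(s),",
      nrow(unique(df[c("micrograph_id", "filament_id")])), "filament(s)\n")
  if (nrow(df)) {
    prov <- table(df$provenance)
    cat("  provenance:", paste(names(prov), prov, sep = "=", collapse = ", "),
        "\n")
    cat("  s_ang:", if (all(is.na(df$s_ang))) "unset" else
        paste0("[", round(min(df$s_ang, na.rm = TRUE), 1), ", ",
               round(max(df$s_ang, na.rm = TRUE), 1), "] A"), "\n")
  }
})

setMethod("show", "FilamentAxis", function(object) {
  cat("FilamentAxis", axisKey(object@micrograph_id, object@filament_id),
      "- length", round(totalLength(object), 1), "A,",
      nrow(object@support), "support point(s)\n")
})

setMethod("show", "TruthTable", function(object) {
  s <- object@sites
  cat("TruthTable:", nrow(s), "repeat sites on", length(object@axes),
      "filament(s);", sum(s$occupied), "occupied (",
      round(100 * mean(s$occupied), 1), "% )\n")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  cat("  spacings:", nrow(object@spacings), " modal spacing:",
      ifelse(is.na(object@modal_spacing_ang), "undefined",
             paste(object@modal_spacing_ang, "A")), "\n")
  if (nrow(object@run_lengths))
    cat("  cluster runs:", sum(object@run_lengths$count), " mean length:",
        round(with(object@run_lengths, sum(run_length * count) / sum(count)), 2),
        "repeats\n")
  if (!is.na(object@occupancy_fraction))
    cat("  occupancy fraction:", round(object@occupancy_fraction, 3), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_micrographs, "micrograph(s) of",
      object@field_px, "px @", object@pixel_size_ang, "A/px;",
      paste(object@filaments_per_micrograph, collapse = "-"),
      "filaments each\n")
  cat("  occupancy: p_start", object@p_start, " p_stay", object@p_stay,
      "; noise", object@loc_noise_ang, "A; mislabel",
      object@register_label_error, "; detection",
      object@seed_detection_rate, "; seed", object@rng_seed, "\n")
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport (ODAcurate", object@version, ")\n")
  cn <- object@stage_counts
  for (nm in names(cn)) {
    v <- cn[[nm]]
    if (is.numeric(v) && length(v) == 1L)
      cat(" ", nm, ":", v, "\n")
  }
  if (length(object@evaluation))
    cat("  precision:", object@evaluation$precision,
        " recall:", object@evaluation$recall, "\n")
})
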