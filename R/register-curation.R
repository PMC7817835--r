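#' @include AllClasses.R filament-geometry.R
NULL

#' Lattice site index of arc positions
#'
#' Nearest integer site index `round(s / step)`, with exact half-way ties
#' broken toward the smaller index (the minus end of the filament).
#'
#' @param s_ang arc positions, Angstroms.
#' @param step_ang lattice step, Angstroms.
#' @return integer site indices.
#' @export
siteIndex <- function(s_ang, step_ang) {
  as.integer(ceiling(s_ang / step_ang - 0.5))
}

#' Minimum-magnitude phase correction
#'
#' The integer number of steps `delta` with smallest magnitude such that
#' `(phase + delta) %% r == reference`; for even `r` exact ties break toward
#' the negative shift.  For `r = 3` this is the unique `delta` in
#' `{-1, 0, +1}`: the "shifted 8 nm" move that brings an off-center register
#' onto the reference register.
#'
#' @param phase integer phase(s) in `0 .. r-1`.
#' @param reference reference phase.
#' @param r number of registers.
#' @return integer shifts, in steps.
#' @export
phaseShift <- function(phase, reference, r) {
  d0 <- (reference - phase) %% r
  as.integer(ifelse(2 * d0 >= r, d0 - r, d0))
}

#' Unify register classes onto the reference phase
#'
#' Shifts each particle along its filament axis by `phaseShift()` steps so
#' all particles share the reference register: the two off-center register
#' classes move one step (8 nm) onto the central one.  Records whose class
#' maps to "non-particle" (`NA` phase) are dropped and counted, as are
#' records whose shifted position falls outside the axis.  Pixel coordinates
#' are recomputed from the new arc position.
#'
#' @param x a [ParticleSet-class] with `s_ang` set.
#' @param axes a [FilamentAxisList-class].
#' @param regmap a [RegisterMap-class]; every `register_class` in `x` must be
#'   mapped.
#' @param lattice a [LatticeSpec-class].
#' @param pixel_size_ang Angstroms per pixel for the recomputed coordinates.
#' @return the unified [ParticleSet-class]; `metadata()$unify_log` holds
#'   counts shifted per delta and dropped (non-particle, clipped).
#' @export
unifyRegisters <- function(x, axes, regmap = RegisterMap(),
                           lattice = LatticeSpec(), pixel_size_ang = 1.36) {
  df <- particleData(x)
  md <- metadata(x)
  r <- registerCount(lattice)
  if (!nrow(df)) {
    md$unify_log <- list(shifted = integer(), dropped_nonparticle = 0L,
                         dropped_clipped = 0L)
    return(ParticleSet(df, md))
  }
  if (anyNA(df$s_ang))
    stop("unifyRegisters requires s_ang on every record; run ",
         "assignArcCoordinates() first", call. = FALSE)
  lab <- as.character(df$register_class)
  unmapped <- setdiff(unique(lab), names(regmap@class_to_phase))
  if (length(unmapped))
    stop("register class(es) not covered by the RegisterMap: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  phase <- regmap@class_to_phase[lab]
  nonparticle <- is.na(phase)
  delta <- integer(nrow(df))
  delta[!nonparticle] <- phaseShift(phase[!nonparticle],
                                    regmap@reference_phase, r)
  s_new <- df$s_ang + delta * stepAng(lattice)
  key <- axisKey(df$micrograph_id, df$filament_id)
  L <- vapply(key, function(k) {
    ax <- axes[[k]]
    if (is.null(ax)) stop("no axis for filament ", k, call. = FALSE)
    totalLength(ax)
  }, numeric(1))
  clipped <- !nonparticle & (s_new < 0 | s_new > L)
  keep <- !nonparticle & !clipped
  shiftTab <- table(factor(delta[keep], levels = sort(unique(delta[keep]))))
  out <- df[keep, , drop = FALSE]
  out$s_ang <- s_new[keep]
  for (k in unique(key[keep])) {
    rows <- which(key[keep] == k)
    pts <- axisPoint(axes[[k]], out$s_ang[rows])
    out$x_px[rows] <- pts[, 1L] / pixel_size_ang
    out$y_px[rows] <- pts[, 2L] / pixel_size_ang
  }
  md$unify_log <- list(
    shifted = stats::setNames(as.integer(shiftTab), names(shiftTab)),
    dropped_nonparticle = sum(nonparticle),
    dropped_clipped = sum(clipped))
  ParticleSet(out, md)
}

#' Snap arc positions to the nearest lattice site
#'
#' Replaces each `s_ang` by the nearest integer multiple of the lattice step
#' (ties toward smaller `s`), enforcing the correct step register the way
#' particles are re-extracted on lattice positions.  Records displaced by
#' more than `tol_ang` are flagged in an extra `snap_flagged` column.
#'
#' @param x a [ParticleSet-class] with `s_ang` set.
#' @param axes a [FilamentAxisList-class] (recomputes pixel coordinates;
#'   pass `NULL` to leave x/y untouched).
#' @param lattice a [LatticeSpec-class].
#' @param tol_ang flag threshold, Angstroms (default half a step).
#' @param pixel_size_ang Angstroms per pixel.
#' @return the snapped [ParticleSet-class]; `metadata()$snap_log` counts
#'   flagged records.
#' @export
snapToLattice <- function(x, axes = NULL, lattice = LatticeSpec(),
                          tol_ang = stepAng(lattice) / 2,
                          pixel_size_ang = 1.36) {
  df <- particleData(x)
  md <- metadata(x)
  if (!nrow(df)) {
    md$snap_log <- list(flagged = 0L)
    return(ParticleSet(df, md))
  }
  step <- stepAng(lattice)
  idx <- pmax(siteIndex(df$s_ang, step), 0L)
  s_new <- idx * step
  displacement <- abs(s_new - df$s_ang)
  df$snap_flagged <- displacement > tol_ang
  df$s_ang <- s_new
  if (!is.null(axes)) {
    key <- axisKey(df$micrograph_id, df$filament_id)
    for (k in unique(key)) {
      rows <- which(key == k)
      ax <- axes[[k]]
      if (is.null(ax)) stop("no axis for filament ", k, call. = FALSE)
      ## clamp to axis end: a snap can overshoot the final site
      df$s_ang[rows] <- pmin(df$s_ang[rows],
                             floor(totalLength(ax) / step + 1e-9) * step)
      pts <- axisPoint(ax, df$s_ang[rows])
      df$x_px[rows] <- pts[, 1L] / pixel_size_ang
      df$y_px[rows] <- pts[, 2L] / pixel_size_ang
    }
  }
  md$snap_log <- list(flagged = sum(df$snap_flagged))
  ParticleSet(df, md)
}

## priority order of a particle table: picked before expanded, then lower
## record_index; returns a permutation of row numbers
.dedupOrder <- function(df) {
  order(match(df$provenance, .PROVENANCE_LEVELS), df$record_index)
}

#' Eliminate duplicate particles
#'
#' Greedy sweep in priority order (`picked` before `expanded`, then lower
#' `record_index`): a record is kept iff its micrograph-plane Euclidean
#' distance to every already-kept record within scope is at least
#' `d_min_ang`.  Original row order of the kept records is preserved.  The
#' operation is idempotent and guarantees all pairwise in-scope distances of
#' the output are `>= d_min_ang`.
#'
#' @param x a [ParticleSet-class].
#' @param policy a [DedupPolicy-class].
#' @param pixel_size_ang Angstroms per pixel (distances are in Angstroms).
#' @return the deduplicated [ParticleSet-class]; `metadata()$dedup_log`
#'   counts removals.
#' @export
deduplicate <- function(x, policy = DedupPolicy(), pixel_size_ang = 1.36) {
  df <- particleData(x)
  md <- metadata(x)
  if (!nrow(df)) {
    md$dedup_log <- list(removed = 0L)
    return(ParticleSet(df, md))
  }
  scopeKey <- if (policy@scope == "same_filament")
    paste(df$micrograph_id, df$filament_id) else df$micrograph_id
  keep <- logical(nrow(df))
  d2min <- (policy@d_min_ang / pixel_size_ang)^2  # compare in pixel units
  for (g in unique(scopeKey)) {
    rows <- which(scopeKey == g)
    ord <- rows[.dedupOrder(df[rows, , drop = FALSE])]
    kx <- ky <- numeric(0)
    for (i in ord) {
      if (!length(kx) ||
          min((kx - df$x_px[i])^2 + (ky - df$y_px[i])^2) >= d2min) {
        keep[i] <- TRUE
        kx <- c(kx, df$x_px[i]); ky <- c(ky, df$y_px[i])
      }
    }
  }
  md$dedup_log <- list(removed = sum(!keep))
  ParticleSet(df[keep, , drop = FALSE], md)
}
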