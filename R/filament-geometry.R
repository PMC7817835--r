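#' @include AllClasses.R
NULL

## default lateral gate: one box half-width at the default pixel size
.DEFAULT_GATE_ANG <- 256 * 1.36

.segLengths <- function(axis) diff(axis@cumlen)

.axisFor <- function(axes, micrograph_id, filament_id) {
  key <- axisKey(micrograph_id, filament_id)
  ax <- axes[[key]]
  if (is.null(ax))
    stop("no axis for filament ", key, call. = FALSE)
  ax
}

#' Build a filament axis from a pick
#'
#' Reconstructs the filament axis from a two-point pick (`chord` mode, the
#' default, matching manual start/end picking) or from explicit support
#' points (`polyline` mode, for curved filaments).  Pick coordinates are in
#' pixels and are converted to Angstroms with `pixel_size_ang`; polyline
#' support points are given directly in Angstroms.
#'
#' @param pick one-row data.frame with `micrograph_id`, `filament_id`,
#'   `start_x_px`, `start_y_px`, `end_x_px`, `end_y_px` (see [readPicks()]).
#' @param pixel_size_ang Angstroms per pixel (default 1.36).
#' @param mode `"chord"` or `"polyline"`.
#' @param support_ang n x 2 matrix of support points in Angstroms
#'   (polyline mode only, n >= 2).
#' @return a [FilamentAxis-class].
#' @examples
#' pick <- data.frame(micrograph_id = "mg1", filament_id = 1,
#'                    start_x_px = 0, start_y_px = 0,
#'                    end_x_px = 0, end_y_px = 1000)
#' totalLength(buildAxis(pick))  # 1360 A
#' @export
buildAxis <- function(pick, pixel_size_ang = 1.36,
                      mode = c("chord", "polyline"), support_ang = NULL) {
  mode <- match.arg(mode)
  if (mode == "chord") {
    start <- c(pick$start_x_px, pick$start_y_px) * pixel_size_ang
    end <- c(pick$end_x_px, pick$end_y_px) * pixel_size_ang
    if (all(start == end))
      stop("zero-length chord for filament ",
           axisKey(pick$micrograph_id, pick$filament_id), call. = FALSE)
    support <- rbind(start, end)
  } else {
    if (is.null(support_ang) || nrow(as.matrix(support_ang)) < 2L)
      stop("polyline mode requires >= 2 support points", call. = FALSE)
    support <- as.matrix(support_ang)
  }
  FilamentAxis(pick$micrograph_id, pick$filament_id, support)
}

#' Build chord axes for a whole pick table
#'
#' @param picks data.frame of picks (see [readPicks()]).
#' @param pixel_size_ang Angstroms per pixel.
#' @return a [FilamentAxisList-class] keyed by [axisKey()].
#' @export
buildAxes <- function(picks, pixel_size_ang = 1.36) {
  FilamentAxisList(lapply(seq_len(nrow(picks)), function(i)
    buildAxis(picks[i, , drop = FALSE], pixel_size_ang)))
}

#' Evaluate the arc-length parameterization of an axis
#'
#' Maps arc lengths `s` to micrograph-plane points (Angstroms) by piecewise
#' linear interpolation along the axis polyline; exact for polylines.
#' Values outside `[0, totalLength(axis)]` are clamped to the endpoints.
#'
#' @param axis a [FilamentAxis-class].
#' @param s numeric vector of arc lengths, Angstroms.
#' @return length(s) x 2 matrix of points in Angstroms.
#' @export
axisPoint <- function(axis, s) {
  cl <- axis@cumlen
  p <- axis@support
  s <- pmin(pmax(s, 0), cl[length(cl)])
  idx <- findInterval(s, cl, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(p) - 1L)
  seg <- diff(cl)
  t <- (s - cl[idx]) / seg[idx]
  p[idx, , drop = FALSE] + t * (p[idx + 1L, , drop = FALSE] -
                                p[idx, , drop = FALSE])
}

#' Divide a filament axis into lattice-step particles
#'
#' Places particle centers along the axis at `s_i = i * stepAng(lattice)` for
#' `i = 0 .. floor(L / step)`, the segmentation that divides a picked
#' filament into 8-nm particles at an 82 Angstrom step.  Segmentation starts
#' at the picked start point and includes the endpoint when the length is an
#' exact multiple of the step; a short axis yields the single center `s = 0`.
#'
#' @param axis a [FilamentAxis-class].
#' @param lattice a [LatticeSpec-class].
#' @param pixel_size_ang Angstroms per pixel, used to express centers in
#'   micrograph pixel coordinates.
#' @return a [ParticleSet-class] with `provenance = "picked"`, `s_ang` set and
#'   `x_px`/`y_px` from the axis parameterization.
#' @export
segmentAxis <- function(axis, lattice = LatticeSpec(), pixel_size_ang = 1.36) {
  L <- totalLength(axis)
  step <- stepAng(lattice)
  n <- floor(L / step + 1e-9)
  s <- (0:n) * step
  pts <- axisPoint(axis, s)
  ParticleSet(data.frame(
    micrograph_id = axis@micrograph_id,
    x_px = pts[, 1L] / pixel_size_ang,
    y_px = pts[, 2L] / pixel_size_ang,
    filament_id = axis@filament_id,
    s_ang = s,
    stringsAsFactors = FALSE))
}

#' Arc-length coordinate of points near an axis
#'
#' Projects micrograph-plane points (Angstroms) onto the axis polyline and
#' returns the arc length of the nearest axis point, with ties broken toward
#' smaller `s`.  Points farther from the axis than `max_dist_ang` (the
#' lateral gate, default one 512-pixel box half-width at 1.36 Angstrom/pixel)
#' are rejected with the offending distance reported.
#'
#' @param axis a [FilamentAxis-class].
#' @param points_ang n x 2 matrix (or length-2 vector) of points in Angstroms.
#' @param max_dist_ang lateral gate in Angstroms; `Inf` disables the gate.
#' @param action on a gated point: `"error"` (default) or `"na"` to return
#'   `NA` for that point.
#' @return data.frame with `s_ang` (arc length) and `dist_ang` (lateral
#'   distance to the axis).
#' @export
arcCoordinate <- function(axis, points_ang, max_dist_ang = .DEFAULT_GATE_ANG,
                          action = c("error", "na")) {
  action <- match.arg(action)
  pts <- matrix(as.numeric(points_ang), ncol = 2L)
  p <- axis@support
  cl <- axis@cumlen
  a <- p[-nrow(p), , drop = FALSE]
  b <- p[-1L, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d^2)
  n <- nrow(pts)
  s_out <- dist_out <- numeric(n)
  for (i in seq_len(n)) {
    rel <- sweep(a, 2L, pts[i, ])
    t <- pmin(pmax(-(rel[, 1L] * d[, 1L] + rel[, 2L] * d[, 2L]) / len2, 0), 1)
    proj <- a + t * d
    dist2 <- rowSums(sweep(proj, 2L, pts[i, ])^2)
    j <- which.min(dist2)           # first minimum = smaller s on exact ties
    s_out[i] <- cl[j] + t[j] * sqrt(len2[j])
    dist_out[i] <- sqrt(dist2[j])
  }
  beyond <- dist_out > max_dist_ang
  if (any(beyond)) {
    if (action == "error")
      stop("point ", which(beyond)[1L], " is ",
           round(dist_out[which(beyond)[1L]], 1),
           " A from the axis (lateral gate ", max_dist_ang, " A)",
           call. = FALSE)
    s_out[beyond] <- NA_real_
  }
  data.frame(s_ang = s_out, dist_ang = dist_out)
}

#' Assign arc-length coordinates to a particle table
#'
#' Computes `s_ang` for every record from its pixel coordinates and the axis
#' of its filament.  Records beyond the lateral gate are dropped and counted
#' in `metadata(x)$gated_out`.
#'
#' @param x a [ParticleSet-class].
#' @param axes a [FilamentAxisList-class] covering every filament in `x`.
#' @param pixel_size_ang Angstroms per pixel.
#' @param max_dist_ang lateral gate, Angstroms.
#' @return the [ParticleSet-class] with `s_ang` filled.
#' @export
assignArcCoordinates <- function(x, axes, pixel_size_ang = 1.36,
                                 max_dist_ang = .DEFAULT_GATE_ANG) {
  df <- particleData(x)
  if (!nrow(df)) {
    x@metadata$gated_out <- 0L
    return(x)
  }
  key <- axisKey(df$micrograph_id, df$filament_id)
  s <- rep(NA_real_, nrow(df))
  for (k in unique(key)) {
    rows <- which(key == k)
    ax <- axes[[k]]
    if (is.null(ax)) stop("no axis for filament ", k, call. = FALSE)
    res <- arcCoordinate(ax, cbind(df$x_px[rows], df$y_px[rows]) *
                               pixel_size_ang,
                         max_dist_ang = max_dist_ang, action = "na")
    s[rows] <- res$s_ang
  }
  keep <- !is.na(s)
  df$s_ang <- s
  md <- metadata(x)
  md$gated_out <- sum(!keep)
  ParticleSet(df[keep, , drop = FALSE], metadata = md)
}
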