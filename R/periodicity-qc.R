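#' @include AllClasses.R register-curation.R
NULL

.emptyQC <- function(counters = list()) {
  new("QCReport",
      spacings = data.frame(micrograph_id = character(),
                            filament_id = integer(), spacing_ang = numeric()),
      histogram = data.frame(bin_lo = numeric(), bin_hi = numeric(),
                             bin_center = numeric(), count = integer()),
      modal_spacing_ang = NA_real_,
      run_lengths = data.frame(run_length = integer(), count = integer()),
      occupancy_fraction = NA_real_, counters = counters)
}

#' Nearest-neighbor spacing statistics
#'
#' Computes, per filament, the successive differences of sorted arc
#' positions, pools them into a histogram with `bin_ang`-wide bins anchored
#' at 0, and reports the modal spacing as the center of mass (data mean) of
#' the highest-count bin, ties toward the smaller spacing.  Filaments holding a single particle
#' contribute no spacings and are counted.  The modal spacing of a correctly
#' curated decorated filament equals the functional repeat (24 nm).
#'
#' @param x a [ParticleSet-class] with `s_ang` set.
#' @param bin_ang histogram bin width, Angstroms (default 10: separates the
#'   82 and 246 Angstrom peaks cleanly).
#' @return a [QCReport-class] with the spacing fields filled.
#' @export
spacingStats <- function(x, bin_ang = 10) {
  stopifnot(bin_ang > 0)
  df <- particleData(x)
  rep_counters <- list(n_filaments = 0L, single_particle_filaments = 0L)
  if (!nrow(df)) return(.emptyQC(rep_counters))
  if (anyNA(df$s_ang)) stop("spacingStats requires s_ang", call. = FALSE)
  key <- paste(df$micrograph_id, df$filament_id)
  spl <- split(seq_len(nrow(df)), key)
  rep_counters$n_filaments <- length(spl)
  recs <- lapply(spl, function(rows) {
    s <- sort(df$s_ang[rows])
    if (length(s) < 2L) return(NULL)
    data.frame(micrograph_id = df$micrograph_id[rows[1L]],
               filament_id = df$filament_id[rows[1L]],
               spacing_ang = diff(s), stringsAsFactors = FALSE)
  })
  rep_counters$single_particle_filaments <-
    sum(vapply(spl, length, integer(1)) == 1L)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(.emptyQC(rep_counters))
  spacings <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  idx <- floor(spacings$spacing_ang / bin_ang)
  tab <- table(idx)
  bins <- as.integer(names(tab))
  o <- order(bins)                        # ascending: first max = smaller bin
  bins <- bins[o]; counts <- as.integer(tab)[o]
  hist <- data.frame(bin_lo = bins * bin_ang, bin_hi = (bins + 1L) * bin_ang,
                     bin_center = (bins + 0.5) * bin_ang, count = counts)
  ## modal spacing: center of mass of the highest-count bin (ties toward the
  ## smaller spacing), so a noiseless lattice reports its repeat exactly
  modalBin <- bins[which.max(counts)]
  inBin <- idx == modalBin
  modal <- mean(spacings$spacing_ang[inBin])
  new("QCReport", spacings = spacings, histogram = hist,
      modal_spacing_ang = modal,
      run_lengths = data.frame(run_length = integer(), count = integer()),
      occupancy_fraction = NA_real_, counters = rep_counters)
}

#' Occupancy-cluster run lengths
#'
#' Maps each particle to its functional-repeat site `j = round(s / repeat)`
#' and reports the distribution of maximal runs of consecutive occupied
#' sites per filament — the cluster structure in which bound complexes are
#' retained.  Particles farther than `tol_ang` from any repeat site are
#' excluded and counted in the `excluded` attribute.
#'
#' @param x a [ParticleSet-class] with `s_ang` set.
#' @param lattice a [LatticeSpec-class].
#' @param tol_ang maximum distance from a repeat site, Angstroms
#'   (default half a step, consistent with deduplication).
#' @return data.frame with `run_length` (in repeat units) and `count`;
#'   attributes `excluded` (particles off-site) and `n_sites` (occupied
#'   sites mapped).
#' @export
detectClusters <- function(x, lattice = LatticeSpec(),
                           tol_ang = stepAng(lattice) / 2) {
  df <- particleData(x)
  empty <- data.frame(run_length = integer(), count = integer())
  if (!nrow(df)) {
    attr(empty, "excluded") <- 0L
    attr(empty, "n_sites") <- 0L
    return(empty)
  }
  rep_ang <- repeatAng(lattice)
  j <- siteIndex(df$s_ang, rep_ang)
  off <- abs(df$s_ang - j * rep_ang) > tol_ang
  key <- paste(df$micrograph_id, df$filament_id)[!off]
  j <- j[!off]
  lens <- integer(0)
  for (g in unique(key)) {
    sites <- sort(unique(j[key == g]))
    if (!length(sites)) next
    breaks <- c(0L, which(diff(sites) > 1L), length(sites))
    lens <- c(lens, diff(breaks))
  }
  tab <- table(lens)
  out <- data.frame(run_length = as.integer(names(tab)),
                    count = as.integer(tab))
  out <- out[order(out$run_length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- sum(off)
  attr(out, "n_sites") <- sum(out$run_length * out$count)
  out
}

#' Score curated particles against ground truth
#'
#' Matches curated particles to occupied ground-truth sites on the same
#' filament, greedily by arc distance and one-to-one, within `tol_ang`.
#' Precision is TP / curated records, recall TP / occupied sites.
#'
#' @param curated a [ParticleSet-class] with `s_ang` set.
#' @param truth a [TruthTable-class].
#' @param tol_ang matching tolerance, Angstroms.
#' @return list with `precision`, `recall`, `tp`, `n_curated`, `n_occupied`.
#' @export
evaluateRecovery <- function(curated, truth, tol_ang = 41) {
  df <- particleData(curated)
  occ <- truthSites(truth)
  occ <- occ[occ$occupied, , drop = FALSE]
  nC <- nrow(df); nO <- nrow(occ)
  if (nC == 0L || nO == 0L)
    return(list(precision = if (nC) 0 else NA_real_,
                recall = if (nO) 0 else NA_real_,
                tp = 0L, n_curated = nC, n_occupied = nO))
  ckey <- paste(df$micrograph_id, df$filament_id)
  okey <- paste(occ$micrograph_id, occ$filament_id)
  tp <- 0L
  for (g in intersect(unique(ckey), unique(okey))) {
    cs <- df$s_ang[ckey == g]
    os <- occ$s_ang[okey == g]
    d <- abs(outer(cs, os, "-"))
    pairs <- which(d <= tol_ang, arr.ind = TRUE)
    if (!nrow(pairs)) next
    pairs <- pairs[order(d[pairs]), , drop = FALSE]
    usedC <- logical(length(cs)); usedO <- logical(length(os))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; k <- pairs[p, 2L]
      if (!usedC[i] && !usedO[k]) {
        usedC[i] <- usedO[k] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  list(precision = tp / nC, recall = tp / nO, tp = tp,
       n_curated = nC, n_occupied = nO)
}

#' Full periodicity/cluster QC report
#'
#' Combines [spacingStats()] and [detectClusters()] and, when axes are
#' given, the occupancy fraction (occupied repeat sites / total repeat sites
#' over all filaments with particles or axes).
#'
#' @param x a [ParticleSet-class] with `s_ang` set.
#' @param axes optional [FilamentAxisList-class] for site totals.
#' @param lattice a [LatticeSpec-class].
#' @param bin_ang spacing histogram bin, Angstroms.
#' @param tol_ang cluster mapping tolerance, Angstroms.
#' @return a [QCReport-class].
#' @export
qcReport <- function(x, axes = NULL, lattice = LatticeSpec(), bin_ang = 10,
                     tol_ang = stepAng(lattice) / 2) {
  rep <- spacingStats(x, bin_ang)
  runs <- detectClusters(x, lattice, tol_ang)
  rep@run_lengths <- runs
  counters <- rep@counters
  counters$cluster_excluded <- attr(runs, "excluded")
  counters$occupied_sites <- attr(runs, "n_sites")
  for (nm in c("unify_log", "snap_log", "dedup_log", "recovery_log",
               "gated_out"))
    if (!is.null(metadata(x)[[nm]])) counters[[nm]] <- metadata(x)[[nm]]
  if (!is.null(axes) && length(axes)) {
    totalSites <- sum(vapply(as.list(axes), function(ax)
      floor(totalLength(ax) / repeatAng(lattice) + 1e-9) + 1, numeric(1)))
    rep@occupancy_fraction <- attr(runs, "n_sites") / totalSites
  }
  rep@counters <- counters
  rep
}

#' Serialize a QC report
#'
#' Writes the report as JSON and the spacing histogram as CSV.
#'
#' @param report a [QCReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeQCReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonPath <- file.path(dir, "qc_report.json")
  csvPath <- file.path(dir, "spacing_histogram.csv")
  jsonlite::write_json(list(
    modal_spacing_ang = report@modal_spacing_ang,
    n_spacings = nrow(report@spacings),
    occupancy_fraction = report@occupancy_fraction,
    run_lengths = report@run_lengths,
    counters = report@counters,
    histogram = report@histogram), jsonPath, auto_unbox = TRUE, digits = NA,
    na = "null", force = TRUE)
  utils::write.csv(report@histogram, csvPath, row.names = FALSE)
  invisible(c(jsonPath, csvPath))
}

#' Plot the spacing histogram of a QC report
#'
#' Bar plot of nearest-neighbor spacings with the modal bin marked; the
#' expected signature of an intact decorated filament is a single dominant
#' peak at the functional repeat.
#'
#' @param report a [QCReport-class].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plotSpacingHistogram <- function(report, ...) {
  h <- report@histogram
  if (!nrow(h)) {
    graphics::plot.new()
    graphics::title(main = "no spacings")
    return(invisible(NULL))
  }
  mids <- graphics::barplot(h$count, names.arg = h$bin_center,
                            xlab = "nearest-neighbor spacing (Å)",
                            ylab = "count", border = NA, ...)
  if (!is.na(report@modal_spacing_ang)) {
    i <- which(h$bin_center == report@modal_spacing_ang)[1L]
    graphics::abline(v = mids[i], lty = 2)
  }
  invisible(mids)
}
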