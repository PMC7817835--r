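#' @include AllClasses.R filament-geometry.R register-curation.R
NULL

## evaluate expr under a private RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Two-state Markov occupancy chain over repeat sites
#'
#' Draws site occupancy along a filament: the first site (and any site after
#' an unoccupied one) is occupied with probability `p_start`; a site
#' following an occupied site is occupied with probability `p_stay`.
#' Occupied run lengths are geometric with mean `1 / (1 - p_stay)` — the
#' clustered retention of bound complexes.
#'
#' @param n number of repeat sites.
#' @param p_start cluster start probability.
#' @param p_stay cluster persistence probability.
#' @return logical vector of length `n`.
#' @export
simulateOccupancy <- function(n, p_start = 0.3, p_stay = 0.8) {
  occ <- logical(n)
  if (!n) return(occ)
  u <- stats::runif(n)
  occ[1L] <- u[1L] < p_start
  for (j in seq_len(n - 1L))
    occ[j + 1L] <- u[j + 1L] < if (occ[j]) p_stay else p_start
  occ
}

## one curved filament axis as a circular arc polyline clipped to the field;
## returns an n x 2 matrix of support points in Angstroms
.simFilamentSupport <- function(fieldAng, lengthAng, radiusAng, ds = 20) {
  margin <- 0.12 * fieldAng
  pos <- stats::runif(2, margin, fieldAng - margin)
  theta <- stats::runif(1, 0, 2 * pi)
  turn <- if (is.finite(radiusAng)) sample(c(-1, 1), 1) * ds / radiusAng else 0
  n <- max(2L, ceiling(lengthAng / ds) + 1L)
  pts <- matrix(NA_real_, n, 2L)
  pts[1L, ] <- pos
  k <- 1L
  while (k < n) {
    nxt <- pts[k, ] + ds * c(cos(theta), sin(theta))
    if (any(nxt < 0) || any(nxt > fieldAng)) break  # clip at the field edge
    k <- k + 1L
    pts[k, ] <- nxt
    theta <- theta + turn
  }
  pts[seq_len(k), , drop = FALSE]
}

#' Simulate a splayed-axoneme coordinate dataset with ground truth
#'
#' Lays curved filaments (circular arcs, clipped to the micrograph field)
#' carrying a step lattice whose functional-repeat sites are occupied in
#' clusters drawn from a two-state Markov chain.  Observed seed records
#' emulate the output of initial picking plus register classification:
#' occupied sites are detected with `seed_detection_rate`; each detected
#' particle is (optionally) displaced a whole step according to a uniformly
#' drawn register, labeled with that register's phase, mislabeled with
#' probability `register_label_error`, and localized with isotropic Gaussian
#' noise.  Unoccupied sites yield spurious records at `false_site_rate`.
#' Identical configs (including `rng_seed`) give identical output; the RNG
#' stream is consumed in (micrograph, filament, site) order so earlier
#' micrographs are unchanged when more are added.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `truth` ([TruthTable-class]), `particles`
#'   (observed seed [ParticleSet-class]; `s_ang` left unset, to be assigned
#'   by geometry), `picks` (start/end pick data.frame, see [readPicks()]),
#'   and `meta` (micrograph metadata data.frame).
#' @export
simulateField <- function(config) {
  validObject(config)
  lattice <- config@lattice
  step <- stepAng(lattice)
  rep_ang <- repeatAng(lattice)
  r <- registerCount(lattice)
  px <- config@pixel_size_ang
  fieldAng <- config@field_px * px
  .withSeed(config@rng_seed, {
    axes <- list()
    siteRows <- list()
    obsRows <- list()
    pickRows <- list()
    for (m in seq_len(config@n_micrographs)) {
      mic <- sprintf("synthetic_%04d.mrc", m)
      fpm <- config@filaments_per_micrograph
      nf <- if (fpm[1L] == fpm[2L]) fpm[1L]
            else sample(seq(fpm[1L], fpm[2L]), 1L)
      for (f in seq_len(nf)) {
        L0 <- stats::runif(1, config@filament_length_range[1L],
                           config@filament_length_range[2L])
        radius <- if (all(is.finite(config@curvature_range)))
          stats::runif(1, config@curvature_range[1L],
                       config@curvature_range[2L]) else Inf
        support <- .simFilamentSupport(fieldAng, L0, radius)
        if (nrow(support) < 2L) next  # start too close to the edge
        ax <- FilamentAxis(mic, f, support)
        L <- totalLength(ax)
        if (L < rep_ang) next        # too short to hold one repeat
        axes[[axisKey(mic, f)]] <- ax
        pickRows[[length(pickRows) + 1L]] <- data.frame(
          micrograph_id = mic, filament_id = f,
          start_x_px = support[1L, 1L] / px, start_y_px = support[1L, 2L] / px,
          end_x_px = support[nrow(support), 1L] / px,
          end_y_px = support[nrow(support), 2L] / px,
          stringsAsFactors = FALSE)
        nSites <- floor(L / rep_ang + 1e-9) + 1L
        occ <- simulateOccupancy(nSites, config@p_start, config@p_stay)
        s_sites <- (seq_len(nSites) - 1L) * rep_ang
        pts <- axisPoint(ax, s_sites)
        siteRows[[length(siteRows) + 1L]] <- data.frame(
          micrograph_id = mic, filament_id = f,
          site_index = seq_len(nSites) - 1L, occupied = occ,
          s_ang = s_sites, x_px = pts[, 1L] / px, y_px = pts[, 2L] / px,
          stringsAsFactors = FALSE)
        for (j in seq_len(nSites)) {
          s0 <- s_sites[j]
          if (occ[j]) {
            if (stats::runif(1) >= config@seed_detection_rate) next
            cOff <- if (config@register_offsets)
              sample(c(-1L, 0L, 1L), 1L) else 0L
            if (s0 + cOff * step < 0 || s0 + cOff * step > L) cOff <- 0L
            phase <- cOff %% r
            if (stats::runif(1) < config@register_label_error)
              phase <- sample(setdiff(0:(r - 1L), phase), 1L)
            p <- axisPoint(ax, s0 + cOff * step)[1L, ] +
                 stats::rnorm(2, 0, config@loc_noise_ang)
            obsRows[[length(obsRows) + 1L]] <- data.frame(
              micrograph_id = mic, x_px = p[1L] / px, y_px = p[2L] / px,
              filament_id = f, register_class = phase,
              stringsAsFactors = FALSE)
          } else if (config@false_site_rate > 0 &&
                     stats::runif(1) < config@false_site_rate) {
            p <- axisPoint(ax, s0)[1L, ] +
                 stats::rnorm(2, 0, config@loc_noise_ang)
            obsRows[[length(obsRows) + 1L]] <- data.frame(
              micrograph_id = mic, x_px = p[1L] / px, y_px = p[2L] / px,
              filament_id = f, register_class = sample(0:(r - 1L), 1L),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    sites <- if (length(siteRows))
      do.call(rbind, c(siteRows, list(make.row.names = FALSE)))
    else data.frame(micrograph_id = character(), filament_id = integer(),
                    site_index = integer(), occupied = logical(),
                    s_ang = numeric(), x_px = numeric(), y_px = numeric())
    obs <- if (length(obsRows))
      do.call(rbind, c(obsRows, list(make.row.names = FALSE)))
    else data.frame(micrograph_id = character(), x_px = numeric(),
                    y_px = numeric(), filament_id = integer(),
                    register_class = integer())
    picks <- if (length(pickRows))
      do.call(rbind, c(pickRows, list(make.row.names = FALSE)))
    else data.frame(micrograph_id = character(), filament_id = integer(),
                    start_x_px = numeric(), start_y_px = numeric(),
                    end_x_px = numeric(), end_y_px = numeric())
    meta <- data.frame(
      micrograph_id = sprintf("synthetic_%04d.mrc",
                              seq_len(config@n_micrographs)),
      width_px = config@field_px, height_px = config@field_px,
      pixel_size_ang = px, stringsAsFactors = FALSE)
    truth <- new("TruthTable", sites = sites, axes = FilamentAxisList(axes),
                 meta = meta, lattice = lattice)
    list(truth = truth, particles = ParticleSet(obs), picks = picks,
         meta = meta)
  })
}

#' Ground-truth candidate verifier, optionally corrupted
#'
#' Builds the acceptance predicate used by [iterateRecovery()] from a
#' [TruthTable-class]: a candidate is accepted iff an occupied site lies
#' within `tol_ang` of its arc position on the same filament — except that
#' occupied sites are missed with probability `fn` and unoccupied sites are
#' falsely accepted with probability `fp`.  Corruption is drawn once per
#' site at construction under `rng_seed`, so the verifier is deterministic:
#' the same candidate always gets the same answer.
#'
#' @param truth a [TruthTable-class].
#' @param fp false-accept probability per unoccupied site.
#' @param fn false-reject probability per occupied site.
#' @param tol_ang position tolerance, Angstroms.
#' @param rng_seed seed for the corruption draws.
#' @return a function mapping candidate records (data.frame with
#'   `micrograph_id`, `filament_id`, `s_ang`) to a logical vector.
#' @export
truthVerifier <- function(truth, fp = 0, fn = 0, tol_ang = 41,
                          rng_seed = 1L) {
  stopifnot(fp >= 0, fp <= 1, fn >= 0, fn <= 1)
  sites <- truthSites(truth)
  rep_ang <- repeatAng(truth@lattice)
  key <- paste(sites$micrograph_id, sites$filament_id, sites$site_index,
               sep = "::")
  accept <- .withSeed(rng_seed, {
    u <- stats::runif(nrow(sites))
    ifelse(sites$occupied, u >= fn, u < fp)
  })
  names(accept) <- key
  occupied <- stats::setNames(sites$occupied, key)
  s_site <- stats::setNames(sites$s_ang, key)
  function(candidates) {
    if (!nrow(candidates)) return(logical(0))
    j <- siteIndex(candidates$s_ang, rep_ang)
    ckey <- paste(candidates$micrograph_id, candidates$filament_id, j,
                  sep = "::")
    known <- ckey %in% names(accept)
    out <- logical(nrow(candidates))
    kk <- ckey[known]
    nearOcc <- occupied[kk] &
      abs(candidates$s_ang[known] - s_site[kk]) <= tol_ang
    ## occupied-and-near sites use the fn draw; all others the fp draw,
    ## except that fp applies only where no occupied site is within reach
    out[known] <- ifelse(nearOcc, accept[kk],
                         !occupied[kk] & accept[kk])
    out
  }
}

#' Read / write a SimConfig as YAML
#'
#' @param path YAML file.
#' @return [readSimConfig()]: a [SimConfig-class]; [writeSimConfig()]:
#'   `path`, invisibly.
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  lat <- y$lattice
  SimConfig(
    n_micrographs = y$n_micrographs, field_px = y$field_px,
    pixel_size_ang = y$pixel_size_ang,
    filaments_per_micrograph = unlist(y$filaments_per_micrograph),
    filament_length_range = unlist(y$filament_length_range),
    curvature_range = {
      cr <- unlist(y$curvature_range)
      cr[cr == ".inf" | cr == "Inf"] <- Inf
      as.numeric(cr)
    },
    lattice = LatticeSpec(lat$step_ang, lat$repeat_multiplier, lat$box_px),
    p_start = y$p_start, p_stay = y$p_stay,
    loc_noise_ang = y$loc_noise_ang,
    register_label_error = y$register_label_error,
    seed_detection_rate = y$seed_detection_rate,
    false_site_rate = y$false_site_rate,
    register_offsets = y$register_offsets,
    rng_seed = y$rng_seed)
}

#' @rdname readSimConfig
#' @param config a [SimConfig-class].
#' @export
writeSimConfig <- function(config, path) {
  y <- list(
    n_micrographs = config@n_micrographs, field_px = config@field_px,
    pixel_size_ang = config@pixel_size_ang,
    filaments_per_micrograph = config@filaments_per_micrograph,
    filament_length_range = config@filament_length_range,
    curvature_range = config@curvature_range,
    lattice = list(step_ang = config@lattice@step_ang,
                   repeat_multiplier = config@lattice@repeat_multiplier,
                   box_px = config@lattice@box_px),
    p_start = config@p_start, p_stay = config@p_stay,
    loc_noise_ang = config@loc_noise_ang,
    register_label_error = config@register_label_error,
    seed_detection_rate = config@seed_detection_rate,
    false_site_rate = config@false_site_rate,
    register_offsets = config@register_offsets,
    rng_seed = config@rng_seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a TruthTable to plain-text files
#'
#' Sites as CSV (`truth_sites.csv`), axes and micrograph metadata as JSON
#' (`truth_meta.json`).
#'
#' @param truth a [TruthTable-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeTruthTable <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sitesPath <- file.path(dir, "truth_sites.csv")
  metaPath <- file.path(dir, "truth_meta.json")
  utils::write.csv(truthSites(truth), sitesPath, row.names = FALSE)
  axes <- lapply(as.list(truthAxes(truth)), function(ax)
    list(micrograph_id = ax@micrograph_id, filament_id = ax@filament_id,
         support_ang = unname(ax@support)))
  jsonlite::write_json(list(meta = truth@meta, axes = axes,
                            lattice = list(step_ang = truth@lattice@step_ang,
                                           repeat_multiplier =
                                             truth@lattice@repeat_multiplier)),
                       metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(sitesPath, metaPath))
}
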