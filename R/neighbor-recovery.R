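#' @include AllClasses.R register-curation.R
NULL

#' Propose neighbor candidates along the filament axis
#'
#' For every seed at arc position `s`, proposes candidate particles at
#' `s +/- m * repeatAng(lattice)` for each `m` in `spec@multiples` — at the
#' defaults, +/-1 and +/-2 functional repeats (+/-24 and +/-48 nm) along the
#' microtubule axis.  Candidates outside `[0, L]` are clipped away; the
#' remaining ones inherit their seed's micrograph and filament identity and
#' get `provenance = "expanded"`.  Duplicates among candidates are *not*
#' removed here.
#'
#' @param seeds a [ParticleSet-class] with valid `s_ang`.
#' @param axes a [FilamentAxisList-class] covering every seed filament.
#' @param lattice a [LatticeSpec-class].
#' @param spec an [ExpansionSpec-class].
#' @param pixel_size_ang Angstroms per pixel for candidate coordinates.
#' @return a [ParticleSet-class] of candidates; `metadata()$n_proposed` is
#'   the count before clipping (`length(seeds) * 2 * length(multiples)`).
#' @export
expandSeeds <- function(seeds, axes, lattice = LatticeSpec(),
                        spec = ExpansionSpec(), pixel_size_ang = 1.36) {
  df <- particleData(seeds)
  rep_ang <- repeatAng(lattice)
  offsets <- c(-rev(spec@multiples), spec@multiples) * rep_ang
  nOff <- length(offsets)
  if (!nrow(df)) {
    out <- ParticleSet()
    out@metadata$n_proposed <- 0L
    return(out)
  }
  key <- axisKey(df$micrograph_id, df$filament_id)
  L <- numeric(nrow(df))
  for (k in unique(key)) {
    ax <- axes[[k]]
    if (is.null(ax))
      stop("seed on filament ", k, " has no axis", call. = FALSE)
    L[key == k] <- totalLength(ax)
  }
  cand <- df[rep(seq_len(nrow(df)), each = nOff), , drop = FALSE]
  cand$s_ang <- cand$s_ang + rep(offsets, times = nrow(df))
  keep <- cand$s_ang >= -1e-9 & cand$s_ang <= rep(L, each = nOff) + 1e-9
  cand <- cand[keep, , drop = FALSE]
  cand$s_ang <- pmin(pmax(cand$s_ang, 0), rep(L, each = nOff)[keep])
  cand$provenance <- "expanded"
  cand$record_index <- seq_len(nrow(cand)) - 1L  # reassigned on merge
  ckey <- axisKey(cand$micrograph_id, cand$filament_id)
  for (k in unique(ckey)) {
    rows <- which(ckey == k)
    pts <- axisPoint(axes[[k]], cand$s_ang[rows])
    cand$x_px[rows] <- pts[, 1L] / pixel_size_ang
    cand$y_px[rows] <- pts[, 2L] / pixel_size_ang
  }
  out <- ParticleSet(cand)
  out@metadata$n_proposed <- nrow(df) * 2L * length(spec@multiples)
  out
}

#' Iterative neighbor recovery to a fixed point
#'
#' Repeats the rescue cycle: propose candidates at +/-`multiples` repeats
#' from every particle of the current curated set, verify the candidates
#' (the verifier stands in for mask-focused classification plus manual
#' inspection), merge accepted candidates, snap to the lattice and remove
#' duplicates — until the curated set stops growing or `max_rounds` is
#' reached.  Seeds always survive: the deduplication priority keeps earlier
#' records over later candidates, so the procedure is monotone (no accepted
#' record is ever lost in a later round).
#'
#' @param seeds a [ParticleSet-class] of validated seed particles.
#' @param axes a [FilamentAxisList-class].
#' @param lattice a [LatticeSpec-class].
#' @param spec an [ExpansionSpec-class].
#' @param policy a [DedupPolicy-class].
#' @param verifier function taking the candidate records (a data.frame with
#'   `micrograph_id`, `filament_id`, `s_ang`, `x_px`, `y_px`) and returning a
#'   logical acceptance vector; see [truthVerifier()].
#' @param pixel_size_ang Angstroms per pixel.
#' @return the curated [ParticleSet-class]; `metadata()$recovery_log` is a
#'   data.frame with per-round `proposed`, `accepted` and `retained` counts,
#'   plus a `converged` flag.
#' @export
iterateRecovery <- function(seeds, axes, lattice = LatticeSpec(),
                            spec = ExpansionSpec(), policy = DedupPolicy(),
                            verifier, pixel_size_ang = 1.36) {
  stopifnot(is.function(verifier))
  current <- seeds
  rounds <- data.frame(round = integer(), proposed = integer(),
                       accepted = integer(), retained = integer())
  converged <- FALSE
  if (length(seeds) == 0L) {
    md <- metadata(seeds)
    md$recovery_log <- list(rounds = rounds, converged = TRUE)
    return(ParticleSet(particleData(seeds), md))
  }
  nextIndex <- max(particleData(seeds)$record_index) + 1L
  for (round in seq_len(spec@max_rounds)) {
    cand <- expandSeeds(current, axes, lattice, spec, pixel_size_ang)
    cdf <- particleData(cand)
    acc <- if (nrow(cdf)) verifier(cdf) else logical(0)
    stopifnot(length(acc) == nrow(cdf))
    accepted <- cdf[acc, , drop = FALSE]
    if (nrow(accepted)) {
      accepted$record_index <- nextIndex + seq_len(nrow(accepted)) - 1L
      nextIndex <- nextIndex + nrow(accepted)
    }
    cur_df <- particleData(current)
    merged <- ParticleSet(rbind(cur_df[, .PARTICLE_COLUMNS, drop = FALSE],
                                accepted[, .PARTICLE_COLUMNS, drop = FALSE]),
                          metadata = metadata(current))
    merged <- snapToLattice(merged, axes, lattice,
                            pixel_size_ang = pixel_size_ang)
    merged <- deduplicate(merged, policy, pixel_size_ang = pixel_size_ang)
    retained <- length(merged) - length(current)
    rounds <- rbind(rounds, data.frame(
      round = round, proposed = metadata(cand)$n_proposed,
      accepted = nrow(accepted), retained = retained))
    current <- merged
    if (retained == 0L) { converged <- TRUE; break }
  }
  md <- metadata(current)
  md$recovery_log <- list(rounds = rounds, converged = converged)
  ParticleSet(particleData(current), md)
}
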