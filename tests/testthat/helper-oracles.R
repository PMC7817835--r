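## Independent oracles and fixture builders shared across the suite.
## Oracles deliberately use plain loops / enumeration, not package internals.

# straight axis along +x of the given length (Angstroms)
makeStraightAxis <- function(length_ang, micrograph_id = "mg1",
                             filament_id = 1L) {
  FilamentAxis(micrograph_id, filament_id,
               rbind(c(0, 0), c(length_ang, 0)))
}

# gently curved circular-arc polyline axis of given arc length and radius
makeArcAxis <- function(length_ang, radius_ang, micrograph_id = "mg1",
                        filament_id = 1L, ds = 1) {
  n <- ceiling(length_ang / ds)
  theta <- (0:n) * (ds / radius_ang)
  support <- cbind(radius_ang * sin(theta), radius_ang * (1 - cos(theta)))
  # rescale so the polyline arc length is exactly length_ang
  chord <- sum(sqrt(rowSums((support[-1, , drop = FALSE] -
                             support[-nrow(support), , drop = FALSE])^2)))
  FilamentAxis(micrograph_id, filament_id, support * (length_ang / chord))
}

# particle table at explicit arc positions on one straight axis
makeParticles <- function(s_ang, micrograph_id = "mg1", filament_id = 1L,
                          register_class = 0L, provenance = "picked",
                          pixel_size_ang = 1.36) {
  ParticleSet(data.frame(
    micrograph_id = micrograph_id, x_px = s_ang / pixel_size_ang, y_px = 0,
    filament_id = filament_id, s_ang = s_ang,
    register_class = register_class, provenance = provenance,
    stringsAsFactors = FALSE))
}

# O(n^2) greedy dedup oracle: keep record i (in priority order) iff all
# previously kept records within scope are >= d_min away
bruteDedup <- function(df, d_min_ang, scope = "same_filament",
                       pixel_size_ang = 1.36) {
  prio <- order(match(df$provenance, c("picked", "expanded")),
                df$record_index)
  scopeKey <- if (scope == "same_filament")
    paste(df$micrograph_id, df$filament_id) else df$micrograph_id
  kept <- integer(0)
  for (i in prio) {
    ok <- TRUE
    for (k in kept) {
      if (scopeKey[k] != scopeKey[i]) next
      d <- sqrt((df$x_px[i] - df$x_px[k])^2 +
                (df$y_px[i] - df$y_px[k])^2) * pixel_size_ang
      if (d < d_min_ang) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# breadth-first reachability over occupied repeat sites with edges +/-m for
# m in multiples; returns the sorted set of reachable occupied site indices
bfsReachable <- function(occupied_idx, seed_idx, multiples = c(1L, 2L)) {
  occ <- unique(occupied_idx)
  frontier <- intersect(unique(seed_idx), occ)
  visited <- frontier
  while (length(frontier)) {
    nxt <- unique(as.vector(outer(frontier,
                                  c(-multiples, multiples), "+")))
    nxt <- setdiff(intersect(nxt, occ), visited)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  sort(visited)
}

# random valid particle table for property tests
randomParticleTable <- function(n, micrographs = 2L, filaments = 3L) {
  data.frame(
    micrograph_id = sprintf("mg%02d.mrc", sample(micrographs, n, TRUE)),
    x_px = round(stats::runif(n, 0, 4096), 3),
    y_px = round(stats::runif(n, 0, 4096), 3),
    filament_id = sample(filaments, n, TRUE),
    s_ang = stats::runif(n, 0, 8000),
    register_class = sample(0:2, n, TRUE),
    provenance = sample(c("picked", "expanded"), n, TRUE),
    stringsAsFactors = FALSE)
}

# hand-built TruthTable on straight axes from a list of occupied site-index
# vectors (one element per filament), all on one micrograph
makeTruth <- function(occupied_sites, n_sites, lattice = LatticeSpec(),
                      micrograph_id = "mg1") {
  rep_ang <- repeatAng(lattice)
  axes <- list()
  rows <- list()
  for (f in seq_along(occupied_sites)) {
    L <- (n_sites[f] - 1L) * rep_ang
    ax <- makeStraightAxis(L, micrograph_id, f)
    axes[[axisKey(micrograph_id, f)]] <- ax
    j <- 0:(n_sites[f] - 1L)
    s <- j * rep_ang
    rows[[f]] <- data.frame(
      micrograph_id = micrograph_id, filament_id = f, site_index = j,
      occupied = j %in% occupied_sites[[f]], s_ang = s,
      x_px = s / 1.36, y_px = 0, stringsAsFactors = FALSE)
  }
  new("TruthTable", sites = do.call(rbind, rows),
      axes = FilamentAxisList(axes),
      meta = data.frame(micrograph_id = micrograph_id, width_px = 4096L,
                        height_px = 4096L, pixel_size_ang = 1.36),
      lattice = lattice)
}
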