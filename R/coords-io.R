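#' @include AllClasses.R star.R
NULL

## STAR tags for the canonical particle columns (RELION particle-table
## dialect); package-specific fields use an _oda prefix so external tools
## ignore them gracefully.
.STAR_PARTICLE_TAGS <- c(
  micrograph_id  = "_rlnMicrographName",
  x_px           = "_rlnCoordinateX",
  y_px           = "_rlnCoordinateY",
  filament_id    = "_rlnHelicalTubeID",
  register_class = "_rlnClassNumber",
  s_ang          = "_odaArcLengthAng",
  provenance     = "_odaProvenance",
  record_index   = "_odaRecordIndex")

.ioFormat <- function(path, format) {
  if (!identical(format, "auto")) return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext, star = "star", csv = "csv", tsv = "tsv",
         stop("cannot infer table format from extension '", ext,
              "'; pass format=", call. = FALSE))
}

#' Read a particle table
#'
#' Reads particle coordinate metadata from a STAR file (RELION particle-table
#' dialect) or its CSV/TSV mirror.  Required columns are the micrograph name
#' and the x/y coordinates; filament id, class label, arc-length, provenance
#' and record index are optional and filled with defaults when absent
#' (`filament_id` defaults to a per-micrograph single filament, flagged in
#' `metadata()`).  Row order is preserved; `record_index` is assigned
#' `0:(n-1)` when the file does not carry it.  Unknown STAR columns are kept
#' verbatim as extra columns and survive a write/read round-trip.
#'
#' @param path file to read.
#' @param format `"star"`, `"csv"`, `"tsv"`, or `"auto"` (by extension).
#' @return a [ParticleSet-class].
#' @seealso [writeParticles()]
#' @export
readParticles <- function(path, format = c("auto", "star", "csv", "tsv")) {
  format <- .ioFormat(path, match.arg(format))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "star") {
    blocks <- .starReadBlocks(path)
    if (!length(blocks)) stop("no data block in STAR file ", path, call. = FALSE)
    raw <- if ("particles" %in% names(blocks)) blocks[["particles"]]
           else blocks[[1L]]
    tags <- .STAR_PARTICLE_TAGS
    req <- tags[c("micrograph_id", "x_px", "y_px")]
    missing <- setdiff(req, names(raw))
    if (length(missing))
      stop("STAR particle table lacks required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    df <- data.frame(micrograph_id = as.character(raw[[tags["micrograph_id"]]]),
                     stringsAsFactors = FALSE)
    df$x_px <- .starNumeric(raw, tags["x_px"], "x coordinate")
    df$y_px <- .starNumeric(raw, tags["y_px"], "y coordinate")
    meta <- list()
    if (tags["filament_id"] %in% names(raw))
      df$filament_id <- .starNumeric(raw, tags["filament_id"], "filament id",
                                     integer = TRUE)
    if (tags["register_class"] %in% names(raw))
      df$register_class <- .starNumeric(raw, tags["register_class"],
                                        "class label", integer = TRUE)
    if (tags["s_ang"] %in% names(raw))
      df$s_ang <- .starNumeric(raw, tags["s_ang"], "arc length")
    if (tags["provenance"] %in% names(raw))
      df$provenance <- as.character(raw[[tags["provenance"]]])
    if (tags["record_index"] %in% names(raw))
      df$record_index <- .starNumeric(raw, tags["record_index"],
                                      "record index", integer = TRUE)
    extra <- setdiff(names(raw), tags)
    for (col in extra) df[[col]] <- raw[[col]]
    ParticleSet(df, metadata = meta)
  } else {
    sep <- if (format == "csv") "," else "\t"
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             na.strings = c("NA", "<NA>"))
    missing <- setdiff(c("micrograph_id", "x_px", "y_px"), names(raw))
    if (length(missing))
      stop("particle table lacks required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    for (col in intersect(c("x_px", "y_px", "s_ang"), names(raw))) {
      val <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & is.na(val) & raw[[col]] != "NA")
      if (length(bad))
        stop("unparsable numeric value in column '", col, "', row ", bad[1L],
             call. = FALSE)
      raw[[col]] <- val
    }
    ParticleSet(raw)
  }
}

#' Write a particle table
#'
#' Writes a [ParticleSet-class] to STAR or CSV/TSV.  Numeric coordinates are
#' written at full double precision so that [readParticles()] is an exact
#' inverse on all supported fields; extra (unknown) columns round-trip
#' verbatim.
#'
#' @param x a [ParticleSet-class].
#' @param path output file.
#' @param format `"star"`, `"csv"`, `"tsv"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
writeParticles <- function(x, path, format = c("auto", "star", "csv", "tsv")) {
  stopifnot(is(x, "ParticleSet"))
  format <- .ioFormat(path, match.arg(format))
  df <- particleData(x)
  if (format == "star") {
    out <- df[, intersect(.PARTICLE_COLUMNS, names(df)), drop = FALSE]
    names(out) <- .STAR_PARTICLE_TAGS[names(out)]
    extra <- setdiff(names(df), .PARTICLE_COLUMNS)
    for (col in extra) out[[col]] <- df[[col]]
    .starWriteBlock(out, path, block = "particles")
  } else {
    sep <- if (format == "csv") "," else "\t"
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], .starFormatNum)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE, na = "<NA>")
  }
  invisible(path)
}

.validatePicks <- function(picks) {
  req <- c("micrograph_id", "filament_id", "start_x_px", "start_y_px",
           "end_x_px", "end_y_px")
  missing <- setdiff(req, names(picks))
  if (length(missing))
    stop("pick table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  same <- picks$start_x_px == picks$end_x_px &
          picks$start_y_px == picks$end_y_px
  if (any(same))
    stop("filament pick with coincident start and end: micrograph '",
         picks$micrograph_id[which(same)[1L]], "', filament ",
         picks$filament_id[which(same)[1L]], call. = FALSE)
  key <- paste(picks$micrograph_id, picks$filament_id)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate filament_id within a micrograph: ", d, call. = FALSE)
  }
  picks$micrograph_id <- as.character(picks$micrograph_id)
  picks$filament_id <- as.integer(picks$filament_id)
  for (col in c("start_x_px", "start_y_px", "end_x_px", "end_y_px"))
    picks[[col]] <- as.numeric(picks[[col]])
  rownames(picks) <- NULL
  picks[, req]
}

#' Read filament picks
#'
#' A filament pick is the start and end coordinate of a manually picked
#' filament on a micrograph.  Two on-disk layouts are supported: a CSV/TSV
#' with one row per filament (`micrograph_id, filament_id, start_x_px,
#' start_y_px, end_x_px, end_y_px`), and a STAR coordinate file with two
#' consecutive rows (start then end) per filament, as written by helical
#' picking tools.
#'
#' @param path file to read.
#' @param format `"star"`, `"csv"`, `"tsv"`, or `"auto"`.
#' @return data.frame of picks, one row per filament; `filament_id` is unique
#'   within each micrograph.
#' @export
readPicks <- function(path, format = c("auto", "star", "csv", "tsv")) {
  format <- .ioFormat(path, match.arg(format))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "star") {
    blocks <- .starReadBlocks(path)
    raw <- if ("picks" %in% names(blocks)) blocks[["picks"]] else blocks[[1L]]
    req <- c("_rlnMicrographName", "_rlnHelicalTubeID",
             "_rlnCoordinateX", "_rlnCoordinateY")
    missing <- setdiff(req, names(raw))
    if (length(missing))
      stop("STAR pick table lacks column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (nrow(raw) %% 2L != 0L)
      stop("STAR pick table must have two rows (start, end) per filament",
           call. = FALSE)
    x <- .starNumeric(raw, "_rlnCoordinateX", "x coordinate")
    y <- .starNumeric(raw, "_rlnCoordinateY", "y coordinate")
    odd <- seq(1L, nrow(raw), by = 2L)
    picks <- data.frame(
      micrograph_id = as.character(raw[["_rlnMicrographName"]][odd]),
      filament_id = .starNumeric(raw, "_rlnHelicalTubeID", "filament id",
                                 integer = TRUE)[odd],
      start_x_px = x[odd], start_y_px = y[odd],
      end_x_px = x[odd + 1L], end_y_px = y[odd + 1L],
      stringsAsFactors = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    picks <- utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
  }
  .validatePicks(picks)
}

#' Write filament picks
#'
#' @param picks data.frame of picks (see [readPicks()] for the columns).
#' @param path output file.
#' @param format `"star"`, `"csv"`, `"tsv"`, or `"auto"`.
#' @return `path`, invisibly.
#' @export
writePicks <- function(picks, path, format = c("auto", "star", "csv", "tsv")) {
  picks <- .validatePicks(picks)
  format <- .ioFormat(path, match.arg(format))
  if (format == "star") {
    n <- nrow(picks)
    out <- data.frame(
      `_rlnMicrographName` = rep(picks$micrograph_id, each = 2L),
      `_rlnHelicalTubeID` = rep(picks$filament_id, each = 2L),
      `_rlnCoordinateX` = as.vector(rbind(picks$start_x_px, picks$end_x_px)),
      `_rlnCoordinateY` = as.vector(rbind(picks$start_y_px, picks$end_y_px)),
      check.names = FALSE, stringsAsFactors = FALSE)
    .starWriteBlock(out, path, block = "picks")
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- picks
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], .starFormatNum)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
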