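## Minimal STAR reader/writer for the particle-table dialect used by
## single-particle processing software: one or more data_ blocks, each either
## a loop_ table or simple tag-value pairs.  Fields are whitespace-delimited
## and contain no embedded whitespace (the convention for particle metadata).

.starReadBlocks <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  blocks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (startsWith(lines[i], "data_")) {
      blockName <- sub("^data_", "", lines[i])
      i <- i + 1L
      ## skip to loop_ or tag-value pairs
      tags <- character()
      rows <- character()
      inLoop <- FALSE
      while (i <= n && !startsWith(lines[i], "data_")) {
        ln <- lines[i]
        if (identical(ln, "loop_")) {
          inLoop <- TRUE
        } else if (startsWith(ln, "_")) {
          tag <- sub("^(\\S+).*$", "\\1", ln)
          tags <- c(tags, tag)
          if (!inLoop) {
            val <- trimws(sub("^\\S+\\s*", "", ln))
            rows <- c(rows, val)
          }
        } else {
          rows <- c(rows, ln)
        }
        i <- i + 1L
      }
      if (length(tags)) {
        if (inLoop) {
          cells <- strsplit(rows, "\\s+")
          bad <- which(lengths(cells) != length(tags))
          if (length(bad))
            stop("STAR block 'data_", blockName, "': row ", bad[1L],
                 " has ", lengths(cells)[bad[1L]], " fields, expected ",
                 length(tags), call. = FALSE)
          df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
        } else {
          df <- as.data.frame(as.list(rows), stringsAsFactors = FALSE)
        }
        if (nrow(df) == 0L || !length(rows))
          df <- as.data.frame(matrix(character(), 0L, length(tags)),
                              stringsAsFactors = FALSE)
        names(df) <- tags
        blocks[[blockName]] <- df
      } else {
        blocks[[blockName]] <- data.frame()
      }
    } else {
      i <- i + 1L
    }
  }
  blocks
}

.starFormatNum <- function(x) {
  ## %.17g round-trips IEEE doubles exactly
  ifelse(is.na(x), "<NA>", sprintf("%.17g", x))
}

.starWriteBlock <- function(df, path, block = "particles", append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  tags <- names(df)
  writeLines(sprintf("%s #%d", tags, seq_along(tags)), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.double(col)) .starFormatNum(col)
      else if (is.integer(col)) ifelse(is.na(col), "<NA>", as.character(col))
      else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

.starNumeric <- function(df, col, what, integer = FALSE) {
  raw <- df[[col]]
  raw[raw == "<NA>"] <- NA
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(val))
  if (length(bad))
    stop("unparsable numeric value in column '", col, "' (", what,
         "), row ", bad[1L], ": '", raw[bad[1L]], "'", call. = FALSE)
  if (integer) as.integer(round(val)) else val
}
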