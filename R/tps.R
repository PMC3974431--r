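#' Read landmark configurations from a TPS file
#'
#' Parses the TPS dialect written by the tpsUtil/tpsDig family of tools: one
#' block per specimen starting with `LM=k`, followed by k coordinate lines
#' (`x y`), then optional `ID=`, `IMAGE=` and `SCALE=` lines. `ID=` is
#' preferred for the specimen identifier, falling back to `IMAGE=` and then to
#' a positional id. Curve data (`CURVES=` / `POINTS=` and their coordinate
#' lines) is skipped with a warning; only fixed landmarks are read. When a
#' `SCALE=` factor is present the coordinates are multiplied by it at ingest,
#' so all specimens are in the digitizer's physical units.
#'
#' Missing landmarks are not supported: a coordinate pair of exactly
#' `-1 -1` (the usual missing-data sentinel) or any non-finite value is a
#' hard error, because the superimposition requires complete configurations.
#'
#' @param path path to a TPS text file.
#' @param metadata optional path to a sidecar CSV with header
#'   `specimen_id,group,side` supplying group labels (TPS itself has no
#'   grouping field); merged onto the result by `specimen_id`.
#' @return a landmark tibble (see [landmark_data()]); columns `specimen_id`,
#'   `group`, `side`, `landmark`, `x`, `y`, `scale`.
#' @export
read_tps <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("TPS file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)

  blocks <- list()
  i <- 1L
  block_no <- 0L
  saw_curves <- FALSE
  n_lines <- length(lines)
  while (i <= n_lines) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", line, ignore.case = TRUE)) {
      stop(sprintf("line %d: expected an LM= block header, got '%s'", i, line),
           call. = FALSE)
    }
    block_no <- block_no + 1L
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", line,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1) {
      stop(sprintf("line %d: malformed LM= header", i), call. = FALSE)
    }
    i <- i + 1L
    coords <- matrix(NA_real_, nrow = k, ncol = 2)
    for (j in seq_len(k)) {
      if (i > n_lines) {
        stop(sprintf("block %d: file ends before %d coordinate lines", block_no, k),
             call. = FALSE)
      }
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      xy <- suppressWarnings(as.numeric(parts))
      if (length(xy) != 2 || anyNA(xy)) {
        stop(sprintf("line %d: malformed coordinate line '%s'", i,
                     trimws(lines[i])), call. = FALSE)
      }
      coords[j, ] <- xy
      i <- i + 1L
    }
    id <- NULL; image <- NULL; scale <- NA_real_
    # trailing keyword lines (and curve data to skip) until next LM=
    while (i <= n_lines) {
      line <- trimws(lines[i])
      if (grepl("^LM\\s*=", line, ignore.case = TRUE)) break
      if (grepl("^ID\\s*=", line, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", line, ignore.case = TRUE)
      } else if (grepl("^IMAGE\\s*=", line, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", line, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", line, ignore.case = TRUE)) {
        scale <- suppressWarnings(
          as.numeric(sub("^SCALE\\s*=\\s*", "", line, ignore.case = TRUE)))
        if (is.na(scale) || scale <= 0) {
          stop(sprintf("line %d: malformed SCALE= line", i), call. = FALSE)
        }
      } else if (grepl("^CURVES\\s*=", line, ignore.case = TRUE)) {
        saw_curves <- TRUE
      } else if (grepl("^POINTS\\s*=", line, ignore.case = TRUE)) {
        saw_curves <- TRUE
        m <- suppressWarnings(as.integer(sub("^POINTS\\s*=\\s*", "", line,
                                             ignore.case = TRUE)))
        if (!is.na(m) && m > 0) i <- i + m  # skip curve coordinate lines
      } else if (line != "" && !grepl("=", line, fixed = TRUE)) {
        stop(sprintf("line %d: unexpected content '%s'", i, line),
             call. = FALSE)
      }
      i <- i + 1L
    }
    missing_lm <- !is.finite(coords) |
      (coords[, 1] == -1 & coords[, 2] == -1)
    if (any(missing_lm)) {
      stop(sprintf("block %d: missing landmark(s) (sentinel -1 -1 or non-finite); complete configurations are required",
                   block_no), call. = FALSE)
    }
    if (!is.na(scale)) coords <- coords * scale
    spec_id <- if (!is.null(id)) id else if (!is.null(image)) image
      else sprintf("specimen_%03d", block_no)
    blocks[[block_no]] <- landmark_data(coords, spec_id, scale = scale)
  }
  if (block_no == 0L) stop("TPS file contains no LM= blocks", call. = FALSE)
  if (saw_curves) {
    warning("TPS file contains CURVES=/POINTS= data; curve points were ignored (only fixed landmarks are read)",
            call. = FALSE)
  }
  ks <- vapply(blocks, function(b) max(b$landmark), integer(1))
  if (length(unique(ks)) > 1) {
    bad <- which(ks != ks[1])[1]
    stop(sprintf(
      "mixed landmark counts: block %d ('%s') has LM=%d but block 1 has LM=%d",
      bad, blocks[[bad]]$specimen_id[1], ks[bad], ks[1]), call. = FALSE)
  }
  out <- dplyr::bind_rows(blocks)
  if (anyDuplicated(unique(out$specimen_id)) ||
      length(unique(out$specimen_id)) != block_no) {
    stop("specimen identifiers are not unique within the TPS file",
         call. = FALSE)
  }
  if (!is.null(metadata)) out <- join_metadata(out, metadata)
  validate_landmarks(out)
  out
}

#' Attach group/side metadata from a sidecar CSV
#'
#' @param data a landmark tibble.
#' @param path CSV file with header `specimen_id,group,side`.
#' @return `data` with `group` and `side` filled in from the CSV.
#' @export
join_metadata <- function(data, path) {
  if (!file.exists(path)) {
    stop("metadata CSV not found: ", path, call. = FALSE)
  }
  meta <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  needed <- c("specimen_id", "group", "side")
  if (!all(needed %in% names(meta))) {
    stop("metadata CSV must have columns specimen_id,group,side",
         call. = FALSE)
  }
  meta <- dplyr::distinct(meta[, needed])
  out <- data
  out$group <- NULL; out$side <- NULL
  out <- dplyr::left_join(out, meta, by = "specimen_id")
  out$side[is.na(out$side)] <- "unknown"
  dplyr::relocate(out, "specimen_id", "group", "side")
}

#' Write landmark configurations to a TPS file
#'
#' One block per specimen, in first-appearance order: `LM=k`, k full-precision
#' coordinate lines, `ID=`, and `SCALE=` when a scale is recorded. When a
#' scale is present the stored coordinates are divided by it before writing,
#' mirroring [read_tps()]'s multiply-at-ingest convention so that
#' read -> write -> read is the identity.
#'
#' @param data a non-empty landmark tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(data, path) {
  if (is.null(data) || nrow(data) == 0) {
    stop("refusing to write an empty landmark dataset", call. = FALSE)
  }
  sp <- lm_split(data)
  has_scale <- "scale" %in% names(sp$meta)
  fmt <- function(v) sprintf("%.17g", v)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (idx in seq_along(sp$ids)) {
    m <- sp$coords[, , idx]
    scale <- if (has_scale) sp$meta$scale[idx] else NA_real_
    if (!is.na(scale)) m <- m / scale
    writeLines(sprintf("LM=%d", sp$k), con)
    writeLines(paste(fmt(m[, 1]), fmt(m[, 2])), con)
    writeLines(sprintf("ID=%s", sp$ids[idx]), con)
    if (!is.na(scale)) writeLines(sprintf("SCALE=%.17g", scale), con)
  }
  invisible(path)
}
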