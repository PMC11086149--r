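# Reading and writing the pipeline's two on-disk formats — delimited gait
# tables (one row per second) and GPX 1.1 traces — and timestamp alignment
# between them.
#
# Gait table schema (comma separated, header required):
#   timestamp, speed, step_length, vertical_oscillation, stance_time,
#   leg_stiffness, cadence
# Timestamps are seconds since epoch (UTC); both gait tables and GPX files
# derive their clocks from the same device, so alignment needs only a
# nearest-neighbour tolerance, not a skew correction.

gait_table_columns <- function() c("timestamp", gait_metrics(), "cadence")

#' Write per-second gait records as delimited text
#'
#' @param records Tibble of gait records (the schema above).
#' @param path Output file path.
#' @export
write_gait_table <- function(records, path) {
  cols <- gait_table_columns()
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(as.data.frame(records)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a delimited gait table
#'
#' Rows with non-numeric or missing values are counted and skipped with a
#' warning naming the file and line; a missing required column is a hard
#' error naming the column. Records are returned sorted by timestamp.
#'
#' @param path Path to a file written by [write_gait_table()] (or matching
#'   its schema).
#' @return A tibble of gait records.
#' @export
read_gait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  cols <- gait_table_columns()
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("gait table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(numeric(0), 0, length(cols))), cols))
    return(out)
  }
  num <- suppressWarnings(
    as.data.frame(lapply(raw[cols], as.numeric), check.names = FALSE))
  bad <- !stats::complete.cases(num)
  if (any(bad)) {
    warning("skipped ", sum(bad), " malformed row(s) in ", path,
            " (lines ", paste(utils::head(which(bad) + 1, 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", ")", call. = FALSE)
  }
  out <- tibble::as_tibble(num[!bad, , drop = FALSE])
  out[order(out$timestamp), ]
}

epoch_to_iso8601 <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ")
}

iso8601_to_epoch <- function(s) {
  as.numeric(as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
}

#' Write a trace as a GPX 1.1 file
#'
#' One track, one track segment, one `trkpt` per sample with `lat`/`lon`
#' attributes (7 decimal places) and `ele`/`time` children.
#'
#' @param trace Tibble with `time`, `lat`, `lon` and optionally `ele`.
#' @param path Output file path.
#' @param creator Creator string for the GPX header.
#' @export
write_gpx <- function(trace, path, creator = "gaitoverlap") {
  pts <- vapply(seq_len(nrow(trace)), function(i) {
    ele <- if ("ele" %in% names(trace) && is.finite(trace$ele[i])) {
      sprintf("<ele>%.3f</ele>", trace$ele[i])
    } else ""
    sprintf('<trkpt lat="%.7f" lon="%.7f">%s<time>%s</time></trkpt>',
            trace$lat[i], trace$lon[i], ele, epoch_to_iso8601(trace$time[i]))
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<gpx version="1.1" creator="', creator,
    '" xmlns="http://www.topografix.com/GPX/1/1">\n',
    "<trk><trkseg>\n", paste(pts, collapse = "\n"),
    "\n</trkseg></trk>\n</gpx>\n"
  )
  writeLines(doc, path)
  invisible(path)
}

#' Read a GPX 1.1 file
#'
#' Track points are returned in document order across all track segments,
#' with the originating segment recorded in `trkseg`. Points without an
#' elevation are retained with `ele = NA`. Malformed XML is a hard error; a
#' GPX document with no track points returns an empty trace with a warning.
#'
#' @param path Path to a GPX file.
#' @return A tibble with columns `time`, `lat`, `lon`, `ele`, `trkseg`.
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)     # malformed XML errors here
  xml2::xml_ns_strip(doc)
  segs <- xml2::xml_find_all(doc, ".//trkseg")
  rows <- list()
  for (s in seq_along(segs)) {
    pts <- xml2::xml_find_all(segs[[s]], ".//trkpt")
    if (length(pts) == 0) next
    ele <- vapply(pts, function(p) {
      e <- xml2::xml_find_first(p, "./ele")
      if (inherits(e, "xml_missing")) NA_real_ else
        as.numeric(xml2::xml_text(e))
    }, numeric(1))
    tm <- vapply(pts, function(p) {
      t <- xml2::xml_find_first(p, "./time")
      if (inherits(t, "xml_missing")) NA_real_ else
        iso8601_to_epoch(xml2::xml_text(t))
    }, numeric(1))
    rows[[length(rows) + 1]] <- tibble::tibble(
      time = tm,
      lat = as.numeric(xml2::xml_attr(pts, "lat")),
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      ele = ele, trkseg = s
    )
  }
  if (length(rows) == 0) {
    warning("GPX file ", path, " contains no track points", call. = FALSE)
    return(tibble::tibble(time = numeric(0), lat = numeric(0),
                          lon = numeric(0), ele = numeric(0),
                          trkseg = integer(0)))
  }
  out <- do.call(rbind, rows)
  bad_lat <- abs(out$lat) > 90
  bad_lon <- abs(out$lon) > 180
  if (any(bad_lat | bad_lon, na.rm = TRUE)) {
    stop("GPX file ", path, " has out-of-range coordinates", call. = FALSE)
  }
  out
}

#' Align gait records with a GNSS trace by timestamp
#'
#' Nearest-neighbour match within a tolerance (default 0.5 s, both files
#' sharing the on-device clock), each trace point used at most once; when
#' two records claim the same trace point the closer one wins. Zero matches
#' with nonempty inputs is a warning, not an error.
#'
#' @param gait Tibble of gait records sorted by `timestamp`.
#' @param trace Tibble of trace points sorted by `time`.
#' @param tolerance Maximum |time difference| for a match, seconds.
#' @param run_id,subject_id,condition Identifiers carried on the result.
#' @return An object of class `aligned_run`: a list with `data` (the gait
#'   records with matched `lat`, `lon`, `ele` columns, NA where unmatched),
#'   `unmatched_fraction`, and the identifiers.
#' @export
align_run <- function(gait, trace, tolerance = 0.5, run_id = NA,
                      subject_id = NA, condition = NA) {
  n <- nrow(gait)
  match_idx <- rep(NA_integer_, n)
  if (n > 0 && nrow(trace) > 0) {
    tt <- trace$time
    pos <- findInterval(gait$timestamp, tt)
    lo <- pmax(pos, 1)
    hi <- pmin(pos + 1, length(tt))
    d_lo <- abs(gait$timestamp - tt[lo])
    d_hi <- abs(gait$timestamp - tt[hi])
    cand <- ifelse(d_hi < d_lo, hi, lo)
    dist <- pmin(d_lo, d_hi)
    ok <- dist <= tolerance
    # resolve duplicate claims on one trace point: closer record wins
    ord <- order(dist)
    used <- logical(length(tt))
    for (i in ord) {
      if (!ok[i]) next
      if (!used[cand[i]]) {
        match_idx[i] <- cand[i]
        used[cand[i]] <- TRUE
      }
    }
    if (all(is.na(match_idx))) {
      warning("no gait records matched the trace within the ", tolerance,
              " s tolerance", call. = FALSE)
    }
  }
  data <- gait
  data$lat <- ifelse(is.na(match_idx), NA_real_, trace$lat[match_idx])
  data$lon <- ifelse(is.na(match_idx), NA_real_, trace$lon[match_idx])
  data$ele <- if ("ele" %in% names(trace)) {
    ifelse(is.na(match_idx), NA_real_, trace$ele[match_idx])
  } else NA_real_
  data$trace_index <- match_idx
  structure(
    list(run_id = run_id, subject_id = subject_id, condition = condition,
         data = data,
         unmatched_fraction = if (n == 0) 0 else mean(is.na(match_idx))),
    class = "aligned_run"
  )
}
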