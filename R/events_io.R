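#' Construct an event table
#'
#' An event table is the basic input of the package: a time-ordered collection
#' of point events, each with a planar or geographic location and a timestamp.
#' It is stored as a `data.frame` with columns `x`, `y`, `t` (plus any extra
#' per-event attributes such as detection confidence) and a
#' `coordinate_system` attribute.
#'
#' @param x,y Numeric event coordinates. For `coordinate_system = "lonlat"`,
#'   `x` is longitude and `y` latitude, in decimal degrees.
#' @param t Event timestamps: integer steps or epoch seconds. Any totally
#'   ordered numeric works; the package only uses the order (and, for
#'   snapshotting, differences).
#' @param ... Optional extra per-event columns (equal length vectors).
#' @param coordinate_system Either `"planar"` or `"lonlat"`. Controls which
#'   distance metric is meaningful for `d_max` in [build_chronnet()].
#'
#' @return An object of class `event_table` (a `data.frame`).
#' @examples
#' ev <- event_table(x = c(0, 1, 2), y = c(0, 0, 1), t = 1:3)
#' n_events(ev)
#' @export
event_table <- function(x, y, t, ..., coordinate_system = c("planar", "lonlat")) {
  coordinate_system <- match.arg(coordinate_system)
  x <- as.numeric(x); y <- as.numeric(y); t <- as.numeric(t)
  if (length(x) != length(y) || length(x) != length(t)) {
    stop("x, y and t must have equal length")
  }
  if (length(t) && (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(t)))) {
    stop("event coordinates and timestamps must be finite")
  }
  df <- data.frame(x = x, y = y, t = t, ...)
  structure(df,
            coordinate_system = coordinate_system,
            class = c("event_table", "data.frame"))
}

#' @rdname event_table
#' @param table An `event_table`.
#' @export
n_events <- function(table) nrow(table)

#' @rdname event_table
#' @export
coordinate_system <- function(table) {
  attr(table, "coordinate_system") %||% "planar"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %d events (%s coordinates)\n",
              nrow(x), coordinate_system(x)))
  if (nrow(x)) {
    cat(sprintf("  t range: [%s, %s]\n", format(min(x$t)), format(max(x$t))))
    print(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat(sprintf("  ... %d more events\n", nrow(x) - 6L))
  }
  invisible(x)
}

as_event_table <- function(df, coordinate_system = "planar") {
  stopifnot(all(c("x", "y", "t") %in% names(df)))
  structure(as.data.frame(df, row.names = NULL),
            coordinate_system = coordinate_system,
            class = c("event_table", "data.frame"))
}

#' Read an event stream from delimited text
#'
#' Reads a delimited (comma or tab) text file with a header row into an
#' [event_table()]. Column names are mapped through `column_map`, so files
#' whose coordinate/time columns have other names can be ingested without
#' rewriting them. Records whose mapped fields fail to parse as numbers are
#' collected into a validation report (attached as the `"bad_records"`
#' attribute, with line numbers) rather than silently dropped; parsing
#' continues past them.
#'
#' Timestamps may be integers or ISO dates/date-times; dates are converted to
#' epoch seconds (UTC) so that time is always an ordered numeric key.
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Named character vector mapping internal names (`x`, `y`,
#'   `t`) to column names in the file. Defaults to identity.
#' @param coordinate_system `"planar"` or `"lonlat"`.
#' @param sep Field separator; `NULL` (default) tries comma then tab.
#' @return An `event_table`, sorted by `t` via [sort_events()]. If any records
#'   were invalid, attribute `"bad_records"` holds a data.frame of line
#'   numbers and reasons.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("x,y,t", "0,0,1", "1,1,2"), f)
#' read_events(f)
#' @export
read_events <- function(path, column_map = c(x = "x", y = "y", t = "t"),
                        coordinate_system = c("planar", "lonlat"), sep = NULL) {
  coordinate_system <- match.arg(coordinate_system)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (length(header) && grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (nrow(raw) == 0L) {
    return(event_table(numeric(), numeric(), numeric(),
                       coordinate_system = coordinate_system))
  }
  for (nm in c("x", "y", "t")) {
    col <- column_map[[nm]] %||% nm
    if (!col %in% names(raw)) {
      stop(sprintf("configuration error: column '%s' (mapped to %s) not in file %s",
                   col, nm, path))
    }
  }
  xs <- parse_numeric_field(raw[[column_map[["x"]] %||% "x"]])
  ys <- parse_numeric_field(raw[[column_map[["y"]] %||% "y"]])
  ts <- parse_time_field(raw[[column_map[["t"]] %||% "t"]])
  bad <- which(is.na(xs) | is.na(ys) | is.na(ts))
  report <- NULL
  if (length(bad)) {
    reason <- vapply(bad, function(i) {
      fields <- c(x = is.na(xs[i]), y = is.na(ys[i]), t = is.na(ts[i]))
      paste("unparseable", paste(names(fields)[fields], collapse = ","))
    }, character(1))
    # +1 for the header line: report line numbers as they appear in the file
    report <- data.frame(line = bad + 1L, reason = reason)
    keep <- setdiff(seq_len(nrow(raw)), bad)
    xs <- xs[keep]; ys <- ys[keep]; ts <- ts[keep]
  }
  tab <- event_table(xs, ys, ts, coordinate_system = coordinate_system)
  tab <- sort_events(tab)
  attr(tab, "bad_records") <- report
  tab
}

parse_numeric_field <- function(v) suppressWarnings(as.numeric(v))

# Integer steps, epoch seconds, ISO dates or ISO date-times -> numeric key.
parse_time_field <- function(v) {
  num <- suppressWarnings(as.numeric(v))
  if (!anyNA(num)) return(num)
  out <- num
  todo <- which(is.na(num) & !is.na(v) & nzchar(v))
  for (i in todo) {
    out[i] <- tryCatch(
      as.numeric(as.POSIXct(v[i], tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                           "%Y-%m-%d %H:%M:%S",
                                           "%Y-%m-%d"))),
      error = function(e) NA_real_)
  }
  out
}

#' Write an event table as delimited text
#'
#' Writes columns `x,y,t` plus any extra attribute columns as comma-delimited
#' text with a header, the inverse of [read_events()].
#'
#' @param table An `event_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sort events chronologically
#'
#' Stable sort by timestamp: events sharing a timestamp keep their input
#' order, which matters downstream when parallel (same-timestamp) events are
#' grouped. Idempotent.
#'
#' @param table An `event_table`.
#' @return The same table, ordered by `t`.
#' @export
sort_events <- function(table) {
  if (nrow(table) <= 1L) return(table)
  ord <- order(table$t)               # order() is a stable sort
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, coordinate_system = coordinate_system(table),
            class = class(table))
}

#' Read MODIS MCD14ML-style active-fire records
#'
#' Parses the global active-fire location dialect: one detection per record
#' with latitude, longitude, acquisition date and time, a percent confidence
#' and a type code (0 = presumed vegetation fire; other codes mark static
#' sources such as active volcanoes or gas flares). Both whitespace- and
#' comma-delimited files with a header are accepted; column names are matched
#' case-insensitively with common aliases (`lat`/`latitude`, `lon`/`long`/
#' `longitude`, `YYYYMMDD`/`acq_date`/`date`, `HHMM`/`acq_time`/`time`,
#' `conf`/`confidence`, `type`).
#'
#' Only records with confidence *strictly greater* than `min_confidence` are
#' retained. Keeping every type code (the default) allows static outlier
#' sources to flow through to outlier detection downstream.
#'
#' @param path Path to the fire-record file.
#' @param min_confidence Percent confidence threshold; records must exceed it
#'   strictly. Default 75.
#' @param keep_types `"all"` or a vector of type codes to retain.
#' @return An `event_table` with `coordinate_system = "lonlat"`, `x` =
#'   longitude, `y` = latitude, `t` = acquisition epoch seconds (UTC), and
#'   extra columns `confidence` and `type`.
#' @export
read_modis_fire <- function(path, min_confidence = 75, keep_types = "all") {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!length(header)) {
    return(as_event_table(
      data.frame(x = numeric(), y = numeric(), t = numeric(),
                 confidence = numeric(), type = integer()),
      coordinate_system = "lonlat"))
  }
  sep <- if (grepl(",", header)) "," else ""
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(names(raw))
  pick <- function(aliases) {
    hit <- intersect(aliases, names(raw))
    if (!length(hit)) {
      stop("unrecognized fire-record dialect: need one of {",
           paste(aliases, collapse = ", "), "} in ", path)
    }
    raw[[hit[1L]]]
  }
  if (nrow(raw) == 0L) {
    return(as_event_table(
      data.frame(x = numeric(), y = numeric(), t = numeric(),
                 confidence = numeric(), type = integer()),
      coordinate_system = "lonlat"))
  }
  lat  <- as.numeric(pick(c("lat", "latitude")))
  lon  <- as.numeric(pick(c("lon", "long", "longitude")))
  date <- pick(c("yyyymmdd", "acq_date", "date"))
  tim  <- pick(c("hhmm", "acq_time", "time"))
  conf <- as.numeric(pick(c("conf", "confidence")))
  type <- as.integer(pick("type"))
  t <- modis_timestamp(date, tim)
  keep <- conf > min_confidence
  if (!identical(keep_types, "all")) keep <- keep & type %in% keep_types
  keep <- keep & !is.na(t) & is.finite(lat) & is.finite(lon)
  out <- data.frame(x = lon[keep], y = lat[keep], t = t[keep],
                    confidence = conf[keep], type = type[keep])
  sort_events(as_event_table(out, coordinate_system = "lonlat"))
}

# YYYYMMDD (or YYYY-MM-DD) date + HHMM time -> epoch seconds UTC
modis_timestamp <- function(date, tim) {
  date <- gsub("-", "", as.character(date))
  tim <- sprintf("%04d", suppressWarnings(as.integer(as.character(tim))))
  as.numeric(suppressWarnings(
    as.POSIXct(paste0(date, tim), format = "%Y%m%d%H%M", tz = "UTC")))
}
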