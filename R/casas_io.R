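#' Read a CASAS-style annotated sensor event log
#'
#' Parses whitespace-delimited smart-home event logs in the CASAS dialect:
#' one event per line with four mandatory fields (date, time, sensor id,
#' sensor status) and optionally two annotation fields (activity name and a
#' `begin`/`end` marker). Runs of spaces and tabs both delimit fields, since
#' real logs mix them.
#'
#' @param input Path to a log file, or a character vector of lines (anything
#'   with more than one element, or one element containing a newline, is
#'   treated as the text itself).
#' @param exclude_prefix Optional character vector of sensor-id prefixes to
#'   drop while reading (e.g. `"T"` to discard temperature sensors). Default
#'   keeps every sensor.
#'
#' @return A [tibble::tibble] of class `casas_events` with one row per event
#'   and columns `date` (`Date`), `time` (character, `HH:MM:SS` with optional
#'   fractional seconds), `sensor`, `status`, `activity`, `marker` (the last
#'   two `NA` when the line carries no annotation) and `line` (source line
#'   number, for error reporting).
#'
#' @details Annotation fields must come in pairs: a line with five fields, or
#'   a marker other than `begin`/`end`, is an error naming the offending line.
#'   Timestamps are expected to be non-decreasing; violations are reported as
#'   a warning (real deployments occasionally log out of order) and the rows
#'   are kept in file order.
#'
#' @seealso [write_events()], [segment_activities()]
#' @export
#' @examples
#' ev <- parse_events(c(
#'   "2010-11-04 05:40:51.303739 M004 ON Bed_to_Toilet begin",
#'   "2010-11-04 05:40:52.342105 M005 OFF"
#' ))
#' ev$sensor
parse_events <- function(input, exclude_prefix = NULL) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(empty_events())
  }

  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  bad <- nf != 4 & nf != 6
  if (any(bad)) {
    stop("malformed event line ", keep[which(bad)[1]], ": expected 4 or 6 ",
         "whitespace-delimited fields, found ", nf[which(bad)[1]],
         call. = FALSE)
  }

  mat <- vapply(fields, function(f) c(f, rep(NA_character_, 6 - length(f))),
                character(6))
  date <- as.Date(mat[1, ], format = "%Y-%m-%d")
  if (anyNA(date)) {
    stop("malformed event line ", keep[which(is.na(date))[1]],
         ": unparseable date '", mat[1, which(is.na(date))[1]], "'",
         call. = FALSE)
  }
  time <- mat[2, ]
  ok_time <- grepl("^([01][0-9]|2[0-3]):[0-5][0-9]:[0-5][0-9](\\.[0-9]+)?$",
                   time)
  if (!all(ok_time)) {
    stop("malformed event line ", keep[which(!ok_time)[1]],
         ": unparseable time '", time[which(!ok_time)[1]], "'", call. = FALSE)
  }
  marker <- mat[6, ]
  bad_marker <- !is.na(marker) & !marker %in% c("begin", "end")
  if (any(bad_marker)) {
    stop("unknown activity marker '", marker[which(bad_marker)[1]],
         "' on line ", keep[which(bad_marker)[1]],
         " (expected 'begin' or 'end')", call. = FALSE)
  }

  ev <- tibble::tibble(
    date = date, time = time,
    sensor = mat[3, ], status = mat[4, ],
    activity = mat[5, ], marker = marker,
    line = keep
  )

  stamp <- paste(format(ev$date), ev$time)
  if (is.unsorted(stamp)) {
    warning("event timestamps are not non-decreasing (first violation near ",
            "line ", ev$line[which(diff(order(stamp)) < 0)[1] + 1L],
            "); keeping file order", call. = FALSE)
  }
  if (!is.null(exclude_prefix)) {
    pat <- paste0("^(", paste(exclude_prefix, collapse = "|"), ")")
    ev <- ev[!grepl(pat, ev$sensor), , drop = FALSE]
  }
  class(ev) <- c("casas_events", class(ev))
  ev
}

empty_events <- function() {
  ev <- tibble::tibble(
    date = as.Date(character()), time = character(),
    sensor = character(), status = character(),
    activity = character(), marker = character(),
    line = integer()
  )
  class(ev) <- c("casas_events", class(ev))
  ev
}

#' Write events back to the CASAS log format
#'
#' Inverse of [parse_events()]: a parse of the written text reproduces the
#' events field for field.
#'
#' @param events A `casas_events` tibble as returned by [parse_events()] or
#'   [generate_events()].
#' @param path Optional file path; when `NULL` the lines are returned
#'   invisibly instead of written.
#' @return Character vector of lines, invisibly.
#' @export
write_events <- function(events, path = NULL) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    out <- character()
  } else {
    out <- paste(format(events$date, "%Y-%m-%d"), events$time,
                 events$sensor, events$status)
    ann <- !is.na(events$activity)
    out[ann] <- paste(out[ann], events$activity[ann], events$marker[ann])
  }
  if (!is.null(path)) {
    writeLines(out, path)
  }
  invisible(out)
}

#' Segment an event stream into labelled activity instances
#'
#' Walks the ordered event stream and pairs every `(activity, begin)` marker
#' with its matching `(activity, end)`. Each pair yields one activity
#' instance whose sensor sequence `sq` contains the sensor id of *every*
#' event from the begin event through the end event inclusive, in stream
#' order. When two activities are open at once (the two-resident case, or
#' the overlapping Bed_to_Toilet/Sleep pair of the worked example) an event
#' inside both spans contributes to both instances.
#'
#' @param events A `casas_events` tibble ordered by timestamp.
#' @return A tibble of class `casas_activities` with one row per instance:
#'   `label`, `bt` and `et` (integer hour of day, 0--23, of the first and
#'   last contributing event), `sq` (list column of character sensor-id
#'   vectors), `begin_date`, `begin_time` (of the begin event, a stable
#'   instance key), and `n_events`.
#' @details An `end` with no open matching activity, and an activity still
#'   open when the stream ends, are skipped with a warning.
#' @export
#' @examples
#' acts <- segment_activities(table1_fixture())
#' acts$label
#' acts$sq[[1]]
segment_activities <- function(events) {
  stopifnot(is.data.frame(events))
  open <- list()   # label -> list(sensors = character(), begin_row = i)
  out <- list()
  for (i in seq_len(nrow(events))) {
    lab <- events$activity[i]
    mk <- events$marker[i]
    if (!is.na(mk) && mk == "begin") {
      if (!is.null(open[[lab]])) {
        warning("activity '", lab, "' re-opened before ending (line ",
                events$line[i], "); discarding the earlier incomplete ",
                "instance", call. = FALSE)
      }
      open[[lab]] <- list(sensors = character(), begin_row = i)
    }
    if (length(open)) {
      for (nm in names(open)) {
        open[[nm]]$sensors <- c(open[[nm]]$sensors, events$sensor[i])
      }
    }
    if (!is.na(mk) && mk == "end") {
      if (is.null(open[[lab]])) {
        warning("'end' marker for '", lab, "' with no open instance (line ",
                events$line[i], "); skipped", call. = FALSE)
      } else {
        b <- open[[lab]]$begin_row
        out[[length(out) + 1L]] <- list(
          label = lab,
          bt = hour_of(events$time[b]),
          et = hour_of(events$time[i]),
          sq = open[[lab]]$sensors,
          begin_date = events$date[b],
          begin_time = events$time[b]
        )
        open[[lab]] <- NULL
      }
    }
  }
  if (length(open)) {
    warning("activities still open at end of stream, skipped: ",
            paste(names(open), collapse = ", "), call. = FALSE)
  }
  activities_tibble(out)
}

hour_of <- function(time) as.integer(substr(time, 1, 2))

activities_tibble <- function(rows) {
  acts <- tibble::tibble(
    label = vapply(rows, `[[`, character(1), "label"),
    bt = vapply(rows, `[[`, integer(1), "bt"),
    et = vapply(rows, `[[`, integer(1), "et"),
    sq = lapply(rows, `[[`, "sq"),
    begin_date = as.Date(
      vapply(rows, function(r) format(r$begin_date), character(1))
    ),
    begin_time = vapply(rows, `[[`, character(1), "begin_time"),
    n_events = lengths(lapply(rows, `[[`, "sq"))
  )
  class(acts) <- c("casas_activities", class(acts))
  acts
}
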