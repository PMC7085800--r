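#' Build the sensor-importance table (SIA)
#'
#' For every sensor that starts at least one activity sequence, the SIA
#' records, for each sensor, the fraction of sequences starting with that
#' start sensor in which it occurs at least once. A sensor fired by the
#' co-resident during someone else's activity occurs only sporadically and
#' so receives a low importance, which is what the de-noising step exploits.
#'
#' @param sequences List of non-empty character vectors of sensor ids
#'   (activity sensor sequences), or a `casas_activities` tibble, in which
#'   case its `sq` column is used.
#' @return An object of class `sia`: a list with `table` (named list: start
#'   sensor -> named numeric vector of importances in (0, 1]) and `fre`
#'   (named integer vector: start sensor -> number of sequences beginning
#'   with it).
#' @export
#' @examples
#' sia <- build_sia(list(
#'   c("M004", "M005", "M007", "M001", "M004", "M004", "M007", "M007"),
#'   c("M004", "M004", "M007", "M007", "M006", "M007", "M005", "M004")
#' ))
#' sia$table$M004   # M001 0.5, M004 1, M005 1, M006 0.5, M007 1
build_sia <- function(sequences) {
  if (is.data.frame(sequences)) sequences <- sequences$sq
  stopifnot(is.list(sequences))
  if (any(lengths(sequences) == 0)) {
    stop("empty sensor sequence in input", call. = FALSE)
  }
  starts <- vapply(sequences, `[`, character(1), 1)
  fre <- table(starts)
  tab <- lapply(split(sequences, starts), function(sqs) {
    counts <- table(unlist(lapply(sqs, unique), use.names = FALSE))
    v <- as.numeric(counts) / length(sqs)
    names(v) <- names(counts)
    v[order(names(v))]
  })
  structure(list(table = tab, fre = stats::setNames(as.integer(fre),
                                                    names(fre))),
            class = "sia")
}

#' @export
print.sia <- function(x, ...) {
  cat("Sensor-importance table over", length(x$table), "start sensors\n")
  for (s0 in names(x$table)) {
    v <- x$table[[s0]]
    cat(sprintf("  %s (n=%d): %s\n", s0, x$fre[[s0]],
                paste(sprintf("%s=%.3g", names(v), v), collapse = " ")))
  }
  invisible(x)
}

#' De-noise one sensor sequence
#'
#' Applies the two filtering rules jointly in one left-to-right pass: an
#' element is kept only if (i) its importance under the sequence's *original*
#' start sensor strictly exceeds the threshold `w`, and (ii) it differs from
#' the previously kept element (consecutive-duplicate removal). The start
#' sensor always survives, its importance being 1; if filtering would empty
#' the sequence the original first element is retained.
#'
#' @param sq Character vector, the raw sensor sequence (non-empty).
#' @param sia An `sia` object built from training data.
#' @param w Importance threshold in `[0, 1)`; elements with importance
#'   `<= w` are dropped (strict `>` keep test). Default 0.25, below the
#'   smallest importance a sensor present in half the sequences can have
#'   with two instances, so light interference is removed without touching
#'   habitual sensors.
#' @param dedup `"consecutive"` (default) removes repeats of the previously
#'   kept element; `"global"` keeps only the first occurrence of each sensor.
#' @return Filtered character vector, never longer than `sq`, order
#'   preserved.
#' @details A start sensor never seen in training gets an empty importance
#'   row: every element except occurrences of the start sensor itself is
#'   dropped, with a warning.
#' @export
denoise_sequence <- function(sq, sia, w = 0.25,
                             dedup = c("consecutive", "global")) {
  dedup <- match.arg(dedup)
  stopifnot(length(sq) >= 1, w >= 0, w < 1)
  start <- sq[[1]]
  imp <- sia$table[[start]]
  if (is.null(imp)) {
    warning("start sensor '", start, "' unseen in training; treating all ",
            "other importances as 0", call. = FALSE)
    imp <- stats::setNames(1, start)
  }
  kept <- character(0)
  seen <- character(0)
  for (s in sq) {
    v <- if (s %in% names(imp)) imp[[s]] else 0
    if (v <= w) next
    if (dedup == "consecutive") {
      if (length(kept) && s == kept[length(kept)]) next
    } else {
      if (s %in% seen) next
      seen <- c(seen, s)
    }
    kept <- c(kept, s)
  }
  if (length(kept) == 0) kept <- start
  kept
}

#' De-noise every activity instance in a table
#'
#' @param activities A `casas_activities` tibble (see
#'   [segment_activities()]).
#' @inheritParams denoise_sequence
#' @return The same tibble with each `sq` replaced by its de-noised version;
#'   `bt`, `et` and `label` are untouched.
#' @export
denoise_activities <- function(activities, sia, w = 0.25,
                               dedup = c("consecutive", "global")) {
  dedup <- match.arg(dedup)
  activities$sq <- lapply(activities$sq, denoise_sequence,
                          sia = sia, w = w, dedup = dedup)
  activities
}
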