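#' Describe one daily activity template
#'
#' A template is the generative model of one activity class: a typical
#' start hour and duration (both Gaussian, truncated to the day and to a
#' minimum of one minute) and a characteristic ordered sensor path walked
#' with optional per-step repeats and skips. The first path sensor is never
#' skipped, so it anchors the begin event and the sequence's start sensor.
#'
#' @param label Activity class name (unique within a scenario).
#' @param resident Resident identifier (e.g. `"R1"`).
#' @param start_mean,start_sd Start-hour distribution (hours, 0--24).
#' @param dur_mean,dur_sd Duration distribution (minutes; truncated at 1).
#' @param path Character vector of sensor ids, length >= 2.
#' @param repeat_prob Probability that an emitted sensor fires again
#'   immediately (applied up to three times per step).
#' @param skip_prob Probability that a non-initial path step is skipped.
#' @return A list of class `activity_template`.
#' @export
activity_template <- function(label, resident, start_mean, start_sd,
                              dur_mean, dur_sd, path,
                              repeat_prob = 0.2, skip_prob = 0.1) {
  stopifnot(length(path) >= 2,
            repeat_prob >= 0, repeat_prob <= 1,
            skip_prob >= 0, skip_prob <= 1,
            start_sd >= 0, dur_sd >= 0, dur_mean >= 1)
  structure(list(label = label, resident = resident,
                 start_mean = start_mean, start_sd = start_sd,
                 dur_mean = dur_mean, dur_sd = dur_sd,
                 path = path, repeat_prob = repeat_prob,
                 skip_prob = skip_prob),
            class = "activity_template")
}

#' Assemble a two-resident simulation scenario
#'
#' @param templates List of [activity_template()]s covering both residents.
#' @param days Number of simulated days (>= 1); every template produces one
#'   instance per day.
#' @param interference_rate Expected number of cross-resident interference
#'   events injected inside each activity instance (Poisson); an injected
#'   event carries a sensor of the *other* resident -- from their
#'   concurrently active template when one exists, otherwise from their
#'   full sensor vocabulary -- and no activity annotation, mimicking how a
#'   co-resident pollutes an activity window.
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @param start_date First simulated calendar date.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(templates, days = 60L, interference_rate = 0.3,
                          seed = 7L, start_date = as.Date("2010-01-01")) {
  stopifnot(days >= 1, interference_rate >= 0, length(templates) >= 1)
  if (anyDuplicated(vapply(templates, `[[`, character(1), "label"))) {
    stop("template labels must be unique", call. = FALSE)
  }
  structure(list(templates = templates, days = as.integer(days),
                 interference_rate = interference_rate,
                 seed = as.integer(seed),
                 start_date = as.Date(start_date)),
            class = "scenario_spec")
}

#' Default two-resident scenario
#'
#' Eight activity classes (four per resident) arranged in three time-of-day
#' groups -- morning, noon, evening -- with disjoint sensor vocabularies
#' between the residents (R1: M001--M013, R2: M016--M028) and begin times
#' close enough that neighbouring activities of the two residents
#' occasionally overlap. This is the study condition every pipeline-level
#' check runs under.
#'
#' @inheritParams scenario_spec
#' @param repeat_prob,skip_prob Path-walk noise shared by all templates.
#' @return A `scenario_spec`.
#' @export
default_scenario <- function(days = 60L, interference_rate = 0.3, seed = 7L,
                             repeat_prob = 0.2, skip_prob = 0.1) {
  tpl <- function(label, res, sm, ssd, dm, dsd, path) {
    activity_template(label, res, sm, ssd, dm, dsd, path,
                      repeat_prob = repeat_prob, skip_prob = skip_prob)
  }
  templates <- list(
    # morning group
    tpl("R1_Bed_to_Toilet", "R1", 5.5, 0.25,  8, 2,
        c("M001", "M002", "M003", "M002", "M001")),
    tpl("R2_Wake",          "R2", 6.3, 0.25, 15, 4,
        c("M016", "M017", "M018", "M017")),
    tpl("R1_Breakfast",     "R1", 7.1, 0.25, 20, 5,
        c("M004", "M005", "M006", "M007", "M006")),
    # noon group
    tpl("R1_Lunch",         "R1", 12.0, 0.25, 20, 5,
        c("M008", "M005", "M006", "M009", "M010")),
    tpl("R2_Lunch",         "R2", 12.8, 0.25, 20, 5,
        c("M019", "M020", "M021", "M022")),
    tpl("R2_Laundry",       "R2", 13.6, 0.25, 30, 6,
        c("M023", "M024", "M025", "M024", "M023")),
    # evening group
    tpl("R1_Watch_TV",      "R1", 20.2, 0.25, 35, 7,
        c("M011", "M012", "M013", "M012")),
    tpl("R2_Sleep_Prep",    "R2", 21.2, 0.25, 15, 4,
        c("M026", "M027", "M028", "M027"))
  )
  scenario_spec(templates, days = days,
                interference_rate = interference_rate, seed = seed)
}

#' Noise-free limiting scenario
#'
#' The [default_scenario()] templates with no interference, no repeats or
#' skips, near-deterministic start times and fixed durations, so every
#' activity's time window is disjoint from every other and every sensor
#' sequence equals its template path exactly.
#'
#' @inheritParams scenario_spec
#' @return A `scenario_spec`.
#' @export
noise_free_scenario <- function(days = 60L, seed = 7L) {
  spec <- default_scenario(days = days, interference_rate = 0,
                           seed = seed, repeat_prob = 0, skip_prob = 0)
  spec$templates <- lapply(spec$templates, function(tp) {
    tp$start_sd <- 0.02
    tp$dur_sd <- 0
    tp
  })
  spec
}

#' Generate a labelled two-resident event stream
#'
#' Samples, for every day and template, a start time and duration, walks
#' the sensor path with the template's repeat/skip noise, annotates the
#' first and last event of each instance with the activity label and a
#' `begin`/`end` marker, injects cross-resident interference events at the
#' scenario's rate, and interleaves everything by timestamp.
#'
#' @param spec A [scenario_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return List with `events` (a `casas_events` tibble, time-sorted) and
#'   `truth` (tibble: `id`, `resident`, `label`, `date`, `begin_time`,
#'   `end_time`, `bt`, `et`, and `injected`, a list column of the
#'   interference sensors injected into that instance's span).
#' @export
generate_events <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(seed)) seed <- spec$seed
  withr::with_seed(as.integer(seed), generate_events_impl(spec))
}

generate_events_impl <- function(spec) {
  vocab <- lapply(split(spec$templates,
                        vapply(spec$templates, `[[`, character(1),
                               "resident")),
                  function(tps) unique(unlist(lapply(tps, `[[`, "path"))))
  residents <- names(vocab)

  inst <- list()
  id <- 0L
  for (day in seq_len(spec$days) - 1L) {
    date <- spec$start_date + day
    for (tp in spec$templates) {
      id <- id + 1L
      start <- truncnorm1(tp$start_mean, tp$start_sd, 0, 23.9)
      dur_h <- max(1, stats::rnorm(1, tp$dur_mean, tp$dur_sd)) / 60
      dur_h <- min(dur_h, 23.99 - start)
      sensors <- walk_path(tp)
      k <- length(sensors)
      times <- if (k == 1) start else
        start + dur_h * c(0, sort(stats::runif(max(0, k - 2))), 1)
      inst[[id]] <- list(id = id, resident = tp$resident, label = tp$label,
                         date = date, start = start, end = start + dur_h,
                         sensors = sensors, times = times, path = tp$path)
    }
  }

  # interference: foreign sensors inside each instance's span
  for (i in seq_along(inst)) {
    a <- inst[[i]]
    other <- setdiff(residents, a$resident)
    if (length(other) == 0 || spec$interference_rate == 0) {
      inst[[i]]$injected <- character(0)
      next
    }
    n_inj <- stats::rpois(1, spec$interference_rate)
    injected <- character(0)
    if (n_inj > 0 && a$end - a$start > 1e-5) {
      t_inj <- stats::runif(n_inj, a$start + 1e-6, a$end - 1e-6)
      for (ti in t_inj) {
        conc <- Filter(function(b) {
          b$resident %in% other && b$date == a$date &&
            b$start <= ti && ti <= b$end
        }, inst)
        pool <- if (length(conc)) conc[[1]]$path else
          vocab[[sample(other, 1)]]
        s <- sample(pool, 1)
        injected <- c(injected, s)
        inst[[i]]$sensors <- c(inst[[i]]$sensors, s)
        inst[[i]]$times <- c(inst[[i]]$times, ti)
      }
    }
    inst[[i]]$injected <- injected
  }

  rows <- lapply(inst, function(a) {
    k0 <- length(a$sensors) - length(a$injected)   # path events come first
    activity <- rep(NA_character_, length(a$sensors))
    marker <- rep(NA_character_, length(a$sensors))
    activity[1] <- a$label; marker[1] <- "begin"
    activity[k0] <- a$label; marker[k0] <- "end"
    tibble::tibble(date = a$date, hour = a$times, sensor = a$sensors,
                   status = "ON", activity = activity, marker = marker)
  })
  ev <- do.call(rbind, rows)
  ev$time <- hours_to_time(ev$hour)
  ev <- ev[order(ev$date, ev$time), c("date", "time", "sensor", "status",
                                      "activity", "marker")]
  ev$line <- seq_len(nrow(ev))
  class(ev) <- c("casas_events", class(ev))

  truth <- tibble::tibble(
    id = vapply(inst, `[[`, integer(1), "id"),
    resident = vapply(inst, `[[`, character(1), "resident"),
    label = vapply(inst, `[[`, character(1), "label"),
    date = as.Date(vapply(inst, function(a) format(a$date), character(1))),
    begin_time = hours_to_time(vapply(inst, function(a) a$times[1],
                                      numeric(1))),
    end_time = hours_to_time(vapply(inst, function(a) {
      k0 <- length(a$sensors) - length(a$injected)
      a$times[k0]
    }, numeric(1))),
    bt = as.integer(vapply(inst, function(a) a$times[1], numeric(1))),
    et = as.integer(vapply(inst, function(a) {
      k0 <- length(a$sensors) - length(a$injected)
      a$times[k0]
    }, numeric(1))),
    injected = lapply(inst, `[[`, "injected")
  )
  list(events = ev, truth = truth)
}

# one truncated-normal draw by rejection, clamped after 100 tries
truncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

walk_path <- function(tp) {
  out <- character(0)
  for (j in seq_along(tp$path)) {
    if (j > 1 && stats::runif(1) < tp$skip_prob) next
    out <- c(out, tp$path[j])
    r <- 0
    while (r < 3 && stats::runif(1) < tp$repeat_prob) {
      out <- c(out, tp$path[j])
      r <- r + 1
    }
  }
  if (length(out) == 1) out <- c(out, out)   # need distinct begin/end events
  out
}

hours_to_time <- function(h) {
  us <- pmin(round(h * 3600 * 1e6), 24 * 3600 * 1e6 - 1)
  sec <- us %/% 1e6
  frac <- us %% 1e6
  sprintf("%02d:%02d:%02d.%06d", sec %/% 3600, (sec %% 3600) %/% 60,
          sec %% 60, frac)
}

#' The twelve-event worked-example fixture
#'
#' The canonical overlapping pair of activities used throughout the
#' documentation: a Bed_to_Toilet instance whose span contains the begin of
#' a Sleep instance, so four events are shared by both sequences.
#'
#' @return A `casas_events` tibble of 12 rows.
#' @export
#' @examples
#' segment_activities(table1_fixture())
table1_fixture <- function() {
  parse_events(c(
    "2010-11-04 05:40:51.303739 M004 ON Bed_to_Toilet begin",
    "2010-11-04 05:40:52.342105 M005 OFF",
    "2010-11-04 05:40:57.176409 M007 OFF",
    "2010-11-04 05:40:57.941486 M001 OFF",
    "2010-11-04 05:43:24.021475 M004 ON Sleep begin",
    "2010-11-04 05:43:26.273181 M004 OFF",
    "2010-11-04 05:43:26.345503 M007 ON",
    "2010-11-04 05:43:26.793102 M007 ON Bed_to_Toilet end",
    "2010-11-04 05:43:27.195347 M006 OFF",
    "2010-11-04 05:43:27.787437 M007 ON",
    "2010-11-04 05:43:29.711796 M005 ON",
    "2010-11-04 05:43:30.279021 M004 OFF Sleep end"
  ))
}
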