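# Fixed measurement-type identifiers used by the generator (one UUID per
# vital, constant across records, as a device firmware would emit).
VITAL_CODES <- c(
  diastolic_bp = "8462e0f8-1a2b-4c3d-9e4f-5a6b7c8d9e0f",
  systolic_bp  = "8480a1b2-2c3d-4e5f-8a6b-7c8d9e0f1a2b",
  heart_rate   = "8867c3d4-3e4f-4a5b-9c6d-8d9e0f1a2b3c"
)

#' Gaussian model of one vital sign
#'
#' Values are drawn from a normal distribution truncated to the
#' physiologically valid range, then rounded to integers (device readouts
#' are integral).
#'
#' @param mean,sd distribution parameters (mmHg or beats/min)
#' @param range length-2 valid range `c(lo, hi)`, `lo < hi`
#' @return object of class `vital_model`
#' @export
vital_model <- function(mean, sd, range) {
  stopifnot(length(range) == 2, range[1] < range[2], sd > 0)
  structure(list(mean = mean, sd = sd, range = range), class = "vital_model")
}

#' Default vital models for a blood-pressure monitor
#'
#' Diastolic N(80, 8) on \[40, 120\] mmHg, systolic N(120, 10) on \[70, 200\]
#' mmHg, heart rate N(70, 8) on \[30, 220\] beats/min — a normotensive adult
#' at rest. The ranges match the default [bpm_rules()] range constraints, so
#' un-injected values always validate.
#'
#' @return named list of [vital_model()]s
#' @export
default_vital_models <- function() {
  list(diastolic_bp = vital_model(80, 8, c(40, 120)),
       systolic_bp = vital_model(120, 10, c(70, 200)),
       heart_rate = vital_model(70, 8, c(30, 220)))
}

#' Error profile for stream generation
#'
#' Named counts of anomalies to inject, keyed by element name
#' (`date`, `time`, `<vital>_code`, `<vital>_value`, `<vital>_unit`).
#' `erroneous` injects invalid-but-present values (malformed dates/times,
#' non-UUID codes, out-of-range values below the valid floor, wrong unit
#' strings); `missing` blanks the element; `absent_records` removes whole
#' records (transmission gaps). Each injected anomaly lands in its own
#' record so injected counts equal validator-recoverable counts.
#'
#' @param erroneous,missing named integer vectors (element -> count)
#' @param absent_records whole records to drop from the stream
#' @return object of class `error_profile`
#' @export
error_profile <- function(erroneous = integer(), missing = integer(),
                          absent_records = 0L) {
  chk <- function(x, what) {
    if (length(x) > 0 && (is.null(names(x)) || any(!names(x) %in% ELEMENTS)))
      stopf("%s counts must be named by element (one of: %s)", what,
            paste(ELEMENTS, collapse = ", "))
    if (any(x < 0)) stopf("%s counts must be >= 0", what)
    x
  }
  structure(list(erroneous = chk(erroneous, "erroneous"),
                 missing = chk(missing, "missing"),
                 absent_records = as.integer(absent_records)),
            class = "error_profile")
}

n_anomalies <- function(profile) {
  sum(profile$erroneous) + sum(profile$missing)
}

rtrunc_norm <- function(n, mean, sd, range) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= range[1] & x <= range[2]
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  round(out)
}

erroneous_value <- function(element, rules, original) {
  rule <- rules[rules$element == element, , drop = FALSE]
  kind <- if (nrow(rule) == 1) rule$constraint else "format"
  switch(kind,
    range = sample.int(max(1, rule$min - 1), 1),      # below the valid floor
    fixed = "??",
    unique_id = "not-a-valid-identifier",
    format = if (element == "date") gsub("-", "/", original)
             else gsub(":", ".", original),
    "??")
}

#' Generate a synthetic device observation stream
#'
#' Emulates a vital-sign monitor transmitting `cadence` records per day for
#' `days` days: timestamps on a fixed daily grid, values drawn from the
#' truncated-Gaussian [vital_model()]s, measurement codes fixed per vital.
#' Anomalies from `profile` are then injected — each in a distinct record,
#' placed uniformly at random — and `absent_records` whole records are
#' removed. The same `(spec, days, vitals, profile, seed)` always produces
#' the identical dataset.
#'
#' @param spec a [device_spec()]
#' @param days observation period in days (>= 1)
#' @param vitals named list of [vital_model()]s (default
#'   [default_vital_models()])
#' @param profile an [error_profile()] (default: no anomalies)
#' @param seed integer seed
#' @param rules rule set used to parameterise injections (valid floors,
#'   fixed units); default [bpm_rules()]
#' @param start_date first calendar day of the stream
#' @return a [device_dataset()]; the injected ground truth is attached as
#'   `attr(ds, "anomalies")` (data frame: record, element, cause)
#' @export
generate_stream <- function(spec, days, vitals = default_vital_models(),
                            profile = error_profile(), seed = 1L,
                            rules = bpm_rules(), start_date = "2018-11-01") {
  stopifnot(inherits(spec, "device_spec"), days >= 1)
  n_slots <- days * spec$cadence
  kept <- n_slots - profile$absent_records
  if (kept < 0)
    stopf("infeasible profile: %d absent records > %d generated slots",
          profile$absent_records, n_slots)
  if (n_anomalies(profile) > kept)
    stopf("infeasible profile: %d anomalies for %d surviving records",
          n_anomalies(profile), kept)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  hours <- floor((seq_len(spec$cadence) - 1) * 24 / spec$cadence)
  dates <- rep(format(as.Date(start_date) + (seq_len(days) - 1), "%Y-%m-%d"),
               each = spec$cadence)
  times <- rep(sprintf("%02d:00:00", hours), times = days)

  recs <- empty_records(n_slots)
  recs$date <- dates
  recs$time <- times
  for (v in VITALS) {
    vm <- vitals[[v]]
    recs[[paste0(v, "_value")]] <- rtrunc_norm(n_slots, vm$mean, vm$sd, vm$range)
    recs[[paste0(v, "_code")]] <- VITAL_CODES[[v]]
    unit_rule <- rules[rules$element == paste0(v, "_unit"), , drop = FALSE]
    recs[[paste0(v, "_unit")]] <- if (nrow(unit_rule) == 1 &&
                                      !is.na(unit_rule$fixed)) unit_rule$fixed else "mmHg"
  }

  if (profile$absent_records > 0) {
    drop <- sort(sample.int(n_slots, profile$absent_records))
    recs <- recs[-drop, , drop = FALSE]
  }

  # one anomaly per record: sample disjoint record sets for every element count
  plan <- rbind(
    if (sum(profile$erroneous) > 0)
      data.frame(element = rep(names(profile$erroneous), profile$erroneous),
                 cause = "erroneous", stringsAsFactors = FALSE),
    if (sum(profile$missing) > 0)
      data.frame(element = rep(names(profile$missing), profile$missing),
                 cause = "missing", stringsAsFactors = FALSE)
  )
  anomalies <- data.frame(record = integer(), element = character(),
                          cause = character(), stringsAsFactors = FALSE)
  if (!is.null(plan) && nrow(plan) > 0) {
    slots <- sample.int(nrow(recs), nrow(plan))
    for (i in seq_len(nrow(plan))) {
      el <- plan$element[i]; at <- slots[i]
      if (plan$cause[i] == "missing") {
        recs[at, el] <- NA
      } else {
        recs[at, el] <- erroneous_value(el, rules, recs[at, el])
      }
      anomalies <- rbind(anomalies,
                         data.frame(record = at, element = el,
                                    cause = plan$cause[i], stringsAsFactors = FALSE))
    }
  }

  ds <- device_dataset(spec, recs, period_days = days)
  attr(ds, "anomalies") <- anomalies[order(anomalies$record), , drop = FALSE]
  ds
}

# Per-device anomaly profiles of the four evaluated blood-pressure monitors:
# record tallies and per-element erroneous/missing counts of the study's
# two-month (61-day, 4 records/day) experiment.
BPM_FIXTURES <- list(
  "iHealth Clear" = list(
    manufacturer = "iHealth", absent = 6L, seed = 101L,
    erroneous = c(diastolic_bp_value = 2, systolic_bp_value = 2,
                  systolic_bp_unit = 1, heart_rate_value = 3),
    missing = c(diastolic_bp_value = 3, systolic_bp_value = 2,
                systolic_bp_unit = 1, heart_rate_value = 3)),
  "iHealth Track" = list(
    manufacturer = "iHealth", absent = 5L, seed = 102L,
    erroneous = c(diastolic_bp_value = 1, systolic_bp_value = 2,
                  systolic_bp_unit = 1, heart_rate_code = 1,
                  heart_rate_value = 2),
    missing = c(date = 1, diastolic_bp_value = 2, systolic_bp_value = 1,
                heart_rate_value = 2)),
  "Withings BPM" = list(
    manufacturer = "Withings", absent = 0L, seed = 103L,
    erroneous = c(diastolic_bp_value = 2, systolic_bp_value = 1,
                  systolic_bp_unit = 1, heart_rate_value = 1),
    missing = c(diastolic_bp_value = 4, systolic_bp_value = 4,
                systolic_bp_unit = 2, heart_rate_code = 1,
                heart_rate_value = 4)),
  "iHealth View" = list(
    manufacturer = "iHealth", absent = 1L, seed = 104L,
    erroneous = c(date = 1, diastolic_bp_value = 3, systolic_bp_value = 1,
                  heart_rate_value = 3),
    missing = c(date = 2, diastolic_bp_value = 3, systolic_bp_code = 1,
                systolic_bp_value = 3, heart_rate_value = 5))
)

#' Names of the bundled blood-pressure-monitor fixtures
#' @return character vector of device names accepted by [make_table_fixture()]
#' @export
bpm_fixture_names <- function() names(BPM_FIXTURES)

#' Generate one of the four reference blood-pressure-monitor datasets
#'
#' Reproduces the record tallies and per-element anomaly profile of the four
#' evaluated devices over a 61-day, 4-records-per-day experiment
#' (e.g. "Withings BPM": 244 records, 20 anomalies of which exactly one —
#' a missing heart-rate code — forces a record drop). Values are synthetic
#' draws from [default_vital_models()]; only the counts reproduce the study,
#' not the measurements themselves.
#'
#' @param device_name one of [bpm_fixture_names()]
#' @param seed integer seed; each device has a fixed default so repeated
#'   calls are byte-identical
#' @return a [device_dataset()]
#' @export
make_table_fixture <- function(device_name, seed = NULL) {
  if (!device_name %in% names(BPM_FIXTURES))
    stopf("unknown fixture device '%s' (expected one of: %s)", device_name,
          paste(names(BPM_FIXTURES), collapse = ", "))
  fx <- BPM_FIXTURES[[device_name]]
  spec <- device_spec(gsub("[^A-Za-z0-9]+", "-", tolower(device_name)),
                      device_name, fx$manufacturer, "BPM", 4L)
  generate_stream(spec, days = 61L,
                  profile = error_profile(fx$erroneous, fx$missing, fx$absent),
                  seed = seed %||% fx$seed)
}
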