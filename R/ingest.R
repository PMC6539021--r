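VITALS <- c("diastolic_bp", "systolic_bp", "heart_rate")

ELEMENTS <- c("date", "time",
              paste0(rep(VITALS, each = 3), c("_code", "_value", "_unit")))

#' Device specification
#'
#' Static description of one IoT medical device: identity, type, and the
#' expected number of observation records per day (its cadence). The cadence
#' together with the observation period defines the device's operating cycle,
#' the denominator of operational availability.
#'
#' @param device_id opaque identifier
#' @param name device model name
#' @param manufacturer manufacturer name
#' @param device_type one of `"AT"` (activity tracker), `"BPM"`
#'   (blood-pressure monitor), `"PO"` (pulse oximeter), `"BWS"` (body-weight
#'   scale), `"GL"` (glucometer)
#' @param cadence expected records per day (positive integer)
#' @return object of class `device_spec`
#' @export
device_spec <- function(device_id, name, manufacturer,
                        device_type = c("BPM", "AT", "PO", "BWS", "GL"),
                        cadence = 4L) {
  device_type <- match.arg(device_type)
  cadence <- as.integer(cadence)
  if (is.na(cadence) || cadence < 1) stopf("cadence must be a positive integer")
  structure(list(device_id = as.character(device_id), name = as.character(name),
                 manufacturer = as.character(manufacturer),
                 device_type = device_type, cadence = cadence),
            class = "device_spec")
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf("<device_spec> %s (%s, %s) cadence %d/day\n",
              x$name, x$device_type, x$manufacturer, x$cadence))
  invisible(x)
}

empty_records <- function(n = 0) {
  df <- data.frame(date = rep(NA_character_, n), time = rep(NA_character_, n),
                   stringsAsFactors = FALSE)
  for (v in VITALS) {
    df[[paste0(v, "_code")]] <- rep(NA_character_, n)
    df[[paste0(v, "_value")]] <- rep(NA_real_, n)
    df[[paste0(v, "_unit")]] <- rep(NA_character_, n)
  }
  df
}

#' Device dataset container
#'
#' Holds a [device_spec()], the ordered observation records (one row per
#' record; a blood-pressure record carries a code/value/unit triple for each
#' of diastolic pressure, systolic pressure and heart rate), and the
#' observation period in days. Records may be dirty: dates kept as raw
#' strings, values possibly missing or out of range — validation belongs to
#' the cleaning stage.
#'
#' @param spec a [device_spec()]
#' @param records data frame with the element columns (`date`, `time`, and
#'   `<vital>_code/_value/_unit` for the three vitals); source order is kept
#' @param period_days observation period (days, >= 1)
#' @return object of class `device_dataset`
#' @export
device_dataset <- function(spec, records = empty_records(), period_days = 61L) {
  stopifnot(inherits(spec, "device_spec"))
  period_days <- as.integer(period_days)
  if (is.na(period_days) || period_days < 1) stopf("period_days must be >= 1")
  missing_cols <- setdiff(ELEMENTS, names(records))
  if (length(missing_cols) > 0)
    stopf("records lack element columns: %s", paste(missing_cols, collapse = ", "))
  records <- records[, ELEMENTS, drop = FALSE]
  rownames(records) <- NULL
  structure(list(spec = spec, records = records, period_days = period_days),
            class = "device_dataset")
}

#' @export
print.device_dataset <- function(x, ...) {
  cat(sprintf("<device_dataset> %s: %d records over %d days (expected %d)\n",
              x$spec$name, nrow(x$records), x$period_days,
              x$period_days * x$spec$cadence))
  invisible(x)
}

#' Number of records in a device dataset
#' @param ds a [device_dataset()]
#' @return integer count
#' @export
n_records <- function(ds) nrow(ds$records)

#' Expected record count (operating cycle) of a device dataset
#' @param ds a [device_dataset()]
#' @return `period_days * cadence`
#' @export
operating_cycle <- function(ds) ds$period_days * ds$spec$cadence

# ---- JSON ------------------------------------------------------------------

rec_to_item <- function(rec) {
  meas <- lapply(VITALS, function(v) {
    m <- list()
    if (!is_blank(rec[[paste0(v, "_code")]])) m$code <- rec[[paste0(v, "_code")]]
    if (!is_blank(rec[[paste0(v, "_value")]])) m$value <- rec[[paste0(v, "_value")]]
    if (!is_blank(rec[[paste0(v, "_unit")]])) m$unit <- rec[[paste0(v, "_unit")]]
    m
  })
  item <- list()
  if (!is_blank(rec$date)) item$date <- rec$date
  if (!is_blank(rec$time)) item$time <- rec$time
  item$measurements <- meas
  item
}

item_to_rec <- function(item) {
  rec <- empty_records(1)
  rec$date <- if (is_blank(item$date)) NA_character_ else as.character(item$date)
  rec$time <- if (is_blank(item$time)) NA_character_ else as.character(item$time)
  meas <- item$measurements %||% list()
  # vital identity is positional: diastolic, systolic, heart rate
  for (i in seq_along(VITALS)) {
    if (i > length(meas)) break
    m <- meas[[i]]
    v <- VITALS[i]
    if (!is_blank(m$code)) rec[[paste0(v, "_code")]] <- as.character(m$code)
    if (!is_blank(m$value)) {
      val <- suppressWarnings(as.numeric(m$value))
      rec[[paste0(v, "_value")]] <- val
    }
    if (!is_blank(m$unit)) rec[[paste0(v, "_unit")]] <- as.character(m$unit)
  }
  rec
}

#' Write a device dataset as JSON
#'
#' The JSON envelope is an object with a `device` block (the spec and
#' period) and an `items` array of observation objects, each with `date`,
#' `time` and a positional `measurements` array of code/value/unit objects
#' (diastolic, systolic, heart rate). Absent fields are omitted.
#'
#' @param ds a [device_dataset()]
#' @param path output file
#' @return invisible `path`
#' @export
write_device_json <- function(ds, path) {
  obj <- list(
    device = list(device_id = ds$spec$device_id, name = ds$spec$name,
                  manufacturer = ds$spec$manufacturer,
                  device_type = ds$spec$device_type,
                  cadence = ds$spec$cadence, period_days = ds$period_days),
    items = lapply(seq_len(nrow(ds$records)),
                   function(i) rec_to_item(ds$records[i, , drop = FALSE]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

default_spec <- function() {
  device_spec("unknown", "unknown device", "unknown", "BPM", 4L)
}

spec_from_meta <- function(meta, period_default = 61L) {
  if (is.null(meta)) return(list(spec = default_spec(), period = period_default))
  sp <- device_spec(meta$device_id %||% "unknown", meta$name %||% "unknown device",
                    meta$manufacturer %||% "unknown",
                    meta$device_type %||% "BPM",
                    meta$cadence %||% 4L)
  list(spec = sp, period = as.integer(meta$period_days %||% period_default))
}

read_device_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stopf("cannot parse JSON '%s': %s",
                                            path, conditionMessage(e)))
  # accept both the {"device":..,"items":[..]} envelope and a bare array
  items <- if (is.null(names(obj))) obj else obj$items %||% list()
  meta <- if (is.null(names(obj))) NULL else obj$device
  sp <- spec_from_meta(meta)
  recs <- if (length(items) == 0) empty_records(0) else
    do.call(rbind, lapply(items, item_to_rec))
  device_dataset(sp$spec, recs, sp$period)
}

# ---- XML -------------------------------------------------------------------

#' Convert a device dataset to XML
#'
#' Produces an `observations` document with one `observation` element per
#' record, each holding `date`, `time` and three `measurement` elements with
#' `measuredValue`, `unit` and `code` children (diastolic, systolic, heart
#' rate, in that order). Absent fields are omitted so the conversion is
#' lossless: parsing the output reproduces the dataset exactly.
#'
#' @param ds a [device_dataset()]
#' @return an `xml2::xml_document`
#' @export
convert_to_xml <- function(ds) {
  doc <- xml2::xml_new_root("observations",
                            "device_id" = ds$spec$device_id,
                            "name" = ds$spec$name,
                            "manufacturer" = ds$spec$manufacturer,
                            "device_type" = ds$spec$device_type,
                            "cadence" = as.character(ds$spec$cadence),
                            "period_days" = as.character(ds$period_days))
  for (i in seq_len(nrow(ds$records))) {
    rec <- ds$records[i, , drop = FALSE]
    obs <- xml2::xml_add_child(doc, "observation")
    if (!is_blank(rec$date)) xml2::xml_add_child(obs, "date", rec$date)
    if (!is_blank(rec$time)) xml2::xml_add_child(obs, "time", rec$time)
    for (v in VITALS) {
      m <- xml2::xml_add_child(obs, "measurement", vital = v)
      val <- rec[[paste0(v, "_value")]]
      if (!is_blank(val))
        xml2::xml_add_child(m, "measuredValue", format(val, scientific = FALSE))
      if (!is_blank(rec[[paste0(v, "_unit")]]))
        xml2::xml_add_child(m, "unit", rec[[paste0(v, "_unit")]])
      if (!is_blank(rec[[paste0(v, "_code")]]))
        xml2::xml_add_child(m, "code", rec[[paste0(v, "_code")]])
    }
  }
  doc
}

#' @rdname convert_to_xml
#' @param path output file
#' @return invisible `path`
#' @export
write_device_xml <- function(ds, path) {
  xml2::write_xml(convert_to_xml(ds), path)
  invisible(path)
}

parse_device_xml <- function(doc) {
  root <- xml2::xml_root(doc)
  meta <- as.list(xml2::xml_attrs(root))
  if (!is.null(meta$cadence)) meta$cadence <- as.integer(meta$cadence)
  if (!is.null(meta$period_days)) meta$period_days <- as.integer(meta$period_days)
  sp <- spec_from_meta(if (length(meta) > 0) meta else NULL)
  obs <- xml2::xml_find_all(root, "./observation")
  recs <- if (length(obs) == 0) empty_records(0) else do.call(rbind, lapply(obs, function(o) {
    rec <- empty_records(1)
    d <- xml2::xml_find_first(o, "./date")
    t <- xml2::xml_find_first(o, "./time")
    if (!inherits(d, "xml_missing")) rec$date <- xml2::xml_text(d)
    if (!inherits(t, "xml_missing")) rec$time <- xml2::xml_text(t)
    ms <- xml2::xml_find_all(o, "./measurement")
    for (i in seq_along(ms)) {
      if (i > length(VITALS)) break
      v <- VITALS[i]
      mv <- xml2::xml_find_first(ms[[i]], "./measuredValue")
      un <- xml2::xml_find_first(ms[[i]], "./unit")
      cd <- xml2::xml_find_first(ms[[i]], "./code")
      if (!inherits(mv, "xml_missing"))
        rec[[paste0(v, "_value")]] <- suppressWarnings(as.numeric(xml2::xml_text(mv)))
      if (!inherits(un, "xml_missing")) rec[[paste0(v, "_unit")]] <- xml2::xml_text(un)
      if (!inherits(cd, "xml_missing")) rec[[paste0(v, "_code")]] <- xml2::xml_text(cd)
    }
    rec
  }))
  device_dataset(sp$spec, recs, sp$period)
}

read_device_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("cannot parse XML '%s': %s",
                                            path, conditionMessage(e)))
  parse_device_xml(doc)
}

#' Read a device dataset from JSON or XML
#'
#' @param path input file
#' @param fmt `"json"`, `"xml"`, or `"auto"` (decide by file extension,
#'   falling back to sniffing the first non-space character)
#' @return a [device_dataset()]
#' @export
read_device_dataset <- function(path, fmt = c("auto", "json", "xml")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("json", "js")) "json"
           else if (ext == "xml") "xml"
           else {
             head <- substr(trimws(readChar(path, 256L)), 1, 1)
             if (head == "<") "xml" else "json"
           }
  }
  switch(fmt, json = read_device_json(path), xml = read_device_xml(path))
}
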