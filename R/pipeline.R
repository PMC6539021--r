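#' Bundled reliability inputs for the four reference BPM devices
#'
#' ICC(2,1) test-retest reliability percentages of the four reference
#' blood-pressure monitors, shipped as a plain-text input fixture for runs
#' that take reliability from an external test-retest analysis instead of
#' computing it from the stream.
#'
#' @return named numeric vector (device name -> ICC percent)
#' @export
bpm_device_icc <- function() {
  d <- utils::read.csv(system.file("extdata", "bpm_device_icc.csv",
                                   package = "iotqa", mustWork = TRUE),
                       stringsAsFactors = FALSE)
  stats::setNames(d$icc_pct, d$device)
}

#' Pipeline run configuration
#'
#' @param rules constraint rule set (default [bpm_rules()])
#' @param icc either `"auto"` (compute ICC(2,1) from each cleaned stream) or
#'   a named numeric vector of reliability percentages per device name
#' @param w_avail,w_icc,quality_threshold quality-gate parameters
#'   (defaults 0.7 / 0.3 / 90)
#' @param map_threshold overall-similarity selection threshold as a percent
#'   (default 90)
#' @param backend semantic backend for the mapper
#' @param catalogue FHIR attribute catalogue (default [fhir_catalogue()])
#' @param use_raw_availability use raw delivered counts as availability
#'   numerator (default `FALSE`: post-cleaning counts)
#' @param out_dir optional output directory; when given, cleaned XML, report
#'   CSVs, FHIR JSON/XML and a manifest CSV are written there
#' @param seed integer seed for any stochastic step
#' @return object of class `run_config`
#' @export
run_config <- function(rules = bpm_rules(), icc = "auto",
                       w_avail = 0.7, w_icc = 0.3, quality_threshold = 90,
                       map_threshold = 90, backend = lexicon_backend(),
                       catalogue = fhir_catalogue(),
                       use_raw_availability = FALSE,
                       out_dir = NULL, seed = 1L) {
  if (quality_threshold <= 0 || quality_threshold > 100)
    stopf("quality threshold must be in (0, 100]")
  if (map_threshold <= 0 || map_threshold > 100)
    stopf("mapper threshold must be in (0, 100]")
  if (abs(w_avail + w_icc - 1) > 1e-12) stopf("weights must sum to 1")
  structure(list(rules = rules, icc = icc, w_avail = w_avail, w_icc = w_icc,
                 quality_threshold = quality_threshold,
                 map_threshold = map_threshold, backend = backend,
                 catalogue = catalogue,
                 use_raw_availability = use_raw_availability,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

device_icc_for <- function(cfg, name, cleaned) {
  if (identical(cfg$icc, "auto")) return(NULL)       # computed downstream
  if (!name %in% names(cfg$icc))
    stopf("no reliability input for device '%s'", name)
  unname(cfg$icc[[name]])
}

#' Run the full pipeline over a set of device datasets
#'
#' For every input dataset: clean against the configured rules, score
#' quality (availability + faulty data + reliability, weighted), apply the
#' keep/discard gate, and — for kept devices only — build the ontology, map
#' its attributes onto the FHIR catalogue and emit FHIR Observations.
#' Discarded devices produce no FHIR output (their cleaned data is erased
#' from the bundle). A failure in one device's stages is caught and recorded
#' without aborting the others.
#'
#' @param cfg a [run_config()]
#' @param inputs named list of [device_dataset()]s, or a character vector of
#'   JSON/XML file paths (names default to each dataset's device name)
#' @return object of class `pipeline_run`: per-device results (`cleaning`,
#'   `quality`, `mapping`, `fhir`, `error`) plus a `manifest` data frame
#'   linking every device to its stage outcomes
#' @export
run_pipeline <- function(cfg, inputs) {
  stopifnot(inherits(cfg, "run_config"), length(inputs) > 0)
  if (is.character(inputs)) inputs <- lapply(inputs, read_device_dataset)
  nm <- names(inputs) %||% rep(NA_character_, length(inputs))
  for (i in seq_along(inputs))
    if (is.na(nm[i]) || !nzchar(nm[i])) nm[i] <- inputs[[i]]$spec$name
  names(inputs) <- nm

  results <- list()
  manifest <- NULL
  for (name in names(inputs)) {
    ds <- inputs[[name]]
    res <- tryCatch({
      cl <- clean_dataset(ds, cfg$rules)
      icc_in <- device_icc_for(cfg, name, cl$dataset)
      qr <- quality_report(cl$report, expected = operating_cycle(ds),
                           icc_pct = icc_in, cleaned = cl$dataset,
                           use_raw = cfg$use_raw_availability,
                           w_avail = cfg$w_avail, w_icc = cfg$w_icc,
                           threshold = cfg$quality_threshold)
      kept <- identical(qr$decision, "keep")
      mapping <- NULL; fhir <- NULL
      if (kept) {
        tree <- build_ontology(convert_to_xml(cl$dataset))
        mapping <- match_dataset(tree, cfg$catalogue, backend = cfg$backend,
                                 threshold = cfg$map_threshold / 100)
        fhir <- to_fhir(cl$dataset, mapping)
      }
      list(cleaning = cl$report,
           cleaned = if (kept) cl$dataset else NULL,   # discarded data is erased
           quality = qr, mapping = mapping, fhir = fhir, error = NULL)
    }, error = function(e) {
      list(cleaning = NULL, cleaned = NULL, quality = NULL, mapping = NULL,
           fhir = NULL, error = conditionMessage(e))
    })
    results[[name]] <- res
    manifest <- rbind(manifest, data.frame(
      device = name,
      records_in = nrow(ds$records),
      records_dropped = if (is.null(res$cleaning)) NA_integer_ else res$cleaning$dropped_records,
      overall_quality_pct = if (is.null(res$quality)) NA_real_ else res$quality$overall_quality_pct,
      decision = if (!is.null(res$error)) "error"
                 else res$quality$decision,
      fhir_observations = if (is.null(res$fhir)) 0L else length(res$fhir),
      error = res$error %||% "",
      stringsAsFactors = FALSE))
  }
  run <- structure(list(results = results, manifest = manifest, config = cfg),
                   class = "pipeline_run")
  if (!is.null(cfg$out_dir)) write_run_outputs(run, cfg$out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d devices\n", nrow(x$manifest)))
  print(x$manifest[, c("device", "records_in", "records_dropped",
                       "overall_quality_pct", "decision", "fhir_observations")],
        row.names = FALSE)
  invisible(x)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cleaning <- do.call(rbind, lapply(Filter(function(r) !is.null(r$cleaning),
                                           run$results),
                                    function(r) as.data.frame(r$cleaning)))
  if (!is.null(cleaning))
    utils::write.csv(cleaning, file.path(out_dir, "cleaning_report.csv"),
                     row.names = FALSE)
  quality <- do.call(rbind, lapply(Filter(function(r) !is.null(r$quality),
                                          run$results),
                                   function(r) as.data.frame(r$quality)))
  if (!is.null(quality))
    utils::write.csv(quality, file.path(out_dir, "quality_report.csv"),
                     row.names = FALSE)
  for (name in names(run$results)) {
    r <- run$results[[name]]
    stub <- gsub("[^A-Za-z0-9]+", "_", tolower(name))
    if (!is.null(r$cleaned))
      write_device_xml(r$cleaned, file.path(out_dir, paste0(stub, "_cleaned.xml")))
    if (!is.null(r$mapping))
      utils::write.csv(r$mapping$selection,
                       file.path(out_dir, paste0(stub, "_mapping.csv")),
                       row.names = FALSE)
    if (!is.null(r$fhir)) {
      fhir_to_json(r$fhir, file.path(out_dir, paste0(stub, "_fhir.json")))
      fhir_to_xml(r$fhir, file.path(out_dir, paste0(stub, "_fhir.xml")))
    }
  }
  utils::write.csv(run$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
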