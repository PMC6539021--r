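#' Operational availability of a device
#'
#' Ratio of delivered records (uptime) to the expected record count over the
#' operating cycle (`cadence * period_days`), capped at 1.
#'
#' @param delivered records actually received (>= 0)
#' @param expected records expected over the operating cycle (> 0)
#' @return fraction in \[0, 1\]
#' @export
availability <- function(delivered, expected) {
  if (expected <= 0) stopf("operating cycle must be positive (got %s)", expected)
  if (delivered < 0) stopf("delivered record count must be >= 0")
  min(delivered / expected, 1)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement — the
#' test-retest reliability form. Computed from the two-way ANOVA mean
#' squares with subjects as rows and repeated sessions as columns:
#'
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (m-1) MS_E + \frac{m}{n}(MS_C - MS_E)}}
#'
#' where `MS_R`, `MS_C`, `MS_E` are the row (subject), column (session) and
#' residual mean squares of an `n x m` matrix. Rows containing missing
#' values are excluded before the decomposition. A matrix with zero total
#' variance returns 1 with a warning; negative estimates are passed through
#' unclamped (ICC(2,1) can legitimately be negative).
#'
#' @param m numeric matrix, subjects x repeated measurements (n >= 2 rows,
#'   >= 2 columns after removing incomplete rows)
#' @return the ICC(2,1) coefficient (<= 1)
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stopf("ICC needs >= 2 complete subjects and >= 2 sessions")
  if (stats::var(as.vector(m)) == 0) {
    warnf("degenerate reliability matrix (zero variance); returning ICC = 1")
    return(1)
  }
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Reliability matrix of a device dataset
#'
#' Lays a dataset out for test-retest reliability: subjects are calendar
#' days, repeated measurements are the cadence slots within the day. One
#' matrix per vital; days with a missing or duplicated slot are dropped.
#'
#' @param ds a (preferably cleaned) [device_dataset()]
#' @param vital one of `"diastolic_bp"`, `"systolic_bp"`, `"heart_rate"`
#' @return numeric matrix (days x slots)
#' @export
reliability_matrix <- function(ds, vital = VITALS) {
  vital <- match.arg(vital)
  recs <- ds$records
  slots <- sort(unique(recs$time))
  days <- unique(recs$date)
  m <- matrix(NA_real_, length(days), length(slots),
              dimnames = list(days, slots))
  for (i in seq_len(nrow(recs))) {
    r <- match(recs$date[i], days); c <- match(recs$time[i], slots)
    if (!is.na(r) && !is.na(c)) m[r, c] <- recs[[paste0(vital, "_value")]][i]
  }
  m[stats::complete.cases(m), , drop = FALSE]
}

#' ICC(2,1) of a device dataset, averaged across vitals
#'
#' @param ds a cleaned [device_dataset()]
#' @return mean ICC(2,1) over the three vitals
#' @export
dataset_icc <- function(ds) {
  mean(vapply(VITALS, function(v) icc_2_1(reliability_matrix(ds, v)), 0))
}

#' Overall data quality score
#'
#' Weighted combination of the device and data quality channels:
#' `(Availability - Faulty_Data) * w_avail + ICC * w_icc`, all three inputs
#' on the percent scale. Defaults: weights 0.7 / 0.3.
#'
#' @param availability availability percent in \[0, 100\]
#' @param faulty faulty-data percent in \[0, 100\]
#' @param icc reliability (ICC) percent in \[-100, 100\] (negative estimates
#'   are legal and flow through unclamped)
#' @param w_avail,w_icc channel weights (default 0.7 and 0.3; must sum to 1)
#' @return overall quality percent (exact, unrounded)
#' @export
overall_quality <- function(availability, faulty, icc,
                            w_avail = 0.7, w_icc = 0.3) {
  stopifnot(availability >= 0, availability <= 100,
            faulty >= 0, faulty <= 100, icc >= -100, icc <= 100)
  if (abs(w_avail + w_icc - 1) > 1e-12) stopf("weights must sum to 1")
  (availability - faulty) * w_avail + icc * w_icc
}

#' Keep/discard gate on overall quality
#'
#' A device's data is kept only when its overall quality strictly exceeds
#' the threshold (default 90 percent); at or below, the dataset is discarded
#' from all downstream stages.
#'
#' @param overall overall-quality percent
#' @param threshold gate threshold percent (default 90)
#' @return `"keep"` or `"discard"`
#' @export
quality_gate <- function(overall, threshold = 90) {
  if (overall > threshold) "keep" else "discard"
}

#' Build a quality report for one device
#'
#' Combines the cleaning results with the device's availability and
#' reliability. Availability uses the post-cleaning record count by default
#' (`use_raw = TRUE` switches the numerator to the raw delivered count).
#' The availability and faulty percentages are rendered at two decimals
#' (half-up) before the weighted combination, matching how such report
#' tables are printed; `overall_quality_pct` is the 2-dp-rendered result.
#'
#' @param report a `cleaning_report` from [clean_dataset()]
#' @param expected expected record count (operating cycle)
#' @param icc_pct reliability percent; either a number (an external
#'   test-retest analysis) or `NULL` to compute it from `cleaned` via
#'   [dataset_icc()]
#' @param cleaned the cleaned [device_dataset()] (needed when `icc_pct` is
#'   `NULL`)
#' @param use_raw use the raw delivered record count as availability
#'   numerator instead of the cleaned count
#' @param w_avail,w_icc,threshold gate parameters (defaults 0.7 / 0.3 / 90)
#' @return object of class `quality_report`
#' @export
quality_report <- function(report, expected, icc_pct = NULL, cleaned = NULL,
                           use_raw = FALSE, w_avail = 0.7, w_icc = 0.3,
                           threshold = 90) {
  delivered <- if (use_raw) report$total_records else report$final_records
  avail_pct <- round_half_up(100 * availability(delivered, expected))
  faulty_pct <- round_half_up(100 * report$faulty_data)
  if (is.null(icc_pct)) {
    if (is.null(cleaned)) stopf("need the cleaned dataset to compute ICC")
    icc_pct <- round_half_up(100 * dataset_icc(cleaned))
  }
  negative_icc <- icc_pct < 0
  overall <- overall_quality(avail_pct, faulty_pct, icc_pct, w_avail, w_icc)
  overall_pct <- round_half_up(overall)
  structure(list(device = report$device,
                 cleaned_records = report$final_records,
                 availability_pct = avail_pct,
                 faulty_data_pct = faulty_pct,
                 icc_pct = icc_pct,
                 negative_icc = negative_icc,
                 overall_quality_pct = overall_pct,
                 weights = c(w_avail = w_avail, w_icc = w_icc),
                 threshold = threshold,
                 decision = quality_gate(overall_pct, threshold)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s\n", x$device))
  cat(sprintf("  availability %.2f%%  faulty %.2f%%  ICC %.2f%%  overall %.2f%% -> %s\n",
              x$availability_pct, x$faulty_data_pct, x$icc_pct,
              x$overall_quality_pct, toupper(x$decision)))
  if (x$negative_icc) cat("  note: negative ICC passed through unclamped\n")
  invisible(x)
}

#' @export
#' @rdname quality_report
#' @param x a `quality_report`
#' @param row.names,optional,... ignored (S3 signature)
as.data.frame.quality_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(device = x$device, cleaned_records = x$cleaned_records,
             availability_pct = x$availability_pct,
             faulty_data_pct = x$faulty_data_pct, icc_pct = x$icc_pct,
             overall_quality_pct = x$overall_quality_pct,
             decision = x$decision, stringsAsFactors = FALSE)
}
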