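#' Cleaning-report metric: data accuracy
#'
#' Fraction of records untouched by any corrective action:
#' `(Total_Records - Total_Actions) / Total_Records`. An action is one
#' corrected anomalous element value, with a dropped record counting as a
#' single action however many elements it breached.
#'
#' @param total_records records in the raw dataset (> 0)
#' @param total_actions corrective actions taken (0..total_records)
#' @return fraction in \[0, 1\]
#' @export
data_accuracy <- function(total_records, total_actions) {
  if (total_records <= 0) stopf("data accuracy undefined for %d records", total_records)
  if (total_actions < 0 || total_actions > total_records)
    stopf("total_actions (%d) outside [0, %d]", total_actions, total_records)
  (total_records - total_actions) / total_records
}

#' Cleaning-report metric: faulty-data fraction
#'
#' The exact complement of accuracy: `1 - Data_Accuracy`.
#'
#' @param accuracy a [data_accuracy()] value
#' @return fraction in \[0, 1\]
#' @export
faulty_fraction <- function(accuracy) 1 - accuracy

#' Cleaning-report metric: data completion
#'
#' Fraction of records surviving the cleaning stage:
#' `(Total_Records - Dropped_Records) / Total_Records`.
#'
#' @param total_records records in the raw dataset (> 0)
#' @param dropped records deleted because a required element was missing or
#'   erroneous
#' @return fraction in \[0, 1\]
#' @export
data_completion <- function(total_records, dropped) {
  if (total_records <= 0) stopf("data completion undefined for %d records", total_records)
  if (dropped < 0 || dropped > total_records)
    stopf("dropped (%d) outside [0, %d]", dropped, total_records)
  (total_records - dropped) / total_records
}

# ---- validation ------------------------------------------------------------

violation <- function(element, cause, detail) {
  data.frame(element = element, cause = cause, detail = detail,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(element = character(), cause = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' Validate one observation record against a rule set
#'
#' Checks every rule: presence for all elements, then — for present values —
#' type conformance, format patterns, numeric ranges, fixed values and UUID
#' well-formedness. Cross-field rules (systolic > diastolic) fire only when
#' both operands are present. The record is never modified.
#'
#' @param rec one record (a single-row data frame with the element columns,
#'   or a named list)
#' @param rules a rule set such as [bpm_rules()]
#' @return data frame of violations (element, cause `"missing"`/`"erroneous"`,
#'   detail); zero rows when the record conforms
#' @export
validate_record <- function(rec, rules) {
  rec <- as.list(rec)
  out <- no_violations()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, , drop = FALSE]
    if (r$constraint == "cross_field") {
      s <- rec$systolic_bp_value; d <- rec$diastolic_bp_value
      if (!is_blank(s) && !is_blank(d) && s <= d)
        out <- rbind(out, violation(r$element, "erroneous",
                                    sprintf("systolic %s <= diastolic %s", s, d)))
      next
    }
    val <- rec[[r$element]]
    if (is_blank(val)) {
      out <- rbind(out, violation(r$element, "missing", "value absent"))
      next
    }
    if (r$type == "integer" &&
        (!is.numeric(val) || !is.finite(val) || val != round(val))) {
      out <- rbind(out, violation(r$element, "erroneous",
                                  sprintf("not an integer: %s", val)))
      next
    }
    bad <- switch(r$constraint,
      format = !grepl(r$pattern, as.character(val)),
      range = is.numeric(val) && (val < r$min || val > r$max),
      fixed = !identical(as.character(val), r$fixed),
      unique_id = !grepl(UUID_PATTERN, as.character(val)),
      FALSE)
    if (isTRUE(bad)) {
      detail <- switch(r$constraint,
        format = sprintf("'%s' does not match %s", val, r$pattern),
        range = sprintf("%s outside [%s, %s]", val, r$min, r$max),
        fixed = sprintf("'%s' != fixed value '%s'", val, r$fixed),
        unique_id = sprintf("'%s' is not a well-formed UUID", val))
      out <- rbind(out, violation(r$element, "erroneous", detail))
    }
  }
  out
}

#' Validate every record of a dataset
#'
#' @param ds a [device_dataset()]
#' @param rules a rule set
#' @return data frame (record, element, cause, detail), zero rows when clean
#' @export
validate_dataset <- function(ds, rules = bpm_rules()) {
  out <- lapply(seq_len(nrow(ds$records)), function(i) {
    v <- validate_record(ds$records[i, , drop = FALSE], rules)
    if (nrow(v) > 0) cbind(record = i, v) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- cbind(record = integer(), no_violations())
  out
}

# ---- completion-strategy selection ----------------------------------------

#' Choose a missing-value completion strategy for a series
#'
#' Low-variation, frequently sampled series are completed with the last
#' non-missing value; medium variation with a moving average of the
#' neighbouring values; high variation or infrequent sampling falls back to
#' machine-learning imputation (kNN / decision tree). Variation is the
#' coefficient of variation (sd/mean) of the observed values.
#'
#' @param series numeric vector with `NA`s for missing entries (>= 1 observed)
#' @param samples_per_day sampling frequency of the series
#' @param cv_low,cv_high CV thresholds for the low/medium tiers (defaults
#'   0.05 and 0.2)
#' @param min_freq minimum samples/day to count as "frequent" (default 2)
#' @return `"last_value"`, `"moving_average"`, or `"ml"`
#' @export
select_completion_strategy <- function(series, samples_per_day,
                                       cv_low = 0.05, cv_high = 0.2,
                                       min_freq = 2) {
  x <- series[!is.na(series)]
  if (length(x) == 0) stopf("unrecoverable series: all values missing")
  cv <- if (length(x) < 2 || mean(x) == 0) 0 else stats::sd(x) / abs(mean(x))
  if (samples_per_day < min_freq) return("ml")
  if (cv < cv_low) "last_value" else if (cv < cv_high) "moving_average" else "ml"
}

moving_average_impute <- function(series, idx) {
  prev <- rev(which(!is.na(series[seq_len(idx - 1)])))
  nxt <- which(!is.na(series)) ; nxt <- nxt[nxt > idx]
  vals <- c(if (length(prev) > 0) series[prev[1]],
            if (length(nxt) > 0) series[nxt[1]])
  if (length(vals) == 0) stopf("unrecoverable series: no neighbours for index %d", idx)
  mean(vals)
}

# ---- kNN imputation --------------------------------------------------------

#' Impute a missing value by k nearest neighbours
#'
#' Rows of `table` with `NA` in `target` are queries; the remaining rows with
#' complete features are the donor pool. Features are z-score standardized
#' over the donors, distance is Euclidean over the features available in the
#' query row, and the imputed value is the mean of `target` over the `k`
#' nearest donors. With fewer than `k` donors the function falls back to a
#' moving average over the target series (with a warning).
#'
#' @param table data frame of numeric columns
#' @param target name of the column to impute
#' @param k neighbour count (default 3)
#' @param features feature column names (default: every other numeric column)
#' @return numeric vector of imputed values, one per query row, in row order
#' @export
impute_knn <- function(table, target, k = 3,
                       features = setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                                          target)) {
  query <- which(is.na(table[[target]]))
  if (length(query) == 0) return(numeric(0))
  donors <- which(!is.na(table[[target]]) &
                  stats::complete.cases(table[, features, drop = FALSE]))
  donors <- setdiff(donors, query)
  if (length(donors) < k) {
    warnf("only %d complete donor rows for kNN (k = %d); falling back to moving average",
          length(donors), k)
    return(vapply(query, function(i) moving_average_impute(table[[target]], i), 0))
  }
  feat <- as.matrix(table[, features, drop = FALSE])
  mu <- colMeans(feat[donors, , drop = FALSE])
  sdv <- apply(feat[donors, , drop = FALSE], 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(feat, 2, mu), 2, sdv, "/")
  vapply(query, function(i) {
    use <- which(!is.na(z[i, ]))
    if (length(use) == 0) return(mean(table[[target]][donors]))
    d <- sqrt(rowSums((z[donors, use, drop = FALSE] -
                       matrix(z[i, use], length(donors), length(use), byrow = TRUE))^2))
    nn <- donors[order(d)][seq_len(k)]
    mean(table[[target]][nn])
  }, 0)
}

# ---- C4.5-style decision-tree imputation -----------------------------------

discretize <- function(x, max_bins = 4) {
  ux <- sort(unique(x[!is.na(x)]))
  if (length(ux) <= max_bins) return(match(x, ux))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = max_bins + 1),
                               na.rm = TRUE, names = FALSE))
  if (length(br) < 3) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE))
}

entropy <- function(bins) {
  p <- table(bins) / length(bins)
  -sum(p * log2(p))
}

grow_tree <- function(rows, fbins, tbins, target, depth, max_depth = 3, min_n = 4) {
  node <- list(mean = mean(target[rows]))
  if (depth >= max_depth || length(rows) < min_n ||
      stats::var(target[rows]) == 0) return(node)
  h <- entropy(tbins[rows])
  best <- list(ratio = 0)
  for (f in names(fbins)) {
    fb <- fbins[[f]][rows]
    have <- !is.na(fb)                     # rows missing this feature are
    if (sum(have) < 2) next                # ignored in the gain computation
    sub <- split(seq_along(rows)[have], fb[have])
    if (length(sub) < 2) next
    w <- vapply(sub, length, 0) / sum(have)
    cond <- sum(w * vapply(sub, function(s) entropy(tbins[rows][s]), 0))
    gain <- (sum(have) / length(rows)) * (h - cond)
    split_info <- -sum(w * log2(w))
    if (split_info <= 0) next
    ratio <- gain / split_info
    if (ratio > best$ratio) best <- list(ratio = ratio, feature = f, groups = sub)
  }
  if (best$ratio <= 0) return(node)
  node$feature <- best$feature
  node$children <- lapply(best$groups, function(s)
    grow_tree(rows[s], fbins, tbins, target, depth + 1, max_depth, min_n))
  node
}

predict_tree <- function(node, fbins, row) {
  while (!is.null(node$feature)) {
    b <- fbins[[node$feature]][row]
    key <- as.character(b)
    if (is.na(b) || is.null(node$children[[key]])) break
    node <- node$children[[key]]
  }
  node$mean
}

#' Impute a missing value with a C4.5-style decision tree
#'
#' Grows a shallow tree (depth <= 3) on the rows where `target` is observed:
#' features are discretized into at most four bins, splits maximize the
#' information gain ratio of the binned target, and rows with a missing
#' feature value are ignored in that feature's gain computation (the gain is
#' down-weighted by the observed fraction, as C4.5 does). Leaves predict the
#' mean of the observed target values they contain.
#'
#' @param table data frame of numeric columns
#' @param target name of the column to impute (`NA` rows are queries)
#' @param features feature column names (default: every other numeric column)
#' @param max_depth maximum tree depth (default 3)
#' @return numeric vector of imputed values, one per query row, in row order
#' @export
impute_tree <- function(table, target,
                        features = setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                                           target),
                        max_depth = 3) {
  query <- which(is.na(table[[target]]))
  if (length(query) == 0) return(numeric(0))
  train <- which(!is.na(table[[target]]))
  if (length(train) == 0) stopf("no observed values of '%s' to learn from", target)
  if (length(train) == 1) return(rep(table[[target]][train], length(query)))
  fbins <- lapply(table[, features, drop = FALSE], discretize)
  tbins <- rep(NA_integer_, nrow(table))
  tbins[train] <- discretize(table[[target]][train])
  y <- table[[target]]
  root <- grow_tree(train, fbins, tbins, y, depth = 0, max_depth = max_depth)
  vapply(query, function(i) predict_tree(root, fbins, i), 0)
}

# ---- full cleaning pass ----------------------------------------------------

new_action <- function(record_index, element, kind, cause) {
  data.frame(record_index = record_index, element = element, kind = kind,
             cause = cause, stringsAsFactors = FALSE)
}

slot_of_day <- function(times) {
  h <- suppressWarnings(as.integer(substr(times, 1, 2)))
  h
}

#' Clean a device dataset against a rule set
#'
#' The three-step process: (i) validate every record; (ii) drop records
#' breaching a required element (date, time, measurement codes) — one action
#' per dropped record; (iii) repair optional-element breaches in the kept
#' records: out-of-range values are invalidated and re-estimated by kNN
#' imputation, missing values are completed by the decision-tree imputer, and
#' missing or wrong units are filled with their fixed value. The cleaned
#' dataset re-validates with zero violations, and a second cleaning pass is a
#' no-op.
#'
#' @param ds a [device_dataset()]
#' @param rules a rule set (default [bpm_rules()])
#' @param k kNN neighbour count (default 3)
#' @return list with `dataset` (the cleaned [device_dataset()]) and `report`
#'   (a `cleaning_report`: tallies, the accuracy / faulty / completion
#'   metrics, and the per-record action log)
#' @export
clean_dataset <- function(ds, rules = bpm_rules(), k = 3) {
  total <- nrow(ds$records)
  viol <- validate_dataset(ds, rules)
  required <- rules$element[rules$required]
  actions <- new_action(integer(), character(), character(), character())

  drop_idx <- integer()
  for (i in unique(viol$record)) {
    vi <- viol[viol$record == i, , drop = FALSE]
    req <- vi[vi$element %in% required, , drop = FALSE]
    if (nrow(req) > 0) {
      drop_idx <- c(drop_idx, i)
      cause <- if (any(req$cause == "erroneous")) "erroneous" else "missing"
      actions <- rbind(actions, new_action(i, req$element[1], "dropped_record", cause))
    }
  }

  recs <- ds$records
  kept <- setdiff(seq_len(total), drop_idx)
  impute_plan <- list()
  for (i in kept) {
    vi <- viol[viol$record == i, , drop = FALSE]
    for (j in seq_len(nrow(vi))) {
      el <- vi$element[j]; cause <- vi$cause[j]
      rule <- rules[rules$element == el, , drop = FALSE]
      if (nrow(rule) != 1 || rule$required) next
      if (rule$constraint == "fixed") {
        recs[i, el] <- rule$fixed
        actions <- rbind(actions, new_action(i, el, "filled_with_value", cause))
      } else if (rule$constraint == "range") {
        if (cause == "erroneous") recs[i, el] <- NA   # invalidate, then re-estimate
        impute_plan[[length(impute_plan) + 1]] <-
          list(record = i, element = el,
               kind = if (cause == "erroneous") "knn_imputation" else "c45_imputation",
               cause = cause)
      }
    }
  }

  if (length(impute_plan) > 0) {
    kept_recs <- recs[kept, , drop = FALSE]
    value_cols <- paste0(VITALS, "_value")
    feat_base <- data.frame(slot = slot_of_day(kept_recs$time))
    for (vc in value_cols) feat_base[[vc]] <- kept_recs[[vc]]
    pos <- match(vapply(impute_plan, `[[`, 0L, "record"), kept)
    for (idx in seq_along(impute_plan)) {
      p <- impute_plan[[idx]]
      qrow <- pos[idx]
      tab <- feat_base
      # donors for the target column are the originally observed values only
      # (imputed cells are not chained into later imputations of the same
      # column; imputed values of *other* columns may serve as features)
      tab[[p$element]] <- kept_recs[[p$element]]
      imputer <- if (p$kind == "knn_imputation") {
        function(tb) impute_knn(tb, p$element, k = k)
      } else {
        function(tb) impute_tree(tb, p$element)
      }
      vals <- imputer(tab)
      v <- round(vals[match(qrow, which(is.na(tab[[p$element]])))])
      recs[p$record, p$element] <- v
      feat_base[[p$element]][qrow] <- v
      actions <- rbind(actions, new_action(p$record, p$element, p$kind, p$cause))
    }
  }

  cleaned <- device_dataset(ds$spec, recs[kept, , drop = FALSE], ds$period_days)
  dropped <- length(drop_idx)
  n_actions <- nrow(actions)
  acc <- data_accuracy(total, n_actions)
  report <- structure(list(
    device = ds$spec$name,
    total_records = total,
    final_records = nrow(cleaned$records),
    total_actions = n_actions,
    dropped_records = dropped,
    errors_corrected = n_actions - dropped,
    data_accuracy = acc,
    faulty_data = faulty_fraction(acc),
    data_completion = data_completion(total, dropped),
    actions = actions
  ), class = "cleaning_report")
  list(dataset = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %s\n", x$device))
  cat(sprintf("  records: %d -> %d (dropped %d), actions: %d (corrected %d)\n",
              x$total_records, x$final_records, x$dropped_records,
              x$total_actions, x$errors_corrected))
  cat(sprintf("  accuracy %.2f%%  faulty %.2f%%  completion %.2f%%\n",
              round_half_up(100 * x$data_accuracy),
              round_half_up(100 * x$faulty_data),
              round_half_up(100 * x$data_completion)))
  invisible(x)
}

#' Render a cleaning report as a one-row summary data frame
#'
#' Percentages are rendered at two decimals (half-up), matching the
#' reporting convention used throughout the package.
#'
#' @param x a `cleaning_report`
#' @param row.names,optional,... ignored (S3 signature)
#' @return one-row data frame
#' @export
as.data.frame.cleaning_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(device = x$device,
             initial_records = x$total_records,
             final_records = x$final_records,
             errors_encountered = x$total_actions,
             records_dropped = x$dropped_records,
             errors_corrected = x$errors_corrected,
             data_accuracy_pct = round_half_up(100 * x$data_accuracy),
             faulty_data_pct = round_half_up(100 * x$faulty_data),
             data_completion_pct = round_half_up(100 * x$data_completion),
             stringsAsFactors = FALSE)
}
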