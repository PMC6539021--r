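test_that("validate_record flags range breaches, missing required, and nothing else", {
  rules <- bpm_rules()
  rec <- clean_record()
  expect_equal(nrow(validate_record(rec, rules)), 0)

  faulty <- clean_record(sys = 7)   # below the 70 mmHg floor
  v <- validate_record(faulty, rules)
  expect_equal(nrow(v), 1)
  expect_equal(v$element, "systolic_bp_value")
  expect_equal(v$cause, "erroneous")

  nocode <- clean_record()
  nocode$heart_rate_code <- NA_character_
  v2 <- validate_record(nocode, rules)
  expect_equal(nrow(v2), 1)
  expect_equal(v2$element, "heart_rate_code")
  expect_equal(v2$cause, "missing")

  baddate <- clean_record(); baddate$date <- "2018/11/13"
  expect_equal(validate_record(baddate, rules)$cause, "erroneous")

  badcode <- clean_record(); badcode$systolic_bp_code <- "not-a-uuid"
  expect_equal(validate_record(badcode, rules)$element, "systolic_bp_code")
})

test_that("the optional systolic > diastolic cross-field rule works when enabled", {
  rules <- bpm_rules(cross_field = TRUE)
  swapped <- clean_record(dia = 110, sys = 90)
  v <- validate_record(swapped, rules)
  expect_true("systolic_gt_diastolic" %in% v$element)
  expect_equal(nrow(validate_record(clean_record(), rules)), 0)
})

test_that("accuracy, faulty and completion follow their defining ratios", {
  expect_equal(round_half_up(100 * data_accuracy(238, 17)), 92.86)
  expect_equal(round_half_up(100 * data_accuracy(244, 20)), 91.80)
  expect_equal(round_half_up(100 * faulty_fraction(data_accuracy(244, 20))), 8.20)
  expect_equal(data_accuracy(100, 0), 1)
  expect_equal(faulty_fraction(1), 0)
  expect_equal(data_completion(100, 0), 1)
  expect_equal(round_half_up(100 * data_completion(243, 4)), 98.35)
  expect_error(data_accuracy(0, 0), "undefined")
  expect_error(data_completion(0, 0), "undefined")
  expect_error(data_accuracy(10, 11), "outside")
  # exact complement at machine precision for arbitrary tallies
  for (ta in 0:20) {
    acc <- data_accuracy(244, ta)
    expect_identical(acc + faulty_fraction(acc), 1)
  }
})

test_that("completion strategy tiers follow variation and sampling frequency", {
  low <- rep(c(98, 102), 10)      # CV ~ 0.02
  med <- rep(c(90, 110), 10)      # CV ~ 0.10
  high <- rep(c(60, 140), 10)     # CV ~ 0.41
  expect_equal(select_completion_strategy(low, samples_per_day = 4), "last_value")
  expect_equal(select_completion_strategy(med, samples_per_day = 4), "moving_average")
  expect_equal(select_completion_strategy(high, samples_per_day = 4), "ml")
  # infrequent sampling forces ML regardless of variation
  expect_equal(select_completion_strategy(low, samples_per_day = 1), "ml")
  expect_error(select_completion_strategy(rep(NA_real_, 5), 4), "unrecoverable")
})

test_that("kNN imputation matches hand-computed neighbours", {
  # all donors identical -> the constant
  tab <- data.frame(f1 = c(1, 2, 3, 4), y = c(50, 50, 50, NA))
  expect_equal(impute_knn(tab, "y", k = 3), 50)

  # 3 donors, k = 1: nearest neighbour by hand (feature distances 1, 4, 9)
  tab2 <- data.frame(f1 = c(1, 4, 9, 0), y = c(10, 20, 30, NA))
  expect_equal(impute_knn(tab2, "y", k = 1), 10)

  # k = number of donors -> grand mean of the field
  expect_equal(impute_knn(tab2, "y", k = 3), mean(c(10, 20, 30)))

  # fewer donors than k -> moving-average fallback with a warning
  tab3 <- data.frame(f1 = c(1, 2, 3), y = c(10, NA, 30))
  expect_warning(v <- impute_knn(tab3, "y", k = 3), "falling back")
  expect_equal(v, 20)
})

test_that("decision-tree imputation agrees with exhaustive single-split oracles", {
  # constant target -> the constant
  tab <- data.frame(f1 = c(1, 2, 3, 4, 5), y = c(7, 7, 7, 7, NA))
  expect_equal(impute_tree(tab, "y"), 7)

  # two observed rows -> their mean (no admissible split at n = 2)
  tab2 <- data.frame(f1 = c(0, 1, 0), y = c(10, 20, NA))
  expect_equal(impute_tree(tab2, "y"), 15)

  # pure binary split available: leaf mean of the matching partition,
  # cross-checked by enumerating every single-feature split
  tab3 <- data.frame(f1 = c(0, 0, 0, 1, 1, 1, 0),
                     f2 = c(5, 6, 7, 5, 6, 7, 6),
                     y = c(10, 10, 10, 20, 20, 20, NA))
  got <- impute_tree(tab3, "y")
  oracle <- local({
    train <- tab3[!is.na(tab3$y), ]
    best <- NULL; best_var <- Inf
    for (f in c("f1", "f2")) for (cut in unique(train[[f]])) {
      g <- train[[f]] <= cut
      if (all(g) || !any(g)) next
      pooled <- sum(tapply(train$y, g, function(v) sum((v - mean(v))^2)))
      if (pooled < best_var) { best_var <- pooled; best <- list(f = f, cut = cut) }
    }
    g <- train[[best$f]] <= best$cut
    side <- tab3[[best$f]][7] <= best$cut
    mean(train$y[g == side])
  })
  expect_equal(got, oracle)   # both must land in the f1 = 0 partition
  expect_equal(got, 10)

  # missing feature values are ignored, not fatal
  tab4 <- data.frame(f1 = c(0, 0, 1, 1, NA, 0), y = c(10, 10, 20, 20, 30, NA))
  expect_true(is.finite(impute_tree(tab4, "y")))
})

test_that("cleaning reproduces the reference overall tallies for all four devices", {
  ref <- reference_cleaning_table()
  for (i in seq_len(nrow(ref))) {
    cl <- clean_dataset(make_table_fixture(ref$device[i]))
    r <- as.data.frame(cl$report)
    expect_equal(r$initial_records, ref$initial[i])
    expect_equal(r$final_records, ref$final[i])
    expect_equal(r$errors_encountered, ref$errors[i])
    expect_equal(r$records_dropped, ref$dropped[i])
    expect_equal(r$errors_corrected, ref$errors[i] - ref$dropped[i])
    expect_equal(r$data_accuracy_pct, ref$accuracy[i])
    expect_equal(r$faulty_data_pct, ref$faulty[i])
    expect_equal(r$data_completion_pct, ref$completion[i])
  }
})

test_that("cleaning is idempotent and leaves a fully valid dataset", {
  cl1 <- clean_dataset(make_table_fixture("iHealth View"))
  expect_equal(nrow(validate_dataset(cl1$dataset)), 0)
  cl2 <- clean_dataset(cl1$dataset)
  expect_equal(cl2$report$total_actions, 0)
  expect_equal(cl2$report$data_accuracy, 1)
  expect_identical(cl2$dataset$records, cl1$dataset$records)
})

test_that("cleaning-report invariants hold across seeds", {
  spec <- device_spec("x", "x", "x", "BPM", 4)
  for (seed in c(2, 9, 27)) {
    p <- error_profile(
      erroneous = c(date = 1, systolic_bp_value = 2, systolic_bp_unit = 1),
      missing = c(heart_rate_code = 1, diastolic_bp_value = 3),
      absent_records = 2)
    ds <- generate_stream(spec, days = 30, profile = p, seed = seed)
    rep <- clean_dataset(ds)$report
    expect_identical(rep$data_accuracy + rep$faulty_data, 1)
    expect_lte(rep$data_accuracy, rep$data_completion)
    expect_equal(rep$errors_corrected, rep$total_actions - rep$dropped_records)
    expect_equal(rep$dropped_records, 2)   # the two required-element breaches
    expect_equal(rep$total_actions, 8)
  }
})

test_that("imputed replacements satisfy the range rules they repair", {
  ds <- make_table_fixture("Withings BPM")
  cl <- clean_dataset(ds)
  imputed <- cl$report$actions[cl$report$actions$kind %in%
                               c("knn_imputation", "c45_imputation"), ]
  expect_gt(nrow(imputed), 0)
  rules <- bpm_rules()
  kept_map <- setdiff(seq_len(n_records(ds)),
                      cl$report$actions$record_index[
                        cl$report$actions$kind == "dropped_record"])
  for (j in seq_len(nrow(imputed))) {
    el <- imputed$element[j]
    row <- match(imputed$record_index[j], kept_map)
    val <- cl$dataset$records[row, el]
    rule <- rules[rules$element == el, ]
    expect_true(val >= rule$min && val <= rule$max)
    expect_equal(val, round(val))
  }
})
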