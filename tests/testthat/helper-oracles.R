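# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# ICC(2,1) via stats::aov on the long-format data
icc_aov_oracle <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subject = factor(as.vector(row(m))),
                   session = factor(as.vector(col(m))))
  a <- stats::anova(stats::aov(y ~ subject + session, data = df))
  msr <- a["subject", "Mean Sq"]
  msc <- a["session", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Brute-force Dice coefficient: explicit pair enumeration plus greedy
# multiset matching by element removal
dice_oracle <- function(a, b) {
  pairs_of <- function(s) {
    toks <- unlist(strsplit(toupper(s), "[^A-Z0-9]+"))
    out <- character()
    for (t in toks) {
      if (is.na(t) || nchar(t) < 2) next
      for (i in seq_len(nchar(t) - 1))
        out <- c(out, substr(t, i, i + 1))
    }
    out
  }
  pa <- pairs_of(a); pb <- pairs_of(b)
  if (length(pa) + length(pb) == 0) return(0)
  pool <- pb; common <- 0
  for (p in pa) {
    j <- match(p, pool)
    if (!is.na(j)) { common <- common + 1; pool <- pool[-j] }
  }
  2 * common / (length(pa) + length(pb))
}

# a conformant single observation record as a one-row data frame
clean_record <- function(dia = 80, sys = 120, hr = 70) {
  codes <- c("8462e0f8-1a2b-4c3d-9e4f-5a6b7c8d9e0f",
             "8480a1b2-2c3d-4e5f-8a6b-7c8d9e0f1a2b",
             "8867c3d4-3e4f-4a5b-9c6d-8d9e0f1a2b3c")
  data.frame(date = "2018-11-13", time = "08:00:00",
             diastolic_bp_code = codes[1], diastolic_bp_value = dia,
             diastolic_bp_unit = "mmHg",
             systolic_bp_code = codes[2], systolic_bp_value = sys,
             systolic_bp_unit = "mmHg",
             heart_rate_code = codes[3], heart_rate_value = hr,
             heart_rate_unit = "bpm",
             stringsAsFactors = FALSE)
}

# the reference overall cleaning tallies of the four BPM devices
reference_cleaning_table <- function() {
  data.frame(
    device = c("iHealth Clear", "iHealth Track", "Withings BPM", "iHealth View"),
    initial = c(238L, 239L, 244L, 243L),
    final = c(238L, 237L, 243L, 239L),
    errors = c(17L, 13L, 20L, 22L),
    dropped = c(0L, 2L, 1L, 4L),
    accuracy = c(92.86, 94.56, 91.80, 90.95),
    faulty = c(7.14, 5.44, 8.20, 9.05),
    completion = c(100.00, 99.16, 99.59, 98.35),
    stringsAsFactors = FALSE)
}
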