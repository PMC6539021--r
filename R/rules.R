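#' Declarative constraint rules for device observation elements
#'
#' A rule set is a data frame with one row per dataset element, mirroring a
#' device manufacturer's element-constraint table. Each element carries a
#' semantic type, a required flag, and exactly one constraint kind:
#'
#' * `format` — the value must match `pattern` (a regular expression);
#' * `range` — a numeric value must lie in `[min, max]`;
#' * `fixed` — the value must equal the `fixed` string (e.g. a unit);
#' * `unique_id` — the value must be a well-formed UUID;
#' * `cross_field` — a predicate over several elements of the same record.
#'
#' @param element element name (must match a dataset column)
#' @param type one of `"string"`, `"integer"`, `"uuid"`
#' @param required logical: a breach on a required element invalidates the
#'   whole record
#' @param constraint one of `"format"`, `"range"`, `"fixed"`, `"unique_id"`,
#'   `"cross_field"`
#' @param pattern,min,max,fixed constraint parameters (unused ones `NA`)
#' @return a one-row `data.frame` of class joining into a rule set via
#'   `rbind()`
#' @export
constraint_rule <- function(element, type, required, constraint,
                            pattern = NA_character_, min = NA_real_,
                            max = NA_real_, fixed = NA_character_) {
  type <- match.arg(type, c("string", "integer", "uuid"))
  constraint <- match.arg(constraint,
                          c("format", "range", "fixed", "unique_id", "cross_field"))
  data.frame(element = element, type = type, required = required,
             constraint = constraint, pattern = pattern,
             min = min, max = max, fixed = fixed,
             stringsAsFactors = FALSE)
}

UUID_PATTERN <- "^[0-9a-fA-F]{8}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{12}$"

#' Default constraint rules for a blood-pressure monitor
#'
#' Eleven elements per observation record: date, time, and a
#' code/value/unit triple for each of diastolic pressure, systolic pressure
#' and heart rate. Date/time and the three measurement codes are required;
#' values and units are optional. Value ranges are physiological plausibility
#' bounds (mmHg for pressures, beats/min for heart rate); units are fixed
#' strings.
#'
#' @param cross_field if `TRUE`, adds the systolic > diastolic cross-field
#'   check (off by default)
#' @return rule-set data frame
#' @export
bpm_rules <- function(cross_field = FALSE) {
  r <- rbind(
    constraint_rule("date", "string", TRUE, "format",
                    pattern = "^\\d{4}-\\d{2}-\\d{2}$"),
    constraint_rule("time", "string", TRUE, "format",
                    pattern = "^\\d{2}:\\d{2}:\\d{2}$"),
    constraint_rule("diastolic_bp_code", "uuid", TRUE, "unique_id"),
    constraint_rule("diastolic_bp_value", "integer", FALSE, "range",
                    min = 40, max = 120),
    constraint_rule("diastolic_bp_unit", "string", FALSE, "fixed",
                    fixed = "mmHg"),
    constraint_rule("systolic_bp_code", "uuid", TRUE, "unique_id"),
    constraint_rule("systolic_bp_value", "integer", FALSE, "range",
                    min = 70, max = 200),
    constraint_rule("systolic_bp_unit", "string", FALSE, "fixed",
                    fixed = "mmHg"),
    constraint_rule("heart_rate_code", "uuid", TRUE, "unique_id"),
    constraint_rule("heart_rate_value", "integer", FALSE, "range",
                    min = 30, max = 220),
    constraint_rule("heart_rate_unit", "string", FALSE, "fixed",
                    fixed = "bpm")
  )
  if (cross_field) {
    r <- rbind(r, constraint_rule("systolic_gt_diastolic", "integer", FALSE,
                                  "cross_field"))
  }
  class(r) <- c("constraint_rules", class(r))
  r
}

#' Read / write a constraint-rules file (YAML)
#'
#' The on-disk format is a YAML list of rule entries with the same fields as
#' [constraint_rule()].
#'
#' @param path file path
#' @return rule-set data frame ([read_constraint_rules()]); invisible path
#'   ([write_constraint_rules()])
#' @export
read_constraint_rules <- function(path) {
  entries <- yaml::read_yaml(path)
  rules <- do.call(rbind, lapply(entries, function(e) {
    constraint_rule(e$element, e$type, isTRUE(e$required), e$constraint,
                    pattern = e$pattern %||% NA_character_,
                    min = e$min %||% NA_real_, max = e$max %||% NA_real_,
                    fixed = e$fixed %||% NA_character_)
  }))
  class(rules) <- c("constraint_rules", class(rules))
  rules
}

#' @rdname read_constraint_rules
#' @param rules rule-set data frame
#' @export
write_constraint_rules <- function(rules, path) {
  entries <- lapply(seq_len(nrow(rules)), function(i) {
    e <- as.list(rules[i, , drop = FALSE])
    e <- lapply(e, function(v) if (length(v) == 1 && is.na(v)) NULL else v)
    Filter(Negate(is.null), e)
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
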