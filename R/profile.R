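#' Patient-record field schema
#'
#' The flat field set a severity rule may reference. Numeric fields carry the
#' units used throughout: blood pressure in mm Hg, lipids and glucose in
#' mmol/L, uric acid in umol/L, BMI in kg/m^2, PHQ-9 as the 0-27 total score.
#'
#' @return character vector of field names.
#' @export
patient_fields <- function() {
  c("patient_id", "sex", "age", "height", "weight", "bmi", "pregnant",
    "disease_history", "glucose", "total_cholesterol", "triglyceride",
    "hdl", "ldl", "uric_acid", "systolic_bp", "diastolic_bp",
    "cigarettes_per_day", "drinks_per_week", "diet", "medications",
    "medication_adherence", "phq9", "ipaq")
}

#' Construct a validated patient record
#'
#' Any field may be missing; missing fields never match a rule condition, so
#' absence of evidence maps to severity 0 rather than an error. BMI is
#' derived from height (cm) and weight (kg) when not given directly.
#'
#' @param patient_id identifier (required).
#' @param ... fields from [patient_fields()].
#' @return a named list of class `edurec_patient`.
#' @export
patient_record <- function(patient_id, ...) {
  rec <- list(...)
  bad <- setdiff(names(rec), setdiff(patient_fields(), "patient_id"))
  if (length(bad) > 0L) stop("unknown patient fields: ",
                             paste(bad, collapse = ", "))
  rec$patient_id <- patient_id
  num_fields <- c("age", "height", "weight", "bmi", "glucose",
                  "total_cholesterol", "triglyceride", "hdl", "ldl",
                  "uric_acid", "systolic_bp", "diastolic_bp",
                  "cigarettes_per_day", "drinks_per_week", "phq9")
  for (f in intersect(num_fields, names(rec))) {
    if (!is.na(rec[[f]]) && rec[[f]] < 0) stop(f, " must be nonnegative")
  }
  if (!is.null(rec$phq9) && !is.na(rec$phq9) && rec$phq9 > 27) {
    stop("phq9 total cannot exceed 27")
  }
  if (!is.null(rec$diet) && !is.na(rec$diet) &&
      !rec$diet %in% c("good", "medium", "poor")) {
    stop("diet must be good/medium/poor")
  }
  if (!is.null(rec$ipaq) && !is.na(rec$ipaq) &&
      !rec$ipaq %in% c("high", "moderate", "low")) {
    stop("ipaq must be high/moderate/low")
  }
  if (is.null(rec$bmi) && !is.null(rec$height) && !is.null(rec$weight)) {
    rec$bmi <- rec$weight / (rec$height / 100)^2
  }
  structure(rec, class = "edurec_patient")
}

rule_env_defaults <- function() {
  list(patient_id = NA_character_, sex = NA_character_, age = NA_real_,
       height = NA_real_, weight = NA_real_, bmi = NA_real_, pregnant = NA,
       disease_history = character(0), glucose = NA_real_,
       total_cholesterol = NA_real_, triglyceride = NA_real_,
       hdl = NA_real_, ldl = NA_real_, uric_acid = NA_real_,
       systolic_bp = NA_real_, diastolic_bp = NA_real_,
       cigarettes_per_day = NA_real_, drinks_per_week = NA_real_,
       diet = NA_character_, medications = character(0),
       medication_adherence = NA_character_, phq9 = NA_real_,
       ipaq = NA_character_)
}

new_ruleset <- function(term, when, value, priority) {
  exprs <- lapply(when, function(w) parse(text = w)[[1L]])
  rs <- data.frame(term = term, when = when, value = as.integer(value),
                   priority = as.integer(priority), stringsAsFactors = FALSE)
  rs$expr <- exprs
  class(rs) <- c("edurec_ruleset", "data.frame")
  rs
}

#' Load a severity ruleset from YAML
#'
#' Each rule is a mapping with keys `term` (a label of the vector space),
#' `when` (an R predicate over [patient_fields()]; comparisons, range and set
#' membership, conjunctions), `value` (integer severity 0-3) and optional
#' `priority` (default 1). Validation is strict and happens at load time: an
#' out-of-range value, a term absent from the space, or a predicate
#' referencing an unknown field each raise an error naming the offending rule.
#'
#' @param source path to a YAML file, or a YAML string.
#' @param space an `edurec_space` the targets must belong to.
#' @return an `edurec_ruleset` data frame (`term`, `when`, `value`,
#'   `priority`, parsed `expr`).
#' @export
load_ruleset <- function(source, space = default_space()) {
  raw <- if (file.exists(source)) yaml::read_yaml(source) else
    yaml::yaml.load(source)
  if (length(raw) == 0L) stop("empty ruleset")
  fields <- patient_fields()
  parsed <- lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    where <- sprintf("rule %d (term '%s')", i, r$term %||% "?")
    if (is.null(r$term) || is.null(r$when) || is.null(r$value)) {
      stop(where, ": needs term, when and value")
    }
    if (!r$term %in% space$terms) {
      stop(where, ": unknown term '", r$term, "'")
    }
    val <- suppressWarnings(as.integer(r$value))
    if (is.na(val) || val < 0L || val > 3L) {
      stop(where, ": value must be an integer in 0..3, got ", r$value)
    }
    expr <- tryCatch(parse(text = as.character(r$when))[[1L]],
                     error = function(e) stop(where, ": malformed predicate: ",
                                              conditionMessage(e)))
    unknown <- setdiff(all.vars(expr), fields)
    if (length(unknown) > 0L) {
      stop(where, ": unknown record fields in predicate: ",
           paste(unknown, collapse = ", "))
    }
    list(term = r$term, when = as.character(r$when), value = val,
         priority = as.integer(r$priority %||% 1L))
  })
  new_ruleset(vapply(parsed, `[[`, character(1), "term"),
              vapply(parsed, `[[`, character(1), "when"),
              vapply(parsed, `[[`, integer(1), "value"),
              vapply(parsed, `[[`, integer(1), "priority"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The shipped default severity ruleset
#'
#' Loads the packaged ruleset covering the default 33-term space: clinical
#' reference ranges for blood pressure, the five lipid/glucose labs and
#' sex- and age-banded uric acid, BMI (Chinese reference range 18.5-23.9),
#' PHQ-9 and IPAQ questionnaire bands, smoking/drinking/diet grading,
#' disease-history and medication mappings. All cut-points are configuration:
#' edit a copy of the YAML (see
#' `system.file("extdata", "default_rules.yaml", package = "edurec")`) to
#' override them.
#'
#' @param space the `edurec_space` to validate against.
#' @return an `edurec_ruleset`.
#' @export
default_ruleset <- function(space = default_space()) {
  load_ruleset(system.file("extdata", "default_rules.yaml",
                           package = "edurec", mustWork = TRUE), space)
}

#' Evaluate severity rules on one patient record
#'
#' For each term of the space, the matching rules with the highest priority
#' are selected and the maximum of their values wins; terms with no matching
#' rule score 0. A condition over missing fields does not match. The result
#' is the patient vector: integer severities 0 (no need) to 3 (worst).
#'
#' @param record an `edurec_patient` (or plain named list of fields).
#' @param ruleset an `edurec_ruleset`.
#' @param space an `edurec_space`; every rule target must belong to it.
#' @return named integer vector over `space$terms` with attribute
#'   `patient_id`.
#' @export
evaluate_rules <- function(record, ruleset, space = default_space()) {
  bad <- setdiff(unique(ruleset$term), space$terms)
  if (length(bad) > 0L) {
    stop("ruleset targets terms outside the space: ",
         paste(bad, collapse = ", "))
  }
  env_fields <- rule_env_defaults()
  for (f in intersect(names(record), names(env_fields))) {
    if (!is.null(record[[f]])) env_fields[[f]] <- record[[f]]
  }
  env <- list2env(env_fields, parent = baseenv())
  matched <- vapply(ruleset$expr, function(e) {
    isTRUE(tryCatch(eval(e, env), error = function(err) FALSE))
  }, logical(1))

  out <- stats::setNames(integer(length(space$terms)), space$terms)
  hit <- ruleset[matched, , drop = FALSE]
  if (nrow(hit) > 0L) {
    for (term in unique(hit$term)) {
      sub <- hit[hit$term == term, , drop = FALSE]
      top <- sub[sub$priority == max(sub$priority), , drop = FALSE]
      out[term] <- max(top$value)
    }
  }
  attr(out, "patient_id") <- record$patient_id %||% NA_character_
  out
}

#' Patient-vector matrix for a list of records
#'
#' @param records list of patient records.
#' @inheritParams evaluate_rules
#' @return integer matrix, patients in rows (named by `patient_id`), terms in
#'   columns.
#' @export
patient_vector_matrix <- function(records, ruleset, space = default_space()) {
  rows <- lapply(records, evaluate_rules, ruleset = ruleset, space = space)
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(records, function(r) r$patient_id %||% NA_character_,
                          character(1))
  out
}
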