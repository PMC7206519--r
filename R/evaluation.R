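#' Keyword-extraction precision against manual annotation
#'
#' Counts, over all documents, the automatically extracted keywords that
#' exactly match a manually annotated keyword (after trimming whitespace and
#' lower-casing) and divides by the total number of manual keywords. When the
#' per-document extraction counts equal the annotation counts, precision
#' equals recall.
#'
#' @param auto named list: `doc_id -> character vector` of extracted surfaces
#'   (an `edurec_keywords` table is also accepted).
#' @param manual named list: `doc_id -> character vector` of manual keywords.
#' @return list of class `edurec_kwprec` with `n_auto`, `n_manual`,
#'   `n_correct` and `precision`.
#' @export
keyword_precision <- function(auto, manual) {
  if (is.data.frame(auto)) {
    auto <- split(auto$surface, auto$doc_id)
  }
  only_auto <- setdiff(names(auto), names(manual))
  only_manual <- setdiff(names(manual), names(auto))
  if (length(only_auto) + length(only_manual) > 0L) {
    stop("document coverage differs: ",
         paste(c(only_auto, only_manual), collapse = ", "))
  }
  norm <- function(x) tolower(trimws(x))
  n_correct <- 0L; n_auto <- 0L; n_manual <- 0L
  for (d in names(manual)) {
    a <- unique(norm(auto[[d]])); m <- unique(norm(manual[[d]]))
    n_correct <- n_correct + length(intersect(a, m))
    n_auto <- n_auto + length(a)
    n_manual <- n_manual + length(m)
  }
  structure(list(n_auto = n_auto, n_manual = n_manual,
                 n_correct = n_correct,
                 precision = n_correct / n_manual),
            class = "edurec_kwprec")
}

#' @export
print.edurec_kwprec <- function(x, ...) {
  cat(sprintf("keyword precision: %d/%d = %.1f%%\n",
              x$n_correct, x$n_manual, 100 * x$precision))
  invisible(x)
}

judgment_lookup <- function(judgments, patient_id = NULL) {
  if (is.data.frame(judgments)) {
    if (!is.null(patient_id)) {
      judgments <- judgments[judgments$patient_id == patient_id, ,
                             drop = FALSE]
    }
    stats::setNames(as.integer(judgments$grade), judgments$doc_id)
  } else {
    stats::setNames(as.integer(judgments), names(judgments))
  }
}

grade_credit <- function(grades) {
  grades[is.na(grades)] <- 0L
  c(0, 0.5, 1)[grades + 1L]
}

#' Credited precision at k
#'
#' `P@k` with graded relevance: a most-need document (grade 2) counts 1, a
#' partial-need document (grade 1) counts 0.5, no-need (grade 0) and unjudged
#' documents count 0. If `k` exceeds the ranking length the metric is
#' computed over the full ranking with a warning.
#'
#' @param ranking character vector of doc_ids in rank order.
#' @param judgments named integer vector `doc_id -> grade` in `{0, 1, 2}`,
#'   or a data frame (`doc_id`, `grade`).
#' @param k cut-off rank (>= 1).
#' @return credited precision in `[0, 1]`.
#' @export
precision_at_k <- function(ranking, judgments, k) {
  stopifnot(k >= 1)
  if (k > length(ranking)) {
    warning("k = ", k, " exceeds ranking length ", length(ranking),
            "; using the full ranking")
    k <- length(ranking)
  }
  grades <- judgment_lookup(judgments)
  top <- grades[ranking[seq_len(k)]]
  sum(grade_credit(top)) / k
}

#' Macro precision at k over patients
#'
#' Arithmetic mean of per-patient credited `P@k`.
#'
#' @param rankings named list: `patient_id -> doc_id ranking`.
#' @param judgments data frame (`patient_id`, `doc_id`, `grade`).
#' @param k cut-off rank.
#' @return macro precision in `[0, 1]`.
#' @export
macro_precision_at_k <- function(rankings, judgments, k) {
  if (length(rankings) == 0L) stop("no patients")
  per <- vapply(names(rankings), function(p) {
    precision_at_k(rankings[[p]], judgment_lookup(judgments, p), k)
  }, numeric(1))
  mean(per)
}

#' Average precision for one patient under graded judgments
#'
#' `AP = (1 / R) * sum_k P@k * rel(k)` where `rel(k)` indicates grade >= 1 at
#' rank `k` (partial need counts as relevant for the indicator, and as 0.5
#' inside the credited `P@k`), and `R` is the number of relevant documents.
#'
#' @inheritParams precision_at_k
#' @return average precision, or `NA` when the patient has no relevant
#'   document.
#' @export
average_precision <- function(ranking, judgments) {
  if (length(ranking) == 0L) stop("empty ranking")
  grades <- judgment_lookup(judgments)
  top <- grades[ranking]
  top[is.na(top)] <- 0L
  rel <- top >= 1L
  r_total <- sum(judgment_lookup(judgments) >= 1L, na.rm = TRUE)
  if (r_total == 0L) return(NA_real_)
  credits <- grade_credit(top)
  p_at <- cumsum(credits) / seq_along(credits)
  sum(p_at[rel]) / r_total
}

#' Mean average precision over patients
#'
#' Mean of per-patient [average_precision()]. Patients with no relevant
#' (grade >= 1) document have undefined AP and are excluded with a warning.
#'
#' @inheritParams macro_precision_at_k
#' @return MAP in `[0, 1]`.
#' @export
mean_average_precision <- function(rankings, judgments) {
  if (length(rankings) == 0L) stop("no patients")
  ap <- vapply(names(rankings), function(p) {
    average_precision(rankings[[p]], judgment_lookup(judgments, p))
  }, numeric(1))
  dropped <- names(ap)[is.na(ap)]
  if (length(dropped) > 0L) {
    warning("patients with no relevant document excluded from MAP: ",
            paste(dropped, collapse = ", "))
  }
  ap <- ap[!is.na(ap)]
  if (length(ap) == 0L) stop("no patient has a relevant document")
  mean(ap)
}

#' Monte-Carlo macro precision of random recommendation
#'
#' Simulates uniformly random rankings of `n` documents for `m` patients,
#' each patient having exactly `relevant_per_patient` most-need (grade 2)
#' documents, and averages macro `P@k` over replicates. Converges to
#' `relevant_per_patient / n`, the expected precision of a random
#' recommender.
#'
#' @param m number of patients.
#' @param n number of documents.
#' @param relevant_per_patient relevant documents per patient (<= n).
#' @param k cut-off rank.
#' @param replicates Monte-Carlo replicates (>= 1).
#' @param seed RNG seed.
#' @return the Monte-Carlo mean macro precision.
#' @export
random_baseline <- function(m, n, relevant_per_patient, k, replicates = 1000,
                            seed = 1) {
  stopifnot(relevant_per_patient <= n, relevant_per_patient >= 0)
  if (replicates < 1) stop("replicates must be >= 1")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  reps <- vapply(seq_len(replicates), function(r) {
    per_patient <- vapply(seq_len(m), function(i) {
      top <- sample.int(n, k)  # top-k of a uniformly random ranking
      sum(top <= relevant_per_patient) / k
    }, numeric(1))
    mean(per_patient)
  }, numeric(1))
  mean(reps)
}

#' Metric report shaped like a method-comparison table
#'
#' Computes MAP and macro `P@k` at the requested cut-offs for one or more
#' named ranking sets (for example one per keyword-extraction method).
#'
#' @param ranking_sets named list of ranking lists (each as in
#'   [macro_precision_at_k()]).
#' @param judgments data frame (`patient_id`, `doc_id`, `grade`).
#' @param at integer vector of cut-offs (default
#'   `c(1, 2, 3, 4, 5, 10, 15, 20, 25, 30)`).
#' @return data frame: one row per method, columns `method`, `map`,
#'   `p_at_<k>`.
#' @export
metrics_report <- function(ranking_sets, judgments,
                           at = c(1, 2, 3, 4, 5, 10, 15, 20, 25, 30)) {
  rows <- lapply(names(ranking_sets), function(method) {
    rk <- ranking_sets[[method]]
    p <- vapply(at, function(k) macro_precision_at_k(rk, judgments, k),
                numeric(1))
    out <- data.frame(method = method,
                      map = mean_average_precision(rk, judgments),
                      stringsAsFactors = FALSE)
    for (i in seq_along(at)) out[[paste0("p_at_", at[i])]] <- p[i]
    out
  })
  do.call(rbind, rows)
}
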