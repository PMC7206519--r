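# Plain-text I/O for the pipeline's interchange formats: JSONL corpora,
# JSON/CSV patient records, CSV judgments and keyword annotations, YAML term
# spaces.

#' Read a corpus from JSONL
#'
#' One JSON object per line with fields `id`, `title`, `text` and optional
#' `reproducible` (default `TRUE`).
#'
#' @param path UTF-8 JSONL file.
#' @param tokenizer,user_dict passed to [build_corpus()].
#' @return an `edurec_corpus`.
#' @export
read_corpus_jsonl <- function(path, tokenizer = whitespace_tokenizer,
                              user_dict = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  records <- data.frame(
    doc_id = vapply(recs, function(r) as.character(r$id), character(1)),
    title = vapply(recs, function(r) as.character(r$title %||% ""),
                   character(1)),
    body = vapply(recs, function(r) as.character(r$text), character(1)),
    reproducible = vapply(recs, function(r) isTRUE(r$reproducible %||% TRUE),
                          logical(1)),
    stringsAsFactors = FALSE)
  build_corpus(records, tokenizer = tokenizer, user_dict = user_dict)
}

#' Write a corpus as JSONL
#'
#' @param corpus an `edurec_corpus`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  docs <- corpus$documents
  for (i in seq_len(nrow(docs))) {
    writeLines(jsonlite::toJSON(list(id = docs$doc_id[i],
                                     title = docs$title[i],
                                     text = docs$body[i],
                                     reproducible = docs$reproducible[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read patient records from JSON or CSV
#'
#' JSON: an array of objects over [patient_fields()]. CSV: one flat row per
#' patient, with `disease_history` and `medications` as semicolon-separated
#' lists.
#'
#' @param path input file; format chosen by extension (`.json` vs `.csv`).
#' @return list of `edurec_patient` records.
#' @export
read_patients <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    lapply(raw, function(r) do.call(patient_record, r))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      r <- r[!vapply(r, function(x) is.na(x) || identical(x, ""), logical(1))]
      for (f in c("disease_history", "medications")) {
        if (!is.null(r[[f]])) {
          r[[f]] <- strsplit(r[[f]], ";")[[1L]]
        }
      }
      do.call(patient_record, r)
    })
  }
}

#' Write patient records as JSON
#'
#' @param records list of `edurec_patient`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_patients <- function(records, path) {
  payload <- lapply(records, function(r) unclass(r))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write relevance judgments (CSV: patient_id, doc_id, grade)
#'
#' @param path CSV file.
#' @return data frame (`patient_id`, `doc_id`, `grade`).
#' @export
read_judgments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "doc_id", "grade")
  if (!all(needed %in% names(df))) {
    stop("judgments CSV needs columns: ", paste(needed, collapse = ", "))
  }
  if (!all(df$grade %in% 0:2)) stop("grades must be 0, 1 or 2")
  df[needed]
}

#' @rdname read_judgments
#' @param judgments data frame to write.
#' @export
write_judgments <- function(judgments, path) {
  utils::write.csv(judgments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read manual keyword annotations (CSV: doc_id, keyword)
#'
#' @param path CSV file.
#' @return named list: doc_id -> character vector of keywords.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("doc_id", "keyword") %in% names(df))) {
    stop("annotations CSV needs columns doc_id, keyword")
  }
  split(df$keyword, df$doc_id)
}

#' Read or write a vector-space configuration (YAML)
#'
#' YAML layout: `terms:` a list whose entries are either bare labels or
#' mappings `label: [alias, ...]`.
#'
#' @param path YAML file.
#' @return an `edurec_space`.
#' @export
read_space <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- raw$terms %||% raw
  terms <- character(0); aliases <- list()
  for (e in entries) {
    if (is.list(e)) {
      terms <- c(terms, names(e))
      if (length(e[[1L]]) > 0L) aliases[[names(e)]] <- as.character(e[[1L]])
    } else {
      terms <- c(terms, as.character(e))
    }
  }
  vector_space(terms, if (length(aliases) > 0L) aliases else NULL)
}

#' @rdname read_space
#' @param space an `edurec_space` to write.
#' @export
write_space <- function(space, path) {
  entries <- lapply(space$terms, function(t) {
    al <- space$aliases[[t]]
    if (is.null(al)) t else stats::setNames(list(as.list(al)), t)
  })
  yaml::write_yaml(list(terms = entries), path)
  invisible(path)
}
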