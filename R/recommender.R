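#' Inner product of a patient vector and a text vector
#'
#' The recommendation score: a non-normalized similarity that reflects both
#' direction and magnitude of the paired vectors. Nonnegative whenever both
#' vectors are (severities are 0-3, text-vector entries are sums of
#' above-threshold cosines).
#'
#' @param p numeric patient vector.
#' @param t numeric text vector of the same length.
#' @return `sum(p * t)`.
#' @export
inner_product <- function(p, t) {
  if (length(p) != length(t)) {
    stop("inner_product: length mismatch (patient ", length(p),
         " vs text ", length(t), ")")
  }
  sum(as.numeric(p) * as.numeric(t))
}

#' Rank documents for one patient
#'
#' Scores every text vector against the patient vector and orders by
#' descending score, breaking ties by lexicographic `doc_id` so rankings are
#' deterministic.
#'
#' @param p numeric patient vector.
#' @param texts numeric matrix of text vectors (documents in rows, named) or
#'   a named list of vectors.
#' @return data frame (`doc_id`, `score`, `rank`) in rank order.
#' @export
rank_documents <- function(p, texts) {
  if (is.list(texts) && !is.data.frame(texts)) {
    texts <- do.call(rbind, texts)
  }
  if (is.null(texts) || nrow(texts) == 0L) {
    return(data.frame(doc_id = character(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  scores <- vapply(seq_len(nrow(texts)), function(i) {
    inner_product(p, texts[i, ])
  }, numeric(1))
  ids <- rownames(texts)
  ord <- order(-scores, ids, method = "radix")
  data.frame(doc_id = ids[ord], score = scores[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Create an empty recommendation queue
#'
#' Holds the documents considered relevant for one patient (score strictly
#' greater than the threshold `v`), in score order, together with the set of
#' documents already delivered. The default threshold `v = 2` is deliberately
#' small relative to the sparsity of the vectors; it is configurable.
#'
#' @param patient_id the queue owner.
#' @param threshold relevance threshold `v` (default 2; strict comparison).
#' @return an object of class `edurec_queue`.
#' @export
recommendation_queue <- function(patient_id, threshold = 2) {
  structure(list(patient_id = patient_id,
                 items = data.frame(doc_id = character(), score = numeric(),
                                    stringsAsFactors = FALSE),
                 delivered = character(0), threshold = threshold),
            class = "edurec_queue")
}

#' @export
print.edurec_queue <- function(x, ...) {
  cat(sprintf("<edurec_queue> patient %s: %d queued (score > %g), %d delivered\n",
              x$patient_id, nrow(x$items), x$threshold, length(x$delivered)))
  invisible(x)
}

#' Rebuild a recommendation queue from a fresh ranking
#'
#' Replaces the queued items wholesale (idempotent rebuild on vector
#' updates): a document is queued when its score is strictly greater than the
#' queue threshold, it has not been delivered, and it is flagged
#' reproducible. Documents prohibited for reproduction are used for training
#' only and never reach patients.
#'
#' @param queue an `edurec_queue`.
#' @param ranking a ranking data frame from [rank_documents()].
#' @param reproducible named logical vector, `doc_id -> flag`; documents not
#'   named are treated as reproducible.
#' @return the updated `edurec_queue`.
#' @export
update_queue <- function(queue, ranking, reproducible = NULL) {
  stopifnot(inherits(queue, "edurec_queue"))
  ok <- ranking$score > queue$threshold &
    !ranking$doc_id %in% queue$delivered
  if (!is.null(reproducible)) {
    flag <- reproducible[ranking$doc_id]
    flag[is.na(flag)] <- TRUE
    ok <- ok & flag
  }
  queue$items <- ranking[ok, c("doc_id", "score"), drop = FALSE]
  rownames(queue$items) <- NULL
  queue
}

#' Pop the next documents to deliver
#'
#' Removes up to `n` highest-scored documents from the queue, marking them
#' delivered so no document is ever pushed twice.
#'
#' @param queue an `edurec_queue`.
#' @param n batch size (>= 1); deployment policy such as a daily push decides
#'   its value.
#' @return list with `doc_ids` (character, possibly shorter than `n` or
#'   empty) and `queue` (the updated queue).
#' @export
pop_next <- function(queue, n) {
  stopifnot(inherits(queue, "edurec_queue"), n >= 1)
  take <- utils::head(queue$items$doc_id, n)
  queue$items <- queue$items[!queue$items$doc_id %in% take, , drop = FALSE]
  rownames(queue$items) <- NULL
  queue$delivered <- union(queue$delivered, take)
  list(doc_ids = take, queue = queue)
}
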