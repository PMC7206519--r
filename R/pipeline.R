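#' Run the full recommendation pipeline
#'
#' Chains the stages end to end: compound induction and resegmentation (when
#' the `compounds` strategy is enabled), keyword extraction, embedding
#' training, text-vector mapping, rule evaluation and inner-product ranking.
#'
#' @param corpus an `edurec_corpus` of educational documents.
#' @param records list of patient records.
#' @param space the shared term space (default [default_space()]).
#' @param ruleset severity ruleset (default [default_ruleset()]).
#' @param method keyword extractor, `"tfidf"` or `"textrank"`.
#' @param config an `edurec_strategy`; its `strategies` field decides which
#'   improvement strategies run (default: all three).
#' @param k keywords per document (default 5).
#' @param stopwords stopword surfaces.
#' @param min_adjacency compound-induction frequency threshold (default 5).
#' @param threshold similarity threshold of the text-vector mapping
#'   (default 0.5).
#' @param embed_args list of arguments for [train_embeddings()] (seed, dim,
#'   epochs, ...).
#' @return list with `rankings` (named list: patient_id -> doc_id vector),
#'   `ranking_tables`, `text_vectors`, `patient_vectors`, `keywords`,
#'   `embeddings` and `lexicon` (NULL when compounds are disabled).
#' @export
recommend_documents <- function(corpus, records, space = default_space(),
                                ruleset = default_ruleset(),
                                method = c("textrank", "tfidf"),
                                config = strategy_config(
                                  strategies = all_strategies()),
                                k = 5, stopwords = character(),
                                min_adjacency = 5, threshold = 0.5,
                                embed_args = list()) {
  method <- match.arg(method)
  lexicon <- NULL
  if ("compounds" %in% config$strategies) {
    res <- apply_compound_strategy(corpus, min_adjacency = min_adjacency)
    corpus <- res$corpus
    lexicon <- res$lexicon
  }
  keywords <- keyword_table(corpus, method = method, k = k, config = config,
                            stopwords = stopwords)
  embeddings <- do.call(train_embeddings, c(list(corpus), embed_args))
  text_vectors <- text_vector_matrix(keywords, embeddings, space, threshold)
  patient_vectors <- patient_vector_matrix(records, ruleset, space)
  ranking_tables <- lapply(rownames(patient_vectors), function(p) {
    rank_documents(patient_vectors[p, ], text_vectors)
  })
  names(ranking_tables) <- rownames(patient_vectors)
  list(rankings = lapply(ranking_tables, `[[`, "doc_id"),
       ranking_tables = ranking_tables, text_vectors = text_vectors,
       patient_vectors = patient_vectors, keywords = keywords,
       embeddings = embeddings, lexicon = lexicon)
}
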