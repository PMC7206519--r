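#' Keyword-extraction strategy configuration
#'
#' Bundles the three optional improvement strategies and their parameters:
#' weight assignment (boost title words and nouns, damp verbs), compound-word
#' identification (handled upstream by resegmenting the corpus with an induced
#' lexicon) and synonym elimination (drop the shorter of two candidates whose
#' character compositions are similar).
#'
#' @param weight_title multiplicative weight for words occurring in the title
#'   (default 3).
#' @param weight_noun multiplicative weight for nouns (default 1.2).
#' @param weight_verb multiplicative weight for verbs (default 0.8).
#' @param synonym_threshold character-set cosine at or above which two
#'   candidates count as synonyms, in `[0, 1]` (default 0.5).
#' @param strategies character subset of
#'   `c("weights", "compounds", "synonyms")`; empty means the unmodified
#'   baseline extractor.
#' @return an object of class `edurec_strategy`.
#' @export
strategy_config <- function(weight_title = 3, weight_noun = 1.2,
                            weight_verb = 0.8, synonym_threshold = 0.5,
                            strategies = character()) {
  stopifnot(weight_title > 0, weight_noun > 0, weight_verb > 0,
            synonym_threshold >= 0, synonym_threshold <= 1)
  bad <- setdiff(strategies, c("weights", "compounds", "synonyms"))
  if (length(bad) > 0L) stop("unknown strategies: ", paste(bad, collapse = ", "))
  structure(list(weight_title = weight_title, weight_noun = weight_noun,
                 weight_verb = weight_verb,
                 synonym_threshold = synonym_threshold,
                 strategies = strategies),
            class = "edurec_strategy")
}

#' The three improvement strategies
#'
#' @return `c("weights", "compounds", "synonyms")`.
#' @export
all_strategies <- function() c("weights", "compounds", "synonyms")

#' Filter a document's tokens to keyword candidates
#'
#' Drops stopwords and surfaces shorter than `min_chars` characters while
#' preserving order and multiplicity.
#'
#' @param tokens a token data frame (see [doc_tokens()]).
#' @param stopwords character vector of surfaces to exclude.
#' @param min_chars minimum surface length in characters (default 2).
#' @return the filtered token data frame.
#' @export
candidate_filter <- function(tokens, stopwords = character(), min_chars = 2) {
  keep <- !(tokens$surface %in% stopwords) & nchar(tokens$surface) >= min_chars
  out <- tokens[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Combined strategy weight per distinct surface in a document:
# title-factor (weight_title if the surface ever occurs in the title, else 1)
# times POS-factor (noun/verb weight by the surface's first occurrence; adj
# and other keep factor 1). Returns a named numeric vector.
surface_weights <- function(tokens, config) {
  surfaces <- unique(tokens$surface)
  first_pos <- tokens$pos[match(surfaces, tokens$surface)]
  in_title <- vapply(surfaces, function(s) {
    any(tokens$in_title[tokens$surface == s])
  }, logical(1))
  w <- ifelse(in_title, config$weight_title, 1) *
    ifelse(first_pos == "noun", config$weight_noun,
           ifelse(first_pos == "verb", config$weight_verb, 1))
  names(w) <- surfaces
  w
}

#' TF-IDF keyword scores for one document
#'
#' `score(t, d) = tf(t, d) * idf(t) * w(t, d)` with raw in-document term
#' frequency, smoothed inverse document frequency
#' `idf(t) = ln((N + 1) / (df(t) + 1)) + 1` computed over the corpus, and the
#' strategy weight `w` (title-factor times POS-factor) applied only when the
#' `weights` strategy is enabled.
#'
#' @param corpus an `edurec_corpus` containing the document.
#' @param doc_id the document to score.
#' @param config an `edurec_strategy` (default: all strategies off).
#' @param stopwords surfaces excluded from candidacy.
#' @return named numeric vector of scores over the document's candidates.
#' @export
tfidf_scores <- function(corpus, doc_id, config = strategy_config(),
                         stopwords = character(), min_chars = 2) {
  stopifnot(inherits(corpus, "edurec_corpus"))
  if (!doc_id %in% doc_ids(corpus)) stop("document not in corpus: ", doc_id)
  cand <- candidate_filter(doc_tokens(corpus, doc_id), stopwords, min_chars)
  if (nrow(cand) == 0L) return(stats::setNames(numeric(0), character(0)))
  tf <- table(cand$surface)
  surfaces <- names(tf)
  n_docs <- corpus$total_docs
  idf <- log((n_docs + 1) / (doc_freq(corpus, surfaces) + 1)) + 1
  score <- as.numeric(tf) * idf
  if ("weights" %in% config$strategies) {
    w <- surface_weights(cand, config)
    score <- score * unname(w[surfaces])
  }
  stats::setNames(score, surfaces)
}

# Co-occurrence graph over distinct candidate surfaces: symmetric matrix of
# counts of pairs falling within a sliding window of `window` positions
# (window = 2 means adjacent candidates). Same-surface pairs are ignored.
cooccurrence_graph <- function(surfaces, window = 2) {
  vocab <- unique(surfaces)
  v <- length(vocab)
  W <- matrix(0, v, v, dimnames = list(vocab, vocab))
  n <- length(surfaces)
  if (n >= 2L && window >= 2L) {
    for (offset in 1:(window - 1L)) {
      if (n <= offset) break
      for (i in seq_len(n - offset)) {
        a <- surfaces[i]; b <- surfaces[i + offset]
        if (a == b) next
        W[a, b] <- W[a, b] + 1
        W[b, a] <- W[b, a] + 1
      }
    }
  }
  W
}

#' Iterate graph-based ranking scores on a weighted undirected graph
#'
#' Runs the damped update
#' `S(v) = (1 - d) + d * sum_u (w_uv / strength(u)) * S(u)` from a uniform
#' start `S = 1` until the largest per-node change falls below `tol` or
#' `max_iter` is reached. Nodes with no neighbours converge to `1 - d`.
#'
#' @param W symmetric nonnegative weight matrix with dimnames.
#' @param damping damping factor `d` (default 0.85).
#' @param tol convergence tolerance on the max per-node change (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return named numeric score vector with attribute `converged` (logical).
#' @export
textrank_graph <- function(W, damping = 0.85, tol = 1e-6, max_iter = 100) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  v <- nrow(W)
  strength <- rowSums(W)
  # M[j, i] = w_ij / strength(i): contribution of node i to node j
  M <- t(W / ifelse(strength > 0, strength, 1))
  s <- rep(1, v)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    s_new <- (1 - damping) + damping * as.numeric(M %*% s)
    if (max(abs(s_new - s)) < tol) {
      s <- s_new
      converged <- TRUE
      break
    }
    s <- s_new
  }
  if (!converged) warning("graph ranking did not converge in ",
                          max_iter, " iterations")
  names(s) <- rownames(W)
  attr(s, "converged") <- converged
  s
}

#' TextRank keyword scores for one document
#'
#' Builds an undirected co-occurrence graph over the document's candidate
#' surfaces (edge weight = number of co-occurrences within a sliding window)
#' and ranks nodes with [textrank_graph()]. When the `weights` strategy is
#' enabled, node scores are post-multiplied by the same title/POS weight used
#' by [tfidf_scores()].
#'
#' @inheritParams tfidf_scores
#' @param window co-occurrence window size (default 2: adjacent candidates).
#' @param damping damping factor (default 0.85).
#' @param tol convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return named numeric score vector (empty when no candidates survive).
#' @export
textrank_scores <- function(corpus, doc_id, window = 2, damping = 0.85,
                            tol = 1e-6, max_iter = 100,
                            config = strategy_config(),
                            stopwords = character(), min_chars = 2) {
  stopifnot(inherits(corpus, "edurec_corpus"))
  if (!doc_id %in% doc_ids(corpus)) stop("document not in corpus: ", doc_id)
  cand <- candidate_filter(doc_tokens(corpus, doc_id), stopwords, min_chars)
  if (nrow(cand) == 0L) return(stats::setNames(numeric(0), character(0)))
  W <- cooccurrence_graph(cand$surface, window)
  s <- textrank_graph(W, damping = damping, tol = tol, max_iter = max_iter)
  conv <- attr(s, "converged")
  s <- as.numeric(s) |> stats::setNames(rownames(W))
  if ("weights" %in% config$strategies) {
    w <- surface_weights(cand, config)
    s <- s * unname(w[names(s)])
  }
  attr(s, "converged") <- conv
  s
}

#' Character-composition cosine between two surfaces
#'
#' Each surface is reduced to the set of its distinct characters (a one-hot
#' character vector); the cosine is `|A | B| / sqrt(|A| * |B|)` where the
#' numerator counts shared characters.
#'
#' @param a,b character scalars.
#' @return cosine in `[0, 1]`.
#' @export
char_cosine <- function(a, b) {
  ca <- unique(strsplit(a, "")[[1L]])
  cb <- unique(strsplit(b, "")[[1L]])
  if (length(ca) == 0L || length(cb) == 0L) return(0)
  length(intersect(ca, cb)) / sqrt(length(ca) * length(cb))
}

#' Eliminate near-synonym candidates by character composition
#'
#' Scans a score-ranked candidate list for pairs whose character-set cosine
#' reaches `threshold` and removes the shorter surface of each such pair (on
#' equal length the lower-scored one; on equal length and score the
#' lexicographically larger one). The survivors keep their score order and
#' are pairwise below the threshold.
#'
#' @param ranked data frame with columns `surface` and `score`, ordered by
#'   non-increasing score.
#' @param threshold cosine threshold in `[0, 1]`.
#' @return the pruned data frame.
#' @export
eliminate_synonyms <- function(ranked, threshold) {
  if (threshold < 0 || threshold > 1) {
    stop("synonym threshold must lie in [0, 1], got ", threshold)
  }
  keep <- rep(TRUE, nrow(ranked))
  n <- nrow(ranked)
  if (n < 2L) return(ranked)
  for (i in seq_len(n - 1L)) {
    if (!keep[i]) next
    for (j in seq((i + 1L), n)) {
      if (!keep[j]) next
      if (char_cosine(ranked$surface[i], ranked$surface[j]) >= threshold) {
        ni <- nchar(ranked$surface[i]); nj <- nchar(ranked$surface[j])
        if (ni > nj) {
          loser <- j
        } else if (nj > ni) {
          loser <- i
        } else if (ranked$score[i] != ranked$score[j]) {
          loser <- if (ranked$score[i] >= ranked$score[j]) j else i
        } else {
          loser <- if (ranked$surface[i] <= ranked$surface[j]) j else i
        }
        keep[loser] <- FALSE
        if (loser == i) break
      }
    }
  }
  out <- ranked[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

rank_scores <- function(scores) {
  if (length(scores) == 0L) {
    return(data.frame(surface = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-scores, names(scores), method = "radix")
  data.frame(surface = names(scores)[ord], score = unname(scores)[ord],
             stringsAsFactors = FALSE)
}

#' Extract the top keywords of a document
#'
#' Scores candidates with TF-IDF or TextRank, optionally applies synonym
#' elimination over the full ranked candidate list (so that lower-ranked
#' candidates can be promoted into the top `k` when synonyms are dropped),
#' and returns the top `k` survivors. Ties are broken by lexicographic
#' surface order. When the `compounds` strategy is intended, the corpus must
#' already be resegmented with the induced lexicon (see
#' [apply_compound_strategy()]).
#'
#' @inheritParams tfidf_scores
#' @param method `"tfidf"` or `"textrank"`.
#' @param k number of keywords to return (default 5); fewer survivors yield
#'   a shorter list.
#' @param ... passed on to the score function (`window`, `damping`, ...).
#' @return data frame of class `edurec_keywords` with columns `doc_id`,
#'   `rank`, `surface`, `score`.
#' @export
extract_keywords <- function(corpus, doc_id, method = c("tfidf", "textrank"),
                             k = 5, config = strategy_config(),
                             stopwords = character(), ...) {
  method <- match.arg(method)
  scores <- switch(method,
    tfidf = tfidf_scores(corpus, doc_id, config = config,
                         stopwords = stopwords, ...),
    textrank = textrank_scores(corpus, doc_id, config = config,
                               stopwords = stopwords, ...))
  ranked <- rank_scores(scores)
  if ("synonyms" %in% config$strategies) {
    ranked <- eliminate_synonyms(ranked, config$synonym_threshold)
  }
  out <- utils::head(ranked, k)
  out <- cbind(doc_id = rep(doc_id, nrow(out)),
               rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("edurec_keywords", "data.frame")
  out
}

#' Induce and apply the compound-word strategy to a corpus
#'
#' Convenience wrapper: [identify_compounds()] on the atom-token corpus,
#' optionally force-adds `extra_entries` (for example the vector-space term
#' labels, so they are kept whole and receive embeddings), then
#' [resegment_with_lexicon()].
#'
#' @inheritParams identify_compounds
#' @param extra_entries optional character vector of multi-atom surfaces to
#'   append to the induced lexicon regardless of frequency; each entry is
#'   split on whitespace into atoms.
#' @return list with elements `corpus` (resegmented) and `lexicon`.
#' @export
apply_compound_strategy <- function(corpus, min_adjacency = 5,
                                    pos_patterns = default_pos_patterns(),
                                    max_atoms = 3, extra_entries = NULL) {
  lex <- identify_compounds(corpus, min_adjacency = min_adjacency,
                            pos_patterns = pos_patterns,
                            max_atoms = max_atoms)
  if (!is.null(extra_entries) && length(extra_entries) > 0L) {
    atoms <- strsplit(extra_entries, "\\s+")
    keep <- vapply(atoms, length, integer(1)) >= 2L
    atoms <- atoms[keep]
    if (length(atoms) > 0L) {
      add <- data.frame(
        surface = vapply(atoms, paste, character(1), collapse = ""),
        count = rep(NA_integer_, length(atoms)),
        n_atoms = vapply(atoms, length, integer(1)),
        pos = rep("noun", length(atoms)), stringsAsFactors = FALSE)
      add$atoms <- atoms
      add <- add[!add$surface %in% lex$surface, , drop = FALSE]
      lex <- rbind(lex, add)
      class(lex) <- c("edurec_lexicon", "data.frame")
    }
  }
  list(corpus = resegment_with_lexicon(corpus, lex), lexicon = lex)
}

#' Keyword table for every document in a corpus
#'
#' @inheritParams extract_keywords
#' @return an `edurec_keywords` data frame covering all documents.
#' @export
keyword_table <- function(corpus, method = c("tfidf", "textrank"), k = 5,
                          config = strategy_config(),
                          stopwords = character(), ...) {
  method <- match.arg(method)
  out <- do.call(rbind, lapply(doc_ids(corpus), function(d) {
    extract_keywords(corpus, d, method = method, k = k, config = config,
                     stopwords = stopwords, ...)
  }))
  rownames(out) <- NULL
  out
}
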