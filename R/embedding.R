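#' Train CBOW word embeddings with negative sampling
#'
#' A compact, single-threaded, seeded implementation of the continuous
#' bag-of-words word2vec model trained by negative sampling: for each token
#' position the context vectors within the window are averaged, the target
#' word plus `negative` noise words (drawn from the unigram distribution
#' raised to 3/4) are scored against the average through a sigmoid, and both
#' layers receive stochastic-gradient updates under a linearly decaying
#' learning rate. Determinism for a fixed seed is part of the contract: there
#' is a single worker and all sampling flows from `seed`.
#'
#' @param corpus an `edurec_corpus` (tokenized; if the compound strategy is in
#'   use, resegment first so multi-atom terms are in the vocabulary).
#' @param dim embedding dimension (default 200).
#' @param window one-sided context window size (default 5).
#' @param seed integer RNG seed.
#' @param epochs training passes over the corpus (default 5).
#' @param min_count minimum corpus count for a surface to enter the
#'   vocabulary (default 1).
#' @param negative number of noise words per target (default 5).
#' @param alpha,min_alpha initial and final learning rate (defaults 0.025 and
#'   1e-4).
#' @return an object of class `edurec_embeddings`: list with `dim`, `vectors`
#'   (numeric matrix, one row per surface) and `meta` (training metadata).
#' @export
train_embeddings <- function(corpus, dim = 200, window = 5, seed = 1,
                             epochs = 5, min_count = 1, negative = 5,
                             alpha = 0.025, min_alpha = 1e-4) {
  stopifnot(inherits(corpus, "edurec_corpus"), dim >= 1, window >= 1,
            epochs >= 1, negative >= 0)
  seqs <- lapply(corpus$tokens, function(tt) tt$surface)
  counts <- table(unlist(seqs, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) stop("empty vocabulary after min_count filter")
  vocab <- sort(names(counts), method = "radix")
  counts <- as.numeric(counts[vocab])
  v <- length(vocab)

  # index sequences, dropping out-of-vocabulary tokens
  iseqs <- lapply(seqs, function(s) {
    idx <- match(s, vocab)
    idx[!is.na(idx)]
  })
  iseqs <- iseqs[vapply(iseqs, length, integer(1)) > 0L]

  noise_cdf <- cumsum(counts^0.75)
  noise_cdf <- noise_cdf / noise_cdf[v]

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  syn0 <- matrix(stats::runif(v * dim, -0.5, 0.5) / dim, nrow = v)
  syn1 <- matrix(0, nrow = v, ncol = dim)

  total <- sum(vapply(iseqs, length, integer(1))) * epochs
  done <- 0L
  for (ep in seq_len(epochs)) {
    for (s in iseqs) {
      n <- length(s)
      for (t in seq_len(n)) {
        done <- done + 1L
        lo <- max(1L, t - window); hi <- min(n, t + window)
        ctx <- s[setdiff(lo:hi, t)]
        if (length(ctx) == 0L) next
        lr <- max(min_alpha, alpha * (1 - done / total))
        h <- colMeans(syn0[ctx, , drop = FALSE])
        target <- s[t]
        negs <- if (negative > 0L) {
          cand <- findInterval(stats::runif(negative), noise_cdf) + 1L
          cand[cand != target]
        } else integer(0)
        outs <- c(target, negs)
        labels <- c(1, rep(0, length(negs)))
        f <- 1 / (1 + exp(-as.numeric(syn1[outs, , drop = FALSE] %*% h)))
        g <- lr * (labels - f)
        e <- as.numeric(crossprod(syn1[outs, , drop = FALSE], g))
        syn1[outs, ] <- syn1[outs, ] + outer(g, h)
        syn0[ctx, ] <- syn0[ctx, ] + rep(e, each = length(ctx))
      }
    }
  }
  rownames(syn0) <- vocab
  structure(list(dim = dim, vectors = syn0,
                 meta = list(window = window, architecture = "cbow",
                             training = "negative-sampling", seed = seed,
                             epochs = epochs, min_count = min_count,
                             negative = negative)),
            class = "edurec_embeddings")
}

#' @export
print.edurec_embeddings <- function(x, ...) {
  cat(sprintf("<edurec_embeddings> %d surfaces x %d dims (%s/%s, seed %s)\n",
              nrow(x$vectors), x$dim, x$meta$architecture, x$meta$training,
              x$meta$seed))
  invisible(x)
}

#' Look up embedding vectors
#'
#' @param table an `edurec_embeddings`.
#' @param surfaces character vector.
#' @return matrix of vectors for the surfaces present; absent surfaces are
#'   dropped (zero rows possible).
#' @export
embedding_vectors <- function(table, surfaces) {
  hit <- surfaces[surfaces %in% rownames(table$vectors)]
  table$vectors[hit, , drop = FALSE]
}

#' Cosine similarity
#'
#' Standard cosine of two equal-length vectors. A zero vector yields
#' similarity 0 with a warning (degenerate-input policy, so pipelines stay
#' total).
#'
#' @param a,b numeric vectors of equal length.
#' @return similarity in `[-1, 1]`.
#' @export
cosine_sim <- function(a, b) {
  if (length(a) != length(b)) {
    stop("cosine_sim: lengths differ (", length(a), " vs ", length(b), ")")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("cosine_sim: zero vector, returning 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Define the shared term vector space
#'
#' The ordered list of term labels into which both patients and documents are
#' projected (33 labels in the default configuration), with optional aliases
#' used to resolve a term's embedding when the label itself is out of
#' vocabulary.
#'
#' @param terms character vector of distinct labels.
#' @param aliases optional named list: term label -> character vector of
#'   alias surfaces.
#' @return an object of class `edurec_space`.
#' @export
vector_space <- function(terms, aliases = NULL) {
  stopifnot(length(terms) >= 1L, !anyDuplicated(terms))
  if (!is.null(aliases)) {
    bad <- setdiff(names(aliases), terms)
    if (length(bad) > 0L) stop("aliases for unknown terms: ",
                               paste(bad, collapse = ", "))
  }
  structure(list(terms = as.character(terms), aliases = aliases),
            class = "edurec_space")
}

#' @export
print.edurec_space <- function(x, ...) {
  cat(sprintf("<edurec_space> %d terms: %s%s\n", length(x$terms),
              paste(utils::head(x$terms, 5), collapse = ", "),
              if (length(x$terms) > 5) ", ..." else ""))
  invisible(x)
}

#' The default 33-term space
#'
#' Chronic-disease education term labels covering diagnoses, physiological
#' indices, lifestyle, questionnaires, demographics and drug classes. The
#' space is configuration, not code: any [vector_space()] can replace it.
#'
#' @return an `edurec_space` of length 33.
#' @export
default_space <- function() {
  vector_space(c(
    "hypertension", "diabetes", "stroke", "hyperlipidemia",
    "coronary_artery_disease", "copd", "kidney_disease", "heart_failure",
    "blood_pressure", "blood_glucose", "total_cholesterol", "triglyceride",
    "hdl", "ldl", "uric_acid", "bmi", "obesity",
    "smoking", "drinking", "diet", "salt_intake", "physical_activity",
    "sleep", "depression", "pregnancy", "male", "female", "age",
    "antihypertensive_drug", "hypoglycemic_drug", "hypolipidemic_drug",
    "medication_adherence", "self_monitoring"))
}

# Resolve one term label to an embedding vector via the label itself or its
# first in-vocabulary alias; NULL when unresolvable.
resolve_term_embedding <- function(term, table, space) {
  cands <- c(term, space$aliases[[term]])
  hit <- cands[cands %in% rownames(table$vectors)][1]
  if (is.na(hit) || is.null(hit)) return(NULL)
  table$vectors[hit, ]
}

#' Map a document's keywords to the term space (text vector)
#'
#' Entry `j` of the text vector is the sum of cosine similarities between
#' term `j`'s embedding and each keyword's embedding, restricted to the
#' similarities that reach `threshold` (inclusive). Keywords absent from the
#' embedding vocabulary contribute nothing; a term with no resolvable
#' embedding yields entry 0 with a warning.
#'
#' @param keywords an `edurec_keywords` data frame (one document) or a
#'   character vector of keyword surfaces.
#' @param table an `edurec_embeddings`.
#' @param space an `edurec_space`.
#' @param threshold similarity threshold in `[0, 1]` (default 0.5).
#' @return named numeric vector over `space$terms` (all entries >= 0), with
#'   attribute `doc_id` when the input carried one.
#' @export
build_text_vector <- function(keywords, table, space, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  did <- NULL
  if (is.data.frame(keywords)) {
    did <- unique(keywords$doc_id)
    if (length(did) > 1L) stop("keywords span several documents")
    surfaces <- keywords$surface
  } else {
    surfaces <- as.character(keywords)
  }
  kw_mat <- embedding_vectors(table, unique(surfaces))
  out <- stats::setNames(numeric(length(space$terms)), space$terms)
  unresolved <- character(0)
  for (term in space$terms) {
    tv <- resolve_term_embedding(term, table, space)
    if (is.null(tv)) {
      unresolved <- c(unresolved, term)
      next
    }
    if (nrow(kw_mat) == 0L) next
    sims <- apply(kw_mat, 1L, cosine_sim, b = tv)
    out[term] <- sum(sims[sims >= threshold])
  }
  if (length(unresolved) > 0L) {
    warning("terms without embeddings contribute 0: ",
            paste(unresolved, collapse = ", "))
  }
  if (!is.null(did)) attr(out, "doc_id") <- did
  out
}

#' Text-vector matrix for a whole keyword table
#'
#' @param keywords an `edurec_keywords` table over several documents.
#' @inheritParams build_text_vector
#' @return numeric matrix, documents in rows, terms in columns.
#' @export
text_vector_matrix <- function(keywords, table, space, threshold = 0.5) {
  ids <- unique(keywords$doc_id)
  rows <- lapply(ids, function(d) {
    suppressWarnings(build_text_vector(
      keywords[keywords$doc_id == d, , drop = FALSE],
      table, space, threshold))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}

#' Write embeddings in the word2vec text format
#'
#' Header line `vocab_size dim`, then one `surface v1 ... vdim` line per
#' surface.
#'
#' @param table an `edurec_embeddings`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(table$vectors), table$dim), con)
  surfs <- rownames(table$vectors)
  for (i in seq_along(surfs)) {
    writeLines(paste(surfs[i],
                     paste(format(table$vectors[i, ], digits = 17,
                                  scientific = TRUE, trim = TRUE),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Read embeddings from the word2vec text format
#'
#' @param path file written by [write_embeddings()] or any tool emitting the
#'   standard text format.
#' @return an `edurec_embeddings` (training metadata absent).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1L], " ")[[1L]])
  v <- hdr[1L]; dim <- hdr[2L]
  parts <- strsplit(lines[1L + seq_len(v)], " ")
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim)))
  rownames(vecs) <- vapply(parts, `[[`, character(1), 1L)
  structure(list(dim = dim, vectors = vecs, meta = list()),
            class = "edurec_embeddings")
}
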