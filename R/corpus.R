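#' Whitespace tokenizer with inline part-of-speech annotation
#'
#' Splits text on whitespace. A token may carry an inline POS annotation as a
#' trailing `/n` (noun), `/v` (verb), `/a` (adjective) or `/x` (other);
#' unannotated tokens are tagged `other`. This is the reference tokenizer used
#' by the synthetic fixtures, where POS tags are explicit in the text. A real
#' segmenter (for unsegmented scripts such as Chinese) can be substituted for
#' it anywhere a `tokenizer` argument is accepted: any function taking
#' `(text, user_dict)` and returning a data frame with columns `surface` and
#' `pos` satisfies the contract.
#'
#' @param text character scalar to segment.
#' @param user_dict optional compound lexicon (see [identify_compounds()]);
#'   adjacent atoms matching a lexicon entry are merged into a single token.
#' @return data frame with columns `surface` (character) and `pos`
#'   (one of `"noun"`, `"verb"`, `"adj"`, `"other"`).
#' @examples
#' whitespace_tokenizer("blood/n pressure/n rises/v quickly")
#' @export
whitespace_tokenizer <- function(text, user_dict = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- strsplit(trimws(text), "\\s+")[[1L]]
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) {
    toks <- data.frame(surface = character(), pos = character(),
                       stringsAsFactors = FALSE)
  } else {
    has_tag <- grepl("/[nvax]$", raw)
    surface <- ifelse(has_tag, substr(raw, 1L, nchar(raw) - 2L), raw)
    tag <- ifelse(has_tag, substr(raw, nchar(raw), nchar(raw)), "x")
    pos <- c(n = "noun", v = "verb", a = "adj", x = "other")[tag]
    toks <- data.frame(surface = surface, pos = unname(pos),
                       stringsAsFactors = FALSE)
    toks <- toks[nzchar(toks$surface), , drop = FALSE]
    rownames(toks) <- NULL
  }
  if (!is.null(user_dict) && nrow(toks) > 0L) {
    toks <- merge_compounds(toks, user_dict)
  }
  toks
}

pos_tags <- function() c("noun", "verb", "adj", "other")

ngram_key <- function(x) paste(x, collapse = "\x1f")

#' Build a corpus from document records
#'
#' Tokenizes every document (title first, then body; title tokens are flagged
#' `in_title`) and computes document frequencies over the resulting surfaces.
#'
#' @param records data frame with columns `doc_id`, `title`, `body` and
#'   optionally `reproducible` (logical, default `TRUE`; documents flagged
#'   `FALSE` are used for training only and never recommended).
#' @param tokenizer a tokenizer function; see [whitespace_tokenizer()].
#' @param user_dict optional compound lexicon applied during segmentation.
#' @return an object of class `edurec_corpus`: a list with elements
#'   `documents` (the record table), `tokens` (named list of per-document
#'   token data frames with columns `surface`, `pos`, `in_title`),
#'   `vocabulary` (data frame `surface`, `df`) and `total_docs`.
#' @examples
#' corp <- build_corpus(data.frame(
#'   doc_id = c("d1", "d2"), title = c("", ""),
#'   body = c("x x y", "y z")))
#' corp$vocabulary
#' @export
build_corpus <- function(records, tokenizer = whitespace_tokenizer,
                         user_dict = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("doc_id", "title", "body")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("cannot build an empty corpus")
  if (is.null(records$reproducible)) records$reproducible <- TRUE
  dup <- unique(records$doc_id[duplicated(records$doc_id)])
  if (length(dup) > 0L) {
    stop("duplicate doc_id: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(records$body))) stop("document bodies must be non-empty")

  tokens <- lapply(seq_len(nrow(records)), function(i) {
    tt <- tokenizer(records$title[i], user_dict)
    bt <- tokenizer(records$body[i], user_dict)
    tt$in_title <- rep(TRUE, nrow(tt))
    bt$in_title <- rep(FALSE, nrow(bt))
    out <- rbind(tt, bt)
    rownames(out) <- NULL
    out
  })
  names(tokens) <- records$doc_id

  corp <- structure(
    list(documents = records, tokens = tokens,
         vocabulary = NULL, total_docs = nrow(records)),
    class = "edurec_corpus")
  attr(corp, "user_dict_applied") <- !is.null(user_dict)
  corp$vocabulary <- compute_df(corp)
  corp
}

compute_df <- function(corpus) {
  per_doc <- lapply(corpus$tokens, function(tt) unique(tt$surface))
  tab <- table(unlist(per_doc, use.names = FALSE))
  if (length(tab) == 0L) {
    return(data.frame(surface = character(), df = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(surface = names(tab), df = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$surface, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.edurec_corpus <- function(x, ...) {
  cat(sprintf("<edurec_corpus> %d documents, %d unique surfaces\n",
              x$total_docs, nrow(x$vocabulary)))
  invisible(x)
}

doc_ids <- function(corpus) corpus$documents$doc_id

#' Per-document token accessor
#'
#' @param corpus an `edurec_corpus`.
#' @param doc_id a document id present in the corpus.
#' @return the document's token data frame (`surface`, `pos`, `in_title`).
#' @export
doc_tokens <- function(corpus, doc_id) {
  stopifnot(inherits(corpus, "edurec_corpus"))
  if (!doc_id %in% names(corpus$tokens)) {
    stop("unknown doc_id: ", doc_id)
  }
  corpus$tokens[[doc_id]]
}

#' Document frequency lookup
#'
#' @param corpus an `edurec_corpus`.
#' @param surfaces character vector of surfaces.
#' @return integer vector of document frequencies (0 for unseen surfaces).
#' @export
doc_freq <- function(corpus, surfaces) {
  idx <- match(surfaces, corpus$vocabulary$surface)
  out <- corpus$vocabulary$df[idx]
  out[is.na(out)] <- 0L
  as.integer(out)
}

default_pos_patterns <- function() {
  list(c("noun", "noun"), c("adj", "noun"), c("noun", "noun", "noun"))
}

#' Induce a compound-word lexicon from adjacency statistics
#'
#' Scans every document for runs of 2 to `max_atoms` strictly adjacent atom
#' tokens whose POS sequence matches one of `pos_patterns`, and keeps every
#' run observed at least `min_adjacency` times corpus-wide. The result is a
#' user dictionary that makes segmentation keep frequent compounds (for
#' example a disease name split into two atoms) whole, so they can compete as
#' keyword candidates.
#'
#' @param corpus an `edurec_corpus` tokenized without a user dictionary.
#' @param min_adjacency minimum corpus-wide adjacency count (default 5).
#' @param pos_patterns list of POS-tag vectors an entry must match; default
#'   noun-noun, adj-noun and noun-noun-noun.
#' @param max_atoms maximum atoms per compound (default 3).
#' @return an object of class `edurec_lexicon`: a data frame with columns
#'   `surface` (atom surfaces concatenated), `count`, `n_atoms`, `pos`
#'   (always `"noun"`) and a list column `atoms`.
#' @export
identify_compounds <- function(corpus, min_adjacency = 5,
                               pos_patterns = default_pos_patterns(),
                               max_atoms = 3) {
  stopifnot(inherits(corpus, "edurec_corpus"), min_adjacency >= 1)
  if (isTRUE(attr(corpus, "user_dict_applied"))) {
    stop("corpus was tokenized with a user dictionary; ",
         "compound induction expects atom tokens")
  }
  pattern_keys <- vapply(pos_patterns, ngram_key, character(1))
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())

  for (tt in corpus$tokens) {
    n <- nrow(tt)
    if (n < 2L) next
    for (len in 2:max_atoms) {
      if (n < len) next
      for (i in seq_len(n - len + 1L)) {
        idx <- i:(i + len - 1L)
        if (!ngram_key(tt$pos[idx]) %in% pattern_keys) next
        key <- ngram_key(tt$surface[idx])
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
        if (is.null(meta[[key]])) meta[[key]] <- tt$surface[idx]
      }
    }
  }

  keys <- ls(counts)
  keep <- keys[vapply(keys, function(k) counts[[k]] >= min_adjacency, logical(1))]
  keep <- sort(keep, method = "radix")
  atoms <- lapply(keep, function(k) meta[[k]])
  lex <- data.frame(
    surface = vapply(atoms, paste, character(1), collapse = ""),
    count = vapply(keep, function(k) as.integer(counts[[k]]), integer(1)),
    n_atoms = vapply(atoms, length, integer(1)),
    pos = rep("noun", length(keep)),
    stringsAsFactors = FALSE)
  lex$atoms <- atoms
  rownames(lex) <- NULL
  class(lex) <- c("edurec_lexicon", "data.frame")
  lex
}

empty_lexicon <- function() {
  lex <- data.frame(surface = character(), count = integer(),
                    n_atoms = integer(), pos = character(),
                    stringsAsFactors = FALSE)
  lex$atoms <- list()
  class(lex) <- c("edurec_lexicon", "data.frame")
  lex
}

# Leftmost-longest, non-overlapping merge of lexicon matches in one token
# sequence. Merged tokens become nouns; a merge is flagged in_title if any
# atom was.
merge_compounds <- function(tt, lexicon) {
  if (nrow(tt) == 0L || NROW(lexicon) == 0L) return(tt)
  keys <- vapply(lexicon$atoms, ngram_key, character(1))
  max_len <- max(lexicon$n_atoms)
  surf_out <- character(0); pos_out <- character(0); title_out <- logical(0)
  has_title <- "in_title" %in% names(tt)
  n <- nrow(tt); i <- 1L
  while (i <= n) {
    merged <- FALSE
    for (len in seq(min(max_len, n - i + 1L), 2L)) {
      if (len < 2L) break
      idx <- i:(i + len - 1L)
      hit <- match(ngram_key(tt$surface[idx]), keys)
      if (!is.na(hit)) {
        surf_out <- c(surf_out, lexicon$surface[hit])
        pos_out <- c(pos_out, "noun")
        title_out <- c(title_out, if (has_title) any(tt$in_title[idx]) else FALSE)
        i <- i + len
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      surf_out <- c(surf_out, tt$surface[i])
      pos_out <- c(pos_out, tt$pos[i])
      title_out <- c(title_out, if (has_title) tt$in_title[i] else FALSE)
      i <- i + 1L
    }
  }
  out <- data.frame(surface = surf_out, pos = pos_out,
                    stringsAsFactors = FALSE)
  if (has_title) out$in_title <- title_out
  out
}

#' Re-segment a corpus with a compound lexicon
#'
#' Merges each maximal lexicon match (leftmost-longest, non-overlapping) in
#' every document's token sequence into a single noun token and recomputes
#' document frequencies. With an empty lexicon the corpus is returned with
#' token sequences unchanged.
#'
#' @param corpus an `edurec_corpus`.
#' @param lexicon an `edurec_lexicon` from [identify_compounds()].
#' @return a new `edurec_corpus`.
#' @export
resegment_with_lexicon <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "edurec_corpus"))
  out <- corpus
  out$tokens <- lapply(corpus$tokens, merge_compounds, lexicon = lexicon)
  out$vocabulary <- compute_df(out)
  attr(out, "resegmented") <- TRUE
  out
}

#' Write a compound lexicon as a plain-text user dictionary
#'
#' One entry per line: `surface count pos`, the conventional user-dictionary
#' layout of common segmenters.
#'
#' @param lexicon an `edurec_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_user_dict <- function(lexicon, path) {
  lines <- sprintf("%s %d %s", lexicon$surface, lexicon$count, lexicon$pos)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
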