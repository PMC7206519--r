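test_that("candidate filter drops stopwords and short surfaces", {
  toks <- whitespace_tokenizer("aaa/n of/x bbb/v x/n")
  out <- candidate_filter(toks, stopwords = "of")
  expect_equal(out$surface, c("aaa", "bbb"))
  expect_equal(nrow(candidate_filter(toks, stopwords = c("aaa", "bbb", "x",
                                                         "of"))), 0L)
  # no stopwords: all multi-character tokens retained with multiplicity
  toks2 <- whitespace_tokenizer("aa aa bb")
  expect_equal(candidate_filter(toks2)$surface, c("aa", "aa", "bb"))
})

test_that("tf-idf matches the smoothed-idf hand computation", {
  corp <- tiny_corpus(c("x x y", "y z"))
  s <- tfidf_scores(corp, "d1", min_chars = 1)
  expect_equal(s[["x"]], 2 * (log(3 / 2) + 1), tolerance = 1e-12)
  expect_equal(s[["y"]], 1.0, tolerance = 1e-12)
  expect_equal(names(which.max(s)), "x")

  # single-document corpus: idf collapses to 1, ranking is by tf alone
  solo <- tiny_corpus("aa aa bb")
  s1 <- tfidf_scores(solo, "d1")
  expect_equal(unname(s1[c("aa", "bb")]), c(2, 1))

  expect_error(tfidf_scores(corp, "nope"), "nope")
})

test_that("title and POS weights shift the tf-idf ranking as configured", {
  # y: noun in the title; x: verb in the body, higher raw tf-idf
  corp <- build_corpus(data.frame(doc_id = c("d1", "d2"),
                                  title = c("y/n", ""),
                                  body = c("x/v x/v", "y/n z/n")))
  cfg_on <- strategy_config(strategies = "weights")
  s_off <- tfidf_scores(corp, "d1", min_chars = 1)
  s_on <- tfidf_scores(corp, "d1", config = cfg_on, min_chars = 1)
  expect_gt(s_off[["x"]], s_off[["y"]])           # baseline prefers x
  expect_equal(s_on[["y"]], 1.0 * 3 * 1.2, tolerance = 1e-12)
  expect_equal(s_on[["x"]], 2 * (log(3 / 2) + 1) * 0.8, tolerance = 1e-12)
  expect_gt(s_on[["y"]], s_on[["x"]])             # weights flip the ranking
})

test_that("each weight parameter scales exactly the tokens it applies to", {
  corp <- build_corpus(data.frame(
    doc_id = "d1", title = "tt/n",
    body = "tt/n nn/n nn/n vv/v oo/x oo/x"))
  base <- tfidf_scores(corp, "d1", config = strategy_config(strategies = "weights"))
  dbl_title <- tfidf_scores(corp, "d1", config = strategy_config(
    weight_title = 6, strategies = "weights"))
  expect_equal(dbl_title[["tt"]], 2 * base[["tt"]], tolerance = 1e-12)
  expect_equal(dbl_title[["nn"]], base[["nn"]], tolerance = 1e-12)
  expect_equal(dbl_title[["vv"]], base[["vv"]], tolerance = 1e-12)

  # a non-title token tagged `other` is never touched by the weights strategy
  off <- tfidf_scores(corp, "d1")
  expect_equal(base[["oo"]], off[["oo"]], tolerance = 1e-12)
})

test_that("textrank reproduces fixed points on canonical small graphs", {
  # symmetric two-candidate document: both scores are exactly 1
  two <- tiny_corpus("aa bb")
  s2 <- textrank_scores(two, "d1")
  expect_equal(unname(s2[c("aa", "bb")]), c(1, 1), tolerance = 1e-4)

  # path graph: the middle node dominates; agree with the closed-form oracle
  path <- tiny_corpus("aa bb cc")
  s3 <- textrank_scores(path, "d1")
  W <- matrix(0, 3, 3, dimnames = list(c("aa", "bb", "cc"),
                                       c("aa", "bb", "cc")))
  W["aa", "bb"] <- W["bb", "aa"] <- 1
  W["bb", "cc"] <- W["cc", "bb"] <- 1
  oracle <- solve_graph_rank(W)
  expect_equal(unname(s3[c("aa", "bb", "cc")]), oracle, tolerance = 1e-5)
  expect_gt(s3[["bb"]], s3[["aa"]])
  expect_equal(s3[["aa"]], s3[["cc"]], tolerance = 1e-6)

  # isolated candidate: empty adjacency fixes the score at 1 - damping
  iso <- tiny_corpus("aa x x")   # single-char neighbours are not candidates
  expect_equal(as.numeric(textrank_scores(iso, "d1")), 0.15,
               tolerance = 1e-9)

  # empty candidate list yields an empty map
  expect_length(textrank_scores(tiny_corpus("x y"), "d1"), 0)
})

test_that("textrank agrees with the dense linear-solve oracle on random graphs", {
  set.seed(42)
  for (rep in 1:25) {
    v <- sample(2:8, 1)
    W <- matrix(0, v, v)
    for (i in seq_len(v - 1)) for (j in (i + 1):v) {
      if (runif(1) < 0.5) W[i, j] <- W[j, i] <- sample(1:4, 1)
    }
    dimnames(W) <- list(paste0("n", 1:v), paste0("n", 1:v))
    s <- suppressWarnings(textrank_graph(W, tol = 1e-10, max_iter = 1000))
    expect_equal(unname(as.numeric(s)), solve_graph_rank(W), tolerance = 1e-8)
  }
})

test_that("synonym elimination removes the shorter of similar surfaces", {
  # character-set cosine 3/sqrt(3*4) ~ 0.866 >= 0.5: shorter one goes
  ranked <- data.frame(surface = c("abc", "abcd"), score = c(2, 1))
  out <- eliminate_synonyms(ranked, 0.5)
  expect_equal(out$surface, "abcd")
  expect_equal(char_cosine("abc", "abcd"), 3 / sqrt(12), tolerance = 1e-12)

  # disjoint characters: untouched
  ranked2 <- data.frame(surface = c("abc", "xyz"), score = c(2, 1))
  expect_equal(eliminate_synonyms(ranked2, 0.5)$surface, c("abc", "xyz"))

  # equal length: the higher-scored one stays
  ranked3 <- data.frame(surface = c("abcd", "abce"), score = c(2, 1))
  expect_equal(eliminate_synonyms(ranked3, 0.5)$surface, "abcd")

  expect_error(eliminate_synonyms(ranked, 1.5), "\\[0, 1\\]")
})

test_that("synonym elimination yields a pairwise-dissimilar subsequence", {
  set.seed(7)
  alpha <- letters[1:8]   # deliberately collision-rich
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    surfaces <- unique(replicate(n, paste(sample(alpha, sample(2:5, 1)),
                                          collapse = "")))
    ranked <- data.frame(surface = surfaces,
                         score = sort(runif(length(surfaces)),
                                      decreasing = TRUE))
    out <- eliminate_synonyms(ranked, 0.6)
    # subsequence of the input
    expect_true(all(out$surface %in% ranked$surface))
    expect_false(is.unsorted(rev(out$score)))
    # survivors pairwise below the threshold
    if (nrow(out) >= 2) {
      for (i in seq_len(nrow(out) - 1)) for (j in (i + 1):nrow(out)) {
        expect_lt(char_cosine(out$surface[i], out$surface[j]), 0.6)
      }
    }
  }
})

test_that("keyword extraction truncates, promotes past synonyms, and ablates", {
  # only 3 distinct candidates: shorter list, no error
  few <- tiny_corpus("aa bb cc")
  expect_equal(nrow(extract_keywords(few, "d1", k = 5)), 3L)

  # synonyms at ranks 5-6 are dropped, ranks 7-8 promoted into the top five
  body <- paste(c(rep("abcde/n", 9), rep("fghij/n", 8), rep("klmno/n", 7),
                  rep("pqrst/n", 6), rep("abcd/n", 5), rep("fghi/n", 4),
                  rep("uvwxy/n", 3), rep("zzyyx/n", 2)), collapse = " ")
  corp <- tiny_corpus(body)
  cfg <- strategy_config(strategies = "synonyms")
  kw <- extract_keywords(corp, "d1", method = "tfidf", k = 5, config = cfg)
  expect_equal(kw$surface, c("abcde", "fghij", "klmno", "pqrst", "uvwxy"))

  # ablation identity: no strategies, no compounds => exactly the baseline
  plain <- extract_keywords(corp, "d1", method = "tfidf", k = 5,
                            config = strategy_config())
  ranked <- sort(tfidf_scores(corp, "d1"), decreasing = TRUE)
  expect_equal(plain$surface, names(ranked)[1:5])
  expect_equal(plain$score, unname(ranked)[1:5])
})

test_that("both extractors recover planted topic words on the fixture", {
  fx <- default_topic_spec(seed = 5)
  gcx <- generate_corpus(fx)
  topic_words <- fx$topics$blood_pressure
  for (method in c("tfidf", "textrank")) {
    kw <- extract_keywords(gcx$corpus, "blood_pressure_01", method = method,
                           k = 5)
    expect_gte(sum(kw$surface %in% topic_words), 4)
  }
})

test_that("keyword sets have non-increasing scores and distinct surfaces", {
  fx <- default_topic_spec(seed = 2)
  gcx <- generate_corpus(fx)
  kw <- keyword_table(gcx$corpus, method = "textrank", k = 5,
                      config = strategy_config(strategies = c("weights",
                                                              "synonyms")))
  for (d in unique(kw$doc_id)) {
    sub <- kw[kw$doc_id == d, ]
    expect_false(is.unsorted(rev(sub$score)))
    expect_false(anyDuplicated(sub$surface) > 0)
    expect_lte(nrow(sub), 5L)
  }
})
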