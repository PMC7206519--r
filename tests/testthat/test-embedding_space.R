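test_that("embedding training honours the dimension and vocabulary contracts", {
  corp <- tiny_corpus(c("aa bb cc aa bb", "bb cc dd"))
  emb <- train_embeddings(corp, seed = 1, epochs = 1)
  expect_equal(ncol(emb$vectors), 200L)   # default dimension
  expect_setequal(rownames(emb$vectors), c("aa", "bb", "cc", "dd"))

  # hapax exclusion under min_count = 2 ("dd" occurs once)
  emb2 <- train_embeddings(corp, dim = 8, seed = 1, epochs = 1, min_count = 2)
  expect_false("dd" %in% rownames(emb2$vectors))

  expect_error(train_embeddings(corp, dim = 8, seed = 1, min_count = 99),
               "empty vocabulary")
})

test_that("embedding training is deterministic for a fixed seed", {
  corp <- generate_corpus(default_topic_spec(seed = 3))$corpus
  e1 <- train_embeddings(corp, dim = 16, seed = 11, epochs = 2)
  e2 <- train_embeddings(corp, dim = 16, seed = 11, epochs = 2)
  expect_identical(e1$vectors, e2$vectors)
  e3 <- train_embeddings(corp, dim = 16, seed = 12, epochs = 2)
  expect_false(identical(e1$vectors, e3$vectors))
})

test_that("same-topic embeddings are closer than cross-topic embeddings", {
  fx <- default_topic_spec(seed = 1)
  gcx <- generate_corpus(fx)
  emb <- train_embeddings(gcx$corpus, dim = 50, epochs = 10, seed = 1)
  same <- c(); cross <- c()
  terms <- names(fx$topics)
  for (a in terms) for (b in terms) {
    wa <- intersect(fx$topics[[a]], rownames(emb$vectors))
    wb <- intersect(fx$topics[[b]], rownames(emb$vectors))
    for (x in wa) for (y in wb) {
      if (x == y) next
      cs <- cosine_sim(emb$vectors[x, ], emb$vectors[y, ])
      if (a == b) same <- c(same, cs) else cross <- c(cross, cs)
    }
  }
  expect_gt(mean(same), mean(cross))
})

test_that("cosine similarity behaves on the canonical cases", {
  v <- c(3, -1, 2)
  expect_equal(cosine_sim(v, v), 1, tolerance = 1e-12)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 1), c(1, 0)), 1 / sqrt(2), tolerance = 1e-12)
  expect_warning(z <- cosine_sim(c(0, 0), c(1, 2)), "zero vector")
  expect_equal(z, 0)
  expect_error(cosine_sim(1:3, 1:4), "lengths differ")
})

test_that("text vectors implement the thresholded similarity sum", {
  # keyword identical to a term contributes exactly cosine 1
  tab <- make_embeddings(list(t1 = c(1, 0, 0), t2 = c(0, 1, 0)))
  sp <- vector_space(c("t1", "t2"))
  tv <- build_text_vector("t1", tab, sp)
  expect_equal(unname(tv), c(1, 0))

  # two keywords at cosines 0.6 and 0.7 to the term sum to 1.3
  tab2 <- make_embeddings(list(
    t1 = c(1, 0, 0),
    k1 = c(0.6, 0.8, 0),
    k2 = c(0.7, 0, sqrt(1 - 0.49))))
  sp1 <- vector_space("t1")
  tv2 <- build_text_vector(c("k1", "k2"), tab2, sp1)
  expect_equal(unname(tv2), 1.3, tolerance = 1e-12)

  # all similarities below the threshold: zero vector
  tab3 <- make_embeddings(list(t1 = c(1, 0), k1 = c(0.2, sqrt(1 - 0.04))))
  expect_equal(unname(build_text_vector("k1", tab3, sp1)), 0)

  # empty keyword set and out-of-vocabulary keywords contribute nothing
  expect_equal(unname(build_text_vector(character(), tab2, sp1)), 0)
  expect_equal(unname(build_text_vector("missing", tab2, sp1)), 0)

  # unresolvable term: entry 0 with a warning
  sp2 <- vector_space(c("t1", "ghost"))
  expect_warning(tvg <- build_text_vector("k1", tab2, sp2), "ghost")
  expect_equal(unname(tvg["ghost"]), 0)

  # aliases resolve a term to an in-vocabulary surface
  sp3 <- vector_space("label", aliases = list(label = "t1"))
  expect_equal(unname(build_text_vector("t1", tab, sp3)), 1)
})

test_that("text vectors equal the brute-force double loop on random fixtures", {
  set.seed(31)
  for (rep in 1:50) {
    n_terms <- sample(2:6, 1)
    n_kw <- sample(0:5, 1)
    dim <- sample(3:8, 1)
    surfaces <- paste0("w", seq_len(n_terms + n_kw + 2))
    vecs <- lapply(surfaces, function(s) rnorm(dim))
    names(vecs) <- surfaces
    tab <- make_embeddings(vecs)
    terms <- surfaces[seq_len(n_terms)]
    kws <- sample(surfaces, n_kw)
    thr <- runif(1)
    got <- build_text_vector(kws, tab, vector_space(terms), thr)
    # independent brute-force accumulation over (keyword, term) pairs
    want <- setNames(numeric(n_terms), terms)
    for (term in terms) for (kw in unique(kws)) {
      cs <- sum(vecs[[kw]] * vecs[[term]]) /
        (sqrt(sum(vecs[[kw]]^2)) * sqrt(sum(vecs[[term]]^2)))
      if (cs >= thr) want[term] <- want[term] + cs
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("text vectors are monotone in keywords and antitone in threshold", {
  set.seed(13)
  surfaces <- paste0("w", 1:12)
  vecs <- lapply(surfaces, function(s) rnorm(6))
  names(vecs) <- surfaces
  tab <- make_embeddings(vecs)
  sp <- vector_space(surfaces[1:4])
  for (rep in 1:100) {
    kws <- sample(surfaces, sample(1:6, 1))
    thr <- runif(1)
    base <- build_text_vector(kws, tab, sp, thr)
    # appending a keyword never decreases any entry
    more <- build_text_vector(c(kws, sample(setdiff(surfaces, kws), 1)),
                              tab, sp, thr)
    expect_true(all(more >= base - 1e-12))
    # raising the threshold never increases any entry
    higher <- build_text_vector(kws, tab, sp, min(1, thr + runif(1, 0, 0.3)))
    expect_true(all(higher <= base + 1e-12))
  }
})

test_that("threshold one with term-identical keywords gives a 0/1 vector", {
  tab <- make_embeddings(list(t1 = c(1, 0, 0), t2 = c(0, 1, 0),
                              t3 = c(0, 0, 1)))
  sp <- vector_space(c("t1", "t2", "t3"))
  tv <- build_text_vector(c("t1", "t3"), tab, sp, threshold = 1)
  expect_equal(unname(tv), c(1, 0, 1))
})

test_that("embeddings round-trip through the word2vec text format", {
  corp <- tiny_corpus("aa bb cc aa")
  emb <- train_embeddings(corp, dim = 12, seed = 4, epochs = 2)
  path <- withr::local_tempfile(fileext = ".vec")
  write_embeddings(emb, path)
  header <- strsplit(readLines(path, n = 1), " ")[[1]]
  expect_equal(as.integer(header), c(nrow(emb$vectors), 12L))
  back <- read_embeddings(path)
  expect_equal(back$dim, 12L)
  expect_equal(back$vectors[rownames(emb$vectors), ], emb$vectors,
               tolerance = 1e-15)
})
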