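test_that("credited precision at k follows the 1/0.5/0 crediting rule", {
  rk <- c("d1", "d2", "d3", "d4", "d5")
  jd <- c(d1 = 2, d2 = 1, d3 = 0, d4 = 1, d5 = 0)
  expect_equal(precision_at_k(rk, jd, 2), 0.75)          # (1 + 0.5) / 2
  expect_equal(precision_at_k(rk, c(d1 = 0, d2 = 0), 2), 0)
  expect_equal(precision_at_k(rk, c(d1 = 2, d2 = 2, d3 = 0, d4 = 1, d5 = 0),
                              5), 0.5)
  # unjudged documents count zero
  expect_equal(precision_at_k(rk, c(d1 = 2), 2), 0.5)
  # k beyond the ranking falls back to the full ranking with a warning
  expect_warning(p <- precision_at_k(rk, jd, 10), "full ranking")
  expect_equal(p, (1 + 0.5 + 0.5) / 5)
})

test_that("macro precision is the arithmetic mean over patients", {
  rks <- list(p1 = c("a", "b"), p2 = c("a", "b"))
  jd <- data.frame(patient_id = c("p1", "p1", "p2", "p2"),
                   doc_id = c("a", "b", "a", "b"),
                   grade = c(2, 2, 0, 0))
  expect_equal(macro_precision_at_k(rks, jd, 2), 0.5)
  # identical patients: macro equals the individual value
  jd2 <- jd; jd2$grade <- c(2, 0, 2, 0)
  expect_equal(macro_precision_at_k(rks, jd2, 2), 0.5)
  expect_error(macro_precision_at_k(list(), jd, 1), "no patients")
})

test_that("average precision matches hand computation under graded rules", {
  # perfect binary ranking scores exactly one
  expect_equal(average_precision(c("a", "b", "c"),
                                 c(a = 2, b = 2, c = 0)), 1)
  # single relevant document at rank 2 of 3: AP = P@2 = 0.5
  expect_equal(average_precision(c("x", "a", "y"), c(a = 2)), 0.5)
  expect_error(average_precision(character(), c(a = 2)), "empty")
})

test_that("MAP equals a brute-force reference on a random 50-patient set", {
  set.seed(23)
  n <- 30
  docs <- sprintf("d%02d", 1:n)
  rankings <- list(); jd <- list()
  for (i in 1:50) {
    p <- sprintf("p%02d", i)
    rankings[[p]] <- sample(docs)
    jd[[p]] <- data.frame(patient_id = p, doc_id = docs,
                          grade = sample(0:2, n, replace = TRUE,
                                         prob = c(0.5, 0.25, 0.25)))
  }
  jd <- do.call(rbind, jd)

  # independent reference: literal loops over the definition
  ap_ref <- function(ranking, grades) {
    g <- grades[ranking]; g[is.na(g)] <- 0
    credit <- ifelse(g == 2, 1, ifelse(g == 1, 0.5, 0))
    r_tot <- sum(grades >= 1)
    acc <- 0
    for (k in seq_along(ranking)) {
      if (g[k] >= 1) acc <- acc + sum(credit[1:k]) / k
    }
    acc / r_tot
  }
  ref <- mean(vapply(names(rankings), function(p) {
    sub <- jd[jd$patient_id == p, ]
    ap_ref(rankings[[p]], setNames(sub$grade, sub$doc_id))
  }, numeric(1)))
  expect_equal(mean_average_precision(rankings, jd), ref, tolerance = 1e-12)

  # macro P@k against the brute-force mean on the same instance
  for (k in c(1, 5, 10)) {
    ref_k <- mean(vapply(names(rankings), function(p) {
      sub <- jd[jd$patient_id == p, ]
      g <- setNames(sub$grade, sub$doc_id)[rankings[[p]][1:k]]
      sum(ifelse(g == 2, 1, ifelse(g == 1, 0.5, 0))) / k
    }, numeric(1)))
    expect_equal(macro_precision_at_k(rankings, jd, k), ref_k,
                 tolerance = 1e-12)
  }
})

test_that("patients without a relevant document are excluded with a warning", {
  rks <- list(p1 = c("a", "b"), p2 = c("a", "b"))
  jd <- data.frame(patient_id = c("p1", "p1", "p2", "p2"),
                   doc_id = c("a", "b", "a", "b"),
                   grade = c(2, 0, 0, 0))
  expect_warning(m <- mean_average_precision(rks, jd), "p2")
  expect_equal(m, 1)
})

test_that("graded metrics reduce to textbook binary metrics", {
  set.seed(11)
  docs <- sprintf("d%02d", 1:20)
  for (rep in 1:20) {
    ranking <- sample(docs)
    relevant <- sample(docs, sample(1:10, 1))
    jd <- setNames(ifelse(docs %in% relevant, 2L, 0L), docs)
    k <- sample(1:20, 1)
    expect_equal(precision_at_k(ranking, jd, k),
                 binary_p_at_k(ranking, relevant, k))
  }
})

test_that("moving a no-need doc above a most-need doc never helps", {
  set.seed(2)
  grades_pool <- expand.grid(rep(list(0:2), 4))  # all length-4 gradings
  for (row in seq_len(nrow(grades_pool))) {
    g <- as.integer(grades_pool[row, ])
    ids <- paste0("d", 1:4)
    jd <- setNames(g, ids)
    for (i in 1:3) for (j in (i + 1):4) {
      if (g[i] == 2 && g[j] == 0) {
        worse <- ids; worse[c(i, j)] <- ids[c(j, i)]  # 0 now above 2
        for (k in 1:4) {
          expect_lte(precision_at_k(worse, jd, k),
                     precision_at_k(ids, jd, k) + 1e-12)
        }
      }
    }
  }
})

test_that("keyword precision counts exact normalized matches", {
  auto <- list(d1 = c("Alpha", "beta"), d2 = c("gamma", "delta"))
  manual <- list(d1 = c("alpha ", "beta"), d2 = c("gamma", "delta"))
  expect_equal(keyword_precision(auto, manual)$precision, 1)

  manual2 <- list(d1 = c("x", "y"), d2 = c("z", "w"))
  expect_equal(keyword_precision(auto, manual2)$precision, 0)

  expect_error(keyword_precision(auto, list(d1 = "a")), "d2")

  # when per-document counts match, precision equals recall
  kp <- keyword_precision(list(d1 = c("a", "b", "c")),
                          list(d1 = c("a", "x", "y")))
  expect_equal(kp$n_auto, kp$n_manual)
  expect_equal(kp$n_correct / kp$n_auto, kp$precision)
})

test_that("the random baseline hits its degenerate and analytic values", {
  expect_equal(random_baseline(5, 10, 10, 3, replicates = 20, seed = 1), 1)
  expect_equal(random_baseline(5, 10, 0, 3, replicates = 20, seed = 1), 0)
  expect_error(random_baseline(5, 10, 2, 3, replicates = 0), "replicates")
  # expectation relevant/n for a uniformly random ranking
  mc <- random_baseline(20, 50, 20, 5, replicates = 400, seed = 7)
  expect_equal(mc, 0.4, tolerance = 0.02)
})

test_that("the metrics report tabulates MAP and macro precision per method", {
  rks <- list(p1 = c("a", "b", "c"), p2 = c("b", "a", "c"))
  jd <- data.frame(patient_id = rep(c("p1", "p2"), each = 3),
                   doc_id = rep(c("a", "b", "c"), 2),
                   grade = c(2, 1, 0, 0, 2, 2))
  rep_tab <- metrics_report(list(m1 = rks, m2 = rks), jd, at = c(1, 2))
  expect_equal(rep_tab$method, c("m1", "m2"))
  expect_equal(rep_tab$p_at_1, rep(1, 2))   # both patients lead with grade 2
  expect_true(all(rep_tab$map >= 0 & rep_tab$map <= 1))
})
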