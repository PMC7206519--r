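# Deterministic synthetic-data generators: planted-topic corpora, patient
# populations with configurable marginal prevalences, and relevance
# judgments derived from the planted ground truth. Synthetic "words" are
# random strings over a small alphabet so that character-composition synonym
# similarity is exercised without real Chinese text.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  force(code)
}

# Synthetic words drawn from a wide ideograph-like alphabet: real Chinese
# composes words from thousands of characters, so unrelated words rarely
# share any -- chance character collisions would otherwise fool the
# character-composition synonym detector.
synth_alphabet <- function(block = 0L, size = 400L) {
  vapply(0x4E00L + block * size + seq_len(size) - 1L, intToUtf8, character(1))
}

synth_words <- function(n, n_chars = c(2L, 4L), alphabet = synth_alphabet()) {
  out <- character(0)
  while (length(out) < n) {
    w <- paste(sample(alphabet, sample(n_chars[1]:n_chars[2], 1L),
                      replace = FALSE), collapse = "")
    out <- union(out, w)
  }
  out[seq_len(n)]
}

#' Specify a planted-topic corpus
#'
#' Describes the synthetic corpus the generator emulates: topical documents
#' whose titles announce their topic, bodies mixing topic words with a shared
#' background vocabulary, plus optional planted compound-word adjacencies and
#' planted near-synonym pairs.
#'
#' @param topics named list: term label -> character vector of topic words
#'   (all treated as nouns; keep the term label itself in its list so the
#'   term receives an embedding). Word lists must be pairwise disjoint.
#' @param background_vocab number of shared background words (default 60).
#' @param docs_per_topic documents generated per topic (default 10).
#' @param tokens_per_doc body length mean and sd (default `c(60, 10)`).
#' @param title_topic_words topic words per title (default 2; the first is
#'   always the term label).
#' @param topic_word_prob probability a body token is a topic word
#'   (default 0.5).
#' @param compound_plants optional list of
#'   `list(atoms = c(a, b), count = N, topic = term)` adjacent plants.
#' @param synonym_plants optional list of `c(short, long)` surface pairs,
#'   recorded for reference (pairs should already be in a topic word list).
#' @param seed RNG seed.
#' @return a list of class `edurec_topic_spec`.
#' @export
topic_model_spec <- function(topics, background_vocab = 60,
                             docs_per_topic = 10,
                             tokens_per_doc = c(60, 10),
                             title_topic_words = 2, topic_word_prob = 0.5,
                             compound_plants = NULL, synonym_plants = NULL,
                             seed = 1) {
  stopifnot(length(topics) >= 1L, !is.null(names(topics)),
            background_vocab >= 1, docs_per_topic >= 1,
            title_topic_words >= 1)
  all_topic_words <- unlist(topics, use.names = FALSE)
  if (anyDuplicated(all_topic_words)) {
    stop("topic word lists must be disjoint")
  }
  short <- names(topics)[vapply(topics, length, integer(1)) < title_topic_words]
  if (length(short) > 0L) {
    stop("title_topic_words exceeds the word list of: ",
         paste(short, collapse = ", "))
  }
  structure(list(topics = topics, background_vocab = background_vocab,
                 docs_per_topic = docs_per_topic,
                 tokens_per_doc = tokens_per_doc,
                 title_topic_words = title_topic_words,
                 topic_word_prob = topic_word_prob,
                 compound_plants = compound_plants,
                 synonym_plants = synonym_plants, seed = seed),
            class = "edurec_topic_spec")
}

#' Default planted-topic spec over vector-space terms
#'
#' Builds a [topic_model_spec()] whose topics are the given term labels, each
#' with the label itself plus synthetic topic words, one planted noun-noun
#' compound per topic (adjacency count 10) and one planted synonym pair per
#' topic (surfaces sharing all but one character).
#'
#' @param terms term labels to use as topics (default: three default-space
#'   terms).
#' @param words_per_topic synthetic words per topic besides the label
#'   (default 10).
#' @param docs_per_topic,seed passed through.
#' @param ... further arguments to [topic_model_spec()].
#' @return an `edurec_topic_spec`.
#' @export
default_topic_spec <- function(terms = c("blood_pressure", "blood_glucose",
                                         "depression"),
                               words_per_topic = 10, docs_per_topic = 10,
                               seed = 1, ...) {
  with_seed(seed * 7919L + 11L, {
    n_topics <- length(terms)
    pool <- synth_words(n_topics * (words_per_topic + 3L))
    topics <- list(); compounds <- list(); synonyms <- list()
    idx <- 1L
    for (i in seq_len(n_topics)) {
      words <- pool[idx:(idx + words_per_topic - 1L)]
      idx <- idx + words_per_topic
      syn_short <- pool[idx]; idx <- idx + 1L
      syn_long <- paste0(syn_short, intToUtf8(0x75C5L))
      atoms <- pool[idx:(idx + 1L)]; idx <- idx + 2L
      topics[[terms[i]]] <- c(terms[i], words, syn_short, syn_long)
      compounds[[i]] <- list(atoms = atoms, count = 10L, topic = terms[i])
      synonyms[[i]] <- c(syn_short, syn_long)
    }
    topic_model_spec(topics = topics, docs_per_topic = docs_per_topic,
                     compound_plants = compounds, synonym_plants = synonyms,
                     seed = seed, ...)
  })
}

#' Generate a planted-topic corpus
#'
#' Deterministic for a fixed spec seed. Every document's title starts with
#' its topic's term label followed by further topic words; bodies mix topic
#' and background words; planted compounds are appended as adjacent atom
#' pairs spread over the topic's documents until each reaches its target
#' count.
#'
#' @param spec an `edurec_topic_spec`.
#' @return list with `corpus` (an `edurec_corpus`) and `topics` (named
#'   character vector: doc_id -> generating term).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "edurec_topic_spec"))
  with_seed(spec$seed, {
    annotate <- function(surface, tag) paste0(surface, "/", tag)
    bg <- synth_words(spec$background_vocab, alphabet = synth_alphabet(block = 1L))
    bg_pos <- sample(c("n", "v", "x"), length(bg), replace = TRUE,
                     prob = c(0.6, 0.25, 0.15))
    terms <- names(spec$topics)
    topic_of <- character(0)
    title_store <- list(); body_store <- list()
    for (term in terms) {
      words <- spec$topics[[term]]
      for (d in seq_len(spec$docs_per_topic)) {
        doc_id <- sprintf("%s_%02d", term, d)
        extra <- if (spec$title_topic_words > 1L) {
          sample(setdiff(words, term), spec$title_topic_words - 1L)
        } else character(0)
        title_store[[doc_id]] <- paste(annotate(c(term, extra), "n"),
                                       collapse = " ")
        n_tok <- max(20L, round(stats::rnorm(1, spec$tokens_per_doc[1],
                                             spec$tokens_per_doc[2])))
        is_topic <- stats::runif(n_tok) < spec$topic_word_prob
        toks <- character(n_tok)
        toks[is_topic] <- annotate(sample(words, sum(is_topic), TRUE), "n")
        bg_idx <- sample(seq_along(bg), sum(!is_topic), TRUE)
        toks[!is_topic] <- annotate(bg[bg_idx], bg_pos[bg_idx])
        body_store[[doc_id]] <- toks
        topic_of[doc_id] <- term
      }
    }
    for (plant in spec$compound_plants %||% list()) {
      docs <- names(topic_of)[topic_of == plant$topic]
      pair <- paste(annotate(plant$atoms, "n"), collapse = " ")
      for (i in seq_len(plant$count)) {
        d <- docs[(i - 1L) %% length(docs) + 1L]
        body_store[[d]] <- c(body_store[[d]], pair)
      }
    }
    ids <- names(body_store)
    records <- data.frame(
      doc_id = ids,
      title = unlist(title_store[ids], use.names = FALSE),
      body = vapply(ids, function(d) paste(body_store[[d]], collapse = " "),
                    character(1)),
      reproducible = rep(TRUE, length(ids)),
      stringsAsFactors = FALSE)
    rownames(records) <- NULL
    list(corpus = build_corpus(records), topics = topic_of)
  })
}

#' Specify a synthetic patient population
#'
#' Marginal prevalences of each abnormal characteristic; every characteristic
#' is drawn independently per patient. The defaults mirror the marginal
#' structure of a 50-patient chronic-disease cohort (all hypertensive and on
#' antihypertensive drugs; 54% abnormal blood pressure, 68% overweight, 14%
#' smokers, and so on).
#'
#' @param m number of patients (default 50).
#' @param prevalence named list overriding individual default prevalences
#'   (see `default_prevalence()` in the source for the full set).
#' @param age_mean,age_sd age distribution in years (defaults 57 and 10).
#' @param seed RNG seed.
#' @return a list of class `edurec_population_spec`.
#' @export
patient_population_spec <- function(m = 50, prevalence = list(),
                                    age_mean = 57, age_sd = 10, seed = 1) {
  base <- default_prevalence()
  bad <- setdiff(names(prevalence), names(base))
  if (length(bad) > 0L) stop("unknown prevalence fields: ",
                             paste(bad, collapse = ", "))
  base[names(prevalence)] <- prevalence
  if (any(unlist(base) < 0 | unlist(base) > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  structure(list(m = m, prevalence = base, age_mean = age_mean,
                 age_sd = age_sd, seed = seed),
            class = "edurec_population_spec")
}

#' Default marginal prevalences of the synthetic population
#'
#' One entry per abnormal characteristic, mirroring the marginal structure of
#' a 50-patient chronic-disease cohort. Override entries through the
#' `prevalence` argument of [patient_population_spec()].
#'
#' @return named list of prevalences in `[0, 1]`.
#' @export
default_prevalence <- function() {
  list(
    female = 0.46, pregnant = 0, overweight = 0.68,
    hist_hypertension = 1.0, hist_diabetes = 0.12, hist_stroke = 0.08,
    hist_hyperlipidemia = 0.24, hist_coronary_artery_disease = 0.06,
    hist_copd = 0.04,
    abn_glucose = 0.28, abn_total_cholesterol = 0.28,
    abn_triglyceride = 0.42, abn_hdl = 0.14, abn_ldl = 0.20,
    abn_uric_acid = 0.22,
    abn_bp = 0.54, smoking = 0.14, drinking = 0.18,
    diet_medium = 0.54, diet_poor = 0.08,
    med_antihypertensive = 1.0, med_hypoglycemic = 0.06,
    med_hypolipidemic = 0.24,
    phq_mild = 0.24, phq_moderate = 0.06, phq_modsevere = 0.04,
    ipaq_moderate = 0.46, ipaq_low = 0.18)
}

lab_ranges <- function() {
  list(glucose = c(3.9, 6.1), total_cholesterol = c(2.9, 5.2),
       triglyceride = c(0.56, 1.70), hdl = c(1.20, 1.68),
       ldl = c(2.07, 3.12))
}

uric_range <- function(sex, age) {
  if (sex == "male") {
    if (age < 60) c(149, 416) else c(250, 476)
  } else {
    if (age < 60) c(89, 357) else c(190, 434)
  }
}

#' Generate a synthetic patient population
#'
#' Draws each characteristic independently at its configured prevalence;
#' abnormal draws place the field outside its reference range (for example an
#' abnormal lab is sampled 1.02-1.7-fold above its upper limit). The true
#' need set of each patient is the set of terms at which [evaluate_rules()]
#' is nonzero under the supplied ruleset, so fixtures and rule engine agree
#' by construction.
#'
#' @param spec an `edurec_population_spec`.
#' @param ruleset the severity ruleset defining needs (default
#'   [default_ruleset()]).
#' @param space the term space (default [default_space()]).
#' @return list with `records` (list of `edurec_patient`) and `needs` (named
#'   list: patient_id -> character vector of need terms).
#' @export
generate_patients <- function(spec, ruleset = default_ruleset(),
                              space = default_space()) {
  stopifnot(inherits(spec, "edurec_population_spec"))
  pv <- spec$prevalence
  with_seed(spec$seed, {
    records <- vector("list", spec$m)
    for (i in seq_len(spec$m)) {
      hit <- function(p) stats::runif(1) < p
      sex <- if (hit(pv$female)) "female" else "male"
      age <- max(18, round(stats::rnorm(1, spec$age_mean, spec$age_sd)))
      bmi <- if (hit(pv$overweight)) stats::runif(1, 24, 33) else
        stats::runif(1, 19, 23.5)
      hist <- character(0)
      for (d in c("hypertension", "diabetes", "stroke", "hyperlipidemia",
                  "coronary_artery_disease", "copd")) {
        if (hit(pv[[paste0("hist_", d)]])) hist <- c(hist, d)
      }
      labs <- list()
      for (lab in names(lab_ranges())) {
        rng <- lab_ranges()[[lab]]
        labs[[lab]] <- if (hit(pv[[paste0("abn_", lab)]])) {
          rng[2] * stats::runif(1, 1.02, 1.7)
        } else stats::runif(1, rng[1], rng[2])
      }
      urng <- uric_range(sex, age)
      uric <- if (hit(pv$abn_uric_acid)) {
        urng[2] * stats::runif(1, 1.02, 1.7)
      } else stats::runif(1, urng[1], urng[2])
      if (hit(pv$abn_bp)) {
        sys <- stats::runif(1, 140, 195); dia <- stats::runif(1, 85, 115)
      } else {
        sys <- stats::runif(1, 100, 135); dia <- stats::runif(1, 65, 85)
      }
      cigarettes <- if (hit(pv$smoking)) sample(5:30, 1L) else 0
      drinks <- if (hit(pv$drinking)) sample(2:20, 1L) else 0
      u <- stats::runif(1)
      diet <- if (u < pv$diet_poor) "poor" else
        if (u < pv$diet_poor + pv$diet_medium) "medium" else "good"
      meds <- character(0)
      for (m in c("antihypertensive", "hypoglycemic", "hypolipidemic")) {
        if (hit(pv[[paste0("med_", m)]])) meds <- c(meds, m)
      }
      u <- stats::runif(1)
      phq9 <- if (u < pv$phq_modsevere) sample(15:20, 1L) else
        if (u < pv$phq_modsevere + pv$phq_moderate) sample(10:14, 1L) else
          if (u < pv$phq_modsevere + pv$phq_moderate + pv$phq_mild) {
            sample(5:9, 1L)
          } else sample(0:4, 1L)
      u <- stats::runif(1)
      ipaq <- if (u < pv$ipaq_low) "low" else
        if (u < pv$ipaq_low + pv$ipaq_moderate) "moderate" else "high"
      records[[i]] <- patient_record(
        patient_id = sprintf("p%03d", i), sex = sex, age = age,
        bmi = round(bmi, 1), pregnant = hit(pv$pregnant) & sex == "female",
        disease_history = hist,
        glucose = round(labs$glucose, 2),
        total_cholesterol = round(labs$total_cholesterol, 2),
        triglyceride = round(labs$triglyceride, 2),
        hdl = round(labs$hdl, 2), ldl = round(labs$ldl, 2),
        uric_acid = round(uric, 1),
        systolic_bp = round(sys), diastolic_bp = round(dia),
        cigarettes_per_day = cigarettes, drinks_per_week = drinks,
        diet = diet, medications = meds, medication_adherence = "good",
        phq9 = phq9, ipaq = ipaq)
    }
    needs <- lapply(records, function(r) {
      v <- evaluate_rules(r, ruleset, space)
      names(v)[v > 0L]
    })
    names(needs) <- vapply(records, `[[`, character(1), "patient_id")
    list(records = records, needs = needs)
  })
}

#' Derive graded relevance judgments from planted ground truth
#'
#' Grade 2 (most need) when a document's topic is in the patient's need set,
#' grade 1 (partial need) when the topic is adjacent to a need term under the
#' supplied adjacency map, grade 0 otherwise.
#'
#' @param true_topics named character vector: doc_id -> topic term.
#' @param true_needs named list: patient_id -> character vector of need
#'   terms.
#' @param adjacent optional list of `c(term_a, term_b)` pairs treated as
#'   symmetric partial-need neighbours.
#' @param space the `edurec_space` all labels must belong to.
#' @return data frame (`patient_id`, `doc_id`, `grade`).
#' @export
generate_judgments <- function(true_topics, true_needs, adjacent = NULL,
                               space = default_space()) {
  labels <- unique(c(true_topics, unlist(true_needs),
                     unlist(adjacent)))
  bad <- setdiff(labels, space$terms)
  if (length(bad) > 0L) {
    stop("labels outside the vector space: ", paste(bad, collapse = ", "))
  }
  neighbours <- function(term) {
    out <- character(0)
    for (pr in adjacent %||% list()) {
      if (pr[1] == term) out <- c(out, pr[2])
      if (pr[2] == term) out <- c(out, pr[1])
    }
    out
  }
  rows <- list()
  for (p in names(true_needs)) {
    needs <- true_needs[[p]]
    grade <- vapply(true_topics, function(topic) {
      if (topic %in% needs) 2L
      else if (any(neighbours(topic) %in% needs)) 1L
      else 0L
    }, integer(1))
    rows[[p]] <- data.frame(patient_id = p, doc_id = names(true_topics),
                            grade = unname(grade), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Planted ground-truth keyword sets for a generated corpus
#'
#' The reference ("manually annotated") keyword set of each document: its
#' topic's word list, the topic's planted compound atoms and their merged
#' surface, and optionally every induced-lexicon compound whose atoms involve
#' this topic's vocabulary and no other topic's (a concatenation of topic
#' words is topic content and counts as correct, mirroring how annotators
#' credit compounds containing a keyword). Planted synonym short forms are
#' excluded: an annotator lists the canonical full form only, so an
#' extractor that spends a slot on the abbreviation matches nothing.
#'
#' @param spec the `edurec_topic_spec` the corpus came from.
#' @param topics_of named character vector doc_id -> topic term (from
#'   [generate_corpus()]).
#' @param lexicon optional `edurec_lexicon` used for resegmentation.
#' @return named list: doc_id -> character vector of correct surfaces.
#' @export
planted_keywords <- function(spec, topics_of, lexicon = NULL) {
  vocab <- lapply(names(spec$topics), function(term) {
    words <- spec$topics[[term]]
    for (p in spec$compound_plants %||% list()) {
      if (p$topic == term) {
        words <- c(words, p$atoms, paste(p$atoms, collapse = ""))
      }
    }
    words
  })
  names(vocab) <- names(spec$topics)
  short_forms <- vapply(spec$synonym_plants %||% list(), `[`, character(1), 1L)
  out <- lapply(topics_of, function(term) {
    correct <- setdiff(vocab[[term]], short_forms)
    if (!is.null(lexicon) && nrow(lexicon) > 0L) {
      other <- unlist(vocab[names(vocab) != term], use.names = FALSE)
      for (i in seq_len(nrow(lexicon))) {
        atoms <- lexicon$atoms[[i]]
        if (any(atoms %in% vocab[[term]]) && !any(atoms %in% other)) {
          correct <- c(correct, lexicon$surface[i])
        }
      }
    }
    unique(correct)
  })
  names(out) <- names(topics_of)
  out
}

#' Fixture presets
#'
#' `"small"` is the desk-scale end-to-end fixture: 3 topics x 10 documents,
#' 10 patients whose only variable characteristics are the three topic
#' conditions (each at prevalence 0.7). `"paper-scale"` mirrors the study
#' dimensions: 5 topics x 20 documents (100 documents), 50 patients at the
#' default marginal prevalences.
#'
#' @param name preset name.
#' @param seed RNG seed shared by both generators.
#' @return list with `corpus_spec`, `population_spec` and `adjacent`.
#' @export
fixture_preset <- function(name = c("small", "paper-scale"), seed = 1) {
  name <- match.arg(name)
  if (name == "small") {
    terms <- c("blood_pressure", "blood_glucose", "depression")
    prev <- default_prevalence()
    prev[] <- 0
    prev$abn_bp <- 0.7; prev$abn_glucose <- 0.7
    prev$phq_mild <- 0.4; prev$phq_moderate <- 0.2; prev$phq_modsevere <- 0.1
    list(corpus_spec = default_topic_spec(terms, docs_per_topic = 10,
                                          seed = seed),
         population_spec = patient_population_spec(m = 10, prevalence = prev,
                                                   seed = seed + 1000L),
         adjacent = NULL)
  } else {
    terms <- c("blood_pressure", "blood_glucose", "diet", "depression",
               "physical_activity")
    list(corpus_spec = default_topic_spec(terms, docs_per_topic = 20,
                                          seed = seed),
         population_spec = patient_population_spec(m = 50, seed = seed + 1000L),
         adjacent = list(c("blood_pressure", "hypertension"),
                         c("blood_glucose", "diabetes")),
         space = default_space())
  }
}
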