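---
title: "Methods: profile-to-document matching in a shared term space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-to-document matching in a shared term space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The matching model

The recommender treats patient profiling and document understanding as two
projections into one ordered list of term labels (the *term space*; 33
labels by default). A patient becomes an integer severity vector
$\mathbf{p} \in \{0,1,2,3\}^L$, a document becomes a nonnegative real vector
$\mathbf{t} \in \mathbb{R}_{\ge 0}^L$, and the recommendation score is the
plain inner product $\sum_j p_j t_j$ — a non-normalized similarity that
rewards both agreement of direction and magnitude of need. The chain of
assumptions is worth stating explicitly:

* the term space is rich enough that both a patient's needs and a document's
  topics are expressible as weights over the same labels;
* severity is ordinal and small (0–3), so a patient vector is sparse and
  integer-valued;
* five keywords, mapped through word-embedding similarity, suffice to locate
  a document in the space.

None of these is innocuous; all three are inherited design commitments of
the system being modeled, and the package treats the term space and the
severity rules as *configuration* (YAML), not code.

## Patient profiling: the severity rule engine

A rule is `term` + `when` (an R predicate over a fixed record schema) +
`value` (0–3) + `priority`. Evaluation is total: the highest-priority
matching rule wins, ties resolve to the maximum value, no matching rule
means 0, and a predicate over missing fields simply does not match
("no evidence of need" rather than an error — the fail-soft posture a
recommender wants, as opposed to a clinical alarm system).

Band rules are written as open-ended lower bounds sharing one priority
(e.g. blood pressure grade 1 at 140/90, grade 2 at 160/100, grade 3 at
180/110, maximum of the systolic and diastolic grades). Under max-ties
resolution this makes single-field monotonicity structural rather than
accidental, and rule order irrelevant by construction — both properties are
tested by permutation and sweep.

Where only a reference range is published (the labs, BMI), grading beyond
"abnormal" is this package's choice: fold-over-limit bands at 1.2× and 1.5×
of the violated limit (symmetric below the lower limit), standard clinical
cut-points for the questionnaires (PHQ-9 bands 0–4/5–9/10–14/≥15; IPAQ
high/moderate/low to 0/1/2), BMI 24/28/32 with the 18.5–23.9 reference
range, disease history presence → 2, current prescriptions → 1. All
cut-points live in `inst/extdata/default_rules.yaml` and are meant to be
overridden per deployment.

## Document understanding

**Candidates.** Tokens that are not stopwords and have at least two
characters. The package's reference tokenizer is whitespace-plus-annotation
(`word/n`, `word/v`, ...); a real segmenter slots in behind the same
function contract.

**TF-IDF** uses raw term frequency and the smoothed inverse document
frequency $\ln\frac{N+1}{\mathrm{df}+1} + 1$ — the variant that stays
finite and positive for corpus-wide terms, so single-document corpora
degrade gracefully to frequency ranking.

**TextRank** builds an undirected graph over distinct candidate surfaces
with edge weights counting co-occurrences within a sliding window (default
2 = adjacency) and iterates
$S(v) = (1-d) + d \sum_{u \in N(v)} \frac{w_{uv}}{\sum_x w_{ux}} S(u)$
with damping $d = 0.85$, uniform start 1, tolerance $10^{-6}$, at most 100
iterations. Isolated candidates sit at $1-d$ exactly. The implementation is
checked against a closed-form dense solve of the same fixed point on random
graphs.

**The three strategies.**

* *Weights*: score multiplied by (title factor) × (POS factor), defaults
  3 / 1.2 / 0.8 for title words / nouns / verbs. The combination rule
  (multiplicative) is a package decision; the three constants are the
  system's published settings. For TextRank the weight applies as a
  post-multiplier on node scores, keeping strategy application symmetric
  across the two extractors. Note the combined weight is *not* homogeneous
  under scaling all three constants together — tokens touched by one, two
  or zero factors scale differently — so the tested contract is
  per-parameter: doubling one weight doubles exactly the scores of tokens
  it applies to and leaves the rest unchanged.
* *Compounds*: frequent, strictly adjacent atom sequences (≥ 5 corpus-wide
  by default, up to 3 atoms) whose POS pattern is noun–noun, adj–noun or
  noun–noun–noun become user-dictionary entries; re-segmentation merges
  maximal matches leftmost-longest (the overlap rule is a package decision).
* *Synonyms*: candidates are compared by the cosine of their
  character-composition one-hot vectors, $|A \cap B| / \sqrt{|A|\,|B|}$;
  at ≥ 0.5 the shorter surface is dropped (tie on length: keep the higher
  score; tie on both: lexicographically smaller survives). Elimination runs
  over the full ranked candidate list *before* top-k truncation, so k
  keywords survive whenever possible.

**Embedding mapping.** CBOW word2vec with negative sampling (window 5,
dimension 200, 5 epochs, 5 negatives, unigram^0.75 noise, linearly decaying
learning rate) is implemented in the package, single-threaded and fully
seeded — bit-reproducibility for a fixed seed is the contract, and
multi-worker speedups are deliberately absent. Entry $j$ of the text vector
sums the cosine similarities between term $j$'s embedding and each keyword's
embedding, keeping only those at or above the threshold (0.5; the
comparison is inclusive, a package decision). Keyword extraction scores do
not weight this sum. Out-of-vocabulary keywords contribute nothing; a term
with no resolvable embedding (directly or via configured aliases) yields 0
with a warning, keeping the pipeline total.

## Ranking, queue, metrics

Ranking is by inner product with lexicographic `doc_id` tie-breaks for
determinism. The delivery queue admits documents scoring *strictly* above
the threshold `v` (default 2 — deliberately small relative to vector
sparsity), never re-delivers, and excludes documents prohibited for
reproduction; rebuilds are wholesale and idempotent.

The metrics implement graded relevance: credit 1 / 0.5 / 0 for grades
2 / 1 / 0 inside $P@k$; the average-precision indicator counts grade ≥ 1 as
relevant — the only reading that uses both stated rules at once. AP is
normalized by the number of relevant documents $R_i$ (standard MAP), so a
perfect binary ranking scores exactly 1; normalizing by the collection size
instead would make MAP depend on $n$ and exceed or undershoot 1 — the
$R_i$ choice is isolated in one function should anyone want the other
reading. Patients with no relevant document have undefined AP and are
excluded with a warning rather than scored 0.

## What the synthetic data emulates — and what it does not

`generate_corpus()` plants topical documents: titles lead with the topic's
term label, bodies mix topic words (probability 0.5 per token) with a
shared background vocabulary, compounds are planted as adjacent atom pairs
at a target count, and each topic carries one synonym pair (full form =
short form plus one character). Words are random strings over wide
disjoint ideograph-range alphabets (400 characters per block, words of 2–4
characters): with a narrow alphabet, unrelated words collide on characters
often enough to fool the composition-based synonym detector, which is a
property of the alphabet, not of the method. Defaults are 3 topics × 10
documents, 10 topic words per topic, 60 background words — wide enough that
incidental adjacency repeats are rare, as in a real corpus.

`generate_patients()` draws each characteristic independently at configured
marginal prevalences (defaults mirror a 50-patient hypertensive cohort:
54% abnormal BP, 68% overweight, 14% smokers, and so on; age mean 57 with
sd 10 chosen as a realistic cohort spread). A record's *true needs* are
defined as the terms where the rule engine is nonzero — generator and
engine agree by construction. `generate_judgments()` grades doc–patient
pairs 2 when the document's topic is a need, 1 for configured adjacent term
pairs (partial need has no generative definition in the source system, so
adjacency is explicit configuration), else 0.

The planted-keyword truth sets model the annotation protocol: only the
canonical long form of a synonym pair is listed (an annotator writes the
full disease name, not the abbreviation), and a compound whose atoms all
belong to one topic's vocabulary counts as correct for that topic. Under
this truth, enabling the three strategies does not decrease extraction
precision on the fixtures. Had the truth credited short forms and atoms
separately, elimination would collapse two credited surfaces into one and
the comparison would be rigged against the strategies regardless of their
quality — a property of the scoring, not the method.

What the fixtures do **not** model: real clinical language and discourse
structure, correlated comorbidities (characteristics are independent
draws), document length/quality variation, and annotator disagreement.
Passing the end-to-end checks therefore demonstrates internal coherence of
the pipeline — planted structure in, planted structure recovered — not
clinical performance on real corpora.

## Numerical and scale choices

* TextRank convergence: max per-node change < 1e-6, cap 100 iterations,
  warning (not error) on non-convergence.
* Cosine of a zero vector is defined as 0 with a warning.
* All ranked outputs break ties deterministically (lexicographic, radix
  order, locale-independent).
* Test and acceptance runs train embeddings at dimension 50 for 10 epochs
  on the 30-document fixture — enough for stable topic separation there —
  while the exported defaults remain the full-scale settings (dimension
  200, 5 epochs). The end-to-end acceptance sweep uses 10 seeds of the
  3-topic / 30-document / 10-patient fixture; the Monte-Carlo baseline uses
  1000 replicates of a 50 × 100 patient–document grid.

## Known limitations

* The shipped 33-term space and 67-rule default ruleset are faithful to
  every published constraint of the system they re-express, but the
  original supplementary artifacts were not available; both are stand-ins
  and explicitly configuration.
* The embedding trainer is a compact reference implementation: correct,
  seeded, and adequate for corpora up to tens of thousands of tokens, not a
  performance-tuned replacement for dedicated word2vec tooling at
  web-corpus scale.
* Keyword matching in the precision metric is exact surface match after
  whitespace/case normalization; no fuzzy or embedding-based credit.
* Word-level methods only: no contextual embeddings, no sentence- or
  document-level semantics.
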