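# Shared helpers: small corpora built in code and a hand-made lexicon
# constructor for resegmentation tests.

tiny_corpus <- function(bodies, titles = rep("", length(bodies)),
                        ids = paste0("d", seq_along(bodies))) {
  build_corpus(data.frame(doc_id = ids, title = titles, body = bodies,
                          stringsAsFactors = FALSE))
}

make_lexicon <- function(atom_seqs, counts = rep(5L, length(atom_seqs))) {
  lex <- data.frame(
    surface = vapply(atom_seqs, paste, character(1), collapse = ""),
    count = as.integer(counts),
    n_atoms = vapply(atom_seqs, length, integer(1)),
    pos = rep("noun", length(atom_seqs)), stringsAsFactors = FALSE)
  lex$atoms <- atom_seqs
  class(lex) <- c("edurec_lexicon", "data.frame")
  lex
}

# Synthetic embedding table from a named list of numeric vectors.
make_embeddings <- function(vectors) {
  mat <- do.call(rbind, vectors)
  rownames(mat) <- names(vectors)
  structure(list(dim = ncol(mat), vectors = mat, meta = list()),
            class = "edurec_embeddings")
}

# Independent closed-form oracle for the damped graph-ranking fixed point:
# S = (1 - d) 1 + d M S  =>  S = (I - d M)^{-1} (1 - d) 1,
# with M[j, i] = w_ij / strength(i) and isolated nodes handled exactly.
solve_graph_rank <- function(W, damping = 0.85) {
  v <- nrow(W)
  strength <- rowSums(W)
  M <- t(W / ifelse(strength > 0, strength, 1))
  as.numeric(solve(diag(v) - damping * M, rep(1 - damping, v)))
}

# Textbook binary precision@k (independent of the package implementation).
binary_p_at_k <- function(ranking, relevant, k) {
  sum(ranking[seq_len(k)] %in% relevant) / k
}

all_normal_record <- function(id = "p0") {
  patient_record(id, sex = "male", age = 57, bmi = 22, pregnant = FALSE,
                 disease_history = character(0),
                 glucose = 5.0, total_cholesterol = 4.5, triglyceride = 1.0,
                 hdl = 1.4, ldl = 2.5, uric_acid = 300,
                 systolic_bp = 118, diastolic_bp = 75,
                 cigarettes_per_day = 0, drinks_per_week = 0,
                 diet = "good", medications = character(0),
                 medication_adherence = "good", phq9 = 2, ipaq = "high")
}
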