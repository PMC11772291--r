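# Shared fixtures and independent oracles used across test files.

# Exhaustive best-path search over all label sequences (Viterbi oracle).
brute_viterbi <- function(em, tr) {
  n <- nrow(em); C <- ncol(em)
  grid <- expand.grid(rep(list(seq_len(C)), n))
  best <- NULL; bs <- -Inf
  for (r in seq_len(nrow(grid))) {
    y <- as.integer(grid[r, ])
    sc <- tr[C + 1L, y[1L]] + sum(em[cbind(seq_len(n), y)]) +
      tr[y[n], C + 2L]
    if (n > 1L) sc <- sc + sum(tr[cbind(y[-n], y[-1L])])
    if (sc > bs + 1e-12) { bs <- sc; best <- y }
  }
  best
}

# Exhaustive maximum one-to-one matching under label + overlap >= 1.
brute_max_match <- function(g, p) {
  best <- 0
  rec <- function(gi, used_p) {
    if (gi > nrow(g)) { best <<- max(best, sum(used_p)); return(invisible()) }
    rec(gi + 1L, used_p)
    for (pi in seq_len(nrow(p))) {
      if (used_p[pi] || p$label[pi] != g$label[gi]) next
      if (min(g$end[gi], p$end[pi]) - max(g$start[gi], p$start[pi]) < 1) next
      used_p[pi] <- TRUE
      rec(gi + 1L, used_p)
      used_p[pi] <- FALSE
    }
  }
  if (nrow(g) && nrow(p)) rec(1L, rep(FALSE, nrow(p)))
  best
}

random_span_set <- function(n, labels = c("a", "b", "c"), doc = "d") {
  s <- sample(0:60, n, replace = TRUE)
  data.frame(start = s, end = s + sample(1:10, n, replace = TRUE),
             label = sample(labels, n, replace = TRUE),
             surface = rep("", n), doc = rep(doc, n),
             stringsAsFactors = FALSE)
}

all_section_titles <- function() {
  vapply(default_section_inventory(), `[[`, "", "title")
}

# Small deterministic sentence fixtures.
toy_sentence <- function() {
  toks <- data.frame(surface = c("patient", "heeft", "Crohns"),
                     start = c(0L, 8L, 14L), end = c(7L, 13L, 20L),
                     stringsAsFactors = FALSE)
  tagged_sentence(toks, c("O", "O", "B-diagnosis"), section = "Anamnese")
}

two_token_entity_sentence <- function() {
  toks <- data.frame(surface = c("terminaal", "ileum"),
                     start = c(0L, 10L), end = c(9L, 15L),
                     stringsAsFactors = FALSE)
  tagged_sentence(toks, c("B-disease_location", "I-disease_location"))
}

# Cached small corpus shared within a test file.
.fixture_env <- new.env(parent = emptyenv())
small_corpus <- function() {
  if (is.null(.fixture_env$corp)) {
    .fixture_env$corp <- synth_corpus(
      corpus_spec(30, seed = 11, unlabeled_fraction = 0.2))
  }
  .fixture_env$corp
}
small_sentences <- function() {
  if (is.null(.fixture_env$sent)) {
    .fixture_env$sent <- corpus_to_sentences(small_corpus())
  }
  .fixture_env$sent
}
tiny_model_bits <- function() {
  if (is.null(.fixture_env$bits)) {
    sch <- label_scheme()
    sent <- small_sentences()
    vocab <- build_vocab(sent, sch)
    cfg <- encoder_config(length(vocab$tokens), hidden_dim = 16L,
                          n_layers = 1L, n_heads = 2L, max_len = 64L,
                          dropout = 0.1, ffn_dim = 24L, seed = 4L)
    .fixture_env$bits <- list(scheme = sch, sentences = sent, vocab = vocab,
                              cfg = cfg)
  }
  .fixture_env$bits
}
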