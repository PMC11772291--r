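test_that("viterbi decoding matches exhaustive search and respects constraints", {
  set.seed(17)
  for (k in 1:60) {
    n <- sample(1:6, 1); C <- sample(2:5, 1)
    em <- matrix(rnorm(n * C), n, C)
    tr <- matrix(rnorm((C + 2L)^2), C + 2L, C + 2L)
    expect_identical(viterbi_decode(em, tr), brute_viterbi(em, tr))
  }
  # zero transitions reduce to the per-token argmax
  em <- matrix(rnorm(12), 4L, 3L)
  tr0 <- matrix(0, 5L, 5L)
  expect_equal(viterbi_decode(em, tr0), apply(em, 1L, which.max))
  # hard-forbidden bigrams never appear in the decoded path
  sch <- label_scheme()
  C <- length(sch$bio_labels)
  trb <- bio_transition_matrix(sch$bio_labels)
  set.seed(4)
  for (k in 1:20) {
    em <- matrix(rnorm(6 * C, sd = 3), 6L, C)
    path <- sch$bio_labels[viterbi_decode(em, trb)]
    sp <- bio_to_spans(data.frame(surface = letters[1:6],
                                  start = 0:5, end = 1:6), path)
    expect_equal(attr(sp, "repairs"), 0L)
  }
})

test_that("bias-mode section fusion is an exact additive logit shift", {
  bits <- tiny_model_bits()
  m <- ner_model(bits$vocab, bits$scheme, bits$cfg, fusion = "bias",
                 sections = c("Anamnese", "Labo"), seed = 2L)
  m$params$sec_bias[1L, ] <- stats::rnorm(ncol(m$params$sec_bias))
  s <- small_sentences()[[1L]]
  s$section <- "Anamnese"
  f1 <- ner_forward(m, s)
  s$section <- NA  # resolves to the (zero) UNK bias
  f0 <- ner_forward(m, s)
  shift <- f1$logits - f0$logits
  for (r in seq_len(nrow(shift))) {
    expect_equal(shift[r, ], m$params$sec_bias[1L, ], tolerance = 1e-10)
  }
  # a zero bias vector makes bias mode coincide with mode none
  m0 <- m; m0$params$sec_bias[] <- 0
  mn <- m; mn$fusion <- "none"
  s$section <- "Anamnese"
  expect_equal(ner_forward(m0, s)$logits, ner_forward(mn, s)$logits,
               tolerance = 1e-12)
  # probability rows normalise
  P <- ibdner:::softmax_rows(f1$logits)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
})

test_that("embed fusion with a zeroed attribute is the identity at init", {
  bits <- tiny_model_bits()
  me <- ner_model(bits$vocab, bits$scheme, bits$cfg, fusion = "embed",
                  sections = all_section_titles(), seed = 3L)
  me$params$sec_emb[] <- 0
  me$params$W_in[-seq_len(bits$cfg$hidden_dim), ] <- 0
  mn <- ner_model(bits$vocab, bits$scheme, bits$cfg, fusion = "none",
                  sections = all_section_titles(), seed = 3L)
  s <- small_sentences()[[2L]]
  expect_equal(ner_forward(me, s)$logits, ner_forward(mn, s)$logits,
               tolerance = 1e-10)
  # with the trained-style (nonzero) attribute, sections change the output
  me2 <- ner_model(bits$vocab, bits$scheme, bits$cfg, fusion = "embed",
                   sections = all_section_titles(), seed = 3L)
  sA <- s; sA$section <- "Anamnese"
  sB <- s; sB$section <- "Labo"
  expect_gt(max(abs(ner_forward(me2, sA)$logits -
                      ner_forward(me2, sB)$logits)), 1e-8)
})

test_that("text fusion prepends the section title before a separator", {
  bits <- tiny_model_bits()
  vocab <- build_vocab(small_sentences(), bits$scheme,
                       extra_tokens = c("Familiaal"))
  cfg <- bits$cfg; cfg$vocab_size <- length(vocab$tokens)
  mt <- ner_model(vocab, bits$scheme, cfg, fusion = "text",
                  sections = "Familiaal", seed = 3L)
  s <- small_sentences()[[1L]]
  s$section <- "Familiaal"
  fw <- ner_forward(mt, s)
  expect_equal(fw$ids[1:3],
               unname(c(vocab$special_ids[["cls"]],
                        match("Familiaal", vocab$tokens),
                        vocab$special_ids[["sec"]])))
  expect_equal(length(fw$core), nrow(s$tokens))
})

test_that("unknown section titles fall back to the UNK attribute", {
  bits <- tiny_model_bits()
  m <- ner_model(bits$vocab, bits$scheme, bits$cfg, fusion = "bias",
                 sections = "Anamnese", seed = 2L)
  s <- small_sentences()[[1L]]
  s$section <- "Nooitgezien"
  expect_warning(ner_forward(m, s), "unknown section")
})

test_that("multi-task head reads h1 only and never leaks into token scores", {
  bits <- tiny_model_bits()
  m <- ner_model(bits$vocab, bits$scheme, bits$cfg, multitask = TRUE,
                 seed = 6L)
  s <- small_sentences()[[3L]]
  out <- multitask_forward(m, s)
  expect_gte(out$sentence_prob, 0)
  expect_lte(out$sentence_prob, 1)
  expect_equal(rowSums(out$token_dists), rep(1, nrow(out$token_dists)),
               tolerance = 1e-6)
  # detaching the sentence head leaves inference-time token scores intact
  m2 <- m
  m2$multitask <- FALSE
  m2$params$w_mt <- NULL; m2$params$b_mt <- NULL
  expect_equal(ner_forward(m, s)$logits, ner_forward(m2, s)$logits,
               tolerance = 1e-12)
  expect_error(multitask_forward(m2, s), "multi-task head")
  # the sentence flag marks peri-anal mentions in generated corpora
  corp <- small_corpus()
  sents <- small_sentences()
  flags <- vapply(sents, `[[`, integer(1), "flag")
  has_pa <- vapply(sents, function(x) {
    any(ibdner:::tag_type(x$tags) == "peri_anal_disease", na.rm = TRUE)
  }, logical(1))
  expect_equal(flags == 1L, has_pa)
})

test_that("encoder forward is deterministic without dropout and bounded", {
  bits <- tiny_model_bits()
  p <- init_encoder_params(bits$cfg, bits$vocab)
  ids <- ibdner:::assemble_input(bits$vocab,
                                 small_sentences()[[1L]]$tokens$surface)$ids
  H1 <- encoder_forward(p, bits$cfg, ids)$H
  H2 <- encoder_forward(p, bits$cfg, ids)$H
  expect_identical(H1, H2)
  expect_true(all(is.finite(H1)))
  expect_error(encoder_forward(p, bits$cfg, rep(1L, bits$cfg$max_len + 1L)),
               "max_len")
  expect_error(encoder_config(10L, hidden_dim = 10L, n_heads = 4L),
               "divisible")
})
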