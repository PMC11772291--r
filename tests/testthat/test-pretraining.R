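pretrain_fixture <- function() {
  bits <- tiny_model_bits()
  sents <- Filter(function(s) any(s$tags != "O"), small_sentences())[1:25]
  list(bits = bits, sents = sents)
}

test_that("the teacher stays bit-identical through pre-training", {
  fx <- pretrain_fixture()
  ck <- run_pretraining(fx$sents, "emlm_cl", fx$bits$vocab, fx$bits$scheme,
                        fx$bits$cfg, steps = 10L, lr = 1e-3, seed = 3L)
  p0 <- init_encoder_params(fx$bits$cfg, fx$bits$vocab)
  expect_identical(ibdner:::params_hash(ck$teacher_params),
                   ibdner:::params_hash(p0))
  # and the student has actually moved
  expect_false(identical(ibdner:::params_hash(ck$params),
                         ibdner:::params_hash(p0)))
})

test_that("the pre-training objective is the exact sum of its two terms", {
  fx <- pretrain_fixture()
  student <- list(params = init_encoder_params(fx$bits$cfg, fx$bits$vocab),
                  cfg = fx$bits$cfg)
  set.seed(2)
  batches <- lapply(fx$sents[1:6], ibdner:::make_pretrain_batch,
                    variant = "emlm", vocab = fx$bits$vocab,
                    scheme = fx$bits$scheme,
                    mask_cfg = masking_config("emlm"))
  res <- pretrain_step(student, student$params, batches,
                       ibdner:::adam_init(student$params), lr = 1e-3,
                       dropout_train = FALSE)
  l <- res$losses
  expect_gte(l$l_cl, 0)
  expect_gte(l$l_emlm, 0)
  expect_identical(l$l_pretrain, l$l_cl + l$l_emlm)
  # zeroing the mask indicator zeroes the contrastive term
  batches0 <- lapply(batches, function(b) {
    b$mask_indicator[] <- 0L
    b$input_ids <- b$target_ids
    b
  })
  res0 <- pretrain_step(student, student$params, batches0,
                        ibdner:::adam_init(student$params), lr = 1e-3,
                        dropout_train = FALSE)
  expect_equal(res0$losses$l_cl, 0)
  # with the teacher absent the step reduces to a reconstruction-only update
  res1 <- pretrain_step(student, NULL, batches,
                        ibdner:::adam_init(student$params), lr = 1e-3,
                        dropout_train = FALSE)
  expect_equal(res1$losses$l_cl, 0)
  expect_identical(res1$losses$l_pretrain, res1$losses$l_emlm)
})

test_that("the MLM variant ignores entity annotations entirely", {
  fx <- pretrain_fixture()
  strip_tags <- lapply(fx$sents, function(s) {
    tagged_sentence(s$tokens, rep("O", length(s$tags)), s$section, s$flag,
                    s$doc_id)
  })
  ck1 <- run_pretraining(fx$sents, "mlm", fx$bits$vocab, fx$bits$scheme,
                         fx$bits$cfg, steps = 5L, seed = 12L)
  ck2 <- run_pretraining(strip_tags, "mlm", fx$bits$vocab, fx$bits$scheme,
                         fx$bits$cfg, steps = 5L, seed = 12L)
  expect_equal(ck1$params, ck2$params, tolerance = 1e-15)
  # the entity variants refuse a corpus with no entities
  expect_error(run_pretraining(strip_tags, "emlm", fx$bits$vocab,
                               fx$bits$scheme, fx$bits$cfg, steps = 2L),
               "entities")
})

test_that("pre-training reduces its loss on the fixture corpus", {
  fx <- pretrain_fixture()
  ck <- run_pretraining(fx$sents, "emlm_cl", fx$bits$vocab, fx$bits$scheme,
                        fx$bits$cfg, steps = 80L, lr = 2e-3, seed = 7L)
  first <- mean(ck$log$l_pretrain[1:10])
  last <- mean(utils::tail(ck$log$l_pretrain, 10L))
  expect_lt(last, first)
})

test_that("checkpoints round trip through the JSON archive", {
  fx <- pretrain_fixture()
  ck <- run_pretraining(fx$sents, "emlm", fx$bits$vocab, fx$bits$scheme,
                        fx$bits$cfg, steps = 3L, seed = 5L)
  path <- file.path(tempdir(), "ck.json")
  save_checkpoint(ck, path)
  back <- load_checkpoint(path)
  expect_identical(back$vocab_tokens, fx$bits$vocab$tokens)
  expect_identical(back$variant, "emlm")
  ids <- ibdner:::assemble_input(fx$bits$vocab,
                                 fx$sents[[1L]]$tokens$surface)$ids
  H1 <- encoder_forward(ck$params, ck$cfg, ids)$H
  H2 <- encoder_forward(back$params, back$cfg, ids)$H
  expect_equal(H1, H2, tolerance = 1e-12)
})
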