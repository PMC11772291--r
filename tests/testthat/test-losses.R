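test_that("entity-MLM loss matches closed forms", {
  V <- 12L
  batch <- list(target_ids = c(3L, 5L, 7L), mask_indicator = c(0L, 0L, 0L))
  logits <- matrix(0, 3L, V)
  expect_equal(emlm_loss(logits, batch), 0)
  # k masked positions under uniform logits give k * ln V
  batch$mask_indicator <- c(1L, 0L, 1L)
  expect_equal(emlm_loss(logits, batch), 2 * log(V), tolerance = 1e-9)
  # hand-set target probabilities 0.5 and 0.25
  l2 <- matrix(0, 2L, 2L)
  l2[1L, ] <- log(c(0.5, 0.5))
  l2[2L, ] <- log(c(0.25, 0.75))
  b2 <- list(target_ids = c(1L, 1L), mask_indicator = c(1L, 1L))
  expect_equal(emlm_loss(l2, b2), -(log(0.5) + log(0.25)), tolerance = 1e-9)
  expect_equal(emlm_loss(l2, b2), 2.0794, tolerance = 1e-4)
  expect_error(emlm_loss(matrix(0, 1L, V), batch), "align")
})

test_that("contrastive loss matches symmetry-forced and brute-force values", {
  # a single-position sentence has a one-candidate softmax: loss 0
  expect_equal(contrastive_loss(matrix(1, 1, 4), matrix(2, 1, 4), 1, 0.5), 0)
  # identical teacher rows make the softmax uniform: k * ln n
  teach <- matrix(rep(c(1, 2, 0.5), 5), 5, 3, byrow = TRUE)
  stud <- matrix(rnorm(15), 5, 3)
  mi <- c(1, 0, 1, 0, 1)
  expect_equal(contrastive_loss(stud, teach, mi, tau = 0.3),
               3 * log(5), tolerance = 1e-9)
  # hand-chosen 2-d vectors against a brute-force cosine/softmax oracle
  stud <- rbind(c(1, 0), c(0, 1), c(1, 1))
  teach <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  mi <- c(1, 0, 0)
  cosv <- apply(teach, 1L, function(t) {
    sum(stud[1, ] * t) / sqrt(sum(stud[1, ]^2) * sum(t^2))
  })
  oracle <- -log(exp(cosv[1]) / sum(exp(cosv)))
  expect_equal(contrastive_loss(stud, teach, mi, tau = 1), oracle,
               tolerance = 1e-9)
  # zero-norm representations are an error, zero mask gives zero loss
  expect_error(contrastive_loss(rbind(c(0, 0)), rbind(c(1, 0)), 1, 1),
               "zero-norm")
  expect_equal(contrastive_loss(stud, teach, c(0, 0, 0), 1), 0)
  expect_error(contrastive_loss(stud, teach, mi, tau = 0), "positive")
})

test_that("cosine softmax path agrees with a dot/norm oracle on random input", {
  set.seed(8)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    S <- matrix(rnorm(n * 4), n, 4)
    T <- matrix(rnorm(n * 4), n, 4)
    mi <- rbinom(n, 1, 0.5)
    tau <- runif(1, 0.05, 2)
    oracle <- 0
    for (i in which(mi == 1)) {
      cosv <- sapply(seq_len(n), function(j) {
        sum(S[i, ] * T[j, ]) / sqrt(sum(S[i, ]^2) * sum(T[j, ]^2))
      })
      oracle <- oracle - (cosv[i] / tau - log(sum(exp(cosv / tau))))
    }
    expect_equal(contrastive_loss(S, T, mi, tau), oracle, tolerance = 1e-6)
  }
})

test_that("token cross-entropy honours label smoothing", {
  C <- 19L
  uni <- matrix(1 / C, 4L, C)
  expect_equal(token_ce_loss(uni, c(1L, 5L, 9L, 19L), epsilon = 0),
               log(C), tolerance = 1e-9)
  onehot <- matrix(0, 1L, 3L); onehot[1L, 2L] <- 1
  expect_equal(token_ce_loss(onehot, 2L, epsilon = 0), 0, tolerance = 1e-9)
  # smoothed two-label toy, evaluated by the closed form
  pred <- matrix(c(0.8, 0.2), 1L)
  eps <- 0.1
  hand <- -(0.95 * log(0.8) + 0.05 * log(0.2))
  expect_equal(token_ce_loss(pred, 1L, epsilon = eps), hand,
               tolerance = 1e-9)
  expect_error(token_ce_loss(matrix(c(0.9, 0.3), 1L), 1L), "normalised")
  expect_error(token_ce_loss(pred, "B-x", epsilon = 0), "classes")
})

test_that("R-drop loss is symmetric, non-negative and matches the KL oracle", {
  P <- matrix(c(0.5, 0.5), 1L)
  expect_equal(rdrop_loss(P, P), 0)
  Q <- matrix(c(0.25, 0.75), 1L)
  hand <- 0.5 * (0.5 * log(0.5 / 0.25) + 0.5 * log(0.5 / 0.75) +
                   0.25 * log(0.25 / 0.5) + 0.75 * log(0.75 / 0.5))
  expect_equal(rdrop_loss(P, Q), hand, tolerance = 1e-9)
  expect_equal(rdrop_loss(P, Q), 0.1373, tolerance = 1e-3)
  set.seed(31)
  for (k in 1:25) {
    n <- sample(1:6, 1); C <- sample(2:8, 1)
    P1 <- ibdner:::softmax_rows(matrix(rnorm(n * C), n, C))
    P2 <- ibdner:::softmax_rows(matrix(rnorm(n * C), n, C))
    v <- rdrop_loss(P1, P2)
    expect_gte(v, 0)
    expect_equal(v, rdrop_loss(P2, P1), tolerance = 1e-12)
  }
})

test_that("the fine-tuning objective is an exact weighted sum, linear in alpha", {
  expect_equal(finetune_loss(1.0, 0.2, alpha = 1), 1.2)
  expect_equal(finetune_loss(0.7, 0.5, alpha = 0), 0.7)
  alphas <- c(0, 0.5, 1, 2)
  vals <- vapply(alphas, function(a) finetune_loss(1, 0.3, a), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(diff(vals) / diff(alphas), rep(0.3, 3L))
})

test_that("analytic gradients match finite differences end to end", {
  sch <- label_scheme()
  s <- toy_sentence()
  vocab <- build_vocab(list(s), sch)
  cfg <- encoder_config(length(vocab$tokens), hidden_dim = 8L,
                        n_layers = 1L, n_heads = 2L, max_len = 16L,
                        dropout = 0, ffn_dim = 12L, seed = 5L)
  ctrl <- finetune_config(alpha = 1, epsilon = 0.1, dropout_rate = 0)
  eps <- 1e-6
  for (fus in c("none", "embed", "bias")) {
    m <- ner_model(vocab, sch, cfg, fusion = fus, sections = "Anamnese",
                   multitask = TRUE, crf_nll = TRUE, seed = 9L)
    st <- ibdner:::sentence_step(m, s, ctrl)
    loss_of <- function(mm) ibdner:::sentence_step(mm, s, ctrl)$losses$l_finetune
    check <- function(nm, i) {
      m1 <- m; m1$params[[nm]][i] <- m1$params[[nm]][i] + eps
      m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] - eps
      num <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      ana <- if (length(st$grads[[nm]]) == 1L) st$grads[[nm]] else
        st$grads[[nm]][i]
      expect_equal(ana, num, tolerance = 1e-4,
                   info = paste(fus, nm, i))
    }
    check("Wc", 5L)
    check("w_mt", 2L)
    check("l1_Wq", 10L)
    check("tok_emb", which(vocab$tokens == "Crohns"))
    # transitions: an entry the gold path actually uses
    gold_idx <- match(s$tags, sch$bio_labels)
    C <- length(sch$bio_labels)
    check("trans", (gold_idx[1L] - 1L) * (C + 2L) + C + 1L)
    if (fus == "embed") { check("sec_emb", 1L); check("W_in", 3L) }
    if (fus == "bias") check("sec_bias", 1L)
  }
})
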