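# Training objectives: entity-MLM negative log-likelihood, masked-entity
# contrastive loss against a frozen teacher, label-smoothed token
# cross-entropy, and the R-drop bidirectional-KL consistency loss.

EPS_PROB <- 1e-12

#' Entity-MLM negative log-likelihood
#'
#' \eqn{-\sum_i m_i \log P(x_i | X^m)}: the reconstruction loss over masked
#' positions only. Unmasked positions contribute exactly zero.
#'
#' @param logits n x V matrix of per-position scores over the vocabulary.
#' @param batch a \code{masked_batch} (supplies \code{target_ids} and
#'   \code{mask_indicator}).
#' @return scalar loss (nats, >= 0).
#' @export
emlm_loss <- function(logits, batch) {
  if (nrow(logits) != length(batch$target_ids)) {
    stopf("logits rows (%d) must align with batch positions (%d)",
          nrow(logits), length(batch$target_ids))
  }
  masked <- which(batch$mask_indicator == 1L)
  if (!length(masked)) return(0)
  loss <- 0
  for (i in masked) {
    lp <- log_softmax(logits[i, ])[batch$target_ids[i]]
    if (!is.finite(lp)) {
      warnf("clamping zero probability at masked position %d", i)
      lp <- log(EPS_PROB)
    }
    loss <- loss - lp
  }
  loss
}

# Loss + gradient wrt logits (used by the training loops).
emlm_loss_grad <- function(logits, batch) {
  masked <- which(batch$mask_indicator == 1L)
  d <- matrix(0, nrow(logits), ncol(logits))
  if (!length(masked)) return(list(loss = 0, dlogits = d))
  loss <- 0
  for (i in masked) {
    p <- exp(log_softmax(logits[i, ]))
    loss <- loss - log(max(p[batch$target_ids[i]], EPS_PROB))
    d[i, ] <- p
    d[i, batch$target_ids[i]] <- d[i, batch$target_ids[i]] - 1
  }
  list(loss = loss, dlogits = d)
}

#' Masked-entity contrastive loss
#'
#' Pulls the student's representation of each masked entity position toward
#' the frozen teacher's representation of the same position and pushes it
#' away from the teacher representations of all other positions of the same
#' sentence, through a temperature-scaled cosine softmax:
#' \eqn{-\sum_i 1[i\ masked]\ \log \frac{\exp(\mathrm{sim}(h^m_i,h_i)/\tau)}
#' {\sum_j \exp(\mathrm{sim}(h^m_i,h_j)/\tau)}}.
#'
#' @param student n x d student representations of the masked input.
#' @param teacher n x d teacher representations of the unmasked input.
#' @param mask_indicator 0/1 vector of masked entity positions.
#' @param tau temperature (> 0); small values sharpen the softmax.
#' @return scalar loss (nats, >= 0).
#' @export
contrastive_loss <- function(student, teacher, mask_indicator, tau = 0.01) {
  contrastive_loss_grad(student, teacher, mask_indicator, tau,
                        want_grad = FALSE)$loss
}

contrastive_loss_grad <- function(student, teacher, mask_indicator, tau,
                                  want_grad = TRUE) {
  if (tau <= 0) stopf("tau must be positive")
  if (nrow(student) != nrow(teacher)) stopf("sequence length mismatch")
  n <- nrow(teacher)
  masked <- which(mask_indicator == 1L)
  dstudent <- if (want_grad) matrix(0, nrow(student), ncol(student)) else NULL
  if (!length(masked)) return(list(loss = 0, dstudent = dstudent))
  tnorm <- sqrt(rowSums(teacher * teacher))
  if (any(tnorm < 1e-12)) stopf("zero-norm teacher representation")
  Tn <- teacher / tnorm
  loss <- 0
  for (i in masked) {
    hm <- student[i, ]
    hn <- sqrt(sum(hm * hm))
    if (hn < 1e-12) stopf("zero-norm student representation")
    cosv <- as.vector(Tn %*% (hm / hn))       # c_ij over all teacher rows j
    lp <- log_softmax(cosv / tau)
    loss <- loss - lp[i]
    if (want_grad) {
      p <- exp(lp)
      dcos <- p / tau
      dcos[i] <- dcos[i] - 1 / tau
      # d c_ij / d hm = h_j/(|hm||h_j|) - c_ij * hm/|hm|^2
      dstudent[i, ] <- as.vector(crossprod(Tn, dcos)) / hn -
        sum(dcos * cosv) * hm / (hn * hn)
    }
  }
  list(loss = loss, dstudent = dstudent)
}

#' Label-smoothed token cross-entropy
#'
#' Mean over tokens of \eqn{-\sum_j y_{i,j}\log \hat y_{i,j}} with smoothed
#' targets \eqn{y = (1-\epsilon)\,\mathrm{onehot} + \epsilon/|C|}. With
#' \eqn{\epsilon = 0} this is the plain NER cross-entropy.
#'
#' @param pred n x |C| matrix of predicted probability distributions (rows
#'   must sum to 1).
#' @param gold integer vector of gold class indices (1-based), or character
#'   tags resolvable against \code{classes}.
#' @param epsilon label smoothing parameter in [0, 1).
#' @param classes optional class labels used to resolve character \code{gold}.
#' @return scalar loss (nats).
#' @export
token_ce_loss <- function(pred, gold, epsilon = 0, classes = NULL) {
  if (is.character(gold)) {
    if (is.null(classes)) stopf("character gold tags require `classes`")
    gold <- match(gold, classes)
    if (anyNA(gold)) stopf("gold tag outside the class set")
  }
  if (nrow(pred) != length(gold)) stopf("pred/gold length mismatch")
  if (any(abs(rowSums(pred) - 1) > 1e-6)) {
    stopf("prediction rows must be normalised distributions")
  }
  if (epsilon < 0 || epsilon >= 1) stopf("epsilon must lie in [0, 1)")
  C <- ncol(pred)
  lp <- log(pmax(pred, EPS_PROB))
  tot <- 0
  for (i in seq_along(gold)) {
    tgt <- rep(epsilon / C, C)
    tgt[gold[i]] <- tgt[gold[i]] + (1 - epsilon)
    tot <- tot - sum(tgt * lp[i, ])
  }
  tot / length(gold)
}

# Cross-entropy from logits, with gradient; mean over tokens.
token_ce_grad <- function(logits, gold_idx, epsilon = 0) {
  n <- nrow(logits); C <- ncol(logits)
  P <- softmax_rows(logits)
  tgt <- matrix(epsilon / C, n, C)
  tgt[cbind(seq_len(n), gold_idx)] <-
    tgt[cbind(seq_len(n), gold_idx)] + (1 - epsilon)
  loss <- -sum(tgt * log(pmax(P, EPS_PROB))) / n
  list(loss = loss, dlogits = (P - tgt) / n)
}

#' R-drop consistency loss
#'
#' Bidirectional KL divergence between the token distributions of two
#' dropout-perturbed forward passes of the same sentence:
#' \eqn{\frac{1}{n}\sum_i \frac12[KL(P_1\|P_2) + KL(P_2\|P_1)]}. Symmetric,
#' non-negative, and zero iff the two distributions coincide.
#'
#' @param P1,P2 n x |C| matrices of token distributions from the two passes.
#' @return scalar loss (nats).
#' @export
rdrop_loss <- function(P1, P2) {
  if (!all(dim(P1) == dim(P2))) stopf("distribution pair shape mismatch")
  if (any(abs(rowSums(P1) - 1) > 1e-6) || any(abs(rowSums(P2) - 1) > 1e-6)) {
    stopf("distribution rows must sum to 1")
  }
  Q1 <- pmax(P1, EPS_PROB); Q2 <- pmax(P2, EPS_PROB)
  kl12 <- rowSums(P1 * (log(Q1) - log(Q2)))
  kl21 <- rowSums(P2 * (log(Q2) - log(Q1)))
  mean(0.5 * (kl12 + kl21))
}

# R-drop from two logit matrices, with gradients wrt both.
rdrop_grad <- function(logits1, logits2) {
  n <- nrow(logits1)
  P1 <- softmax_rows(logits1); P2 <- softmax_rows(logits2)
  L1 <- log(pmax(P1, EPS_PROB)); L2 <- log(pmax(P2, EPS_PROB))
  diff <- L1 - L2
  kl12 <- rowSums(P1 * diff)        # KL(P1||P2) per token
  kl21 <- -rowSums(P2 * diff)       # KL(P2||P1) per token
  loss <- mean(0.5 * (kl12 + kl21))
  # d/dz1 KL(P1||P2) = P1*(diff - kl12); d/dz1 KL(P2||P1) = P1 - P2
  d1 <- 0.5 * (P1 * (diff - kl12) + (P1 - P2)) / n
  # symmetric counterpart for z2 (diff flips sign)
  d2 <- 0.5 * (P2 * (-diff - kl21) + (P2 - P1)) / n
  list(loss = loss, dlogits1 = d1, dlogits2 = d2)
}

#' Combined fine-tuning loss
#'
#' \eqn{L_{finetune} = L_{CE} + \alpha L_{rdrop}}.
#'
#' @param l_ce cross-entropy component.
#' @param l_rdrop consistency component.
#' @param alpha non-negative weight coefficient.
#' @return scalar.
#' @export
finetune_loss <- function(l_ce, l_rdrop, alpha = 1) {
  stopifnot(is.finite(l_ce), is.finite(l_rdrop), alpha >= 0)
  l_ce + alpha * l_rdrop
}
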