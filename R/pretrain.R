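# Continued pre-training: domain MLM, entity MLM with inserted label tokens,
# and frozen-teacher contrastive token learning over the small encoder.

# Tied-embedding LM head: logits over the vocabulary from representations.
lm_logits <- function(params, H) {
  tcrossprod(H, params$tok_emb) + rep(params$lm_b, each = nrow(H))
}

# Backward of the tied LM head restricted to rows with non-zero gradient.
lm_head_backward <- function(params, H, dlogits) {
  list(dH = dlogits %*% params$tok_emb,
       g = list(tok_emb = crossprod(dlogits, H),
                lm_b = colSums(dlogits)))
}

#' Bundle of named training losses
#'
#' @param l_emlm entity-MLM (or MLM) reconstruction loss.
#' @param l_cl contrastive loss (0 when disabled).
#' @param l_ce,l_rdrop,l_finetune downstream fine-tuning components.
#' @return named list with the derived total \code{l_pretrain = l_cl +
#'   l_emlm}.
#' @export
loss_bundle <- function(l_emlm = 0, l_cl = 0, l_ce = 0, l_rdrop = 0,
                        l_finetune = 0) {
  vals <- c(l_emlm, l_cl, l_ce, l_rdrop, l_finetune)
  if (any(!is.finite(vals))) stopf("non-finite loss component")
  list(l_emlm = l_emlm, l_cl = l_cl, l_pretrain = l_cl + l_emlm,
       l_ce = l_ce, l_rdrop = l_rdrop, l_finetune = l_finetune)
}

# Build the masked batch for one sentence under a pre-training variant.
make_pretrain_batch <- function(sentence, variant, vocab, scheme, mask_cfg) {
  if (variant == "mlm") {
    asm <- assemble_input(vocab, sentence$tokens$surface)
    mlm_mask(asm$ids, mask_cfg, vocab, protected = asm$protected)
  } else {
    lseq <- insert_entity_labels(sentence, scheme)
    emlm_mask(lseq, mask_cfg, vocab)
  }
}

#' One pre-training update step
#'
#' Computes the reconstruction loss (and, for the contrastive variant, the
#' masked-entity contrastive loss against the frozen teacher) over a list of
#' masked batches, backpropagates through the student only, and applies one
#' Adam update. The teacher's parameters are read but never written.
#'
#' @param student list with \code{params} and \code{cfg}.
#' @param teacher_params frozen teacher parameter list (same architecture),
#'   or \code{NULL} when the contrastive term is disabled.
#' @param batches list of \code{masked_batch} objects.
#' @param opt Adam state from [adam_init()].
#' @param lr learning rate for this step.
#' @param tau contrastive temperature.
#' @param dropout_train use dropout during the student pass.
#' @return list with updated \code{student}, \code{opt}, and a
#'   [loss_bundle()].
#' @export
pretrain_step <- function(student, teacher_params, batches, opt, lr,
                          tau = 0.01, dropout_train = TRUE) {
  grads <- NULL
  l_emlm_tot <- 0
  l_cl_tot <- 0
  for (b in batches) {
    fw <- encoder_forward(student$params, student$cfg, b$input_ids,
                          train = dropout_train)
    masked <- which(b$mask_indicator == 1L)
    dH <- matrix(0, length(b$input_ids), student$cfg$hidden_dim)
    if (length(masked)) {
      Hm <- fw$H[masked, , drop = FALSE]
      logits_m <- lm_logits(student$params, Hm)
      sub <- list(target_ids = b$target_ids[masked],
                  mask_indicator = rep(1L, length(masked)))
      eg <- emlm_loss_grad(logits_m, sub)
      l_emlm_tot <- l_emlm_tot + eg$loss
      hb <- lm_head_backward(student$params, Hm, eg$dlogits)
      dH[masked, ] <- dH[masked, ] + hb$dH
      grads <- acc_grads(grads, hb$g)
    }
    if (!is.null(teacher_params)) {
      tfw <- encoder_forward(teacher_params, student$cfg, b$target_ids,
                             train = FALSE)
      cg <- contrastive_loss_grad(fw$H, tfw$H, b$mask_indicator, tau)
      l_cl_tot <- l_cl_tot + cg$loss
      if (!is.null(cg$dstudent)) dH <- dH + cg$dstudent
    }
    eb <- encoder_backward(student$params, student$cfg, fw$cache, dH)
    grads <- acc_grads(grads, eb$grads)
  }
  upd <- adam_step(student$params, grads, opt, lr)
  student$params <- upd$params
  list(student = student, opt = upd$state,
       losses = loss_bundle(l_emlm = l_emlm_tot, l_cl = l_cl_tot))
}

#' Run continued pre-training
#'
#' Trains the student encoder on tagged sentences under one of three
#' variants: \code{mlm} (random masking, annotations ignored), \code{emlm}
#' (entity masking with inserted label tokens), or \code{emlm_cl} (entity
#' masking plus the frozen-teacher contrastive objective; student and
#' teacher start from the identical initialisation). Masks are re-drawn
#' every step (dynamic masking). Convergence is operationalised as a fixed
#' step budget.
#'
#' @param sentences list of [tagged_sentence()] objects (BIO annotations
#'   required for the entity-masking variants; pseudo-labels are
#'   acceptable).
#' @param variant \code{"mlm"}, \code{"emlm"} or \code{"emlm_cl"}.
#' @param vocab,scheme vocabulary and label scheme.
#' @param cfg an [encoder_config()].
#' @param steps number of optimisation steps.
#' @param batch_size sentences per step.
#' @param lr peak Adam learning rate.
#' @param warmup_ratio fraction of steps spent in linear warmup.
#' @param tau contrastive temperature.
#' @param mask_cfg optional [masking_config()]; defaults to p = 0.15 for
#'   \code{mlm} and eta = 0.7 for the entity variants.
#' @param seed training seed (batch order, masks, dropout).
#' @param init_params optional starting encoder parameters.
#' @return object of class \code{ner_checkpoint}: \code{params},
#'   \code{cfg}, \code{vocab_tokens}, \code{variant} and a per-step
#'   \code{log} (data.frame of losses).
#' @export
run_pretraining <- function(sentences, variant = c("mlm", "emlm", "emlm_cl"),
                            vocab, scheme, cfg, steps = 200L,
                            batch_size = 8L, lr = 1e-4, warmup_ratio = 0.1,
                            tau = 0.01, mask_cfg = NULL, seed = 1L,
                            init_params = NULL) {
  variant <- match.arg(variant)
  if (!length(sentences)) stopf("no sentences to pre-train on")
  if (variant != "mlm") {
    has_ent <- any(vapply(sentences, function(s) any(s$tags != "O"),
                          logical(1)))
    if (!has_ent) {
      stopf("entity-masking variant %s requires a corpus with entities",
            variant)
    }
  }
  if (is.null(mask_cfg)) {
    mask_cfg <- if (variant == "mlm") masking_config("mlm") else
      masking_config("emlm")
  }
  student <- list(params = init_params %||% init_encoder_params(cfg, vocab),
                  cfg = cfg)
  teacher_params <- if (variant == "emlm_cl") student$params else NULL
  opt <- adam_init(student$params)
  log <- vector("list", steps)
  with_seed(derive_seed(seed, 11L), {
    for (step in seq_len(steps)) {
      pick <- sample.int(length(sentences), min(batch_size,
                                                length(sentences)))
      batches <- lapply(sentences[pick], make_pretrain_batch,
                        variant = variant, vocab = vocab, scheme = scheme,
                        mask_cfg = mask_cfg)
      res <- pretrain_step(student, teacher_params, batches, opt,
                           lr = lr_schedule(step, steps, lr, warmup_ratio),
                           tau = tau)
      student <- res$student
      opt <- res$opt
      log[[step]] <- data.frame(step = step,
                                l_emlm = res$losses$l_emlm,
                                l_cl = res$losses$l_cl,
                                l_pretrain = res$losses$l_pretrain)
      if (!is.finite(res$losses$l_pretrain)) {
        stopf("non-finite pre-training loss at step %d", step)
      }
    }
  })
  structure(list(params = student$params, cfg = cfg,
                 vocab_tokens = vocab$tokens, variant = variant,
                 log = do.call(rbind, log),
                 teacher_params = teacher_params),
            class = "ner_checkpoint")
}

#' @export
print.ner_checkpoint <- function(x, ...) {
  cat("<ner_checkpoint>", x$variant, "-", nrow(x$log), "steps, final",
      "l_pretrain", format(utils::tail(x$log$l_pretrain, 1), digits = 4),
      "\n")
  invisible(x)
}

#' Mean student/teacher cosine alignment at masked entity positions
#'
#' Diagnostic for the contrastive objective: the average cosine similarity
#' between the student's representation of masked entity tokens and the
#' teacher's representation of the same (unmasked) positions.
#'
#' @param student_params,teacher_params parameter lists.
#' @param cfg encoder config.
#' @param batches list of \code{masked_batch} objects.
#' @return mean cosine over all masked positions (NA when none).
#' @export
masked_alignment <- function(student_params, teacher_params, cfg, batches) {
  sims <- c()
  for (b in batches) {
    masked <- which(b$mask_indicator == 1L)
    if (!length(masked)) next
    Hs <- encoder_forward(student_params, cfg, b$input_ids)$H
    Ht <- encoder_forward(teacher_params, cfg, b$target_ids)$H
    for (i in masked) {
      sims <- c(sims, sum(Hs[i, ] * Ht[i, ]) /
                  (sqrt(sum(Hs[i, ]^2)) * sqrt(sum(Ht[i, ]^2))))
    }
  }
  if (!length(sims)) NA_real_ else mean(sims)
}
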