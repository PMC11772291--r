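# Supervised fine-tuning: label-smoothed cross-entropy, R-drop consistency,
# class up-sampling, pseudo-labelling, early stopping; exposed through the
# classic modelling interface `ner_fit()`.

#' Fine-tuning control parameters
#'
#' @param lr peak Adam learning rate. The default (1e-3) is calibrated for
#'   the package's small from-scratch encoder; adapted pre-trained encoders
#'   of realistic scale would use far smaller rates (order 5e-5).
#' @param batch_size sentences per optimisation step.
#' @param epochs maximum training epochs.
#' @param alpha R-drop weight coefficient (>= 0; 0 disables the second
#'   stochastic pass).
#' @param epsilon label-smoothing parameter in [0, 1); 0 recovers plain
#'   cross-entropy.
#' @param dropout_rate encoder dropout (the perturbation behind R-drop).
#' @param patience early-stopping rounds without dev strict-F1 improvement.
#' @param warmup_ratio linear learning-rate warmup fraction.
#' @param seed training seed.
#' @return object of class \code{finetune_config}.
#' @export
finetune_config <- function(lr = 1e-3, batch_size = 16L, epochs = 30L,
                            alpha = 1, epsilon = 0.1, dropout_rate = 0.1,
                            patience = 10L, warmup_ratio = 0.1, seed = 1L) {
  if (alpha < 0) stopf("alpha must be non-negative")
  if (epsilon < 0 || epsilon >= 1) stopf("epsilon must lie in [0, 1)")
  if (patience < 1L) stopf("patience must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), alpha = alpha,
                 epsilon = epsilon, dropout_rate = dropout_rate,
                 patience = as.integer(patience),
                 warmup_ratio = warmup_ratio, seed = as.integer(seed)),
            class = "finetune_config")
}

#' Two stochastic forward passes of the same sentence
#'
#' Passes one sentence through the model twice under independent dropout
#' draws and returns the two per-token label distributions. With a dropout
#' rate of zero the passes coincide exactly.
#'
#' @param model a [ner_model()] whose config has the desired dropout rate.
#' @param sentence a [tagged_sentence()].
#' @return list with \code{P1}, \code{P2} (row-normalised distribution
#'   matrices) and the two forward caches.
#' @export
two_pass_forward <- function(model, sentence) {
  fw1 <- ner_forward(model, sentence, train = TRUE)
  fw2 <- ner_forward(model, sentence, train = TRUE)
  list(P1 = softmax_rows(fw1$logits), P2 = softmax_rows(fw2$logits),
       fw1 = fw1, fw2 = fw2)
}

#' Up-sample sentences of under-represented entity classes
#'
#' Counts, per entity type, the number of sentences containing that type and
#' duplicates sentences of classes whose count falls below (max class count)
#' / \code{ratio} until they reach that floor. All original sentences are
#' retained; the result is a multiset superset of the input.
#'
#' @param sentences list of [tagged_sentence()].
#' @param ratio maximum tolerated ratio between the largest class's sentence
#'   count and any other class's.
#' @return augmented sentence list.
#' @export
upsample <- function(sentences, ratio = 2) {
  if (!length(sentences)) stopf("empty training set")
  types_of <- lapply(sentences, function(s) unique(tag_type(s$tags[s$tags !=
                                                                     "O"])))
  all_types <- unique(unlist(types_of))
  if (!length(all_types)) return(sentences)
  counts <- vapply(all_types, function(t) {
    sum(vapply(types_of, function(ts) t %in% ts, logical(1)))
  }, numeric(1))
  floor_n <- ceiling(max(counts) / ratio)
  out <- sentences
  for (t in all_types[counts < floor_n]) {
    pool <- which(vapply(types_of, function(ts) t %in% ts, logical(1)))
    need <- floor_n - counts[[t]]
    extra <- pool[((seq_len(need) - 1L) %% length(pool)) + 1L]
    out <- c(out, sentences[extra])
  }
  out
}

#' Generate pseudo-labels for unlabelled sentences
#'
#' Decodes every sentence with the fitted model (Viterbi over the label
#' dependency layer), repairs any residual BIO violations, and returns the
#' predictions as silver-standard training data, flagged distinct from gold.
#'
#' @param object a fitted [ner_fit()] model (or a bare [ner_model()]).
#' @param sentences unlabelled [tagged_sentence()] list (tags are ignored).
#' @param threshold optional confidence filter: sentences whose mean
#'   max-probability falls below it are dropped; \code{NULL} keeps all.
#' @return list of silver [tagged_sentence()] objects with a
#'   \code{"provenance"} attribute; empty input yields an empty set with a
#'   warning.
#' @export
pseudo_label <- function(object, sentences, threshold = NULL) {
  model <- if (inherits(object, "ner_fit")) object$model else object
  if (!length(sentences)) {
    warnf("empty unlabelled pool; returning an empty silver set")
    return(structure(list(), provenance = "pseudo_label"))
  }
  out <- list()
  for (s in sentences) {
    dec <- decode_sentence(model, s)
    conf <- mean(apply(dec$probs, 1L, max))
    if (!is.null(threshold) && conf < threshold) next
    out[[length(out) + 1L]] <- tagged_sentence(
      s$tokens, dec$tags, section = s$section, flag = s$flag,
      doc_id = s$doc_id, silver = TRUE)
  }
  structure(out, provenance = sprintf("pseudo_label(threshold=%s)",
                                      threshold %||% "none"))
}

# Gradient-bearing training step for one sentence. Returns grads and losses.
sentence_step <- function(model, sentence, control) {
  gold_idx <- match(sentence$tags, model$scheme$bio_labels)
  use_rdrop <- control$alpha > 0 && model$cfg$dropout > 0
  fw1 <- ner_forward(model, sentence, train = TRUE)
  l_rdrop <- 0
  if (use_rdrop) fw2 <- ner_forward(model, sentence, train = TRUE)
  if (model$crf_nll) {
    cg1 <- crf_nll_grad(fw1$logits, model_transitions(model), gold_idx)
    l_ce <- cg1$loss / length(gold_idx)
    d1 <- cg1$d_emissions / length(gold_idx)
    g_tr <- cg1$d_trans / length(gold_idx)
    if (use_rdrop) {
      cg2 <- crf_nll_grad(fw2$logits, model_transitions(model), gold_idx)
      l_ce <- (l_ce + cg2$loss / length(gold_idx)) / 2
      d1 <- d1 / 2
      d2 <- cg2$d_emissions / (2 * length(gold_idx))
      g_tr <- (g_tr + cg2$d_trans / length(gold_idx)) / 2
    }
  } else {
    tg1 <- token_ce_grad(fw1$logits, gold_idx, control$epsilon)
    l_ce <- tg1$loss
    d1 <- tg1$dlogits
    g_tr <- NULL
    if (use_rdrop) {
      tg2 <- token_ce_grad(fw2$logits, gold_idx, control$epsilon)
      l_ce <- (l_ce + tg2$loss) / 2
      d1 <- d1 / 2
      d2 <- tg2$dlogits / 2
    }
  }
  if (use_rdrop) {
    rgl <- rdrop_grad(fw1$logits, fw2$logits)
    l_rdrop <- rgl$loss
    d1 <- d1 + control$alpha * rgl$dlogits1
    d2 <- d2 + control$alpha * rgl$dlogits2
  }
  # multi-task sentence head (binary cross-entropy on the [CLS] state)
  dflag1 <- NULL
  l_mt <- 0
  if (model$multitask) {
    y <- sentence$flag
    p1 <- fw1$flag_prob
    l_mt <- -(y * log(max(p1, EPS_PROB)) +
                (1 - y) * log(max(1 - p1, EPS_PROB)))
    dflag1 <- p1 - y
  }
  g <- ner_backward(model, fw1, d1, dflag_pre = dflag1)
  if (use_rdrop) {
    g <- acc_grads(g, ner_backward(model, fw2, d2))
  }
  if (!is.null(g_tr)) g$trans <- g_tr
  list(grads = g,
       losses = list(l_ce = l_ce, l_rdrop = l_rdrop, l_mt = l_mt,
                     l_finetune = finetune_loss(l_ce, l_rdrop,
                                                control$alpha) + l_mt))
}

#' Fit the clinical NER model
#'
#' The package's central fitting function: supervised sequence-labelling
#' training of the token-classification model on gold (plus optional silver)
#' tagged sentences, with label smoothing, R-drop consistency
#' regularisation, section fusion, an optional multi-task sentence head, and
#' early stopping on development-set strict micro-F1. Returns a classed
#' model object with \code{print}, \code{summary}, \code{predict},
#' \code{plot} and \code{coef} methods.
#'
#' @param sentences training [tagged_sentence()] list (gold and/or silver).
#' @param dev development sentences used for model selection and early
#'   stopping; when \code{NULL}, the final epoch's parameters are kept.
#' @param scheme a [label_scheme()].
#' @param vocab optional [build_vocab()] vocabulary; built from the training
#'   sentences when missing. Must match \code{checkpoint} when one is given.
#' @param checkpoint optional \code{ner_checkpoint} whose encoder weights
#'   initialise the model (continued pre-training output).
#' @param fusion section-fusion mode; see [ner_model()].
#' @param multitask enable the sentence-flag head.
#' @param crf_nll train the label-dependency layer with sequence NLL.
#' @param control a [finetune_config()].
#' @param encoder_cfg an [encoder_config()] used when no checkpoint is
#'   given; its vocab_size is overridden to match the vocabulary.
#' @param upsample_ratio optional class up-sampling ratio (see
#'   [upsample()]); \code{NULL} disables.
#' @return object of class \code{ner_fit}.
#' @export
ner_fit <- function(sentences, dev = NULL, scheme = label_scheme(),
                    vocab = NULL, checkpoint = NULL, fusion = "none",
                    multitask = FALSE, crf_nll = FALSE,
                    control = finetune_config(), encoder_cfg = NULL,
                    upsample_ratio = NULL) {
  if (!length(sentences)) stopf("empty training set")
  if (is.null(vocab)) vocab <- build_vocab(sentences, scheme)
  if (!is.null(checkpoint)) {
    if (!identical(checkpoint$vocab_tokens, vocab$tokens)) {
      stopf("checkpoint vocabulary does not match the supplied vocabulary")
    }
    cfg <- checkpoint$cfg
    init <- checkpoint$params
  } else {
    cfg <- encoder_cfg %||% encoder_config(length(vocab$tokens),
                                           seed = control$seed)
    cfg$vocab_size <- length(vocab$tokens)
    init <- NULL
  }
  cfg$dropout <- control$dropout_rate
  sections <- unique(stats::na.omit(vapply(sentences, `[[`, "", "section")))
  model <- ner_model(vocab, scheme, cfg, fusion = fusion,
                     sections = sections, multitask = multitask,
                     crf_nll = crf_nll, init_params = init,
                     seed = control$seed)
  if (!is.null(upsample_ratio)) {
    sentences <- upsample(sentences, upsample_ratio)
  }
  opt <- adam_init(model$params)
  n_steps_total <- ceiling(length(sentences) / control$batch_size) *
    control$epochs
  step <- 0L
  best <- list(f1 = -Inf, params = model$params, epoch = 0L)
  bad_epochs <- 0L
  log <- list()
  with_seed(derive_seed(control$seed, 23L), {
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(length(sentences))
      ep_losses <- c(l_ce = 0, l_rdrop = 0, l_finetune = 0)
      nb <- 0L
      for (first in seq(1L, length(ord), by = control$batch_size)) {
        idx <- ord[first:min(first + control$batch_size - 1L, length(ord))]
        grads <- NULL
        for (i in idx) {
          st <- sentence_step(model, sentences[[i]], control)
          grads <- acc_grads(grads, st$grads)
          ep_losses <- ep_losses + c(st$losses$l_ce, st$losses$l_rdrop,
                                     st$losses$l_finetune)
          nb <- nb + 1L
        }
        step <- step + 1L
        upd <- adam_step(model$params, grads,
                         opt, lr_schedule(step, n_steps_total, control$lr,
                                          control$warmup_ratio))
        model$params <- upd$params
        opt <- upd$state
      }
      rec <- data.frame(epoch = epoch,
                        l_ce = ep_losses[["l_ce"]] / nb,
                        l_rdrop = ep_losses[["l_rdrop"]] / nb,
                        l_finetune = ep_losses[["l_finetune"]] / nb,
                        dev_strict_f1 = NA_real_, dev_type_f1 = NA_real_,
                        dev_strict_p = NA_real_, dev_strict_r = NA_real_)
      if (!is.null(dev) && length(dev)) {
        ev <- evaluate_sentences(model, dev)
        rec$dev_strict_f1 <- ev$strict$micro["f1"]
        rec$dev_type_f1 <- ev$type$micro["f1"]
        rec$dev_strict_p <- ev$strict$micro["precision"]
        rec$dev_strict_r <- ev$strict$micro["recall"]
        if (rec$dev_strict_f1 > best$f1) {
          best <- list(f1 = rec$dev_strict_f1, params = model$params,
                       epoch = epoch)
          bad_epochs <- 0L
        } else {
          bad_epochs <- bad_epochs + 1L
        }
      } else {
        best <- list(f1 = NA_real_, params = model$params, epoch = epoch)
      }
      log[[epoch]] <- rec
      if (!is.null(dev) && bad_epochs >= control$patience) break
    }
  })
  model$params <- best$params
  structure(list(model = model, control = control,
                 log = do.call(rbind, log), best_epoch = best$epoch,
                 dev_strict_f1 = best$f1, fusion = fusion,
                 multitask = multitask, crf_nll = crf_nll,
                 n_train = length(sentences)),
            class = "ner_fit")
}

# Decode a sentence list and score against its gold tags.
evaluate_sentences <- function(model, sentences) {
  gold <- list(); pred <- list()
  for (k in seq_along(sentences)) {
    s <- sentences[[k]]
    doc <- if (is.na(s$doc_id)) sprintf("s%05d", k) else
      sprintf("%s#%05d", s$doc_id, k)
    gsp <- bio_to_spans(s$tokens, s$tags)
    psp <- bio_to_spans(s$tokens, decode_sentence(model, s)$tags)
    if (nrow(gsp)) { gsp$doc <- doc; gold[[length(gold) + 1L]] <- gsp }
    if (nrow(psp)) { psp$doc <- doc; pred[[length(pred) + 1L]] <- psp }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(start = integer(), end = integer(), label = character(),
               surface = character(), doc = character(),
               stringsAsFactors = FALSE)
  evaluate_ner(bind(gold), bind(pred))
}
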