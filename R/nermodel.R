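# Token-classification model: encoder + linear tag head, three section-fusion
# injection modes, a label-dependency (simulated CRF) layer decoded with
# Viterbi, and an optional multi-task sentence head.

#' Construct an NER model
#'
#' Wraps the encoder with a token classification head over the BIO label set,
#' one of four section-fusion modes, a transition-score layer for decoding,
#' and optionally a sentence-level head predicting a binary flag from the
#' first-position ([CLS]) state.
#'
#' Fusion modes: \code{none} (plain encoding); \code{embed} (the token
#' embedding is concatenated with a learned section-attribute embedding and
#' projected back to model width; the projection starts as the identity on
#' the token part and zero on the attribute part, so a zero-initialised
#' attribute leaves the model unchanged at initialisation); \code{text} (the
#' section title tokens are prepended to the input followed by a [SEC]
#' separator); \code{bias} (a learned per-section offset vector is added to
#' every token's label scores).
#'
#' @param vocab a [build_vocab()] vocabulary.
#' @param scheme a [label_scheme()].
#' @param cfg an [encoder_config()]; its \code{vocab_size} must match.
#' @param fusion one of \code{"none"}, \code{"embed"}, \code{"text"},
#'   \code{"bias"}.
#' @param sections known section titles (an UNK attribute is always added).
#' @param multitask enable the sentence-flag head.
#' @param crf_nll train the transition layer with linear-chain sequence NLL
#'   instead of per-token cross-entropy.
#' @param init_params optional pre-trained encoder parameters (e.g. from
#'   [run_pretraining()]); head parameters are always freshly initialised.
#' @param sec_dim width of the section attribute embedding (embed mode).
#' @param seed seed for head initialisation.
#' @return object of class \code{ner_model}.
#' @export
ner_model <- function(vocab, scheme, cfg, fusion = "none",
                      sections = character(0), multitask = FALSE,
                      crf_nll = FALSE, init_params = NULL, sec_dim = 8L,
                      seed = cfg$seed) {
  fusion <- match.arg(fusion, c("none", "embed", "text", "bias"))
  if (cfg$vocab_size != length(vocab$tokens)) {
    stopf("encoder vocab_size (%d) does not match vocabulary (%d)",
          cfg$vocab_size, length(vocab$tokens))
  }
  C <- length(scheme$bio_labels)
  d <- cfg$hidden_dim
  params <- init_params %||% init_encoder_params(cfg, vocab)
  sections <- unique(c(sections, "<UNK>"))
  with_seed(derive_seed(seed, 77L), {
    params$Wc <- rnorm_mat(d, C)
    params$bc <- rep(0, C)
    if (fusion == "embed") {
      # identity on the token part; small random attribute rows so the
      # section pathway has gradient (zero rows + zero attribute is a
      # saddle where the pathway can never start learning)
      params$sec_emb <- rnorm_mat(length(sections), sec_dim)
      params$W_in <- rbind(diag(d), rnorm_mat(sec_dim, d))
    }
    if (fusion == "bias") {
      params$sec_bias <- matrix(0, length(sections), C)
    }
    if (multitask) {
      params$w_mt <- stats::rnorm(d, sd = 0.02)
      params$b_mt <- 0
    }
    if (crf_nll) {
      params$trans <- matrix(0, C + 2L, C + 2L)
    }
  })
  structure(list(params = params, cfg = cfg, vocab = vocab, scheme = scheme,
                 fusion = fusion, sections = sections, multitask = multitask,
                 crf_nll = crf_nll, sec_dim = as.integer(sec_dim),
                 trans_constraint = bio_transition_matrix(scheme$bio_labels)),
            class = "ner_model")
}

section_index <- function(model, section) {
  if (is.null(section) || is.na(section)) {
    return(match("<UNK>", model$sections))
  }
  i <- match(section, model$sections)
  if (is.na(i)) {
    warnf("unknown section title %s; using the UNK attribute",
          dQuote(section))
    i <- match("<UNK>", model$sections)
  }
  i
}

# Effective transition matrix used for decoding / sequence NLL.
model_transitions <- function(model) {
  if (model$crf_nll) model$trans_constraint + model$params$trans else
    model$trans_constraint
}

#' Forward pass of the NER model
#'
#' Encodes one tagged sentence under the model's fusion mode and returns
#' per-token label scores for the sentence's own tokens (special and any
#' prepended section-title positions are excluded), plus the sentence-flag
#' probability when the multi-task head is enabled.
#'
#' @param model a [ner_model()].
#' @param sentence a [tagged_sentence()].
#' @param train enable dropout (draws from the current RNG stream).
#' @return list with \code{logits} (n_tokens x |C|), \code{H}, \code{cache},
#'   \code{core} (positions of the sentence tokens in the input),
#'   \code{sec_idx}, \code{ids}, and \code{flag_prob} (or \code{NA}).
#' @export
ner_forward <- function(model, sentence, train = FALSE) {
  surfaces <- sentence$tokens$surface
  # only the embed/bias modes consume the section attribute; plain and text
  # modes must not warn about titles they never use
  sec_idx <- if (model$fusion %in% c("embed", "bias")) {
    section_index(model, sentence$section)
  } else {
    match("<UNK>", model$sections)
  }
  prefix <- character(0)
  if (model$fusion == "text" && !is.null(sentence$section) &&
      !is.na(sentence$section)) {
    prefix <- c(tokenize_text(sentence$section)$surface, "[SEC]")
  }
  all_surf <- c(prefix, surfaces)
  asm <- assemble_input(model$vocab, all_surf)
  ids <- asm$ids
  core <- asm$core_positions[(length(prefix) + 1L):length(all_surf)]
  override <- NULL
  embcat <- NULL
  if (model$fusion == "embed") {
    E <- model$params$tok_emb[ids, , drop = FALSE]
    svec <- model$params$sec_emb[sec_idx, ]
    embcat <- cbind(E, matrix(svec, length(ids), model$sec_dim, byrow = TRUE))
    override <- embcat %*% model$params$W_in
  }
  fw <- encoder_forward(model$params, model$cfg, ids, train = train,
                        input_override = override)
  Hc <- fw$H[core, , drop = FALSE]
  logits <- Hc %*% model$params$Wc +
    rep(model$params$bc, each = length(core))
  if (model$fusion == "bias") {
    logits <- logits + rep(model$params$sec_bias[sec_idx, ],
                           each = length(core))
  }
  flag_prob <- NA_real_
  if (model$multitask) {
    z <- sum(model$params$w_mt * fw$H[1L, ]) + model$params$b_mt
    flag_prob <- 1 / (1 + exp(-z))
  }
  list(logits = logits, H = fw$H, cache = fw$cache, core = core,
       sec_idx = sec_idx, ids = ids, embcat = embcat, flag_prob = flag_prob)
}

#' Per-token label scores from encoder representations
#'
#' Applies the linear tag head to a representation matrix; in \code{bias}
#' mode a section-specific offset vector shifts every token's scores by the
#' same amount.
#'
#' @param model a [ner_model()].
#' @param H n x d representation matrix.
#' @param section section title (resolved against the model's inventory) or
#'   \code{NULL}.
#' @return n x |C| score matrix.
#' @export
token_logits <- function(model, H, section = NULL) {
  if (any(!is.finite(H))) stopf("non-finite representations")
  logits <- H %*% model$params$Wc + rep(model$params$bc, each = nrow(H))
  if (model$fusion == "bias") {
    logits <- logits + rep(model$params$sec_bias[section_index(model,
                                                               section), ],
                           each = nrow(H))
  }
  logits
}

#' Joint sentence-flag and token predictions
#'
#' Runs the multi-task forward: the sentence head reads only the
#' first-position ([CLS]) state while the token head reads the remaining
#' positions. Requires a model built with \code{multitask = TRUE}.
#'
#' @param model a [ner_model()] with the multi-task head.
#' @param sentence a [tagged_sentence()].
#' @return list with \code{sentence_prob} and \code{token_dists} (rows sum
#'   to 1).
#' @export
multitask_forward <- function(model, sentence) {
  if (!model$multitask) stopf("model was built without the multi-task head")
  fw <- ner_forward(model, sentence, train = FALSE)
  list(sentence_prob = fw$flag_prob,
       token_dists = softmax_rows(fw$logits))
}

# Backward through heads + encoder. dlogits: gradient at token label scores;
# dflag_pre: gradient at the sentence-head pre-activation (or NULL).
ner_backward <- function(model, fw, dlogits, dflag_pre = NULL) {
  p <- model$params
  n <- length(fw$ids)
  d <- model$cfg$hidden_dim
  Hc <- fw$H[fw$core, , drop = FALSE]
  g <- list(Wc = crossprod(Hc, dlogits), bc = colSums(dlogits))
  dH <- matrix(0, n, d)
  dH[fw$core, ] <- tcrossprod(dlogits, p$Wc)
  if (model$fusion == "bias") {
    g$sec_bias <- matrix(0, nrow(p$sec_bias), ncol(p$sec_bias))
    g$sec_bias[fw$sec_idx, ] <- colSums(dlogits)
  }
  if (!is.null(dflag_pre) && model$multitask) {
    g$w_mt <- dflag_pre * fw$H[1L, ]
    g$b_mt <- dflag_pre
    dH[1L, ] <- dH[1L, ] + dflag_pre * p$w_mt
  }
  eb <- encoder_backward(p, model$cfg, fw$cache, dH)
  g <- acc_grads(g, eb$grads)
  if (model$fusion == "embed") {
    dX0 <- eb$dX0
    g$W_in <- crossprod(fw$embcat, dX0)
    dcat <- tcrossprod(dX0, p$W_in)
    dtok <- dcat[, seq_len(d), drop = FALSE]
    agg <- rowsum(dtok, group = fw$ids)
    g$tok_emb[as.integer(rownames(agg)), ] <-
      g$tok_emb[as.integer(rownames(agg)), , drop = FALSE] + agg
    g$sec_emb <- matrix(0, nrow(p$sec_emb), ncol(p$sec_emb))
    g$sec_emb[fw$sec_idx, ] <- colSums(dcat[, d + seq_len(model$sec_dim),
                                            drop = FALSE])
  }
  g
}

# Decode BIO tags for one sentence with the current model.
decode_sentence <- function(model, sentence) {
  fw <- ner_forward(model, sentence, train = FALSE)
  idx <- viterbi_decode(fw$logits, model_transitions(model))
  list(tags = model$scheme$bio_labels[idx],
       probs = softmax_rows(fw$logits),
       flag_prob = fw$flag_prob)
}
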