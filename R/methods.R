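# S3 methods for fitted NER models.

#' @export
print.ner_fit <- function(x, ...) {
  cat("Clinical NER model (", x$model$cfg$n_layers, "layers,",
      x$model$cfg$hidden_dim, "dims )\n")
  cat("  fusion:", x$fusion,
      " multitask:", x$multitask,
      " crf_nll:", x$crf_nll, "\n")
  cat("  trained on", x$n_train, "sentences;")
  if (!is.na(x$dev_strict_f1)) {
    cat(" best dev strict F1", format(x$dev_strict_f1, digits = 4),
        "at epoch", x$best_epoch, "\n")
  } else {
    cat(" no dev set (kept final epoch", x$best_epoch, ")\n")
  }
  invisible(x)
}

#' Summarise a fitted NER model
#'
#' Without new data, reports the training trajectory; with a sentence list,
#' decodes it and returns the full [evaluate_ner()] report.
#'
#' @param object a [ner_fit()] result.
#' @param sentences optional gold [tagged_sentence()] list to score.
#' @param ... unused.
#' @return an \code{eval_report} (with data) or the training log.
#' @export
summary.ner_fit <- function(object, sentences = NULL, ...) {
  if (!is.null(sentences)) {
    return(evaluate_sentences(object$model, sentences))
  }
  print(object)
  cat("\nTraining log (last epochs):\n")
  print(utils::tail(object$log, 5L), row.names = FALSE)
  invisible(object$log)
}

#' Predict entities with a fitted NER model
#'
#' @param object a [ner_fit()] result.
#' @param newdata a [clinical_note()], a list of notes or corpus entries, or
#'   a list of [tagged_sentence()] objects.
#' @param type \code{"spans"} (data.frame of entity spans with doc ids),
#'   \code{"tags"} (list of BIO tag vectors), or \code{"prob"} (list of
#'   per-token distribution matrices).
#' @param ... unused.
#' @return see \code{type}.
#' @export
predict.ner_fit <- function(object, newdata, type = c("spans", "tags",
                                                      "prob"), ...) {
  type <- match.arg(type)
  model <- object$model
  if (inherits(newdata, "clinical_note")) newdata <- list(newdata)
  # normalise to (sentence, text, doc) triples
  items <- list()
  for (el in newdata) {
    if (inherits(el, "tagged_sentence")) {
      items[[length(items) + 1L]] <- list(s = el, text = NULL,
                                          doc = el$doc_id)
    } else {
      note <- if (inherits(el, "clinical_note")) el else el$note
      sent <- split_sentences(note)
      sent <- sent[!sent$is_header, , drop = FALSE]
      for (k in seq_len(nrow(sent))) {
        toks <- tokenize_text(sent$text[k], base_offset = sent$start[k])
        if (!nrow(toks)) next
        s <- tagged_sentence(toks, rep("O", nrow(toks)),
                             section = sent$section[k],
                             doc_id = note$doc_id)
        items[[length(items) + 1L]] <- list(s = s, text = note$text,
                                            doc = note$doc_id)
      }
    }
  }
  tags <- list(); probs <- list(); spans <- list()
  for (it in items) {
    dec <- decode_sentence(model, it$s)
    tags[[length(tags) + 1L]] <- dec$tags
    probs[[length(probs) + 1L]] <- dec$probs
    if (type == "spans") {
      sp <- bio_to_spans(it$s$tokens, dec$tags, text = it$text)
      if (nrow(sp)) {
        sp$doc <- it$doc %||% NA_character_
        spans[[length(spans) + 1L]] <- sp
      }
    }
  }
  switch(type,
         tags = tags,
         prob = probs,
         spans = if (length(spans)) do.call(rbind, spans) else empty_spans())
}

#' Model coefficients of a fitted NER model
#'
#' @param object a [ner_fit()] result.
#' @param ... unused.
#' @return list with the tag-head weights, decoding transition matrix, and
#'   (when present) the section fusion parameters.
#' @export
coef.ner_fit <- function(object, ...) {
  p <- object$model$params
  out <- list(tag_head = p$Wc, tag_bias = p$bc,
              transitions = model_transitions(object$model))
  if (!is.null(p$sec_bias)) out$section_bias <- p$sec_bias
  if (!is.null(p$sec_emb)) out$section_embedding <- p$sec_emb
  if (!is.null(p$w_mt)) out$sentence_head <- c(p$w_mt, intercept = p$b_mt)
  out
}

#' Plot the training trajectory
#'
#' Training loss per epoch and, when a dev set was used, dev strict/type F1.
#'
#' @param x a [ner_fit()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ner_fit <- function(x, ...) {
  log <- x$log
  op <- graphics::par(mfrow = c(1L, if (all(is.na(log$dev_strict_f1))) 1L
                                else 2L))
  on.exit(graphics::par(op))
  graphics::plot(log$epoch, log$l_finetune, type = "b", pch = 16,
                 xlab = "epoch", ylab = "fine-tuning loss", ...)
  if (!all(is.na(log$dev_strict_f1))) {
    graphics::plot(log$epoch, log$dev_strict_f1, type = "b", pch = 16,
                   ylim = c(0, 1), xlab = "epoch", ylab = "dev F1")
    graphics::lines(log$epoch, log$dev_type_f1, type = "b", pch = 1,
                    lty = 2)
    graphics::legend("bottomright", c("strict", "entity type"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
    graphics::abline(v = x$best_epoch, col = "grey", lty = 3)
  }
  invisible(x)
}
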