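# Masking strategies: random MLM, and entity MLM (EMLM) with inserted label
# tokens. Masks are re-drawn on every call, so training loops that call these
# functions each epoch implement dynamic masking.

#' Configure a masking strategy
#'
#' @param strategy \code{"mlm"} (random masking over all maskable tokens at
#'   rate \code{p}) or \code{"emlm"} (masking restricted to entity tokens at
#'   rate \code{eta}, with label tokens inserted around every entity token).
#' @param p MLM masking probability (default 0.15, the standard rate).
#' @param eta entity masking ratio for EMLM (default 0.7).
#' @param seed optional seed; when \code{NULL}, draws come from the caller's
#'   RNG stream (the training loops rely on this for per-epoch re-draws).
#' @return object of class \code{masking_config}.
#' @export
masking_config <- function(strategy = c("mlm", "emlm"), p = 0.15, eta = 0.7,
                           seed = NULL) {
  strategy <- match.arg(strategy)
  if (p < 0 || p > 1 || eta < 0 || eta > 1) stopf("p and eta must lie in [0,1]")
  structure(list(strategy = strategy, p = p, eta = eta, seed = seed),
            class = "masking_config")
}

new_masked_batch <- function(input_ids, target_ids, mask_indicator,
                             label_token_positions, protected) {
  stopifnot(length(input_ids) == length(target_ids),
            length(mask_indicator) == length(input_ids))
  structure(list(input_ids = input_ids, target_ids = target_ids,
                 mask_indicator = as.integer(mask_indicator),
                 label_token_positions = as.integer(label_token_positions),
                 protected = protected),
            class = "masked_batch")
}

#' @export
print.masked_batch <- function(x, ...) {
  cat("<masked_batch>", length(x$input_ids), "positions,",
      sum(x$mask_indicator), "masked,", length(x$label_token_positions),
      "label tokens\n")
  invisible(x)
}

#' Random masked-language-model corruption
#'
#' Selects each maskable position independently with probability \code{p} and
#' applies the standard 80/10/10 corruption: replace with [MASK], replace
#' with a random vocabulary token, or keep the original. Special and label
#' tokens are never selected. The reconstruction targets are always the
#' uncorrupted ids.
#'
#' @param ids integer token ids (typically [CLS] ... [SEP]).
#' @param config a [masking_config()] with \code{strategy = "mlm"}.
#' @param vocab the vocabulary (supplies the [MASK] id and the range of
#'   ordinary tokens used for random replacement).
#' @param protected logical vector marking unmaskable positions; defaults to
#'   special/label-token ids found in \code{vocab}.
#' @return a \code{masked_batch}.
#' @export
mlm_mask <- function(ids, config, vocab, protected = NULL) {
  stopifnot(inherits(config, "masking_config"))
  if (config$strategy != "mlm") stopf("mlm_mask requires strategy 'mlm'")
  if (!length(ids)) stopf("empty input")
  if (is.null(protected)) {
    protected <- ids %in% c(vocab$special_ids, vocab$label_ids)
  }
  run <- function() {
    sel <- !protected & stats::runif(length(ids)) < config$p
    input <- ids
    ind <- as.integer(sel)
    if (any(sel)) {
      u <- stats::runif(sum(sel))
      w <- which(sel)
      mask_these <- w[u < 0.8]
      rand_these <- w[u >= 0.8 & u < 0.9]
      input[mask_these] <- vocab$special_ids[["mask"]]
      if (length(rand_these)) {
        ordinary <- setdiff(seq_along(vocab$tokens),
                            c(vocab$special_ids, vocab$label_ids))
        input[rand_these] <- sample(ordinary, length(rand_these),
                                    replace = TRUE)
      }
    }
    new_masked_batch(input, ids, ind, integer(0), protected)
  }
  if (is.null(config$seed)) run() else with_seed(config$seed, run())
}

#' Insert entity label tokens around entity tokens
#'
#' For every token carrying a non-O BIO tag, a label token encoding that tag
#' (e.g. \code{<B-diagnosis>}) is placed immediately before and after it.
#' Label tokens are drawn from the reserved vocabulary block and behave as
#' ordinary context during entity MLM; the origin map allows exact recovery
#' of the unlabelled sequence.
#'
#' @param sentence a [tagged_sentence()].
#' @param scheme the [label_scheme()] (tags outside it are an error).
#' @return object of class \code{labeled_sequence}: list with \code{tokens}
#'   (surfaces including label tokens), \code{origin_map} (source position in
#'   the original sentence, \code{NA} for label tokens),
#'   \code{entity_positions} (indices of entity tokens in the new sequence)
#'   and \code{label_positions}.
#' @export
insert_entity_labels <- function(sentence, scheme) {
  check_tags(sentence$tags, scheme)
  toks <- sentence$tokens$surface
  tags <- sentence$tags
  out <- character(0)
  origin <- integer(0)
  entity_pos <- integer(0)
  for (i in seq_along(toks)) {
    if (tags[i] == "O") {
      out <- c(out, toks[i]); origin <- c(origin, i)
    } else {
      lab <- label_token_for_tag(tags[i])
      out <- c(out, lab, toks[i], lab)
      origin <- c(origin, NA_integer_, i, NA_integer_)
      entity_pos <- c(entity_pos, length(out) - 1L)
    }
  }
  structure(list(tokens = out, origin_map = origin,
                 entity_positions = entity_pos,
                 label_positions = which(is.na(origin)),
                 tags = tags, sentence = sentence),
            class = "labeled_sequence")
}

#' Strip inserted label tokens
#'
#' Exact inverse of [insert_entity_labels()] via the origin map.
#'
#' @param lseq a \code{labeled_sequence}.
#' @return character vector of the original token surfaces.
#' @export
strip_entity_labels <- function(lseq) {
  stopifnot(inherits(lseq, "labeled_sequence"))
  keep <- !is.na(lseq$origin_map)
  orig <- lseq$tokens[keep]
  src <- lseq$origin_map[keep]
  if (length(src) && (anyDuplicated(src) || any(diff(src) != 1L) ||
                      src[1L] != 1L)) {
    stopf("corrupted origin map")
  }
  orig
}

#' Entity-MLM corruption
#'
#' Masks entity tokens of a label-inserted sequence independently with
#' probability \code{eta}, replacing them with [MASK]. Label tokens and
#' non-entity tokens are never masked. A sentence with no entity tokens
#' returns an empty mask rather than an error. The returned batch is the
#' assembled model input ([CLS] ... [SEP]).
#'
#' @param lseq a \code{labeled_sequence} from [insert_entity_labels()].
#' @param config a [masking_config()] with \code{strategy = "emlm"}.
#' @param vocab the vocabulary.
#' @return a \code{masked_batch}.
#' @export
emlm_mask <- function(lseq, config, vocab) {
  stopifnot(inherits(lseq, "labeled_sequence"),
            inherits(config, "masking_config"))
  if (config$strategy != "emlm") stopf("emlm_mask requires strategy 'emlm'")
  asm <- assemble_input(vocab, lseq$tokens,
                        label_positions = lseq$label_positions)
  entity_pos <- lseq$entity_positions + 1L  # shift for [CLS]
  run <- function() {
    ind <- integer(length(asm$ids))
    input <- asm$ids
    if (length(entity_pos)) {
      sel <- entity_pos[stats::runif(length(entity_pos)) < config$eta]
      ind[sel] <- 1L
      input[sel] <- vocab$special_ids[["mask"]]
    }
    new_masked_batch(input, asm$ids, ind, lseq$label_positions + 1L,
                     asm$protected)
  }
  b <- if (is.null(config$seed)) run() else with_seed(config$seed, run())
  b$entity_positions <- entity_pos
  b
}
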