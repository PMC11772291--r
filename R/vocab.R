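# Vocabulary construction and id encoding.

#' Build a vocabulary from tagged sentences
#'
#' The vocabulary opens with the special markers ([PAD], [CLS], [SEP],
#' [MASK], [UNK], [SEC]) followed by the reserved label-token block (one
#' \code{<B-type>}/\code{<I-type>} token per entity type, used by entity MLM)
#' and then all corpus word types by decreasing frequency.
#'
#' @param sentences list of [tagged_sentence()] objects (or any list with a
#'   \code{tokens$surface} field).
#' @param scheme a [label_scheme()].
#' @param extra_tokens additional surfaces guaranteed an id (e.g. section
#'   title words for text-mode fusion).
#' @param min_count minimum corpus frequency for a word type.
#' @return object of class \code{ner_vocab}: list with \code{tokens}
#'   (character vector; position = id), \code{special_ids} (named),
#'   \code{label_ids}, and lookup helpers.
#' @export
build_vocab <- function(sentences, scheme, extra_tokens = character(0),
                        min_count = 1L) {
  specials <- unname(scheme$special_tokens[c("pad", "cls", "sep", "mask",
                                             "unk", "sec")])
  labels <- label_token_surfaces(scheme)
  words <- unlist(lapply(sentences, function(s) s$tokens$surface))
  tab <- sort(table(words), decreasing = TRUE)
  keep <- names(tab)[tab >= min_count]
  keep <- unique(c(keep, extra_tokens))
  keep <- setdiff(keep, c(specials, labels))
  tokens <- c(specials, labels, keep)
  special_ids <- match(specials, tokens)
  names(special_ids) <- c("pad", "cls", "sep", "mask", "unk", "sec")
  structure(list(tokens = tokens,
                 special_ids = special_ids,
                 label_ids = match(labels, tokens),
                 label_surfaces = labels),
            class = "ner_vocab")
}

#' @export
print.ner_vocab <- function(x, ...) {
  cat("<ner_vocab>", length(x$tokens), "tokens (",
      length(x$label_ids), "label tokens )\n")
  invisible(x)
}

#' Encode token surfaces as vocabulary ids
#'
#' @param vocab a [build_vocab()] vocabulary.
#' @param surfaces character vector of token surfaces.
#' @return integer ids; unknown surfaces map to the [UNK] id.
#' @export
encode_tokens <- function(vocab, surfaces) {
  ids <- match(surfaces, vocab$tokens)
  ids[is.na(ids)] <- vocab$special_ids[["unk"]]
  ids
}

# Assemble [CLS] + tokens + [SEP]; returns ids plus a `protected` flag vector
# marking positions that must never be masked (specials and label tokens).
assemble_input <- function(vocab, surfaces, label_positions = integer(0)) {
  core <- encode_tokens(vocab, surfaces)
  ids <- c(vocab$special_ids[["cls"]], core, vocab$special_ids[["sep"]])
  protected <- c(TRUE, rep(FALSE, length(core)), TRUE)
  if (length(label_positions)) protected[label_positions + 1L] <- TRUE
  list(ids = unname(ids), protected = protected,
       core_positions = seq_along(core) + 1L)
}
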