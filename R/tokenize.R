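# Tokenisation, sentence splitting and span <-> BIO conversion.
#
# All character offsets in this package are 0-based, half-open intervals into
# the note text, matching the BRAT standoff convention: a span (s, e) covers
# characters s+1 .. e of the R string.

#' Tokenise text with exact character offsets
#'
#' Splits text into maximal runs of non-space, non-punctuation characters plus
#' single punctuation tokens, preserving the character range of every token so
#' that entity spans can be mapped losslessly between characters and tokens.
#'
#' @param text a single string.
#' @param base_offset 0-based offset of \code{text} within its parent
#'   document; added to all returned offsets.
#' @return data.frame with columns \code{surface}, \code{start}, \code{end}
#'   (0-based, half-open), ordered left to right.
#' @export
tokenize_text <- function(text, base_offset = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[^[:space:][:punct:]]+|[[:punct:]]", text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  start <- as.integer(m) - 1L + as.integer(base_offset)
  data.frame(surface = substring(text, as.integer(m), as.integer(m) + len - 1L),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

#' Split a clinical note into sentences
#'
#' Sentences are non-empty lines of the note text. Each sentence inherits the
#' title of the section whose character range encloses it; lines outside any
#' section get \code{NA}. Lines that consist of a section header (the title
#' followed by a colon) are flagged so downstream consumers can skip them.
#'
#' @param note a \code{clinical_note} (see [clinical_note()]).
#' @return data.frame with columns \code{start}, \code{end} (0-based,
#'   half-open), \code{text}, \code{section}, \code{is_header}. The ranges
#'   cover every non-whitespace character of the note exactly once.
#' @export
split_sentences <- function(note) {
  stopifnot(inherits(note, "clinical_note"))
  text <- note$text
  if (!nzchar(text)) stopf("note text is empty")
  # locate newline-delimited lines with offsets
  nl <- c(0L, which(strsplit(text, "", fixed = TRUE)[[1L]] == "\n"))
  bounds <- c(nl, nchar(text) + 1L)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s0 <- bounds[i]          # 0-based start of line content
    e0 <- bounds[i + 1L] - 1L
    if (e0 <= s0) next
    line <- substr(text, s0 + 1L, e0)
    # trim surrounding whitespace, keeping offsets exact
    lead <- nchar(sub("^([[:space:]]*).*$", "\\1", line))
    trail <- nchar(sub("^.*?([[:space:]]*)$", "\\1", line))
    if (lead + trail >= nchar(line)) next
    s <- s0 + lead
    e <- e0 - trail
    out[[length(out) + 1L]] <- data.frame(
      start = s, end = e, text = substr(text, s + 1L, e),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stopf("note contains no non-whitespace text")
  sent <- do.call(rbind, out)
  secs <- note$sections
  sent$section <- NA_character_
  sent$is_header <- FALSE
  if (!is.null(secs) && nrow(secs)) {
    for (k in seq_len(nrow(secs))) {
      inside <- sent$start >= secs$start[k] & sent$end <= secs$end[k]
      sent$section[inside] <- secs$title[k]
      hdr <- inside & grepl(":[[:space:]]*$", sent$text) &
        startsWith(sent$text, secs$title[k])
      sent$is_header[hdr] <- TRUE
    }
  }
  sent
}

#' Convert character-offset entity spans to token-level BIO tags
#'
#' The first token overlapping a span receives \code{B-<type>}; subsequent
#' overlapping tokens receive \code{I-<type>}; all other tokens are \code{O}.
#' Gold spans are assumed flat: overlapping spans are an error.
#'
#' @param tokens token data.frame from [tokenize_text()].
#' @param spans data.frame with columns \code{start}, \code{end},
#'   \code{label} (0-based half-open character offsets).
#' @return character vector of BIO tags, one per token.
#' @export
spans_to_bio <- function(tokens, spans) {
  tags <- rep("O", nrow(tokens))
  if (is.null(spans) || nrow(spans) == 0L) return(tags)
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  if (nrow(spans) > 1L &&
      any(spans$start[-1L] < spans$end[-nrow(spans)])) {
    stopf("overlapping gold spans are not supported (flat entities assumed)")
  }
  for (k in seq_len(nrow(spans))) {
    hit <- which(tokens$start < spans$end[k] & tokens$end > spans$start[k])
    if (!length(hit)) next
    tags[hit[1L]] <- paste0("B-", spans$label[k])
    if (length(hit) > 1L) tags[hit[-1L]] <- paste0("I-", spans$label[k])
  }
  tags
}

#' Convert BIO tags back to character-offset spans
#'
#' Inverse of [spans_to_bio()] at token-boundary granularity. Invalid
#' sequences produced by a model (an \code{I-} tag opening a sentence,
#' following \code{O}, or following a different entity type) are repaired by
#' promotion to \code{B-}; the number of repairs is recorded in the
#' \code{"repairs"} attribute of the result.
#'
#' @param tokens token data.frame.
#' @param tags BIO tag vector, same length as \code{nrow(tokens)}.
#' @param text optional note text used to recover exact surfaces (including
#'   inter-token characters); when absent, surfaces are token strings joined
#'   by single spaces.
#' @param scheme optional [label_scheme()]; when supplied, tags outside the
#'   scheme raise an error.
#' @return data.frame of spans (\code{start}, \code{end}, \code{label},
#'   \code{surface}) with attribute \code{repairs}.
#' @export
bio_to_spans <- function(tokens, tags, text = NULL, scheme = NULL) {
  if (nrow(tokens) != length(tags)) stopf("tokens and tags length mismatch")
  if (!is.null(scheme)) check_tags(tags, scheme)
  if (any(!grepl("^(O|[BI]-.+)$", tags))) {
    stopf("malformed BIO tag: %s",
          paste(unique(tags[!grepl("^(O|[BI]-.+)$", tags)]), collapse = ", "))
  }
  repairs <- 0L
  n <- length(tags)
  pre <- tag_prefix(tags)
  typ <- tag_type(tags)
  for (i in seq_len(n)) {
    if (pre[i] == "I") {
      ok <- i > 1L && pre[i - 1L] %in% c("B", "I") && typ[i - 1L] == typ[i]
      if (!ok) {
        pre[i] <- "B"
        repairs <- repairs + 1L
      }
    }
  }
  spans <- list()
  open <- NULL
  close_span <- function(open, last) {
    s <- tokens$start[open$first]; e <- tokens$end[last]
    surface <- if (!is.null(text)) substr(text, s + 1L, e) else
      paste(tokens$surface[open$first:last], collapse = " ")
    data.frame(start = s, end = e, label = open$type, surface = surface,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    if (pre[i] == "B") {
      if (!is.null(open)) spans[[length(spans) + 1L]] <- close_span(open, i - 1L)
      open <- list(first = i, type = typ[i])
    } else if (pre[i] == "O") {
      if (!is.null(open)) spans[[length(spans) + 1L]] <- close_span(open, i - 1L)
      open <- NULL
    }
  }
  if (!is.null(open)) spans[[length(spans) + 1L]] <- close_span(open, n)
  out <- if (length(spans)) do.call(rbind, spans) else
    data.frame(start = integer(), end = integer(), label = character(),
               surface = character(), stringsAsFactors = FALSE)
  attr(out, "repairs") <- repairs
  out
}
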