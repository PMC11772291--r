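# Tagged sentences and CoNLL-style TSV round tripping.

#' Construct a tagged sentence
#'
#' Tokens with character offsets, their BIO tags, the enclosing section title,
#' and an optional sentence-level binary flag (used by the multi-task head,
#' e.g. "does this sentence mention peri-anal disease").
#'
#' @param tokens token data.frame (\code{surface,start,end}).
#' @param tags BIO tag vector, one per token.
#' @param section section title or \code{NA}.
#' @param flag binary sentence label (0/1).
#' @param doc_id originating document id.
#' @param silver \code{TRUE} for pseudo-labelled (silver) sentences.
#' @return object of class \code{tagged_sentence}.
#' @export
tagged_sentence <- function(tokens, tags, section = NA_character_, flag = 0L,
                            doc_id = NA_character_, silver = FALSE) {
  if (nrow(tokens) != length(tags)) stopf("tags/tokens length mismatch")
  if (any(!nzchar(tokens$surface))) stopf("empty token surface")
  structure(list(tokens = tokens, tags = as.character(tags),
                 section = section, flag = as.integer(flag),
                 doc_id = doc_id, silver = isTRUE(silver)),
            class = "tagged_sentence")
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat("<tagged_sentence>", if (!is.na(x$section)) paste0("[", x$section, "] "),
      paste(x$tokens$surface, collapse = " "), "\n")
  ent <- x$tags != "O"
  if (any(ent)) cat("  tags:", paste0(x$tokens$surface[ent], "/", x$tags[ent],
                                      collapse = " "), "\n")
  invisible(x)
}

#' Write tagged sentences as CoNLL-style TSV
#'
#' One token per row with columns \code{token}, \code{section}, \code{flag},
#' \code{tag}, tab-separated, a blank line between sentences. Missing
#' sections are serialised as \code{_}. Comment lines (\code{# key = value})
#' at the top carry provenance for silver data.
#'
#' @param sentences list of [tagged_sentence()] objects.
#' @param path output path.
#' @param provenance optional named character vector written as header
#'   comments.
#' @return invisibly, \code{path}.
#' @export
write_conll <- function(sentences, path, provenance = NULL) {
  out <- character(0)
  if (!is.null(provenance)) {
    out <- sprintf("# %s = %s", names(provenance), provenance)
  }
  for (s in sentences) {
    if (any(grepl("\t", s$tokens$surface, fixed = TRUE))) {
      stopf("token containing a tab cannot be serialised to CoNLL")
    }
    sec <- if (is.na(s$section)) "_" else s$section
    out <- c(out, sprintf("%s\t%s\t%d\t%s%s", s$tokens$surface, sec, s$flag,
                          s$tags, if (s$silver) "\tsilver" else ""), "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read tagged sentences from CoNLL-style TSV
#'
#' Inverse of [write_conll()]. Character offsets are reconstructed by joining
#' tokens with single spaces (the original document offsets are not stored in
#' the format). Ragged rows raise a parse error naming the line.
#'
#' @param path input path.
#' @return list of [tagged_sentence()]; provenance comments, if any, are
#'   attached as the \code{"provenance"} attribute.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  prov <- grep("^#", lines, value = TRUE)
  sentences <- list()
  buf <- list()
  flush <- function(buf) {
    if (!length(buf)) return(NULL)
    surf <- vapply(buf, `[[`, "", 1L)
    width <- nchar(surf)
    start <- cumsum(c(0L, width[-length(width)] + 1L))
    toks <- data.frame(surface = surf, start = start, end = start + width,
                       stringsAsFactors = FALSE)
    sec <- buf[[1L]][2L]
    tagged_sentence(toks, vapply(buf, `[[`, "", 4L),
                    section = if (identical(sec, "_")) NA_character_ else sec,
                    flag = as.integer(buf[[1L]][3L]),
                    silver = length(buf[[1L]]) >= 5L &&
                      identical(buf[[1L]][5L], "silver"))
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^#", ln)) next
    if (!nzchar(ln)) {
      s <- flush(buf)
      if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
      buf <- list()
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 4L || length(parts) > 5L) {
      stopf("line %d: expected 4 or 5 tab-separated fields, got %d",
            i, length(parts))
    }
    buf[[length(buf) + 1L]] <- parts
  }
  s <- flush(buf)
  if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
  if (length(prov)) attr(sentences, "provenance") <- prov
  sentences
}
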