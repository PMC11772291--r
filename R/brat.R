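# BRAT standoff reading and writing (.txt / .ann pairs).

#' Construct a clinical note
#'
#' A clinical note is the raw document text together with its section
#' segmentation: an ordered list of (title, character range) entries. Ranges
#' are 0-based half-open, must lie within the text, and may not overlap.
#'
#' @param doc_id document identifier.
#' @param text full note text.
#' @param sections data.frame with columns \code{title}, \code{start},
#'   \code{end}, or \code{NULL} for an unsegmented note.
#' @return object of class \code{clinical_note}.
#' @export
clinical_note <- function(doc_id, text, sections = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  if (is.null(sections)) {
    sections <- data.frame(title = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("title", "start", "end") %in% names(sections)))
  if (nrow(sections)) {
    if (any(sections$start < 0L) || any(sections$end > nchar(text)) ||
        any(sections$start >= sections$end)) {
      stopf("section ranges must be 0 <= start < end <= nchar(text)")
    }
    o <- order(sections$start)
    sections <- sections[o, , drop = FALSE]
    if (nrow(sections) > 1L &&
        any(sections$start[-1L] < sections$end[-nrow(sections)])) {
      stopf("section ranges overlap")
    }
  }
  structure(list(doc_id = doc_id, text = text, sections = sections),
            class = "clinical_note")
}

#' @export
print.clinical_note <- function(x, ...) {
  cat("<clinical_note>", x$doc_id, "-", nchar(x$text), "chars,",
      nrow(x$sections), "sections\n")
  invisible(x)
}

validate_spans <- function(spans, text, scheme = NULL, where = "annotation") {
  if (!nrow(spans)) return(invisible(TRUE))
  for (k in seq_len(nrow(spans))) {
    s <- spans$start[k]; e <- spans$end[k]
    if (is.na(s) || is.na(e) || s < 0L || e > nchar(text) || s >= e) {
      stopf("%s %d: offsets (%s, %s) out of bounds for text of %d chars",
            where, k, s, e, nchar(text))
    }
    got <- substr(text, s + 1L, e)
    if (!identical(got, spans$surface[k])) {
      stopf("%s %d: surface %s does not match text slice %s",
            where, k, dQuote(spans$surface[k]), dQuote(got))
    }
  }
  if (!is.null(scheme)) {
    bad <- setdiff(unique(spans$label), scheme$entity_types)
    if (length(bad)) stopf("unknown entity type(s): %s",
                           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a BRAT standoff document
#'
#' Parses a \code{.txt}/\code{.ann} pair. Only text-bound \code{T} lines are
#' consumed (\code{T<k>\\tTYPE START END\\tSURFACE}); attribute, relation and
#' event lines are ignored. Every span is validated against the text and the
#' label scheme; a mismatching surface or out-of-bounds offset is an error
#' naming the offending line.
#'
#' @param txt_path path to the text file.
#' @param ann_path path to the annotation file; a missing file yields zero
#'   spans (an unlabelled note).
#' @param scheme [label_scheme()] used to validate entity types, or
#'   \code{NULL} to skip type validation.
#' @param doc_id document id; defaults to the txt file name without extension.
#' @return list with elements \code{note} (a \code{clinical_note}) and
#'   \code{spans} (data.frame \code{start,end,label,surface}).
#' @export
read_brat <- function(txt_path, ann_path, scheme = NULL, doc_id = NULL) {
  if (!file.exists(txt_path)) stopf("missing text file: %s", txt_path)
  text <- paste(readLines(txt_path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  if (is.null(doc_id)) doc_id <- sub("\\.txt$", "", basename(txt_path))
  spans <- data.frame(start = integer(), end = integer(), label = character(),
                      surface = character(), stringsAsFactors = FALSE)
  if (!is.null(ann_path) && file.exists(ann_path)) {
    lines <- readLines(ann_path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    tb <- grep("^T", lines, value = TRUE)
    rows <- lapply(seq_along(tb), function(i) {
      parts <- strsplit(tb[i], "\t", fixed = TRUE)[[1L]]
      if (length(parts) < 3L) stopf("malformed annotation line %d: %s", i, tb[i])
      head <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
      if (length(head) != 3L) stopf("malformed type/offset field in line %d: %s",
                                    i, tb[i])
      st <- suppressWarnings(as.integer(head[2L]))
      en <- suppressWarnings(as.integer(head[3L]))
      if (is.na(st) || is.na(en)) stopf("non-integer offsets in line %d: %s",
                                        i, tb[i])
      data.frame(start = st, end = en, label = head[1L], surface = parts[3L],
                 stringsAsFactors = FALSE)
    })
    if (length(rows)) spans <- do.call(rbind, rows)
  }
  validate_spans(spans, text, scheme, where = "annotation line")
  note <- clinical_note(doc_id, text, sections = detect_sections(text))
  list(note = note, spans = spans)
}

# Recover the section segmentation from header lines of the form "Title :".
# A section runs from its header to the next header (or end of text).
detect_sections <- function(text) {
  if (!nzchar(text)) {
    return(data.frame(title = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  starts <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]
  is_hdr <- grepl("^[^[:space:]].*[[:space:]]*:[[:space:]]*$", lines) &
    !grepl("\t", lines)
  idx <- which(is_hdr)
  if (!length(idx)) {
    return(data.frame(title = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  title <- sub("[[:space:]]*:[[:space:]]*$", "", lines[idx])
  s <- starts[idx]
  e <- c(s[-1L], nchar(text))
  data.frame(title = title, start = s, end = e, stringsAsFactors = FALSE)
}

#' Write a BRAT standoff document
#'
#' @param note a \code{clinical_note}.
#' @param spans span data.frame (\code{start,end,label,surface}).
#' @param dir output directory, created if needed.
#' @param write_ann if \code{FALSE} only the \code{.txt} is written (used for
#'   unlabelled notes).
#' @return invisibly, the paths written.
#' @export
write_brat <- function(note, spans, dir, write_ann = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  validate_spans(spans, note$text)
  txt <- file.path(dir, paste0(note$doc_id, ".txt"))
  writeLines(note$text, txt, useBytes = TRUE, sep = "")
  paths <- txt
  if (write_ann) {
    ann <- file.path(dir, paste0(note$doc_id, ".ann"))
    lines <- character(0)
    if (nrow(spans)) {
      lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(spans)),
                       spans$label, spans$start, spans$end, spans$surface)
    }
    writeLines(lines, ann, useBytes = TRUE)
    paths <- c(paths, ann)
  }
  invisible(paths)
}
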