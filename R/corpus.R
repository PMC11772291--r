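# Synthetic clinical-note corpus generator.
#
# Produces reproducible BRAT-format pseudo-Dutch IBD consultation notes with
# the structural features the downstream pipeline has to cope with: nine
# entity types under heavy class imbalance (peri-anal disease rarest),
# section-dependent entity validity (diagnosis strings under the family
# history section are NOT entities), abbreviation ambiguity (CD/UC reused as
# lab measurements), multi-entity sentences joined by conjunctions, and
# Montreal-classification vocabulary (L1-L3, B1-B3, E1-E3). Text is
# template-based: realism is not the goal, exact offsets and controllable
# statistics are.

#' Default section inventory
#'
#' The section titles emitted by the generator together with the entity types
#' admissible under each. The family-history section ("Familiaal") and the
#' laboratory section ("Labo") admit no entities at all: diagnosis-like
#' strings occurring there are deliberate non-entity distractors.
#'
#' @return list of entries with fields \code{title} and \code{admissible}.
#' @export
default_section_inventory <- function() {
  list(
    list(title = "Anamnese",
         admissible = c("diagnosis", "diagnosis_date", "body_weight")),
    list(title = "Voorgeschiedenis",
         admissible = c("previous_surgery", "diagnosis", "diagnosis_date")),
    list(title = "Familiaal", admissible = character(0)),
    list(title = "Klinisch onderzoek",
         admissible = c("length", "body_weight")),
    list(title = "Endoscopie",
         admissible = c("disease_location", "disease_behavior",
                        "disease_extent", "peri_anal_disease")),
    list(title = "Labo", admissible = character(0)),
    list(title = "Besluit",
         admissible = c("diagnosis", "diagnosis_date", "disease_location",
                        "disease_behavior", "disease_extent",
                        "peri_anal_disease", "previous_surgery"))
  )
}

# Relative per-class frequencies. The source corpus reports its distribution
# only graphically, so these are order-of-magnitude choices realising the
# documented imbalance: diagnosis-related classes common, peri-anal disease
# rarest.
default_entity_weights <- function() {
  c(diagnosis = 25, diagnosis_date = 14, disease_location = 10,
    disease_behavior = 6, peri_anal_disease = 2, previous_surgery = 7,
    disease_extent = 6, length = 12, body_weight = 14)
}

#' Specify a synthetic corpus
#'
#' @param n_notes number of notes to generate.
#' @param seed integer seed; a fixed seed yields a byte-identical corpus.
#' @param entity_weights named non-negative relative frequencies over the
#'   entity types (not all zero). Classes with weight zero never occur.
#' @param section_inventory section titles with per-section admissibility
#'   maps; see [default_section_inventory()].
#' @param ambiguity_rate fraction of notes carrying a family-history sentence
#'   that contains a diagnosis surface form with no gold span.
#' @param conjunction_rate fraction of entity sentences realised as two
#'   same-type entities joined by a conjunction token ("en").
#' @param unlabeled_fraction fraction of notes emitted without annotations
#'   (the pool used for continued pre-training and pseudo-labelling).
#' @param mean_entities mean number of entity mentions per note.
#' @return object of class \code{corpus_spec}.
#' @export
corpus_spec <- function(n_notes, seed = 1L,
                        entity_weights = default_entity_weights(),
                        section_inventory = default_section_inventory(),
                        ambiguity_rate = 0.3, conjunction_rate = 0.15,
                        unlabeled_fraction = 0.0, mean_entities = 5) {
  n_notes <- as.integer(n_notes)
  if (is.na(n_notes) || n_notes < 1L) stopf("n_notes must be a positive count")
  if (!length(section_inventory)) stopf("section inventory is empty")
  if (is.null(names(entity_weights)) || any(!nzchar(names(entity_weights)))) {
    stopf("entity_weights must be a named vector")
  }
  if (any(entity_weights < 0)) stopf("entity weights must be non-negative")
  if (all(entity_weights == 0)) stopf("entity weights are all zero")
  for (r in c(ambiguity_rate, conjunction_rate, unlabeled_fraction)) {
    if (!is.numeric(r) || is.na(r) || r < 0 || r > 1) {
      stopf("rates must lie in [0, 1]")
    }
  }
  admissible_anywhere <- unique(unlist(lapply(section_inventory,
                                              `[[`, "admissible")))
  orphan <- setdiff(names(entity_weights)[entity_weights > 0],
                    admissible_anywhere)
  if (length(orphan)) {
    stopf("entity type(s) with positive weight admissible in no section: %s",
          paste(orphan, collapse = ", "))
  }
  structure(list(n_notes = n_notes, seed = as.integer(seed),
                 entity_weights = entity_weights,
                 section_inventory = section_inventory,
                 ambiguity_rate = ambiguity_rate,
                 conjunction_rate = conjunction_rate,
                 unlabeled_fraction = unlabeled_fraction,
                 mean_entities = mean_entities),
            class = "corpus_spec")
}

# Surface-form samplers ------------------------------------------------------

surface_pools <- function() {
  list(
    diagnosis = c("ziekte van Crohn", "colitis ulcerosa", "Morbus Crohn",
                  "CD", "UC"),
    disease_location = c("terminaal ileum", "colitis tot 40 cm", "L1", "L2",
                         "L3", "rectum", "colon ascendens", "caecum",
                         "sigmoid"),
    disease_behavior = c("B1", "B2", "B3", "stenoserend",
                         "fistel en fisteltraject", "penetrerend"),
    peri_anal_disease = c("peri-anale fistel", "peri-anaal abces",
                          "peri-anale ziekte"),
    previous_surgery = c("colectomie", "ileocoecale resectie",
                         "colectomie met tijdelijk ileostoma",
                         "appendectomie", "hemicolectomie rechts"),
    disease_extent = c("E1", "E2", "E3", "pancolitis", "proctitis")
  )
}

sample_surface <- function(type) {
  pools <- surface_pools()
  switch(type,
    diagnosis_date = {
      if (runif(1) < 0.5) {
        sprintf("%02d/%02d/%d", sample(28L, 1L), sample(12L, 1L),
                sample(1995:2024, 1L))
      } else {
        sprintf("in %d", sample(1995:2024, 1L))
      }
    },
    length = sprintf("%d cm", sample(150:195, 1L)),
    body_weight = sprintf("%d kg", sample(45:110, 1L)),
    sample(pools[[type]], 1L)
  )
}

sentence_templates <- function() {
  list(
    diagnosis = c("Patient heeft {E} .", "Gekende {E} sinds jaren .",
                  "Beeld van {E} ."),
    diagnosis_date = c("Diagnose gesteld op {E} .", "Gekend sinds {E} ."),
    disease_location = c("Ontsteking ter hoogte van {E} .",
                         "Letsels in {E} ."),
    disease_behavior = c("Ziektegedrag type {E} .", "Evolutie naar {E} ."),
    peri_anal_disease = c("Voorgeschiedenis van {E} .",
                          "Actieve {E} vastgesteld ."),
    previous_surgery = c("Status na {E} .", "Vroeger {E} ondergaan ."),
    disease_extent = c("Uitgebreidheid {E} .", "Montreal klasse {E} ."),
    length = c("Lengte {E} .", "Lichaamslengte {E} ."),
    body_weight = c("Gewicht {E} .", "Lichaamsgewicht {E} .")
  )
}

# Family-history distractors. Half come from a fixed family-context pool;
# half reuse the *diagnosis* sentence templates verbatim, so that without the
# section title the sentence is indistinguishable from a true diagnosis
# mention and only section information can veto the entity.
ambiguity_sentences <- function() {
  c("Zus en nicht van moeder :, ziekte van Crohn .",
    "Broers met Morbus Crohn .",
    "Vader gekend met colitis ulcerosa .")
}

render_ambiguity_sentence <- function() {
  if (stats::runif(1) < 0.5) {
    sample(ambiguity_sentences(), 1L)
  } else {
    render_entity_sentence("diagnosis", conjoin = FALSE)$text
  }
}

lab_sentences <- function() {
  c("CD 45 mg / l .", "UC 12 E / l .", "CRP 8 mg / l .")
}

filler_sentences <- function() {
  c("Geen bijzonderheden .", "Verder geen klachten .",
    "Algemene toestand goed .")
}

# Render one entity sentence; returns list(text, spans) with spans relative
# to the sentence start.
render_entity_sentence <- function(type, conjoin) {
  tmpl <- sample(sentence_templates()[[type]], 1L)
  slot <- if (conjoin) "{E} en {E}" else "{E}"
  tmpl <- sub("{E}", slot, tmpl, fixed = TRUE)
  parts <- strsplit(tmpl, "{E}", fixed = TRUE)[[1L]]
  if (!grepl("\\{E\\}$", tmpl)) n_slots <- length(parts) - 1L else
    n_slots <- length(parts)
  text <- ""
  spans <- list()
  for (k in seq_len(n_slots)) {
    text <- paste0(text, parts[k])
    surf <- sample_surface(type)
    spans[[k]] <- data.frame(start = nchar(text),
                             end = nchar(text) + nchar(surf),
                             label = type, surface = surf,
                             stringsAsFactors = FALSE)
    text <- paste0(text, surf)
  }
  if (length(parts) > n_slots) text <- paste0(text, parts[length(parts)])
  list(text = text, spans = do.call(rbind, spans))
}

#' Generate a synthetic clinical corpus
#'
#' Draws entity mentions per note from the multinomial defined by
#' \code{entity_weights}, places each in a section that admits its type,
#' renders template sentences around sampled surface forms, and records gold
#' spans with exact 0-based half-open character offsets. With probability
#' \code{ambiguity_rate} a note carries a family-history sentence containing
#' a diagnosis surface form that is deliberately NOT annotated, emulating
#' section-dependent entity validity. A \code{unlabeled_fraction} of notes is
#' flagged unlabelled; their gold spans are retained in memory for auditing
#' pseudo-labels but are never written to disk.
#'
#' @param spec a [corpus_spec()].
#' @return object of class \code{synthetic_corpus}: list with \code{notes}
#'   (each a list \code{note}, \code{spans}, \code{is_labeled}) and
#'   \code{spec}.
#' @examples
#' corp <- synth_corpus(corpus_spec(5, seed = 42))
#' corpus_stats(corp)
#' @export
synth_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    inv <- spec$section_inventory
    titles <- vapply(inv, `[[`, "", "title")
    w <- spec$entity_weights[spec$entity_weights > 0]
    notes <- vector("list", spec$n_notes)
    n_unlab <- round(spec$n_notes * spec$unlabeled_fraction)
    unlab <- if (n_unlab > 0) sample(spec$n_notes, n_unlab) else integer(0)
    for (i in seq_len(spec$n_notes)) {
      n_ent <- 1L + stats::rpois(1L, max(spec$mean_entities - 1, 0))
      types <- sample(names(w), n_ent, replace = TRUE, prob = w)
      # assign each mention to a section admitting its type
      sec_of <- vapply(types, function(t) {
        ok <- which(vapply(inv, function(s) t %in% s$admissible, logical(1)))
        ok[sample.int(length(ok), 1L)]
      }, integer(1))
      active <- sort(unique(sec_of))
      fam <- which(titles == "Familiaal")
      lab <- which(titles == "Labo")
      has_fam <- length(fam) && runif(1) < spec$ambiguity_rate
      has_lab <- length(lab) && runif(1) < 0.3
      if (has_fam) active <- sort(unique(c(active, fam)))
      if (has_lab) active <- sort(unique(c(active, lab)))
      lines <- character(0)
      spans <- list()
      offset <- 0L
      emit <- function(line, line_spans = NULL) {
        if (!is.null(line_spans) && nrow(line_spans)) {
          line_spans$start <- line_spans$start + offset
          line_spans$end <- line_spans$end + offset
          spans[[length(spans) + 1L]] <<- line_spans
        }
        lines[[length(lines) + 1L]] <<- line
        offset <<- offset + nchar(line) + 1L  # +1 for the newline
      }
      for (s_idx in active) {
        emit(paste0(titles[s_idx], " :"))
        if (s_idx %in% sec_of) {
          for (j in which(sec_of == s_idx)) {
            conjoin <- runif(1) < spec$conjunction_rate
            r <- render_entity_sentence(types[j], conjoin)
            emit(r$text, r$spans)
          }
        }
        if (has_fam && s_idx == fam) emit(render_ambiguity_sentence())
        if (has_lab && s_idx == lab) emit(sample(lab_sentences(), 1L))
        if (runif(1) < 0.25) emit(sample(filler_sentences(), 1L))
      }
      text <- paste(lines, collapse = "\n")
      note <- clinical_note(sprintf("note_%05d", i), text,
                            sections = detect_sections(text))
      sp <- if (length(spans)) do.call(rbind, spans) else
        data.frame(start = integer(), end = integer(), label = character(),
                   surface = character(), stringsAsFactors = FALSE)
      validate_spans(sp, text, where = sprintf("note %d span", i))
      notes[[i]] <- list(note = note, spans = sp,
                         is_labeled = !(i %in% unlab))
    }
    structure(list(notes = notes, spec = spec), class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  nl <- sum(vapply(x$notes, `[[`, logical(1), "is_labeled"))
  cat("<synthetic_corpus>", length(x$notes), "notes (", nl, "labelled,",
      length(x$notes) - nl, "unlabelled ), seed", x$spec$seed, "\n")
  invisible(x)
}

#' Corpus frequency report
#'
#' Per-entity counts, per-section by per-entity counts (sections resolved by
#' span containment), and the distribution of note word counts.
#'
#' @param corpus a \code{synthetic_corpus}, or any list of elements with
#'   fields \code{note} and \code{spans}.
#' @return object of class \code{corpus_stats}: list with
#'   \code{entity_counts}, \code{section_entity} (matrix sections x types),
#'   and \code{note_words}.
#' @export
corpus_stats <- function(corpus) {
  notes <- if (inherits(corpus, "synthetic_corpus")) corpus$notes else corpus
  if (!length(notes)) stopf("empty corpus")
  types <- sort(unique(unlist(lapply(notes, function(n) n$spans$label))))
  secs <- sort(unique(unlist(lapply(notes, function(n) n$note$sections$title))))
  mat <- matrix(0L, nrow = max(length(secs), 1L), ncol = length(types),
                dimnames = list(if (length(secs)) secs else "(none)", types))
  words <- integer(length(notes))
  for (i in seq_along(notes)) {
    n <- notes[[i]]
    words[i] <- nrow(tokenize_text(n$note$text))
    if (!nrow(n$spans)) next
    for (k in seq_len(nrow(n$spans))) {
      sec <- n$note$sections
      hit <- which(sec$start <= n$spans$start[k] & sec$end >= n$spans$end[k])
      row <- if (length(hit)) sec$title[hit[1L]] else "(none)"
      mat[row, n$spans$label[k]] <- mat[row, n$spans$label[k]] + 1L
    }
  }
  structure(list(entity_counts = colSums(mat), section_entity = mat,
                 note_words = words),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("Entity counts:\n")
  print(x$entity_counts)
  cat("\nNote length (words): median", stats::median(x$note_words),
      " range", min(x$note_words), "-", max(x$note_words), "\n")
  invisible(x)
}

#' Write a synthetic corpus as BRAT pairs plus a manifest
#'
#' Each note becomes \code{<id>.txt}; labelled notes additionally get
#' \code{<id>.ann}. A \code{manifest.json} lists the labelled and unlabelled
#' document ids and the generating spec's seed.
#'
#' @param corpus a \code{synthetic_corpus}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
write_brat_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- character(0); unlab <- character(0)
  for (n in corpus$notes) {
    write_brat(n$note, n$spans, dir, write_ann = n$is_labeled)
    if (n$is_labeled) lab <- c(lab, n$note$doc_id) else
      unlab <- c(unlab, n$note$doc_id)
  }
  jsonlite::write_json(list(labeled = lab, unlabeled = unlab,
                            seed = corpus$spec$seed),
                       file.path(dir, "manifest.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' Read a BRAT corpus directory
#'
#' @param dir directory of \code{.txt}/\code{.ann} pairs (a manifest is not
#'   required; notes without an \code{.ann} are treated as unlabelled).
#' @param scheme optional [label_scheme()] for type validation.
#' @return list of elements (\code{note}, \code{spans}, \code{is_labeled}).
#' @export
read_brat_corpus <- function(dir, scheme = NULL) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) stopf("no .txt files under %s", dir)
  lapply(txts, function(tp) {
    ap <- sub("\\.txt$", ".ann", tp)
    d <- read_brat(tp, ap, scheme)
    list(note = d$note, spans = d$spans, is_labeled = file.exists(ap))
  })
}

#' Flatten a corpus into tagged sentences
#'
#' Splits every note into sentences, tokenises with document offsets,
#' projects gold spans to BIO tags, attaches the section title, and sets the
#' sentence flag to 1 where the sentence contains a peri-anal disease
#' mention (the multi-task target). Section header lines are dropped.
#'
#' @param corpus a \code{synthetic_corpus} or list from [read_brat_corpus()].
#' @param which \code{"labeled"}, \code{"unlabeled"} or \code{"all"}.
#'   Unlabelled notes are emitted with all-\code{O} tags.
#' @param flag_entity entity type driving the sentence flag.
#' @return list of [tagged_sentence()] objects.
#' @export
corpus_to_sentences <- function(corpus, which = "labeled",
                                flag_entity = "peri_anal_disease") {
  which <- match.arg(which, c("labeled", "unlabeled", "all"))
  notes <- if (inherits(corpus, "synthetic_corpus")) corpus$notes else corpus
  out <- list()
  for (n in notes) {
    if (which == "labeled" && !n$is_labeled) next
    if (which == "unlabeled" && n$is_labeled) next
    sent <- split_sentences(n$note)
    sent <- sent[!sent$is_header, , drop = FALSE]
    for (k in seq_len(nrow(sent))) {
      toks <- tokenize_text(sent$text[k], base_offset = sent$start[k])
      if (!nrow(toks)) next
      sp <- n$spans[n$spans$start >= sent$start[k] &
                      n$spans$end <= sent$end[k], , drop = FALSE]
      if (!n$is_labeled) sp <- sp[0, , drop = FALSE]
      tags <- spans_to_bio(toks, sp)
      out[[length(out) + 1L]] <- tagged_sentence(
        toks, tags, section = sent$section[k],
        flag = as.integer(any(sp$label == flag_entity)),
        doc_id = n$note$doc_id)
    }
  }
  out
}
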