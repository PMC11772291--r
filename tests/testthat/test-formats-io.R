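test_that("BRAT standoff parsing handles direct, empty and malformed input", {
  dir <- tempdir()
  txt <- file.path(dir, "n1.txt"); ann <- file.path(dir, "n1.ann")
  writeLines("Diagnose is Crohns vandaag", txt, sep = "")
  writeLines("T1\tdiagnosis 12 18\tCrohns", ann)
  sch <- label_scheme()
  d <- read_brat(txt, ann, sch)
  expect_equal(d$spans$start, 12L)
  expect_equal(d$spans$end, 18L)
  expect_equal(d$spans$label, "diagnosis")
  expect_equal(d$spans$surface, "Crohns")
  # empty annotation file: note returned, zero spans
  writeLines(character(0), ann)
  d0 <- read_brat(txt, ann, sch)
  expect_equal(nrow(d0$spans), 0L)
  expect_identical(d0$note$text, "Diagnose is Crohns vandaag")
  # surface mismatching the text slice is rejected with the line named
  writeLines("T1\tdiagnosis 12 18\tWRONGX", ann)
  expect_error(read_brat(txt, ann, sch), "does not match")
  # out-of-bounds offsets rejected
  writeLines("T1\tdiagnosis 20 99\tCrohns", ann)
  expect_error(read_brat(txt, ann, sch), "out of bounds")
  # unknown entity type rejected when a scheme is given
  writeLines("T1\tmedication 12 18\tCrohns", ann)
  expect_error(read_brat(txt, ann, sch), "unknown entity type")
})

test_that("sentence splitting partitions the note and inherits sections", {
  text <- "Anamnese :\nPatient heeft CD .\nFamiliaal :\nBroers met Morbus Crohn ."
  note <- clinical_note("x", text,
                        sections = data.frame(
                          title = c("Anamnese", "Familiaal"),
                          start = c(0L, 30L), end = c(30L, nchar(text))))
  sent <- split_sentences(note)
  expect_equal(nrow(sent), 4L)
  expect_equal(sent$section, c("Anamnese", "Anamnese", "Familiaal",
                               "Familiaal"))
  expect_equal(sent$is_header, c(TRUE, FALSE, TRUE, FALSE))
  # concatenating the slices reproduces the text minus separators
  joined <- paste(substring(text, sent$start + 1L, sent$end),
                  collapse = "\n")
  expect_identical(joined, text)
  # single-sentence note
  n1 <- clinical_note("y", "Gewicht 70 kg .")
  s1 <- split_sentences(n1)
  expect_equal(nrow(s1), 1L)
  expect_equal(c(s1$start, s1$end), c(0L, 15L))
})

test_that("spans_to_bio assigns B/I/O per overlap and rejects overlaps", {
  s <- toy_sentence()
  spans <- data.frame(start = 14L, end = 20L, label = "diagnosis",
                      surface = "Crohns")
  expect_equal(spans_to_bio(s$tokens, spans), c("O", "O", "B-diagnosis"))
  s2 <- two_token_entity_sentence()
  sp2 <- data.frame(start = 0L, end = 15L, label = "disease_location",
                    surface = "terminaal ileum")
  expect_equal(spans_to_bio(s2$tokens, sp2),
               c("B-disease_location", "I-disease_location"))
  expect_equal(spans_to_bio(s$tokens, NULL), rep("O", 3L))
  bad <- data.frame(start = c(0L, 5L), end = c(10L, 15L),
                    label = c("diagnosis", "diagnosis"),
                    surface = c("", ""))
  expect_error(spans_to_bio(s2$tokens, bad), "overlapping")
})

test_that("bio_to_spans inverts spans_to_bio and repairs stray I- tags", {
  corp <- small_corpus()
  sents <- small_sentences()
  for (s in sents[1:20]) {
    sp <- bio_to_spans(s$tokens, s$tags)
    expect_equal(spans_to_bio(s$tokens, sp), s$tags)
  }
  toks <- data.frame(surface = c("a", "b"), start = c(0L, 2L),
                     end = c(1L, 3L))
  rep1 <- bio_to_spans(toks, c("O", "I-diagnosis"))
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$start, 2L)
  expect_equal(attr(rep1, "repairs"), 1L)
  expect_equal(nrow(bio_to_spans(toks, c("O", "O"))), 0L)
  expect_error(bio_to_spans(toks, c("O", "X-bad")), "malformed BIO")
})

test_that("CoNLL write/read round trips sentences losslessly", {
  sents <- small_sentences()[1:12]
  path <- file.path(tempdir(), "sents.conll")
  write_conll(sents, path, provenance = c(source = "unit-test"))
  back <- read_conll(path)
  expect_length(back, length(sents))
  for (k in seq_along(sents)) {
    expect_identical(back[[k]]$tokens$surface, sents[[k]]$tokens$surface)
    expect_identical(back[[k]]$tags, sents[[k]]$tags)
    expect_identical(back[[k]]$section, sents[[k]]$section)
    expect_identical(back[[k]]$flag, sents[[k]]$flag)
    expect_identical(back[[k]]$silver, sents[[k]]$silver)
  }
  expect_match(attr(back, "provenance"), "unit-test")
  # blank-line separation yields two sentences
  writeLines(c("a\t_\t0\tO", "", "b\t_\t0\tO", ""), path)
  expect_length(read_conll(path), 2L)
  # ragged rows are a parse error naming the line
  writeLines(c("a\t_\t0", ""), path)
  expect_error(read_conll(path), "line 1")
  # a token containing a tab cannot be serialised
  toks <- data.frame(surface = "a\tb", start = 0L, end = 3L)
  bad <- tagged_sentence(toks, "O")
  expect_error(write_conll(list(bad), path), "tab")
})

test_that("tokeniser offsets index exactly into the text", {
  text <- "Gewicht 72.5 kg , peri-anale fistel ."
  toks <- tokenize_text(text)
  expect_identical(substring(text, toks$start + 1L, toks$end),
                   toks$surface)
  expect_true(all(diff(toks$start) > 0))
})
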