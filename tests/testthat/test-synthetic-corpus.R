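test_that("corpus specification validates its inputs", {
  expect_error(corpus_spec(0), "positive count")
  expect_error(corpus_spec(5, entity_weights = c(diagnosis = -1)),
               "non-negative")
  expect_error(corpus_spec(5, entity_weights = c(diagnosis = 0)),
               "all zero")
  expect_error(corpus_spec(5, ambiguity_rate = 1.2), "rates")
  expect_error(corpus_spec(5, section_inventory = list()), "empty")
})

test_that("fixed seed yields byte-identical corpora", {
  spec <- corpus_spec(8, seed = 99, unlabeled_fraction = 0.25)
  c1 <- synth_corpus(spec)
  c2 <- synth_corpus(spec)
  expect_identical(c1, c2)
  d1 <- file.path(tempdir(), "brat1"); d2 <- file.path(tempdir(), "brat2")
  write_brat_corpus(c1, d1); write_brat_corpus(c2, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
})

test_that("span offsets are valid and surfaces match the note text", {
  corp <- small_corpus()
  for (n in corp$notes) {
    if (!nrow(n$spans)) next
    expect_true(all(n$spans$start >= 0))
    expect_true(all(n$spans$start < n$spans$end))
    expect_true(all(n$spans$end <= nchar(n$note$text)))
    got <- substring(n$note$text, n$spans$start + 1L, n$spans$end)
    expect_identical(got, n$spans$surface)
  }
})

test_that("zero-weight classes never occur and admissibility is respected", {
  w <- default_entity_weights()
  w["peri_anal_disease"] <- 0
  corp <- synth_corpus(corpus_spec(40, seed = 3, entity_weights = w))
  labs <- unlist(lapply(corp$notes, function(n) n$spans$label))
  expect_false("peri_anal_disease" %in% labs)
  # no gold span may sit in a section that forbids its type
  inv <- default_section_inventory()
  adm <- stats::setNames(lapply(inv, `[[`, "admissible"),
                         vapply(inv, `[[`, "", "title"))
  for (n in corp$notes) {
    st <- corpus_stats(list(n))
    for (sec in rownames(st$section_entity)) {
      present <- colnames(st$section_entity)[st$section_entity[sec, ] > 0]
      expect_true(all(present %in% adm[[sec]]),
                  info = paste("section", sec))
    }
  }
})

test_that("family-history sections carry diagnosis surfaces with no gold span", {
  corp <- synth_corpus(corpus_spec(25, seed = 5, ambiguity_rate = 1))
  n_fam <- 0L
  for (n in corp$notes) {
    sec <- n$note$sections
    fam <- sec[sec$title == "Familiaal", ]
    if (!nrow(fam)) next
    n_fam <- n_fam + 1L
    # no gold span inside the family-history range
    inside <- n$spans$start >= fam$start & n$spans$end <= fam$end
    expect_false(any(inside))
  }
  expect_equal(n_fam, length(corp$notes))
})

test_that("empirical class frequencies track the configured weights", {
  # law-of-large-numbers check on a 9:1 two-class spec
  w <- c(diagnosis = 9, peri_anal_disease = 1)
  corp <- synth_corpus(corpus_spec(400, seed = 21, entity_weights = w,
                                   ambiguity_rate = 0, mean_entities = 7))
  st <- corpus_stats(corp)
  ratio <- st$entity_counts[["diagnosis"]] /
    st$entity_counts[["peri_anal_disease"]]
  expect_gt(ratio, 9 * 0.8)
  expect_lt(ratio, 9 * 1.25)
  # chi-square goodness of fit on the full default inventory
  corp2 <- synth_corpus(corpus_spec(150, seed = 22, mean_entities = 6))
  st2 <- corpus_stats(corp2)
  expect_gt(sum(st2$entity_counts), 500)
  w0 <- default_entity_weights()[names(st2$entity_counts)]
  pval <- suppressWarnings(
    stats::chisq.test(st2$entity_counts, p = w0 / sum(w0))$p.value)
  expect_gt(pval, 1e-3)
})

test_that("corpus_stats conserves counts and rejects empty corpora", {
  corp <- small_corpus()
  st <- corpus_stats(corp)
  expect_equal(colSums(st$section_entity), st$entity_counts)
  total <- sum(vapply(corp$notes, function(n) nrow(n$spans), numeric(1)))
  expect_equal(sum(st$entity_counts), total)
  expect_error(corpus_stats(list()), "empty")
})

test_that("BRAT corpus round trip preserves text, spans and labelling split", {
  corp <- small_corpus()
  dir <- file.path(tempdir(), "bratrt")
  write_brat_corpus(corp, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  back <- read_brat_corpus(dir, label_scheme())
  expect_length(back, length(corp$notes))
  for (k in seq_along(back)) {
    orig <- corp$notes[[k]]
    expect_identical(back[[k]]$note$text, orig$note$text)
    expect_identical(back[[k]]$is_labeled, orig$is_labeled)
    if (orig$is_labeled) {
      o <- orig$spans[order(orig$spans$start), ]
      b <- back[[k]]$spans[order(back[[k]]$spans$start), ]
      expect_equal(b$start, o$start)
      expect_equal(b$end, o$end)
      expect_equal(b$label, o$label)
      expect_equal(b$surface, o$surface)
    } else {
      expect_true(orig$note$doc_id %in% manifest$unlabeled)
    }
  }
})
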