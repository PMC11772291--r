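test_that("boundary-missed predictions count for type but not strict", {
  # gold "warfarin" vs predicted "of warfarin", same entity type
  gold <- data.frame(start = 8L, end = 16L, label = "drug",
                     surface = "warfarin", doc = "d1")
  pred <- data.frame(start = 5L, end = 16L, label = "drug",
                     surface = "of warfarin", doc = "d1")
  ev <- evaluate_ner(gold, pred)
  expect_equal(unname(ev$strict$micro[c("tp", "fp", "fn")]), c(0, 1, 1))
  expect_equal(ev$type$micro[["tp"]], 1)
  expect_equal(ev$type$micro[["f1"]], 1)
  expect_equal(ev$strict$micro[["f1"]], 0)
})

test_that("identical gold and prediction sets score perfectly", {
  set.seed(3)
  g <- random_span_set(6L)
  ev <- evaluate_ner(g, g)
  expect_equal(ev$strict$micro[["f1"]], 1)
  expect_equal(ev$type$micro[["f1"]], 1)
  expect_true(all(ev$strict$per_class$f1 == 1))
})

test_that("a hand-counted mixed case yields the expected P/R", {
  gold <- data.frame(start = c(0L, 10L, 20L), end = c(5L, 15L, 25L),
                     label = c("a", "a", "b"),
                     surface = c("", "", ""), doc = "d")
  pred <- data.frame(start = c(0L, 11L), end = c(5L, 16L),
                     label = c("a", "a"), surface = c("", ""), doc = "d")
  ev <- evaluate_ner(gold, pred)
  expect_equal(ev$strict$micro[["precision"]], 0.5)
  expect_equal(ev$strict$micro[["recall"]], 1 / 3)
  expect_equal(ev$type$micro[["precision"]], 1.0)
  expect_equal(ev$type$micro[["recall"]], 2 / 3)
  p <- ev$type$micro[["precision"]]; r <- ev$type$micro[["recall"]]
  expect_equal(ev$type$micro[["f1"]], 2 * p * r / (p + r))
})

test_that("counts conserve and the matcher equals the exhaustive oracle", {
  set.seed(99)
  for (k in 1:150) {
    g <- random_span_set(sample(0:8, 1L))
    p <- random_span_set(sample(0:8, 1L))
    ev <- evaluate_ner(g, p)
    for (crit in c("strict", "type")) {
      m <- ev[[crit]]$micro
      expect_equal(m[["tp"]] + m[["fn"]], nrow(g))
      expect_equal(m[["tp"]] + m[["fp"]], nrow(p))
      pc <- ev[[crit]]$per_class
      expect_equal(sum(pc$tp), m[["tp"]])
      expect_equal(sum(pc$support), nrow(g))
    }
    expect_equal(ev$type$micro[["tp"]], brute_max_match(g, p))
    expect_gte(ev$type$micro[["tp"]], ev$strict$micro[["tp"]])
    expect_gte(ev$type$micro[["f1"]], ev$strict$micro[["f1"]])
  }
})

test_that("matching never crosses documents", {
  g <- data.frame(start = 0L, end = 5L, label = "a", surface = "", doc = "d1")
  p <- data.frame(start = 0L, end = 5L, label = "a", surface = "", doc = "d2")
  ev <- evaluate_ner(g, p)
  expect_equal(ev$strict$micro[["tp"]], 0)
  expect_equal(ev$type$micro[["tp"]], 0)
})

test_that("the error taxonomy reproduces its defining cases", {
  # one prediction merging two same-type golds across a conjunction
  text <- "terminaal ileum en colitis tot 40 cm"
  gold <- data.frame(start = c(0L, 19L), end = c(15L, 36L),
                     label = "disease_location",
                     surface = c("terminaal ileum", "colitis tot 40 cm"),
                     doc = "d")
  pred <- data.frame(start = 0L, end = 36L, label = "disease_location",
                     surface = text, doc = "d")
  err <- classify_errors(gold, pred)
  expect_equal(err$category, "conjunction_merge")
  # prediction extending beyond the annotated span
  gold2 <- data.frame(start = 0L, end = 8L, label = "disease_location",
                      surface = "rectitis", doc = "d")
  pred2 <- data.frame(start = 0L, end = 36L, label = "disease_location",
                      surface = "rectitis ulcerohemorrhagica voor 5 cm",
                      doc = "d")
  expect_equal(classify_errors(gold2, pred2)$category, "extra_information")
  # prediction of a different entity type over the same surface
  gold3 <- data.frame(start = 0L, end = 13L, label = "disease_location",
                      surface = "Crohn colitis", doc = "d")
  pred3 <- data.frame(start = c(0L, 6L), end = c(5L, 13L),
                      label = c("diagnosis", "disease_location"),
                      surface = c("Crohn", "colitis"), doc = "d")
  err3 <- classify_errors(gold3, pred3)
  expect_true("different_entity_type" %in% err3$category)
  # prediction strictly inside the gold span
  gold4 <- data.frame(start = 0L, end = 30L, label = "disease_location",
                      surface = "aantasting van het rectum over", doc = "d")
  pred4 <- data.frame(start = 19L, end = 25L, label = "disease_location",
                      surface = "rectum", doc = "d")
  expect_equal(classify_errors(gold4, pred4)$category,
               "missing_information")
  # prediction with no gold at all
  pred5 <- data.frame(start = 50L, end = 60L, label = "previous_surgery",
                      surface = "colectomie", doc = "d")
  expect_equal(classify_errors(gold4, pred5)$category,
               "missing_gold_annotation")
  # exact matches generate no error cases
  expect_equal(nrow(classify_errors(gold4, gold4)), 0L)
})

test_that("token accuracy is a simple agreement rate", {
  expect_equal(tag_accuracy(c("O", "B-a", "O"), c("O", "B-a", "B-a")), 2 / 3)
  expect_error(tag_accuracy("O", c("O", "O")), "length")
})
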