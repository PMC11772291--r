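# The runnable variant matrix: named method settings combining pre-training
# strategy, section fusion, pseudo-labelling and R-drop, compared on shared
# document-level splits.

#' Resolve a variant name into its switches
#'
#' The compared method settings: \code{FT} (fine-tune only), \code{FT-FS}
#' (+ section fusion), \code{FT-FS-PL} (+ pseudo-labels and R-drop),
#' \code{MLM-FT-FS-PL} (random-masking continued pre-training),
#' \code{EMLM-FT} (entity-masking pre-training, plain fine-tune),
#' \code{EMLM-FT-FS-PL}, and \code{EMLM-CL-FT-FS-PL} (entity masking with
#' frozen-teacher contrastive learning).
#'
#' @param name variant name.
#' @return object of class \code{variant_spec}: list with \code{name},
#'   \code{pretrain} (\code{"none"}, \code{"mlm"}, \code{"emlm"},
#'   \code{"emlm_cl"}), \code{fusion}, \code{pseudo_labels}, \code{rdrop}.
#' @export
variant_spec <- function(name) {
  table <- list(
    "FT"               = list(pretrain = "none",    fusion = "none",
                              pseudo_labels = FALSE, rdrop = FALSE),
    "FT-FS"            = list(pretrain = "none",    fusion = "embed",
                              pseudo_labels = FALSE, rdrop = FALSE),
    "FT-FS-PL"         = list(pretrain = "none",    fusion = "embed",
                              pseudo_labels = TRUE,  rdrop = TRUE),
    "MLM-FT-FS-PL"     = list(pretrain = "mlm",     fusion = "embed",
                              pseudo_labels = TRUE,  rdrop = TRUE),
    "EMLM-FT"          = list(pretrain = "emlm",    fusion = "none",
                              pseudo_labels = FALSE, rdrop = FALSE),
    "EMLM-FT-FS-PL"    = list(pretrain = "emlm",    fusion = "embed",
                              pseudo_labels = TRUE,  rdrop = TRUE),
    "EMLM-CL-FT-FS-PL" = list(pretrain = "emlm_cl", fusion = "embed",
                              pseudo_labels = TRUE,  rdrop = TRUE)
  )
  if (!name %in% names(table)) {
    stopf("unknown variant %s; known: %s", dQuote(name),
          paste(names(table), collapse = ", "))
  }
  structure(c(list(name = name), table[[name]]), class = "variant_spec")
}

#' Document-level train/dev/test split
#'
#' Splits the labelled notes of a corpus by document (never by sentence, so
#' no sentence-level leakage) and flattens each part into tagged sentences.
#' Unlabelled notes form a separate pool for continued pre-training and
#' pseudo-labelling; test documents appear in no other pool.
#'
#' @param corpus a [synth_corpus()] result (or [read_brat_corpus()] list).
#' @param train,dev fractions of labelled documents (test gets the rest).
#' @param seed split seed.
#' @return list with sentence lists \code{train}, \code{dev}, \code{test},
#'   \code{unlabeled}, and the test note objects in \code{test_notes}.
#' @export
split_corpus <- function(corpus, train = 0.7, dev = 0.15, seed = 1L) {
  notes <- if (inherits(corpus, "synthetic_corpus")) corpus$notes else corpus
  lab <- which(vapply(notes, `[[`, logical(1), "is_labeled"))
  if (length(lab) < 3L) stopf("need at least 3 labelled notes to split")
  with_seed(derive_seed(seed, 5L), {
    ord <- sample(lab)
    n_tr <- max(1L, floor(length(ord) * train))
    n_dev <- max(1L, floor(length(ord) * dev))
    tr <- ord[seq_len(n_tr)]
    dv <- ord[n_tr + seq_len(min(n_dev, length(ord) - n_tr - 1L))]
    te <- setdiff(ord, c(tr, dv))
    part <- function(idx) corpus_to_sentences(
      structure(list(notes = notes[idx]), class = "synthetic_corpus"),
      which = "all")
    list(train = part(tr), dev = part(dv), test = part(te),
         unlabeled = corpus_to_sentences(
           structure(list(notes = notes), class = "synthetic_corpus"),
           which = "unlabeled"),
         test_notes = notes[te])
  })
}

run_one_variant <- function(vs, splits, vocab, scheme, cfg, control,
                            pretrain_steps, pretrain_lr, tau, seed) {
  control$seed <- seed
  if (!vs$rdrop) control$alpha <- 0
  ckpt <- NULL
  if (vs$pretrain != "none") {
    pre_sent <- if (vs$pretrain == "mlm") {
      c(splits$train, splits$unlabeled)
    } else {
      splits$train
    }
    cfg_pre <- cfg
    cfg_pre$seed <- seed
    ckpt <- run_pretraining(pre_sent, variant = vs$pretrain, vocab = vocab,
                            scheme = scheme, cfg = cfg_pre,
                            steps = pretrain_steps, lr = pretrain_lr,
                            tau = tau, seed = seed)
  }
  fit <- ner_fit(splits$train, dev = splits$dev, scheme = scheme,
                 vocab = vocab, checkpoint = ckpt, fusion = vs$fusion,
                 control = control,
                 encoder_cfg = if (is.null(ckpt)) cfg else NULL)
  if (vs$pseudo_labels && length(splits$unlabeled)) {
    silver <- pseudo_label(fit, splits$unlabeled)
    fit <- ner_fit(c(splits$train, silver), dev = splits$dev,
                   scheme = scheme, vocab = vocab, checkpoint = ckpt,
                   fusion = vs$fusion, control = control,
                   encoder_cfg = if (is.null(ckpt)) cfg else NULL)
  }
  ev <- evaluate_sentences(fit$model, splits$test)
  data.frame(variant = vs$name, seed = seed,
             strict_p = ev$strict$micro[["precision"]],
             strict_r = ev$strict$micro[["recall"]],
             strict_f1 = ev$strict$micro[["f1"]],
             type_f1 = ev$type$micro[["f1"]],
             dev_f1 = fit$dev_strict_f1,
             best_epoch = fit$best_epoch,
             stringsAsFactors = FALSE)
}

#' Run the variant comparison matrix
#'
#' Trains and evaluates a set of named variants on shared document-level
#' splits of one corpus, repeating each over a list of seeds, and reports
#' strict P/R/F1 and entity-type F1 per variant (mean and sd over seeds).
#'
#' @param corpus a [synth_corpus()] corpus (typically generated with a
#'   nonzero \code{unlabeled_fraction} so pseudo-labelling has a pool).
#' @param variants character vector of variant names (see [variant_spec()]).
#' @param seeds integer vector; each variant is run once per seed.
#' @param scheme label scheme.
#' @param encoder_cfg encoder configuration template (vocab_size is set from
#'   the shared vocabulary).
#' @param control a [finetune_config()] template (seed/alpha overridden per
#'   run).
#' @param pretrain_steps,pretrain_lr,tau continued pre-training settings.
#' @param split_seed seed of the shared document split.
#' @return object of class \code{variant_matrix}: \code{results} (one row
#'   per variant with mean/sd columns), \code{runs} (per-seed rows), and the
#'   split sizes.
#' @export
run_matrix <- function(corpus, variants, seeds = 1L,
                       scheme = label_scheme(), encoder_cfg = NULL,
                       control = finetune_config(),
                       pretrain_steps = 150L, pretrain_lr = 1e-3,
                       tau = 0.01, split_seed = 1L) {
  vspecs <- lapply(variants, variant_spec)
  splits <- split_corpus(corpus, seed = split_seed)
  vocab <- build_vocab(c(splits$train, splits$unlabeled), scheme)
  cfg <- encoder_cfg %||% encoder_config(length(vocab$tokens))
  cfg$vocab_size <- length(vocab$tokens)
  runs <- list()
  for (vs in vspecs) {
    for (sd in seeds) {
      runs[[length(runs) + 1L]] <- run_one_variant(
        vs, splits, vocab, scheme, cfg, control, pretrain_steps,
        pretrain_lr, tau, seed = as.integer(sd))
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(unique(runs$variant), function(v) {
    r <- runs[runs$variant == v, ]
    data.frame(variant = v,
               strict_p = mean(r$strict_p), strict_r = mean(r$strict_r),
               strict_f1 = mean(r$strict_f1), strict_f1_sd =
                 if (nrow(r) > 1) stats::sd(r$strict_f1) else 0,
               type_f1 = mean(r$type_f1), type_f1_sd =
                 if (nrow(r) > 1) stats::sd(r$type_f1) else 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(results = agg, runs = runs,
                 sizes = c(train = length(splits$train),
                           dev = length(splits$dev),
                           test = length(splits$test),
                           unlabeled = length(splits$unlabeled))),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, digits = 3, ...) {
  cat("Variant comparison (", paste(names(x$sizes), x$sizes,
                                    collapse = ", "), "sentences )\n")
  df <- x$results
  df[-1] <- round(df[-1], digits)
  print(df, row.names = FALSE)
  invisible(x)
}
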