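# Strict and entity-type matched NER evaluation plus the five-category
# error taxonomy.

empty_spans <- function() {
  data.frame(start = integer(), end = integer(), label = character(),
             surface = character(), doc = character(),
             stringsAsFactors = FALSE)
}

normalise_spans <- function(x, who) {
  if (is.null(x) || !nrow(x)) return(empty_spans())
  need <- c("start", "end", "label")
  if (!all(need %in% names(x))) stopf("%s spans need columns start,end,label",
                                      who)
  if (is.null(x$doc)) x$doc <- "doc1"
  if (is.null(x$surface)) x$surface <- ""
  if (any(x$start >= x$end)) stopf("%s spans must satisfy start < end", who)
  x[, c("start", "end", "label", "surface", "doc")]
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}

# Match gold and pred spans of one document under the entity-type criterion:
# label must match and character overlap must be >= 1; each gold and each
# pred is used at most once. The matching is maximum-cardinality (Kuhn's
# augmenting paths), seeded with exact (start,end,label) matches and with
# candidate edges ordered by decreasing overlap (ties toward the leftmost
# gold then leftmost pred) so pair selection is deterministic. Maximality
# guarantees that the exact matches of the strict criterion can never
# outnumber the type matches.
type_match_doc <- function(gold, pred) {
  ng <- nrow(gold); np <- nrow(pred)
  match_of_pred <- rep(0L, np)                # pred index -> gold index
  if (ng && np) {
    # adjacency: for each gold, candidate preds ordered by overlap
    adj <- vector("list", ng)
    for (gi in seq_len(ng)) {
      ov <- pmin(gold$end[gi], pred$end) - pmax(gold$start[gi], pred$start)
      cand <- which(pred$label == gold$label[gi] & ov >= 1L)
      adj[[gi]] <- cand[order(-ov[cand], pred$start[cand])]
    }
    # seed exact matches
    seeded <- rep(FALSE, ng)
    for (gi in seq_len(ng)) {
      hit <- which(match_of_pred == 0L & pred$label == gold$label[gi] &
                     pred$start == gold$start[gi] & pred$end == gold$end[gi])
      if (length(hit)) {
        match_of_pred[hit[1L]] <- gi
        seeded[gi] <- TRUE
      }
    }
    try_augment <- function(gi, vis) {
      for (pi in adj[[gi]]) {
        if (vis$seen[pi]) next
        vis$seen[pi] <- TRUE
        owner <- match_of_pred[pi]
        if (owner == 0L || try_augment(owner, vis)) {
          match_of_pred[pi] <<- gi
          return(TRUE)
        }
      }
      FALSE
    }
    order_g <- order(gold$start, gold$end)
    for (gi in order_g[!seeded[order_g]]) {
      vis <- new.env()
      vis$seen <- rep(FALSE, np)
      try_augment(gi, vis)
    }
  }
  pairs <- lapply(which(match_of_pred > 0L),
                  function(pi) c(match_of_pred[pi], pi))
  list(gold_matched = seq_len(ng) %in% match_of_pred,
       pred_matched = match_of_pred > 0L, pairs = pairs)
}

#' Evaluate predicted entity spans against gold spans
#'
#' Computes micro and per-entity-type precision, recall and F1 under two
#' criteria. \emph{Strict}: a predicted entity counts only as an exact
#' (start, end, type) match. \emph{Entity type}: the type must be correct
#' and the surfaces must overlap by at least one character (the boundary may
#' be missed); each gold entity is credited at most once.
#'
#' @param gold,pred span data.frames with columns \code{start}, \code{end},
#'   \code{label}, optional \code{surface} and \code{doc} (document id; all
#'   spans are assumed to come from one document when absent, and matching
#'   never crosses documents).
#' @param conjunctions conjunction lexicon for the error taxonomy.
#' @return object of class \code{eval_report}: per-class and micro
#'   \code{strict} and \code{type} scores, support counts, and the
#'   [classify_errors()] error-case table.
#' @export
evaluate_ner <- function(gold, pred, conjunctions = c("en", "of", "met")) {
  gold <- normalise_spans(gold, "gold")
  pred <- normalise_spans(pred, "pred")
  classes <- sort(unique(c(gold$label, pred$label)))
  docs <- unique(c(gold$doc, pred$doc))
  strict_tp <- type_tp <- stats::setNames(numeric(length(classes)), classes)
  for (d in docs) {
    g <- gold[gold$doc == d, , drop = FALSE]
    p <- pred[pred$doc == d, , drop = FALSE]
    # strict: multiset exact matching
    used <- rep(FALSE, nrow(p))
    for (gi in seq_len(nrow(g))) {
      hit <- which(!used & p$label == g$label[gi] & p$start == g$start[gi] &
                     p$end == g$end[gi])
      if (length(hit)) {
        used[hit[1L]] <- TRUE
        strict_tp[g$label[gi]] <- strict_tp[g$label[gi]] + 1
      }
    }
    tm <- type_match_doc(g, p)
    for (pr in tm$pairs) {
      type_tp[g$label[pr[1L]]] <- type_tp[g$label[pr[1L]]] + 1
    }
  }
  n_gold <- vapply(classes, function(cl) sum(gold$label == cl), numeric(1))
  n_pred <- vapply(classes, function(cl) sum(pred$label == cl), numeric(1))
  per_class <- function(tp) {
    rows <- lapply(classes, function(cl) {
      as.data.frame(t(prf(tp[[cl]], n_pred[[cl]] - tp[[cl]],
                          n_gold[[cl]] - tp[[cl]])))
    })
    out <- do.call(rbind, rows)
    out <- cbind(data.frame(class = classes, support = unname(n_gold)), out)
    rownames(out) <- NULL
    out
  }
  report <- list(
    strict = list(per_class = per_class(strict_tp),
                  micro = prf(sum(strict_tp), sum(n_pred) - sum(strict_tp),
                              sum(n_gold) - sum(strict_tp))),
    type = list(per_class = per_class(type_tp),
                micro = prf(sum(type_tp), sum(n_pred) - sum(type_tp),
                            sum(n_gold) - sum(type_tp))),
    n_gold = sum(n_gold), n_pred = sum(n_pred),
    errors = classify_errors(gold, pred, conjunctions)
  )
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("NER evaluation:", x$n_gold, "gold /", x$n_pred, "predicted spans\n")
  m <- rbind(strict = x$strict$micro[1:3], entity_type = x$type$micro[1:3])
  print(round(m, digits))
  if (nrow(x$errors)) {
    cat("\nError cases:\n")
    print(table(x$errors$category))
  }
  invisible(x)
}

#' Classify prediction errors into the five-category taxonomy
#'
#' Deterministic rules applied per predicted span (exact matches are not
#' errors): a prediction strictly inside a same-type gold span is
#' \code{missing_information}; one strictly containing a same-type gold is
#' \code{extra_information}; one covering two or more same-type golds whose
#' gaps contain a conjunction token is \code{conjunction_merge}; one with no
#' overlapping gold at all is \code{missing_gold_annotation}; one
#' overlapping a gold of a different type is \code{different_entity_type}.
#' Remaining mismatches are reported as \code{uncategorized}.
#'
#' @param gold,pred span data.frames (see [evaluate_ner()]).
#' @param conjunctions conjunction surface lexicon.
#' @return data.frame with columns \code{doc}, \code{category},
#'   \code{pred_label}, \code{pred_surface}, \code{gold_labels},
#'   \code{gold_surfaces}.
#' @export
classify_errors <- function(gold, pred, conjunctions = c("en", "of", "met")) {
  gold <- normalise_spans(gold, "gold")
  pred <- normalise_spans(pred, "pred")
  out <- list()
  rec <- function(doc, category, p, g) {
    out[[length(out) + 1L]] <<- data.frame(
      doc = doc, category = category,
      pred_label = p$label, pred_surface = p$surface,
      gold_labels = paste(g$label, collapse = "; "),
      gold_surfaces = paste(g$surface, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  for (d in unique(pred$doc)) {
    g <- gold[gold$doc == d, , drop = FALSE]
    p <- pred[pred$doc == d, , drop = FALSE]
    for (pi in seq_len(nrow(p))) {
      ps <- p[pi, , drop = FALSE]
      ov <- which(g$start < ps$end & g$end > ps$start)
      if (!length(ov)) {
        rec(d, "missing_gold_annotation", ps, g[0, ])
        next
      }
      same <- ov[g$label[ov] == ps$label]
      exact <- same[g$start[same] == ps$start & g$end[same] == ps$end]
      if (length(exact)) next
      contained <- same[g$start[same] >= ps$start & g$end[same] <= ps$end]
      if (length(contained) >= 2L) {
        gc <- g[contained, , drop = FALSE]
        gc <- gc[order(gc$start), , drop = FALSE]
        gap_has_conj <- FALSE
        for (k in seq_len(nrow(gc) - 1L)) {
          gap <- substr(ps$surface, gc$end[k] - ps$start + 1L,
                        gc$start[k + 1L] - ps$start)
          gap_toks <- tokenize_text(gap)$surface
          if (any(gap_toks %in% conjunctions)) gap_has_conj <- TRUE
        }
        if (gap_has_conj) {
          rec(d, "conjunction_merge", ps, gc)
          next
        }
      }
      if (length(contained) &&
          (ps$start < min(g$start[contained]) ||
             ps$end > max(g$end[contained]))) {
        rec(d, "extra_information", ps, g[contained, , drop = FALSE])
        next
      }
      inside <- same[g$start[same] <= ps$start & g$end[same] >= ps$end]
      if (length(inside)) {
        rec(d, "missing_information", ps, g[inside[1L], , drop = FALSE])
        next
      }
      diff_type <- ov[g$label[ov] != ps$label]
      if (length(diff_type)) {
        rec(d, "different_entity_type", ps, g[diff_type[1L], , drop = FALSE])
        next
      }
      rec(d, "uncategorized", ps, g[ov, , drop = FALSE])
    }
  }
  if (!length(out)) {
    return(data.frame(doc = character(), category = character(),
                      pred_label = character(), pred_surface = character(),
                      gold_labels = character(), gold_surfaces = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Token-level tagging accuracy
#'
#' Secondary diagnostic: fraction of tokens whose predicted BIO tag equals
#' the gold tag.
#'
#' @param gold,pred equal-length BIO tag vectors.
#' @return accuracy in [0, 1].
#' @export
tag_accuracy <- function(gold, pred) {
  if (length(gold) != length(pred)) stopf("tag vectors differ in length")
  if (!length(gold)) return(NA_real_)
  mean(gold == pred)
}
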