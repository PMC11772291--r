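# Label-dependency layer: transition scores over BIO tags with Viterbi
# decoding, plus an optional linear-chain CRF negative log-likelihood for
# training the transitions. This simulates a CRF as an additional layer of
# weights modelling NER label dependencies.

#' BIO transition constraint matrix
#'
#' Square score matrix over the BIO labels plus start/stop states. Entries
#' are 0 for admissible bigrams and a large negative score for structurally
#' invalid ones (an \code{I-x} tag may only follow \code{B-x} or \code{I-x};
#' a sentence may not start with \code{I-x}).
#'
#' @param labels character vector of BIO labels (the class set C).
#' @param forbid score assigned to invalid transitions.
#' @return (|C|+2) x (|C|+2) matrix; rows = from, cols = to; the last two
#'   indices are the start and stop states.
#' @export
bio_transition_matrix <- function(labels, forbid = -1e4) {
  C <- length(labels)
  M <- matrix(0, C + 2L, C + 2L,
              dimnames = list(c(labels, "<start>", "<stop>"),
                              c(labels, "<start>", "<stop>")))
  pre <- tag_prefix(labels)
  typ <- tag_type(labels)
  for (j in seq_len(C)) {
    if (pre[j] != "I") next
    ok_from <- which(pre %in% c("B", "I") & typ == typ[j])
    bad <- setdiff(seq_len(C), ok_from)
    M[bad, j] <- forbid
    M[C + 1L, j] <- forbid               # cannot open a sentence with I-
  }
  M[, C + 1L] <- forbid                  # nothing transitions into start
  M[C + 2L, ] <- forbid                  # nothing leaves stop
  M
}

#' Viterbi decoding
#'
#' Returns the label sequence maximising the sum of per-token emission
#' scores and label-bigram transition scores (including start/stop
#' transitions). Ties break deterministically toward the lowest label index.
#'
#' @param emissions n x |C| matrix of per-token label scores.
#' @param transitions (|C|+2) x (|C|+2) transition matrix as produced by
#'   [bio_transition_matrix()] (possibly plus learned weights).
#' @return integer vector of decoded label indices (1-based into C).
#' @export
viterbi_decode <- function(emissions, transitions) {
  n <- nrow(emissions)
  if (n == 0L) stopf("empty emission matrix")
  C <- ncol(emissions)
  stopifnot(nrow(transitions) == C + 2L)
  start <- C + 1L; stop_s <- C + 2L
  delta <- transitions[start, seq_len(C)] + emissions[1L, ]
  back <- matrix(0L, n, C)
  if (n > 1L) {
    Tm <- transitions[seq_len(C), seq_len(C)]
    for (t in 2:n) {
      cand <- delta + Tm                 # cand[i, j] = delta_i + T[i -> j]
      best <- apply(cand, 2L, which.max) # first max = lowest index tie-break
      delta <- cand[cbind(best, seq_len(C))] + emissions[t, ]
      back[t, ] <- best
    }
  }
  final <- delta + transitions[seq_len(C), stop_s]
  path <- integer(n)
  path[n] <- which.max(final)
  if (n > 1L) {
    for (t in n:2) path[t - 1L] <- back[t, path[t]]
  }
  path
}

# Linear-chain CRF negative log-likelihood with gradients.
# emissions: n x C; trans: (C+2)^2; tags: integer gold indices.
# Returns loss, d_emissions, d_trans (gradient only over label-label,
# start->label and label->stop entries).
crf_nll_grad <- function(emissions, trans, tags) {
  n <- nrow(emissions); C <- ncol(emissions)
  start <- C + 1L; stop_s <- C + 2L
  Tm <- trans[seq_len(C), seq_len(C)]
  # forward (alpha) and backward (beta) in log space
  alpha <- matrix(-Inf, n, C)
  alpha[1L, ] <- trans[start, seq_len(C)] + emissions[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      for (j in seq_len(C)) {
        alpha[t, j] <- logsumexp(alpha[t - 1L, ] + Tm[, j]) + emissions[t, j]
      }
    }
  }
  logZ <- logsumexp(alpha[n, ] + trans[seq_len(C), stop_s])
  beta <- matrix(-Inf, n, C)
  beta[n, ] <- trans[seq_len(C), stop_s]
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      for (i in seq_len(C)) {
        beta[t, i] <- logsumexp(Tm[i, ] + emissions[t + 1L, ] + beta[t + 1L, ])
      }
    }
  }
  # gold path score
  score <- trans[start, tags[1L]] + sum(emissions[cbind(seq_len(n), tags)]) +
    trans[tags[n], stop_s]
  if (n > 1L) score <- score + sum(Tm[cbind(tags[-n], tags[-1L])])
  loss <- logZ - score
  # unary marginals
  marg <- exp(alpha + beta - logZ)
  d_em <- marg
  d_em[cbind(seq_len(n), tags)] <- d_em[cbind(seq_len(n), tags)] - 1
  # pairwise marginals for transition gradient
  d_tr <- matrix(0, C + 2L, C + 2L)
  if (n > 1L) {
    for (t in seq_len(n - 1L)) {
      lp <- outer(alpha[t, ], rep(1, C)) + Tm +
        outer(rep(1, C), emissions[t + 1L, ] + beta[t + 1L, ]) - logZ
      d_tr[seq_len(C), seq_len(C)] <- d_tr[seq_len(C), seq_len(C)] + exp(lp)
      d_tr[tags[t], tags[t + 1L]] <- d_tr[tags[t], tags[t + 1L]] - 1
    }
  }
  d_tr[start, seq_len(C)] <- exp(alpha[1L, ] + beta[1L, ] - logZ)
  d_tr[start, tags[1L]] <- d_tr[start, tags[1L]] - 1
  d_tr[seq_len(C), stop_s] <- exp(alpha[n, ] + trans[seq_len(C), stop_s] -
                                    logZ)
  d_tr[tags[n], stop_s] <- d_tr[tags[n], stop_s] - 1
  list(loss = loss, d_emissions = d_em, d_trans = d_tr)
}
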