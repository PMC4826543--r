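#' Area under the ROC curve
#'
#' Computed as the Mann–Whitney statistic with half credit for ties
#' (equivalent to the trapezoidal area under the empirical ROC curve).
#'
#' @param scores Numeric prediction scores, larger meaning more positive.
#' @param labels Logical or 0/1 vector of true classes (`TRUE`/1 positive).
#' @return AUROC in `[0, 1]`; 0.5 when scores carry no information.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average precision: the stepwise-interpolated area, summing precision at
#' each positive retrieved times the recall increment, descending the score
#' ordering (ties grouped).
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0L || sum(!labels) == 0L) stop("both classes must be present")
  agg <- stats::aggregate(cbind(tp = labels, n = rep(1L, length(labels))),
                          by = list(score = scores), FUN = sum)
  agg <- agg[order(-agg$score), ]
  tp <- cumsum(agg$tp)
  fp <- cumsum(agg$n - agg$tp)
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}

#' Grey-zone precision, recall and accuracy of designed-peptide predictions
#'
#' Compares predicted reactivity classes (H/L) with measured intensities
#' around a two-sided cutoff `center ± delta` (fluorescence units; default
#' center 5500, the middle of the unlabeled 1,000–10,000 band). Peptides
#' whose measurements fall inside the grey zone `[center - delta, center +
#' delta]` are excluded from both numerator and denominator; among the rest,
#' the true class is high iff intensity strictly exceeds `center + delta`.
#' At `delta = 0` every measurement counts; at `delta = 4500` the grey zone
#' is exactly the open band (1000, 10000).
#'
#' @param intensities Measured signal intensities.
#' @param predicted Predicted classes, `"H"` or `"L"`.
#' @param center Cutoff center (default 5500).
#' @param delta Half-width of the grey zone, `0 <= delta <= center - 1`.
#' @return A one-row `data.frame`: `delta`, `precision`, `recall`,
#'   `accuracy`, `excluded_fraction`, `n_used`. Metrics are `NA` (with a
#'   warning) when every peptide is excluded; precision is `NA` when
#'   nothing is predicted H among the retained peptides.
#' @export
delta_metrics <- function(intensities, predicted, center = 5500, delta = 0) {
  stopifnot(delta >= 0, delta <= center - 1,
            all(predicted %in% c("H", "L")),
            length(intensities) == length(predicted))
  keep <- intensities < center - delta | intensities > center + delta
  excluded_fraction <- 1 - mean(keep)
  if (!any(keep)) {
    warning("all peptides fall in the grey zone; metrics undefined")
    return(data.frame(delta = delta, precision = NA_real_, recall = NA_real_,
                      accuracy = NA_real_,
                      excluded_fraction = excluded_fraction, n_used = 0L))
  }
  truth_high <- intensities[keep] > center + delta
  pred_high <- predicted[keep] == "H"
  tp <- sum(pred_high & truth_high)
  precision <- if (sum(pred_high)) tp / sum(pred_high) else NA_real_
  recall <- if (sum(truth_high)) tp / sum(truth_high) else NA_real_
  accuracy <- mean(pred_high == truth_high)
  data.frame(delta = delta, precision = precision, recall = recall,
             accuracy = accuracy, excluded_fraction = excluded_fraction,
             n_used = sum(keep))
}

#' @rdname delta_metrics
#' @param deltas Numeric grid of grey-zone half-widths.
#' @return For `delta_metrics_curve`, one row per `delta`.
#' @export
delta_metrics_curve <- function(intensities, predicted, center = 5500,
                                deltas = seq(0, center - 1000, length.out = 50)) {
  do.call(rbind, lapply(deltas, function(d) {
    delta_metrics(intensities, predicted, center, d)
  }))
}

#' Permutation test of the F1 score of H-class predictions
#'
#' Computes the F1 score treating H as the positive class, then permutes the
#' true labels `B` times (default 1000) and reports the one-sided p-value
#' `(1 + #{permuted F1 >= observed}) / (B + 1)`, which can never fall below
#' `1 / (B + 1)`.
#'
#' @param predicted Predicted classes (`"H"`/`"L"`).
#' @param truth True classes (`"H"`/`"L"` or logical, `TRUE` = high).
#' @param B Number of permutations.
#' @param rng_seed Integer seed.
#' @return A `permutation_test_result` list: `observed_f1`, `permuted_f1`,
#'   `B`, `p_value`.
#' @export
permutation_f1_pvalue <- function(predicted, truth, B = 1000L, rng_seed = 1L) {
  if (is.character(truth) || is.factor(truth)) truth <- truth == "H"
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2L) stop("both classes must be present in truth")
  pred_high <- predicted == "H"
  f1 <- function(tr) {
    tp <- sum(pred_high & tr)
    if (tp == 0L) return(0)
    p <- tp / sum(pred_high)
    r <- tp / sum(tr)
    2 * p * r / (p + r)
  }
  if (!any(pred_high) || all(pred_high)) {
    warning("degenerate one-class prediction; F1 taken as 0")
  }
  observed <- f1(truth)
  rng <- local_rng(rng_seed)
  permuted <- vapply(seq_len(B), function(i) {
    f1(with_rng(rng, sample(truth)))
  }, numeric(1))
  p_value <- (1 + sum(permuted >= observed)) / (B + 1)
  structure(list(observed_f1 = observed, permuted_f1 = permuted, B = B,
                 p_value = p_value),
            class = "permutation_test_result")
}

#' Hamming distance between equal-length sequences
#'
#' @param p1,p2 Sequences of equal length.
#' @return Number of disagreeing positions.
#' @export
hamming <- function(p1, p2) {
  if (nchar(p1) != nchar(p2)) stop("Hamming distance needs equal lengths")
  sum(strsplit(p1, "", fixed = TRUE)[[1]] != strsplit(p2, "", fixed = TRUE)[[1]])
}

hamming_matrix <- function(sequences) {
  chars <- seq_char_matrix(sequences)
  n <- nrow(chars)
  D <- matrix(0L, n, n)
  for (j in seq_len(ncol(chars))) {
    D <- D + outer(chars[, j], chars[, j], "!=")
  }
  D
}

#' Sequence-diversity profile via maximal independent sets
#'
#' For each Hamming cutoff `c`, connects two peptides when their distance is
#' strictly below `c`, then for every vertex grows a maximal independent set
#' seeded at that vertex (greedily, visiting the remaining vertices in
#' ascending id order) and reports the mean of the n set sizes. Mutually
#' distant sets keep a mean of n until `c` exceeds the minimum pairwise
#' distance; similar sets collapse early.
#'
#' @param sequences Equal-length peptide sequences.
#' @param cutoffs Integer vector of Hamming cutoffs `c`.
#' @param ids Optional ids fixing the greedy visit order (default input
#'   order).
#' @return `data.frame` with `cutoff` and `mean_mis_size`.
#' @export
diversity_profile <- function(sequences, cutoffs = 1:15, ids = NULL) {
  n <- length(sequences)
  if (is.null(ids)) ids <- paste0("p", seq_len(n))
  visit <- order(ids)
  D <- hamming_matrix(sequences)
  out <- vapply(cutoffs, function(cc) {
    adj <- D < cc
    diag(adj) <- FALSE
    sizes <- vapply(seq_len(n), function(v) {
      set <- v
      for (u in visit) {
        if (u != v && !any(adj[u, set])) set <- c(set, u)
      }
      length(set)
    }, numeric(1))
    mean(sizes)
  }, numeric(1))
  data.frame(cutoff = cutoffs, mean_mis_size = out)
}

#' Positional residue-propensity matrix
#'
#' Position-specific residue frequencies of a true-positive peptide set
#' divided by those of a negative set, with a pseudocount added to both so
#' all ratios are finite and positive; a value of 1 means no enrichment.
#'
#' @param true_positives,negatives Character vectors of equal-length
#'   peptides (both non-empty).
#' @param alphabet A [peptide_alphabet()].
#' @param pseudocount Added to every per-position frequency; default
#'   `1 / (n_tp + alphabet size)`.
#' @return Numeric matrix, positions x residues, class `propensity_matrix`.
#' @export
propensity_matrix <- function(true_positives, negatives,
                              alphabet = peptide_alphabet(),
                              pseudocount = NULL) {
  stopifnot(length(true_positives) > 0, length(negatives) > 0)
  syms <- unclass(alphabet)
  if (is.null(pseudocount)) {
    pseudocount <- 1 / (length(true_positives) + length(syms))
  }
  pwm <- function(seqs) {
    chars <- seq_char_matrix(seqs)
    t(apply(chars, 2L, function(col) {
      tabulate(factor(col, levels = syms), nbins = length(syms)) / length(col)
    }))
  }
  tp <- pwm(true_positives)
  ng <- pwm(negatives)
  if (ncol(seq_char_matrix(true_positives)) != ncol(seq_char_matrix(negatives))) {
    stop("peptide sets must share one length")
  }
  m <- (tp + pseudocount) / (ng + pseudocount)
  dimnames(m) <- list(position = seq_len(nrow(m)), residue = syms)
  class(m) <- c("propensity_matrix", "matrix", "array")
  m
}
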