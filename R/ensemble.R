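#' Feature-vector builders ("featurizers") for SVM base classifiers
#'
#' A featurizer turns peptide records into a numeric feature matrix, with an
#' optional fit step that freezes corpus-dependent state at training time:
#'
#' * `featurizer_matrix(m)` — residue-matrix row concatenation
#'   ([encode_with_matrix()]).
#' * `featurizer_aaindex(table, cfg)` — AAIndex sliding-window block
#'   ([aaindex_feature_block()]).
#' * `featurizer_dock(n_bins)` — normalized docking-score histograms; the
#'   equal-width bin edges are fixed on the training corpus at fit time and
#'   reused for prediction ([dock_score_histogram()]).
#'
#' @param m A residue encoding matrix.
#' @param table An [aaindex_table()].
#' @param cfg A [window_feature_config()].
#' @param n_bins Number of histogram bins (default 20).
#' @name featurizers
NULL

#' @rdname featurizers
#' @export
featurizer_matrix <- function(m) {
  structure(list(type = "matrix", matrix = m), class = "featurizer")
}

#' @rdname featurizers
#' @export
featurizer_aaindex <- function(table = NULL, cfg = window_feature_config()) {
  structure(list(type = "aaindex", table = table, cfg = cfg),
            class = "featurizer")
}

#' @rdname featurizers
#' @export
featurizer_dock <- function(n_bins = 20L) {
  structure(list(type = "dock", n_bins = as.integer(n_bins), breaks = NULL),
            class = "featurizer")
}

fit_featurizer <- function(f, records, dock_scores = NULL) {
  if (f$type == "dock") {
    if (is.null(dock_scores)) stop("dock featurizer needs docking scores")
    f$breaks <- dock_score_bins(dock_scores[records$id], f$n_bins)
  }
  if (f$type == "aaindex" && is.null(f$table)) {
    f$table <- aaindex_table(quiet = TRUE)
  }
  f
}

apply_featurizer <- function(f, records, dock_scores = NULL) {
  switch(f$type,
    matrix = encode_with_matrix(records$sequence, f$matrix),
    aaindex = aaindex_feature_block(records$sequence, f$table, f$cfg),
    dock = {
      if (is.null(dock_scores)) stop("dock featurizer needs docking scores")
      missing <- setdiff(records$id, names(dock_scores))
      if (length(missing)) stop("no docking scores for: ",
                                paste(utils::head(missing, 5), collapse = ", "))
      t(vapply(dock_scores[records$id],
               dock_score_histogram, numeric(f$n_bins), breaks = f$breaks))
    })
}

#' Base classifier specification
#'
#' One member of the SVM ensemble: either a string kernel trained through a
#' precomputed Gram matrix, or a featurizer whose vectors feed a
#' radial-basis-function SVM. Hyperparameters are selected by grid search
#' with k-fold cross-validation; the conventional coarse log grids of the
#' libsvm tooling are the defaults.
#'
#' @param name Member name (used in reports and model bundles).
#' @param input A [kernel_spec()] or a [featurizers] object.
#' @param cost Candidate soft-margin costs C (default `2^seq(-5, 15, 2)`).
#' @param sigma Candidate RBF inverse-width parameters, used only for
#'   featurizer inputs (default `2^seq(-15, 3, 2)`).
#' @param cv_folds Cross-validation folds (default 5).
#' @return A `base_classifier_spec` list.
#' @export
base_classifier_spec <- function(name, input,
                                 cost = 2^seq(-5, 15, 2),
                                 sigma = 2^seq(-15, 3, 2),
                                 cv_folds = 5L) {
  stopifnot(length(cost) >= 1L, cv_folds >= 2L)
  structure(list(name = name, input = input,
                 cost = sort(cost), sigma = sort(sigma),
                 cv_folds = as.integer(cv_folds)),
            class = "base_classifier_spec")
}

#' Default ensemble member specifications
#'
#' The seven-member zoo: combined k-spectrum (k = 3..6), sparse spatial
#' sample (displacement <= 6), bounded-range substrings (r = 8), BLOSUM50
#' row encoding, two reduced physicochemical encodings (18- and 10-column),
#' the AAIndex local-composition window block, and — only when docking
#' scores are supplied to [train_ensemble()] — a docking-score histogram
#' member.
#'
#' @param cost,sigma,cv_folds Passed to every [base_classifier_spec()].
#' @param aaindex_cfg [window_feature_config()] for the local-composition
#'   member.
#' @param include Character subset of member names to keep.
#' @return Named list of `base_classifier_spec`s.
#' @export
default_member_specs <- function(cost = 2^seq(-5, 15, 2),
                                 sigma = 2^seq(-15, 3, 2),
                                 cv_folds = 5L,
                                 aaindex_cfg = window_feature_config(),
                                 include = NULL) {
  aai <- aaindex_table(quiet = TRUE)
  specs <- list(
    k_spectrum = base_classifier_spec("k_spectrum", kernel_spec("spectrum", k = 3:6),
                                      cost = cost, cv_folds = cv_folds),
    sssk = base_classifier_spec("sssk", kernel_spec("sssk", max_displacement = 6L),
                                cost = cost, cv_folds = cv_folds),
    bounded_range = base_classifier_spec("bounded_range", kernel_spec("bounded_range", r = 8L),
                                         cost = cost, cv_folds = cv_folds),
    blosum = base_classifier_spec("blosum", featurizer_matrix(blosum50_encoding()),
                                  cost = cost, sigma = sigma, cv_folds = cv_folds),
    nlf_style = base_classifier_spec("nlf_style", featurizer_matrix(nlf_style_encoding(aai)),
                                     cost = cost, sigma = sigma, cv_folds = cv_folds),
    sa_style = base_classifier_spec("sa_style", featurizer_matrix(sa_style_encoding(aai)),
                                    cost = cost, sigma = sigma, cv_folds = cv_folds),
    local_composition = base_classifier_spec("local_composition",
                                             featurizer_aaindex(aai, aaindex_cfg),
                                             cost = cost, sigma = sigma,
                                             cv_folds = cv_folds),
    structure = base_classifier_spec("structure", featurizer_dock(),
                                     cost = cost, sigma = sigma, cv_folds = cv_folds)
  )
  if (!is.null(include)) specs <- specs[include]
  specs
}

# Stratified fold assignment, deterministic under the rng stream.
cv_fold_ids <- function(y, folds, rng) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- with_rng(rng, sample(idx))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Train one base classifier
#'
#' Runs the grid search with stratified k-fold cross-validation, selects the
#' grid point with maximal fold-averaged accuracy (ties break toward smaller
#' cost, then smaller sigma), refits on the full training set at that point
#' with Platt-style probability calibration, and records the winning
#' cross-validation accuracy as the member's ensemble weight.
#'
#' @param spec A [base_classifier_spec()].
#' @param records Training records (`sequence`, `label` in
#'   positive/negative, `id`).
#' @param seed Integer seed controlling fold assignment and calibration.
#' @param dock_scores Named list (id -> numeric vector) for dock featurizers.
#' @return A `trained_base_classifier`: `spec`, fitted `model`,
#'   `cv_accuracy`, selected `cost`/`sigma`, plus the state needed to score
#'   new peptides (training sequences for kernels, fitted featurizer for
#'   vectors).
#' @export
train_base_classifier <- function(spec, records, seed = 1L,
                                  dock_scores = NULL) {
  y <- factor(records$label, levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2L) stop("training set must contain both classes")
  rng <- local_rng(seed)
  fold <- cv_fold_ids(y, spec$cv_folds, rng)
  is_kernel <- inherits(spec$input, "kernel_spec")

  if (is_kernel) {
    K <- build_kernel_matrix(records$sequence, spec$input)
    if (all(K == 0)) stop("degenerate all-zero kernel matrix")
    grid <- data.frame(cost = spec$cost, sigma = NA_real_)
    acc_fun <- function(g, tr, va) {
      m <- kernlab::ksvm(kernlab::as.kernelMatrix(K[tr, tr, drop = FALSE]),
                         y[tr], kernel = "matrix", C = g$cost, type = "C-svc")
      Kva <- K[va, tr, drop = FALSE][, kernlab::SVindex(m), drop = FALSE]
      mean(kernlab::predict(m, kernlab::as.kernelMatrix(Kva)) == y[va])
    }
  } else {
    featurizer <- fit_featurizer(spec$input, records, dock_scores)
    X <- apply_featurizer(featurizer, records, dock_scores)
    grid <- expand.grid(sigma = spec$sigma, cost = spec$cost)[, c("cost", "sigma")]
    grid <- grid[order(grid$cost, grid$sigma), ]
    acc_fun <- function(g, tr, va) {
      m <- kernlab::ksvm(X[tr, , drop = FALSE], y[tr], kernel = "rbfdot",
                         kpar = list(sigma = g$sigma), C = g$cost,
                         type = "C-svc", scaled = FALSE)
      mean(kernlab::predict(m, X[va, , drop = FALSE]) == y[va])
    }
  }

  cv_acc <- vapply(seq_len(nrow(grid)), function(gi) {
    mean(vapply(seq_len(spec$cv_folds), function(f) {
      tr <- which(fold != f); va <- which(fold == f)
      acc_fun(grid[gi, ], tr, va)
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(cv_acc)  # grid ordered cost asc, sigma asc: ties break small

  model <- with_rng(rng, {
    if (is_kernel) {
      kernlab::ksvm(kernlab::as.kernelMatrix(K), y, kernel = "matrix",
                    C = grid$cost[best], type = "C-svc", prob.model = TRUE)
    } else {
      kernlab::ksvm(X, y, kernel = "rbfdot",
                    kpar = list(sigma = grid$sigma[best]), C = grid$cost[best],
                    type = "C-svc", scaled = FALSE, prob.model = TRUE)
    }
  })

  structure(list(spec = spec, model = model,
                 cv_accuracy = cv_acc[best],
                 cost = grid$cost[best], sigma = grid$sigma[best],
                 train_sequences = if (is_kernel) records$sequence,
                 featurizer = if (!is_kernel) featurizer,
                 is_kernel = is_kernel),
            class = "trained_base_classifier")
}

#' Posterior positive-class probabilities from one trained member
#'
#' @param object A `trained_base_classifier`.
#' @param records Peptide records (or a bare character vector of sequences).
#' @param dock_scores Named list of docking scores for dock members.
#' @param ... Unused.
#' @return Numeric vector in `[0, 1]`, one probability per peptide, in input
#'   order.
#' @export
predict_probability <- function(object, records, dock_scores = NULL, ...) {
  if (is.character(records)) {
    records <- data.frame(id = paste0("q", seq_along(records)),
                          sequence = records, stringsAsFactors = FALSE)
  }
  if (object$is_kernel) {
    K <- build_kernel_matrix(records$sequence, object$spec$input,
                             sequences2 = object$train_sequences)
    K <- K[, kernlab::SVindex(object$model), drop = FALSE]
    p <- kernlab::predict(object$model, kernlab::as.kernelMatrix(K),
                 type = "probabilities")
  } else {
    X <- apply_featurizer(object$featurizer, records, dock_scores)
    p <- kernlab::predict(object$model, X, type = "probabilities")
  }
  unname(p[, "positive"])
}

#' Combine member probabilities into the ensemble posterior
#'
#' The ensemble posterior for one peptide is the accuracy-weighted mean of
#' its members' calibrated probabilities,
#' `p_ens = (1/A) * sum_j a_j p_j` with `A = sum_j a_j`, a convex
#' combination bounded by the member minimum and maximum.
#'
#' @param probs Numeric vector (one peptide) or matrix (peptides x members)
#'   of member probabilities.
#' @param weights Positive member weights `a_j` (cross-validation
#'   accuracies).
#' @return Ensemble probability (vector over peptides).
#' @examples
#' combine_ensemble(c(0.2, 0.8), c(1, 1))      # 0.5
#' combine_ensemble(c(1, 0), c(0.9, 0.6))      # 0.6
#' @export
combine_ensemble <- function(probs, weights) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1L)
  if (ncol(probs) != length(weights)) stop("one weight per member required")
  if (any(weights <= 0)) stop("weights must be positive")
  drop(probs %*% weights) / sum(weights)
}

#' Hard class call from the ensemble posterior
#'
#' @param p Ensemble probabilities in `[0, 1]`.
#' @param tau Decision threshold (default 0.5); the boundary is inclusive:
#'   `p >= tau` is called positive.
#' @return Character vector `"positive"` / `"negative"`.
#' @export
classify <- function(p, tau = 0.5) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p >= tau, "positive", "negative")
}

#' Rank test peptides by standardized weighted member scores
#'
#' For rank-ordered candidate lists the member probability vectors are first
#' scaled to unit standard deviation over the test set (a member whose
#' scores have zero variance is skipped with a warning), then combined with
#' the accuracy weights. Sorted descending; ties break by peptide id so the
#' ordering is reproducible.
#'
#' @param probs Matrix of member probabilities (peptides x members).
#' @param weights Member weights `a_j`.
#' @param ids Peptide ids (rownames of `probs` when `NULL`).
#' @return `data.frame` with `id` and `score`, ordered best-first.
#' @export
rank_predictions <- function(probs, weights, ids = rownames(probs)) {
  if (nrow(probs) < 2L) stop("ranking needs at least two peptides")
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(probs)))
  sds <- apply(probs, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance member(s) skipped in ranking")
  }
  if (!any(keep)) stop("no member with score variance; cannot rank")
  z <- sweep(probs[, keep, drop = FALSE], 2L, sds[keep], "/")
  score <- drop(z %*% weights[keep]) / sum(weights[keep])
  ord <- order(-score, ids)
  data.frame(id = ids[ord], score = score[ord], stringsAsFactors = FALSE)
}

#' Train the full ensemble
#'
#' Trains every member spec on the training records, records each member's
#' cross-validation accuracy `a_j` as its weight, and stores the decision
#' threshold `tau`. A `structure` (dock) member is trained only when docking
#' scores are supplied; otherwise it is dropped and the remaining weights
#' renormalize implicitly through `A`.
#'
#' @param records Training records with both classes.
#' @param specs Named list of [base_classifier_spec()]s
#'   (default [default_member_specs()]).
#' @param seed Integer seed; member j trains with `seed + j - 1`.
#' @param tau Decision threshold in (0, 1).
#' @param dock_scores Optional named list of docking-score vectors.
#' @return An `ensemble_model`: `members`, `weights`, `A`, `tau`.
#' @export
train_ensemble <- function(records, specs = default_member_specs(),
                           seed = 1L, tau = 0.5, dock_scores = NULL) {
  stopifnot(tau > 0, tau < 1)
  needs_dock <- vapply(specs, function(s) {
    !inherits(s$input, "kernel_spec") && s$input$type == "dock"
  }, logical(1))
  if (is.null(dock_scores) && any(needs_dock)) {
    message("no docking scores supplied; dropping member(s): ",
            paste(names(specs)[needs_dock], collapse = ", "))
    specs <- specs[!needs_dock]
  }
  if (!length(specs)) stop("no members to train")
  members <- vector("list", length(specs))
  names(members) <- names(specs)
  for (j in seq_along(specs)) {
    members[[j]] <- train_base_classifier(specs[[j]], records,
                                          seed = seed + j - 1L,
                                          dock_scores = dock_scores)
  }
  weights <- vapply(members, `[[`, numeric(1), "cv_accuracy")
  structure(list(members = members, weights = weights,
                 A = sum(weights), tau = tau),
            class = "ensemble_model")
}

#' @exportS3Method base::print
print.ensemble_model <- function(x, ...) {
  cat("ensemble_model with", length(x$members), "members (tau =", x$tau, ")\n")
  for (nm in names(x$members)) {
    m <- x$members[[nm]]
    cat(sprintf("  %-18s a=%.4f  C=%g%s\n", nm, m$cv_accuracy, m$cost,
                if (is.na(m$sigma)) "" else sprintf("  sigma=%g", m$sigma)))
  }
  invisible(x)
}

#' Score peptides with a trained ensemble
#'
#' @param model An `ensemble_model`.
#' @param records Peptide records or a character vector of sequences.
#' @param dock_scores Docking scores for dock members, if any.
#' @return A list: `member_probs` (matrix peptides x members), `ensemble`
#'   (combined posterior), `class` (threshold calls at the model's `tau`).
#' @export
predict_ensemble <- function(model, records, dock_scores = NULL) {
  member_probs <- vapply(model$members, predict_probability,
                         numeric(if (is.character(records)) length(records) else nrow(records)),
                         records = records, dock_scores = dock_scores)
  if (is.vector(member_probs)) member_probs <- matrix(member_probs, nrow = 1L,
                                                      dimnames = list(NULL, names(model$members)))
  p <- combine_ensemble(member_probs, model$weights)
  list(member_probs = member_probs, ensemble = p,
       class = classify(p, model$tau))
}
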