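test_that("the ensemble combination is the weighted convex mean", {
  expect_equal(combine_ensemble(c(0.2, 0.8), c(1, 1)), 0.5)
  expect_equal(combine_ensemble(c(1.0, 0.0), c(0.9, 0.6)), 0.6)
  set.seed(2)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    p <- runif(m); a <- runif(m, 0.1, 1)
    v <- combine_ensemble(p, a)
    expect_gte(v, min(p)); expect_lte(v, max(p))
    expect_equal(combine_ensemble(rep(0.37, m), a), 0.37)
  }
  expect_error(combine_ensemble(c(0.1, 0.9), c(1, 1, 1)), "one weight per member")
})

test_that("the decision rule is boundary-inclusive at tau", {
  expect_equal(classify(0.5, 0.5), "positive")
  expect_equal(classify(0.49, 0.5), "negative")
  expect_true(all(classify(runif(20), 0) == "positive"))
})

test_that("SD-1 ranking is monotone, weight-scale invariant and id-tie-broken", {
  set.seed(3)
  probs <- cbind(a = runif(10), b = runif(10))
  ids <- sprintf("p%02d", 1:10)
  r1 <- rank_predictions(probs[, 1, drop = FALSE], 0.8, ids)
  expect_equal(r1$id, ids[order(-probs[, 1])])

  r <- rank_predictions(probs, c(0.9, 0.7), ids)
  r_scaled <- rank_predictions(probs, 10 * c(0.9, 0.7), ids)
  expect_equal(r$id, r_scaled$id)
  expect_equal(r$score, r_scaled$score)

  # two members with identical rankings preserve the common order
  probs2 <- cbind(probs[, 1], 2 * probs[, 1] + 1)
  r2 <- rank_predictions(probs2, c(0.5, 0.5), ids)
  expect_equal(r2$id, r1$id)

  const <- cbind(probs[, 1], rep(0.5, 10))
  expect_warning(rc <- rank_predictions(const, c(1, 1), ids), "zero-variance")
  expect_equal(rc$id, r1$id)

  tied <- cbind(rep(c(0.8, 0.2), each = 5))
  rt <- rank_predictions(tied, 1, ids)
  expect_equal(rt$id[1:5], ids[1:5])  # ties resolved by ascending id
})

test_that("base classifiers reach ~1 CV accuracy on separable data and ~0.5 on noise", {
  sp <- small_split(40, 40, seed = 19)
  spec <- small_member_specs("k_spectrum")[[1]]
  fit <- train_base_classifier(spec, sp$train, seed = 4)
  expect_gte(fit$cv_accuracy, 0.95)
  p_train <- predict_probability(fit, sp$train)
  expect_true(all(p_train >= 0 & p_train <= 1))
  expect_gte(mean(p_train[sp$train$label == "positive"] > 0.8), 0.9)

  shuffled <- sp$train
  set.seed(8)
  shuffled$label <- sample(shuffled$label)
  fit0 <- train_base_classifier(spec, shuffled, seed = 4)
  expect_lt(abs(fit0$cv_accuracy - 0.5), 0.15)  # binomial error at n = 80
})

test_that("base training is seed-deterministic and rejects degenerate input", {
  sp <- small_split(20, 20, seed = 23)
  spec <- small_member_specs("blosum")[[1]]
  f1 <- train_base_classifier(spec, sp$train, seed = 5)
  f2 <- train_base_classifier(spec, sp$train, seed = 5)
  expect_identical(f1$cost, f2$cost)
  expect_identical(f1$cv_accuracy, f2$cv_accuracy)
  expect_equal(predict_probability(f1, sp$test), predict_probability(f2, sp$test))

  onecls <- sp$train[sp$train$label == "positive", ]
  expect_error(train_base_classifier(spec, onecls, seed = 1), "both classes")
})

test_that("member probabilities are order-preserving and duplicate-consistent", {
  sp <- small_split(20, 20, seed = 29)
  fit <- train_base_classifier(small_member_specs("sssk")[[1]], sp$train, seed = 2)
  seqs <- c(sp$test$sequence[1:4], sp$test$sequence[2])
  p <- predict_probability(fit, seqs)
  expect_length(p, 5L)
  expect_equal(p[5], p[2])
  expect_equal(p[1:4], predict_probability(fit, sp$test$sequence[1:4]))
})

test_that("the ensemble trains all members, weights by CV accuracy, and
           drops the dock member when no scores are given", {
  sp <- small_split(30, 60, seed = 37)
  specs <- small_member_specs(c("k_spectrum", "blosum", "structure"))
  expect_message(model <- train_ensemble(sp$train, specs, seed = 6),
                 "dropping member")
  expect_named(model$members, c("k_spectrum", "blosum"))
  expect_equal(model$A, sum(model$weights))
  pred <- predict_ensemble(model, sp$test)
  expect_true(all(pred$ensemble >= apply(pred$member_probs, 1, min) - 1e-12))
  expect_true(all(pred$ensemble <= apply(pred$member_probs, 1, max) + 1e-12))
  expect_equal(pred$class, classify(pred$ensemble, model$tau))
})

test_that("the dock-featurized member learns a separation planted in scores", {
  sp <- small_split(25, 25, seed = 41)
  ds_train <- generate_dock_scores(sp$train, separation = 3, rng_seed = 1,
                                   n_poses = 300)
  ds_test <- generate_dock_scores(sp$test, separation = 3, rng_seed = 2,
                                  n_poses = 300)
  model <- train_ensemble(sp$train, small_member_specs("structure"),
                          seed = 3, dock_scores = ds_train)
  pred <- predict_ensemble(model, sp$test, dock_scores = ds_test)
  expect_gte(auroc(pred$ensemble, sp$test$label == "positive"), 0.9)
})
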