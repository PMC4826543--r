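test_that("AUROC matches pairwise concordance and handles ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  set.seed(10)
  for (i in 1:5) {
    n <- sample(20:100, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    l <- runif(n) < 0.4
    if (!any(l) || all(l)) next
    expect_equal(auroc(s, l), naive_auroc(s, l))
  }
  # scores independent of labels hover near 0.5
  set.seed(11)
  s <- runif(4000); l <- runif(4000) < 0.5
  expect_lt(abs(auroc(s, l) - 0.5), 0.03)
})

test_that("AUPR is 1 for perfect separation and near prevalence for noise", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(12)
  s <- runif(4000); l <- runif(4000) < 0.25
  expect_lt(abs(aupr(s, l) - 0.25), 0.05)
})

test_that("grey-zone metrics reduce to plain threshold metrics at delta 0", {
  set.seed(13)
  intens <- runif(200, 0, 20000)
  pred <- ifelse(runif(200) < 0.5, "H", "L")
  m0 <- delta_metrics(intens, pred, delta = 0)
  truth <- intens > 5500
  ph <- pred == "H"
  expect_equal(m0$excluded_fraction, 0)
  expect_equal(m0$precision, sum(ph & truth) / sum(ph))
  expect_equal(m0$recall, sum(ph & truth) / sum(truth))
  expect_equal(m0$accuracy, mean(ph == truth))
})

test_that("the grey zone at delta 4500 is exactly the (1000, 10000) band", {
  intens <- c(999, 1000, 1001, 5500, 9999, 10000, 10001)
  pred <- rep("H", 7)
  m <- delta_metrics(intens, pred, delta = 4500)
  expect_equal(m$n_used, 2L)             # only 999 and 10001 lie outside [1000, 10000]
  expect_equal(m$excluded_fraction, 5 / 7)
  expect_equal(m$recall, 1)              # the single true high (10001) is called H
  expect_equal(m$precision, 1 / 2)       # 999 was also called H
})

test_that("perfect predictions score 1 at every delta; exclusion grows with delta", {
  intens <- c(runif(50, 0, 1000), runif(50, 10000, 30000))
  pred <- rep(c("L", "H"), each = 50)
  for (d in c(0, 2000, 4500)) {
    m <- delta_metrics(intens, pred, delta = d)
    expect_equal(m$precision, 1)
    expect_equal(m$recall, 1)
    expect_equal(m$accuracy, 1)
  }
  curve <- delta_metrics_curve(runif(100, 0, 11000), sample(c("H", "L"), 100, TRUE))
  expect_true(all(diff(curve$excluded_fraction) >= 0))
  expect_warning(m_all <- delta_metrics(rep(5500, 4), rep("H", 4), delta = 10),
                 "grey zone")
  expect_true(is.na(m_all$precision))
})

test_that("the permutation F1 p-value is bounded below and detects signal", {
  truth <- rep(c("H", "L"), each = 20)
  res <- permutation_f1_pvalue(truth, truth, B = 1000, rng_seed = 1)
  expect_equal(res$observed_f1, 1)
  expect_equal(res$p_value, 1 / 1001)
  expect_gte(res$p_value, 1 / (res$B + 1))

  res0 <- permutation_f1_pvalue(truth, truth, B = 0, rng_seed = 1)
  expect_equal(res0$p_value, 1)

  expect_warning(
    deg <- permutation_f1_pvalue(rep("L", 40), truth, B = 10, rng_seed = 1),
    "degenerate")
  expect_equal(deg$observed_f1, 0)
})

test_that("hamming counts disagreeing positions symmetrically", {
  expect_equal(hamming("ACDEF", "ACDEF"), 0)
  a <- random_peptides(1, 15, 71); b <- random_peptides(1, 15, 72)
  expect_equal(hamming(a, b), hamming(b, a))
  expect_equal(hamming(paste(rep("A", 15), collapse = ""),
                       paste(rep("C", 15), collapse = "")), 15)
  expect_error(hamming("AC", "ACD"), "equal lengths")
})

test_that("diversity profiles: distant sets span, identical peptides collapse", {
  # mutually distant: one repeated residue per peptide, pairwise distance 15
  distant <- vapply(CANONICAL_AA[1:8], function(a) {
    paste(rep(a, 15), collapse = "")
  }, character(1))
  prof <- diversity_profile(distant, cutoffs = c(1, 9, 15))
  expect_equal(prof$mean_mis_size, c(8, 8, 8))

  twins <- rep("ACDEFGHIKLMNPQR", 2)
  expect_equal(diversity_profile(twins, cutoffs = 1)$mean_mis_size, 1)

  set.seed(14)
  randset <- random_peptides(15, 15, 99)
  prof_r <- diversity_profile(randset, cutoffs = 1:15)
  expect_true(all(diff(prof_r$mean_mis_size) <= 1e-12))
})

test_that("propensity matrices are ratio-1 for identical sets and finite always", {
  seqs <- random_peptides(20, 15, 81)
  m <- propensity_matrix(seqs, seqs)
  expect_true(all(abs(m - 1) < 1e-12))

  tp <- rep(paste(rep("W", 15), collapse = ""), 5)
  ng <- rep(paste(rep("A", 15), collapse = ""), 5)
  m2 <- propensity_matrix(tp, ng)
  expect_true(all(is.finite(m2)))
  expect_true(all(m2[, "W"] > 1))
  expect_true(all(m2[, "A"] < 1))

  m3 <- propensity_matrix(sample(seqs), seqs)
  expect_equal(m3, propensity_matrix(seqs, seqs))
})
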