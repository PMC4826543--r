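test_that("k-mer indexing collects exactly the reference substrings", {
  idx <- build_kmer_index(list(high = "ACDEF"), kmer = 4)
  expect_setequal(idx$high, c("ACDE", "CDEF"))
  expect_length(build_kmer_index(list(high = character(0)), 4)$high, 0L)

  x <- c("ACDEFGHIKL"); y <- c("MNPQRSTVWY")
  both <- build_kmer_index(list(s = c(x, y)), 4)$s
  expect_setequal(both, union(build_kmer_index(list(s = x), 4)$s,
                              build_kmer_index(list(s = y), 4)$s))
})

test_that("the shared-k-mer rule fires on 4-mers but not on 3-mers", {
  idx <- build_kmer_index(list(high = "ACDEFGHIKL"), kmer = 4)
  expect_true(violates_shared_kmer("WWWACDEWWWWWWWW", idx, "high"))
  expect_false(violates_shared_kmer("WWWACDWWWWWWWWW", idx, "high"))  # 3-mer only
  expect_false(violates_shared_kmer("ZZZZZZZZZZZZZZZ", idx, "high"))
})

test_that("the window-identity rule counts matches in 11-windows at all offsets", {
  cons <- diversity_constraints()
  ref <- "ACDEFGHIKLMNPQR"
  # identical in 7 consecutive positions -> violation
  cand7 <- paste0("ACDEFGH", "WWYWYWYW")
  expect_true(violates_window_identity(cand7, ref, cons))
  # equal sequences always violate
  expect_true(violates_window_identity(ref, ref, cons))
  # at most 6 matches per window everywhere -> pass
  cand6 <- paste0("ACDEFG", "WYWYWYWYW")
  expect_false(violates_window_identity(cand6, ref, cons))
  # a shifted alignment can create the violating window
  shifted <- paste0("W", substr(ref, 1, 10), "WYWY")  # ref[1..10] at offset 1
  expect_true(violates_window_identity(shifted, ref, cons))
  # sequences shorter than the window compare over the whole overlap
  expect_true(violates_window_identity("ACDEFGHI", "ACDEFGHI", cons))
  expect_false(violates_window_identity("ACDEFG", "ACDEFG", cons))  # 6 <= 6
})

test_that("random walks stop at the first constraint-satisfying sequence", {
  seed_seq <- "ACDEFGHIKLMNPQR"
  empty_idx <- build_kmer_index(list(high = character(0), test = character(0)), 4)
  res <- random_walk_design(seed_seq, "high", empty_idx, list(character(0)))
  expect_equal(res$sequence, seed_seq)
  expect_equal(res$mutation_count, 0L)

  refs <- random_peptides(20, 15, 51)
  idx <- build_kmer_index(list(high = refs, test = character(0)), 4)
  r1 <- random_walk_design(seed_seq, "high", idx, list(refs), rng_seed = 9)
  r2 <- random_walk_design(seed_seq, "high", idx, list(refs), rng_seed = 9)
  expect_identical(r1$sequence, r2$sequence)
  expect_equal(nchar(r1$sequence), 15L)
  expect_true(naive_design_ok(r1$sequence, refs))
})

test_that("an unsatisfiable walk hits the mutation cap with an error", {
  ab <- peptide_alphabet(c("A", "C"))
  idx <- build_kmer_index(list(high = c("AAAA", "CCCC", "ACAC", "CACA",
                                        "AACC", "CCAA", "ACCA", "CAAC",
                                        "AAAC", "AACA", "ACAA", "CAAA",
                                        "CCCA", "CCAC", "CACC", "ACCC")), 4)
  expect_error(
    random_walk_design("AAAA", "high", idx, list(), rng_seed = 1,
                       alphabet = ab, max_mutations = 50),
    "exceeded 50 mutations")
})

test_that("campaigns produce the configured H/M/L split ordered by score", {
  sp <- small_split(30, 60, seed = 61)
  model <- train_ensemble(sp$train, small_member_specs("k_spectrum"), seed = 2)
  cand <- run_design_campaign(sp$train, sp$test$sequence, model,
                              n_high_seeds = 10, n_low_seeds = 10,
                              n_high = 5, n_low = 5, rng_seed = 3)
  expect_equal(as.integer(table(cand$class)[c("H", "M", "L")]), c(5L, 10L, 5L))
  expect_gte(min(cand$probability[cand$class == "H"]),
             max(cand$probability[cand$class == "M"]))
  expect_gte(min(cand$probability[cand$class == "M"]),
             max(cand$probability[cand$class == "L"]))
  expect_true(all(nchar(cand$sequence) == 15L))

  two <- run_design_campaign(sp$train, sp$test$sequence, model,
                             n_high_seeds = 1, n_low_seeds = 1,
                             n_high = 1, n_low = 1, rng_seed = 4)
  expect_setequal(two$class, c("H", "L"))
  expect_gte(two$probability[two$class == "H"],
             two$probability[two$class == "L"])
})

test_that("every campaign candidate passes the naive independent checker", {
  sp <- small_split(25, 50, seed = 67)
  model <- train_ensemble(sp$train, small_member_specs("sssk"), seed = 5)
  cand <- run_design_campaign(sp$train, sp$test$sequence, model,
                              n_high_seeds = 12, n_low_seeds = 12,
                              n_high = 6, n_low = 6, rng_seed = 6)
  ord <- order(-sp$train$intensity, sp$train$id)
  refs <- list(high = sp$train$sequence[ord[1:12]],
               low = sp$train$sequence[rev(ord)[1:12]],
               test = sp$test$sequence)
  for (i in seq_len(nrow(cand))) {
    expect_true(naive_design_ok(cand$sequence[i],
                                c(refs[[cand$seed_category[i]]], refs$test)))
  }
  expect_equal(verify_design_constraints(cand, refs), 0L)
})
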