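test_that("peptide tables read in file order without assigning labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tintensity",
               "ACDEFGHIKLMNPQR\t500",
               "STVWYACDEFGHIKL\t11000",
               "MNPQRSTVWYACDEF\t5000"), path)
  recs <- read_peptide_table(path)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$sequence[1], "ACDEFGHIKLMNPQR")
  expect_equal(recs$intensity, c(500, 11000, 5000))
  expect_true(all(recs$label == "unlabeled"))
})

test_that("the reader rejects residues outside the alphabet, naming the row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tintensity", "ACDEB\t100"), path)
  expect_error(read_peptide_table(path), "row 1.*B")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("seq\tintensity", "ACDEF\t100"), path2)
  expect_error(read_peptide_table(path2), "format error")
})

test_that("pool construction applies the intensity thresholds strictly", {
  recs <- data.frame(id = c("a", "b", "c"),
                     sequence = rep("ACDEFGHIKLMNPQR", 3),
                     intensity = c(500, 11000, 5000),
                     label = "unlabeled", stringsAsFactors = FALSE)
  pools <- build_pools(recs)
  expect_equal(pools$positive$id, "b")
  expect_equal(pools$negative$id, "a")
  expect_equal(pools$positive$label, "positive")

  recs$intensity <- c(0, 0, 0)
  pools0 <- build_pools(recs)
  expect_equal(nrow(pools0$negative), 3L)
  expect_equal(nrow(pools0$positive), 0L)
})

test_that("the replicate rule requires every replicate below threshold", {
  recs <- data.frame(id = c("a", "b"), sequence = rep("ACDEFGHIKLMNPQR", 2),
                     intensity = c(990, 500),
                     r1 = c(900, 400), r2 = c(900, 500), r3 = c(1200, 600),
                     label = "unlabeled", stringsAsFactors = FALSE)
  pools <- build_pools(recs, replicate_cols = c("r1", "r2", "r3"))
  expect_equal(pools$negative$id, "b")   # "a" has a 1200 replicate
  # rule off: aggregated intensity decides
  pools2 <- build_pools(recs, pool_config(replicate_rule = FALSE),
                        replicate_cols = c("r1", "r2", "r3"))
  expect_setequal(pools2$negative$id, c("a", "b"))
})

test_that("pool membership partitions records and ignores row order", {
  set.seed(42)
  recs <- data.frame(id = paste0("p", 1:50),
                     sequence = random_peptides(50, 15, 42),
                     intensity = exp(runif(50, log(100), log(50000))),
                     label = "unlabeled", stringsAsFactors = FALSE)
  pools <- build_pools(recs)
  expect_length(intersect(pools$positive$id, pools$negative$id), 0L)
  shuffled <- recs[sample(nrow(recs)), ]
  pools2 <- build_pools(shuffled)
  expect_setequal(pools$positive$id, pools2$positive$id)
  expect_setequal(pools$negative$id, pools2$negative$id)
})

test_that("train/test splits are disjoint, exhaustive and seed-deterministic", {
  sp0 <- small_split(30, 60, seed = 3)
  pos <- sp0$train[sp0$train$label == "positive", ]
  for (seed in c(1L, 9L, 123L)) {
    pool <- generate_pool(synthetic_config(n_pos = 30, n_neg = 60), seed)
    pools <- build_pools(pool)
    sp <- make_train_test_split(pools$positive, pools$negative, 10, 20, seed)
    expect_equal(nrow(sp$train), 30L)
    expect_equal(nrow(sp$test), 60L)
    expect_length(intersect(sp$train$id, sp$test$id), 0L)
    expect_setequal(c(sp$train$id, sp$test$id), pool$id)
    sp2 <- make_train_test_split(pools$positive, pools$negative, 10, 20, seed)
    expect_identical(sp$train$id, sp2$train$id)
  }
})

test_that("degenerate and invalid split requests are handled", {
  pool <- generate_pool(synthetic_config(n_pos = 5, n_neg = 5), 1)
  pools <- build_pools(pool)
  sp <- make_train_test_split(pools$positive, pools$negative, 0, 0, seed = 1)
  expect_equal(nrow(sp$train), 0L)
  expect_equal(nrow(sp$test), 10L)
  expect_error(make_train_test_split(pools$positive, pools$negative, 6, 0),
               "exceeds pool")
})

test_that("FASTA round-trips ids and sequences", {
  peps <- data.frame(id = paste0("pep", 1:100),
                     sequence = random_peptides(100, 15, 11),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(peps, path)
  back <- read_fasta(path)
  expect_identical(back$id, peps$id)
  expect_identical(back$sequence, peps$sequence)

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDEF", ">p1", "GHIKL"), dup)
  expect_warning(res <- read_fasta(dup), "duplicate")
  expect_equal(anyDuplicated(res$id), 0L)
})

test_that("encoding matrices and dock score files round-trip", {
  m <- matrix(rnorm(40), 20, 2, dimnames = list(CANONICAL_AA, c("c1", "c2")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_encoding_matrix(m, path)
  back <- read_encoding_matrix(path)
  expect_equal(back, m, tolerance = 1e-12)

  dpath <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2\t5.5", "1\t3.25", "3\t7.0"), dpath)
  expect_equal(read_dock_scores(dpath), c(3.25, 5.5, 7.0))
})
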