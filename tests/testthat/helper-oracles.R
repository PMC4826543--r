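# Independent brute-force oracles. These deliberately avoid the package's
# count-table machinery: kernels are evaluated by quadratic position-by-
# position comparison, AUROC by pairwise concordance, and the designer
# rules by direct substring scans.

all_substrings <- function(s, k) {
  d <- nchar(s)
  if (k > d) return(character(0))
  vapply(1:(d - k + 1), function(i) substr(s, i, i + k - 1), character(1))
}

naive_spectrum <- function(p1, p2, ks) {
  total <- 0
  for (k in ks) {
    s1 <- all_substrings(p1, k)
    s2 <- all_substrings(p2, k)
    for (a in s1) for (b in s2) if (a == b) total <- total + 1
  }
  total
}

naive_sssk <- function(p1, p2, dmax) {
  triples <- function(p) {
    a <- strsplit(p, "")[[1]]
    out <- character(0)
    for (i in seq_along(a)) for (j in seq_along(a)) {
      if (j > i && j - i <= dmax) out <- c(out, paste(a[i], j - i, a[j]))
    }
    out
  }
  t1 <- triples(p1); t2 <- triples(p2)
  total <- 0
  for (x in t1) for (y in t2) if (x == y) total <- total + 1
  total
}

naive_bounded_range <- function(p1, p2, r) {
  total <- 0
  for (L in 1:r) total <- total + naive_spectrum(p1, p2, L)
  total
}

naive_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Direct re-check of both designer rules by substring scans, no index.
naive_design_ok <- function(candidate, refs, kmer = 4, window = 11,
                            max_ident = 6) {
  for (ref in refs) {
    for (km in all_substrings(candidate, kmer)) {
      if (grepl(km, ref, fixed = TRUE)) return(FALSE)
    }
  }
  a <- strsplit(candidate, "")[[1]]
  for (ref in refs) {
    b <- strsplit(ref, "")[[1]]
    for (off in (-(length(a) - 1)):(length(b) - 1)) {
      i1 <- max(1, 1 - off); i2 <- min(length(a), length(b) - off)
      ov <- i2 - i1 + 1
      if (ov < window && ov < min(length(a), length(b))) next
      if (ov < 1) next
      w <- min(window, ov)
      for (s in i1:(i2 - w + 1)) {
        if (sum(a[s:(s + w - 1)] == b[(s + off):(s + off + w - 1)]) > max_ident) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

random_peptides <- function(n, len, seed, alphabet = peptide_alphabet()) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(unclass(alphabet), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Small, fast member zoo shared by ensemble-level tests: three string
# kernels plus one numeric encoding, tiny hyperparameter grids.
small_member_specs <- function(include = c("k_spectrum", "sssk",
                                           "bounded_range", "blosum")) {
  default_member_specs(cost = 2^c(0, 4), sigma = 2^c(-9, -5),
                       cv_folds = 3L,
                       aaindex_cfg = window_feature_config(
                         property_ids = c("KYTJ820101", "GRAR740102",
                                          "ZIMJ680104", "CHOC760101",
                                          "JANJ780101")),
                       include = include)
}

small_split <- function(n_pos = 60, n_neg = 120, seed = 7) {
  pool <- generate_pool(synthetic_config(n_pos = n_pos, n_neg = n_neg),
                        rng_seed = seed)
  pools <- build_pools(pool)
  make_train_test_split(pools$positive, pools$negative,
                        n_pos %/% 2, n_neg %/% 2, seed = seed)
}
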