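#' Diversity constraints for designed peptides
#'
#' Designed sequences must be genuinely novel: a candidate may not share any
#' k-mer (default 4-mer) with any same-category training sequence, and may
#' not match any reference — training same-category or withheld test set —
#' in more than `max_identities` (default 6) positions within any
#' `window`-length (default 11) stretch, at any ungapped alignment offset.
#'
#' @param kmer k-mer length for the shared-substring rule (default 4).
#' @param window Window length for the local-identity rule (default 11).
#' @param max_identities Maximum tolerated positional matches per window
#'   (default 6; more than this violates).
#' @return A `diversity_constraints` list.
#' @export
diversity_constraints <- function(kmer = 4L, window = 11L,
                                  max_identities = 6L) {
  stopifnot(max_identities < window, kmer <= window)
  structure(list(kmer = as.integer(kmer), window = as.integer(window),
                 max_identities = as.integer(max_identities)),
            class = "diversity_constraints")
}

#' Index the k-mers of reference sequence sets
#'
#' @param reference_sets Named list of character vectors of sequences, one
#'   per reactivity category (plus, conventionally, `"test"`).
#' @param kmer k-mer length.
#' @return A `kmer_index`: named list of k-mer sets.
#' @export
build_kmer_index <- function(reference_sets, kmer = 4L) {
  idx <- lapply(reference_sets, function(refs) {
    unique(unlist(lapply(refs, substrings_of, k = kmer), use.names = FALSE))
  })
  structure(idx, kmer = as.integer(kmer), class = "kmer_index")
}

#' Does a candidate share a k-mer with an indexed reference set?
#'
#' @param candidate Candidate sequence.
#' @param index A [build_kmer_index()].
#' @param category Which reference set to check against.
#' @return `TRUE` iff any k-mer of the candidate occurs in the set.
#' @export
violates_shared_kmer <- function(candidate, index, category) {
  kmers <- substrings_of(candidate, attr(index, "kmer"))
  any(kmers %in% index[[category]])
}

#' Does a candidate locally match a reference too closely?
#'
#' Slides the candidate along the reference at every ungapped offset with
#' overlap at least `window` long and counts positional identities in every
#' window of that length; more than `max_identities` matches anywhere is a
#' violation. Pairs whose maximal overlap is shorter than the window are
#' compared over the whole overlap.
#'
#' @param candidate Candidate sequence.
#' @param references Character vector of reference sequences.
#' @param constraints A [diversity_constraints()].
#' @return `TRUE` iff any reference exhibits a too-similar window.
#' @export
violates_window_identity <- function(candidate, references, constraints) {
  w <- constraints$window
  mx <- constraints$max_identities
  a <- strsplit(candidate, "", fixed = TRUE)[[1]]
  for (ref in references) {
    b <- strsplit(ref, "", fixed = TRUE)[[1]]
    la <- length(a); lb <- length(b)
    for (off in (-(la - 1)):(lb - 1)) {
      # candidate position i aligns with reference position i + off
      i1 <- max(1L, 1L - off); i2 <- min(la, lb - off)
      ov <- i2 - i1 + 1L
      if (ov < 1L) next
      eff_w <- min(w, ov)
      if (ov < w && ov < min(la, lb)) next  # partial overlaps shorter than
                                            # the window: only the full-overlap
                                            # comparison applies
      m <- as.integer(a[i1:i2] == b[(i1 + off):(i2 + off)])
      cs <- cumsum(c(0L, m))
      wins <- cs[(eff_w + 1):(ov + 1)] - cs[1:(ov - eff_w + 1)]
      if (any(wins > mx)) return(TRUE)
    }
  }
  FALSE
}

check_all_constraints <- function(candidate, category, index, window_refs,
                                  constraints) {
  if (violates_shared_kmer(candidate, index, category)) return(FALSE)
  if ("test" %in% names(index) &&
      violates_shared_kmer(candidate, index, "test")) return(FALSE)
  for (refs in window_refs) {
    if (length(refs) && violates_window_identity(candidate, refs, constraints)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Design one novel peptide by a constrained random walk
#'
#' Starts from a seed sequence and applies point substitutions — a uniform
#' random position, a uniform random replacement drawn from the alphabet
#' minus the current residue (citrulline included) — until the sequence
#' shares no k-mer with the same-category training references or the test
#' set and triggers no local-identity window against either, then stops at
#' that first satisfying sequence.
#'
#' @param seed_sequence Seed peptide (typically a training-set member of the
#'   target category).
#' @param category Reactivity category of the seed (a name in `index`).
#' @param index [build_kmer_index()] over training categories and `"test"`.
#' @param window_refs List of reference sequence vectors for the
#'   window-identity rule (same-category training refs and test set).
#' @param constraints [diversity_constraints()].
#' @param rng_seed Integer seed; equal seeds reproduce the candidate.
#' @param alphabet A [peptide_alphabet()].
#' @param max_mutations Iteration cap (default 10000).
#' @return A list: `sequence`, `seed_sequence`, `category`,
#'   `mutation_count`; or an error when the cap is exceeded.
#' @export
random_walk_design <- function(seed_sequence, category, index, window_refs,
                               constraints = diversity_constraints(),
                               rng_seed = 1L,
                               alphabet = peptide_alphabet(),
                               max_mutations = 10000L) {
  rng <- local_rng(rng_seed)
  syms <- unclass(alphabet)
  cur <- strsplit(seed_sequence, "", fixed = TRUE)[[1]]
  d <- length(cur)
  n_mut <- 0L
  repeat {
    cand <- paste(cur, collapse = "")
    if (check_all_constraints(cand, category, index, window_refs, constraints)) {
      return(list(sequence = cand, seed_sequence = seed_sequence,
                  category = category, mutation_count = n_mut))
    }
    if (n_mut >= max_mutations) {
      stop(sprintf("random walk from seed '%s' exceeded %d mutations",
                   seed_sequence, max_mutations))
    }
    pos <- with_rng(rng, sample.int(d, 1L))
    repl <- with_rng(rng, sample(setdiff(syms, cur[pos]), 1L))
    cur[pos] <- repl
    n_mut <- n_mut + 1L
  }
}

#' Run a full design campaign
#'
#' Reproduces the design workflow at configurable scale: seed the walker
#' with the `n_high_seeds` highest- and `n_low_seeds` lowest-intensity
#' training peptides (defaults 3000 + 3000), run one constrained walk per
#' seed, score all candidates with the ensemble posterior, and split the
#' pooled, sorted list into reactivity classes — the top `n_high` become H,
#' the bottom `n_low` become L, the middle stays M (defaults 1500 / 3000 /
#' 1500).
#'
#' @param train Training records (with `intensity`; rows of both pools).
#' @param test_sequences Withheld test-set sequences (constraint references).
#' @param model A trained [train_ensemble()] model.
#' @param n_high_seeds,n_low_seeds Seeds drawn from the intensity extremes.
#' @param n_high,n_low Sizes of the H and L classes after ranking.
#' @param constraints [diversity_constraints()].
#' @param rng_seed Integer seed for the walks.
#' @param alphabet A [peptide_alphabet()].
#' @param dock_scores Optional docking scores for candidates (named by
#'   candidate id) when the model has a structure member.
#' @return `data.frame` of design candidates: `id`, `sequence`, `seed_id`,
#'   `seed_category`, `mutation_count`, `probability`, `class` (H/M/L).
#' @export
run_design_campaign <- function(train, test_sequences, model,
                                n_high_seeds = 3000L, n_low_seeds = 3000L,
                                n_high = 1500L, n_low = 1500L,
                                constraints = diversity_constraints(),
                                rng_seed = 1L,
                                alphabet = peptide_alphabet(),
                                dock_scores = NULL) {
  n_seeds <- n_high_seeds + n_low_seeds
  if (nrow(train) < n_seeds) stop("fewer training peptides than requested seeds")
  if (n_high + n_low > n_seeds) stop("class sizes exceed the number of seeds")
  ord <- order(-train$intensity, train$id)
  high_seeds <- train[ord[seq_len(n_high_seeds)], , drop = FALSE]
  low_seeds <- train[rev(ord)[seq_len(n_low_seeds)], , drop = FALSE]

  cat_refs <- list(high = high_seeds$sequence, low = low_seeds$sequence,
                   test = test_sequences)
  index <- build_kmer_index(cat_refs, constraints$kmer)

  design_one <- function(seeds, category, offset) {
    refs <- list(cat_refs[[category]], test_sequences)
    lapply(seq_len(nrow(seeds)), function(i) {
      res <- random_walk_design(seeds$sequence[i], category, index, refs,
                                constraints,
                                rng_seed = rng_seed + offset + i,
                                alphabet = alphabet)
      res$seed_id <- seeds$id[i]
      res
    })
  }
  walks <- c(design_one(high_seeds, "high", 0L),
             design_one(low_seeds, "low", n_high_seeds))

  cand <- data.frame(
    id = paste0("design_", seq_along(walks)),
    sequence = vapply(walks, `[[`, character(1), "sequence"),
    seed_id = vapply(walks, `[[`, character(1), "seed_id"),
    seed_category = vapply(walks, `[[`, character(1), "category"),
    mutation_count = vapply(walks, `[[`, integer(1), "mutation_count"),
    stringsAsFactors = FALSE
  )
  pred <- predict_ensemble(model, cand, dock_scores = dock_scores)
  cand$probability <- pred$ensemble

  ord2 <- order(-cand$probability, cand$id)
  cls <- rep("M", nrow(cand))
  cls[ord2[seq_len(n_high)]] <- "H"
  cls[rev(ord2)[seq_len(n_low)]] <- "L"
  cand$class <- cls
  cand[ord2, , drop = FALSE]
}

#' Independently re-check design candidates against the diversity rules
#'
#' A deliberately naive re-verification (direct substring and window
#' comparisons, no index) used before writing campaign output: any violation
#' indicates a walker bug.
#'
#' @param candidates Design candidate `data.frame` (needs `sequence`,
#'   `seed_category`).
#' @param reference_sets Named list of reference sequences per category plus
#'   `"test"`.
#' @param constraints [diversity_constraints()].
#' @return Integer count of violating candidates (0 when all pass).
#' @export
verify_design_constraints <- function(candidates, reference_sets,
                                      constraints = diversity_constraints()) {
  k <- constraints$kmer
  bad <- 0L
  for (i in seq_len(nrow(candidates))) {
    s <- candidates$sequence[i]
    refs <- c(reference_sets[[candidates$seed_category[i]]],
              reference_sets[["test"]])
    kmers <- substrings_of(s, k)
    shares <- any(vapply(refs, function(r) {
      any(vapply(kmers, grepl, logical(1), x = r, fixed = TRUE))
    }, logical(1)))
    windows <- violates_window_identity(s, refs, constraints)
    if (shares || windows) bad <- bad + 1L
  }
  bad
}
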