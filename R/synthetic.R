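#' Configuration for synthetic peptide pools
#'
#' The generator emulates the statistical structure the classifier assumes:
#' fixed-length peptides over the 21-symbol alphabet, class-discriminative
#' planted k-mer motifs, and a bimodal intensity distribution straddling the
#' 1,000 / 10,000 pool thresholds. Intensities are drawn log-normally around
#' the two modes and truncated to the label-consistent side of the
#' thresholds, so pool construction recovers exactly `n_pos` positives and
#' `n_neg` negatives by design. Negatives are rejection-sampled so they
#' contain no planted motif.
#'
#' @param n_pos,n_neg Pool sizes.
#' @param length Peptide length (default 15).
#' @param motifs Character vector of planted motifs for positives (default
#'   two 4-mers).
#' @param motif_prob Per-motif insertion probability (recycled; every
#'   positive gets at least one motif, so with a single motif at probability
#'   1 every positive contains it).
#' @param pos_meanlog,pos_sdlog Log-scale location/spread of the positive
#'   intensity mode (default around 22,000).
#' @param neg_meanlog,neg_sdlog Negative mode (default around 330).
#' @param background Residue sampling weights over the alphabet; default
#'   uniform over the 20 canonical residues with citrulline at one tenth of
#'   a canonical weight, mirroring its rarity in real pools.
#' @param alphabet A [peptide_alphabet()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_pos = 200L, n_neg = 600L, length = 15L,
                             motifs = c("WCDE", "HKNP"),
                             motif_prob = 0.6,
                             pos_meanlog = log(22000), pos_sdlog = 0.45,
                             neg_meanlog = log(330), neg_sdlog = 0.8,
                             background = NULL,
                             alphabet = peptide_alphabet()) {
  if (any(nchar(motifs) > length)) stop("motif longer than peptide length")
  if (is.null(background)) {
    background <- stats::setNames(rep(1, base::length(unclass(alphabet))),
                                  unclass(alphabet))
    if ("Z" %in% names(background)) background["Z"] <- 0.1
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length = as.integer(length), motifs = motifs,
                 motif_prob = rep_len(motif_prob, base::length(motifs)),
                 pos_meanlog = pos_meanlog, pos_sdlog = pos_sdlog,
                 neg_meanlog = neg_meanlog, neg_sdlog = neg_sdlog,
                 background = background, alphabet = alphabet),
            class = "synthetic_config")
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower = -Inf, upper = Inf, rng) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- with_rng(rng, stats::rlnorm(n, meanlog, sdlog))
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic labeled peptide pool
#'
#' @param cfg A [synthetic_config()].
#' @param rng_seed Integer seed; equal seeds give identical pools.
#' @return Peptide record `data.frame` (`id`, `sequence`, `intensity`,
#'   `label`) with `n_pos` positives followed by `n_neg` negatives.
#' @export
generate_pool <- function(cfg = synthetic_config(), rng_seed = 1L) {
  rng <- local_rng(rng_seed)
  syms <- names(cfg$background)
  w <- cfg$background / sum(cfg$background)
  draw_bg <- function() {
    paste(with_rng(rng, sample(syms, cfg$length, replace = TRUE, prob = w)),
          collapse = "")
  }
  has_motif <- function(s) any(vapply(cfg$motifs, grepl, logical(1), x = s,
                                      fixed = TRUE))
  plant <- function(s, motif) {
    pos <- with_rng(rng, sample.int(cfg$length - nchar(motif) + 1L, 1L))
    paste0(substr(s, 1L, pos - 1L), motif,
           substr(s, pos + nchar(motif), cfg$length))
  }
  positives <- character(cfg$n_pos)
  for (i in seq_len(cfg$n_pos)) {
    s <- draw_bg()
    ins <- with_rng(rng, stats::runif(length(cfg$motifs))) < cfg$motif_prob
    if (!any(ins)) ins[with_rng(rng, sample.int(length(cfg$motifs), 1L))] <- TRUE
    for (m in cfg$motifs[ins]) s <- plant(s, m)
    positives[i] <- s
  }
  negatives <- character(cfg$n_neg)
  for (i in seq_len(cfg$n_neg)) {
    repeat {
      s <- draw_bg()
      if (!has_motif(s)) break
    }
    negatives[i] <- s
  }
  pos_int <- rlnorm_trunc(cfg$n_pos, cfg$pos_meanlog, cfg$pos_sdlog,
                          lower = 10000, rng = rng)
  neg_int <- rlnorm_trunc(cfg$n_neg, cfg$neg_meanlog, cfg$neg_sdlog,
                          upper = 1000, rng = rng)
  data.frame(
    id = paste0(rep(c("pos", "neg"), c(cfg$n_pos, cfg$n_neg)),
                c(seq_len(cfg$n_pos), seq_len(cfg$n_neg))),
    sequence = c(positives, negatives),
    intensity = c(pos_int, neg_int),
    label = rep(c("positive", "negative"), c(cfg$n_pos, cfg$n_neg)),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic docking-score sets
#'
#' Emulates rigid-docking output for featurization tests: each peptide gets
#' `n_poses` scores (default 2000, one per docking pose) drawn from a normal
#' distribution, with positive-labeled peptides shifted upward by
#' `separation`, mimicking score distributions skewed toward high values for
#' true binders.
#'
#' @param records Peptide records with `id` and `label`.
#' @param separation Mean shift for positives (same units as scores).
#' @param rng_seed Integer seed.
#' @param n_poses Scores per peptide (default 2000).
#' @param base_mean,base_sd Negative-class score distribution.
#' @return Named list (id -> numeric vector of length `n_poses`).
#' @export
generate_dock_scores <- function(records, separation = 2, rng_seed = 1L,
                                 n_poses = 2000L, base_mean = 10,
                                 base_sd = 2) {
  stopifnot(separation >= 0)
  rng <- local_rng(rng_seed)
  out <- vector("list", nrow(records))
  names(out) <- records$id
  for (i in seq_len(nrow(records))) {
    shift <- if (identical(records$label[i], "positive")) separation else 0
    out[[i]] <- with_rng(rng, stats::rnorm(n_poses, base_mean + shift, base_sd))
  }
  out
}

#' Motif-count oracle binding score for synthetic designs
#'
#' A ground-truth surrogate used to audit design campaigns on synthetic
#' data: the number of sequence windows lying within `max_mismatch` Hamming
#' mismatches of a planted motif. Candidates designed for the high class
#' should out-score low-class candidates under this oracle whenever the
#' classifier has learned the planted signal — the shared-k-mer rule bans
#' the *exact* motif from designs, so the default tolerance of one mismatch
#' credits the near-motifs that remain reachable.
#'
#' @param sequences Character vector.
#' @param motifs Planted motifs.
#' @param max_mismatch Mismatches tolerated per window (default 1).
#' @return Numeric vector of near-motif window counts.
#' @export
oracle_motif_score <- function(sequences, motifs, max_mismatch = 1L) {
  motif_chars <- lapply(motifs, function(m) strsplit(m, "", fixed = TRUE)[[1]])
  vapply(sequences, function(s) {
    a <- strsplit(s, "", fixed = TRUE)[[1]]
    total <- 0L
    for (mc in motif_chars) {
      k <- length(mc)
      if (k > length(a)) next
      for (i in seq_len(length(a) - k + 1L)) {
        if (sum(a[i:(i + k - 1L)] != mc) <= max_mismatch) total <- total + 1L
      }
    }
    as.numeric(total)
  }, numeric(1), USE.NAMES = FALSE)
}
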