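#' Read a peptide table
#'
#' Reads a tab- or comma-separated table with one peptide per row. The table
#' must contain a sequence column; an intensity column and any number of
#' replicate-intensity columns are optional. Rows are returned in file order
#' and sequences are validated against the alphabet.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param sequence_col Name of the sequence column (default `"sequence"`).
#' @param intensity_col Name of the aggregated intensity column, or `NULL`.
#' @param replicate_cols Character vector of per-replicate intensity column
#'   names, or `NULL`. When present, the negative-pool rule of
#'   [build_pools()] applies to every replicate.
#' @param id_col Name of an id column; when absent ids `p1..pn` are minted.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.csv` means comma, anything else tab).
#' @param alphabet A [peptide_alphabet()].
#' @return A `data.frame` with columns `id`, `sequence`, `intensity` (NA when
#'   absent), one column per replicate (named as in the file), and `label`
#'   initialised to `"unlabeled"` — the reader never assigns pools.
#' @seealso [build_pools()], [make_train_test_split()]
#' @export
read_peptide_table <- function(path, sequence_col = "sequence",
                               intensity_col = "intensity",
                               replicate_cols = NULL,
                               id_col = NULL, sep = NULL,
                               alphabet = peptide_alphabet()) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  if (!sequence_col %in% names(tab)) {
    stop(sprintf("format error: no sequence column '%s' in %s",
                 sequence_col, path))
  }
  sequences <- toupper(as.character(tab[[sequence_col]]))
  validate_sequences(sequences, alphabet, where = paste0("row ", seq_along(sequences)))
  ids <- if (!is.null(id_col) && id_col %in% names(tab)) {
    as.character(tab[[id_col]])
  } else {
    paste0("p", seq_along(sequences))
  }
  out <- data.frame(id = ids, sequence = sequences, stringsAsFactors = FALSE)
  out$intensity <- if (!is.null(intensity_col) && intensity_col %in% names(tab)) {
    as.numeric(tab[[intensity_col]])
  } else NA_real_
  for (rc in replicate_cols) {
    if (!rc %in% names(tab)) stop(sprintf("replicate column '%s' missing", rc))
    out[[rc]] <- as.numeric(tab[[rc]])
  }
  if (length(replicate_cols) && all(is.na(out$intensity))) {
    out$intensity <- apply(as.matrix(out[replicate_cols]), 1L, mean)
  }
  out$label <- "unlabeled"
  attr(out, "replicate_cols") <- replicate_cols
  out
}

#' Write a peptide table as TSV
#'
#' @param records A peptide record `data.frame` (see [read_peptide_table()]).
#' @param path Output path.
#' @param comment Optional comment lines written with a leading `#`.
#' @export
write_peptide_table <- function(records, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pool configuration
#'
#' Intensity thresholds used to call binders and non-binders from microarray
#' signal intensities (fluorescence units). Defaults follow the convention
#' that peptides above 10,000 are high-confidence binders and peptides below
#' 1,000 in every replicate are high-confidence non-binders; the band in
#' between stays unlabeled.
#'
#' @param positive_threshold Intensity strictly above which a peptide is a
#'   positive (default 10000).
#' @param negative_threshold Intensity strictly below which a peptide is a
#'   negative (default 1000).
#' @param replicate_rule When `TRUE` (default) and replicate intensities are
#'   present, a negative call requires every replicate below the threshold.
#' @return A `pool_config` list.
#' @export
pool_config <- function(positive_threshold = 10000,
                        negative_threshold = 1000,
                        replicate_rule = TRUE) {
  stopifnot(negative_threshold < positive_threshold)
  structure(list(positive_threshold = positive_threshold,
                 negative_threshold = negative_threshold,
                 replicate_rule = replicate_rule),
            class = "pool_config")
}

#' Build positive and negative peptide pools by intensity thresholds
#'
#' Positives are records with intensity strictly above the positive
#' threshold. Negatives are records with intensity strictly below the
#' negative threshold; when replicate intensities are present and the
#' replicate rule is on, *all* replicates must fall below it. Records in the
#' band between the thresholds belong to neither pool and keep the
#' `"unlabeled"` label.
#'
#' @param records Peptide record `data.frame` with an `intensity` column and
#'   optionally replicate columns (attribute `replicate_cols`, or pass
#'   `replicate_cols`).
#' @param cfg A [pool_config()].
#' @param replicate_cols Names of replicate intensity columns; defaults to
#'   the attribute set by [read_peptide_table()].
#' @return A list with elements `positive` and `negative`, each a record
#'   `data.frame` with `label` set.
#' @export
build_pools <- function(records, cfg = pool_config(), replicate_cols = NULL) {
  if (is.null(replicate_cols)) replicate_cols <- attr(records, "replicate_cols")
  if (any(is.na(records$intensity)) && !length(replicate_cols)) {
    stop("records lack intensities; pools cannot be built")
  }
  pos <- records$intensity > cfg$positive_threshold
  if (length(replicate_cols) && cfg$replicate_rule) {
    reps <- as.matrix(records[replicate_cols])
    neg <- apply(reps < cfg$negative_threshold, 1L, all)
  } else {
    neg <- records$intensity < cfg$negative_threshold
  }
  positive <- records[pos, , drop = FALSE]
  negative <- records[!pos & neg, , drop = FALSE]
  if (nrow(positive)) positive$label <- "positive"
  if (nrow(negative)) negative$label <- "negative"
  list(positive = positive, negative = negative)
}

#' Split pools into training and test sets
#'
#' Samples `n_pos_train` positives and `n_neg_train` negatives uniformly at
#' random without replacement into the training set; everything else in the
#' two pools becomes the test set. The canonical full-data configuration —
#' pools of 6,841 positives and 20,437 negatives with 3,420 + 10,218 drawn
#' for training — yields 13,638 training and 13,640 test peptides.
#'
#' @param positive,negative Record `data.frame`s (pool members).
#' @param n_pos_train,n_neg_train Training-set sample sizes per pool.
#' @param seed Integer RNG seed; equal seeds give identical splits.
#' @return A list of class `train_test_split` with elements `train`, `test`
#'   (record `data.frame`s) and `seed`.
#' @export
make_train_test_split <- function(positive, negative, n_pos_train,
                                  n_neg_train, seed = 1L) {
  if (n_pos_train > nrow(positive) || n_neg_train > nrow(negative)) {
    stop("requested training sample exceeds pool size")
  }
  rng <- local_rng(seed)
  pos_idx <- sample_without_replacement(nrow(positive), n_pos_train, rng)
  neg_idx <- sample_without_replacement(nrow(negative), n_neg_train, rng)
  train <- rbind(positive[pos_idx, , drop = FALSE],
                 negative[neg_idx, , drop = FALSE])
  test <- rbind(positive[setdiff(seq_len(nrow(positive)), pos_idx), , drop = FALSE],
                negative[setdiff(seq_len(nrow(negative)), neg_idx), , drop = FALSE])
  rownames(train) <- rownames(test) <- NULL
  structure(list(train = train, test = test, seed = seed),
            class = "train_test_split")
}

# A private RNG stream so library code does not disturb the caller's
# .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  eval.parent(substitute(expr))
}

sample_without_replacement <- function(n, size, rng) {
  if (size == 0L) return(integer(0))
  with_rng(rng, sample.int(n, size, replace = FALSE))
}

#' Read peptides from a FASTA file
#'
#' @param path FASTA path (single-line or wrapped records).
#' @param alphabet A [peptide_alphabet()] used for validation.
#' @return A `data.frame` with columns `id` and `sequence`. Duplicate ids are
#'   suffix-deduplicated with a warning.
#' @export
read_fasta <- function(path, alphabet = peptide_alphabet()) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids; deduplicating with numeric suffixes")
    ids <- make.unique(ids, sep = "_")
  }
  sequences <- toupper(as.character(ss))
  if (length(sequences)) validate_sequences(sequences, alphabet, where = ids)
  data.frame(id = ids, sequence = unname(sequences), stringsAsFactors = FALSE)
}

#' Write peptides to a FASTA file
#'
#' Round-trips with [read_fasta()]: `read_fasta(write_fasta(x, path))`
#' reproduces ids and sequences.
#'
#' @param peptides A `data.frame` with `id` and `sequence` columns.
#' @param path Output path.
#' @export
write_fasta <- function(peptides, path) {
  ss <- Biostrings::BStringSet(peptides$sequence)
  names(ss) <- peptides$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read / write a whitespace-delimited residue encoding matrix
#'
#' The format is a header row of residue letters followed by one numeric row
#' per residue, first field the residue letter (the layout used for
#' substitution-matrix text files). For rectangular encodings the header
#' holds column labels instead.
#'
#' @param path File path.
#' @return A numeric matrix with residue rownames.
#' @export
read_encoding_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_encoding_matrix
#' @param m Numeric matrix with residue rownames.
#' @export
write_encoding_matrix <- function(m, path) {
  tab <- data.frame(residue = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-peptide docking scores
#'
#' Each peptide's docking scores live in a two-column whitespace-delimited
#' text file (pose rank, score), one row per docking pose.
#'
#' @param path File path.
#' @return Numeric vector of scores in pose-rank order.
#' @export
read_dock_scores <- function(path) {
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) < 2L) stop("dock score files need two columns: rank, score")
  as.numeric(tab[[2]][order(tab[[1]])])
}
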