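#' Residue encoding matrices
#'
#' A residue encoding matrix maps each amino acid to a fixed-width numeric
#' row; a peptide is encoded by concatenating the rows of its residues.
#' Three encodings are bundled:
#'
#' * `blosum50_encoding()` — the 20 substitution-score columns of BLOSUM50
#'   (width 20), taken from the matrix shipped with Biostrings.
#' * `nlf_style_encoding()` — an 18-column reduced physicochemical matrix.
#' * `sa_style_encoding()` — a 10-column reduced physicochemical matrix.
#'
#' The published nlf (nonlinear Fisher transform) and sa
#' (clustering + PCA) matrices are not redistributable here, so the
#' `*_style` constructors derive stand-ins of the same shape by principal
#' component reduction of the full AAIndex property table; load the
#' published values with [read_encoding_matrix()] if you have them.
#'
#' Citrulline (`Z`) has no row in any of these sources. Under the default
#' policy an all-zero row is appended (with a one-time warning), so numeric
#' encodings carry no citrulline information — its influence on the
#' classifier comes from the string kernels instead. Set
#' `z_policy = "error"` to refuse citrulline-containing peptides.
#'
#' @param z_policy `"zero"` (default) or `"error"`.
#' @return A numeric matrix with residue rownames, class
#'   `residue_encoding_matrix`, attribute `name`.
#' @name residue-encodings
NULL

encoding_matrix <- function(m, name, z_policy = c("zero", "error")) {
  z_policy <- match.arg(z_policy)
  if (z_policy == "zero" && !"Z" %in% rownames(m)) {
    m <- rbind(m, Z = 0)
  }
  structure(m, name = name, z_policy = z_policy,
            class = c("residue_encoding_matrix", "matrix", "array"))
}

#' @rdname residue-encodings
#' @export
blosum50_encoding <- function(z_policy = "zero") {
  b50 <- get_blosum50()
  m <- b50[CANONICAL_AA, CANONICAL_AA]
  encoding_matrix(m, "blosum50", z_policy)
}

get_blosum50 <- function() {
  e <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = e)
  e$BLOSUM50
}

#' @rdname residue-encodings
#' @param table An [aaindex_table()] used to derive the reduced matrix.
#' @export
nlf_style_encoding <- function(table = aaindex_table(), z_policy = "zero") {
  encoding_matrix(aaindex_pca_matrix(table, 18L), "nlf_style", z_policy)
}

#' @rdname residue-encodings
#' @export
sa_style_encoding <- function(table = aaindex_table(), z_policy = "zero") {
  encoding_matrix(aaindex_pca_matrix(table, 10L), "sa_style", z_policy)
}

# 20 x ncomp matrix of principal-component scores of the standardized
# AAIndex property table (rows = canonical residues).
aaindex_pca_matrix <- function(table, ncomp) {
  props <- sapply(table$properties, function(p) p$values[CANONICAL_AA])
  keep <- apply(props, 2L, stats::sd) > 0
  pc <- stats::prcomp(props[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  rownames(scores) <- CANONICAL_AA
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  scores
}

#' Load the AAIndex physicochemical property table
#'
#' Wraps the AAIndex release 9.x bundled with seqinr: 544 properties, each a
#' map from the 20 canonical amino acids to a real value. Properties with
#' missing residue values are dropped at load time with a message giving the
#' count.
#'
#' @param property_ids Optional character vector restricting the table to a
#'   subset of AAIndex accession ids (e.g. `"KYTJ820101"`).
#' @param quiet Suppress the dropped-property message.
#' @return A list of class `aaindex_table` with element `properties`: a named
#'   list of `list(id, values)` where `values` is a length-20 named numeric
#'   vector over one-letter codes.
#' @export
aaindex_table <- function(property_ids = NULL, quiet = FALSE) {
  e <- new.env()
  utils::data("aaindex", package = "seqinr", envir = e)
  aai <- e$aaindex
  three <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
             "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
             "Tyr", "Val")
  one <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  props <- list()
  dropped <- 0L
  for (nm in names(aai)) {
    v <- aai[[nm]]$I[three]
    if (any(is.na(v))) { dropped <- dropped + 1L; next }
    names(v) <- one
    props[[nm]] <- list(id = nm, values = v)
  }
  if (!is.null(property_ids)) {
    missing <- setdiff(property_ids, names(props))
    if (length(missing)) stop("unknown/incomplete AAIndex ids: ",
                              paste(missing, collapse = ", "))
    props <- props[property_ids]
  }
  if (dropped && !quiet && is.null(property_ids)) {
    message(sprintf("aaindex_table: dropped %d properties with missing residue values", dropped))
  }
  structure(list(properties = props), class = "aaindex_table")
}

#' Encode a peptide by residue-matrix row concatenation
#'
#' Replaces each residue of the peptide with its row in the encoding matrix
#' and concatenates: a length-`d` peptide under a width-`m` matrix becomes an
#' `m * d`-dimensional vector (300 for a 15-mer under BLOSUM50).
#'
#' @param sequences Character vector of peptide sequences (equal length not
#'   required).
#' @param m A `residue_encoding_matrix` (see [blosum50_encoding()]) or any
#'   numeric matrix with residue rownames.
#' @return For a single sequence, a numeric vector; for several, a matrix
#'   with one row per peptide (sequences must then share one length).
#' @export
encode_with_matrix <- function(sequences, m) {
  z_policy <- attr(m, "z_policy")
  enc1 <- function(s) {
    a <- strsplit(s, "", fixed = TRUE)[[1]]
    missing <- setdiff(a, rownames(m))
    if (length(missing)) {
      stop(sprintf("no encoding row for residue(s): %s",
                   paste(missing, collapse = ", ")))
    }
    if ("Z" %in% a && identical(z_policy, "zero")) warn_z_once(attr(m, "name"))
    as.vector(t(m[a, , drop = FALSE]))
  }
  if (length(sequences) == 1L) return(enc1(sequences))
  do.call(rbind, lapply(sequences, enc1))
}

warn_z_once <- local({
  seen <- character(0)
  function(name) {
    key <- if (is.null(name)) "?" else name
    if (!key %in% seen) {
      seen[[length(seen) + 1L]] <<- key
      warning(sprintf("citrulline 'Z' encoded as an all-zero row under '%s'", key),
              call. = FALSE)
    }
  }
})

#' Sliding-window mean of an AAIndex property along a peptide
#'
#' For a length-`d` peptide and window `w`, returns the `d - w + 1` means of
#' the property over every fully contained window.
#'
#' @param sequence A peptide sequence.
#' @param values Named numeric vector mapping residues to property values.
#'   Residues without a value (citrulline under AAIndex) contribute 0 by the
#'   zero-substitution policy.
#' @param w Window length, `1 <= w <= nchar(sequence)`.
#' @return Numeric vector of length `d - w + 1`.
#' @export
aaindex_window_features <- function(sequence, values, w) {
  a <- strsplit(sequence, "", fixed = TRUE)[[1]]
  d <- length(a)
  if (w > d) stop("window length exceeds peptide length")
  v <- unname(values[a])
  v[is.na(v)] <- 0
  cs <- cumsum(c(0, v))
  (cs[(w + 1):(d + 1)] - cs[1:(d - w + 1)]) / w
}

#' Window-feature configuration
#'
#' @param windows Integer vector of window lengths (default `3:5`).
#' @param property_ids Optional AAIndex accession subset; `NULL` means every
#'   complete property.
#' @return A `window_feature_config` list.
#' @export
window_feature_config <- function(windows = 3:5, property_ids = NULL) {
  stopifnot(all(windows >= 1L))
  structure(list(windows = as.integer(windows), property_ids = property_ids),
            class = "window_feature_config")
}

#' Full AAIndex window-feature block for peptides
#'
#' Concatenates [aaindex_window_features()] over every configured property
#' and window length, properties outermost, windows inner, in table order:
#' the block for property `j` and window `w` occupies a contiguous run of
#' `d - w + 1` entries. Total dimension is
#' `sum_w (d - w + 1) * n_properties` — 19,584 for all 544 properties,
#' `w in 3:5` and 15-mers.
#'
#' @param sequences Character vector of equal-length peptides.
#' @param table An [aaindex_table()].
#' @param cfg A [window_feature_config()].
#' @return Matrix with one row per peptide.
#' @export
aaindex_feature_block <- function(sequences, table = aaindex_table(quiet = TRUE),
                                  cfg = window_feature_config()) {
  props <- table$properties
  if (!is.null(cfg$property_ids)) props <- props[cfg$property_ids]
  d <- unique(nchar(sequences))
  if (length(d) != 1L) stop("sequences must share one length")
  if (any(cfg$windows > d)) stop("window length exceeds peptide length")
  chars <- seq_char_matrix(sequences)
  n <- length(sequences)
  blocks <- vector("list", length(props) * length(cfg$windows))
  bi <- 0L
  for (p in props) {
    v <- matrix(p$values[chars], nrow = n)
    v[is.na(v)] <- 0
    cs <- cbind(0, t(apply(v, 1L, cumsum)))
    for (w in cfg$windows) {
      bi <- bi + 1L
      blocks[[bi]] <- (cs[, (w + 1):(d + 1), drop = FALSE] -
                         cs[, 1:(d - w + 1), drop = FALSE]) / w
    }
  }
  do.call(cbind, blocks)
}

#' Histogram featurization of docking scores
#'
#' Turns a list of docking scores for one peptide (one score per pose,
#' nominally 2000) into a normalized histogram over fixed bins: the fraction
#' of poses per bin. Bin edges are chosen once from the training corpus (see
#' [dock_score_bins()]) and reused at prediction time; scores outside the
#' edges are clipped into the terminal bins.
#'
#' @param scores Numeric vector of docking scores (length >= 1).
#' @param breaks Strictly increasing numeric vector of bin edges.
#' @return Numeric vector of length `length(breaks) - 1` summing to 1.
#' @export
dock_score_histogram <- function(scores, breaks) {
  if (!length(scores)) stop("empty docking score list")
  if (is.unsorted(breaks, strictly = TRUE)) stop("bin edges must be strictly increasing")
  x <- pmin(pmax(scores, breaks[1]), breaks[length(breaks)])
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(breaks) - 1L)
  counts / length(scores)
}

#' Equal-width docking-score bins fixed on a training corpus
#'
#' @param score_sets List of numeric score vectors (training peptides).
#' @param n_bins Number of equal-width bins (default 20).
#' @return Numeric vector of `n_bins + 1` edges spanning the observed range.
#' @export
dock_score_bins <- function(score_sets, n_bins = 20L) {
  all_scores <- unlist(score_sets, use.names = FALSE)
  r <- range(all_scores)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = n_bins + 1L)
}
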