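#' String-kernel specifications
#'
#' All three kernel families are explicit-feature inner products of substring
#' count vectors, so every Gram matrix is symmetric positive semidefinite:
#'
#' * **spectrum** — counts of all length-`k` substrings. `k` may be a vector,
#'   in which case the per-`k` kernels are summed (the default `k = 3:6`
#'   feeds one combined spectrum classifier).
#' * **sssk** — sparse spatial sample kernel: counts of ordered residue-pair
#'   probes `(a, t, b)`, a residue `a` followed at displacement
#'   `1 <= t <= max_displacement` by residue `b` (single-character probes).
#' * **bounded_range** — counts of all substrings of length 1..`r`, each
#'   length weighted equally by default (`weights` overrides, one weight per
#'   length).
#'
#' @param kind One of `"spectrum"`, `"sssk"`, `"bounded_range"`.
#' @param k Spectrum substring length(s), default `3:6`.
#' @param max_displacement SSSK maximum probe displacement, default 6.
#' @param r Bounded-range maximum substring length, default 8.
#' @param weights Optional per-length weights for `bounded_range`.
#' @param normalize Apply cosine normalization
#'   `K(p,q)/sqrt(K(p,p) K(q,q))` to Gram matrices (default `FALSE`).
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("spectrum", "sssk", "bounded_range"),
                        k = 3:6, max_displacement = 6L, r = 8L,
                        weights = NULL, normalize = FALSE) {
  kind <- match.arg(kind)
  stopifnot(all(k >= 1L), max_displacement >= 1L, r >= 1L)
  if (!is.null(weights) && length(weights) != r) {
    stop("need one weight per substring length 1..r")
  }
  structure(list(kind = kind, k = as.integer(k),
                 max_displacement = as.integer(max_displacement),
                 r = as.integer(r), weights = weights, normalize = normalize),
            class = "kernel_spec")
}

# All substrings of s of length k, in position order.
substrings_of <- function(s, k) {
  d <- nchar(s)
  if (k > d) return(character(0))
  substring(s, 1:(d - k + 1), k:d)
}

# Named feature-count lists per sequence for a kernel spec. Each element is a
# named integer vector (feature string -> count). The weight vector w is
# applied as sqrt(w) on both sides so inner products carry weight w.
kernel_feature_counts <- function(sequences, spec) {
  feats <- switch(spec$kind,
    spectrum = lapply(sequences, function(s) {
      unlist(lapply(spec$k, function(k) {
        if (k > nchar(s)) stop("spectrum k exceeds peptide length")
        paste0(k, ":", substrings_of(s, k))
      }))
    }),
    sssk = lapply(sequences, function(s) {
      a <- strsplit(s, "", fixed = TRUE)[[1]]
      d <- length(a)
      if (d < 2L) stop("SSSK needs peptides of length >= 2")
      out <- character(0)
      for (t in seq_len(min(spec$max_displacement, d - 1L))) {
        i <- seq_len(d - t)
        out <- c(out, paste0(a[i], ":", t, ":", a[i + t]))
      }
      out
    }),
    bounded_range = lapply(sequences, function(s) {
      unlist(lapply(seq_len(min(spec$r, nchar(s))), function(L) {
        paste0(L, ":", substrings_of(s, L))
      }))
    })
  )
  lapply(feats, function(f) {
    cnt <- table(f)
    v <- as.numeric(cnt)
    if (spec$kind == "bounded_range" && !is.null(spec$weights)) {
      L <- as.integer(sub(":.*$", "", names(cnt)))
      v <- v * sqrt(spec$weights[L])
    }
    stats::setNames(v, names(cnt))
  })
}

# Sparse peptide x feature count matrix over the union of observed features.
counts_to_sparse <- function(counts) {
  feats <- unique(unlist(lapply(counts, names), use.names = FALSE))
  i <- rep(seq_along(counts), lengths(counts))
  j <- match(unlist(lapply(counts, names), use.names = FALSE), feats)
  Matrix::sparseMatrix(i = i, j = j, x = unlist(counts, use.names = FALSE),
                       dims = c(length(counts), length(feats)))
}

kernel_from_counts <- function(c1, c2) {
  shared <- intersect(names(c1), names(c2))
  sum(c1[shared] * c2[shared])
}

#' Evaluate a string kernel between two peptides
#'
#' @param p1,p2 Peptide sequences.
#' @param spec A [kernel_spec()]; for convenience [spectrum_kernel()] and
#'   friends take the bare parameter.
#' @return The kernel value (a non-negative real; an integer count for unit
#'   weights).
#' @examples
#' spectrum_kernel("AAAA", "AAAA", k = 3)  # 4: "AAA" occurs twice, 2*2
#' bounded_range_kernel("AA", "AA", r = 8) # 5: length-1 2*2 + length-2 1*1
#' @export
string_kernel <- function(p1, p2, spec) {
  cc <- kernel_feature_counts(c(p1, p2), spec)
  v <- kernel_from_counts(cc[[1]], cc[[2]])
  if (isTRUE(spec$normalize)) {
    v / sqrt(kernel_from_counts(cc[[1]], cc[[1]]) *
               kernel_from_counts(cc[[2]], cc[[2]]))
  } else v
}

#' @rdname string_kernel
#' @param k Spectrum substring length(s).
#' @export
spectrum_kernel <- function(p1, p2, k = 3:6) {
  string_kernel(p1, p2, kernel_spec("spectrum", k = k))
}

#' @rdname string_kernel
#' @param max_displacement SSSK maximum displacement.
#' @export
sssk_kernel <- function(p1, p2, max_displacement = 6L) {
  string_kernel(p1, p2, kernel_spec("sssk", max_displacement = max_displacement))
}

#' @rdname string_kernel
#' @param r Bounded-range maximum substring length.
#' @param weights Optional per-length weights.
#' @export
bounded_range_kernel <- function(p1, p2, r = 8L, weights = NULL) {
  string_kernel(p1, p2, kernel_spec("bounded_range", r = r, weights = weights))
}

#' Build a kernel matrix over peptide lists
#'
#' With one list, returns the symmetric Gram matrix `K[i, j] =
#' kernel(p_i, p_j)`. With two lists, returns the rectangular
#' `length(sequences) x length(sequences2)` cross-kernel used to score test
#' peptides against a training set.
#'
#' @param sequences Character vector of peptides (rows).
#' @param spec A [kernel_spec()].
#' @param sequences2 Optional second peptide vector (columns).
#' @param ids,ids2 Optional dimnames.
#' @return A dense numeric matrix.
#' @export
build_kernel_matrix <- function(sequences, spec, sequences2 = NULL,
                                ids = NULL, ids2 = NULL) {
  counts <- kernel_feature_counts(c(sequences, sequences2), spec)
  X <- counts_to_sparse(counts)
  n1 <- length(sequences)
  X1 <- X[seq_len(n1), , drop = FALSE]
  X2 <- if (is.null(sequences2)) X1 else X[-seq_len(n1), , drop = FALSE]
  K <- as.matrix(Matrix::tcrossprod(X1, X2))
  if (isTRUE(spec$normalize)) {
    d1 <- sqrt(Matrix::rowSums(X1^2))
    d2 <- sqrt(Matrix::rowSums(X2^2))
    K <- K / outer(d1, d2)
  }
  if (is.null(sequences2)) K <- (K + t(K)) / 2  # enforce exact symmetry
  dimnames(K) <- list(ids, if (is.null(sequences2)) ids else ids2)
  K
}

#' Serialize / restore a kernel matrix as plain text
#'
#' Writes the id list as a commented header block followed by the numeric
#' matrix at full precision (bit-exact round-trip via `format(..., digits =
#' 17)`).
#'
#' @param K Numeric matrix with dimnames.
#' @param path File path.
#' @export
write_kernel_matrix <- function(K, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ids: ", paste(rownames(K), collapse = "\t")), con)
  utils::write.table(format(K, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_matrix
#' @export
read_kernel_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  ids <- strsplit(sub("^# ids: ", "", header), "\t", fixed = TRUE)[[1]]
  m <- as.matrix(utils::read.table(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- list(ids, ids)
  m
}
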