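# Bit-string representation and Hamming metric.
#
# A bit string of length B is stored as an integer (or numeric) vector of 0s
# and 1s; a set of N strings is an N x B matrix with one string per row.

.check_bits <- function(x, arg = "bit string") {
  if (!is.numeric(x)) stop(arg, " must be a numeric 0/1 vector or matrix")
  if (length(x) < 1L) stop(arg, " must have length B >= 1")
  if (any(x != 0 & x != 1)) stop(arg, " may contain only 0 and 1")
  invisible(x)
}

# Coerce a bit-string set (matrix, or a bs_population) to a double matrix so
# that distance computations go through BLAS.
.as_bit_matrix <- function(x) {
  if (inherits(x, "bs_population")) x <- x$members
  if (!is.matrix(x)) stop("a bit-string set must be a matrix with one string per row")
  .check_bits(x, "bit-string set")
  storage.mode(x) <- "double"
  x
}

.bit_keys <- function(X) apply(X, 1L, paste, collapse = "")

#' Hamming distance between two bit strings
#'
#' The number of positions at which two equal-length binary arrays differ.
#' This is a metric on the set of length-B strings: nonnegative, symmetric,
#' zero only for identical strings, and satisfying the triangle inequality.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return Integer in `[0, length(a)]`.
#' @examples
#' hamming_distance(c(0, 0, 0, 0, 0, 0), c(1, 1, 0, 0, 0, 0)) # 2
#' @seealso [hamming_matrix()] for all pairwise distances of a set.
#' @export
hamming_distance <- function(a, b) {
  .check_bits(a, "a"); .check_bits(b, "b")
  if (length(a) != length(b))
    stop("bit strings have different lengths (", length(a), " vs ", length(b), ")")
  as.integer(sum(a != b))
}

#' Pairwise Hamming distances of a bit-string set
#'
#' Computes the full symmetric distance matrix of an N x B 0/1 matrix in one
#' BLAS product: for binary vectors, H(x, y) = |x| + |y| - 2 x.y.
#' Thresholding this matrix at G reproduces the edge set of
#' [similarity_network()] for that G, which makes sweeps over G cheap.
#'
#' @param X 0/1 matrix, one bit string per row.
#' @return Integer N x N matrix with zero diagonal.
#' @export
hamming_matrix <- function(X) {
  X <- .as_bit_matrix(X)
  r <- rowSums(X)
  D <- round(outer(r, r, "+") - 2 * tcrossprod(X))
  storage.mode(D) <- "integer"
  diag(D) <- 0L
  D
}

#' Number of bit strings at a given Hamming distance
#'
#' There are `choose(B, H)` strings at distance exactly H from any fixed
#' string of length B.
#'
#' @param B String length.
#' @param H Distance, `0 <= H <= B`.
#' @export
count_at_distance <- function(B, H) {
  stopifnot(B >= 1)
  if (any(H < 0 | H > B)) stop("H must lie in [0, B]")
  choose(B, H)
}

#' All bit strings of length B
#'
#' Exhaustive enumeration, intended as an oracle for small B.
#'
#' @param B String length (at most 20).
#' @return `2^B` x B integer matrix in counting order.
#' @export
all_bitstrings <- function(B) {
  stopifnot(B >= 1, B <= 20)
  X <- outer(0:(2^B - 1), 0:(B - 1), function(i, k) bitwAnd(bitwShiftR(i, k), 1L))
  storage.mode(X) <- "integer"
  X
}

#' Enumerate all strings within distance G of a string
#'
#' Returns every string b' != b with `hamming_distance(b, b') <= G`; their
#' count is the neighbourhood volume M_G = sum_{H=1}^{G} choose(B, H), which
#' is the same for every b. Exhaustive, so restricted to small B.
#'
#' @param b 0/1 vector of length B (B at most 20).
#' @param G Threshold, `1 <= G <= B`.
#' @return Matrix of bit strings, one per row; `b` itself is excluded.
#' @export
bitstrings_within <- function(b, G) {
  .check_bits(b, "b")
  B <- length(b)
  stopifnot(B <= 20)
  if (G < 1 || G > B) stop("G must lie in [1, B]")
  A <- all_bitstrings(B)
  d <- rowSums(A) + sum(b) - 2 * drop(A %*% b)
  A[d >= 1 & d <= G, , drop = FALSE]
}

#' Uniform random set of distinct bit strings
#'
#' Draws N distinct strings of length B uniformly without replacement from
#' the `2^B` possibilities. For small B the full code space is sampled by
#' index; for large B strings are drawn bitwise and the (rare) duplicates
#' redrawn, which preserves exact uniformity. Reproducible under
#' `set.seed()`.
#'
#' @param N Number of strings (`N <= 2^B`).
#' @param B String length.
#' @return N x B integer 0/1 matrix with distinct rows.
#' @examples
#' set.seed(1)
#' X <- random_bitstring_set(10, 6)
#' @export
random_bitstring_set <- function(N, B) {
  stopifnot(N >= 1, B >= 1)
  if (B <= 30 && N > 2^B)
    stop("cannot draw ", N, " distinct strings of length ", B, " (only ", 2^B, " exist)")
  if (B <= 24) {
    idx <- sample.int(2^B, N) - 1L
    X <- outer(idx, 0:(B - 1), function(i, k) bitwAnd(bitwShiftR(i, k), 1L))
  } else {
    X <- matrix(sample(0:1, N * B, replace = TRUE), N, B)
    repeat {
      dup <- duplicated(.bit_keys(X))
      if (!any(dup)) break
      X[dup, ] <- sample(0:1, sum(dup) * B, replace = TRUE)
    }
  }
  storage.mode(X) <- "integer"
  X
}

#' Read / write a bit-string set file
#'
#' Plain-text format: one string of B characters from \{0, 1\} per line, no
#' header. The reader validates a uniform length and alphabet.
#'
#' @param path File path.
#' @return `read_bitstring_set()`: integer 0/1 matrix, one string per row.
#' @export
read_bitstring_set <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no bit strings in ", path)
  if (any(!grepl("^[01]+$", lines)))
    stop("bit-string file may contain only characters 0 and 1")
  if (length(unique(nchar(lines))) != 1L)
    stop("all bit strings in a set must have the same length")
  X <- do.call(rbind, lapply(strsplit(lines, ""), as.integer))
  X
}

#' @rdname read_bitstring_set
#' @param X 0/1 matrix, one bit string per row.
#' @export
write_bitstring_set <- function(X, path) {
  X <- .as_bit_matrix(X)
  writeLines(.bit_keys(X), path)
  invisible(path)
}
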