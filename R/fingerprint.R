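#' Map a two-lead segment onto a binary co-occurrence matrix
#'
#' Each time point `t` contributes one marked cell: row `x1[t] + 1`, column
#' `x2[t] + 1` (values are 0-based ADC codes after the +500 shift; matrix
#' indices are 1-based). Duplicate value pairs mark the same cell once, so the
#' number of nonzero cells never exceeds the segment length. Values outside
#' `[0, N)` are clipped to the boundary with a warning reporting how many.
#'
#' @param x1,x2 Equal-length integer vectors of shifted samples (lead 1 gives
#'   the row, lead 2 the column).
#' @param N Matrix side length (default 1300, covering 12-bit data after the
#'   +500 shift).
#' @return A sparse binary `N x N` matrix (`Matrix::dgCMatrix` with 0/1
#'   entries).
#' @export
map_to_matrix <- function(x1, x2, N = 1300L) {
  if (length(x1) != length(x2)) abort("x1 and x2 must have equal length")
  if (length(x1) == 0L) abort("empty segment")
  N <- as.integer(N)
  x1 <- as.integer(x1)
  x2 <- as.integer(x2)
  n_out <- sum(x1 < 0L | x1 >= N | x2 < 0L | x2 >= N)
  if (n_out > 0L) {
    warn(sprintf("%d sample pair(s) outside [0, %d) clipped to range", n_out, N))
    x1 <- pmin(pmax(x1, 0L), N - 1L)
    x2 <- pmin(pmax(x2, 0L), N - 1L)
  }
  M <- Matrix::sparseMatrix(i = x1 + 1L, j = x2 + 1L, x = 1, dims = c(N, N))
  M@x[] <- 1
  M
}

nonzero_indices <- function(M) {
  if (is(M, "Matrix")) {
    s <- Matrix::summary(as(M, "TsparseMatrix"))
    cbind(row = as.integer(s$i), col = as.integer(s$j))
  } else {
    idx <- which(M != 0, arr.ind = TRUE)
    cbind(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]))
  }
}

#' Reduce a binary matrix by block binarization
#'
#' Binary max-pooling: the matrix is tiled with `m x m` blocks (trailing
#' blocks may be smaller when `m` does not divide the side length) and each
#' output cell is 1 iff its block contains at least one nonzero. The output
#' side is `ceiling(N / m)`; `m = 1` is the identity.
#'
#' @param M A binary matrix (base or Matrix sparse).
#' @param m Block side length, `1 <= m <= nrow(M)`.
#' @return A sparse binary matrix of dimensions
#'   `ceiling(dim(M) / m)`.
#' @export
reduce_matrix <- function(M, m) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L || m > min(dim(M))) {
    abort("block size m must satisfy 1 <= m <= matrix side")
  }
  d <- as.integer(ceiling(dim(M) / m))
  idx <- nonzero_indices(M)
  if (nrow(idx) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = d))
  }
  ri <- (idx[, "row"] - 1L) %/% m + 1L
  ci <- (idx[, "col"] - 1L) %/% m + 1L
  keep <- !duplicated(ri + as.numeric(d[1]) * (ci - 1))
  R <- Matrix::sparseMatrix(i = ri[keep], j = ci[keep], x = 1, dims = d)
  R@x[] <- 1
  R
}

new_fingerprint <- function(d, m, coords) {
  structure(
    list(d = as.integer(d), m = as.integer(m),
         coords = matrix(as.integer(coords), ncol = 2,
                         dimnames = list(NULL, c("row", "col")))),
    class = "ecg_fingerprint"
  )
}

#' Store a binary matrix as a sparse coordinate-format fingerprint
#'
#' Because all stored values are 1, only (row, column) pairs are kept, in
#' column-major order (every row of column `c` before column `c + 1`),
#' 1-based. Cell `(i, j)` corresponds to lead-1 value `i - 1` and lead-2 value
#' `j - 1` times the block size.
#'
#' @param M A square binary matrix (usually the reduced matrix).
#' @param m Block size that produced `M`; kept as metadata (`NA` if unknown).
#' @return An object of class `ecg_fingerprint` with fields `d` (side length),
#'   `m`, and `coords` (n x 2 integer matrix).
#' @export
to_coo <- function(M, m = NA_integer_) {
  if (nrow(M) != ncol(M)) abort("fingerprint matrices must be square")
  idx <- nonzero_indices(M)
  ord <- order(idx[, "col"], idx[, "row"])
  new_fingerprint(nrow(M), m, idx[ord, , drop = FALSE])
}

#' Densify a sparse fingerprint
#'
#' @param fp An `ecg_fingerprint`.
#' @return A dense base `d x d` 0/1 matrix with ones exactly at `fp$coords`.
#' @export
from_coo <- function(fp) {
  stopifnot(inherits(fp, "ecg_fingerprint"))
  d <- fp$d
  if (nrow(fp$coords) > 0L &&
      (min(fp$coords) < 1L || max(fp$coords) > d)) {
    abort("fingerprint coordinate outside [1, d]")
  }
  M <- matrix(0, d, d)
  M[fp$coords] <- 1
  M
}

#' Full fingerprint pipeline for one segment
#'
#' Composes [map_to_matrix()], [reduce_matrix()] and [to_coo()]: the segment's
#' paired values mark an `N x N` binary co-occurrence matrix, which is block-
#' binarized with block size `m` and stored as a COO fingerprint.
#'
#' @inheritParams map_to_matrix
#' @param m Reduction block size (default 10: 1300 -> 130 per side).
#' @return An `ecg_fingerprint`.
#' @examples
#' fp <- fingerprint_pipeline(c(5L, 6L, 7L), c(4L, 4L, 4L), N = 10, m = 1)
#' fp$coords
#' @export
fingerprint_pipeline <- function(x1, x2, N = 1300L, m = 10L) {
  to_coo(reduce_matrix(map_to_matrix(x1, x2, N), m), m = m)
}

#' Fingerprint every segment in a segment table
#'
#' @param segments An `ecg_segments` tibble (see [extract_segments()]).
#' @inheritParams fingerprint_pipeline
#' @return The input tibble with an `fp` list-column of fingerprints.
#' @export
fingerprint_segments <- function(segments, N = 1300L, m = 10L) {
  segments$fp <- map2(segments$x1, segments$x2,
                      function(a, b) fingerprint_pipeline(a, b, N = N, m = m))
  segments
}

# Linear cell keys (column-major) used by the sparse correlation fast path.
fp_keys <- function(fp) {
  (fp$coords[, "col"] - 1) * as.numeric(fp$d) + fp$coords[, "row"]
}

#' @export
print.ecg_fingerprint <- function(x, ...) {
  cat(sprintf("<ecg_fingerprint> %d x %d (block m = %s), %d nonzero cells\n",
              x$d, x$d, as.character(x$m), nrow(x$coords)))
  invisible(x)
}

#' @export
format.ecg_fingerprint <- function(x, ...) {
  sprintf("<fp %dx%d nnz=%d>", x$d, x$d, nrow(x$coords))
}

#' Write / read the plain-text fingerprint format
#'
#' Header line `d m`, then one `row col` pair per line, 1-based and
#' column-major; the round trip is exact.
#'
#' @param fp An `ecg_fingerprint`.
#' @param path File path.
#' @return `write_fingerprint()` returns `path` invisibly; `read_fingerprint()`
#'   returns the fingerprint.
#' @export
write_fingerprint <- function(fp, path) {
  header <- sprintf("%d %s", fp$d, as.character(fp$m))
  body <- sprintf("%d %d", fp$coords[, "row"], fp$coords[, "col"])
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  d <- as.integer(hd[1])
  m <- suppressWarnings(as.integer(hd[2]))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    return(new_fingerprint(d, m, matrix(integer(), ncol = 2)))
  }
  parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  coords <- matrix(as.integer(parts), ncol = 2)
  if (anyNA(coords)) abort("malformed fingerprint file")
  new_fingerprint(d, m, coords)
}
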