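# Fixtures are generated in code; nothing is read from disk.

# Random sparse binary fingerprint with ~density nonzero cells.
random_fp <- function(d = 20L, density = 0.1, m = NA_integer_) {
  n <- max(1L, stats::rbinom(1L, d * d, density))
  keys <- sample.int(d * d, n)
  row <- (keys - 1L) %% d + 1L
  col <- (keys - 1L) %/% d + 1L
  ord <- order(col, row)
  ecg2id:::new_fingerprint(d, m, cbind(row[ord], col[ord]))
}

# Random dense binary matrix.
random_binary_matrix <- function(nr = 20L, nc = nr, density = 0.15) {
  matrix(as.numeric(stats::runif(nr * nc) < density), nr, nc)
}

# Exhaustive block-any oracle for block binarization.
reduce_oracle <- function(M, m) {
  d <- ceiling(dim(M) / m)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      ri <- ((i - 1) * m + 1):min(i * m, nrow(M))
      ci <- ((j - 1) * m + 1):min(j * m, ncol(M))
      out[i, j] <- as.numeric(any(M[ri, ci, drop = FALSE] != 0))
    }
  }
  out
}

# Definitional Pearson correlation: means removed, covariances term by term.
cor_oracle <- function(A, B) {
  a <- as.vector(A)
  b <- as.vector(B)
  ca <- a - mean(a)
  cb <- b - mean(b)
  mean(ca * cb) / sqrt(mean(ca^2) * mean(cb^2))
}

# Term-by-term rank-weighted RBP distance over the full word range.
rbp_distance_oracle <- function(a, b) {
  m <- attr(a, "m_bits")
  num <- 0
  den <- 0
  for (w in 0:(2^m - 1)) {
    ia <- match(w, a$word)
    ib <- match(w, b$word)
    if (!is.na(ia) && !is.na(ib)) {
      num <- num + abs(a$rank[ia] - b$rank[ib]) * a$p[ia] * b$p[ib]
      den <- den + a$p[ia] * b$p[ib]
    }
  }
  if (den == 0) 1 else num / ((2^m - 1) * den)
}

# A small fingerprinted cohort shared across test files (computed once).
small_cohort_fps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_subjects = 6L, seed = 7L)
      segs <- prepare_cohort(generate_cohort(spec))
      cache <<- fingerprint_segments(segs)
    }
    cache
  }
})
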