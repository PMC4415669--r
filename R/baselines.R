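#' Reduced binary pattern encoding
#'
#' Symbolises a signal into up/down bits: bit `t` is 1 when sample `t + 1`
#' strictly increases over sample `t`, else 0. The output has one bit fewer
#' than the input has samples.
#'
#' @param x Numeric signal with at least 2 samples.
#' @return Integer 0/1 vector of length `length(x) - 1`.
#' @examples
#' rbp_encode(c(1, 3, 2, 2)) # 1 0 0
#' @export
rbp_encode <- function(x) {
  if (length(x) < 2L) abort("rbp_encode needs at least 2 samples")
  as.integer(diff(x) > 0)
}

#' Word frequencies and ranks of a reduced binary pattern
#'
#' Sliding windows of `m_bits` consecutive bits (stride 1, first bit most
#' significant) are read as integer words in `[0, 2^m_bits)`. Each observed
#' word gets its relative frequency `p` and a frequency rank (1 = most
#' frequent; ties broken by the smaller word value). Unobserved words carry
#' zero probability and are simply absent.
#'
#' @param bits 0/1 integer vector, length at least `m_bits`.
#' @param m_bits Word length in bits (default 8).
#' @return A tibble of class `rbp_model` with columns `word`, `p`, `rank`;
#'   attribute `m_bits`.
#' @export
rbp_stats <- function(bits, m_bits = 8L) {
  m_bits <- as.integer(m_bits)
  if (m_bits < 1L) abort("m_bits must be >= 1")
  nw <- length(bits) - m_bits + 1L
  if (nw < 1L) abort("bit sequence shorter than the word length")
  if (!all(bits %in% c(0L, 1L))) abort("bits must be 0/1")
  w <- integer(nw)
  for (b in seq_len(m_bits)) {
    w <- w * 2L + bits[b:(b + nw - 1L)]
  }
  counts <- table(w)
  word <- as.integer(names(counts))
  p <- as.numeric(counts) / nw
  ord <- order(-p, word)
  out <- tibble(word = word, p = p)[ord, ]
  out$rank <- seq_len(nrow(out))
  out <- arrange(out, .data$word)
  attr(out, "m_bits") <- m_bits
  class(out) <- c("rbp_model", class(out))
  out
}

#' Rank-weighted distance between two reduced binary patterns
#'
#' `D_m = sum_k |R1(w_k) - R2(w_k)| p1(w_k) p2(w_k) /
#' ((2^m - 1) sum_k p1(w_k) p2(w_k))`, summed over words observed in both
#' sequences. The `2^m - 1` factor bounds the distance to `[0, 1]`; identical
#' models are at distance 0. Disjoint word supports make the normaliser zero,
#' in which case the distance is defined as 1 (maximally dissimilar).
#'
#' @param a,b `rbp_model` objects with the same `m_bits`.
#' @return Distance in `[0, 1]`.
#' @export
rbp_distance <- function(a, b) {
  ma <- attr(a, "m_bits")
  mb <- attr(b, "m_bits")
  if (is.null(ma) || is.null(mb) || ma != mb) {
    abort("rbp models must share the same m_bits")
  }
  shared <- dplyr::inner_join(
    as_tibble(a), as_tibble(b),
    by = "word", suffix = c("1", "2")
  )
  denom <- sum(shared$p1 * shared$p2)
  if (nrow(shared) == 0L || denom == 0) {
    return(1)
  }
  num <- sum(abs(shared$rank1 - shared$rank2) * shared$p1 * shared$p2)
  num / ((2^ma - 1) * denom)
}

#' RBP score matrix for the shared evaluation harness
#'
#' Single-lead baseline: one lead of each segment is RBP-encoded and
#' summarised ([rbp_stats()]); the score of a probe against a subject is the
#' *negated* rank distance to that subject's template segment, so that larger
#' is better and the threshold machinery ([train_thresholds()],
#' [evaluate_scores()]) applies unchanged.
#'
#' @param segments Segment tibble with `subject_id`, `role`, and the lead
#'   column named by `lead`.
#' @param m_bits Word length in bits.
#' @param lead `"x1"` or `"x2"`: which lead to encode.
#' @param template_index Enrollment segment used as each subject's template.
#' @return A list with `scores` (probes x subjects matrix of negated
#'   distances), `truth` (probe subject ids), and `train` (per-subject
#'   within-subject score sets for threshold training).
#' @export
rbp_scores <- function(segments, m_bits = 8L, lead = "x1",
                       template_index = 7L) {
  models <- map(segments[[lead]], function(x) rbp_stats(rbp_encode(x), m_bits))
  segments$model <- models
  enroll <- filter(segments, .data$role == "enroll")
  probes <- filter(segments, .data$role == "probe")
  subj <- sort(unique(enroll$subject_id))
  templates <- map(subj, function(s) {
    tpl <- filter(enroll, .data$subject_id == s)$model
    if (template_index > length(tpl)) abort("template_index out of range")
    tpl[[template_index]]
  })
  scores <- t(vapply(probes$model, function(pm) {
    vapply(templates, function(tm) -rbp_distance(pm, tm), numeric(1))
  }, numeric(length(subj))))
  colnames(scores) <- subj
  train <- tibble(
    subject_id = subj,
    scores = map(subj, function(s) {
      tpl <- filter(enroll, .data$subject_id == s)$model
      pairs <- combn(length(tpl), 2L)
      apply(pairs, 2L, function(p) -rbp_distance(tpl[[p[1]]], tpl[[p[2]]]))
    })
  )
  list(scores = scores, truth = probes$subject_id, train = train)
}

#' Difference matrix of the basic two-dimensional method
#'
#' Elementwise `(A - B) / 2` of the densified fingerprints: zero when the two
#' fingerprints coincide, entries in `{-1/2, 0, 1/2}` otherwise.
#'
#' @param A,B `ecg_fingerprint`s (or matrices) of equal dimensions.
#' @return A dense numeric matrix.
#' @export
basic2d_diff <- function(A, B) {
  MA <- if (inherits(A, "ecg_fingerprint")) from_coo(A) else as.matrix(A)
  MB <- if (inherits(B, "ecg_fingerprint")) from_coo(B) else as.matrix(B)
  if (!all(dim(MA) == dim(MB))) abort("dimension mismatch")
  (MA - MB) / 2
}

#' Basic-2D similarity of a probe to a subject
#'
#' The probe's difference to the subject's template, correlated against the
#' subject's enrolled within-subject difference baseline. Genuine probes
#' differ from the template the way enrollment segments differ from each
#' other; impostor probes differ structurally, decorrelating from the
#' baseline.
#'
#' @param probe,template `ecg_fingerprint`s.
#' @param baseline A dense baseline difference matrix ([basic2d_diff()] of two
#'   within-subject templates).
#' @return Pearson correlation of the two difference matrices (0 when either
#'   is constant).
#' @export
basic2d_score <- function(probe, template, baseline) {
  d <- basic2d_diff(probe, template)
  va <- as.vector(d)
  vb <- as.vector(baseline)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    return(0)
  }
  as.numeric(cor(va, vb))
}

#' Basic-2D score matrix for the shared evaluation harness
#'
#' For each subject the baseline is the difference of its first two
#' enrollment templates other than `template_index`; training scores come
#' from the remaining enrollment segments played as genuine probes.
#'
#' @param probes Tibble of probe rows with `subject_id` and `fp`.
#' @param lib An `ecg_library`.
#' @param template_index Enrollment template each probe is differenced
#'   against.
#' @return A list with `scores`, `truth`, `train` (as [rbp_scores()]).
#' @export
basic2d_scores <- function(probes, lib, template_index = 7L) {
  if ("role" %in% names(probes)) probes <- filter(probes, .data$role == "probe")
  subj <- lib$subject_id
  pieces <- map(lib$templates, function(tpl) {
    others <- setdiff(seq_along(tpl), template_index)
    if (length(others) < 2L) abort("need at least 3 templates for basic2d")
    base_pair <- others[1:2]
    list(
      template = tpl[[template_index]],
      baseline = basic2d_diff(tpl[[base_pair[1]]], tpl[[base_pair[2]]]),
      train_idx = others,
      tpl = tpl
    )
  })
  scores <- t(vapply(probes$fp, function(p) {
    vapply(pieces, function(pc) basic2d_score(p, pc$template, pc$baseline),
           numeric(1))
  }, numeric(length(subj))))
  colnames(scores) <- subj
  train <- tibble(
    subject_id = subj,
    scores = map(pieces, function(pc) {
      vapply(pc$train_idx, function(k) {
        basic2d_score(pc$tpl[[k]], pc$template, pc$baseline)
      }, numeric(1))
    })
  )
  list(scores = scores, truth = probes$subject_id, train = train)
}

#' Fit the PCA two-lead fusion baseline
#'
#' Each training segment is vectorised as lead 1 followed by lead 2 (length
#' `2L`); the vectors are centred and the top `k` principal axes of their
#' covariance are retained. Rows of the projection matrix are orthonormal
#' eigenvectors; projected components of the training data are mutually
#' uncorrelated with non-increasing variance.
#'
#' @param segments Segment tibble (enrollment rows are used when a `role`
#'   column is present) with list-columns `x1`, `x2`.
#' @param k Number of retained components (default 19).
#' @return An `ecg_pca` object: `k`, `center` (mean vector), `rotation`
#'   (`2L x k`, orthonormal columns), `sdev`.
#' @export
pca_fit <- function(segments, k = 19L) {
  if ("role" %in% names(segments)) {
    segments <- filter(segments, .data$role == "enroll")
  }
  X <- do.call(rbind, map2(segments$x1, segments$x2, function(a, b) c(a, b)))
  k <- as.integer(k)
  max_rank <- min(nrow(X) - 1L, ncol(X))
  if (k < 1L || k > max_rank) {
    abort(sprintf("k = %d exceeds the available rank (%d)", k, max_rank))
  }
  pr <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(
    k = k,
    center = pr$center,
    rotation = pr$rotation[, seq_len(k), drop = FALSE],
    sdev = pr$sdev[seq_len(k)]
  ), class = "ecg_pca")
}

#' Project a segment into the fitted PCA feature space
#'
#' @param proj An [pca_fit()] object.
#' @param x1,x2 One segment's two leads.
#' @return Numeric vector of length `proj$k`.
#' @export
pca_project <- function(proj, x1, x2) {
  stopifnot(inherits(proj, "ecg_pca"))
  v <- c(x1, x2)
  if (length(v) != length(proj$center)) abort("segment length does not match the fit")
  drop((v - proj$center) %*% proj$rotation)
}

#' PCA score matrix for the shared evaluation harness
#'
#' Enrollment and probe segments are projected; a probe's score against a
#' subject is the Pearson correlation of the two k-dimensional feature
#' vectors (the same correlation-threshold machinery as the sparse
#' fingerprints, applied in PCA space).
#'
#' @param segments Segment tibble with `subject_id`, `role`, `x1`, `x2`.
#' @param proj A fitted [pca_fit()] projection.
#' @param template_index Enrollment segment used as each subject's template.
#' @return A list with `scores`, `truth`, `train` (as [rbp_scores()]).
#' @export
pca_scores <- function(segments, proj, template_index = 7L) {
  feats <- map2(segments$x1, segments$x2,
                function(a, b) pca_project(proj, a, b))
  segments$feat <- feats
  enroll <- filter(segments, .data$role == "enroll")
  probes <- filter(segments, .data$role == "probe")
  subj <- sort(unique(enroll$subject_id))
  vec_cor <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
    as.numeric(cor(u, v))
  }
  templates <- map(subj, function(s) {
    tpl <- filter(enroll, .data$subject_id == s)$feat
    if (template_index > length(tpl)) abort("template_index out of range")
    tpl[[template_index]]
  })
  scores <- t(vapply(probes$feat, function(pf) {
    vapply(templates, function(tf) vec_cor(pf, tf), numeric(1))
  }, numeric(length(subj))))
  colnames(scores) <- subj
  train <- tibble(
    subject_id = subj,
    scores = map(subj, function(s) {
      tpl <- filter(enroll, .data$subject_id == s)$feat
      pairs <- combn(length(tpl), 2L)
      apply(pairs, 2L, function(p) vec_cor(tpl[[p[1]]], tpl[[p[2]]]))
    })
  )
  list(scores = scores, truth = probes$subject_id, train = train)
}

#' Classify one probe segment with the PCA baseline
#'
#' @param x1,x2 Probe segment leads.
#' @param proj A fitted [pca_fit()] projection.
#' @param templates Tibble with `subject_id` and `feat` (list of projected
#'   template vectors, one per subject).
#' @param thresholds An `ecg_thresholds` model trained on projected features.
#' @return Accepted `subject_id` or `NA_character_`.
#' @export
pca_classify <- function(x1, x2, proj, templates, thresholds) {
  pf <- pca_project(proj, x1, x2)
  scores <- tibble(
    subject_id = templates$subject_id,
    r = map_dbl(templates$feat, function(tf) {
      if (stats::sd(pf) == 0 || stats::sd(tf) == 0) 0 else as.numeric(cor(pf, tf))
    })
  )
  classify_max_r(scores, thresholds)
}
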