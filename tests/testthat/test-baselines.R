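test_that("up/down encoding follows strict increases and drops one sample", {
  expect_equal(rbp_encode(c(1, 3, 2, 2)), c(1L, 0L, 0L))
  expect_equal(rbp_encode(1:10), rep(1L, 9))
  expect_equal(rbp_encode(rep(5, 8)), rep(0L, 7))
  expect_equal(rbp_encode(10:1), rep(0L, 9))
  set.seed(2)
  x <- rnorm(100)
  expect_length(rbp_encode(x), 99L)
  expect_error(rbp_encode(5), "at least 2")
})

test_that("word statistics count sliding windows most-significant-bit first", {
  m <- rbp_stats(c(1L, 0L, 1L, 0L), m_bits = 2L)
  expect_equal(m$p[m$word == 2L], 2 / 3)
  expect_equal(m$p[m$word == 1L], 1 / 3)
  expect_equal(m$rank[m$word == 2L], 1L)
  expect_equal(m$rank[m$word == 1L], 2L)

  z <- rbp_stats(rep(0L, 10), m_bits = 3L)
  expect_equal(nrow(z), 1L)
  expect_equal(z$word, 0L)
  expect_equal(z$p, 1)

  expect_error(rbp_stats(c(1L, 0L), m_bits = 3L), "shorter")
})

test_that("word frequencies match a brute-force window count and sum to one", {
  set.seed(31)
  bits <- as.integer(runif(300) > 0.5)
  mod <- rbp_stats(bits, m_bits = 4L)
  expect_equal(sum(mod$p), 1)
  # brute force: slide a window and assemble each word by hand
  counts <- integer(16)
  for (i in 1:(300 - 3)) {
    w <- sum(bits[i:(i + 3)] * c(8L, 4L, 2L, 1L))
    counts[w + 1L] <- counts[w + 1L] + 1L
  }
  seen <- which(counts > 0) - 1L
  expect_equal(sort(mod$word), sort(seen))
  expect_equal(mod$p[match(seen, mod$word)], counts[seen + 1L] / (300 - 3))
  # ranks are a permutation 1..n over represented words
  expect_equal(sort(mod$rank), seq_len(nrow(mod)))
})

test_that("rank-weighted distance is zero on identity, symmetric, bounded, and definitional", {
  set.seed(32)
  a <- rbp_stats(as.integer(runif(200) > 0.5), 4L)
  expect_equal(rbp_distance(a, a), 0)
  for (rep in 1:25) {
    b1 <- rbp_stats(as.integer(runif(150) > runif(1, 0.2, 0.8)), 4L)
    b2 <- rbp_stats(as.integer(runif(150) > runif(1, 0.2, 0.8)), 4L)
    d <- rbp_distance(b1, b2)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d, rbp_distance(b2, b1))
    expect_equal(d, rbp_distance_oracle(b1, b2), tolerance = 1e-12)
  }
  # disjoint supports are maximally dissimilar by convention
  up <- rbp_stats(rep(c(0L, 1L), 20), 2L)   # words 1, 2 only
  cc <- rbp_stats(rep(0L, 20), 2L)          # word 0 only
  expect_equal(rbp_distance(up, cc), 1)
  expect_error(rbp_distance(a, up), "m_bits")
})

test_that("difference matrices vanish on identity and are half-integer on disjoint support", {
  set.seed(41)
  A <- random_fp(15L, 0.2)
  expect_equal(basic2d_diff(A, A), matrix(0, 15, 15))
  # build disjoint fingerprints
  M1 <- matrix(0, 10, 10); M1[1:3, 1] <- 1
  M2 <- matrix(0, 10, 10); M2[5:7, 4] <- 1
  b <- basic2d_diff(to_coo(M1), to_coo(M2))
  expect_true(all(b[b != 0] %in% c(-0.5, 0.5)))
  expect_equal(sum(b != 0), 6)
  expect_error(basic2d_diff(A, random_fp(9L)), "mismatch")
})

test_that("the basic-2D method runs through the shared evaluation harness", {
  fps <- small_cohort_fps()
  lib <- build_library(fps)
  probes <- dplyr::filter(fps, role == "probe")
  sc <- basic2d_scores(probes, lib, template_index = 7L)
  expect_equal(dim(sc$scores), c(60L, 6L))
  rep_ <- evaluate_scores(sc$scores, sc$truth,
                          train_thresholds(sc$train, delta = 0))
  expect_true(all(c(rep_$fa, rep_$fr) >= 0 & c(rep_$fa, rep_$fr) <= 1))
  expect_equal(rep_$acc, 1 - (rep_$fa + rep_$fr) / 2, tolerance = 1e-12)
})

test_that("PCA fit yields orthonormal axes, uncorrelated scores, and exact low-rank recovery", {
  set.seed(51)
  # data on an exact k-dimensional affine subspace
  k <- 3L
  basis <- qr.Q(qr(matrix(rnorm(40 * k), 40, k)))
  center <- rnorm(40)
  V <- t(center + basis %*% matrix(rnorm(k * 30), k, 30))
  segs <- tibble::tibble(
    subject_id = "A",
    x1 = lapply(seq_len(30), function(i) V[i, 1:20]),
    x2 = lapply(seq_len(30), function(i) V[i, 21:40])
  )
  proj <- pca_fit(segs, k = k)
  expect_equal(crossprod(proj$rotation), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # zero reconstruction error on the rank-k fixture
  feats <- t(vapply(seq_len(30), function(i) pca_project(proj, V[i, 1:20], V[i, 21:40]),
                    numeric(k)))
  recon <- sweep(feats %*% t(proj$rotation), 2L, proj$center, "+")
  expect_equal(recon, V, tolerance = 1e-6, ignore_attr = TRUE)
  # projected components are mutually uncorrelated
  cv <- cov(feats)
  expect_true(all(abs(cv[upper.tri(cv)]) < 1e-8 * max(diag(cv))))
  # variance is non-increasing with component index
  expect_true(all(diff(proj$sdev) <= 1e-12))
  expect_error(pca_fit(segs, k = 40L), "rank")
})

test_that("the first principal axis separates two clusters split along one direction", {
  set.seed(52)
  n <- 20L
  shift <- c(rep(0, n / 2), rep(50, n / 2))
  segs <- tibble::tibble(
    subject_id = "A",
    x1 = lapply(seq_len(n), function(i) rnorm(10, shift[i], 0.5)),
    x2 = lapply(seq_len(n), function(i) rnorm(10, shift[i], 0.5))
  )
  proj <- pca_fit(segs, k = 1L)
  f <- vapply(seq_len(n), function(i) pca_project(proj, segs$x1[[i]], segs$x2[[i]]),
              numeric(1))
  expect_true(max(f[1:(n / 2)]) < min(f[(n / 2 + 1):n]) ||
                min(f[1:(n / 2)]) > max(f[(n / 2 + 1):n]))
})

test_that("PCA lead fusion identifies subjects through the shared machinery", {
  fps <- small_cohort_fps()
  proj <- pca_fit(fps, k = 19L)
  sc <- pca_scores(fps, proj, template_index = 7L)
  thr <- train_thresholds(sc$train, delta = 0)
  rep_ <- evaluate_scores(sc$scores, sc$truth, thr)
  expect_true(all(c(rep_$fa, rep_$fr) >= 0 & c(rep_$fa, rep_$fr) <= 1))

  # a probe equal to a training segment matches its own subject
  enroll <- dplyr::filter(fps, role == "enroll")
  templates <- enroll |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(feat = list(pca_project(
      proj, x1[[7]], x2[[7]]
    )), .groups = "drop")
  row7 <- dplyr::filter(enroll, subject_id == "S01")[7, ]
  got <- pca_classify(row7$x1[[1]], row7$x2[[1]], proj, templates, thr)
  expect_equal(got, "S01")
})

test_that("the RBP baseline produces a usable score matrix and training sets", {
  fps <- small_cohort_fps()
  sc <- rbp_scores(fps, m_bits = 8L, lead = "x1", template_index = 7L)
  expect_equal(dim(sc$scores), c(60L, 6L))
  expect_true(all(sc$scores >= -1 & sc$scores <= 0)) # negated distances
  rep_ <- evaluate_scores(sc$scores, sc$truth,
                          train_thresholds(sc$train, delta = 0))
  expect_equal(rep_$acc, 1 - (rep_$fa + rep_$fr) / 2, tolerance = 1e-12)
})
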