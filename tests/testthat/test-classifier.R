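fp_from_vec <- function(v, d) to_coo(matrix(v, d, d))

test_that("fingerprint correlation matches its dense definition", {
  set.seed(14)
  # self-correlation of a non-constant fingerprint is exactly 1
  fp <- random_fp(30L, 0.1)
  expect_equal(fp_correlation(fp, fp), 1)

  # cross-covariance cancels for these two 2x2 patterns
  a <- fp_from_vec(c(1, 0, 1, 0), 2L)
  b <- fp_from_vec(c(1, 0, 0, 1), 2L)
  expect_equal(fp_correlation(a, b), 0)

  # sparse closed form == term-by-term definitional oracle == stats::cor
  for (rep in 1:25) {
    x <- random_fp(40L, runif(1, 0.02, 0.4))
    y <- random_fp(40L, runif(1, 0.02, 0.4))
    r <- fp_correlation(x, y)
    expect_equal(r, cor_oracle(from_coo(x), from_coo(y)), tolerance = 1e-12)
    expect_equal(r, cor(as.vector(from_coo(x)), as.vector(from_coo(y))),
                 tolerance = 1e-12)
    expect_equal(r, fp_correlation(y, x), tolerance = 1e-12) # symmetry
    expect_gte(r, -1)
    expect_lte(r, 1)
  }
})

test_that("correlation is invariant under a shared permutation of cells", {
  set.seed(15)
  A <- random_binary_matrix(8L, 8L, 0.3)
  B <- random_binary_matrix(8L, 8L, 0.3)
  perm <- sample(64L)
  r1 <- fp_correlation(A, B)
  r2 <- fp_correlation(matrix(A[perm], 8, 8), matrix(B[perm], 8, 8))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("degenerate fingerprints correlate to 0 with a warning", {
  empty <- to_coo(matrix(0, 4, 4))
  full <- to_coo(matrix(1, 4, 4))
  normal <- fp_from_vec(c(1, rep(0, 15)), 4L)
  expect_warning(expect_equal(fp_correlation(empty, normal), 0), "constant")
  expect_warning(expect_equal(fp_correlation(full, normal), 0), "constant")
  expect_error(fp_correlation(normal, random_fp(5L)), "dimensions differ")
})

test_that("threshold training implements min-minus-delta and the mean", {
  thr <- train_thresholds(
    tibble::tibble(subject_id = "A", scores = list(c(0.90, 0.95, 0.92))),
    delta = 0.05
  )
  expect_equal(thr$epsilon, 0.85)
  expect_equal(thr$r_min, 0.90)
  expect_equal(thr$r_mean, mean(c(0.90, 0.95, 0.92)))

  thr0 <- train_thresholds(
    tibble::tibble(subject_id = c("A", "B"),
                   scores = list(c(0.7, 0.8), c(0.6, 0.9))),
    delta = 0
  )
  expect_equal(thr0$epsilon, thr0$r_min) # delta = 0 uses the training minimum
})

test_that("a library of identical templates trains epsilon = 1 - delta", {
  fp <- random_fp(20L, 0.2)
  lib <- build_library(tibble::tibble(
    subject_id = rep("A", 3), fp = list(fp, fp, fp)
  ))
  thr <- train_thresholds(lib, delta = 0.1)
  expect_equal(thr$r_min, 1)
  expect_equal(thr$epsilon, 0.9)
})

test_that("library construction validates its invariants", {
  set.seed(8)
  expect_error(
    build_library(tibble::tibble(subject_id = "A", fp = list(random_fp(10L)))),
    "at least 2"
  )
  expect_error(
    build_library(tibble::tibble(
      subject_id = c("A", "A"), fp = list(random_fp(10L), random_fp(12L))
    )),
    "same d"
  )
})

test_that("probe scoring covers every subject and ignores enrollment order", {
  set.seed(19)
  fps <- small_cohort_fps()
  lib <- build_library(fps)
  probe <- dplyr::filter(fps, role == "probe")$fp[[1]]
  sc <- score_all(probe, lib, template_index = 7L)
  expect_equal(nrow(sc), 6L)
  expect_true(all(sc$r >= -1 & sc$r <= 1))

  enroll <- dplyr::filter(fps, role == "enroll")
  ord <- unlist(lapply(sample(unique(enroll$subject_id)),
                       function(s) which(enroll$subject_id == s)))
  shuffled <- build_library(enroll[ord, ])
  sc2 <- score_all(probe, shuffled, template_index = 7L)
  expect_equal(sc2, sc)

  tpl <- lib$templates[[3]][[7]]
  self <- score_all(tpl, lib, template_index = 7L)
  expect_equal(self$r[self$subject_id == lib$subject_id[3]], 1)
  expect_error(score_all(probe, lib, template_index = 99L), "template_index")
})

test_that("max-correlation identification applies per-subject thresholds", {
  thr <- ecg2id:::new_thresholds(
    tibble::tibble(subject_id = c("A", "B"), r_min = 0.85, r_mean = 0.9,
                   epsilon = c(0.85, 0.85)),
    delta = 0
  )
  sc <- tibble::tibble(subject_id = c("A", "B"), r = c(0.95, 0.40))
  expect_equal(classify_max_r(sc, thr), "A")
  sc$r <- c(0.50, 0.40)
  expect_true(is.na(classify_max_r(sc, thr)))

  # ties on the maximum break toward the smallest subject label
  tie <- tibble::tibble(subject_id = c("B", "A"), r = c(0.9, 0.9))
  expect_equal(classify_max_r(tie, thr), "A")

  never <- ecg2id:::new_thresholds(
    tibble::tibble(subject_id = c("A", "B"), r_min = 0, r_mean = 0,
                   epsilon = -1), delta = 1)
  expect_equal(classify_max_r(sc, never), "A") # epsilon = -1 never rejects
  always <- ecg2id:::new_thresholds(
    tibble::tibble(subject_id = c("A", "B"), r_min = 1, r_mean = 1,
                   epsilon = 1), delta = 0)
  expect_true(is.na(classify_max_r(sc, always)))
})

test_that("least-squares identification minimises the squared deviation from the training mean", {
  thr <- ecg2id:::new_thresholds(
    tibble::tibble(subject_id = c("A", "B"), r_min = 0.8, r_mean = c(0.92, 0.90),
                   epsilon = 0.8), delta = 0)
  sc <- tibble::tibble(subject_id = c("A", "B"), r = c(0.91, 0.60))
  expect_equal(classify_least_squares(sc, thr), "A")

  sc$r <- c(0.5, 0.90) # exact match on B's mean
  expect_equal(classify_least_squares(sc, thr), "B")

  set.seed(27)
  for (rep in 1:20) {
    ids <- sprintf("S%02d", 1:10)
    thr_r <- ecg2id:::new_thresholds(
      tibble::tibble(subject_id = ids, r_min = 0, r_mean = runif(10),
                     epsilon = 0), delta = 0)
    sc_r <- tibble::tibble(subject_id = ids, r = runif(10))
    want <- ids[which.min((sc_r$r - thr_r$r_mean)^2)]
    expect_equal(classify_least_squares(sc_r, thr_r), want)
  }
})
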