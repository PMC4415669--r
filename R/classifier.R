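#' Pearson correlation of two fingerprints
#'
#' The two binary matrices are conceptually densified, flattened to vectors,
#' and correlated: `r = cov(a, b) / sqrt(cov(a, a) * cov(b, b))` with means
#' removed. For 0/1 matrices this reduces to a closed form in the nonzero
#' counts and their overlap, which is what is computed (no densification);
#' the dense definition is recovered exactly. If either flattened vector is
#' constant (an all-zero or all-one fingerprint) the correlation is undefined
#' and 0 is returned with a warning: a degenerate fingerprint matches nothing.
#'
#' @param a,b `ecg_fingerprint` objects with equal side length `d`, or plain
#'   numeric matrices of equal dimensions.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
fp_correlation <- function(a, b) {
  if (inherits(a, "ecg_fingerprint") && inherits(b, "ecg_fingerprint")) {
    if (a$d != b$d) abort("fingerprint dimensions differ")
    n <- as.numeric(a$d)^2
    na_ <- nrow(a$coords)
    nb_ <- nrow(b$coords)
    if (na_ == 0 || nb_ == 0 || na_ == n || nb_ == n) {
      warn("constant fingerprint: correlation undefined, returning 0")
      return(0)
    }
    ov <- length(intersect(fp_keys(a), fp_keys(b)))
    num <- n * ov - na_ * nb_
    den <- sqrt((n * na_ - na_^2) * (n * nb_ - nb_^2))
    return(num / den)
  }
  A <- if (inherits(a, "ecg_fingerprint")) from_coo(a) else as.matrix(a)
  B <- if (inherits(b, "ecg_fingerprint")) from_coo(b) else as.matrix(b)
  if (!all(dim(A) == dim(B))) abort("matrix dimensions differ")
  va <- as.vector(A)
  vb <- as.vector(B)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warn("constant input: correlation undefined, returning 0")
    return(0)
  }
  as.numeric(cor(va, vb))
}

#' Build an enrollment template library
#'
#' Groups enrolled fingerprints by subject. All fingerprints must share the
#' same side length `d` and block size `m`; every subject needs at least two
#' templates so that within-subject training correlations exist.
#'
#' @param fps A tibble with columns `subject_id` and `fp` (list of
#'   fingerprints), e.g. the output of [fingerprint_segments()]. If a `role`
#'   column is present only rows with `role == "enroll"` are used.
#' @return A tibble of class `ecg_library` with one row per subject (sorted by
#'   `subject_id`) and a `templates` list-column; attributes `d` and `m`.
#' @export
build_library <- function(fps) {
  if (!all(c("subject_id", "fp") %in% names(fps))) {
    abort("fps must have subject_id and fp columns")
  }
  if ("role" %in% names(fps)) fps <- filter(fps, .data$role == "enroll")
  ds <- map_int(fps$fp, function(f) f$d)
  ms <- map_int(fps$fp, function(f) f$m)
  if (length(unique(ds)) != 1L) abort("all fingerprints must share the same d")
  lib <- as_tibble(fps[c("subject_id", "fp")]) |>
    group_by(.data$subject_id) |>
    summarise(templates = list(.data$fp), .groups = "drop") |>
    arrange(.data$subject_id)
  n_t <- map_int(lib$templates, length)
  if (any(n_t < 2L)) {
    abort("every subject needs at least 2 enrollment templates")
  }
  attr(lib, "d") <- ds[1]
  attr(lib, "m") <- if (length(unique(ms)) == 1L) ms[1] else NA_integer_
  class(lib) <- c("ecg_library", class(lib))
  lib
}

#' Within-subject training correlations
#'
#' For each subject, the Pearson correlations over all unordered pairs of that
#' subject's enrollment templates (C(8,2) = 28 values with the default 8
#' templates). These are the training sets from which acceptance thresholds
#' are derived.
#'
#' @param lib An [build_library()] template library.
#' @return A tibble with `subject_id` and a `scores` list-column.
#' @export
training_scores <- function(lib) {
  tibble(
    subject_id = lib$subject_id,
    scores = map(lib$templates, function(tpl) {
      pairs <- combn(length(tpl), 2L)
      apply(pairs, 2L, function(p) fp_correlation(tpl[[p[1]]], tpl[[p[2]]]))
    })
  )
}

new_thresholds <- function(tbl, delta) {
  attr(tbl, "delta") <- delta
  class(tbl) <- c("ecg_thresholds", class(tbl))
  tbl
}

#' Train per-subject acceptance thresholds
#'
#' For subject i with training correlations R, the threshold is
#' `eps_i = min(R) - delta`: a probe is accepted by subject i only if it
#' correlates with i's template more strongly than `eps_i`. `r_mean` (the
#' average training correlation) is kept for the least-squares rule. `delta`
#' is a global margin; `delta = 0` uses the training minimum itself.
#'
#' @param lib An `ecg_library`, or a tibble with `subject_id` and `scores`
#'   list-column (per-subject training score sets, as from
#'   [training_scores()]) so baseline methods can reuse the same machinery.
#' @param delta Global threshold margin (default 0).
#' @return A tibble of class `ecg_thresholds` with columns `subject_id`,
#'   `r_min`, `r_mean`, `epsilon`; attribute `delta`.
#' @export
train_thresholds <- function(lib, delta = 0) {
  scores <- if (inherits(lib, "ecg_library")) training_scores(lib) else lib
  if (!all(c("subject_id", "scores") %in% names(scores))) {
    abort("need an ecg_library or a subject_id/scores table")
  }
  if (any(map_int(scores$scores, length) < 1L)) {
    abort("every subject needs at least one training score (>= 2 templates)")
  }
  out <- tibble(
    subject_id = scores$subject_id,
    r_min = map_dbl(scores$scores, min),
    r_mean = map_dbl(scores$scores, mean)
  ) |>
    mutate(epsilon = .data$r_min - delta) |>
    arrange(.data$subject_id)
  new_thresholds(out, delta)
}

#' Score a probe against every enrolled subject
#'
#' Correlates the probe fingerprint with template number `template_index` of
#' each subject. Any of the enrollment segments can serve as the comparison
#' template; index 7 is the default operating point.
#'
#' @param probe An `ecg_fingerprint`.
#' @param lib An `ecg_library`.
#' @param template_index Which enrollment template to compare against.
#' @return A tibble with `subject_id` and `r`, sorted by `subject_id`.
#' @export
score_all <- function(probe, lib, template_index = 7L) {
  n_t <- map_int(lib$templates, length)
  if (template_index < 1L || any(template_index > n_t)) {
    abort(sprintf("template_index %d not available for every subject", template_index))
  }
  tibble(
    subject_id = lib$subject_id,
    r = map_dbl(lib$templates, function(tpl) {
      fp_correlation(probe, tpl[[template_index]])
    })
  ) |> arrange(.data$subject_id)
}

#' Identify by the maximum-correlation rule
#'
#' The candidate is the subject with the largest correlation; the probe is
#' accepted as that subject only if the correlation exceeds the subject's
#' threshold, otherwise it is rejected as belonging to no enrolled subject.
#' Ties on the maximum go to the lexicographically smallest `subject_id`.
#'
#' @param scores A `subject_id`/`r` tibble from [score_all()].
#' @param thresholds An [train_thresholds()] model covering the same subjects.
#' @return The accepted `subject_id`, or `NA_character_` for rejection.
#' @export
classify_max_r <- function(scores, thresholds) {
  if (nrow(scores) == 0L) abort("empty score set")
  tab <- left_join(scores, thresholds, by = "subject_id") |>
    arrange(.data$subject_id)
  if (anyNA(tab$epsilon)) abort("thresholds missing for some scored subjects")
  i <- which.max(tab$r)
  if (tab$r[i] > tab$epsilon[i]) tab$subject_id[i] else NA_character_
}

#' Identify by the least-squares rule
#'
#' Computes `Delta_i = (r_i - rbar_i)^2` against each subject's mean training
#' correlation `rbar_i` and returns the subject minimising it. This rule is
#' closed-set: it always names some enrolled subject. Ties go to the
#' lexicographically smallest `subject_id`.
#'
#' @inheritParams classify_max_r
#' @return The winning `subject_id`.
#' @export
classify_least_squares <- function(scores, thresholds) {
  if (nrow(scores) == 0L) abort("empty score set")
  tab <- left_join(scores, thresholds, by = "subject_id") |>
    arrange(.data$subject_id)
  if (anyNA(tab$r_mean)) abort("thresholds missing for some scored subjects")
  delta2 <- (tab$r - tab$r_mean)^2
  tab$subject_id[which.min(delta2)]
}
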