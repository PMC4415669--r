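#' Score matrix of probes against every subject's template
#'
#' @param probes A tibble with a `fp` list-column (and optionally
#'   `subject_id` giving ground truth). If a `role` column is present only
#'   rows with `role == "probe"` are used.
#' @param lib An `ecg_library`.
#' @param template_index Enrollment template to compare against (default 7).
#' @return A numeric matrix, one row per probe and one column per subject
#'   (columns sorted by `subject_id`).
#' @export
score_matrix <- function(probes, lib, template_index = 7L) {
  if ("role" %in% names(probes)) probes <- filter(probes, .data$role == "probe")
  R <- t(vapply(
    probes$fp,
    function(p) score_all(p, lib, template_index)$r,
    numeric(nrow(lib))
  ))
  colnames(R) <- sort(lib$subject_id)
  rownames(R) <- probes$subject_id %||% NULL
  R
}

#' False-acceptance / false-rejection evaluation of a score matrix
#'
#' Genuine trials: each probe against its true subject under the
#' maximum-correlation rule; a genuine trial fails (counts toward FR) if the
#' probe is rejected outright *or* attributed to the wrong subject. Impostor
#' trials: each probe paired with every other subject as a claimed identity;
#' the claim is falsely accepted (counts toward FA) if the probe's correlation
#' with the claimed subject's template exceeds that subject's threshold.
#' Combined accuracy is `Acc = 1 - (FA + FR) / 2`.
#'
#' @param scores A probes-by-subjects score matrix ([score_matrix()]) with
#'   subject ids as column names.
#' @param truth Character vector of true subject ids, one per score row.
#' @param thresholds An `ecg_thresholds` model.
#' @return A one-row tibble of class `ecg_eval` with columns `fa`, `fr`,
#'   `mean_error`, `acc`, `success_rate`, `delta`; attribute `per_subject`
#'   holds the per-subject FA/FR breakdown.
#' @export
evaluate_scores <- function(scores, truth, thresholds) {
  if (nrow(scores) == 0L || ncol(scores) == 0L) abort("empty score matrix")
  if (length(truth) != nrow(scores)) abort("truth must match score rows")
  subj <- colnames(scores)
  thr <- arrange(as_tibble(thresholds), .data$subject_id)
  if (!setequal(thr$subject_id, subj)) abort("thresholds do not cover scored subjects")
  eps <- setNames(thr$epsilon, thr$subject_id)[subj]
  ord <- order(subj)
  scores <- scores[, ord, drop = FALSE]
  subj <- subj[ord]
  eps <- eps[ord]

  pred_idx <- max.col(scores, ties.method = "first")
  pred <- subj[pred_idx]
  pred_r <- scores[cbind(seq_len(nrow(scores)), pred_idx)]
  genuine_ok <- pred == truth & pred_r > eps[pred_idx]

  accept <- sweep(scores, 2L, eps, ">")
  impostor <- outer(truth, subj, "!=")
  fa <- sum(accept & impostor) / sum(impostor)
  fr <- 1 - mean(genuine_ok)

  per_subject <- tibble(
    subject_id = subj,
    fr = vapply(subj, function(s) {
      idx <- truth == s
      if (!any(idx)) NA_real_ else 1 - mean(genuine_ok[idx])
    }, numeric(1), USE.NAMES = FALSE),
    fa = vapply(seq_along(subj), function(j) {
      idx <- impostor[, j]
      if (!any(idx)) NA_real_ else mean(accept[idx, j])
    }, numeric(1))
  )

  out <- tibble(
    fa = fa, fr = fr,
    mean_error = (fa + fr) / 2,
    acc = accuracy(fa, fr),
    success_rate = 1 - fr,
    delta = attr(thresholds, "delta") %||% NA_real_
  )
  attr(out, "per_subject") <- per_subject
  class(out) <- c("ecg_eval", class(out))
  out
}

#' Combined identification accuracy from FA and FR rates
#'
#' `Acc = 1 - (FA + FR) / 2`: one minus the mean of the false-acceptance and
#' false-rejection rates.
#'
#' @param fa,fr Rates in `[0, 1]`.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' accuracy(0.0941, 0) # 0.95295
#' @export
accuracy <- function(fa, fr) {
  if (any(fa < 0 | fa > 1) || any(fr < 0 | fr > 1)) {
    abort("fa and fr must lie in [0, 1]")
  }
  1 - (fa + fr) / 2
}

#' End-to-end FA/FR report for probe fingerprints
#'
#' Convenience wrapper: scores the probes, trains thresholds at `delta`, and
#' evaluates.
#'
#' @param probes Tibble with `subject_id` (truth) and `fp` list-column; rows
#'   with `role == "probe"` are used if a `role` column exists.
#' @param lib An `ecg_library`.
#' @param delta Threshold margin.
#' @param template_index Enrollment template to compare against.
#' @return An `ecg_eval` one-row tibble (see [evaluate_scores()]).
#' @export
fa_fr <- function(probes, lib, delta = 0, template_index = 7L) {
  if ("role" %in% names(probes)) probes <- filter(probes, .data$role == "probe")
  R <- score_matrix(probes, lib, template_index)
  out <- evaluate_scores(R, probes$subject_id, train_thresholds(lib, delta))
  out$template_index <- template_index
  out
}

#' Fraction of genuine probes identified as their true subject
#'
#' Under `"maxr"` this is the complement of FR: a trial succeeds when the
#' maximum-correlation rule both picks the true subject and passes its
#' threshold. Under `"lsq"` the closed-set least-squares rule is used and
#' thresholds play no role in the decision.
#'
#' @inheritParams fa_fr
#' @param method `"maxr"` or `"lsq"`.
#' @return Success rate in `[0, 1]`.
#' @export
success_rate <- function(probes, lib, delta = 0, template_index = 7L,
                         method = c("maxr", "lsq")) {
  method <- match.arg(method)
  if ("role" %in% names(probes)) probes <- filter(probes, .data$role == "probe")
  if (nrow(probes) == 0L) abort("no genuine trials")
  thr <- train_thresholds(lib, delta)
  R <- score_matrix(probes, lib, template_index)
  if (method == "maxr") {
    return(evaluate_scores(R, probes$subject_id, thr)$success_rate)
  }
  pred <- vapply(seq_len(nrow(R)), function(i) {
    classify_least_squares(tibble(subject_id = colnames(R), r = R[i, ]), thr)
  }, character(1))
  mean(pred == probes$subject_id)
}

#' Evaluate across a grid of threshold margins
#'
#' Correlations are computed once; thresholds are retrained and the FA/FR
#' report recomputed at each `delta`. As `delta` grows, thresholds fall, so FR
#' is non-increasing and FA non-decreasing along the grid.
#'
#' @inheritParams fa_fr
#' @param deltas Margin grid (default 0 to 0.20 in steps of 0.01, 21 points).
#' @return A tibble of class `ecg_sweep`, one `ecg_eval` row per `delta`;
#'   attribute `best_delta` is the grid point minimising `(FA + FR) / 2`.
#' @export
sweep_delta <- function(probes, lib, deltas = seq(0, 0.20, by = 0.01),
                        template_index = 7L) {
  if (length(deltas) == 0L) abort("empty delta grid")
  if ("role" %in% names(probes)) probes <- filter(probes, .data$role == "probe")
  R <- score_matrix(probes, lib, template_index)
  train <- training_scores(lib)
  reports <- map(deltas, function(dl) {
    rep <- evaluate_scores(R, probes$subject_id, train_thresholds(train, dl))
    rep$delta <- dl
    rep$template_index <- template_index
    rep
  })
  out <- bind_rows(reports)
  attr(out, "best_delta") <- deltas[which.min(out$mean_error)]
  class(out) <- c("ecg_sweep", class(out))
  out
}

#' Per-template, per-delta evaluation grid
#'
#' One FA/FR report for every combination of enrollment template index and
#' threshold margin, supporting the choice of an operating point (the default
#' protocol elsewhere in the package is template 7, `delta = 0`).
#'
#' @inheritParams sweep_delta
#' @param template_indices Enrollment template indices to evaluate
#'   (default 1:8).
#' @return A tibble, one row per (template_index, delta).
#' @export
per_template_eval <- function(probes, lib, template_indices = 1:8,
                              deltas = seq(0, 0.20, by = 0.01)) {
  n_t <- map_int(lib$templates, length)
  if (any(max(template_indices) > n_t)) {
    abort("fewer enrollment templates than requested")
  }
  bind_rows(map(template_indices, function(t_idx) {
    sweep_delta(probes, lib, deltas, template_index = t_idx)
  }))
}
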