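#' Tidy a sparse fingerprint into its coordinate table
#'
#' @param x An `ecg_fingerprint`.
#' @param ... Unused.
#' @return A tibble with `row` and `col` (1-based, column-major order).
#' @method tidy ecg_fingerprint
#' @export
tidy.ecg_fingerprint <- function(x, ...) {
  as_tibble(x$coords)
}

#' One-row summary of a fingerprint
#'
#' @param x An `ecg_fingerprint`.
#' @param ... Unused.
#' @return A tibble with `d`, `m`, `nnz` and `density`.
#' @method glance ecg_fingerprint
#' @export
glance.ecg_fingerprint <- function(x, ...) {
  nnz <- nrow(x$coords)
  tibble(d = x$d, m = x$m, nnz = nnz, density = nnz / as.numeric(x$d)^2)
}

#' @method tidy ecg_thresholds
#' @export
tidy.ecg_thresholds <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Per-subject breakdown of an evaluation report
#'
#' @param x An `ecg_eval` report.
#' @param ... Unused.
#' @return The per-subject FA/FR tibble attached to the report.
#' @method tidy ecg_eval
#' @export
tidy.ecg_eval <- function(x, ...) {
  attr(x, "per_subject")
}

#' @method glance ecg_eval
#' @export
glance.ecg_eval <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Best operating point of a threshold sweep
#'
#' @param x An `ecg_sweep`.
#' @param ... Unused.
#' @return The sweep row minimising `(FA + FR) / 2`.
#' @method glance ecg_sweep
#' @export
glance.ecg_sweep <- function(x, ...) {
  tbl <- as_tibble(unclass(x))
  tbl[which.min(tbl$mean_error), ]
}

#' Plot a two-lead record
#'
#' @param object An `ecg_record`.
#' @param seconds How many seconds to show from the start (default 10).
#' @param ... Unused.
#' @return A ggplot with one facet per lead.
#' @method autoplot ecg_record
#' @export
autoplot.ecg_record <- function(object, seconds = 10, ...) {
  fs <- attr(object, "fs")
  n <- min(nrow(object), ceiling(seconds * fs))
  df <- tidyr::pivot_longer(
    as_tibble(object[seq_len(n), ]),
    c("lead1", "lead2"), names_to = "lead", values_to = "adc"
  )
  df$time_s <- (df$sample - 1) / fs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$adc)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "time (s)", y = "ADC value",
      title = sprintf("Two-lead ECG, subject %s", attr(object, "subject_id"))
    )
}

#' Plot a fingerprint's nonzero cells
#'
#' @param object An `ecg_fingerprint`.
#' @param ... Unused.
#' @return A ggplot of the reduced co-occurrence support.
#' @method autoplot ecg_fingerprint
#' @export
autoplot.ecg_fingerprint <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(width = 1, height = 1) +
    ggplot2::coord_fixed(xlim = c(1, object$d), ylim = c(1, object$d)) +
    ggplot2::labs(
      x = "lead-2 block", y = "lead-1 block",
      title = sprintf("Sparse fingerprint (%d nonzero cells)", nrow(df))
    )
}

#' Plot FA/FR/accuracy across a threshold sweep
#'
#' @param object An `ecg_sweep`.
#' @param ... Unused.
#' @return A ggplot of the three rates against `delta`, faceted by template
#'   index when several are present.
#' @method autoplot ecg_sweep
#' @export
autoplot.ecg_sweep <- function(object, ...) {
  df <- as_tibble(unclass(object)) |>
    tidyr::pivot_longer(c("fa", "fr", "acc"),
                        names_to = "rate", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = .data$value,
                                        colour = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(delta), y = "rate", colour = NULL)
  if ("template_index" %in% names(df) &&
      length(unique(df$template_index)) > 1L) {
    p <- p + ggplot2::facet_wrap(~template_index)
  }
  p
}
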