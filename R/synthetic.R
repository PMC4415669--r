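#' Specify a synthetic two-lead ECG cohort
#'
#' Defines the study conditions for a reproducible synthetic cohort: 18
#' subjects recorded at 128 Hz for at least 18 segments of 1280 samples each
#' (8 enrollment + 10 probe), integer ADC values that land in `[0, 1300)`
#' after the +500 shift, and between-subject morphology variation exceeding
#' within-subject noise. Each subject's beat is a sum of five Gaussian bumps
#' (P, Q, R, S, T) per lead; both leads share one beat-time process. Records
#' include white sensor noise, beat-interval jitter, a persistent low-
#' amplitude respiratory wander, and a baseline-settling drift that is
#' strongest at the start of the recording and decays away, as electrode
#' contact stabilises in long-term ambulatory recordings.
#'
#' @param n_subjects Number of subjects (default 18).
#' @param n_samples Record length in samples (default 18 x 1280 = 23040,
#'   i.e. 180 s at 128 Hz).
#' @param fs Sampling rate, Hz.
#' @param seed Master seed; everything downstream is a pure function of it.
#' @param amp_dispersion Between-subject log-sd of wave amplitudes.
#' @param center_sd_ms Between-subject sd of wave centres (ms).
#' @param width_dispersion Between-subject log-sd of wave widths.
#' @param period_mean_ms,period_sd_ms Between-subject heart-period
#'   distribution (ms).
#' @param jitter_sd_ms Within-subject beat-to-beat interval jitter (ms).
#' @param noise_sd Within-subject white noise sd (ADC units).
#' @param drift_amp Initial baseline-settling amplitude (ADC units).
#' @param drift_tau_s Settling time constant (s).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 18L, n_samples = 18L * 1280L, fs = 128,
                        seed = 42L, amp_dispersion = 0.2, center_sd_ms = 10,
                        width_dispersion = 0.15, period_mean_ms = 850,
                        period_sd_ms = 70, jitter_sd_ms = 15, noise_sd = 3,
                        drift_amp = 45, drift_tau_s = 25) {
  stopifnot(n_subjects >= 1, n_samples >= 1, fs > 0, noise_sd >= 0)
  structure(list(
    n_subjects = as.integer(n_subjects), n_samples = as.integer(n_samples),
    fs = fs, seed = as.integer(seed), amp_dispersion = amp_dispersion,
    center_sd_ms = center_sd_ms, width_dispersion = width_dispersion,
    period_mean_ms = period_mean_ms, period_sd_ms = period_sd_ms,
    jitter_sd_ms = jitter_sd_ms, noise_sd = noise_sd,
    drift_amp = drift_amp, drift_tau_s = drift_tau_s
  ), class = "cohort_spec")
}

# Population-average beat morphology: centre (ms relative to the R peak),
# width (ms), and per-lead amplitudes (ADC units) of the P, Q, R, S, T bumps.
# Two leads view the same activity from different angles, hence different
# projections of the same waves.
beat_template_base <- function() {
  list(
    wave = c("P", "Q", "R", "S", "T"),
    center_ms = c(-180, -35, 0, 30, 160),
    width_ms = c(25, 10, 14, 11, 50),
    amp1 = c(70, -110, 550, -170, 160),
    amp2 = c(45, -80, 420, -200, 210)
  )
}

#' Draw one subject's generative parameters
#'
#' Deterministic in `(spec$seed, index)`: the master seed fixes a vector of
#' per-subject seeds, and the subject's morphology, heart period, and drift
#' parameters are drawn from their between-subject distributions under that
#' subject seed. Distinct indices give distinct draws.
#'
#' @param spec A [cohort_spec()].
#' @param index Subject index in `1:n_subjects`.
#' @return An `ecg_subject_params` list.
#' @export
sample_subject <- function(spec, index) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > spec$n_subjects) {
    abort(sprintf("subject index %s out of range", as.character(index)))
  }
  seeds <- withr::with_seed(
    spec$seed,
    sample.int(.Machine$integer.max - 1L, spec$n_subjects)
  )
  sseed <- seeds[index]
  base <- beat_template_base()
  params <- withr::with_seed(sseed, list(
    subject_id = sprintf("S%02d", index),
    seed = sseed,
    record_seed = sample.int(.Machine$integer.max - 1L, 1L),
    fs = spec$fs,
    period_ms = max(500, rnorm(1, spec$period_mean_ms, spec$period_sd_ms)),
    jitter_sd_ms = spec$jitter_sd_ms,
    noise_sd = spec$noise_sd,
    center_ms = base$center_ms + rnorm(5, 0, spec$center_sd_ms),
    width_ms = base$width_ms * exp(rnorm(5, 0, spec$width_dispersion)),
    amp1 = base$amp1 * exp(rnorm(5, 0, spec$amp_dispersion)),
    amp2 = base$amp2 * exp(rnorm(5, 0, spec$amp_dispersion)),
    drift_amp = spec$drift_amp * exp(rnorm(1, 0, 0.3)),
    drift_tau_s = spec$drift_tau_s,
    drift_freq_hz = runif(1, 0.10, 0.35),
    drift_phase = runif(1, 0, 2 * pi),
    resp_amp = 6 * exp(rnorm(1, 0, 0.2)),
    resp_freq_hz = runif(1, 0.20, 0.35),
    resp_phase = runif(1, 0, 2 * pi)
  ))
  structure(params, class = "ecg_subject_params")
}

#' Generate one subject's two-lead record
#'
#' Both leads are rendered from a single jittered beat-time process: each beat
#' adds the subject's five Gaussian waves at lead-specific amplitudes. Shared
#' baseline drift (settling plus respiration, attenuated on lead 2), then
#' independent white noise, then rounding to integer ADC units. Fully
#' deterministic given the parameters.
#'
#' @param params An [sample_subject()] parameter set.
#' @param n_samples Record length in samples.
#' @return An [ecg_record()].
#' @export
generate_record <- function(params, n_samples = 18L * 1280L) {
  stopifnot(n_samples > 0)
  withr::with_seed(params$record_seed, {
    fs <- params$fs
    t_ms <- (seq_len(n_samples) - 1) / fs * 1000
    dur_ms <- n_samples / fs * 1000
    n_beats <- ceiling(dur_ms / params$period_ms) + 3L
    intervals <- pmax(300, params$period_ms +
                        rnorm(n_beats, 0, params$jitter_sd_ms))
    beat_ms <- cumsum(intervals) - intervals[1] + runif(1, 0, params$period_ms)
    beat_ms <- beat_ms - params$period_ms # allow a partial first beat
    beat_ms <- beat_ms[beat_ms > -400 & beat_ms < dur_ms + 400]

    lead1 <- numeric(n_samples)
    lead2 <- numeric(n_samples)
    for (b in beat_ms) {
      lo <- max(1L, floor((b - 450) / 1000 * fs) + 1L)
      hi <- min(n_samples, ceiling((b + 500) / 1000 * fs) + 1L)
      if (lo > hi) next
      tt <- t_ms[lo:hi] - b
      for (w in 1:5) {
        g <- exp(-((tt - params$center_ms[w])^2) /
                   (2 * params$width_ms[w]^2))
        lead1[lo:hi] <- lead1[lo:hi] + params$amp1[w] * g
        lead2[lo:hi] <- lead2[lo:hi] + params$amp2[w] * g
      }
    }
    t_s <- t_ms / 1000
    drift <- params$drift_amp * exp(-t_s / params$drift_tau_s) *
      sin(2 * pi * params$drift_freq_hz * t_s + params$drift_phase)
    resp <- params$resp_amp *
      sin(2 * pi * params$resp_freq_hz * t_s + params$resp_phase)
    lead1 <- lead1 + drift + resp + rnorm(n_samples, 0, params$noise_sd)
    lead2 <- lead2 + 0.7 * drift + 0.8 * resp +
      rnorm(n_samples, 0, params$noise_sd)
    ecg_record(round(lead1), round(lead2), params$subject_id, fs)
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `ecg_cohort` with columns `subject_id`, `seed`,
#'   `params` (list) and `record` (list of [ecg_record()]s); attribute
#'   `manifest` (spec, per-subject seeds and parameter hashes) allows exact
#'   regeneration.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  params <- map(seq_len(spec$n_subjects), function(i) sample_subject(spec, i))
  records <- map(params, generate_record, n_samples = spec$n_samples)
  out <- tibble(
    subject_id = map_chr(params, "subject_id"),
    seed = map_int(params, "seed"),
    params = params,
    record = records
  )
  attr(out, "manifest") <- list(
    spec = unclass(spec),
    subjects = tibble(
      subject_id = out$subject_id,
      seed = out$seed,
      params_hash = map_chr(params, rlang::hash)
    )
  )
  class(out) <- c("ecg_cohort", class(out))
  out
}

#' Write a cohort's regeneration manifest as JSON
#'
#' The manifest records the generating spec, per-subject seeds and parameter
#' hashes; together with [generate_cohort()] it allows bit-identical
#' regeneration of the cohort.
#'
#' @param cohort An `ecg_cohort`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  man <- attr(cohort, "manifest")
  if (is.null(man)) abort("cohort carries no manifest")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Shift and segment a cohort for enrollment and probing
#'
#' Applies the +`offset` value shift to every record and cuts
#' `n_enroll + n_probe` non-overlapping segments of length `L` from its start:
#' the first `n_enroll` are enrollment templates, the following `n_probe` are
#' probes taken after them (so probes never overlap enrollment data).
#'
#' @param cohort An `ecg_cohort`, or any tibble with `subject_id` and `record`
#'   columns.
#' @param L Segment length (default 1280).
#' @param n_enroll,n_probe Segments per subject for each role (defaults 8
#'   and 10).
#' @param offset Value shift applied before segmentation (default 500).
#' @return A tibble with `subject_id`, `segment`, `role` (`"enroll"` or
#'   `"probe"`), `origin`, `x1`, `x2`.
#' @export
prepare_cohort <- function(cohort, L = 1280L, n_enroll = 8L, n_probe = 10L,
                           offset = 500L) {
  segs <- map2(cohort$record, cohort$subject_id, function(rec, sid) {
    attr(rec, "subject_id") <- sid
    extract_segments(shift_offset(rec, offset), L = L,
                     n_segments = n_enroll + n_probe)
  })
  out <- bind_rows(segs)
  out$role <- rep(rep(c("enroll", "probe"), c(n_enroll, n_probe)),
                  times = nrow(cohort))
  out
}
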