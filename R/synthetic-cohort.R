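#' Profile specification for a synthetic patient recording
#'
#' Describes one synthetic patient: ward profile, recording length, per-channel
#' baselines, the slow latent trend driving each channel, measurement noise and
#' motion-artefact bursts. Defaults per profile emulate the three wards of the
#' study design: cardiology (~23 h recordings), postsurgical (~23 h) and
#' dialysis (~4 h sessions with a within-session systolic drift).
#'
#' Channels are generated at the vital-sign level (no waveform synthesis).
#' The latent trend of each channel is a mean-reverting (Ornstein-Uhlenbeck)
#' process with stationary standard deviation `trend_amplitude` and
#' correlation time `trend_timescale_s`. Systolic pressure is built as
#' diastolic + pulse pressure so that SBP > DBP holds at every clean sample,
#' and MAP = DBP + (SBP - DBP)/3. `trend_amplitude["sbp"]` drives the pulse
#' pressure; the systolic trend is the sum of the diastolic and
#' pulse-pressure latents.
#'
#' @param name Profile: `"cardiology"`, `"postsurgical"` or `"dialysis"`.
#' @param duration_min Recording length in minutes.
#' @param baseline Named numeric: central values for `hr` (BPM), `rr` (BPM),
#'   `sbp`, `dbp` (mmHg), `spo2` (%).
#' @param trend_timescale_s Correlation time of the slow latent process (s).
#' @param trend_amplitude Named numeric, stationary sd of the latent trend
#'   per channel (same names as `baseline`).
#' @param noise_sd Named numeric, white measurement-noise sd per channel.
#' @param artefact_rate_per_hour Expected motion-artefact bursts per hour.
#' @param artefact_amplitude Named numeric, burst excursion per channel.
#' @param sbp_drift_mmhg Total linear systolic drift over the recording
#'   (mmHg); defaults to -20 for dialysis sessions, 0 otherwise.
#' @param seed Integer seed for this patient's stream.
#' @param patient_id Identifier; autogenerated from profile and seed if NULL.
#'
#' @return An object of class `profile_spec` (a list).
#' @export
#' @examples
#' profile_spec("dialysis", duration_min = 240, seed = 11)
profile_spec <- function(name = c("cardiology", "postsurgical", "dialysis"),
                         duration_min = NULL,
                         baseline = NULL,
                         trend_timescale_s = NULL,
                         trend_amplitude = NULL,
                         noise_sd = NULL,
                         artefact_rate_per_hour = NULL,
                         artefact_amplitude = NULL,
                         sbp_drift_mmhg = NULL,
                         seed = 1L,
                         patient_id = NULL) {
  name <- match.arg(name)
  def <- vc_profile_defaults(name)
  merge_named <- function(user, default) {
    if (is.null(user)) return(default)
    out <- default
    out[names(user)] <- user
    out
  }
  spec <- list(
    name = name,
    duration_min = duration_min %||% def$duration_min,
    baseline = merge_named(baseline, def$baseline),
    trend_timescale_s = trend_timescale_s %||% def$trend_timescale_s,
    trend_amplitude = merge_named(trend_amplitude, def$trend_amplitude),
    noise_sd = merge_named(noise_sd, def$noise_sd),
    artefact_rate_per_hour = artefact_rate_per_hour %||% def$artefact_rate_per_hour,
    artefact_amplitude = merge_named(artefact_amplitude, def$artefact_amplitude),
    sbp_drift_mmhg = sbp_drift_mmhg %||% def$sbp_drift_mmhg,
    seed = as.integer(seed),
    patient_id = patient_id %||% sprintf("%s_%03d", name, as.integer(seed))
  )
  validate_profile_spec(spec)
  structure(spec, class = "profile_spec")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

vc_profile_defaults <- function(name) {
  base <- switch(name,
    cardiology = list(
      duration_min = 23 * 60,
      baseline = c(hr = 78, rr = 16, sbp = 124, dbp = 72, spo2 = 96.5),
      trend_amplitude = c(hr = 8, rr = 2.5, sbp = 9, dbp = 6, spo2 = 1.2),
      sbp_drift_mmhg = 0
    ),
    postsurgical = list(
      duration_min = 23 * 60,
      baseline = c(hr = 82, rr = 15, sbp = 118, dbp = 68, spo2 = 96),
      trend_amplitude = c(hr = 7, rr = 2, sbp = 7, dbp = 5, spo2 = 1.2),
      sbp_drift_mmhg = 0
    ),
    dialysis = list(
      duration_min = 4 * 60,
      baseline = c(hr = 75, rr = 14, sbp = 138, dbp = 76, spo2 = 96),
      trend_amplitude = c(hr = 9, rr = 2.5, sbp = 11, dbp = 6, spo2 = 1.2),
      sbp_drift_mmhg = -20
    )
  )
  c(base, list(
    trend_timescale_s = 7200,
    noise_sd = c(hr = 3, rr = 1.2, sbp = 4, dbp = 3, spo2 = 0.7),
    artefact_rate_per_hour = 4,
    artefact_amplitude = c(hr = 25, rr = 8, sbp = 25, dbp = 15, spo2 = 6)
  ))
}

validate_profile_spec <- function(spec) {
  ch <- c("hr", "rr", "sbp", "dbp", "spo2")
  stopifnot(all(ch %in% names(spec$baseline)))
  if (spec$duration_min < 1) {
    abort("duration_min too short: need at least one 1-min segment.")
  }
  b <- spec$baseline
  ok <- b[["hr"]] >= 30 && b[["hr"]] <= 200 &&
    b[["rr"]] >= 4 && b[["rr"]] <= 50 &&
    b[["sbp"]] >= 60 && b[["sbp"]] <= 220 &&
    b[["spo2"]] >= 70 && b[["spo2"]] <= 100 &&
    b[["dbp"]] < b[["sbp"]]
  if (!ok) abort("baseline outside physiologic ranges (HR 30-200, RR 4-50, SBP 60-220, SpO2 70-100, DBP < SBP).")
  amps <- c(spec$trend_amplitude, spec$noise_sd, spec$artefact_amplitude)
  if (any(amps < 0)) abort("all amplitudes must be >= 0.")
  if (spec$trend_timescale_s <= 0) abort("trend_timescale_s must be > 0.")
  if (spec$artefact_rate_per_hour < 0) abort("artefact_rate_per_hour must be >= 0.")
  invisible(spec)
}

## Stationary AR(1) discretisation of an OU process at 1 Hz.
ou_path <- function(n, amplitude, timescale_s) {
  if (amplitude == 0) return(rep(0, n))
  a <- exp(-1 / timescale_s)
  innov <- rnorm(n, sd = amplitude * sqrt(1 - a^2))
  s <- numeric(n)
  s[1] <- rnorm(1, sd = amplitude)
  if (n > 1) {
    ## filter() runs the AR(1) recursion s[t] = a s[t-1] + innov[t]
    s <- as.numeric(stats::filter(c(s[1], innov[-1]), a, method = "recursive"))
  }
  s
}

#' Generate one synthetic vital-sign recording
#'
#' Simulates a 1 Hz multichannel recording for one patient: slow latent
#' trends, additive white measurement noise and motion-artefact bursts
#' (duration 5-30 s, random sign) on a shared per-sample artefact mask.
#' The noise-free latents are returned alongside as ground truth.
#'
#' @param profile A [profile_spec()].
#' @return A list with elements
#'   * `recording`: tibble `timestamp_s, hr_bpm, rr_bpm, sbp_mmhg, dbp_mmhg,
#'     map_mmhg, spo2_pct, artefact`, with attributes `patient_id`, `profile`
#'     and `rate_hz`;
#'   * `truth`: tibble of `_clean`-suffixed noise-free channels, the latent
#'     trend states and the artefact mask.
#' @export
#' @examples
#' rec <- generate_recording(profile_spec("dialysis", duration_min = 120, seed = 3))
#' dim(rec$recording)
generate_recording <- function(profile) {
  stopifnot(inherits(profile, "profile_spec"))
  validate_profile_spec(profile)
  n <- as.integer(round(profile$duration_min * 60))
  if (n < 60) abort("duration too short for one 1-min segment.")

  set.seed(profile$seed)
  tau <- profile$trend_timescale_s
  amp <- profile$trend_amplitude
  b <- profile$baseline

  s_hr <- ou_path(n, amp[["hr"]], tau)
  s_rr <- ou_path(n, amp[["rr"]], tau)
  s_dbp <- ou_path(n, amp[["dbp"]], tau)
  s_pp <- ou_path(n, amp[["sbp"]], tau)
  s_spo2 <- ou_path(n, amp[["spo2"]], tau)

  drift <- if (profile$sbp_drift_mmhg != 0) {
    profile$sbp_drift_mmhg * (seq_len(n) - 1) / max(n - 1, 1)
  } else {
    rep(0, n)
  }

  pp_base <- b[["sbp"]] - b[["dbp"]]
  hr_clean <- pmax(b[["hr"]] + s_hr, 30)
  rr_clean <- pmax(b[["rr"]] + s_rr, 4)
  dbp_clean <- pmax(b[["dbp"]] + s_dbp, 30)
  pp_clean <- pmax(pp_base + s_pp + drift, 5)
  sbp_clean <- dbp_clean + pp_clean
  map_clean <- dbp_clean + pp_clean / 3
  spo2_clean <- pmin(pmax(b[["spo2"]] + s_spo2, 70), 100)

  ## Motion-artefact bursts: Poisson count, 5-30 s each, random sign/channel.
  mask <- rep(FALSE, n)
  burst <- matrix(0, nrow = n, ncol = 5,
                  dimnames = list(NULL, c("hr", "rr", "sbp", "dbp", "spo2")))
  hours <- n / 3600
  n_burst <- rpois(1, profile$artefact_rate_per_hour * hours)
  if (n_burst > 0) {
    starts <- sample.int(n, n_burst, replace = TRUE)
    durs <- sample(5:30, n_burst, replace = TRUE)
    for (j in seq_len(n_burst)) {
      idx <- starts[j]:min(starts[j] + durs[j] - 1, n)
      mask[idx] <- TRUE
      for (ch in colnames(burst)) {
        sgn <- sample(c(-1, 1), 1)
        burst[idx, ch] <- burst[idx, ch] + sgn * profile$artefact_amplitude[[ch]]
      }
    }
  }

  nz <- function(sdv) if (sdv > 0) rnorm(n, sd = sdv) else rep(0, n)
  hr_obs <- hr_clean + nz(profile$noise_sd[["hr"]]) + burst[, "hr"]
  rr_obs <- pmax(rr_clean + nz(profile$noise_sd[["rr"]]) + burst[, "rr"], 0)
  dbp_obs <- dbp_clean + nz(profile$noise_sd[["dbp"]]) + burst[, "dbp"]
  sbp_obs <- sbp_clean + nz(profile$noise_sd[["sbp"]]) + burst[, "sbp"]
  map_obs <- dbp_obs + (sbp_obs - dbp_obs) / 3
  spo2_obs <- pmin(pmax(spo2_clean + nz(profile$noise_sd[["spo2"]]) + burst[, "spo2"], 0), 100)

  ts <- seq_len(n) - 1
  recording <- tibble(
    timestamp_s = ts,
    hr_bpm = hr_obs, rr_bpm = rr_obs,
    sbp_mmhg = sbp_obs, dbp_mmhg = dbp_obs, map_mmhg = map_obs,
    spo2_pct = spo2_obs,
    artefact = mask
  )
  attr(recording, "patient_id") <- profile$patient_id
  attr(recording, "profile") <- profile$name
  attr(recording, "rate_hz") <- 1

  truth <- tibble(
    timestamp_s = ts,
    hr_clean = hr_clean, rr_clean = rr_clean,
    sbp_clean = sbp_clean, dbp_clean = dbp_clean, map_clean = map_clean,
    spo2_clean = spo2_clean,
    latent_hr = s_hr, latent_rr = s_rr, latent_dbp = s_dbp,
    latent_pp = s_pp, latent_spo2 = s_spo2,
    artefact = mask
  )
  list(recording = recording, truth = truth)
}

#' Generate a cohort of synthetic recordings
#'
#' @param profiles A list of [profile_spec()] objects (nonempty).
#' @return Named list of recording tibbles, one per profile, names being the
#'   unique patient ids. Duplicate seeds across patients trigger a warning.
#' @export
generate_cohort <- function(profiles) {
  if (length(profiles) == 0) abort("profiles must be a nonempty list.")
  seeds <- vapply(profiles, function(p) p$seed, integer(1))
  if (anyDuplicated(seeds)) warn("duplicate seeds across patients; recordings may coincide.")
  ids <- vapply(profiles, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
  }
  out <- purrr::map2(profiles, ids, function(p, id) {
    p$patient_id <- id
    generate_recording(p)$recording
  })
  names(out) <- ids
  out
}

#' Generate a learnable synthetic cohort
#'
#' Produces recordings whose future-window statistics are predictable from
#' the preceding 70 minutes: every channel is driven by a slow mean-reverting
#' latent process (correlation time 2 h), artefact bursts are disabled and
#' the white-noise floor is the trend amplitude divided by `snr`. Used to
#' demonstrate forecasting skill over the naive persistence baseline.
#'
#' @param n_patients Number of patients (>= 2).
#' @param snr Trend-amplitude to noise-sd ratio (> 0).
#' @param seed Master seed; per-patient streams are split deterministically.
#' @param duration_min Recording length per patient (default 360 min).
#' @return List of `list(recording, truth)` pairs as from
#'   [generate_recording()].
#' @export
generate_learnable_cohort <- function(n_patients, snr, seed = 1L,
                                      duration_min = 360) {
  if (n_patients < 2) abort("n_patients must be >= 2.")
  if (!is.numeric(snr) || snr <= 0) abort("snr must be > 0.")
  def_amp <- c(hr = 8, rr = 2.5, sbp = 9, dbp = 6, spo2 = 1.2)
  purrr::map(seq_len(n_patients), function(i) {
    p <- profile_spec(
      "cardiology",
      duration_min = duration_min,
      trend_timescale_s = 7200,
      trend_amplitude = def_amp,
      noise_sd = def_amp / snr,
      artefact_rate_per_hour = 0,
      seed = as.integer(seed) + 7919L * i,
      patient_id = sprintf("learn_%03d", i)
    )
    generate_recording(p)
  })
}

#' Write / read a recording in the per-patient CSV dialect
#'
#' Columns: `timestamp_s, hr_bpm, rr_bpm, sbp_mmhg, dbp_mmhg, map_mmhg,
#' spo2_pct, artefact`, one row per second. Ground truth, when given, goes to
#' a sidecar `<path>_clean.csv` with `_clean`-suffixed columns.
#'
#' @param recording Recording tibble from [generate_recording()].
#' @param path Output CSV path.
#' @param truth Optional ground-truth tibble for the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path, truth = NULL) {
  readr::write_csv(recording, path)
  if (!is.null(truth)) {
    side <- sub("\\.csv$", "", path)
    readr::write_csv(truth, paste0(side, "_clean.csv"))
  }
  invisible(path)
}

#' @rdname write_recording_csv
#' @param patient_id Patient id to attach on read.
#' @export
read_recording_csv <- function(path, patient_id = NULL) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  rec <- as_tibble(rec)
  attr(rec, "patient_id") <- patient_id %||% sub("\\.csv$", "", basename(path))
  attr(rec, "rate_hz") <- 1
  rec
}
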