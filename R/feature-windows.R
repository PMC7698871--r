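#' The 11 statistical features of one channel window
#'
#' From a one-hour (3600-sample) denoised window: `min, max, mean, median,
#' sd, var, energy` of the signal and `min, max, mean, sd` of its first
#' difference (3599 adjacent-sample differences). Energy is the sum of
#' squared samples. Sample (n-1) conventions are used for sd and variance.
#'
#' @param window Numeric vector of exactly 3600 finite samples.
#' @return Named numeric vector of length 11 in the fixed order
#'   `sig_min, sig_max, sig_mean, sig_median, sig_sd, sig_var, sig_energy,
#'   d1_min, d1_max, d1_mean, d1_sd`.
#' @export
#' @examples
#' extract_channel_features(rep(80, 3600))["sig_energy"]  # 3600 * 80^2
extract_channel_features <- function(window) {
  if (length(window) != 3600) {
    abort(sprintf("window must have exactly 3600 samples, got %d.", length(window)))
  }
  if (any(!is.finite(window))) abort("window values must be finite.")
  d1 <- diff(window)
  c(sig_min = min(window), sig_max = max(window), sig_mean = mean(window),
    sig_median = median(window), sig_sd = sd(window), sig_var = var(window),
    sig_energy = sum(window^2),
    d1_min = min(d1), d1_max = max(d1), d1_mean = mean(d1), d1_sd = sd(d1))
}

#' Feature layout of a prediction instance
#'
#' The input vector of an instance concatenates, for window A (the earlier
#' hour, minutes `[t_end-70, t_end-10)`) then window B (the later hour,
#' `[t_end-60, t_end)`), the 11 features of each of the 7 channels
#' (hr, rr, sbp, dbp, map, spo2, pp): 77 per window, 154 in total.
#'
#' @return Tibble `index, name, window, channel, feature` with one row per
#'   input dimension.
#' @export
feature_grid <- function() {
  feats <- c("sig_min", "sig_max", "sig_mean", "sig_median", "sig_sd",
             "sig_var", "sig_energy", "d1_min", "d1_max", "d1_mean", "d1_sd")
  g <- tidyr::crossing(window = c("A", "B"),
                       channel = factor(vc_feature_channels(),
                                        levels = vc_feature_channels()),
                       feature = factor(feats, levels = feats))
  g <- dplyr::arrange(g, .data$window, .data$channel, .data$feature)
  g$channel <- as.character(g$channel)
  g$feature <- as.character(g$feature)
  g$index <- seq_len(nrow(g))
  g$name <- sprintf("x_%03d", g$index)
  dplyr::select(g, "index", "name", "window", "channel", "feature")
}

## matrix of denoised channel values (columns hr..spo2 + derived pp)
channel_matrix <- function(recording) {
  cols <- vc_csv_columns()
  miss <- setdiff(unname(cols), names(recording))
  if (length(miss) > 0) {
    abort(paste("recording lacks channel columns:", paste(miss, collapse = ", ")))
  }
  m <- sapply(names(cols), function(ch) recording[[cols[[ch]]]])
  cbind(m, pp = m[, "sbp"] - m[, "dbp"])
}

target_column <- function(vital, stat, horizon) {
  sprintf("tgt_%s_%s_h%d", vital, stat, horizon)
}

#' Build one prediction instance
#'
#' Extracts the two overlapping feature windows ending at minute `t_end`
#' (window A spans minutes `[t_end-70, t_end-10)`, window B
#' `[t_end-60, t_end)`; 50 min / 3000 samples shared) and the future-window
#' target statistics (min, max, mean of HR, SBP, SpO2, RR, PP) for each
#' requested horizon whose full hour `[t_end+(h-1)*60, t_end+h*60)` lies
#' inside the recording. Targets for horizons that do not fit are `NA`.
#'
#' @param recording Denoised recording tibble at 1 Hz (see
#'   [denoise_recording()]); a `filtered`/`artefact` column, when present,
#'   feeds the instance quality flag.
#' @param t_end End of the 70-min feature span, in minutes (>= 70).
#' @param horizons Integer horizons in hours, subset of `1:3`.
#' @return One-row tibble: `patient_id, t_end, quality`, feature columns
#'   `x_001 ... x_154`, and target columns `tgt_<vital>_<stat>_h<h>`.
#' @export
build_instance <- function(recording, t_end, horizons = 1:3) {
  n <- nrow(recording)
  if (t_end < 70) abort("t_end must be >= 70 minutes.")
  if (t_end * 60 > n) abort("t_end exceeds the recording.")
  m <- channel_matrix(recording)
  chans <- vc_feature_channels()

  win_idx <- list(
    A = ((t_end - 70) * 60 + 1):((t_end - 10) * 60),
    B = ((t_end - 60) * 60 + 1):(t_end * 60)
  )
  x <- unlist(lapply(win_idx, function(idx) {
    as.numeric(vapply(chans, function(ch) extract_channel_features(m[idx, ch]),
                      numeric(11)))
  }), use.names = FALSE)
  grid <- feature_grid()
  names(x) <- grid$name

  artefact <- if ("artefact" %in% names(recording)) recording$artefact else rep(FALSE, n)
  span_idx <- ((t_end - 70) * 60 + 1):(t_end * 60)
  quality <- !any(artefact[span_idx])

  v2c <- vc_vital_channel()
  targets <- list()
  for (h in horizons) {
    idx <- ((t_end + (h - 1) * 60) * 60 + 1):((t_end + h * 60) * 60)
    fits <- max(idx) <= n
    for (v in vc_target_vitals()) {
      vals <- if (fits) m[idx, v2c[[v]]] else NULL
      targets[[target_column(v, "min", h)]] <- if (fits) min(vals) else NA_real_
      targets[[target_column(v, "max", h)]] <- if (fits) max(vals) else NA_real_
      targets[[target_column(v, "mean", h)]] <- if (fits) mean(vals) else NA_real_
    }
  }
  dplyr::bind_cols(
    tibble(patient_id = attr(recording, "patient_id") %||% "patient",
           t_end = t_end, quality = quality),
    as_tibble(as.list(x)),
    as_tibble(targets)
  )
}

#' Enumerate prediction instances over a recording
#'
#' Emits one instance every `step_min` minutes starting at `t_end = 70`,
#' keeping instances for which at least one requested horizon's target
#' window fits inside the recording.
#'
#' @inheritParams build_instance
#' @param step_min Emission step in minutes (default 10).
#' @return Tibble of instances (possibly empty, with a warning).
#' @export
enumerate_instances <- function(recording, step_min = 10, horizons = 1:3) {
  if (step_min < 1) abort("step_min must be >= 1.")
  n_min <- nrow(recording) %/% 60
  h_min <- min(horizons)
  last_ok <- n_min - h_min * 60
  ends <- seq(70, max(70, last_ok), by = step_min)
  ends <- ends[ends + h_min * 60 <= n_min & ends <= n_min]
  if (length(ends) == 0) {
    warn("recording too short for any prediction instance.")
    return(tibble())
  }
  purrr::map_dfr(ends, function(te) build_instance(recording, te, horizons))
}

#' Enumerate instances for a whole cohort
#'
#' @param recordings List of denoised recording tibbles.
#' @inheritParams enumerate_instances
#' @return Tibble of instances with a unique `id` column.
#' @export
cohort_instances <- function(recordings, step_min = 10, horizons = 1:3) {
  inst <- purrr::map_dfr(recordings, enumerate_instances,
                         step_min = step_min, horizons = horizons)
  if (nrow(inst) > 0) {
    inst <- dplyr::mutate(inst,
      id = sprintf("%s_t%04d", .data$patient_id, .data$t_end), .before = 1)
  }
  inst
}
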