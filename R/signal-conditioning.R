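#' Low-pass filter specification
#'
#' Fourth-order zero-phase Butterworth low-pass by default, cut-off 0.035 Hz
#' (the middle of the 0.03-0.04 Hz range appropriate for minute-scale
#' physiological trends at 1 Hz sampling).
#'
#' @param order Filter order (>= 1).
#' @param cutoff_hz Low-pass cut-off in Hz, below Nyquist.
#' @param rate_hz Sampling rate of the series the filter applies to.
#' @param zero_phase Apply forward-backward (zero phase)? Default TRUE.
#' @return Object of class `filter_spec` carrying the Butterworth
#'   coefficients.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 0.035, rate_hz = 1,
                        zero_phase = TRUE) {
  if (order < 1) abort("order must be >= 1.")
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    abort("cutoff_hz must lie in (0, rate_hz/2).")
  }
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  structure(
    list(order = order, cutoff_hz = cutoff_hz, rate_hz = rate_hz,
         zero_phase = zero_phase, b = as.numeric(bf$b), a = as.numeric(bf$a)),
    class = "filter_spec"
  )
}

## One IIR pass started in steady state for the first sample, so that a
## constant input is an exact fixed point (unit DC gain filters only).
iir_pass_ss <- function(b, a, x) {
  ord <- length(a) - 1
  n <- length(x)
  x_ext <- c(rep(x[1], ord), x)
  v <- stats::filter(x_ext, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[(ord + 1):(ord + n)]
  y <- stats::filter(v, -a[-1], method = "recursive", init = rep(x[1], ord))
  as.numeric(y)
}

#' Apply a zero-phase low-pass filter
#'
#' Forward-backward Butterworth filtering (squared magnitude response, zero
#' phase lag). Edges are handled by odd-reflection padding of `3 * order`
#' samples plus steady-state initial conditions, so a constant series is
#' returned unchanged and the operation is linear in its input. Series
#' shorter than the padding requirement (`3 * order + 1` samples) are passed
#' through unchanged with a warning.
#'
#' @param x Numeric series on a uniform grid at `spec$rate_hz`.
#' @param spec A [filter_spec()].
#' @return Filtered numeric series, same length as `x`.
#' @export
#' @examples
#' apply_zero_phase_lowpass(rep(80, 60), filter_spec())
apply_zero_phase_lowpass <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  pad <- 3 * spec$order
  if (n < pad + 1) {
    warn(sprintf("series of length %d shorter than padding requirement (%d); passthrough.",
                 n, pad + 1))
    return(x)
  }
  ## odd (point-symmetric) reflection about the end samples
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(left, x, right)
  y <- iir_pass_ss(spec$b, spec$a, xe)
  if (spec$zero_phase) {
    y <- rev(iir_pass_ss(spec$b, spec$a, rev(y)))
  }
  y[(pad + 1):(pad + n)]
}

#' Resample a series onto a uniform grid
#'
#' Linear interpolation onto an exact `1/rate_hz` grid spanning the input
#' range. Grid points falling inside an input gap wider than `max_gap_s`
#' seconds are flagged `quality = FALSE` (values are still interpolated so
#' downstream alignment is preserved).
#'
#' @param timestamps Strictly increasing sample times (s), length >= 2.
#' @param values Numeric values at `timestamps`.
#' @param rate_hz Target rate (default 1 Hz).
#' @param max_gap_s Gap threshold in seconds (default 5).
#' @return Tibble `timestamp_s, value, quality`.
#' @export
resample_uniform <- function(timestamps, values, rate_hz = 1, max_gap_s = 5) {
  if (length(timestamps) < 2) abort("need at least 2 samples.")
  if (any(diff(timestamps) <= 0)) abort("timestamps must be strictly increasing.")
  if (length(timestamps) != length(values)) abort("timestamps and values differ in length.")
  step <- 1 / rate_hz
  grid <- seq(timestamps[1], timestamps[length(timestamps)], by = step)
  out <- approx(timestamps, values, xout = grid, method = "linear")$y
  ## a grid point is low quality if its bracketing input interval is a gap
  gap_starts <- timestamps[-length(timestamps)][diff(timestamps) > max_gap_s]
  gap_ends <- timestamps[-1][diff(timestamps) > max_gap_s]
  quality <- rep(TRUE, length(grid))
  if (length(gap_starts) > 0) {
    for (g in seq_along(gap_starts)) {
      quality[grid > gap_starts[g] & grid < gap_ends[g]] <- FALSE
    }
  }
  tibble(timestamp_s = grid, value = out, quality = quality)
}

#' Denoise a 1 Hz series minute by minute
#'
#' Partitions the series into consecutive non-overlapping 60-sample segments
#' and zero-phase low-pass filters each segment independently. A trailing
#' partial segment (< 60 samples) is left unfiltered and flagged.
#'
#' @param x Numeric series at 1 Hz.
#' @param spec A [filter_spec()].
#' @param continuous If TRUE, filter the whole series in one pass and then
#'   segment (the alternative reading of per-minute denoising); default
#'   FALSE (independent per-segment filtering).
#' @return Tibble `sample, value, filtered` of the same length as `x`.
#' @export
denoise_by_minute <- function(x, spec = filter_spec(), continuous = FALSE) {
  n <- length(x)
  if (n == 0) abort("empty series.")
  if (continuous) {
    y <- apply_zero_phase_lowpass(x, spec)
    return(tibble(sample = seq_len(n), value = y, filtered = TRUE))
  }
  n_full <- n %/% 60
  y <- x
  filtered <- rep(FALSE, n)
  if (n_full > 0) {
    for (s in seq_len(n_full)) {
      idx <- ((s - 1) * 60 + 1):(s * 60)
      y[idx] <- apply_zero_phase_lowpass(x[idx], spec)
      filtered[idx] <- TRUE
    }
  }
  tibble(sample = seq_len(n), value = y, filtered = filtered)
}

#' Denoise every channel of a recording
#'
#' Applies [denoise_by_minute()] to each vital-sign column of a recording
#' tibble, leaving `timestamp_s` and `artefact` untouched.
#'
#' @param recording Recording tibble (CSV dialect columns).
#' @param spec A [filter_spec()], or a named list of specs keyed by channel
#'   (`hr`, `rr`, ...) for per-channel cut-offs.
#' @param continuous Passed to [denoise_by_minute()].
#' @return Recording tibble with denoised channels and a `filtered` column.
#' @export
denoise_recording <- function(recording, spec = filter_spec(),
                              continuous = FALSE) {
  cols <- vc_csv_columns()
  out <- recording
  filtered <- NULL
  for (ch in names(cols)) {
    col <- cols[[ch]]
    if (!col %in% names(recording)) next
    sp <- if (inherits(spec, "filter_spec")) spec else spec[[ch]] %||% filter_spec()
    d <- denoise_by_minute(recording[[col]], sp, continuous = continuous)
    out[[col]] <- d$value
    filtered <- if (is.null(filtered)) d$filtered else filtered & d$filtered
  }
  out$filtered <- filtered %||% rep(TRUE, nrow(recording))
  for (a in c("patient_id", "profile", "rate_hz")) {
    attr(out, a) <- attr(recording, a)
  }
  out
}
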