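#' Statistics of a one-minute segment
#'
#' @param segment Numeric vector, 1 to 60 finite samples.
#' @return One-row tibble `min, max, mean, median`.
#' @export
segment_statistics <- function(segment) {
  n <- length(segment)
  if (n < 1) abort("empty segment.")
  if (n > 60) abort("segment longer than one minute (60 samples).")
  if (any(!is.finite(segment))) abort("segment values must be finite.")
  tibble(min = min(segment), max = max(segment),
         mean = mean(segment), median = median(segment))
}

#' Per-minute EWS component stream
#'
#' Denoises each vital-sign channel minute by minute, computes the four
#' segment statistics (min, max, mean, median) of every complete 60-sample
#' segment and scores each statistic independently against the threshold
#' table. Segments overlapping artefact-flagged samples keep their scores
#' but carry `quality = FALSE`.
#'
#' @param recording Recording tibble at 1 Hz (CSV dialect columns).
#' @param table An [ews_table()].
#' @param spec A [filter_spec()].
#' @return Tibble `segment_index, channel, vital, stat, value, score,
#'   quality`, one row per segment x scoreable vital x statistic. A
#'   recording shorter than one minute yields an empty tibble with a
#'   warning.
#' @export
minute_ews_stream <- function(recording, table = zol_ews_table(),
                              spec = filter_spec()) {
  n <- nrow(recording)
  n_seg <- n %/% 60
  empty <- tibble(segment_index = integer(), channel = character(),
                  vital = character(), stat = character(),
                  value = double(), score = integer(), quality = logical())
  if (n_seg == 0) {
    warn("recording shorter than one minute; empty score stream.")
    return(empty)
  }
  cols <- vc_csv_columns()
  v2c <- vc_vital_channel()
  vitals <- intersect(vc_ews_vitals(), unique(table$vital[table$in_use]))
  artefact <- if ("artefact" %in% names(recording)) recording$artefact else rep(FALSE, n)
  seg_quality <- vapply(seq_len(n_seg), function(s) {
    !any(artefact[((s - 1) * 60 + 1):(s * 60)])
  }, logical(1))

  purrr::map_dfr(vitals, function(v) {
    ch <- v2c[[v]]
    col <- cols[[ch]]
    if (!col %in% names(recording)) {
      abort(sprintf("recording lacks channel column '%s' for vital %s.", col, v))
    }
    den <- denoise_by_minute(recording[[col]], spec)$value
    purrr::map_dfr(seq_len(n_seg), function(s) {
      seg <- den[((s - 1) * 60 + 1):(s * 60)]
      st <- segment_statistics(seg)
      vals <- c(min = st$min, max = st$max, mean = st$mean, median = st$median)
      tibble(segment_index = s, channel = ch, vital = v,
             stat = names(vals), value = unname(vals),
             score = score_component(v, unname(vals), table),
             quality = seg_quality[s])
    })
  })
}

#' Moving-median EWS component score
#'
#' Scores the median of a one-minute window sliding one sample at a time
#' over the denoised signal of one vital.
#'
#' @param recording Recording tibble at 1 Hz.
#' @param vital Which vital to score (`"HR"`, `"RR"`, `"SBP"`, `"SpO2"`).
#' @param table An [ews_table()].
#' @param spec A [filter_spec()].
#' @param window_s Window width in samples at 1 Hz (default 60).
#' @return Tibble `window_start, median, score` of length `N - window_s + 1`;
#'   empty if the recording is shorter than one window.
#' @export
moving_median_score <- function(recording, vital = "HR",
                                table = zol_ews_table(),
                                spec = filter_spec(), window_s = 60) {
  col <- vc_csv_columns()[[vc_vital_channel()[[vital]]]]
  x <- recording[[col]]
  if (length(x) < window_s) {
    return(tibble(window_start = integer(), median = double(), score = integer()))
  }
  den <- denoise_by_minute(x, spec)$value
  med <- zoo::rollapply(den, width = window_s, FUN = median, align = "left")
  tibble(window_start = seq_along(med), median = med,
         score = score_component(vital, med, table))
}
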