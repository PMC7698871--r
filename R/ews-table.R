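#' Early-warning-score threshold table
#'
#' An `ews_table` is a tibble of contiguous score bands, one row per band:
#' `vital, resolution, lower, upper, score, in_use`. Bounds are closed
#' intervals on the vital's resolution grid (`-Inf`/`Inf` at the ends);
#' values are rounded half-up to the resolution before lookup, which makes
#' the printed integer bands (e.g. "40-50" next to "51-100") total over the
#' reals. Scores are integers 0-3.
#'
#' @param bands Tibble/data.frame with columns
#'   `vital, resolution, lower, upper, score` and optionally `in_use`.
#' @return Validated `ews_table`.
#' @export
ews_table <- function(bands) {
  tb <- as_tibble(bands)
  req <- c("vital", "resolution", "lower", "upper", "score")
  if (!all(req %in% names(tb))) {
    abort(paste("ews_table needs columns:", paste(req, collapse = ", ")))
  }
  if (!"in_use" %in% names(tb)) tb$in_use <- TRUE
  if (!all(tb$score %in% 0:3)) abort("scores must be integers in 0-3.")
  for (v in unique(tb$vital)) {
    bb <- dplyr::arrange(dplyr::filter(tb, .data$vital == v), .data$lower)
    res <- bb$resolution[1]
    if (bb$lower[1] != -Inf || bb$upper[nrow(bb)] != Inf) {
      abort(sprintf("bands for %s must cover the whole real line.", v))
    }
    if (nrow(bb) > 1) {
      gaps <- bb$lower[-1] - bb$upper[-nrow(bb)]
      if (any(abs(gaps - res) > 1e-9)) {
        abort(sprintf("bands for %s are not contiguous on the %.9g grid.", v, res))
      }
    }
  }
  class(tb) <- c("ews_table", class(tb))
  tb
}

#' The ZOL hospital EWS threshold table
#'
#' Score bands per vital sign as used at Ziekenhuis Oost-Limburg: heart rate,
#' respiration rate, oxygen saturation and systolic blood pressure at 1-unit
#' resolution, body temperature at 0.1 degC. The temperature row is shipped
#' for completeness but flagged `in_use = FALSE` (the wearable measures no
#' temperature). The systolic table prints six bands; the high-score-3 slot
#' is unused, and a value on the shared printed boundary (180) takes the
#' lower band's score.
#'
#' @return An [ews_table()].
#' @export
#' @examples
#' score_component("SpO2", 89)  # 3
#' score_component("SBP", 65)   # 3
zol_ews_table <- function() {
  band <- function(vital, res, lower, upper, score, in_use = TRUE) {
    tibble(vital = vital, resolution = res, lower = lower, upper = upper,
           score = as.integer(score), in_use = in_use)
  }
  ews_table(dplyr::bind_rows(
    ## Heart rate (BPM): <40 | 40-50 | 51-100 | 101-110 | 111-130 | >130
    band("HR", 1, -Inf, 39, 2), band("HR", 1, 40, 50, 1),
    band("HR", 1, 51, 100, 0), band("HR", 1, 101, 110, 1),
    band("HR", 1, 111, 130, 2), band("HR", 1, 131, Inf, 3),
    ## Respiration rate (BPM): <9 | 9-14 | 15-20 | 21-30 | >30
    band("RR", 1, -Inf, 8, 2), band("RR", 1, 9, 14, 0),
    band("RR", 1, 15, 20, 1), band("RR", 1, 21, 30, 2),
    band("RR", 1, 31, Inf, 3),
    ## Oxygen saturation (%): <91 | 91-93 | 94-95 | >95
    band("SpO2", 1, -Inf, 90, 3), band("SpO2", 1, 91, 93, 2),
    band("SpO2", 1, 94, 95, 1), band("SpO2", 1, 96, Inf, 0),
    ## Systolic blood pressure (mmHg):
    ## <70 | 70-80 | 81-100 | 101-180 | 180-200 | >200 (boundary 180 -> lower band)
    band("SBP", 1, -Inf, 69, 3), band("SBP", 1, 70, 80, 2),
    band("SBP", 1, 81, 100, 1), band("SBP", 1, 101, 180, 0),
    band("SBP", 1, 181, 200, 1), band("SBP", 1, 201, Inf, 2),
    ## Temperature (degC): <35.1 | 35.1-36.5 | 36.6-37.5 | >37.5 (unused)
    band("Temp", 0.1, -Inf, 35.0, 2, FALSE), band("Temp", 0.1, 35.1, 36.5, 1, FALSE),
    band("Temp", 0.1, 36.6, 37.5, 0, FALSE), band("Temp", 0.1, 37.6, Inf, 1, FALSE)
  ))
}

## round half away from zero on the resolution grid (vitals are positive)
round_to_resolution <- function(x, res) {
  floor(x / res + 0.5) * res
}

#' Score a vital-sign value against an EWS table
#'
#' The value is rounded half-up to the vital's resolution, then matched to
#' exactly one band of the table.
#'
#' @param vital Vital name present in the table (e.g. `"HR"`, `"SpO2"`).
#' @param value Numeric value(s) in channel units; must be finite.
#' @param table An [ews_table()]; defaults to [zol_ews_table()].
#' @return Integer score(s) in 0-3, vectorised over `value`.
#' @export
score_component <- function(vital, value, table = zol_ews_table()) {
  stopifnot(inherits(table, "ews_table"))
  bb <- dplyr::filter(table, .data$vital == !!vital)
  if (nrow(bb) == 0) abort(sprintf("unknown vital '%s'.", vital))
  if (any(!is.finite(value))) abort("value must be finite.")
  res <- bb$resolution[1]
  v <- round_to_resolution(value, res)
  ## half a grid step of slack so rounded values sit strictly inside bands
  hit <- outer(v, bb$lower - res / 2, ">=") & outer(v, bb$upper + res / 2, "<")
  if (any(rowSums(hit) != 1)) abort("value did not match exactly one band.")
  as.integer(bb$score[apply(hit, 1, which)])
}

#' Read / write an EWS table as YAML
#'
#' Hot-swappable per-hospital threshold configuration: one entry per vital
#' with its resolution and an ordered band list.
#'
#' @param table An [ews_table()].
#' @param path YAML file path.
#' @return `read_ews_table()` returns an [ews_table()];
#'   `write_ews_table()` returns `path` invisibly.
#' @export
write_ews_table <- function(table, path) {
  stopifnot(inherits(table, "ews_table"))
  out <- lapply(split(table, table$vital), function(bb) {
    bb <- bb[order(bb$lower), ]
    list(
      resolution = bb$resolution[1],
      in_use = bb$in_use[1],
      bands = lapply(seq_len(nrow(bb)), function(i) {
        list(lower = if (is.infinite(bb$lower[i])) ".inf" else bb$lower[i],
             upper = if (is.infinite(bb$upper[i])) ".inf" else bb$upper[i],
             score = bb$score[i])
      })
    )
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_ews_table
#' @export
read_ews_table <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- purrr::imap(raw, function(entry, vital) {
    purrr::map(entry$bands, function(b) {
      lo <- if (identical(b$lower, ".inf")) -Inf else as.numeric(b$lower)
      up <- if (identical(b$upper, ".inf")) Inf else as.numeric(b$upper)
      tibble(vital = vital, resolution = entry$resolution,
             lower = lo, upper = up, score = as.integer(b$score),
             in_use = entry$in_use %||% TRUE)
    })
  })
  ews_table(dplyr::bind_rows(purrr::flatten(rows)))
}
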