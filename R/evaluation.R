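#' Naive persistence (NaiveMean) prediction
#'
#' Forecasts every horizon's future-window mean as the mean of the most
#' recent 60-min feature window (window B), read from the instance's own
#' feature vector.
#'
#' @param instances Tibble of prediction instances (see
#'   [cohort_instances()]).
#' @param vital One of `"HR"`, `"SBP"`, `"SpO2"`, `"RR"`, `"PP"`.
#' @return Numeric vector, one prediction per instance row.
#' @export
naive_predict_mean <- function(instances, vital) {
  ch <- unname(vc_vital_channel()[vital])
  if (is.na(ch)) abort(sprintf("unknown vital '%s'.", vital))
  g <- feature_grid()
  row <- dplyr::filter(g, .data$window == "B", .data$channel == ch,
                       .data$feature == "sig_mean")
  col <- row$name
  if (!col %in% names(instances)) abort(sprintf("missing feature column %s.", col))
  instances[[col]]
}

#' Mean absolute percentage error
#'
#' `100 * mean(|y_true - y_pred| / |y_true|)`. Zero-valued truths are
#' excluded from the mean; the number excluded is reported via a message.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return MAPE in percent.
#' @export
mape <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("length mismatch.")
  zero <- y_true == 0
  if (any(zero)) {
    message(sprintf("mape: excluded %d zero-valued truths.", sum(zero)))
  }
  keep <- !zero
  if (!any(keep)) abort("no nonzero truths to average over.")
  100 * mean(abs(y_true[keep] - y_pred[keep]) / abs(y_true[keep]))
}

#' Leave-one-instance-out evaluation
#'
#' For each instance and each requested target (vital x statistic x
#' horizon), the training pool is every other instance (any patient); the
#' localized kNN-LS-SVM predicts the held-out target. The held-out instance
#' is excluded from the pool before neighbour selection, so it can never
#' appear in its own neighbourhood. For the mean statistic the NaiveMean
#' baseline is evaluated alongside.
#'
#' @param instances Tibble from [cohort_instances()] (needs `id` and the
#'   feature/target columns).
#' @param hp A [hyperparams()] object (k = 25 for cardiology/postsurgical,
#'   15 for dialysis).
#' @param targets Tibble with columns `vital, stat, horizon`; defaults to
#'   the +1 h mean of every target vital.
#' @return Tibble of prediction records: `id, vital, statistic, horizon,
#'   y_true, y_model, y_naive`.
#' @export
loio_evaluate <- function(instances, hp = hyperparams(),
                          targets = tidyr::crossing(
                            vital = vc_target_vitals(),
                            stat = "mean", horizon = 1L)) {
  if (!"id" %in% names(instances)) {
    instances$id <- sprintf("inst_%05d", seq_len(nrow(instances)))
  }
  feat_cols <- feature_grid()$name
  X <- as.matrix(instances[, feat_cols])
  N <- nrow(X)
  if (N < hp$k + 1) abort("pool smaller than k + 1 instances.")

  purrr::pmap_dfr(targets, function(vital, stat, horizon) {
    tcol <- target_column(vital, stat, horizon)
    if (!tcol %in% names(instances)) {
      abort(sprintf("instances lack target column %s.", tcol))
    }
    y <- instances[[tcol]]
    usable <- which(is.finite(y))
    naive <- if (stat == "mean") naive_predict_mean(instances, vital) else rep(NA_real_, N)
    preds <- purrr::map_dbl(usable, function(i) {
      pool <- setdiff(usable, i)
      predict_local(X[i, ], X[pool, , drop = FALSE], y[pool], hp)
    })
    tibble(id = instances$id[usable], vital = vital, statistic = stat,
           horizon = as.integer(horizon), y_true = y[usable],
           y_model = preds, y_naive = naive[usable])
  })
}

#' Attach EWS component scores to prediction records
#'
#' Scores the true and predicted values of the mean statistic for the
#' scoreable vitals; the EWS error is `|score(pred) - score(true)|`.
#'
#' @param records Prediction records from [loio_evaluate()].
#' @param table An [ews_table()].
#' @param vitals Vitals to score; must be EWS vitals (PP is rejected).
#' @param stat Which statistic feeds the scores (default `"mean"`).
#' @return Records filtered to `vitals`/`stat`, with columns `ews_true,
#'   ews_model, ews_naive, ews_error, ews_error_naive` added.
#' @export
ews_error_records <- function(records, table = zol_ews_table(),
                              vitals = vc_ews_vitals(), stat = "mean") {
  bad <- setdiff(vitals, vc_ews_vitals())
  if (length(bad) > 0) {
    abort(paste("not an EWS vital:", paste(bad, collapse = ", ")))
  }
  rec <- dplyr::filter(records, .data$vital %in% vitals, .data$statistic == stat)
  purrr::map_dfr(split(rec, rec$vital), function(rr) {
    v <- rr$vital[1]
    rr$ews_true <- score_component(v, rr$y_true, table)
    rr$ews_model <- score_component(v, rr$y_model, table)
    rr$ews_naive <- if (all(is.finite(rr$y_naive))) {
      score_component(v, rr$y_naive, table)
    } else {
      NA_integer_
    }
    rr$ews_error <- abs(rr$ews_model - rr$ews_true)
    rr$ews_error_naive <- abs(rr$ews_naive - rr$ews_true)
    rr
  })
}

#' Normalized EWS-error histogram
#'
#' @param errors Integer vector with values in `{0, 1, 2, 3}`.
#' @return Named numeric vector of four bin masses summing to 1.
#' @export
ews_error_histogram <- function(errors) {
  if (length(errors) == 0) abort("empty error vector.")
  if (!all(errors %in% 0:3)) abort("EWS errors must be in {0, 1, 2, 3}.")
  counts <- tabulate(errors + 1, nbins = 4)
  stats::setNames(counts / length(errors), paste0("err", 0:3))
}

#' Paired t-test between two absolute-error series
#'
#' Two-sided paired t-test on the per-instance differences. Zero-variance
#' differences are a degenerate case: the report carries `t = 0, p = 1` for
#' identical arrays and a signed infinite statistic otherwise.
#'
#' @param ae_model,ae_naive Equal-length (>= 2) paired error vectors.
#' @param alpha Significance level (default 0.01).
#' @return One-row tibble `t, df, p_value, alpha, significant, degenerate`.
#' @export
paired_ttest_report <- function(ae_model, ae_naive, alpha = 0.01) {
  n <- length(ae_model)
  if (n != length(ae_naive)) abort("length mismatch.")
  if (n < 2) abort("need at least 2 paired observations.")
  d <- ae_model - ae_naive
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble(t = 0, df = n - 1, p_value = 1, alpha = alpha,
                    significant = FALSE, degenerate = TRUE))
    }
    return(tibble(t = sign(mean(d)) * Inf, df = n - 1, p_value = 0,
                  alpha = alpha, significant = TRUE, degenerate = TRUE))
  }
  tt <- t.test(ae_model, ae_naive, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, alpha = alpha,
         significant = tt$p.value < alpha, degenerate = FALSE)
}

#' Full evaluation report
#'
#' Summarises prediction records the way the study reports them: per
#' (vital, statistic, horizon) absolute-error summaries and MAPE; per vital
#' a normalized EWS-error histogram for the model and the naive baseline
#' (mean statistic); per (vital, horizon) a paired t-test of model vs naive
#' absolute errors on the mean statistic.
#'
#' @param records Prediction records from [loio_evaluate()].
#' @param table An [ews_table()].
#' @param alpha Significance level for the paired t-tests.
#' @return Object of class `vc_report` with elements `errors` (tibble),
#'   `histograms` (tibble), `ttests` (tibble) and `records`.
#' @export
evaluation_report <- function(records, table = zol_ews_table(), alpha = 0.01) {
  errors <- records |>
    dplyr::group_by(.data$vital, .data$statistic, .data$horizon) |>
    dplyr::summarise(
      n = dplyr::n(),
      mae_model = mean(abs(.data$y_model - .data$y_true)),
      mae_naive = mean(abs(.data$y_naive - .data$y_true)),
      mape_model = mape(.data$y_true, .data$y_model),
      mape_naive = if (all(is.finite(.data$y_naive))) {
        mape(.data$y_true, .data$y_naive)
      } else {
        NA_real_
      },
      .groups = "drop"
    )

  scored <- ews_error_records(records, table)
  histograms <- purrr::map_dfr(split(scored, scored$vital), function(rr) {
    hm <- ews_error_histogram(rr$ews_error)
    hn <- if (all(is.finite(rr$ews_error_naive))) {
      ews_error_histogram(rr$ews_error_naive)
    } else {
      rep(NA_real_, 4)
    }
    tibble(vital = rr$vital[1], error = 0:3, model = unname(hm),
           naive = unname(hn), n = nrow(rr))
  })

  ttests <- records |>
    dplyr::filter(.data$statistic == "mean", is.finite(.data$y_naive)) |>
    dplyr::group_by(.data$vital, .data$horizon) |>
    dplyr::group_modify(function(g, key) {
      paired_ttest_report(abs(g$y_model - g$y_true),
                          abs(g$y_naive - g$y_true), alpha = alpha)
    }) |>
    dplyr::ungroup()

  structure(list(errors = errors, histograms = histograms,
                 ttests = ttests, records = records, alpha = alpha),
            class = "vc_report")
}

#' @export
print.vc_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d prediction records\n", nrow(x$records)))
  cat("\nPer-target error summary:\n")
  print(x$errors, n = Inf)
  cat("\nPaired t-tests (model vs naive absolute error, mean statistic):\n")
  print(x$ttests, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vc_report <- function(x, ...) x$errors

#' @exportS3Method generics::glance
glance.vc_report <- function(x, ...) {
  tibble(
    n_records = nrow(x$records),
    n_targets = nrow(x$errors),
    mean_mape_model = mean(x$errors$mape_model),
    mean_mape_naive = mean(x$errors$mape_naive, na.rm = TRUE),
    all_significant = all(x$ttests$significant),
    alpha = x$alpha
  )
}
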