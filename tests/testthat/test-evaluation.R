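test_that("the naive predictor is the previous hour's mean", {
  rec <- make_constant_recording(140)
  inst <- build_instance(rec, 70, horizons = 1)
  expect_equal(naive_predict_mean(inst, "HR"), 80)
  expect_equal(naive_predict_mean(inst, "HR"), inst$tgt_HR_mean_h1)  # error 0

  ## a step of +12 BPM between the feature span and the target window
  vals <- c(rep(80, 70 * 60), rep(92, 70 * 60))
  step_rec <- make_series_recording(vals)
  step_inst <- build_instance(step_rec, 70, horizons = 1)
  expect_equal(naive_predict_mean(step_inst, "HR"), 80)
  expect_equal(abs(naive_predict_mean(step_inst, "HR") - step_inst$tgt_HR_mean_h1),
               12)
  expect_error(naive_predict_mean(step_inst, "EtCO2"), "unknown vital")
})

test_that("MAPE matches hand arithmetic and excludes zero truths", {
  expect_equal(mape(c(100, 50), c(100, 50)), 0)
  expect_equal(mape(c(100, 50), c(104, 51)), 3)
  expect_message(m <- mape(c(0, 100), c(5, 110)), "excluded 1")
  expect_equal(m, 10)
  expect_error(suppressMessages(mape(0, 1)), "no nonzero")
  expect_error(mape(1:3, 1:2), "length")
})

test_that("oxygen-saturation MAPE is bounded for in-range values", {
  ## SpO2 lives in (80, 100]; predictions in that range can miss by at most
  ## 20 points against a truth of at least 80, bounding MAPE by 25%
  set.seed(9)
  y <- runif(500, 80.001, 100)
  yhat <- runif(500, 80.001, 100)
  expect_lte(mape(y, yhat), 25)
})

test_that("EWS errors of predictions follow the threshold table", {
  records <- tibble::tibble(
    id = c("a", "b", "c"),
    vital = c("HR", "SpO2", "HR"),
    statistic = "mean", horizon = 1L,
    y_true = c(105, 89, 80), y_model = c(95, 97, 80.2),
    y_naive = c(105, 89, 80)
  )
  scored <- ews_error_records(records)
  hr <- dplyr::filter(scored, id == "a")
  expect_equal(hr$ews_true, 1L)    # 105 in 101-110
  expect_equal(hr$ews_model, 0L)   # 95 in 51-100
  expect_equal(hr$ews_error, 1L)
  sp <- dplyr::filter(scored, id == "b")
  expect_equal(sp$ews_error, 3L)   # 89 -> 3 vs 97 -> 0
  expect_equal(dplyr::filter(scored, id == "c")$ews_error, 0L)
  expect_error(ews_error_records(records, vitals = c("HR", "PP")),
               "not an EWS vital")
})

test_that("EWS-error histograms are normalized and average under concatenation", {
  expect_equal(unname(ews_error_histogram(c(0, 0, 0))), c(1, 0, 0, 0))
  expect_equal(unname(ews_error_histogram(c(0, 1, 0))), c(2 / 3, 1 / 3, 0, 0))
  expect_error(ews_error_histogram(integer(0)), "empty")
  expect_error(ews_error_histogram(c(0, 4)), "\\{0, 1, 2, 3\\}")

  set.seed(13)
  e1 <- sample(0:3, 17, replace = TRUE)
  e2 <- sample(0:3, 29, replace = TRUE)
  h12 <- ews_error_histogram(c(e1, e2))
  h_avg <- (17 * ews_error_histogram(e1) + 29 * ews_error_histogram(e2)) / 46
  expect_equal(h12, h_avg)
  expect_equal(sum(h12), 1, tolerance = 1e-9)
})

test_that("the paired t-test report matches closed forms and symmetries", {
  same <- paired_ttest_report(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  r <- paired_ttest_report(c(2, 4, 6), c(1, 2, 3))   # differences 1, 2, 3
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)  # 3.4641
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)
  expect_false(r$significant)

  flipped <- paired_ttest_report(c(1, 2, 3), c(2, 4, 6))
  expect_equal(flipped$t, -r$t)
  expect_equal(flipped$p_value, r$p_value)

  const_shift <- paired_ttest_report(c(2, 3, 4), c(1, 2, 3))
  expect_true(const_shift$degenerate)
  expect_equal(const_shift$t, Inf)
})

test_that("identical pools give zero leave-one-instance-out error", {
  rec <- make_constant_recording(140)
  inst <- dplyr::bind_rows(replicate(12, build_instance(rec, 70, horizons = 1),
                                     simplify = FALSE))
  inst$id <- sprintf("i%02d", seq_len(nrow(inst)))
  out <- loio_evaluate(inst, hyperparams(k = 5),
                       targets = tibble::tibble(vital = "HR", stat = "mean",
                                                horizon = 1L))
  expect_equal(out$y_model, out$y_true, tolerance = 1e-6)
  expect_equal(out$y_naive, out$y_true)
})

test_that("the held-out instance never predicts itself", {
  ## two interleaved clusters where each instance's nearest OTHER point has a
  ## different response; self-inclusion at k = 1 would return the own value
  set.seed(17)
  fx <- learnable_fixture()
  inst <- fx$instances[1:40, ]
  g <- feature_grid()$name
  out <- loio_evaluate(inst, hyperparams(k = 1),
                       targets = tibble::tibble(vital = "HR", stat = "mean",
                                                horizon = 1L))
  X <- as.matrix(inst[, g])
  y <- inst$tgt_HR_mean_h1
  for (i in seq_len(nrow(inst))) {
    sel <- knn_select(X[i, ], X[-i, , drop = FALSE], 1)
    expect_equal(out$y_model[i], y[-i][sel$indices], tolerance = 1e-9)
  }
  expect_false(any(abs(out$y_model - out$y_true) < 1e-12))
})

test_that("loio_evaluate rejects pools smaller than the neighbourhood", {
  rec <- make_constant_recording(140)
  inst <- dplyr::bind_rows(replicate(5, build_instance(rec, 70, horizons = 1),
                                     simplify = FALSE))
  expect_error(loio_evaluate(inst, hyperparams(k = 25)), "smaller than k")
})

test_that("a perfect predictor yields zero MAPE and a unit histogram mass at zero", {
  fx <- learnable_fixture()
  inst <- fx$instances[1:30, ]
  perfect <- purrr::map_dfr(c("HR", "SBP", "SpO2", "RR"), function(v) {
    truth <- inst[[paste0("tgt_", v, "_mean_h1")]]
    tibble::tibble(id = inst$id, vital = v, statistic = "mean", horizon = 1L,
                   y_true = truth, y_model = truth,
                   y_naive = naive_predict_mean(inst, v))
  })
  expect_equal(mape(perfect$y_true, perfect$y_model), 0)
  scored <- ews_error_records(perfect)
  expect_equal(unname(ews_error_histogram(scored$ews_error)), c(1, 0, 0, 0))
})

test_that("the evaluation report aggregates errors, histograms and tests", {
  records <- loio_fixture()
  rep <- evaluation_report(records)
  expect_s3_class(rep, "vc_report")
  expect_equal(nrow(rep$errors), 5)          # 5 vitals x mean x +1 h
  expect_true(all(rep$histograms$model >= 0))
  sums <- rep$histograms |>
    dplyr::group_by(vital) |>
    dplyr::summarise(s = sum(model))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_equal(nrow(rep$ttests), 5)
  expect_true(all(c("t", "p_value", "significant") %in% names(rep$ttests)))

  td <- tidy(rep)
  expect_equal(td, rep$errors)
  gl <- glance(rep)
  expect_equal(gl$n_records, nrow(records))

  p1 <- plot_absolute_error(records)
  p2 <- plot_ews_error_histograms(rep)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_s3_class(autoplot(rep, "histogram"), "ggplot")
})
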