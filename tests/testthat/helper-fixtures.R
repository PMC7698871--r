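# Fixtures built in code: constant / piecewise recordings and a cached
# learnable cohort shared by the evaluation and acceptance tests.

make_constant_recording <- function(n_min, hr = 80, rr = 14, sbp = 120,
                                    dbp = 70, spo2 = 97, id = "const") {
  n <- n_min * 60
  rec <- tibble::tibble(
    timestamp_s = seq_len(n) - 1,
    hr_bpm = rep(hr, n), rr_bpm = rep(rr, n),
    sbp_mmhg = rep(sbp, n), dbp_mmhg = rep(dbp, n),
    map_mmhg = rep(dbp + (sbp - dbp) / 3, n),
    spo2_pct = rep(spo2, n),
    artefact = rep(FALSE, n)
  )
  attr(rec, "patient_id") <- id
  attr(rec, "rate_hz") <- 1
  rec
}

## all channels equal to a shared series (handy for window-geometry checks)
make_series_recording <- function(values, id = "series") {
  n <- length(values)
  rec <- tibble::tibble(
    timestamp_s = seq_len(n) - 1,
    hr_bpm = values, rr_bpm = values, sbp_mmhg = values + 50,
    dbp_mmhg = values, map_mmhg = values + 50 / 3, spo2_pct = values,
    artefact = rep(FALSE, n)
  )
  attr(rec, "patient_id") <- id
  attr(rec, "rate_hz") <- 1
  rec
}

noise_free_profile <- function(name = "cardiology", duration_min = 120,
                               seed = 1L) {
  profile_spec(
    name, duration_min = duration_min,
    noise_sd = c(hr = 0, rr = 0, sbp = 0, dbp = 0, spo2 = 0),
    artefact_rate_per_hour = 0, seed = seed
  )
}

## Learnable-cohort fixture: generated once per test run at the study
## conditions (10 patients, snr = 5, 6 h recordings) and reused.
learnable_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_learnable_cohort(10, snr = 5, seed = 42)
      recs <- lapply(cohort, function(p) denoise_recording(p$recording))
      instances <- cohort_instances(recs, horizons = 1)
      cache <<- list(cohort = cohort, instances = instances)
    }
    cache
  }
})

loio_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- learnable_fixture()
      cache <<- loio_evaluate(fx$instances, hyperparams(k = 25))
    }
    cache
  }
})
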