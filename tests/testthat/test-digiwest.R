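calib <- default_mw_calibration()

test_that("reconstruct_lane re-indexes without touching intensities", {
  flat <- data.frame(fraction_index = 0:95, mfi = 100)
  lane <- reconstruct_lane(flat, calib)
  expect_true(all(lane$intensity == 100))
  expect_false(is.unsorted(lane$kda))

  # orientation invariance: reversing the calibration direction gives the
  # same lane after sorting
  rev_calib <- data.frame(fraction_index = 0:95, kda = rev(calib$kda))
  prof <- gaussian_profile(1000, 55, 1.5)
  l1 <- reconstruct_lane(prof, calib)
  prof_rev <- prof
  prof_rev$fraction_index <- 95 - prof_rev$fraction_index
  l2 <- reconstruct_lane(prof_rev, rev_calib)
  expect_equal(l1$kda, l2$kda)
  expect_equal(l1$intensity, l2$intensity)

  # peak lands at the fraction nearest the generating MW
  peak_kda <- l1$kda[which.max(l1$intensity)]
  expect_equal(peak_kda, calib$kda[which.min(abs(calib$kda - 55))])

  expect_error(reconstruct_lane(flat[-3, ], calib), "missing fraction index 2")
  expect_error(reconstruct_lane(rbind(flat, flat[1, ]), calib), "duplicate")
})

test_that("peak integral matches the analytic Gaussian area", {
  # AFI ~ A * sigma * sqrt(2*pi) for a noise-free peak, window +/- 4 sigma
  sigma <- 1.5
  for (amp in c(1000, 2000)) {
    for (mw in c(30, 55, 120)) {
      prof <- gaussian_profile(amp, mw, sigma)
      lane <- reconstruct_lane(prof, calib)
      dlog <- abs(diff(log(range(calib$kda)))) / 95
      w <- mw * (exp(4 * sigma * dlog) - 1)
      rec <- integrate_peak(lane, list(analyte_id = "A", expected_mw = mw,
                                       window_kda = w))
      expect_equal(rec$afi, amp * sigma * sqrt(2 * pi), tolerance = 0.01)
    }
  }
})

test_that("peak integral is invariant to a constant baseline", {
  sigma <- 1.5
  prof0 <- gaussian_profile(1000, 55, sigma, baseline = 0)
  lane0 <- reconstruct_lane(prof0, calib)
  dlog <- abs(diff(log(range(calib$kda)))) / 95
  spec <- list(analyte_id = "A", expected_mw = 55,
               window_kda = 55 * (exp(4 * sigma * dlog) - 1))
  afi0 <- integrate_peak(lane0, spec)$afi
  for (b in c(50, 200, 5000)) {
    lane_b <- reconstruct_lane(gaussian_profile(1000, 55, sigma, baseline = b),
                               calib)
    expect_equal(integrate_peak(lane_b, spec)$afi, afi0, tolerance = 0.02)
  }
})

test_that("peak integral scales linearly with amplitude and floors at zero", {
  spec <- list(analyte_id = "A", expected_mw = 55)
  a1 <- integrate_peak(reconstruct_lane(gaussian_profile(500, 55, 1.5), calib),
                       spec)$afi
  a2 <- integrate_peak(reconstruct_lane(gaussian_profile(1000, 55, 1.5), calib),
                       spec)$afi
  expect_equal(a2 / a1, 2, tolerance = 0.01)

  # flat lane: background equals signal, AFI exactly 0
  flat <- reconstruct_lane(data.frame(fraction_index = 0:95, mfi = 300), calib)
  expect_equal(integrate_peak(flat, spec)$afi, 0)

  expect_error(integrate_peak(flat, list(analyte_id = "A", expected_mw = 500)),
               "outside calibrated range")
})

test_that("AFI matrix composition, missing lanes, and truth recovery", {
  cfg <- cohort_config(n_pairs = 2, n_analytes = 3, noise_cv = 0,
                       baseline_level = 10, loading_cv = 0.1, n_immune = 0,
                       seed = 13)
  sim <- simulate_digiwest_cohort(cfg)
  em <- build_afi_matrix(sim$profiles, sim$specs, sim$calibration,
                         samples = sim$metadata)

  # composition: every cell equals the standalone integrate_peak result
  prof <- sim$profiles[sim$profiles$sample_id == "P02_PTT" &
                         sim$profiles$antibody_id == "Ab002", ]
  lane <- reconstruct_lane(prof, sim$calibration)
  solo <- integrate_peak(lane, sim$specs[2, ], "P02_PTT")
  expect_identical(em$values["A002", "P02_PTT"], solo$afi)

  # noise-free truth recovery within 1% relative error
  lf <- sim$truth$loading_factor[colnames(em$values)]
  expected <- sweep(sim$truth$true_abundance[, colnames(em$values)], 2, lf, `*`)
  expect_lt(max(abs(em$values / expected - 1)), 0.01)

  # a missing lane is flagged, not dropped
  drop <- sim$profiles[!(sim$profiles$sample_id == "P01_PDM" &
                           sim$profiles$antibody_id == "Ab001"), ]
  expect_warning(
    em2 <- build_afi_matrix(drop, sim$specs, sim$calibration),
    "missing lane")
  expect_true(is.na(em2$values["A001", "P01_PDM"]))
  expect_true(em2$below_limit["A001", "P01_PDM"])
  expect_equal(sum(is.na(em2$values)), 1L)
})

test_that("total-protein normalization rescales by the cohort median", {
  v <- matrix(c(100, 200, 300, 400), 2, 2,
              dimnames = list(c("A1", "A2"), c("S1", "S2")))
  em <- expression_matrix(v, "raw_afi")

  eq <- normalize_total_protein(em, data.frame(sample_id = c("S1", "S2"),
                                               total_protein = c(8, 8)))
  expect_equal(eq$values, v)
  expect_identical(eq$scale_tag, "total_normalized")

  # a 2x-loaded sample's column is halved relative to the other
  tw <- normalize_total_protein(em, data.frame(sample_id = c("S1", "S2"),
                                               total_protein = c(5, 10)))
  ratio_s2 <- tw$values[, "S2"] / v[, "S2"]
  ratio_s1 <- tw$values[, "S1"] / v[, "S1"]
  expect_equal(unname(ratio_s2 / ratio_s1), c(0.5, 0.5))
  expect_equal(unname(tw$values[, "S2"]), unname(v[, "S2"] * 7.5 / 10))

  expect_error(
    normalize_total_protein(em, data.frame(sample_id = "S1",
                                           total_protein = 5)),
    "S2")
  expect_error(
    normalize_total_protein(em, data.frame(sample_id = c("S1", "S2"),
                                           total_protein = c(5, 0))),
    "S2")
})

test_that("weak-signal imputation applies 'limit minus one' with a floor", {
  v <- matrix(c(100, 500, 0, 900, 250, 120), 2, 3,
              dimnames = list(c("A1", "A2"), c("S1", "S2", "S3")))
  em <- expression_matrix(v, "raw_afi")
  imp <- impute_weak_signals(em)
  expect_equal(imp$values["A1", "S2"], 99)  # smallest positive 100 -> 99
  expect_true(all(imp$values >= 1))
  expect_true(imp$below_limit["A1", "S2"])
  expect_false(any(imp$below_limit[, "S1"]))

  # values untouched when everything is above the limit
  em_ok <- expression_matrix(v[, 1:2] + 1, "raw_afi")
  expect_equal(impute_weak_signals(em_ok)$values, v[, 1:2] + 1)

  # limit <= 1: imputed value floored at 1 (log2-safe)
  v2 <- matrix(c(0.5, 0, 3, 4), 1, 4,
               dimnames = list("A1", paste0("S", 1:4)))
  imp2 <- impute_weak_signals(expression_matrix(v2, "raw_afi"))
  expect_equal(unname(imp2$values[1, 2]), 1)
  expect_true(all(imp2$values >= 1))

  expect_warning(
    impute_weak_signals(expression_matrix(
      matrix(0, 1, 2, dimnames = list("A1", c("S1", "S2"))), "raw_afi")),
    "no positive signal")
})

test_that("median centering on log2 scale hits zero over the scope", {
  v <- matrix(c(2, 4, 8), 1, 3, dimnames = list("A1", c("S1", "S2", "S3")))
  em <- expression_matrix(v, "raw_afi")
  cent <- median_center_log2(em, "all")
  expect_equal(unname(cent$values[1, ]), c(-1, 0, 1))
  expect_identical(cent$scale_tag, "median_centered")

  # single-sample scope zeroes that column
  cent1 <- median_center_log2(em, "S3")
  expect_equal(unname(cent1$values[1, "S3"]), 0)

  # definitional invariant on random matrices, both scopes
  set.seed(1)
  for (i in 1:5) {
    vv <- matrix(2^runif(60, 1, 10), 6, 10,
                 dimnames = list(paste0("A", 1:6), paste0("P", 1:10)))
    meta <- data.frame(sample_id = colnames(vv),
                       tissue = rep(c("PDM", "PTT"), 5))
    emr <- expression_matrix(vv, "raw_afi", samples = meta)
    c_all <- median_center_log2(emr, "all")
    expect_lt(max(abs(apply(c_all$values, 1, median))), 1e-9)
    c_pdm <- median_center_log2(emr, "pdm")
    pdm_ids <- meta$sample_id[meta$tissue == "PDM"]
    expect_lt(max(abs(apply(c_pdm$values[, pdm_ids], 1, median))), 1e-9)
    expect_identical(c_pdm$centering_scope, pdm_ids)
  }

  expect_error(median_center_log2(em, character(0)), "empty")
})

test_that("scale-tag transitions are enforced in order", {
  v <- matrix(c(2, 4, 8, 16), 2, 2,
              dimnames = list(c("A1", "A2"), c("S1", "S2")))
  totals <- data.frame(sample_id = c("S1", "S2"), total_protein = c(5, 5))
  cent <- median_center_log2(expression_matrix(v, "raw_afi"), "all")
  expect_error(normalize_total_protein(cent, totals), "one-way")
  expect_error(impute_weak_signals(cent), "scale")
  expect_error(median_center_log2(cent, "all"), "scale")
  # un-imputed (NA) matrices are rejected before centering
  v_na <- v; v_na[1, 1] <- NA
  expect_error(median_center_log2(expression_matrix(v_na, "raw_afi"), "all"),
               "impute")
})

test_that("log2 AFI recovers latent abundance at low noise (r >= 0.99)", {
  cfg <- cohort_config(n_pairs = 10, n_analytes = 5, noise_cv = 0.05,
                       baseline_level = 20, loading_cv = 0.15, n_immune = 0,
                       seed = 17)
  sim <- simulate_digiwest_cohort(cfg)
  em <- build_afi_matrix(sim$profiles, sim$specs, sim$calibration,
                         samples = sim$metadata)
  em <- normalize_total_protein(em, sim$totals)
  truth <- sim$truth$true_abundance[, colnames(em$values)]
  r <- vapply(seq_len(nrow(truth)), function(a) {
    cor(log2(em$values[a, ]), log2(truth[a, ]))
  }, numeric(1))
  expect_true(all(r >= 0.99))
})
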