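# Standard curves, LOQ, sample calls, panel metrics, and quantification.

test_that("a noiseless perfect-doubling series is recovered exactly", {
  concs <- 100 / 10^(0:5)
  plate <- noiseless_plate(-3.3219, 38, concs)
  curve <- fit_standard_curve(plate)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-6)
  expect_equal(curve$intercept, 38, tolerance = 1e-6)
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)
  expect_equal(curve$efficiency_pct, 100, tolerance = 0.01)
  expect_true(curve$valid)
  expect_equal(curve$loq, min(concs))   # everything detected
})

test_that("curve fitting rejects unusable standards", {
  allnd <- make_standards(c(1, 10, 100), list(rep(NA_real_, 3),
                                              rep(NA_real_, 3),
                                              rep(NA_real_, 3)))
  expect_error(fit_standard_curve(allnd), "usable concentrations")
  two <- noiseless_plate(-3.4, 36, c(10, 100))
  expect_error(fit_standard_curve(two), ">= 3 usable")
  expect_error(determine_loq(data.frame(sample_id = "a", role = "NTC",
                                        replicate = 1, cq = NA,
                                        known_conc_pg_per_ul = NA,
                                        template_ul = 2)), "no standard")
})

test_that("a positive slope is flagged invalid", {
  bad <- noiseless_plate(+3.3, 20, c(1, 10, 100))
  expect_warning(curve <- fit_standard_curve(bad), "positive slope")
  expect_false(curve$valid)
  expect_error(quantify_environmental(bad, curve, 1, 100, 1000), "invalid")
})

test_that("the LOQ is the lowest consistently detected concentration", {
  concs <- c(100, 10, 1, 0.1, 0.01, 0.001)
  cqs <- lapply(concs, function(cc) rep(36 + -3.5 * log10(cc), 3))
  cqs[[5]][2] <- NA  # dropout below 0.1
  cqs[[6]] <- rep(NA_real_, 3)
  std <- make_standards(concs, cqs)
  loq <- determine_loq(std)
  expect_true(loq$defined)
  expect_equal(loq$loq, 0.1)
  expect_equal(loq$loq_cq, 36 + -3.5 * log10(0.1))
  # everything detected: LOQ is the lowest standard
  full <- noiseless_plate(-3.5, 36, concs[1:4])
  expect_equal(determine_loq(full)$loq, 0.1)
  # nothing fully detected anywhere
  nohit <- make_standards(c(1, 10), list(c(30, NA, 30), c(28, NA, 28)))
  expect_false(determine_loq(nohit)$defined)
})

test_that("determine_loq equals a brute-force scan of its definition", {
  concs <- c(100, 10, 1, 0.1, 0.01)
  withr::with_seed(211, {
    for (rep in 1:200) {
      cqs <- lapply(concs, function(cc) {
        v <- rep(30, 3)
        v[stats::runif(3) < 0.3] <- NA
        v
      })
      std <- make_standards(concs, cqs)
      got <- determine_loq(std)
      want <- oracle_loq(std)
      if (is.na(want)) expect_false(got$defined)
      else expect_equal(got$loq, want)
    }
  })
})

test_that("replicate and sample calls follow the LOQ rule", {
  plate <- noiseless_plate(-3.5, 36, c(100, 10, 1, 0.1))
  curve <- fit_standard_curve(plate)   # LOQ 0.1, LOQ Cq = 36 + 3.5 = 39.5
  expect_equal(curve$loq_cq, 39.5, tolerance = 1e-9)
  rx <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s2", "s3", "s3", "s3"),
    role = "environmental", replicate = rep(1:3, 3),
    cq = c(30, 31, 30,  30, 30, NA,  NA, NA, NA),
    known_conc_pg_per_ul = NA_real_, template_ul = 2)
  calls <- call_sample(rx, curve)
  expect_equal(stats::setNames(calls$status, calls$sample_id),
               c(s1 = "quantified", s2 = "BLOQ", s3 = "ND"))
  expect_equal(calls$detected, c(TRUE, TRUE, FALSE))
  # Cq above the LOQ Cq: detection below quantification by default,
  # negative under the strict rule
  hi <- data.frame(sample_id = "h", role = "environmental", replicate = 1:3,
                   cq = c(39.8, 39.9, 39.7), known_conc_pg_per_ul = NA_real_,
                   template_ul = 2)
  expect_equal(call_sample(hi, curve)$status, "BLOQ")
  expect_equal(call_sample(hi, curve, above_loq = "negative")$status, "ND")
})

test_that("panel metrics reproduce the formulas with half-up rounding", {
  pm <- panel_metrics(tp = 4, fn = 0, tn = 21, fp = 5)
  expect_equal(pm$sensitivity_pct, 100)
  expect_equal(pm$specificity_pct, 81)   # 21/26 = 80.77
  expect_equal(panel_metrics(tp = 3, fn = 0, tn = 29, fp = 8)$specificity_pct,
               78)                        # 29/37 = 78.38
  expect_equal(panel_metrics(tp = 3, fn = 0, tn = 9, fp = 0)$specificity_pct,
               100)
  expect_error(panel_metrics(tp = 0, fn = 0, tn = 0, fp = 0), "empty")
  # from labeled calls
  calls <- data.frame(sample_id = c("a", "b", "c", "d"),
                      detected = c(TRUE, TRUE, FALSE, TRUE))
  labels <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  pm2 <- panel_metrics(calls = calls, labels = labels)
  expect_equal(pm2$tp, 2); expect_equal(pm2$fp, 1)
  expect_equal(pm2$tn, 1); expect_equal(pm2$fn, 0)
  expect_error(panel_metrics(calls = calls, labels = labels[1:3]), "label")
})

test_that("quantification inverts the forward model exactly when noiseless", {
  plate <- noiseless_plate(-3.4, 37, c(100, 10, 1, 0.1))
  curve <- fit_standard_curve(plate)
  true_conc <- 0.06   # pg per mL of water
  rx <- simulate_environmental(true_conc, curve, n = 3, dilution_factor = 5,
                               extract_volume_ul = 100,
                               filtered_volume_ml = 2000, sigma = 0)
  est <- quantify_environmental(rx, curve, dilution_factor = 5,
                                extract_volume_ul = 100,
                                filtered_volume_ml = 2000)
  expect_equal(est$status, "quantified")
  expect_equal(est$mean_pg_per_ml, true_conc, tolerance = 1e-9)
  expect_equal(est$ci95_half_width, 0, tolerance = 1e-9)
})

test_that("the 95% interval matches the hand-computed t formula", {
  plate <- noiseless_plate(-3.4, 37, c(100, 10, 1, 0.1))
  curve <- fit_standard_curve(plate)
  rx <- simulate_environmental(5, curve, n = 3, dilution_factor = 1,
                               extract_volume_ul = 100,
                               filtered_volume_ml = 1000,
                               sigma = 0.2, seed = 42)
  est <- quantify_environmental(rx, curve, dilution_factor = 1,
                                extract_volume_ul = 100,
                                filtered_volume_ml = 1000)
  per_rep <- 10^((rx$cq - curve$intercept) / curve$slope) * 100 / 1000
  expect_equal(est$mean_pg_per_ml, mean(per_rep), tolerance = 1e-12)
  expect_equal(est$ci95_half_width,
               stats::qt(0.975, 2) * stats::sd(per_rep) / sqrt(3),
               tolerance = 1e-12)
  # BLOQ/ND samples never yield a number
  rx$cq[1] <- NA
  est2 <- quantify_environmental(rx, curve, 1, 100, 1000)
  expect_equal(est2$status, "BLOQ")
  expect_true(is.na(est2$mean_pg_per_ml))
})

test_that("NTC amplification raises a contamination warning", {
  df <- data.frame(sample_id = c("ntc", "ntc"), role = "NTC",
                   replicate = 1:2, cq = c(NA, 38.2),
                   known_conc_pg_per_ul = NA_real_, template_ul = 2)
  expect_warning(validate_plate(df), "contamination")
})
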