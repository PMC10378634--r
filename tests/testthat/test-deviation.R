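test_that("fractional dose deviation follows the prescription-scaled band rule", {
  expect_equal(fractional_dose_deviation(60, 59, 61, 60), 0)
  expect_equal(fractional_dose_deviation(57, 58, 62, 60), 100 * (58 - 57) / 60)
  expect_equal(fractional_dose_deviation(63.5, 58, 62, 60), 2.5)
  expect_equal(fractional_dose_deviation(58, 58, 62, 60), 0)   # closed bound
  expect_equal(fractional_dose_deviation(62, 58, 62, 60), 0)
  expect_error(fractional_dose_deviation(60, 58, 62, 0), "D_Rx")
  expect_error(fractional_dose_deviation(60, 62, 58, 60), "invalid band")
})

test_that("fractional volume deviation is the excursion in percentage points", {
  expect_equal(fractional_volume_deviation(95, 96, 100), 1.0)
  expect_equal(fractional_volume_deviation(98, 96, 100), 0)
  expect_equal(fractional_volume_deviation(100, 90, 99.5), 0.5)
  expect_equal(fractional_volume_deviation(96, 96, 100), 0)    # closed bound
  expect_error(fractional_volume_deviation(101, 0, 100), "\\[0, 100\\]")
  expect_error(fractional_volume_deviation(50, 60, 40), "invalid band")
})

test_that("deviation is zero exactly for in-band values", {
  set.seed(11)
  for (i in 1:200) {
    b <- sort(stats::runif(2, 40, 70))
    v <- stats::runif(1, 30, 80)
    dev <- fractional_dose_deviation(v, b[1], b[2], 60)
    inside <- within_band(v, b[1], b[2]) == "inside"
    expect_identical(dev == 0, inside)
    vb <- sort(stats::runif(2, 0, 100)); vv <- stats::runif(1, 0, 100)
    devv <- fractional_volume_deviation(vv, vb[1], vb[2])
    expect_identical(devv == 0, within_band(vv, vb[1], vb[2]) == "inside")
  }
})

test_that("evaluate_fraction emits one record per structure/metric/setting", {
  cfg <- mini_config()
  plan <- build_patient_plan(cfg, "PNN")
  bands <- compute_bands(plan$phantom, plan$beams, setups = c(3, 5),
                         isocenter = plan$isocenter)
  rec <- evaluate_fraction(plan$phantom, plan$beams, bands,
                           fraction_shift(2, -1, 1, yaw = 1),
                           isocenter = plan$isocenter)
  # 2 targets x (D95, V100) + 3 OARs, at 2 setup settings
  expect_equal(nrow(rec), 2 * (2 * 2 + 3))
  expect_setequal(unique(rec$setup_mm), c(3, 5))

  # zero-error fraction: everything inside with zero deviation
  rec0 <- evaluate_fraction(plan$phantom, plan$beams, bands, fraction_shift(),
                            isocenter = plan$isocenter)
  expect_true(all(rec0$status == "inside"))
  expect_true(all(rec0$deviation == 0))

  # missing band is a configuration error
  expect_error(evaluate_fraction(plan$phantom, plan$beams,
                                 bands[bands$setup_mm == 3, ], fraction_shift(),
                                 isocenter = plan$isocenter),
               "missing band")
})

test_that("a pure 2 mm lateral shift stays inside the 3 mm primary bands", {
  cfg <- mini_config()
  plan <- build_patient_plan(cfg, "PO")
  bands <- compute_bands(plan$phantom, plan$beams, setups = 3,
                         isocenter = plan$isocenter)
  rec <- evaluate_fraction(plan$phantom, plan$beams, bands,
                           fraction_shift(ty = 2), setups = 3,
                           isocenter = plan$isocenter)
  pri <- rec[rec$structure == "CTV_primary", ]
  expect_true(all(pri$status == "inside"))
})

test_that("summaries compute the documented aggregates", {
  rec <- data.frame(
    class = "PNN", tier = "primary", setup_mm = 3,
    status = c(rep("inside", 8), "below", "above"),
    deviation = c(rep(0, 8), 1, 3))
  s <- summarize_deviations(rec)
  expect_equal(s$pct_outside, 20)
  expect_equal(s$n_outside, 2)
  expect_equal(s$mean_deviation, 2)
  expect_equal(s$min_deviation, 1)
  expect_equal(s$max_deviation, 3)
  expect_equal(s$pct_below, 10)

  all_in <- rec[rec$status == "inside", ]
  s0 <- summarize_deviations(all_in)
  expect_equal(s0$pct_outside, 0)
  expect_equal(s0$n_outside, 0)
  expect_equal(s0$mean_deviation, 0)

  si <- summarize_deviations(rec, include_zeros = TRUE)
  expect_equal(si$mean_deviation, 0.4)
  expect_error(summarize_deviations(rec[0, ]), "no records")
})

test_that("pooled summaries equal the weighted combination of class summaries", {
  set.seed(21)
  rec <- data.frame(
    class = rep(c("PO", "PNN"), c(40, 60)),
    tier = "primary", setup_mm = 3,
    status = sample(c("inside", "below"), 100, TRUE, prob = c(0.7, 0.3)))
  rec$deviation <- ifelse(rec$status == "inside", 0, stats::runif(100, 0.1, 5))
  by_class <- summarize_deviations(rec, by = "class")
  pooled <- summarize_deviations(cbind(rec, all = "all"), by = "all")
  expect_equal(pooled$pct_outside,
               sum(by_class$n_outside) / sum(by_class$n) * 100)
  expect_equal(pooled$mean_deviation,
               sum(by_class$mean_deviation * by_class$n_outside) /
                 sum(by_class$n_outside))
})
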