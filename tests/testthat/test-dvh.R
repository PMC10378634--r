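# independent oracles: type-7 quantile for the rank-interpolated dose-at-volume
# convention, explicit counting for volume-at-dose
oracle_d_at <- function(doses, p) {
  n <- length(doses)
  unname(stats::quantile(doses, (n - p * n / 100) / (n - 1), type = 7))
}
oracle_v_at <- function(doses, t) {
  hits <- 0L
  for (d in doses) if (d >= t) hits <- hits + 1L
  100 * hits / length(doses)
}

test_that("trivial DVH cases behave as defined", {
  m <- rep(TRUE, 10)
  expect_equal(d_at_volume(rep(60, 10), m, 95), 60)
  expect_equal(d_at_volume(1:100, rep(TRUE, 100), 100), 1)    # minimum dose
  expect_equal(d_at_volume(1:100, rep(TRUE, 100), 50), 51)    # threshold-scan value
  expect_equal(v_at_dose(rep(60, 10), m, 50), 100)
  expect_equal(v_at_dose(c(rep(10, 63), rep(90, 37)), rep(TRUE, 100), 50), 37)
  expect_equal(v_at_dose(1:10, m, 0), 100)
  expect_equal(oar_metric(c(0, 10, 20), rep(TRUE, 3), "mean"), 10)
  expect_equal(oar_metric(c(0, 10, 20), rep(TRUE, 3), "max"), 20)
})

test_that("empty masks and bad arguments raise errors naming the structure", {
  expect_error(d_at_volume(1:4, rep(FALSE, 4), 95, name = "cordX"), "cordX")
  expect_error(v_at_dose(1:4, rep(FALSE, 4), 1, name = "cordX"), "cordX")
  expect_error(oar_metric(1:4, rep(FALSE, 4), "max", name = "cordX"), "cordX")
  expect_error(d_at_volume(1:4, rep(TRUE, 4), 0), "p_pct")
  expect_error(v_at_dose(1:4, rep(TRUE, 4), -1), "threshold")
  expect_error(cumulative_dvh(1:4, rep(TRUE, 4), 0), "bin_width")
})

test_that("metrics match brute-force oracles on random cases", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(50:1000, 1)
    doses <- switch(1 + i %% 3,
                    stats::rnorm(n, 60, 8),
                    stats::runif(n, 0, 70),
                    round(stats::rnorm(n, 60, 5), 1))  # with ties
    p <- stats::runif(1, 5, 100)
    t <- stats::runif(1, 0, 70)
    m <- rep(TRUE, n)
    expect_equal(d_at_volume(doses, m, p), oracle_d_at(doses, p),
                 tolerance = 1e-9)
    expect_equal(v_at_dose(doses, m, t), oracle_v_at(doses, t),
                 tolerance = 1e-9)
    expect_equal(oar_metric(doses, m, "max"), sort(doses)[n], tolerance = 1e-9)
    expect_equal(oar_metric(doses, m, "mean"), sum(doses) / n, tolerance = 1e-9)
  }
})

test_that("d_at_volume and v_at_dose are monotone and mutually consistent", {
  set.seed(33)
  doses <- stats::rnorm(400, 60, 10)
  m <- rep(TRUE, 400)
  ps <- seq(5, 100, by = 5)
  dv <- vapply(ps, function(p) d_at_volume(doses, m, p), numeric(1))
  expect_true(all(diff(dv) <= 1e-12))                  # non-increasing in p
  ts <- seq(30, 90, by = 5)
  vv <- vapply(ts, function(t) v_at_dose(doses, m, t), numeric(1))
  expect_true(all(diff(vv) <= 1e-12))                  # non-increasing in t
  for (p in ps)                                        # Galois connection
    expect_gte(v_at_dose(doses, m, d_at_volume(doses, m, p)), p - 1e-9)
})

test_that("metrics are homogeneous of degree one in dose", {
  set.seed(9)
  doses <- stats::rgamma(300, 20, 0.4)
  m <- rep(TRUE, 300)
  c_ <- 1.7
  expect_equal(d_at_volume(c_ * doses, m, 95), c_ * d_at_volume(doses, m, 95))
  expect_equal(oar_metric(c_ * doses, m, "max"), c_ * oar_metric(doses, m, "max"))
  expect_equal(oar_metric(c_ * doses, m, "mean"), c_ * oar_metric(doses, m, "mean"))
  expect_equal(v_at_dose(c_ * doses, m, c_ * 50), v_at_dose(doses, m, 50))
})

test_that("cumulative DVH curve matches a sort-based oracle and is well-formed", {
  set.seed(5)
  doses <- stats::runif(500, 0, 65)
  m <- rep(TRUE, 500)
  cv <- cumulative_dvh(doses, m, bin_width_Gy = 0.5)
  expect_equal(cv$cumulative_volume_pct[1], 100)
  expect_true(all(diff(cv$cumulative_volume_pct) <= 0))
  expect_equal(cv$cumulative_volume_pct[length(cv$dose_edges)], 0)
  s <- sort(doses)
  for (k in c(2, 50, 100)) {
    e <- cv$dose_edges[k]
    expect_equal(cv$cumulative_volume_pct[k], 100 * sum(s >= e) / 500)
  }
  # two-voxel plateau case
  cv2 <- cumulative_dvh(c(0, 60), c(TRUE, TRUE), 1)
  mid <- cv2$dose_edges > 0 & cv2$dose_edges <= 60
  expect_true(all(cv2$cumulative_volume_pct[mid] == 50))
})

test_that("dvh_metrics bundles the four metrics consistently", {
  set.seed(77)
  doses <- stats::rnorm(200, 60, 5)
  m <- rep(TRUE, 200)
  mm <- dvh_metrics(doses, m, prescription_Gy = 60)
  expect_equal(mm$D95_Gy, d_at_volume(doses, m, 95))
  expect_equal(mm$V100_pct, v_at_dose(doses, m, 60))
  expect_gte(mm$Dmax_Gy, mm$Dmean_Gy)
  expect_lte(mm$D95_Gy, mm$Dmax_Gy)
  expect_true(mm$V100_pct >= 0 && mm$V100_pct <= 100)
})
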