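test_that("ttb is the CT distance and needs both means", {
  expect_equal(ttb(5.9, 43.1), 37.2)
  expect_equal(ttb(9.3, 41.2), 31.9)
  expect_equal(ttb(8.5, 41.6), 33.1)
  expect_equal(ttb(17, 17), 0)
  s <- tolerance_summary("x", 9.3, 41.2, 1.67, 1.42, n = 8)
  expect_equal(ttb(s), 31.9)
  s$ct_max_mean <- NA_real_
  expect_error(ttb(s), "both CT means")
})

test_that("thermal_safety_margin is CTmax minus To and rejects To beyond it", {
  expect_equal(thermal_safety_margin(43.1, 36.7), 6.4)
  expect_equal(thermal_safety_margin(41.6, 28.6), 13.0)
  expect_equal(thermal_safety_margin(30, 30), 0)
  expect_error(thermal_safety_margin(40, 41), "exceeds")
})

test_that("summarize_tolerance aggregates per species and validates ordering", {
  rec <- data.frame(
    individual_id = c("a", "b", "c", "d"),
    species = c("s1", "s1", "s2", "s2"),
    ct_min_c = c(5, 7, 9, 11),
    ct_max_c = c(41, 43, 39, 41))
  out <- summarize_tolerance(rec)
  expect_equal(out$s1$ct_min_mean, 6)
  expect_equal(out$s1$ct_max_mean, 42)
  expect_equal(ttb(out$s2), 30)
  rec$ct_max_c[1] <- 4
  expect_error(summarize_tolerance(rec), "ct_min >= ct_max")
})

test_that("derive_metrics agrees with brute-force oracles", {
  par <- reference_params("gumbel_peak")
  fam <- tpc_family("gumbel_peak")
  anch <- tolerance_summary("x", 8.5, 41.6, n = 38)
  tt <- seq(12, 40, length.out = 7)
  fit <- fit_family(tt, fam$eval(tt, par), "gumbel_peak", anch, seed = 2)
  m <- derive_metrics(fit)
  f <- function(x) tpc_eval_clamped(fam, x, fit$params, 8.5, 41.6)
  # argmax against the 0.001 C brute-force grid
  expect_equal(m$t_o, brute_argmax(f, 8.5, 41.6, 0.001),
               tolerance = 0.01)
  expect_equal(m$v_max, f(m$t_o))
  expect_true(all(m$v_max >= f(seq(8.5, 41.6, 0.01)) - 1e-9))
  # defining property of the breadth endpoints
  expect_equal(f(m$b80_low) / m$v_max, 0.8, tolerance = 1e-3)
  expect_equal(f(m$b80_high) / m$v_max, 0.8, tolerance = 1e-3)
  expect_true(anch$ct_min_mean <= m$b80_low && m$b80_low < m$t_o &&
              m$t_o < m$b80_high && m$b80_high <= anch$ct_max_mean)
  # identities
  expect_equal(m$tsm, 41.6 - m$t_o)
  expect_equal(m$ttb, 33.1)
})

test_that("a symmetric curve yields a breadth symmetric about its optimum", {
  # EMG with a very fast exponential is Gaussian-symmetric in the limit
  par <- c(a = 60, mu = 27, sigma = 5, lambda = 50)
  fam <- tpc_family("emg_peak")
  anch <- tolerance_summary("x", 5, 49, n = 20)
  tt <- seq(12, 42, length.out = 9)
  fit <- fit_family(tt, fam$eval(tt, par), "emg_peak", anch, seed = 4)
  m <- derive_metrics(fit)
  expect_equal(m$t_o - m$b80_low, m$b80_high - m$t_o, tolerance = 0.05)
})

test_that("breadth shrinks monotonically as the level rises", {
  par <- reference_params("asym_logistic_peak")
  fam <- tpc_family("asym_logistic_peak")
  anch <- tolerance_summary("x", 9.3, 41.2, n = 31)
  tt <- seq(12, 40, length.out = 7)
  fit <- fit_family(tt, fam$eval(tt, par), "asym_logistic_peak", anch,
                    seed = 2)
  widths <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.97), function(lv) {
    m <- derive_metrics(fit, level = lv)
    m$b80_high - m$b80_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("breadth endpoints truncate at the CT limits with a warning", {
  # wide curve relative to the window: 80% level never reached inside;
  # the fit object is forged so the curve itself stays wide
  anch <- tolerance_summary("x", 20, 30, n = 10)
  fit <- structure(list(species = "x", family = "gumbel_peak",
                        params = c(a = 10, mu = 25, sigma = 40),
                        converged = TRUE, anchors = anch),
                   class = "tpc_fit")
  expect_warning(m <- derive_metrics(fit), "truncated")
  expect_true(m$boundary_warning)
  expect_equal(c(m$b80_low, m$b80_high), c(20, 30))
})
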