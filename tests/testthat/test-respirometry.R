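mk_trace <- function(fe, flow = 100, fi = 0, dt = 1) {
  resp_trace("id", 30, seq(0, by = dt, length.out = length(fe)), fe,
             flow_rate = flow, fi_co2 = fi, species = "sp",
             body_mass = 10)
}

test_that("resp_trace validates the sampling grid and fractions", {
  expect_error(mk_trace(c(0.1, 1.2, 0.1)), "\\[0, 1\\)")
  expect_error(resp_trace("id", 30, c(0, 1, 3), rep(0.001, 3)),
               "uniform")
  expect_silent(mk_trace(rep(0.001, 200)))
})

test_that("stable_mean finds the lowest window and matches brute force", {
  # constant trace: every window equals the constant
  expect_equal(stable_mean(mk_trace(rep(0.002, 300))), 0.002)
  # strictly decreasing trace: final window wins
  fe <- seq(0.005, 0.001, length.out = 400)
  expect_equal(stable_mean(mk_trace(fe)),
               mean(fe[301:400]), tolerance = 1e-12)
  # random 600 s trace at 1 Hz vs exhaustive enumeration
  set.seed(11)
  fe <- 0.002 + abs(rnorm(600, 0, 2e-4))
  expect_equal(stable_mean(mk_trace(fe)),
               brute_min_window_mean(fe, 100), tolerance = 1e-12)
  # 0.5 Hz sampling: window is 50 samples
  fe2 <- 0.002 + abs(rnorm(300, 0, 2e-4))
  expect_equal(stable_mean(mk_trace(fe2, dt = 2)),
               brute_min_window_mean(fe2, 50), tolerance = 1e-12)
  expect_error(stable_mean(mk_trace(rep(0.001, 50))), "shorter")
})

test_that("stable_mean never exceeds the overall mean", {
  set.seed(12)
  for (i in 1:10) {
    fe <- 0.002 * (1 + 0.5 * exp(-(1:500) / 100)) + rnorm(500, 0, 5e-5)
    fe <- pmax(fe, 0)
    expect_lte(stable_mean(mk_trace(fe)), mean(fe))
  }
})

test_that("vco2 applies the flow equation and warns on negative rates", {
  expect_equal(vco2(100, 0.0010), 0.1)
  expect_equal(vco2(100, 0.003, 0.003), 0)
  expect_equal(vco2(50, 0.002, 0.001), 0.05)
  expect_warning(out <- vco2(100, 0.001, 0.002), "negative")
  expect_equal(out, -0.1)
  expect_error(vco2(100, 1.2), "\\[0, 1\\)")
})

test_that("rmr_from_trace composes the window rule with the flow equation", {
  expect_equal(mk_trace(rep(0.0010, 200))$flow_rate, 100)
  expect_equal(rmr_from_trace(mk_trace(rep(0.0010, 200)))$vco2_ml_min,
               0.1)
  # a transient spike then a plateau longer than the window: spike ignored
  fe <- c(rep(0.004, 80), rep(0.0015, 300))
  expect_equal(rmr_from_trace(mk_trace(fe))$vco2_ml_min, 0.15)
  # non-zero incurrent baseline is subtracted
  fe <- rep(0.0025, 200)
  expect_equal(rmr_from_trace(mk_trace(fe, fi = 0.0005))$vco2_ml_min,
               0.2)
})

test_that("q10 evaluates the rate-ratio power law and canonicalises order", {
  expect_equal(q10(0.1, 15, 0.2, 25)$q10, 2)
  expect_equal(q10(0.1, 10, 0.4, 30)$q10, 2)
  expect_equal(q10(0.3, 20, 0.3, 35)$q10, 1)
  # swapped order canonicalises to t2 > t1
  r <- q10(0.2, 25, 0.1, 15)
  expect_equal(r$q10, 2)
  expect_equal(c(r$t1, r$t2), c(15, 25))
  expect_error(q10(0, 15, 0.2, 25), "positive")
  expect_error(q10(0.1, 15, 0.2, 15), "differ")
})

test_that("q10 is scale-invariant and log-multiplicative", {
  set.seed(3)
  for (i in 1:20) {
    r1 <- runif(1, 0.01, 1); r2 <- runif(1, 0.01, 1)
    t1 <- runif(1, 10, 20); t2 <- t1 + runif(1, 2, 15)
    k <- runif(1, 0.1, 50)
    expect_equal(q10(k * r1, t1, k * r2, t2)$q10,
                 q10(r1, t1, r2, t2)$q10)
    # composition over a midpoint reproduces the whole-interval value
    tm <- (t1 + t2) / 2; rm <- sqrt(r1 * r2)
    whole <- q10(r1, t1, r2, t2)$q10
    part1 <- q10(r1, t1, rm, tm)$q10
    part2 <- q10(rm, tm, r2, t2)$q10
    w <- (tm - t1) / (t2 - t1)
    expect_equal(whole, part1^w * part2^(1 - w), tolerance = 1e-10)
  }
})

test_that("q10_table computes cells from treatment means and tolerates gaps", {
  # exact exponential scaling: every cell equals the generating g
  g <- 2.2; r0 <- 0.05
  tt <- c(15, 25, 30, 33, 36)
  rec <- expand.grid(individual_id = paste0("i", 1:4), treatment_c = tt)
  rec$species <- "sp"
  rec$vco2_ml_min <- r0 * g^((rec$treatment_c - 15) / 10) *
    rep(c(0.8, 0.9, 1.1, 1.2), times = length(tt))  # mean-preserving spread
  out <- q10_table(rec)
  cells <- unlist(out[1, -1])
  expect_equal(unname(cells), rep(g, 5), tolerance = 1e-12)
  # only the overall cell is computable from two extreme treatments
  rec2 <- rec[rec$treatment_c %in% c(15, 36), ]
  out2 <- q10_table(rec2)
  expect_true(is.na(out2$q10_15_25) && is.na(out2$q10_30_33))
  expect_false(is.na(out2$q10_overall))
  # all-equal means give Q10 = 1 everywhere
  rec$vco2_ml_min <- 0.1
  expect_equal(unname(unlist(q10_table(rec)[1, -1])), rep(1, 5))
  expect_error(q10_table(rec[rec$treatment_c == 15, ]), "two treatments")
})
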