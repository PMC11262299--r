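test_that("profiles satisfy their invariants and match the stated anchors", {
  profs <- make_default_profiles()
  expect_length(profs, 3)
  expect_equal(profs$crotalus_polystictus$ct_max_mean, 43.1)
  expect_equal(profs$conopsis_lineata$ct_min_mean, 9.3)
  expect_equal(profs$thamnophis_melanogaster$rmr_mass_slope, 0.674)
  expect_equal(profs$crotalus_polystictus$rmr_mass_slope, 0.760)
  for (p in profs) {
    expect_lt(p$ct_min_mean, p$ct_max_mean)
    expect_false(is.unsorted(p$rmr_offsets))
    expect_gt(p$v_max, 0)
    expect_true(p$t_o > p$ct_min_mean && p$t_o < p$ct_max_mean)
  }
  # offsets must be rejected when non-monotone
  expect_error(species_profile(
    "bad", 10, 10, 5, 1, 0.2, 5, 1, 40, 1, "gumbel_peak",
    c(a = 10, mu = 25, sigma = 5), rmr_intercept = -1,
    rmr_offsets = c(`25` = 0.4, `30` = 0.2, `33` = 0.5, `36` = 0.6),
    rmr_mass_slope = 0.7), "nondecreasing")
})

test_that("generators are pure functions of (profile, seed)", {
  p <- default_profile("conopsis_lineata")
  expect_identical(simulate_tolerance(p, seed = 7),
                   simulate_tolerance(p, seed = 7))
  expect_identical(simulate_speeds(p, seed = 7),
                   simulate_speeds(p, seed = 7))
  expect_identical(simulate_swims(p, seed = 7),
                   simulate_swims(p, seed = 7))
  expect_identical(simulate_rmr(p, seed = 7), simulate_rmr(p, seed = 7))
  expect_false(identical(simulate_rmr(p, seed = 7),
                         simulate_rmr(p, seed = 8)))
  # generation does not disturb the caller's RNG stream
  set.seed(123); invisible(simulate_rmr(p, seed = 7)); a <- rnorm(1)
  set.seed(123); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("tolerance draws degenerate to the means at sd = 0 and recover them at large n", {
  p <- default_profile("thamnophis_melanogaster")
  p0 <- p; p0$ct_min_sd <- 0; p0$ct_max_sd <- 0
  tol0 <- simulate_tolerance(p0, seed = 1)
  expect_true(all(tol0$ct_min_c == p$ct_min_mean))
  expect_true(all(tol0$ct_max_c == p$ct_max_mean))
  pN <- p; pN$n_tolerance <- 10000L
  tolN <- simulate_tolerance(pN, seed = 2)
  expect_equal(mean(tolN$ct_min_c), p$ct_min_mean,
               tolerance = 3 * p$ct_min_sd / sqrt(10000) / p$ct_min_mean)
  expect_equal(mean(tolN$ct_max_c), p$ct_max_mean,
               tolerance = 3 * p$ct_max_sd / sqrt(10000) / p$ct_max_mean)
  expect_true(all(tolN$ct_min_c < tolN$ct_max_c))
})

test_that("noise-free swim trials reproduce the generating curve within rounding", {
  p <- default_profile("thamnophis_melanogaster")
  p$speed_noise_sd <- 0; p$ind_speed_sdlog <- 0
  trials <- simulate_swims(p, seed = 3)
  obs <- speeds_from_trials(trials)
  truth <- tpc_eval_clamped(p$tpc_family, obs$treatment_c, p$tpc_params,
                            p$ct_min_mean, p$ct_max_mean)
  expect_equal(obs$max_speed_cm_s, truth, tolerance = 0.02)
})

test_that("noise-free traces recover the generating VCO2 exactly", {
  p <- default_profile("conopsis_lineata")
  st <- simulate_traces(p, treatments = c(15, 30), seed = 4,
                        duration = 300, noise = FALSE,
                        transient = FALSE)
  got <- vapply(st$traces, function(tr) rmr_from_trace(tr)$vco2_ml_min,
                numeric(1))
  expect_equal(got, st$truth$vco2_ml_min, tolerance = 1e-12)
})

test_that("noise-free Q10 table equals the closed form implied by the offsets", {
  p <- default_profile("crotalus_polystictus")
  rmr <- simulate_rmr(p, seed = 5, noise = FALSE)
  # drop the late cohort so every treatment mean uses the same animals
  # (closed form below assumes a balanced design)
  late <- unique(rmr$individual_id)[seq_len(p$n_tolerance)]
  q <- q10_table(rmr[!rmr$individual_id %in% late, ])
  off <- c(0, p$rmr_offsets)
  tt <- c(15, 25, 30, 33, 36)
  expected <- c(10^(diff(off) * 10 / diff(tt)),
                10^((off[5] - off[1]) * 10 / (36 - 15)))
  expect_equal(unname(unlist(q[1, -1])), unname(expected),
               tolerance = 1e-10)
})

test_that("the late cohort lacks the 33 C respirometry treatment", {
  p <- default_profile("conopsis_lineata")
  rmr <- simulate_rmr(p, seed = 6)
  late <- unique(rmr$individual_id)[seq_len(p$n_tolerance)]
  with33 <- unique(rmr$individual_id[rmr$treatment_c == 33])
  expect_length(intersect(late, with33), 0)
  others <- setdiff(unique(rmr$individual_id), late)
  expect_setequal(with33, others)
})

test_that("every generated dataset passes its schema validation cleanly", {
  sim <- simulate_study(seed = 11)
  expect_equal(nrow(validate(sim$speeds, "speeds")), 0)
  expect_equal(nrow(validate(sim$tolerance, "tolerance")), 0)
  expect_equal(nrow(validate(sim$trials, "trials")), 0)
  expect_equal(nrow(validate(sim$rmr, "rmr")), 0)
  # and reduction emits no warnings (full five-segment trials)
  expect_silent(speeds_from_trials(sim$trials))
})
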