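mk_rmr <- function(n_ind = 12, treatments = c(15, 25, 30, 36),
                   intercept = -0.9, offsets = c(0, 0.2, 0.4, 0.6),
                   slope = 0.7, u_sd = 0.1, e_sd = 0.08, seed = 1) {
  set.seed(seed)
  mass <- 10^rnorm(n_ind, 1.3, 0.3)
  u <- rnorm(n_ind, 0, u_sd)
  sex <- sample(c("M", "F"), n_ind, replace = TRUE)
  g <- expand.grid(i = seq_len(n_ind), t = seq_along(treatments))
  data.frame(
    individual_id = paste0("i", g$i), species = "sp",
    sex = sex[g$i], treatment_c = treatments[g$t],
    body_mass_g = mass[g$i],
    vco2_ml_min = 10^(intercept + offsets[g$t] + slope * log10(mass[g$i]) +
                        u[g$i] + rnorm(nrow(g), 0, e_sd)))
}

test_that("log10_prepare transforms and drops non-positive rows", {
  d <- mk_rmr()
  out <- log10_prepare(d)
  expect_equal(out$log10_vco2, log10(d$vco2_ml_min))
  expect_equal(out$log10_mass, log10(d$body_mass_g))
  expect_identical(levels(out$treatment)[1], "15")
  d2 <- d; d2$vco2_ml_min[3] <- 0
  expect_message(out2 <- log10_prepare(d2), "dropped 1")
  expect_equal(nrow(out2), nrow(d) - 1)
  d3 <- d; d3$vco2_ml_min <- 0
  expect_error(log10_prepare(d3), "no rows")
})

test_that("candidate_set builds the documented seven-model roster", {
  specs <- candidate_set()
  expect_length(specs, 7)
  names_ <- vapply(specs, `[[`, character(1), "name")
  expect_setequal(names_, c("T", "M", "S", "T+M", "T+M+S", "T+S",
                            "T+M+TxM"))
  has_int <- vapply(specs, function(s)
    "treatment:log_mass" %in% s$fixed_terms, logical(1))
  expect_equal(sum(has_int), 1L)
  expect_error(candidate_set(list(c("log_mass", "treatment:log_mass"))),
               "both main effects")
  expect_error(candidate_set(list("elevation")), "unknown term")
})

test_that("the perfect-fit limit recovers coefficients and R2 exactly", {
  d <- log10_prepare(mk_rmr(u_sd = 0, e_sd = 0, seed = 5))
  out <- suppressWarnings(
    fit_candidates(d, candidate_set(list(c("treatment", "log_mass")))))
  f <- out$best
  truth <- c(-0.9, 0.2, 0.4, 0.6, 0.7)
  expect_equal(unname(f$coefficients$estimate), truth, tolerance = 1e-6)
  expect_equal(f$conditional_r2, 1, tolerance = 1e-6)
})

test_that("fit_candidates selects sensibly and reports honest components", {
  d <- log10_prepare(mk_rmr(n_ind = 20, seed = 8))
  out <- suppressWarnings(fit_candidates(d))
  expect_s3_class(out$best, "model_fit")
  # generating structure is T+M; with these effect sizes the winner
  # must at least contain both terms
  expect_true(all(c("treatment", "log_mass") %in%
                  out$best$spec$fixed_terms))
  r2 <- vapply(out$fits, `[[`, numeric(1), "conditional_r2")
  expect_true(all(r2 >= 0 & r2 <= 1))
  vc <- out$best$variance_components
  expect_true(all(vc >= 0))
  # conditional R2 rises when residual noise shrinks, all else equal
  d_lo <- log10_prepare(mk_rmr(n_ind = 20, e_sd = 0.02, seed = 8))
  out_lo <- suppressWarnings(
    fit_candidates(d_lo, candidate_set(list(c("treatment", "log_mass")))))
  expect_gt(out_lo$best$conditional_r2, out$fits[["T+M"]]$conditional_r2)
})

test_that("AICc prefers the simpler nested structure on pure-noise data", {
  # response carries no sex effect: T+S must lose to T most of the time
  wins_simple <- 0
  for (r in 1:60) {
    d <- log10_prepare(mk_rmr(n_ind = 10, slope = 0, seed = 100 + r))
    out <- suppressWarnings(
      fit_candidates(d, candidate_set(list("treatment",
                                           c("treatment", "sex")))))
    wins_simple <- wins_simple + (out$best$spec$name == "T")
  }
  expect_gt(wins_simple, 30)
})

test_that("species_adjusted_comparison recovers group offsets at common mass", {
  mk2 <- function(shift_b, seed) {
    a <- mk_rmr(n_ind = 25, seed = seed)
    b <- mk_rmr(n_ind = 25, intercept = -0.9 + shift_b, seed = seed + 50)
    b$species <- "spB"; b$individual_id <- paste0("b", b$individual_id)
    rbind(a, b)
  }
  # null case: equal intercepts and slopes
  cmp0 <- species_adjusted_comparison(log10_prepare(mk2(0, 1)))
  expect_lt(abs(cmp0$contrasts$t[1]), 2.5)
  # shifted case: +0.2 offset recovered
  est <- replicate(20, {
    s <- sample.int(1e6, 1)
    cmp <- species_adjusted_comparison(log10_prepare(mk2(0.2, s)),
                                       retain_interaction = "never")
    diff(cmp$adjusted_means$adjusted_mean)
  })
  expect_equal(mean(est), 0.2, tolerance = 0.03)
  # invariance to recentring log10 mass
  d <- log10_prepare(mk2(0.1, 3))
  cmp1 <- species_adjusted_comparison(d, retain_interaction = "never")
  d2 <- d; d2$log10_mass <- d2$log10_mass - 5
  cmp2 <- species_adjusted_comparison(d2, retain_interaction = "never")
  expect_equal(cmp1$adjusted_means$adjusted_mean,
               cmp2$adjusted_means$adjusted_mean, tolerance = 1e-10)
  expect_error(species_adjusted_comparison(log10_prepare(mk_rmr())),
               ">= 2 species")
})

test_that("rank_group_tests matches the rank formula and handles ties", {
  out <- rank_group_tests(c(1, 2, 3, 101, 102, 103, 201, 202, 203),
                          rep(1:3, each = 3))
  # hand-computed tie-free H for perfectly separated equal groups
  expect_equal(out$h, 7.2)
  expect_equal(out$df, 2)
  # agreement with the standard implementation on tied data
  set.seed(2)
  x <- sample(rep(1:6, 5)); g <- rep(1:3, each = 10)
  expect_equal(rank_group_tests(x, g)$h,
               unname(stats::kruskal.test(x, factor(g))$statistic))
  # degenerate all-tied data
  out0 <- rank_group_tests(rep(4, 9), rep(1:3, each = 3))
  expect_equal(out0$h, 0)
  expect_equal(out0$p, 1)
  expect_true(all(out0$pairwise$p_adj == 1))
  # two identical groups: adjusted pairwise p of 1
  out2 <- rank_group_tests(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))
  expect_true(all(out2$pairwise$p_adj == 1))
})

test_that("rank_group_tests is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- rlnorm(30); g <- rep(1:3, each = 10)
  base <- rank_group_tests(x, g)
  for (f in list(log, sqrt, function(v) v^3 + 5)) {
    tr <- rank_group_tests(f(x), g)
    expect_equal(tr$h, base$h)
    expect_equal(tr$pairwise$z, base$pairwise$z)
  }
})
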