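#!/usr/bin/env Rscript
# One-time solver for the default synthetic-species TPC parameters.
#
# For each species profile the generating curve family is fixed and the
# shape parameters are chosen (once, by this script) to minimise a
# weighted squared mismatch against the target optimum (To), the 80%
# breadth endpoints, and near-zero performance at the critical thermal
# limits, with the amplitude then scaled so the peak equals the target
# Vmax. Near-zero boundary values are part of the stated world: the
# fitting pipeline anchors curves to zero at the CT means, so a
# self-consistent generator must be (approximately) zero there too.
# The three families cannot reproduce every printed breadth exactly
# (their tails are too heavy for wide-B80/moderate-TTB combinations);
# the compromise solved here prioritises To and the boundary zeros.
#
# Output: a block of constants pasted into make_default_profiles().
# Run from the repository root: Rscript scripts/solve_profiles.R

for (f in list.files("R", full.names = TRUE)) source(f)

solve_profile <- function(family_name, targets, w_to = 3, w_bound = 3,
                          n_starts = 60, seed = 42) {
  fam <- tpc_family(family_name)
  shape_metrics <- function(theta) {
    par <- c(1, theta)
    f <- function(x) fam$eval(x, par)
    opt <- tryCatch(
      stats::optimize(f, c(targets$ct_min, targets$ct_max),
                      maximum = TRUE, tol = 1e-7),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective) || opt$objective <= 0)
      return(NULL)
    to <- opt$maximum; pk <- opt$objective
    g <- function(x) f(x) - 0.8 * pk
    lo <- tryCatch(
      if (g(targets$ct_min) < 0)
        stats::uniroot(g, c(targets$ct_min, to), tol = 1e-6)$root
      else targets$ct_min, error = function(e) NA_real_)
    hi <- tryCatch(
      if (g(targets$ct_max) < 0)
        stats::uniroot(g, c(to, targets$ct_max), tol = 1e-6)$root
      else targets$ct_max, error = function(e) NA_real_)
    if (!is.finite(lo) || !is.finite(hi)) return(NULL)
    list(to = to, peak = pk, lo = lo, hi = hi,
         z_min = f(targets$ct_min) / pk, z_max = f(targets$ct_max) / pk)
  }
  obj <- function(theta) {
    m <- shape_metrics(theta)
    if (is.null(m)) return(1e6)
    w_to^2 * (m$to - targets$t_o)^2 +
      (m$lo - targets$b80_low)^2 + (m$hi - targets$b80_high)^2 +
      w_bound^2 * (10 * m$z_min)^2 + w_bound^2 * (10 * m$z_max)^2
  }
  starts <- .tpc_starts(fam, c(targets$ct_min, targets$ct_max),
                        c(0, 0), n_starts, seed)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                                 control = list(maxit = 2000,
                                                reltol = 1e-13)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  m <- shape_metrics(best$par)
  a <- targets$v_max / m$peak   # scale the peak to Vmax
  params <- c(a, best$par)
  names(params) <- fam$param_names
  achieved <- list(t_o = m$to, v_max = targets$v_max,
                   b80_low = m$lo, b80_high = m$hi,
                   frac_at_ct_min = m$z_min, frac_at_ct_max = m$z_max,
                   objective = best$value)
  list(params = params, achieved = achieved)
}

targets <- list(
  crotalus_polystictus = list(
    family = "emg_peak", ct_min = 5.9, ct_max = 43.1,
    t_o = 36.7, v_max = 42.0, b80_low = 26.3, b80_high = 39.2),
  conopsis_lineata = list(
    family = "asym_logistic_peak", ct_min = 9.3, ct_max = 41.2,
    t_o = 27.8, v_max = 29.3, b80_low = 20.1, b80_high = 34.3),
  thamnophis_melanogaster = list(
    family = "gumbel_peak", ct_min = 8.5, ct_max = 41.6,
    t_o = 28.6, v_max = 71.7, b80_low = 20.7, b80_high = 34.9))

for (sp in names(targets)) {
  tg <- targets[[sp]]
  sol <- solve_profile(tg$family, tg)
  cat("\n==", sp, "(", tg$family, ")\n")
  cat("params:", paste(sprintf("%s = %.6f", names(sol$params),
                               sol$params), collapse = ", "), "\n")
  cat(sprintf(paste0("achieved: To = %.2f (target %.2f), ",
                     "B80 = [%.2f, %.2f] (target [%.2f, %.2f])\n",
                     "curve/Vmax at CTmin = %.4f, at CTmax = %.4f\n"),
              sol$achieved$t_o, tg$t_o, sol$achieved$b80_low,
              sol$achieved$b80_high, tg$b80_low, tg$b80_high,
              sol$achieved$frac_at_ct_min, sol$achieved$frac_at_ct_max))
}
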