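# Shared fixtures and independent oracles, built in code.

# A tolerance summary whose CT limits sit where the raw curve is
# numerically zero (< 1e-7 of the peak), so a curve's own anchored fit
# is exactly self-consistent. Purely a test device: real CT limits are
# biological, these are numerical.
far_anchor_summary <- function(family_name, params, n = 38L) {
  fam <- tpc_family(family_name)
  grid <- seq(-150, 350, by = 0.1)
  y <- fam$eval(grid, params)
  ipk <- which.max(y)
  pk <- y[ipk]
  lo <- max(grid[seq_len(ipk)][y[seq_len(ipk)] < 1e-7 * pk])
  hi <- min(grid[ipk:length(grid)][y[ipk:length(grid)] < 1e-7 * pk])
  tolerance_summary("synthetic", lo, hi, n = n)
}

# Brute-force grid argmax oracle (step in deg C)
brute_argmax <- function(f, lo, hi, step = 0.001) {
  grid <- seq(lo, hi, by = step)
  grid[which.max(f(grid))]
}

# Brute-force sliding-window minimum-mean oracle
brute_min_window_mean <- function(x, w) {
  min(vapply(seq_len(length(x) - w + 1),
             function(i) mean(x[i:(i + w - 1)]), numeric(1)))
}

# Identifiable reference parameter sets per family (moderate shape
# values away from degenerate ridges)
reference_params <- function(family_name) {
  switch(family_name,
    emg_peak = c(a = 400, mu = 24, sigma = 3.5, lambda = 0.12),
    asym_logistic_peak = c(a = 29.3, c = 33.490826, b = -4.991221,
                           d = 3.140272),
    gumbel_peak = c(a = 71.7, mu = 28.623018, sigma = -4.215384))
}

default_profile <- function(which) make_default_profiles()[[which]]
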