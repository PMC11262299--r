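#' Thermal tolerance summary for one species
#'
#' Holds the species-level means and standard deviations of the critical
#' thermal minimum (CTmin) and maximum (CTmax) determined by
#' loss-of-righting-response trials, plus the sample size. The CT means
#' anchor the TPC boundaries and define the thermal tolerance breadth.
#'
#' @param species Species label.
#' @param ct_min_mean,ct_max_mean Mean critical thermal limits (deg C).
#' @param ct_min_sd,ct_max_sd Standard deviations (deg C, >= 0).
#' @param n Number of individuals tested (>= 1), `NA` if unknown.
#' @return A `tolerance_summary` object.
#' @export
tolerance_summary <- function(species, ct_min_mean, ct_max_mean,
                              ct_min_sd = NA_real_, ct_max_sd = NA_real_,
                              n = NA_integer_) {
  stopifnot(is.numeric(ct_min_mean), is.numeric(ct_max_mean))
  if (is.finite(ct_min_mean) && is.finite(ct_max_mean) &&
      ct_min_mean >= ct_max_mean)
    stop("tolerance_summary(): ct_min_mean must be below ct_max_mean")
  for (s in c(ct_min_sd, ct_max_sd))
    if (is.finite(s) && s < 0)
      stop("tolerance_summary(): standard deviations must be >= 0")
  if (is.finite(n) && n < 1)
    stop("tolerance_summary(): n must be >= 1")
  structure(list(species = species,
                 ct_min_mean = as.numeric(ct_min_mean),
                 ct_min_sd = as.numeric(ct_min_sd),
                 ct_max_mean = as.numeric(ct_max_mean),
                 ct_max_sd = as.numeric(ct_max_sd),
                 n = as.integer(n)),
            class = "tolerance_summary")
}

#' @export
print.tolerance_summary <- function(x, ...) {
  cat(sprintf(
    "<tolerance_summary> %s: CTmin %.2f +/- %.2f, CTmax %.2f +/- %.2f (n = %s)\n",
    x$species, x$ct_min_mean, x$ct_min_sd, x$ct_max_mean, x$ct_max_sd,
    ifelse(is.na(x$n), "?", x$n)))
  invisible(x)
}

#' Summarise per-individual critical thermal limits by species
#'
#' @param records Data frame with columns `individual_id`, `species`,
#'   `ct_min_c`, `ct_max_c` (either limit may be `NA` per individual).
#' @return Named list of [tolerance_summary()] objects, one per species.
#' @export
summarize_tolerance <- function(records) {
  need <- c("individual_id", "species", "ct_min_c", "ct_max_c")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("summarize_tolerance(): missing columns: ",
         paste(miss, collapse = ", "))
  both <- !is.na(records$ct_min_c) & !is.na(records$ct_max_c)
  if (any(records$ct_min_c[both] >= records$ct_max_c[both]))
    stop("summarize_tolerance(): found ct_min >= ct_max for an individual")
  out <- lapply(split(records, records$species), function(d) {
    tolerance_summary(
      species = d$species[1],
      ct_min_mean = mean(d$ct_min_c, na.rm = TRUE),
      ct_min_sd = stats::sd(d$ct_min_c, na.rm = TRUE),
      ct_max_mean = mean(d$ct_max_c, na.rm = TRUE),
      ct_max_sd = stats::sd(d$ct_max_c, na.rm = TRUE),
      n = nrow(d))
  })
  out
}

#' Thermal tolerance breadth (TTB)
#'
#' TTB is the distance in deg C between the mean critical thermal maximum
#' and minimum.
#'
#' @param summary A [tolerance_summary()], or a numeric CTmin mean when
#'   `ct_max` is given.
#' @param ct_max Optional numeric CTmax mean (deg C) for the two-number
#'   form `ttb(ct_min, ct_max)`.
#' @return TTB in deg C.
#' @export
ttb <- function(summary, ct_max = NULL) {
  if (is.numeric(summary) && !is.null(ct_max)) {
    ct_min_mean <- summary; ct_max_mean <- ct_max
  } else {
    stopifnot(inherits(summary, "tolerance_summary"))
    ct_min_mean <- summary$ct_min_mean; ct_max_mean <- summary$ct_max_mean
  }
  if (!is.finite(ct_min_mean) || !is.finite(ct_max_mean))
    stop("ttb(): both CT means must be present")
  ct_max_mean - ct_min_mean
}

#' Thermal safety margin (TSM)
#'
#' The buffer between the performance optimum and the upper tolerance
#' limit: `ct_max - t_o`.
#'
#' @param ct_max Mean critical thermal maximum (deg C).
#' @param t_o Optimal temperature of the fitted TPC (deg C).
#' @return TSM in deg C (>= 0).
#' @export
thermal_safety_margin <- function(ct_max, t_o) {
  stopifnot(is.finite(ct_max), is.finite(t_o))
  if (t_o > ct_max)
    stop("thermal_safety_margin(): t_o (", t_o,
         ") exceeds ct_max (", ct_max, "); fit is outside the tolerance ",
         "limits")
  ct_max - t_o
}

#' Derive thermal metrics from a fitted TPC
#'
#' Extracts, from the clamped fitted curve on `[ct_min, ct_max]`:
#' \describe{
#'   \item{`v_max`}{maximum performance (cm/s);}
#'   \item{`t_o`}{optimal temperature (argmax, deg C), located by a dense
#'     grid search then golden-section refinement;}
#'   \item{`b80_low`, `b80_high`}{the performance-breadth endpoints where
#'     the curve crosses `level * v_max` (default 80%), found by root
#'     bracketing on each side of the optimum;}
#'   \item{`tsm`}{thermal safety margin `ct_max - t_o`;}
#'   \item{`ttb`}{thermal tolerance breadth `ct_max - ct_min`.}
#' }
#'
#' If the curve never falls below `level * v_max` on one side before the
#' tolerance limit, that endpoint is reported at the limit and flagged in
#' `boundary_warning` (with a warning). A clamped curve with more than
#' one local maximum above `level * v_max` is rejected as ambiguous.
#'
#' @param fit A `tpc_fit` from [fit_family()].
#' @param anchors Optional [tolerance_summary()]; defaults to the one
#'   stored in the fit.
#' @param level Breadth level in (0, 1); default 0.8.
#' @param grid_step Grid step for the argmax search (deg C).
#' @return A `thermal_metrics` object (list with the fields above).
#' @export
derive_metrics <- function(fit, anchors = NULL, level = 0.8,
                           grid_step = 0.01) {
  stopifnot(inherits(fit, "tpc_fit"))
  if (!isTRUE(fit$converged))
    stop("derive_metrics(): fit did not converge")
  if (!(level > 0 && level < 1))
    stop("derive_metrics(): level must be in (0, 1)")
  if (is.null(anchors)) anchors <- fit$anchors
  stopifnot(inherits(anchors, "tolerance_summary"))
  fam <- tpc_family(fit$family)
  lo <- anchors$ct_min_mean; hi <- anchors$ct_max_mean

  f <- function(x) tpc_eval_clamped(fam, x, fit$params, lo, hi)
  grid <- seq(lo, hi, by = grid_step)
  yg <- f(grid)
  i <- which.max(yg)
  # local refinement around the grid argmax
  a <- grid[max(1, i - 1)]; b <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(f, c(a, b), maximum = TRUE,
                         tol = min(grid_step / 100, 1e-6))
  t_o <- opt$maximum; v_max <- opt$objective
  if (v_max <= 0)
    stop("derive_metrics(): fitted curve is non-positive on the interval")

  # multimodality guard: count strict local maxima above level * v_max
  is_max <- which(diff(sign(diff(yg))) == -2) + 1L
  high <- is_max[yg[is_max] > level * v_max]
  if (length(high) > 1)
    stop("derive_metrics(): clamped curve has multiple local maxima ",
         "above the breadth level; metrics are ambiguous")

  target <- level * v_max
  g <- function(x) f(x) - target
  boundary_warning <- FALSE
  b80_low <- if (g(lo) < 0) {
    stats::uniroot(g, c(lo, t_o), tol = 1e-4)$root
  } else {
    boundary_warning <- TRUE; lo
  }
  b80_high <- if (g(hi) < 0) {
    stats::uniroot(g, c(t_o, hi), tol = 1e-4)$root
  } else {
    boundary_warning <- TRUE; hi
  }
  if (boundary_warning)
    warning("derive_metrics(): breadth endpoint(s) truncated at the ",
            "tolerance limit")

  structure(list(
    species = fit$species, family = fit$family,
    v_max = v_max, t_o = t_o, b80_low = b80_low, b80_high = b80_high,
    tsm = thermal_safety_margin(hi, t_o), ttb = ttb(anchors),
    level = level, boundary_warning = boundary_warning
  ), class = "thermal_metrics")
}

#' @export
print.thermal_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<thermal_metrics> %s (%s)\n",
           "  Vmax = %.1f cm/s at To = %.1f C\n",
           "  B%d = [%.1f, %.1f] C, TSM = %.1f C, TTB = %.1f C%s\n"),
    ifelse(is.na(x$species), "?", x$species), x$family, x$v_max, x$t_o,
    round(100 * x$level), x$b80_low, x$b80_high, x$tsm, x$ttb,
    if (x$boundary_warning) "  [breadth truncated]" else ""))
  invisible(x)
}
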