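#' Small-sample corrected Akaike information criterion for least squares
#'
#' For a Gaussian least-squares fit with residual sum of squares `rss`,
#' `n` observations and `k` estimated curve parameters,
#' \deqn{AICc = n \log(rss/n) + 2k + \frac{2k(k+1)}{n - k - 1}.}
#' Additive constants common to all candidates are dropped, so only
#' differences are meaningful.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Sample size entering the correction (> k + 1).
#' @param k Number of fitted parameters.
#' @return AICc value (finite numeric scalar).
#' @export
aicc_ls <- function(rss, n, k) {
  stopifnot(length(rss) == 1, length(n) == 1, length(k) == 1)
  if (!is.finite(rss) || rss <= 0)
    stop("aicc_ls(): rss must be a positive finite number")
  if (n <= k + 1)
    stop("aicc_ls(): AICc undefined for n <= k + 1 (n = ", n,
         ", k = ", k, ")")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one TPC family to anchored performance data
#'
#' Fits a unimodal curve family to `(temperature, performance)` points by
#' multi-start nonlinear least squares. The critical thermal limits enter
#' as two ordinary zero-performance points (`(ct_min_mean, 0)` and
#' `(ct_max_mean, 0)`) with weight `anchor_weight`, so the fitted curve is
#' pulled to zero at the tolerance boundaries; downstream evaluation is
#' additionally hard-clamped outside them.
#'
#' The amplitude parameter is profiled out analytically (the model is
#' linear in it), and the remaining shape parameters are optimised from
#' `n_starts` Latin-hypercube starting points over data-driven bounds
#' (Nelder-Mead, then a BFGS polish of the best start). The fit is
#' deterministic given `seed`.
#'
#' @param temp,perf Numeric vectors: treatment temperatures (deg C) and
#'   performance values (cm/s), typically per-treatment means.
#' @param family A [tpc_family()] or family name.
#' @param anchors A [tolerance_summary()] supplying the CT means.
#' @param n_reported Sample size used in the AICc correction. The
#'   convention in this literature is the number of individuals behind
#'   the treatment means; `n_fit` uses the fitted point count instead.
#' @param anchor_weight Weight of the two boundary points (default 1).
#' @param n_starts Number of multi-start points (default 20).
#' @param seed Integer seed for start generation.
#' @return A `tpc_fit` object: list with `species`, `family`, `params`
#'   (named), `rss`, `r2`, `aicc`, `n_fit_points`, `n_reported`,
#'   `converged`, `anchors`.
#' @export
fit_family <- function(temp, perf, family, anchors,
                       n_reported = c("individuals", "n_fit"),
                       anchor_weight = 1, n_starts = 20, seed = 1L) {
  if (is.character(family)) family <- tpc_family(family)
  stopifnot(inherits(family, "tpc_family"),
            inherits(anchors, "tolerance_summary"),
            length(temp) == length(perf), all(is.finite(temp)),
            all(is.finite(perf)), all(perf >= 0), anchor_weight > 0)
  if (is.character(n_reported)) {
    n_reported <- match.arg(n_reported)
    n_reported <- if (n_reported == "individuals" && !is.na(anchors$n))
      anchors$n else length(temp) + 2L
  }
  n_reported <- as.integer(n_reported)

  tt <- c(temp, anchors$ct_min_mean, anchors$ct_max_mean)
  yy <- c(perf, 0, 0)
  ww <- c(rep(1, length(temp)), anchor_weight, anchor_weight)
  n_fit <- length(tt)
  if (n_fit < family$n_params + 2L)
    stop("fit_family(): need at least n_params + 2 = ",
         family$n_params + 2L, " points including anchors, got ", n_fit)

  wmean <- sum(ww * yy) / sum(ww)
  tss <- sum(ww * (yy - wmean)^2)
  if (tss <= 0) stop("fit_family(): degenerate data, total SS is zero")

  # amplitude profiled out: for fixed shape theta, phi = f(tt; a = 1) and
  # a* = sum(w y phi) / sum(w phi^2) >= 0 since y, phi >= 0
  shape_obj <- function(theta) {
    par <- .tpc_assemble(family, 1, theta)
    phi <- family$eval(tt, par)
    if (any(!is.finite(phi))) return(list(rss = Inf, a = NA_real_))
    den <- sum(ww * phi^2)
    if (den <= 0) return(list(rss = Inf, a = NA_real_))
    a <- sum(ww * yy * phi) / den
    list(rss = sum(ww * (yy - a * phi)^2), a = a)
  }
  obj <- function(theta) shape_obj(theta)$rss

  starts <- .tpc_starts(family, tt, yy, n_starts, seed)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                   control = list(maxit = 800, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  converged <- FALSE
  if (!is.null(best)) {
    polish <- tryCatch(
      stats::optim(best$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(polish) && is.finite(polish$value) &&
        polish$value <= best$value) best <- polish
    # final Nelder-Mead sweep: BFGS with numeric gradients can stall
    polish2 <- tryCatch(
      stats::optim(best$par, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(polish2) && is.finite(polish2$value) &&
        polish2$value <= best$value) best <- polish2
    converged <- is.finite(best$value)
  }
  if (is.null(best))
    stop("fit_family(): all optimisation starts failed for family ",
         family$name)

  sol <- shape_obj(best$par)
  params <- .tpc_assemble(family, sol$a, best$par)
  names(params) <- family$param_names
  rss <- max(best$value, 1e-300)  # floor so AICc stays finite at machine-0
  r2 <- 1 - best$value / tss

  structure(list(
    species = anchors$species, family = family$name, params = params,
    rss = rss, r2 = r2,
    aicc = aicc_ls(rss, n_reported, family$n_params),
    n_fit_points = n_fit, n_reported = n_reported,
    converged = converged, anchors = anchors,
    anchor_weight = anchor_weight
  ), class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("<tpc_fit> ", x$family,
      if (!is.na(x$species)) paste0(" [", x$species, "]"),
      "\n  params: ",
      paste(sprintf("%s = %.4g", names(x$params), x$params),
            collapse = ", "),
      sprintf("\n  rss = %.4g, R2 = %.4f, AICc = %.3f (n = %d, k = %d)%s\n",
              x$rss, x$r2, x$aicc, x$n_reported,
              length(x$params), if (x$converged) "" else "  NOT CONVERGED"),
      sep = "")
  invisible(x)
}

# parameter vector = amplitude followed by shape params, in family order
.tpc_assemble <- function(family, a, theta) c(a, theta)

# Latin-hypercube starts over data-driven shape-parameter bounds.
# Location spans the observed temperature range; scales span a fraction
# to the whole of it. For sign-flippable scales both orientations are
# covered by alternating signs across starts.
.tpc_starts <- function(family, tt, yy, n_starts, seed) {
  rng <- range(tt)
  span <- diff(rng)
  lhs <- function(lo, hi, u) lo + (hi - lo) * u
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- matrix(stats::runif(n_starts * 3), n_starts, 3)
  # stratify first column (location) for coverage
  u[, 1] <- (sample(n_starts) - stats::runif(n_starts)) / n_starts
  switch(family$name,
    gumbel_peak = {
      m <- cbind(mu = lhs(rng[1], rng[2], u[, 1]),
                 sigma = lhs(0.05 * span, 0.8 * span, u[, 2]))
      m[, 2] <- m[, 2] * rep_len(c(1, -1), n_starts)
      m
    },
    emg_peak = {
      cbind(mu = lhs(rng[1], rng[2], u[, 1]),
            sigma = lhs(0.05 * span, 0.6 * span, u[, 2]),
            lambda = exp(lhs(log(0.02), log(2), u[, 3])))
    },
    asym_logistic_peak = {
      m <- cbind(c = lhs(rng[1], rng[2], u[, 1]),
                 b = lhs(0.03 * span, 0.5 * span, u[, 2]),
                 d = exp(lhs(log(0.2), log(20), u[, 3])))
      m[, 2] <- m[, 2] * rep_len(c(1, -1), n_starts)
      m
    })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit all TPC families and select the best
#'
#' Convenience wrapper: fits every family in [tpc_family_names()] via
#' [fit_family()] and applies [select_tpc()].
#'
#' @inheritParams fit_family
#' @param families Character vector of family names to try.
#' @param r2_floor Minimum R2 for a candidate to enter selection.
#' @return List with `fits` (all `tpc_fit`s) and `best`.
#' @export
fit_tpc <- function(temp, perf, anchors, families = tpc_family_names(),
                    n_reported = "individuals", anchor_weight = 1,
                    n_starts = 20, seed = 1L, r2_floor = 0.9) {
  fits <- lapply(families, function(fam)
    fit_family(temp, perf, fam, anchors, n_reported = n_reported,
               anchor_weight = anchor_weight, n_starts = n_starts,
               seed = seed))
  names(fits) <- families
  list(fits = fits, best = select_tpc(fits, r2_floor = r2_floor))
}

#' Select the best TPC among candidate fits
#'
#' Mirrors the standard workflow: candidates are screened by an R2 floor
#' and the survivor with the lowest AICc wins. Ties are broken by fewer
#' parameters, then by family name order. Non-converged fits never enter
#' selection.
#'
#' @param fits List of `tpc_fit` objects.
#' @param r2_floor Minimum R2 (default 0.9, exclusive).
#' @return The winning `tpc_fit`.
#' @export
select_tpc <- function(fits, r2_floor = 0.9) {
  stopifnot(length(fits) > 0)
  ok <- vapply(fits, function(f) isTRUE(f$converged) && f$r2 > r2_floor,
               logical(1))
  if (!any(ok)) {
    best_r2 <- suppressWarnings(max(vapply(fits, `[[`, numeric(1), "r2")))
    stop("select_tpc(): no converged fit exceeds the R2 floor of ",
         r2_floor, " (best R2 achieved: ", signif(best_r2, 4), ")")
  }
  cand <- fits[ok]
  aiccs <- vapply(cand, `[[`, numeric(1), "aicc")
  ks <- vapply(cand, function(f) length(f$params), numeric(1))
  fam <- vapply(cand, `[[`, character(1), "family")
  ord <- order(aiccs, ks, fam)
  cand[[ord[1]]]
}
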