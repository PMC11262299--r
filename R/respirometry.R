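#' Construct an open-flow respirometry trace
#'
#' One animal's CO2 trace in a push-through respirometry chamber:
#' incurrent air is scrubbed of water and CO2 and pumped through at a
#' known flow rate; the fractional CO2 concentration of the excurrent
#' air is logged on a uniform time grid.
#'
#' @param individual_id Identifier.
#' @param treatment_temp Chamber temperature (deg C).
#' @param sample_times Sampling times in s, uniformly spaced.
#' @param fe_co2 Excurrent fractional CO2 concentrations (dimensionless,
#'   in `[0, 1)`).
#' @param flow_rate Incurrent flow in ml/min (default 100).
#' @param fi_co2 Incurrent fractional CO2 (default 0: scrubbed air).
#' @param species,body_mass Optional covariates.
#' @return A `resp_trace` object.
#' @export
resp_trace <- function(individual_id, treatment_temp, sample_times,
                       fe_co2, flow_rate = 100, fi_co2 = 0,
                       species = NA_character_, body_mass = NA_real_) {
  stopifnot(length(sample_times) == length(fe_co2),
            length(sample_times) >= 2, flow_rate > 0)
  dt <- diff(sample_times)
  if (any(abs(dt - dt[1]) > 1e-8 * max(dt[1], 1)))
    stop("resp_trace(): sample_times must be uniformly spaced")
  if (dt[1] <= 0) stop("resp_trace(): sample_times must be increasing")
  if (any(fe_co2 < 0 | fe_co2 >= 1) || fi_co2 < 0 || fi_co2 >= 1)
    stop("resp_trace(): fractional concentrations must lie in [0, 1)")
  structure(list(individual_id = individual_id, species = species,
                 treatment_temp = treatment_temp, body_mass = body_mass,
                 sample_times = as.numeric(sample_times),
                 fe_co2 = as.numeric(fe_co2),
                 flow_rate = flow_rate, fi_co2 = fi_co2,
                 dt = dt[1]),
            class = "resp_trace")
}

#' Lowest stable window mean of a CO2 trace
#'
#' Finds the minimum, over all contiguous windows of `window` seconds
#' (advancing one sample at a time), of the window mean of the excurrent
#' fractional CO2. This is the standard stable-segment rule: the lowest
#' sustained CO2 level over the window length is taken as the resting
#' signal, ignoring activity transients.
#'
#' @param trace A [resp_trace()].
#' @param window Window length in s (default 100).
#' @return Minimal window mean (fractional CO2).
#' @export
stable_mean <- function(trace, window = 100) {
  stopifnot(inherits(trace, "resp_trace"), window > 0)
  w <- as.integer(round(window / trace$dt))
  n <- length(trace$fe_co2)
  if (w < 1 || w > n)
    stop("stable_mean(): trace (", round(n * trace$dt), " s) is shorter ",
         "than the ", window, " s window")
  cs <- cumsum(c(0, trace$fe_co2))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  min(means)
}

#' Rate of CO2 production from flow and gas fractions
#'
#' \deqn{\dot{V}CO_2 = FR_i (F_eCO_2 - F_iCO_2)} with the incurrent flow
#' `FR_i` in ml/min and fractional excurrent/incurrent CO2
#' concentrations. A negative result (excurrent below incurrent, e.g.
#' baseline drift) warns but is returned so that instrument problems stay
#' visible downstream.
#'
#' @param flow_rate Incurrent flow in ml/min.
#' @param fe_co2,fi_co2 Fractional CO2 concentrations in `[0, 1)`.
#' @return VCO2 in ml CO2/min.
#' @examples
#' vco2(100, 0.0010)  # 0.1 ml/min
#' @export
vco2 <- function(flow_rate, fe_co2, fi_co2 = 0) {
  stopifnot(flow_rate > 0)
  if (any(fe_co2 < 0 | fe_co2 >= 1) || any(fi_co2 < 0 | fi_co2 >= 1))
    stop("vco2(): fractional concentrations must lie in [0, 1)")
  out <- flow_rate * (fe_co2 - fi_co2)
  if (any(out < 0))
    warning("vco2(): excurrent CO2 below incurrent; negative rate ",
            "returned (check baseline)")
  out
}

#' Resting metabolic rate from one respirometry trace
#'
#' Composes [stable_mean()] and [vco2()]: RMR is the VCO2 implied by the
#' lowest 100 s (by default) average excurrent CO2 level.
#'
#' @param trace A [resp_trace()].
#' @param window Stable-window length in s (default 100).
#' @return One-row data frame (an `RMRRecord`): `individual_id`,
#'   `species`, `treatment_c`, `body_mass_g`, `vco2_ml_min`.
#' @export
rmr_from_trace <- function(trace, window = 100) {
  stopifnot(inherits(trace, "resp_trace"))
  fe <- stable_mean(trace, window = window)
  data.frame(individual_id = trace$individual_id,
             species = trace$species,
             treatment_c = trace$treatment_temp,
             body_mass_g = trace$body_mass,
             vco2_ml_min = vco2(trace$flow_rate, fe, trace$fi_co2),
             stringsAsFactors = FALSE)
}

#' Q10 thermal sensitivity coefficient
#'
#' \deqn{Q_{10} = (RMR_2 / RMR_1)^{10 / (T_2 - T_1)}} — the factor by
#' which the metabolic rate changes per 10 deg C. Inputs are
#' canonicalised so that `t2 > t1`.
#'
#' @param rmr1,rmr2 Metabolic rates (ml CO2/min, > 0) at `t1` and `t2`.
#' @param t1,t2 Temperatures (deg C, distinct).
#' @return A `q10_result` list: `t1`, `t2`, `rmr1`, `rmr2`, `q10`.
#' @examples
#' q10(0.1, 15, 0.2, 25)$q10  # doubling over 10 C -> 2
#' @export
q10 <- function(rmr1, t1, rmr2, t2) {
  if (!is.finite(rmr1) || !is.finite(rmr2) || rmr1 <= 0 || rmr2 <= 0)
    stop("q10(): metabolic rates must be positive")
  if (t1 == t2) stop("q10(): temperatures must differ")
  if (t2 < t1) { tmp <- list(rmr1, t1); rmr1 <- rmr2; t1 <- t2
                 rmr2 <- tmp[[1]]; t2 <- tmp[[2]] }
  structure(list(t1 = t1, t2 = t2, rmr1 = rmr1, rmr2 = rmr2,
                 q10 = (rmr2 / rmr1)^(10 / (t2 - t1))),
            class = "q10_result")
}

#' @export
print.q10_result <- function(x, ...) {
  cat(sprintf("<q10_result> Q10(%g-%g C) = %.3f\n", x$t1, x$t2, x$q10))
  invisible(x)
}

#' Per-species Q10 table across thermal treatments
#'
#' Computes Q10 between consecutive treatment pairs and over the whole
#' span, from per-treatment arithmetic mean RMR. Treatments missing for
#' a species leave the corresponding cells `NA` rather than failing
#' (partial designs are common: e.g. a cohort without a 33 deg C
#' treatment).
#'
#' @param records Data frame of RMR records with columns `species`,
#'   `treatment_c`, `vco2_ml_min`.
#' @param treatments Ordered treatment temperatures defining the
#'   consecutive pairs (default the five-treatment design).
#' @return Data frame: one row per species, one column per interval
#'   (`q10_15_25`, ..., `q10_overall`).
#' @export
q10_table <- function(records, treatments = c(15, 25, 30, 33, 36)) {
  need <- c("species", "treatment_c", "vco2_ml_min")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("q10_table(): missing columns: ", paste(miss, collapse = ", "))
  treatments <- sort(treatments)
  if (length(unique(records$treatment_c)) < 2)
    stop("q10_table(): need at least two treatments")
  pairs <- cbind(treatments[-length(treatments)], treatments[-1])
  pairs <- rbind(pairs, c(treatments[1], treatments[length(treatments)]))
  labs <- c(sprintf("q10_%g_%g", pairs[-nrow(pairs), 1],
                    pairs[-nrow(pairs), 2]), "q10_overall")
  rows <- lapply(split(records, records$species), function(d) {
    mu <- tapply(d$vco2_ml_min, d$treatment_c, mean)
    cell <- function(t1, t2) {
      k1 <- as.character(t1); k2 <- as.character(t2)
      if (!k1 %in% names(mu) || !k2 %in% names(mu)) return(NA_real_)
      if (mu[[k1]] <= 0 || mu[[k2]] <= 0) return(NA_real_)
      q10(mu[[k1]], t1, mu[[k2]], t2)$q10
    }
    vals <- mapply(cell, pairs[, 1], pairs[, 2])
    out <- data.frame(species = d$species[1], stringsAsFactors = FALSE)
    out[labs] <- as.list(vals)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
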