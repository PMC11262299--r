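#' Validate a pipeline input table against a named schema
#'
#' Schemas: `"speeds"`, `"tolerance"`, `"trials"`, `"rmr"`, `"traces"`.
#' Checks required columns, types, and value constraints (non-negative
#' speeds, CT ordering, positive frame counts, positive flow, uniform
#' trace timestamps), reporting every violation with row/column
#' coordinates instead of stopping at the first.
#'
#' @param x A data frame or a path to a CSV file.
#' @param schema Schema name.
#' @return Data frame with columns `row`, `column`, `message`; zero rows
#'   for a clean table.
#' @export
validate <- function(x, schema = c("speeds", "tolerance", "trials",
                                   "rmr", "traces")) {
  schema <- match.arg(schema)
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  issues <- list()
  bad <- function(rows, column, message) {
    if (length(rows) == 0 || !any(rows, na.rm = TRUE)) return()
    issues[[length(issues) + 1]] <<- data.frame(
      row = which(rows), column = column, message = message,
      stringsAsFactors = FALSE)
  }
  need <- switch(schema,
    speeds = c("individual_id", "species", "treatment_c",
               "max_speed_cm_s"),
    tolerance = c("individual_id", "species", "ct_min_c", "ct_max_c"),
    trials = c("individual_id", "species", "treatment_c"),
    rmr = c("individual_id", "species", "treatment_c", "body_mass_g",
            "vco2_ml_min"),
    traces = c("individual_id", "species", "treatment_c", "time_s",
               "fe_co2"))
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    return(data.frame(row = NA_integer_, column = missing_cols,
                      message = "required column is missing",
                      stringsAsFactors = FALSE))
  switch(schema,
    speeds = {
      bad(!is.finite(x$max_speed_cm_s) | x$max_speed_cm_s < 0,
          "max_speed_cm_s", "speed must be a non-negative number")
      bad(!is.finite(x$treatment_c), "treatment_c",
          "treatment temperature must be numeric")
    },
    tolerance = {
      both <- is.finite(x$ct_min_c) & is.finite(x$ct_max_c)
      bad(both & x$ct_min_c >= x$ct_max_c, "ct_min_c",
          "ct_min must be below ct_max")
      if ("cooling_rate_c_min" %in% names(x))
        bad(is.finite(x$cooling_rate_c_min) & x$cooling_rate_c_min <= 0,
            "cooling_rate_c_min", "rate must be positive")
      if ("heating_rate_c_min" %in% names(x))
        bad(is.finite(x$heating_rate_c_min) & x$heating_rate_c_min <= 0,
            "heating_rate_c_min", "rate must be positive")
    },
    trials = {
      long <- all(c("segment_index", "frames") %in% names(x))
      segcols <- grep("^seg[0-9]+$", names(x), value = TRUE)
      if (!long && !length(segcols))
        return(data.frame(row = NA_integer_, column = "frames",
                          message = paste("need long columns",
                            "(segment_index, frames) or wide seg1..segN"),
                          stringsAsFactors = FALSE))
      fcols <- if (long) "frames" else segcols
      for (cl in fcols) {
        v <- x[[cl]]
        bad(!is.na(v) & (v <= 0 | v != round(v)), cl,
            "frame counts must be positive whole numbers")
      }
      if ("frame_rate" %in% names(x))
        bad(is.finite(x$frame_rate) & x$frame_rate <= 0, "frame_rate",
            "frame rate must be positive")
    },
    rmr = {
      bad(!is.finite(x$vco2_ml_min), "vco2_ml_min",
          "VCO2 must be numeric")
      bad(is.finite(x$body_mass_g) & x$body_mass_g <= 0, "body_mass_g",
          "body mass must be positive")
    },
    traces = {
      bad(!is.finite(x$fe_co2) | x$fe_co2 < 0 | x$fe_co2 >= 1,
          "fe_co2", "fractional CO2 must lie in [0, 1)")
      key <- interaction(x$individual_id, x$treatment_c, drop = TRUE)
      for (k in levels(key)) {
        idx <- which(key == k)
        ts <- x$time_s[idx]
        dt <- diff(ts[order(ts)])
        if (length(dt) && any(abs(dt - dt[1]) > 1e-8 * max(dt[1], 1)))
          bad(seq_along(x$time_s) %in% idx[1], "time_s",
              paste0("non-uniform timestamps for trace ", k))
      }
    })
  if (!length(issues))
    return(data.frame(row = integer(), column = character(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

.stop_if_invalid <- function(x, schema) {
  rep <- validate(x, schema)
  if (nrow(rep))
    stop("validation failed for schema '", schema, "':\n",
         paste(utils::capture.output(print(rep)), collapse = "\n"),
         call. = FALSE)
  invisible(x)
}

#' Run the full thermal-physiology analysis pipeline
#'
#' Orchestrates: tolerance summaries and TTB; per-species TPC fitting
#' over all curve families with AICc selection and thermal metrics; RMR
#' records (from a pre-reduced table or from swim-trial-style traces)
#' and the Q10 table; per-species candidate mixed models with AICc
#' selection; and the cross-species mass-adjusted comparison. All
#' randomness (fit multi-starts) flows from `seed`. Inputs are
#' validated first; results are returned as a list of data frames and,
#' if `out_dir` is given, also written as CSV files plus a JSON
#' manifest recording the seed, options and per-stage row counts.
#'
#' @param speeds Speed observations (data frame or CSV path). May be
#'   `NULL` if `trials` is given.
#' @param tolerance Per-individual tolerance records (data frame or CSV
#'   path). Required for TPC fitting.
#' @param trials Optional swim-trial frame counts; reduced via
#'   [speeds_from_trials()] when `speeds` is absent.
#' @param rmr Optional pre-reduced RMR records.
#' @param out_dir Optional output directory (created if needed; existing
#'   result files are only overwritten when `overwrite = TRUE`).
#' @param seed Integer seed for the fit multi-starts.
#' @param treatments The design's treatment grid for the Q10 table.
#' @param r2_floor,b_level,anchor_weight TPC options (see
#'   [select_tpc()], [derive_metrics()], [fit_family()]).
#' @param n_reported AICc sample-size convention for TPC fits
#'   (`"individuals"` or `"n_fit"`).
#' @param roster Optional candidate-model roster for [candidate_set()].
#' @param p_adjust Adjustment for species contrasts.
#' @param overwrite Allow overwriting existing outputs.
#' @param verbose Log stage boundaries and row counts.
#' @return List: `tolerance_summaries`, `tpc_fits`, `tpc_metrics`,
#'   `rmr`, `q10`, `model_selection`, `coefficients`,
#'   `species_contrasts`, `adjusted_means`, `manifest`.
#' @export
run_all <- function(speeds = NULL, tolerance = NULL, trials = NULL,
                    rmr = NULL, out_dir = NULL, seed = 1L,
                    treatments = default_treatments(), r2_floor = 0.9,
                    b_level = 0.8, anchor_weight = 1,
                    n_reported = "individuals", roster = NULL,
                    p_adjust = "none", overwrite = FALSE,
                    verbose = TRUE) {
  say <- function(...) if (verbose) message("[run_all] ", ...)
  read_in <- function(x) if (is.character(x))
    utils::read.csv(x, stringsAsFactors = FALSE) else x
  speeds <- read_in(speeds); tolerance <- read_in(tolerance)
  trials <- read_in(trials); rmr <- read_in(rmr)
  if (is.null(speeds) && is.null(trials) && is.null(rmr))
    stop("run_all(): no analysis input given")

  counts <- list()
  if (!is.null(trials)) .stop_if_invalid(trials, "trials")
  if (is.null(speeds) && !is.null(trials)) {
    speeds <- speeds_from_trials(trials)
    say("reduced ", nrow(trials), " trial rows to ", nrow(speeds),
        " speed observations")
  }
  out <- list()

  if (!is.null(speeds)) {
    .stop_if_invalid(speeds, "speeds")
    if (is.null(tolerance))
      stop("run_all(): TPC fitting needs tolerance records")
    .stop_if_invalid(tolerance, "tolerance")
    counts$speeds <- nrow(speeds); counts$tolerance <- nrow(tolerance)
    summaries <- summarize_tolerance(tolerance)
    fits_rows <- list(); metr_rows <- list()
    for (sp in sort(unique(speeds$species))) {
      if (!sp %in% names(summaries)) {
        say("species ", sp, " has no tolerance records; skipped")
        next
      }
      d <- speeds[speeds$species == sp, ]
      mu <- tapply(d$max_speed_cm_s, d$treatment_c, mean)
      tt <- as.numeric(names(mu))
      anch <- summaries[[sp]]
      n_rep <- if (identical(n_reported, "individuals"))
        length(unique(d$individual_id)) else length(tt) + 2L
      res <- fit_tpc(tt, as.numeric(mu), anch, n_reported = n_rep,
                     anchor_weight = anchor_weight, seed = seed,
                     r2_floor = r2_floor)
      for (f in res$fits)
        fits_rows[[length(fits_rows) + 1]] <- data.frame(
          species = sp, family = f$family,
          params = paste(sprintf("%s=%.6g", names(f$params), f$params),
                         collapse = ";"),
          rss = f$rss, r2 = f$r2, aicc = f$aicc,
          n_reported = f$n_reported, converged = f$converged,
          selected = identical(f$family, res$best$family),
          stringsAsFactors = FALSE)
      m <- withCallingHandlers(
        derive_metrics(res$best, level = b_level),
        warning = function(w) {
          say("species ", sp, ": ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      metr_rows[[sp]] <- data.frame(
        species = sp, family = m$family,
        ct_min_c = anch$ct_min_mean, ct_max_c = anch$ct_max_mean,
        ttb_c = m$ttb, t_o_c = m$t_o, tsm_c = m$tsm,
        v_max_cm_s = m$v_max, b80_low_c = m$b80_low,
        b80_high_c = m$b80_high, stringsAsFactors = FALSE)
      say("TPC for ", sp, ": ", m$family,
          sprintf(" (To %.1f C, Vmax %.1f cm/s)", m$t_o, m$v_max))
    }
    out$tolerance_summaries <- do.call(rbind, lapply(summaries,
      function(s) data.frame(species = s$species,
                             ct_min_mean = s$ct_min_mean,
                             ct_min_sd = s$ct_min_sd,
                             ct_max_mean = s$ct_max_mean,
                             ct_max_sd = s$ct_max_sd,
                             ttb = ttb(s), n = s$n,
                             stringsAsFactors = FALSE)))
    rownames(out$tolerance_summaries) <- NULL
    out$tpc_fits <- do.call(rbind, fits_rows)
    out$tpc_metrics <- do.call(rbind, metr_rows)
    rownames(out$tpc_metrics) <- NULL
  }

  if (!is.null(rmr)) {
    .stop_if_invalid(rmr, "rmr")
    counts$rmr <- nrow(rmr)
    out$rmr <- rmr
    q10t <- q10_table(rmr, treatments = treatments)
    # drop interval columns that are empty for every species
    keep <- vapply(q10t, function(cl) !all(is.na(cl)), logical(1))
    out$q10 <- q10t[, keep, drop = FALSE]
    say("Q10 table over ", sum(keep) - 1L, " interval(s)")

    sel_rows <- list(); coef_rows <- list()
    for (sp in sort(unique(rmr$species))) {
      d <- log10_prepare(rmr[rmr$species == sp, ])
      if (nlevels(droplevels(d$treatment)) < 2) next
      cand <- fit_candidates(d, candidate_set(roster))
      for (f in cand$fits)
        sel_rows[[length(sel_rows) + 1]] <- data.frame(
          species = sp, model = f$spec$name, aicc = f$aicc,
          conditional_r2 = f$conditional_r2, singular = f$singular,
          best = identical(f$spec$name, cand$best$spec$name),
          stringsAsFactors = FALSE)
      cf <- cand$best$coefficients
      cf <- cbind(species = sp, model = cand$best$spec$name, cf)
      coef_rows[[sp]] <- cf
      say("best RMR model for ", sp, ": ", cand$best$spec$name,
          sprintf(" (AICc %.1f, conditional R2 %.2f)", cand$best$aicc,
                  cand$best$conditional_r2))
    }
    out$model_selection <- do.call(rbind, sel_rows)
    out$coefficients <- do.call(rbind, coef_rows)
    rownames(out$coefficients) <- NULL

    if (length(unique(rmr$species)) >= 2) {
      cmp <- species_adjusted_comparison(log10_prepare(rmr),
                                         p_adjust = p_adjust)
      out$adjusted_means <- cmp$adjusted_means
      out$species_contrasts <- cmp$contrasts
    }
  }

  out$manifest <- list(
    package_version = as.character(utils::packageVersion("thermoperf")),
    seed = seed, treatments = treatments,
    options = list(r2_floor = r2_floor, b_level = b_level,
                   anchor_weight = anchor_weight,
                   n_reported = n_reported, p_adjust = p_adjust),
    row_counts = counts,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(out_dir)) .write_bundle(out, out_dir, overwrite, say)
  invisible(out)
}

.write_bundle <- function(out, out_dir, overwrite, say) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("tolerance_summaries", "tpc_fits", "tpc_metrics", "rmr",
              "q10", "model_selection", "coefficients",
              "adjusted_means", "species_contrasts")
  for (nm in tables) {
    if (is.null(out[[nm]])) next
    path <- file.path(out_dir, paste0(nm, ".csv"))
    if (file.exists(path) && !overwrite)
      stop("run_all(): refusing to overwrite ", path,
           " (set overwrite = TRUE)")
    utils::write.csv(out[[nm]], path, row.names = FALSE)
    say("wrote ", path, " (", nrow(out[[nm]]), " rows)")
  }
  jsonlite::write_json(out$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

#' Write a simulated study to CSV files
#'
#' Writes the [simulate_study()] bundle (tolerance, speeds, trials, rmr)
#' plus a manifest recording profiles and seed.
#'
#' @param out_dir Output directory.
#' @param profiles,treatments,seed Passed to [simulate_study()].
#' @param overwrite Allow overwriting existing files.
#' @return The simulated bundle, invisibly.
#' @export
write_simulated_study <- function(out_dir,
                                  profiles = make_default_profiles(),
                                  treatments = default_treatments(),
                                  seed = 1L, overwrite = FALSE) {
  sim <- simulate_study(profiles, treatments, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    if (file.exists(path) && !overwrite)
      stop("write_simulated_study(): refusing to overwrite ", path)
    utils::write.csv(sim[[nm]], path, row.names = FALSE)
  }
  manifest <- list(
    seed = seed, treatments = treatments,
    profiles = lapply(profiles, function(p)
      p[setdiff(names(p), c("sex_probs"))]),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sim)
}
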