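#' Construct a synthetic species profile
#'
#' A species profile is the complete stated world for one species: the
#' trial design, the generating TPC, the generating log10-scale RMR mixed
#' model, and the measurement-noise levels. [make_default_profiles()]
#' returns three profiles parameterised from a comparative study of a
#' rattlesnake, a fossorial colubrid, and a semiaquatic garter snake.
#'
#' @param species Species label.
#' @param n_performance,n_rmr,n_tolerance Individuals in the swimming,
#'   respirometry and tolerance samples. The tolerance subset doubles as
#'   the late cohort that lacks the 33 deg C respirometry treatment.
#' @param mass_log10_mean,mass_log10_sd Body-mass distribution (log10 g).
#' @param ct_min_mean,ct_min_sd,ct_max_mean,ct_max_sd Critical thermal
#'   limits (deg C).
#' @param tpc_family_name,tpc_params Generating TPC family and parameters.
#' @param speed_noise_sd Per-observation speed noise, as a fraction of
#'   the curve's maximum.
#' @param ind_speed_sdlog SD of the lognormal individual speed factor.
#' @param rmr_intercept Intercept of the generating RMR model (log10 ml
#'   CO2/min at the reference treatment, log10 mass = 0).
#' @param rmr_offsets Named vector of treatment offsets (log10 units)
#'   relative to the 15 deg C reference; must be nondecreasing in
#'   temperature.
#' @param rmr_mass_slope Allometric slope on log10 mass.
#' @param random_intercept_sd,residual_sd Mixed-model variance components
#'   (log10 units).
#' @param sex_probs Named probabilities for sexes `M`, `F`, `J`.
#' @param flow_rate Respirometry flow (ml/min).
#' @param trace_noise_sd Trace noise as a fraction of the plateau.
#' @param transient_amp,transient_tau Settle-in transient: initial
#'   fractional elevation above the plateau and its decay constant (s).
#' @return A `species_profile` object. `v_max` and `t_o` implied by the
#'   TPC parameters are precomputed and stored.
#' @export
species_profile <- function(species, n_performance, n_rmr, n_tolerance,
                            mass_log10_mean, mass_log10_sd,
                            ct_min_mean, ct_min_sd, ct_max_mean,
                            ct_max_sd, tpc_family_name, tpc_params,
                            speed_noise_sd = 0.10,
                            ind_speed_sdlog = 0.10,
                            rmr_intercept, rmr_offsets, rmr_mass_slope,
                            random_intercept_sd = 0.10,
                            residual_sd = 0.08,
                            sex_probs = c(M = 0.4, F = 0.4, J = 0.2),
                            flow_rate = 100, trace_noise_sd = 0.02,
                            transient_amp = 0.5, transient_tau = 120) {
  stopifnot(ct_min_mean < ct_max_mean, ct_min_sd >= 0, ct_max_sd >= 0,
            speed_noise_sd >= 0, ind_speed_sdlog >= 0,
            random_intercept_sd >= 0, residual_sd >= 0,
            flow_rate > 0, trace_noise_sd >= 0)
  if (is.unsorted(rmr_offsets))
    stop("species_profile(): treatment offsets must be nondecreasing ",
         "in temperature")
  fam <- tpc_family(tpc_family_name)
  f <- function(x) fam$eval(x, tpc_params)
  opt <- stats::optimize(f, c(ct_min_mean, ct_max_mean), maximum = TRUE,
                         tol = 1e-7)
  structure(list(
    species = species, n_performance = n_performance, n_rmr = n_rmr,
    n_tolerance = n_tolerance, mass_log10_mean = mass_log10_mean,
    mass_log10_sd = mass_log10_sd, ct_min_mean = ct_min_mean,
    ct_min_sd = ct_min_sd, ct_max_mean = ct_max_mean,
    ct_max_sd = ct_max_sd, tpc_family = tpc_family_name,
    tpc_params = tpc_params, v_max = opt$objective, t_o = opt$maximum,
    speed_noise_sd = speed_noise_sd, ind_speed_sdlog = ind_speed_sdlog,
    rmr_intercept = rmr_intercept, rmr_offsets = rmr_offsets,
    rmr_mass_slope = rmr_mass_slope,
    random_intercept_sd = random_intercept_sd, residual_sd = residual_sd,
    sex_probs = sex_probs / sum(sex_probs), flow_rate = flow_rate,
    trace_noise_sd = trace_noise_sd, transient_amp = transient_amp,
    transient_tau = transient_tau), class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<species_profile> %s: %s TPC (Vmax %.1f cm/s, To %.1f C), ",
           "CT [%.1f, %.1f] C,\n  n = %d/%d/%d ",
           "(performance/RMR/tolerance)\n"),
    x$species, x$tpc_family, x$v_max, x$t_o, x$ct_min_mean,
    x$ct_max_mean, x$n_performance, x$n_rmr, x$n_tolerance))
  invisible(x)
}

#' Default three-species profiles
#'
#' The stated world of the package: a terrestrial rattlesnake
#' (*Crotalus polystictus*, exponentially modified Gaussian TPC, warm
#' optimum, weak metabolic thermal sensitivity), a small fossorial snake
#' (*Conopsis lineata*, asymmetric logistic TPC, cool optimum), and a
#' semiaquatic garter snake (*Thamnophis melanogaster*, extreme-value
#' TPC, fastest swimmer, highest mass-adjusted RMR). Critical thermal
#' limits, sample sizes, and RMR model coefficients follow the reported
#' species values; TPC shape parameters were solved once by
#' `scripts/solve_profiles.R` so that each family's optimum matches the
#' reported optimum as closely as the family allows while performance is
#' near zero at the CT limits (the anchored-fitting assumption). The
#' published performance breadths are wider than these families can
#' reach under that boundary constraint, so breadths here are narrower
#' than the printed ones by design.
#'
#' @return Named list of three [species_profile()] objects.
#' @export
make_default_profiles <- function() {
  tr_off <- function(...) {
    off <- c(...)
    names(off) <- c("25", "30", "33", "36")
    off
  }
  list(
    crotalus_polystictus = species_profile(
      species = "Crotalus polystictus",
      n_performance = 33, n_rmr = 41, n_tolerance = 10,
      mass_log10_mean = 1.55, mass_log10_sd = 0.35,
      ct_min_mean = 5.9, ct_min_sd = 0.27,
      ct_max_mean = 43.1, ct_max_sd = 0.92,
      tpc_family_name = "emg_peak",
      tpc_params = c(a = 672.992530, mu = 31.7303, sigma = 6.3924,
                     lambda = 27.4027),
      rmr_intercept = -0.944,
      rmr_offsets = tr_off(0.182, 0.252, 0.371, 0.381),
      rmr_mass_slope = 0.760,
      sex_probs = c(M = 12, F = 14, J = 7)),
    conopsis_lineata = species_profile(
      species = "Conopsis lineata",
      n_performance = 31, n_rmr = 26, n_tolerance = 8,
      mass_log10_mean = 1.25, mass_log10_sd = 0.35,
      ct_min_mean = 9.3, ct_min_sd = 1.67,
      ct_max_mean = 41.2, ct_max_sd = 1.42,
      tpc_family_name = "asym_logistic_peak",
      tpc_params = c(a = 29.3, c = 33.490826, b = -4.991221,
                     d = 3.140272),
      rmr_intercept = -0.931,
      rmr_offsets = tr_off(0.399, 0.536, 0.608, 0.709),
      rmr_mass_slope = 0.610,
      sex_probs = c(M = 16, F = 15, J = 2)),
    thamnophis_melanogaster = species_profile(
      species = "Thamnophis melanogaster",
      n_performance = 38, n_rmr = 36, n_tolerance = 7,
      mass_log10_mean = 1.50, mass_log10_sd = 0.35,
      ct_min_mean = 8.5, ct_min_sd = 1.14,
      ct_max_mean = 41.6, ct_max_sd = 1.34,
      tpc_family_name = "gumbel_peak",
      tpc_params = c(a = 71.7, mu = 28.623018, sigma = -4.215384),
      rmr_intercept = -0.965,
      rmr_offsets = tr_off(0.358, 0.581, 0.659, 0.774),
      rmr_mass_slope = 0.674,
      sex_probs = c(M = 12, F = 15, J = 11)))
}

#' The five-treatment thermal design
#' @return Numeric vector of treatment temperatures (deg C).
#' @export
default_treatments <- function() c(15, 25, 30, 33, 36)

# with_seed: run code under a seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  code
}

.ind_ids <- function(profile, n) {
  ab <- toupper(substr(gsub("[^A-Za-z]", "", profile$species), 1, 3))
  sprintf("%s_%02d", ab, seq_len(n))
}

# shared per-individual covariates; tolerance-subset individuals (the
# first n_tolerance ids) form the late cohort lacking the 33 C treatment
.ind_frame <- function(profile, n, seed) {
  .with_seed(seed, {
    data.frame(
      individual_id = .ind_ids(profile, n),
      species = profile$species,
      sex = sample(names(profile$sex_probs), n, replace = TRUE,
                   prob = profile$sex_probs),
      body_mass_g = 10^stats::rnorm(n, profile$mass_log10_mean,
                                    profile$mass_log10_sd),
      stringsAsFactors = FALSE)
  })
}

#' Simulate per-individual critical thermal limits
#'
#' Draws CTmin and CTmax independently from the profile's normal
#' distributions, redrawing any individual whose CTmin would not fall
#' below its CTmax.
#'
#' @param profile A [species_profile()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return Data frame: `individual_id`, `species`, `ct_min_c`,
#'   `ct_max_c`, `cooling_rate_c_min`, `heating_rate_c_min`.
#' @export
simulate_tolerance <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "species_profile"))
  n <- profile$n_tolerance
  .with_seed(seed + 101L, {
    ct_min <- stats::rnorm(n, profile$ct_min_mean, profile$ct_min_sd)
    ct_max <- stats::rnorm(n, profile$ct_max_mean, profile$ct_max_sd)
    bad <- which(ct_min >= ct_max)
    while (length(bad)) {
      ct_min[bad] <- stats::rnorm(length(bad), profile$ct_min_mean,
                                  profile$ct_min_sd)
      ct_max[bad] <- stats::rnorm(length(bad), profile$ct_max_mean,
                                  profile$ct_max_sd)
      bad <- which(ct_min >= ct_max)
    }
    data.frame(individual_id = .ind_ids(profile, n),
               species = profile$species,
               ct_min_c = ct_min, ct_max_c = ct_max,
               cooling_rate_c_min = 1.0, heating_rate_c_min = 1.5,
               stringsAsFactors = FALSE)
  })
}

#' Simulate per-individual maximum swimming speeds
#'
#' The observation-level generator behind the TPC machinery: each
#' individual carries a lognormal speed factor (between-animal
#' heterogeneity), and its observed maximum speed at a treatment is the
#' clamped generating TPC times that factor plus Gaussian noise with sd
#' `speed_noise_sd * v_max`, truncated at zero.
#'
#' @param profile A [species_profile()].
#' @param treatments Treatment temperatures (deg C).
#' @param seed Integer seed.
#' @return Data frame of speed observations (`individual_id`, `species`,
#'   `sex`, `body_mass_g`, `treatment_c`, `max_speed_cm_s`).
#' @export
simulate_speeds <- function(profile, treatments = default_treatments(),
                            seed = 1L) {
  stopifnot(inherits(profile, "species_profile"))
  n <- profile$n_performance
  ind <- .ind_frame(profile, n, seed + 202L)
  .with_seed(seed + 203L, {
    fac <- stats::rlnorm(n, 0, profile$ind_speed_sdlog)
    base <- tpc_eval_clamped(profile$tpc_family, treatments,
                             profile$tpc_params, profile$ct_min_mean,
                             profile$ct_max_mean)
    grid <- expand.grid(i = seq_len(n), t = seq_along(treatments))
    speed <- base[grid$t] * fac[grid$i] +
      stats::rnorm(nrow(grid), 0, profile$speed_noise_sd * profile$v_max)
    out <- ind[grid$i, ]
    out$treatment_c <- treatments[grid$t]
    out$max_speed_cm_s <- pmax(speed, 0)
    rownames(out) <- NULL
    out
  })
}

#' Simulate swim trials as per-segment frame counts
#'
#' Emulates the videography protocol: five 30 cm segments filmed at
#' 60 fps, a 120 s trial cap. Each segment's realised speed is the
#' individual's true speed at that temperature with per-segment noise;
#' frame counts are `round(segment_length / speed * frame_rate)`. Frame
#' counts are capped at `duration_cap * frame_rate / n_segments` per
#' segment, emulating the protocol guarantee (snakes are stimulated to
#' cover five marks within the trial), so very slow animals are
#' speed-censored at 1.25 cm/s rather than dropped.
#'
#' @param profile A [species_profile()].
#' @param treatments Treatment temperatures (deg C).
#' @param seed Integer seed.
#' @param n_segments,frame_rate,segment_length,duration_cap Trial
#'   geometry (defaults: 5 segments, 60 fps, 30 cm, 120 s).
#' @return Long-format data frame: `individual_id`, `species`, `sex`,
#'   `body_mass_g`, `treatment_c`, `frame_rate`, `segment_length_cm`,
#'   `segment_index`, `frames`.
#' @export
simulate_swims <- function(profile, treatments = default_treatments(),
                           seed = 1L, n_segments = 5, frame_rate = 60,
                           segment_length = 30, duration_cap = 120) {
  stopifnot(inherits(profile, "species_profile"))
  n <- profile$n_performance
  ind <- .ind_frame(profile, n, seed + 202L)  # same animals as speeds
  max_frames <- floor(duration_cap * frame_rate / n_segments)
  .with_seed(seed + 204L, {
    fac <- stats::rlnorm(n, 0, profile$ind_speed_sdlog)
    base <- tpc_eval_clamped(profile$tpc_family, treatments,
                             profile$tpc_params, profile$ct_min_mean,
                             profile$ct_max_mean)
    grid <- expand.grid(i = seq_len(n), t = seq_along(treatments),
                        segment_index = seq_len(n_segments))
    speed <- base[grid$t] * fac[grid$i] +
      stats::rnorm(nrow(grid), 0, profile$speed_noise_sd * profile$v_max)
    floor_speed <- segment_length * frame_rate / max_frames
    speed <- pmax(speed, floor_speed)
    frames <- pmin(pmax(round(segment_length / speed * frame_rate), 1L),
                   max_frames)
    out <- ind[grid$i, ]
    out$treatment_c <- treatments[grid$t]
    out$frame_rate <- frame_rate
    out$segment_length_cm <- segment_length
    out$segment_index <- grid$segment_index
    out$frames <- as.integer(frames)
    out <- out[order(out$individual_id, out$treatment_c,
                     out$segment_index), ]
    rownames(out) <- NULL
    out
  })
}

# generating VCO2 (ml/min) per individual x treatment from the profile's
# log10-scale mixed model; returns the design grid with truth attached
.rmr_truth <- function(profile, treatments, seed, noise = TRUE) {
  n <- profile$n_rmr
  ind <- .ind_frame(profile, n, seed + 301L)
  late <- ind$individual_id %in% .ind_ids(profile, profile$n_tolerance)
  .with_seed(seed + 302L, {
    u <- stats::rnorm(n, 0, if (noise) profile$random_intercept_sd else 0)
    grid <- expand.grid(i = seq_len(n), t = seq_along(treatments))
    tt <- treatments[grid$t]
    keep <- !(late[grid$i] & tt == 33)   # late cohort skips 33 C
    grid <- grid[keep, ]; tt <- tt[keep]
    off <- ifelse(tt == min(treatments), 0,
                  profile$rmr_offsets[as.character(tt)])
    if (any(is.na(off)))
      stop("simulate: treatment without a profile offset: ",
           paste(unique(tt[is.na(off)]), collapse = ", "))
    eps <- stats::rnorm(nrow(grid), 0,
                        if (noise) profile$residual_sd else 0)
    log10_v <- profile$rmr_intercept + off +
      profile$rmr_mass_slope * log10(ind$body_mass_g[grid$i]) +
      u[grid$i] + eps
    out <- ind[grid$i, ]
    out$treatment_c <- tt
    out$vco2_ml_min = 10^log10_v
    rownames(out) <- NULL
    out
  })
}

#' Simulate resting metabolic rate records
#'
#' Draws per-individual random intercepts and residual noise around the
#' profile's generating model
#' `log10 VCO2 = intercept + offset(T) + slope * log10 mass + u_i + e`,
#' over the treatment design. Individuals in the late cohort (the
#' tolerance subset) have no 33 deg C trial, reproducing the partial
#' design.
#'
#' @param profile A [species_profile()].
#' @param treatments Treatment temperatures (deg C).
#' @param seed Integer seed.
#' @param noise Set `FALSE` for the deterministic (zero-variance) limit.
#' @return Data frame of RMR records (`individual_id`, `species`, `sex`,
#'   `body_mass_g`, `treatment_c`, `vco2_ml_min`).
#' @export
simulate_rmr <- function(profile, treatments = default_treatments(),
                         seed = 1L, noise = TRUE) {
  stopifnot(inherits(profile, "species_profile"))
  .rmr_truth(profile, treatments, seed, noise = noise)
}

#' Simulate open-flow respirometry traces
#'
#' For each individual-by-treatment cell of [simulate_rmr()], builds the
#' CO2 trace the analyser would log: a plateau at
#' `vco2 / flow_rate`, an initial activity transient decaying
#' exponentially (amplitude `transient_amp` of the plateau, time
#' constant `transient_tau` s), and Gaussian noise with sd
#' `trace_noise_sd` of the plateau, sampled at 1 Hz for `duration` s.
#'
#' @inheritParams simulate_rmr
#' @param duration Trace length in s (default 1800, the 30 min trial).
#' @param transient Set `FALSE` to drop the settle-in transient.
#' @return List with `traces` (list of [resp_trace()] objects) and
#'   `truth` (the generating RMR records).
#' @export
simulate_traces <- function(profile, treatments = default_treatments(),
                            seed = 1L, duration = 1800, noise = TRUE,
                            transient = TRUE) {
  stopifnot(inherits(profile, "species_profile"))
  truth <- .rmr_truth(profile, treatments, seed, noise = noise)
  tt <- seq(0, duration - 1)
  traces <- .with_seed(seed + 303L, {
    lapply(seq_len(nrow(truth)), function(r) {
      plateau <- truth$vco2_ml_min[r] / profile$flow_rate
      fe <- plateau * (1 + (if (transient) profile$transient_amp else 0) *
                         exp(-tt / profile$transient_tau)) +
        stats::rnorm(length(tt), 0,
                     if (noise) profile$trace_noise_sd * plateau else 0)
      fe <- pmin(pmax(fe, 0), 1 - 1e-9)
      resp_trace(individual_id = truth$individual_id[r],
                 treatment_temp = truth$treatment_c[r],
                 sample_times = tt, fe_co2 = fe,
                 flow_rate = profile$flow_rate, fi_co2 = 0,
                 species = truth$species[r],
                 body_mass = truth$body_mass_g[r])
    })
  })
  list(traces = traces, truth = truth)
}

#' Simulate the full multi-species study
#'
#' Generates every pipeline input (tolerance records, speed
#' observations, swim trials, RMR records) for a set of profiles under
#' one seed. Respirometry traces are generated on demand by
#' [simulate_traces()] and are not included here for size reasons.
#'
#' @param profiles List of [species_profile()]s (default
#'   [make_default_profiles()]).
#' @param treatments Treatment temperatures (deg C).
#' @param seed Integer seed; species are decorrelated internally.
#' @return List of data frames: `tolerance`, `speeds`, `trials`, `rmr`.
#' @export
simulate_study <- function(profiles = make_default_profiles(),
                           treatments = default_treatments(),
                           seed = 1L) {
  seeds <- seed + 1000L * seq_along(profiles)
  bind <- function(f, ...) do.call(rbind, Map(f, profiles, seeds, ...))
  out <- list(
    tolerance = bind(function(p, s) simulate_tolerance(p, seed = s)),
    speeds = bind(function(p, s)
      simulate_speeds(p, treatments = treatments, seed = s)),
    trials = bind(function(p, s)
      simulate_swims(p, treatments = treatments, seed = s)),
    rmr = bind(function(p, s)
      simulate_rmr(p, treatments = treatments, seed = s)))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
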