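#' Prepare RMR records for log-scale modelling
#'
#' Metabolic rate scales allometrically with body mass, so both RMR and
#' mass are log10-transformed before linear modelling. Rows with
#' non-positive VCO2 or mass cannot be transformed and are dropped with a
#' message reporting the count.
#'
#' @param records Data frame with columns `individual_id`, `species`,
#'   `treatment_c`, `body_mass_g`, `vco2_ml_min`, optionally `sex`.
#' @param reference_treatment Treatment level used as the factor
#'   reference (default 15 deg C).
#' @return Data frame with added `log10_vco2` and `log10_mass` columns
#'   and `treatment` as a factor with the reference level first.
#' @export
log10_prepare <- function(records, reference_treatment = 15) {
  need <- c("individual_id", "species", "treatment_c", "body_mass_g",
            "vco2_ml_min")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("log10_prepare(): missing columns: ",
         paste(miss, collapse = ", "))
  bad <- !(records$vco2_ml_min > 0) | !(records$body_mass_g > 0) |
    is.na(records$vco2_ml_min) | is.na(records$body_mass_g)
  if (all(bad))
    stop("log10_prepare(): no rows with positive VCO2 and mass")
  if (any(bad))
    message("log10_prepare(): dropped ", sum(bad),
            " row(s) with non-positive VCO2 or mass")
  d <- records[!bad, , drop = FALSE]
  d$log10_vco2 <- log10(d$vco2_ml_min)
  d$log10_mass <- log10(d$body_mass_g)
  levs <- sort(unique(d$treatment_c))
  levs <- c(reference_treatment, setdiff(levs, reference_treatment))
  d$treatment <- factor(d$treatment_c, levels = levs)
  rownames(d) <- NULL
  d
}

#' The candidate set of RMR mixed models
#'
#' Seven fixed-effect structures over thermal treatment (categorical),
#' log10 body mass, and sex, each with an individual random intercept to
#' absorb repeated measures on the same animal:
#' `T`, `M`, `S`, `T+M`, `T+M+S`, `T+S`, and `T+M+TxM` (the
#' treatment-by-mass interaction, with both main effects).
#'
#' @param roster Optional list of character vectors of fixed terms
#'   (subsets of `"treatment"`, `"log_mass"`, `"sex"`,
#'   `"treatment:log_mass"`) to override the default seven.
#' @return List of `model_spec` objects (`name`, `fixed_terms`).
#' @export
candidate_set <- function(roster = NULL) {
  if (is.null(roster))
    roster <- list(
      c("treatment"),
      c("log_mass"),
      c("sex"),
      c("treatment", "log_mass"),
      c("treatment", "log_mass", "sex"),
      c("treatment", "sex"),
      c("treatment", "log_mass", "treatment:log_mass"))
  lapply(roster, function(terms) {
    allowed <- c("treatment", "log_mass", "sex", "treatment:log_mass")
    if (!all(terms %in% allowed))
      stop("candidate_set(): unknown term(s): ",
           paste(setdiff(terms, allowed), collapse = ", "))
    if ("treatment:log_mass" %in% terms &&
        !all(c("treatment", "log_mass") %in% terms))
      stop("candidate_set(): interaction requires both main effects")
    abbrev <- c(treatment = "T", log_mass = "M", sex = "S",
                `treatment:log_mass` = "TxM")
    structure(list(name = paste(abbrev[terms], collapse = "+"),
                   fixed_terms = terms),
              class = "model_spec")
  })
}

.spec_formula <- function(spec) {
  rhs <- c(treatment = "treatment", log_mass = "log10_mass", sex = "sex",
           `treatment:log_mass` = "treatment:log10_mass")[spec$fixed_terms]
  stats::as.formula(paste("log10_vco2 ~", paste(rhs, collapse = " + "),
                          "+ (1 | individual_id)"))
}

#' Fit the candidate RMR mixed models and select by AICc
#'
#' Each candidate is fit by maximum likelihood (not REML, so that AICc is
#' comparable across fixed-effect structures) with `lme4`. AICc counts
#' `k` = fixed coefficients + 2 variance components (random intercept and
#' residual). Conditional R2 follows the fixed-plus-random over total
#' variance decomposition,
#' \eqn{R^2_c = (\sigma^2_f + \sigma^2_u) / (\sigma^2_f + \sigma^2_u + \sigma^2_e)},
#' where \eqn{\sigma^2_f} is the variance of the fixed-effect predictor.
#' Singular fits are reported but excluded from selection with a
#' warning.
#'
#' @param table Output of [log10_prepare()].
#' @param specs List of model specs from [candidate_set()].
#' @return List with `fits` (per-spec `model_fit` objects, each with
#'   `spec`, `aicc`, `conditional_r2`, `coefficients`,
#'   `variance_components`, `n_obs`, `n_individuals`, `singular`,
#'   `model`) and `best` (lowest-AICc non-singular fit).
#' @export
fit_candidates <- function(table, specs = candidate_set()) {
  stopifnot(all(c("log10_vco2", "log10_mass", "treatment",
                  "individual_id") %in% names(table)))
  if (nlevels(droplevels(table$treatment)) < 2)
    stop("fit_candidates(): need >= 2 treatment levels")
  fits <- lapply(specs, function(spec) .fit_one_spec(table, spec))
  names(fits) <- vapply(specs, `[[`, character(1), "name")
  usable <- !vapply(fits, `[[`, logical(1), "singular")
  if (!any(usable))
    stop("fit_candidates(): every candidate fit was singular")
  if (any(!usable))
    warning("fit_candidates(): excluded singular fit(s): ",
            paste(names(fits)[!usable], collapse = ", "))
  aiccs <- vapply(fits[usable], `[[`, numeric(1), "aicc")
  list(fits = fits, best = fits[usable][[which.min(aiccs)]])
}

.fit_one_spec <- function(table, spec) {
  form <- .spec_formula(spec)
  mod <- lme4::lmer(form, data = table, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  beta <- lme4::fixef(mod)
  vc <- as.data.frame(lme4::VarCorr(mod))
  sigma_u2 <- vc$vcov[vc$grp == "individual_id"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  X <- lme4::getME(mod, "X")
  fix_pred <- as.vector(X %*% beta)
  # population-variance convention (divide by n) for the fixed component
  sigma_f2 <- mean((fix_pred - mean(fix_pred))^2)
  cond_r2 <- (sigma_f2 + sigma_u2) / (sigma_f2 + sigma_u2 + sigma_e2)
  n <- stats::nobs(mod)
  k <- length(beta) + 2L
  aicc <- -2 * as.numeric(stats::logLik(mod)) + 2 * k +
    2 * k * (k + 1) / (n - k - 1)
  se <- sqrt(diag(as.matrix(stats::vcov(mod))))
  structure(list(
    spec = spec,
    coefficients = data.frame(term = names(beta), estimate = beta,
                              se = se, t = beta / se,
                              row.names = NULL),
    aicc = aicc, conditional_r2 = cond_r2,
    variance_components = c(individual = sigma_u2, residual = sigma_e2),
    n_obs = n,
    n_individuals = length(unique(table$individual_id)),
    singular = lme4::isSingular(mod, tol = 1e-5),
    model = mod), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "<model_fit> %s: AICc = %.2f, conditional R2 = %.3f (n = %d obs, %d ind)%s\n",
    x$spec$name, x$aicc, x$conditional_r2, x$n_obs, x$n_individuals,
    if (x$singular) "  [singular]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Mass-adjusted comparison of RMR between species
#'
#' Fits a fixed-effects model `log10 RMR ~ species + log10 mass`, first
#' testing the species-by-mass interaction (retained only if significant
#' at `alpha`, mirroring standard practice of testing for heterogeneous
#' allometric slopes before comparing adjusted means). Adjusted
#' (marginal) means are the model predictions per species at the grand
#' mean of log10 mass, and all pairwise contrasts are reported with t
#' statistics.
#'
#' @param table Output of [log10_prepare()] covering >= 2 species.
#' @param alpha Significance level for the interaction test.
#' @param retain_interaction `"test"` (default: keep if significant),
#'   `"always"`, or `"never"`.
#' @param p_adjust Adjustment method for contrast p-values (a
#'   [stats::p.adjust()] method; default `"none"`).
#' @return A `marginal_comparison` object: `adjusted_means` (per
#'   species, at the reference mass), `contrasts` (pairwise differences,
#'   SE, t, df, p), `interaction_retained`, `reference_log10_mass`.
#' @export
species_adjusted_comparison <- function(table, alpha = 0.05,
                                        retain_interaction = c("test",
                                          "always", "never"),
                                        p_adjust = "none") {
  retain_interaction <- match.arg(retain_interaction)
  stopifnot(all(c("log10_vco2", "log10_mass", "species") %in%
                names(table)))
  table$species <- factor(table$species)
  if (nlevels(table$species) < 2)
    stop("species_adjusted_comparison(): need >= 2 species")
  m_add <- stats::lm(log10_vco2 ~ species + log10_mass, data = table)
  m_int <- stats::lm(log10_vco2 ~ species * log10_mass, data = table)
  p_int <- stats::anova(m_add, m_int)[2, "Pr(>F)"]
  keep <- switch(retain_interaction,
                 test = is.finite(p_int) && p_int < alpha,
                 always = TRUE, never = FALSE)
  mod <- if (keep) m_int else m_add
  mbar <- mean(table$log10_mass)
  levs <- levels(table$species)
  newd <- data.frame(species = factor(levs, levels = levs),
                     log10_mass = mbar)
  pred <- stats::predict(mod, newdata = newd, se.fit = TRUE)
  means <- data.frame(species = levs, adjusted_mean = pred$fit,
                      se = pred$se.fit, row.names = NULL)
  # pairwise contrasts via the prediction design matrix
  Xp <- stats::model.matrix(stats::delete.response(stats::terms(mod)),
                            newd)
  V <- stats::vcov(mod)
  df <- stats::df.residual(mod)
  pairs <- utils::combn(seq_along(levs), 2)
  ctr <- apply(pairs, 2, function(ij) {
    cvec <- Xp[ij[1], ] - Xp[ij[2], ]
    est <- sum(cvec * stats::coef(mod))
    se <- sqrt(as.numeric(t(cvec) %*% V %*% cvec))
    tval <- est / se
    c(estimate = est, se = se, t = tval,
      p = 2 * stats::pt(-abs(tval), df))
  })
  contrasts <- data.frame(
    group1 = levs[pairs[1, ]], group2 = levs[pairs[2, ]],
    t(ctr), df = df, row.names = NULL)
  contrasts$p_adj <- stats::p.adjust(contrasts$p, method = p_adjust)
  structure(list(adjusted_means = means, contrasts = contrasts,
                 interaction_retained = keep, interaction_p = p_int,
                 reference_log10_mass = mbar, model = mod),
            class = "marginal_comparison")
}

#' @export
print.marginal_comparison <- function(x, ...) {
  cat("<marginal_comparison> adjusted means at log10 mass =",
      sprintf("%.3f", x$reference_log10_mass),
      if (x$interaction_retained) "(species x mass interaction retained)",
      "\n")
  print(x$adjusted_means, digits = 4)
  cat("pairwise contrasts:\n")
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Rank-based comparison of groups (Kruskal-Wallis + Dunn)
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference
#' distribution, followed by Dunn's pairwise z tests with Holm-adjusted
#' p-values (by default).
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length (>= 2 groups with
#'   >= 2 values each).
#' @param p_adjust Adjustment for the Dunn p-values (default `"holm"`).
#' @return A `rank_tests` object: `h`, `df`, `p`, and `pairwise` (z,
#'   p, adjusted p per group pair).
#' @export
rank_group_tests <- function(values, groups, p_adjust = "holm") {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  groups <- droplevels(groups)
  g <- nlevels(groups)
  if (g < 2) stop("rank_group_tests(): need >= 2 groups")
  ni <- table(groups)
  if (any(ni < 2))
    stop("rank_group_tests(): every group needs >= 2 values")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  h_raw <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  corr <- 1 - tie_term / (N^3 - N)
  if (corr <= 0) {           # all observations tied
    h <- 0; p <- 1
  } else {
    h <- h_raw / corr
    p <- stats::pchisq(h, df = g - 1, lower.tail = FALSE)
  }
  # Dunn z: tie-corrected pooled variance of mean-rank differences
  sigma2 <- (N * (N + 1) / 12) - tie_term / (12 * (N - 1))
  pairs <- utils::combn(seq_len(g), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    denom <- sqrt(sigma2 * (1 / ni[i] + 1 / ni[j]))
    if (denom <= 0) 0 else (rbar[i] - rbar[j]) / denom
  })
  pw <- data.frame(group1 = levels(groups)[pairs[1, ]],
                   group2 = levels(groups)[pairs[2, ]],
                   z = z, p = 2 * stats::pnorm(-abs(z)),
                   row.names = NULL)
  pw$p_adj <- stats::p.adjust(pw$p, method = p_adjust)
  structure(list(h = h, df = g - 1, p = p, pairwise = pw),
            class = "rank_tests")
}

#' @export
print.rank_tests <- function(x, ...) {
  cat(sprintf("<rank_tests> Kruskal-Wallis H = %.3f, df = %d, p = %.4g\n",
              x$h, x$df, x$p))
  print(x$pairwise, digits = 4)
  invisible(x)
}
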