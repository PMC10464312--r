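# Synthetic NHIS-like cohort generator with known causal structure:
# race -> covariates -> mediators -> additive-hazard mortality with
# race x mediator interactions, administrative censoring at end of 2015,
# age as the timescale with delayed entry at age-at-survey.

.med_predictors <- c("intercept", "black", "hispanic", "age", "edu_medium",
                     "edu_high", "married", "year", "women")

.default_mediator_laws <- function() {
  mk <- function(levels, ...) {
    m <- rbind(...)
    dimnames(m) <- list(levels, .med_predictors)
    m
  }
  list(
    alcohol_category = mk(
      c("never", "former", "cat_II", "cat_III"),
      c(-1.26, 0.67,  0.375, 0.010, -0.2, -0.5,  0.0,  0.005, 0.57),
      c(-2.00, 0.17, -0.200, 0.015, -0.1, -0.3,  0.0,  0.000, -0.30),
      c(-3.10, -0.23, -0.35, 0.005,  0.0, -0.3, -0.2,  0.000, -1.00),
      c(-3.10, -0.23, -0.35, 0.005,  0.0, -0.6, -0.5,  0.000, -1.00)),
    smoking_category = mk(
      c("former", "someday", "everyday"),
      c(-0.43, -0.60, -0.65,  0.030,  0.0, -0.2,  0.1,  0.000, -0.44),
      c(-2.44,  0.42,  0.44, -0.010,  0.0, -0.5, -0.1, -0.010, -0.18),
      c(-0.83, -0.10, -0.68, -0.005, -0.2, -1.0, -0.3, -0.020, -0.29)),
    bmi_category = mk(
      c("underweight", "overweight", "obese"),
      c(-3.43,  0.03, 0.13,  0.000,  0.0,  0.0, -0.2, 0.000,  0.30),
      c( 0.33, -0.07, 0.20,  0.010,  0.0, -0.1,  0.1, 0.005, -0.86),
      c(-0.22,  0.22, 0.22,  0.010, -0.1, -0.3,  0.05, 0.015, -0.43)),
    activity_category = mk(
      c("somewhat", "sedentary"),
      c(-1.18, 0.03, 0.03, 0.005, -0.1, -0.3, 0.0, 0.000, 0.44),
      c(-0.45, 0.41, 0.56, 0.015, -0.3, -0.8, 0.0, 0.005, 0.22)))
}

.default_gamma <- function() {
  list(alcohol_category  = c(cat_I = 0, never = 2e-4, former = 1e-3,
                             cat_II = 8e-4, cat_III = 2e-3),
       smoking_category  = c(never = 0, former = 8e-4, someday = 1.5e-3,
                             everyday = 2.5e-3),
       bmi_category      = c(normal = 0, underweight = 2e-3,
                             overweight = 2e-4, obese = 8e-4),
       activity_category = c(active = 0, somewhat = 8e-4, sedentary = 1.8e-3))
}

.default_delta <- function() {
  black <- list(
    alcohol_category  = c(cat_I = 0, never = -1e-4, former = -4e-4,
                          cat_II = -4e-4, cat_III = -6e-4),
    smoking_category  = c(never = 0, former = 1e-4, someday = 2e-4,
                          everyday = 3e-4),
    bmi_category      = c(normal = 0, underweight = -2e-4,
                          overweight = -1e-4, obese = -2e-4),
    activity_category = c(active = 0, somewhat = -1e-4, sedentary = -1.5e-4))
  hispanic <- lapply(black, function(v) 0.6 * v)
  list(black = black, hispanic = hispanic)
}

#' Synthetic-cohort generator parameters
#'
#' Bundles the sampling laws of an NHIS-like cohort with known causal
#' structure: exposure marginals, race-conditional covariate laws,
#' baseline-category logit mediator laws, and an additive mortality hazard
#' \eqn{\lambda(a) = \lambda_0^{sex}(a) + \beta_{race} + \sum_k
#' (\gamma_k[m_k] + \delta_{race,k}[m_k]) + covariates} on the age timescale,
#' with administrative censoring at the end of 2015 and a hard age cap.
#' Defaults are loosely calibrated to published NHIS 1997--2014 prevalences
#' and are illustrative, not estimates.
#'
#' @param exposure_levels race/ethnicity groups generated (reference first)
#' @param exposure_probs marginal probabilities, named by level
#' @param mediator_laws per-mediator coefficient matrices (non-reference
#'   levels x predictors \code{intercept, black, hispanic, age (centered at
#'   46), edu_medium, edu_high, married, year (centered at 2005), women})
#' @param gamma per-mediator additive hazard effects per level (per
#'   person-year; reference level 0)
#' @param delta per non-reference race, per-mediator additive race-by-mediator
#'   interaction effects (per person-year; reference level 0)
#' @param beta_direct direct additive race effect, named per non-reference
#'   level (per person-year)
#' @param covariate_hazard additive hazard effects of education (medium,
#'   high; low is reference), marriage, and survey year (centered at 2005)
#' @param baseline named list of per-sex baseline hazard rates, each a vector
#'   over one-year age bins \code{18:100} (per person-year)
#' @param age_bounds,age_mean,age_sd truncated-normal age-at-survey law;
#'   \code{age_mean} named per race, women shifted by \code{age_women_shift}
#' @param age_women_shift additive shift of mean age for women, years
#' @param education_probs race x \{low, medium, high\} probability matrix
#' @param married_probs marriage probability per race
#' @param sex_probs marginal sex probabilities
#' @param year_range inclusive survey-year range
#' @param admin_year administrative censoring year (follow-up ends Dec 31 of
#'   \code{admin_year - 1}); censoring age = entry + (admin_year - survey_year)
#' @param max_age hard age cap, years
#' @return object of class \code{cohort_params}
#' @export
cohort_params <- function(exposure_levels = c("white", "black"),
                          exposure_probs = NULL,
                          mediator_laws = .default_mediator_laws(),
                          gamma = .default_gamma(),
                          delta = .default_delta(),
                          beta_direct = c(black = 2.37e-3, hispanic = 5e-4),
                          covariate_hazard = c(edu_medium = -1e-4,
                                               edu_high = -2e-4,
                                               married = -2e-4,
                                               year = -5e-6),
                          baseline = NULL,
                          age_bounds = c(18, 85),
                          age_mean = c(white = 48, black = 45, hispanic = 41),
                          age_sd = 16,
                          age_women_shift = 1.5,
                          education_probs = rbind(
                            white = c(low = 0.39, medium = 0.30, high = 0.31),
                            black = c(low = 0.54, medium = 0.30, high = 0.16),
                            hispanic = c(low = 0.68, medium = 0.21, high = 0.11)),
                          married_probs = c(white = 0.59, black = 0.42,
                                            hispanic = 0.60),
                          sex_probs = c(men = 0.45, women = 0.55),
                          year_range = c(1997, 2014),
                          admin_year = 2016,
                          max_age = 100) {
  stopifnot(length(exposure_levels) >= 2, exposure_levels[1] == "white",
            all(exposure_levels %in% .race_levels))
  if (is.null(exposure_probs)) {
    exposure_probs <- stats::setNames(
      c(0.77, rep(0.23 / (length(exposure_levels) - 1),
                  length(exposure_levels) - 1)), exposure_levels)
    if (length(exposure_levels) == 3)
      exposure_probs <- c(white = 0.66, black = 0.16, hispanic = 0.18)
  }
  ages <- 18:(max_age - 1) + 0.5
  if (is.null(baseline))
    baseline <- list(men   = 5e-4 + exp(-9.8 + 0.085 * ages),
                     women = 4e-4 + 0.6 * exp(-9.8 + 0.085 * ages))
  stopifnot(abs(sum(exposure_probs) - 1) < 1e-8,
            all(vapply(baseline, length, 1L) == max_age - 18),
            all(unlist(baseline) >= 0))
  p <- list(exposure_levels = exposure_levels,
            exposure_probs = exposure_probs[exposure_levels],
            mediator_laws = mediator_laws, gamma = gamma, delta = delta,
            beta_direct = beta_direct, covariate_hazard = covariate_hazard,
            baseline = baseline, age_bounds = age_bounds,
            age_mean = age_mean, age_sd = age_sd,
            age_women_shift = age_women_shift,
            education_probs = education_probs,
            married_probs = married_probs, sex_probs = sex_probs,
            year_range = year_range, admin_year = admin_year,
            max_age = max_age)
  class(p) <- "cohort_params"
  p
}

# Mediator category probabilities for given subjects under a fixed exposure.
# Returns an n x L matrix (levels in canonical order, reference first).
.mediator_probs <- function(law, levels, race, age, education, married, year,
                            sex) {
  n <- length(age)
  X <- cbind(intercept = 1,
             black = as.numeric(race == "black"),
             hispanic = as.numeric(race == "hispanic"),
             age = age - 46,
             edu_medium = as.numeric(education == "medium"),
             edu_high = as.numeric(education == "high"),
             married = as.numeric(married),
             year = year - 2005,
             women = as.numeric(sex == "women"))
  eta <- X %*% t(law[, .med_predictors, drop = FALSE])  # n x (L-1)
  expeta <- cbind(1, exp(eta))                          # reference first
  pr <- expeta / rowSums(expeta)
  colnames(pr) <- c(setdiff(levels, rownames(law)), rownames(law))
  pr[, levels, drop = FALSE]
}

# Per-subject constant additive hazard shift (everything except the baseline).
.hazard_shift <- function(params, race, mediators, education, married, year) {
  n <- length(race)
  shift <- numeric(n)
  bd <- params$beta_direct
  for (r in setdiff(params$exposure_levels, "white"))
    shift <- shift + ifelse(race == r, bd[[r]], 0)
  for (m in names(params$gamma)) {
    lev <- as.character(mediators[[m]])
    shift <- shift + params$gamma[[m]][lev]
    for (r in setdiff(params$exposure_levels, "white"))
      shift <- shift + ifelse(race == r, params$delta[[r]][[m]][lev], 0)
  }
  ch <- params$covariate_hazard
  shift <- shift + ch[["edu_medium"]] * (education == "medium") +
    ch[["edu_high"]] * (education == "high") +
    ch[["married"]] * married + ch[["year"]] * (year - 2005)
  unname(shift)
}

#' Sample event ages from a piecewise-constant hazard by inverse transform
#'
#' Inverts the cumulative hazard \eqn{H(t) = \int_{entry}^t \lambda(u) du}
#' at \eqn{E = -\log(u)}. Rates are constant on the one-year (or arbitrary)
#' bins defined by \code{breaks}; beyond the last break the hazard is zero,
#' so draws that never accumulate \eqn{E} return \code{Inf} (censored by the
#' age cap).
#'
#' @param entry_age entry ages (vector)
#' @param breaks increasing bin edges, length B + 1
#' @param rates nonnegative rates per bin: vector of length B (shared) or an
#'   n x B matrix (per subject)
#' @param u uniform(0,1) draws, one per subject
#' @return event ages, \code{> entry_age}, possibly \code{Inf}
#' @export
sample_event_age <- function(entry_age, breaks, rates, u) {
  n <- length(entry_age)
  B <- length(breaks) - 1L
  if (is.matrix(rates)) stopifnot(nrow(rates) == n, ncol(rates) == B)
  else { stopifnot(length(rates) == B)
         rates <- matrix(rates, n, B, byrow = TRUE) }
  if (any(rates < 0)) .stop_domain("hazard rates must be nonnegative")
  stopifnot(all(entry_age >= breaks[1]), all(entry_age < breaks[B + 1]),
            all(u > 0 & u <= 1))
  E <- -log(u)
  lo <- breaks[-(B + 1)]; hi <- breaks[-1]
  CH <- matrix(0, n, B)
  acc <- numeric(n)
  for (b in seq_len(B)) {
    dur <- pmax(0, hi[b] - pmax(lo[b], entry_age))
    acc <- acc + rates[, b] * dur
    CH[, b] <- acc
  }
  idx <- rowSums(CH < E) + 1L
  out <- rep(Inf, n)
  fin <- idx <= B
  if (any(fin)) {
    i <- which(fin)
    j <- idx[fin]
    prev <- ifelse(j > 1L, CH[cbind(i, pmax(j - 1L, 1L))], 0)
    prev[j == 1L] <- 0
    left <- pmax(lo[j], entry_age[fin])
    out[fin] <- left + (E[fin] - prev) / rates[cbind(i, j)]
  }
  out
}

#' Generate a synthetic cohort
#'
#' Samples race, covariates, mediators and left-truncated survival on the age
#' timescale from \code{\link{cohort_params}}. Event ages come from the
#' additive hazard by inverse transform through the piecewise-constant
#' baseline plus the subject's constant shift; exits are the earlier of event
#' age, administrative censoring age (entry + \code{admin_year} - survey
#' year), and the age cap. Negative assembled rates are clipped at 0; the
#' person-time fraction affected is recorded in attribute
#' \code{"clip_fraction"} and must stay below 1\%.
#'
#' @param params a \code{\link{cohort_params}} object
#' @param n number of subjects
#' @param seed integer seed (fully determines the cohort)
#' @return validated \code{cohort} with attributes \code{clip_fraction},
#'   \code{params}, \code{seed}
#' @export
generate_cohort <- function(params, n, seed) {
  stopifnot(inherits(params, "cohort_params"), n >= 1)
  set.seed(substream_seed(seed, "cohort"))
  sex <- sample(.sex_levels, n, TRUE, prob = params$sex_probs)
  race <- sample(params$exposure_levels, n, TRUE, prob = params$exposure_probs)

  mu <- unname(params$age_mean[race]) +
    ifelse(sex == "women", params$age_women_shift, 0)
  lo <- stats::pnorm(params$age_bounds[1], mu, params$age_sd)
  hi <- stats::pnorm(params$age_bounds[2], mu, params$age_sd)
  age <- stats::qnorm(lo + stats::runif(n) * (hi - lo), mu, params$age_sd)
  age <- pmin(pmax(age, params$age_bounds[1]), params$age_bounds[2])

  education <- character(n)
  for (r in unique(race)) {
    i <- race == r
    education[i] <- sample(.edu_levels, sum(i), TRUE,
                           prob = params$education_probs[r, ])
  }
  married <- stats::rbinom(n, 1, unname(params$married_probs[race]))
  year <- sample(params$year_range[1]:params$year_range[2], n, TRUE)

  mediators <- list()
  for (m in names(params$mediator_laws)) {
    pr <- .mediator_probs(params$mediator_laws[[m]], .mediator_levels[[m]],
                          race, age, education, married, year, sex)
    cum <- pr
    for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1] + cum[, j]
    u <- stats::runif(n)
    idx <- rowSums(cum < u) + 1L
    mediators[[m]] <- factor(colnames(pr)[idx], levels = .mediator_levels[[m]])
  }

  shift <- .hazard_shift(params, race, mediators, education, married, year)
  breaks <- 18:params$max_age  # baseline support: one-year bins to the cap
  B <- length(breaks) - 1L
  rates_raw <- matrix(0, n, B)
  for (s in .sex_levels) {
    i <- sex == s
    if (any(i))
      rates_raw[i, ] <- matrix(params$baseline[[s]], sum(i), B, byrow = TRUE) +
        shift[i]
  }
  cens_age <- pmin(age + (params$admin_year - year), params$max_age)
  # person-time-weighted clipping fraction over each subject's window
  losp <- breaks[-(B + 1)]; hisp <- breaks[-1]
  exposure_dur <- outer(rep(1, n), hisp) # placeholder, filled below
  exposure_dur <- pmax(0, pmin(matrix(hisp, n, B, byrow = TRUE), cens_age) -
                          pmax(matrix(losp, n, B, byrow = TRUE), age))
  clip_frac <- sum(exposure_dur[rates_raw < 0]) / sum(exposure_dur)
  if (clip_frac >= 0.01)
    .stop_domain("hazard clipping fraction ", signif(clip_frac, 3),
                 " >= 1%; reduce negative additive effects or raise the baseline")
  rates <- pmax(rates_raw, 0)

  event_age <- sample_event_age(age, breaks, rates, stats::runif(n))
  exit_age <- pmin(event_age, cens_age)
  event <- as.integer(event_age <= cens_age)

  d <- data.frame(subject_id = sprintf("s%07d", seq_len(n)),
                  race_ethnicity = race, sex = sex, age_at_survey = age,
                  education = education, married = married,
                  survey_year = year,
                  alcohol_category = mediators$alcohol_category,
                  smoking_category = mediators$smoking_category,
                  bmi_category = mediators$bmi_category,
                  activity_category = mediators$activity_category,
                  entry_age = age, exit_age = exit_age, event = event,
                  stringsAsFactors = FALSE)
  out <- validate_cohort(d)
  attr(out, "clip_fraction") <- clip_frac
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}

#' @rdname generate_cohort
#' @param object a \code{cohort_params} object
#' @param nsim number of subjects to draw (alias of \code{n})
#' @param ... unused
#' @export
simulate.cohort_params <- function(object, nsim = 1000, seed = 1, ...)
  generate_cohort(object, n = nsim, seed = seed)

#' True effect decomposition implied by generator parameters
#'
#' Computes the decomposition the marginal-structural estimator targets,
#' per sex and per race contrast, on the additive hazard scale (reported per
#' 10,000 person-years): differential exposure through mediator k is
#' \eqn{E_C[\sum_m \gamma_k[m] (P(M_k = m | R = r, C) - P(M_k = m | R = 0,
#' C))]}; differential vulnerability is the mediated interaction
#' \eqn{E_C[D_k(r) - D_k(0)]} with \eqn{D_k(r') = \sum_m \delta_k[m] P(M_k =
#' m | R = r', C)}; the direct effect is the pure direct effect
#' \eqn{\beta_r + \sum_k E_C[D_k(0)]}. Expectations are over the covariate
#' distribution of the two-group analytic sample (both exposure groups,
#' conditioned on sex). Under the additive generating hazard all components
#' are invariant to the baseline \eqn{\lambda_0}.
#'
#' In \code{closed_form} mode the mediator-law probabilities are used
#' exactly; in \code{monte_carlo} mode mediator values are drawn and the same
#' functionals averaged, giving a self-consistency check.
#'
#' @param params a \code{\link{cohort_params}} object
#' @param mode \code{"closed_form"} or \code{"monte_carlo"}
#' @param mc_size covariate sample size for the expectation
#' @param seed integer seed
#' @return data.frame of class \code{true_decomposition}: sex, contrast,
#'   component, mediator, truth (per 10,000 person-years), mc_se
#' @export
true_decomposition <- function(params, mode = c("closed_form", "monte_carlo"),
                               mc_size = 2e5, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "cohort_params"))
  if (mode == "monte_carlo" && mc_size < 1e4)
    warning("mc_size below 10^4; Monte-Carlo truth will be noisy")
  set.seed(substream_seed(seed, paste0("truth_", mode)))
  contrasts <- setdiff(params$exposure_levels, "white")
  rows <- list()
  for (s in .sex_levels) {
    for (r in contrasts) {
      pr2 <- params$exposure_probs[c("white", r)]
      race <- sample(c("white", r), mc_size, TRUE, prob = pr2 / sum(pr2))
      mu <- unname(params$age_mean[race]) +
        if (s == "women") params$age_women_shift else 0
      lo <- stats::pnorm(params$age_bounds[1], mu, params$age_sd)
      hi <- stats::pnorm(params$age_bounds[2], mu, params$age_sd)
      age <- stats::qnorm(lo + stats::runif(mc_size) * (hi - lo), mu,
                          params$age_sd)
      education <- character(mc_size)
      for (rr in unique(race)) {
        i <- race == rr
        education[i] <- sample(.edu_levels, sum(i), TRUE,
                               prob = params$education_probs[rr, ])
      }
      married <- stats::rbinom(mc_size, 1, unname(params$married_probs[race]))
      year <- sample(params$year_range[1]:params$year_range[2], mc_size, TRUE)

      per_draw_exp <- per_draw_vul <- per_draw_d0 <- list()
      for (m in names(params$mediator_laws)) {
        levs <- .mediator_levels[[m]]
        p0 <- .mediator_probs(params$mediator_laws[[m]], levs,
                              rep("white", mc_size), age, education, married,
                              year, rep(s, mc_size))
        p1 <- .mediator_probs(params$mediator_laws[[m]], levs,
                              rep(r, mc_size), age, education, married, year,
                              rep(s, mc_size))
        if (mode == "monte_carlo") {
          p0 <- .draw_indicator(p0)
          p1 <- .draw_indicator(p1)
        }
        g <- params$gamma[[m]][levs]
        dl <- params$delta[[r]][[m]][levs]
        per_draw_exp[[m]] <- as.numeric((p1 - p0) %*% g)
        per_draw_vul[[m]] <- as.numeric((p1 - p0) %*% dl)
        per_draw_d0[[m]] <- as.numeric(p0 %*% dl)
      }
      direct_draws <- params$beta_direct[[r]] + Reduce(`+`, per_draw_d0)
      total_draws <- direct_draws +
        Reduce(`+`, per_draw_exp) + Reduce(`+`, per_draw_vul)
      net_draws <- total_draws - direct_draws
      add_row <- function(component, mediator, draws) {
        rows[[length(rows) + 1L]] <<- data.frame(
          sex = s, contrast = r, component = component, mediator = mediator,
          truth = mean(draws) * 1e4,
          mc_se = stats::sd(draws) / sqrt(mc_size) * 1e4,
          stringsAsFactors = FALSE)
      }
      add_row("total", NA_character_, total_draws)
      add_row("direct", NA_character_, direct_draws)
      add_row("net_indirect", NA_character_, net_draws)
      for (m in names(params$mediator_laws)) {
        add_row("exposure", m, per_draw_exp[[m]])
        add_row("vulnerability", m, per_draw_vul[[m]])
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  class(out) <- c("true_decomposition", "data.frame")
  out
}

# one-hot draws from row-stochastic probability matrix
.draw_indicator <- function(pr) {
  cum <- pr
  for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1] + cum[, j]
  idx <- rowSums(cum < stats::runif(nrow(pr))) + 1L
  out <- matrix(0, nrow(pr), ncol(pr), dimnames = dimnames(pr))
  out[cbind(seq_len(nrow(pr)), idx)] <- 1
  out
}
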