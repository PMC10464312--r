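# Orchestration of the full mediation pipeline: per sex stratum, fit the four
# mediator models, expand over auxiliary exposures, weight, truncate, fit the
# weighted Lin-Ying MSM, and map coefficients to the three-component
# decomposition (direct effect, per-mediator differential exposure, and
# per-mediator differential vulnerability), reported per 10,000 person-years.

#' Build the marginal-structural design from an expanded cohort
#'
#' Design columns: indicators of observed exposure per non-reference level
#' (direct effect), indicators of each auxiliary exposure \code{R*_k}
#' (differential exposure), their matched and cross products (differential
#' vulnerability), and the covariates (education dummies unless
#' \code{covariate_set = "no_education"}, marriage, survey year centered at
#' 2005). Age enters only as the timescale.
#'
#' @param expanded weighted \code{\link{expand_cohort}} table
#' @param covariate_set \code{"full"} or \code{"no_education"} (the
#'   education-free sensitivity analysis)
#' @return a \code{\link{survival_design}} clustered on subject
#' @export
build_msm_design <- function(expanded,
                             covariate_set = c("full", "no_education")) {
  covariate_set <- match.arg(covariate_set)
  mediators <- attr(expanded, "mediators")
  exposure_levels <- attr(expanded, "exposure_levels")
  needed <- c("education", "married", "survey_year")
  if (!all(needed %in% names(expanded)))
    .stop_domain("expanded data lacks covariate column(s): ",
                 paste(setdiff(needed, names(expanded)), collapse = ", "))
  nonref <- setdiff(exposure_levels, exposure_levels[1])
  cols <- list()
  for (a in nonref)
    cols[[paste0("race_", a)]] <-
      as.numeric(expanded$race_ethnicity == a)
  for (m in mediators) for (a in nonref)
    cols[[paste0("rstar_", m, "_", a)]] <-
      as.numeric(expanded[[paste0("rstar_", m)]] == a)
  for (m in mediators) for (a in nonref) for (b in nonref)
    cols[[paste0("race_", a, "_x_rstar_", m, "_", b)]] <-
      cols[[paste0("race_", a)]] * cols[[paste0("rstar_", m, "_", b)]]
  if (covariate_set == "full") {
    cols$edu_medium <- as.numeric(expanded$education == "medium")
    cols$edu_high <- as.numeric(expanded$education == "high")
  }
  cols$married <- as.numeric(expanded$married)
  cols$year_c <- as.numeric(expanded$survey_year) - 2005
  Z <- do.call(cbind, cols)
  colnames(Z) <- names(cols)
  survival_design(expanded$entry_age, expanded$exit_age, expanded$event, Z,
                  weights = expanded$weight, cluster = expanded$subject_id)
}

# Map MSM coefficients to decomposition components for one contrast.
# Returns the 11-vector (total, direct, net, exposure x4, vulnerability x4)
# per person-year, plus the linear combination matrix for variance work.
.component_map <- function(coefs, contrast, mediators) {
  nm <- names(coefs)
  pick <- function(x) { i <- match(x, nm); stopifnot(!is.na(i)); i }
  idx_direct <- pick(paste0("race_", contrast))
  idx_exp <- vapply(mediators,
                    function(m) pick(paste0("rstar_", m, "_", contrast)), 1L)
  idx_vul <- vapply(mediators, function(m)
    pick(paste0("race_", contrast, "_x_rstar_", m, "_", contrast)), 1L)
  L <- matrix(0, 3 + 2 * length(mediators), length(coefs))
  rn <- c("total", "direct", "net_indirect",
          paste0("exposure.", mediators), paste0("vulnerability.", mediators))
  rownames(L) <- rn
  L["direct", idx_direct] <- 1
  for (k in seq_along(mediators)) {
    L[paste0("exposure.", mediators[k]), idx_exp[k]] <- 1
    L[paste0("vulnerability.", mediators[k]), idx_vul[k]] <- 1
  }
  L["net_indirect", c(idx_exp, idx_vul)] <- 1
  L["total", c(idx_direct, idx_exp, idx_vul)] <- 1
  list(est = as.numeric(L %*% coefs), L = L, names = rn)
}

# One full pipeline pass on a sex-stratum subset restricted to
# {white, contrast}. 'counts' are bootstrap resample counts per row of 'dat'.
.decompose_stratum <- function(dat, contrast, mediators, covariate_set,
                               truncate_percentile, stabilize = FALSE,
                               counts = NULL, se = FALSE, warm = NULL) {
  if (is.null(counts)) {
    dsub <- dat
    wcount <- rep(1, nrow(dat))
  } else {
    keep <- counts > 0
    dsub <- dat[keep, , drop = FALSE]
    wcount <- counts[keep]
  }
  models <- list()
  for (m in mediators)
    models[[m]] <- fit_mediator_model(dsub, m, weights = wcount,
                                      start = warm[[m]],
                                      check_cells = is.null(counts))
  ex <- expand_cohort(dsub, c("white", contrast), mediators)
  ex <- compute_weights(ex, models, stabilize = stabilize)
  ex <- truncate_weights(ex, truncate_percentile)
  wdiag <- attr(ex, "weight_diagnostics")
  trunc <- attr(ex, "truncation")
  subj <- attr(ex, "subject_index")
  ex$weight <- ex$weight * wcount[subj]   # bootstrap counts enter after
  des <- build_msm_design(ex, covariate_set)
  fit <- fit_additive_hazard(des, se = se)
  cm <- .component_map(fit$coefficients, contrast, mediators)
  list(components = stats::setNames(cm$est, cm$names), fit = fit, L = cm$L,
       models = models, weight_diagnostics = wdiag, truncation = trunc,
       n = nrow(dsub), n_events = sum(dsub$event),
       person_years = sum(dsub$exit_age - dsub$entry_age))
}

# Unweighted, unexpanded marginal fit of race + covariates (diagnostic total)
.marginal_total <- function(dat, contrast, covariate_set) {
  cols <- list(race = as.numeric(dat$race_ethnicity == contrast))
  if (covariate_set == "full") {
    cols$edu_medium <- as.numeric(dat$education == "medium")
    cols$edu_high <- as.numeric(dat$education == "high")
  }
  cols$married <- as.numeric(dat$married)
  cols$year_c <- as.numeric(dat$survey_year) - 2005
  Z <- do.call(cbind, cols)
  colnames(Z) <- names(cols)
  des <- survival_design(dat$entry_age, dat$exit_age, dat$event, Z,
                         cluster = dat$subject_id)
  fit <- fit_additive_hazard(des, se = FALSE)
  unname(fit$coefficients["race"])
}

#' Causal mediation decomposition of mortality differences
#'
#' Decomposes the difference in all-cause mortality between each contrast
#' group and the reference (white) into a direct effect plus per-mediator
#' differential-exposure and differential-vulnerability components on the
#' additive hazard scale, separately by sex, via the marginal-structural
#' natural-effects pipeline: multinomial mediator models, counterfactual
#' expansion over auxiliary exposures, probability-ratio weights (truncated
#' at an upper percentile), and a weighted Lin-Ying additive hazards fit
#' with age as the timescale. Estimates are reported as additional deaths
#' per 10,000 person-years; the total and net indirect effects are the sums
#' of the fitted components, so additivity holds exactly.
#'
#' Confidence intervals are subject-level nonparametric bootstrap percentile
#' intervals when \code{B > 0} (the entire pipeline reruns per replicate);
#' otherwise normal intervals from the cluster-sandwich covariance.
#'
#' @param data validated cohort (see \code{\link{validate_cohort}});
#'   records with race "other" are excluded automatically
#' @param contrasts non-reference race levels to contrast against white
#' @param sexes sex strata to fit (separate models per sex)
#' @param mediators the four lifestyle mediator columns
#' @param covariate_set \code{"full"} (education, marriage, survey year) or
#'   \code{"no_education"} (sensitivity analysis)
#' @param truncate_percentile weight-truncation percentile in (50, 100]
#' @param stabilize stabilize weights within auxiliary pattern (default
#'   FALSE)
#' @param B bootstrap replicates (0 = sandwich intervals)
#' @param seed master seed; all bootstrap substreams derive from it
#' @param level confidence level
#' @return object of class \code{medhaz}: \code{$results} (sex, contrast,
#'   component, mediator, estimate, se, lower, upper -- per 10,000
#'   person-years), \code{$metadata}, \code{$fits}
#' @export
medhaz <- function(data, contrasts = "black",
                   sexes = c("men", "women"),
                   mediators = unname(.mediator_columns),
                   covariate_set = c("full", "no_education"),
                   truncate_percentile = 99.5, stabilize = FALSE,
                   B = 0, seed = 1, level = 0.95) {
  covariate_set <- match.arg(covariate_set)
  stopifnot(inherits(data, "data.frame"), length(contrasts) >= 1)
  d <- as.data.frame(data)
  if ("in_decomposition" %in% names(d)) d <- d[d$in_decomposition, ]
  available <- table(d$race_ethnicity)
  for (r in contrasts)
    if (is.na(available[r]) || available[r] == 0)
      .stop_domain("contrast level '", r, "' absent from cohort")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  results <- list()
  fits <- list()
  meta_strata <- list()
  for (s in sexes) for (r in contrasts) {
    key <- paste(s, r, sep = ".")
    dat <- d[d$sex == s & d$race_ethnicity %in% c("white", r), , drop = FALSE]
    dat$race_ethnicity <- droplevels(dat$race_ethnicity)
    if (sum(dat$event) < 1)
      .stop_domain("stage additive_hazard: no events in stratum ", key)
    point <- .decompose_stratum(dat, r, mediators, covariate_set,
                                truncate_percentile, stabilize,
                                se = (B == 0))
    est <- point$components
    if (B > 0) {
      warm <- lapply(point$models, `[[`, "wts")
      boot <- matrix(NA_real_, B, length(est),
                     dimnames = list(NULL, names(est)))
      fails <- 0L
      n <- nrow(dat)
      for (bb in seq_len(B)) {
        set.seed(substream_seed(seed, paste("boot", key, bb)))
        counts <- tabulate(sample.int(n, n, replace = TRUE), n)
        rep_est <- try(.decompose_stratum(
          dat, r, mediators, covariate_set, truncate_percentile, stabilize,
          counts = counts, se = FALSE, warm = warm)$components,
          silent = TRUE)
        if (inherits(rep_est, "try-error")) fails <- fails + 1L
        else boot[bb, ] <- rep_est
      }
      if (fails > 0.1 * B)
        .stop_domain("stage bootstrap: ", fails, " of ", B,
                     " replicates failed in stratum ", key)
      lower <- apply(boot, 2, stats::quantile, probs = (1 - level) / 2,
                     na.rm = TRUE, type = 7)
      upper <- apply(boot, 2, stats::quantile, probs = 1 - (1 - level) / 2,
                     na.rm = TRUE, type = 7)
      se_vec <- apply(boot, 2, stats::sd, na.rm = TRUE)
    } else {
      V <- point$L %*% point$fit$vcov %*% t(point$L)
      se_vec <- sqrt(diag(V))
      lower <- est - zq * se_vec
      upper <- est + zq * se_vec
      boot <- NULL
    }
    comp <- names(est)
    results[[key]] <- data.frame(
      sex = s, contrast = r,
      component = sub("\\..*$", "", comp),
      mediator = ifelse(grepl("\\.", comp), sub("^[^.]*\\.", "", comp),
                        NA_character_),
      estimate = unname(est) * 1e4, se = unname(se_vec) * 1e4,
      lower = unname(lower) * 1e4, upper = unname(upper) * 1e4,
      stringsAsFactors = FALSE)
    fits[[key]] <- point
    meta_strata[[key]] <- list(
      n = point$n, n_events = point$n_events,
      person_years = point$person_years,
      weight_diagnostics = point$weight_diagnostics,
      truncation = point$truncation,
      marginal_total = .marginal_total(dat, r, covariate_set) * 1e4,
      bootstrap_failures = if (B > 0) fails else NA_integer_)
  }
  out <- list(results = do.call(rbind, c(results, make.row.names = FALSE)),
              metadata = list(contrasts = contrasts, sexes = sexes,
                              mediators = mediators,
                              covariate_set = covariate_set,
                              truncate_percentile = truncate_percentile,
                              stabilize = stabilize, B = B, seed = seed,
                              level = level, strata = meta_strata),
              fits = fits)
  class(out) <- "medhaz"
  out
}

#' @export
print.medhaz <- function(x, digits = 1, ...) {
  cat("Causal mediation decomposition (additive hazard scale,",
      "per 10,000 person-years)\n")
  cat("Covariates:", x$metadata$covariate_set, "  CI:",
      if (x$metadata$B > 0) paste0("bootstrap percentile (B = ",
                                   x$metadata$B, ")")
      else "cluster-sandwich normal", "\n\n")
  print(report_table(x, digits = digits), right = FALSE)
  invisible(x)
}

#' @export
summary.medhaz <- function(object, ...) {
  st <- object$metadata$strata
  cat("Strata:\n")
  for (k in names(st))
    cat(sprintf("  %-16s n = %d, events = %d, person-years = %.0f, max weight = %.2f, marginal total (diagnostic) = %.1f\n",
                k, st[[k]]$n, st[[k]]$n_events, st[[k]]$person_years,
                st[[k]]$weight_diagnostics[["max_weight"]],
                st[[k]]$marginal_total))
  cat("\n")
  print(object)
  invisible(object)
}

#' @export
coef.medhaz <- function(object, ...) {
  r <- object$results
  key <- paste(r$contrast, r$sex, sep = ".")
  comp <- ifelse(is.na(r$mediator), r$component,
                 paste(r$component, r$mediator, sep = "."))
  out <- tapply(r$estimate, list(comp, key), identity)
  out[unique(comp), , drop = FALSE]
}

#' @export
confint.medhaz <- function(object, ...) {
  object$results[, c("sex", "contrast", "component", "mediator",
                     "lower", "upper")]
}

#' @export
plot.medhaz <- function(x, ...) {
  r <- x$results
  r$label <- paste0(ifelse(is.na(r$mediator), r$component,
                           paste(r$component, r$mediator)), "\n",
                    r$contrast, " ", r$sex)
  n <- nrow(r)
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(r$estimate, seq_len(n), xlim = range(r$lower, r$upper),
                 yaxt = "n", xlab = "Additional deaths per 10,000 person-years",
                 ylab = "", pch = 19, ...)
  graphics::segments(r$lower, seq_len(n), r$upper, seq_len(n))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n),
                 labels = gsub("\n", " / ", r$label), las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Formatted decomposition table
#'
#' Rows: total, direct, net indirect, then per-mediator exposure and
#' vulnerability pairs; one column per contrast-by-sex stratum; one decimal
#' place, rounded half away from zero; negative values mean fewer deaths.
#'
#' @param result a \code{\link{medhaz}} object
#' @param digits decimal places (default 1)
#' @return character data.frame, cells \code{"est (lo, hi)"}
#' @export
report_table <- function(result, digits = 1) {
  r <- result$results
  med_label <- c(alcohol_category = "Alcohol use",
                 smoking_category = "Smoking",
                 bmi_category = "BMI",
                 activity_category = "Physical activity")
  row_label <- function(component, mediator) {
    base <- c(total = "Total effect", direct = "'Direct' effect",
              net_indirect = "Net indirect effect")
    ifelse(is.na(mediator), base[component],
           paste0(med_label[mediator], ": ",
                  ifelse(component == "exposure", "differential exposure",
                         "differential vulnerability")))
  }
  fmt <- function(x) sprintf(paste0("%.", digits, "f"),
                             round_half_away(x, digits))
  r$cell <- paste0(fmt(r$estimate), " (", fmt(r$lower), ", ",
                   fmt(r$upper), ")")
  r$rl <- row_label(r$component, r$mediator)
  meds <- result$metadata$mediators
  row_order <- c("Total effect", "'Direct' effect", "Net indirect effect",
                 as.vector(rbind(paste0(med_label[meds],
                                        ": differential exposure"),
                                 paste0(med_label[meds],
                                        ": differential vulnerability"))))
  cols <- unique(paste(r$contrast, r$sex))
  out <- data.frame(row.names = row_order)
  for (cc in cols) {
    sub <- r[paste(r$contrast, r$sex) == cc, ]
    out[[cc]] <- sub$cell[match(row_order, sub$rl)]
  }
  out
}

#' Repeated-simulation recovery study
#'
#' Repeatedly generates cohorts from \code{params} and runs the full
#' decomposition, reporting bias, empirical SE, RMSE and (when \code{B > 0})
#' bootstrap CI coverage of every component against the closed-form truth.
#'
#' @param params \code{\link{cohort_params}}
#' @param n_reps number of simulation replicates
#' @param n subjects per replicate
#' @param seed master seed
#' @param B bootstrap replicates within each run (0 = no CIs)
#' @param sexes,contrasts passed to \code{\link{medhaz}}
#' @param truth_mc covariate sample size for the closed-form truth
#' @param ... further arguments to \code{\link{medhaz}}
#' @return data.frame of class \code{simulation_study}: per component truth,
#'   mean estimate, bias, empirical SE, RMSE, coverage
#' @export
simulation_study <- function(params, n_reps, n, seed = 1, B = 0,
                             sexes = "men",
                             contrasts = setdiff(params$exposure_levels,
                                                 "white"),
                             truth_mc = 2e5, ...) {
  truth <- true_decomposition(params, "closed_form", mc_size = truth_mc,
                              seed = substream_seed(seed, "truth"))
  truth <- truth[truth$sex %in% sexes & truth$contrast %in% contrasts, ]
  tkey <- paste(truth$sex, truth$contrast, truth$component, truth$mediator)
  ests <- covers <- matrix(NA_real_, n_reps, nrow(truth))
  n_failed <- 0L
  for (i in seq_len(n_reps)) {
    # a replicate cohort can be degenerate (e.g. an empty rare mediator cell
    # at this n); record and move on, as in the bootstrap failure policy
    ok <- try({
      co <- generate_cohort(params, n, seed = substream_seed(seed,
                                                             paste("rep", i)))
      fit <- medhaz(co, contrasts = contrasts, sexes = sexes, B = B,
                    seed = substream_seed(seed, paste("boot", i)), ...)
      r <- fit$results
      rkey <- paste(r$sex, r$contrast, r$component, r$mediator)
      m <- match(tkey, rkey)
      ests[i, ] <- r$estimate[m]
      if (B > 0)
        covers[i, ] <- r$lower[m] <= truth$truth & truth$truth <= r$upper[m]
    }, silent = TRUE)
    if (inherits(ok, "try-error")) n_failed <- n_failed + 1L
  }
  if (n_failed > n_reps / 2)
    .stop_domain("simulation study: ", n_failed, " of ", n_reps,
                 " replicates failed")
  err2 <- (ests - matrix(truth$truth, n_reps, nrow(truth), byrow = TRUE))^2
  out <- data.frame(truth[, c("sex", "contrast", "component", "mediator")],
                    truth = truth$truth,
                    mean_est = colMeans(ests, na.rm = TRUE),
                    bias = colMeans(ests, na.rm = TRUE) - truth$truth,
                    emp_se = apply(ests, 2, stats::sd, na.rm = TRUE),
                    rmse = sqrt(colMeans(err2, na.rm = TRUE)),
                    coverage = if (B > 0) colMeans(covers, na.rm = TRUE)
                               else NA_real_)
  attr(out, "n_reps") <- n_reps
  attr(out, "n_failed") <- n_failed
  attr(out, "n") <- n
  attr(out, "estimates") <- ests
  class(out) <- c("simulation_study", "data.frame")
  out
}
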