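# Baseline-category multinomial logistic models of mediator category given
# exposure (race/ethnicity) and covariates, fit per sex stratum. These are
# the ingredients of the marginal-structural weights: the reference category
# of each mediator follows the analysis (cat_I, never smoker, normal weight,
# active), age and survey year enter linearly, education as two dummies.

.mediator_formula <- function(mediator) {
  stats::as.formula(paste(
    mediator, "~ race_ethnicity + I(age_at_survey - 46) + education +",
    "married + I(survey_year - 2005)"))
}

#' Fit a baseline-category multinomial mediator model
#'
#' Maximum-likelihood multinomial logit (via \code{nnet::multinom}) of one
#' mediator category on race/ethnicity, age (linear), education (two
#' dummies), marital status and survey year (linear). The cohort must
#' already be restricted to one sex stratum and to the exposure groups under
#' analysis. Every mediator level must be observed in every race group, or
#' the fit stops naming the empty cell. On failed convergence a ridge
#' fallback (weight decay 1e-6) is attempted once and reported.
#'
#' @param cohort validated cohort (one sex stratum)
#' @param mediator mediator column name, e.g. \code{"smoking_category"}
#' @param weights optional nonnegative case weights (e.g. bootstrap counts);
#'   zero-weight rows are dropped
#' @param start optional warm-start network weights from a previous fit
#' @param check_cells require every mediator level observed in every race
#'   group (default TRUE). Bootstrap replicates of an already-identified fit
#'   set this to FALSE: resamples of a cohort with rare cells routinely lose
#'   a cell, and the parametric logit still extrapolates it smoothly.
#' @return object of class \code{mediator_model}: coefficient matrix
#'   (non-reference levels x predictors), levels, terms, convergence flag,
#'   log-likelihood
#' @export
fit_mediator_model <- function(cohort, mediator, weights = NULL,
                               start = NULL, check_cells = TRUE) {
  if (!mediator %in% names(.mediator_levels))
    .stop_domain("unknown mediator: ", mediator)
  d <- as.data.frame(cohort)
  d$race_ethnicity <- droplevels(d$race_ethnicity)
  if (is.null(weights)) weights <- rep(1, nrow(d))
  keep <- weights > 0
  d <- d[keep, , drop = FALSE]
  w <- weights[keep]

  y <- d[[mediator]]
  observed <- table(race = d$race_ethnicity, level = y)
  if (sum(colSums(observed) > 0) < 2L)
    .stop_domain("degenerate mediator '", mediator,
                 "': fewer than two observed levels")
  if (check_cells) {
    empty <- which(observed == 0, arr.ind = TRUE)
    if (nrow(empty))
      .stop_domain("mediator '", mediator, "' level '",
                   colnames(observed)[empty[1, 2]],
                   "' unobserved in race group '",
                   rownames(observed)[empty[1, 1]],
                   "'; weights are not identified")
  } else {
    if (sum(observed[, 1]) == 0)
      .stop_domain("mediator '", mediator,
                   "' reference level unobserved; cannot anchor the fit")
    d[[mediator]] <- droplevels(y)
    y <- d[[mediator]]
    if (nlevels(y) < ncol(observed)) start <- NULL  # network shape changed
  }

  fml <- .mediator_formula(mediator)
  fit_args <- list(fml, data = d, weights = w, trace = FALSE,
                   maxit = 400, reltol = 1e-12, Hess = FALSE, model = FALSE)
  if (!is.null(start)) fit_args$Wts <- start
  fit <- try(suppressWarnings(do.call(nnet::multinom, fit_args)),
             silent = TRUE)
  ridged <- FALSE
  bad <- inherits(fit, "try-error") || fit$convergence != 0 ||
    any(!is.finite(stats::coef(fit)))
  if (bad) {  # separation or non-convergence: tiny L2 penalty, reported
    ridged <- TRUE
    fit_args$decay <- 1e-6
    fit_args$Wts <- NULL
    fit <- suppressWarnings(do.call(nnet::multinom, fit_args))
    if (fit$convergence != 0)
      .stop_domain("mediator model for '", mediator,
                   "' failed to converge even with ridge fallback")
    warning("mediator model for '", mediator,
            "' used ridge fallback (decay 1e-6)", call. = FALSE)
  }

  cf <- stats::coef(fit)
  if (is.null(dim(cf))) {  # two-level mediator: coerce to matrix
    cf <- matrix(cf, nrow = 1, dimnames = list(fit$lev[2], names(cf)))
  }
  structure(list(mediator = mediator,
                 levels = fit$lev,
                 reference = fit$lev[1],
                 coefficients = cf,
                 terms = stats::delete.response(stats::terms(fml)),
                 xlevels = list(race_ethnicity = levels(d$race_ethnicity),
                                education = levels(d$education)),
                 convergence = fit$convergence == 0,
                 ridged = ridged,
                 logLik = as.numeric(stats::logLik(fit)),
                 n = nrow(d),
                 wts = fit$wts),
            class = "mediator_model")
}

#' @export
print.mediator_model <- function(x, ...) {
  cat("Multinomial mediator model:", x$mediator,
      "(reference:", x$reference, ")\n")
  cat("n =", x$n, " logLik =", format(x$logLik), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted mediator-category probabilities under a set exposure
#'
#' Evaluates the fitted baseline-category softmax for each row of
#' \code{newdata} with the race/ethnicity column overridden by
#' \code{exposure_value}. Probabilities are strictly positive and sum to 1.
#'
#' @param model a \code{\link{fit_mediator_model}} fit
#' @param newdata data.frame with the model's covariate columns
#' @param exposure_value race level at which to evaluate; \code{NULL} keeps
#'   each row's observed exposure
#' @return matrix n x levels (reference category first)
#' @export
predict_category_probs <- function(model, newdata, exposure_value = NULL) {
  stopifnot(inherits(model, "mediator_model"))
  d <- as.data.frame(newdata)
  if (!is.null(exposure_value)) {
    if (!exposure_value %in% model$xlevels$race_ethnicity)
      .stop_domain("unknown exposure level: ", exposure_value)
    d$race_ethnicity <- factor(exposure_value,
                               levels = model$xlevels$race_ethnicity)
  } else {
    d$race_ethnicity <- factor(as.character(d$race_ethnicity),
                               levels = model$xlevels$race_ethnicity)
  }
  d$education <- factor(as.character(d$education),
                        levels = model$xlevels$education)
  X <- stats::model.matrix(model$terms, stats::model.frame(
    model$terms, d, na.action = stats::na.fail))
  cfn <- colnames(model$coefficients)
  if (!all(cfn %in% colnames(X)))
    .stop_domain("newdata does not provide the model's predictors")
  eta <- X[, cfn, drop = FALSE] %*% t(model$coefficients)
  expeta <- cbind(1, exp(eta))
  pr <- expeta / rowSums(expeta)
  colnames(pr) <- model$levels
  pr
}
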