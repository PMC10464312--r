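# Counterfactual data expansion for the natural-effects marginal structural
# model: each subject is replicated over every joint assignment of auxiliary
# exposures (R*_1, ..., R*_K), one per mediator, and weighted by the ratio of
# mediator-model probabilities of the observed mediator value under the
# auxiliary versus the observed exposure.

#' Expand a cohort over auxiliary exposure assignments
#'
#' Builds the Cartesian-product replicate table: with L exposure levels and K
#' mediators every subject contributes L^K rows, one per joint auxiliary
#' assignment (columns \code{rstar_<mediator>}). Survival fields, covariates
#' and observed mediators are copied unchanged; exactly one replicate per
#' subject (the identity replicate, flag \code{identity_replicate}) has every
#' auxiliary exposure equal to the observed exposure.
#'
#' @param cohort validated cohort, already restricted to one sex stratum and
#'   to the exposure levels under analysis
#' @param exposure_levels character vector of exposure levels (reference
#'   first)
#' @param mediators mediator column names (K of them)
#' @return expanded data.frame of class \code{expanded_cohort} with
#'   \code{weight} unset (1); attribute \code{"mediators"}
#' @export
expand_cohort <- function(cohort,
                          exposure_levels = c("white", "black"),
                          mediators = unname(.mediator_columns)) {
  d <- as.data.frame(cohort)
  if (!all(mediators %in% names(d)))
    .stop_domain("mediator column(s) absent from cohort: ",
                 paste(setdiff(mediators, names(d)), collapse = ", "))
  if (!all(as.character(d$race_ethnicity) %in% exposure_levels))
    .stop_domain("cohort contains exposure levels outside 'exposure_levels'")
  n <- nrow(d)
  K <- length(mediators)
  L <- length(exposure_levels)
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), K)))
  P <- nrow(grid)  # L^K replicates per subject

  subj <- rep(seq_len(n), each = P)
  pat <- rep(seq_len(P), times = n)
  out <- d[subj, c("subject_id", "race_ethnicity", "sex", "age_at_survey",
                   "education", "married", "survey_year", mediators,
                   "entry_age", "exit_age", "event"), drop = FALSE]
  rownames(out) <- NULL
  out$replicate_id <- pat
  race_idx <- match(as.character(d$race_ethnicity), exposure_levels)
  identity <- rep(TRUE, n * P)
  for (k in seq_len(K)) {
    gk <- grid[pat, k]
    out[[paste0("rstar_", mediators[k])]] <-
      factor(exposure_levels[gk], levels = exposure_levels)
    identity <- identity & gk == race_idx[subj]
  }
  out$identity_replicate <- identity
  out$weight <- 1
  attr(out, "mediators") <- mediators
  attr(out, "exposure_levels") <- exposure_levels
  attr(out, "subject_index") <- subj
  attr(out, "pattern_grid") <- grid
  class(out) <- c("expanded_cohort", "data.frame")
  out
}

#' Compute marginal-structural natural-effects weights
#'
#' For subject i with observed exposure r_i, mediator values m_{ki} and
#' covariates C_i, the replicate with auxiliary assignment (r*_1, ..., r*_K)
#' receives the unstabilized weight
#' \deqn{W = \prod_k \hat P_k(m_{ki} | R = r*_k, C_i) /
#'                   \hat P_k(m_{ki} | R = r_i, C_i).}
#' The identity replicate's weight is exactly 1. With \code{stabilize =
#' TRUE}, weights are rescaled to mean 1 within each auxiliary-assignment
#' pattern (variance control; leaves the estimating equation's population
#' solution unchanged).
#'
#' @param expanded an \code{\link{expand_cohort}} table
#' @param models named list of \code{\link{fit_mediator_model}} fits, one per
#'   mediator, fitted on the same stratum
#' @param stabilize logical; default FALSE (unstabilized, as in the
#'   natural-effects template)
#' @return \code{expanded} with \code{weight} filled in; attribute
#'   \code{"weight_diagnostics"} (max weight, effective sample size)
#' @export
compute_weights <- function(expanded, models, stabilize = FALSE) {
  mediators <- attr(expanded, "mediators")
  exposure_levels <- attr(expanded, "exposure_levels")
  subj <- attr(expanded, "subject_index")
  grid <- attr(expanded, "pattern_grid")
  if (!all(mediators %in% names(models)))
    .stop_domain("'models' must contain a fit for every mediator")
  first <- !duplicated(subj)
  base <- as.data.frame(expanded)[first, , drop = FALSE]  # one row/subject
  n <- nrow(base)
  race_idx <- match(as.character(base$race_ethnicity), exposure_levels)

  logw <- numeric(nrow(expanded))
  pat <- expanded$replicate_id
  for (k in seq_along(mediators)) {
    m <- mediators[k]
    obs_level <- as.character(base[[m]])
    pk <- matrix(NA_real_, n, length(exposure_levels))
    for (l in seq_along(exposure_levels)) {
      pr <- predict_category_probs(models[[m]], base, exposure_levels[l])
      pk[, l] <- pr[cbind(seq_len(n), match(obs_level, colnames(pr)))]
    }
    den <- pk[cbind(seq_len(n), race_idx)]
    small <- den < 1e-12
    if (any(small))
      .stop_domain("positivity violation: mediator '", m, "', subject ",
                   base$subject_id[which(small)[1]],
                   " has denominator probability < 1e-12")
    ratio <- log(pk) - log(den)        # n x L, column r_i is exactly 0
    logw <- logw + ratio[cbind(subj, grid[pat, k])]
  }
  w <- exp(logw)
  w[expanded$identity_replicate] <- 1  # exact, not just numerically
  if (stabilize) {
    pm <- tapply(w, pat, mean)
    w <- w / as.numeric(pm[pat])
  }
  expanded$weight <- w
  attr(expanded, "weight_diagnostics") <-
    c(max_weight = max(w), min_weight = min(w),
      ess = sum(w)^2 / sum(w^2), n_rows = length(w))
  expanded
}

#' Truncate extreme weights at an upper percentile
#'
#' Weights above the stated percentile of the weight distribution are set to
#' the percentile value (variance control; the count and weight mass affected
#' are recorded in attribute \code{"truncation"}).
#'
#' @param expanded weighted \code{\link{expand_cohort}} table
#' @param upper_percentile percentile in (50, 100\]; 100 leaves weights
#'   unchanged
#' @return \code{expanded} with truncated weights
#' @export
truncate_weights <- function(expanded, upper_percentile = 99.5) {
  if (upper_percentile <= 50 || upper_percentile > 100)
    .stop_domain("upper_percentile must be in (50, 100]")
  w <- expanded$weight
  cap <- stats::quantile(w, upper_percentile / 100, names = FALSE, type = 7)
  hit <- w > cap
  mass_before <- sum(w)
  w[hit] <- cap
  expanded$weight <- w
  attr(expanded, "truncation") <-
    c(percentile = upper_percentile, cap = cap, n_truncated = sum(hit),
      mass_removed = mass_before - sum(w))
  expanded
}
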