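# Descriptive outputs: prevalence tables, person-years, and left-truncated
# survival by group on the age timescale.

#' Left-truncated Kaplan-Meier survival by group
#'
#' Product-limit estimator with delayed entry (risk set at age a contains
#' subjects with entry < a <= exit), via \code{survival::survfit} on
#' \code{Surv(entry, exit, event)}. Confidence intervals use the log-log
#' transform. Groups whose risk set is empty before the first event start at
#' the first age with a nonzero risk set and are flagged.
#'
#' @param cohort validated cohort
#' @param group_by grouping column names (default sex and race/ethnicity)
#' @return object of class \code{km_curves}: the \code{survfit} object plus
#'   group labels
#' @export
km_left_truncated <- function(cohort, group_by = c("sex", "race_ethnicity")) {
  d <- as.data.frame(cohort)
  d$.group <- interaction(d[group_by], drop = TRUE, sep = "/")
  ev <- tapply(d$event, d$.group, sum)
  sf <- survival::survfit(survival::Surv(entry_age, exit_age, event) ~ .group,
                          data = d, conf.type = "log-log")
  structure(list(survfit = sf, groups = levels(d$.group),
                 group_by = group_by,
                 zero_event_groups = names(ev)[ev < 1]),
            class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  cat("Left-truncated survival curves (age timescale) for",
      length(x$groups), "groups\n")
  print(median_survival_age(x))
  invisible(x)
}

#' @export
plot.km_curves <- function(x, col = seq_along(x$groups), ...) {
  graphics::plot(x$survfit, col = col, xlab = "Age (years)",
                 ylab = "Survival probability", ...)
  graphics::legend("bottomleft", legend = x$groups, col = col, lty = 1,
                   cex = 0.7)
  invisible(x)
}

#' Median survival age with confidence interval
#'
#' First age at which the survival curve drops to 0.5 or below, with log-log
#' (Greenwood) confidence limits. Curves that never cross 0.5 are reported
#' as not reached (NA).
#'
#' @param curves a \code{\link{km_left_truncated}} object
#' @return data.frame: group, median, lower, upper, reached
#' @export
median_survival_age <- function(curves) {
  stopifnot(inherits(curves, "km_curves"))
  q <- stats::quantile(curves$survfit, probs = 0.5)
  if (is.matrix(q$quantile)) {
    med <- q$quantile[, 1]; lo <- q$lower[, 1]; hi <- q$upper[, 1]
  } else {
    med <- q$quantile; lo <- q$lower; hi <- q$upper
  }
  data.frame(group = curves$groups, median = as.numeric(med),
             lower = as.numeric(lo), upper = as.numeric(hi),
             reached = !is.na(as.numeric(med)), row.names = NULL)
}

#' Unweighted prevalence and person-years table by stratum
#'
#' For each sex-by-race stratum: sample size, mean age at survey, total
#' person-years, death count and crude percentage, and the unweighted
#' percentage in every level of each lifestyle factor, education, and
#' marriage. Empty strata yield zero rows and are flagged.
#'
#' @param cohort validated cohort
#' @return long data.frame: sex, race_ethnicity, variable, level, value
#' @export
prevalence_table <- function(cohort) {
  d <- as.data.frame(cohort)
  strata <- expand.grid(sex = .sex_levels,
                        race_ethnicity = levels(d$race_ethnicity),
                        stringsAsFactors = FALSE)
  cat_vars <- c(names(.mediator_levels), "education")
  rows <- list()
  add <- function(s, r, variable, level, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      sex = s, race_ethnicity = r, variable = variable, level = level,
      value = value, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(strata))) {
    s <- strata$sex[i]; r <- strata$race_ethnicity[i]
    sub <- d[d$sex == s & d$race_ethnicity == r, , drop = FALSE]
    if (nrow(sub) == 0L) {
      add(s, r, "n", NA, 0)
      next
    }
    add(s, r, "n", NA, nrow(sub))
    add(s, r, "mean_age", NA, mean(sub$age_at_survey))
    add(s, r, "person_years", NA, sum(sub$exit_age - sub$entry_age))
    add(s, r, "deaths", NA, sum(sub$event))
    add(s, r, "deaths_pct", NA, 100 * mean(sub$event))
    add(s, r, "married_pct", NA, 100 * mean(sub$married))
    for (v in cat_vars) {
      tab <- table(sub[[v]])
      for (lev in names(tab))
        add(s, r, v, lev, 100 * tab[[lev]] / nrow(sub))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
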