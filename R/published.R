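# Published reference decomposition (NHIS 1997-2014 linked to mortality
# follow-up through 2015): additional deaths per 10,000 person-years by sex
# and race contrast, as printed at one decimal place. Used for arithmetic
# consistency checks and as a worked target shape; the microdata behind it
# are not redistributable, so these are reference values, not something the
# package recomputes.

#' Published US mortality-inequality decomposition estimates
#'
#' Reference decomposition of Black-vs-White and Hispanic-vs-White
#' differences in all-cause mortality among US adults (NHIS 1997--2014,
#' deaths through 2015), per sex, on the additive hazard scale: total,
#' direct, net indirect, and per-mediator differential-exposure /
#' differential-vulnerability components with 95\% CIs, in additional deaths
#' per 10,000 person-years, printed to one decimal.
#'
#' @return data.frame: sex, contrast, component, mediator, estimate, lower,
#'   upper
#' @export
published_decomposition <- function() {
  comp <- c("total", "direct", "net_indirect",
            rep(c("exposure", "vulnerability"), 4))
  med <- c(NA, NA, NA,
           rep(c("alcohol_category", "smoking_category", "bmi_category",
                 "activity_category"), each = 2))
  block <- function(sex, contrast, est, lo, hi)
    data.frame(sex = sex, contrast = contrast, component = comp,
               mediator = med, estimate = est, lower = lo, upper = hi,
               stringsAsFactors = FALSE)
  rbind(
    block("men", "black",
          c(21.7, 23.7, -2.0, 1.4, -2.6, -5.9, 2.2, 0.5, -1.4, 4.6, -0.7),
          c(19.9, 21.8, -4.9, 0.7, -4.2, -6.5, 0.7, -0.1, -2.9, 3.9, -2.2),
          c(23.5, 25.6, 0.8, 2.0, -1.1, -5.3, 3.8, 1.1, 0.2, 5.2, 0.8)),
    block("women", "black",
          c(11.5, 17.1, -5.6, 5.1, -4.5, -10.4, 1.0, 0.8, -3.7, 7.8, -1.7),
          c(10.1, 15.5, -7.7, 4.5, -5.7, -11.0, -0.2, 0.2, -4.9, 7.2, -2.9),
          c(12.9, 18.7, -3.4, 5.7, -3.3, -9.8, 2.2, 1.4, -2.5, 8.4, -0.5)),
    block("men", "hispanic",
          c(1.4, 5.1, -3.6, -0.4, -0.7, -12.0, 6.4, -1.9, 1.3, 6.6, -2.9),
          c(0.0, 3.6, -5.7, -1.0, -1.9, -12.6, 5.2, -2.5, 0.1, 6.0, -4.1),
          c(2.8, 6.6, -1.6, 0.2, 0.5, -11.4, 7.6, -1.2, 2.5, 7.2, -1.7)),
    block("women", "hispanic",
          c(-9.3, -8.9, -0.4, 4.9, -2.9, -17.0, 11.7, -1.4, 1.8, 7.5, -5.0),
          c(-10.5, -10.3, -2.1, 4.3, -4.0, -17.6, 10.6, -2.0, 0.7, 6.9, -6.0),
          c(-8.1, -7.5, 1.3, 5.5, -1.9, -16.4, 12.8, -0.8, 2.8, 8.1, -3.9)))
}

#' Additivity check on published decomposition values
#'
#' The decomposition satisfies total = direct + net indirect and
#' net indirect = sum of the eight per-mediator components. On values
#' printed to one decimal these identities can only hold up to accumulated
#' rounding: each printed cell carries up to 0.05 of rounding error, so a
#' sum of k cells is compared at tolerance 0.05 * (k + 1). Returns the
#' reconstruction residuals per stratum together with those tolerances.
#'
#' @param published data.frame in the layout of
#'   \code{\link{published_decomposition}}
#' @return data.frame: sex, contrast, identity, residual, tolerance, pass
#' @export
decomposition_additivity <- function(published = published_decomposition()) {
  rows <- list()
  for (key in unique(paste(published$sex, published$contrast))) {
    p <- published[paste(published$sex, published$contrast) == key, ]
    total <- p$estimate[p$component == "total"]
    direct <- p$estimate[p$component == "direct"]
    net <- p$estimate[p$component == "net_indirect"]
    parts <- p$estimate[p$component %in% c("exposure", "vulnerability")]
    res1 <- (direct + net) - total
    res2 <- sum(parts) - net
    tol1 <- 0.05 * 3          # three printed cells in the identity
    tol2 <- 0.05 * (length(parts) + 1)
    rows[[key]] <- data.frame(
      sex = p$sex[1], contrast = p$contrast[1],
      identity = c("total = direct + net_indirect",
                   "net_indirect = sum(components)"),
      residual = c(res1, res2), tolerance = c(tol1, tol2),
      pass = abs(c(res1, res2)) <= c(tol1, tol2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
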