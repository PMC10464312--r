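# Weighted constant-coefficient additive hazards (Lin-Ying-type) with
# nonparametric baseline and delayed entry on the age timescale. The
# estimating equation solved exactly (integrals decomposed over the segments
# between consecutive distinct entry/exit ages) is
#   [ sum_i w_i int Y_i(t) (Z_i - Zbar_w(t)) (Z_i - Zbar_w(t))' dt ] beta
#     = sum_i w_i int (Z_i - Zbar_w(t)) dN_i(t)
# with Y_i(t) = 1 on (entry_i, exit_i] and Zbar_w the weighted risk-set mean.
# Simultaneous entry/event ties are events-first (a subject entering at t is
# not yet at risk at t); exact ties among event ages aggregate.

#' Construct a survival design
#'
#' The design carries the at-risk intervals (half-open \code{(entry, exit]}),
#' event indicators, a named design matrix, case weights and cluster ids
#' (subjects, for replicate data).
#'
#' @param entry,exit entry and exit ages; \code{exit > entry}
#' @param event 0/1 event indicator at \code{exit}
#' @param Z numeric design matrix with column names
#' @param weights positive case weights (default 1)
#' @param cluster cluster identifiers (default one per row)
#' @return list of class \code{survival_design}
#' @export
survival_design <- function(entry, exit, event, Z, weights = NULL,
                            cluster = NULL) {
  Z <- as.matrix(Z)
  n <- length(entry)
  stopifnot(length(exit) == n, length(event) == n, nrow(Z) == n,
            !is.null(colnames(Z)))
  if (any(exit <= entry)) .stop_domain("exit must exceed entry for every row")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) .stop_domain("weights must be positive")
  if (is.null(cluster)) cluster <- seq_len(n)
  structure(list(entry = as.numeric(entry), exit = as.numeric(exit),
                 event = as.integer(event), Z = Z,
                 weights = as.numeric(weights), cluster = cluster),
            class = "survival_design")
}

# Shared segment decomposition. Returns breakpoints, per-row segment spans,
# and weighted risk-set sums S0 (scalar) and S1 (p-vector) per segment.
.ly_segments <- function(design) {
  entry <- design$entry; exit <- design$exit
  w <- design$weights; Z <- design$Z
  bt <- sort(unique(c(entry, exit)))
  K <- length(bt)
  ei <- match(entry, bt)
  xi <- match(exit, bt)
  nseg <- K - 1L
  delta <- bt[-1] - bt[-K]
  # difference arrays: row i at risk on segments ei..(xi-1)
  d0 <- numeric(K)
  add0 <- rowsum(c(w, -w), c(ei, xi))
  d0[as.integer(rownames(add0))] <- add0
  S0 <- cumsum(d0)[seq_len(nseg)]
  wz <- Z * w
  d1 <- matrix(0, K, ncol(Z))
  add1 <- rowsum(rbind(wz, -wz), c(ei, xi))
  d1[as.integer(rownames(add1)), ] <- add1
  S1 <- apply(d1, 2, cumsum)[seq_len(nseg), , drop = FALSE]
  list(bt = bt, ei = ei, xi = xi, nseg = nseg, delta = delta,
       S0 = S0, S1 = S1)
}

.ly_system <- function(design, seg) {
  w <- design$weights; Z <- design$Z
  dur <- design$exit - design$entry
  A1 <- crossprod(Z * sqrt(w * dur))
  fac <- ifelse(seg$S0 > 0, seg$delta / seg$S0, 0)
  A2 <- crossprod(seg$S1 * sqrt(fac))
  A <- A1 - A2
  ev <- design$event == 1L
  es <- seg$xi[ev] - 1L                     # risk segment ending at event age
  Zbar_e <- seg$S1[es, , drop = FALSE] / seg$S0[es]
  b <- colSums((design$Z[ev, , drop = FALSE] - Zbar_e) * w[ev])
  list(A = A, b = b)
}

#' Fit a weighted Lin-Ying additive hazards model from a design
#'
#' Low-level engine behind \code{\link{lin_ying}}; see there for the model.
#'
#' @param design a \code{\link{survival_design}}
#' @param se compute the cluster-sandwich covariance (default TRUE)
#' @param baseline compute the baseline cumulative hazard and the
#'   negative-fitted-hazard diagnostic (default FALSE)
#' @return object of class \code{lin_ying}
#' @export
fit_additive_hazard <- function(design, se = TRUE, baseline = FALSE) {
  stopifnot(inherits(design, "survival_design"))
  if (sum(design$event) < 1L) .stop_domain("no events in the design")
  seg <- .ly_segments(design)
  sys <- .ly_system(design, seg)
  p <- ncol(design$Z)
  qa <- qr(sys$A)
  if (qa$rank < p) {
    bad <- colnames(design$Z)[qa$pivot[(qa$rank + 1):p]]
    .stop_domain("integrated design matrix is singular; collinear column(s): ",
                 paste(bad, collapse = ", "))
  }
  beta <- solve(qa, sys$b)
  names(beta) <- colnames(design$Z)
  fit <- structure(list(coefficients = beta, A = sys$A,
                        n = length(unique(design$cluster)),
                        n_rows = length(design$entry),
                        n_events = sum(design$event),
                        person_years = sum(design$weights *
                                             (design$exit - design$entry)),
                        vcov = NULL, naive_vcov = NULL, baseline = NULL,
                        frac_negative_hazard = NA_real_),
                   class = "lin_ying")
  if (se) fit$vcov <- cluster_sandwich_vcov(fit, design, seg = seg)
  if (baseline) {
    bl <- estimate_baseline(fit, design, seg = seg)
    fit$baseline <- bl
    fit$frac_negative_hazard <- attr(bl, "frac_negative_hazard")
  }
  fit
}

#' Lin-Ying additive hazards regression
#'
#' Fits the semiparametric additive hazards model
#' \eqn{\lambda(t | Z) = \lambda_0(t) + Z' \beta} with constant (time
#' invariant) coefficients, nonparametric baseline, delayed entry and case
#' weights, by solving the weighted least-squares estimating equation exactly
#' (integrals decomposed over consecutive distinct entry/exit ages).
#' Coefficients are hazard differences in events per person-year (per unit of
#' the time variable). Standard errors are cluster-robust sandwich estimates
#' with martingale-increment scores summed within cluster.
#'
#' @param formula \code{survival::Surv(entry, exit, event) ~ covariates}
#' @param data data.frame
#' @param weights optional positive case weights
#' @param cluster optional cluster identifier (a column name or vector);
#'   defaults to independent rows
#' @param se,baseline see \code{\link{fit_additive_hazard}}
#' @return object of class \code{lin_ying} with \code{coef}, \code{vcov},
#'   \code{confint}, \code{summary}, \code{predict} and \code{residuals}
#'   methods
#' @examples
#' d <- data.frame(entry = rep(0, 80), exit = rexp(80, 0.1) + 0.01,
#'                 event = 1, grp = rep(0:1, 40))
#' lin_ying(survival::Surv(entry, exit, event) ~ grp, d)
#' @export
lin_ying <- function(formula, data, weights = NULL, cluster = NULL,
                     se = TRUE, baseline = FALSE) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv") || attr(y, "type") != "counting")
    .stop_domain("left-hand side must be survival::Surv(entry, exit, event)")
  Z <- stats::model.matrix(stats::terms(formula), mf)
  Z <- Z[, colnames(Z) != "(Intercept)", drop = FALSE]
  if (is.character(cluster) && length(cluster) == 1L)
    cluster <- data[[cluster]]
  design <- survival_design(y[, 1], y[, 2], y[, 3], Z,
                            weights = weights, cluster = cluster)
  fit <- fit_additive_hazard(design, se = se, baseline = baseline)
  fit$call <- match.call()
  fit$design <- design
  fit
}

#' Baseline cumulative hazard of a Lin-Ying fit
#'
#' Aalen-Breslow-type estimator: at each event age the baseline jumps by the
#' weighted event mass over the weighted risk set, and between event ages it
#' drifts by \eqn{-\bar Z_w(t)' \hat\beta \, dt}. With \eqn{\hat\beta = 0}
#' and unit weights this is the Nelson-Aalen estimator.
#'
#' @param fit a \code{lin_ying} fit
#' @param design the \code{\link{survival_design}} it was fitted to (taken
#'   from the fit if present)
#' @param seg internal segment cache
#' @return data.frame \code{(time, cumhaz)} evaluated at the segment
#'   breakpoints; attribute \code{"frac_negative_hazard"} reports the
#'   person-time fraction with negative fitted total hazard
#' @export
estimate_baseline <- function(fit, design = fit$design, seg = NULL) {
  if (is.null(design)) .stop_domain("design not stored; pass it explicitly")
  if (is.null(seg)) seg <- .ly_segments(design)
  beta <- fit$coefficients
  ev <- design$event == 1L
  es <- seg$xi[ev] - 1L
  jump <- numeric(seg$nseg)   # event mass at the END of each segment
  jp <- rowsum(design$weights[ev] / seg$S0[es], es)
  jump[as.integer(rownames(jp))] <- jp
  zbar_beta <- as.numeric(seg$S1 %*% beta) / ifelse(seg$S0 > 0, seg$S0, Inf)
  drift <- -zbar_beta * seg$delta
  cumhaz <- cumsum(jump + drift)
  out <- data.frame(time = seg$bt, cumhaz = c(0, cumhaz))
  # diagnostic: fraction of person-time where lambda0 + Z'beta < 0,
  # on a row subsample when the full n x segment grid would be large
  dl0 <- ifelse(seg$delta > 0, (jump + drift) / seg$delta, 0)
  zb <- as.numeric(design$Z %*% beta)
  n <- length(zb)
  rows <- if (n * seg$nseg > 4e6) sort(sample.int(n, ceiling(4e6 / seg$nseg)))
          else seq_len(n)
  rowhaz <- outer(zb[rows], dl0, "+")
  atrisk <- outer(seg$ei[rows], seq_len(seg$nseg), "<=") &
    outer(seg$xi[rows], seq_len(seg$nseg), ">")
  dur <- matrix(seg$delta, length(rows), seg$nseg, byrow = TRUE)
  neg_time <- sum(dur[atrisk & rowhaz < 0])
  attr(out, "frac_negative_hazard") <-
    neg_time / sum(design$exit[rows] - design$entry[rows])
  out
}

#' Cluster-sandwich covariance of a Lin-Ying fit
#'
#' Sandwich variance \eqn{A^{-1} (\sum_c U_c U_c') A^{-1}} where the
#' martingale-increment score contributions
#' \eqn{U_i = w_i \int (Z_i - \bar Z_w(t)) \{dN_i(t) - Y_i(t) (Z_i'\hat\beta
#' \, dt + d\hat\Lambda_0(t))\}} are summed within cluster before the outer
#' product. Scores sum to zero at the solution.
#'
#' @inheritParams estimate_baseline
#' @return covariance matrix of the coefficients
#' @export
cluster_sandwich_vcov <- function(fit, design = fit$design, seg = NULL) {
  if (is.null(design)) .stop_domain("design not stored; pass it explicitly")
  if (length(unique(design$cluster)) < 2L)
    .stop_domain("sandwich variance needs at least two clusters")
  if (is.null(seg)) seg <- .ly_segments(design)
  beta <- fit$coefficients
  w <- design$weights; Z <- design$Z
  ev <- design$event == 1L
  es <- seg$xi - 1L                       # segment ending at each row's exit
  S0 <- seg$S0
  Zbar <- seg$S1 / ifelse(S0 > 0, S0, Inf)
  jump <- numeric(seg$nseg)
  jp <- rowsum(w[ev] / S0[es[ev]], es[ev])
  jump[as.integer(rownames(jp))] <- jp

  # per-segment cumulative quantities, indexed so that range sums over a
  # row's risk segments ei..(xi-1) are cum[xi-1] - cum[ei-1]
  pad <- function(x) rbind(0, x)
  cumQ <- pad(apply(Zbar * seg$delta, 2, cumsum))        # int Zbar dt
  cumJ <- c(0, cumsum(jump))                             # int dLambda0
  cumJZ <- pad(apply(Zbar * jump, 2, cumsum))            # int Zbar dLambda0

  zb <- as.numeric(Z %*% beta)
  dur <- design$exit - design$entry
  intZbar <- cumQ[seg$xi, , drop = FALSE] - cumQ[seg$ei, , drop = FALSE]
  lam0rng <- cumJ[seg$xi] - cumJ[seg$ei]
  intZbarJ <- cumJZ[seg$xi, , drop = FALSE] - cumJZ[seg$ei, , drop = FALSE]

  U <- -(Z * (zb * dur) - intZbar * zb) - (Z * lam0rng - intZbarJ)
  U[ev, ] <- U[ev, , drop = FALSE] +
    (Z[ev, , drop = FALSE] - Zbar[es[ev], , drop = FALSE])
  U <- U * w
  Uc <- rowsum(U, design$cluster)
  Ainv <- solve(fit$A)
  V <- Ainv %*% crossprod(Uc) %*% Ainv
  dimnames(V) <- list(names(beta), names(beta))
  V
}

#' Brute-force solution of the additive-hazard estimating equation
#'
#' Independent oracle for \code{\link{fit_additive_hazard}}: enumerates risk
#' intervals and event times explicitly with elementwise loops and solves the
#' resulting linear system directly. Restricted to small designs.
#'
#' @param design a \code{\link{survival_design}} with at most 50 rows
#' @return coefficient vector
#' @export
brute_force_estimating_equation <- function(design) {
  stopifnot(inherits(design, "survival_design"))
  n <- length(design$entry)
  if (n > 50) .stop_domain("brute-force oracle is restricted to <= 50 rows")
  entry <- design$entry; exit <- design$exit
  w <- design$weights; Z <- design$Z; p <- ncol(Z)
  times <- sort(unique(c(entry, exit)))
  A <- matrix(0, p, p)
  b <- numeric(p)
  zbar_at <- function(t_left, t_right) {
    # risk set constant on (t_left, t_right]
    at <- which(entry <= t_left & exit >= t_right)
    if (!length(at)) return(NULL)
    sw <- sum(w[at])
    zb <- numeric(p)
    for (i in at) zb <- zb + w[i] * Z[i, ]
    list(at = at, zbar = zb / sw)
  }
  for (s in seq_len(length(times) - 1)) {
    rs <- zbar_at(times[s], times[s + 1])
    if (is.null(rs)) next
    dt <- times[s + 1] - times[s]
    for (i in rs$at) {
      zc <- Z[i, ] - rs$zbar
      A <- A + w[i] * (zc %o% zc) * dt
    }
    # events at the right end of this segment
    evs <- which(design$event == 1L & exit == times[s + 1])
    for (i in evs) b <- b + w[i] * (Z[i, ] - rs$zbar)
  }
  beta <- solve(A, b)
  names(beta) <- colnames(Z)
  beta
}

#' @export
coef.lin_ying <- function(object, ...) object$coefficients

#' @export
vcov.lin_ying <- function(object, ...) object$vcov

#' @export
confint.lin_ying <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(object$vcov)) .stop_domain("fit has no covariance; refit with se = TRUE")
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.lin_ying <- function(x, digits = 4, ...) {
  cat("Lin-Ying additive hazards fit:", x$n, "clusters,", x$n_rows, "rows,",
      x$n_events, "events,", format(round(x$person_years), big.mark = ","),
      "weighted person-years\n")
  cat("Hazard differences (per person-year):\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.lin_ying <- function(object, scale = 1, ...) {
  est <- object$coefficients * scale
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) * scale else NA
  tab <- data.frame(estimate = est, se = se,
                    lower = est - 1.96 * se, upper = est + 1.96 * se,
                    z = est / se,
                    p = 2 * stats::pnorm(-abs(est / se)))
  structure(list(table = tab, scale = scale, n_events = object$n_events,
                 person_years = object$person_years,
                 frac_negative_hazard = object$frac_negative_hazard),
            class = "summary.lin_ying")
}

#' @export
print.summary.lin_ying <- function(x, ...) {
  cat("Hazard differences (x", x$scale, "person-years):\n")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
residuals.lin_ying <- function(object, ...) {
  if (is.null(object$design))
    .stop_domain("design not stored; refit via lin_ying()")
  design <- object$design
  seg <- .ly_segments(design)
  # per-row score residuals, same construction as the sandwich
  beta <- object$coefficients
  w <- design$weights; Z <- design$Z
  ev <- design$event == 1L
  es <- seg$xi - 1L
  Zbar <- seg$S1 / ifelse(seg$S0 > 0, seg$S0, Inf)
  jump <- numeric(seg$nseg)
  jp <- rowsum(w[ev] / seg$S0[es[ev]], es[ev])
  jump[as.integer(rownames(jp))] <- jp
  pad <- function(x) rbind(0, x)
  cumQ <- pad(apply(Zbar * seg$delta, 2, cumsum))
  cumJ <- c(0, cumsum(jump))
  cumJZ <- pad(apply(Zbar * jump, 2, cumsum))
  zb <- as.numeric(Z %*% beta)
  dur <- design$exit - design$entry
  intZbar <- cumQ[seg$xi, , drop = FALSE] - cumQ[seg$ei, , drop = FALSE]
  lam0rng <- cumJ[seg$xi] - cumJ[seg$ei]
  intZbarJ <- cumJZ[seg$xi, , drop = FALSE] - cumJZ[seg$ei, , drop = FALSE]
  U <- -(Z * (zb * dur) - intZbar * zb) - (Z * lam0rng - intZbarJ)
  U[ev, ] <- U[ev, , drop = FALSE] +
    (Z[ev, , drop = FALSE] - Zbar[es[ev], , drop = FALSE])
  U * w
}

#' @export
predict.lin_ying <- function(object, newdata = NULL, times = NULL,
                             type = c("cumhaz", "survival"), ...) {
  type <- match.arg(type)
  if (is.null(object$baseline))
    object$baseline <- estimate_baseline(object)
  bl <- object$baseline
  if (is.null(times)) times <- bl$time
  l0 <- stats::approx(bl$time, bl$cumhaz, xout = times, rule = 2)$y
  if (is.null(newdata)) {
    ch <- l0
  } else {
    Z <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
    zb <- as.numeric(Z %*% object$coefficients)
    ch <- outer(zb, times - bl$time[1]) + rep(l0, each = nrow(Z))
  }
  if (type == "cumhaz") ch else exp(-ch)
}
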