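test_that("solver matches the brute-force oracle on random small designs", {
  set.seed(61)
  for (i in 1:30) {
    d <- random_design()
    expect_equal(coef(fit_additive_hazard(d, se = FALSE)),
                 brute_force_estimating_equation(d), tolerance = 1e-10)
  }
})

test_that("smallest nondegenerate design solves exactly and singularities are named", {
  d <- survival_design(entry = c(0, 0), exit = c(1, 2), event = c(1, 0),
                       Z = cbind(z = c(1, 0)))
  expect_equal(coef(fit_additive_hazard(d, se = FALSE)),
               brute_force_estimating_equation(d), tolerance = 1e-12)
  dz <- survival_design(entry = c(0, 0), exit = c(1, 2), event = c(1, 1),
                        Z = cbind(z = c(1, 1), zero = c(0, 0)))
  expect_error(fit_additive_hazard(dz, se = FALSE), "collinear.*zero")
  d0 <- survival_design(entry = c(0, 0), exit = c(1, 2), event = c(0, 0),
                        Z = cbind(z = c(1, 0)))
  expect_error(fit_additive_hazard(d0, se = FALSE), "no events")
})

test_that("estimates are invariant to weight scaling and equivariant to recoding", {
  set.seed(67)
  d <- random_design(n = 40, p = 2)
  b <- coef(fit_additive_hazard(d, se = FALSE))
  d2 <- d; d2$weights <- 2 * d$weights
  expect_equal(coef(fit_additive_hazard(d2, se = FALSE)), b,
               tolerance = 1e-12)
  d3 <- d; d3$Z[, 1] <- 3 * d$Z[, 1] + 5
  b3 <- coef(fit_additive_hazard(d3, se = FALSE))
  expect_equal(unname(b3[1]), unname(b[1]) / 3, tolerance = 1e-10)
  expect_equal(unname(b3[2]), unname(b[2]), tolerance = 1e-10)
})

test_that("baseline reduces to the delayed-entry Nelson-Aalen when beta is 0", {
  set.seed(71)
  n <- 300
  entry <- stats::runif(n, 0, 1)
  exit <- entry + stats::rexp(n, 0.3)
  event <- stats::rbinom(n, 1, 0.8)
  d <- survival_design(entry, exit, event, cbind(z = stats::rnorm(n)))
  fit <- fit_additive_hazard(d, se = FALSE)
  fit$coefficients[] <- 0
  bl <- estimate_baseline(fit, d)
  sf <- survival::survfit(survival::Surv(entry, exit, event) ~ 1,
                          data.frame(entry, exit, event), ctype = 1)
  na <- cumsum(sf$n.event / sf$n.risk)
  at <- match(sf$time[sf$n.event > 0], bl$time)
  expect_equal(bl$cumhaz[at], na[sf$n.event > 0], tolerance = 1e-12)
})

test_that("baseline slope recovers a constant hazard", {
  set.seed(73)
  n <- 5000
  lam <- 0.05
  exit <- stats::rexp(n, lam)
  d <- survival_design(rep(0, n), exit, rep(1L, n),
                       cbind(z = stats::rbinom(n, 1, 0.5) - 0.5))
  fit <- fit_additive_hazard(d, se = FALSE, baseline = TRUE)
  bl <- fit$baseline
  t90 <- stats::quantile(exit, 0.9)
  slope <- bl$cumhaz[which.min(abs(bl$time - t90))] / t90
  expect_lt(abs(slope - lam), 3 * lam / sqrt(n) * 2)
})

test_that("two-group constant-hazard fit matches the Nelson-Aalen slope reading", {
  set.seed(79)
  n <- 20000
  lam0 <- 0.03; b <- 0.01
  g <- rep(0:1, each = n / 2)
  tt <- stats::rexp(n, lam0 + b * g)
  ex <- pmin(tt, 30)
  ev <- as.integer(tt <= 30)
  d <- survival_design(rep(0, n), pmax(ex, 1e-9), ev, cbind(grp = g))
  fit <- fit_additive_hazard(d)
  se <- sqrt(fit$vcov["grp", "grp"])
  expect_lt(abs(coef(fit)[["grp"]] - b), 3 * se)
  # least-squares slope of the Nelson-Aalen difference against age
  naslope <- function(gg) {
    sf <- survival::survfit(survival::Surv(ex, ev) ~ 1,
                            subset = g == gg,
                            data = data.frame(ex, ev, g), ctype = 1)
    stats::approxfun(sf$time, cumsum(sf$n.event / sf$n.risk), rule = 2)
  }
  grid <- seq(1, 25, by = 1)
  dna <- naslope(1)(grid) - naslope(0)(grid)
  ls_slope <- sum(grid * dna) / sum(grid^2)
  expect_lt(abs(ls_slope - b), 3 * se * 2)
})

test_that("left truncation keeps late entrants out of early risk sets", {
  # a late-entering censored subject must not change the early baseline
  base <- data.frame(entry = c(0, 0, 0), exit = c(2, 3, 4),
                     event = c(1, 1, 0), z = c(1, 0, 1))
  extra <- rbind(base, data.frame(entry = 3.5, exit = 6, event = 0, z = 1))
  f1 <- lin_ying(survival::Surv(entry, exit, event) ~ z, base, se = FALSE)
  f2 <- lin_ying(survival::Surv(entry, exit, event) ~ z, extra, se = FALSE)
  b1 <- estimate_baseline(f1)
  b2 <- estimate_baseline(f2)
  expect_equal(b1$cumhaz[b1$time <= 3], b2$cumhaz[b2$time <= 3],
               tolerance = 1e-12)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("cluster sandwich honors replicate weighting and sums scores to zero", {
  set.seed(83)
  n <- 80
  d <- random_design(n = n, p = 2)
  d$cluster <- seq_len(n)
  f1 <- fit_additive_hazard(d)
  dd <- survival_design(rep(d$entry, 2), rep(d$exit, 2), rep(d$event, 2),
                        rbind(d$Z, d$Z), weights = rep(d$weights / 2, 2),
                        cluster = rep(seq_len(n), 2))
  f2 <- fit_additive_hazard(dd)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-8)
  df <- data.frame(entry = d$entry, exit = d$exit, event = d$event,
                   z1 = d$Z[, 1], z2 = d$Z[, 2])
  fit <- lin_ying(survival::Surv(entry, exit, event) ~ z1 + z2, df,
                  weights = d$weights)
  expect_lt(max(abs(colSums(residuals(fit)))), 1e-10)
  d1 <- d; d1$cluster <- rep(1, n)
  expect_error(cluster_sandwich_vcov(f1, d1), "two clusters")
})

test_that("sandwich confidence intervals attain near-nominal coverage", {
  set.seed(89)
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    n <- 1500
    g <- stats::rbinom(n, 1, 0.5)
    tt <- stats::rexp(n, 0.02 + 0.01 * g)
    ev <- as.integer(tt <= 10)
    f <- fit_additive_hazard(survival_design(
      rep(0, n), pmax(pmin(tt, 10), 1e-9), ev, cbind(grp = g)))
    se <- sqrt(f$vcov[1, 1])
    hits <- hits + (abs(coef(f)[["grp"]] - 0.01) <= 1.96 * se)
  }
  expect_gte(hits / reps, 0.90)
  expect_lte(hits / reps, 0.99)
})

test_that("formula interface, methods and negative-hazard diagnostic work", {
  set.seed(97)
  n <- 400
  df <- data.frame(entry = rep(0, n), exit = stats::rexp(n, 0.1) + 1e-3,
                   event = stats::rbinom(n, 1, 0.8),
                   z = stats::rnorm(n))
  df$event[1] <- 1L
  fit <- lin_ying(survival::Surv(entry, exit, event) ~ z, df,
                  baseline = TRUE)
  expect_s3_class(fit, "lin_ying")
  expect_named(coef(fit), "z")
  expect_true(all(dim(vcov(fit)) == c(1, 1)))
  ci <- confint(fit)
  expect_lt(ci[1, 1], coef(fit))
  expect_gt(ci[1, 2], coef(fit))
  expect_false(is.na(fit$frac_negative_hazard))
  s <- summary(fit, scale = 1e4)
  expect_true(is.finite(s$table$p[1]))
  surv <- predict(fit, newdata = data.frame(z = 0), times = c(1, 5),
                  type = "survival")
  expect_true(all(surv <= 1 & surv > 0))
  expect_output(print(fit), "additive hazards")
  expect_error(lin_ying(survival::Surv(exit, event) ~ z, df), "entry")
})

test_that("brute-force oracle refuses designs over 50 rows", {
  set.seed(101)
  d <- random_design(n = 51, p = 1)
  expect_error(brute_force_estimating_equation(d), "50 rows")
})
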