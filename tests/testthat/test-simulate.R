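test_that("generation is deterministic given the seed", {
  p <- test_params()
  a <- generate_cohort(p, 500, seed = 7)
  b <- generate_cohort(p, 500, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(p, 500, seed = 8)
  expect_false(identical(a$exit_age, c2$exit_age))
})

test_that("piecewise event-age sampling inverts the cumulative hazard", {
  # constant rate: closed-form exponential
  u <- c(0.3, 0.7, 0.05)
  got <- sample_event_age(rep(1, 3), breaks = c(0, 200), rates = 0.1, u = u)
  expect_equal(got, 1 - log(u) / 0.1)
  # zero hazard: always censored
  expect_identical(sample_event_age(0.5, c(0, 10), 0, u = 0.4), Inf)
  # two-piece hazard crossing the breakpoint, hand inversion:
  # H jumps 0.5 over (0,1] at rate .5, then rate 2: E = 1.2 -> t = 1 + 0.7/2
  u <- exp(-1.2)
  expect_equal(sample_event_age(0, c(0, 1, 5), c(0.5, 2), u), 1.35)
  expect_error(sample_event_age(0, c(0, 1), -0.1, 0.5), "nonnegative")
})

test_that("with no mediator or covariate effects the group hazard difference equals beta", {
  p <- test_params()
  p$gamma <- lapply(p$gamma, function(v) v * 0)
  p$delta <- lapply(p$delta, function(l) lapply(l, function(v) v * 0))
  p$covariate_hazard[] <- 0
  b <- 0.004
  p$beta_direct <- c(black = b, hispanic = 0)
  p$baseline <- lapply(p$baseline, function(x) rep(0.01, length(x)))
  co <- generate_cohort(p, 60000, seed = 31)
  py <- tapply(co$exit_age - co$entry_age, co$race_ethnicity, sum)
  dth <- tapply(co$event, co$race_ethnicity, sum)
  diff <- dth[["black"]] / py[["black"]] - dth[["white"]] / py[["white"]]
  se <- sqrt(dth[["black"]] / py[["black"]]^2 + dth[["white"]] / py[["white"]]^2)
  expect_lt(abs(diff - b), 3 * se)
})

test_that("constant-hazard durations follow the censored exponential law", {
  p <- test_params()
  lam <- 0.05
  p$baseline <- list(men = rep(lam, 82), women = rep(lam, 82))
  p$gamma <- lapply(p$gamma, function(v) v * 0)
  p$delta <- lapply(p$delta, function(l) lapply(l, function(v) v * 0))
  p$beta_direct <- c(black = 0, hispanic = 0)
  p$covariate_hazard[] <- 0
  p$year_range <- c(1997, 1997)          # common 19-year admin window
  p$age_mean <- c(white = 30, black = 30, hispanic = 30)
  p$age_sd <- 1e-9
  p$age_bounds <- c(30, 30.0001)
  co <- generate_cohort(p, 10000, seed = 8)
  cens <- 2016 - 1997
  dur <- co$exit_age - co$entry_age
  expect_lte(max(dur), cens + 1e-3)
  evd <- dur[co$event == 1]
  ks <- stats::ks.test(evd, function(t)
    (1 - exp(-lam * t)) / (1 - exp(-lam * cens)))
  expect_gt(ks$p.value, 0.01)
})

test_that("excessive hazard clipping aborts generation", {
  p <- test_params()
  p$covariate_hazard["married"] <- -0.05  # dominates the youngest baseline
  expect_error(generate_cohort(p, 2000, seed = 1), "clipping")
})

test_that("closed-form truth obeys its structural nulls and additivity", {
  tr <- true_decomposition(null_exposure_params(), "closed_form",
                           mc_size = 2e4, seed = 3)
  expect_true(all(tr$truth[tr$component == "exposure"] == 0))
  tr2 <- true_decomposition(null_vulnerability_params(), "closed_form",
                            mc_size = 2e4, seed = 3)
  expect_true(all(tr2$truth[tr2$component == "vulnerability"] == 0))
  # additivity is exact in closed form
  for (tt in list(tr, tr2)) {
    for (key in unique(paste(tt$sex, tt$contrast))) {
      p <- tt[paste(tt$sex, tt$contrast) == key, ]
      expect_equal(p$truth[p$component == "total"],
                   p$truth[p$component == "direct"] +
                     sum(p$truth[p$component %in% c("exposure",
                                                    "vulnerability")]),
                   tolerance = 1e-12)
      expect_equal(p$truth[p$component == "net_indirect"],
                   sum(p$truth[p$component %in% c("exposure",
                                                  "vulnerability")]),
                   tolerance = 1e-12)
    }
  }
})

test_that("truth is invariant to the baseline hazard", {
  p <- test_params()
  a <- true_decomposition(p, "closed_form", mc_size = 1e4, seed = 5)
  p$baseline <- lapply(p$baseline, function(x) x * 3 + 0.001)
  b <- true_decomposition(p, "closed_form", mc_size = 1e4, seed = 5)
  expect_identical(a$truth, b$truth)
})

test_that("closed-form and Monte-Carlo truths agree within 3 MC SE", {
  p <- test_params()
  cf <- true_decomposition(p, "closed_form", mc_size = 1e5, seed = 11)
  mc <- true_decomposition(p, "monte_carlo", mc_size = 4e4, seed = 12)
  m <- match(paste(cf$sex, cf$contrast, cf$component, cf$mediator),
             paste(mc$sex, mc$contrast, mc$component, mc$mediator))
  se <- sqrt(cf$mc_se^2 + mc$mc_se[m]^2)
  expect_true(all(abs(cf$truth - mc$truth[m]) <= 3 * se + 1e-12))
  expect_warning(true_decomposition(p, "monte_carlo", mc_size = 5000),
                 "noisy")
})

test_that("person-years and deaths scale roughly linearly with n", {
  p <- test_params()
  a <- generate_cohort(p, 2000, seed = 13)
  b <- generate_cohort(p, 8000, seed = 14)
  ratio_py <- sum(b$exit_age - b$entry_age) / sum(a$exit_age - a$entry_age)
  ratio_d <- sum(b$event) / sum(a$event)
  expect_lt(abs(ratio_py - 4), 0.4)
  expect_lt(abs(ratio_d - 4), 0.8)
})
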