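test_that("MSM design has the documented column structure", {
  co <- generate_cohort(test_params(), 600, seed = 103)
  men <- co[co$sex == "men", ]
  men$race_ethnicity <- droplevels(men$race_ethnicity)
  ex <- expand_cohort(men)
  ex$weight <- 1
  des <- build_msm_design(ex, "full")
  expect_equal(ncol(des$Z), 13)   # 1 + 4 + 4 + 2 + 1 + 1
  expect_true(all(c("race_black", "rstar_smoking_category_black",
                    "race_black_x_rstar_smoking_category_black",
                    "edu_medium", "edu_high", "married", "year_c") %in%
                    colnames(des$Z)))
  des2 <- build_msm_design(ex, "no_education")
  expect_equal(ncol(des2$Z), 11)
  expect_false(any(grepl("edu", colnames(des2$Z))))
})

test_that("decomposition additivity holds exactly and mediator order is immaterial", {
  co <- generate_cohort(test_params(), 4000, seed = 107)
  fit <- medhaz(co, sexes = "men", B = 0, seed = 1)
  r <- fit$results
  total <- r$estimate[r$component == "total"]
  direct <- r$estimate[r$component == "direct"]
  net <- r$estimate[r$component == "net_indirect"]
  parts <- r$estimate[r$component %in% c("exposure", "vulnerability")]
  expect_equal(total, direct + net, tolerance = 1e-10)
  expect_equal(net, sum(parts), tolerance = 1e-10)

  perm <- rev(unname(medhaz:::.mediator_columns))
  fit2 <- medhaz(co, sexes = "men", mediators = perm, B = 0, seed = 1)
  r2 <- fit2$results
  m <- match(paste(r$component, r$mediator), paste(r2$component, r2$mediator))
  expect_equal(r$estimate, r2$estimate[m], tolerance = 1e-8)
})

test_that("the education-free sensitivity analysis changes only estimates", {
  co <- generate_cohort(test_params(), 3000, seed = 109)
  full <- medhaz(co, sexes = "women", B = 0, seed = 1)
  noed <- medhaz(co, sexes = "women", covariate_set = "no_education",
                 B = 0, seed = 1)
  expect_equal(noed$metadata$covariate_set, "no_education")
  expect_setequal(paste(noed$results$component, noed$results$mediator),
                  paste(full$results$component, full$results$mediator))
  expect_false(all(noed$results$estimate == full$results$estimate))
})

test_that("bootstrap intervals are deterministic and bracket the point estimate", {
  co <- generate_cohort(test_params(), 5000, seed = 113)
  f1 <- medhaz(co, sexes = "men", B = 50, seed = 99)
  f2 <- medhaz(co, sexes = "men", B = 50, seed = 99)
  expect_identical(f1$results, f2$results)
  expect_true(all(f1$results$lower <= f1$results$estimate + 1e-9))
  expect_true(all(f1$results$upper >= f1$results$estimate - 1e-9))
  f3 <- medhaz(co, sexes = "men", B = 50, seed = 100)
  expect_false(identical(f1$results$lower, f3$results$lower))
})

test_that("metadata captures run conditions and the marginal-total diagnostic", {
  co <- generate_cohort(test_params(), 6000, seed = 127)
  fit <- medhaz(co, B = 0, seed = 5, truncate_percentile = 98)
  expect_equal(fit$metadata$truncate_percentile, 98)
  st <- fit$metadata$strata
  expect_setequal(names(st), c("men.black", "women.black"))
  for (k in names(st)) {
    expect_gt(st[[k]]$n, 0)
    expect_true(is.finite(st[[k]]$marginal_total))
    expect_true(st[[k]]$weight_diagnostics[["ess"]] > 0)
  }
  expect_error(medhaz(co, contrasts = "hispanic"), "absent")
})

test_that("print, coef, confint, report_table and plot methods run", {
  co <- generate_cohort(test_params(), 2500, seed = 131)
  fit <- medhaz(co, sexes = "men", B = 0, seed = 1)
  expect_output(print(fit), "per 10,000 person-years")
  expect_output(summary(fit), "Strata")
  cf <- coef(fit)
  expect_equal(nrow(cf), 11)
  ci <- confint(fit)
  expect_true(all(c("lower", "upper") %in% names(ci)))
  tab <- report_table(fit)
  expect_equal(rownames(tab)[1:3],
               c("Total effect", "'Direct' effect", "Net indirect effect"))
  expect_match(tab[1, 1], "^-?[0-9]+\\.[0-9] \\(")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
  # one-decimal formatting rounds half away from zero
  expect_equal(medhaz:::round_half_away(1.45, 1), 1.5)
  expect_equal(medhaz:::round_half_away(-1.45, 1), -1.5)
})

test_that("simulation study reports recovery metrics reproducibly", {
  p <- test_params()
  s1 <- simulation_study(p, n_reps = 2, n = 2500, seed = 7, sexes = "men")
  s2 <- simulation_study(p, n_reps = 2, n = 2500, seed = 7, sexes = "men")
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(is.finite(s1$bias)))
  expect_true(all(is.finite(s1$rmse)))
  expect_equal(nrow(s1), 11)
})
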