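test_that("expansion yields the Cartesian replicate structure", {
  co <- validate_cohort(toy_cohort_df(3))
  ex <- expand_cohort(co, c("white", "black"))
  expect_equal(nrow(ex), 3 * 2^4)
  expect_equal(sum(ex$identity_replicate), 3)  # exactly once per subject
  co2 <- validate_cohort(toy_cohort_df(2))
  ex3 <- expand_cohort(co2, c("white", "black", "hispanic"))
  expect_equal(nrow(ex3), 2 * 3^4)
  expect_equal(sum(ex3$identity_replicate), 2)
  # per-subject identity replicate matches the observed exposure everywhere
  idr <- ex[ex$identity_replicate, ]
  for (m in attr(ex, "mediators"))
    expect_equal(as.character(idr[[paste0("rstar_", m)]]),
                 as.character(idr$race_ethnicity))
  expect_error(expand_cohort(co, c("white", "black"),
                             mediators = c("alcohol_category", "nope")),
               "absent")
})

test_that("identity replicates carry weight exactly 1", {
  co <- generate_cohort(test_params(), 1500, seed = 41)
  men <- co[co$sex == "men", ]
  men$race_ethnicity <- droplevels(men$race_ethnicity)
  models <- lapply(medhaz:::.mediator_columns, function(m)
    fit_mediator_model(men, m))
  names(models) <- unname(medhaz:::.mediator_columns)
  ex <- compute_weights(expand_cohort(men), models)
  expect_identical(unique(ex$weight[ex$identity_replicate]), 1)
  expect_true(all(ex$weight > 0))
  expect_true(all(is.finite(ex$weight)))
})

test_that("exposure-independent mediator models give unit weights everywhere", {
  co <- generate_cohort(test_params(), 6000, seed = 43)
  men <- co[co$sex == "men", ]
  men$race_ethnicity <- droplevels(men$race_ethnicity)
  models <- lapply(medhaz:::.mediator_columns, function(m) {
    f <- fit_mediator_model(men, m)
    f$coefficients[, "race_ethnicityblack"] <- 0   # sever exposure
    f
  })
  names(models) <- unname(medhaz:::.mediator_columns)
  ex <- compute_weights(expand_cohort(men), models)
  expect_identical(unique(ex$weight), 1)
})

test_that("a hand-specified single-mediator model gives the 2.0 weight", {
  d <- toy_cohort_df(1)           # white subject
  d$smoking_category <- "everyday"
  co <- validate_cohort(d)
  m <- handmade_binary_mediator(0.3, 0.6)
  ex <- expand_cohort(co, c("white", "black"),
                      mediators = "smoking_category")
  ex <- compute_weights(ex, list(smoking_category = m))
  w_cf <- ex$weight[!ex$identity_replicate]
  expect_equal(w_cf, 2, tolerance = 1e-12)   # 0.6 / 0.3
})

test_that("subject weight sums are invariant to mediator order", {
  co <- generate_cohort(test_params(), 6000, seed = 47)
  men <- co[co$sex == "men", ]
  men$race_ethnicity <- droplevels(men$race_ethnicity)
  meds <- unname(medhaz:::.mediator_columns)
  models <- lapply(meds, function(m) fit_mediator_model(men, m))
  names(models) <- meds
  ex1 <- compute_weights(expand_cohort(men, mediators = meds), models)
  perm <- rev(meds)
  ex2 <- compute_weights(expand_cohort(men, mediators = perm), models[perm])
  s1 <- tapply(ex1$weight, ex1$subject_id, sum)
  s2 <- tapply(ex2$weight, ex2$subject_id, sum)
  expect_equal(s1[order(names(s1))], s2[order(names(s2))], tolerance = 1e-10)
})

test_that("weighted replicate frequencies track the counterfactual mediator law", {
  co <- generate_cohort(test_params(), 12000, seed = 53)
  men <- co[co$sex == "men", ]
  men$race_ethnicity <- droplevels(men$race_ethnicity)
  fitm <- fit_mediator_model(men, "smoking_category")
  ex <- compute_weights(
    expand_cohort(men, mediators = "smoking_category"),
    list(smoking_category = fitm))
  # among replicates assigned R* = black, the weighted frequency of each
  # smoking level should match the model's counterfactual law averaged over C
  sub <- ex[ex$rstar_smoking_category == "black", ]
  pr <- predict_category_probs(fitm, sub, "black")
  for (lev in c("never", "everyday")) {
    wf <- sum(sub$weight * (sub$smoking_category == lev)) / sum(sub$weight)
    target <- mean(pr[, lev])
    se <- stats::sd(pr[, lev]) / sqrt(nrow(sub)) +
      sqrt(target * (1 - target) / nrow(men))
    expect_lt(abs(wf - target), 3 * se)
  }
})

test_that("weight truncation caps at the requested percentile", {
  co <- validate_cohort(toy_cohort_df(10))
  ex <- expand_cohort(co, c("white", "black"), mediators = "smoking_category")
  ex <- ex[1:10, ]
  ex$weight <- c(rep(1, 9), 100)
  tr <- truncate_weights(ex, 90)
  expect_equal(max(tr$weight), 10.9)     # hand percentile (type 7)
  expect_equal(unname(attr(tr, "truncation")["n_truncated"]), 1)
  same <- truncate_weights(ex, 100)
  expect_equal(same$weight, ex$weight)
  ex$weight <- rep(2, 10)
  expect_equal(truncate_weights(ex, 75)$weight, rep(2, 10))
  expect_error(truncate_weights(ex, 50), "50, 100")
  expect_error(truncate_weights(ex, 101), "50, 100")
})
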