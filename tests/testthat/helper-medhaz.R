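# Shared fixtures, all generated in code.

# Default generator, binary white/black contrast.
test_params <- function(...) cohort_params(...)

# Generator with mediator laws identical across race groups (null
# differential exposure): race coefficients zeroed in every mediator law.
null_exposure_params <- function() {
  p <- cohort_params()
  p$mediator_laws <- lapply(p$mediator_laws, function(m) {
    m[, c("black", "hispanic")] <- 0
    m
  })
  p
}

# Generator with no race-by-mediator interaction (null vulnerability).
null_vulnerability_params <- function() {
  p <- cohort_params()
  p$delta <- lapply(p$delta, function(l) lapply(l, function(v) v * 0))
  p
}

# Small well-formed cohort data.frame (not yet validated).
toy_cohort_df <- function(n = 3) {
  data.frame(subject_id = paste0("s", seq_len(n)),
             race_ethnicity = rep(c("white", "black", "white"), length.out = n),
             sex = rep("men", n), age_at_survey = 50 + seq_len(n),
             education = rep(c("low", "medium", "high"), length.out = n),
             married = rep(1L, n), survey_year = rep(2000L, n),
             alcohol_category = rep("cat_I", n),
             smoking_category = rep("never", n),
             bmi_category = rep("normal", n),
             activity_category = rep("active", n),
             entry_age = 50 + seq_len(n),
             exit_age = 55 + seq_len(n), event = rep(c(1L, 0L), length.out = n),
             stringsAsFactors = FALSE)
}

# Random small survival design for estimator fuzz tests.
random_design <- function(n = NULL, p = NULL) {
  if (is.null(n)) n <- sample(5:20, 1)
  if (is.null(p)) p <- sample(1:3, 1)
  entry <- stats::runif(n, 0, 2)
  exit <- entry + stats::rexp(n, 0.5) + 1e-3
  event <- stats::rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[1] <- 1L
  Z <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("z", seq_len(p))))
  survival_design(entry, exit, event, Z, weights = stats::runif(n, 0.5, 2))
}

# Hand-built two-level mediator model with prescribed probabilities of the
# non-reference level under white/black exposure (for weight arithmetic).
handmade_binary_mediator <- function(p_white, p_black,
                                     mediator = "smoking_category",
                                     levels = c("never", "everyday")) {
  int <- log(p_white / (1 - p_white))
  race <- log(p_black / (1 - p_black)) - int
  fml <- medhaz:::.mediator_formula(mediator)
  cf <- matrix(c(int, race, 0, 0, 0, 0, 0, 0),
               nrow = 1,
               dimnames = list(levels[2],
                               c("(Intercept)", "race_ethnicityblack",
                                 "I(age_at_survey - 46)", "educationmedium",
                                 "educationhigh", "married",
                                 "I(survey_year - 2005)", "unused")))
  cf <- cf[, 1:7, drop = FALSE]
  structure(list(mediator = mediator, levels = levels, reference = levels[1],
                 coefficients = cf,
                 terms = stats::delete.response(stats::terms(fml)),
                 xlevels = list(race_ethnicity = c("white", "black"),
                                education = c("low", "medium", "high")),
                 convergence = TRUE, ridged = FALSE, logLik = NA_real_,
                 n = 0L, wts = NULL),
            class = "mediator_model")
}
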