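#' @keywords internal
"_PACKAGE"

# Canonical factor levels used throughout; reference level first where a
# reference is defined by the analysis.
.race_levels     <- c("white", "black", "hispanic", "other")
.sex_levels      <- c("men", "women")
.edu_levels      <- c("low", "medium", "high")
.alcohol_levels  <- c("cat_I", "never", "former", "cat_II", "cat_III")
.smoking_levels  <- c("never", "former", "someday", "everyday")
.bmi_levels      <- c("normal", "underweight", "overweight", "obese")
.activity_levels <- c("active", "somewhat", "sedentary")

.mediator_columns <- c(alcohol  = "alcohol_category",
                       smoking  = "smoking_category",
                       bmi      = "bmi_category",
                       activity = "activity_category")

.mediator_levels <- list(alcohol_category  = .alcohol_levels,
                         smoking_category  = .smoking_levels,
                         bmi_category      = .bmi_levels,
                         activity_category = .activity_levels)

#' Derive a reproducible substream seed from a master seed
#'
#' Named substreams keep the generator, bootstrap and simulation-study draws
#' independent while fully determined by one master seed.
#'
#' @param seed master integer seed
#' @param name character substream label
#' @return an integer in \[0, 2^31 - 2\]
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629)
}

# Round half away from zero (printed-table convention; R's round() is
# half-to-even).
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# factor with fixed level set; unexpected values become NA (caught by
# validation)
.as_level <- function(x, levels) factor(as.character(x), levels = levels)

.stop_domain <- function(...) stop(..., call. = FALSE)
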