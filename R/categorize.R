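#' Convert drinking frequency and quantity to grams of pure alcohol per day
#'
#' Assumes 14 g of pure alcohol per drink and a 365-day year:
#' \code{days * drinks * 14 / 365}.
#'
#' @param drinking_days_per_year days with any drinking in the past year
#'   (0--366)
#' @param drinks_per_occasion usual number of drinks on a drinking day
#' @return grams of pure alcohol per day (vectorized)
#' @examples
#' alcohol_grams_per_day(365, 1) # one drink every day = 14 g/day
#' @export
alcohol_grams_per_day <- function(drinking_days_per_year, drinks_per_occasion) {
  if (any(drinking_days_per_year < 0, na.rm = TRUE) ||
      any(drinks_per_occasion < 0, na.rm = TRUE))
    .stop_domain("drinking frequency and quantity must be nonnegative")
  if (any(drinking_days_per_year > 366, na.rm = TRUE))
    .stop_domain("drinking_days_per_year cannot exceed 366")
  drinking_days_per_year * drinks_per_occasion * 14 / 365
}

#' Categorize alcohol use (WHO drinking categories)
#'
#' Never drinkers: no drinks in the past year and never 12+ drinks in any
#' year. Former drinkers: no drinks in the past year but 12+ drinks in some
#' year. Current drinkers fall into sex-specific half-open g/day intervals
#' (left endpoint excluded, right included): men (0,40], (40,60], (60,Inf);
#' women (0,20], (20,40], (40,Inf) for categories I (reference), II, III.
#'
#' @param gpd grams of pure alcohol per day
#' @param sex "men" or "women"
#' @param lifetime_12plus logical, ever had at least 12 drinks in one year
#' @param past_year_any logical, any drinks in the past 12 months
#' @return factor with levels cat_I (reference), never, former, cat_II,
#'   cat_III
#' @export
categorize_alcohol <- function(gpd, sex, lifetime_12plus, past_year_any) {
  n <- max(length(gpd), length(sex), length(lifetime_12plus),
           length(past_year_any))
  gpd <- rep_len(gpd, n); sex <- rep_len(as.character(sex), n)
  lifetime_12plus <- rep_len(as.logical(lifetime_12plus), n)
  past_year_any <- rep_len(as.logical(past_year_any), n)
  if (any(gpd < 0, na.rm = TRUE)) .stop_domain("gpd must be nonnegative")
  if (!all(sex %in% .sex_levels)) .stop_domain("sex must be 'men' or 'women'")
  bad <- gpd > 0 & !past_year_any
  if (any(bad, na.rm = TRUE))
    .stop_domain("inconsistent alcohol report: positive g/day with no past-year drinking (",
                 sum(bad, na.rm = TRUE), " record(s))")
  hi <- ifelse(sex == "men", 60, 40)  # cat_II upper bound
  lo <- ifelse(sex == "men", 40, 20)  # cat_I upper bound
  out <- ifelse(!past_year_any,
                ifelse(lifetime_12plus, "former", "never"),
                ifelse(gpd <= lo, "cat_I",
                       ifelse(gpd <= hi, "cat_II", "cat_III")))
  .as_level(out, .alcohol_levels)
}

#' Categorize smoking status
#'
#' Never smokers have not smoked 100 cigarettes in their life (reference);
#' those who have are former smokers if they currently smoke "none", else
#' current someday or everyday smokers.
#'
#' @param smoked_100 logical, smoked at least 100 cigarettes ever
#' @param current_smoking "none", "someday" or "everyday"
#' @return factor with levels never (reference), former, someday, everyday
#' @export
categorize_smoking <- function(smoked_100, current_smoking) {
  n <- max(length(smoked_100), length(current_smoking))
  smoked_100 <- rep_len(as.logical(smoked_100), n)
  current_smoking <- rep_len(as.character(current_smoking), n)
  if (!all(current_smoking %in% c("none", "someday", "everyday"), na.rm = TRUE))
    .stop_domain("current_smoking must be one of none/someday/everyday")
  bad <- !smoked_100 & current_smoking != "none"
  if (any(bad, na.rm = TRUE))
    .stop_domain("inconsistent smoking report: current smoker without 100 lifetime cigarettes (",
                 sum(bad, na.rm = TRUE), " record(s))")
  out <- ifelse(!smoked_100, "never",
                ifelse(current_smoking == "none", "former", current_smoking))
  .as_level(out, .smoking_levels)
}

#' Categorize body mass index
#'
#' BMI = weight / height^2 (kg/m^2), classified with right-open intervals:
#' underweight \[0, 18.5), normal \[18.5, 25) (reference), overweight
#' \[25, 30), obese \[30, Inf).
#'
#' @param weight_kg body weight in kilograms
#' @param height_m standing height in meters
#' @return factor with levels normal (reference), underweight, overweight,
#'   obese
#' @export
categorize_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_m <= 0, na.rm = TRUE))
    .stop_domain("weight and height must be positive")
  bmi <- weight_kg / height_m^2
  out <- cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
             labels = c("underweight", "normal", "overweight", "obese"))
  .as_level(as.character(out), .bmi_levels)
}

#' Categorize leisure-time physical activity
#'
#' One vigorous minute counts as two moderate-equivalent minutes. Sedentary
#' is exactly zero equivalent minutes per week; somewhat active is (0, 150);
#' active (reference) is at least 150.
#'
#' @param vigorous_min_wk vigorous activity, minutes per week
#' @param moderate_min_wk light-moderate activity, minutes per week
#' @return factor with levels active (reference), somewhat, sedentary
#' @export
categorize_activity <- function(vigorous_min_wk, moderate_min_wk) {
  if (any(vigorous_min_wk < 0, na.rm = TRUE) ||
      any(moderate_min_wk < 0, na.rm = TRUE))
    .stop_domain("activity minutes must be nonnegative")
  total <- 2 * vigorous_min_wk + moderate_min_wk
  out <- ifelse(total == 0, "sedentary",
                ifelse(total < 150, "somewhat", "active"))
  .as_level(out, .activity_levels)
}
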