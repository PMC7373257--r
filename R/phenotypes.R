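# Purchase phenotypes from cafeteria transaction logs: the traffic-light
# Healthy Purchasing Score, purchase quantities, daily-first meal timing
# medians, survey dichotomization, and the 3-month baseline window.

TL_WEIGHTS <- c(green = 1, yellow = 0.5, red = 0)
MEAL_WINDOWS <- list(breakfast = c(360, 600), lunch = c(660, 840))

tx_minutes <- function(timestamp) {
  tt <- as.POSIXlt(timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M"))
  tt$hour * 60L + tt$min
}

tx_date <- function(timestamp) as.Date(substr(timestamp, 1, 10))

#' Healthy Purchasing Score
#'
#' 100 x mean traffic-light weight over labeled purchases (green = 1,
#' yellow = 0.5, red = 0); unlabeled items enter neither numerator nor
#' denominator. Returns `NA` when no labeled transaction exists (the
#' participant is excluded from quality analyses).
#'
#' @param transactions data.frame with a `color` column.
#' @return Percentage in \[0, 100\], or `NA_real_`.
#' @export
healthy_purchasing_score <- function(transactions) {
  wt <- TL_WEIGHTS[transactions$color]
  wt <- wt[!is.na(wt)]
  if (!length(wt)) return(NA_real_)
  100 * mean(wt)
}

#' Purchase quantity counts
#'
#' Counts are label-independent: unlabeled items still count.
#'
#' @param transactions data.frame with an `item_class` column
#'   (food/beverage).
#' @return Named numeric vector `total, food, beverage`.
#' @export
purchase_counts <- function(transactions) {
  food <- sum(transactions$item_class == "food")
  bev <- sum(transactions$item_class == "beverage")
  c(total = food + bev, food = food, beverage = bev)
}

#' Median daily-first meal purchase time
#'
#' Per calendar day, the earliest food-class purchase inside the meal
#' window (breakfast 06:00-10:00, lunch 11:00-14:00, bounds inclusive) is
#' taken; the phenotype is the median of those daily first-purchase times
#' over days with at least one qualifying purchase.
#'
#' @param transactions data.frame with `timestamp` and `item_class`.
#' @param meal `"breakfast"` or `"lunch"`.
#' @param food_only Restrict to `item_class == "food"` (default, matching
#'   the "first food purchased" definition).
#' @return Minutes since midnight, or `NA_real_` if no qualifying day.
#' @export
meal_time_median <- function(transactions, meal = c("breakfast", "lunch"),
                             food_only = TRUE) {
  meal <- match.arg(meal)
  win <- MEAL_WINDOWS[[meal]]
  if (nrow(transactions) == 0) return(NA_real_)
  mins <- tx_minutes(transactions$timestamp)
  keep <- mins >= win[1] & mins <= win[2]
  if (food_only) keep <- keep & transactions$item_class == "food"
  if (!any(keep)) return(NA_real_)
  firsts <- tapply(mins[keep], tx_date(transactions$timestamp[keep]), min)
  as.numeric(median(firsts))
}

#' Dichotomize survey meal habits
#'
#' Skipping: "Never" maps to 0 (daily eater), any skipping to 1.
#' Home-prepared: fewer than 3 days/week ("Never", "1-2 days") maps to 0,
#' 3 or more days to 1.
#'
#' @param survey data.frame with columns `skip_breakfast, skip_lunch,
#'   skip_dinner, home_breakfast, home_lunch, home_dinner` holding the
#'   five frequency categories.
#' @return data.frame of six 0/1 columns `skips_*`, `prepares_*_home`
#'   (plus `participant_id` if present in the input).
#' @export
dichotomize_survey <- function(survey) {
  norm <- function(x) gsub("–", "-", trimws(x))   # en-dash tolerant
  levels_ok <- c("Never", "1-2 days", "3-4 days", "5-6 days", "Every day")
  code <- function(x, cutpoint) {
    x <- norm(x)
    bad <- setdiff(unique(x), levels_ok)
    if (length(bad))
      stop("unrecognized survey category: ", paste(bad, collapse = ", "))
    as.integer(match(x, levels_ok) > cutpoint)
  }
  out <- data.frame(
    skips_breakfast = code(survey$skip_breakfast, 1L),
    skips_lunch = code(survey$skip_lunch, 1L),
    skips_dinner = code(survey$skip_dinner, 1L),
    prepares_breakfast_home = code(survey$home_breakfast, 2L),
    prepares_lunch_home = code(survey$home_lunch, 2L),
    prepares_dinner_home = code(survey$home_dinner, 2L))
  if (!is.null(survey$participant_id))
    out <- cbind(participant_id = survey$participant_id, out)
  out
}

#' Restrict transactions to the 3-month baseline window
#'
#' Keeps records with `enrollment_date - 91 <= date < enrollment_date`
#' (91 fixed days, half-open at enrollment).
#'
#' @param transactions data.frame with a `timestamp` column.
#' @param enrollment_date The participant's enrollment `Date`.
#' @return The filtered transactions.
#' @export
baseline_window <- function(transactions, enrollment_date) {
  enrollment_date <- as.Date(enrollment_date)
  if (nrow(transactions) == 0) return(transactions)
  d <- tx_date(transactions$timestamp)
  transactions[d >= enrollment_date - 91 & d < enrollment_date, ,
               drop = FALSE]
}

#' Derive all purchase phenotypes per participant
#'
#' Applies the baseline window per participant (enrollment dates from the
#' covariate table), then computes the Healthy Purchasing Score, the three
#' quantity counts, breakfast/lunch timing medians, and the six survey
#' binaries. Participants with no transactions get zero counts and missing
#' quality/timing phenotypes.
#'
#' @param transactions Transaction log data.frame.
#' @param survey Survey data.frame (five-category strings).
#' @param covariates Covariate data.frame with `participant_id` and
#'   `enrollment_date`.
#' @return One row per covariate-table participant.
#' @export
derive_phenotypes <- function(transactions, survey, covariates) {
  ids <- covariates$participant_id
  tx_split <- split(transactions,
                    factor(transactions$participant_id, levels = ids))
  rows <- lapply(seq_along(ids), function(i) {
    tx <- baseline_window(tx_split[[i]], covariates$enrollment_date[i])
    cnt <- purchase_counts(tx)
    data.frame(participant_id = ids[i],
               healthy_purchasing_score = healthy_purchasing_score(tx),
               total_items = unname(cnt["total"]),
               food_items = unname(cnt["food"]),
               beverage_items = unname(cnt["beverage"]),
               breakfast_time_median = meal_time_median(tx, "breakfast"),
               lunch_time_median = meal_time_median(tx, "lunch"),
               stringsAsFactors = FALSE)
  })
  phen <- do.call(rbind, rows)
  sv <- dichotomize_survey(survey)
  merge(phen, sv, by = "participant_id", all.x = TRUE, sort = FALSE)
}
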