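# Association stage: rank-based inverse normal transform, seasonality
# harmonics, adjusted quartile-contrast models (effects on the natural
# scale, P values from the transformed scale), trend tests, CNS/non-CNS
# heterogeneity tests, and Benjamini-Hochberg FDR correction.

#' Rank-based inverse normal transform
#'
#' z = qnorm((rank - 0.5) / n) with average ranks for ties; `NA`s are
#' preserved in place and excluded from the ranking.
#'
#' @param values Numeric vector, at least 2 non-missing, non-constant.
#' @return Transformed vector in the input order.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2) stop("inverse normal transform needs n >= 2")
  if (sd(x) == 0) stop("inverse normal transform undefined for constant input")
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - 0.5) / length(x))
  out
}

#' Seasonality harmonics for an enrollment date
#'
#' First-order annual harmonic pair: theta = 2*pi*(day-of-year - 1)/365.25,
#' returning (sin theta, cos theta), so January 1 maps to (0, 1).
#'
#' @param enrollment_date Date (or coercible) vector.
#' @return data.frame with columns `season_sin`, `season_cos`.
#' @export
seasonality_terms <- function(enrollment_date) {
  yday0 <- as.POSIXlt(as.Date(enrollment_date))$yday  # 0-based
  theta <- 2 * pi * yday0 / 365.25
  data.frame(season_sin = sin(theta), season_cos = cos(theta))
}

check_model_frame <- function(df, n_params) {
  if (nrow(df) < 10 * n_params)
    stop(sprintf(
      "too few complete cases (%d) for %d parameters (need >= %d)",
      nrow(df), n_params, 10 * n_params))
  invisible(df)
}

check_singular <- function(fit) {
  al <- is.na(coef(fit))
  if (any(al))
    stop("singular design: collinear column(s) ",
         paste(names(coef(fit))[al], collapse = ", "))
  invisible(fit)
}

#' Adjusted quartile-contrast model
#'
#' Continuous outcomes are fitted twice: once untransformed, giving the
#' effect and 95% CI in natural units, and once inverse-normalized, giving
#' the reported P value. Binary outcomes use logistic regression with the
#' effect reported as an odds ratio with Wald 95% CI. Quartiles enter as
#' indicator contrasts against Q1.
#'
#' @param data data.frame holding `outcome`, a `quartile` factor
#'   (levels Q1..Q4), and any covariate columns.
#' @param outcome Name of the outcome column.
#' @param type `"continuous"` or `"binary"`.
#' @param covariates Character vector of covariate column names.
#' @return data.frame with one row per contrast (Q2/Q3/Q4 vs Q1):
#'   `contrast, n, effect, ci_low, ci_high, p, est, se, flag` where
#'   `est`/`se` are on the modeling scale (identity or log-odds) for
#'   downstream heterogeneity tests; `flag` marks separation.
#' @export
fit_quartile_model <- function(data, outcome, type = c("continuous", "binary"),
                               covariates = character(0)) {
  type <- match.arg(type)
  use <- c(outcome, "quartile", covariates)
  df <- data[complete.cases(data[, use, drop = FALSE]), use, drop = FALSE]
  df$quartile <- factor(as.character(df$quartile), levels = paste0("Q", 1:4))
  n_params <- 4 + length(covariates)
  check_model_frame(df, n_params)
  rhs <- paste(c("quartile", covariates), collapse = " + ")
  f_nat <- as.formula(paste0("`", outcome, "` ~ ", rhs))
  rows <- paste0("quartileQ", 2:4)
  if (type == "continuous") {
    m_nat <- lm(f_nat, data = df)
    check_singular(m_nat)
    df_t <- df
    df_t[[outcome]] <- inverse_normal_transform(df_t[[outcome]])
    m_t <- lm(f_nat, data = df_t)
    ci <- confint(m_nat)[rows, , drop = FALSE]
    p <- summary(m_t)$coefficients[rows, 4]
    out <- data.frame(contrast = paste0("Q", 2:4),
                      n = nrow(df),
                      effect = unname(coef(m_nat)[rows]),
                      ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                      p = unname(p),
                      est = unname(coef(m_nat)[rows]),
                      se = unname(summary(m_nat)$coefficients[rows, 2]),
                      flag = "", stringsAsFactors = FALSE)
  } else {
    m <- suppressWarnings(glm(f_nat, data = df, family = binomial()))
    check_singular(m)
    sm <- summary(m)$coefficients[rows, , drop = FALSE]
    sep <- !m$converged | sm[, 2] > 20
    or <- exp(sm[, 1])
    lo <- exp(sm[, 1] - 1.959964 * sm[, 2])
    hi <- exp(sm[, 1] + 1.959964 * sm[, 2])
    lo[sep] <- NA; hi[sep] <- NA
    out <- data.frame(contrast = paste0("Q", 2:4),
                      n = nrow(df),
                      effect = unname(or),
                      ci_low = unname(lo), ci_high = unname(hi),
                      p = unname(sm[, 4]),
                      est = unname(sm[, 1]), se = unname(sm[, 2]),
                      flag = ifelse(sep, "possible_separation", ""),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Test for trend across quartiles
#'
#' Refits the model with the quartile index entered as a single ordinal
#' term (1-4); the trend P is that term's Wald P from the transformed
#' (continuous) or logistic (binary) model.
#'
#' @inheritParams fit_quartile_model
#' @return Single P value.
#' @export
trend_test <- function(data, outcome, type = c("continuous", "binary"),
                       covariates = character(0)) {
  type <- match.arg(type)
  use <- c(outcome, "quartile", covariates)
  df <- data[complete.cases(data[, use, drop = FALSE]), use, drop = FALSE]
  df$qidx <- as.integer(factor(as.character(df$quartile),
                               levels = paste0("Q", 1:4)))
  n_params <- 2 + length(covariates)
  check_model_frame(df, n_params)
  rhs <- paste(c("qidx", covariates), collapse = " + ")
  f <- as.formula(paste0("`", outcome, "` ~ ", rhs))
  if (type == "continuous") {
    df[[outcome]] <- inverse_normal_transform(df[[outcome]])
    m <- lm(f, data = df)
  } else {
    m <- suppressWarnings(glm(f, data = df, family = binomial()))
  }
  check_singular(m)
  unname(summary(m)$coefficients["qidx", 4])
}

#' Per-SD continuous-score model
#'
#' Sensitivity fit entering the standardized score as a single continuous
#' exposure.
#'
#' @param data data.frame with `standardized`, the outcome, covariates.
#' @inheritParams fit_quartile_model
#' @return One-row data.frame: effect per SD (difference or OR), CI, P.
#' @export
fit_continuous_model <- function(data, outcome,
                                 type = c("continuous", "binary"),
                                 covariates = character(0)) {
  type <- match.arg(type)
  use <- c(outcome, "standardized", covariates)
  df <- data[complete.cases(data[, use, drop = FALSE]), use, drop = FALSE]
  check_model_frame(df, 2 + length(covariates))
  rhs <- paste(c("standardized", covariates), collapse = " + ")
  f <- as.formula(paste0("`", outcome, "` ~ ", rhs))
  if (type == "continuous") {
    m_nat <- lm(f, data = df)
    df_t <- df; df_t[[outcome]] <- inverse_normal_transform(df_t[[outcome]])
    m_t <- lm(f, data = df_t)
    ci <- confint(m_nat)["standardized", ]
    data.frame(contrast = "per_SD", n = nrow(df),
               effect = unname(coef(m_nat)["standardized"]),
               ci_low = ci[[1]], ci_high = ci[[2]],
               p = unname(summary(m_t)$coefficients["standardized", 4]),
               est = unname(coef(m_nat)["standardized"]),
               se = unname(summary(m_nat)$coefficients["standardized", 2]),
               flag = "", stringsAsFactors = FALSE)
  } else {
    m <- suppressWarnings(glm(f, data = df, family = binomial()))
    sm <- summary(m)$coefficients["standardized", ]
    data.frame(contrast = "per_SD", n = nrow(df),
               effect = exp(sm[[1]]),
               ci_low = exp(sm[[1]] - 1.959964 * sm[[2]]),
               ci_high = exp(sm[[1]] + 1.959964 * sm[[2]]),
               p = sm[[4]], est = sm[[1]], se = sm[[2]],
               flag = "", stringsAsFactors = FALSE)
  }
}

#' CNS vs non-CNS heterogeneity test
#'
#' z = (b_cns - b_noncns) / sqrt(se_cns^2 + se_noncns^2), two-sided normal
#' tail. For odds ratios the inputs must be on the log-odds scale.
#'
#' @param b_cns,se_cns,b_noncns,se_noncns Stratified estimates and their
#'   standard errors (SEs positive).
#' @return Two-sided interaction P value.
#' @export
heterogeneity_test <- function(b_cns, se_cns, b_noncns, se_noncns) {
  if (!all(is.finite(c(b_cns, b_noncns, se_cns, se_noncns))))
    stop("heterogeneity test needs finite estimates and SEs")
  if (se_cns <= 0 || se_noncns <= 0)
    stop("heterogeneity test needs positive standard errors")
  z <- (b_cns - b_noncns) / sqrt(se_cns^2 + se_noncns^2)
  2 * pnorm(-abs(z))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment returning q values in the input order; never smaller
#' than the raw P values.
#'
#' @param p_values Numeric vector of P values in (0, 1].
#' @return Adjusted P values.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("P values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

# outcome menu: name -> type
OUTCOME_TYPES <- c(
  healthy_purchasing_score = "continuous", total_items = "continuous",
  food_items = "continuous", beverage_items = "continuous",
  breakfast_time_median = "continuous", lunch_time_median = "continuous",
  skips_breakfast = "binary", skips_lunch = "binary",
  skips_dinner = "binary",
  prepares_breakfast_home = "binary", prepares_lunch_home = "binary",
  prepares_dinner_home = "binary")

OUTCOME_FAMILY <- c(
  healthy_purchasing_score = "purchases", total_items = "purchases",
  food_items = "purchases", beverage_items = "purchases",
  breakfast_time_median = "purchases", lunch_time_median = "purchases",
  skips_breakfast = "survey", skips_lunch = "survey",
  skips_dinner = "survey",
  prepares_breakfast_home = "survey", prepares_lunch_home = "survey",
  prepares_dinner_home = "survey")

#' Run the full association analysis
#'
#' For each score set and each outcome: quartile contrasts vs Q1 (natural
#' scale effects, inverse-normal P values), a trend P, and a per-SD
#' continuous-score sensitivity fit. BH-FDR is applied to the quartile
#' contrast P values within each outcome family (purchases; survey
#' behaviors), and the CNS vs non-CNS heterogeneity P is attached to the
#' stratified rows of matching outcome and contrast.
#'
#' @param scores Named list of score-set data.frames (e.g. `BMI_GPS`,
#'   `BMI_97`, `BMI_CNS`, `BMI_nonCNS`).
#' @param phenotypes Output of [derive_phenotypes()].
#' @param covariates Covariate table with `participant_id, age, sex,
#'   enrollment_date` and optionally `PC1..PCk` plus sensitivity columns.
#' @param pcs Optional ancestry PC table to merge in.
#' @param outcomes Character vector of outcome names (default: all).
#' @param extra_covariates Additional covariate column names for
#'   sensitivity models (e.g. job type, education, smoking, physical
#'   activity).
#' @return data.frame: `score, outcome, contrast, n, effect, ci_low,
#'   ci_high, p, p_trend, p_adj, p_int, flag`, with a fit log in
#'   `attr(, "log")`.
#' @export
run_full_analysis <- function(scores, phenotypes, covariates, pcs = NULL,
                              outcomes = names(OUTCOME_TYPES),
                              extra_covariates = character(0)) {
  stopifnot(is.list(scores), length(scores) >= 1)
  outcomes <- as.character(unlist(outcomes))          # YAML-safe
  extra_covariates <- as.character(unlist(extra_covariates))
  base <- merge(phenotypes, covariates, by = "participant_id")
  if (!is.null(pcs)) base <- merge(base, pcs, by = "participant_id")
  orphans <- setdiff(unique(unlist(lapply(scores, function(s)
    s$participant_id))), base$participant_id)
  if (length(orphans))
    stop("participant ID(s) missing from phenotype/covariate tables: ",
         paste(head(orphans, 5), collapse = ", "))
  base <- cbind(base, seasonality_terms(base$enrollment_date))
  base$sex <- factor(base$sex)
  covs <- c("age", "sex", "season_sin", "season_cos",
            grep("^PC[0-9]+$", names(base), value = TRUE),
            extra_covariates)
  bad_out <- setdiff(outcomes, names(OUTCOME_TYPES))
  if (length(bad_out))
    stop("unknown outcome(s): ", paste(bad_out, collapse = ", "))

  all_rows <- list()
  fit_log <- list()
  for (sc in names(scores)) {
    df <- merge(scores[[sc]], base, by = "participant_id")
    for (oc in outcomes) {
      type <- OUTCOME_TYPES[[oc]]
      res <- tryCatch({
        q <- fit_quartile_model(df, oc, type, covs)
        q$p_trend <- trend_test(df, oc, type, covs)
        cont <- fit_continuous_model(df, oc, type, covs)
        cont$p_trend <- NA_real_
        rbind(q, cont)
      }, error = function(e) {
        warning(sprintf("model %s ~ %s failed: %s", oc, sc,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(res)) next
      res <- cbind(score = sc, outcome = oc, res,
                   stringsAsFactors = FALSE)
      all_rows[[length(all_rows) + 1L]] <- res
      fit_log[[length(fit_log) + 1L]] <-
        list(score = sc, outcome = oc, type = type, n = res$n[1],
             covariates = covs)
    }
  }
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  out$family <- OUTCOME_FAMILY[out$outcome]

  # FDR within family over the primary quartile-contrast tests
  out$p_adj <- NA_real_
  primary <- out$contrast %in% paste0("Q", 2:4)
  for (fam in unique(out$family)) {
    sel <- primary & out$family == fam & !is.na(out$p)
    if (any(sel)) out$p_adj[sel] <- bh_fdr(out$p[sel])
  }

  # CNS vs non-CNS heterogeneity on matching outcome x contrast rows
  out$p_int <- NA_real_
  if (all(c("BMI_CNS", "BMI_nonCNS") %in% names(scores))) {
    for (oc in unique(out$outcome)) {
      for (ctr in unique(out$contrast)) {
        i <- which(out$score == "BMI_CNS" & out$outcome == oc &
                     out$contrast == ctr)
        j <- which(out$score == "BMI_nonCNS" & out$outcome == oc &
                     out$contrast == ctr)
        if (length(i) == 1 && length(j) == 1 &&
            all(is.finite(c(out$est[c(i, j)], out$se[c(i, j)]))) &&
            all(out$se[c(i, j)] > 0)) {
          p_int <- heterogeneity_test(out$est[i], out$se[i],
                                      out$est[j], out$se[j])
          out$p_int[c(i, j)] <- p_int
        }
      }
    }
  }
  attr(out, "log") <- fit_log
  out
}
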