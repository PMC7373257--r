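# Synthetic cohort generator: genotypes with block LD, anthropometrics,
# cafeteria transaction streams, meal-habit surveys, and covariates, all
# driven by known generative parameters so downstream stages are testable
# without protected cohort data.

#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic cohort.
#' Defaults describe a workplace cohort of hospital employees with
#' year-round enrollment, a 3-month cafeteria purchase history per
#' participant, and a polygenic architecture for BMI in which the true
#' score accounts for `bmi_h2` of the non-covariate BMI variance.
#'
#' @param n_participants Number of participants.
#' @param n_variants Number of variants; must be divisible by `n_blocks`.
#' @param n_blocks Number of LD blocks. Blocks are placed >250 kb apart so
#'   clumping cannot cross blocks.
#' @param block_r2 Target squared correlation between adjacent variants
#'   within a block (first-order Markov haplotype copying; r2 between
#'   variants k apart decays as `block_r2^k`).
#' @param maf_range Length-2 vector; allele frequencies drawn uniformly
#'   from this interval (one frequency per block).
#' @param effect_sd SD of causal per-allele effects on the BMI liability.
#' @param frac_causal Proportion of variants that are causal.
#' @param bmi_h2 Share of non-covariate BMI variance explained by the true
#'   polygenic liability.
#' @param purchase_effects Named list of standardized effects per SD of the
#'   true score: `quality` (percentage points of Healthy Purchasing Score),
#'   `quantity` (items per 3 months), `breakfast_timing` (minutes), and
#'   log-odds shifts for the six survey binaries.
#' @param baseline_rates Named list: `mean_items` (items per 3 months),
#'   `dispersion` (negative-binomial size), `breakfast_time` and
#'   `lunch_time` (minutes since midnight), `color_probs` (named
#'   probabilities for green/yellow/red/unlabeled).
#' @param enrollment_window Length-2 character/Date vector of enrollment
#'   dates.
#' @param missing_rate Per-call missingness rate in the dosage matrix.
#' @param causal_p_max Causal variants receive discovery P values uniform
#'   on (1e-8, `causal_p_max`); null variants uniform on (0, 1).
#' @param null_beta_frac Null variants' weight-table betas are drawn with
#'   SD `effect_sd * null_beta_frac` (discovery noise).
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_participants = 500,
                              n_variants = 2000,
                              n_blocks = 200,
                              block_r2 = 0.3,
                              maf_range = c(0.05, 0.5),
                              effect_sd = 0.06,
                              frac_causal = 0.10,
                              bmi_h2 = 0.148,
                              purchase_effects = list(
                                quality = -1.9,
                                quantity = 6,
                                breakfast_timing = 6,
                                skips_breakfast = 0.27,
                                skips_lunch = 0,
                                skips_dinner = 0,
                                prepares_breakfast_home = -0.27,
                                prepares_lunch_home = -0.35,
                                prepares_dinner_home = -0.45),
                              baseline_rates = list(
                                mean_items = 120,
                                dispersion = 8,
                                breakfast_time = 465,
                                lunch_time = 740,
                                color_probs = c(green = 0.31, yellow = 0.33,
                                                red = 0.26, unlabeled = 0.10)),
                              enrollment_window = c("2016-09-01", "2018-02-28"),
                              missing_rate = 0.002,
                              causal_p_max = 0.19,
                              null_beta_frac = 0.1,
                              seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_variants = as.integer(n_variants),
              n_blocks = as.integer(n_blocks),
              block_r2 = block_r2,
              maf_range = maf_range,
              effect_sd = effect_sd,
              frac_causal = frac_causal,
              bmi_h2 = bmi_h2,
              purchase_effects = purchase_effects,
              baseline_rates = baseline_rates,
              enrollment_window = as.Date(enrollment_window),
              missing_rate = missing_rate,
              causal_p_max = causal_p_max,
              null_beta_frac = null_beta_frac,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_participants < 2) fail("n_participants", "must be >= 2")
  if (cfg$n_variants < 1) fail("n_variants", "must be >= 1")
  if (cfg$n_blocks < 1 || cfg$n_variants %% cfg$n_blocks != 0)
    fail("n_blocks", "must divide n_variants")
  if (!is.numeric(cfg$block_r2) || cfg$block_r2 < 0 || cfg$block_r2 > 1)
    fail("block_r2", "must lie in [0, 1]")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0.01 ||
      cfg$maf_range[2] >= 0.5001 || cfg$maf_range[1] > cfg$maf_range[2])
    fail("maf_range", "must be an increasing pair within (0.01, 0.5]")
  if (cfg$frac_causal < 0 || cfg$frac_causal > 1)
    fail("frac_causal", "must lie in [0, 1]")
  if (cfg$bmi_h2 < 0 || cfg$bmi_h2 > 1) fail("bmi_h2", "must lie in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    fail("missing_rate", "must lie in [0, 1]")
  cp <- cfg$baseline_rates$color_probs
  if (any(cp < 0) || any(cp > 1) || abs(sum(cp) - 1) > 1e-8)
    fail("baseline_rates$color_probs", "must be probabilities summing to 1")
  if (cfg$causal_p_max <= 0 || cfg$causal_p_max > 1)
    fail("causal_p_max", "must lie in (0, 1]")
  if (cfg$baseline_rates$mean_items < 0)
    fail("baseline_rates$mean_items", "must be non-negative")
  if (anyNA(cfg$enrollment_window) ||
      cfg$enrollment_window[1] > cfg$enrollment_window[2])
    fail("enrollment_window", "must be an ordered pair of dates")
  invisible(cfg)
}

#' Construct a genotype matrix object
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns,
#'   values in \[0, 2\] or `NA`.
#' @param variants data.frame with columns `id`, `chr`, `pos`, `a1`
#'   (the counted allele), `a2`, `freq` (a1 frequency), `impq`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), ncol(dosage) == nrow(variants))
  need <- c("id", "chr", "pos", "a1", "a2", "freq", "impq")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  colnames(dosage) <- variants$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("P%04d", seq_len(nrow(dosage)))
  out <- list(dosage = dosage, variants = as.data.frame(variants),
              samples = rownames(dosage))
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%d chromosomes)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$variants$chr))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param g A `genotype_matrix`.
#' @param samples Optional character/logical/integer sample selector.
#' @param variants Optional character/logical/integer variant selector.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, g$variants$id)
    g$variants <- g$variants[variants, , drop = FALSE]
    g$dosage <- g$dosage[, variants, drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, g$samples)
    g$dosage <- g$dosage[samples, , drop = FALSE]
    g$samples <- rownames(g$dosage)
  }
  g
}

#' Simulate genotype dosages with block LD structure
#'
#' Haplotypes are simulated per LD block by first-order Markov copying:
#' each variant's allele is copied from the previous variant with
#' probability `sqrt(block_r2)`, otherwise drawn fresh at the block allele
#' frequency, so adjacent-variant genotype r2 targets `block_r2` and decays
#' geometrically with distance. Blocks sit >250 kb apart (1 Mb spacing) on
#' chromosomes 1-22, so LD never spans blocks.
#'
#' @param config A `sim_config`.
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (causal betas, true standardized score, weight tables, realized
#'   effects). The truth component is never consumed by the pipeline.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  V <- config$n_variants
  B <- config$n_blocks
  m <- V %/% B
  copy_p <- sqrt(config$block_r2)

  block_freq <- runif(B, config$maf_range[1], config$maf_range[2])
  sim_block <- function(p, m) {
    hap <- function() {
      H <- matrix(0L, n, m)
      H[, 1] <- rbinom(n, 1L, p)
      if (m > 1) for (j in 2:m) {
        cp <- rbinom(n, 1L, copy_p)
        fresh <- rbinom(n, 1L, p)
        H[, j] <- ifelse(cp == 1L, H[, j - 1L], fresh)
      }
      H
    }
    hap() + hap()
  }
  dosage <- matrix(0, n, V)
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * m + 1L):(b * m)
    dosage[, cols] <- sim_block(block_freq[b], m)
  }
  storage.mode(dosage) <- "double"

  # variant metadata: blocks round-robin over chromosomes, 1 Mb apart
  chr <- rep(((seq_len(B) - 1L) %% 22L) + 1L, each = m)
  within_chr_block <- (seq_len(B) - 1L) %/% 22L
  pos <- rep(within_chr_block * 1000000L + 1L, each = m) +
    rep(seq_len(m) - 1L, times = B) * 1000L
  allele_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  ap <- allele_pairs[sample.int(4L, V, replace = TRUE)]
  a1 <- vapply(ap, `[`, character(1), 1L)
  a2 <- vapply(ap, `[`, character(1), 2L)
  impq <- ifelse(runif(V) < 0.03, runif(V, 0.2, 0.5), rbeta(V, 12, 1))

  # missingness, then empirical frequency of the counted allele
  if (config$missing_rate > 0) {
    nmiss <- rbinom(1L, n * V, config$missing_rate)
    if (nmiss > 0) dosage[sample.int(n * V, nmiss)] <- NA_real_
  }
  freq <- colMeans(dosage, na.rm = TRUE) / 2

  variants <- data.frame(id = sprintf("var%05d", seq_len(V)),
                         chr = chr, pos = pos, a1 = a1, a2 = a2,
                         freq = freq, impq = round(impq, 4),
                         stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("P%04d", seq_len(n))
  geno <- genotype_matrix(dosage, variants)

  # causal architecture and the discovery-style weight tables
  n_causal <- round(config$frac_causal * V)
  causal_idx <- sort(sample.int(V, n_causal))
  beta_true <- numeric(V)
  beta_true[causal_idx] <- rnorm(n_causal, 0, config$effect_sd)
  imp <- dosage
  for (j in which(colSums(is.na(imp)) > 0))
    imp[is.na(imp[, j]), j] <- 2 * freq[j]
  raw_liab <- drop(imp %*% beta_true)
  sdl <- sd(raw_liab)
  true_score <- if (sdl > 0) (raw_liab - mean(raw_liab)) / sdl else raw_liab * 0

  beta_w <- beta_true
  nulls <- setdiff(seq_len(V), causal_idx)
  beta_w[nulls] <- rnorm(length(nulls), 0, config$effect_sd * config$null_beta_frac)
  pval <- runif(V)
  pval[causal_idx] <- runif(n_causal, 1e-8, config$causal_p_max)
  flip <- runif(V) < 0.5   # random reported orientation
  weights <- data.frame(ID = variants$id, CHR = variants$chr,
                        POS = variants$pos,
                        EA = ifelse(flip, a2, a1),
                        OA = ifelse(flip, a1, a2),
                        BETA = ifelse(flip, -beta_w, beta_w),
                        P = pval, CNS = "unannotated",
                        stringsAsFactors = FALSE)

  # 97-variant panel: the largest-|beta| variants, 54 CNS / 43 non-CNS
  n97 <- min(97L, V)
  top <- order(abs(beta_w), decreasing = TRUE)[seq_len(n97)]
  top <- sort(top)
  w97 <- weights[top, ]
  n_cns <- round(n97 * 54 / 97)
  cns_pick <- sample.int(n97, n_cns)
  w97$CNS <- "non-CNS"
  w97$CNS[cns_pick] <- "CNS"
  rownames(w97) <- NULL

  truth <- list(causal_betas = data.frame(id = variants$id, beta = beta_true),
                true_score = setNames(true_score, rownames(dosage)),
                weights_gws = weights, weights_97 = w97,
                true_effects = list(bmi_h2 = config$bmi_h2,
                                    purchase = config$purchase_effects))
  list(genotypes = geno, truth = truth)
}

# slope of the expected Healthy Purchasing Score (in percentage points)
# with respect to the color log-odds shift, at shift 0
hps_logit_slope <- function(color_probs) {
  g <- color_probs[["green"]]; y <- color_probs[["yellow"]]
  r <- color_probs[["red"]]
  N0 <- g + 0.5 * y; D0 <- g + y + r
  100 * (g * D0 - N0 * (g - r)) / D0^2
}

#' Simulate phenotypes, transactions, and surveys for a genotype set
#'
#' BMI is linear in the true standardized score (variance share `bmi_h2`
#' of the non-covariate variance) plus small age/sex effects and Gaussian
#' noise. Each participant receives a 3-month (91-day) transaction stream:
#' the item count is negative-binomial with mean shifted by the quantity
#' effect, traffic-light colors are multinomial with green-vs-red log-odds
#' shifted so the expected Healthy Purchasing Score moves by the
#' configured percentage points per SD of true score, and breakfast
#' purchase times are normal around a mean shifted by the timing effect.
#' Survey habit categories are drawn through logistic models with the
#' configured log-odds so that the standard dichotomization recovers them.
#' Timestamps fall on working days within cafeteria hours (06:00-20:00).
#'
#' @param genotypes,truth Output of [simulate_genotypes()].
#' @param config The same `sim_config`.
#' @return List with `covariates` (incl. measured BMI), `transactions`,
#'   and `survey` data frames.
#' @export
simulate_phenotypes <- function(genotypes, truth, config) {
  validate_sim_config(config)
  if (!identical(names(truth$true_score), genotypes$samples))
    stop("genotypes and truth are not from the same simulation")
  set.seed(config$seed + 1L)
  n <- length(genotypes$samples)
  id <- genotypes$samples
  Z <- unname(truth$true_score)
  pe <- config$purchase_effects
  br <- config$baseline_rates

  age <- pmin(75, pmax(20, rnorm(n, 44.9, 12.8)))
  sex <- ifelse(runif(n) < 0.809, "female", "male")
  days <- seq(config$enrollment_window[1], config$enrollment_window[2], by = "day")
  enroll <- sample(days, n, replace = TRUE)
  job <- sample(c("administrative/service", "craft/technicians",
                  "management/professionals", "MDs/PhDs"),
                n, replace = TRUE, prob = c(0.091, 0.093, 0.713, 0.103))
  edu <- sample(c("high school/some college", "college degree", "graduate degree"),
                n, replace = TRUE, prob = c(0.081, 0.431, 0.488))
  smoker <- runif(n) < 0.025
  pa <- sample(c("low", "moderate", "high"), n, replace = TRUE,
               prob = c(0.023, 0.280, 0.697))

  sigma_p <- 5.5
  g_sd <- sqrt(config$bmi_h2) * sigma_p
  e_sd <- sqrt(1 - config$bmi_h2) * sigma_p
  bmi <- 27.9 + 0.04 * (age - 44.9) - 0.4 * (sex == "female") +
    g_sd * Z + rnorm(n, 0, e_sd)

  covariates <- data.frame(participant_id = id, age = round(age, 1), sex = sex,
                           enrollment_date = enroll, bmi = round(bmi, 2),
                           job_type = job, education = edu,
                           smoking = as.integer(smoker), physical_activity = pa,
                           stringsAsFactors = FALSE)

  # transaction streams
  kappa <- if (!is.null(pe$quality) && pe$quality != 0)
    pe$quality / hps_logit_slope(br$color_probs) else 0
  u <- br$color_probs[["unlabeled"]]
  cal_days <- lapply(seq_len(n), function(i) {
    dd <- seq(enroll[i] - 91, enroll[i] - 1, by = "day")
    dd[!format(dd, "%u") %in% c("6", "7")]
  })
  tx_list <- vector("list", n)
  for (i in seq_len(n)) {
    mu <- max(0.1, br$mean_items + (pe$quantity %||% 0) * Z[i])
    k <- rnbinom(1L, size = br$dispersion, mu = mu)
    if (k == 0L) next
    delta <- kappa * Z[i]
    labp <- c(br$color_probs[["green"]] * exp(delta),
              br$color_probs[["yellow"]],
              br$color_probs[["red"]] * exp(-delta))
    labp <- labp / sum(labp) * (1 - u)
    color <- sample(c("green", "yellow", "red", "unlabeled"), k,
                    replace = TRUE, prob = c(labp, u))
    meal <- sample(c("breakfast", "lunch", "other"), k, replace = TRUE,
                   prob = c(0.30, 0.45, 0.25))
    minutes <- integer(k)
    nb <- sum(meal == "breakfast")
    nl <- sum(meal == "lunch")
    no <- sum(meal == "other")
    bmean <- br$breakfast_time + (pe$breakfast_timing %||% 0) * Z[i]
    if (nb) minutes[meal == "breakfast"] <-
      pmin(599L, pmax(360L, round(rnorm(nb, bmean, 25))))
    if (nl) minutes[meal == "lunch"] <-
      pmin(839L, pmax(660L, round(rnorm(nl, br$lunch_time, 25))))
    if (no) minutes[meal == "other"] <- sample(360:1199, no, replace = TRUE)
    is_food <- ifelse(meal == "other", runif(k) < 0.5, runif(k) < 0.85)
    day <- sample(cal_days[[i]], k, replace = TRUE)
    tx_list[[i]] <- data.frame(
      participant_id = id[i],
      timestamp = sprintf("%s %02d:%02d:00", format(day, "%Y-%m-%d"),
                          minutes %/% 60L, minutes %% 60L),
      item_id = sprintf("I%04d", sample.int(1200L, k, replace = TRUE)),
      item_class = ifelse(is_food, "food", "beverage"),
      color = color, stringsAsFactors = FALSE)
  }
  transactions <- do.call(rbind, tx_list[!vapply(tx_list, is.null, logical(1))])
  if (is.null(transactions))
    transactions <- data.frame(participant_id = character(), timestamp = character(),
                               item_id = character(), item_class = character(),
                               color = character(), stringsAsFactors = FALSE)
  rownames(transactions) <- NULL

  # survey categories generated so the standard dichotomization inverts them
  skip_cat <- function(base, lo) {
    yes <- runif(n) < plogis(qlogis(base) + lo * Z)
    ifelse(yes, sample(c("1-2 days", "3-4 days", "5-6 days", "Every day"),
                       n, replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1)),
           "Never")
  }
  home_cat <- function(base, lo) {
    yes <- runif(n) < plogis(qlogis(base) + lo * Z)
    ifelse(yes, sample(c("3-4 days", "5-6 days", "Every day"),
                       n, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
           sample(c("Never", "1-2 days"), n, replace = TRUE, prob = c(0.4, 0.6)))
  }
  survey <- data.frame(
    participant_id = id,
    skip_breakfast = skip_cat(0.413, pe$skips_breakfast %||% 0),
    skip_lunch = skip_cat(0.345, pe$skips_lunch %||% 0),
    skip_dinner = skip_cat(0.209, pe$skips_dinner %||% 0),
    home_breakfast = home_cat(0.287, pe$prepares_breakfast_home %||% 0),
    home_lunch = home_cat(0.096, pe$prepares_lunch_home %||% 0),
    home_dinner = home_cat(0.549, pe$prepares_dinner_home %||% 0),
    stringsAsFactors = FALSE)

  list(covariates = covariates, transactions = transactions, survey = survey)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_genotypes()] then [simulate_phenotypes()] under one
#' config and returns everything a pipeline run consumes, plus the ground
#' truth (which the pipeline never reads).
#'
#' @param config A `sim_config`.
#' @return List: `genotypes`, `truth`, `weights_gws`, `weights_97`,
#'   `covariates`, `transactions`, `survey`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  gt <- simulate_genotypes(config)
  ph <- simulate_phenotypes(gt$genotypes, gt$truth, config)
  list(genotypes = gt$genotypes, truth = gt$truth,
       weights_gws = gt$truth$weights_gws, weights_97 = gt$truth$weights_97,
       covariates = ph$covariates, transactions = ph$transactions,
       survey = ph$survey)
}
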