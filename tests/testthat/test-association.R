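test_that("inverse normal transform matches normal quantiles and handles ties", {
  z <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(z, qnorm(c(1, 3, 5) / 6), tolerance = 1e-10)
  expect_equal(z[2], 0)
  # tied middle pair of n = 4 averages to rank 2.5 -> qnorm(0.5) = 0
  z4 <- inverse_normal_transform(c(1, 5, 5, 9))
  expect_equal(z4[2], 0); expect_equal(z4[3], 0)
  # rank invariance: shuffling permutes the outputs identically
  x <- c(3.2, 1.1, 8.9, 4.4, 0.2, 7.7)
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(inverse_normal_transform(x)[perm],
               inverse_normal_transform(x[perm]))
  expect_error(inverse_normal_transform(rep(1, 5)), "constant")
  expect_error(inverse_normal_transform(c(2)), "n >= 2")
})

test_that("transform is monotone and rank-idempotent", {
  set.seed(5)
  x <- rexp(200)    # skewed input
  z <- inverse_normal_transform(x)
  expect_true(all(diff(z[order(x)]) > 0))
  expect_equal(inverse_normal_transform(z), z, tolerance = 1e-6)
  expect_lt(abs(mean(z)), 1e-8)
})

test_that("seasonality harmonics trace the annual cycle", {
  jan1 <- seasonality_terms(as.Date("2017-01-01"))
  expect_equal(jan1$season_sin, 0, tolerance = 1e-6)
  expect_equal(jan1$season_cos, 1, tolerance = 1e-6)
  apr2 <- seasonality_terms(as.Date("2017-04-02"))  # day 92
  expect_equal(apr2$season_sin, 1, tolerance = 0.02)
  expect_equal(apr2$season_cos, 0, tolerance = 0.02)
  dd <- seq(as.Date("2016-01-01"), as.Date("2016-12-31"), by = "day")
  st <- seasonality_terms(dd)
  expect_equal(st$season_sin^2 + st$season_cos^2, rep(1, length(dd)))
})

test_that("heterogeneity z-test arithmetic", {
  expect_lt(abs(heterogeneity_test(0.5, 0.1, 0.1, 0.1) - 0.00468), 1e-4)
  expect_equal(heterogeneity_test(0.3, 0.2, 0.3, 0.4), 1.0)
  expect_error(heterogeneity_test(0.5, 0, 0.1, 0.1), "positive")
  expect_error(heterogeneity_test(NA, 1, 0.1, 0.1), "finite")
})

test_that("BH adjustment matches the hand step-up on the worked examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.73), 0.73)
  expect_equal(bh_fdr(c(0.001, 0.9)), c(0.002, 0.9))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH equals the step-up oracle on permutations", {
  set.seed(7)
  for (i in 1:40) {
    p <- runif(sample(2:5, 1))
    for (perm in list(seq_along(p), rev(seq_along(p)),
                      sample(seq_along(p)))) {
      expect_equal(bh_fdr(p[perm]), bh_oracle(p[perm]), tolerance = 1e-12)
    }
    expect_true(all(bh_fdr(p) >= p))
  }
})

sim_assoc_data <- function(n, q4_effect = 0, type = "continuous",
                           outcome = "y") {
  score <- rnorm(n)
  quart <- assign_quartiles(score)
  age <- runif(n, 20, 75)
  sex <- factor(sample(c("female", "male"), n, replace = TRUE))
  delta <- c(0, q4_effect / 3, 2 * q4_effect / 3, q4_effect)[as.integer(quart)]
  df <- data.frame(quartile = quart, standardized = score, age = age,
                   sex = sex)
  if (type == "continuous") {
    df[[outcome]] <- 70 + 0.05 * age + delta + rnorm(n, 0, 8)
  } else {
    df[[outcome]] <- rbinom(n, 1, plogis(-0.5 + delta))
  }
  df
}

test_that("quartile model recovers a known Q4 - Q1 contrast", {
  set.seed(11)
  est <- replicate(40, {
    df <- sim_assoc_data(1500, q4_effect = -5)
    fit <- fit_quartile_model(df, "y", "continuous", c("age", "sex"))
    fit$effect[fit$contrast == "Q4"]
  })
  expect_equal(mean(est), -5, tolerance = 0.35)
})

test_that("binary quartile model reports calibrated odds ratios", {
  set.seed(13)
  df <- sim_assoc_data(2000, q4_effect = log(2), type = "binary")
  fit <- fit_quartile_model(df, "y", "binary", c("age", "sex"))
  q4 <- fit[fit$contrast == "Q4", ]
  expect_gt(q4$effect, 1)
  expect_true(q4$ci_low <= q4$effect & q4$effect <= q4$ci_high)
  expect_true(all(fit$effect > 0))
})

test_that("logistic CI coverage is near nominal under the null covariate", {
  set.seed(17)
  hits <- replicate(150, {
    df <- sim_assoc_data(800, q4_effect = log(1.8), type = "binary")
    df$noise <- rnorm(800)   # true log-odds 0
    m <- glm(y ~ quartile + age + sex + noise, data = df, family = binomial())
    ci <- coef(m)["noise"] + c(-1, 1) * 1.959964 *
      summary(m)$coefficients["noise", 2]
    ci[1] <= 0 & 0 <= ci[2]
  })
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("model guards: too few cases, singular design, separation flag", {
  set.seed(19)
  df <- sim_assoc_data(30)
  expect_error(fit_quartile_model(df, "y", "continuous",
                                  c("age", "sex")), "complete cases")
  df2 <- sim_assoc_data(400)
  df2$age2 <- df2$age * 2
  expect_error(fit_quartile_model(df2, "y", "continuous", c("age", "age2")),
               "collinear")
  # engineered separation: outcome constant within Q4
  df3 <- sim_assoc_data(400, type = "binary")
  df3$y[df3$quartile == "Q4"] <- 1
  fit <- fit_quartile_model(df3, "y", "binary")
  q4 <- fit[fit$contrast == "Q4", ]
  expect_equal(q4$flag, "possible_separation")
  expect_true(is.na(q4$ci_low))
})

test_that("trend test pools the quartile ordering", {
  set.seed(23)
  df <- sim_assoc_data(1200, q4_effect = -6)
  p_q2 <- fit_quartile_model(df, "y", "continuous", c("age", "sex"))
  pt <- trend_test(df, "y", "continuous", c("age", "sex"))
  expect_lt(pt, p_q2$p[p_q2$contrast == "Q2"])
  expect_error(trend_test(sim_assoc_data(8), "y", "continuous"),
               "complete cases")
})

test_that("full analysis produces the expected bookkeeping", {
  cfg <- simulation_config(n_participants = 350, n_variants = 200,
                           n_blocks = 40, seed = 311)
  ds <- simulate_dataset(cfg)
  # variant QC + PCs only: relatedness pruning is exercised elsewhere and
  # is too noisy at a 200-marker panel to leave a usable sample
  vqc <- variant_qc(ds$genotypes, qc_thresholds())
  g <- subset_genotypes(ds$genotypes, variants = which(vqc$keep))
  pcs <- ancestry_pcs(g, k = 3)
  cv <- ds$covariates
  w97 <- ds$weights_97[ds$weights_97$ID %in% g$variants$id, ]
  scores <- partition_scores(w97, g)
  phen <- derive_phenotypes(ds$transactions, ds$survey, cv)
  out <- run_full_analysis(scores, phen, cv, pcs = pcs,
                           outcomes = c("healthy_purchasing_score",
                                        "total_items", "skips_breakfast"))
  # 3 scores x 3 outcomes x (Q2,Q3,Q4,per_SD)
  expect_equal(nrow(out), 3 * 3 * 4)
  expect_true(all(out$ci_low <= out$effect & out$effect <= out$ci_high,
                  na.rm = TRUE))
  prim <- out$contrast %in% c("Q2", "Q3", "Q4")
  expect_true(all(out$p_adj[prim] >= out$p[prim]))
  expect_true(all(is.na(out$p_adj[!prim])))
  # heterogeneity P present exactly on the stratified score rows
  expect_true(all(!is.na(out$p_int[out$score %in% c("BMI_CNS", "BMI_nonCNS")])))
  expect_true(all(is.na(out$p_int[out$score == "BMI_97"])))
  expect_true(all(out$p > 0 & out$p <= 1))
  # orphan participants are reported by ID
  bad <- scores
  bad$BMI_97$participant_id[1] <- "ghost"
  expect_error(run_full_analysis(bad, phen, cv, pcs = pcs,
                                 outcomes = "total_items"), "ghost")
})
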