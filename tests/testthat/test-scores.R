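test_that("ld_r2 matches hand-computed values and rejects bad input", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1.0)
  expect_equal(ld_r2(c(1, 1, -1, -1), c(1, -1, 1, -1)), 0.0)
  # hand computation: r = 2/sqrt(5.6), r2 = 5/7
  expect_equal(ld_r2(c(0, 1, 2, 0, 1), c(0, 1, 2, 1, 1)), 5 / 7,
               tolerance = 1e-10)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_error(ld_r2(c(1), c(0)), "length")
})

test_that("clumping keeps the strongest signal and its independent neighbors", {
  # engineered LD: v1-v2 correlated, v3 nearly independent
  set.seed(41)
  n <- 400
  v1 <- rbinom(n, 2, 0.4)
  copy <- rbinom(n, 1, 0.75)
  v2 <- ifelse(copy == 1, v1, rbinom(n, 2, 0.4))
  v3 <- rbinom(n, 2, 0.4)
  stopifnot(cor(v1, v2)^2 > 0.3, cor(v1, v3)^2 < 0.1)
  g <- make_genotypes(cbind(v1, v2, v3), pos = c(1000L, 2000L, 3000L))
  w <- make_weights(g, p = c(1e-9, 1e-5, 0.2))
  expect_equal(clump(w, g, gps_config()), c("v001", "v003"))
  # different chromosomes: window never applies
  g2 <- make_genotypes(cbind(v1, v2), chr = c(1L, 2L), pos = c(1000L, 1000L))
  w2 <- make_weights(g2, p = c(1e-9, 1e-5))
  expect_setequal(clump(w2, g2, gps_config()), c("v001", "v002"))
  # single variant trivially retained
  g3 <- make_genotypes(cbind(v1))
  expect_equal(clump(make_weights(g3), g3, gps_config()), "v001")
  # missing genotype column is an error naming the variant
  w_bad <- make_weights(g3); w_bad$ID <- "vXXX"
  expect_error(clump(w_bad, g3, gps_config()), "vXXX")
})

test_that("greedy clumping equals the literal oracle on random instances", {
  set.seed(43)
  cfg <- gps_config(clump_window = 5000, clump_r2 = 0.1)
  for (i in 1:60) {
    V <- sample(2:20, 1)
    n <- 40
    # blocky LD so r2 values straddle the cutoff
    p <- runif(V, 0.1, 0.5)
    d <- matrix(0, n, V)
    d[, 1] <- rbinom(n, 2, p[1])
    for (j in 2:max(2, V)) {
      if (V == 1) break
      cp <- rbinom(n, 1, runif(1, 0, 0.9))
      d[, j] <- ifelse(cp == 1, d[, j - 1], rbinom(n, 2, p[j]))
    }
    g <- make_genotypes(d, chr = sample(1:2, V, replace = TRUE),
                        pos = sample.int(20000L, V))
    w <- make_weights(g, p = signif(runif(V), 3))
    expect_identical(clump(w, g, cfg), clump_oracle(w, g, cfg))
  }
})

test_that("raw score arithmetic and missing-dosage imputation", {
  g <- make_genotypes(cbind(c(1, 0, NA), c(2, 0, 2)))
  w <- make_weights(g, beta = c(0.1, 0.3))
  rs <- raw_score(w, g)
  expect_equal(unname(rs[1]), 0.1 * 1 + 0.3 * 2)
  expect_equal(unname(rs[2]), 0)
  # missing dosage imputed at 2 x effect-allele frequency (freq of v001 = 0.25)
  expect_equal(unname(rs[3]), 0.1 * 2 * 0.25 + 0.3 * 2)
})

test_that("scores are invariant to reported allele orientation", {
  set.seed(47)
  g <- random_genotypes(80, 30)
  beta <- rnorm(30, 0, 0.1)
  w <- make_weights(g, beta = beta, p = runif(30))
  flip <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  w2 <- w
  w2$EA[flip] <- w$OA[flip]; w2$OA[flip] <- w$EA[flip]
  w2$BETA[flip] <- -w$BETA[flip]
  expect_equal(raw_score(w, g), raw_score(w2, g), tolerance = 1e-10)
  # strand-flipped alleles resolve via complement
  w3 <- w
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  w3$EA <- unname(comp[w3$EA]); w3$OA <- unname(comp[w3$OA])
  expect_equal(raw_score(w, g), raw_score(w3, g), tolerance = 1e-10)
  # unresolvable alleles error with the variant named
  w4 <- w; w4$EA[1] <- "A"; w4$OA[1] <- "T"; w4$OA[2] <- w4$EA[2]
  expect_error(raw_score(w4, g), "mismatch")
})

test_that("PRS scaling puts scores on the risk-allele-count scale", {
  g <- make_genotypes(cbind(c(1, 2, 0), c(2, 2, 0)))
  w <- make_weights(g, beta = c(0.1, 0.3))
  raw <- raw_score(w, g)
  scaled <- scale_prs(raw, w)
  expect_equal(unname(scaled[1]), 0.7 * 4 / 0.8)  # = 3.5
  expect_equal(unname(scaled[2]), 4)              # 2M at max risk load
  expect_equal(unname(scaled[3]), 0)
  expect_error(scale_prs(raw, make_weights(g, beta = c(0, 0))), "positive")
})

test_that("GPS threshold behavior: monotone counts, errors at empty sets", {
  set.seed(53)
  g <- random_genotypes(150, 40)
  g$variants$pos <- seq_len(40) * 400000L  # no clumping interference
  pv <- runif(40, 0.001, 1)
  pv[1:6] <- runif(6, 1e-4, 9e-4)  # strictest threshold keeps a scoreable set
  w <- make_weights(g, beta = rnorm(40, 0, 0.05), p = pv)
  cfg <- gps_config()
  counts <- sapply(cfg$thresholds, function(t)
    attr(build_gps(w, g, t, cfg), "n_variants"))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[length(counts)], 40)   # threshold 1.0 keeps all clumped
  expect_error(build_gps(w, g, 1e-9, cfg), "survive")
})

test_that("best-fit scan picks the signal-bearing threshold", {
  set.seed(59)
  n <- 800; V <- 60
  g <- random_genotypes(n, V)
  g$variants$pos <- seq_len(V) * 400000L
  causal <- 1:20
  beta <- numeric(V); beta[causal] <- rnorm(20, 0, 0.15)
  pv <- runif(V); pv[causal] <- runif(20, 1e-8, 0.15)
  # null variants carry junk discovery weights, so permissive thresholds
  # dilute the score and the scan should stop at or before 0.5
  w_beta <- beta + rnorm(V, 0, 0.01)
  w_beta[-causal] <- rnorm(V - 20, 0, 0.15)
  w <- make_weights(g, beta = w_beta, p = pv)
  bmi <- 27 + drop(g$dosage %*% beta) * 3 + rnorm(n, 0, 1.5)
  bf <- best_fit_threshold(g, w, bmi, cfg = gps_config())
  expect_lte(bf$threshold, 0.5)
  expect_true(all(na.omit(bf$r2_by_threshold$r2) >= 0 &
                    na.omit(bf$r2_by_threshold$r2) <= 1))
  # single-threshold grid returns that threshold
  bf1 <- best_fit_threshold(g, w, bmi, cfg = gps_config(thresholds = 0.3))
  expect_equal(bf1$threshold, 0.3)
  expect_error(best_fit_threshold(g, w, rep(25, n)), "constant")
})

test_that("partition scores decompose the full panel exactly", {
  set.seed(61)
  g <- random_genotypes(100, 30)
  w <- make_weights(g, beta = rnorm(30, 0.05, 0.05), p = runif(30),
                    cns = sample(c("CNS", "non-CNS"), 30, replace = TRUE))
  ps <- partition_scores(w, g)
  expect_equal(ps$BMI_97$raw, ps$BMI_CNS$raw + ps$BMI_nonCNS$raw,
               tolerance = 1e-10)
  expect_gt(cor(ps$BMI_97$raw, ps$BMI_CNS$raw), 0)
  expect_gt(cor(ps$BMI_97$raw, ps$BMI_nonCNS$raw), 0)
  n_cns <- attr(ps$BMI_CNS, "n_variants")
  expect_equal(n_cns + attr(ps$BMI_nonCNS, "n_variants"),
               attr(ps$BMI_97, "n_variants"))
  w_bad <- w; w_bad$CNS[3] <- "unannotated"
  expect_error(partition_scores(w_bad, g), "unannotated")
  w_one <- w; w_one$CNS <- "CNS"
  expect_error(partition_scores(w_one, g), "empty")
})

test_that("standardized scores have mean 0 and SD 1", {
  set.seed(67)
  g <- random_genotypes(200, 25)
  w <- make_weights(g, beta = rnorm(25, 0, 0.1), p = runif(25))
  ss <- build_gps(w, g, 1.0, gps_config())
  expect_lt(abs(mean(ss$standardized)), 1e-8)
  expect_lt(abs(sd(ss$standardized) - 1), 1e-8)
})

test_that("quartile assignment cuts at empirical quartiles, ties downward", {
  q <- assign_quartiles(1:8)
  expect_equal(as.character(q), rep(paste0("Q", 1:4), each = 2))
  expect_error(assign_quartiles(rep(2, 10)), "degenerate")
  expect_error(assign_quartiles(1:3), "at least 4")
  set.seed(71)
  x <- sample(seq(0, 1, length.out = 397))
  sizes <- sort(as.integer(table(assign_quartiles(x))), decreasing = TRUE)
  expect_equal(sizes, c(100, 99, 99, 99))
  # oracle: sorting reproduces the assignment
  q2 <- assign_quartiles(x)
  expect_true(all(x[q2 == "Q1"] < min(x[q2 == "Q4"])))
  expect_equal(levels(q2)[1], "Q1")
})
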