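# Polygenic scores: allele-orientation resolution, beta-weighted allele
# sums, the risk-allele-count scaling, greedy LD clumping with a P-value
# threshold scan and best-fit selection, CNS/non-CNS partition scores, and
# population quartiles.

#' GPS construction parameters
#'
#' @param clump_window Clumping window in base pairs (+/- from the index
#'   variant, inclusive).
#' @param clump_r2 Squared-correlation cutoff: variants with r2 above this
#'   with a retained index variant are removed.
#' @param thresholds Discovery P-value grid for the threshold scan.
#' @param maf_min,impq_min Variant pre-filters applied before clumping.
#' @return A validated list of class `gps_config`.
#' @export
gps_config <- function(clump_window = 250000,
                       clump_r2 = 0.1,
                       thresholds = c(0.001, 0.01, 0.05, 0.1, 0.19,
                                      0.25, 0.5, 1.0),
                       maf_min = 0.01, impq_min = 0.50) {
  if (clump_window <= 0) stop("clump_window must be positive")
  if (clump_r2 <= 0 || clump_r2 >= 1) stop("clump_r2 must lie in (0, 1)")
  if (!length(thresholds) || any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  structure(list(clump_window = clump_window, clump_r2 = clump_r2,
                 thresholds = sort(unique(thresholds)),
                 maf_min = maf_min, impq_min = impq_min),
            class = "gps_config")
}

#' Squared Pearson correlation between two dosage vectors
#'
#' @param dosages_a,dosages_b Equal-length numeric vectors (length >= 2,
#'   non-constant).
#' @return r2 in \[0, 1\].
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b) || length(dosages_a) < 2)
    stop("dosage vectors must have equal length >= 2")
  if (sd(dosages_a) == 0 || sd(dosages_b) == 0)
    stop("correlation undefined for a constant dosage vector")
  min(1, cor(dosages_a, dosages_b)^2)
}

#' Greedy LD clumping
#'
#' Repeatedly retains the unretired variant with the smallest discovery P
#' (ties broken by smaller position, then lexicographic ID) and retires
#' every unretired variant on the same chromosome within the window whose
#' in-sample r2 with the index exceeds `clump_r2`.
#'
#' @param weights Weight table (`ID, CHR, POS, EA, OA, BETA, P, CNS`).
#' @param genotypes A `genotype_matrix` holding every weight variant.
#' @param cfg A [gps_config()].
#' @return Character vector of retained variant IDs sorted by chromosome
#'   and position.
#' @export
clump <- function(weights, genotypes, cfg = gps_config()) {
  miss <- setdiff(weights$ID, genotypes$variants$id)
  if (length(miss))
    stop("genotypes lack variant(s): ", paste(head(miss, 5), collapse = ", "))
  d <- genotypes$dosage[, match(weights$ID, genotypes$variants$id),
                        drop = FALSE]
  # mean-impute missing calls so correlations are defined
  for (j in which(colSums(is.na(d)) > 0))
    d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  ord <- order(weights$P, weights$POS, weights$ID)
  retired <- rep(FALSE, nrow(weights))
  retained <- logical(nrow(weights))
  for (i in ord) {
    if (retired[i]) next
    retained[i] <- TRUE
    retired[i] <- TRUE
    cand <- which(!retired &
                    weights$CHR == weights$CHR[i] &
                    abs(weights$POS - weights$POS[i]) <= cfg$clump_window)
    if (length(cand)) {
      sd_i <- sd(d[, i])
      if (sd_i == 0) next   # monomorphic index tags nothing
      sds <- apply(d[, cand, drop = FALSE], 2, sd)
      r2 <- rep(0, length(cand))
      nz <- sds > 0
      if (any(nz)) r2[nz] <- drop(cor(d[, i], d[, cand[nz], drop = FALSE]))^2
      retired[cand[r2 > cfg$clump_r2]] <- TRUE
    }
  }
  keep <- weights[retained, ]
  keep$ID[order(keep$CHR, keep$POS)]
}

# Resolve effect-allele orientation against the genotype matrix.
# Negative-beta rows are first flipped to risk orientation (allele swap +
# sign flip); then the effect dosage is the stored dosage when EA matches
# the counted allele, 2 - dosage when swapped, with strand complements
# tried before failing. Returns the effect-allele dosage matrix (missing
# calls imputed as 2 x effect-allele frequency) and the risk-oriented
# betas.
orient_weights <- function(weights, genotypes) {
  w <- weights
  neg <- w$BETA < 0
  tmp <- w$EA[neg]; w$EA[neg] <- w$OA[neg]; w$OA[neg] <- tmp
  w$BETA[neg] <- -w$BETA[neg]
  idx <- match(w$ID, genotypes$variants$id)
  if (anyNA(idx))
    stop("genotypes lack variant(s): ",
         paste(head(w$ID[is.na(idx)], 5), collapse = ", "))
  v <- genotypes$variants[idx, ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip_strand <- function(x) unname(comp[x])
  direct <- w$EA == v$a1 & w$OA == v$a2
  swapped <- w$EA == v$a2 & w$OA == v$a1
  s_direct <- flip_strand(w$EA) == v$a1 & flip_strand(w$OA) == v$a2
  s_swapped <- flip_strand(w$EA) == v$a2 & flip_strand(w$OA) == v$a1
  use_direct <- direct | (!direct & !swapped & s_direct)
  use_swapped <- (!use_direct) & (swapped | s_swapped)
  bad <- !use_direct & !use_swapped
  if (any(bad))
    stop("allele mismatch for variant(s): ",
         paste(head(w$ID[bad], 5), collapse = ", "))
  d <- genotypes$dosage[, idx, drop = FALSE]
  ea_freq <- ifelse(use_direct, v$freq, 1 - v$freq)
  for (j in seq_len(ncol(d))) {
    if (use_swapped[j]) d[, j] <- 2 - d[, j]
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- 2 * ea_freq[j]
  }
  list(dosage = d, beta = w$BETA)
}

#' Beta-weighted risk-allele sum
#'
#' raw_score = sum_i beta_i * dosage_i after resolving effect-allele
#' orientation (negative-beta variants flipped to risk orientation, so all
#' betas are non-negative at summation). Missing dosages are imputed as
#' 2 x effect-allele frequency.
#'
#' @param weights Weight table.
#' @param genotypes A `genotype_matrix`.
#' @return Named numeric vector, one raw score per participant.
#' @export
raw_score <- function(weights, genotypes) {
  o <- orient_weights(weights, genotypes)
  setNames(drop(o$dosage %*% o$beta), genotypes$samples)
}

#' Scale a raw PRS to the risk-allele-count scale
#'
#' scaled = raw x (2M) / (2 * sum(beta)) with M the variant count and
#' betas risk-oriented (all non-negative), so the scaled score lies in
#' \[0, 2M\] and reads as a weighted count of risk alleles.
#'
#' @param raw Raw scores from [raw_score()].
#' @param weights The weight table the raw scores came from.
#' @return Scaled scores.
#' @export
scale_prs <- function(raw, weights) {
  sum_beta <- sum(abs(weights$BETA))
  if (sum_beta <= 0) stop("sum of beta coefficients must be positive")
  raw * (2 * nrow(weights)) / (2 * sum_beta)
}

standardize <- function(x) (x - mean(x)) / sd(x)

#' Assign population quartiles
#'
#' Cut points at the empirical 25th/50th/75th percentiles; boundary ties
#' go to the lower quartile (right-closed intervals). Q1 holds the lowest
#' scores.
#'
#' @param scores Numeric vector, length >= 4.
#' @return Ordered factor with levels Q1..Q4.
#' @export
assign_quartiles <- function(scores) {
  if (length(scores) < 4) stop("quartiles need at least 4 observations")
  br <- quantile(scores, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  if (anyDuplicated(br))
    stop("degenerate score distribution: quartile cut points coincide")
  cut(scores, breaks = br, labels = paste0("Q", 1:4),
      include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

score_set <- function(participant, raw, weights, score_name) {
  data.frame(participant_id = participant, score_name = score_name,
             raw = unname(raw), scaled = unname(scale_prs(raw, weights)),
             standardized = unname(standardize(raw)),
             quartile = assign_quartiles(raw), stringsAsFactors = FALSE)
}

#' Build a genome-wide polygenic score at one P-value threshold
#'
#' Pre-filters the weight table to MAF > `maf_min` and imputation quality
#' >= `impq_min` (from the genotype metadata), clumps, keeps retained
#' variants with P <= `threshold`, and computes the beta-weighted score.
#'
#' @param weights Genome-wide weight table.
#' @param genotypes A `genotype_matrix`.
#' @param threshold Discovery P-value cutoff.
#' @param cfg A [gps_config()].
#' @param clumped Optional pre-computed retained-ID vector (the clumping
#'   does not depend on the threshold, so scans reuse it).
#' @return Score-set data.frame with attribute `n_variants`.
#' @export
build_gps <- function(weights, genotypes, threshold, cfg = gps_config(),
                      clumped = NULL) {
  w <- filter_weights(weights, genotypes, cfg)
  if (is.null(clumped)) clumped <- clump(w, genotypes, cfg)
  w <- w[w$ID %in% clumped & w$P <= threshold, ]
  if (nrow(w) == 0)
    stop(sprintf("no variants survive P <= %g after clumping", threshold))
  raw <- raw_score(w, genotypes)
  out <- score_set(genotypes$samples, raw, w, "BMI_GPS")
  attr(out, "n_variants") <- nrow(w)
  out
}

filter_weights <- function(weights, genotypes, cfg) {
  idx <- match(weights$ID, genotypes$variants$id)
  if (anyNA(idx))
    stop("genotypes lack variant(s): ",
         paste(head(weights$ID[is.na(idx)], 5), collapse = ", "))
  v <- genotypes$variants[idx, ]
  maf <- pmin(v$freq, 1 - v$freq)
  weights[maf > cfg$maf_min & v$impq >= cfg$impq_min, ]
}

#' Best-fit threshold scan for the genome-wide score
#'
#' For each threshold in the grid, regresses rank-based inverse-normalized
#' BMI on the standardized score (plus any covariates) and selects the
#' threshold maximizing the model R-squared; ties go to the smaller
#' threshold.
#'
#' @param genotypes A `genotype_matrix`.
#' @param weights Genome-wide weight table.
#' @param bmi Numeric BMI per participant (genotype sample order).
#' @param covariates Optional data.frame of additional regressors.
#' @param cfg A [gps_config()] whose `thresholds` define the scan grid.
#' @return List: `threshold`, `score_set` (winning), `r2_by_threshold`
#'   data.frame with the scanned R2 profile and included-variant counts.
#' @export
best_fit_threshold <- function(genotypes, weights, bmi, covariates = NULL,
                               cfg = gps_config()) {
  if (length(cfg$thresholds) < 1) stop("threshold grid is empty")
  if (length(bmi) != length(genotypes$samples))
    stop("bmi length must match the genotype samples")
  if (sd(bmi, na.rm = TRUE) == 0) stop("degenerate BMI: constant values")
  w <- filter_weights(weights, genotypes, cfg)
  clumped <- clump(w, genotypes, cfg)
  y <- inverse_normal_transform(bmi)
  X <- if (is.null(covariates)) data.frame(row.names = seq_along(bmi))
       else as.data.frame(covariates)
  scans <- lapply(cfg$thresholds, function(t) {
    w_t <- w[w$ID %in% clumped & w$P <= t, ]
    if (nrow(w_t) == 0)
      return(list(r2 = NA_real_, n = 0L, score = NULL, weights = NULL))
    raw <- raw_score(w_t, genotypes)
    df <- cbind(data.frame(y = y, score = standardize(raw)), X)
    fit <- lm(y ~ ., data = df)
    list(r2 = summary(fit)$r.squared, n = nrow(w_t), raw = raw,
         weights = w_t)
  })
  r2 <- vapply(scans, function(s) s$r2, numeric(1))
  if (all(is.na(r2))) stop("no variants survive any threshold in the grid")
  best <- which(r2 == max(r2, na.rm = TRUE))[1]   # grid sorted ascending
  win <- scans[[best]]
  ss <- score_set(genotypes$samples, win$raw, win$weights, "BMI_GPS")
  attr(ss, "n_variants") <- win$n
  list(threshold = cfg$thresholds[best], score_set = ss,
       r2_by_threshold = data.frame(threshold = cfg$thresholds, r2 = r2,
                                    n_variants = vapply(scans, function(s)
                                      s$n, integer(1))))
}

#' Full / CNS / non-CNS partition scores
#'
#' Computes three scaled score sets from the annotated PRS weight table:
#' the full panel and its disjoint CNS and non-CNS subsets.
#'
#' @param weights Annotated weight table; every row must carry `CNS` in
#'   `{"CNS", "non-CNS"}`.
#' @param genotypes A `genotype_matrix`.
#' @return Named list of score-set data.frames: `BMI_97`, `BMI_CNS`,
#'   `BMI_nonCNS` (each with attribute `n_variants`).
#' @export
partition_scores <- function(weights, genotypes) {
  bad <- !weights$CNS %in% c("CNS", "non-CNS")
  if (any(bad))
    stop("unannotated variant(s) in the PRS table: ",
         paste(head(weights$ID[bad], 5), collapse = ", "))
  subsets <- list(BMI_97 = weights,
                  BMI_CNS = weights[weights$CNS == "CNS", ],
                  BMI_nonCNS = weights[weights$CNS == "non-CNS", ])
  out <- lapply(names(subsets), function(nm) {
    w <- subsets[[nm]]
    if (nrow(w) == 0) stop("empty ", nm, " variant subset")
    ss <- score_set(genotypes$samples, raw_score(w, genotypes), w, nm)
    attr(ss, "n_variants") <- nrow(w)
    ss
  })
  names(out) <- names(subsets)
  out
}
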