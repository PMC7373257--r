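# Genotype quality control: variant filters (exact Hardy-Weinberg test,
# minor allele frequency, call rate, imputation quality), sample filters
# (call rate, heterozygosity fence), method-of-moments relatedness
# (pi-hat), greedy relatedness pruning, and ancestry principal components.

#' QC thresholds
#'
#' Defaults: HWE P >= 1e-6, MAF >= 0.01, variant call rate >= 0.98,
#' sample call rate >= 0.95, heterozygosity fence median + 3*IQR (high
#' side only), pi-hat <= 0.25, imputation quality >= 0.50.
#'
#' @param hwe_p_min,maf_min,variant_call_min,sample_call_min,het_iqr_mult,pihat_max,impq_min
#'   Numeric thresholds; see Details above.
#' @return A validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-6, maf_min = 0.01,
                          variant_call_min = 0.98, sample_call_min = 0.95,
                          het_iqr_mult = 3, pihat_max = 0.25,
                          impq_min = 0.50) {
  thr <- list(hwe_p_min = hwe_p_min, maf_min = maf_min,
              variant_call_min = variant_call_min,
              sample_call_min = sample_call_min,
              het_iqr_mult = het_iqr_mult, pihat_max = pihat_max,
              impq_min = impq_min)
  unit <- c("hwe_p_min", "maf_min", "variant_call_min", "sample_call_min",
            "pihat_max", "impq_min")
  for (f in unit)
    if (!is.numeric(thr[[f]]) || thr[[f]] < 0 || thr[[f]] > 1)
      stop(sprintf("invalid QC threshold: '%s' must lie in [0, 1]", f),
           call. = FALSE)
  if (thr$het_iqr_mult < 0)
    stop("invalid QC threshold: 'het_iqr_mult' must be >= 0", call. = FALSE)
  class(thr) <- "qc_thresholds"
  thr
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on genotype counts: the P value is the sum of
#' probabilities of all heterozygote counts (conditional on the allele
#' counts) whose probability does not exceed that of the observed table.
#' Probabilities follow the Levene-Haldane conditional distribution,
#' evaluated by the usual stable recurrence from the modal heterozygote
#' count.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts.
#' @return Exact two-sided P value in \[0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(c(n_AA, n_Aa, n_aa) %% 1 != 0))
    stop("genotype counts must be non-negative integers")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  rare <- 2 * min(n_AA, n_aa) + n_Aa   # rarer allele count
  if (rare == 0) return(1.0)           # monomorphic: single attainable table
  # heterozygote counts share the parity of the rare allele count
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1L
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  probs <- numeric(length(hets))
  names(probs) <- hets
  probs[as.character(mid)] <- 1
  # downward recurrence: P(h-2)/P(h) = h(h-1) / ((r-h+2)(2n-r-h+2))
  h <- mid
  while (h >= 2 && (h - 2) >= min(hets)) {
    probs[as.character(h - 2)] <- probs[as.character(h)] *
      h * (h - 1) / ((rare - h + 2) * (2 * n - rare - h + 2))
    h <- h - 2
  }
  # upward: P(h+2)/P(h) = (r-h)(2n-r-h) / ((h+2)(h+1))
  h <- mid
  while ((h + 2) <= max(hets)) {
    probs[as.character(h + 2)] <- probs[as.character(h)] *
      (rare - h) * (2 * n - rare - h) / ((h + 2) * (h + 1))
    h <- h + 2
  }
  probs <- probs / sum(probs)
  p_obs <- probs[as.character(n_Aa)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

hard_calls <- function(dosage) {
  hc <- round(dosage)
  hc[hc < 0] <- 0; hc[hc > 2] <- 2
  hc
}

#' Variant-level QC
#'
#' A variant is kept iff HWE exact P >= `hwe_p_min`, MAF >= `maf_min`,
#' call rate >= `variant_call_min`, and imputation quality >= `impq_min`.
#' HWE is computed on hard-called genotypes (dosage rounded to the nearest
#' integer) over all retained samples.
#'
#' @param genotypes A `genotype_matrix`.
#' @param thr A [qc_thresholds()].
#' @return List with `keep` (named logical over variants) and `report`
#'   (data.frame of exclusions with comma-joined reason codes).
#' @export
variant_qc <- function(genotypes, thr = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (nrow(d) == 0 || ncol(d) == 0) stop("empty genotype matrix")
  call_rate <- colMeans(!is.na(d))
  freq <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  hc <- hard_calls(d)
  hwe_p <- vapply(seq_len(ncol(hc)), function(j) {
    g <- hc[!is.na(hc[, j]), j]
    if (!length(g)) return(1.0)
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  }, numeric(1))
  fails <- cbind(hwe = hwe_p < thr$hwe_p_min,
                 maf = maf < thr$maf_min | is.na(maf),
                 call_rate = call_rate < thr$variant_call_min,
                 impq = genotypes$variants$impq < thr$impq_min)
  keep <- rowSums(fails) == 0
  names(keep) <- genotypes$variants$id
  excl <- which(!keep)
  report <- data.frame(
    id = genotypes$variants$id[excl],
    reason = vapply(excl, function(j)
      paste(colnames(fails)[fails[j, ]], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  list(keep = keep, report = report,
       stats = data.frame(id = genotypes$variants$id, call_rate = call_rate,
                          maf = maf, hwe_p = hwe_p,
                          impq = genotypes$variants$impq))
}

#' Sample-level QC
#'
#' A sample is kept iff its call rate is >= `sample_call_min` and its
#' heterozygosity rate (proportion of hard-called heterozygous genotypes
#' among non-missing calls) does not exceed median + `het_iqr_mult` * IQR.
#' The fence is one-sided high and is computed over samples that pass the
#' call-rate filter. Duplicated samples are not flagged here; relatedness
#' pruning handles them.
#'
#' @inheritParams variant_qc
#' @return List with `keep` (named logical over samples) and `report`.
#' @export
sample_qc <- function(genotypes, thr = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (nrow(d) < 2) stop("sample QC needs at least 2 samples (IQR undefined)")
  call_rate <- rowMeans(!is.na(d))
  hc <- hard_calls(d)
  het <- rowSums(hc == 1, na.rm = TRUE) / rowSums(!is.na(hc))
  cr_pass <- call_rate >= thr$sample_call_min
  fence <- if (any(cr_pass))
    median(het[cr_pass]) + thr$het_iqr_mult * IQR(het[cr_pass]) else Inf
  fails <- cbind(call_rate = !cr_pass, heterozygosity = het > fence)
  keep <- rowSums(fails) == 0
  names(keep) <- genotypes$samples
  excl <- which(!keep)
  report <- data.frame(
    id = genotypes$samples[excl],
    reason = vapply(excl, function(i)
      paste(colnames(fails)[fails[i, ]], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  list(keep = keep, report = report,
       stats = data.frame(id = genotypes$samples, call_rate = call_rate,
                          het_rate = het, het_fence = fence))
}

#' Method-of-moments relatedness (pi-hat) for all sample pairs
#'
#' PLINK-style moment estimator: identity-by-state counts per pair are
#' combined with the expected IBS distribution given allele frequencies to
#' solve for P(IBD=0), P(IBD=1), P(IBD=2); pi-hat = P(IBD=1)/2 + P(IBD=2),
#' with components clamped to \[0, 1\]. The expected IBS probabilities use
#' unbiased factorial-moment estimators of the allele-frequency products
#' (e.g. p^2*q^2 estimated by a(a-1)(T-a)(T-a-1)/T(T-1)(T-2)(T-3) for
#' allele count a of T chromosomes), the finite-sample correction that
#' keeps the estimator centred when frequencies come from the sample
#' itself. Computed on hard calls over variants that are polymorphic and
#' fully observed (the estimator is meant for a post-QC matrix with
#' near-complete calls).
#'
#' @param genotypes A `genotype_matrix` with at least 2 samples and 50
#'   usable variants.
#' @return data.frame `sample_a, sample_b, pihat` over all unordered pairs.
#' @export
estimate_pihat <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (nrow(d) < 2) stop("relatedness needs at least 2 samples")
  hc <- hard_calls(d)
  ok <- colSums(is.na(hc)) == 0
  p <- colMeans(hc, na.rm = TRUE) / 2
  poly <- apply(hc, 2, function(x) sd(x, na.rm = TRUE) > 0) &
    p > 0 & p < 1
  use <- ok & poly
  if (!any(poly)) stop("monomorphic-only panel: pi-hat undefined")
  if (sum(use) < 50)
    stop("fewer than 50 complete polymorphic variants; pi-hat unreliable")
  G <- hc[, use, drop = FALSE]
  m <- ncol(G)
  I0 <- (G == 0) * 1; I1 <- (G == 1) * 1; I2 <- (G == 2) * 1
  # pairwise IBS counts via indicator cross-products
  N_ibs0 <- I0 %*% t(I2) + I2 %*% t(I0)
  N_ibs2 <- I0 %*% t(I0) + I1 %*% t(I1) + I2 %*% t(I2)
  N_ibs1 <- m - N_ibs0 - N_ibs2
  # unbiased estimators of allele-frequency products from allele counts
  # (falling factorials), per SNP: a copies of the counted allele, b of
  # the other, T = a + b chromosomes
  a <- colSums(G)
  TT <- 2 * nrow(G)
  b <- TT - a
  ff <- function(x, k) {
    out <- rep(1, length(x))
    for (i in 0:(k - 1)) out <- out * (x - i)
    out
  }
  denom4 <- ff(TT, 4); denom3 <- ff(TT, 3)
  p2q2 <- ff(a, 2) * ff(b, 2) / denom4
  p3q <- ff(a, 3) * b / denom4
  pq3 <- a * ff(b, 3) / denom4
  p4 <- ff(a, 4) / denom4
  q4 <- ff(b, 4) / denom4
  p2q <- ff(a, 2) * b / denom3
  pq2 <- a * ff(b, 2) / denom3
  # expected per-SNP IBS probabilities conditional on IBD state, summed
  S00 <- sum(2 * p2q2)
  S10 <- sum(4 * p3q + 4 * pq3)
  S20 <- sum(p4 + q4 + 4 * p2q2)
  S11 <- sum(2 * p2q + 2 * pq2)
  S21 <- m - S11
  n <- nrow(G)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  P0 <- N_ibs0[pairs] / S00
  P1 <- (N_ibs1[pairs] - P0 * S10) / S11
  P2 <- (N_ibs2[pairs] - P0 * S20 - P1 * S21) / m
  P0 <- pmin(1, pmax(0, P0)); P1 <- pmin(1, pmax(0, P1))
  P2 <- pmin(1, pmax(0, P2))
  pihat <- pmin(1, pmax(0, P1 / 2 + P2))
  data.frame(sample_a = genotypes$samples[pairs[, 1]],
             sample_b = genotypes$samples[pairs[, 2]],
             pihat = pihat, stringsAsFactors = FALSE)
}

#' Greedy pruning of related samples
#'
#' Builds the graph of pairs with pi-hat above `pihat_max` and repeatedly
#' drops the sample with the most remaining related partners (ties broken
#' by lexicographically smallest ID) until no edge remains, so exactly one
#' member of an isolated related pair is removed.
#'
#' @param pairs Output of [estimate_pihat()].
#' @param thr A [qc_thresholds()]; uses `pihat_max`.
#' @return Character vector of sample IDs to drop (possibly empty).
#' @export
prune_related <- function(pairs, thr = qc_thresholds()) {
  edges <- pairs[pairs$pihat > thr$pihat_max, c("sample_a", "sample_b")]
  drop <- character(0)
  while (nrow(edges) > 0) {
    deg <- sort(table(c(edges$sample_a, edges$sample_b)), decreasing = TRUE)
    top <- deg[deg == deg[1]]
    victim <- sort(names(top))[1]
    drop <- c(drop, victim)
    edges <- edges[edges$sample_a != victim & edges$sample_b != victim, ,
                   drop = FALSE]
  }
  drop
}

#' Ancestry principal components
#'
#' Top-k principal components of the column-standardized dosage matrix
#' (missing dosages mean-imputed, zero-variance columns dropped). The sign
#' of each component is fixed so the largest-magnitude variant loading is
#' positive, making the decomposition deterministic.
#'
#' @param genotypes A post-QC `genotype_matrix`.
#' @param k Number of components; `k = 0` returns an empty table.
#' @return data.frame with `participant_id` and columns `PC1..PCk`.
#' @export
ancestry_pcs <- function(genotypes, k = 5) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  out <- data.frame(participant_id = genotypes$samples,
                    stringsAsFactors = FALSE)
  if (k == 0) return(out)
  d <- genotypes$dosage
  for (j in which(colSums(is.na(d)) > 0))
    d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  sds <- apply(d, 2, sd)
  d <- d[, sds > 0, drop = FALSE]
  d <- scale(d)
  if (k > min(dim(d))) stop("k exceeds the rank of the genotype matrix")
  pc <- prcomp(d, center = FALSE, scale. = FALSE, rank. = k)
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      pc$rotation[, j] <- -load
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- as.data.frame(pc$x[, seq_len(k), drop = FALSE])
  names(scores) <- paste0("PC", seq_len(k))
  cbind(out, scores)
}

#' Run the full genotype QC stage
#'
#' Variant QC, then sample QC, then relatedness pruning and ancestry PCs
#' on the filtered matrix; mirrors the usual marker-then-sample ordering
#' of array QC.
#'
#' @inheritParams variant_qc
#' @param n_pcs Number of ancestry PCs to compute.
#' @return List: `genotypes` (filtered), `pcs`, `variant_report`,
#'   `sample_report`, `related_dropped`, `relatedness_pairs`, and counts.
#' @export
run_qc <- function(genotypes, thr = qc_thresholds(), n_pcs = 5) {
  vqc <- variant_qc(genotypes, thr)
  g <- subset_genotypes(genotypes, variants = which(vqc$keep))
  sqc <- sample_qc(g, thr)
  g <- subset_genotypes(g, samples = which(sqc$keep))
  pairs <- estimate_pihat(g)
  dropped <- prune_related(pairs, thr)
  if (length(dropped))
    g <- subset_genotypes(g, samples = which(!g$samples %in% dropped))
  pcs <- ancestry_pcs(g, k = min(n_pcs, min(dim(g$dosage)) - 1L))
  list(genotypes = g, pcs = pcs, variant_report = vqc$report,
       sample_report = sqc$report, related_dropped = dropped,
       relatedness_pairs = pairs[pairs$pihat > thr$pihat_max, ],
       n_variants_in = ncol(genotypes$dosage),
       n_variants_kept = ncol(g$dosage),
       n_samples_in = nrow(genotypes$dosage),
       n_samples_kept = nrow(g$dosage))
}
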