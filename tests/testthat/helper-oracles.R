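# Independent oracles, deliberately naive: direct log-factorial
# enumeration for the exact HWE distribution, a literal re-reading of the
# greedy clumping rule, and a by-hand Benjamini-Hochberg step-up.

# Exact HWE by full enumeration: Levene-Haldane conditional probability of
# each attainable heterozygote count, evaluated directly from factorials.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (2 * n - nA - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# Literal greedy clumping: re-sorts the remaining variants at every step
# and checks the window/r2 rule pairwise with plain loops.
clump_oracle <- function(weights, genotypes, cfg) {
  d <- genotypes$dosage[, match(weights$ID, genotypes$variants$id),
                        drop = FALSE]
  for (j in seq_len(ncol(d)))
    if (anyNA(d[, j])) d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  remaining <- seq_len(nrow(weights))
  retained <- integer(0)
  while (length(remaining) > 0) {
    ord <- remaining[order(weights$P[remaining], weights$POS[remaining],
                           weights$ID[remaining])]
    idx <- ord[1]
    retained <- c(retained, idx)
    keep <- logical(0)
    for (j in setdiff(remaining, idx)) {
      near <- weights$CHR[j] == weights$CHR[idx] &&
        abs(weights$POS[j] - weights$POS[idx]) <= cfg$clump_window
      r2 <- if (near && sd(d[, idx]) > 0 && sd(d[, j]) > 0)
        cor(d[, idx], d[, j])^2 else 0
      if (!(near && r2 > cfg$clump_r2)) keep <- c(keep, j)
    }
    remaining <- keep
  }
  weights$ID[retained][order(weights$CHR[retained], weights$POS[retained])]
}

# All permutations of 1..m as a list of index vectors (recursive).
combinat_perms <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(m - 1)) {
    for (pos in 0:(m - 1)) {
      out[[length(out) + 1L]] <- append(sub, m, after = pos)
    }
  }
  out
}

# Step-up FDR by hand: q_i = min over j >= i (rank order) of p_j * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)   # rank of p[i]
    cand <- vapply(r:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}
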