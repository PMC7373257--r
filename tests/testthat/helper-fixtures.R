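# Shared fixtures: small genotype matrices and configs built in code.

make_genotypes <- function(dosage, chr = NULL, pos = NULL, a1 = "A",
                           a2 = "G", impq = 1) {
  V <- ncol(dosage)
  genotype_matrix(dosage, data.frame(
    id = sprintf("v%03d", seq_len(V)),
    chr = if (is.null(chr)) rep(1L, V) else chr,
    pos = if (is.null(pos)) seq_len(V) * 1000L else pos,
    a1 = rep_len(a1, V), a2 = rep_len(a2, V),
    freq = colMeans(dosage, na.rm = TRUE) / 2,
    impq = rep_len(impq, V), stringsAsFactors = FALSE))
}

random_genotypes <- function(n, m, maf = c(0.1, 0.5)) {
  p <- runif(m, maf[1], maf[2])
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  make_genotypes(d)
}

tiny_sim_config <- function(...) {
  simulation_config(n_participants = 120, n_variants = 200, n_blocks = 40,
                    ...)
}

make_weights <- function(genotypes, beta = NULL, p = NULL, cns = NULL) {
  v <- genotypes$variants
  V <- nrow(v)
  data.frame(ID = v$id, CHR = v$chr, POS = v$pos, EA = v$a1, OA = v$a2,
             BETA = if (is.null(beta)) rep(0.1, V) else beta,
             P = if (is.null(p)) rep(0.5, V) else p,
             CNS = if (is.null(cns)) rep("unannotated", V) else cns,
             stringsAsFactors = FALSE)
}
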