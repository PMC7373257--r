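# Readers and writers for the pipeline's file formats. Dosage matrices
# travel either as a tab-delimited table (variants in rows, one column per
# sample) or as a minimal VCFv4.2 with GT and DS fields; weight tables are
# tab-delimited ID/CHR/POS/EA/OA/BETA/P/CNS; transactions, surveys and
# covariates are headered CSV.

#' Write a genotype matrix as a tab-delimited dosage table
#'
#' Variants in rows; columns `id, chr, pos, a1, a2, freq, impq` followed by
#' one dosage column per sample. Missing calls are empty cells.
#'
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @export
write_dosage_matrix <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- cbind(g$variants, as.data.frame(t(g$dosage)))
  data.table::fwrite(tab, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read a tab-delimited dosage table
#'
#' @param path Path written by [write_dosage_matrix()].
#' @return A `genotype_matrix`.
#' @export
read_dosage_matrix <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  meta_cols <- c("id", "chr", "pos", "a1", "a2", "freq", "impq")
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss))
    stop("dosage table lacks columns: ", paste(miss, collapse = ", "))
  samp <- setdiff(names(tab), meta_cols)
  dosage <- t(as.matrix(tab[, samp, drop = FALSE]))
  rownames(dosage) <- samp
  genotype_matrix(dosage, tab[, meta_cols])
}

#' Write a genotype matrix as VCF with GT and DS fields
#'
#' Minimal VCFv4.2: `a2` is written as REF and `a1` (the counted allele)
#' as ALT, so the ALT dosage equals the stored dosage. Imputation quality
#' travels in `INFO/IMPQ`; hard genotypes are the rounded dosage.
#'
#' @param g A `genotype_matrix`.
#' @param path Output path (plain text).
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=IMPQ,Number=1,Type=Float,Description=\"Imputation quality (rsq)\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  gt_code <- function(d) {
    hard <- round(d)
    out <- character(length(d))
    out[is.na(d)] <- "./.:."
    ok <- !is.na(d)
    out[ok] <- paste0(c("0/0", "0/1", "1/1")[hard[ok] + 1L], ":",
                      sprintf("%g", d[ok]))
    out
  }
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chr[j], v$pos[j], v$id[j], v$a2[j], v$a1[j], ".", "PASS",
            sprintf("IMPQ=%g", v$impq[j]),
            "GT:DS", gt_code(g$dosage[, j])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Uses the DS (dosage) FORMAT field when present, otherwise counts ALT
#' alleles from GT. The ALT allele becomes the counted allele `a1`.
#'
#' @param path VCF path (plain or bgzipped).
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  fmt_has_ds <- any(grepl("DS", vcf@gt[, "FORMAT"]))
  if (fmt_has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, 2, function(x) {
      x <- gsub("\\|", "/", x)
      out <- rep(NA_real_, length(x))
      out[x == "0/0"] <- 0; out[x %in% c("0/1", "1/0")] <- 1
      out[x == "1/1"] <- 2
      out
    })
    rownames(ds) <- rownames(gt)
  }
  impq <- suppressWarnings(as.numeric(sub(".*IMPQ=([0-9.eE+-]+).*", "\\1",
                                          fix$INFO)))
  impq[is.na(impq)] <- 1
  dosage <- t(ds)
  freq <- colMeans(dosage, na.rm = TRUE) / 2
  variants <- data.frame(id = fix$ID, chr = as.integer(fix$CHROM),
                         pos = as.integer(fix$POS), a1 = fix$ALT, a2 = fix$REF,
                         freq = freq, impq = impq, stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants)
}

#' Read a GWAS weight table
#'
#' Tab-delimited with header `ID CHR POS EA OA BETA P CNS`; `CNS` may be
#' absent (treated as unannotated).
#'
#' @param path File path.
#' @export
read_weight_table <- function(path) {
  w <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("ID", "CHR", "POS", "EA", "OA", "BETA", "P")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stop("weight table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(w$CNS)) w$CNS <- "unannotated"
  validate_weight_table(w)
  w
}

validate_weight_table <- function(w) {
  if (anyDuplicated(w$ID)) stop("weight table has duplicated variant IDs")
  if (any(!is.finite(w$BETA))) stop("weight table has non-finite BETA")
  if (any(w$P <= 0 | w$P > 1)) stop("weight table P values must lie in (0, 1]")
  invisible(w)
}

#' Write a weight table
#' @param w Weight table data.frame.
#' @param path Output path.
#' @export
write_weight_table <- function(w, path) {
  data.table::fwrite(w, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a transaction log CSV
#'
#' Columns: `participant_id, timestamp (ISO-8601), item_id, item_class
#' (food/beverage), color (green/yellow/red/unlabeled)`.
#'
#' @param path File path.
#' @export
read_transactions <- function(path) {
  tx <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = "timestamp"))
  need <- c("participant_id", "timestamp", "item_id", "item_class", "color")
  miss <- setdiff(need, names(tx))
  if (length(miss))
    stop("transaction log lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tx$color), c("green", "yellow", "red", "unlabeled"))
  if (length(bad))
    stop("unrecognized traffic-light color(s): ", paste(bad, collapse = ", "))
  tx
}

#' Read a survey CSV
#' @param path File path.
#' @export
read_survey <- function(path) {
  sv <- data.table::fread(path, data.table = FALSE)
  need <- c("participant_id", "skip_breakfast", "skip_lunch", "skip_dinner",
            "home_breakfast", "home_lunch", "home_dinner")
  miss <- setdiff(need, names(sv))
  if (length(miss))
    stop("survey table lacks columns: ", paste(miss, collapse = ", "))
  sv
}

#' Read a covariate CSV
#' @param path File path.
#' @export
read_covariates <- function(path) {
  cv <- data.table::fread(path, data.table = FALSE)
  need <- c("participant_id", "age", "sex", "enrollment_date")
  miss <- setdiff(need, names(cv))
  if (length(miss))
    stop("covariate table lacks columns: ", paste(miss, collapse = ", "))
  cv$enrollment_date <- as.Date(cv$enrollment_date)
  cv
}

#' Write a simulated dataset to a directory
#'
#' Emits every file the pipeline stages read: genotypes as both VCF and
#' dosage table, both weight tables, transactions/survey/covariates CSVs,
#' and the ground truth as a separate CSV never consumed by the pipeline.
#'
#' @param ds Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dosage_matrix(ds$genotypes, file.path(dir, "dosages.tsv"))
  write_genotypes_vcf(ds$genotypes, file.path(dir, "genotypes.vcf"))
  write_weight_table(ds$weights_gws, file.path(dir, "weights_gws.tsv"))
  write_weight_table(ds$weights_97, file.path(dir, "weights_97.tsv"))
  data.table::fwrite(ds$transactions, file.path(dir, "transactions.csv"))
  data.table::fwrite(ds$survey, file.path(dir, "survey.csv"))
  data.table::fwrite(ds$covariates, file.path(dir, "covariates.csv"))
  data.table::fwrite(ds$truth$causal_betas, file.path(dir, "ground_truth_betas.csv"))
  data.table::fwrite(data.frame(participant_id = names(ds$truth$true_score),
                                true_score = unname(ds$truth$true_score)),
                     file.path(dir, "ground_truth_score.csv"))
  invisible(dir)
}
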