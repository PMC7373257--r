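# End-to-end orchestration: simulate -> QC -> scores -> phenotypes ->
# associate, one directory per run, with a manifest (config hash, file
# checksums, per-stage counts) and a human-readable summary.

#' Default pipeline configuration
#'
#' Nested list with one element per stage: `sim` ([simulation_config()]
#' arguments), `qc` ([qc_thresholds()] arguments), `gps` ([gps_config()]
#' arguments), and `association` (outcome list, number of PCs, sensitivity
#' covariates).
#'
#' @param seed Seed forwarded to the simulation stage.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(sim = list(seed = as.integer(seed)),
       qc = list(),
       gps = list(),
       association = list(n_pcs = 5,
                          outcomes = names(OUTCOME_TYPES),
                          extra_covariates = character(0)))
}

validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) stop("pipeline config must be a list")
  extra <- setdiff(names(cfg), c("sim", "qc", "gps", "association"))
  if (length(extra))
    stop("unknown pipeline config section(s): ", paste(extra, collapse = ", "))
  # constructors validate ranges and name the offending field
  sim_cfg <- do.call(simulation_config, cfg$sim %||% list())
  thr <- do.call(qc_thresholds, cfg$qc %||% list())
  gcfg <- do.call(gps_config, cfg$gps %||% list())
  assoc <- modifyList(default_pipeline_config()$association,
                      cfg$association %||% list())
  list(sim = sim_cfg, qc = thr, gps = gcfg, association = assoc)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Stage order: simulate (or load) inputs, genotype QC, score
#' construction (best-fit genome-wide score plus the 97-variant partition
#' scores), purchase phenotypes, association models. Each stage writes
#' its outputs under a numbered subdirectory of `out_dir`; stages never
#' overwrite their inputs. A `manifest.json` (config hash, seed, file
#' checksums, per-stage counts) and `summary.txt` are written at the end.
#'
#' @param config A nested config list (see [default_pipeline_config()]),
#'   or the path of a YAML file holding one.
#' @param out_dir Output directory; one directory per run.
#' @param seed Optional override of the simulation seed.
#' @return Invisibly, a list with the association `results`, the
#'   `manifest`, and the stage output paths.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  # 1 -- simulate
  ds <- simulate_dataset(cfg$sim)
  sim_dir <- file.path(out_dir, "01_simulated")
  write_dataset(ds, sim_dir)
  counts$simulated <- list(participants = length(ds$genotypes$samples),
                           variants = ncol(ds$genotypes$dosage),
                           transactions = nrow(ds$transactions))

  # 2 -- genotype QC
  qc <- run_qc(ds$genotypes, cfg$qc, n_pcs = cfg$association$n_pcs)
  qc_dir <- file.path(out_dir, "02_qc")
  dir.create(qc_dir, showWarnings = FALSE)
  data.table::fwrite(qc$variant_report, file.path(qc_dir, "variants_excluded.csv"))
  data.table::fwrite(qc$sample_report, file.path(qc_dir, "samples_excluded.csv"))
  data.table::fwrite(data.frame(id = qc$related_dropped),
                     file.path(qc_dir, "related_dropped.csv"))
  data.table::fwrite(qc$pcs, file.path(qc_dir, "pcs.csv"))
  counts$qc <- list(variants_kept = qc$n_variants_kept,
                    variants_excluded = qc$n_variants_in - qc$n_variants_kept,
                    samples_kept = qc$n_samples_kept,
                    related_dropped = length(qc$related_dropped))

  # 3 -- scores
  g <- qc$genotypes
  cv <- ds$covariates[match(g$samples, ds$covariates$participant_id), ]
  w_gws <- ds$weights_gws[ds$weights_gws$ID %in% g$variants$id, ]
  w_97 <- ds$weights_97[ds$weights_97$ID %in% g$variants$id, ]
  bf <- best_fit_threshold(g, w_gws, cv$bmi, covariates = NULL, cfg$gps)
  prs <- partition_scores(w_97, g)
  scores <- c(list(BMI_GPS = bf$score_set), prs)
  score_dir <- file.path(out_dir, "03_scores")
  dir.create(score_dir, showWarnings = FALSE)
  data.table::fwrite(do.call(rbind, scores), file.path(score_dir, "scores.csv"))
  data.table::fwrite(bf$r2_by_threshold,
                     file.path(score_dir, "gps_threshold_scan.csv"))
  counts$scores <- list(best_fit_threshold = bf$threshold,
                        gps_variants = attr(bf$score_set, "n_variants"),
                        prs_variants = attr(prs$BMI_97, "n_variants"))

  # 4 -- phenotypes
  phen <- derive_phenotypes(ds$transactions, ds$survey, cv)
  phen_dir <- file.path(out_dir, "04_phenotypes")
  dir.create(phen_dir, showWarnings = FALSE)
  data.table::fwrite(phen, file.path(phen_dir, "phenotypes.csv"))
  counts$phenotypes <- list(participants = nrow(phen),
                            missing_quality = sum(is.na(phen$healthy_purchasing_score)))

  # 5 -- association
  results <- run_full_analysis(scores, phen, cv, pcs = qc$pcs,
                               outcomes = cfg$association$outcomes,
                               extra_covariates = cfg$association$extra_covariates)
  assoc_dir <- file.path(out_dir, "05_association")
  dir.create(assoc_dir, showWarnings = FALSE)
  data.table::fwrite(results, file.path(assoc_dir, "results.csv"))
  writeLines(jsonlite::toJSON(attr(results, "log"), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(assoc_dir, "fit_log.json"))
  counts$association <- list(models = length(attr(results, "log")),
                             rows = nrow(results))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% c("manifest.json", "summary.txt")]
  manifest <- list(config_hash = config_hash(config),
                   seed = cfg$sim$seed,
                   counts = counts,
                   checksums = as.list(setNames(unname(tools::md5sum(files)),
                                                substring(files, nchar(out_dir) + 2L))),
                   created = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))

  summ <- c(
    sprintf("cafescore run (seed %d)", cfg$sim$seed),
    sprintf("simulated: %d participants, %d variants, %d transactions",
            counts$simulated$participants, counts$simulated$variants,
            counts$simulated$transactions),
    sprintf("QC: %d/%d variants kept; %d samples kept (%d related dropped)",
            counts$qc$variants_kept,
            counts$qc$variants_kept + counts$qc$variants_excluded,
            counts$qc$samples_kept, counts$qc$related_dropped),
    sprintf("GPS best-fit threshold %.3g with %d variants; PRS panel %d variants",
            counts$scores$best_fit_threshold, counts$scores$gps_variants,
            counts$scores$prs_variants),
    sprintf("association: %d models, %d result rows",
            counts$association$models, counts$association$rows))
  writeLines(summ, file.path(out_dir, "summary.txt"))

  invisible(list(results = results, manifest = manifest, scores = scores,
                 phenotypes = phen, qc = qc, best_fit = bf,
                 out_dir = out_dir))
}
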