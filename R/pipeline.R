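#' Default pipeline configuration
#'
#' Returns the full default configuration for [run_pipeline()]. Any
#' subset of it can be overridden with a list or a YAML file.
#'
#' @return A named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    out_dir = ".",
    seed = 1L,
    threshold = 0.3,
    alpha = 0.01,
    bonferroni_mode = "tested",      # or "fixed:<int>"
    age_norm = "minmax",             # or "lifespan"
    call_threshold = 0.5,
    train_strain = "B6",
    test_strain = "DBA",
    drop_xy = list(clock = TRUE, corr = FALSE, diffmeth = TRUE),
    paths = list(betas = NULL, samples = NULL, annotation = NULL,
                 homology = NULL, human_betas = NULL, human_ages = NULL,
                 human_annotation = NULL),
    simulate = list()                # cohort_spec() overrides
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.validate_config <- function(config) {
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    stop("config error: alpha must lie in (0, 1)")
  if (!is.numeric(config$threshold) || !is.finite(config$threshold))
    stop("config error: threshold must be a finite number")
  if (!config$age_norm %in% c("minmax", "lifespan"))
    stop("config error: age_norm must be 'minmax' or 'lifespan'")
  if (!(identical(config$bonferroni_mode, "tested") ||
        grepl("^fixed:[0-9]+$", config$bonferroni_mode)))
    stop("config error: bonferroni_mode must be 'tested' or 'fixed:<int>'")
  invisible(config)
}

.bonferroni_m <- function(config) {
  if (identical(config$bonferroni_mode, "tested")) NULL
  else as.integer(sub("^fixed:", "", config$bonferroni_mode))
}

.out_path <- function(config, file) file.path(config$out_dir, file)

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Provenance block: inputs' checksums + parameters + seed + version.
# Deliberately excludes timestamps so reruns are byte-identical.
.write_provenance <- function(config, stage, inputs, params) {
  files <- as.character(unlist(inputs))
  files <- files[file.exists(files)]
  prov <- list(stage = stage,
               tool = "museclock",
               version = as.character(utils::packageVersion("museclock")),
               seed = config$seed,
               parameters = params,
               input_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(prov, .out_path(config, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.stage_simulate <- function(config) {
  spec <- do.call(cohort_spec, c(config$simulate, list(seed = config$seed)))
  cohort <- generate_mouse_cohort(spec)
  write_beta_matrix(cohort$betas, .out_path(config, "betas.tsv"))
  .write_tsv(cohort$sheet, .out_path(config, "samples.tsv"))
  .write_tsv(cohort$annotation, .out_path(config, "annotation.tsv"))
  .write_tsv(cohort$truth, .out_path(config, "truth.tsv"))
  human <- generate_human_cohort(cohort$truth, seed = config$seed + 1L)
  write_beta_matrix(human$betas, .out_path(config, "human_betas.tsv"))
  .write_tsv(data.frame(sample_id = names(human$ages_years),
                        age_years = unname(human$ages_years)),
             .out_path(config, "human_ages.tsv"))
  .write_tsv(human$annotation, .out_path(config, "human_annotation.tsv"))
  homology <- generate_homology_table(human$links, attrition = 0.2,
                                      seed = config$seed + 2L)
  .write_tsv(homology, .out_path(config, "homology.tsv"))
  .write_provenance(config, "simulate", list(), list(spec = unclass(spec)))
  invisible(NULL)
}

.config_paths <- function(config) {
  defaults <- list(betas = "betas.tsv", samples = "samples.tsv",
                   annotation = "annotation.tsv", homology = "homology.tsv",
                   human_betas = "human_betas.tsv", human_ages = "human_ages.tsv",
                   human_annotation = "human_annotation.tsv")
  for (nm in names(defaults)) {
    if (is.null(config$paths[[nm]]))
      config$paths[[nm]] <- .out_path(config, defaults[[nm]])
  }
  config
}

.stage_qc <- function(config) {
  mat <- read_beta_matrix(config$paths$betas)
  ann <- read_probe_annotation(config$paths$annotation)
  res <- suppressMessages(qc_filter(mat, ann, drop_xy = isTRUE(config$drop_xy$clock)))
  write_beta_matrix(res$betas, .out_path(config, "qc_betas.tsv"))
  write_qc_report(res$report, .out_path(config, "qc_report.json"))
  .write_provenance(config, "qc",
                    list(betas = config$paths$betas, annotation = config$paths$annotation),
                    list(drop_xy = isTRUE(config$drop_xy$clock)))
  invisible(NULL)
}

.stage_select <- function(config) {
  mat <- read_beta_matrix(.out_path(config, "qc_betas.tsv"))
  sheet <- read_sample_sheet(config$paths$samples)
  sheet <- sheet[sheet$sample_id %in% colnames(mat), , drop = FALSE]
  norm <- normalize_ages(sheet, method = config$age_norm)
  sets <- list()
  for (strain in c(config$train_strain, config$test_strain)) {
    s <- norm[norm$strain == strain, , drop = FALSE]
    x <- stats::setNames(s$age_norm, s$sample_id)
    cs <- select_candidates(mat[, s$sample_id, drop = FALSE], x,
                            threshold = config$threshold, strain = strain)
    sets[[strain]] <- cs
    .write_tsv(cs$table, .out_path(config, sprintf("slopes_%s.tsv", strain)))
  }
  venn <- intersect_candidates(sets[[1L]], sets[[2L]])
  writeLines(venn$shared, .out_path(config, "intersection.txt"))
  jsonlite::write_json(as.list(venn$counts), .out_path(config, "venn.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_provenance(config, "select",
                    list(betas = .out_path(config, "qc_betas.tsv"),
                         samples = config$paths$samples),
                    list(threshold = config$threshold, age_norm = config$age_norm))
  invisible(NULL)
}

.stage_train_ensemble <- function(config) {
  mat <- read_beta_matrix(.out_path(config, "qc_betas.tsv"))
  sheet <- read_sample_sheet(config$paths$samples)
  sheet <- sheet[sheet$sample_id %in% colnames(mat), , drop = FALSE]
  probes <- readLines(.out_path(config, "intersection.txt"))
  if (length(probes) == 0L) stop("stage train-ensemble: empty candidate intersection")
  train <- sheet[sheet$strain == config$train_strain, , drop = FALSE]
  norm <- normalize_ages(train, method = config$age_norm)
  clock <- suppressWarnings(
    fit_ensemble(mat[probes, norm$sample_id, drop = FALSE], norm))
  write_clock(clock, .out_path(config, "ensemble_clock.json"))
  .write_provenance(config, "train_ensemble",
                    list(betas = .out_path(config, "qc_betas.tsv"),
                         intersection = .out_path(config, "intersection.txt")),
                    list(train_strain = config$train_strain, age_norm = config$age_norm))
  invisible(NULL)
}

.stage_predict <- function(config) {
  mat <- read_beta_matrix(.out_path(config, "qc_betas.tsv"))
  sheet <- read_sample_sheet(config$paths$samples)
  clock <- read_clock(.out_path(config, "ensemble_clock.json"))
  test <- sheet[sheet$strain == config$test_strain & sheet$sample_id %in% colnames(mat), ,
                drop = FALSE]
  pred <- vapply(seq_len(nrow(test)), function(i)
    suppressWarnings(predict_ensemble(clock, mat[, test$sample_id[i]],
                                      strain = test$strain[i], sex = test$sex[i])),
    numeric(1))
  out <- data.frame(sample_id = test$sample_id,
                    predicted_weeks = pred, true_weeks = test$age_weeks,
                    delta = pred - test$age_weeks, stringsAsFactors = FALSE)
  .write_tsv(out, .out_path(config, "predictions.tsv"))
  .write_provenance(config, "predict",
                    list(betas = .out_path(config, "qc_betas.tsv"),
                         clock = .out_path(config, "ensemble_clock.json")),
                    list(test_strain = config$test_strain))
  invisible(NULL)
}

.stage_evaluate <- function(config) {
  pred <- utils::read.delim(.out_path(config, "predictions.tsv"))
  metrics <- evaluate_predictions(pred$predicted_weeks, pred$true_weeks)
  jsonlite::write_json(unclass(metrics), .out_path(config, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_provenance(config, "evaluate",
                    list(predictions = .out_path(config, "predictions.tsv")), list())
  invisible(NULL)
}

.stage_diffmeth <- function(config) {
  mat <- read_beta_matrix(config$paths$betas)
  ann <- read_probe_annotation(config$paths$annotation)
  sheet <- read_sample_sheet(config$paths$samples)
  keep <- ann$probe_id[!(.strip_chr(ann$chrom) %in% c("X", "Y")) &
                         !ann$is_snp & !ann$is_cross_reactive]
  mat <- mat[intersect(rownames(mat), keep), , drop = FALSE]
  res <- differential_methylation(mat, sheet, alpha = config$alpha,
                                  bonferroni_m = .bonferroni_m(config))
  .write_tsv(res, .out_path(config, "diffmeth.tsv"))
  jsonlite::write_json(list(n_tested = attr(res, "n_tested"),
                            n_significant = sum(res$significant),
                            m = attr(res, "m"), alpha = config$alpha),
                       .out_path(config, "diffmeth_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_provenance(config, "diffmeth",
                    list(betas = config$paths$betas, samples = config$paths$samples),
                    list(alpha = config$alpha, bonferroni_mode = config$bonferroni_mode))
  invisible(NULL)
}

.stage_corr_matrix <- function(config) {
  # correlation matrix keeps X/Y probes, unlike the clock analyses
  mat <- read_beta_matrix(config$paths$betas)
  if (isTRUE(config$drop_xy$corr)) {
    ann <- read_probe_annotation(config$paths$annotation)
    mat <- suppressMessages(qc_filter(mat, ann, drop_xy = TRUE))$betas
  }
  sc <- sample_correlation_matrix(mat)
  df <- data.frame(sample_id = sc$sample_ids,
                   formatC(sc$r, digits = 6, format = "f"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", sc$sample_ids)
  .write_tsv(df, .out_path(config, "corr_matrix.tsv"))
  .write_provenance(config, "corr_matrix", list(betas = config$paths$betas),
                    list(drop_xy = isTRUE(config$drop_xy$corr)))
  invisible(NULL)
}

.stage_homology <- function(config) {
  regions <- read_homology_table(config$paths$homology)
  hann <- read_probe_annotation(config$paths$human_annotation)
  hbetas <- read_beta_matrix(config$paths$human_betas)
  hages <- utils::read.delim(config$paths$human_ages)
  ages <- stats::setNames(hages$age_years, hages$sample_id)
  assignments <- assign_human_cpgs(regions, hann)
  .write_tsv(assignments, .out_path(config, "assignments.tsv"))
  hres <- suppressWarnings(human_age_association(hbetas, ages, alpha = config$alpha))
  .write_tsv(hres, .out_path(config, "human_association.tsv"))
  sa <- utils::read.delim(.out_path(config, sprintf("slopes_%s.tsv", config$train_strain)))
  sb <- utils::read.delim(.out_path(config, sprintf("slopes_%s.tsv", config$test_strain)))
  report <- conserved_candidates(assignments, sa, sb, hres)
  .write_tsv(report, .out_path(config, "conserved_report.tsv"))
  .write_provenance(config, "homology",
                    list(homology = config$paths$homology,
                         human_betas = config$paths$human_betas),
                    list(alpha = config$alpha))
  invisible(NULL)
}

.stage_report <- function(config) {
  collect <- function(file) {
    p <- .out_path(config, file)
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
  }
  conserved <- {
    p <- .out_path(config, "conserved_report.tsv")
    if (file.exists(p)) nrow(utils::read.delim(p)) else NULL
  }
  report <- list(qc = collect("qc_report.json"),
                 venn = collect("venn.json"),
                 metrics = collect("metrics.json"),
                 diffmeth = collect("diffmeth_summary.json"),
                 n_conserved = conserved)
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       .out_path(config, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

.pipeline_stages <- c("simulate", "qc", "select", "train_ensemble", "predict",
                      "evaluate", "diffmeth", "corr_matrix", "homology", "report")

#' Run the analysis pipeline
#'
#' Wires the full workflow — simulate, QC, slope-based selection,
#' ensemble-clock training and cross-strain prediction, evaluation,
#' differential methylation, sample correlation matrix, homology mapping,
#' and a summary report — executing the requested stages in dependency
#' order. Every stage writes plain-text TSV/JSON outputs plus a
#' provenance JSON (input checksums, parameters, seed, tool version);
#' identical config and inputs produce byte-identical outputs.
#'
#' @param config A configuration list (merged over
#'   [default_run_config()]) or the path of a YAML file holding one.
#' @param stages Character vector of stages to run, in any order; default
#'   all. See `museclock:::.pipeline_stages`.
#' @return The resolved configuration, invisibly.
#' @export
run_pipeline <- function(config = list(), stages = .pipeline_stages) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- .merge_config(default_run_config(), config)
  .validate_config(config)
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  config <- .config_paths(config)
  runners <- list(simulate = .stage_simulate, qc = .stage_qc, select = .stage_select,
                  train_ensemble = .stage_train_ensemble, predict = .stage_predict,
                  evaluate = .stage_evaluate, diffmeth = .stage_diffmeth,
                  corr_matrix = .stage_corr_matrix, homology = .stage_homology,
                  report = .stage_report)
  for (st in stages) {
    tryCatch(runners[[st]](config),
             error = function(e) stop("stage ", st, " failed: ", conditionMessage(e),
                                      call. = FALSE))
  }
  invisible(config)
}
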