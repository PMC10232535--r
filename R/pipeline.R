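# Composite pipeline: validate inputs, train the base model, fit the
# transfer correction, screen the candidate library, and write all
# artifacts (models, reports, ranked library, run summary) to an output
# directory. Configuration is a YAML file or an equivalent named list;
# unknown keys are rejected before any computation.

RUN_CONFIG_KEYS <- c(
  "descriptors", "source_records", "target_records", "library",
  "context", "base_spec", "delta_spec", "k", "seed", "thresholds",
  "outdir")

parse_spec_config <- function(x, default) {
  if (is.null(x)) return(default)
  do.call(regressor_spec,
          c(list(algorithm = x$algorithm %||% "linear_svr",
                 scaling = x$scaling %||% "standardize"),
            x$hyperparameters %||% list()))
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  need <- c("descriptors", "source_records", "target_records", "library",
            "context", "outdir")
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys)) {
    stop("config missing key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  config$k <- config$k %||% 10
  config$seed <- config$seed %||% 0
  config$thresholds <- config$thresholds %||% c(0.40, 0.80)
  config
}

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full knowledge-transfer pipeline
#'
#' Stages: `validate` (descriptor/record consistency), `train` (base
#' model cross-validation and fit), `transfer` (residuals, leave-one-out
#' report, delta fit), `screen` (candidate ranking and binning),
#' `report` (artifact writing). Every output records the config hash and
#' the seed.
#'
#' @param config Path to a YAML file or a named list with keys:
#'   `descriptors` (list of `indole`/`alkene`/`cca` CSV paths),
#'   `source_records`, `target_records`, `library` (CSV paths),
#'   `context` (list or YAML path: `indole_id`, `alkene_id`,
#'   `temperature`), optional `base_spec`/`delta_spec`
#'   (`algorithm`/`hyperparameters`/`scaling`), `k`, `seed`,
#'   `thresholds`, and `outdir`.
#' @return The run summary (list), invisibly; written as
#'   `run_summary.json` in `outdir` alongside `base_model.json`,
#'   `transfer_model.json`, `loo_report.json`, `validation.json` and
#'   `screening.csv`.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  cfg_hash <- content_hash(config[setdiff(names(config), "outdir")])

  log_stage("validate", "loading inputs")
  for (f in unlist(config$descriptors)) {
    if (!file.exists(f)) stop("[validate] descriptor file not found: ", f, call. = FALSE)
  }
  for (key in c("source_records", "target_records", "library")) {
    if (!file.exists(config[[key]])) {
      stop("[validate] ", key, " file not found: ", config[[key]], call. = FALSE)
    }
  }
  tables <- list(
    indole = read_descriptor_table(config$descriptors$indole, "indole"),
    alkene = read_descriptor_table(config$descriptors$alkene, "alkene"),
    cca = read_descriptor_table(config$descriptors$cca, "cca"))
  source_records <- read_reaction_records(config$source_records, "source")
  target_records <- read_reaction_records(config$target_records, "target")
  report_src <- validate_dataset(source_records, tables)
  report_tgt <- validate_dataset(target_records, tables)
  if (nrow(report_src) || nrow(report_tgt)) {
    stop("[validate] dataset rejected with ",
         nrow(report_src) + nrow(report_tgt), " issue(s)", call. = FALSE)
  }
  context <- config$context
  if (is.character(context)) context <- yaml::read_yaml(context)

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_validation_report(report_src, file.path(config$outdir, "validation.json"))

  base_spec <- parse_spec_config(config$base_spec, regressor_spec("linear_svr"))
  delta_spec <- parse_spec_config(config$delta_spec, delta_spec_default())

  log_stage("train", "k=", config$k, " seed=", config$seed)
  ds <- encoded_dataset(source_records, tables)
  cv <- kfold_cv(ds, base_spec, k = config$k, seed = config$seed)
  base <- fit_base(ds, base_spec)
  log_stage("train", "cv_pearson_r=", round(cv$pearson_r, 4),
            " cv_mae=", round(cv$mae, 4))

  log_stage("transfer", "n_target=", nrow(target_records))
  transfer <- fit_transfer(base, target_records, tables, delta_spec)
  log_stage("transfer", "loo_mae_uncorrected=",
            round(transfer$loo$mae_uncorrected, 4),
            " loo_mae_corrected=", round(transfer$loo$mae_corrected, 4))

  log_stage("screen", "library=", config$library)
  lib_df <- utils::read.csv(config$library, check.names = FALSE,
                            stringsAsFactors = FALSE)
  cand <- enumerate_candidates(unique(lib_df$backbone_id),
                               unique(lib_df$substituent_id), lib_df)
  result <- screen(transfer, cand, context, tables)
  bins <- bin_distribution(result, config$thresholds)
  log_stage("screen", "bins=", paste(names(bins), bins, sep = ":", collapse = " "))

  log_stage("report", "writing artifacts to ", config$outdir)
  if (base$fit$kind == "linear") {
    write_model(base, file.path(config$outdir, "base_model.json"))
    write_model(transfer, file.path(config$outdir, "transfer_model.json"))
  }
  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = config$seed,
         n = transfer$loo$n,
         mae_uncorrected = transfer$loo$mae_uncorrected,
         mae_corrected = transfer$loo$mae_corrected,
         per_point = transfer$loo$per_point),
    file.path(config$outdir, "loo_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_screening_csv(result, file.path(config$outdir, "screening.csv"))

  summary <- list(
    config_hash = cfg_hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("chirtransfer")),
    n_source = nrow(source_records), n_target = nrow(target_records),
    n_candidates = nrow(result),
    base_algorithm = base_spec$algorithm,
    delta_algorithm = delta_spec$algorithm,
    cv_pearson_r = cv$pearson_r, cv_mae = cv$mae,
    loo_mae_uncorrected = transfer$loo$mae_uncorrected,
    loo_mae_corrected = transfer$loo$mae_corrected,
    bins = as.list(bins),
    top3 = top_k(result, min(3, nrow(result)))[, c("candidate_id", "ddg_pred", "ee_pred")])
  jsonlite::write_json(summary, file.path(config$outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
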