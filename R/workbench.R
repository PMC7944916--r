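# Experiment orchestration: staged runs with manifests, seeds and logging.

.stages <- c("curate", "train-generator", "train-predictor", "rl-train",
             "sample", "evaluate")

.validate_run_config <- function(config) {
  if (is.null(config$stage) || !config$stage %in% .stages)
    stop(sprintf("stage must be one of: %s", paste(.stages, collapse = ", ")))
  if (is.null(config$out)) stop("config$out (output directory) is required")
  ins <- unlist(config$inputs)
  missing <- ins[!file.exists(ins)]
  if (length(missing))
    stop(sprintf("missing input(s): %s", paste(missing, collapse = ", ")))
  invisible(TRUE)
}

.objective_from_config <- function(sc, inputs) {
  name <- sc$objective %||% "logp-range"
  switch(name,
    "logp-range" = reward_spec("logp_range",
                               logp_bounds = unlist(sc$logp_bounds %||% c(1, 4))),
    "pic50-max" = reward_spec("maximize_pic50",
                              predictor_oracle(readRDS(inputs$predictor))),
    "pic50-min" = reward_spec("minimize_pic50",
                              predictor_oracle(readRDS(inputs$predictor))),
    stop(sprintf("unknown objective '%s'", name)))
}

#' Run one experiment stage
#'
#' Executes a pipeline stage (`curate`, `train-generator`, `train-predictor`,
#' `rl-train`, `sample`, `evaluate`) into an output directory and writes a
#' manifest recording the configuration, MD5 hashes of all inputs and
#' produced artifacts, the seed and the wall clock. Identical configuration
#' and seed reproduce identical artifact hashes for the deterministic stages.
#' When the output directory already holds a manifest, the run aborts unless
#' `config$resume` is set, in which case the completed stage is returned
#' as-is and nothing is overwritten.
#'
#' @param config A list (e.g. parsed from YAML via [read_run_config()]) with
#'   fields `stage`, `inputs` (named paths), `out`, `seed`, and
#'   `stage_config` (stage-specific parameters).
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(config) {
  .validate_run_config(config)
  out <- config$out
  manifest_path <- file.path(out, "manifest.json")
  if (file.exists(manifest_path)) {
    if (isTRUE(config$resume))
      return(invisible(jsonlite::read_json(manifest_path, simplifyVector = TRUE)))
    stop(sprintf("'%s' already contains a completed run (use resume)", out))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  sc <- config$stage_config %||% list()
  t0 <- Sys.time()
  artifacts <- character(0)

  if (config$stage == "curate") {
    src <- config$inputs$corpus
    recs <- if (grepl("\\.csv$", src)) read_activity_csv(src) else read_smi(src)
    cur <- curate_corpus(recs,
                         logp_range = unlist(sc$logp_range %||% c(-2, 6)),
                         mw_range = unlist(sc$mw_range %||% c(200, 600)))
    dest <- file.path(out, if ("pic50" %in% names(cur)) "curated.csv" else "curated.smi")
    if ("pic50" %in% names(cur)) utils::write.csv(cur, dest, row.names = FALSE)
    else write_smi(cur$smiles, dest)
    jsonlite::write_json(list(n = nrow(cur), dropped = as.list(attr(cur, "dropped"))),
                         file.path(out, "curation.json"), auto_unbox = TRUE)
    artifacts <- c(dest, file.path(out, "curation.json"))
  } else if (config$stage == "train-generator") {
    corpus <- read_smi(config$inputs$corpus)
    gcfg <- do.call(generator_config, sc[intersect(names(sc),
                    names(formals(generator_config)))])
    model <- train_generator(corpus, gcfg, seed = seed)
    ckpt <- file.path(out, "generator")
    save_policy(model, ckpt)
    artifacts <- list.files(ckpt, full.names = TRUE)
  } else if (config$stage == "train-predictor") {
    dat <- read_activity_csv(config$inputs$data)
    qcfg <- do.call(qsar_config, sc[intersect(names(sc), names(formals(qsar_config)))])
    fit <- train_qsar(dat, qcfg, seed = seed)
    saveRDS(fit, file.path(out, "qsar.rds"))
    jsonlite::write_json(list(mse = fit$report$mse, q2 = fit$report$q2,
                              per_fold = fit$report$per_fold),
                         file.path(out, "qsar_report.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- file.path(out, c("qsar.rds", "qsar_report.json"))
  } else if (config$stage == "rl-train") {
    g_u <- load_policy(config$inputs$generator)
    objective <- .objective_from_config(sc, config$inputs)
    rcfg_args <- sc[setdiff(intersect(names(sc), names(formals(rl_config))),
                            "objective")]
    rcfg <- do.call(rl_config, c(list(objective = objective), rcfg_args))
    run <- rl_training_run(g_u, rcfg, seed = seed)
    log_path <- file.path(out, "rl_log.jsonl")
    writeLines(vapply(seq_len(nrow(run$log)), function(i)
      jsonlite::toJSON(as.list(run$log[i, ]), auto_unbox = TRUE, digits = NA),
      character(1)), log_path)
    save_policy(run$model, file.path(out, "generator_final"))
    save_policy(run$best_model, file.path(out, "generator_best"))
    jsonlite::write_json(list(best_iteration = run$best_iteration,
                              history = run$history),
                         file.path(out, "rl_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(log_path, file.path(out, "rl_summary.json"),
                   list.files(file.path(out, "generator_final"), full.names = TRUE),
                   list.files(file.path(out, "generator_best"), full.names = TRUE))
  } else if (config$stage == "sample") {
    model <- load_policy(config$inputs$generator)
    sm <- sample_batch(model, sc$n %||% 500L,
                       temperature = sc$temperature %||% 1, seed = seed)
    dest <- file.path(out, "samples.smi")
    write_smi(vapply(sm, `[[`, character(1), "smiles"), dest)
    artifacts <- dest
  } else if (config$stage == "evaluate") {
    samples <- read_smi(config$inputs$samples)
    if (length(samples) == 0L) stop("empty samples file")
    reference <- if (!is.null(config$inputs$reference))
      read_smi(config$inputs$reference)
    desir <- if (!is.null(sc$objective) || is.null(config$inputs$predictor))
      desirability_rule(.objective_from_config(sc, config$inputs))
    rep_out <- evaluate_generated_set(samples, reference = reference,
                                      desirability = desir)
    rep_json <- unclass(rep_out)
    rep_json$internal_diversity <- as.list(rep_json$internal_diversity)
    if (!is.null(rep_json$external_diversity))
      rep_json$external_diversity <- as.list(rep_json$external_diversity)
    jsonlite::write_json(rep_json, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    artifacts <- file.path(out, "report.json")
  }

  manifest <- list(
    stage = config$stage,
    config = config[setdiff(names(config), "resume")],
    seed = seed,
    input_md5 = as.list(tools::md5sum(unlist(lapply(
      unlist(config$inputs %||% list()), function(p)
        if (dir.exists(p)) list.files(p, full.names = TRUE, recursive = TRUE)
        else p)))),
    artifact_md5 = as.list(tools::md5sum(artifacts)),
    timing = list(started = format(t0, "%Y-%m-%d %H:%M:%S"),
                  wall_secs = as.numeric(Sys.time() - t0, units = "secs"))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file mirroring the [run_experiment()] config structure.
#' @return The configuration list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Render evaluation reports as a table
#'
#' Reads the `report.json` of one or more evaluate-stage run directories and
#' prints the standard columns (% desirable, % unique, % valid, internal
#' Tanimoto diversity, mean SAS) side by side.
#'
#' @param run_dirs Character vector of run directories.
#' @return The assembled data.frame, invisibly.
#' @export
render_report <- function(run_dirs) {
  rows <- lapply(run_dirs, function(d) {
    p <- file.path(d, "report.json")
    if (!file.exists(p)) stop(sprintf("no evaluation report in '%s'", d))
    r <- jsonlite::read_json(p, simplifyVector = TRUE)
    data.frame(run = basename(normalizePath(d)),
               pct_desirable = r$pct_desirable %||% NA_real_,
               pct_unique = r$pct_unique %||% NA_real_,
               pct_valid = r$pct_valid,
               diversity = r$internal_diversity[["tanimoto"]] %||% NA_real_,
               mean_sas = r$mean_sas %||% NA_real_)
  })
  tab <- do.call(rbind, rows)
  out <- tab
  names(out) <- c("Run", "% Desirable", "% Unique", "% Valid",
                  "Diversity", "SAS")
  print(format(out, digits = 4), row.names = FALSE)
  invisible(tab)
}
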