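#' Pipeline run configuration
#'
#' Bundles every setting of an end-to-end run: the synthetic study design
#' (or a directory of recorded data), filter and network parameters, the
#' labelling grid, the classifier configuration and stage toggles. One
#' master seed fans out to per-stage seeds via [derive_seed()], so stages
#' are independently re-runnable.
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param design A [study_design()] for the simulate stage.
#' @param species Hemoglobin species analysed in the network/stats stages.
#' @param sparsity Binarization sparsity. Default 0.45.
#' @param n_random Matched random networks per small-worldness estimate.
#' @param sigma_nulls Nulls for the per-session sigma column in the stats
#'   stage (0 to skip sigma there).
#' @param labeling List with `hi`, `step`, `min_group` for the threshold
#'   scan (`lo` comes from the k-means split).
#' @param classifier A [classifier_config()].
#' @param stages Character vector of stages to run, a subset of
#'   `simulate, network, features, label, stats, classify`.
#' @param write_data Write the simulated recordings as CSV/JSON.
#' @param seed Master seed.
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir,
                       design = study_design(),
                       species = "HbO",
                       sparsity = 0.45,
                       n_random = 100,
                       sigma_nulls = 0,
                       labeling = list(hi = 5.00, step = 0.01, min_group = 3),
                       classifier = classifier_config(),
                       stages = c("simulate", "network", "features",
                                  "label", "stats", "classify"),
                       write_data = FALSE,
                       seed = 1) {
  known <- c("simulate", "network", "features", "label", "stats", "classify")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, design = design, species = species,
                 sparsity = sparsity, n_random = n_random,
                 sigma_nulls = sigma_nulls, labeling = labeling,
                 classifier = classifier, stages = stages,
                 write_data = write_data, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields override [run_config()] defaults; `design:` and
#' `classifier:` sub-maps override [study_design()] and
#' [classifier_config()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("design", "classifier"))]
  if (!is.null(y$design)) args$design <- do.call(study_design, y$design)
  if (!is.null(y$classifier))
    args$classifier <- do.call(classifier_config, y$classifier)
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, network (per-session
#' connectivity/metric table), features, label, stats, classify — writing
#' each stage's table under `config$out_dir` and returning a manifest
#' (config hash, seeds, stage outputs). A failing stage halts the run
#' with the stage named; completed outputs are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `manifest` (also written as JSON) and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config_fingerprint(config), cfg_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_json)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("fatiguenet")),
                   stages = list())
  results <- list()
  outfile <- function(name) file.path(config$out_dir, name)
  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(
      outputs = res$outputs, seconds = round(proc.time()[["elapsed"]] - t0, 2))
    results[[name]] <<- res$value
    invisible(NULL)
  }

  stage("simulate", function() {
    design <- config$design
    design$seed <- derive_seed(config$seed, "simulate")
    sessions <- generate_study(
      design, out_dir = if (config$write_data) outfile("data") else NULL)
    list(value = sessions,
         outputs = if (config$write_data) "data/" else character())
  })

  stage("network", function() {
    tab <- study_metric_table(results$simulate, species = config$species,
                              sigma_nulls = config$sigma_nulls,
                              seed = derive_seed(config$seed, "network"))
    utils::write.csv(tab, outfile("network_metrics.csv"), row.names = FALSE)
    list(value = tab, outputs = "network_metrics.csv")
  })

  stage("features", function() {
    feat <- study_features(results$simulate)
    utils::write.csv(feat, outfile("features.csv"), row.names = FALSE)
    list(value = feat, outputs = "features.csv")
  })

  stage("label", function() {
    lab <- label_fatigue(results$simulate,
                         seed = derive_seed(config$seed, "label"),
                         hi = config$labeling$hi,
                         step = config$labeling$step,
                         min_group = config$labeling$min_group)
    utils::write.csv(lab$scores, outfile("labels.csv"), row.names = FALSE)
    utils::write.csv(lab$trace, outfile("threshold_scan.csv"),
                     row.names = FALSE)
    list(value = lab, outputs = c("labels.csv", "threshold_scan.csv"))
  })

  stage("stats", function() {
    tab <- results$network
    lab <- results$label$scores
    tab$level <- lab$level[match(tab$participant_id, lab$participant_id)]
    cmp <- band_metric_comparison(tab)
    utils::write.csv(cmp$anova, outfile("anova.csv"), row.names = FALSE)
    outs <- "anova.csv"
    if (!is.null(cmp$posthoc)) {
      utils::write.csv(cmp$posthoc, outfile("posthoc.csv"), row.names = FALSE)
      outs <- c(outs, "posthoc.csv")
    }
    list(value = cmp, outputs = outs)
  })

  stage("classify", function() {
    feat <- results$features
    lab <- results$label$scores
    lev <- lab$level[match(feat$participant_id, lab$participant_id)]
    xcols <- setdiff(names(feat), c("participant_id", "task", "session",
                                    "level"))
    reports <- list()
    for (tk in c("nonfatigue_vs_fatigue", "moderate_vs_severe")) {
      yy <- task_labels(lev, tk)
      ok <- !is.na(yy)
      cfg <- config$classifier
      cfg$task <- tk
      if (any(table(droplevels(yy[ok])) < cfg$cv_folds)) next
      reports[[tk]] <- crossvalidate(feat[ok, xcols], yy[ok], cfg,
                                     seed = derive_seed(config$seed,
                                                        "classify", tk))
    }
    jsonlite::write_json(
      lapply(reports, function(r) list(
        task = r$task, positive = r$positive, accuracy = r$accuracy,
        recall = r$recall, f1 = r$f1, per_fold = r$per_fold,
        best_params = r$best_params, seed = r$seed)),
      outfile("cv_reports.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    list(value = reports, outputs = "cv_reports.json")
  })

  manifest_path <- outfile("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = results))
}

# serializable summary of a run_config for hashing
config_fingerprint <- function(config) {
  d <- config$design
  list(seed = config$seed, species = config$species,
       sparsity = config$sparsity, n_random = config$n_random,
       sigma_nulls = config$sigma_nulls, labeling = config$labeling,
       stages = config$stages,
       design = list(n_per_cell = d$n_per_cell, duration = d$duration,
                     fs = d$fs, seed = d$seed, tasks = d$tasks,
                     levels = d$levels,
                     amplitudes = as.list(d$coupling$amplitudes),
                     noise_sd = d$coupling$noise_sd,
                     kappa = d$coupling$kappa),
       classifier = unclass(config$classifier))
}
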