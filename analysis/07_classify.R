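#!/usr/bin/env Rscript
# Fatigue-state classification: random forest with Gini-importance
# feature selection and genetic-algorithm hyperparameter tuning, nested
# in stratified fivefold cross-validation. Two binary tasks:
# non-fatigue vs fatigue, and moderate vs severe fatigue.

source(file.path("analysis", "00_config.R"))

sessions <- generate_study(study)
lab <- label_fatigue(sessions, seed = derive_seed(MASTER_SEED, "label"))
feat <- study_features(sessions)
lev <- lab$scores$level[match(feat$participant_id,
                              lab$scores$participant_id)]
xcols <- setdiff(names(feat), c("participant_id", "task", "session", "level"))

cfg <- classifier_config(population = 8, generations = 5, n_features = 50)
reports <- list()
for (tk in c("nonfatigue_vs_fatigue", "moderate_vs_severe")) {
  y <- task_labels(lev, tk)
  ok <- !is.na(y)
  cfg$task <- tk
  if (any(table(droplevels(y[ok])) < cfg$cv_folds)) {
    cat("Skipping", tk, "- a class has fewer members than cv_folds.\n")
    next
  }
  rep_tk <- crossvalidate(feat[ok, xcols], y[ok], cfg,
                          seed = derive_seed(MASTER_SEED, "cv", tk))
  reports[[tk]] <- rep_tk
  cat(sprintf("\n%s (positive class: %s)\n", tk, rep_tk$positive))
  cat(sprintf("  accuracy %.1f%%  recall %.1f%%  F1 %.1f%%\n",
              100 * rep_tk$accuracy, 100 * rep_tk$recall, 100 * rep_tk$f1))
  print(rep_tk$confusion)
}

jsonlite::write_json(
  lapply(reports, function(r) list(
    task = r$task, positive = r$positive, accuracy = r$accuracy,
    recall = r$recall, f1 = r$f1, per_fold = r$per_fold,
    selected_features = r$selected_features[[1]][1:10],
    best_params = r$best_params)),
  out_path("cv_reports.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nWrote", out_path("cv_reports.json"), "\n")
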