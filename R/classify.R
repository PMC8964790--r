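#' Classifier configuration
#'
#' Settings for fatigue-state classification: which binary task, how many
#' top-ranked features to keep, the random-forest hyperparameter search
#' space and the genetic-algorithm settings.
#'
#' @param task `"nonfatigue_vs_fatigue"` (positive class: fatigue =
#'   L2 + L3) or `"moderate_vs_severe"` (positive class: severe = L3).
#' @param n_features Features kept after Gini ranking.
#' @param ntree_range,mtry_frac_range,nodesize_range Search-space bounds
#'   for tree count, feature-subsample fraction and minimum node size.
#' @param population,generations,crossover,mutation GA settings: even
#'   population size >= 4, generation count, per-gene uniform-crossover
#'   and mutation probabilities.
#' @param cv_folds Outer cross-validation folds (default 5).
#' @param inner_folds Inner folds for GA fitness (default 3).
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(task = c("nonfatigue_vs_fatigue",
                                       "moderate_vs_severe"),
                              n_features = 50,
                              ntree_range = c(100, 500),
                              mtry_frac_range = c(0.05, 0.5),
                              nodesize_range = c(1, 5),
                              population = 8, generations = 5,
                              crossover = 0.5, mutation = 0.2,
                              cv_folds = 5, inner_folds = 3) {
  task <- match.arg(task)
  if (population < 4) stop("GA population must be >= 4")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  for (rng in list(ntree_range, mtry_frac_range, nodesize_range))
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[2] < rng[1])
      stop("search-space bounds must be finite ranges")
  structure(list(task = task, n_features = n_features,
                 ntree_range = ntree_range,
                 mtry_frac_range = mtry_frac_range,
                 nodesize_range = nodesize_range,
                 population = population, generations = generations,
                 crossover = crossover, mutation = mutation,
                 cv_folds = cv_folds, inner_folds = inner_folds),
            class = "classifier_config")
}

# map a genome in [0,1]^3 to hyperparameters
decode_genome <- function(g, config) {
  list(
    ntree = round(config$ntree_range[1] +
                    g[1] * diff(config$ntree_range)),
    mtry_frac = config$mtry_frac_range[1] +
      g[2] * diff(config$mtry_frac_range),
    nodesize = round(config$nodesize_range[1] +
                       g[3] * diff(config$nodesize_range))
  )
}

fit_rf <- function(x, y, params, seed) {
  mtry <- max(1, round(params$mtry_frac * ncol(x)))
  with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = params$ntree, mtry = mtry,
    nodesize = params$nodesize))
}

# stratified fold assignment, deterministic given seed
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  })
  folds
}

#' Rank features by random-forest Gini importance
#'
#' Fits a default-parameter forest and orders features by mean decrease
#' in Gini impurity.
#'
#' @param x Feature matrix or data frame (sessions x features).
#' @param y Class factor with >= 2 classes, >= 2 members each.
#' @param seed Integer seed.
#' @param ntree Trees for the ranking forest. Default 300.
#' @return Character vector of feature names, most important first.
#' @export
gini_rank_features <- function(x, y, seed = 1, ntree = 300) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs >= 2 members")
  x <- as.data.frame(x)
  rf <- with_seed(seed, randomForest::randomForest(x = x, y = y,
                                                   ntree = ntree,
                                                   importance = FALSE))
  imp <- randomForest::importance(rf, type = 2)[, 1]
  names(imp)[order(-imp, seq_along(imp))]
}

#' Genetic-algorithm hyperparameter search
#'
#' Real-coded GA (tournament selection of size 2, uniform crossover,
#' per-gene mutation, one elite) maximizing inner stratified k-fold CV
#' accuracy of the random forest on the training split only.
#'
#' @param x,y Training features and labels.
#' @param config A [classifier_config()].
#' @param seed Integer seed.
#' @return List with `params` (decoded best hyperparameters), `fitness`
#'   (best inner-CV accuracy) and `trace` (best-so-far per generation,
#'   non-decreasing).
#' @export
ga_optimize <- function(x, y, config = classifier_config(), seed = 1) {
  y <- droplevels(factor(y))
  x <- as.data.frame(x)
  inner <- stratified_folds(y, config$inner_folds, derive_seed(seed, "folds"))
  evaluate <- function(g, tag) {
    params <- decode_genome(g, config)
    preds <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(config$inner_folds)) {
      tr <- inner != f
      if (nlevels(droplevels(y[tr])) < 2) return(0)
      rf <- fit_rf(x[tr, , drop = FALSE], y[tr], params,
                   derive_seed(seed, "fit", tag, f))
      preds[!tr] <- stats::predict(rf, x[!tr, , drop = FALSE])
    }
    mean(preds == y)
  }
  ngene <- 3
  pop <- with_seed(derive_seed(seed, "init"),
                   matrix(stats::runif(config$population * ngene),
                          config$population, ngene))
  fit <- vapply(seq_len(config$population),
                function(i) evaluate(pop[i, ], paste0("g0i", i)), 0)
  trace <- numeric(config$generations + 1)
  trace[1] <- max(fit)
  for (gen in seq_len(config$generations)) {
    newpop <- with_seed(derive_seed(seed, "gen", gen), {
      np <- matrix(0, config$population, ngene)
      np[1, ] <- pop[which.max(fit), ]   # elite
      for (i in 2:config$population) {
        t1 <- sample.int(config$population, 2)
        t2 <- sample.int(config$population, 2)
        p1 <- pop[t1[which.max(fit[t1])], ]
        p2 <- pop[t2[which.max(fit[t2])], ]
        child <- ifelse(stats::runif(ngene) < config$crossover, p1, p2)
        mut <- stats::runif(ngene) < config$mutation
        child[mut] <- stats::runif(sum(mut))
        np[i, ] <- child
      }
      np
    })
    newfit <- fit
    newfit[1] <- max(fit)   # elite fitness carries over
    for (i in 2:config$population)
      newfit[i] <- evaluate(newpop[i, ], paste0("g", gen, "i", i))
    pop <- newpop
    fit <- newfit
    trace[gen + 1] <- max(trace[gen], max(fit))
  }
  best <- which.max(fit)
  list(params = decode_genome(pop[best, ], config), fitness = max(fit),
       trace = trace)
}

#' Nested cross-validated fatigue classification
#'
#' Stratified outer k-fold cross-validation; inside each training fold:
#' Gini feature ranking, top-`n_features` selection, GA hyperparameter
#' tuning (inner CV), final fit, prediction of the held-out fold. Feature
#' selection and tuning never see outer test rows. Metrics are pooled
#' over the outer folds.
#'
#' @param x Feature matrix or data frame (sessions x features).
#' @param y Binary class factor; the positive class (fatigue / severe) is
#'   taken from `config$task` conventions: the *second* level of
#'   `factor(y)` unless a level named `"fatigue"` or `"severe"` exists.
#' @param config A [classifier_config()].
#' @param seed Master seed.
#' @return A `cv_report`: list with `accuracy`, `recall`, `f1`,
#'   `per_fold` accuracies, `confusion` matrix, `selected_features`
#'   (per fold), `best_params` (per fold), `positive`, `seed`.
#' @export
crossvalidate <- function(x, y, config = classifier_config(), seed = 1) {
  y <- droplevels(factor(y))
  x <- as.data.frame(x)
  if (nlevels(y) != 2) stop("crossvalidate expects a binary task, got ",
                            nlevels(y), " classes")
  if (any(table(y) < config$cv_folds))
    stop("every class needs >= cv_folds (", config$cv_folds,
         ") members; reduce cv_folds")
  positive <- if ("fatigue" %in% levels(y)) "fatigue"
              else if ("severe" %in% levels(y)) "severe"
              else levels(y)[2]
  folds <- stratified_folds(y, config$cv_folds, derive_seed(seed, "outer"))
  preds <- factor(rep(NA_character_, length(y)), levels = levels(y))
  selected <- list()
  params <- list()
  per_fold <- numeric(config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]
    ytr <- y[tr]
    ranking <- gini_rank_features(xtr, ytr, derive_seed(seed, "rank", f))
    keep <- ranking[seq_len(min(config$n_features, length(ranking)))]
    ga <- ga_optimize(xtr[keep], ytr, config, derive_seed(seed, "ga", f))
    rf <- fit_rf(xtr[keep], ytr, ga$params, derive_seed(seed, "final", f))
    preds[!tr] <- stats::predict(rf, x[!tr, keep, drop = FALSE])
    per_fold[f] <- mean(preds[!tr] == y[!tr])
    selected[[f]] <- keep
    params[[f]] <- ga$params
  }
  confusion <- table(truth = y, predicted = preds)
  tp <- sum(y == positive & preds == positive)
  fp <- sum(y != positive & preds == positive)
  fn <- sum(y == positive & preds != positive)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(accuracy = mean(preds == y), recall = recall, f1 = f1,
                 per_fold = per_fold, confusion = confusion,
                 selected_features = selected, best_params = params,
                 positive = positive, task = config$task, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s (positive: %s): accuracy %.1f%%, recall %.1f%%, F1 %.1f%%\n",
              x$task, x$positive, 100 * x$accuracy, 100 * x$recall,
              100 * x$f1))
  print(x$confusion)
  invisible(x)
}

#' Binary labels for the two classification tasks
#'
#' Maps `L1/L2/L3` fatigue levels to the task's binary factor:
#' `nonfatigue_vs_fatigue` contrasts L1 (`"nonfatigue"`) with L2 + L3
#' (`"fatigue"`); `moderate_vs_severe` contrasts L2 (`"moderate"`) with
#' L3 (`"severe"`), dropping L1 rows (returned as `NA`).
#'
#' @param levels Character vector of `"L1"`, `"L2"`, `"L3"`.
#' @param task Classification task name.
#' @return Factor aligned with `levels` (with `NA` for dropped rows).
#' @export
task_labels <- function(levels, task = c("nonfatigue_vs_fatigue",
                                         "moderate_vs_severe")) {
  task <- match.arg(task)
  if (task == "nonfatigue_vs_fatigue") {
    factor(ifelse(levels == "L1", "nonfatigue", "fatigue"),
           levels = c("nonfatigue", "fatigue"))
  } else {
    factor(ifelse(levels == "L2", "moderate",
                  ifelse(levels == "L3", "severe", NA)),
           levels = c("moderate", "severe"))
  }
}
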