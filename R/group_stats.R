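#' Two-way fixed-effects ANOVA with partial eta squared
#'
#' Fits `value ~ level * task` with sum-to-zero factor coding and Type III
#' sums of squares (robust to unbalanced cells), and reports F, p and
#' partial eta squared (`SS_effect / (SS_effect + SS_error)`) for both
#' main effects and the interaction.
#'
#' @param values Numeric response.
#' @param level,task Factors (coerced).
#' @return An `anova_result` object: data frame `effects` with columns
#'   `effect, df, sum_sq, F, p, partial_eta2`, plus `cell_means` and
#'   `cell_counts`.
#' @export
two_way_anova <- function(values, level, task) {
  level <- factor(level)
  task <- factor(task)
  stopifnot(length(values) == length(level), length(values) == length(task))
  if (nlevels(level) < 2 || nlevels(task) < 2)
    stop("both factors need at least 2 levels")
  counts <- table(level, task)
  if (any(counts == 0))
    stop("empty design cell(s): ",
         paste(apply(which(counts == 0, arr.ind = TRUE), 1, function(ij)
           paste0("(", rownames(counts)[ij[1]], ",",
                  colnames(counts)[ij[2]], ")")), collapse = ", "))
  df <- data.frame(y = values, level = level, task = task)
  fit <- stats::lm(y ~ level * task, data = df,
                   contrasts = list(level = "contr.sum", task = "contr.sum"))
  ss_err <- sum(stats::residuals(fit)^2)
  if (ss_err <= .Machine$double.eps * sum(values^2))
    stop("zero residual variance: ANOVA degenerate")
  a3 <- car::Anova(fit, type = 3)
  rows <- c("level", "task", "level:task")
  eff <- data.frame(
    effect = c("level", "task", "interaction"),
    df = a3[rows, "Df"],
    sum_sq = a3[rows, "Sum Sq"],
    F = a3[rows, "F value"],
    p = a3[rows, "Pr(>F)"],
    partial_eta2 = a3[rows, "Sum Sq"] / (a3[rows, "Sum Sq"] + ss_err)
  )
  structure(list(effects = eff,
                 df_error = a3["Residuals", "Df"],
                 ss_error = ss_err,
                 cell_means = tapply(values, list(level, task), mean),
                 cell_counts = counts),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$effects, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey-Kramer pairwise comparisons
#'
#' All pairwise group mean differences with the Tukey-Kramer unequal-n
#' standard error `sqrt(MSE/2 * (1/n_i + 1/n_j))` and studentized-range
#' p-values.
#'
#' @param values Numeric response.
#' @param group Factor (coerced); every group needs n >= 2.
#' @return Data frame: `group1, group2, diff, se, q, p`.
#' @export
tukey_kramer <- function(values, group) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  n <- table(group)
  if (any(n < 2)) stop("group(s) with fewer than 2 observations: ",
                       paste(names(n)[n < 2], collapse = ", "))
  k <- nlevels(group)
  means <- tapply(values, group, mean)
  df_err <- length(values) - k
  mse <- sum((values - means[group])^2) / df_err
  pairs <- utils::combn(levels(group), 2)
  res <- apply(pairs, 2, function(pr) {
    d <- means[[pr[2]]] - means[[pr[1]]]
    se <- sqrt(mse / 2 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    q <- abs(d) / se
    c(diff = d, se = se, q = q,
      p = stats::ptukey(q, k, df_err, lower.tail = FALSE))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], t(res),
             row.names = NULL)
}

#' Per-band group comparison of connectivity and network metrics
#'
#' Runs [two_way_anova()] (fatigue level x task) on every ROI-pair
#' connectivity strength and every network metric, per band, and applies
#' [tukey_kramer()] across levels wherever the level main effect is
#' significant (`p < alpha`) while the interaction is not — the
#' standard reporting rule for crossed designs.
#'
#' @param table Data frame with columns `band`, `target` (ROI pair or
#'   metric name), `value`, `level`, `task`; one row per session and
#'   target (see [study_metric_table()]).
#' @param alpha Significance level. Default 0.05.
#' @return List with `anova` (tidy data frame: band, target, effect, df,
#'   F, p, partial_eta2) and `posthoc` (Tukey-Kramer rows for qualifying
#'   band/target combinations).
#' @export
band_metric_comparison <- function(table, alpha = 0.05) {
  need <- c("band", "target", "value", "level", "task")
  missing <- setdiff(need, names(table))
  if (length(missing)) stop("table missing column(s): ",
                            paste(missing, collapse = ", "))
  combos <- unique(table[c("band", "target")])
  anova_rows <- list()
  posthoc_rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- table[table$band == combos$band[i] &
                 table$target == combos$target[i], ]
    res <- two_way_anova(sub$value, sub$level, sub$task)
    eff <- res$effects
    eff$band <- combos$band[i]
    eff$target <- combos$target[i]
    anova_rows[[i]] <- eff[c("band", "target", "effect", "df", "F", "p",
                             "partial_eta2")]
    p_level <- eff$p[eff$effect == "level"]
    p_inter <- eff$p[eff$effect == "interaction"]
    if (!is.na(p_level) && p_level < alpha &&
        (is.na(p_inter) || p_inter >= alpha)) {
      ph <- tukey_kramer(sub$value, sub$level)
      ph$band <- combos$band[i]
      ph$target <- combos$target[i]
      posthoc_rows[[length(posthoc_rows) + 1]] <- ph
    }
  }
  list(anova = do.call(rbind, anova_rows),
       posthoc = if (length(posthoc_rows)) do.call(rbind, posthoc_rows)
                 else NULL)
}

#' Tidy per-session table of connectivity strengths and network metrics
#'
#' Builds the input for [band_metric_comparison()] from per-session
#' artifacts of one hemoglobin species: one row per session x band x
#' target, where targets are the 28 ROI-pair `|r|` strengths plus the
#' network metrics `C`, `L` (and `sigma` when `metrics_fun` provides it).
#'
#' @param sessions List of labelled [participant_session()]s.
#' @param species Hemoglobin species to analyse. Default `"HbO"`.
#' @param bands Bands to include. Default all five.
#' @param montage A [montage()].
#' @param sigma_nulls If > 0, also compute weighted small-worldness with
#'   this many matched random networks per session (seeded per session).
#' @param seed Seed for the small-worldness nulls.
#' @return Data frame `participant_id, task, level, band, target, value`.
#' @export
study_metric_table <- function(sessions, species = "HbO",
                               bands = default_bands(),
                               montage = default_montage(),
                               sigma_nulls = 0, seed = 1) {
  rows <- list()
  pairs <- utils::combn(montage$roi_order, 2)
  pair_names <- paste(pairs[1, ], pairs[2, ], sep = "~")
  pair_idx <- t(utils::combn(length(montage$roi_order), 2))
  for (s in sessions) {
    rec <- s$recordings[[species]]
    if (is.null(rec)) stop("session ", s$participant_id, " lacks ", species)
    series <- roi_aggregate(rec, montage, bands)
    for (b in names(series)) {
      net <- fc_matrix(series[[b]])
      vals <- c(net$w[pair_idx],
                C = clustering_coefficient(net$w),
                L = as.numeric(characteristic_path_length(net$w)))
      targets <- c(pair_names, "C", "L")
      if (sigma_nulls > 0) {
        sw <- small_worldness(net$w, n_random = sigma_nulls,
                              seed = derive_seed(seed, s$participant_id, b))
        vals <- c(vals, sigma = sw$sigma)
        targets <- c(targets, "sigma")
      }
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = s$participant_id, task = s$task,
        level = s$fatigue_level, band = b, target = targets,
        value = unname(vals))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
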