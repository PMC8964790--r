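test_that("two-way ANOVA matches the hand-computed balanced 2x2 oracle", {
  # cells: A1B1 {1,2}, A1B2 {1,2}, A2B1 {3,4}, A2B2 {3,4}
  y <- c(1, 2, 1, 2, 3, 4, 3, 4)
  A <- rep(c("a1", "a2"), each = 4)
  B <- rep(c("b1", "b1", "b2", "b2"), 2)
  res <- two_way_anova(y, A, B)
  eff <- res$effects
  # independent sums-of-squares evaluation for the balanced design
  gm <- mean(y)
  ss_a <- 4 * sum((tapply(y, A, mean) - gm)^2)
  ss_b <- 4 * sum((tapply(y, B, mean) - gm)^2)
  cellm <- tapply(y, list(A, B), mean)
  ss_ab <- 2 * sum((sweep(sweep(cellm, 1, tapply(y, A, mean)), 2,
                          tapply(y, B, mean)) + gm)^2)
  ss_e <- sum((y - cellm[cbind(A, B)])^2)
  expect_equal(eff$sum_sq, c(ss_a, ss_b, ss_ab), tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "level"], 16)
  expect_equal(eff$F[eff$effect == "task"], 0)
  expect_equal(eff$F[eff$effect == "interaction"], 0)
  expect_equal(eff$partial_eta2[eff$effect == "level"], 0.8)
  expect_equal(eff$p[eff$effect == "level"],
               stats::pf(16, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("ANOVA is exchangeable, validates cells, rejects degenerate data", {
  set.seed(50)
  y <- rnorm(36)
  A <- sample(rep(c("L1", "L2", "L3"), 12))
  B <- sample(rep(c("t1", "t2"), 18))
  # guard against an empty random cell
  while (any(table(A, B) == 0)) {
    A <- sample(A)
  }
  r1 <- two_way_anova(y, A, B)
  perm <- sample(36)
  r2 <- two_way_anova(y[perm], A[perm], B[perm])
  expect_equal(r1$effects, r2$effects, tolerance = 1e-10)

  expect_error(two_way_anova(rep(1, 8), rep(c("a", "b"), 4),
                             rep(c("x", "y"), each = 4)),
               "zero residual variance")
  expect_error(two_way_anova(1:4, c("a", "a", "b", "b"), rep("x", 4)),
               "at least 2 levels")
  expect_error(two_way_anova(1:6, c("a", "a", "a", "b", "b", "b"),
                             c("x", "x", "x", "y", "y", "x")),
               "empty design cell")
})

test_that("ANOVA type-I error is calibrated on null data", {
  set.seed(123)
  pvals <- replicate(200, {
    y <- rnorm(36)
    A <- rep(c("L1", "L2", "L3"), each = 12)
    B <- rep(rep(c("t1", "t2", "t3"), each = 4), 3)
    two_way_anova(y, A, B)$effects$p[1]
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("Tukey-Kramer comparisons behave on hand-checkable groups", {
  # identical groups: no difference, p essentially 1
  y <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  tk <- tukey_kramer(y, g)
  expect_equal(tk$diff, 0)
  expect_gt(tk$p, 0.99)

  # one far group with tiny variance: its pairs are significant
  set.seed(60)
  y2 <- c(rnorm(5, 0, 0.01), rnorm(5, 0, 0.01), rnorm(5, 5, 0.01))
  g2 <- rep(c("a", "b", "c"), each = 5)
  tk2 <- tukey_kramer(y2, g2)
  expect_lt(tk2$p[tk2$group1 == "a" & tk2$group2 == "c"], 0.01)
  expect_lt(tk2$p[tk2$group1 == "b" & tk2$group2 == "c"], 0.01)
  expect_gt(tk2$p[tk2$group1 == "a" & tk2$group2 == "b"], 0.5)

  # antisymmetry under group relabelling
  tk_rev <- tukey_kramer(y2, factor(g2, levels = c("c", "b", "a")))
  d1 <- tk2$diff[tk2$group1 == "a" & tk2$group2 == "c"]
  d2 <- tk_rev$diff[tk_rev$group1 == "c" & tk_rev$group2 == "a"]
  expect_equal(d1, -d2)

  expect_error(tukey_kramer(1:3, c("a", "a", "b")), "fewer than 2")
})

test_that("Tukey-Kramer agrees with TukeyHSD on unbalanced groups", {
  set.seed(61)
  y <- c(rnorm(4, 0), rnorm(7, 1), rnorm(5, 3))
  g <- factor(rep(c("a", "b", "c"), c(4, 7, 5)))
  ours <- tukey_kramer(y, g)
  ref <- stats::TukeyHSD(stats::aov(y ~ g))$g
  for (i in seq_len(nrow(ours))) {
    key <- paste0(ours$group2[i], "-", ours$group1[i])
    expect_equal(ours$diff[i], ref[key, "diff"], tolerance = 1e-10)
    expect_equal(ours$p[i], ref[key, "p adj"], tolerance = 1e-8)
  }
})

test_that("band/metric comparison follows the crossed-design reporting rule", {
  set.seed(62)
  n <- 36
  level <- rep(c("L1", "L2", "L3"), each = 12)
  task <- rep(rep(c("PVT", "cognitive", "driving"), each = 4), 3)
  rows <- list()
  for (b in c("I", "II")) {
    for (target in c("p1", "p2", "C")) {
      shift <- if (b == "II" && target == "C") (level == "L1") * 2 else 0
      rows[[paste(b, target)]] <- data.frame(
        band = b, target = target, value = rnorm(n, sd = 0.5) + shift,
        level = level, task = task)
    }
  }
  tab <- do.call(rbind, rows)
  cmp <- band_metric_comparison(tab)
  expect_equal(nrow(cmp$anova), 2 * 3 * 3)   # bands x targets x effects
  sig <- cmp$anova[cmp$anova$effect == "level" & cmp$anova$p < 0.05, ]
  expect_true(any(sig$band == "II" & sig$target == "C"))
  # post-hoc only for qualifying combinations, and it flags the L1 shift
  expect_true(!is.null(cmp$posthoc))
  ph <- cmp$posthoc[cmp$posthoc$band == "II" & cmp$posthoc$target == "C", ]
  expect_true(all(ph$p[ph$group1 == "L1"] < 0.05))
  expect_true(all(c("band", "target", "effect", "F", "p", "partial_eta2")
                  %in% names(cmp$anova)))
})

test_that("study metric tables have the advertised shape", {
  d <- tiny_design(n_per_cell = 1, duration = 60)
  sess <- generate_study(d, species = "HbO")
  tab <- study_metric_table(sess, bands = default_bands()[c("III", "IV")])
  # per session and band: 28 pairs + C + L
  expect_equal(nrow(tab), length(sess) * 2 * 30)
  expect_true(all(c("C", "L") %in% tab$target))
  expect_equal(length(unique(tab$target)), 30)
  with_sigma <- study_metric_table(sess[1:2], bands = default_bands()["IV"],
                                   sigma_nulls = 10)
  expect_true("sigma" %in% with_sigma$target)
  expect_equal(nrow(with_sigma), 2 * 31)
})
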