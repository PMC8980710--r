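# Mixed-ANOVA reference values were computed with an independent
# implementation (pingouin 0.6.1) on these fixed balanced datasets before
# this module was written, and frozen here.

balanced_2x2 <- function() {
  y1 <- c(10, 11.5, 9, 10.5, 13, 14, 12.5, 15)
  y2 <- c(12, 14, 11, 13.5, 13.5, 13, 14.5, 15.5)
  data.frame(subject = rep(sprintf("s%d", 1:8), 2),
             group = rep(rep(c("g1", "g2"), each = 4), 2),
             focus = rep(c("other", "self"), each = 8),
             y = c(y1, y2))
}

balanced_3x2 <- function() {
  y1 <- c(1, 1.5, 0.5, 1.2, 2, 2.5, 1.8, 2.2, 3, 3.5, 2.8, 3.2)
  y2 <- c(2, 2.5, 2.2, 1.8, 2.1, 2, 2.6, 2.4, 2, 2.5, 1.5, 2.2)
  data.frame(subject = rep(sprintf("t%d", 1:12), 2),
             group = rep(rep(c("a", "b", "c"), each = 4), 2),
             focus = rep(c("other", "self"), each = 12),
             y = c(y1, y2))
}

test_that("mixed ANOVA matches the frozen independent oracle", {
  ma <- mixed_anova(balanced_2x2(), "y", "focus", "group", "subject")
  ref <- data.frame(
    effect = c("group", "focus", "interaction"),
    F = c(10.394077, 19.120482, 8.132530),
    p = c(0.018046, 0.004705, 0.029114),
    np2 = c(0.634014, 0.761151, 0.575448))
  expect_equal(ma$F, ref$F, tolerance = 1e-3)
  expect_equal(ma$p, ref$p, tolerance = 1e-3)
  expect_equal(ma$partial_eta_sq, ref$np2, tolerance = 1e-3)
  expect_equal(ma$df_num, c(1, 1, 1))
  expect_equal(ma$df_den, c(6, 6, 6))

  ma3 <- mixed_anova(balanced_3x2(), "y", "focus", "group", "subject")
  ref3 <- data.frame(F = c(13.892789, 0.174757, 21.776332),
                     p = c(0.001772, 0.685716, NA),
                     np2 = c(0.755339, 0.019048, NA))
  expect_equal(ma3$F[1:2], ref3$F[1:2], tolerance = 1e-3)
  expect_equal(ma3$p[1:2], ref3$p[1:2], tolerance = 1e-3)
  expect_equal(ma3$partial_eta_sq[1:2], ref3$np2[1:2], tolerance = 1e-3)
  expect_equal(ma3$df_num, c(2, 1, 2))
  expect_equal(ma3$df_den, c(9, 9, 9))
  # partial eta squared is SS / (SS + SS_error) by construction
  expect_equal(ma3$partial_eta_sq, ma3$ss / (ma3$ss + ma3$ss_error))
})

test_that("mixed ANOVA degenerate and bookkeeping behaviour", {
  d <- balanced_2x2()
  # identical values across within levels: focus effect vanishes
  d2 <- d
  d2$y[d2$focus == "self"] <- d2$y[d2$focus == "other"]
  ma <- mixed_anova(d2, "y", "focus", "group", "subject")
  expect_lt(ma$F[ma$effect == "focus"], 1e-9)
  # a subject missing one level is dropped listwise and logged
  d3 <- d[-1, ]
  ma3 <- mixed_anova(d3, "y", "focus", "group", "subject")
  expect_equal(attr(ma3, "n_dropped"), 1)
  expect_equal(ma3$df_den[1], 5)
  expect_error(mixed_anova(data.frame(subject = "a", group = "g",
                                      focus = "x", y = 1),
                           "y", "focus", "group", "subject"), "2 levels")
  checks <- attr(mixed_anova(d, "y", "focus", "group", "subject"), "checks")
  expect_true(all(c("shapiro_p_between", "levene_p") %in% names(checks)))
})

test_that("type-I error of the between effect is nominal on null data", {
  rej <- 0
  n_sim <- 200
  for (s in seq_len(n_sim)) {
    set.seed(3000 + s)
    d <- data.frame(subject = rep(sprintf("s%02d", 1:54), each = 2),
                    group = rep(rep(c("a", "b", "c"), each = 18), each = 2),
                    focus = rep(c("other", "self"), 54),
                    y = rnorm(108))
    ma <- mixed_anova(d, "y", "focus", "group", "subject")
    if (ma$p[ma$effect == "group"] < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_sim, 0.02)
  expect_lt(rej / n_sim, 0.09)
})

test_that("pairwise comparisons apply the Bonferroni factor", {
  set.seed(31)
  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), 10)
  pw <- pairwise_bonferroni(v, g)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p_raw))
  expect_true(all(pw$p_adj >= pw$p_raw))   # monotonicity
  # identical groups: adjusted p = 1
  pw2 <- pairwise_bonferroni(rep(c(1, 2, 3), 6), rep(c("a", "b"), each = 9))
  expect_equal(pw2$p_adj, 1)
  # Welch t against the closed-form statistic
  a <- v[g == "a"]; b <- v[g == "b"]
  tstat <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(pw$statistic[pw$pair == "a vs b"], tstat)
  # under-sized group is skipped and logged
  pw3 <- pairwise_bonferroni(c(v, 0), c(g, "d"))
  expect_true("a vs d" %in% attr(pw3, "skipped"))
  # rank-based variant runs
  pww <- pairwise_bonferroni(v, g, test = "wilcox")
  expect_equal(nrow(pww), 3)
})

test_that("Kruskal-Wallis matches the hand rank formula", {
  v <- c(2.1, 3.4, 1.2, 5.5, 4.4, 3.3, 7.1, 6.0, 2.2)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  rk <- rank(v)
  n <- length(v)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(rk, g, function(r) length(r) * mean(r)^2)) - 3 * (n + 1)
  expect_equal(kw$statistic, h, tolerance = 1e-9)   # no ties here
  expect_equal(kw$df, 2)
  # all values tied: H = 0
  expect_equal(kruskal_wallis(rep(1, 9), g)$statistic, 0)
})

test_that("Spearman correlation handles monotone and tied data", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # tied data: rank-Pearson oracle
  y <- c(2, 2, 3, 5, 5, 8)
  expect_equal(spearman_cor(x, y)$rho, cor(rank(x), rank(y)),
               tolerance = 1e-12)
  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$rho))
})

test_that("stepwise regression selects true predictors and screens noise", {
  set.seed(51)
  n <- 150
  X <- as.data.frame(matrix(rnorm(n * 7), n, 7))
  names(X) <- paste0("x", 1:7)
  X$y <- 1.5 * X$x2 - 1.2 * X$x5 + rnorm(n)
  sw <- stepwise_regression(X, "y", paste0("x", 1:7))
  expect_true(all(c("x2", "x5") %in% sw$selected))
  expect_gt(sw$r_squared, 0.5)
  expect_equal(sw$trace$action[1], "start")
  # single candidate equal to the outcome: selected with R^2 = 1
  d1 <- data.frame(y = rnorm(30))
  d1$x1 <- d1$y
  d1$x2 <- rnorm(30)
  # the outcome-equals-candidate fit is exact; R warns about perfect fits
  sw1 <- suppressWarnings(stepwise_regression(d1, "y", c("x1", "x2")))
  expect_true("x1" %in% sw1$selected)
  expect_equal(sw1$r_squared, 1)
  # strict criterion keeps null models mostly empty
  empties <- 0
  for (s in 1:20) {
    set.seed(6100 + s)
    Z <- as.data.frame(matrix(rnorm(100 * 5), 100, 5))
    names(Z) <- paste0("x", 1:5)
    Z$y <- rnorm(100)
    if (length(stepwise_regression(Z, "y", paste0("x", 1:5),
                                   criterion = "bic")$selected) == 0) {
      empties <- empties + 1
    }
  }
  expect_gt(empties, 10)
  # exact duplicates are screened out as collinear
  d2 <- data.frame(y = rnorm(50), a = rnorm(50))
  d2$b <- d2$a
  expect_warning(sw2 <- stepwise_regression(d2, "y", c("a", "b")),
                 "collinear")
  expect_lt(length(setdiff(c("a", "b"), sw2$dropped_collinear)), 2)
  expect_error(stepwise_regression(X[1:5, ], "y", paste0("x", 1:7)),
               "candidates")
})

test_that("the report bundle assembles available stages and logs gaps", {
  qcfg <- quest_gen_config()
  q <- generate_questionnaires(qcfg, c(nPTSD = 6, sPTSD = 6, fPTSD = 6),
                               seed = 71)
  q <- classify_cohort(q)
  q$pcl_total <- rowSums(q[, paste0("pcl_", 1:17)])
  q$group <- q$group_true   # analysis by generated group for the smoke test
  set.seed(72)
  asym <- data.frame(subject = q$subject, group = q$group,
                     region = "posterior",
                     other = rnorm(18), self = rnorm(18))
  bundle <- assemble_report(scores = q, asymmetry = asym,
                            autonomic = NULL, responses = NULL,
                            excluded = c(S99 = "75% epochs rejected"),
                            settings = list(symptom_min = 4))
  expect_s3_class(bundle$sections$asymmetry$posterior,
                  "mixed_anova_result")
  expect_identical(bundle$sections$autonomic, "absent")
  expect_identical(bundle$sections$microstates, "absent")
  expect_true("pcl_total" %in% names(bundle$sections$self_report))
  expect_equal(bundle$excluded[["S99"]], "75% epochs rejected")
  expect_equal(bundle$log$symptom_min, 4)
})
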