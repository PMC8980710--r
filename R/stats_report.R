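#' Mixed (split-plot) ANOVA with a two-level within factor
#'
#' Repeated-measures ANOVA with one between-subjects factor and one
#' two-level within-subjects factor (e.g. focus = other vs self), the design
#' used throughout this paradigm. With two within levels sphericity is
#' trivially satisfied and the classical decomposition applies: the
#' between-subjects effect is tested on subject means, the within effect and
#' interaction on subject differences, with Type III sums of squares
#' (sum-to-zero contrasts) for unbalanced groups. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. Normality (Shapiro-Wilk on
#' residuals) and homogeneity (Levene) checks are reported, not enforced.
#'
#' Subjects missing a within level are dropped listwise (logged in the
#' result).
#'
#' @param data Long-format data frame.
#' @param dv,within,between,subject Column names.
#' @return A `mixed_anova_result`: data frame with one row per effect
#'   (`group`, `focus`, `interaction`): `F`, `df_num`, `df_den`, `p`,
#'   `partial_eta_sq`, `ss`, `ss_error`; plus attributes `checks` and
#'   `n_dropped`.
#' @export
mixed_anova <- function(data, dv, within, between, subject) {
  d <- data[, c(dv, within, between, subject)]
  names(d) <- c("y", "w", "g", "id")
  d$w <- factor(d$w); d$g <- factor(d$g); d$id <- factor(d$id)
  if (nlevels(d$w) != 2) {
    stopf("within factor must have exactly 2 levels, got %d", nlevels(d$w))
  }
  cnt <- table(d$id)
  complete <- names(cnt)[cnt == 2]
  n_dropped <- sum(cnt != 2)
  d <- d[d$id %in% complete, ]
  wide <- merge(
    d[d$w == levels(d$w)[1], c("id", "g", "y")],
    d[d$w == levels(d$w)[2], c("id", "y")], by = "id",
    suffixes = c("_1", "_2"))
  wide$m <- (wide$y_1 + wide$y_2) / 2
  wide$dff <- wide$y_2 - wide$y_1
  n <- nrow(wide)
  ng <- nlevels(droplevels(wide$g))
  if (n <= ng) stopf("not enough complete subjects")
  opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opts))

  # between: one-way ANOVA on subject means (x2 to the mixed-design scale)
  mb <- stats::lm(m ~ g, data = wide)
  ab <- stats::anova(mb)
  ss_b <- 2 * ab["g", "Sum Sq"]; ss_be <- 2 * ab["Residuals", "Sum Sq"]
  f_b <- ab["g", "F value"]

  # within + interaction: Type III on subject differences (/2 to scale)
  md <- stats::lm(dff ~ g, data = wide)
  if (sum(stats::residuals(md)^2) < 1e-12 * max(1, stats::var(wide$y_1))) {
    # degenerate within data (e.g. both levels identical): null effects
    ss_f <- ss_i <- ss_we <- 0
    f_f <- f_i <- 0
  } else {
    aw <- car::Anova(md, type = 3)
    ss_f <- aw["(Intercept)", "Sum Sq"] / 2
    ss_i <- aw["g", "Sum Sq"] / 2
    ss_we <- aw["Residuals", "Sum Sq"] / 2
    f_f <- aw["(Intercept)", "F value"]
    f_i <- aw["g", "F value"]
  }

  df_den <- n - ng
  eff <- data.frame(
    effect = c("group", "focus", "interaction"),
    F = c(f_b, f_f, f_i),
    df_num = c(ng - 1, 1, ng - 1),
    df_den = df_den,
    ss = c(ss_b, ss_f, ss_i),
    ss_error = c(ss_be, ss_we, ss_we),
    stringsAsFactors = FALSE)
  eff$p <- stats::pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$partial_eta_sq <- eff$ss / (eff$ss + eff$ss_error)

  checks <- list(
    shapiro_p_between = tryCatch(stats::shapiro.test(stats::residuals(mb))$p.value,
                                 error = function(e) NA_real_),
    shapiro_p_within = tryCatch(stats::shapiro.test(stats::residuals(md))$p.value,
                                error = function(e) NA_real_),
    levene_p = tryCatch(car::leveneTest(m ~ g, data = wide)[1, "Pr(>F)"],
                        error = function(e) NA_real_))
  structure(eff, class = c("mixed_anova_result", "data.frame"),
            checks = checks, n_dropped = n_dropped)
}

#' Pairwise group comparisons with Bonferroni correction
#'
#' Tests every pair of groups (Welch t or Mann-Whitney) and multiplies raw
#' p-values by the number of pairs (capped at 1). Pairs where either group
#' has fewer than 2 observations are skipped with a log entry.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param test `"t"` or `"wilcox"`.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame: `pair`, `statistic`, `p_raw`, `p_adj`, `significant`;
#'   skipped pairs in the `skipped` attribute.
#' @export
pairwise_bonferroni <- function(values, groups, test = c("t", "wilcox"),
                                alpha = 0.05) {
  test <- match.arg(test)
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2) stopf("need at least 2 groups")
  pairs <- utils::combn(gl, 2)
  m <- ncol(pairs)
  skipped <- character(0)
  rows <- list()
  for (j in seq_len(m)) {
    a <- values[groups == pairs[1, j]]
    b <- values[groups == pairs[2, j]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    pr_name <- paste(pairs[1, j], pairs[2, j], sep = " vs ")
    if (length(a) < 2 || length(b) < 2) {
      skipped <- c(skipped, pr_name)
      next
    }
    ht <- if (test == "t") stats::t.test(a, b) else
      suppressWarnings(stats::wilcox.test(a, b))
    rows[[length(rows) + 1]] <- data.frame(
      pair = pr_name, statistic = unname(ht$statistic),
      p_raw = ht$p.value, p_adj = min(1, m * ht$p.value),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pair = character(0), statistic = numeric(0),
               p_raw = numeric(0), p_adj = numeric(0))
  out$significant <- out$p_adj < alpha
  attr(out, "skipped") <- skipped
  attr(out, "m") <- m
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected rank-based H statistic (via [stats::kruskal.test()]),
#' returned in the `(statistic, df, p)` shape used throughout the reports.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values)
  g <- factor(groups[ok])
  if (length(unique(values[ok])) == 1) {
    # every observation tied: no rank variation, H = 0 by convention
    return(list(statistic = 0, df = nlevels(g) - 1, p_value = 1))
  }
  kt <- stats::kruskal.test(values[ok], g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Spearman rank correlation
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped).
#' @return List: `rho`, `p_value`, `n`. Constant input yields missing
#'   values rather than an error.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# Information criteria for an lm fit, with k = number of estimated
# parameters including the error variance. AICc is the small-sample
# corrected AIC; BIC penalizes by log(n) and is the strict choice.
ic_of <- function(fit, criterion = "aicc") {
  n <- stats::nobs(fit)
  rss <- sum(stats::residuals(fit)^2)
  k <- length(stats::coef(fit)) + 1
  if (criterion == "bic") return(n * log(rss / n) + k * log(n))
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Both-ways stepwise regression by corrected AIC
#'
#' Starting from the empty (intercept-only) model, alternates forward
#' additions and backward deletions, each step taking the move that most
#' improves the corrected information criterion (AICc), until no move
#' improves it. Candidate predictors that are numerically collinear
#' (condition number of the full design above `max_condition`) are dropped
#' up front with a warning. The full step trace is returned.
#'
#' @param data Data frame containing outcome and candidates.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate predictor columns.
#' @param direction Only `"both"` is implemented (forward and backward
#'   moves at every step).
#' @param criterion `"aicc"` (default) or the stricter `"bic"`.
#' @param max_condition Condition-number threshold for the collinearity
#'   screen.
#' @return A `stepwise_model`: `formula`, `selected`, `fit` (the final lm),
#'   `coefficients` (with SE, t, p), `r_squared`, `trace` (data frame of
#'   steps), `dropped_collinear`.
#' @export
stepwise_regression <- function(data, outcome, candidates,
                                direction = "both", criterion = c("aicc", "bic"),
                                max_condition = 1e8) {
  stopifnot(direction == "both")
  criterion <- match.arg(criterion)
  d <- stats::na.omit(data[, c(outcome, candidates)])
  n <- nrow(d)
  if (n <= length(candidates) + 2) {
    stopf("need n > number of candidates + 2 (n = %d, candidates = %d)",
          n, length(candidates))
  }
  X <- scale(as.matrix(d[, candidates, drop = FALSE]))
  sv <- svd(cbind(1, X), nu = 0, nv = 0)$d
  dropped <- character(0)
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > max_condition) {
    # drop candidates until the design is well conditioned
    remaining <- candidates
    repeat {
      Xr <- scale(as.matrix(d[, remaining, drop = FALSE]))
      sv <- svd(cbind(1, Xr), nu = 0, nv = 0)$d
      if (sv[length(sv)] > 0 && sv[1] / sv[length(sv)] <= max_condition) break
      cors <- abs(stats::cor(Xr))
      diag(cors) <- 0
      worst <- remaining[which.max(apply(cors, 1, max))]
      dropped <- c(dropped, worst)
      remaining <- setdiff(remaining, worst)
      if (length(remaining) == 0) break
    }
    warnf("dropped collinear candidate(s): %s",
          paste(dropped, collapse = ", "))
    candidates <- setdiff(candidates, dropped)
  }
  current <- character(0)
  fit <- stats::lm(stats::reformulate("1", outcome), data = d)
  crit <- ic_of(fit, criterion)
  trace <- data.frame(step = 0L, action = "start", term = "",
                      ic = crit, stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    moves <- list()
    for (tm in setdiff(candidates, current)) {
      moves[[length(moves) + 1]] <- list(action = "add", term = tm,
                                         terms = c(current, tm))
    }
    for (tm in current) {
      moves[[length(moves) + 1]] <- list(action = "drop", term = tm,
                                         terms = setdiff(current, tm))
    }
    if (length(moves) == 0) break
    scores <- vapply(moves, function(mv) {
      rhs <- if (length(mv$terms) == 0) "1" else mv$terms
      ic_of(stats::lm(stats::reformulate(rhs, outcome), data = d), criterion)
    }, 0)
    if (min(scores) >= crit - 1e-10) break
    bestm <- moves[[which.min(scores)]]
    current <- bestm$terms
    crit <- min(scores)
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i, action = bestm$action,
                                     term = bestm$term, ic = crit,
                                     stringsAsFactors = FALSE))
  }
  rhs <- if (length(current) == 0) "1" else current
  fit <- stats::lm(stats::reformulate(rhs, outcome), data = d)
  sm <- summary(fit)
  structure(list(
    formula = stats::formula(fit),
    criterion = criterion,
    selected = current,
    fit = fit,
    coefficients = sm$coefficients,
    r_squared = sm$r.squared,
    trace = trace,
    dropped_collinear = dropped
  ), class = "stepwise_model")
}

#' Assemble the cohort-level results bundle
#'
#' Runs the statistical battery on whatever stage outputs are supplied and
#' collects the results with a run log of the active settings. Missing
#' stages are marked absent; the run continues.
#'
#' @param scores Questionnaire table after [classify_cohort()] (or `NULL`).
#' @param asymmetry Data frame `subject`, `group`, `region`, `other`, `self`
#'   (phase means per subject; or `NULL`).
#' @param autonomic Data frame `subject`, `group`, `measure`, `other`,
#'   `self` (or `NULL`).
#' @param responses Microstate duration-response table from
#'   [fit_cohort_microstates()] (or `NULL`).
#' @param excluded Named character vector of excluded subjects with reasons.
#' @param settings Named list of active design settings to log.
#' @return A `results_bundle` list of per-analysis sections plus `log`.
#' @export
assemble_report <- function(scores = NULL, asymmetry = NULL,
                            autonomic = NULL, responses = NULL,
                            excluded = character(0), settings = list()) {
  bundle <- list(sections = list(), excluded = excluded,
                 log = c(list(time = format(Sys.time())), settings))
  long2 <- function(df, measure_cols) {
    do.call(rbind, lapply(measure_cols, function(cl) {
      data.frame(subject = rep(df$subject, 2), group = rep(df$group, 2),
                 focus = rep(c("other", "self"), each = nrow(df)),
                 y = c(df[[cl[1]]], df[[cl[2]]]),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(scores)) {
    vars <- intersect(c("pcl_total", "scs_sf_total", "dass_depression",
                        "dass_anxiety", "dass_stress", "fscsr_inadequate",
                        "fscsr_hated", "fscsr_reassured"), names(scores))
    bundle$sections$self_report <- lapply(stats::setNames(vars, vars),
      function(v) {
        list(kruskal = kruskal_wallis(scores[[v]], scores$group),
             pairwise = pairwise_bonferroni(scores[[v]], scores$group))
      })
  } else bundle$sections$self_report <- "absent"
  section_anova <- function(df) {
    long <- long2(df, list(c("other", "self")))
    mixed_anova(long, "y", "focus", "group", "subject")
  }
  for (nm in c("asymmetry", "autonomic")) {
    df <- get(nm)
    if (is.null(df)) {
      bundle$sections[[nm]] <- "absent"
      next
    }
    split_col <- if (nm == "asymmetry") "region" else "measure"
    bundle$sections[[nm]] <- lapply(split(df, df[[split_col]]),
                                    section_anova)
  }
  if (!is.null(responses)) {
    # within = microstate (B vs C mean duration response), between = group
    sub <- responses[responses$state %in% c("B", "C"), ]
    agg <- stats::aggregate(response_ms ~ subject + group + state,
                            data = sub, FUN = mean)
    names(agg)[names(agg) == "state"] <- "focus"
    bundle$sections$microstates <- mixed_anova(agg, "response_ms", "focus",
                                               "group", "subject")
  } else bundle$sections$microstates <- "absent"
  class(bundle) <- "results_bundle"
  bundle
}
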