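# Published scoring keys for the self-report battery. Item index vectors are
# the instruments' standard subscale assignments.

pcl_cluster_items <- function() {
  list(intrusion = 1:5, avoidance_numbing = 6:12, hyperarousal = 13:17)
}

dass_subscale_items <- function() {
  list(depression = c(3, 5, 10, 13, 16, 17, 21, 24, 26, 31, 34, 37, 38, 42),
       anxiety = c(2, 4, 7, 9, 15, 19, 20, 23, 25, 28, 30, 36, 40, 41),
       stress = c(1, 6, 8, 11, 12, 14, 18, 22, 27, 29, 32, 33, 35, 39))
}

fscsr_subscale_items <- function() {
  list(inadequate = c(1, 2, 4, 6, 7, 14, 17, 18, 20),
       hated = c(9, 10, 12, 15, 22),
       reassured = c(3, 5, 8, 11, 13, 16, 19, 21))
}

scs_sf_reverse_items <- function() c(1, 4, 8, 9, 11, 12)

#' Score the 17-item PCL-C checklist
#'
#' Computes the total severity score and the per-cluster counts of present
#' symptoms. A symptom is present when its item score is at least
#' `symptom_min`; the default 4 implements the "score above 3" rule, setting
#' `symptom_min = 3` gives the conventional moderate-or-above (>= 3) rule.
#'
#' @param items Integer vector of 17 item scores, each in 1..5.
#' @param symptom_min Minimum item score that counts as a present symptom.
#' @return A `pcl_result` list: `items`, `total` (17..85), and symptom counts
#'   `n_intrusion`, `n_avoid_numb`, `n_hyper`.
#' @export
#' @examples
#' score_pcl(rep(1, 17))$total
score_pcl <- function(items, symptom_min = 4) {
  if (length(items) != 17) {
    stopf("PCL-C requires 17 items, got %d", length(items))
  }
  bad <- which(!(items %in% 1:5))
  if (length(bad) > 0) {
    stopf("PCL-C item %d out of range 1..5 (value %s)", bad[1],
          format(items[bad[1]]))
  }
  cl <- pcl_cluster_items()
  present <- items >= symptom_min
  structure(list(
    items = as.integer(items),
    total = sum(items),
    n_intrusion = sum(present[cl$intrusion]),
    n_avoid_numb = sum(present[cl$avoidance_numbing]),
    n_hyper = sum(present[cl$hyperarousal]),
    symptom_min = symptom_min
  ), class = "pcl_result")
}

#' Classify PTSD status from a scored PCL-C
#'
#' Applies the three-group rules: full PTSD requires at least 1 intrusion,
#' 3 avoidance/numbing and 2 hyperarousal symptoms with total above the
#' caseness cutoff; subsyndromal PTSD requires the intrusion criterion plus at
#' least one of the other two cluster criteria (full PTSD taking precedence);
#' no PTSD requires that no cluster criterion is met and total below the
#' cutoff. Anything else is `unclassified` and must be resolved explicitly
#' (see `override`).
#'
#' @param pcl A `pcl_result` from [score_pcl()].
#' @param total_cutoff Caseness cutoff on the total score (default 44; full
#'   PTSD needs total > cutoff, no PTSD needs total < cutoff, both strict).
#' @param override Optional label forced onto an `unclassified` result
#'   (mirrors a manual clinical reassignment); ignored for classified cases.
#' @return One of `"nPTSD"`, `"sPTSD"`, `"fPTSD"`, `"unclassified"`.
#' @export
#' @examples
#' classify_ptsd(score_pcl(rep(5, 17)))
classify_ptsd <- function(pcl, total_cutoff = 44, override = NULL) {
  stopifnot(inherits(pcl, "pcl_result"))
  crit_b <- pcl$n_intrusion >= 1
  crit_c <- pcl$n_avoid_numb >= 3
  crit_d <- pcl$n_hyper >= 2
  label <-
    if (crit_b && crit_c && crit_d && pcl$total > total_cutoff) "fPTSD"
    else if (crit_b && (crit_c || crit_d)) "sPTSD"
    else if (!crit_b && !crit_c && !crit_d && pcl$total < total_cutoff) "nPTSD"
    else "unclassified"
  if (label == "unclassified" && !is.null(override)) {
    stopifnot(override %in% c("nPTSD", "sPTSD", "fPTSD"))
    label <- override
  }
  label
}

#' Score the PCL-C rows of a subject table and classify each subject
#'
#' @param subjects Data frame with columns `pcl_1` .. `pcl_17` and `subject`.
#' @param symptom_min Passed to [score_pcl()].
#' @param total_cutoff Passed to [classify_ptsd()].
#' @param overrides Optional named character vector `subject -> label`
#'   resolving individual `unclassified` cases.
#' @return The input with columns `pcl_total`, `n_intrusion`, `n_avoid_numb`,
#'   `n_hyper` and `group` appended. Unclassified subjects are retained and
#'   flagged, never dropped.
#' @export
classify_cohort <- function(subjects, symptom_min = 4, total_cutoff = 44,
                            overrides = NULL) {
  cols <- paste0("pcl_", 1:17)
  stopifnot(all(cols %in% names(subjects)))
  res <- lapply(seq_len(nrow(subjects)), function(i) {
    p <- score_pcl(as.integer(subjects[i, cols]), symptom_min = symptom_min)
    ov <- if (!is.null(overrides)) overrides[[subjects$subject[i]]] else NULL
    data.frame(pcl_total = p$total, n_intrusion = p$n_intrusion,
               n_avoid_numb = p$n_avoid_numb, n_hyper = p$n_hyper,
               group = classify_ptsd(p, total_cutoff, override = ov),
               stringsAsFactors = FALSE)
  })
  cbind(subjects, do.call(rbind, res))
}

#' Score the SCS-SF, DASS and FSCSR instruments
#'
#' SCS-SF: 12 items on 1..5, reverse-keyed items inverted (6 - x), total
#' reported. DASS: 42 items on 0..3, subscale totals. FSCSR: 22 items on
#' 0..4, subscale means. Any supplied VAS scores (0..100) are passed through.
#'
#' @param scs_sf,dass,fscsr Integer item vectors (12 / 42 / 22 items) or
#'   `NULL` to skip an instrument.
#' @param vas Optional named numeric vector of VAS scores in 0..100.
#' @return A `scale_scores` list with the computed totals/means.
#' @export
score_scales <- function(scs_sf = NULL, dass = NULL, fscsr = NULL,
                         vas = NULL) {
  out <- list()
  check <- function(x, n, lo, hi, name) {
    if (length(x) != n) stopf("%s requires %d items, got %d", name, n,
                              length(x))
    bad <- which(x < lo | x > hi | x != round(x))
    if (length(bad) > 0) stopf("%s item %d out of range %d..%d", name,
                               bad[1], lo, hi)
  }
  if (!is.null(scs_sf)) {
    check(scs_sf, 12, 1, 5, "SCS-SF")
    x <- scs_sf
    rev <- scs_sf_reverse_items()
    x[rev] <- 6 - x[rev]
    out$scs_sf_total <- sum(x)
  }
  if (!is.null(dass)) {
    check(dass, 42, 0, 3, "DASS")
    it <- dass_subscale_items()
    out$dass_depression <- sum(dass[it$depression])
    out$dass_anxiety <- sum(dass[it$anxiety])
    out$dass_stress <- sum(dass[it$stress])
  }
  if (!is.null(fscsr)) {
    check(fscsr, 22, 0, 4, "FSCSR")
    it <- fscsr_subscale_items()
    out$fscsr_inadequate <- mean(fscsr[it$inadequate])
    out$fscsr_hated <- mean(fscsr[it$hated])
    out$fscsr_reassured <- mean(fscsr[it$reassured])
  }
  if (!is.null(vas)) {
    if (any(vas < 0 | vas > 100)) stopf("VAS scores must lie in 0..100")
    out[names(vas)] <- as.list(vas)
  }
  structure(out, class = "scale_scores")
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Uncorrected (no continuity correction) Pearson chi-square with expected
#' counts `row_total * col_total / grand_total`, as used for the demographic
#' group comparisons.
#'
#' @param table Matrix of non-negative counts (groups x categories).
#' @return A `chisq_result` list: `statistic`, `df`, `p_value`, `expected`.
#' @export
#' @examples
#' chi_square_independence(rbind(c(15, 2), c(10, 9), c(17, 3)))$statistic
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stopf("counts must be non-negative")
  if (sum(table) <= 0) stopf("grand total must be positive")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("zero marginal row/column: expected counts undefined")
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    stopf("need at least 2 rows and 2 columns (df would be 0)")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 expected = ct$expected),
            class = "chisq_result")
}

#' Demographic group comparisons (contingency tables + chi-square)
#'
#' Builds a group x category contingency table per categorical variable and
#' tests independence with the uncorrected Pearson chi-square. Subjects with
#' a missing category value are excluded from that variable's table, with the
#' excluded count reported.
#'
#' @param subjects Data frame with a `group` column plus the categorical
#'   variables.
#' @param variables Character vector of column names to compare.
#' @return Named list per variable: `table`, `result` ([chi_square_independence()]),
#'   `n_missing`.
#' @export
demographics_report <- function(subjects, variables) {
  stopifnot("group" %in% names(subjects))
  if (length(unique(subjects$group)) < 2) {
    stopf("need at least 2 groups (df would be 0)")
  }
  out <- lapply(variables, function(v) {
    if (!v %in% names(subjects)) stopf("variable '%s' not in table", v)
    ok <- !is.na(subjects[[v]])
    tab <- table(subjects$group[ok], subjects[[v]][ok])
    list(table = unclass(tab),
         result = chi_square_independence(tab),
         n_missing = sum(!ok))
  })
  names(out) <- variables
  out
}
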