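#' Configuration for the synthetic questionnaire generator
#'
#' Per-group generative profiles for the self-report battery: categorical
#' item-score distributions for the 17 PCL-C items, per-item mean/SD targets
#' for SCS-SF, DASS and FSCSR, visual-analogue-scale means at the three
#' timepoints, and per-group demographic category probabilities.
#'
#' The default profiles are synthetic stand-ins chosen so that the three
#' generated groups respect the PCL-C classification rules (no-PTSD items
#' never reach the symptomatic range; the full-PTSD profile satisfies all
#' cluster criteria and the caseness cutoff; the subsyndromal profile has high
#' intrusion and hyperarousal but low avoidance/numbing) and so that the
#' demographic category frequencies resemble a civilian trauma-survivor
#' cohort.
#'
#' @param groups Group labels, in generation order.
#' @param pcl_item_probs Named list (per group) of probability vectors over
#'   item scores 1-5. A single 5-vector applies to all 17 items; a 17 x 5
#'   matrix gives per-item distributions.
#' @param scale_profiles Named list (per group) with elements `scs_sf`,
#'   `dass`, `fscsr`, `vas`: each a list of per-item `mean` and `sd` targets
#'   (see defaults for structure).
#' @param demographics Named list of demographic variables; each is a list
#'   with `categories` and a groups x categories probability matrix `probs`.
#' @return A `quest_gen_config` list, validated.
#' @export
quest_gen_config <- function(groups = c("nPTSD", "sPTSD", "fPTSD"),
                             pcl_item_probs = NULL,
                             scale_profiles = NULL,
                             demographics = NULL) {
  if (is.null(pcl_item_probs)) {
    pcl_item_probs <- list(
      nPTSD = c(0.60, 0.30, 0.10, 0.00, 0.00),
      sPTSD = rbind(
        matrix(rep(c(0.05, 0.10, 0.20, 0.40, 0.25), 5), 5, byrow = TRUE),
        matrix(rep(c(0.50, 0.30, 0.15, 0.05, 0.00), 7), 7, byrow = TRUE),
        matrix(rep(c(0.05, 0.15, 0.20, 0.35, 0.25), 5), 5, byrow = TRUE)),
      fPTSD = c(0.00, 0.05, 0.15, 0.40, 0.40)
    )[groups]
  }
  if (is.null(scale_profiles)) {
    prof <- function(scs_m, dass_m, fscsr_m, vas_c, vas_cr) {
      list(scs_sf = list(mean = scs_m, sd = 0.8),
           dass = list(mean = dass_m, sd = 0.7),
           fscsr = list(mean = fscsr_m, sd = 0.8),
           vas = list(compassion = vas_c, criticism = vas_cr, sd = 12))
    }
    scale_profiles <- list(
      nPTSD = prof(3.6, c(dep = 0.5, anx = 0.4, str = 0.7),
                   c(inadequate = 1.2, hated = 0.5, reassured = 2.6),
                   vas_c = c(62, 64, 70), vas_cr = c(35, 34, 28)),
      sPTSD = prof(2.7, c(dep = 1.0, anx = 0.9, str = 1.3),
                   c(inadequate = 2.2, hated = 1.0, reassured = 1.9),
                   vas_c = c(48, 50, 55), vas_cr = c(52, 51, 46)),
      fPTSD = prof(2.4, c(dep = 1.8, anx = 1.6, str = 1.9),
                   c(inadequate = 2.8, hated = 1.9, reassured = 1.5),
                   vas_c = c(40, 42, 46), vas_cr = c(63, 62, 57))
    )[groups]
  }
  if (is.null(demographics)) {
    dem <- function(categories, ...) {
      probs <- rbind(...)
      dimnames(probs) <- list(groups, categories)
      list(categories = categories, probs = probs)
    }
    demographics <- list(
      sex = dem(c("Male", "Female"),
                c(0.24, 0.76), c(0.15, 0.85), c(0.21, 0.79)),
      medication = dem(c("No", "Yes"),
                       c(0.88, 0.12), c(0.85, 0.15), c(0.53, 0.47)),
      handedness = dem(c("Right", "Left"),
                       c(0.88, 0.12), c(0.90, 0.10), c(0.95, 0.05)),
      meditation = dem(c("No", "Yes"),
                       c(0.82, 0.18), c(0.65, 0.35), c(0.63, 0.37))
    )
  }
  for (nm in names(pcl_item_probs)) {
    p <- pcl_item_probs[[nm]]
    if (!is.matrix(p)) p <- matrix(rep(p, 17), 17, byrow = TRUE)
    if (ncol(p) != 5 || nrow(p) != 17) {
      stopf("pcl_item_probs[[%s]] must be 5 probabilities or 17 x 5", nm)
    }
    if (any(abs(rowSums(p) - 1) > 1e-9)) {
      stopf("pcl_item_probs[[%s]] rows must sum to 1", nm)
    }
    pcl_item_probs[[nm]] <- p
  }
  structure(list(groups = groups, pcl_item_probs = pcl_item_probs,
                 scale_profiles = scale_profiles,
                 demographics = demographics),
            class = "quest_gen_config")
}

# Draw integer Likert items around per-item mean targets, clamped to range.
draw_items <- function(n_items, mean, sd, lo, hi) {
  mean <- rep(mean, length.out = n_items)
  x <- round(stats::rnorm(n_items, mean = mean, sd = sd))
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic questionnaire table
#'
#' One row per subject with PCL-C items, SCS-SF / DASS / FSCSR items, VAS
#' scores at the three timepoints, demographic categories, and the true
#' generating group label (`group_true`) for recovery testing.
#'
#' @param cfg A [quest_gen_config()].
#' @param n_per_group Named (or ordered) vector of subjects per group.
#' @param seed Integer seed.
#' @return A data frame, one row per subject.
#' @export
generate_questionnaires <- function(cfg, n_per_group, seed) {
  stopifnot(inherits(cfg, "quest_gen_config"))
  if (is.null(names(n_per_group))) names(n_per_group) <- cfg$groups
  stopifnot(all(n_per_group >= 1))
  with_seed(seed, {
    rows <- list()
    sid <- 0L
    for (g in cfg$groups) {
      pp <- cfg$pcl_item_probs[[g]]
      sp <- cfg$scale_profiles[[g]]
      for (i in seq_len(n_per_group[[g]])) {
        sid <- sid + 1L
        pcl <- vapply(seq_len(17), function(j) {
          sample.int(5, 1, prob = pp[j, ])
        }, 0L)
        scs <- draw_items(12, sp$scs_sf$mean, sp$scs_sf$sd, 1, 5)
        dass <- c(draw_items(14, sp$dass$mean[["dep"]], sp$dass$sd, 0, 3),
                  draw_items(14, sp$dass$mean[["anx"]], sp$dass$sd, 0, 3),
                  draw_items(14, sp$dass$mean[["str"]], sp$dass$sd, 0, 3))
        # dass items are generated subscale-blocked then placed on the
        # published item order
        dass_items <- integer(42)
        dass_items[dass_subscale_items()$depression] <- dass[1:14]
        dass_items[dass_subscale_items()$anxiety] <- dass[15:28]
        dass_items[dass_subscale_items()$stress] <- dass[29:42]
        fs <- integer(22)
        fi <- fscsr_subscale_items()
        fs[fi$inadequate] <- draw_items(length(fi$inadequate),
                                        sp$fscsr$mean[["inadequate"]],
                                        sp$fscsr$sd, 0, 4)
        fs[fi$hated] <- draw_items(length(fi$hated),
                                   sp$fscsr$mean[["hated"]], sp$fscsr$sd,
                                   0, 4)
        fs[fi$reassured] <- draw_items(length(fi$reassured),
                                       sp$fscsr$mean[["reassured"]],
                                       sp$fscsr$sd, 0, 4)
        vas_c <- pmin(pmax(stats::rnorm(3, sp$vas$compassion, sp$vas$sd),
                           0), 100)
        vas_cr <- pmin(pmax(stats::rnorm(3, sp$vas$criticism, sp$vas$sd),
                            0), 100)
        dems <- lapply(cfg$demographics, function(d) {
          d$categories[sample.int(length(d$categories), 1,
                                  prob = d$probs[g, ])]
        })
        row <- c(list(subject = sprintf("S%03d", sid), group_true = g),
                 stats::setNames(as.list(pcl), paste0("pcl_", 1:17)),
                 stats::setNames(as.list(scs), paste0("scs_", 1:12)),
                 stats::setNames(as.list(dass_items), paste0("dass_", 1:42)),
                 stats::setNames(as.list(fs), paste0("fscsr_", 1:22)),
                 stats::setNames(as.list(round(vas_c, 1)),
                                 paste0("vas_compassion_t", 1:3)),
                 stats::setNames(as.list(round(vas_cr, 1)),
                                 paste0("vas_criticism_t", 1:3)),
                 dems)
        rows[[sid]] <- as.data.frame(row, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Cohort-level configuration for the synthetic study
#'
#' Bundles the per-modality generator configurations with the cohort layout.
#' The default layout mirrors a three-group civilian trauma cohort of
#' 17 / 20 / 19 subjects (no, subsyndromal, full PTSD).
#'
#' @param n_per_group Named vector of subjects per group.
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param eeg,autonomic,questionnaire Module generator configurations.
#' @param n_lkm_minutes Number of induction minutes (11 in the full session).
#' @param post Include a post-induction resting minute.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(nPTSD = 17, sPTSD = 20,
                                          fPTSD = 19),
                          seed = 1,
                          eeg = eeg_gen_config(),
                          autonomic = autonomic_gen_config(),
                          questionnaire = quest_gen_config(
                            groups = names(n_per_group)),
                          n_lkm_minutes = 11,
                          post = TRUE) {
  stopifnot(all(n_per_group >= 1))
  structure(list(n_per_group = n_per_group, seed = seed, eeg = eeg,
                 autonomic = autonomic, questionnaire = questionnaire,
                 n_lkm_minutes = n_lkm_minutes, post = post),
            class = "cohort_config")
}

#' Simulate a synthetic cohort
#'
#' Generates the questionnaire table and, per subject, the EEG recording,
#' RR series and SCL trace for a session of `1 + n_lkm_minutes (+ 1)`
#' annotated minutes. EEG generation can be switched off when only the
#' autonomic/questionnaire channels are needed.
#'
#' @param cfg A [cohort_config()].
#' @param eeg Generate EEG recordings (they dominate run time).
#' @return List with `questionnaires` (data frame) and `subjects` (list of
#'   per-subject lists with `recording`, `rr`, `scl`, `group`).
#' @export
simulate_cohort <- function(cfg, eeg = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  labels <- c("B", paste0("LKM", seq_len(cfg$n_lkm_minutes)),
              if (cfg$post) "P")
  n_minutes <- length(labels)
  quest <- generate_questionnaires(cfg$questionnaire, cfg$n_per_group,
                                   seed = child_seed(cfg$seed, 0L))
  subjects <- vector("list", nrow(quest))
  names(subjects) <- quest$subject
  for (i in seq_len(nrow(quest))) {
    rec <- if (eeg) {
      generate_microstate_eeg(cfg$eeg, n_minutes,
                              seed = child_seed(cfg$seed, 3L * i + 1L),
                              labels = labels)
    } else NULL
    rr <- generate_rr_series(cfg$autonomic, n_minutes,
                             seed = child_seed(cfg$seed, 3L * i + 2L))
    scl <- generate_scl_trace(cfg$autonomic, n_minutes,
                              seed = child_seed(cfg$seed, 3L * i + 3L))
    subjects[[i]] <- list(subject = quest$subject[i],
                          group = quest$group_true[i],
                          recording = rec, rr = rr, scl = scl)
  }
  list(questionnaires = quest, subjects = subjects,
       minute_labels = labels, seed = cfg$seed)
}

#' Write a simulated cohort to disk
#'
#' EEG goes to EDF with JSON sidecars; RR, SCL and questionnaires to CSV;
#' minute annotations to JSON. All formats round-trip through the package's
#' own readers.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$questionnaires,
                   file.path(dir, "questionnaires.csv"), row.names = FALSE)
  for (s in cohort$subjects) {
    if (!is.null(s$recording)) {
      write_recording(s$recording,
                      file.path(dir, paste0(s$subject, "_eeg.edf")))
    }
    utils::write.csv(as.data.frame(s$rr),
                     file.path(dir, paste0(s$subject, "_rr.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(s$scl),
                     file.path(dir, paste0(s$subject, "_scl.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(minute_labels = cohort$minute_labels, seed = cohort$seed),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
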