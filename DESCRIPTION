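Package: lkmstates
Title: EEG Microstate, Alpha-Asymmetry and Autonomic Analysis of a
    Self-Compassion Induction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for neurophysiological studies of a
    loving-kindness meditation self-compassion induction in trauma survivors.
    Scores the PCL-C checklist and classifies participants into no,
    subsyndromal and full PTSD groups; conditions multi-channel EEG (epoching,
    amplitude artifact rejection, acceptance accounting); computes anterior and
    posterior alpha-band hemispheric asymmetry; performs polarity-invariant
    modified k-means EEG microstate segmentation with winner-takes-all
    backfitting and duration-response statistics; processes heart rate,
    high-frequency heart-rate variability and range-corrected skin conductance
    responses; and runs the group-level statistical battery (mixed ANOVA,
    Bonferroni pairwise tests, Kruskal-Wallis, Spearman, both-ways stepwise
    regression). Includes a synthetic-cohort generator with recoverable
    ground-truth parameters so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
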