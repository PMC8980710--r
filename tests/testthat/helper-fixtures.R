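# Shared fixture builders. Everything is generated in code at test time.

scalp_montage <- function() setdiff(default_montage(), c("A1", "A2"))

# A recording holding a raw data matrix with standard 60-s minute labels.
quick_recording <- function(data, fs, channels, n_minutes = 1) {
  eeg_recording(data, fs, channels,
                annotations = data.frame(
                  label = c("B", if (n_minutes > 1)
                    paste0("LKM", seq_len(n_minutes - 1))),
                  start_s = (seq_len(n_minutes) - 1) * 60,
                  end_s = seq_len(n_minutes) * 60))
}

# Independent literal transcription of the PTSD grouping rules, used as a
# brute-force oracle against classify_ptsd(). Deliberately written flat.
oracle_classify <- function(items, symptom_min = 4, cutoff = 44) {
  total <- sum(items)
  b <- sum(items[1:5] >= symptom_min)
  c <- sum(items[6:12] >= symptom_min)
  d <- sum(items[13:17] >= symptom_min)
  if (b >= 1 && c >= 3 && d >= 2 && total > cutoff) return("fPTSD")
  if (b >= 1 && (c >= 3 || d >= 2)) return("sPTSD")
  if (b == 0 && c < 3 && d < 2 && total < cutoff) return("nPTSD")
  "unclassified"
}

# Hand-rolled Pearson chi-square oracle.
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Printed reference values for the demographic group comparisons.
table2_reference <- function() {
  data.frame(
    variable = c("sex", "marital_status", "occupation", "education",
                 "medication", "trauma_type", "number_of_traumas",
                 "meditation", "handedness"),
    statistic = c(0.45974, 2.045, 6.7713, 4.4931, 7.7251, 2.7973,
                  0.0372, 1.8809, 0.5103),
    df = c(2, 2, 6, 2, 2, 4, 2, 2, 2))
}

# Agreement with a printed statistic at its printed precision.
expect_printed_equal <- function(x, ref) {
  expect_lt(abs(x - ref), 5e-4)
}
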