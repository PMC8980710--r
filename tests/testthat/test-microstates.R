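test_that("GFP is the per-sample population SD across channels", {
  rec <- eeg_recording(rbind(c(1, 2, 0), c(1, -2, 0)), 10, c("a", "b"))
  g <- gfp(rec)
  expect_equal(as.numeric(g), c(0, 2, 0))   # equal channels -> 0; (+a,-a) -> a
  set.seed(2)
  m <- matrix(rnorm(30 * 200), 30)
  g2 <- gfp(eeg_recording(m, 10, paste0("c", 1:30)))
  oracle <- apply(m, 2, function(col) sqrt(mean((col - mean(col))^2)))
  expect_equal(as.numeric(g2), oracle, tolerance = 1e-12)
  expect_error(gfp(eeg_recording(m[1, , drop = FALSE], 10, "c1")),
               "2 channels")
})

test_that("GFP peaks are strict interior local maxima", {
  expect_length(gfp_peaks(1:10), 0)
  expect_equal(gfp_peaks(c(0, 1, 2, 3, 2, 1, 0)), 4)
  fs <- 125
  t <- seq_len(10 * fs) / fs
  g <- 2 + sin(2 * pi * 7 * t)
  expect_lt(abs(length(gfp_peaks(g)) - 70), 2)
})

test_that("peak map sampling selects the strongest topographies", {
  set.seed(3)
  n <- 2000
  data <- matrix(rnorm(10 * n), 10, n)
  rec <- eeg_recording(sweep(data, 2, colMeans(data)), 125, paste0("c", 1:10))
  g <- gfp(rec)
  pk <- gfp_peaks(g)
  expect_gt(length(pk), 150)
  maps <- sample_peak_maps(rec, pk, n = 100)
  expect_equal(dim(maps), c(100, 10))
  expect_equal(rowSums(maps^2), rep(1, 100), tolerance = 1e-9)
  # minimum selected GFP >= maximum excluded GFP
  sel_gfp <- sort(attr(maps, "gfp"))
  excluded <- sort(g[pk], decreasing = TRUE)[-seq_len(100)]
  expect_gte(sel_gfp[1], max(excluded))
  # fewer peaks than requested: all kept, with a warning
  expect_warning(maps2 <- sample_peak_maps(rec, pk[1:40], n = 100),
                 "40")
  expect_equal(nrow(maps2), 40)
  expect_error(sample_peak_maps(rec, integer(0)), "no GFP peaks")
})

test_that("modified k-means recovers planted orthogonal maps", {
  tm <- canonical_templates(scalp_montage())
  set.seed(4)
  n <- 400
  assign_true <- sample.int(4, n, replace = TRUE)
  signs <- sample(c(-1, 1), n, replace = TRUE)
  maps <- tm[assign_true, ] * signs + matrix(rnorm(n * ncol(tm), sd = 0.002),
                                             n)
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowSums(maps^2))
  model <- modified_kmeans(maps, 4, n_restarts = 10, seed = 9)
  cc <- abs(lkmstates:::spatial_corr(t(model$maps), tm))
  best <- apply(cc, 2, max)
  expect_true(all(best > 0.999))
  expect_gt(model$gev, 0.999)

  # sign-flipping any subset of input maps leaves the fit invariant
  flip <- rep(1, n)
  flip[sample.int(n, 150)] <- -1
  model_f <- modified_kmeans(maps * flip, 4, n_restarts = 10, seed = 9)
  cc_ff <- abs(lkmstates:::spatial_corr(t(model_f$maps), model$maps))
  expect_true(all(apply(cc_ff, 2, max) > 1 - 1e-9))
  expect_equal(model_f$gev, model$gev, tolerance = 1e-9)

  # k = number of maps: every map its own prototype, GEV = 1
  small <- maps[1:6, ]
  attr(small, "gfp") <- rep(1, 6)
  expect_equal(modified_kmeans(small, 6, n_restarts = 5, seed = 1)$gev, 1,
               tolerance = 1e-9)
  expect_error(modified_kmeans(small, 7), "at least k")
})

test_that("canonical alignment recovers permutations and polarity flips", {
  tm <- canonical_templates(scalp_montage())
  mk_model <- function(maps) {
    structure(list(maps = maps, labels = as.character(seq_len(nrow(maps))),
                   gev = 1, k = nrow(maps), channels = colnames(tm)),
              class = "microstate_model")
  }
  al <- align_to_canonical(mk_model(tm))
  expect_equal(al$labels, c("A", "B", "C", "D"))
  expect_equal(al$alignment_corr, 4, tolerance = 1e-9)
  expect_equal(unname(al$maps), unname(tm))

  perm <- c(3, 1, 4, 2)
  flips <- c(-1, 1, -1, 1)
  scrambled <- tm[perm, ] * flips
  al2 <- align_to_canonical(mk_model(scrambled))
  # after alignment row j must match template j up to sign
  cc <- abs(lkmstates:::spatial_corr(t(al2$maps), tm))
  expect_true(all(diag(cc) > 1 - 1e-9))
  expect_warning(align_to_canonical(mk_model(tm[1:3, ])), "labels left")
})

test_that("backfit assigns winner-takes-all labels, polarity-free", {
  tm <- canonical_templates(scalp_montage())
  model <- structure(list(maps = tm, labels = rownames(tm), gev = 1, k = 4,
                          channels = colnames(tm)),
                     class = "microstate_model")
  # alternating blocks of maps A and C, with polarity flips inside blocks
  blocks <- rep(c(1, 3), each = 50, times = 4)
  signs <- rep(c(1, -1), length.out = length(blocks))
  data <- t(tm[blocks, ] * signs)
  rec <- eeg_recording(data, 125, colnames(tm))
  sq <- backfit(model, rec)
  expect_equal(sq$states, blocks)
  expect_equal(sq$labels[unique(sq$states)], c("A", "C"))
  expect_true(all(sq$corr > 1 - 1e-9))
  # montage mismatch is an error naming channels
  bad <- eeg_recording(data[1:10, ], 125, colnames(tm)[1:10])
  expect_error(backfit(model, bad), "montage mismatch")
})

test_that("explained variance matches its brute-force formula", {
  tm <- canonical_templates(scalp_montage())
  model <- structure(list(maps = tm, labels = rownames(tm), gev = 1, k = 4,
                          channels = colnames(tm)),
                     class = "microstate_model")
  # noise-free single-map data: GEV = 1
  env <- abs(sin(seq_len(500) / 20)) + 0.1
  rec1 <- eeg_recording(t(tm[rep(2, 500), ] * env), 125, colnames(tm))
  expect_equal(variance_explained(model, rec1), 1, tolerance = 1e-9)

  set.seed(6)
  m <- matrix(rnorm(length(colnames(tm)) * 300), ncol = 300)
  m <- sweep(m, 2, colMeans(m))
  rec2 <- eeg_recording(m, 125, colnames(tm))
  gev <- variance_explained(model, rec2)
  # brute force: per-sample GFP and winning |Pearson corr| across channels
  g <- apply(m, 2, function(x) sqrt(mean((x - mean(x))^2)))
  corr <- apply(m, 2, function(x) max(abs(cor(x, t(tm)))))
  expect_equal(gev, sum((g * corr)^2) / sum(g^2), tolerance = 1e-9)
  expect_lt(gev, 1)
})

test_that("durations are exact run-length statistics", {
  mk_seq <- function(states, fs = 125, minutes = NULL) {
    n <- length(states)
    if (is.null(minutes)) {
      minutes <- data.frame(label = "B", start_s = 0, end_s = n / fs)
    }
    structure(list(states = states, labels = c("A", "B", "C", "D"),
                   corr = rep(1, n), fs_hz = fs, annotations = minutes),
              class = "microstate_sequence")
  }
  # constant minute: one run of the full length
  d <- microstate_durations(mk_seq(rep(2L, 60 * 125)))
  expect_equal(d$mean_ms[d$state == "B"], 60000)
  expect_equal(d$n_runs[d$state == "B"], 1)
  expect_true(is.na(d$mean_ms[d$state == "A"]))

  # strict alternation: every run is one sample = 8 ms at 125 Hz
  d2 <- microstate_durations(mk_seq(rep(c(1L, 2L), 500)))
  expect_equal(d2$mean_ms[d2$state %in% c("A", "B")], c(8, 8))

  # hand run-length encoding
  d3 <- microstate_durations(mk_seq(c(rep(1L, 10), rep(2L, 5), rep(1L, 5))))
  expect_equal(d3$mean_ms[d3$state == "A"], mean(c(10, 5)) * 8)
  expect_equal(d3$mean_ms[d3$state == "B"], 40)

  # boundary runs can be dropped on request
  d4 <- microstate_durations(mk_seq(c(rep(1L, 10), rep(2L, 5), rep(1L, 5))),
                             drop_boundary_runs = TRUE)
  expect_equal(d4$n_runs[d4$state == "A"], 0)
  expect_equal(d4$mean_ms[d4$state == "B"], 40)
})

test_that("durations equal a brute-force RLE oracle on random sequences", {
  set.seed(7)
  for (i in seq_len(1000)) {
    n <- sample(20:120, 1)
    states <- sample.int(4, n, replace = TRUE)
    seqobj <- structure(list(states = states, labels = c("A", "B", "C", "D"),
                             corr = rep(1, n), fs_hz = 125,
                             annotations = data.frame(label = "B",
                                                      start_s = 0,
                                                      end_s = n / 125)),
                        class = "microstate_sequence")
    d <- microstate_durations(seqobj)
    r <- rle(states)
    for (s in 1:4) {
      runs <- r$lengths[r$values == s]
      got <- d$mean_ms[d$state == c("A", "B", "C", "D")[s]]
      if (length(runs) == 0) expect_true(is.na(got))
      else expect_equal(got, mean(runs) * 8, tolerance = 1e-12)
    }
    # conservation of labelled time
    expect_equal(sum(d$mean_ms * d$n_runs, na.rm = TRUE), n * 8,
                 tolerance = 1e-9)
  }
})

test_that("duration response subtracts the baseline minute", {
  d <- data.frame(minute = rep(c("B", "LKM2"), each = 2),
                  state = rep(c("A", "B"), 2),
                  mean_ms = c(50, 60, 50, 80), n_runs = 5)
  r <- duration_response(d)
  expect_equal(r$response_ms, c(0, 20))
  base_only <- d[d$minute == "B", ]
  expect_equal(nrow(duration_response(base_only)), 0)
  expect_error(duration_response(d, baseline_minute = "X"), "missing")
})

test_that("the microstate chain is invariant to a positive gain", {
  cfg <- eeg_gen_config()
  rec <- generate_microstate_eeg(cfg, 1, seed = 31)
  tm <- canonical_templates(scalp_montage())
  model <- structure(list(maps = tm, labels = rownames(tm), gev = 1, k = 4,
                          channels = colnames(tm)),
                     class = "microstate_model")
  s1 <- backfit(model, prepare_microstate_data(rec))
  rec$data <- 10 * rec$data
  s2 <- backfit(model, prepare_microstate_data(rec))
  expect_identical(s1$states, s2$states)
  expect_identical(microstate_durations(s1)$mean_ms,
                   microstate_durations(s2)$mean_ms)
})

test_that("fitted models beat random maps in explained variance", {
  cfg <- eeg_gen_config()
  rec <- generate_microstate_eeg(cfg, 1, seed = 32)
  prep <- prepare_microstate_data(rec)
  pk <- gfp_peaks(gfp(prep))
  maps <- sample_peak_maps(prep, pk, n = 200)
  model <- modified_kmeans(maps, 4, n_restarts = 10, seed = 2)
  gev_fit <- variance_explained(model, prep)
  set.seed(8)
  nch <- length(model$channels)
  for (i in 1:20) {
    rnd <- matrix(rnorm(4 * nch), 4)
    rnd <- rnd - rowMeans(rnd)
    rnd <- rnd / sqrt(rowSums(rnd^2))
    rmodel <- structure(list(maps = rnd, labels = as.character(1:4),
                             gev = NA, k = 4, channels = model$channels),
                        class = "microstate_model")
    expect_gt(gev_fit, variance_explained(rmodel, prep))
  }
})

test_that("the k scan reports a GEV value per candidate k", {
  cfg <- eeg_gen_config()
  rec <- generate_microstate_eeg(cfg, 1, seed = 33)
  prep <- prepare_microstate_data(rec)
  maps <- sample_peak_maps(prep, gfp_peaks(gfp(prep)), n = 150)
  scan <- kmeans_scan(maps, ks = 2:5, n_restarts = 3, seed = 1)
  expect_equal(scan$k, 2:5)
  expect_true(all(diff(scan$gev) > -0.02))  # GEV does not drop with k
  expect_true(all(scan$gev > 0 & scan$gev <= 1))
})
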