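test_that("record and clip containers validate their invariants", {
  sig <- matrix(rnorm(20), 10, 2)
  rec <- eeg_record(sig, fs = 5, fine_labels = rep(0:1, each = 5))
  expect_s3_class(rec, "eeg_record")
  expect_error(eeg_record(sig, fs = 0), "positive")
  expect_error(eeg_record(sig, fs = 5, fine_labels = rep(2L, 10)), "binary")
  expect_error(eeg_record(sig, fs = 5, fine_labels = c(0, 1)), "length")

  clip <- eeg_clip(sig, fs = 5, fine_labels = rep(0:1, each = 5),
                   seizure_class = "CF", clip_seconds = 2)
  expect_identical(clip$coarse_label, 1L)
  # non-seizure clip is forced to class "none" even in a CF record
  clip0 <- eeg_clip(sig, fs = 5, fine_labels = integer(10),
                    seizure_class = "CF", clip_seconds = 2)
  expect_identical(clip0$coarse_label, 0L)
  expect_identical(clip0$seizure_class, "none")
  expect_error(eeg_clip(sig, fs = 5, fine_labels = integer(10),
                        clip_seconds = 3), "clip_seconds")
})

test_that("derive_coarse_label is max over fine labels", {
  expect_identical(derive_coarse_label(c(0, 0, 0, 1, 1, 1, 0, 0, 0)), 1L)
  expect_identical(derive_coarse_label(rep(0L, 7)), 0L)
  expect_identical(derive_coarse_label(rep(1L, 7)), 1L)
  expect_error(derive_coarse_label(integer(0)), "non-empty")
  set.seed(1)
  for (i in 1:20) {
    fine <- rbinom(sample(1:30, 1), 1, 0.3)
    expect_identical(derive_coarse_label(fine), as.integer(max(fine)))
  }
})

test_that("resample_signal maps signal and labels correctly", {
  sig <- matrix(rnorm(40), 20, 2)
  rec <- eeg_record(sig, fs = 4, fine_labels = rep(c(0L, 1L), 10))
  expect_identical(resample_signal(rec, 4), rec)   # identity case
  expect_error(resample_signal(rec, -1), "positive")

  # pure 10 Hz sine at 400 Hz resampled to 200 Hz stays a 10 Hz sine
  t400 <- (0:799) / 400
  rec2 <- eeg_record(cbind(sin(2 * pi * 10 * t400)), fs = 400)
  out <- resample_signal(rec2, 200)
  expect_equal(nrow(out$signal), 400)
  t200 <- (0:399) / 200
  expect_lt(max(abs(out$signal[, 1] - sin(2 * pi * 10 * t200))), 0.01)

  # fine labels by nearest-neighbour index mapping: [0,0,1,1] @4Hz -> [0,1]
  rec3 <- eeg_record(matrix(0, 4, 1), fs = 4,
                     fine_labels = c(0L, 0L, 1L, 1L))
  expect_identical(resample_signal(rec3, 2)$fine_labels, c(0L, 1L))
})

test_that("slice_clips cuts exact non-overlapping clips", {
  fs <- 200
  rec <- eeg_record(matrix(rnorm(30 * fs * 2), 30 * fs, 2), fs = fs,
                    fine_labels = c(rep(0L, 4000), rep(1L, 500),
                                    rep(0L, 1500)),
                    seizure_class = "AB")
  clips <- slice_clips(rec, 12)
  expect_length(clips, 2)                      # 30 s -> 2 clips, 6 s dropped
  expect_equal(nrow(clips[[1]]$signal), 2400)  # 12 s x 200 Hz
  # concatenating clips reproduces a prefix of the record
  expect_identical(rbind(clips[[1]]$signal, clips[[2]]$signal),
                   rec$signal[1:4800, ])
  expect_identical(c(clips[[1]]$fine_labels, clips[[2]]$fine_labels),
                   rec$fine_labels[1:4800])
  # labels: clip 2 (steps 2401..4800) contains the seizure span
  expect_identical(clips[[1]]$coarse_label, 0L)
  expect_identical(clips[[1]]$seizure_class, "none")
  expect_identical(clips[[2]]$coarse_label, 1L)
  expect_identical(clips[[2]]$seizure_class, "AB")

  short <- eeg_record(matrix(0, 100, 2), fs = fs)
  expect_warning(out <- slice_clips(short, 12), "shorter")
  expect_length(out, 0)
})

test_that("build_dist_graph computes the thresholded Gaussian kernel", {
  # three unit vectors with hand-computed chord distances
  coords <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  lay <- electrode_layout(c("a", "b", "c"), coords)
  d12 <- sqrt(sum((coords[1, ] - coords[2, ])^2))
  g <- build_dist_graph(lay, sigma = 1, kappa = 0)
  expect_equal(g$weights[1, 2], exp(-d12^2 / 1))
  expect_equal(g$weights[2, 3], exp(-2))             # d^2 = 2 for all pairs
  expect_equal(diag(g$weights), rep(1, 3), ignore_attr = TRUE)

  # coincident electrodes have weight exp(0) = 1
  lay2 <- electrode_layout(c("a", "b"), rbind(c(0, 0, 1), c(0, 0, 1)))
  g2 <- build_dist_graph(lay2, sigma = 1, kappa = 0)
  expect_equal(g2$weights[1, 2], 1)

  # symmetry and rotation invariance on a random layout
  set.seed(4)
  pts <- matrix(rnorm(30), 10, 3)
  pts <- pts / sqrt(rowSums(pts^2))
  lay3 <- electrode_layout(letters[1:10], pts)
  g3 <- build_dist_graph(lay3, sigma = 1, kappa = 0.1)
  expect_identical(g3$weights, t(g3$weights))
  th <- 0.83
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  g3r <- build_dist_graph(electrode_layout(letters[1:10], pts %*% rot),
                          sigma = 1, kappa = 0.1)
  expect_equal(g3r$weights, g3$weights, tolerance = 1e-12)

  # kappa that empties the graph is an error
  expect_error(build_dist_graph(lay, sigma = 0.1, kappa = 0.99), "empty")
})

test_that("electrode layouts round-trip through the text format", {
  lay <- standard_1020_layout()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layout(lay, path)
  back <- read_layout(path)
  expect_identical(back$names, lay$names)
  expect_equal(back$coords, lay$coords, tolerance = 1e-12)
})

test_that("EDF writer/reader round-trips a synthetic 19-channel record", {
  cfg <- synth_config(fs = 256, record_seconds = 4,
                      seizure_duration = c(1, 2), seed = 5)
  rec <- generate_record(cfg, seizure_class = "none", record_id = "edf-test")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path, channels = standard_1020_layout()$names)
  expect_equal(back$fs, 256)
  expect_equal(ncol(back$signal), 19)
  expect_equal(nrow(back$signal), nrow(rec$signal))
  # 16-bit quantisation: error bounded by ~range/65535 per channel
  tol <- max(apply(rec$signal, 2, function(x) diff(range(x)))) / 3e4
  expect_lt(max(abs(back$signal - rec$signal)), tol)

  # a file lacking O2 raises an error naming the channel
  rec18 <- rec
  keep <- rec$channel_names != "O2"
  rec18$signal <- rec$signal[, keep]
  rec18$channel_names <- rec$channel_names[keep]
  path2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec18, path2)
  expect_error(read_edf(path2, channels = standard_1020_layout()$names),
               "O2")
})

test_that("clip sets round-trip bitwise through the binary container", {
  cfg <- synth_config(fs = 32, record_seconds = 12, seed = 9)
  clips <- slice_clips(generate_record(cfg, seizure_class = "CT"), 6)
  path <- withr::local_tempfile(fileext = ".clipset")
  write_clipset(clips, path)
  back <- read_clipset(path)
  expect_length(back, length(clips))
  for (i in seq_along(clips)) {
    expect_identical(back[[i]]$signal, unname(clips[[i]]$signal))
    expect_identical(back[[i]]$fine_labels, clips[[i]]$fine_labels)
    expect_identical(back[[i]]$seizure_class, clips[[i]]$seizure_class)
    expect_identical(back[[i]]$parent_id, clips[[i]]$parent_id)
  }
  expect_error(read_clipset(path <- withr::local_tempfile(lines = "junk!")),
               "magic")
})

test_that("checkpoints restore bit-identical forward passes", {
  model <- tiny_model()
  model$tau <- 1.23
  clip <- random_clip(n = 15, m = 5)
  h1 <- encode_clip(clip, model)$hidden
  path <- withr::local_tempfile(fileext = ".ckpt")
  write_checkpoint(model, path)
  back <- read_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(back$tau, model$tau)
  expect_identical(encode_clip(clip, back)$hidden, h1)
})
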