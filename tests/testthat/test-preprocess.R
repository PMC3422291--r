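test_that("matrix-dialect recordings round-trip exactly", {
  rec <- synthetic_recording(n_trials = 2)
  d <- withr::local_tempdir()
  write_recording(rec, d)
  r2 <- load_recording(d)
  expect_equal(r2$data, rec$data, tolerance = 1e-12)
  expect_identical(r2$labels, rec$labels)
  expect_identical(r2$events$sample, rec$events$sample)
  expect_identical(r2$events$code, rec$events$code)
})

test_that("BDF files with mastoid channels load, scale and expose events", {
  set.seed(11)
  fs <- 512
  n <- fs * 10
  dat <- matrix(round(stats::rnorm(66 * n, sd = 50)), 66, n)
  labels <- c(paste0("ch", 1:64), "M1", "M2")
  ev <- data.frame(sample = c(600L, 2000L, 3500L),
                   code = c(1L, 3L, 4L))
  rec <- as_recording(dat, fs, labels, ev)
  f <- withr::local_tempfile(fileext = ".bdf")
  tfsldecode:::write_edf_bdf(rec, f, bits = 24L)
  r2 <- load_recording(f, "bdf")
  expect_equal(nrow(r2$data), 66)
  expect_equal(r2$data[, seq_len(n)], rec$data, tolerance = 1e-12)
  expect_identical(r2$events$sample, ev$sample)
  expect_identical(r2$events$code, ev$code)
  # after mastoid re-referencing 64 scalp channels remain
  r3 <- rereference_to_mastoids(r2, c("M1", "M2"))
  expect_equal(nrow(r3$data), 64)
})

test_that("EDF files round-trip integer microvolt data", {
  set.seed(12)
  rec <- as_recording(matrix(round(stats::rnorm(4 * 1024, sd = 30)), 4, 1024),
                      512, events = data.frame(sample = 100L, code = 1L))
  f <- withr::local_tempfile(fileext = ".edf")
  tfsldecode:::write_edf_bdf(rec, f, bits = 16L)
  r2 <- load_recording(f, "edf")
  expect_equal(r2$data[, 1:1024], rec$data, tolerance = 1e-12)
})

test_that("recordings without events are refused", {
  rec <- synthetic_recording(n_trials = 1)
  rec$events <- rec$events[0, ]
  d <- withr::local_tempdir()
  write_recording(rec, d)
  expect_error(load_recording(d), "no events")
})

test_that("unknown formats and malformed inputs give descriptive errors", {
  expect_error(load_recording(tempfile(), format = "xyz"))
  f <- withr::local_tempfile(fileext = ".bdf")
  writeBin(as.raw(1:64), f)
  expect_error(load_recording(f, "bdf"), "magic")
})

test_that("mastoid re-referencing subtracts the mastoid average and drops mastoids", {
  set.seed(4)
  dat <- rbind(matrix(stats::rnorm(3 * 100), 3, 100),
               M1 = stats::rnorm(100), M2 = stats::rnorm(100))
  rec <- as_recording(dat, 512, c("a", "b", "c", "M1", "M2"))
  rr <- rereference_to_mastoids(rec, c("M1", "M2"))
  # brute-force per-sample oracle
  ref <- (dat[4, ] + dat[5, ]) / 2
  for (i in 1:3) expect_equal(rr$data[i, ], dat[i, ] - ref)
  expect_identical(rr$labels, c("a", "b", "c"))

  # identically zero mastoids leave the data unchanged
  dat0 <- dat; dat0[4:5, ] <- 0
  rr0 <- rereference_to_mastoids(as_recording(dat0, 512, rec$labels),
                                 c("M1", "M2"))
  expect_equal(rr0$data, dat0[1:3, ])

  # constant mastoids shift every sample by (c1 + c2) / 2
  datc <- dat; datc[4, ] <- 3; datc[5, ] <- 5
  rrc <- rereference_to_mastoids(as_recording(datc, 512, rec$labels),
                                 c("M1", "M2"))
  expect_equal(rrc$data, datc[1:3, ] - 4)

  expect_error(rereference_to_mastoids(rec, c("M1", "M9")), "M9")
})

test_that("epoching labels both faces by the final choice", {
  rec <- synthetic_recording(n_trials = 4)
  eps <- epoch_and_label(rec, tail_samples = 175)
  # odd trials respond left = face 1 chosen: F1 chosen, F2 not chosen
  expect_identical(as.character(eps$F1$labels),
                   c("chosen", "not_chosen", "chosen", "not_chosen"))
  expect_identical(as.character(eps$F2$labels),
                   c("not_chosen", "chosen", "not_chosen", "chosen"))
  # label complementarity holds trial-wise
  expect_true(all((eps$F1$labels == "chosen") ==
                    (eps$F2$labels == "not_chosen")))
  # epochs are cut at the onsets: F1 epoch equals the raw segment
  onset <- rec$events$sample[rec$events$code == event_codes()$f1_onset][1]
  expect_equal(eps$F1$trials[1, , ],
               rec$data[, onset:(onset + 687 - 1)])
  # counterbalanced response mapping flips the labels
  eps_r <- epoch_and_label(rec, tail_samples = 175,
                           face1_response = "right")
  expect_identical(as.character(eps_r$F1$labels),
                   c("not_chosen", "chosen", "not_chosen", "chosen"))
})

test_that("epoching drops trials that run past the recording end, with a warning", {
  rec <- synthetic_recording(n_trials = 3, gap = 3000)
  rec$data <- rec$data[, seq_len(3 * 3000 + 1500)]   # truncate final epoch
  expect_warning(eps <- epoch_and_label(rec, tail_samples = 175),
                 "past end")
  expect_equal(dim(eps$F1$trials)[1], 2)
})

test_that("a recording with no complete trial yields empty trialsets without error", {
  rec <- synthetic_recording(n_trials = 1)
  rec$events <- rec$events[rec$events$code == 1L, , drop = FALSE]
  eps <- epoch_and_label(rec, tail_samples = 175)
  expect_equal(dim(eps$F1$trials)[1], 0)
  expect_equal(dim(eps$F2$trials)[1], 0)
})

test_that("amplitude threshold rejection drops contaminated trials", {
  rec <- synthetic_recording(n_trials = 3)
  onset <- rec$events$sample[rec$events$code == event_codes()$f1_onset][2]
  rec$data[1, onset + 50] <- 5000
  eps <- epoch_and_label(rec, tail_samples = 175, reject_uv = 1000)
  expect_equal(dim(eps$F1$trials)[1], 2)
})
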