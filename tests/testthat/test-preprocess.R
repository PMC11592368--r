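probe_recording <- function(freq, dur = 10, fs = 1000, labels = "Cz") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  data <- matrix(rep(sin(2 * pi * freq * t), length(labels)),
                 nrow = length(labels), byrow = TRUE,
                 dimnames = list(labels, NULL))
  raw_recording(data, fs)
}

interior_rms <- function(x, fs = 1000) {
  n <- length(x)
  sqrt(mean(x[(fs + 1):(n - fs)]^2))  # drop 1 s of edge transients
}

test_that("the notch removes a 50 Hz probe and the pass band preserves 10 Hz", {
  out50 <- filter_signal(probe_recording(50), band = c(0.1, 40), notch = 50)
  expect_lt(interior_rms(out50$data[1, ]), 0.1 * sqrt(0.5))
  out10 <- filter_signal(probe_recording(10), band = c(0.1, 40), notch = 50)
  expect_equal(interior_rms(out10$data[1, ]), sqrt(0.5), tolerance = 0.1)
  # stop-band attenuation beyond the upper edge
  out80 <- filter_signal(probe_recording(80), band = c(0.1, 40), notch = 50)
  expect_lt(interior_rms(out80$data[1, ]), 0.1 * sqrt(0.5))
})

test_that("filter configuration errors are rejected", {
  rec <- probe_recording(10, dur = 3)
  expect_error(filter_signal(rec, band = c(50, 10)), "band")
  expect_error(filter_signal(rec, band = c(1, 600)), "band")
  expect_error(filter_signal(rec, notch = 700), "notch")
})

test_that("mastoid re-referencing subtracts the mastoid mean", {
  set.seed(31)
  labels <- c("Cz", "Pz", "TP9", "TP10")
  data <- matrix(rnorm(4 * 100), nrow = 4, dimnames = list(labels, NULL))
  data[c("TP9", "TP10"), ] <- 0
  rec <- raw_recording(data, 1000)
  expect_identical(rereference(rec)$data, rec$data)  # zero reference no-op

  ref <- rnorm(100)
  data2 <- rbind(Cz = ref, Pz = ref, TP9 = ref, TP10 = ref)
  expect_true(all(rereference(raw_recording(data2, 1000))$data == 0))

  expect_error(rereference(raw_recording(matrix(0, 1, 10,
                                                dimnames = list("Cz")), 1000)),
               "mastoid")
})

test_that("re-referencing is idempotent once the mastoids carry the reference", {
  set.seed(32)
  labels <- c("Cz", "Pz", "TP9", "TP10")
  data <- matrix(rnorm(400), nrow = 4, dimnames = list(labels, NULL))
  once <- rereference(raw_recording(data, 1000))
  twice <- rereference(once)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
})

test_that("epoching follows the half-open window convention and zeroes the baseline", {
  fs <- 1000
  markers <- data.frame(sample = c(1000L, 5000L), code = "S 1")
  const <- raw_recording(matrix(7, 2, 8000,
                                dimnames = list(c("Cz", "Pz"), NULL)),
                         fs, markers = markers)
  ep <- epoch_baseline(const, c(-500, 2000), c(-500, 0))
  expect_identical(dim(ep$data), c(2L, 2L, 2500L))   # 2500 samples per epoch
  expect_true(all(ep$data == 0))                     # constant minus baseline

  set.seed(33)
  noisy <- raw_recording(matrix(rnorm(16000), 2, 8000,
                                dimnames = list(c("Cz", "Pz"), NULL)),
                         fs, markers = markers)
  epn <- epoch_baseline(noisy, c(-500, 2000), c(-500, 0))
  bl <- apply(epn$data[, , 1:500], c(1, 2), mean)
  expect_true(all(abs(bl) < 1e-9 * sd(noisy$data)))
})

test_that("edge markers are dropped with a warning; zero markers give an empty result", {
  fs <- 1000
  rec <- raw_recording(matrix(rnorm(3000), 1, 3000, dimnames = list("Cz")),
                       fs, markers = data.frame(sample = c(200L, 1000L),
                                                code = "S 1"))
  expect_warning(ep <- epoch_baseline(rec, c(-500, 2000), c(-500, 0)),
                 "1 epoch")
  expect_identical(dim(ep$data)[1], 1L)
  expect_identical(attr(ep, "n_dropped"), 1L)

  rec0 <- raw_recording(matrix(rnorm(3000), 1, 3000, dimnames = list("Cz")),
                        fs)
  ep0 <- epoch_baseline(rec0, c(-500, 2000), c(-500, 0))
  expect_identical(dim(ep0$data)[1], 0L)
})

test_that("window and baseline preconditions are validated", {
  rec <- probe_recording(10, dur = 3)
  expect_error(epoch_baseline(rec, c(500, 2000)), "window")
  expect_error(epoch_baseline(rec, c(-500, 2000), c(-600, 0)), "baseline")
})

test_that("filtering commutes with epoching away from segment edges", {
  set.seed(34)
  fs <- 1000
  x <- rnorm(12000)
  rec <- raw_recording(matrix(x, 1, dimnames = list("Cz")), fs,
                       markers = data.frame(sample = 6000L, code = "S 1"))
  filt_then_epoch <- epoch_baseline(filter_signal(rec), c(-500, 2000),
                                    c(-500, 0))$data[1, 1, ]
  # filter a generous local segment around the epoch instead of the record
  seg <- raw_recording(matrix(x[2000:10000], 1, dimnames = list("Cz")), fs,
                       markers = data.frame(sample = 4001L, code = "S 1"))
  local_filt <- epoch_baseline(filter_signal(seg), c(-500, 2000),
                               c(-500, 0))$data[1, 1, ]
  expect_gt(cor(filt_then_epoch, local_filt), 0.999)
})

test_that("BrainVision triplets round-trip data, labels, rate and markers", {
  set.seed(35)
  rec <- raw_recording(
    matrix(rnorm(3 * 500, sd = 20), nrow = 3,
           dimnames = list(c("Fz", "Cz", "Pz"), NULL)),
    fs = 500,
    markers = data.frame(sample = c(100L, 300L), code = c("S 1", "S 2")))
  base <- file.path(withr::local_tempdir(), "rec")
  write_brainvision(rec, base)
  back <- read_brainvision(paste0(base, ".vhdr"))
  expect_identical(channel_labels(back), c("Fz", "Cz", "Pz"))
  expect_equal(back$fs, 500)
  expect_identical(back$markers, rec$markers)
  expect_equal(back$data, rec$data, tolerance = 1e-6)
  expect_error(read_brainvision("nope.vhdr"), "not found")
})
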