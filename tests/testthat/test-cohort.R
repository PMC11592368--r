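small_spec <- function(...) {
  cohort_spec(n_subjects = 6L, channels = c("Cz", "Pz"),
              n_epochs_metacontrol = 1L, n_trials = 20L, n_items = 4L,
              seed = 3L, ...)
}

test_that("cohort generation is deterministic given the seed", {
  a <- gen_cohort(small_spec())
  b <- gen_cohort(small_spec())
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$ratings, b$ratings)
  ea <- a$eeg_for(2, "metacontrol")
  eb <- b$eeg_for(2, "metacontrol")
  expect_identical(ea$data, eb$data)
  expect_identical(ea$markers, eb$markers)
  # different seed, different data
  c0 <- gen_cohort(cohort_spec(n_subjects = 6L, channels = c("Cz", "Pz"),
                               n_epochs_metacontrol = 1L, n_trials = 20L,
                               n_items = 4L, seed = 4L))
  expect_false(identical(a$behavior, c0$behavior))
})

test_that("cohort spec invariants are enforced", {
  expect_error(cohort_spec(n_subjects = 7), "even")
  expect_error(cohort_spec(pink_weight_high = 0.4, pink_weight_low = 0.6),
               "pink_weight")
  expect_error(cohort_spec(fs = 0), "fs")
  expect_error(cohort_spec(icc_target = 0), "icc_target")
  expect_error(cohort_spec(channels = c("Cz", "XX9")), "XX9")
})

test_that("profiles split half/half and drive the EEG mixture weight", {
  co <- gen_cohort(small_spec())
  expect_identical(as.vector(table(co$profiles$profile)), c(3L, 3L))
  wh <- co$profiles$pink_weight[co$profiles$profile == "high"]
  wl <- co$profiles$pink_weight[co$profiles$profile == "low"]
  expect_gt(mean(wh), mean(wl))
})

test_that("mean coarse-scale SampEn increases strictly with the pink weight", {
  # generator property: the mixture weight is a monotone complexity dial at
  # scale 10 (estimated over >= 20 subjects per weight)
  means <- vapply(c(0.2, 0.5, 0.8), function(w) {
    spec <- cohort_spec(n_subjects = 24L, channels = "Cz",
                        n_epochs_metacontrol = 1L,
                        pink_weight_high = w, pink_weight_low = w,
                        pink_weight_sd = 0, seed = 21L)
    co <- gen_cohort(spec)
    vals <- vapply(co$profiles$subject, function(sid) {
      ep <- epoch_baseline(co$eeg_for(sid, "metacontrol"),
                          spec$epoch_ms_metacontrol, c(-500, 0))
      x <- ep$data[1, 1, ]
      cv <- mse_curve(x, mse_params(scales = c(1, 10)))
      cv$sampen[2]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("median split on adaptive scores recovers the latent profiles", {
  agree <- vapply(1:5, function(s) {
    co <- gen_cohort(cohort_spec(seed = s))
    sc <- behavior_scores(co$behavior, rt_scale = co$spec$rt_scale)
    grp <- median_split(stats::setNames(sc$adaptive_score, sc$subject))
    truth <- stats::setNames(co$profiles$profile, co$profiles$subject)
    mean(unclass(grp)[names(truth)] == truth)
  }, numeric(1))
  expect_gte(mean(agree), 0.8)
})

test_that("generated adaptive-score gap matches the configured behavior effect", {
  gaps <- vapply(1:8, function(s) {
    co <- gen_cohort(cohort_spec(seed = s))
    sc <- behavior_scores(co$behavior, rt_scale = co$spec$rt_scale)
    m <- merge(sc, co$profiles)
    mean(m$adaptive_score[m$profile == "high"]) -
      mean(m$adaptive_score[m$profile == "low"])
  }, numeric(1))
  expect_lt(abs(mean(gaps) - 0.046), 0.01)
})

test_that("a serialized cohort round-trips through the BrainVision container", {
  dir <- withr::local_tempdir()
  spec <- small_spec()
  co <- gen_cohort(spec, dir = dir, tasks = "metacontrol")
  expect_true(file.exists(file.path(dir, "behavior.tsv")))
  expect_true(file.exists(file.path(dir, "ratings.tsv")))
  sidecar <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                 simplifyVector = TRUE)
  expect_identical(as.integer(sidecar$spec$n_subjects), 6L)
  expect_identical(sidecar$profiles$subject, co$profiles$subject)
  rec0 <- co$eeg_for(1, "metacontrol")
  rec1 <- read_brainvision(file.path(dir, "S01_metacontrol.vhdr"))
  expect_identical(channel_labels(rec1), channel_labels(rec0))
  expect_identical(rec1$markers, rec0$markers)
  expect_equal(rec1$fs, rec0$fs)
  # data stored as float32
  expect_equal(rec1$data, rec0$data, tolerance = 1e-6)
})
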