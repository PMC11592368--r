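#' Synthetic cohort specification
#'
#' Parameters of the synthetic study cohort the package can generate in place
#' of (unavailable) subject data. Defaults emulate the study design the
#' analysis assumes: 58 subjects in two latent complexity profiles, 64-channel
#' 10-20 montage at 1000 Hz, 2.5 s stimulus-locked epochs for the metacontrol
#' task and a single 20.5 s epoch for the divergent-thinking (AUT) task.
#'
#' EEG channels are mixtures `(1 - w) * white + w * pink` of unit-variance
#' noises; the pink weight `w` is the latent complexity dial: subjects in the
#' "high" profile draw `w` around `pink_weight_high`, "low" subjects around
#' `pink_weight_low` (per-subject SD `pink_weight_sd`), so the high profile
#' carries more long-range temporal structure and hence higher sample entropy
#' at coarse scales.
#'
#' @param n_subjects Even count of subjects, split half/half into latent
#'   high/low complexity profiles. Default 58.
#' @param n_channels Number of montage channels to generate (first
#'   `n_channels` labels of the bundled 64-channel montage). Default 64.
#' @param channels Optional explicit character vector of montage labels to
#'   generate instead of the first `n_channels` (useful for reduced designs
#'   that still span all functional networks).
#' @param fs Sampling rate in Hz. Default 1000.
#' @param epoch_ms_metacontrol,epoch_ms_aut Epoch windows in ms relative to
#'   the stimulus.
#' @param n_epochs_metacontrol EEG trials recorded per subject in the
#'   metacontrol task. Default 6.
#' @param pink_weight_high,pink_weight_low Mean pink-noise mixture weight of
#'   the high/low complexity profile, `0 <= low <= high <= 1`.
#' @param pink_weight_sd Between-subject SD of the mixture weight. Default
#'   0.05.
#' @param behavior_effect Mean adaptive-score gap between profiles. Default
#'   0.046.
#' @param n_trials Behavioral trials per task. Default 60.
#' @param rt_scale RT unit constant of the performance ratio (10 = accuracy
#'   per 100 ms with RT in seconds). Default 10.
#' @param icc_target Target inter-rater reliability ICC(2,k) of the synthetic
#'   originality ratings. Default 0.844.
#' @param n_raters,n_items Raters and rated items per subject. Defaults 4
#'   and 10.
#' @param amplitude_uv EEG signal scale in microvolts (RMS). Default 10.
#' @param seed Integer master seed; all stage seeds are spawned from it.
#'
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 58L, n_channels = 64L, channels = NULL,
                        fs = 1000,
                        epoch_ms_metacontrol = c(-500, 2000),
                        epoch_ms_aut = c(-500, 20000),
                        n_epochs_metacontrol = 6L,
                        pink_weight_high = 0.75, pink_weight_low = 0.60,
                        pink_weight_sd = 0.05,
                        behavior_effect = 0.046, n_trials = 60L,
                        rt_scale = 10, icc_target = 0.844,
                        n_raters = 4L, n_items = 10L,
                        amplitude_uv = 10, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L || n_subjects %% 2L != 0L)
    config_error("`n_subjects` must be an even integer >= 2 (equal profile split)")
  if (!(fs > 0)) config_error("`fs` must be positive")
  if (!(0 <= pink_weight_low && pink_weight_low <= pink_weight_high &&
        pink_weight_high <= 1))
    config_error("need 0 <= pink_weight_low <= pink_weight_high <= 1")
  if (!(icc_target > 0 && icc_target <= 1))
    config_error("`icc_target` must lie in (0, 1]")
  if (!is.null(channels)) {
    unknown <- setdiff(channels, montage_64())
    if (length(unknown) > 0)
      config_error(sprintf("unknown montage label(s): %s",
                           paste(unknown, collapse = ", ")))
    n_channels <- length(channels)
  } else {
    n_channels <- as.integer(n_channels)
    if (is.na(n_channels) || n_channels < 1L || n_channels > 64L)
      config_error("`n_channels` must be between 1 and 64")
    channels <- montage_64()[seq_len(n_channels)]
  }
  structure(
    list(n_subjects = n_subjects, n_channels = n_channels,
         channels = channels, fs = fs,
         epoch_ms_metacontrol = epoch_ms_metacontrol,
         epoch_ms_aut = epoch_ms_aut,
         n_epochs_metacontrol = as.integer(n_epochs_metacontrol),
         pink_weight_high = pink_weight_high,
         pink_weight_low = pink_weight_low,
         pink_weight_sd = pink_weight_sd,
         behavior_effect = behavior_effect,
         n_trials = as.integer(n_trials), rt_scale = rt_scale,
         icc_target = icc_target, n_raters = as.integer(n_raters),
         n_items = as.integer(n_items), amplitude_uv = amplitude_uv,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Standard 64-channel montage labels
#'
#' Labels of the extended 10-20 64-channel cap used by the synthetic
#' generator, including the mastoid-adjacent sites TP9/TP10.
#'
#' @return Character vector of 64 labels.
#' @export
montage_64 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
    "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
    "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8")
}

# Hierarchical seed spawning: one master seed deterministically yields a named
# table of independent 31-bit sub-seeds, one per stage and per subject/task,
# so any stage can be regenerated in isolation.
spawn_seeds <- function(spec) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  keys <- c("profiles", "behavior", "ratings",
            paste0("eeg.", rep(seq_len(spec$n_subjects), each = 2L), ".",
                   c("metacontrol", "aut")))
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(keys)), keys)
}

subject_ids <- function(n) sprintf("S%02d", seq_len(n))

# Latent per-subject state: profile, pink weight, behavioral targets.
gen_profiles <- function(spec) {
  seeds <- spawn_seeds(spec)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds[["profiles"]])
  n <- spec$n_subjects
  profile <- sample(rep(c("high", "low"), n / 2L))
  w_mean <- ifelse(profile == "high", spec$pink_weight_high,
                   spec$pink_weight_low)
  w <- pmin(1, pmax(0, rnorm(n, w_mean, spec$pink_weight_sd)))
  data.frame(subject = subject_ids(n), profile = profile, pink_weight = w,
             stringsAsFactors = FALSE)
}

rtruncnorm01 <- function(n, mean, sd) {
  # truncated normal on (0, 1] by inverse-CDF sampling
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

# Trial-level behavior: per-subject target performance ratios with the
# profile gap injected on the easy task (the difficult task is profile-blind,
# matching the reported pattern of a significant easy-task difference only).
gen_behavior <- function(spec, profiles) {
  seeds <- spawn_seeds(spec)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds[["behavior"]])
  n <- spec$n_subjects
  shift <- ifelse(profiles$profile == "high", 1, -1) * spec$behavior_effect / 2
  ratio_easy <- 0.176 + shift + rnorm(n, 0, 0.012)
  ratio_diff <- 0.138 + rnorm(n, 0, 0.012)
  acc_easy <- rtruncnorm01(n, 0.92, 0.04)
  acc_diff <- rtruncnorm01(n, 0.88, 0.04)
  rt_easy <- acc_easy / (ratio_easy * spec$rt_scale)   # seconds
  rt_diff <- acc_diff / (ratio_diff * spec$rt_scale)
  one_task <- function(task, acc, rt) {
    do.call(rbind, lapply(seq_len(n), function(s) {
      correct <- rbinom(spec$n_trials, 1L, acc[s])
      sdlog <- 0.2
      rts <- rlnorm(spec$n_trials, log(rt[s]) - sdlog^2 / 2, sdlog)
      data.frame(subject = profiles$subject[s], task = task,
                 trial = seq_len(spec$n_trials), acc = correct,
                 rt = round(rts, 4))
    }))
  }
  rbind(one_task("easy", acc_easy, rt_easy),
        one_task("difficult", acc_diff, rt_diff))
}

# Four-rater originality ratings: item truth + rater bias + residual noise,
# calibrated analytically so ICC(2,k) of the rounded 1-5 scores lands on
# icc_target. Rounding to the Likert grid adds ~1/12 of residual variance,
# which the calibration subtracts from the continuous noise budget.
gen_ratings <- function(spec, profiles) {
  seeds <- spawn_seeds(spec)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds[["ratings"]])
  n <- spec$n_subjects
  k <- spec$n_raters
  sd_subject <- 0.10; sd_item <- 0.50; sd_rater <- 0.10
  profile_gap <- 0.24  # high/low originality-mean gap on the 1-5 scale
  var_rows <- sd_subject^2 + (profile_gap / 2)^2 + sd_item^2
  var_noise_total <- k * var_rows * (1 / spec$icc_target - 1) - sd_rater^2
  var_resid <- var_noise_total - 1 / 12  # rounding variance allowance
  if (var_resid <= 0) {
    deviation_warning("icc_target too high for the Likert grid; residual noise floored")
    var_resid <- 1e-4
  }
  subj_mean <- 2.86 + ifelse(profiles$profile == "high", 1, -1) *
    profile_gap / 2 + rnorm(n, 0, sd_subject)
  rater_bias <- rnorm(k, 0, sd_rater)
  grid <- expand.grid(item = seq_len(spec$n_items), subject = seq_len(n),
                      KEEP.OUT.ATTRS = FALSE)
  truth <- subj_mean[grid$subject] + rnorm(nrow(grid), 0, sd_item)
  out <- do.call(rbind, lapply(seq_len(k), function(r) {
    score <- truth + rater_bias[r] + rnorm(nrow(grid), 0, sqrt(var_resid))
    data.frame(subject = profiles$subject[grid$subject],
               item = paste0("item", grid$item),
               rater = paste0("R", r),
               score = pmin(5L, pmax(1L, as.integer(round(score)))))
  }))
  out[order(out$subject, out$item, out$rater), ]
}

# Continuous EEG for one subject/task: stationary white/pink mixture with
# stimulus markers; epochs are separated by a 1 s inter-trial gap so the
# epoching windows never collide.
gen_eeg <- function(spec, subject_index, task, pink_weight) {
  seeds <- spawn_seeds(spec)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  key <- sprintf("eeg.%d.%s", subject_index, task)
  set.seed(seeds[[key]])
  win <- if (task == "metacontrol") spec$epoch_ms_metacontrol else
    spec$epoch_ms_aut
  n_ep <- if (task == "metacontrol") spec$n_epochs_metacontrol else 1L
  fs <- spec$fs
  pre <- as.integer(round(-win[1] * fs / 1000))
  post <- as.integer(round(win[2] * fs / 1000))
  gap <- as.integer(fs)  # 1 s between trials
  trial_len <- pre + post + gap
  n_samp <- n_ep * trial_len + gap
  labels <- spec$channels
  w <- pink_weight
  data <- matrix(0, nrow = length(labels), ncol = n_samp,
                 dimnames = list(labels, NULL))
  for (ci in seq_along(labels)) {
    x <- (1 - w) * gen_noise_raw("white", n_samp) +
      w * gen_noise_raw("pink", n_samp, fs)
    data[ci, ] <- spec$amplitude_uv * x / sd(x)
  }
  markers <- data.frame(
    sample = gap + pre + (seq_len(n_ep) - 1L) * trial_len + 1L,
    code = sprintf("S %s", if (task == "metacontrol") "1" else "2")
  )
  raw_recording(data, fs, markers = markers)
}

# unseeded noise draw using the ambient RNG stream (callers manage seeding)
gen_noise_raw <- function(kind, n, fs = 1000) {
  w <- rnorm(n)
  x <- if (kind == "white") {
    w
  } else {
    f <- fs * (seq_len(n) - 1) / n
    f <- pmin(f, fs - f)
    amp <- c(0, 1 / sqrt(f[-1]))
    Re(fft(fft(w) * amp, inverse = TRUE)) / n
  }
  x <- x - mean(x)
  x / sd(x)
}

#' Generate a synthetic study cohort
#'
#' Builds the complete synthetic inputs of the analysis: latent subject
#' profiles (the ground truth), trial-level behavior, multi-rater originality
#' scores, and — lazily, via the returned `eeg_for()` accessor — continuous
#' multichannel EEG with stimulus markers per subject and task. Everything is
#' reproducible from `spec$seed` through a hierarchical seed-spawning rule
#' (one documented sub-seed per stage and per subject/task), so any component
#' can be regenerated independently.
#'
#' With `dir` supplied, the EEG is also written to disk as one BrainVision
#' triplet per subject/task alongside tab-separated `behavior.tsv` and
#' `ratings.tsv` tables and a `cohort.json` sidecar holding the spec and the
#' ground-truth profiles.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory for the serialized cohort.
#' @param tasks Tasks to generate EEG for. Default both.
#' @param write_eeg Write EEG files when `dir` is given. Set `FALSE` to write
#'   only the behavioral tables. Default `TRUE`.
#'
#' @return List with `spec`, `profiles` (subject, profile, pink_weight),
#'   `behavior` (trial table), `ratings` (rater table), `eeg_for(subject,
#'   task)` accessor returning a [raw_recording()], and `dir` (or `NULL`).
#' @export
gen_cohort <- function(spec = cohort_spec(), dir = NULL,
                       tasks = c("metacontrol", "aut"), write_eeg = TRUE) {
  if (!inherits(spec, "cohort_spec"))
    config_error("`spec` must be a `cohort_spec`")
  tasks <- match.arg(tasks, several.ok = TRUE)
  profiles <- gen_profiles(spec)
  behavior <- gen_behavior(spec, profiles)
  ratings <- gen_ratings(spec, profiles)
  eeg_for <- function(subject, task) {
    si <- if (is.character(subject)) match(subject, profiles$subject) else
      as.integer(subject)
    if (is.na(si) || si < 1L || si > spec$n_subjects)
      data_error(sprintf("unknown subject: %s", subject))
    task <- match.arg(task, c("metacontrol", "aut"))
    gen_eeg(spec, si, task, profiles$pink_weight[si])
  }
  out <- list(spec = spec, profiles = profiles, behavior = behavior,
              ratings = ratings, eeg_for = eeg_for, dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.table(behavior, file.path(dir, "behavior.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ratings, file.path(dir, "ratings.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sidecar <- list(spec = unclass(spec), profiles = profiles)
    jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (write_eeg) {
      for (si in seq_len(spec$n_subjects)) {
        for (task in tasks) {
          rec <- gen_eeg(spec, si, task, profiles$pink_weight[si])
          write_brainvision(rec, file.path(
            dir, sprintf("%s_%s", profiles$subject[si], task)))
        }
      }
    }
  }
  out
}
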