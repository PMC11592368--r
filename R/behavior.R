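#' Adaptive (metacontrol) score
#'
#' Difference of performance ratios between the easy and the difficult task.
#' The performance ratio is accuracy divided by mean correct-trial reaction
#' time, `ACC / (RT * rt_scale)`; larger adaptive scores indicate a larger
#' easy-task advantage. `rt_scale` sets the RT unit entering the ratio
#' (`rt_scale = 10` with RT in seconds expresses the ratio as accuracy per
#' 100 ms, which puts cohort means in the conventional 0.1-0.2 range).
#'
#' @param acc_easy,acc_difficult Proportion correct in `[0, 1]`.
#' @param rt_easy,rt_difficult Mean correct-trial reaction time, positive.
#' @param rt_scale Positive unit constant applied to both RTs. Default 1.
#'
#' @return Numeric adaptive score(s); vectorized over its arguments.
#' @export
#'
#' @examples
#' adaptive_score(0.9, 0.5, 0.8, 0.8)  # 1.8 - 1.0 = 0.8
adaptive_score <- function(acc_easy, rt_easy, acc_difficult, rt_difficult,
                           rt_scale = 1) {
  if (any(rt_easy <= 0) || any(rt_difficult <= 0) || rt_scale <= 0)
    numeric_error("reaction times (and rt_scale) must be positive")
  accs <- c(acc_easy, acc_difficult)
  if (any(accs < 0 | accs > 1))
    numeric_error("accuracies must lie in [0, 1]")
  acc_easy / (rt_easy * rt_scale) - acc_difficult / (rt_difficult * rt_scale)
}

#' Subject-level scores from trial-level behavior
#'
#' Aggregates a trial table (one row per trial: `subject`, `task` in
#' `{"easy","difficult"}`, `acc` in `{0,1}`, `rt` in seconds) into per-subject
#' accuracy, mean correct-trial RT, and the adaptive score.
#'
#' @param trials Data frame with columns `subject`, `task`, `acc`, `rt`.
#' @param rt_scale Passed to [adaptive_score()]. Default 10 (accuracy per
#'   100 ms).
#' @return Data frame: `subject`, `acc_easy`, `rt_easy`, `acc_difficult`,
#'   `rt_difficult`, `adaptive_score`.
#' @export
behavior_scores <- function(trials, rt_scale = 10) {
  need <- c("subject", "task", "acc", "rt")
  if (!all(need %in% names(trials)))
    data_error("`trials` needs columns subject, task, acc, rt")
  if (!all(trials$task %in% c("easy", "difficult")))
    data_error("`task` must be 'easy' or 'difficult'")
  agg <- function(tsk) {
    d <- trials[trials$task == tsk, ]
    acc <- tapply(d$acc, d$subject, mean)
    rt <- tapply(ifelse(d$acc == 1, d$rt, NA_real_), d$subject, mean,
                 na.rm = TRUE)
    data.frame(subject = names(acc), acc = as.numeric(acc),
               rt = as.numeric(rt))
  }
  e <- agg("easy"); d <- agg("difficult")
  out <- merge(e, d, by = "subject", suffixes = c("_easy", "_difficult"))
  names(out) <- c("subject", "acc_easy", "rt_easy", "acc_difficult",
                  "rt_difficult")
  out$adaptive_score <- adaptive_score(out$acc_easy, out$rt_easy,
                                       out$acc_difficult, out$rt_difficult,
                                       rt_scale = rt_scale)
  out
}

#' Median split into high/low groups
#'
#' Assigns subjects strictly above the median to the first (`high`) label and
#' strictly below to the second (`low`). Subjects exactly at the median are
#' assigned alternately, starting with `low`, in input order — a deterministic
#' tie rule that preserves the balanced split (an even number of distinct
#' scores always yields two equal groups).
#'
#' @param scores Named (or unnamed) numeric vector, length >= 2.
#' @param labels Length-2 character vector `(high, low)`.
#' @return Character vector of group labels, same length and names as
#'   `scores`; attribute `n_ties` counts median-tied subjects.
#' @export
#'
#' @examples
#' median_split(c(a = 1, b = 2, c = 3, d = 4))  # b,a low; c,d high
median_split <- function(scores, labels = c("high", "low")) {
  if (length(scores) < 2L)
    data_error("need at least two scores to split")
  if (length(unique(scores)) == 1L)
    numeric_error("unsplittable: all scores are identical")
  med <- median(scores)
  out <- rep(NA_character_, length(scores))
  out[scores > med] <- labels[1]
  out[scores < med] <- labels[2]
  ties <- which(scores == med)
  if (length(ties) > 0) {
    # alternate starting with "low" to keep the split balanced
    out[ties] <- labels[c(2, 1)][(seq_along(ties) - 1L) %% 2L + 1L]
  }
  names(out) <- names(scores)
  attr(out, "n_ties") <- length(ties)
  out
}

#' Originality scores and inter-rater reliability
#'
#' Averages a complete rater-by-item rating design into per-subject
#' originality scores and computes ICC(2,k), the two-way random-effects
#' intraclass correlation for the reliability of the k-rater mean
#' (Shrout-Fleiss): `(MSR - MSE) / (MSR + (MSC - MSE) / n)` with `MSR` the
#' between-unit, `MSC` the between-rater and `MSE` the residual mean square,
#' `n` the number of rated units (subject-item answers) and `k` the number of
#' raters.
#'
#' @param ratings Data frame with columns `subject`, `item`, `rater`, `score`;
#'   every subject-item-rater cell must be present exactly once (no
#'   imputation is attempted).
#' @return List with `originality` (data frame `subject`, `originality`: mean
#'   score over raters and items), `icc2k`, and the mean squares
#'   (`ms_rows`, `ms_cols`, `ms_error`).
#' @export
originality_icc <- function(ratings) {
  need <- c("subject", "item", "rater", "score")
  if (!all(need %in% names(ratings)))
    data_error("`ratings` needs columns subject, item, rater, score")
  if (anyNA(ratings[need]))
    data_error("incomplete design: missing values in ratings")
  unit <- interaction(ratings$subject, ratings$item, drop = TRUE)
  rater <- factor(ratings$rater)
  n <- nlevels(unit); k <- nlevels(rater)
  if (k < 2L) data_error("need at least two raters")
  if (n < 2L) data_error("need at least two rated units")
  tab <- table(unit, rater)
  if (any(tab != 1L))
    data_error("incomplete design: every unit must be scored once by every rater")

  y <- ratings$score
  grand <- mean(y)
  row_means <- tapply(y, unit, mean)
  col_means <- tapply(y, rater, mean)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc2k <- (ms_rows - ms_err) / (ms_rows + (ms_cols - ms_err) / n)

  orig <- tapply(y, factor(ratings$subject), mean)
  list(
    originality = data.frame(subject = names(orig),
                             originality = as.numeric(orig)),
    icc2k = icc2k,
    ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_err
  )
}
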