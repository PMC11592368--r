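test_that("adaptive score is the difference of performance ratios", {
  expect_identical(adaptive_score(0.9, 0.5, 0.8, 0.8), 0.8)
  expect_identical(adaptive_score(0.85, 0.6, 0.85, 0.6), 0)
  # rt_scale rescales both ratios jointly
  expect_equal(adaptive_score(0.9, 0.5, 0.8, 0.8, rt_scale = 10), 0.08)
  expect_error(adaptive_score(0.9, 0, 0.8, 0.5), "positive")
  expect_error(adaptive_score(1.2, 0.5, 0.8, 0.5), "\\[0, 1\\]")
})

test_that("the mean adaptive score is the difference of mean ratios", {
  # linearity: cohort ratio means 0.176 and 0.138 give mean score 0.038
  set.seed(51)
  n <- 40
  r_easy <- 0.176 + scale(rnorm(n), scale = FALSE)[, 1] * 0.01
  r_diff <- 0.138 + scale(rnorm(n), scale = FALSE)[, 1] * 0.01
  acc <- rep(0.9, n)
  scores <- adaptive_score(acc, acc / r_easy, acc, acc / r_diff)
  expect_equal(mean(scores), 0.176 - 0.138, tolerance = 1e-12)
})

test_that("behavior_scores aggregates trial tables per subject and task", {
  trials <- data.frame(
    subject = rep("s1", 6),
    task = rep(c("easy", "difficult"), each = 3),
    acc = c(1, 1, 0, 1, 0, 0),
    rt = c(0.4, 0.6, 9, 0.8, 9, 9))
  sc <- behavior_scores(trials, rt_scale = 1)
  expect_equal(sc$acc_easy, 2 / 3)
  expect_equal(sc$rt_easy, 0.5)           # correct trials only
  expect_equal(sc$acc_difficult, 1 / 3)
  expect_equal(sc$rt_difficult, 0.8)
  expect_equal(sc$adaptive_score, (2 / 3) / 0.5 - (1 / 3) / 0.8)
  expect_error(behavior_scores(data.frame(subject = 1)), "columns")
})

test_that("median split puts strict halves around the median with balanced ties", {
  g <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_identical(unclass(g)[c("c", "d")], c(c = "high", d = "high"))
  expect_identical(unclass(g)[c("a", "b")], c(a = "low", b = "low"))

  # ties at the median alternate starting with "low"
  gt <- median_split(c(s1 = 1, s2 = 2, s3 = 2, s4 = 3))
  expect_identical(sum(gt == "high"), 2L)
  expect_identical(sum(gt == "low"), 2L)
  expect_identical(unclass(gt)[["s2"]], "low")
  expect_identical(unclass(gt)[["s3"]], "high")
  expect_identical(attr(gt, "n_ties"), 2L)

  expect_error(median_split(c(5, 5, 5)), "unsplittable")
  expect_error(median_split(3), "two scores")
})

test_that("negating distinct scores swaps the median-split labels exactly", {
  set.seed(52)
  x <- stats::setNames(rnorm(20), paste0("s", 1:20))
  g1 <- median_split(x)
  g2 <- median_split(-x)
  expect_identical(c(unclass(g2)), ifelse(c(unclass(g1)) == "high",
                                          "low", "high"))
})

test_that("ICC(2,k) is 1 for perfectly agreeing raters and matches the ANOVA oracle", {
  items <- data.frame(subject = rep(c("s1", "s2"), each = 3),
                      item = rep(paste0("i", 1:3), 2))
  perfect <- do.call(rbind, lapply(1:3, function(r)
    cbind(items, rater = paste0("R", r),
          score = rep(c(1, 3, 5, 2, 4, 1)))))
  res <- originality_icc(perfect)
  expect_equal(res$icc2k, 1)

  set.seed(53)
  noisy <- do.call(rbind, lapply(1:4, function(r)
    cbind(items[rep(1:6, 5), ], unit_rep = 1:30, rater = paste0("R", r),
          score = 0)))
  truth <- rnorm(30, 3, 1)
  bias <- rnorm(4, 0, 0.3)
  noisy$score <- truth[noisy$unit_rep] + bias[as.integer(sub("R", "", noisy$rater))] +
    rnorm(nrow(noisy), 0, 0.5)
  noisy$item <- paste0(noisy$item, "_", noisy$unit_rep)
  res2 <- originality_icc(noisy)
  expect_equal(res2$icc2k, unname(icc2k_oracle(noisy)), tolerance = 1e-9)
  expect_lte(res2$icc2k, 1)
})

test_that("per-subject originality is the mean over raters and items", {
  ratings <- expand.grid(subject = c("s1", "s2"), item = c("i1", "i2"),
                         rater = c("R1", "R2"), stringsAsFactors = FALSE)
  ratings$score <- ifelse(ratings$subject == "s1", 2, 4)
  ratings$score[1] <- 5  # s1, i1, R1
  res <- originality_icc(ratings)
  orig <- stats::setNames(res$originality$originality, res$originality$subject)
  expect_equal(orig[["s1"]], (5 + 2 + 2 + 2) / 4)
  expect_equal(orig[["s2"]], 4)
})

test_that("degenerate rating designs are rejected", {
  one_item <- data.frame(subject = "s1", item = "i1",
                         rater = c("R1", "R2"), score = c(1, 2))
  expect_error(originality_icc(one_item), "two rated units")
  one_rater <- data.frame(subject = c("s1", "s1"), item = c("i1", "i2"),
                          rater = "R1", score = c(1, 2))
  expect_error(originality_icc(one_rater), "two raters")
  incomplete <- data.frame(subject = c("s1", "s1", "s2"),
                           item = "i1", rater = c("R1", "R2", "R1"),
                           score = 1:3)
  expect_error(originality_icc(incomplete), "incomplete")
})

test_that("synthetic ratings recover the target reliability", {
  co <- gen_cohort(cohort_spec(seed = 6))
  icc <- originality_icc(co$ratings)$icc2k
  expect_lt(abs(icc - 0.844), 0.05)
})
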