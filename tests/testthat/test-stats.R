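split_plot_toy <- function() {
  data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    w = rep(c("w1", "w2"), 4),
    y = c(3, 5, 4, 6, 7, 9, 8, 12))
}

random_split_plot <- function(seed, n = 6, k1 = 3, k2 = 2) {
  set.seed(seed)
  grid <- expand.grid(subject = sprintf("s%d", 1:n),
                      w1 = paste0("a", 1:k1), w2 = paste0("b", 1:k2),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(as.integer(sub("s", "", grid$subject)) <= n / 2,
                       "g1", "g2")
  grid$y <- rnorm(nrow(grid))
  grid
}

test_that("split-plot sums of squares match the hand-worked textbook example", {
  res <- mixed_anova(split_plot_toy(), dv = "y", subject = "subject",
                     between = "group", within = "w")
  pick <- function(e, col) res[res$effect == e, col]
  # grand mean 6.75; SS computed by hand from cell/marginal means
  expect_equal(pick("group", "ss"), 40.5, tolerance = 1e-9)
  expect_equal(pick("group", "ss_error"), 5, tolerance = 1e-9)
  expect_equal(pick("w", "ss"), 12.5, tolerance = 1e-9)
  expect_equal(pick("w", "ss_error"), 1, tolerance = 1e-9)
  expect_equal(pick("group:w", "ss"), 0.5, tolerance = 1e-9)
  expect_equal(pick("group", "F"), 16.2, tolerance = 1e-9)
  expect_equal(pick("w", "F"), 25, tolerance = 1e-9)
  expect_equal(pick("group:w", "F"), 1, tolerance = 1e-9)
  # partial eta squared from the same sums
  expect_equal(pick("group", "pes"), 40.5 / 45.5, tolerance = 1e-12)
  # a 2-level within factor trivially satisfies sphericity
  expect_identical(pick("w", "epsilon_gg"), 1)
  expect_false(pick("w", "gg_applied"))
})

test_that("the SS decomposition is exact on random balanced designs", {
  for (seed in c(71, 72, 73)) {
    d <- random_split_plot(seed)
    res <- mixed_anova(d, "y", "subject", "group", c("w1", "w2"))
    ss_total <- sum((d$y - mean(d$y))^2)
    strata <- unique(res[, c("df_den", "ss_error")])
    expect_equal(sum(res$ss) + sum(strata$ss_error), ss_total,
                 tolerance = 1e-9)
  }
})

test_that("identical groups give a null between-subjects effect", {
  d <- random_split_plot(74)
  # mirror group g1's data into g2, subject-for-subject
  d2 <- d
  d2$y[d2$group == "g2"] <- d$y[d$group == "g1"]
  res <- mixed_anova(d2, "y", "subject", "group", c("w1", "w2"))
  expect_equal(res$F[res$effect == "group"], 0, tolerance = 1e-12)
  expect_equal(res$p[res$effect == "group"], 1, tolerance = 1e-12)
})

test_that("Greenhouse-Geisser epsilon respects its bounds on random data", {
  for (seed in 75:80) {
    set.seed(seed)
    k <- sample(3:5, 1)
    n <- 10
    grid <- expand.grid(subject = sprintf("s%d", 1:n),
                        w1 = paste0("a", 1:k), stringsAsFactors = FALSE)
    grid$group <- ifelse(as.integer(sub("s", "", grid$subject)) <= n / 2,
                         "g1", "g2")
    # induce arbitrary covariance across levels
    L <- matrix(rnorm(k * k), k)
    Z <- matrix(rnorm(n * k), n) %*% L
    grid$y <- Z[cbind(match(grid$subject, sprintf("s%d", 1:n)),
                      match(grid$w1, paste0("a", 1:k)))]
    res <- mixed_anova(grid, "y", "subject", "group", "w1")
    eps <- res$epsilon_gg[res$effect == "w1"]
    expect_gte(eps, 1 / (k - 1))
    expect_lte(eps, 1)
    expect_true(is.finite(res$mauchly_p[res$effect == "w1"]))
  }
})

test_that("incomplete or duplicated designs are rejected", {
  d <- random_split_plot(81)
  expect_error(mixed_anova(d[-1, ], "y", "subject", "group", c("w1", "w2")),
               "design error")
  expect_error(mixed_anova(rbind(d, d[1, ]), "y", "subject", "group",
                           c("w1", "w2")), "design error")
})

test_that("t-map handles null, swapped and degenerate cells as documented", {
  set.seed(82)
  subj <- sprintf("s%d", 1:10)
  groups <- stats::setNames(rep(c("high", "low"), each = 5), subj)
  vals <- expand.grid(subject = subj, electrode = c("Cz", "Pz"), scale = 1:2,
                      stringsAsFactors = FALSE)
  vals$value <- rnorm(nrow(vals))

  # identical groups: copy high values onto low subjects cell-wise
  ident <- vals
  for (e in c("Cz", "Pz")) for (s in 1:2) {
    i <- ident$electrode == e & ident$scale == s
    v <- ident$value[i][1:5]
    ident$value[i] <- c(v, v)
  }
  tm <- ttest_map(ident, groups)
  expect_true(all(abs(tm$t) < 1e-12))
  expect_true(all(tm$p == 1))

  # swapping group labels negates t and keeps p
  tm1 <- ttest_map(vals, groups)
  swapped <- stats::setNames(ifelse(groups == "high", "low", "high"), subj)
  tm2 <- ttest_map(vals, swapped)
  expect_equal(tm2$t, -tm1$t, tolerance = 1e-12)
  expect_equal(tm2$p, tm1$p, tolerance = 1e-12)
  expect_identical(tm1$significant, tm1$p < 0.01)

  # zero-variance conventions
  dg <- vals
  dg$value <- rep(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 4)
  tmd <- ttest_map(dg, groups)
  expect_true(all(tmd$p == 0))
  expect_true(all(tmd$degenerate))
  dg$value <- 1
  tme <- ttest_map(dg, groups)
  expect_true(all(tme$p == 1))
  expect_true(all(tme$t == 0))
})

test_that("correlations report exact linear association and BH-adjusted p", {
  x <- 1:10
  res <- corr_bh(x, 2 * x + 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p, 0)

  set.seed(83)
  Y <- matrix(rnorm(10 * 6), 10, dimnames = list(NULL, paste0("e", 1:6)))
  out <- corr_bh(rnorm(10), Y)
  # step-up oracle computed directly from the definition
  p <- out$p
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))[order(o)]
  expect_equal(out$p_bh, adj, tolerance = 1e-12)
  expect_true(all(out$p_bh >= out$p))

  Yz <- cbind(Y, zed = rep(1, 10))
  res2 <- corr_bh(rnorm(10), Yz)
  expect_true(res2$degenerate[res2$electrode == "zed"])
  expect_true(is.na(res2$r[res2$electrode == "zed"]))
  expect_error(corr_bh(1:2, matrix(1:2)), "three subjects")
})

test_that("Cohen's d matches its definition and degenerates to NA", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  s <- sqrt(0.5)
  expect_equal(cohens_d(c(1 - s, 1 + s), c(-s, s)), 1, tolerance = 1e-12)
  set.seed(84)
  a <- rnorm(15); b <- rnorm(12)
  sp <- sqrt(((14) * var(a) + (11) * var(b)) / 25)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))))
})

test_that("Bonferroni post-hocs multiply pairwise p by the family size", {
  set.seed(85)
  d <- expand.grid(subject = sprintf("s%d", 1:8), w = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + ifelse(d$w == "c", 1, 0)
  ph <- posthoc_bonferroni(d, "y", "w", "subject")
  expect_identical(nrow(ph), 3L)
  expect_equal(ph$p_bonf, pmin(1, ph$p * 3), tolerance = 1e-12)
})
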