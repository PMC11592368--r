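#' Split-plot (mixed) repeated-measures ANOVA
#'
#' Fits the orthodox subject-nested split-plot ANOVA for a balanced design
#' with one between-subjects factor and one or two within-subjects factors:
#' sums of squares are partitioned via `stats::aov` with
#' `Error(subject/(w1*w2))` strata, so each within effect (and its interaction
#' with the group) is tested against its own subject-by-effect error stratum.
#' For every within effect, sphericity is assessed with Mauchly's test on the
#' pooled covariance of the orthonormal-contrast projection, and the
#' Greenhouse-Geisser epsilon is computed from the same matrix; when
#' sphericity is rejected at `sphericity_alpha` (or cannot be tested because
#' the covariance is rank-deficient, i.e. fewer error degrees of freedom than
#' contrast dimensions) the reported degrees of freedom and p-value are
#' epsilon-adjusted. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error_stratum)`.
#'
#' @param data Long-format data frame: one row per subject x within-cell, one
#'   value per cell (pre-averaged). Unbalanced or incomplete designs are
#'   rejected.
#' @param dv,subject,between Column names of the value, subject identifier and
#'   between-subjects factor.
#' @param within Character vector of one or two within-subject factor column
#'   names.
#' @param sphericity_alpha Significance level of Mauchly's test gating the
#'   correction. Default 0.05.
#'
#' @return Data frame with one row per effect: `effect`, `df_num`, `df_den`,
#'   `ss`, `ss_error`, `F`, `p` (epsilon-adjusted where applied), `pes`
#'   (partial eta squared), `epsilon_gg`, `mauchly_p`, `sphericity_ok`,
#'   `gg_applied`, plus the unadjusted `p_uncorrected`.
#' @export
mixed_anova <- function(data, dv, subject, between, within,
                        sphericity_alpha = 0.05) {
  cols <- c(dv, subject, between, within)
  if (!all(cols %in% names(data)))
    data_error(sprintf("missing column(s): %s",
                       paste(setdiff(cols, names(data)), collapse = ", ")))
  if (length(within) < 1L || length(within) > 2L)
    config_error("`within` must name one or two factors")
  d <- data.frame(
    y = data[[dv]],
    s = factor(data[[subject]]),
    g = factor(data[[between]])
  )
  for (i in seq_along(within)) d[[paste0("w", i)]] <- factor(data[[within[i]]])
  wnames <- paste0("w", seq_along(within))
  if (anyNA(d$y)) data_error("design error: missing values in the response")

  # balance checks: full crossing, one value per cell, one group per subject
  cells <- interaction(d[c("s", wnames)], drop = FALSE)
  counts <- table(cells)
  if (any(counts != 1L))
    data_error("design error: need exactly one value per subject x within cell")
  if (any(rowSums(table(d$s, d$g) > 0) != 1L))
    data_error("design error: each subject must belong to exactly one group")

  wform <- paste(wnames, collapse = "*")
  form <- stats::as.formula(
    sprintf("y ~ g * %s + Error(s/(%s))", wform, wform))
  fit <- aov(form, data = d)
  smry <- summary(fit)

  # harvest effects and their stratum errors
  rows <- list()
  for (stratum in names(smry)) {
    tab <- smry[[stratum]][[1L]]
    terms <- trimws(rownames(tab))
    err_i <- which(terms == "Residuals")
    ss_err <- tab[err_i, "Sum Sq"]; df_err <- tab[err_i, "Df"]
    for (i in setdiff(seq_along(terms), err_i)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], df_num = tab[i, "Df"], df_den = df_err,
        ss = tab[i, "Sum Sq"], ss_error = ss_err,
        F = tab[i, "F value"], p_uncorrected = tab[i, "Pr(>F)"]
      )
    }
  }
  res <- do.call(rbind, rows)

  # sphericity diagnostics per within effect, from the subject x cell matrix
  lev <- lapply(wnames, function(w) levels(d[[w]]))
  cell_grid <- expand.grid(lev, KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
  names(cell_grid) <- wnames
  subjects <- levels(d$s)
  Y <- matrix(NA_real_, nrow = length(subjects), ncol = nrow(cell_grid))
  key_d <- do.call(paste, c(d[wnames], sep = "\r"))
  key_c <- do.call(paste, c(cell_grid, sep = "\r"))
  for (j in seq_len(nrow(cell_grid))) {
    dj <- d[key_d == key_c[j], ]
    Y[match(as.character(dj$s), subjects), j] <- dj$y
  }
  grp <- d$g[match(subjects, as.character(d$s))]

  orth <- function(k) {
    cm <- stats::contr.helmert(k)
    qr.Q(qr(cm))  # orthonormal columns, each orthogonal to the constant
  }
  norm1 <- function(k) matrix(1 / sqrt(k), nrow = k)

  eps_tab <- list()
  w_levels <- vapply(wnames, function(w) nlevels(d[[w]]), integer(1))
  w_effects <- unlist(lapply(seq_along(wnames), function(sz)
    utils::combn(wnames, sz, simplify = FALSE)), recursive = FALSE)
  for (eff in w_effects) {
    C <- Reduce(function(a, b) a %x% b, rev(lapply(wnames, function(w)
      if (w %in% eff) orth(w_levels[[w]]) else norm1(w_levels[[w]]))))
    Z <- Y %*% C
    dd <- ncol(C)
    Zc <- Z - rowsum(Z, grp)[grp, , drop = FALSE] /
      as.vector(table(grp))[grp]
    df_e <- length(subjects) - nlevels(grp)
    S <- crossprod(Zc) / df_e
    trS <- sum(diag(S)); trS2 <- sum(S * S)
    eps <- if (dd == 1L) 1 else trS^2 / (dd * trS2)
    mauchly_p <- NA_real_
    if (dd == 1L) {
      mauchly_p <- 1  # sphericity trivially satisfied with one contrast
    } else if (df_e > dd) {
      W <- det(S) / (trS / dd)^dd
      if (is.finite(W) && W > 0) {
        f <- df_e - (2 * dd^2 + dd + 2) / (6 * dd)
        stat <- -f * log(W)
        mauchly_p <- pchisq(stat, dd * (dd + 1) / 2 - 1, lower.tail = FALSE)
      }
    }
    eps_tab[[paste(eff, collapse = ":")]] <-
      list(eps = eps, mauchly_p = mauchly_p, d = dd)
  }

  # attach diagnostics: an effect inherits the epsilon of its within part
  res$epsilon_gg <- NA_real_
  res$mauchly_p <- NA_real_
  res$sphericity_ok <- NA
  res$gg_applied <- FALSE
  res$p <- res$p_uncorrected
  for (i in seq_len(nrow(res))) {
    parts <- strsplit(res$effect[i], ":", fixed = TRUE)[[1L]]
    wpart <- intersect(parts, wnames)
    if (length(wpart) == 0L) next  # pure between effect
    key <- paste(wnames[wnames %in% wpart], collapse = ":")
    e <- eps_tab[[key]]
    res$epsilon_gg[i] <- e$eps
    res$mauchly_p[i] <- e$mauchly_p
    res$sphericity_ok[i] <- if (is.na(e$mauchly_p)) NA else
      e$mauchly_p >= sphericity_alpha
    apply_gg <- e$d > 1L &&
      (is.na(e$mauchly_p) || e$mauchly_p < sphericity_alpha)
    if (apply_gg) {
      res$gg_applied[i] <- TRUE
      res$df_num[i] <- res$df_num[i] * e$eps
      res$df_den[i] <- res$df_den[i] * e$eps
      res$p[i] <- pf(res$F[i], res$df_num[i], res$df_den[i],
                     lower.tail = FALSE)
    }
  }
  res$pes <- res$ss / (res$ss + res$ss_error)
  # readable effect names
  relabel <- c(g = between, stats::setNames(within, wnames))
  res$effect <- vapply(strsplit(res$effect, ":", fixed = TRUE),
                       function(p) paste(relabel[p], collapse = ":"),
                       character(1))
  rownames(res) <- NULL
  res[, c("effect", "df_num", "df_den", "ss", "ss_error", "F", "p", "pes",
          "epsilon_gg", "mauchly_p", "sphericity_ok", "gg_applied",
          "p_uncorrected")]
}

#' Per-cell unpaired t-test map
#'
#' Runs an independent-samples t-test (pooled variance by default, matching
#' the classical unpaired t) between the two groups in every electrode x scale
#' cell and flags two-tailed significance at `alpha`.
#'
#' Degenerate cells follow the documented conventions: both groups constant
#' and equal means gives `t = 0, p = 1`; constant groups with unequal means
#' gives `p = 0` with `degenerate = TRUE`.
#'
#' @param values Data frame with columns `subject`, `electrode`, `scale`,
#'   `value`.
#' @param groups Named character/factor vector mapping subject -> group (two
#'   levels).
#' @param alpha Two-tailed significance threshold. Default 0.01.
#' @param var_equal Pooled-variance t (default `TRUE`).
#'
#' @return Data frame: `electrode`, `scale`, `t`, `df`, `p`, `significant`,
#'   `degenerate`. The sign of `t` is positive when the first group level
#'   mean exceeds the second.
#' @export
ttest_map <- function(values, groups, alpha = 0.01, var_equal = TRUE) {
  need <- c("subject", "electrode", "scale", "value")
  if (!all(need %in% names(values)))
    data_error("`values` needs columns subject, electrode, scale, value")
  g <- factor(groups)
  if (nlevels(g) != 2L) data_error("`groups` must have exactly two levels")
  values$g <- g[match(as.character(values$subject), names(groups))]
  if (anyNA(values$g)) data_error("subjects missing from `groups`")

  cells <- split(values, list(values$electrode, values$scale), drop = TRUE)
  rows <- lapply(cells, function(cell) {
    a <- cell$value[cell$g == levels(g)[1]]
    b <- cell$value[cell$g == levels(g)[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      data_error("need at least two subjects per group per cell")
    out <- data.frame(electrode = cell$electrode[1], scale = cell$scale[1],
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      degenerate = FALSE)
    if (var(a) == 0 && var(b) == 0) {
      if (mean(a) == mean(b)) {
        out$t <- 0; out$p <- 1; out$df <- length(a) + length(b) - 2
      } else {
        out$t <- sign(mean(a) - mean(b)) * Inf
        out$p <- 0; out$df <- length(a) + length(b) - 2
        out$degenerate <- TRUE
      }
    } else {
      tt <- t.test(a, b, var.equal = var_equal)
      out$t <- unname(tt$statistic); out$df <- unname(tt$parameter)
      out$p <- tt$p.value
    }
    out
  })
  res <- do.call(rbind, rows)
  res$significant <- res$p < alpha
  rownames(res) <- NULL
  res[order(res$electrode, res$scale),
      c("electrode", "scale", "t", "df", "p", "significant", "degenerate")]
}

#' Pearson correlations with Benjamini-Hochberg adjustment
#'
#' Correlates a per-subject score with each column of a per-electrode value
#' matrix and applies the BH step-up false-discovery-rate adjustment across
#' the electrode family. Zero-variance electrodes yield an undefined
#' correlation (`NA` with `degenerate = TRUE`) and are excluded from the BH
#' family.
#'
#' @param x Numeric score vector, length >= 3, finite.
#' @param Y Numeric matrix, subjects in rows (aligned with `x`), electrodes in
#'   columns.
#' @return Data frame: `electrode`, `r`, `p`, `p_bh`, `degenerate`.
#' @export
corr_bh <- function(x, Y) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L, dimnames = list(NULL, "y"))
  if (length(x) != nrow(Y))
    data_error("`x` and rows of `Y` must align")
  if (length(x) < 3L) data_error("need at least three subjects")
  if (!all(is.finite(x)) || !all(is.finite(Y)))
    data_error("inputs must be finite")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("e", seq_len(ncol(Y)))
  n <- length(x)
  if (var(x) == 0) numeric_error("undefined correlation: score has zero variance")
  res <- data.frame(electrode = colnames(Y), r = NA_real_, p = NA_real_,
                    degenerate = FALSE)
  for (j in seq_len(ncol(Y))) {
    if (var(Y[, j]) == 0) { res$degenerate[j] <- TRUE; next }
    r <- cor(x, Y[, j])
    tval <- r * sqrt((n - 2) / (1 - r^2))
    res$r[j] <- r
    res$p[j] <- if (abs(r) == 1) 0 else 2 * pt(abs(tval), n - 2,
                                               lower.tail = FALSE)
  }
  res$p_bh <- NA_real_
  ok <- !res$degenerate
  res$p_bh[ok] <- p.adjust(res$p[ok], method = "BH")
  res
}

#' Cohen's d for two independent groups
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the pooled
#' standard deviation weighted by degrees of freedom.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Cohen's d, or `NA` when the pooled SD is zero (undefined).
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    data_error("both groups need at least two observations")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Bonferroni-adjusted pairwise post-hoc t-tests
#'
#' Pairwise comparisons between the levels of one factor with Bonferroni
#' adjustment, paired within subject for within-subject factors.
#'
#' @param data Long data frame.
#' @param dv,factor_col,subject Column names.
#' @param paired Paired (within-subject) comparisons. Default `TRUE`.
#' @return Data frame: `level_a`, `level_b`, `mean_diff`, `t`, `df`, `p_bonf`.
#' @export
posthoc_bonferroni <- function(data, dv, factor_col, subject,
                               paired = TRUE) {
  f <- factor(data[[factor_col]])
  levs <- levels(f)
  prs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    da <- data[f == pr[1], ]; db <- data[f == pr[2], ]
    if (paired) {
      a <- da[[dv]][order(da[[subject]])]
      b <- db[[dv]][order(db[[subject]])]
      tt <- t.test(a, b, paired = TRUE)
    } else {
      tt <- t.test(da[[dv]], db[[dv]], var.equal = TRUE)
    }
    data.frame(level_a = pr[1], level_b = pr[2],
               mean_diff = mean(da[[dv]]) - mean(db[[dv]]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  res <- do.call(rbind, rows)
  res$p_bonf <- pmin(1, res$p * nrow(res))
  res
}
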