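# Validation statistics for multi-reader ordinal index studies: Spearman rank
# correlation with a Fisher-z / Bonett-Wright interval, one-way random-effects
# intraclass correlation, weighted Cohen kappa with the Fleiss-Cohen-Everitt
# large-sample variance, and inverse-variance pooling of stratum estimates.

#' Spearman rank correlation with confidence interval
#'
#' Average-rank Spearman rho with a confidence interval obtained by the Fisher
#' z transform using the Bonett-Wright standard error
#' `sqrt((1 + rho^2/2) / (n - 3))` (default) or the Fieller-Hartley-Pearson
#' standard error `sqrt(1.06 / (n - 3))`, back-transformed. A rho of 0.6 is
#' the pre-specified meaningfulness threshold.
#'
#' @param x,y paired numeric score vectors; pairs with a missing value are
#'   dropped (complete-case).
#' @param conf.level confidence level, default 0.95.
#' @param se_method `"bonett"` (default) or `"fieller"`.
#' @param threshold meaningfulness threshold on rho, default 0.6.
#' @param stratum optional label carried into reports.
#'
#' @return An object of class `sema_cor`: `rho`, `ci_low`, `ci_high`, `n`,
#'   `stratum`, `meets_threshold`. Errors when fewer than 4 complete pairs
#'   remain or either vector is constant (undefined correlation).
#' @examples
#' spearman_ci(1:5, c(2, 1, 4, 3, 5))   # rho = 0.7
#' @export
spearman_ci <- function(x, y, conf.level = 0.95,
                        se_method = c("bonett", "fieller"),
                        threshold = 0.6, stratum = "") {
  se_method <- match.arg(se_method)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in a score vector", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    ci <- c(rho, rho)
  } else {
    se <- switch(se_method,
                 bonett = sqrt((1 + rho^2 / 2) / (n - 3)),
                 fieller = sqrt(1.06 / (n - 3)))
    z <- atanh(rho) + c(-1, 1) * stats::qnorm(1 - (1 - conf.level) / 2) * se
    ci <- tanh(z)
  }
  structure(list(rho = rho, ci_low = ci[1L], ci_high = ci[2L], n = n,
                 stratum = stratum, meets_threshold = rho >= threshold,
                 threshold = threshold, conf.level = conf.level,
                 se_method = se_method),
            class = "sema_cor")
}

#' @export
print.sema_cor <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman rho = %.*f (%d%% CI %.*f to %.*f), n = %d%s%s\n",
              digits, x$rho, round(100 * x$conf.level), digits, x$ci_low,
              digits, x$ci_high, x$n,
              if (nzchar(x$stratum)) paste0(", stratum: ", x$stratum) else "",
              if (x$meets_threshold) sprintf(" [>= %.1f]", x$threshold) else ""))
  invisible(x)
}

.icc_band <- function(icc) {
  # <0.50 poor, [0.50,0.75) moderate, [0.75,0.90] good, >0.90 excellent
  ifelse(icc < 0.50, "poor",
         ifelse(icc < 0.75, "moderate",
                ifelse(icc <= 0.90, "good", "excellent")))
}

#' One-way random-effects intraclass correlation
#'
#' Single-score ICC with the video (subject) as the only random effect:
#' `ICC(1) = sigma2_b / (sigma2_b + sigma2_w)`, truncated at 0. Reader pairs
#' rotate over the pool so a fully crossed reader-by-video design does not
#' exist; a one-way model is the appropriate agreement model. On balanced data
#' the variance components come from the ANOVA method of moments and the
#' confidence interval is the exact F interval; on unbalanced data (e.g.
#' adjudicated videos carrying 3 reads) the point estimate is REML via
#' [lme4::lmer()] and the interval uses the F interval with the
#' Satterthwaite-style average group size
#' `k0 = (N - sum(k_i^2)/N) / (n_groups - 1)`.
#'
#' @param data data.frame in long format with a grouping column and a score
#'   column (defaults `video_id`, `score`); rows with missing scores dropped.
#' @param group,score column names.
#' @param conf.level confidence level, default 0.95.
#'
#' @return An object of class `sema_icc`: `icc`, `ci_low`, `ci_high`,
#'   `variance_between`, `variance_within`, `band` (poor / moderate / good /
#'   excellent), `n_groups`, `n_obs`, `method`. Errors when no video carries
#'   at least 2 reads.
#' @export
icc_oneway <- function(data, group = "video_id", score = "score",
                       conf.level = 0.95) {
  g <- as.character(data[[group]])
  y <- as.numeric(data[[score]])
  keep <- !is.na(y) & !is.na(g)
  g <- g[keep]; y <- y[keep]
  ki <- table(g)
  if (length(ki) < 2) stop("need at least 2 videos", call. = FALSE)
  if (max(ki) < 2) stop("no video has 2 or more reads: within-video variance undefined",
                        call. = FALSE)
  n_grp <- length(ki)
  N <- length(y)
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ssb <- sum(as.numeric(ki) * (means[names(ki)] - grand)^2)
  ssw <- sum((y - means[g])^2)
  msb <- ssb / (n_grp - 1)
  msw <- ssw / (N - n_grp)
  balanced <- length(unique(as.numeric(ki))) == 1L
  if (balanced) {
    k0 <- as.numeric(ki[1L])
    vb <- max((msb - msw) / k0, 0)
    vw <- msw
    method <- "anova"
  } else {
    k0 <- (N - sum(as.numeric(ki)^2) / N) / (n_grp - 1)
    fit <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | g), data = data.frame(y = y, g = g), REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vb <- vc$vcov[vc$grp == "g"]
    vw <- vc$vcov[vc$grp == "Residual"]
    method <- "reml"
  }
  icc <- if (vb + vw == 0) 1 else max(vb / (vb + vw), 0)
  alpha <- 1 - conf.level
  if (msw == 0) {
    ci <- c(1, 1)
    icc <- 1
  } else {
    fobs <- msb / msw
    fl <- fobs / stats::qf(1 - alpha / 2, n_grp - 1, N - n_grp)
    fu <- fobs * stats::qf(1 - alpha / 2, N - n_grp, n_grp - 1)
    ci <- c((fl - 1) / (fl + k0 - 1), (fu - 1) / (fu + k0 - 1))
    ci <- pmin(pmax(ci, -1), 1)
  }
  structure(list(icc = icc, ci_low = ci[1L], ci_high = ci[2L],
                 variance_between = vb, variance_within = vw,
                 band = .icc_band(icc), n_groups = n_grp, n_obs = N,
                 method = method, conf.level = conf.level),
            class = "sema_icc")
}

#' @export
print.sema_icc <- function(x, digits = 2, ...) {
  cat(sprintf("One-way ICC = %.*f (%d%% CI %.*f to %.*f) [%s], %d videos / %d reads (%s)\n",
              digits, x$icc, round(100 * x$conf.level), digits, x$ci_low,
              digits, x$ci_high, x$band, x$n_groups, x$n_obs, x$method))
  invisible(x)
}

.kappa_band <- function(kappa) {
  # moderate 0.41-0.60, good 0.61-0.80, very good > 0.80
  ifelse(kappa < 0.41, "below_moderate",
         ifelse(kappa <= 0.60, "moderate",
                ifelse(kappa <= 0.80, "good", "very_good")))
}

#' Weighted Cohen kappa for two ordinal raters
#'
#' Chance-corrected agreement with partial credit for near-misses:
#' `kappa_w = 1 - sum(w o) / sum(w e)` with disagreement weights
#' `w_ij = |i - j| / (k - 1)` (linear, default) or its square (quadratic),
#' observed cell proportions `o` and expected proportions `e` from the row and
#' column marginals. The confidence interval uses the Fleiss-Cohen-Everitt
#' large-sample variance of the weighted kappa estimate.
#'
#' @param a,b equal-length rating vectors (values among `categories`).
#' @param categories ordered category levels; defaults to the factor levels of
#'   `a` if it is a factor, else the sorted union of values.
#' @param scheme `"linear"` (default) or `"quadratic"` weights.
#' @param conf.level confidence level, default 0.95.
#' @param reader_pair optional length-2 identifier carried into reports.
#'
#' @return An object of class `sema_kappa`: `kappa`, `ci_low`, `ci_high`,
#'   `var`, `weight_scheme`, `band` (below_moderate / moderate / good /
#'   very_good), `n`, `reader_pair`. With 2 categories and linear weights the
#'   statistic equals unweighted Cohen kappa. Errors on empty input or when
#'   expected agreement is 1 (both raters constant at one category).
#' @export
weighted_kappa <- function(a, b, categories = NULL,
                           scheme = c("linear", "quadratic"),
                           conf.level = 0.95, reader_pair = NULL) {
  scheme <- match.arg(scheme)
  if (length(a) != length(b)) stop("rating vectors must have equal length", call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0) stop("no complete rating pairs", call. = FALSE)
  if (is.null(categories)) {
    categories <- if (is.factor(a)) levels(a) else sort(unique(c(a, b)))
  }
  if (!all(c(as.character(a), as.character(b)) %in% as.character(categories))) {
    stop("ratings outside the declared categories", call. = FALSE)
  }
  k <- length(categories)
  fa <- factor(a, levels = categories)
  fb <- factor(b, levels = categories)
  o <- table(fa, fb) / n
  pr <- rowSums(o); pc <- colSums(o)
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  if (scheme == "quadratic") d <- d^2
  w <- 1 - d                       # agreement weights, 1 on the diagonal
  e <- outer(pr, pc)
  po <- sum(w * o)
  pe <- sum(w * e)
  if (1 - pe < .Machine$double.eps^0.5) {
    stop("undefined kappa: expected agreement is 1", call. = FALSE)
  }
  kap <- (po - pe) / (1 - pe)
  wbar_row <- as.vector(w %*% pc)  # sum_j p.j w_ij
  wbar_col <- as.vector(pr %*% w)  # sum_i pi. w_ij
  wd <- w - (1 - kap) * (outer(wbar_row, rep(1, k)) + outer(rep(1, k), wbar_col))
  v <- (sum(o * wd^2) - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  v <- max(v, 0)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- kap + c(-1, 1) * z * sqrt(v)
  ci <- pmin(ci, 1)
  structure(list(kappa = kap, ci_low = ci[1L], ci_high = ci[2L], var = v,
                 weight_scheme = scheme, band = .kappa_band(kap), n = n,
                 reader_pair = reader_pair, conf.level = conf.level),
            class = "sema_kappa")
}

#' @export
print.sema_kappa <- function(x, digits = 2, ...) {
  pair <- if (is.null(x$reader_pair)) "" else
    paste0(" [", paste(x$reader_pair, collapse = " vs "), "]")
  cat(sprintf("Weighted kappa (%s) = %.*f (%d%% CI %.*f to %.*f) [%s], n = %d%s\n",
              x$weight_scheme, digits, x$kappa, round(100 * x$conf.level),
              digits, x$ci_low, digits, x$ci_high, x$band, x$n, pair))
  invisible(x)
}

#' Pool pairwise kappas across reader pairs
#'
#' Inverse-variance weighted mean of the pairwise weighted kappas (e.g. the 6
#' unordered pairs of a 4-reader pool), with the pooled variance `1/sum(w)`.
#'
#' @param pair_results list of [weighted_kappa()] results.
#' @param conf.level confidence level, default 0.95.
#' @return A `sema_kappa` object with `reader_pair = "POOLED"`.
#' @export
pool_kappas <- function(pair_results, conf.level = 0.95) {
  if (inherits(pair_results, "sema_kappa")) pair_results <- list(pair_results)
  if (!length(pair_results)) stop("no pair results to pool", call. = FALSE)
  kap <- vapply(pair_results, `[[`, numeric(1L), "kappa")
  v <- vapply(pair_results, `[[`, numeric(1L), "var")
  n <- sum(vapply(pair_results, `[[`, numeric(1L), "n"))
  finite <- is.finite(v)
  if (!any(finite)) stop("all pair variances are infinite", call. = FALSE)
  kap <- kap[finite]; v <- v[finite]
  if (any(v == 0)) {      # degenerate perfect-agreement pairs dominate
    kap_pool <- mean(kap[v == 0])
    v_pool <- 0
  } else {
    w <- 1 / v
    kap_pool <- sum(w * kap) / sum(w)
    v_pool <- 1 / sum(w)
  }
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- pmin(kap_pool + c(-1, 1) * z * sqrt(v_pool), 1)
  structure(list(kappa = kap_pool, ci_low = ci[1L], ci_high = ci[2L],
                 var = v_pool, weight_scheme = pair_results[[1L]]$weight_scheme,
                 band = .kappa_band(kap_pool), n = n, reader_pair = "POOLED",
                 conf.level = conf.level),
            class = "sema_kappa")
}

#' Inverse-variance pooled mean difference across strata
#'
#' Per-stratum mean paired difference and variance of the mean, pooled with
#' weights `w_i = 1 / var(mean_i)`; a 95% normal interval from the pooled
#' variance `1/sum(w)`. The sign convention is first-listed minus
#' second-listed reader in the fixed pair order. Strata with fewer than 2
#' differences (variance not estimable) are dropped with a warning.
#'
#' @param diffs named list of numeric difference vectors (one per stratum), or
#'   a data.frame with columns `stratum` and `diff`.
#' @param conf.level confidence level, default 0.95.
#'
#' @return An object of class `sema_pooled_diff`: `mean_diff`, `ci_low`,
#'   `ci_high`, and a `strata` data.frame (label, mean, var_of_mean, n).
#' @export
pooled_mean_difference <- function(diffs, conf.level = 0.95) {
  if (is.data.frame(diffs)) {
    diffs <- split(diffs$diff, diffs$stratum)
  }
  if (is.null(names(diffs))) names(diffs) <- paste0("stratum_", seq_along(diffs))
  diffs <- lapply(diffs, function(d) d[!is.na(d)])
  ns <- lengths(diffs)
  if (any(ns < 2)) {
    warning("dropping stratum with fewer than 2 differences: ",
            paste(names(diffs)[ns < 2], collapse = ", "), call. = FALSE)
    diffs <- diffs[ns >= 2]
  }
  if (!length(diffs)) stop("no stratum has at least 2 differences", call. = FALSE)
  m <- vapply(diffs, mean, numeric(1L))
  vm <- vapply(diffs, function(d) stats::var(d) / length(d), numeric(1L))
  n <- lengths(diffs)
  if (any(vm == 0)) {
    zv <- vm == 0
    pooled <- stats::weighted.mean(m[zv], n[zv])
    v_pool <- 0
  } else {
    w <- 1 / vm
    pooled <- sum(w * m) / sum(w)
    v_pool <- 1 / sum(w)
  }
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- pooled + c(-1, 1) * z * sqrt(v_pool)
  structure(list(mean_diff = pooled, ci_low = ci[1L], ci_high = ci[2L],
                 strata = data.frame(label = names(diffs), mean = m,
                                     var_of_mean = vm, n = n, row.names = NULL),
                 conf.level = conf.level),
            class = "sema_pooled_diff")
}

#' @export
print.sema_pooled_diff <- function(x, digits = 2, ...) {
  cat(sprintf("Pooled mean difference = %.*f (%d%% CI %.*f to %.*f), %d strata\n",
              digits, x$mean_diff, round(100 * x$conf.level), digits, x$ci_low,
              digits, x$ci_high, nrow(x$strata)))
  invisible(x)
}

#' Correlation of pre-to-post change between two indices
#'
#' Computes per-patient changes (post minus pre) for both indices over the
#' patients with both timepoints, then the Spearman correlation of the two
#' change scores — the sensitivity-to-change analysis.
#'
#' @param tab data.frame with columns `patient_id`, `timepoint` (`"pre"` /
#'   `"post"`), `sema`, `ses`.
#' @param ... passed to [spearman_ci()].
#' @return A `sema_cor` object (stratum `"change"`).
#' @export
change_score_correlation <- function(tab, ...) {
  need <- c("patient_id", "timepoint", "sema", "ses")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  pre <- tab[tab$timepoint == "pre", ]
  post <- tab[tab$timepoint == "post", ]
  ids <- intersect(pre$patient_id, post$patient_id)
  i_pre <- match(ids, pre$patient_id)
  i_post <- match(ids, post$patient_id)
  d_sema <- post$sema[i_post] - pre$sema[i_pre]
  d_ses <- post$ses[i_post] - pre$ses[i_pre]
  spearman_ci(d_sema, d_ses, stratum = "change", ...)
}
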