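# Reliability statistics against independent oracles

test_that("spearman_ci matches the rank formula and honours its contracts", {
  r <- spearman_ci(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)               # 1 - 6*4/(5*24), sum(d^2) = 4
  expect_equal(r$rho, oracle_spearman_noties(1:5, c(2, 1, 4, 3, 5)))
  expect_lte(r$ci_low, r$rho)
  expect_gte(r$ci_high, r$rho)
  expect_true(r$meets_threshold)
  expect_equal(spearman_ci(1:10, (1:10)^3)$rho, 1)    # monotone relabeling
  expect_equal(spearman_ci(1:10, -(1:10))$rho, -1)
  expect_error(spearman_ci(1:3, 3:1), "at least 4")
  expect_error(spearman_ci(1:5, rep(2, 5)), "zero variance")
})

test_that("spearman_ci is invariant to strictly increasing transforms", {
  set.seed(1)
  for (i in 1:25) {
    x <- rnorm(20)
    y <- rnorm(20)
    base <- spearman_ci(x, y)
    tr <- spearman_ci(exp(x), 3 * y^3 + y)
    expect_equal(tr$rho, base$rho)
    expect_equal(tr$ci_low, base$ci_low)
    expect_equal(spearman_ci(x, y)$rho, oracle_spearman_noties(x, y))
  }
})

test_that("weighted kappa equals brute-force contingency evaluation", {
  set.seed(2)
  cats <- SEMA_BANDS
  for (i in 1:250) {
    n <- sample(10:60, 1L)
    a <- sample(cats, n, replace = TRUE, prob = runif(5))
    b <- ifelse(runif(n) < 0.6, a, sample(cats, n, replace = TRUE))
    if (length(unique(c(a, b))) < 2) next
    scheme <- sample(c("linear", "quadratic"), 1L)
    got <- weighted_kappa(a, b, categories = cats, scheme = scheme)
    expect_equal(got$kappa, oracle_weighted_kappa(a, b, cats, scheme))
    expect_lte(got$ci_low, got$kappa)
    expect_gte(got$ci_high, got$kappa)
  }
})

test_that("weighted kappa special cases: identity, two categories, chance", {
  a <- rep(SEMA_BANDS, times = c(3, 4, 5, 6, 2))
  expect_equal(weighted_kappa(a, a, categories = SEMA_BANDS)$kappa, 1)
  # 2 categories + linear weights reduce to unweighted Cohen kappa
  set.seed(3)
  for (i in 1:25) {
    x <- sample(c("lo", "hi"), 40, replace = TRUE)
    y <- ifelse(runif(40) < 0.7, x, sample(c("lo", "hi"), 40, replace = TRUE))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(weighted_kappa(x, y, categories = c("lo", "hi"))$kappa,
                 oracle_unweighted_kappa(x, y, c("lo", "hi")))
  }
  # independent ratings give kappa near 0
  set.seed(4)
  x <- sample(SEMA_BANDS, 4000, replace = TRUE)
  y <- sample(SEMA_BANDS, 4000, replace = TRUE)
  expect_lt(abs(weighted_kappa(x, y, categories = SEMA_BANDS)$kappa), 0.05)
  expect_error(weighted_kappa(character(0), character(0)), "no complete")
  expect_error(weighted_kappa(rep("a", 5), rep("a", 5),
                              categories = c("a", "b")),
               "expected agreement")
})

test_that("kappa banding follows the printed agreement scale", {
  expect_equal(semacd:::.kappa_band(c(0.3, 0.41, 0.60, 0.61, 0.80, 0.81)),
               c("below_moderate", "moderate", "moderate", "good", "good",
                 "very_good"))
})

test_that("one-way ICC matches the ANOVA closed form on balanced data", {
  toy <- data.frame(video_id = rep(paste0("V", 1:5), each = 2),
                    score = c(1, 2, 4, 5, 7, 9, 10, 10, 14, 12))
  got <- icc_oneway(toy)
  expect_equal(got$icc, oracle_icc_balanced(toy$video_id, toy$score, 2))
  expect_equal(got$method, "anova")
  # duplicated reads: no within-video variance
  dup <- data.frame(video_id = rep(paste0("V", 1:20), each = 2),
                    score = rep(rnorm(20), each = 2))
  expect_equal(icc_oneway(dup)$icc, 1)
  # i.i.d. noise, no video effect
  set.seed(6)
  noise <- data.frame(video_id = rep(paste0("V", 1:400), each = 2),
                      score = rnorm(800))
  expect_lt(icc_oneway(noise)$icc, 0.1)
  expect_error(icc_oneway(data.frame(video_id = c("a", "b"), score = 1:2)),
               "no video has 2")
})

test_that("unbalanced ICC via REML recovers known variance components", {
  set.seed(7)
  n <- 400
  b <- rnorm(n, sd = 2)                         # sigma2_b = 4
  ki <- sample(2:3, n, replace = TRUE)          # adjudicated videos have 3 reads
  dat <- data.frame(video_id = rep(seq_len(n), ki),
                    score = rep(b, ki) + rnorm(sum(ki)))  # sigma2_w = 1
  got <- icc_oneway(dat)
  expect_equal(got$method, "reml")
  expect_lt(abs(got$icc - 0.8), 0.05)
  expect_lte(got$ci_low, got$icc)
  expect_gte(got$ci_high, got$icc)
  expect_equal(got$band, "good")
})

test_that("ICC banding assigns the boundary values as documented", {
  expect_equal(semacd:::.icc_band(c(0.2, 0.5, 0.74, 0.75, 0.90, 0.91)),
               c("poor", "moderate", "moderate", "good", "good", "excellent"))
})

test_that("pool_kappas is an inverse-variance average", {
  a <- rep(SEMA_BANDS, times = c(3, 4, 5, 6, 2))
  b <- rev(a)
  k1 <- weighted_kappa(a, b, categories = SEMA_BANDS)
  expect_equal(pool_kappas(list(k1))$kappa, k1$kappa)
  # hand arithmetic: weights 100 and 400
  k_lo <- structure(list(kappa = 0.6, var = 0.01, n = 50,
                         weight_scheme = "linear"), class = "sema_kappa")
  k_hi <- structure(list(kappa = 0.9, var = 0.0025, n = 50,
                         weight_scheme = "linear"), class = "sema_kappa")
  pooled <- pool_kappas(list(k_lo, k_hi))
  expect_equal(pooled$kappa, 0.84)
  expect_equal(pooled$var, 1 / 500)
  # equal variances reduce to the simple mean
  k_hi2 <- k_hi; k_hi2$var <- 0.01
  expect_equal(pool_kappas(list(k_lo, k_hi2))$kappa, 0.75)
})

test_that("pooled_mean_difference weights strata by inverse variance", {
  one <- pooled_mean_difference(list(s1 = c(1, -1, 0, 0)))
  expect_equal(one$mean_diff, 0)
  # hand arithmetic: var-of-mean 0.25 and 0.0625 give weights 4 and 16,
  # pooled (4*0.5 + 16*(-0.5)) / 20 = -0.3
  d1 <- c(0, 1)                                   # mean 0.5, var-of-mean 0.25
  d2 <- -0.5 + c(-0.5, -sqrt(0.125), sqrt(0.125), 0.5)  # mean -0.5, vom 0.0625
  expect_equal(var(d2) / 4, 0.0625)
  expect_equal(pooled_mean_difference(list(a = d1, b = d2))$mean_diff, -0.3)
  # symmetric strata reduce to the midpoint
  set.seed(8)
  base <- rnorm(30)
  base <- base - mean(base)
  sym <- pooled_mean_difference(list(a = base + 1, b = base + 3))
  expect_equal(sym$mean_diff, 2, tolerance = 1e-10)
  expect_warning(pooled_mean_difference(list(a = c(1, 2), b = 3)), "dropping")
  expect_error(suppressWarnings(pooled_mean_difference(list(a = 1))),
               "at least 2")
})

test_that("change-score correlation works on per-patient deltas", {
  tab <- data.frame(patient_id = rep(paste0("P", 1:8), 2),
                    timepoint = rep(c("pre", "post"), each = 8),
                    sema = c(10, 12, 4, 8, 15, 3, 9, 6, 5, 11, 4, 2, 9, 3, 1, 6))
  tab$ses <- ifelse(tab$timepoint == "post", 2, 0) +
    2 * tab$sema        # delta_ses = 2*delta_sema + 2, a monotone map
  expect_equal(change_score_correlation(tab)$rho, 1)
  flat <- tab
  flat$sema <- rep(rep(c(1, 2, 3, 4), 2), 2)
  flat$ses <- 5
  expect_error(change_score_correlation(flat), "zero variance")
})
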