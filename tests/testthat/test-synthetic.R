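# Synthetic study generator: noise law, study layout, determinism

test_that("perturb_rating is the identity at p_exact = 1 and respects clipping", {
  segs <- c(ascending = 2L, transverse = 0L, descending = 3L, rectum = 1L)
  set.seed(9)
  for (i in 1:20) {
    p <- perturb_rating(3L, segs, p_exact = 1)
    expect_equal(p$ileum, 3L)
    expect_equal(unname(p$segment_grades), unname(segs))
    expect_equal(p$colon_overall, 3L)
    expect_equal(unname(p$involved), unname(segs > 0))
  }
  # grade 0 never goes negative, grade 4 never exceeds 4
  set.seed(10)
  for (i in 1:200) {
    lo <- perturb_rating(0L, c(ascending = 0L, transverse = 0L,
                               descending = 0L, rectum = 0L),
                         p_exact = 0.2, bias = -1)
    expect_gte(lo$ileum, 0L)
    expect_gte(lo$colon_overall, 0L)
    hi <- perturb_rating(4L, c(ascending = 4L, transverse = 4L,
                               descending = 4L, rectum = 4L),
                         p_exact = 0.2, bias = 1)
    expect_lte(hi$ileum, 4L)
    expect_lte(hi$colon_overall, 4L)
  }
  # a not-assessed ileum is never perturbed
  set.seed(11)
  p <- perturb_rating(NA, segs, p_exact = 0.1)
  expect_true(is.na(p$ileum))
})

test_that("the one-step error law has the stated distribution", {
  set.seed(12)
  n <- 20000
  draws <- vapply(seq_len(n), function(i) {
    perturb_rating(2L, c(ascending = 1L, transverse = 0L, descending = 0L,
                         rectum = 0L), p_exact = 0.7, bias = 0)$ileum
  }, integer(1L))
  tab <- table(factor(draws, levels = 1:3)) / n
  # law is (0.15, 0.70, 0.15) over {1, 2, 3}
  expect_lt(max(abs(as.numeric(tab) - c(0.15, 0.70, 0.15))), 0.02)
  chisq <- sum((table(factor(draws, levels = 1:3)) -
                  n * c(0.15, 0.70, 0.15))^2 / (n * c(0.15, 0.70, 0.15)))
  expect_lt(chisq, qchisq(0.999, df = 2))
})

test_that("the default study reproduces the layout and severity marginals", {
  st <- generate_study(study_config(seed = 101))
  expect_equal(nrow(st$patients), 110L)
  expect_equal(sum(st$patients$cohort == "pediatric"), 36L)
  expect_equal(nrow(st$truth), 220L)
  # each video carries 2 primary reads by distinct readers
  prim <- st$ratings[st$ratings$occasion %in% c("primary_1", "primary_2"), ]
  expect_equal(nrow(prim), 440L)
  both <- tapply(prim$reader_id, prim$video_id, function(r) length(unique(r)))
  expect_true(all(both == 2L))
  # 15% re-reads
  expect_equal(sum(st$ratings$occasion == "reread"), 33L)
  # baseline severity marginal close to the configured mix
  pre <- st$truth[st$truth$timepoint == "pre", ]
  mix <- table(factor(pre$ses_band, levels = SES_BANDS)) / nrow(pre)
  expect_lt(max(abs(as.numeric(mix) - st$config$severity_mix)), 0.10)
  # SES items are a monotone function of the latent grade map
  expect_true(all(diff(rowSums(SES_ITEM_MAP)) >= 0))
  expect_equal(unname(SES_ITEM_MAP["4", "ulcer_size"]), 3L)
  expect_equal(unname(SES_ITEM_MAP["4", "narrowing"]), 3L)
  expect_true(all(apply(SES_ITEM_MAP, 2, function(col) all(diff(col) >= 0))))
})

test_that("noiseless readers reproduce the truth and never trigger adjudication", {
  st <- generate_study(study_config(seed = 102, p_exact = 1,
                                    p_nonintubation = 0))
  scored <- score_ratings(st$ratings)
  prim <- scored[scored$occasion %in% c("primary_1", "primary_2"), ]
  truth_total <- st$truth$true_sema_total[match(prim$video_id,
                                                st$truth$video_id)]
  expect_equal(prim$sema_total, truth_total)
  expect_equal(sum(scored$occasion == "adjudication"), 0L)
  # positive concordance of the two indices on noiseless data
  res <- resolve_panel(scored, rereads = st$panel$rereads)
  ses <- ses_total(st$ses)
  tau <- cor(res$final_score, ses$total[match(res$video_id, ses$video_id)],
             method = "kendall")
  expect_gt(tau, 0)
  rho <- spearman_ci(res$final_score,
                     ses$total[match(res$video_id, ses$video_id)])
  expect_gt(rho$rho, 0.6)
})

test_that("a null treatment effect centres the change scores at zero", {
  st <- generate_study(study_config(seed = 103, n_patients = 150,
                                    treatment_effect = 0))
  d <- st$truth$true_sema_total[st$truth$timepoint == "post"] -
    st$truth$true_sema_total[st$truth$timepoint == "pre"]
  d <- d[!is.na(d)]
  expect_gt(t.test(d)$p.value, 0.001)
  expect_lt(abs(mean(d)), 1)
})

test_that("identical seeds give byte-identical CSV outputs", {
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  write_study(generate_study(study_config(seed = 104, n_patients = 25)), d1)
  write_study(generate_study(study_config(seed = 104, n_patients = 25)), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("config validation and YAML round trip", {
  expect_error(study_config(), "seed")
  expect_error(study_config(seed = 1, p_exact = 0), "p_exact")
  expect_error(study_config(seed = 1, severity_mix = c(1, 2)), "severity_mix")
  cfg <- study_config(seed = 5, n_patients = 12, treatment_effect = 0.3)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_patients = 12, treatment_effect = 0.3, seed = 5), path)
  cfg2 <- read_study_config(path)
  expect_equal(cfg2$n_patients, cfg$n_patients)
  expect_equal(cfg2$severity_mix, cfg$severity_mix)
  yaml::write_yaml(list(seed = 1, nonsense = 2), path)
  expect_error(read_study_config(path), "unknown config key")
  unlink(path)
})
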