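# SEMA-CD / SES-CD calculators and severity bands

test_that("sema_total reproduces the product-plus-ileum formula on worked cases", {
  expect_equal(sema_total(4, 4, 4)$total, 20)           # maximal disease
  expect_equal(sema_total(0, 0, 0)$total, 0)            # full remission
  expect_equal(sema_total(2, 3, 2)$total, 8)            # 2 + 3*2
  p <- sema_total(NA, 1, 1)                             # non-intubated ileum
  expect_equal(p$total, 1)
  expect_equal(p$colon_component, 1)
  expect_true(p$partial)
  expect_false(p$ileum_assessed)
})

test_that("sema_total rejects invariant-violating ratings with the field named", {
  expect_error(sema_total(3, 3, 0), "involved_segments")
  expect_error(sema_total(1, 0, 2), "involved_segments")
  expect_error(sema_total(1, NA, 1), "involved_segments")
  expect_error(sema_total(5, 0, 0), "ileum")
  expect_error(sema_total(0, 2.5, 1), "colon")
  expect_error(sema_total(0, 0, 7), "n_involved")
})

test_that("exhaustive enumeration: range, extremes and monotonicity of the total", {
  states <- enumerate_sema_states()
  sc <- sema_total(states$ileum, states$colon, states$n_involved)
  full <- !sc$partial
  expect_true(all(sc$total[full] >= 0 & sc$total[full] <= 20))
  expect_equal(max(sc$total[full]), 20)
  expect_equal(min(sc$total[full]), 0)
  # independent arithmetic on every fully assessed state
  expect_equal(sc$total[full],
               states$ileum[full] + states$colon[full] * states$n_involved[full])
  # monotone in the ileum grade at fixed colon state
  for (g in 0:4) for (k in 0:4) {
    if ((g == 0) != (k == 0)) next
    tot <- sema_total(0:4, rep(g, 5), rep(k, 5))$total
    expect_true(all(diff(tot) >= 0))
  }
  # monotone in colon grade at fixed positive involvement, and in involvement
  for (k in 1:4) {
    expect_true(all(diff(sema_total(rep(2, 4), 1:4, rep(k, 4))$total) >= 0))
  }
  for (g in 1:4) {
    expect_true(all(diff(sema_total(rep(2, 4), rep(g, 4), 1:4)$total) >= 0))
  }
})

test_that("involvement flags are permutation-invariant (only the count matters)", {
  base <- data.frame(video_id = "V1", reader_id = "R1", occasion = "primary_1",
                     ileum = 2, colon_overall = 3,
                     seg_ascending = 1, seg_transverse = 0,
                     seg_descending = 0, seg_rectum = 1)
  perm <- base
  perm[, c("seg_ascending", "seg_transverse", "seg_descending", "seg_rectum")] <-
    c(0, 1, 1, 0)
  expect_equal(score_ratings(base)$sema_total, score_ratings(perm)$sema_total)
})

test_that("ses_total sums items over assessed segments and validates input", {
  zero <- data.frame(segment = SES_SEGMENTS, ulcer_size = 0,
                     ulcerated_surface = 0, affected_surface = 0,
                     narrowing = 0, assessed = TRUE)
  expect_equal(ses_total(zero)$total, 0)
  one <- zero
  one[one$segment == "rectum", SES_ITEMS] <- 3
  expect_equal(ses_total(one)$total, 12)
  dup <- rbind(zero, zero[1L, ])
  expect_error(ses_total(dup), "duplicated")
  none <- zero
  none$assessed <- FALSE
  expect_error(ses_total(none), "unassessed")
  bad <- zero
  bad$ulcer_size[1L] <- 4
  expect_error(ses_total(bad), "0..3")
})

test_that("ses_total equals independent brute-force summation on random tables", {
  set.seed(42)
  for (rep in 1:200) {
    tab <- random_ses_table()
    brute <- sum(as.matrix(tab[, SES_ITEMS]))
    res <- ses_total(tab)
    expect_equal(res$total, brute)
    expect_equal(res$n_assessed_segments, nrow(tab))
  }
})

test_that("SEMA-CD bands reproduce the printed integer cutoffs and extend to medians", {
  got <- as.character(classify_sema(0:20))
  want <- c("inactive", "minimal", rep("mild", 3), rep("moderate", 5),
            rep("severe", 11))
  expect_equal(got, want)
  # half-integer medians fall in the half-open interval containing them
  expect_equal(as.character(classify_sema(4.5)), "mild")
  expect_equal(as.character(classify_sema(9.5)), "moderate")
  expect_equal(as.character(classify_sema(1.5)), "minimal")
  expect_error(classify_sema(-0.5), "\\[0, 20\\]")
  expect_error(classify_sema(20.5), "\\[0, 20\\]")
  expect_true(is.na(classify_sema(NA)))
})

test_that("SES-CD bands reproduce the printed integer partition", {
  got <- as.character(classify_ses(0:40))
  want <- c(rep("inactive", 3), rep("mild", 4), rep("moderate", 9),
            rep("severe", 25))
  expect_equal(got, want)
  expect_equal(as.character(classify_ses(37)), "severe")
  expect_error(classify_ses(-1), "non-negative")
})
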