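# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementation.

# weighted kappa by explicit contingency-table evaluation of
# 1 - sum(d*O)/sum(d*E) with disagreement weights d
oracle_weighted_kappa <- function(a, b, cats, scheme = "linear") {
  k <- length(cats)
  O <- matrix(0, k, k)
  for (idx in seq_along(a)) {
    i <- match(a[idx], cats)
    j <- match(b[idx], cats)
    O[i, j] <- O[i, j] + 1
  }
  O <- O / length(a)
  d <- abs(row(O) - col(O)) / (k - 1)
  if (scheme == "quadratic") d <- d^2
  E <- outer(rowSums(O), colSums(O))
  1 - sum(d * O) / sum(d * E)
}

# unweighted Cohen kappa from the diagonal of the contingency table
oracle_unweighted_kappa <- function(a, b, cats) {
  fa <- factor(a, levels = cats)
  fb <- factor(b, levels = cats)
  O <- table(fa, fb) / length(a)
  po <- sum(diag(O))
  pe <- sum(rowSums(O) * colSums(O))
  (po - pe) / (1 - pe)
}

# classical no-ties Spearman rank formula 1 - 6*sum(d^2)/(n(n^2-1))
oracle_spearman_noties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# balanced one-way ICC from aov() mean squares: (MSB-MSW)/(MSB+(k-1)MSW)
oracle_icc_balanced <- function(id, score, k) {
  ms <- summary(stats::aov(score ~ factor(id)))[[1L]][["Mean Sq"]]
  (ms[1L] - ms[2L]) / (ms[1L] + (k - 1) * ms[2L])
}

# a valid random SES-CD findings table for one video
random_ses_table <- function() {
  n_seg <- sample(1:5, 1L)
  segs <- sample(semacd::SES_SEGMENTS, n_seg)
  tab <- data.frame(segment = segs,
                    ulcer_size = sample(0:3, n_seg, replace = TRUE),
                    ulcerated_surface = sample(0:3, n_seg, replace = TRUE),
                    affected_surface = sample(0:3, n_seg, replace = TRUE),
                    narrowing = sample(0:3, n_seg, replace = TRUE),
                    assessed = TRUE)
  tab
}

# every valid fully-specified SEMA-CD rating state (ileum may be NA)
enumerate_sema_states <- function() {
  states <- expand.grid(ileum = c(0:4, NA), colon = 0:4, n_involved = 0:4)
  ok <- (states$colon == 0 & states$n_involved == 0) |
    (states$colon > 0 & states$n_involved > 0)
  states[ok, ]
}

small_config <- function(seed, n_patients = 40, ...) {
  semacd::study_config(n_patients = n_patients, seed = seed, ...)
}
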