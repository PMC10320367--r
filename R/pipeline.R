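# Orchestration: generate -> score -> resolve -> reliability report, mirroring
# a central-reading validation study's Results layout (validity / reliability
# / usability / feasibility) on synthetic data.

.pair_label <- function(a, b) paste(sort(c(a, b)), collapse = "-")

#' Build the full validation report for a synthetic study
#'
#' Scores all reads, resolves the panel (adjudication + median-of-reads),
#' computes per-video SES-CD comparator totals, and assembles: validity
#' (overall, per-cohort, per-baseline-severity-stratum and change-score
#' Spearman correlations of the final median SEMA-CD against SES-CD),
#' reliability (inter-rater one-way ICC, inverse-variance pooled reader-pair
#' mean difference, the pairwise and pooled weighted kappas on the severity
#' bands, intra-rater ICC and mean difference from the re-read subsample),
#' feasibility (correlations by video quality, nonscorable count) and the
#' usability tally. Complete-case throughout; no imputation.
#'
#' @param study a `sema_study_data` object from [generate_study()].
#' @param conf.level confidence level for all intervals, default 0.95.
#' @param kappa_scheme weight scheme for the kappas, `"linear"` (default) or
#'   `"quadratic"`.
#'
#' @return An object of class `sema_study` with elements `validity`,
#'   `reliability`, `feasibility`, `usability`, `provenance`, plus the
#'   per-video analysis table in `data` and the per-patient change table in
#'   `change_data`.
#' @export
study_report <- function(study, conf.level = 0.95,
                         kappa_scheme = c("linear", "quadratic")) {
  kappa_scheme <- match.arg(kappa_scheme)
  if (!inherits(study, "sema_study_data")) {
    stop("study must be a sema_study_data object", call. = FALSE)
  }
  cfg <- study$config
  scored <- score_ratings(study$ratings)
  resolved <- resolve_panel(scored, threshold = cfg$adjudication_threshold,
                            rereads = study$panel$rereads)
  ses <- ses_total(study$ses)
  dat <- data.frame(
    video_id = study$truth$video_id,
    patient_id = study$truth$patient_id,
    timepoint = study$truth$timepoint,
    cohort = study$truth$cohort,
    video_quality = study$truth$video_quality,
    stringsAsFactors = FALSE
  )
  dat$sema <- resolved$final_score[match(dat$video_id, resolved$video_id)]
  dat$adjudicated <- resolved$adjudicated[match(dat$video_id, resolved$video_id)]
  dat$ses <- ses$total[match(dat$video_id, ses$video_id)]
  dat$ses_band <- as.character(classify_ses(dat$ses))

  ## --- validity -----------------------------------------------------------
  overall <- spearman_ci(dat$sema, dat$ses, conf.level = conf.level,
                         stratum = "overall")
  by_cohort <- lapply(c("pediatric", "adult"), function(ch) {
    sub <- dat[dat$cohort == ch, ]
    tryCatch(spearman_ci(sub$sema, sub$ses, conf.level = conf.level,
                         stratum = ch),
             error = function(e) NULL)
  })
  names(by_cohort) <- c("pediatric", "adult")
  pre <- dat[dat$timepoint == "pre", ]
  by_severity <- lapply(SES_BANDS, function(bnd) {
    sub <- pre[pre$ses_band == bnd, ]
    tryCatch(spearman_ci(sub$sema, sub$ses, conf.level = conf.level,
                         stratum = bnd),
             error = function(e) structure(
               list(rho = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    n = nrow(sub), stratum = bnd, meets_threshold = NA,
                    threshold = 0.6, conf.level = conf.level,
                    se_method = "bonett", note = conditionMessage(e)),
               class = "sema_cor"))
  })
  names(by_severity) <- SES_BANDS
  change_tab <- dat[, c("patient_id", "timepoint", "sema", "ses")]
  change <- change_score_correlation(change_tab, conf.level = conf.level)
  pre_rows <- dat[dat$timepoint == "pre", ]
  post_rows <- dat[dat$timepoint == "post", ]
  ids <- intersect(pre_rows$patient_id, post_rows$patient_id)
  change_data <- data.frame(
    patient_id = ids,
    d_sema = post_rows$sema[match(ids, post_rows$patient_id)] -
      pre_rows$sema[match(ids, pre_rows$patient_id)],
    d_ses = post_rows$ses[match(ids, post_rows$patient_id)] -
      pre_rows$ses[match(ids, pre_rows$patient_id)],
    stringsAsFactors = FALSE)

  ## --- inter-rater reliability -------------------------------------------
  long_inter <- data.frame(
    video_id = rep(resolved$video_id, 3L),
    score = c(resolved$total_read1, resolved$total_read2, resolved$total_adjud)
  )
  icc_inter <- icc_oneway(long_inter, conf.level = conf.level)

  asg <- study$panel$assignments
  pair_of <- vapply(seq_len(nrow(asg)), function(i)
    .pair_label(asg$reader_1[i], asg$reader_2[i]), character(1L))
  diff_12 <- resolved$total_read1 - resolved$total_read2
  mean_diff_inter <- pooled_mean_difference(
    split(diff_12, pair_of[match(resolved$video_id, asg$video_id)]),
    conf.level = conf.level)

  # pairwise kappas on the severity bands, fixed reader order within a pair
  prim <- scored[scored$occasion %in% c("primary_1", "primary_2"), ]
  pool <- sort(cfg$reader_pool)
  pairs <- utils::combn(pool, 2L)
  kappas <- list()
  for (j in seq_len(ncol(pairs))) {
    ra <- pairs[1L, j]; rb <- pairs[2L, j]
    vids <- asg$video_id[pair_of == .pair_label(ra, rb)]
    sub <- prim[prim$video_id %in% vids, ]
    a <- sub[sub$reader_id == ra, ]
    b <- sub[sub$reader_id == rb, ]
    common <- intersect(a$video_id, b$video_id)
    ka <- tryCatch(weighted_kappa(
      as.character(a$severity_band[match(common, a$video_id)]),
      as.character(b$severity_band[match(common, b$video_id)]),
      categories = SEMA_BANDS, scheme = kappa_scheme,
      conf.level = conf.level, reader_pair = c(ra, rb)),
      error = function(e) NULL)
    if (!is.null(ka)) kappas[[.pair_label(ra, rb)]] <- ka
  }
  kappa_pooled <- pool_kappas(kappas, conf.level = conf.level)

  ## --- intra-rater reliability -------------------------------------------
  rr <- study$panel$rereads
  reread <- scored[scored$occasion == "reread", ]
  initial <- prim[paste(prim$video_id, prim$reader_id) %in%
                    paste(rr$video_id, rr$reader_id), ]
  key <- paste(rr$video_id, rr$reader_id)
  t_init <- initial$sema_total[match(key, paste(initial$video_id, initial$reader_id))]
  t_re <- reread$sema_total[match(key, paste(reread$video_id, reread$reader_id))]
  ok <- stats::complete.cases(t_init, t_re)
  icc_intra <- icc_oneway(data.frame(
    video_id = rep(key[ok], 2L), score = c(t_init[ok], t_re[ok])),
    conf.level = conf.level)
  mean_diff_intra <- pooled_mean_difference(
    split(t_init[ok] - t_re[ok], rr$reader_id[ok]), conf.level = conf.level)

  ## --- feasibility and usability -----------------------------------------
  by_quality <- lapply(c("optimal", "readable_not_optimal"), function(q) {
    sub <- dat[dat$video_quality == q, ]
    tryCatch(spearman_ci(sub$sema, sub$ses, conf.level = conf.level,
                         stratum = q),
             error = function(e) NULL)
  })
  names(by_quality) <- c("optimal", "readable_not_optimal")
  nonscorable <- sum(is.na(dat$sema))
  us <- table(factor(study$usability$rating, levels = USABILITY_LEVELS))
  usability <- data.frame(rating = names(us), n = as.integer(us),
                          pct = 100 * as.integer(us) / sum(us))

  provenance <- list(seed = cfg$seed, config_hash = .config_hash(cfg),
                     n_patients = cfg$n_patients, n_videos = nrow(dat),
                     n_rating_rows = nrow(study$ratings),
                     adjudication_rate = mean(dat$adjudicated),
                     generated_at = "fixed-seed synthetic study")

  structure(list(
    validity = list(overall = overall, by_cohort = by_cohort,
                    by_severity = by_severity, change = change),
    reliability = list(icc_inter = icc_inter,
                       mean_diff_inter = mean_diff_inter,
                       kappas = kappas, kappa_pooled = kappa_pooled,
                       icc_intra = icc_intra,
                       mean_diff_intra = mean_diff_intra),
    feasibility = list(by_quality = by_quality, nonscorable = nonscorable),
    usability = usability,
    provenance = provenance,
    data = dat, change_data = change_data, resolved = resolved
  ), class = "sema_study")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(config)), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Run the whole pipeline from a configuration
#'
#' Generates the synthetic study, scores and resolves all reads, and builds
#' the validation report. When `out_dir` is given, writes the study CSVs, the
#' resolved table, the report JSON (full precision), the flat statistics
#' table, and the two scatter-plot data files (SEMA-CD vs SES-CD per video;
#' change in SEMA-CD vs change in SES-CD per patient).
#'
#' @param config a [study_config()], or the path of a YAML config file.
#' @param out_dir optional output directory.
#' @param seed optional seed overriding the config's.
#' @return The `sema_study` report, invisibly when `out_dir` is given.
#' @export
run_study <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  if (!is.null(seed)) {
    cfg_args <- unclass(config)
    cfg_args$seed <- as.integer(seed)
    config <- do.call(study_config, cfg_args)
  }
  study <- generate_study(config)
  rep <- study_report(study)
  if (!is.null(out_dir)) {
    write_study(study, out_dir)
    utils::write.csv(rep$resolved, file.path(out_dir, "resolved.csv"),
                     row.names = FALSE)
    write_report(rep, out_dir)
    return(invisible(rep))
  }
  rep
}

#' Flatten a report into one row per statistic
#'
#' @param x a `sema_study` report.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame: `section`, `name`, `estimate`, `ci_low`, `ci_high`,
#'   `n`, `band_or_flag`.
#' @export
as.data.frame.sema_study <- function(x, row.names = NULL, optional = FALSE, ...) {
  row <- function(section, name, est, lo, hi, n, flag) {
    data.frame(section = section, name = name, estimate = est, ci_low = lo,
               ci_high = hi, n = n, band_or_flag = as.character(flag),
               stringsAsFactors = FALSE)
  }
  cor_row <- function(section, name, cc) {
    if (is.null(cc)) return(NULL)
    row(section, name, cc$rho, cc$ci_low, cc$ci_high, cc$n,
        if (isTRUE(cc$meets_threshold)) "meets_0.6" else "below_0.6")
  }
  out <- list(
    cor_row("validity", "spearman_overall", x$validity$overall),
    cor_row("validity", "spearman_pediatric", x$validity$by_cohort$pediatric),
    cor_row("validity", "spearman_adult", x$validity$by_cohort$adult)
  )
  for (bnd in names(x$validity$by_severity)) {
    out <- c(out, list(cor_row("validity", paste0("spearman_", bnd),
                               x$validity$by_severity[[bnd]])))
  }
  out <- c(out, list(
    cor_row("validity", "spearman_change", x$validity$change),
    row("reliability", "icc_inter", x$reliability$icc_inter$icc,
        x$reliability$icc_inter$ci_low, x$reliability$icc_inter$ci_high,
        x$reliability$icc_inter$n_groups, x$reliability$icc_inter$band),
    row("reliability", "mean_diff_inter", x$reliability$mean_diff_inter$mean_diff,
        x$reliability$mean_diff_inter$ci_low, x$reliability$mean_diff_inter$ci_high,
        sum(x$reliability$mean_diff_inter$strata$n), ""),
    row("reliability", "icc_intra", x$reliability$icc_intra$icc,
        x$reliability$icc_intra$ci_low, x$reliability$icc_intra$ci_high,
        x$reliability$icc_intra$n_groups, x$reliability$icc_intra$band),
    row("reliability", "mean_diff_intra", x$reliability$mean_diff_intra$mean_diff,
        x$reliability$mean_diff_intra$ci_low, x$reliability$mean_diff_intra$ci_high,
        sum(x$reliability$mean_diff_intra$strata$n), "")
  ))
  for (nm in names(x$reliability$kappas)) {
    ka <- x$reliability$kappas[[nm]]
    out <- c(out, list(row("reliability", paste0("kappa_", nm), ka$kappa,
                           ka$ci_low, ka$ci_high, ka$n, ka$band)))
  }
  kp <- x$reliability$kappa_pooled
  out <- c(out, list(
    row("reliability", "kappa_pooled", kp$kappa, kp$ci_low, kp$ci_high, kp$n,
        kp$band),
    cor_row("feasibility", "spearman_optimal", x$feasibility$by_quality$optimal),
    cor_row("feasibility", "spearman_readable_not_optimal",
            x$feasibility$by_quality$readable_not_optimal),
    row("feasibility", "nonscorable_videos", x$feasibility$nonscorable,
        NA_real_, NA_real_, nrow(x$data), "")
  ))
  res <- do.call(rbind, Filter(Negate(is.null), out))
  rownames(res) <- NULL
  res
}

#' @export
print.sema_study <- function(x, digits = 2, ...) {
  cat("Multi-reader validation report (synthetic study)\n")
  cat(sprintf("  %d patients, %d videos, adjudication rate %.1f%%, seed %d\n",
              x$provenance$n_patients, x$provenance$n_videos,
              100 * x$provenance$adjudication_rate, x$provenance$seed))
  cat("Validity\n  "); print(x$validity$overall, digits = digits)
  cat("  "); print(x$validity$change, digits = digits)
  cat("Reliability\n  "); print(x$reliability$icc_inter, digits = digits)
  cat("  "); print(x$reliability$icc_intra, digits = digits)
  cat("  "); print(x$reliability$kappa_pooled, digits = digits)
  easier <- sum(x$usability$pct[x$usability$rating %in%
                                  c("much_easier", "somewhat_easier", "slightly_easier")])
  cat(sprintf("Usability: rated easier %.1f%% of readings\n", easier))
  invisible(x)
}

#' @export
summary.sema_study <- function(object, digits = 2, ...) {
  tab <- as.data.frame(object)
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(tab)
}

#' @export
plot.sema_study <- function(x, which = c("scores", "change"), ...) {
  which <- match.arg(which)
  if (which == "scores") {
    plot(x$data$ses, x$data$sema, xlab = "SES-CD total",
         ylab = "SEMA-CD final (median of reads)",
         main = sprintf("rho = %.2f", x$validity$overall$rho), ...)
  } else {
    plot(x$change_data$d_ses, x$change_data$d_sema,
         xlab = "Change in SES-CD", ylab = "Change in SEMA-CD",
         main = sprintf("rho = %.2f", x$validity$change$rho), ...)
    abline(h = 0, v = 0, col = "grey70", lty = 2)
  }
  invisible(x)
}

#' Write a report to disk
#'
#' Writes `report.json` (full precision), `report_table.csv` (the flat
#' statistics table, display-rounded to 2 decimals), and the scatter data
#' files `scatter_scores.csv` and `scatter_change.csv`.
#'
#' @param report a `sema_study` report.
#' @param dir output directory (created if needed).
#' @return invisibly, the report JSON path.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- as.data.frame(report)
  json <- list(
    statistics = tab,
    usability = report$usability,
    provenance = report$provenance,
    banding = list(
      icc = "poor <0.50; moderate [0.50,0.75); good [0.75,0.90]; excellent >0.90",
      kappa = "below_moderate <0.41; moderate [0.41,0.60]; good (0.60,0.80]; very_good >0.80",
      sema_bands = "inactive [0,1); minimal [1,2); mild [2,5); moderate [5,10); severe [10,20]",
      ses_bands = "inactive 0-2; mild 3-6; moderate 7-15; severe >=16"
    )
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA, na = "null")
  disp <- tab
  num <- vapply(disp, is.numeric, logical(1L))
  disp[num] <- lapply(disp[num], round, digits = 2)
  utils::write.csv(disp, file.path(dir, "report_table.csv"), row.names = FALSE)
  utils::write.csv(report$data[, c("video_id", "cohort", "timepoint",
                                   "video_quality", "sema", "ses")],
                   file.path(dir, "scatter_scores.csv"), row.names = FALSE)
  utils::write.csv(report$change_data, file.path(dir, "scatter_change.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a ratings CSV
#'
#' One row per video x reader x read occasion; `ileum` and `colon_overall`
#' accept `NA` for not-assessed regions.
#'
#' @param path CSV path.
#' @return data.frame in the ratings schema.
#' @export
read_ratings_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Score a ratings CSV file
#'
#' Reads a ratings CSV, appends `sema_total` and `severity_band` (plus
#' `n_involved` and the partial flag) and writes the scored CSV. Rows
#' violating the scoring invariants abort with a row-indexed message.
#'
#' @param in_csv input ratings CSV.
#' @param out_csv output path.
#' @return invisibly, the scored data.frame.
#' @export
score_file <- function(in_csv, out_csv) {
  ratings <- read_ratings_csv(in_csv)
  scored <- score_ratings(ratings)
  utils::write.csv(scored, out_csv, row.names = FALSE)
  invisible(scored)
}

#' Resolve a scored ratings CSV file
#'
#' @param in_csv scored ratings CSV (from [score_file()]).
#' @param out_csv output path for the resolved per-video table.
#' @param threshold adjudication margin, default 5.
#' @return invisibly, the resolved data.frame.
#' @export
resolve_file <- function(in_csv, out_csv, threshold = 5) {
  scored <- utils::read.csv(in_csv, stringsAsFactors = FALSE)
  resolved <- resolve_panel(scored, threshold = threshold)
  utils::write.csv(resolved, out_csv, row.names = FALSE)
  invisible(resolved)
}
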