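# Synthetic two-cohort ileocolonoscopy study: latent per-patient severity
# drives ordinal pathology in 5 bowel segments (ileum + 4 colonic) via a
# cumulative-threshold model; professional central readers are emulated by an
# ordinal misclassification model at the region level. Everything downstream
# (scoring, panel resolution, reliability statistics) runs on the output.

#' Monotone map from a segment grade to SES-CD items
#'
#' Fixed tabulated map used by the generator to derive SES-CD findings from
#' the true ordinal segment grade (0-4): item values never decrease with
#' grade; grade 0 is all-zero, grade 4 reaches maximal ulcer size and a
#' non-passable stricture.
#'
#' @format Integer matrix, one row per grade 0-4, columns [SES_ITEMS].
#' @export
SES_ITEM_MAP <- matrix(
  c(0L, 0L, 0L, 0L,
    1L, 0L, 1L, 0L,
    2L, 1L, 2L, 1L,
    3L, 2L, 3L, 2L,
    3L, 3L, 3L, 3L),
  nrow = 5L, byrow = TRUE,
  dimnames = list(grade = 0:4,
                  item = c("ulcer_size", "ulcerated_surface",
                           "affected_surface", "narrowing")))

#' Usability-scale levels (ease of scoring relative to the comparator)
#' @format Character vector of the 7 scale levels.
#' @export
USABILITY_LEVELS <- c("much_easier", "somewhat_easier", "slightly_easier",
                      "equal", "slightly_more_difficult",
                      "somewhat_more_difficult", "much_more_difficult")

# latent-scale proposal intervals per baseline severity band; the band is
# enforced by rejection on the realized SES-CD total
.BAND_THETA <- list(inactive = c(-0.8, 0.4), mild = c(0.2, 1.1),
                    moderate = c(0.8, 2.0), severe = c(1.6, 4.0))

#' Configuration of a synthetic validation study
#'
#' Defaults emulate the validation study layout: 110 patients (36 pediatric,
#' 74 adult), pre- and post-treatment videos, a 4-reader central pool with two
#' blinded reads per video, adjudication above a 5-point disagreement, a 15%
#' re-read subsample, a baseline severity mix of 4.5 / 19.1 / 40.9 / 35.5%
#' (inactive / mild / moderate / severe by SES-CD band), 48.2% optimal-quality
#' videos, and 2% ileum non-intubation.
#'
#' @param n_patients number of patients (default 110).
#' @param prop_pediatric fraction of pediatric patients (default 36/110).
#' @param severity_mix probabilities of the baseline SES-CD bands, in the
#'   order of [SES_BANDS]; normalized to sum to 1.
#' @param treatment_effect mean latent improvement pre to post (standardized
#'   latent units; default 0.8), with standard deviation `effect_sd`
#'   (default 0.6), truncated so the post latent stays in the support.
#' @param p_exact per-reader probability of reproducing a region grade
#'   exactly (scalar or one value per reader; default 0.8); with probability
#'   `1 - p_exact` the grade moves one step, clipped to 0-4.
#' @param bias per-reader direction bias of the one-step error in `[-1, 1]`
#'   (0 = symmetric; default 0).
#' @param reader_pool reader identifiers (default `R1`-`R4`).
#' @param reread_fraction fraction of videos re-read (default 0.15).
#' @param adjudication_threshold disagreement margin triggering the third
#'   read (default 5, strict inequality).
#' @param p_optimal probability a video is "optimal" quality (default 0.482),
#'   else "readable_not_optimal".
#' @param p_nonintubation probability the ileum is not intubated (default
#'   0.02); such videos carry a not-assessed ileum.
#' @param segment_sd SD of the ordinal jitter added per segment draw
#'   (default 0.5).
#' @param offset_sd SD of the per-patient, per-segment latent offsets that
#'   create ileum-only / colon-only involvement patterns (default 0.7).
#' @param usability_probs probabilities over [USABILITY_LEVELS] (default:
#'   most readings easier, ~zero more difficult).
#' @param seed integer RNG seed (mandatory: every run is reproducible).
#'
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_patients = 110,
                         prop_pediatric = 36 / 110,
                         severity_mix = c(inactive = 0.045, mild = 0.191,
                                          moderate = 0.409, severe = 0.355),
                         treatment_effect = 0.8,
                         effect_sd = 0.6,
                         p_exact = 0.8,
                         bias = 0,
                         reader_pool = paste0("R", 1:4),
                         reread_fraction = 0.15,
                         adjudication_threshold = 5,
                         p_optimal = 0.482,
                         p_nonintubation = 0.02,
                         segment_sd = 0.5,
                         offset_sd = 0.7,
                         usability_probs = c(much_easier = 0.21,
                                             somewhat_easier = 0.21,
                                             slightly_easier = 0.21,
                                             equal = 0.366,
                                             slightly_more_difficult = 0.004,
                                             somewhat_more_difficult = 0,
                                             much_more_difficult = 0),
                         seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  if (prop_pediatric < 0 || prop_pediatric > 1) stop("prop_pediatric in [0,1]", call. = FALSE)
  if (length(severity_mix) != 4 || any(severity_mix < 0) || sum(severity_mix) <= 0) {
    stop("severity_mix: 4 non-negative probabilities over the SES-CD bands",
         call. = FALSE)
  }
  severity_mix <- severity_mix / sum(severity_mix)
  names(severity_mix) <- SES_BANDS
  nr <- length(reader_pool)
  if (nr < 3) stop("reader_pool: need at least 3 readers", call. = FALSE)
  p_exact <- rep_len(p_exact, nr)
  bias <- rep_len(bias, nr)
  if (any(p_exact <= 0) || any(p_exact > 1)) stop("p_exact in (0, 1]", call. = FALSE)
  if (any(abs(bias) > 1)) stop("bias in [-1, 1]", call. = FALSE)
  if (length(usability_probs) != 7 || any(usability_probs < 0) ||
      sum(usability_probs) <= 0) {
    stop("usability_probs: 7 non-negative probabilities", call. = FALSE)
  }
  usability_probs <- usability_probs / sum(usability_probs)
  names(usability_probs) <- USABILITY_LEVELS
  structure(list(
    n_patients = as.integer(n_patients), prop_pediatric = prop_pediatric,
    severity_mix = severity_mix, treatment_effect = treatment_effect,
    effect_sd = effect_sd,
    p_exact = stats::setNames(p_exact, reader_pool),
    bias = stats::setNames(bias, reader_pool),
    reader_pool = reader_pool, reread_fraction = reread_fraction,
    adjudication_threshold = adjudication_threshold,
    p_optimal = p_optimal, p_nonintubation = p_nonintubation,
    segment_sd = segment_sd, offset_sd = offset_sd,
    usability_probs = usability_probs, seed = as.integer(seed)
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose keys are [study_config()] arguments (`seed`
#'   required).
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  for (k in c("severity_mix", "usability_probs", "p_exact", "bias")) {
    if (!is.null(vals[[k]])) vals[[k]] <- unlist(vals[[k]])
  }
  do.call(study_config, vals)
}

# ordinal segment grade from latent severity: count of thresholds 1..4
# exceeded by theta + patient-segment offset + draw-level jitter
.draw_grades <- function(theta, offsets, segment_sd) {
  lat <- theta + offsets + stats::rnorm(length(offsets), 0, segment_sd)
  vapply(lat, function(v) sum(v > 1:4), numeric(1L))
}

.ses_items_of_grades <- function(grades) SES_ITEM_MAP[grades + 1L, , drop = FALSE]

.ses_total_of_grades <- function(grades) sum(SES_ITEM_MAP[grades + 1L, ])

#' Perturb a true region-level rating with ordinal reader noise
#'
#' Each assessed region grade is reproduced exactly with probability
#' `p_exact`, otherwise moved one step (direction biased by `bias`, up with
#' probability `(1 + bias)/2`) and clipped to 0-4. The colon is perturbed as a
#' region: the one-step shift applies to every involved segment's implied
#' grade, involvement flags follow (a segment is flagged iff its perturbed
#' implied grade is positive), and the overall colon grade is the maximum. A
#' reader upgrading a disease-free colon flags a single random segment. A
#' not-assessed ileum is never perturbed.
#'
#' @param ileum true ileum grade 0-4 or `NA` (not assessed).
#' @param colon_segments named integer vector of the 4 true colonic segment
#'   grades (names among [SEMA_COLON_SEGMENTS]).
#' @param p_exact probability of exact reproduction, in (0, 1].
#' @param bias error-direction bias in `[-1, 1]`.
#'
#' @return list with `ileum`, `colon_overall`, `involved` (logical vector
#'   over [SEMA_COLON_SEGMENTS]), `segment_grades` (perturbed implied grades).
#' @export
perturb_rating <- function(ileum, colon_segments, p_exact = 0.8, bias = 0) {
  stopifnot(length(colon_segments) == 4L)
  if (is.null(names(colon_segments))) names(colon_segments) <- SEMA_COLON_SEGMENTS
  step <- function() {
    if (stats::runif(1) < p_exact) 0L
    else sample(c(-1L, 1L), 1L, prob = c((1 - bias) / 2, (1 + bias) / 2))
  }
  out_ileum <- if (is.na(ileum)) NA_integer_ else
    min(max(ileum + step(), 0L), 4L)
  seg <- colon_segments
  if (all(seg == 0)) {
    d <- step()
    seg_pert <- rep(0L, 4L)
    if (d > 0) seg_pert[sample.int(4L, 1L)] <- 1L
  } else {
    d <- step()
    seg_pert <- ifelse(seg > 0, pmin(pmax(seg + d, 0L), 4L), 0L)
  }
  names(seg_pert) <- names(colon_segments)
  involved <- seg_pert > 0
  list(ileum = out_ileum, colon_overall = max(seg_pert), involved = involved,
       segment_grades = seg_pert)
}

#' Generate a complete synthetic validation study
#'
#' Draws latent patient severities targeted at the configured baseline
#' severity mix (by rejection on the realized baseline SES-CD band), segment
#' pathology for pre- and post-treatment videos, SES-CD findings via the
#' fixed [SES_ITEM_MAP], true SEMA-CD region grades, a reader-panel
#' assignment, noisy reader ratings with adjudication and re-reads, video
#' quality labels, and per-reading usability ratings. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [study_config()] object.
#'
#' @return An object of class `sema_study_data`: list with data.frames
#'   `patients`, `truth` (per video: latent severity, true grades, true
#'   SEMA-CD and SES-CD totals), `ses` (per video x segment findings),
#'   `ratings` (per video x reader x occasion, the scoring CSV schema),
#'   `usability`, the `panel` assignment, and `config`.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "study_config")) stop("config must be a study_config", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_patients
  n_ped <- round(config$prop_pediatric * n)
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    cohort = c(rep("pediatric", n_ped), rep("adult", n - n_ped)),
    stringsAsFactors = FALSE
  )
  band <- sample(SES_BANDS, n, replace = TRUE, prob = config$severity_mix)
  offsets <- matrix(stats::rnorm(n * 5L, 0, config$offset_sd), nrow = n,
                    dimnames = list(NULL, SES_SEGMENTS))

  # baseline latent severity + segment grades, rejection-matched to the band
  theta_pre <- numeric(n)
  grades_pre <- matrix(0L, n, 5L, dimnames = list(NULL, SES_SEGMENTS))
  for (i in seq_len(n)) {
    lim <- .BAND_THETA[[band[i]]]
    for (try in 1:60) {
      th <- stats::runif(1, lim[1L], lim[2L])
      g <- .draw_grades(th, offsets[i, ], config$segment_sd)
      if (as.character(classify_ses(.ses_total_of_grades(g))) == band[i]) break
    }
    theta_pre[i] <- th
    grades_pre[i, ] <- g
  }
  improvement <- stats::rnorm(n, config$treatment_effect, config$effect_sd)
  theta_post <- pmax(theta_pre - improvement, -1)
  grades_post <- t(vapply(seq_len(n), function(i) {
    .draw_grades(theta_post[i], offsets[i, ], config$segment_sd)
  }, numeric(5L)))
  colnames(grades_post) <- SES_SEGMENTS

  patients$band_target <- band
  patients$theta_pre <- theta_pre
  patients$theta_post <- theta_post

  # per-video tables
  videos <- data.frame(
    video_id = c(sprintf("%s_pre", patients$patient_id),
                 sprintf("%s_post", patients$patient_id)),
    patient_id = rep(patients$patient_id, 2L),
    timepoint = rep(c("pre", "post"), each = n),
    cohort = rep(patients$cohort, 2L),
    theta = c(theta_pre, theta_post),
    stringsAsFactors = FALSE
  )
  grades <- rbind(grades_pre, grades_post)
  nonintubated <- stats::runif(nrow(videos)) < config$p_nonintubation
  quality <- ifelse(stats::runif(nrow(videos)) < config$p_optimal,
                    "optimal", "readable_not_optimal")

  # SES-CD findings (items NA and assessed = FALSE for a non-intubated ileum)
  ses <- do.call(rbind, lapply(seq_len(nrow(videos)), function(v) {
    items <- .ses_items_of_grades(grades[v, ])
    df <- data.frame(video_id = videos$video_id[v], segment = SES_SEGMENTS,
                     items, assessed = TRUE, row.names = NULL,
                     stringsAsFactors = FALSE)
    if (nonintubated[v]) {
      df[df$segment == "ileum", SES_ITEMS] <- NA_integer_
      df$assessed[df$segment == "ileum"] <- FALSE
    }
    df
  }))
  rownames(ses) <- NULL

  colon_idx <- match(c("right_colon", "transverse_colon", "left_colon", "rectum"),
                     SES_SEGMENTS)
  true_ileum <- ifelse(nonintubated, NA_integer_, grades[, "ileum"])
  colon_grades <- grades[, colon_idx, drop = FALSE]
  colnames(colon_grades) <- SEMA_COLON_SEGMENTS
  true_colon <- apply(colon_grades, 1L, max)
  true_ninv <- rowSums(colon_grades > 0)
  true_sema <- sema_total(true_ileum, true_colon, true_ninv)
  true_ses <- vapply(seq_len(nrow(videos)), function(v) {
    g <- grades[v, ]
    keep <- if (nonintubated[v]) SES_SEGMENTS != "ileum" else rep(TRUE, 5L)
    sum(SES_ITEM_MAP[g[keep] + 1L, ])
  }, numeric(1L))

  truth <- cbind(videos, data.frame(
    true_ileum = true_ileum,
    true_seg_ascending = colon_grades[, "ascending"],
    true_seg_transverse = colon_grades[, "transverse"],
    true_seg_descending = colon_grades[, "descending"],
    true_seg_rectum = colon_grades[, "rectum"],
    true_colon_overall = true_colon,
    true_n_involved = true_ninv, true_sema_total = true_sema$total,
    true_ses_total = true_ses, ses_band = as.character(classify_ses(true_ses)),
    video_quality = quality, stringsAsFactors = FALSE
  ))

  panel <- assign_panel(videos$video_id, config$reader_pool,
                        config$reread_fraction, seed = NULL)

  one_read <- function(v, reader, occasion) {
    p <- perturb_rating(true_ileum[v], colon_grades[v, ],
                        config$p_exact[[reader]], config$bias[[reader]])
    flags <- as.integer(p$involved)
    data.frame(video_id = videos$video_id[v], patient_id = videos$patient_id[v],
               timepoint = videos$timepoint[v], reader_id = reader,
               occasion = occasion, ileum = p$ileum,
               colon_overall = p$colon_overall,
               seg_ascending = flags[1L], seg_transverse = flags[2L],
               seg_descending = flags[3L], seg_rectum = flags[4L],
               video_quality = quality[v], stringsAsFactors = FALSE)
  }
  read_total <- function(row) {
    sema_total(row$ileum, row$colon_overall,
               row$seg_ascending + row$seg_transverse + row$seg_descending +
                 row$seg_rectum)$total
  }

  asg <- panel$assignments
  ratings <- vector("list", nrow(videos))
  for (v in seq_len(nrow(videos))) {
    r1 <- one_read(v, asg$reader_1[v], "primary_1")
    r2 <- one_read(v, asg$reader_2[v], "primary_2")
    t1 <- read_total(r1); t2 <- read_total(r2)
    rows <- rbind(r1, r2)
    if (!is.na(t1) && !is.na(t2) &&
        abs(t1 - t2) > config$adjudication_threshold) {
      rows <- rbind(rows, one_read(v, asg$adjudicator[v], "adjudication"))
    }
    ratings[[v]] <- rows
  }
  ratings <- do.call(rbind, ratings)
  if (nrow(panel$rereads)) {
    reread_rows <- do.call(rbind, lapply(seq_len(nrow(panel$rereads)), function(j) {
      v <- match(panel$rereads$video_id[j], videos$video_id)
      one_read(v, panel$rereads$reader_id[j], "reread")
    }))
    ratings <- rbind(ratings, reread_rows)
  }
  rownames(ratings) <- NULL

  usability <- data.frame(
    video_id = ratings$video_id, reader_id = ratings$reader_id,
    occasion = ratings$occasion,
    rating = sample(USABILITY_LEVELS, nrow(ratings), replace = TRUE,
                    prob = config$usability_probs),
    stringsAsFactors = FALSE
  )

  structure(list(patients = patients, truth = truth, ses = ses,
                 ratings = ratings, usability = usability, panel = panel,
                 config = config),
            class = "sema_study_data")
}

#' @export
print.sema_study_data <- function(x, ...) {
  cat("Synthetic validation study\n")
  cat("  patients:", nrow(x$patients),
      sprintf("(%d pediatric / %d adult)\n",
              sum(x$patients$cohort == "pediatric"),
              sum(x$patients$cohort == "adult")))
  cat("  videos:", nrow(x$truth), " rating rows:", nrow(x$ratings), "\n")
  cat("  baseline severity mix:",
      paste(capture_mix(x), collapse = "  "), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

capture_mix <- function(x) {
  pre <- x$truth[x$truth$timepoint == "pre", ]
  tab <- table(factor(pre$ses_band, levels = SES_BANDS))
  sprintf("%s=%.1f%%", names(tab), 100 * tab / sum(tab))
}

#' Write the study tables as CSV files
#'
#' Writes `ratings.csv`, `ses.csv`, `truth.csv`, `patients.csv`,
#' `usability.csv` and `rereads.csv` into `dir`. Byte-identical output for
#' identical seeds.
#'
#' @param study a `sema_study_data` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(ratings = "ratings.csv", ses = "ses.csv", truth = "truth.csv",
             patients = "patients.csv", usability = "usability.csv")
  for (nm in names(files)) {
    utils::write.csv(study[[nm]], file.path(dir, files[[nm]]), row.names = FALSE)
  }
  utils::write.csv(study$panel$rereads, file.path(dir, "rereads.csv"),
                   row.names = FALSE)
  cfg <- unclass(study$config)
  cfg <- lapply(cfg, function(v) if (is.numeric(v)) unname(v) else v)
  cfg$severity_mix <- as.list(study$config$severity_mix)
  cfg$usability_probs <- as.list(study$config$usability_probs)
  cfg$p_exact <- as.list(study$config$p_exact)
  cfg$bias <- as.list(study$config$bias)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(file.path(dir, c(files, "rereads.csv", "config.yaml")))
}

#' Read a study back from a directory of CSVs
#'
#' Reconstructs a `sema_study_data` object from the files written by
#' [write_study()] (the panel assignment is rebuilt from the primary and
#' adjudication reads), so a report can be produced from a directory handoff.
#'
#' @param dir directory containing `ratings.csv`, `ses.csv`, `truth.csv`,
#'   `patients.csv`, `usability.csv`, `rereads.csv` and `config.yaml`.
#' @return A `sema_study_data` object.
#' @export
read_study <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  config <- read_study_config(file.path(dir, "config.yaml"))
  ratings <- rd("ratings.csv")
  vids <- unique(ratings$video_id)
  reader_of <- function(occ) {
    sub <- ratings[ratings$occasion == occ, ]
    sub$reader_id[match(vids, sub$video_id)]
  }
  panel <- structure(list(
    assignments = data.frame(video_id = vids,
                             reader_1 = reader_of("primary_1"),
                             reader_2 = reader_of("primary_2"),
                             adjudicator = reader_of("adjudication"),
                             stringsAsFactors = FALSE),
    rereads = rd("rereads.csv"),
    reader_pool = config$reader_pool
  ), class = "panel_assignment")
  structure(list(patients = rd("patients.csv"), truth = rd("truth.csv"),
                 ses = rd("ses.csv"), ratings = ratings,
                 usability = rd("usability.csv"), panel = panel,
                 config = config),
            class = "sema_study_data")
}
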