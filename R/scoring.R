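# Index definitions: SEMA-CD (ileum grade 0-4 plus overall colon grade 0-4
# multiplied by the number of involved colonic segments; range 0-20) and its
# comparator SES-CD (4 items, each 0-3, summed over 5 bowel segments).
# "Not assessed" regions are encoded as NA throughout.

#' Colonic segments recorded on the SEMA-CD case report form
#' @format Character vector of the four colonic segments.
#' @export
SEMA_COLON_SEGMENTS <- c("ascending", "transverse", "descending", "rectum")

#' Bowel segments of the SES-CD
#' @format Character vector of the five SES-CD segments.
#' @export
SES_SEGMENTS <- c("ileum", "right_colon", "transverse_colon", "left_colon", "rectum")

#' Item columns of an SES-CD findings table
#' @format Character vector of the four per-segment items.
#' @export
SES_ITEMS <- c("ulcer_size", "ulcerated_surface", "affected_surface", "narrowing")

#' SEMA-CD severity bands
#'
#' A-priori candidate cutoffs for the 0-20 SEMA-CD total: 0 inactive,
#' 1 minimal, 2-4 mild, 5-9 moderate, >=10 severe. Realized as half-open real
#' intervals so that half-integer medians of two reads classify
#' deterministically; on integers the printed integer bands are reproduced.
#' @format Character vector of the five band labels, ordered by severity.
#' @export
SEMA_BANDS <- c("inactive", "minimal", "mild", "moderate", "severe")

#' SES-CD severity bands
#'
#' Bands on the SES-CD total: 0-2 inactive, 3-6 mild, 7-15 moderate,
#' >=16 severe.
#' @format Character vector of the four band labels, ordered by severity.
#' @export
SES_BANDS <- c("inactive", "mild", "moderate", "severe")

.check_grade <- function(x, field) {
  bad <- !is.na(x) & (!is.finite(x) | x != round(x) | x < 0 | x > 4)
  if (any(bad)) {
    stop(sprintf("%s: grade must be an integer in 0..4 or NA (not assessed); offending value(s): %s",
                 field, paste(utils::head(x[bad], 3L), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Compute SEMA-CD totals
#'
#' The colon component is the overall colon grade (the grade of the most
#' severe colonic segment) multiplied by the number of colonic segments with
#' any active disease; the ileum grade is added to it. Strictures of the
#' ileocecal valve are scored within the ileum grade upstream; non-intubation
#' of the ileum without stricture is recorded as not assessed (`NA`), in which
#' case the total is the colon component alone and is flagged partial.
#'
#' @param ileum integer vector of ileum grades, 0-4 or `NA` (not assessed).
#' @param colon integer vector of overall colon grades, 0-4 or `NA`.
#' @param n_involved integer vector, number of involved colonic segments
#'   (0-4). Must be 0 exactly when `colon` is 0 or `NA`, and at least 1 when
#'   `colon` is 1-4 (the overall grade is the worst involved segment's grade).
#'
#' @return A data.frame with one row per rating: `ileum_component`,
#'   `colon_component`, `total`, `ileum_assessed`, `colon_assessed`,
#'   `partial`. `total` is `NA` only when both regions are unassessed
#'   (a nonscorable video).
#'
#' @examples
#' sema_total(ileum = 4, colon = 4, n_involved = 4)      # maximal disease: 20
#' sema_total(ileum = 2, colon = 3, n_involved = 2)      # 2 + 3*2 = 8
#' sema_total(ileum = NA, colon = 1, n_involved = 1)     # partial, total 1
#' @export
sema_total <- function(ileum, colon, n_involved) {
  n <- max(length(ileum), length(colon), length(n_involved))
  ileum <- rep_len(as.numeric(ileum), n)
  colon <- rep_len(as.numeric(colon), n)
  n_involved <- rep_len(as.numeric(n_involved), n)
  .check_grade(ileum, "ileum")
  .check_grade(colon, "colon")
  if (any(is.na(n_involved) | n_involved != round(n_involved) |
          n_involved < 0 | n_involved > 4)) {
    stop("n_involved: must be an integer in 0..4", call. = FALSE)
  }
  zero_mismatch <- !is.na(colon) & colon == 0 & n_involved > 0
  if (any(zero_mismatch)) {
    stop("involved_segments: segments flagged while colon grade is 0 (row ",
         paste(utils::head(which(zero_mismatch), 3L), collapse = ", "), ")",
         call. = FALSE)
  }
  pos_mismatch <- !is.na(colon) & colon > 0 & n_involved == 0
  if (any(pos_mismatch)) {
    stop("involved_segments: colon grade > 0 requires at least one involved segment (row ",
         paste(utils::head(which(pos_mismatch), 3L), collapse = ", "), ")",
         call. = FALSE)
  }
  na_mismatch <- is.na(colon) & n_involved > 0
  if (any(na_mismatch)) {
    stop("involved_segments: segments flagged while colon is not assessed (row ",
         paste(utils::head(which(na_mismatch), 3L), collapse = ", "), ")",
         call. = FALSE)
  }
  colon_component <- colon * n_involved
  ileum_assessed <- !is.na(ileum)
  colon_assessed <- !is.na(colon)
  total <- ifelse(ileum_assessed & colon_assessed, ileum + colon_component,
                  ifelse(ileum_assessed, ileum,
                         ifelse(colon_assessed, colon_component, NA_real_)))
  data.frame(
    ileum_component = ileum,
    colon_component = colon_component,
    total = total,
    ileum_assessed = ileum_assessed,
    colon_assessed = colon_assessed,
    partial = !(ileum_assessed & colon_assessed)
  )
}

#' Compute SES-CD totals from a segment-level findings table
#'
#' Plain sum of the four items (ulcer size, ulcerated surface, affected
#' surface, narrowing; each 0-3) over assessed segments. No renormalization is
#' applied for unassessed segments.
#'
#' @param items data.frame with columns `segment` (values among
#'   [SES_SEGMENTS]), the four item columns of [SES_ITEMS], and logical
#'   `assessed`. At most one row per segment. If a `video_id` column is
#'   present, totals are computed per video.
#'
#' @return A data.frame with columns `total` and `n_assessed_segments` (plus
#'   `video_id` when grouped). Errors on a duplicated segment, out-of-range
#'   items in an assessed segment, or a video with no assessed segment.
#'
#' @examples
#' tab <- data.frame(segment = SES_SEGMENTS, ulcer_size = 0,
#'                   ulcerated_surface = 0, affected_surface = 0,
#'                   narrowing = 0, assessed = TRUE)
#' ses_total(tab)   # total 0
#' @export
ses_total <- function(items) {
  need <- c("segment", SES_ITEMS, "assessed")
  miss <- setdiff(need, names(items))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(items$segment %in% SES_SEGMENTS)) {
    stop("segment: values must be among ", paste(SES_SEGMENTS, collapse = ", "), call. = FALSE)
  }
  if (is.null(items$video_id)) {
    one <- .ses_total_one(items)
    return(data.frame(total = one[1L], n_assessed_segments = one[2L]))
  }
  split_tab <- split(items, items$video_id)
  res <- t(vapply(split_tab, .ses_total_one, numeric(2L)))
  data.frame(video_id = names(split_tab), total = res[, 1L],
             n_assessed_segments = res[, 2L], row.names = NULL)
}

.ses_total_one <- function(tab) {
  if (anyDuplicated(tab$segment)) {
    stop("segment: duplicated segment record for '",
         tab$segment[duplicated(tab$segment)][1L], "'", call. = FALSE)
  }
  assessed <- as.logical(tab$assessed)
  if (!any(assessed)) stop("all segments unassessed: SES-CD total undefined", call. = FALSE)
  vals <- as.matrix(tab[assessed, SES_ITEMS, drop = FALSE])
  if (any(is.na(vals)) || any(vals != round(vals)) || any(vals < 0) || any(vals > 3)) {
    stop("items: each SES-CD item of an assessed segment must be an integer in 0..3",
         call. = FALSE)
  }
  c(sum(vals), sum(assessed))
}

#' Classify a SEMA-CD total into a severity band
#'
#' Bands are half-open real intervals `[0,1)` inactive, `[1,2)` minimal,
#' `[2,5)` mild, `[5,10)` moderate, `[10,20]` severe, so that half-integer
#' medians of two reads classify deterministically while integer totals
#' reproduce the printed integer cutoffs (0; 1; 2-4; 5-9; >=10).
#'
#' @param total numeric vector of SEMA-CD totals in `[0, 20]`; half-integers
#'   (medians of two reads) allowed. `NA` propagates.
#' @return factor with levels [SEMA_BANDS].
#' @examples
#' classify_sema(c(0, 1, 4, 4.5, 9, 10, 20))
#' @export
classify_sema <- function(total) {
  total <- as.numeric(total)
  ok <- is.na(total) | (is.finite(total) & total >= 0 & total <= 20)
  if (!all(ok)) stop("total: SEMA-CD total must lie in [0, 20]", call. = FALSE)
  cut(total, breaks = c(0, 1, 2, 5, 10, 20), labels = SEMA_BANDS,
      right = FALSE, include.lowest = TRUE)
}

#' Classify an SES-CD total into a severity band
#'
#' Integer bands: 0-2 inactive, 3-6 mild, 7-15 moderate, >=16 severe.
#'
#' @param total numeric vector of non-negative SES-CD totals. `NA` propagates.
#' @return factor with levels [SES_BANDS].
#' @examples
#' classify_ses(c(0, 2, 3, 7, 16, 37))
#' @export
classify_ses <- function(total) {
  total <- as.numeric(total)
  ok <- is.na(total) | (is.finite(total) & total >= 0)
  if (!all(ok)) stop("total: SES-CD total must be non-negative", call. = FALSE)
  cut(total, breaks = c(0, 3, 7, 16, Inf), labels = SES_BANDS,
      right = FALSE, include.lowest = TRUE)
}

#' Score a ratings table
#'
#' Applies [sema_total()] and [classify_sema()] to a ratings table in the
#' package's CSV schema (one row per video x reader x read occasion, with
#' segment-involvement 0/1 flag columns `seg_ascending`, `seg_transverse`,
#' `seg_descending`, `seg_rectum`). Rows violating the scoring invariants are
#' rejected with row-indexed messages.
#'
#' @param ratings data.frame in the ratings schema (see [read_ratings_csv()]).
#' @return `ratings` with `n_involved`, `sema_total`, `partial` and
#'   `severity_band` columns appended.
#' @export
score_ratings <- function(ratings) {
  flag_cols <- paste0("seg_", SEMA_COLON_SEGMENTS)
  need <- c("ileum", "colon_overall", flag_cols)
  miss <- setdiff(need, names(ratings))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  flags <- as.matrix(ratings[, flag_cols])
  if (any(is.na(flags)) || !all(flags %in% c(0, 1))) {
    stop("segment involvement flags must be 0/1", call. = FALSE)
  }
  n_involved <- rowSums(flags)
  sc <- tryCatch(
    sema_total(ratings$ileum, ratings$colon_overall, n_involved),
    error = function(e) stop("ratings table: ", conditionMessage(e), call. = FALSE)
  )
  ratings$n_involved <- n_involved
  ratings$sema_total <- sc$total
  ratings$partial <- sc$partial
  ratings$severity_band <- classify_sema(sc$total)
  ratings
}
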