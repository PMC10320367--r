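# Central-reading workflow: two blinded primary reads per video from a rotating
# reader pool, a standby adjudicator triggered when the primaries disagree by
# more than the allowed margin (strictly > threshold), median-of-reads final
# scores, and a re-read subsample for intra-rater analysis.

#' Assign a central-reader panel to a set of videos
#'
#' Each video receives two distinct primary readers and a distinct standby
#' adjudicator drawn from the pool. Primary pairs rotate round-robin over the
#' unordered reader pairs (so with 4 readers the 6 pairs are used as evenly as
#' possible: max-min pair load <= 1), with the within-pair order randomized.
#' A fraction of videos is sampled uniformly without replacement for a re-read
#' by one of its original readers after a minimum two-week gap.
#'
#' @param video_ids character or integer vector of video identifiers.
#' @param reader_pool character vector of at least 3 reader identifiers
#'   (default 4 readers, `R1`-`R4`).
#' @param reread_fraction fraction of videos re-read for intra-rater analysis;
#'   default 0.15. The re-read set size is round-half-up of
#'   `reread_fraction * n_videos`.
#' @param seed optional integer; when given, `set.seed(seed)` is called so the
#'   assignment is reproducible.
#'
#' @return An object of class `panel_assignment`: a list with
#'   `assignments` (data.frame: `video_id`, `reader_1`, `reader_2`,
#'   `adjudicator`), `rereads` (data.frame: `video_id`, `reader_id`,
#'   `gap_days`, all gaps >= 14), and `reader_pool`.
#' @examples
#' assign_panel(paste0("V", 1:6), reread_fraction = 0, seed = 1)
#' @export
assign_panel <- function(video_ids, reader_pool = paste0("R", 1:4),
                         reread_fraction = 0.15, seed = NULL) {
  if (length(reader_pool) < 3) stop("reader_pool: need at least 3 readers", call. = FALSE)
  if (anyDuplicated(reader_pool)) stop("reader_pool: duplicated reader id", call. = FALSE)
  if (reread_fraction < 0 || reread_fraction > 1) {
    stop("reread_fraction: must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(video_ids)
  pairs <- utils::combn(reader_pool, 2L)
  npair <- ncol(pairs)
  idx <- ((seq_len(n) - 1L) %% npair) + 1L
  flip <- stats::runif(n) < 0.5
  reader_1 <- ifelse(flip, pairs[2L, idx], pairs[1L, idx])
  reader_2 <- ifelse(flip, pairs[1L, idx], pairs[2L, idx])
  adjudicator <- vapply(seq_len(n), function(i) {
    rest <- setdiff(reader_pool, c(reader_1[i], reader_2[i]))
    if (length(rest) == 1L) rest else sample(rest, 1L)
  }, character(1L))
  n_reread <- floor(reread_fraction * n + 0.5)
  reread_idx <- if (n_reread > 0) sort(sample.int(n, n_reread)) else integer(0)
  rereads <- data.frame(
    video_id = video_ids[reread_idx],
    reader_id = vapply(reread_idx, function(i) {
      sample(c(reader_1[i], reader_2[i]), 1L)
    }, character(1L)),
    gap_days = if (n_reread > 0) sample(22:35, n_reread, replace = TRUE) else integer(0),
    stringsAsFactors = FALSE
  )
  structure(list(
    assignments = data.frame(video_id = video_ids, reader_1 = reader_1,
                             reader_2 = reader_2, adjudicator = adjudicator,
                             stringsAsFactors = FALSE),
    rereads = rereads,
    reader_pool = reader_pool
  ), class = "panel_assignment")
}

#' @export
print.panel_assignment <- function(x, ...) {
  cat("Central-reader panel assignment\n")
  cat("  videos:", nrow(x$assignments), " readers:", length(x$reader_pool), "\n")
  load <- table(c(x$assignments$reader_1, x$assignments$reader_2))
  cat("  primary-read load:", paste(names(load), load, sep = "=", collapse = "  "), "\n")
  cat("  re-reads:", nrow(x$rereads), "(gaps",
      if (nrow(x$rereads)) paste0(min(x$rereads$gap_days), "-", max(x$rereads$gap_days))
      else "-", "days)\n")
  invisible(x)
}

#' Resolve the reads of one video
#'
#' Adjudication is requested if and only if the two primary totals differ by
#' strictly more than `threshold` points (a difference of exactly the
#' threshold does not trigger it). The final score is the median of the
#' available totals, so the mean of two concordant reads or the middle order
#' statistic of three.
#'
#' @param total_1,total_2 the two primary-read totals (partial totals enter as
#'   recorded).
#' @param adjudicate a function of no arguments returning the adjudicator's
#'   total, called only when adjudication is triggered; or a number.
#' @param threshold adjudication trigger margin; default 5.
#' @param partial_1,partial_2 optional logicals; a mismatch in assessed-region
#'   flags between the two reads is reported as a data-quality warning.
#'
#' @return list with `final_score`, `adjudicated`, `totals` (the 2 or 3
#'   contributing totals).
#' @examples
#' resolve_reads(4, 9)                    # |diff| = 5: no adjudication, final 6.5
#' resolve_reads(4, 10, adjudicate = 8)   # triggered, final median(4, 10, 8) = 8
#' @export
resolve_reads <- function(total_1, total_2, adjudicate = NULL, threshold = 5,
                          partial_1 = FALSE, partial_2 = FALSE) {
  if (is.na(total_1) || is.na(total_2)) {
    stop("primary totals must be available to resolve a video", call. = FALSE)
  }
  if (isTRUE(partial_1) != isTRUE(partial_2)) {
    warning("assessed-region flags disagree between the primary reads; ",
            "totals compared as recorded", call. = FALSE)
  }
  adjudicated <- abs(total_1 - total_2) > threshold
  totals <- c(total_1, total_2)
  if (adjudicated) {
    third <- if (is.function(adjudicate)) adjudicate() else adjudicate
    if (is.null(third) || is.na(third)) {
      stop("adjudication required (totals differ by more than ", threshold,
           ") but no adjudicator read is available", call. = FALSE)
    }
    totals <- c(totals, third)
  }
  list(final_score = stats::median(totals), adjudicated = adjudicated, totals = totals)
}

#' Resolve a scored ratings table into per-video final scores
#'
#' Pivots a scored long ratings table (one row per video x reader x occasion,
#' as produced by [score_ratings()]) into one row per video, applying the
#' adjudication rule and the median-of-reads final score. Re-reads never enter
#' the final score; they are carried through for intra-rater analysis.
#'
#' @param scored scored ratings data.frame with columns `video_id`,
#'   `reader_id`, `occasion` (`primary_1`, `primary_2`, `adjudication`,
#'   `reread`) and `sema_total`.
#' @param threshold adjudication trigger margin; default 5.
#' @param rereads optional data.frame (`video_id`, `gap_days`) supplying
#'   re-read gap metadata for the resolved table.
#'
#' @return data.frame with one row per video: `video_id`, `total_read1`,
#'   `total_read2`, `total_adjud`, `adjudicated`, `final_score`,
#'   `reread_total`, `reread_gap_days`. Errors if a video required
#'   adjudication but has no adjudication row, or carries a spurious one.
#' @export
resolve_panel <- function(scored, threshold = 5, rereads = NULL) {
  need <- c("video_id", "reader_id", "occasion", "sema_total")
  miss <- setdiff(need, names(scored))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  get_total <- function(tab, occ) {
    i <- which(tab$occasion == occ)
    if (length(i) > 1L) stop("video ", tab$video_id[1L], ": duplicated ", occ,
                             " read", call. = FALSE)
    if (length(i)) tab$sema_total[i] else NA_real_
  }
  rows <- lapply(split(scored, scored$video_id), function(tab) {
    t1 <- get_total(tab, "primary_1")
    t2 <- get_total(tab, "primary_2")
    ta <- get_total(tab, "adjudication")
    if (is.na(t1) || is.na(t2)) {
      stop("video ", tab$video_id[1L], ": both primary reads are required",
           call. = FALSE)
    }
    adj <- abs(t1 - t2) > threshold
    if (adj && is.na(ta)) {
      stop("video ", tab$video_id[1L], ": adjudication required but absent",
           call. = FALSE)
    }
    if (!adj && !is.na(ta)) {
      stop("video ", tab$video_id[1L], ": adjudication present but not triggered",
           call. = FALSE)
    }
    data.frame(video_id = tab$video_id[1L], total_read1 = t1, total_read2 = t2,
               total_adjud = ta, adjudicated = adj,
               final_score = stats::median(c(t1, t2, if (adj) ta)),
               reread_total = get_total(tab, "reread"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$reread_gap_days <- if (!is.null(rereads)) {
    rereads$gap_days[match(out$video_id, rereads$video_id)]
  } else NA_integer_
  # keep input video order
  out <- out[match(unique(scored$video_id), out$video_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
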