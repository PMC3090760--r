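# genome scanning and threshold / partial-AUC evaluation

#' Window length rule for family scanning
#'
#' The scanning window is the maximum member length plus a fixed pad
#' (default 20), so that a member plus moderate indels fits in one
#' window.
#'
#' @param member_lengths integer vector of member sequence lengths.
#' @param pad pad added to the maximum (default 20).
#' @return window length `max(member_lengths) + pad`.
#' @examples
#' window_length_rule(c(87, 90, 94))  # 114
#' @export
window_length_rule <- function(member_lengths, pad = 20L) {
  if (length(member_lengths) == 0)
    stop("window_length_rule: empty member length list", call. = FALSE)
  as.integer(max(member_lengths) + pad)
}

#' Scan a genome with the local structural aligner
#'
#' Slides a window of length `window_len` along the genome (step
#' `step`, default 1: every region) and records the optimal local
#' structural alignment score of the query inside each window.
#'
#' @inheritParams align_local
#' @param genome target sequence, possibly genome-length.
#' @param window_len window length (see [window_length_rule()]).
#' @param step step between window starts.
#' @param revcomp also scan the reverse-complement strand (records get
#'   `strand = "-"` with coordinates on the forward strand).
#' @param mode aligner applied to each window: `"local"` (default),
#'   `"global"` or `"semiglobal"`, enabling the comparison between the
#'   local affine aligner and its global counterpart on the same windows.
#' @return data.frame of scan records: `query_id`, `target_id`,
#'   `window_start`, `window_end` (1-based inclusive), `score`,
#'   `q_begin`, `q_end`, `t_begin`, `t_end` (alignment coordinates;
#'   target coordinates are genome-absolute), `strand`.
#' @export
scan <- function(query, structure, genome, window_len, step = 1L,
                 scheme = default_scheme(), revcomp = FALSE,
                 mode = c("local", "global", "semiglobal")) {
  mode <- match.arg(mode)
  aligner <- switch(mode, local = align_local, global = align_global,
                    semiglobal = align_semiglobal)
  query <- as_rna(query, id = "query")
  genome <- as_rna(genome, id = "genome")
  st <- as_structure(structure, m = nchar(query$residues))
  stopifnot(window_len >= 1, step >= 1)
  glen <- nchar(genome$residues)
  if (window_len > glen) {
    warning("window length ", window_len, " exceeds genome length ", glen,
            "; scanning one truncated window")
    window_len <- glen
  }
  strands <- if (revcomp) c("+", "-") else "+"
  out <- list()
  for (strand in strands) {
    g <- if (strand == "+") genome else reverse_complement(genome)
    starts <- seq.int(1L, glen - window_len + 1L, by = step)
    for (ws in starts) {
      we <- ws + window_len - 1L
      win <- substr(g$residues, ws, we)
      aln <- aligner(query, st, win, scheme, traceback = TRUE)
      tb <- aln$target_range + ws - 1L
      if (strand == "-") {  # report forward-strand coordinates
        tb <- c(glen - tb[2] + 1L, glen - tb[1] + 1L)
        wsf <- glen - we + 1L; wef <- glen - ws + 1L
      } else {
        wsf <- ws; wef <- we
      }
      out[[length(out) + 1L]] <- data.frame(
        query_id = query$id, target_id = genome$id,
        window_start = wsf, window_end = wef, score = aln$score,
        q_begin = aln$query_range[1], q_end = aln$query_range[2],
        t_begin = tb[1], t_end = tb[2], strand = strand)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$target_id, res$window_start), , drop = FALSE]
}

#' Threshold and partial-AUC evaluation of scan scores
#'
#' Implements the evaluation protocol for separating real family
#' members from false (background) hits:
#'
#' * the zero-false-positive threshold is the smallest threshold with no
#'   false positive, i.e. `max(false_scores)`; a real hit is *missed*
#'   when its score is smaller than or equal to the threshold;
#' * for each false positive rate level `alpha`, the threshold is the
#'   smallest observed score `t` with `mean(false_scores > t) <= alpha`;
#' * the area under the ROC curve restricted to FPR <= `pauc_fpr`
#'   (trapezoidal, with linear interpolation at the boundary), divided
#'   by `pauc_fpr` so that it is normalized to `[0, 1]`.
#'
#' Positives are scores strictly greater than the threshold, matching
#' the miss rule.  All quantities are rank-based: applying any strictly
#' increasing transform to both score lists leaves them unchanged.
#'
#' @param real_scores scores of the known real hits.
#' @param false_scores scores of background regions.
#' @param fpr_levels false-positive-rate levels (default 5% and 10%).
#' @param pauc_fpr FPR cap for the normalized partial AUC (default 0.1).
#' @return list: `zero_fp_threshold`, `misses_zero_fp`,
#'   `miss_rate_zero_fp`, `levels` (data.frame with `fpr`, `threshold`,
#'   `misses`, `miss_rate`), `pauc`.
#' @export
evaluate_thresholds <- function(real_scores, false_scores,
                                fpr_levels = c(0.05, 0.10),
                                pauc_fpr = 0.10) {
  if (!length(real_scores) || !length(false_scores))
    stop("evaluate_thresholds: empty score list", call. = FALSE)
  nr <- length(real_scores); nf <- length(false_scores)
  t0 <- max(false_scores)
  misses0 <- sum(real_scores <= t0)
  lev <- lapply(fpr_levels, function(alpha) {
    cand <- sort(unique(c(real_scores, false_scores)))
    ok <- vapply(cand, function(tt) mean(false_scores > tt) <= alpha,
                 logical(1))
    thr <- cand[which(ok)[1]]   # smallest admissible threshold
    data.frame(fpr = alpha, threshold = thr,
               misses = sum(real_scores <= thr),
               miss_rate = sum(real_scores <= thr) / nr)
  })
  lev <- do.call(rbind, lev)
  # ROC: sweep thresholds over all observed scores (plus +/- extremes)
  thr <- sort(unique(c(real_scores, false_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(tt) sum(real_scores > tt) / nr, numeric(1))
  fpr <- vapply(thr, function(tt) sum(false_scores > tt) / nf, numeric(1))
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  pauc <- partial_auc(fpr, tpr, cap = pauc_fpr)
  list(zero_fp_threshold = t0, misses_zero_fp = misses0,
       miss_rate_zero_fp = misses0 / nr, levels = lev, pauc = pauc)
}

# trapezoidal area under (fpr, tpr) up to fpr = cap, normalized by cap;
# the curve is interpolated linearly at the cap
partial_auc <- function(fpr, tpr, cap = 0.10) {
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]
    y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x0 >= cap) break
    if (x1 > cap) {  # clip the segment at the cap
      y1 <- y0 + (y1 - y0) * (cap - x0) / (x1 - x0)
      x1 <- cap
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area / cap
}

#' Label scan windows and collect per-member hit scores
#'
#' Given scan records and the true embedded intervals of a fixture, a
#' window is a *real hit* if it overlaps a truth interval by at least
#' `min_overlap` of that member's length; all other windows are false
#' hits.  The per-member score is the maximum score over the windows
#' overlapping it (that is how a member is found); the false scores are
#' all remaining windows' scores.
#'
#' @param records data.frame from [scan()].
#' @param truth data.frame with columns `start`, `end` (1-based
#'   inclusive) of the embedded members.
#' @param min_overlap minimum overlap fraction of the member length
#'   (default 0.5).
#' @return list: `real_scores` (one per truth interval),
#'   `false_scores`, and `records` with an `is_real_hit` column added.
#' @export
label_scan_hits <- function(records, truth, min_overlap = 0.5) {
  stopifnot(nrow(truth) >= 1)
  is_real <- rep(FALSE, nrow(records))
  real_scores <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ov <- pmin(records$window_end, truth$end[i]) -
      pmax(records$window_start, truth$start[i]) + 1
    memlen <- truth$end[i] - truth$start[i] + 1
    hit <- ov >= min_overlap * memlen
    is_real <- is_real | hit
    real_scores[i] <- if (any(hit)) max(records$score[hit]) else -Inf
  }
  records$is_real_hit <- is_real
  list(real_scores = real_scores,
       false_scores = records$score[!is_real],
       records = records)
}
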