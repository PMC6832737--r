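#' Match detected plants to ground truth
#'
#' Greedy one-to-one matching: all detection-truth pairs within the distance
#' tolerance are considered in order of ascending distance; each detection
#' and each truth plant is used at most once. Unmatched detections are false
#' positives, unmatched truth plants false negatives.
#'
#' @param detected data.frame with columns `id`, `x`, `y` (corrected ground
#'   coordinates, metres).
#' @param truth data.frame with columns `plant_id`, `x`, `y` (a
#'   `truth_table`, or any table of reference positions).
#' @param tolerance Maximum match distance, metres. Default 0.05 (about half
#'   the smallest spacing seen in dense maize stands, so a double cannot
#'   match its neighbour's truth position).
#' @return An object of class `match_result`: list with `pairs` (data.frame
#'   `detected_id`, `truth_id`, `distance`), counts `TP`, `FP`, `FN`,
#'   `tolerance`, and id vectors `false_positives`, `false_negatives`.
#' @export
match_detections <- function(detected, truth, tolerance = 0.05) {
  stopifnot(is.data.frame(detected), is.data.frame(truth), tolerance > 0)
  nd <- nrow(detected); nt <- nrow(truth)
  pairs <- data.frame(detected_id = integer(0), truth_id = integer(0),
                      distance = numeric(0))
  if (nd > 0L && nt > 0L) {
    dx <- outer(detected$x, truth$x, "-")
    dy <- outer(detected$y, truth$y, "-")
    dist <- sqrt(dx * dx + dy * dy)
    cand <- which(dist <= tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(dist[cand]), , drop = FALSE]
      used_d <- logical(nd); used_t <- logical(nt)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- used_t[j] <- TRUE
          keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- data.frame(detected_id = detected$id[cand[, 1]],
                          truth_id = truth$plant_id[cand[, 2]],
                          distance = dist[cand])
    }
  }
  tp <- nrow(pairs)
  structure(list(pairs = pairs, TP = tp, FP = nd - tp, FN = nt - tp,
                 tolerance = tolerance,
                 false_positives = setdiff(detected$id, pairs$detected_id),
                 false_negatives = setdiff(truth$plant_id, pairs$truth_id)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Match: TP %d, FP %d, FN %d (tolerance %.3f m)\n",
              x$TP, x$FP, x$FN, x$tolerance))
  cat(sprintf("  precision %.3f, recall %.3f\n",
              suppressWarnings(precision(x)),
              suppressWarnings(recall(x))))
  invisible(x)
}

#' Detection precision and recall
#'
#' Precision = TP / (TP + FP), the fraction of detections that are real
#' plants; recall = TP / (TP + FN), the fraction of real plants detected.
#' Both accept a `match_result` or raw counts.
#'
#' @param m A [match_detections()] result, or a list with elements `TP`,
#'   `FP` (`FN` for recall).
#' @return Fraction in `[0, 1]`; `NaN` with a warning when the denominator
#'   is zero.
#' @export
precision <- function(m) {
  if (m$TP + m$FP == 0) {
    warning("precision undefined: no detections")
    return(NaN)
  }
  m$TP / (m$TP + m$FP)
}

#' @rdname precision
#' @export
recall <- function(m) {
  if (m$TP + m$FN == 0) {
    warning("recall undefined: no truth plants")
    return(NaN)
  }
  m$TP / (m$TP + m$FN)
}

#' Agreement between estimated and measured plant spacings
#'
#' Resolves each estimated spacing record's endpoints to truth plants via
#' the detection match, keeps only records whose endpoints are matched truth
#' plants that are *adjacent within their truth row* (an interval spanning a
#' missed plant, or touching a false positive or negative, is discarded),
#' and computes over the n valid pairs the agreement index
#' `d_e = mean(|d_est - d_meas|)`, the aggregate relative error
#' `r = d_e / mean(d_meas)`, and the per-pair relative errors
#' `|d_est - d_meas| / d_meas`.
#'
#' @param spacings Spacing records from [spacing_along_rows()]
#'   (`plant_a`/`plant_b` are detection ids).
#' @param truth A `truth_table` (or any table with `plant_id`, `row_index`,
#'   `y` giving per-row along-row order).
#' @param match A [match_detections()] result linking detections to truth.
#' @return An object of class `spacing_eval`: `d_e` (m), `r`, `n`,
#'   `per_pair` (data.frame `est`, `meas`, `abs_err`, `rel_err`), and
#'   `records` (the input with `valid` flags and measured distances).
#' @export
spacing_agreement <- function(spacings, truth, match) {
  stopifnot(is.data.frame(spacings), inherits(match, "match_result"))
  if (nrow(spacings) == 0L) stop("no spacing records to evaluate")
  to_truth <- match$pairs$truth_id[match(spacings$plant_a,
                                         match$pairs$detected_id)]
  to_truth_b <- match$pairs$truth_id[match(spacings$plant_b,
                                           match$pairs$detected_id)]
  ti <- match(to_truth, truth$plant_id)
  tj <- match(to_truth_b, truth$plant_id)
  meas <- rep(NA_real_, nrow(spacings))
  valid <- !is.na(ti) & !is.na(tj)
  if (any(valid)) {
    same_row <- truth$row_index[ti] == truth$row_index[tj]
    same_row[is.na(same_row)] <- FALSE
    # adjacency in the truth row ordering (rank difference of 1)
    rk <- stats::ave(truth$y, truth$row_index, FUN = rank)
    adj <- abs(rk[ti] - rk[tj]) == 1
    adj[is.na(adj)] <- FALSE
    valid <- valid & same_row & adj
    meas[valid] <- abs(truth$y[ti[valid]] - truth$y[tj[valid]])
  }
  n <- sum(valid)
  if (n == 0L) stop("no valid spacing pairs: nothing to evaluate")
  est <- spacings$distance[valid]
  mv <- meas[valid]
  abs_err <- abs(est - mv)
  out <- spacings
  out$valid <- valid
  out$measured <- meas
  structure(list(d_e = mean(abs_err), r = mean(abs_err) / mean(mv), n = n,
                 per_pair = data.frame(est = est, meas = mv,
                                       abs_err = abs_err,
                                       rel_err = abs_err / mv),
                 records = out),
            class = "spacing_eval")
}

#' @export
print.spacing_eval <- function(x, ...) {
  cat(sprintf("Spacing agreement over %d valid pairs:\n", x$n))
  cat(sprintf("  d_e %.4f m, r %.3f, median per-pair relative error %.3f\n",
              x$d_e, x$r, stats::median(x$per_pair$rel_err)))
  invisible(x)
}

#' Full plot evaluation against ground truth
#'
#' Runs [match_detections()] and, when spacing records are supplied,
#' [spacing_agreement()], collecting the plot's accuracy metrics in one
#' object.
#'
#' @inheritParams match_detections
#' @param spacings Optional spacing records from [spacing_along_rows()].
#' @return An object of class `stand_eval`: `match`, `precision`, `recall`,
#'   and (with spacings) `spacing` (a `spacing_eval`).
#' @export
evaluate_stand <- function(detected, truth, spacings = NULL,
                           tolerance = 0.05) {
  m <- match_detections(detected, truth, tolerance)
  out <- list(match = m, precision = precision(m), recall = recall(m),
              spacing = NULL)
  if (!is.null(spacings) && nrow(spacings) > 0L && m$TP > 0L)
    out$spacing <- tryCatch(spacing_agreement(spacings, truth, m),
                            error = function(e) NULL)
  structure(out, class = "stand_eval")
}

#' @export
print.stand_eval <- function(x, ...) {
  cat(sprintf("Detection: TP %d FP %d FN %d | precision %.1f%%, recall %.1f%%\n",
              x$match$TP, x$match$FP, x$match$FN,
              100 * x$precision, 100 * x$recall))
  if (!is.null(x$spacing)) print(x$spacing)
  invisible(x)
}
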