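.metrics_from_counts <- function(tp, fp, fn) {
  sens <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  ppv <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  f <- if (is.na(sens) || is.na(ppv) || sens + ppv == 0) NA_real_ else
    2 * sens * ppv / (sens + ppv)
  list(tp = tp, fp = fp, fn = fn, sens = sens, ppv = ppv, f = f,
       undefined = is.na(sens) || is.na(ppv))
}

#' Sensitivity, PPV and F-score from predicted sites
#'
#' `sens = TP/(TP+FN)`, `ppv = TP/(TP+FP)`, `F` = harmonic mean of the
#' two. Metrics with a zero denominator are reported as `NA` with the
#' `undefined` flag set, never silently as 0.
#'
#' @param predicted predicted sites (vector), or the TP count if all
#'   three arguments are single non-overlapping counts.
#' @param positive true positive sites, or the FP count.
#' @param negative negative sites (optional; sites outside
#'   positive/negative are ignored), or the FN count.
#' @param counts interpret the three arguments as TP/FP/FN counts.
#' @return list with `tp`, `fp`, `fn`, `sens`, `ppv`, `f`, `undefined`.
#' @export
confusion_metrics <- function(predicted, positive, negative = NULL,
                              counts = FALSE) {
  if (counts)
    return(.metrics_from_counts(predicted, positive, negative))
  tp <- sum(predicted %in% positive)
  fp <- if (is.null(negative)) sum(!predicted %in% positive) else
    sum(predicted %in% negative)
  fn <- sum(!positive %in% predicted)
  .metrics_from_counts(tp, fp, fn)
}

#' Tolerance-windowed mature 5'-end accuracy
#'
#' True 5'-ends within the hairpin intervals are the positive sites;
#' calls inside a hairpin interval within `tolerance` nt of an unmatched
#' positive site are true positives (nearest-first greedy matching, each
#' positive used at most once); other in-hairpin calls are false
#' positives; calls outside every hairpin interval are ignored
#' (negatives are defined only within hairpins).
#'
#' @param calls integer vector of predicted 5'-end positions.
#' @param truth integer vector of true 5'-end positions.
#' @param hairpins data.frame with `start`/`end` of hairpin intervals.
#' @param tolerance allowed distance in nt (0, 1 or 2).
#' @return list as in [confusion_metrics()].
#' @export
five_end_accuracy <- function(calls, truth, hairpins, tolerance = 0L) {
  inside <- function(pos) {
    if (!nrow(hairpins)) return(rep(FALSE, length(pos)))
    vapply(pos, function(p)
      any(p >= hairpins$start & p <= hairpins$end), logical(1))
  }
  calls <- unique(calls[inside(calls)])
  if (length(calls) == 0L)
    return(.metrics_from_counts(0L, 0L, length(truth)))
  d <- abs(outer(calls, truth, "-"))
  used_call <- logical(length(calls)); used_truth <- logical(length(truth))
  tp <- 0L
  repeat {
    d2 <- d
    d2[used_call, ] <- Inf; d2[, used_truth] <- Inf
    if (!any(is.finite(d2)) || min(d2) > tolerance) break
    hit <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    used_call[hit[1]] <- TRUE; used_truth[hit[2]] <- TRUE
    tp <- tp + 1L
  }
  .metrics_from_counts(tp, sum(!used_call), sum(!used_truth))
}

#' Ranking curve for hairpin detection
#'
#' Segments are sorted by score (descending); the curve reports, for
#' each prefix of N segments, how many distinct truth hairpins are hit.
#' A segment hits a hairpin when they overlap by at least `min_overlap`
#' nt (or reciprocally by 50% when `reciprocal` is TRUE).
#'
#' @param segments data.frame with `start`, `end`, `score`.
#' @param truth data.frame with `hairpin_start`, `hairpin_end` (or
#'   `start`/`end`).
#' @param min_overlap minimal overlap in nt.
#' @param reciprocal require 50% reciprocal overlap instead.
#' @return data.frame with `n` and cumulative `hits`.
#' @export
ranking_curve <- function(segments, truth, min_overlap = 1L,
                          reciprocal = FALSE) {
  ts <- truth[["hairpin_start"]] %||% truth[["start"]]
  te <- truth[["hairpin_end"]] %||% truth[["end"]]
  if (nrow(segments) == 0L)
    return(data.frame(n = integer(), hits = integer()))
  ord <- order(-segments$score)
  hit_set <- logical(length(ts))
  hits <- integer(nrow(segments))
  for (r in seq_along(ord)) {
    s <- segments$start[ord[r]]; e <- segments$end[ord[r]]
    ov <- pmin(e, te) - pmax(s, ts) + 1L
    ok <- if (reciprocal)
      ov >= 0.5 * (e - s + 1L) & ov >= 0.5 * (te - ts + 1L)
    else ov >= min_overlap
    hit_set <- hit_set | ok
    hits[r] <- sum(hit_set)
  }
  data.frame(n = seq_along(ord), hits = hits)
}

#' Evaluate stitched posterior tracks against bundle truth
#'
#' Sweeps the threshold grid, computing hairpin-level sensitivity
#' (detected truth hairpins / all truth hairpins), PPV (segments
#' overlapping a truth hairpin / all segments) and F-score at each
#' threshold; reports the F-maximizing operating point and, there, the
#' 5'-end accuracy at tolerances 0, 1 and 2 nt plus the fraction of
#' detected hairpins carrying a 5'-end call within 2 nt of truth.
#'
#' @param p_mi,p_5end stitched probability tracks (genome coordinates).
#' @param truth bundle truth data.frame (see [generate_genome()]).
#' @param thresholds probability thresholds to sweep.
#' @param gate gate 5'-end calls to called segments.
#' @return an object of class `eval_report`.
#' @export
evaluate_scan <- function(p_mi, p_5end, truth,
                          thresholds = seq(0.05, 0.95, by = 0.05),
                          gate = TRUE) {
  truth_ends <- c(truth$five_end_1, truth$five_end_2)
  truth_ends <- truth_ends[!is.na(truth_ends)]
  hp_iv <- data.frame(start = truth$hairpin_start,
                      end = truth$hairpin_end)
  sweep <- data.frame(threshold = thresholds, tp = NA_integer_,
                      fp = NA_integer_, fn = NA_integer_,
                      sens = NA_real_, ppv = NA_real_, f = NA_real_)
  seg_cache <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    segs <- call_hairpins(p_mi, thresholds[i])
    seg_cache[[i]] <- segs
    detected <- logical(nrow(truth))
    fp <- 0L
    for (s in seq_len(nrow(segs))) {
      ov <- pmin(segs$end[s], hp_iv$end) -
        pmax(segs$start[s], hp_iv$start) + 1L
      if (nrow(hp_iv) && any(ov >= 1L)) detected <- detected | ov >= 1L
      else fp <- fp + 1L
    }
    m <- .metrics_from_counts(sum(detected), fp, sum(!detected))
    sweep[i, c("tp", "fp", "fn")] <- c(m$tp, m$fp, m$fn)
    sweep[i, c("sens", "ppv", "f")] <- c(m$sens, m$ppv, m$f)
  }
  ok <- which(!is.na(sweep$f))
  best_i <- if (length(ok)) ok[which.max(sweep$f[ok])] else 1L
  best_t <- thresholds[best_i]
  segs <- seg_cache[[best_i]]
  calls <- call_5ends(p_5end, best_t, segs, gate = gate)
  tol <- lapply(0:2, function(tl)
    five_end_accuracy(calls$pos, truth_ends, hp_iv, tl))
  names(tol) <- paste0("tol", 0:2)
  # among detected hairpins, fraction with a 5'-end call within 2 nt
  det_frac <- {
    det <- vapply(seq_len(nrow(truth)), function(h) {
      if (!nrow(segs)) return(NA)
      ov <- pmin(segs$end, truth$hairpin_end[h]) -
        pmax(segs$start, truth$hairpin_start[h]) + 1L
      any(ov >= 1L)
    }, logical(1))
    ends_of <- function(h)
      c(truth$five_end_1[h], truth$five_end_2[h])
    with5 <- vapply(which(det), function(h) {
      e <- ends_of(h); e <- e[!is.na(e)]
      any(vapply(e, function(x) any(abs(calls$pos - x) <= 2L),
                 logical(1)))
    }, logical(1))
    if (any(det, na.rm = TRUE)) mean(with5) else NA_real_
  }
  structure(list(sweep = sweep, best_threshold = best_t,
                 best = as.list(sweep[best_i, ]),
                 five_end = tol, segments = segs, calls = calls,
                 detected_with_5end_2nt = det_frac,
                 ranking = ranking_curve(segs, truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: F-max %.3f at T = %.2f (sens %.3f, ppv %.3f)\n",
    x$best$f, x$best_threshold, x$best$sens, x$best$ppv))
  for (tl in 0:2)
    cat(sprintf("  5'-end tol %d nt: sens %.3f, ppv %.3f\n", tl,
                x$five_end[[tl + 1]]$sens, x$five_end[[tl + 1]]$ppv))
  cat(sprintf("  detected hairpins with 5'-end call within 2 nt: %s\n",
              format(x$detected_with_5end_2nt)))
  invisible(x)
}

#' Position-wise feature profiles around an anchor
#'
#' Mean and median of the raw conservation and base-pair-potential
#' dimensions (d1, d4, d5), position-aligned at an anchor such as the
#' duplex 5' start or the mature 5' end — the diagnostic used to check
#' that synthetic data reproduces the expected hairpin profile (high
#' conservation and pairing over the duplex, a sharp dip at the DRB,
#' mature arm elevated over passenger arm).
#'
#' @param raws list of [build_raw_features()] results.
#' @param anchors integer vector, one anchor position per element of
#'   `raws`.
#' @param rel relative positions to profile.
#' @return list of two matrices (`mean`, `median`), rows = `rel`,
#'   columns = d1, d4, d5.
#' @export
profile_features <- function(raws, anchors, rel = -30:100) {
  stopifnot(length(raws) == length(anchors))
  dims <- c("d1", "d4", "d5")
  acc <- array(NA_real_, c(length(rel), length(dims), length(raws)))
  for (e in seq_along(raws)) {
    pos <- anchors[e] + rel
    ok <- pos >= 1L & pos <= nrow(raws[[e]])
    for (d in seq_along(dims))
      acc[ok, d, e] <- raws[[e]][[dims[d]]][pos[ok]]
  }
  mk <- function(fun) {
    m <- apply(acc, c(1, 2), fun, na.rm = TRUE)
    dimnames(m) <- list(rel, dims)
    m
  }
  list(mean = mk(mean), median = mk(median))
}

#' Cross-validation over pre-partitioned bundles
#'
#' For each fold, trains on the examples of all other folds (excluding
#' hairpins sharing a family with any test-fold hairpin), selects the
#' penalty constant on the internal split, scans the held-out bundle's
#' genome, and evaluates against its truth.
#'
#' @param bundles list of [generate_genome()] bundles, one per fold.
#' @param config a [training_config()].
#' @param families optional list (parallel to `bundles`) of character
#'   family ids, one per hairpin, enabling homolog exclusion.
#' @param scan_window,scan_overlap scan window geometry.
#' @param fold_cfg a [fold_config()].
#' @param pair_threshold BPP threshold for the base-pair distance.
#' @return list of `eval_report`, one per fold, with the per-fold
#'   selected penalty in attribute `c_best`.
#' @export
cross_validate <- function(bundles, config = training_config(),
                           families = NULL, scan_window = 2000L,
                           scan_overlap = 400L,
                           fold_cfg = fold_config(),
                           pair_threshold = 0.5) {
  reports <- vector("list", length(bundles))
  for (fold in seq_along(bundles)) {
    test_fams <- if (!is.null(families)) families[[fold]] else character()
    train_bundles <- bundles[-fold]
    train_fams <- if (!is.null(families)) families[-fold] else
      lapply(train_bundles, function(b) rep(NA_character_,
                                            nrow(b$truth)))
    keep <- lapply(train_fams, function(f) !(f %in% test_fams))
    if (!any(unlist(keep))) {
      warning("fold ", fold, " has no training hairpins; skipped")
      next
    }
    model <- train_on_bundles(train_bundles, config = config,
                              keep_hairpins = keep,
                              fold_cfg = fold_cfg,
                              pair_threshold = pair_threshold)
    test <- bundles[[fold]]
    pred <- scan_genome(model, test$sequence, test$tracks,
                        window = scan_window, overlap = scan_overlap,
                        t_hairpin = 0.5, fold_cfg = fold_cfg,
                        pair_threshold = pair_threshold)
    rep_f <- evaluate_scan(pred$p_mi, pred$p_5end, test$truth,
                           thresholds = config$threshold_grid)
    attr(rep_f, "c_best") <- model$meta$c_best
    reports[[fold]] <- rep_f
  }
  reports
}
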