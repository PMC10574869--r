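#' One-vs-rest confusion counts per severity class
#'
#' @param pred,truth Equal-length vectors of classes (levels
#'   [foot_classes]).
#' @return Tibble `class, tp, fp, fn, tn, n_total`.
#' @export
confusion_summary <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    abort("`pred` and `truth` must be nonempty and of equal length.",
          class = "flatfootr_error_input")
  }
  pred <- factor(as.character(pred), levels = foot_classes)
  truth <- factor(as.character(truth), levels = foot_classes)
  n <- length(pred)
  purrr::map(foot_classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn,
           n_total = n)
  }) |> list_rbind()
}

# ratio * 100, NA (undefined marker) on zero denominator
pct <- function(num, den) ifelse(den == 0, NA_real_, num / den * 100)

#' Per-class performance metrics on the percent scale
#'
#' Standard one-vs-rest formulas: precision TP/(TP+FP), recall TP/(TP+FN),
#' specificity TN/(TN+FP), accuracy (TP+TN)/n, error rate (FN+FP)/n, and
#' the F-score as the harmonic mean of precision and recall — all expressed
#' on the 0-100 scale.  Zero-denominator cases yield `NA`, the explicit
#' undefined marker, never a crash; averaging helpers should skip and count
#' them.
#'
#' @param cs Confusion tibble from [confusion_summary] (or any subset of
#'   its rows).
#' @return Tibble `class, precision, recall, specificity, accuracy,
#'   f_score, error_rate`.
#' @export
class_metrics <- function(cs) {
  res <- cs |>
    mutate(
      precision = pct(.data$tp, .data$tp + .data$fp),
      recall = pct(.data$tp, .data$tp + .data$fn),
      specificity = pct(.data$tn, .data$tn + .data$fp),
      accuracy = pct(.data$tp + .data$tn,
                     .data$tp + .data$fn + .data$fp + .data$tn),
      error_rate = pct(.data$fn + .data$fp,
                       .data$tp + .data$fn + .data$fp + .data$tn)
    )
  res$f_score <- ifelse(
    is.na(res$precision) | is.na(res$recall) |
      (res$precision + res$recall) == 0,
    NA_real_,
    2 * res$precision * res$recall / (res$precision + res$recall))
  select(res, "class", "precision", "recall", "specificity", "accuracy",
         "f_score", "error_rate")
}

#' Overall accuracy across the three angles
#'
#' Per-angle multiclass accuracy (percent of images whose class predicted
#' from that angle matches the ground truth), averaged over the three
#' angles.
#'
#' @param per_angle_preds Named list `cia`, `ma`, `aa` of predicted class
#'   vectors, each the same length as `truth`.
#' @param truth Ground-truth class vector.
#' @return Percent in `[0, 100]`.
#' @export
overall_accuracy <- function(per_angle_preds, truth) {
  need <- c("cia", "ma", "aa")
  miss <- setdiff(need, names(per_angle_preds))
  if (length(miss) > 0) {
    abort(paste0("Missing per-angle predictions: ",
                 paste(miss, collapse = ", ")),
          class = "flatfootr_error_input")
  }
  acc <- map_dbl(per_angle_preds[need], function(p) {
    stopifnot(length(p) == length(truth))
    mean(as.character(p) == as.character(truth)) * 100
  })
  mean(acc)
}

#' Per-angle one-vs-rest error rates for one foot type
#'
#' The error-rate formula (FN+FP)/n * 100 applied one-vs-rest for the given
#' foot type, separately per angle.
#'
#' @inheritParams overall_accuracy
#' @param foot_type One of [foot_classes].
#' @return Named numeric vector `cia, ma, aa` of percentages.
#' @export
per_angle_error_rates <- function(per_angle_preds, truth, foot_type) {
  foot_type <- match.arg(foot_type, foot_classes)
  need <- c("cia", "ma", "aa")
  miss <- setdiff(need, names(per_angle_preds))
  if (length(miss) > 0) {
    abort(paste0("Missing per-angle predictions: ",
                 paste(miss, collapse = ", ")),
          class = "flatfootr_error_input")
  }
  map_dbl(per_angle_preds[need], function(p) {
    cs <- confusion_summary(p, truth)
    r <- cs[cs$class == foot_type, ]
    (r$fn + r$fp) / r$n_total * 100
  })
}

#' Seeded k-fold split
#'
#' Shuffles `1:n_items` with the given seed and deals the indices into `k`
#' folds whose sizes differ by at most one.
#'
#' @param n_items Number of items (must be >= k).
#' @param k Number of folds (default 10).
#' @param seed RNG seed.
#' @return List of `k` integer index vectors (the test folds); attribute
#'   `pairs` gives the k `(train, test)` splits.
#' @export
kfold_split <- function(n_items, k = 10, seed = 1) {
  if (n_items < k) {
    abort("Need at least as many items as folds.",
          class = "flatfootr_error_input")
  }
  set.seed(seed)
  idx <- sample.int(n_items)
  folds <- split(idx, rep_len(seq_len(k), n_items))
  folds <- unname(lapply(folds, sort))
  attr(folds, "pairs") <- lapply(folds, function(f)
    list(train = setdiff(seq_len(n_items), f), test = f))
  folds
}

#' Sweep the matching threshold and record mean localization accuracy
#'
#' For each threshold, candidates are recomputed from cached score maps,
#' the best match (rank 1 by similarity) per landmark is taken, and the
#' localization score `1/(1 + d)` against the ground truth landmark is
#' averaged over all landmarks and images.  Candidate counts are verified
#' to be monotonically non-increasing in the threshold.
#'
#' @param images Named list of [radiograph]s.
#' @param landmarks Ground truth tibble `image_id, poi_id, x, y`.
#' @param library A [template_library].
#' @param thresholds Similarity thresholds in (0, 1); default
#'   `seq(0.50, 0.95, by = 0.05)`.
#' @param templates_per_poi Cap on templates per landmark (default all).
#' @return Tibble `threshold, mean_localization, n_candidates, n_missing`.
#' @export
threshold_sweep <- function(images, landmarks, library,
                            thresholds = seq(0.50, 0.95, by = 0.05),
                            templates_per_poi = Inf) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("Thresholds must lie strictly between 0 and 1.",
          class = "flatfootr_error_config")
  }
  pois <- sort(unique(map_dbl(library$templates, "poi_id")))
  # cache score maps: per image, per poi, list of maps
  cache <- imap(images, function(img, id) {
    lapply(pois, function(pid) {
      tms <- library$templates[map_dbl(library$templates, "poi_id") == pid]
      if (is.finite(templates_per_poi) && length(tms) > templates_per_poi)
        tms <- tms[seq_len(templates_per_poi)]
      maps <- score_map_engine(img$pixels, lapply(tms, `[[`, "patch"))
      lapply(maps, function(m) {
        class(m) <- c("score_map", class(m)); m
      })
    })
  })
  prev_count <- Inf
  out <- purrr::map(sort(thresholds), function(th) {
    scores <- c(); n_cand <- 0L; n_missing <- 0L
    for (id in names(images)) {
      for (j in seq_along(pois)) {
        pid <- pois[j]
        cands <- list_rbind(lapply(cache[[id]][[j]], find_candidates,
                                   poi_id = pid, threshold = th,
                                   top_k = Inf))
        n_cand <- n_cand + nrow(cands)
        gt <- landmarks[landmarks$image_id == id &
                          landmarks$poi_id == pid, ]
        if (nrow(cands) == 0L || nrow(gt) == 0L) {
          n_missing <- n_missing + 1L
          next
        }
        best <- cands[order(-cands$similarity,
                            seq_len(nrow(cands)))[1], ]
        scores <- c(scores, localization_score(
          c(gt$x[1], gt$y[1]), poi_center(c(best$sx, best$sy))))
      }
    }
    stopifnot(n_cand <= prev_count)   # monotone filter
    prev_count <<- n_cand
    tibble(threshold = th,
           mean_localization = if (length(scores)) mean(scores) else NA_real_,
           n_candidates = n_cand, n_missing = n_missing)
  }) |> list_rbind()
  class(out) <- c("threshold_sweep", class(out))
  out
}
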