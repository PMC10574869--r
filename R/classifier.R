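#' Train the landmark patch classifier
#'
#' Fits a 9-class (optionally 10-class with a background class) Random
#' Forest on feature vectors of ground-truth-centered training patches.
#' Each supplied patch is complemented by `n_jitter` copies cropped at
#' starts displaced uniformly within `jitter` pixels of the true start, so
#' the forest sees the near-miss appearance of every class.  With a fixed
#' seed, retraining on identical data reproduces identical predictions.
#'
#' @param training Tibble with columns `image_id, poi_id, x, y` (0-based
#'   ground-truth landmark coordinates).
#' @param images Named list of [radiograph]s keyed by `image_id`.
#' @param n_trees Number of trees (default 100).
#' @param seed RNG seed for jitter draws and the forest (default 42).
#' @param jitter Max absolute landmark displacement of jittered crops, in
#'   pixels (default 8).
#' @param n_jitter Jittered copies per patch (default 4).
#' @param background If `TRUE`, adds a "0" background class trained on
#'   non-landmark patches — half sampled uniformly away from all
#'   landmarks, half at near-miss ring offsets just outside the jitter
#'   radius — giving the forest a probability gradient that discounts
#'   off-landmark candidates (off by default).
#' @param backend Classifier backend; `"random_forest"` ships.
#' @param feature_backend Passed to [extract_features].
#' @return Object of class `poi_classifier`.
#' @importFrom randomForest randomForest
#' @export
train_poi_classifier <- function(training, images, n_trees = 100, seed = 42,
                                 jitter = 8, n_jitter = 4,
                                 background = FALSE,
                                 backend = "random_forest",
                                 feature_backend = "pixel_hog") {
  if (!identical(backend, "random_forest")) {
    abort(sprintf("Classifier backend '%s' is not available.", backend),
          class = "flatfootr_error_config")
  }
  missing_cls <- setdiff(poi_ids, unique(training$poi_id))
  if (length(missing_cls) > 0) {
    abort(paste0("No training examples for PoI(s): ",
                 paste(missing_cls, collapse = ", ")),
          class = "flatfootr_error_training")
  }
  cnt <- table(training$poi_id)
  if (any(cnt < 2)) {
    abort(paste0("Every PoI class needs >= 2 examples; short: ",
                 paste(names(cnt)[cnt < 2], collapse = ", ")),
          class = "flatfootr_error_training")
  }

  set.seed(seed)
  rows <- vector("list", nrow(training))
  labs <- vector("list", nrow(training))
  for (i in seq_len(nrow(training))) {
    im <- images[[training$image_id[i]]]
    if (is.null(im)) {
      abort(paste0("Image not found: ", training$image_id[i]),
            class = "flatfootr_error_input")
    }
    x0 <- round(training$x[i]) - 50L
    y0 <- round(training$y[i]) - 50L
    dx <- c(0L, as.integer(round(runif(n_jitter, -jitter, jitter))))
    dy <- c(0L, as.integer(round(runif(n_jitter, -jitter, jitter))))
    h <- nrow(im$pixels); w <- ncol(im$pixels)
    sx <- pmin(pmax(x0 + dx, 0L), w - 100L)
    sy <- pmin(pmax(y0 + dy, 0L), h - 100L)
    rows[[i]] <- lapply(seq_along(sx), function(j)
      extract_features(cut_patch(im, sx[j], sy[j]),
                       backend = feature_backend))
    labs[[i]] <- rep(training$poi_id[i], length(sx))
  }
  feat <- do.call(rbind, unlist(rows, recursive = FALSE))
  lab <- unlist(labs)

  if (background) {
    # half far-field random patches, half near-miss "ring" offsets just
    # outside the jitter radius: the latter teach the forest to discount
    # candidates that qualify on similarity but sit off the landmark
    n_bg <- max(18L, nrow(training))
    ids <- sample(names(images), n_bg, replace = TRUE)
    bg <- lapply(seq_along(ids), function(j) {
      im <- images[[ids[j]]]
      h <- nrow(im$pixels); w <- ncol(im$pixels)
      gt <- training[training$image_id == ids[j], ]
      if (j %% 2 == 0 && nrow(gt) > 0) {
        g <- gt[sample.int(nrow(gt), 1L), ]
        rr <- runif(1, jitter + 4, 45); aa <- runif(1, 0, 2 * pi)
        sx <- round(g$x + rr * cos(aa)) - 50L
        sy <- round(g$y + rr * sin(aa)) - 50L
        sx <- min(max(sx, 0L), w - 100L); sy <- min(max(sy, 0L), h - 100L)
        return(extract_features(cut_patch(im, sx, sy),
                                backend = feature_backend))
      }
      repeat {
        sx <- sample.int(w - 100L, 1L) - 1L
        sy <- sample.int(h - 100L, 1L) - 1L
        if (nrow(gt) == 0 ||
            min(sqrt((gt$x - sx - 50)^2 + (gt$y - sy - 50)^2)) > 60) {
          return(extract_features(cut_patch(im, sx, sy),
                                  backend = feature_backend))
        }
      }
    })
    feat <- rbind(feat, do.call(rbind, bg))
    lab <- c(lab, rep(0L, n_bg))
  }

  classes <- if (background) c(0L, poi_ids) else poi_ids
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = feat, y = factor(lab, levels = classes), ntree = n_trees)
  structure(
    list(fit = fit, classes = classes, n_trees = n_trees, seed = seed,
         backend = backend, feature_backend = feature_backend,
         jitter = jitter, n_jitter = n_jitter, background = background,
         n_train = nrow(feat), feature_length = ncol(feat)),
    class = "poi_classifier")
}

#' @export
print.poi_classifier <- function(x, ...) {
  cat(sprintf(
    "<poi_classifier> %s (%d trees, seed %d), %d classes, %d training patches\n",
    x$backend, x$n_trees, x$seed, length(x$classes), x$n_train))
  invisible(x)
}

#' @export
glance.poi_classifier <- function(x, ...) {
  tibble(backend = x$backend, n_trees = x$n_trees, seed = x$seed,
         n_classes = length(x$classes), n_train = x$n_train,
         feature_length = x$feature_length,
         oob_error = mean(x$fit$err.rate[x$n_trees, "OOB"]))
}

#' @export
tidy.poi_classifier <- function(x, ...) {
  err <- x$fit$err.rate[x$n_trees, ]
  tibble(class = names(err)[-1], oob_error = unname(err[-1]))
}

#' Predict class probabilities for raw patches
#'
#' @param clf A fitted [train_poi_classifier] model.
#' @param patches List of 100 x 100 matrices.
#' @return Matrix of per-class probabilities (rows sum to 1), one row per
#'   patch, columns named by class.
#' @export
predict_patch_prob <- function(clf, patches) {
  if (!inherits(clf, "poi_classifier")) {
    abort("Classifier is not fitted.", class = "flatfootr_error_state")
  }
  feat <- do.call(rbind, lapply(patches, extract_features,
                                backend = clf$feature_backend))
  predict(clf$fit, feat, type = "prob")
}

#' Score template-matching candidates with the classifier
#'
#' Sets each candidate's `likelihood` to the classifier's predicted
#' probability that the candidate patch belongs to its own landmark class.
#'
#' @param clf A [train_poi_classifier] fit.
#' @param cands Candidate tibble from [match_templates] / [find_candidates].
#' @param img The [radiograph] the candidates were found in.
#' @return `cands` with a `likelihood` column appended.
#' @export
score_candidates <- function(clf, cands, img) {
  if (!inherits(clf, "poi_classifier")) {
    abort("Classifier is not fitted.", class = "flatfootr_error_state")
  }
  if (nrow(cands) == 0L) {
    return(mutate(cands, likelihood = double()))
  }
  patches <- map2(cands$sx, cands$sy, ~ cut_patch(img, .x, .y))
  prob <- predict_patch_prob(clf, patches)
  cands$likelihood <- prob[cbind(seq_len(nrow(cands)),
                                 match(cands$poi_id, colnames(prob)))]
  cands
}

#' Select one landmark per point of interest
#'
#' For each landmark id, the candidate with the maximum likelihood wins;
#' exact ties are broken by original candidate order (the first one).  The
#' landmark coordinate is the patch center, [poi_center] of the start.
#'
#' @param cands Scored candidate tibble (with `likelihood`).
#' @param required Landmark ids that must be present (default all nine).
#' @return Tibble `poi_id, x, y, likelihood` with one row per landmark.
#' @export
select_landmarks <- function(cands, required = poi_ids) {
  missing_ids <- setdiff(required, unique(cands$poi_id))
  if (length(missing_ids) > 0) {
    abort(paste0("No candidates for PoI(s): ",
                 paste(missing_ids, collapse = ", ")),
          class = "flatfootr_error_missing_landmark",
          poi_id = missing_ids)
  }
  cands |>
    mutate(.ord = seq_len(dplyr::n())) |>
    group_by(.data$poi_id) |>
    filter(seq_len(dplyr::n()) ==
             which.max(.data$likelihood == max(.data$likelihood))) |>
    ungroup() |>
    arrange(.data$poi_id) |>
    mutate(x = .data$sx + 50, y = .data$sy + 50) |>
    select("poi_id", "x", "y", "likelihood")
}
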