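#' Pipeline configuration
#'
#' One serializable object holding every tunable of the diagnosis
#' pipeline; a run's config travels with its output.
#'
#' @param size Canonical image edge (default 1024).
#' @param threshold Matching similarity threshold (default 0.90).
#' @param top_k Per-landmark candidate cap (default 50).
#' @param templates_per_poi Templates used per landmark during matching
#'   (default `Inf` = all in the library).
#' @param n_trees,seed Random-forest configuration (defaults 100 trees,
#'   seed 42).
#' @param backend,feature_backend Classifier and feature backends.
#' @param adjust Intensity adjustment method (default `"none"`).
#' @param assume_left Treat unknown laterality as left.
#' @param background Train with a background class.
#' @param keep_candidates Keep the scored candidate table in reports.
#' @param intervals Angle interval table (default [foot_intervals()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(size = 1024, threshold = 0.90, top_k = 50,
                            templates_per_poi = Inf, n_trees = 100,
                            seed = 42, backend = "random_forest",
                            feature_backend = "pixel_hog",
                            adjust = "none", assume_left = FALSE,
                            background = FALSE, keep_candidates = FALSE,
                            intervals = foot_intervals()) {
  structure(
    list(size = size, threshold = threshold, top_k = top_k,
         templates_per_poi = templates_per_poi, n_trees = n_trees,
         seed = seed, backend = backend,
         feature_backend = feature_backend, adjust = adjust,
         assume_left = assume_left, background = background,
         keep_candidates = keep_candidates, intervals = intervals),
    class = "pipeline_config")
}

#' Run the full diagnosis pipeline on one radiograph
#'
#' standardize -> orient -> (optional intensity adjustment) -> template
#' matching -> classifier re-ranking -> one landmark per PoI -> three
#' angles -> interval classification -> majority vote.  Every intermediate
#' needed to re-derive the diagnosis is bundled in the report; a missing
#' landmark or degenerate geometry aborts the image's diagnosis with a
#' typed error naming the image.
#'
#' @param img A [radiograph].
#' @param library A [template_library] covering all nine landmarks.
#' @param clf A fitted [train_poi_classifier].
#' @param cfg A [pipeline_config].
#' @param matcher Optional [prepare_matcher] cache reused across images.
#' @return List of class `foot_report`: `image_id`, `landmarks`, `angles`,
#'   `diagnosis`, optionally `candidates`, and `config`.
#' @export
run_diagnosis <- function(img, library, clf, cfg = pipeline_config(),
                          matcher = NULL) {
  stopifnot(inherits(img, "radiograph"))
  id <- img$image_id
  withCallingHandlers({
    std <- standardize(img, size = cfg$size)
    std <- orient(std, assume_left = cfg$assume_left)
    if (!identical(cfg$adjust, "none")) {
      std <- adjust_intensity(std, method = cfg$adjust)
    }
    cands <- match_templates(std, library, threshold = cfg$threshold,
                             top_k = cfg$top_k,
                             templates_per_poi = cfg$templates_per_poi,
                             matcher = matcher)
    cands <- score_candidates(clf, cands, std)
    lmk <- select_landmarks(cands)
    angles <- measure_foot_angles(lmk, image_id = id)
    dg <- diagnose_angles(angles, table = cfg$intervals)
    out <- list(image_id = id, landmarks = lmk, angles = angles,
                diagnosis = dg, config = cfg)
    if (cfg$keep_candidates) out$candidates <- cands
    structure(out, class = "foot_report")
  }, error = function(e) {
    if (is.null(e$image_id)) e$image_id <- id
    stop(e)
  })
}

#' Diagnose directly from known landmark coordinates
#'
#' The measurement half of the pipeline on its own: used for auditing a
#' report from its serialized landmarks and as the perfect-landmark oracle
#' on phantoms.
#'
#' @param landmarks Tibble `poi_id, x, y`.
#' @param image_id Identifier for the report.
#' @param cfg A [pipeline_config].
#' @return A `foot_report`.
#' @export
run_diagnosis_from_landmarks <- function(landmarks, image_id = "img",
                                         cfg = pipeline_config()) {
  angles <- measure_foot_angles(landmarks, image_id = image_id)
  dg <- diagnose_angles(angles, table = cfg$intervals)
  structure(list(image_id = image_id, landmarks = landmarks,
                 angles = angles, diagnosis = dg, config = cfg),
            class = "foot_report")
}

#' @export
print.foot_report <- function(x, ...) {
  cat(sprintf("<foot_report> %s\n", x$image_id))
  cat(sprintf("  CIA %.2f  AA %.2f  MA %.2f\n", x$angles$cia_deg,
              x$angles$aa_deg, x$angles$ma_deg))
  print(x$diagnosis)
  invisible(x)
}

#' @export
tidy.foot_report <- function(x, ...) {
  tibble(image_id = x$image_id, cia_deg = x$angles$cia_deg,
         aa_deg = x$angles$aa_deg, ma_deg = x$angles$ma_deg,
         vote_cia = unname(x$diagnosis$votes[["cia"]]),
         vote_ma = unname(x$diagnosis$votes[["ma"]]),
         vote_aa = unname(x$diagnosis$votes[["aa"]]),
         final = as.character(x$diagnosis$final),
         tie_broken = x$diagnosis$tie_broken,
         n_flags = length(x$diagnosis$flags))
}

#' Serialize a foot report to JSON
#'
#' @param x A `foot_report`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "foot_report"))
  obj <- list(image_id = x$image_id,
              landmarks = x$landmarks,
              angles = x$angles,
              votes = as.list(x$diagnosis$votes),
              counts = as.list(x$diagnosis$counts),
              final = as.character(x$diagnosis$final),
              flags = x$diagnosis$flags,
              config = x$config[setdiff(names(x$config), "intervals")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Evaluate the pipeline over a phantom dataset
#'
#' Runs [run_diagnosis] per image (or the perfect-landmark oracle when
#' `landmark_source = "ground_truth"`), compares against the manifest, and
#' reports per-class metrics, per-angle error rates, overall accuracy and
#' mean localization score.  A failing image is recorded and excluded; it
#' never aborts the run.
#'
#' @param ds A `phantom_dataset` (rendered, unless using the oracle).
#' @param library,clf,cfg Pipeline components (ignored by the oracle path).
#' @param landmark_source `"pipeline"` (default) or `"ground_truth"`.
#' @return List of class `dataset_evaluation`: `results` tibble,
#'   `metrics`, `error_rates`, `overall_accuracy`, `final_accuracy`,
#'   `mean_localization`, `n_failed`, `failures`.
#' @export
evaluate_dataset <- function(ds, library = NULL, clf = NULL,
                             cfg = pipeline_config(),
                             landmark_source = c("pipeline",
                                                 "ground_truth")) {
  landmark_source <- match.arg(landmark_source)
  if (length(ds$phantoms) == 0L) {
    abort("Empty dataset.", class = "flatfootr_error_input")
  }
  gt_lmk <- dataset_landmarks(ds)
  matcher <- NULL
  if (landmark_source == "pipeline") {
    matcher <- prepare_matcher(library, size = cfg$size,
                               templates_per_poi = cfg$templates_per_poi)
  }
  rows <- list(); failures <- list()
  for (id in names(ds$phantoms)) {
    ph <- ds$phantoms[[id]]
    rep <- tryCatch({
      if (landmark_source == "ground_truth") {
        run_diagnosis_from_landmarks(ph$truth$landmarks, image_id = id,
                                     cfg = cfg)
      } else {
        run_diagnosis(ph$image, library, clf, cfg, matcher = matcher)
      }
    }, error = function(e) e)
    if (inherits(rep, "error")) {
      failures[[id]] <- conditionMessage(rep)
      next
    }
    gt <- gt_lmk[gt_lmk$image_id == id, ]
    loc <- mean(localization_score(
      as.matrix(gt[order(gt$poi_id), c("x", "y")]),
      as.matrix(rep$landmarks[order(rep$landmarks$poi_id),
                              c("x", "y")])))
    rows[[id]] <- mutate(tidy(rep), truth = ph$truth$class,
                         mean_localization = loc)
  }
  if (length(rows) == 0L) {
    abort("Every image in the dataset failed.",
          class = "flatfootr_error_input")
  }
  results <- list_rbind(rows)
  per_angle <- list(cia = results$vote_cia, ma = results$vote_ma,
                    aa = results$vote_aa)
  cs <- confusion_summary(results$final, results$truth)
  err <- purrr::map(foot_classes, function(ft)
    tibble(class = ft, !!!as.list(
      per_angle_error_rates(per_angle, results$truth, ft)))) |>
    list_rbind()
  structure(
    list(results = results,
         metrics = class_metrics(cs),
         confusion = cs,
         error_rates = err,
         overall_accuracy = overall_accuracy(per_angle, results$truth),
         final_accuracy = mean(results$final == results$truth) * 100,
         mean_localization = mean(results$mean_localization),
         n_failed = length(failures), failures = failures),
    class = "dataset_evaluation")
}

#' @export
print.dataset_evaluation <- function(x, ...) {
  cat(sprintf(paste0("<dataset_evaluation> %d images (%d failed)\n",
                     "  final-diagnosis accuracy: %.2f%%\n",
                     "  overall per-angle accuracy: %.2f%%\n",
                     "  mean localization score: %.3f\n"),
              nrow(x$results) + x$n_failed, x$n_failed,
              x$final_accuracy, x$overall_accuracy,
              x$mean_localization))
  print(x$metrics)
  invisible(x)
}

#' @export
glance.dataset_evaluation <- function(x, ...) {
  tibble(n_images = nrow(x$results) + x$n_failed, n_failed = x$n_failed,
         final_accuracy = x$final_accuracy,
         overall_accuracy = x$overall_accuracy,
         mean_localization = x$mean_localization)
}

#' @export
tidy.dataset_evaluation <- function(x, ...) {
  left_join(x$metrics, x$error_rates, by = "class") |>
    rename(err_cia = "cia", err_ma = "ma", err_aa = "aa")
}
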