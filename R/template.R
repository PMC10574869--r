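#' Construct a single landmark template
#'
#' A template is a 100 x 100 intensity patch whose landmark sits at the
#' exact patch center (0-based offset (50, 50) from the patch start).
#'
#' @param patch 100 x 100 numeric matrix, intensities in `[0, 255]`.
#' @param poi_id Landmark identity 1-9.
#' @param source_id Opaque provenance label (e.g. source image id).
#' @param size Required patch edge (default 100).
#' @return Object of class `template`.
#' @export
template <- function(patch, poi_id, source_id = "tmpl", size = 100) {
  if (!is.matrix(patch) || nrow(patch) != size || ncol(patch) != size) {
    abort(sprintf("Template patch must be exactly %d x %d.", size, size),
          class = "flatfootr_error_dimension")
  }
  poi_id <- as.integer(poi_id)
  if (!poi_id %in% poi_ids) {
    abort("`poi_id` must be one of 1..9.", class = "flatfootr_error_input")
  }
  structure(list(patch = patch, poi_id = poi_id,
                 source_id = as.character(source_id)),
            class = "template")
}

#' Bundle templates into a library
#'
#' @param templates List of [template] objects.
#' @return Object of class `template_library`.
#' @export
template_library <- function(templates) {
  stopifnot(all(map_dbl(templates, ~ inherits(.x, "template")) == 1))
  structure(list(templates = templates), class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  tab <- table(factor(map_dbl(x$templates, "poi_id"), levels = poi_ids))
  cat(sprintf("<template_library> %d templates\n", length(x$templates)))
  print(tab)
  invisible(x)
}

#' Cut a patch out of a radiograph
#'
#' @param img A [radiograph] or matrix.
#' @param sx,sy 0-based patch start.
#' @param size Patch edge (default 100).
#' @return `size` x `size` numeric matrix.
#' @export
cut_patch <- function(img, sx, sy, size = 100) {
  px <- if (inherits(img, "radiograph")) img$pixels else img
  if (sx < 0 || sy < 0 || sx + size > ncol(px) || sy + size > nrow(px)) {
    abort("Patch does not fit inside the image.",
          class = "flatfootr_error_dimension")
  }
  px[(sy + 1):(sy + size), (sx + 1):(sx + size), drop = FALSE]
}

#' Write a template library to disk
#'
#' Layout: one PNG per patch named `poi<k>_<source_id>.png` plus an index
#' CSV (`poi_id,filename,source_id`).
#'
#' @param library A [template_library].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_template_library <- function(library, dir) {
  stopifnot(inherits(library, "template_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- imap(library$templates, function(tm, i) {
    fn <- sprintf("poi%d_%s_%03d.png", tm$poi_id, tm$source_id, i)
    png::writePNG(tm$patch / 255, file.path(dir, fn))
    tibble(poi_id = tm$poi_id, filename = fn, source_id = tm$source_id)
  }) |> list_rbind()
  readr::write_csv(idx, file.path(dir, "index.csv"))
  invisible(dir)
}

#' Read a template library written by [write_template_library]
#'
#' @param dir Directory containing `index.csv` and patch PNGs.
#' @return A [template_library].
#' @export
read_template_library <- function(dir) {
  idx <- readr::read_csv(file.path(dir, "index.csv"),
                         show_col_types = FALSE)
  tms <- pmap(idx, function(poi_id, filename, source_id) {
    template(round(png::readPNG(file.path(dir, filename)) * 255),
             poi_id = poi_id, source_id = source_id)
  })
  template_library(tms)
}
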