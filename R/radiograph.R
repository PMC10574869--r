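#' Construct a radiograph object
#'
#' A radiograph is a light container around an 8-bit grayscale pixel matrix
#' plus laterality metadata.  Pixels are stored as a numeric matrix indexed
#' `[y + 1, x + 1]` for the 0-based point `(x, y)` (x = column, y = row,
#' origin top-left); intensities lie in `[0, 255]`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @param laterality One of `"left"`, `"right"`, `"unknown"`.
#' @param image_id Opaque identifier string.
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(pixels, laterality = "unknown", image_id = "img") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.", class = "flatfootr_error_input")
  }
  if (nrow(pixels) == 0L || ncol(pixels) == 0L) {
    abort("Radiograph is empty.", class = "flatfootr_error_input")
  }
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    abort("Intensities must be finite and within [0, 255].",
          class = "flatfootr_error_input")
  }
  laterality <- match.arg(laterality, c("left", "right", "unknown"))
  structure(
    list(pixels = pixels, laterality = laterality,
         image_id = as.character(image_id)),
    class = "radiograph"
  )
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %s  %d x %d px  laterality: %s\n",
              x$image_id, ncol(x$pixels), nrow(x$pixels), x$laterality))
  invisible(x)
}

#' @export
dim.radiograph <- function(x) dim(x$pixels)

#' Read a radiograph from a PNG or TIFF file
#'
#' RGB inputs of grayscale scans are collapsed by channel averaging; pixel
#' values are rescaled to the 0-255 byte range.
#'
#' @param path Path to an 8-bit grayscale (or collapsible RGB) PNG/TIFF.
#' @param laterality Laterality of the imaged foot, if known.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A [radiograph].
#' @export
read_radiograph <- function(path, laterality = "unknown", image_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "flatfootr_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      abort(paste0("Unsupported image format: .", ext),
            class = "flatfootr_error_io")
    ),
    error = function(e) {
      if (inherits(e, "flatfootr_error_io")) stop(e)
      abort(paste0("Could not decode image: ", conditionMessage(e)),
            class = "flatfootr_error_io")
    }
  )
  if (is.list(arr)) {
    abort("Multi-frame images are not supported.",
          class = "flatfootr_error_io")
  }
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    } else {
      arr <- arr[, , 1]
    }
  }
  radiograph(round(arr * 255), laterality = laterality,
             image_id = image_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a radiograph to a PNG or TIFF file
#'
#' @param img A [radiograph].
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(img, path) {
  stopifnot(inherits(img, "radiograph"))
  arr <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    abort(paste0("Unsupported image format: .", ext),
          class = "flatfootr_error_io")
  )
  invisible(path)
}

#' Standardize a radiograph to the canonical square geometry
#'
#' Smaller images are centered and padded with background (intensity 0);
#' larger images are center-cropped.  Content is never resampled, so pixel
#' geometry (and hence any measured angle) is preserved exactly.  Offsets
#' use floor division, so the operation is idempotent.
#'
#' @param img A [radiograph].
#' @param size Canonical edge length in pixels (default 1024).
#' @return A `size` x `size` [radiograph].
#' @export
standardize <- function(img, size = 1024) {
  stopifnot(inherits(img, "radiograph"))
  if (size <= 100) {
    abort("Canonical size must exceed the 100 px template size.",
          class = "flatfootr_error_config")
  }
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  out <- matrix(0, size, size)

  copy_span <- function(n, size) {
    # returns c(src_from, dst_from, len) in 1-based indices
    if (n >= size) {
      off <- (n - size) %/% 2L
      c(off + 1L, 1L, size)
    } else {
      off <- (size - n) %/% 2L
      c(1L, off + 1L, n)
    }
  }
  ys <- copy_span(h, size); xs <- copy_span(w, size)
  out[ys[2]:(ys[2] + ys[3] - 1L), xs[2]:(xs[2] + xs[3] - 1L)] <-
    px[ys[1]:(ys[1] + ys[3] - 1L), xs[1]:(xs[1] + xs[3] - 1L)]
  radiograph(out, laterality = img$laterality, image_id = img$image_id)
}

#' Mirror right-foot radiographs into the canonical left-foot orientation
#'
#' Right-foot images are flipped about the vertical axis (pixel `(x, y)`
#' moves to `(width - 1 - x, y)`) and relabeled left; left-foot images pass
#' through unchanged.
#'
#' @param img A [radiograph].
#' @param assume_left If `TRUE`, unknown laterality is treated as left
#'   instead of raising an error.
#' @return A left-oriented [radiograph].
#' @export
orient <- function(img, assume_left = FALSE) {
  stopifnot(inherits(img, "radiograph"))
  lat <- img$laterality
  if (lat == "unknown") {
    if (!assume_left) {
      abort("Laterality unknown; pass `assume_left = TRUE` to proceed.",
            class = "flatfootr_error_laterality")
    }
    lat <- "left"
  }
  if (lat == "right") {
    px <- img$pixels[, ncol(img$pixels):1, drop = FALSE]
    radiograph(px, laterality = "left", image_id = img$image_id)
  } else {
    radiograph(img$pixels, laterality = "left", image_id = img$image_id)
  }
}

#' Adjust radiograph brightness/contrast
#'
#' Off by default in the pipeline: clinical images receive adjustment only
#' when bones are not clearly visible, so it is an explicit step rather
#' than an automatic one.
#'
#' @param img A [radiograph].
#' @param method `"none"` (identity), `"linear_stretch"` (min-max map to
#'   0-255; constant images pass through), or `"clahe"` (EBImage CLAHE).
#' @param ... Extra parameters passed to the CLAHE backend.
#' @return A [radiograph] with intensities in `[0, 255]`.
#' @export
adjust_intensity <- function(img, method = c("none", "linear_stretch", "clahe"),
                             ...) {
  stopifnot(inherits(img, "radiograph"))
  method <- tryCatch(match.arg(method),
                     error = function(e)
                       abort("Unknown intensity adjustment method.",
                             class = "flatfootr_error_config"))
  px <- img$pixels
  px <- switch(method,
    none = px,
    linear_stretch = {
      rng <- range(px)
      if (diff(rng) == 0) px else (px - rng[1]) / diff(rng) * 255
    },
    clahe = {
      out <- EBImage::clahe(EBImage::Image(t(px) / 255), ...)
      pmin(pmax(t(EBImage::imageData(out)) * 255, 0), 255)
    }
  )
  radiograph(px, laterality = img$laterality, image_id = img$image_id)
}
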