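#' Extract a deterministic feature vector from a 100 x 100 patch
#'
#' Default backend (`"pixel_hog"`): the concatenation of
#' * a 16 x 16 block-mean downsample of the patch, scaled to `[0, 1]`
#'   (256 values), and
#' * an 8-bin gradient-orientation histogram for each cell of a 4 x 4
#'   spatial grid (25 x 25 px cells), gradient-magnitude weighted and
#'   L2-normalized over the 128 values (all zero for a constant patch).
#'
#' The vector length (384) depends only on the backend, never on content,
#' and the computation is fully deterministic — no downloaded weights.
#'
#' @param patch 100 x 100 numeric matrix.
#' @param backend Feature backend id; only `"pixel_hog"` ships.
#' @return Named numeric vector of length 384.
#' @export
extract_features <- function(patch, backend = "pixel_hog") {
  if (!identical(backend, "pixel_hog")) {
    abort(sprintf("Unknown feature backend '%s'.", backend),
          class = "flatfootr_error_config")
  }
  if (!is.matrix(patch) || nrow(patch) != 100 || ncol(patch) != 100) {
    abort("Patch must be exactly 100 x 100.",
          class = "flatfootr_error_dimension")
  }

  # 16 x 16 block means (nearly equal bins of 100 rows/cols)
  grp <- function(n, k) as.integer(cut(seq_len(n), k, labels = FALSE))
  gy <- grp(100, 16); gx <- grp(100, 16)
  dn <- rowsum(patch, gy)                       # 16 x 100 sums
  dn <- t(rowsum(t(dn), gx))                    # 16 x 16 sums
  cnt <- tcrossprod(tabulate(gy, 16), tabulate(gx, 16))
  intensity <- as.vector(dn / cnt) / 255

  # gradient-orientation histograms, 4 x 4 cells x 8 bins
  dx <- matrix(0, 100, 100); dy <- matrix(0, 100, 100)
  dx[, 2:99] <- (patch[, 3:100] - patch[, 1:98]) / 2
  dy[2:99, ] <- (patch[3:100, ] - patch[1:98, ]) / 2
  mag <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)                          # (-pi, pi]
  bin <- pmin(floor((ang + pi) / (2 * pi / 8)), 7) + 1L
  cy <- grp(100, 4); cx <- grp(100, 4)
  cell <- (matrix(cy, 100, 100) - 1L) * 4L + matrix(cx[col(patch)], 100, 100)
  idx <- (cell - 1L) * 8L + bin
  hist <- numeric(128)
  acc <- rowsum(as.vector(mag), as.vector(idx))
  hist[as.integer(rownames(acc))] <- acc
  nrm <- sqrt(sum(hist^2))
  if (nrm > 0) hist <- hist / nrm

  out <- c(intensity, hist)
  names(out) <- c(sprintf("int%03d", seq_len(256)),
                  sprintf("hog%03d", seq_len(128)))
  out
}
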