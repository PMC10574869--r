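#' Per-class ground-truth angle sampling ranges
#'
#' Angles for a phantom of a given class are drawn uniformly inside the
#' class's published interval, keeping a 0.5-degree margin from every
#' boundary (annotation-grade separation) and bounding the open-ended
#' tails at clinically plausible extremes (CIA moderate down to 3, AA
#' moderate up to 195, MA moderate up to 25).
#'
#' @return Nested list `class -> angle -> c(lo, hi)`.
#' @export
phantom_angle_ranges <- function() {
  list(
    normal   = list(cia = c(20.5, 29.5), aa = c(150.5, 164.5),
                    ma = c(0.5, 3.5)),
    mild     = list(cia = c(10.5, 19.5), aa = c(165.5, 179.5),
                    ma = c(4.5, 14.5)),
    moderate = list(cia = c(3.0, 9.5),   aa = c(180.5, 195.0),
                    ma = c(15.5, 25.0))
  )
}

#' Specification for one synthetic radiograph phantom
#'
#' @param target_class Severity class to sample angles from (all three
#'   angles drawn inside that class's interval, so the phantom is
#'   class-consistent), or `NULL` when `angles` is given explicitly.
#' @param angles Optional explicit `c(cia, aa, ma)` degrees.
#' @param noise_sd Additive Gaussian intensity noise (default 5).
#' @param blur_sd Gaussian blur sigma in pixels (default 1).
#' @param seed Integer seed; fully determines the phantom.
#' @param size Frame edge in pixels (default 1024).
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(target_class = NULL, angles = NULL, noise_sd = 5,
                         blur_sd = 1, seed = 1, size = 1024) {
  if (is.null(target_class) && is.null(angles)) {
    abort("Give either `target_class` or explicit `angles`.",
          class = "flatfootr_error_config")
  }
  if (!is.null(target_class)) {
    target_class <- match.arg(target_class, foot_classes)
  }
  structure(list(target_class = target_class, angles = angles,
                 noise_sd = noise_sd, blur_sd = blur_sd,
                 seed = as.integer(seed), size = as.integer(size)),
            class = "phantom_spec")
}

# 2-D rotation by `deg` degrees under the raster (y-down) convention:
# positive = clockwise on screen.
rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
}

# Construct the nine ground-truth landmarks realizing (cia, aa, ma).
# Anchors and segment lengths receive seeded jitter (whole-construction
# translation, per-bone length scaling); angles are realized exactly.
phantom_landmarks <- function(cia, aa, ma, size = 1024, jitter = TRUE) {
  shift <- if (jitter) runif(2, -25, 25) else c(0, 0)
  sc <- function() if (jitter) runif(1, 0.96, 1.04) else 1

  p5 <- c(230, 770) + shift
  p9 <- p5 + c(500 * sc(), 0)                       # base line: horizontal
  u <- c(cos(cia * pi / 180), -sin(cia * pi / 180)) # inclined calcaneal line
  p6 <- p5 + 185 * sc() * u

  delta <- 180 - aa
  v <- as.vector(rot2(delta) %*% u)                 # 5th metatarsal direction
  # the arch apex: the posterior 5th-metatarsal landmark sits at a fixed
  # offset from the anterior calcaneus, so its neighborhood looks alike
  # across phantoms (AA depends only on the line directions, not on p3)
  p3 <- p6 + c(25, -20)
  p4 <- p3 + 215 * sc() * v   # short of the forefoot: keeps the two
                              # metatarsal heads out of each other's patch

  # Meary's angle split symmetrically about the 18-degree midfoot axis:
  # the talar and first-metatarsal axes each carry ma/2, which keeps the
  # per-bone orientation spread small across the class ranges
  wt <- c(cos((18 - ma / 2) * pi / 180), sin((18 - ma / 2) * pi / 180))
  p7 <- c(390, 540) + shift
  p8 <- p7 + 150 * sc() * wt
  wm <- as.vector(rot2(ma) %*% wt)                  # 1st metatarsal axis
  p1 <- p8 + 35 * wt
  p2 <- p1 + 190 * sc() * wm

  pts <- rbind(p1, p2, p3, p4, p5, p6, p7, p8, p9)
  margin <- 60
  if (any(pts < margin) || any(pts > size - 1 - margin)) {
    abort(paste("Requested angles place a bone outside the frame;",
                "use a smaller construction scale or milder angles."),
          class = "flatfootr_error_generation")
  }
  tibble(poi_id = poi_ids, x = unname(pts[, 1]), y = unname(pts[, 2]))
}

# Rasterize bright capsule "bones" over a dark background.  Each bone has
# a distinct base intensity plus a sinusoidal + linear texture along its
# axis so that 100 x 100 patches at different positions (and on different
# bones) are discriminable.  Overlaps take the brighter value.
render_phantom_image <- function(landmarks, size = 1024) {
  X <- matrix(0:(size - 1), size, size, byrow = TRUE)
  Y <- matrix(0:(size - 1), size, size)
  img <- matrix(0, size, size)
  pt <- function(id) unlist(landmarks[landmarks$poi_id == id, c("x", "y")])

  capsule <- function(img, p1, p2, r, base, amp, period, ramp) {
    d <- p2 - p1; L2 <- sum(d^2); L <- sqrt(L2)
    if (L2 == 0) {                          # disc
      m <- (X - p1[1])^2 + (Y - p1[2])^2 <= r^2
      return(ifelse(m, pmax(img, base), img))
    }
    t <- ((X - p1[1]) * d[1] + (Y - p1[2]) * d[2]) / L2
    tc <- pmin(pmax(t, 0), 1)
    dist2 <- (X - (p1[1] + tc * d[1]))^2 + (Y - (p1[2] + tc * d[2]))^2
    m <- dist2 <= r^2
    # texture phase is anchored at the nearer endpoint so landmark-centered
    # patches look alike across phantoms despite length jitter; the linear
    # ramp tells the two ends of a bone apart
    s <- pmin(tc, 1 - tc) * L
    val <- base + amp * sin(2 * pi * s / period) + ramp * tc
    ifelse(m, pmax(img, val), img)
  }

  img <- capsule(img, pt(5), pt(6), 36, 190, 14, 37, 25)   # calcaneus
  img <- capsule(img, pt(3), pt(4), 26, 120, 12, 23, 20)   # 5th metatarsal
  img <- capsule(img, pt(7), pt(8), 30, 160, 12, 29, -20)  # talus
  img <- capsule(img, pt(1), pt(2), 26,  90, 10, 17, 18)   # 1st metatarsal
  # rounded epiphyses/styloid: rotation-invariant bulges centered on the
  # metatarsal landmarks, so their patches match across shaft orientations
  img <- capsule(img, pt(4), pt(4), 22, 175,  0,  1,  0)  # MT5 head
  img <- capsule(img, pt(3), pt(3), 18, 150,  0,  1,  0)  # MT5 styloid
  img <- capsule(img, pt(2), pt(2), 18, 135,  0,  1,  0)  # MT1 head
  img <- capsule(img, pt(1), pt(1), 16, 115,  0,  1,  0)  # MT1 base
  img <- capsule(img, pt(9), pt(9), 20, 235,  0,  1,  0)   # sesamoid
  pmin(pmax(img, 0), 255)
}

#' Generate one synthetic radiograph phantom with exact ground truth
#'
#' Renders five stylized bright bones (calcaneus, talus, first and fifth
#' metatarsals, sesamoid) whose construction realizes the requested CIA,
#' AA (including reflex configurations of 180 degrees and above) and MA
#' exactly at known landmark coordinates, then applies Gaussian blur and
#' additive Gaussian noise clipped to `[0, 255]`.  Everything is a
#' deterministic function of the spec's seed.
#'
#' @param spec A [phantom_spec].
#' @param render If `FALSE`, skip rasterization and return ground truth
#'   only (fast path for geometry-only studies).
#' @return List of class `phantom`: `image` ([radiograph] or `NULL`),
#'   `truth` (list with `landmarks` tibble, `angles` tibble, `class`),
#'   `spec`.
#' @export
generate_phantom <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  if (!is.null(spec$angles)) {
    ang <- spec$angles
  } else {
    rg <- phantom_angle_ranges()[[spec$target_class]]
    ang <- c(runif(1, rg$cia[1], rg$cia[2]),
             runif(1, rg$aa[1], rg$aa[2]),
             runif(1, rg$ma[1], rg$ma[2]))
  }
  lmk <- phantom_landmarks(ang[1], ang[2], ang[3], size = spec$size)
  id <- sprintf("phantom_s%d", spec$seed)
  angles <- tibble(image_id = id, cia_deg = ang[1], aa_deg = ang[2],
                   ma_deg = ang[3])
  cls <- spec$target_class %||%
    as.character(diagnose_angles(angles)$final)

  img <- NULL
  if (render) {
    px <- render_phantom_image(lmk, spec$size)
    if (spec$blur_sd > 0) {
      px <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(px / 255), sigma = spec$blur_sd)) * 255
    }
    if (spec$noise_sd > 0) {
      px <- px + rnorm(length(px), 0, spec$noise_sd)
    }
    px <- round(pmin(pmax(px, 0), 255))
    img <- radiograph(px, laterality = "left", image_id = id)
  }
  structure(list(image = img,
                 truth = list(landmarks = lmk, angles = angles,
                              class = cls),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s  class: %s  CIA %.1f  AA %.1f  MA %.1f%s\n",
              x$truth$angles$image_id, x$truth$class,
              x$truth$angles$cia_deg, x$truth$angles$aa_deg,
              x$truth$angles$ma_deg,
              if (is.null(x$image)) "  (not rendered)" else ""))
  invisible(x)
}

#' Build a template library from phantoms with known landmarks
#'
#' One 100 x 100 crop per landmark per phantom, started at the rounded
#' landmark minus (50, 50) so [poi_center] of the start recovers the
#' landmark.  Landmarks too close to a border are skipped with a warning;
#' a landmark id left with zero templates is an error.
#'
#' @param phantoms List of `phantom` objects (rendered).
#' @return A [template_library].
#' @export
build_templates <- function(phantoms) {
  tms <- list()
  for (ph in phantoms) {
    stopifnot(inherits(ph, "phantom"))
    if (is.null(ph$image)) {
      abort("Phantom was generated with render = FALSE.",
            class = "flatfootr_error_input")
    }
    size <- nrow(ph$image$pixels)
    for (i in seq_len(nrow(ph$truth$landmarks))) {
      sx <- as.integer(round(ph$truth$landmarks$x[i])) - 50L
      sy <- as.integer(round(ph$truth$landmarks$y[i])) - 50L
      if (sx < 0 || sy < 0 || sx + 100 > size || sy + 100 > size) {
        warn(sprintf("Skipping PoI %d of %s: too close to the border.",
                     ph$truth$landmarks$poi_id[i], ph$image$image_id))
        next
      }
      tms[[length(tms) + 1L]] <- template(
        cut_patch(ph$image, sx, sy),
        poi_id = ph$truth$landmarks$poi_id[i],
        source_id = ph$image$image_id)
    }
  }
  got <- unique(map_dbl(tms, "poi_id"))
  missing_ids <- setdiff(poi_ids, got)
  if (length(missing_ids) > 0) {
    abort(paste0("No usable templates for PoI(s): ",
                 paste(missing_ids, collapse = ", ")),
          class = "flatfootr_error_input")
  }
  template_library(tms)
}

# EBImage affine matrix for p' = c + s R(theta) (p - c) in the package's
# 0-based (x, y) convention.  EBImage transforms (d1, d2) = (y, x) row
# vectors with pixel centers at index - 0.5, i.e. d = coord0 + 0.5.
similarity_affine_matrix <- function(theta_deg, s, size) {
  th <- theta_deg * pi / 180
  B <- matrix(c(s * cos(th), -s * sin(th),
                s * sin(th),  s * cos(th)), 2, 2, byrow = TRUE)
  cd <- c(size / 2, size / 2)
  rbind(B, cd - as.vector(cd %*% B))
}

#' Augment a phantom by random rotation and scaling
#'
#' Draws a rotation uniformly from `rotation_range` and a scale uniformly
#' from `[1, max_scale]`, applies the similarity transform about the image
#' center to both pixels (bilinear interpolation, background 0) and
#' landmark coordinates, and carries the ground-truth angles over
#' unchanged — similarity transforms preserve angles between lines.  Draws
#' that push a landmark out of frame are rejected and redrawn (bounded
#' retries).
#'
#' @param ph A `phantom` (rendered or not).
#' @param rotation_range Degrees, default `c(-15, 15)`.
#' @param max_scale Upper scale bound, default 1.5.
#' @param seed Optional seed for the draws.
#' @param max_retry Retry budget for out-of-frame draws (default 25).
#' @return A transformed `phantom` (with `rotation` and `scale` recorded
#'   in its spec).
#' @export
augment_phantom <- function(ph, rotation_range = c(-15, 15), max_scale = 1.5,
                            seed = NULL, max_retry = 25) {
  stopifnot(inherits(ph, "phantom"))
  if (rotation_range[1] < -15 || rotation_range[2] > 15 || max_scale > 1.5) {
    abort("Augmentation limited to rotation within [-15, 15] and scale <= 1.5.",
          class = "flatfootr_error_config")
  }
  if (!is.null(seed)) set.seed(seed)
  size <- ph$spec$size
  ctr <- (size - 1) / 2
  margin <- 52   # transformed landmarks must still admit a 100 px patch

  for (try in seq_len(max_retry)) {
    theta <- runif(1, rotation_range[1], rotation_range[2])
    s <- runif(1, 1, max_scale)
    R <- rot2(theta)
    pts <- as.matrix(ph$truth$landmarks[, c("x", "y")])
    new_pts <- t(ctr + s * R %*% (t(pts) - ctr))
    if (all(new_pts >= margin) && all(new_pts <= size - 1 - margin)) {
      out <- ph
      out$truth$landmarks$x <- new_pts[, 1]
      out$truth$landmarks$y <- new_pts[, 2]
      if (!is.null(ph$image)) {
        m <- similarity_affine_matrix(theta, s, size)
        warped <- EBImage::affine(EBImage::Image(ph$image$pixels / 255), m,
                                  filter = "bilinear", bg.col = 0)
        px <- round(pmin(pmax(EBImage::imageData(warped) * 255, 0), 255))
        out$image <- radiograph(px, laterality = ph$image$laterality,
                                image_id = paste0(ph$image$image_id, "_aug"))
      }
      out$spec$rotation <- theta
      out$spec$scale <- s
      return(out)
    }
  }
  abort("Could not find an in-frame augmentation draw.",
        class = "flatfootr_error_generation")
}

#' Sample a seeded phantom dataset
#'
#' @param n_per_class Named counts, e.g. `c(normal = 20, mild = 20,
#'   moderate = 20)`.
#' @param seed Master seed; per-phantom seeds are derived from it, so the
#'   manifest plus seed fully reproduces the dataset.
#' @param noise_sd,blur_sd,size Passed to every [phantom_spec].
#' @param render Rasterize images (default `TRUE`).
#' @return List of class `phantom_dataset`: `phantoms` (named list) and
#'   `manifest` tibble (`image_id, class, cia_deg, aa_deg, ma_deg, seed`).
#' @export
sample_phantom_dataset <- function(n_per_class, seed = 1, noise_sd = 5,
                                   blur_sd = 1, size = 1024, render = TRUE) {
  stopifnot(all(names(n_per_class) %in% foot_classes),
            all(n_per_class >= 0))
  set.seed(seed)
  cls <- rep(names(n_per_class), times = n_per_class)
  seeds <- sample.int(2^30, length(cls))
  phantoms <- vector("list", length(cls))
  rows <- vector("list", length(cls))
  for (i in seq_along(cls)) {
    ph <- generate_phantom(
      phantom_spec(target_class = cls[i], noise_sd = noise_sd,
                   blur_sd = blur_sd, seed = seeds[i], size = size),
      render = render)
    id <- sprintf("ph%03d_%s", i, cls[i])
    if (!is.null(ph$image)) ph$image$image_id <- id
    ph$truth$angles$image_id <- id
    phantoms[[i]] <- ph
    rows[[i]] <- mutate(ph$truth$angles, class = cls[i], seed = seeds[i],
                        .after = "image_id")
  }
  names(phantoms) <- sprintf("ph%03d_%s", seq_along(cls), cls)
  structure(list(phantoms = phantoms, manifest = list_rbind(rows)),
            class = "phantom_dataset")
}

#' Ground-truth landmark table of a phantom dataset
#'
#' @param ds A `phantom_dataset`.
#' @return Tibble `image_id, poi_id, x, y`.
#' @export
dataset_landmarks <- function(ds) {
  imap(ds$phantoms, function(ph, id)
    mutate(ph$truth$landmarks, image_id = id, .before = 1)) |>
    list_rbind()
}

#' Write a phantom dataset to disk
#'
#' Layout: `images/<id>.png`, `manifest.csv`, `landmarks.csv` (landmark
#' coordinates rounded to the nearest pixel in the integer-pixel CSV;
#' in-memory ground truth stays real-valued).
#'
#' @param ds A `phantom_dataset` (rendered).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(ds$phantoms)) {
    img <- ds$phantoms[[id]]$image
    if (is.null(img)) {
      abort("Dataset was sampled with render = FALSE.",
            class = "flatfootr_error_input")
    }
    write_radiograph(img, file.path(dir, "images", paste0(id, ".png")))
  }
  readr::write_csv(ds$manifest, file.path(dir, "manifest.csv"))
  lmk <- dataset_landmarks(ds) |>
    mutate(x = round(.data$x), y = round(.data$y))
  readr::write_csv(lmk, file.path(dir, "landmarks.csv"))
  invisible(dir)
}
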