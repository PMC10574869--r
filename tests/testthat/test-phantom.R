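test_that("phantoms are bit-identical under a fixed seed", {
  a <- generate_phantom(phantom_spec(target_class = "normal", seed = 7))
  b <- generate_phantom(phantom_spec(target_class = "normal", seed = 7))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom(phantom_spec(target_class = "normal", seed = 8))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("explicit angles round-trip through measurement", {
  ph <- generate_phantom(phantom_spec(angles = c(25, 158, 2), seed = 3),
                         render = FALSE)
  m <- measure_foot_angles(ph$truth$landmarks)
  expect_equal(m$cia_deg, 25, tolerance = 0.5)
  expect_equal(m$aa_deg, 158, tolerance = 0.5)
  expect_equal(m$ma_deg, 2, tolerance = 0.5)

  reflex <- generate_phantom(phantom_spec(angles = c(6, 185, 18),
                                          seed = 4), render = FALSE)
  expect_equal(measure_foot_angles(reflex$truth$landmarks)$aa_deg, 185,
               tolerance = 0.5)
})

test_that("geometry that cannot fit the frame raises a generation error", {
  expect_error(
    generate_phantom(phantom_spec(angles = c(25, 158, 2), seed = 1,
                                  size = 700), render = FALSE),
    class = "flatfootr_error_generation")
})

test_that("noiseless render is piecewise constant with exact background", {
  ph <- generate_phantom(phantom_spec(target_class = "mild", noise_sd = 0,
                                      blur_sd = 0, seed = 5))
  px <- ph$image$pixels
  expect_equal(px[1, 1], 0)
  expect_equal(sort(unique(c(px[1:50, ], px[, 1:50]))), 0)
  expect_gt(max(px), 200)
  # bones carve out a nontrivial bright region
  expect_gt(mean(px > 0), 0.05)
  expect_lt(mean(px > 0), 0.5)
})

test_that("sampled datasets are class-consistent and reproducible", {
  n <- c(normal = 5, mild = 5, moderate = 5)
  ds <- sample_phantom_dataset(n, seed = 99, render = FALSE)
  expect_equal(nrow(ds$manifest), 15)
  expect_equal(unname(table(ds$manifest$class)[foot_classes]),
               unname(n), ignore_attr = TRUE)
  for (ph in ds$phantoms) {
    dg <- diagnose_angles(ph$truth$angles)
    expect_identical(as.character(dg$final), ph$truth$class)
    # unanimity: every angle votes the phantom's class
    expect_true(all(tidy(dg)$vote == ph$truth$class))
  }
  ds2 <- sample_phantom_dataset(n, seed = 99, render = FALSE)
  expect_identical(ds$manifest, ds2$manifest)
})

test_that("template construction inverts poi_center", {
  fx <- pipeline_fixture()
  lib <- fx$lib
  expect_lte(length(lib$templates), 9 * length(fx$tds$phantoms))
  expect_equal(length(lib$templates), 9 * length(fx$tds$phantoms))
  lmk <- dataset_landmarks(fx$tds)
  for (tm in lib$templates[c(1, 10, 25, 50)]) {
    expect_equal(dim(tm$patch), c(100, 100))
  }
  # crop start = rounded landmark - 50 for a spot-checked landmark
  g <- lmk[lmk$image_id == names(fx$tds$phantoms)[1] & lmk$poi_id == 5, ]
  patch <- cut_patch(fx$tds$phantoms[[1]]$image,
                     round(g$x) - 50, round(g$y) - 50)
  tm5 <- lib$templates[vapply(lib$templates, function(t)
    t$poi_id == 5 && t$source_id == g$image_id, TRUE)][[1]]
  expect_identical(tm5$patch, patch)
})

test_that("template library round-trips through disk", {
  fx <- pipeline_fixture()
  sub <- template_library(fx$lib$templates[1:18])
  dir <- withr::local_tempdir()
  write_template_library(sub, dir)
  expect_true(file.exists(file.path(dir, "index.csv")))
  back <- read_template_library(dir)
  expect_equal(length(back$templates), 18)
  expect_equal(back$templates[[3]]$patch, sub$templates[[3]]$patch)
  expect_equal(vapply(back$templates, `[[`, 1L, "poi_id"),
               vapply(sub$templates, `[[`, 1L, "poi_id"))
})

test_that("augmentation preserves angles and transforms vectors correctly", {
  ph <- generate_phantom(phantom_spec(target_class = "mild", seed = 31),
                         render = FALSE)
  base <- ph$truth$angles
  for (s in 1:10) {
    aug <- augment_phantom(ph, seed = s)
    m <- measure_foot_angles(aug$truth$landmarks)
    expect_lt(abs(m$cia_deg - base$cia_deg), 1e-6)
    expect_lt(abs(m$aa_deg - base$aa_deg), 1e-6)
    expect_lt(abs(m$ma_deg - base$ma_deg), 1e-6)
    # the vector between two landmarks is the original rotated and scaled
    th <- aug$spec$rotation * pi / 180; sc <- aug$spec$scale
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                byrow = TRUE)
    v0 <- unlist(ph$truth$landmarks[6, c("x", "y")]) -
      unlist(ph$truth$landmarks[5, c("x", "y")])
    v1 <- unlist(aug$truth$landmarks[6, c("x", "y")]) -
      unlist(aug$truth$landmarks[5, c("x", "y")])
    expect_equal(v1, as.vector(sc * R %*% v0), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("augmented images track their landmarks", {
  ph <- generate_phantom(phantom_spec(target_class = "normal", seed = 41,
                                      noise_sd = 0, blur_sd = 0))
  aug <- augment_phantom(ph, seed = 5)
  # bright pixels should surround each transformed landmark
  px <- aug$image$pixels
  for (i in c(5, 9)) {
    g <- aug$truth$landmarks[aug$truth$landmarks$poi_id == i, ]
    win <- px[round(g$y) + 1 + (-5:5), round(g$x) + 1 + (-5:5)]
    expect_gt(mean(win), 30)
  }
  # rotation 0, scale 1 is the identity on landmarks
  same <- augment_phantom(ph, rotation_range = c(-1e-9, 1e-9),
                          max_scale = 1 + 1e-12, seed = 1)
  expect_equal(same$truth$landmarks$x, ph$truth$landmarks$x,
               tolerance = 1e-6)
})

test_that("phantom datasets write standard files to disk", {
  ds <- sample_phantom_dataset(c(normal = 1, mild = 1), seed = 17)
  dir <- withr::local_tempdir()
  write_phantom_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "landmarks.csv")))
  expect_length(list.files(file.path(dir, "images")), 2)
  lmk <- readr::read_csv(file.path(dir, "landmarks.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(lmk), 18)
  expect_true(all(lmk$x == round(lmk$x)))
})
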