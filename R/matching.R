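# --- FFT matching engine -------------------------------------------------
#
# R(sy, sx) = sum((T - W)^2) / sqrt(sum(T^2) * sum(W^2)) for the window W
# at 0-based start (sx, sy).  The cross term sum(T * W) is a valid-region
# cross-correlation computed by FFT (the template is zero-padded to the
# image size, so no circular wrap reaches a valid start); window energies
# come from an exact integral image.  Two real templates are packed into
# one complex FFT pair, halving transform count.

# per-start window energy via integral image of squared intensities
window_sq_sum <- function(px, th, tw) {
  H <- nrow(px); W <- ncol(px)
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- apply(apply(px * px, 2, cumsum), 1, cumsum) |> t()
  oh <- H - th + 1; ow <- W - tw + 1
  S[(th + 1):(H + 1), (tw + 1):(W + 1)] -
    S[1:oh, (tw + 1):(W + 1)] -
    S[(th + 1):(H + 1), 1:ow] +
    S[1:oh, 1:ow]
}

# precompute the (index-reversed) spectra of zero-padded template pairs;
# reusable across images of the same size
pack_template_ffts <- function(patches, H, W) {
  th <- nrow(patches[[1]]); tw <- ncol(patches[[1]])
  stopifnot(all(vapply(patches, nrow, 1L) == th),
            all(vapply(patches, ncol, 1L) == tw))
  revi <- c(1, if (H > 1) H:2)
  revj <- c(1, if (W > 1) W:2)
  n <- length(patches)
  Zr <- vector("list", ceiling(n / 2))
  for (k in seq(1, n, by = 2)) {
    T1 <- patches[[k]]
    T2 <- if (k + 1 <= n) patches[[k + 1]] else NULL
    tp <- matrix(0 + 0i, H, W)
    tp[1:th, 1:tw] <- T1 + (if (is.null(T2)) 0 else 1i * T2)
    Z <- fft(tp)
    Zr[[(k + 1) %/% 2]] <- Z[revi, revj]
  }
  list(Zr = Zr, t2 = vapply(patches, function(p) sum(p^2), 1),
       n = n, th = th, tw = tw, H = H, W = W)
}

# list of score maps for same-sized templates against one image
score_map_engine <- function(px, patches = NULL, prep = NULL) {
  H <- nrow(px); W <- ncol(px)
  if (is.null(prep)) prep <- pack_template_ffts(patches, H, W)
  stopifnot(prep$H == H, prep$W == W)
  th <- prep$th; tw <- prep$tw
  oh <- H - th + 1; ow <- W - tw + 1
  FI <- fft(px)
  win2 <- window_sq_sum(px, th, tw)
  n <- prep$n
  corr <- vector("list", n)
  for (k in seq(1, n, by = 2)) {
    # correlation of the packed template pair collapses to FI * Z[-k mod N]:
    # Re(ifft) is corr(T1), Im(ifft) is corr(T2)
    Cc <- fft(FI * prep$Zr[[(k + 1) %/% 2]], inverse = TRUE) / (H * W)
    corr[[k]] <- Re(Cc)[1:oh, 1:ow, drop = FALSE]
    if (k + 1 <= n) corr[[k + 1]] <- Im(Cc)[1:oh, 1:ow, drop = FALSE]
  }
  lapply(seq_len(n), function(k) {
    t2 <- prep$t2[k]
    if (t2 <= 1e-12) {
      R <- matrix(1, oh, ow)
    } else {
      R <- (t2 - 2 * corr[[k]] + win2) / sqrt(t2 * win2)
      R[win2 <= 1e-12] <- 1
      R <- pmin(pmax(R, 0), 1)
    }
    R
  })
}

#' Normalized squared-difference score map
#'
#' Slides a template over the image and computes, for every valid 0-based
#' start `(Sx, Sy)`, the normalized squared difference
#' \deqn{R = \frac{\sum (T - W)^2}{\sqrt{\sum T^2 \cdot \sum W^2}}}
#' between the template \eqn{T} and the image window \eqn{W} starting
#' there.  Lower is better; 0 is a perfect match.  Scores are clamped to
#' `[0, 1]` (ratios above 1 carry no match information).  Windows or
#' templates with zero energy are assigned the worst score 1; a warning is
#' raised when the template itself is all zero or when every window is
#' degenerate (isolated zero windows, e.g. padded black borders, are
#' expected and stay silent).
#'
#' @param img A [radiograph] or a numeric matrix.
#' @param tmpl A `template` (see [template_library]) or a numeric matrix no
#'   larger than the image.
#' @return Matrix of class `score_map`: entry `[sy + 1, sx + 1]` is
#'   `R(Sx = sx, Sy = sy)`.
#' @export
score_map <- function(img, tmpl) {
  px <- if (inherits(img, "radiograph")) img$pixels else img
  tp <- if (inherits(tmpl, "template")) tmpl$patch else tmpl
  stopifnot(is.matrix(px), is.matrix(tp))
  if (nrow(tp) > nrow(px) || ncol(tp) > ncol(px)) {
    abort("Template is larger than the image.",
          class = "flatfootr_error_dimension")
  }
  out <- score_map_engine(px, list(tp))[[1]]
  if (all(tp == 0)) {
    warn("All-zero template: every score set to the worst value 1.")
  } else if (all(out >= 1)) {
    warn("All windows degenerate or non-matching at score 1.")
  }
  class(out) <- c("score_map", class(out))
  out
}

#' Threshold a score map into candidate patches
#'
#' Keeps every start position whose similarity `1 - R` reaches `threshold`,
#' in row-major scan order (y fastest within a row ordering: left-to-right,
#' top-to-bottom).  If more than `top_k` qualify, the `top_k` with highest
#' similarity are kept, ties resolved by scan order.  An empty result is
#' returned as a zero-row tibble, not an error.
#'
#' @param map A [score_map].
#' @param poi_id Landmark identity (1-9) the template belongs to.
#' @param threshold Minimum similarity in (0, 1); default 0.90.
#' @param top_k Cap on candidates kept (default 50); `Inf` disables.
#' @param source_id Optional template source label carried through.
#' @return Tibble with columns `poi_id, sx, sy, similarity, source_id`
#'   (`sx`, `sy` are 0-based patch starts).
#' @export
find_candidates <- function(map, poi_id, threshold = 0.90, top_k = 50,
                            source_id = NA_character_) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.",
          class = "flatfootr_error_config")
  }
  sim <- 1 - unclass(map)
  keep <- which(t(sim) >= threshold)   # t(): row-major scan order
  if (length(keep) == 0L) {
    return(tibble(poi_id = integer(), sx = integer(), sy = integer(),
                  similarity = double(), source_id = character()))
  }
  nc <- ncol(sim)
  sx <- (keep - 1L) %% nc          # 0-based column
  sy <- (keep - 1L) %/% nc         # 0-based row
  s <- sim[cbind(sy + 1L, sx + 1L)]
  out <- tibble(poi_id = as.integer(poi_id), sx = as.integer(sx),
                sy = as.integer(sy), similarity = s,
                source_id = source_id)
  if (is.finite(top_k) && nrow(out) > top_k) {
    ord <- order(-out$similarity, seq_len(nrow(out)))
    out <- out[sort(ord[seq_len(top_k)]), ]
  }
  out
}

# Pick k templates spanning the appearance space: the most central patch
# first, then greedily the template farthest (normalized SSD) from those
# already chosen.  Deterministic; much better coverage than taking every
# n-th library entry when geometry varies within a landmark class.
thin_templates <- function(tms, k) {
  n <- length(tms)
  if (n <= k) return(tms)
  P <- lapply(tms, `[[`, "patch")
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sum((P[[i]] - P[[j]])^2) /
        sqrt(sum(P[[i]]^2) * sum(P[[j]]^2))
      D[i, j] <- d; D[j, i] <- d
    }
  }
  sel <- which.min(rowSums(D))
  while (length(sel) < k) {
    rest <- setdiff(seq_len(n), sel)
    dmin <- vapply(rest, function(r) min(D[r, sel]), 1)
    sel <- c(sel, rest[which.max(dmin)])
  }
  tms[sort(sel)]
}

#' Precompute the reusable half of template matching
#'
#' Thins the library per landmark to a diverse subset (greedy
#' farthest-point selection under the normalized squared-difference
#' distance, starting from the most central patch) and precomputes the
#' padded template spectra for a given image size, so that matching many
#' images against one library costs one image FFT plus one inverse FFT
#' per template pair each.
#'
#' @param library A [template_library].
#' @param size Image edge length the matcher will be used on.
#' @param templates_per_poi Per-landmark template cap (see
#'   [match_templates]).
#' @return Object of class `poi_matcher`.
#' @export
prepare_matcher <- function(library, size = 1024, templates_per_poi = Inf) {
  stopifnot(inherits(library, "template_library"))
  pois <- sort(unique(map_dbl(library$templates, "poi_id")))
  sel <- vector("list", length(pois))
  for (k in seq_along(pois)) {
    tms <- library$templates[map_dbl(library$templates, "poi_id") ==
                               pois[k]]
    if (is.finite(templates_per_poi)) {
      tms <- thin_templates(tms, templates_per_poi)
    }
    sel[[k]] <- tms
  }
  flat <- unlist(sel, recursive = FALSE)
  structure(
    list(pois = pois, sel = sel,
         grp = rep(seq_along(pois), times = lengths(sel)),
         prep = pack_template_ffts(lapply(flat, `[[`, "patch"),
                                   size, size),
         size = size),
    class = "poi_matcher")
}

#' Localization similarity between a predicted and a true landmark
#'
#' `1 / (1 + d)` with `d` the Euclidean pixel distance; 1 is an exact hit.
#'
#' @param gt,pred Length-2 numeric vectors `(x, y)`, or two-column
#'   matrices of points compared row-wise.
#' @return Numeric score(s) in (0, 1].
#' @export
localization_score <- function(gt, pred) {
  gt <- rbind(gt); pred <- rbind(pred)
  d <- sqrt(rowSums((gt - pred)^2))
  unname(1 / (1 + d))
}

#' Match a template library against a radiograph
#'
#' Runs [score_map] + [find_candidates] for every template and merges
#' candidates per landmark.  Candidate order within a landmark is template
#' order then row-major scan order — the order the tie rule "first one
#' wins" refers to.  When several templates flag the same start for the
#' same landmark, the occurrence with the highest similarity is kept (at
#' its earliest position).
#'
#' @param img A [radiograph].
#' @param library A [template_library].
#' @param threshold Similarity threshold (default 0.90).
#' @param top_k Per-landmark candidate cap after merging (default 50).
#' @param templates_per_poi Optional cap on templates used per landmark:
#'   the library is thinned to a diverse subset per PoI (greedy
#'   farthest-point selection in patch space). `Inf` uses all.
#' @param matcher Optional [prepare_matcher] object; supplying one reuses
#'   the precomputed template spectra across images (the `library`,
#'   `templates_per_poi` arguments are then ignored).
#' @return Tibble of candidates: `poi_id, sx, sy, similarity, source_id`.
#' @export
match_templates <- function(img, library = NULL, threshold = 0.90,
                            top_k = 50, templates_per_poi = Inf,
                            matcher = NULL) {
  stopifnot(inherits(img, "radiograph"))
  px <- img$pixels
  if (is.null(matcher)) {
    matcher <- prepare_matcher(library, size = nrow(px),
                               templates_per_poi = templates_per_poi)
  }
  stopifnot(inherits(matcher, "poi_matcher"))
  pois <- matcher$pois
  # one engine call for every template: image FFT and window energies are
  # computed once per image, template spectra once per matcher
  maps <- score_map_engine(px, prep = matcher$prep)
  grp <- matcher$grp
  out <- vector("list", length(pois))
  for (k in seq_along(pois)) {
    pid <- pois[k]
    tms <- matcher$sel[[k]]
    cands <- list_rbind(map2(maps[grp == k], tms, function(m, tm) {
      class(m) <- c("score_map", class(m))
      find_candidates(m, pid, threshold = threshold, top_k = top_k,
                      source_id = tm$source_id)
    }))
    if (nrow(cands) > 0L) {
      # de-duplicate identical starts: keep best similarity, earliest order
      cands <- cands |>
        mutate(.ord = seq_len(dplyr::n())) |>
        group_by(.data$sx, .data$sy) |>
        arrange(desc(.data$similarity), .data$.ord, .by_group = TRUE) |>
        slice(1) |>
        ungroup() |>
        arrange(.data$.ord) |>
        select(-".ord")
      if (is.finite(top_k) && nrow(cands) > top_k) {
        ord <- order(-cands$similarity, seq_len(nrow(cands)))
        cands <- cands[sort(ord[seq_len(top_k)]), ]
      }
    }
    out[[k]] <- cands
  }
  list_rbind(out)
}
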