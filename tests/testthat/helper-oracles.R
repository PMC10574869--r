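# Independent oracles used across tests.  These deliberately avoid the
# package's computational paths (double loops, enumeration, direction
# vectors) so agreement is evidence, not tautology.

# brute-force normalized squared-difference map (double loop)
brute_score_map <- function(img, tm) {
  th <- nrow(tm); tw <- ncol(tm)
  oh <- nrow(img) - th + 1; ow <- ncol(img) - tw + 1
  R <- matrix(NA_real_, oh, ow)
  for (sy in 0:(oh - 1)) {
    for (sx in 0:(ow - 1)) {
      W <- img[(sy + 1):(sy + th), (sx + 1):(sx + tw)]
      t2 <- sum(tm^2); w2 <- sum(W^2)
      R[sy + 1, sx + 1] <- if (t2 <= 1e-12 || w2 <= 1e-12) 1 else
        min(1, max(0, sum((tm - W)^2) / sqrt(t2 * w2)))
    }
  }
  R
}

# angle between two lines of slopes m1, m2 via unit direction vectors
vector_angle_oracle <- function(m1, m2) {
  dir <- function(m) {
    if (is.infinite(m)) c(0, 1) else c(1, m) / sqrt(1 + m^2)
  }
  d <- abs(sum(dir(m1) * dir(m2)))
  acos(min(1, d)) * 180 / pi
}

# majority vote by exhaustive count, tie -> CIA's vote
vote_oracle <- function(cia, ma, aa) {
  votes <- c(cia, ma, aa)
  counts <- table(factor(votes, levels = flatfootr::foot_classes))
  if (sum(counts == max(counts)) > 1) cia else
    names(counts)[which.max(counts)]
}

# per-item one-vs-rest tally
tally_oracle <- function(pred, truth, cl) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == cl; t <- truth[i] == cl
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
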