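#' Default angle-interval table for severity classification
#'
#' Encodes the published degree intervals, with the two printed gaps
#' closed: the arch-angle mild class runs over the full (165, 180) span
#' between the normal and moderate rows, and Meary's mild class extends to
#' (but excludes) 15 where moderate begins.  At the shared CIA boundary of
#' exactly 20 degrees the normal row (inclusive) wins.
#'
#' Columns: `angle` (`"cia"`, `"aa"`, `"ma"`), `class`, `lo`, `hi`,
#' `lo_closed`, `hi_closed` — value v belongs to the row when
#' `lo (<|<=) v (<|<=) hi` per the closed flags.  Open-ended sides use
#' infinities.
#'
#' @return Tibble describing the intervals.
#' @export
foot_intervals <- function() {
  tibble::tribble(
    ~angle, ~class,     ~lo,   ~hi,  ~lo_closed, ~hi_closed,
    "cia", "normal",     20,    30,  TRUE,  TRUE,
    "cia", "mild",       10,    20,  TRUE,  FALSE,
    "cia", "moderate", -Inf,    10,  FALSE, FALSE,
    "aa",  "normal",    150,   165,  TRUE,  TRUE,
    "aa",  "mild",      165,   180,  FALSE, FALSE,
    "aa",  "moderate",  180,   Inf,  TRUE,  FALSE,
    "ma",  "normal",      0,     4,  TRUE,  FALSE,
    "ma",  "mild",        4,    15,  TRUE,  FALSE,
    "ma",  "moderate",   15,   Inf,  TRUE,  FALSE
  )
}

#' Classify one measured angle into a severity class
#'
#' Values outside every stated interval (the healthy-side extremes, e.g. a
#' cavus-range CIA above 30, an arch angle below 150, or a negative
#' Meary's angle) are mapped to the class of the nearest interval boundary
#' and flagged out-of-range rather than silently classified.
#'
#' @param name Angle name: `"cia"`, `"aa"` or `"ma"` (case-insensitive).
#' @param value Measured angle in degrees (finite).
#' @param table Interval table, by default [foot_intervals()].
#' @return One-row tibble `angle, value, class, out_of_range`.
#' @export
classify_angle <- function(name, value, table = foot_intervals()) {
  name <- tolower(name)
  if (!name %in% unique(table$angle)) {
    abort(paste0("Unknown angle name: ", name),
          class = "flatfootr_error_config")
  }
  if (!is.finite(value)) {
    abort("Angle value must be finite.", class = "flatfootr_error_input")
  }
  rows <- table[table$angle == name, ]
  inside <- (ifelse(rows$lo_closed, value >= rows$lo, value > rows$lo) &
             ifelse(rows$hi_closed, value <= rows$hi, value < rows$hi))
  if (any(inside)) {
    cls <- rows$class[which(inside)[1]]
    oor <- FALSE
  } else {
    # nearest finite boundary's class
    bounds <- c(rows$lo, rows$hi)
    cls_of <- rep(rows$class, 2L)
    ok <- is.finite(bounds)
    i <- which.min(abs(bounds[ok] - value))
    cls <- cls_of[ok][i]
    oor <- TRUE
  }
  tibble(angle = name, value = value,
         class = factor(cls, levels = foot_classes), out_of_range = oor)
}

#' Combine the three per-angle votes into a final diagnosis
#'
#' The class with the maximum vote count wins.  The only possible tie with
#' three votes over three classes is a 1-1-1 split, which is broken by the
#' angle-reliability priority CIA > MA > AA (the calcaneal inclination is
#' the most dependable measurement, the arch angle the least): the final
#' class is the vote of the highest-priority angle.
#'
#' @param votes Named character/factor vector of exactly three classes,
#'   names `cia`, `ma`, `aa` (any order).
#' @param flags Optional character vector of out-of-range warnings carried
#'   into the result.
#' @return Object of class `foot_diagnosis`: list with `votes`, `counts`,
#'   `final`, `tie_broken`, `flags`.
#' @export
majority_vote <- function(votes, flags = character()) {
  need <- c("cia", "ma", "aa")
  votes <- setNames(as.character(votes), tolower(names(votes)))
  miss <- setdiff(need, names(votes))
  if (length(miss) > 0 || length(votes) != 3L) {
    abort(paste0("Incomplete measurement; missing angle vote(s): ",
                 paste(miss, collapse = ", ")),
          class = "flatfootr_error_incomplete")
  }
  if (!all(votes %in% foot_classes)) {
    abort("Votes must be normal/mild/moderate.",
          class = "flatfootr_error_input")
  }
  counts <- table(factor(votes, levels = foot_classes))
  top <- max(counts)
  tie <- sum(counts == top) > 1L          # only possible as a 1-1-1 split
  final <- if (tie) votes[["cia"]] else names(counts)[which.max(counts)]
  structure(
    list(votes = votes[need],
         counts = setNames(as.integer(counts), foot_classes),
         final = factor(final, levels = foot_classes),
         tie_broken = tie, flags = flags),
    class = "foot_diagnosis")
}

#' Diagnose a measured angle set
#'
#' Classifies each angle against the interval table and majority-votes the
#' result.
#'
#' @param angles One-row tibble `cia_deg, aa_deg, ma_deg` (as produced by
#'   [measure_foot_angles]); an `image_id` column is carried through.
#' @param table Interval table (default [foot_intervals()]).
#' @return A `foot_diagnosis` with an `angles` element attached.
#' @export
diagnose_angles <- function(angles, table = foot_intervals()) {
  stopifnot(nrow(angles) == 1L)
  per <- bind_rows(
    classify_angle("cia", angles$cia_deg, table),
    classify_angle("ma",  angles$ma_deg,  table),
    classify_angle("aa",  angles$aa_deg,  table))
  flags <- sprintf("%s value %.2f out of stated intervals",
                   per$angle[per$out_of_range], per$value[per$out_of_range])
  dg <- majority_vote(setNames(as.character(per$class), per$angle),
                      flags = flags)
  dg$angles <- angles
  dg$per_angle <- per
  dg
}

#' @export
print.foot_diagnosis <- function(x, ...) {
  cat("<foot_diagnosis> final:", as.character(x$final),
      if (x$tie_broken) "(tie broken by CIA > MA > AA)" else "", "\n")
  cat("  votes: ", paste(names(x$votes), x$votes, sep = "=",
                         collapse = "  "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
tidy.foot_diagnosis <- function(x, ...) {
  tibble(angle = names(x$votes), vote = unname(x$votes),
         value = if (!is.null(x$per_angle))
           x$per_angle$value[match(names(x$votes), x$per_angle$angle)]
         else NA_real_,
         out_of_range = if (!is.null(x$per_angle))
           x$per_angle$out_of_range[match(names(x$votes),
                                          x$per_angle$angle)]
         else NA)
}

#' @export
glance.foot_diagnosis <- function(x, ...) {
  tibble(final = as.character(x$final),
         n_normal = x$counts[["normal"]], n_mild = x$counts[["mild"]],
         n_moderate = x$counts[["moderate"]],
         tie_broken = x$tie_broken, n_flags = length(x$flags))
}
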