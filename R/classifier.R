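# Latent-space tissue classification: a 2 x 2 rectangular partition of the
# 2-D latent plane, per-lesion tissue scoring, boundary calibration from a
# labelled subset, and cohort summaries.

default_class_map <- function() {
  c(lo_lo = 1L, lo_hi = 2L, hi_lo = 3L, hi_hi = 4L)
}

#' Rectangular latent-space class boundaries
#'
#' The latent plane is split by an x and a y threshold into four half-open
#' quadrants, each mapped bijectively onto one tissue class. With the default
#' map: `x < xt, y < yt` is class 1 (patent); `x < xt, y >= yt` class 2
#' (partially patent); `x >= xt, y < yt` class 3 (mostly occluded, soft);
#' `x >= xt, y >= yt` class 4 (mostly occluded, hard). Upper sides are
#' closed (`>=`) so the partition is exact. Thresholds default to 0.8, the
#' published by-inspection values; for a freshly trained model use
#' [calibrate_boundaries()] since latent geometry varies per training run.
#'
#' @param x_threshold,y_threshold Latent thresholds, default 0.8.
#' @param class_map Named integer vector assigning classes to the quadrants
#'   `lo_lo`, `lo_hi`, `hi_lo`, `hi_hi`; must be a permutation of 1:4.
#' @return A `class_boundaries`.
#' @export
class_boundaries <- function(x_threshold = 0.8, y_threshold = 0.8,
                             class_map = default_class_map()) {
  stopifnot(is.finite(x_threshold), is.finite(y_threshold))
  quadrants <- c("lo_lo", "lo_hi", "hi_lo", "hi_hi")
  if (!setequal(names(class_map), quadrants) ||
      !setequal(as.integer(class_map), 1:4))
    stop("`class_map` must map the quadrants lo_lo/lo_hi/hi_lo/hi_hi ",
         "bijectively onto classes 1-4", call. = FALSE)
  structure(list(x_threshold = as.numeric(x_threshold),
                 y_threshold = as.numeric(y_threshold),
                 class_map = vapply(quadrants, function(q)
                   as.integer(class_map[[q]]), integer(1))),
            class = "class_boundaries")
}

#' @export
print.class_boundaries <- function(x, ...) {
  cat(sprintf("<class_boundaries> x >= %.3g | y >= %.3g; map %s\n",
              x$x_threshold, x$y_threshold,
              paste(names(x$class_map), x$class_map, sep = "->",
                    collapse = " ")))
  ag <- attr(x, "agreement")
  if (!is.null(ag)) cat(sprintf("  calibration agreement: %.1f%%\n", 100 * ag))
  invisible(x)
}

#' Classify latent points into tissue classes
#'
#' Assigns each point exactly one class from its half-open quadrant (see
#' [class_boundaries()]).
#'
#' @param points Data frame with numeric columns `x` and `y` (finite).
#' @param boundaries A [class_boundaries()].
#' @return The input tibble with an integer `class` column appended.
#' @export
#' @examples
#' classify_points(data.frame(x = c(0, 0), y = c(0, 3)), class_boundaries())
classify_points <- function(points, boundaries = class_boundaries()) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)),
            inherits(boundaries, "class_boundaries"))
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    stop("latent coordinates must be finite", call. = FALSE)
  quad_idx <- 1L + 2L * (points$x >= boundaries$x_threshold) +
    (points$y >= boundaries$y_threshold)  # lo_lo, lo_hi, hi_lo, hi_hi
  out <- tibble::as_tibble(points)
  out$class <- unname(boundaries$class_map[quad_idx])
  out
}

#' Score a lesion from its per-slice tissue classes
#'
#' Applies the fixed score map ([tissue_score_map()]): the average tissue
#' score is the sum of per-slice scores divided by the number of slices, and
#' class percentages are the share of slices per class (reported to one
#' decimal; raw fractions retained).
#'
#' @param classes Non-empty integer vector of per-slice classes in 1-4 (in
#'   axial order), or a data frame with a `class` column as produced by
#'   [classify_points()].
#' @param lesion_id Lesion identifier.
#' @return A `lesion_report`; see [tidy.lesion_report()] for the one-row
#'   tabular form.
#' @export
score_lesion <- function(classes, lesion_id = "lesion") {
  if (is.data.frame(classes)) classes <- classes$class
  classes <- as.integer(classes)
  if (length(classes) == 0L) stop("no slices to score", call. = FALSE)
  if (!all(classes %in% 1:4))
    stop("classes must lie in {1, 2, 3, 4}", call. = FALSE)
  scores <- tissue_score_map()
  n <- length(classes)
  counts <- tabulate(classes, 4L)
  fractions <- counts / n
  structure(list(lesion_id = lesion_id,
                 per_slice_class = classes,
                 n_slices = n,
                 average_tissue_score = sum(scores[classes]) / n,
                 class_fractions = fractions,
                 class_percentages = round(100 * fractions, 1)),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf("<lesion_report> '%s': %d slices, average tissue score %.2f\n",
              x$lesion_id, x$n_slices, x$average_tissue_score))
  cat(sprintf("  class percentages: I %.1f  II %.1f  III %.1f  IV %.1f\n",
              x$class_percentages[1], x$class_percentages[2],
              x$class_percentages[3], x$class_percentages[4]))
  invisible(x)
}

#' Tidy a lesion report
#'
#' @param x A `lesion_report`.
#' @param ... Unused.
#' @return One-row tibble: `lesion_id`, `n_slices`, `pct_class_1` ..
#'   `pct_class_4` (one decimal) and `average_tissue_score`.
#' @method tidy lesion_report
#' @export
tidy.lesion_report <- function(x, ...) {
  tibble::tibble(lesion_id = x$lesion_id, n_slices = x$n_slices,
                 pct_class_1 = x$class_percentages[1],
                 pct_class_2 = x$class_percentages[2],
                 pct_class_3 = x$class_percentages[3],
                 pct_class_4 = x$class_percentages[4],
                 average_tissue_score = x$average_tissue_score)
}

#' @method glance lesion_report
#' @export
glance.lesion_report <- function(x, ...) tidy(x)

#' Calibrate latent-space boundaries from labelled points
#'
#' Automates the by-inspection partition of the latent plane: grid search
#' over candidate (x, y) threshold pairs (midpoints between sorted unique
#' coordinates, thinned to at most `max_candidates` per axis) and all 24
#' quadrant-to-class assignments, maximizing agreement with the labels. Ties
#' resolve to the first (smallest-threshold) maximum.
#'
#' @param points Data frame with columns `x`, `y` and optionally `label`.
#' @param labels Integer labels in 1-4 (taken from `points$label` when
#'   omitted); every class must be represented.
#' @param max_candidates Maximum threshold candidates per axis, default 61.
#' @return A [class_boundaries()] with attribute `agreement` (achieved
#'   fraction of matching labels).
#' @export
calibrate_boundaries <- function(points, labels = NULL, max_candidates = 61) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (is.null(labels)) labels <- points$label
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(points))
  missing_cls <- setdiff(1:4, unique(labels))
  if (length(missing_cls) > 0L)
    stop("no labelled points for class ", missing_cls[1], call. = FALSE)

  cand <- function(v) {
    u <- sort(unique(v))
    mids <- (u[-1] + u[-length(u)]) / 2
    if (length(mids) > max_candidates)
      mids <- stats::quantile(mids, seq(0, 1, length.out = max_candidates),
                              names = FALSE)
    if (length(mids) == 0L) mids <- u[1]
    mids
  }
  xs <- cand(points$x)
  ys <- cand(points$y)
  perms <- permutations4()
  n <- nrow(points)

  best <- list(agree = -1)
  for (xt in xs) {
    xhi <- points$x >= xt
    for (yt in ys) {
      quad <- 1L + 2L * xhi + (points$y >= yt)
      tab <- matrix(tabulate(labels + 4L * (quad - 1L), 16L), 4, 4)
      for (pi in seq_len(nrow(perms))) {
        agree <- sum(tab[cbind(perms[pi, ], 1:4)])
        if (agree > best$agree) best <- list(agree = agree, xt = xt, yt = yt,
                                             perm = perms[pi, ])
      }
    }
  }
  b <- class_boundaries(best$xt, best$yt,
                        class_map = stats::setNames(best$perm,
                          c("lo_lo", "lo_hi", "hi_lo", "hi_hi")))
  attr(b, "agreement") <- best$agree / n
  b
}

# the 24 permutations of 1:4, rows = assignments quadrant -> class
permutations4 <- function() {
  out <- matrix(0L, 24, 4)
  i <- 1L
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    out[i, ] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
    i <- i + 1L
  }
  out
}

#' Summarize a lesion cohort
#'
#' Per tissue class, the minimum and maximum of the nonzero class percentages
#' across lesions, plus the total slice count.
#'
#' @param cohort A cohort table (tibble with columns `pct_class_1` ..
#'   `pct_class_4` and `n_slices`, one row per lesion, as produced by
#'   [tidy.lesion_report()] and `dplyr::bind_rows()`), or a list of
#'   `lesion_report`s.
#' @return Tibble with one row per class: `class`, `min_pct`, `max_pct`
#'   (NA when the class is absent from every lesion), `n_lesions_present`
#'   and `total_slices` (constant column).
#' @export
summarize_cohort <- function(cohort) {
  if (is.list(cohort) && !is.data.frame(cohort) &&
      all(vapply(cohort, inherits, logical(1), "lesion_report")))
    cohort <- dplyr::bind_rows(lapply(cohort, tidy))
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L,
            all(c(paste0("pct_class_", 1:4), "n_slices") %in% names(cohort)))
  total <- sum(cohort$n_slices)
  purrr::map_dfr(1:4, function(cl) {
    p <- cohort[[paste0("pct_class_", cl)]]
    nz <- p[p > 0]
    tibble::tibble(class = cl,
                   min_pct = if (length(nz)) min(nz) else NA_real_,
                   max_pct = if (length(nz)) max(nz) else NA_real_,
                   n_lesions_present = length(nz),
                   total_slices = total)
  })
}

#' Plot latent points with class boundaries
#'
#' Scatter of latent embeddings, colored by tissue class when available,
#' with the rectangular class boundaries drawn as dashed lines.
#'
#' @param points Data frame with `x`, `y` and optionally `class` or `label`.
#' @param boundaries Optional [class_boundaries()] to draw.
#' @return A ggplot.
#' @export
plot_latent_space <- function(points, boundaries = NULL) {
  stopifnot(is.data.frame(points))
  col <- if ("class" %in% names(points)) "class"
         else if ("label" %in% names(points)) "label" else NULL
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if (is.null(col)) {
    p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = factor(.data[[col]])),
                            alpha = 0.6, size = 0.8) +
      ggplot2::labs(color = "tissue class")
  }
  if (!is.null(boundaries)) {
    p <- p +
      ggplot2::geom_vline(xintercept = boundaries$x_threshold,
                          linetype = "dashed", color = "red") +
      ggplot2::geom_hline(yintercept = boundaries$y_threshold,
                          linetype = "dashed", color = "red")
  }
  p + ggplot2::labs(x = "latent x", y = "latent y") + ggplot2::theme_minimal()
}

#' Plot a per-slice tissue-class map
#'
#' Greyscale strip of the tissue class of each axial slice along the lesion
#' (dark = hard tissue, light = patent).
#'
#' @param report A `lesion_report`.
#' @return A ggplot.
#' @export
plot_class_map <- function(report) {
  stopifnot(inherits(report, "lesion_report"))
  df <- tibble::tibble(slice = seq_along(report$per_slice_class),
                       class = report$per_slice_class)
  greys <- c(`1` = "grey90", `2` = "grey65", `3` = "grey40", `4` = "grey10")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = 1,
                                   fill = factor(.data$class))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = greys, name = "tissue class",
                               drop = FALSE) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "axial slice", y = NULL,
                  title = sprintf("%s (average tissue score %.2f)",
                                  report$lesion_id,
                                  report$average_tissue_score)) +
    ggplot2::theme_minimal()
}

#' @method autoplot lesion_report
#' @export
autoplot.lesion_report <- function(object, ...) plot_class_map(object)
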