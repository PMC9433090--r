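#' Maximum-intensity z-projection
#'
#' Collapses a `(z, y, x)` stack to a 2-D image by taking the per-pixel
#' maximum over z. With `z_window` set, only a slab of that many planes
#' centred on the globally brightest plane is projected — useful when a
#' second, deeper neuron should be excluded.
#'
#' @param stack 3-D numeric array indexed `(z, y, x)`.
#' @param z_window Optional odd number of planes to project around the
#'   brightest plane; `NULL` (default) projects the full stack.
#' @return Numeric matrix `(y, x)`.
#' @export
max_projection <- function(stack, z_window = NULL) {
  if (length(dim(stack)) != 3) stop("stack must be a 3-D array", call. = FALSE)
  if (!is.null(z_window)) {
    plane_max <- apply(stack, 1, max)
    zc <- which.max(plane_max)
    h <- floor(z_window / 2)
    zr <- max(1, zc - h):min(dim(stack)[1], zc + h)
    stack <- stack[zr, , , drop = FALSE]
  }
  apply(stack, c(2, 3), max)
}

median_filter_3x3 <- function(image) {
  ny <- nrow(image); nx <- ncol(image)
  # replicate-pad by one pixel, then take the median of each 3x3 neighbourhood
  padded <- image[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]
  shifts <- array(NA_real_, dim = c(ny, nx, 9))
  idx <- 1
  for (dy in 0:2) {
    for (dx in 0:2) {
      shifts[, , idx] <- padded[dy + seq_len(ny), dx + seq_len(nx)]
      idx <- idx + 1
    }
  }
  apply(shifts, c(1, 2), stats::median)
}

label_components <- function(mask) {
  # 4-connected component labelling by flood fill
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  current <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      y <- ((i - 1) %% ny) + 1; x <- ((i - 1) %/% ny) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        yy <- y + d[1]; xx <- x + d[2]
        if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
        j <- (xx - 1) * ny + yy
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- current
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Locate the soma and draw an ROI box around it
#'
#' Median-filters the image (3x3), thresholds halfway between the robust
#' background (image median) and the filtered maximum, finds the connected
#' component containing the brightest filtered pixel, and centres a box of
#' half-width `box_halfwidth` on that component's centroid. The box is
#' clipped to the image bounds.
#'
#' @param image 2-D intensity matrix `(y, x)`, e.g. from [max_projection()].
#' @param box_halfwidth Half-width of the ROI box in pixels (default 9,
#'   roughly three times the soma radius of the synthetic fixtures).
#' @return List of class `roi`: `y0`, `y1`, `x0`, `x1` (1-based, inclusive)
#'   and `center = c(y, x)`.
#' @export
locate_soma_roi <- function(image, box_halfwidth = 9L) {
  if (!is.matrix(image)) stop("image must be a matrix", call. = FALSE)
  filtered <- median_filter_3x3(image)
  bg <- stats::median(filtered)
  peak <- max(filtered)
  if (peak - bg <= .Machine$double.eps * max(1, abs(peak))) {
    stop("no soma detected: image is flat after filtering", call. = FALSE)
  }
  mask <- filtered >= bg + 0.5 * (peak - bg)
  labels <- label_components(mask)
  bright_label <- labels[which.max(filtered)]
  comp <- which(labels == bright_label)
  ny <- nrow(image)
  ys <- ((comp - 1) %% ny) + 1
  xs <- ((comp - 1) %/% ny) + 1
  cy <- round(mean(ys)); cx <- round(mean(xs))
  structure(list(
    y0 = max(1L, as.integer(cy - box_halfwidth)),
    y1 = min(nrow(image), as.integer(cy + box_halfwidth)),
    x0 = max(1L, as.integer(cx - box_halfwidth)),
    x1 = min(ncol(image), as.integer(cx + box_halfwidth)),
    center = c(y = cy, x = cx)
  ), class = "roi")
}

#' Extract ROI pixels from an image
#'
#' @param image 2-D intensity matrix.
#' @param roi `roi` object from [locate_soma_roi()].
#' @return Numeric vector of pixel intensities inside the box.
#' @export
roi_pixels <- function(image, roi) {
  as.numeric(image[roi$y0:roi$y1, roi$x0:roi$x1])
}

#' Percentile fluorescence score
#'
#' Mean of the top 5 percent of pixels minus mean of the bottom 5 percent:
#' the bright tail
#' captures the soma, the dim tail the local background. Tail size is
#' `ceiling(tail_percent/100 * n)` pixels taken from a stable sort, so the
#' score is deterministic and invariant to pixel order. Adding a constant to
#' every pixel leaves the score unchanged.
#'
#' @param pixels Numeric vector of ROI pixel intensities (>= 20 values so the
#'   5 percent tails are non-empty).
#' @param tail_percent Tail size in percent (default 5).
#' @return Raw fluorescence score (always >= 0).
#' @export
percentile_score <- function(pixels, tail_percent = 5) {
  n <- length(pixels)
  if (n < 20) {
    stop("percentile_score() needs >= 20 pixels (got ", n, ")", call. = FALSE)
  }
  k <- ceiling(tail_percent / 100 * n)
  sorted <- sort(pixels, method = "radix")
  mean(sorted[(n - k + 1):n]) - mean(sorted[seq_len(k)])
}

#' Score a z-stack end to end
#'
#' Convenience wrapper: max projection, automatic soma ROI, percentile score.
#'
#' @inheritParams max_projection
#' @inheritParams locate_soma_roi
#' @inheritParams percentile_score
#' @return List with `score`, `roi` and the projected `image`.
#' @export
score_stack <- function(stack, box_halfwidth = 9L, tail_percent = 5,
                        z_window = NULL) {
  image <- max_projection(stack, z_window = z_window)
  roi <- locate_soma_roi(image, box_halfwidth = box_halfwidth)
  list(score = percentile_score(roi_pixels(image, roi), tail_percent),
       roi = roi, image = image)
}

#' Normalize scores to same-session controls
#'
#' Divides each raw score by the mean raw score of the control group (fed
#' wild-type animals in the original design) measured in the same imaging
#' session, so sessions with different laser power or exposure remain
#' comparable. After normalization the control group mean is 1 within every
#' session.
#'
#' @param scores Data frame with columns `sample`, `session_id`, `group`,
#'   `raw`.
#' @param control_group Group label of the within-session controls.
#' @return The input tibble with a `normalized` column appended.
#' @export
normalize_by_control <- function(scores, control_group) {
  scores <- tibble::as_tibble(scores)
  req <- c("session_id", "group", "raw")
  if (!all(req %in% names(scores))) {
    stop("scores need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  sessions <- unique(scores$session_id)
  ctrl_mean <- vapply(sessions, function(s) {
    sel <- scores$session_id == s & scores$group == control_group
    if (!any(sel)) {
      stop("session '", s, "' has no '", control_group, "' control animals",
           call. = FALSE)
    }
    m <- mean(scores$raw[sel])
    if (m <= 0) stop("control mean is not positive in session '", s, "'",
                     call. = FALSE)
    m
  }, numeric(1))
  scores$normalized <-
    unname(scores$raw / ctrl_mean[match(scores$session_id, sessions)])
  scores
}

#' Pairwise group comparisons of normalized scores
#'
#' Two-tailed two-sample t-tests (Welch by default) for each requested pair
#' of groups, Bonferroni-corrected over the number of pairs.
#'
#' @param scores Tibble from [normalize_by_control()] (needs `group` and
#'   `normalized`).
#' @param comparisons List of length-2 character vectors naming group pairs.
#' @param equal_var Pool variances instead of Welch.
#' @return Tibble with `group1`, `group2`, `statistic`, `p_raw`, `p_adj`.
#' @export
compare_conditions <- function(scores, comparisons, equal_var = FALSE) {
  scores <- as.data.frame(scores)
  m <- length(comparisons)
  rows <- lapply(comparisons, function(pair) {
    a <- scores$normalized[scores$group == pair[[1]]]
    b <- scores$normalized[scores$group == pair[[2]]]
    if (length(a) < 2 || length(b) < 2) {
      stop("group '", pair[[which(c(length(a), length(b)) < 2)[1]]],
           "' has fewer than 2 observations", call. = FALSE)
    }
    res <- two_sample_t(a, b, equal_var = equal_var, n_comparisons = m)
    tibble::tibble(group1 = pair[[1]], group2 = pair[[2]],
                   statistic = res$statistic, p_raw = res$p_raw,
                   p_adj = res$p_adj)
  })
  do.call(rbind, rows)
}
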