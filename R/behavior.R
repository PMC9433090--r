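#' Chemotaxis index
#'
#' `(n_odor - n_control) / (n_odor + n_control + n_other)`: +1 when every
#' scored animal reached the odor spot, -1 when every animal reached the
#' control (ethanol) spot, 0 when the two are balanced. Vectorized over
#' plates.
#'
#' @param n_odor,n_control,n_other Animal counts per plate (`n_other` counts
#'   animals that reached neither spot).
#' @return Numeric index per plate, in \[-1, 1\].
#' @examples
#' chemotaxis_index(90, 10, 0) # 0.8
#' @export
chemotaxis_index <- function(n_odor, n_control, n_other = 0) {
  total <- n_odor + n_control + n_other
  if (any(c(n_odor, n_control, n_other) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(total == 0)) stop("no scored animals on at least one plate", call. = FALSE)
  (n_odor - n_control) / total
}

#' Food-choice index
#'
#' Fraction of animals in the experimental food patch among animals that
#' settled in either patch: `n_exp / (n_exp + n_control)`. Animals outside
#' both patches are excluded. Vectorized over plates.
#'
#' @param n_exp,n_control Animal counts in the experimental and control patch.
#' @return Numeric index per plate, in \[0, 1\].
#' @export
food_choice_index <- function(n_exp, n_control) {
  if (any(c(n_exp, n_control) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(n_exp + n_control == 0)) {
    stop("both patches empty on at least one plate", call. = FALSE)
  }
  n_exp / (n_exp + n_control)
}

#' Summarize per-plate indices
#'
#' @param values Numeric per-plate index values.
#' @return One-row tibble with `mean`, `sem`, `n`.
#' @export
index_summary <- function(values) {
  n <- length(values)
  tibble::tibble(
    mean = mean(values),
    sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
    n = as.integer(n)
  )
}

# cells crossed by one segment, exact: cut the segment at every gridline it
# crosses and read off the cell of each sub-interval midpoint
segment_cells <- function(p0, p1, origin, cell) {
  u0 <- (p0 - origin) / cell
  u1 <- (p1 - origin) / cell
  ts <- c(0, 1)
  for (d in 1:2) {
    if (u1[d] != u0[d]) {
      lines <- seq(ceiling(min(u0[d], u1[d])), floor(max(u0[d], u1[d])))
      ts <- c(ts, (lines - u0[d]) / (u1[d] - u0[d]))
    }
  }
  ts <- sort(unique(ts[ts >= 0 & ts <= 1]))
  mids <- (utils::head(ts, -1) + utils::tail(ts, -1)) / 2
  if (!length(mids)) mids <- 0.5
  cx <- floor(u0[1] + mids * (u1[1] - u0[1]))
  cy <- floor(u0[2] + mids * (u1[2] - u0[2]))
  unique(cx * 1e6 + cy)  # cell key; grids here are far smaller than 1e6
}

#' Exploration grid coverage
#'
#' Counts the grid squares a trajectory visits, emulating the manual scoring
#' of on-food exploration assays where the plate is laid over a grid of
#' 3.5 mm squares and squares containing tracks are counted. The grid is
#' anchored to the corner of the plate's bounding square (plate centre
#' assumed at the coordinate origin), and segments are rasterized exactly, so
#' a fast-moving animal cannot skip squares between frames. Because the real
#' assay's grid placement is unregistered, `average_phases = TRUE` reports
#' the mean count over four half-cell grid offsets.
#'
#' @param track Data frame with columns `x_mm`, `y_mm` (and optionally
#'   `time_s`).
#' @param square_mm Grid square side in mm (default 3.5).
#' @param plate_diameter Plate diameter in mm (default 60); sets the grid
#'   origin at `(-plate_diameter/2, -plate_diameter/2)`.
#' @param average_phases Average the count over 4 grid phase offsets.
#' @return Number of squares covered (a scalar; non-integer when phases are
#'   averaged).
#' @export
exploration_coverage <- function(track, square_mm = 3.5, plate_diameter = 60,
                                 average_phases = FALSE) {
  track <- as.data.frame(track)
  if (!nrow(track)) stop("empty track", call. = FALSE)
  x <- track$x_mm; y <- track$y_mm
  if (any(abs(x) > plate_diameter / 2 + 1e-9) ||
      any(abs(y) > plate_diameter / 2 + 1e-9)) {
    stop("track leaves the stated plate", call. = FALSE)
  }
  count_at <- function(offset) {
    origin <- c(-plate_diameter / 2, -plate_diameter / 2) + offset
    if (nrow(track) == 1) {
      return(1L)
    }
    keys <- unlist(lapply(seq_len(nrow(track) - 1), function(i) {
      segment_cells(c(x[i], y[i]), c(x[i + 1], y[i + 1]), origin, square_mm)
    }))
    length(unique(keys))
  }
  if (!average_phases) {
    return(count_at(c(0, 0)))
  }
  h <- square_mm / 2
  mean(vapply(list(c(0, 0), c(h, 0), c(0, h), c(h, h)), count_at, numeric(1)))
}

#' Centroid speed from a trajectory
#'
#' Per-interval displacement divided by the frame interval; the mean speed is
#' total path length over total time.
#'
#' @param track Data frame with columns `time_s`, `x_mm`, `y_mm`.
#' @return List with `time` (interval end times), `speed` (mm/s, length
#'   `n - 1`) and `mean_speed`.
#' @export
centroid_speed <- function(track) {
  track <- as.data.frame(track)
  if (nrow(track) < 2) stop(">= 2 frames required", call. = FALSE)
  dt <- diff(track$time_s)
  if (any(dt <= 0)) stop("duplicate or decreasing timestamps", call. = FALSE)
  disp <- sqrt(diff(track$x_mm)^2 + diff(track$y_mm)^2)
  list(time = track$time_s[-1], speed = disp / dt,
       mean_speed = sum(disp) / (track$time_s[nrow(track)] - track$time_s[1]))
}
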