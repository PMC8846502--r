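#' Prediction-grid specification
#'
#' The prediction grid is anchored at admission (time 0) with half-open
#' windows `[start, start + window_hours)`. A prediction "for" a window is
#' issued at the window end using only data observed at or before the window
#' start, so the first prediction after a radiograph at time `x` belongs to
#' the window whose start is the smallest grid point `>= x`.
#'
#' @param task `"low_risk"` (48-hour instance span, label = ever deteriorates)
#'   or `"high_risk"` (five-day span, label = deterioration within 120 h).
#' @param window_hours grid step in hours (default 4).
#' @param horizon_hours span of the instance grid; defaults to 48 for the
#'   low-risk task and 120 for the high-risk task.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(task = c("low_risk", "high_risk"), window_hours = 4,
                      horizon_hours = NULL) {
  task <- match.arg(task)
  if (is.null(horizon_hours)) {
    horizon_hours <- if (task == "low_risk") 48 else 120
  }
  check_scalar(window_hours, "window_hours", 1)
  check_scalar(horizon_hours, "horizon_hours", window_hours)
  if (horizon_hours %% window_hours != 0) {
    stop("'window_hours' must divide 'horizon_hours'", call. = FALSE)
  }
  structure(list(task = task, window_hours = window_hours,
                 horizon_hours = horizon_hours), class = "grid_spec")
}

#' Reduce a raw deterioration-index stream to the 4-hour grid
#'
#' Takes the maximum of all raw index scores falling in each half-open grid
#' window `[start, start + window)`. This mirrors how a 15-minute-cadence
#' index is compared against 4-hourly models; a stream already at the grid
#' cadence maps through unchanged. Windows with no raw observation inherit
#' the most recent reduced value (last observation carried forward); windows
#' before the first observation get `NA`.
#'
#' @param times,scores numeric vectors: observation times (hours from
#'   admission, strictly increasing) and scores in `[0,1]`.
#' @param grid a [grid_spec()].
#' @return Data frame with `window_start` and `score`, one row per grid
#'   window from 0 through `horizon_hours`.
#' @export
reduce_index_to_windows <- function(times, scores, grid = grid_spec("high_risk")) {
  if (length(times) == 0) stop("empty index stream", call. = FALSE)
  if (length(times) != length(scores)) {
    stop("'times' and 'scores' must have equal length", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  w <- grid$window_hours
  starts <- seq(0, grid$horizon_hours, by = w)
  bin <- findInterval(times, starts) # window index, 1-based
  bin[times < 0 | bin > length(starts)] <- NA
  val <- rep(NA_real_, length(starts))
  ok <- !is.na(bin)
  if (any(ok)) {
    mx <- tapply(scores[ok], bin[ok], max)
    val[as.integer(names(mx))] <- mx
  }
  # carry forward over empty windows
  for (i in seq_along(val)[-1]) {
    if (is.na(val[i])) val[i] <- val[i - 1]
  }
  data.frame(window_start = starts, score = val)
}

#' Carry the most recent image score forward onto the grid
#'
#' For each requested window start, selects the latest radiograph whose time
#' is `<=` the window start (a radiograph exactly at the window start counts)
#' and reports its score together with the elapsed time since it was taken.
#' Windows that precede the first radiograph are omitted: the combined index
#' only predicts once an image exists.
#'
#' @param xray_times,xray_scores radiograph times (hours) and scores.
#' @param window_starts numeric vector of grid window starts.
#' @return Data frame `window_start`, `image_score`, `hours_since_xray`,
#'   restricted to windows at or after the first radiograph.
#' @export
carry_forward_image <- function(xray_times, xray_scores, window_starts) {
  if (length(xray_times) == 0) stop("no radiographs supplied", call. = FALSE)
  o <- order(xray_times)
  xray_times <- xray_times[o]
  xray_scores <- xray_scores[o]
  idx <- findInterval(window_starts, xray_times) # latest x-ray <= start
  keep <- idx >= 1
  data.frame(
    window_start = window_starts[keep],
    image_score = xray_scores[idx[keep]],
    hours_since_xray = window_starts[keep] - xray_times[idx[keep]]
  )
}

#' Build fused prediction instances for one hospitalization
#'
#' Lays out the task grid for a single hospitalization and assembles, per
#' window, the four-element feature vector of the image-augmented model:
#' carried-forward image score, deterioration-index score, hours since the
#' radiograph, and hours since admission. Every feature is a function of data
#' observed at or before the window start: the index feature for the window
#' starting at `s` is the grid-reduced index value of the interval
#' `[s - window, s)` (the most recent completed interval). Windows run from
#' the first grid point at or after the first radiograph.
#'
#' For the low-risk task, windows span through 48 h (label: hospitalization
#' ever deteriorates). For the high-risk task they span through 120 h (label:
#' deterioration within 120 h), and the window containing the deterioration
#' event plus the one immediately before it are dropped, censoring the
#' immediate pre-event period against label leakage. In both tasks windows
#' stop at exit from hospital.
#'
#' @param hosp one-row data frame with `hosp_id`, `exit_time`,
#'   `deterioration_time` (`NA` if none).
#' @param index_times,index_scores the raw deterioration-index stream.
#' @param xray_times,xray_scores the radiograph score stream.
#' @param grid a [grid_spec()].
#' @return Data frame of prediction instances: `hosp_id`, `window_start`,
#'   `image_score`, `index_score`, `hours_since_xray`, `hours_since_admit`
#'   (window end, by convention), `label`. Possibly zero rows (with a
#'   warning) when no valid window exists.
#' @export
make_instances <- function(hosp, index_times, index_scores,
                           xray_times, xray_scores, grid) {
  stopifnot(nrow(hosp) == 1L)
  w <- grid$window_hours
  det <- hosp$deterioration_time
  ever <- !is.na(det)

  first_xray <- min(xray_times)
  first_start <- ceiling_grid(first_xray, w)
  last_start <- grid$horizon_hours - if (grid$task == "high_risk") w else 0
  # windows do not extend past exit from hospital
  last_start <- min(last_start, floor_grid(hosp$exit_time, w) -
                      if (hosp$exit_time %% w == 0) w else 0)
  if (grid$task == "high_risk" && ever) {
    # drop the event-containing window and the one immediately before it
    last_start <- min(last_start, floor_grid(det, w) - 2 * w)
  }
  if (last_start < first_start) {
    warning(sprintf("hospitalization %s: no valid prediction windows",
                    hosp$hosp_id), call. = FALSE)
    return(empty_instances())
  }
  starts <- seq(first_start, last_start, by = w)

  img <- carry_forward_image(xray_times, xray_scores, starts)
  red <- reduce_index_to_windows(index_times, index_scores, grid)
  # index feature: reduced value of the completed interval [s - w, s)
  idx_val <- red$score[match(starts - w, red$window_start)]

  out <- data.frame(
    hosp_id = hosp$hosp_id,
    window_start = starts,
    image_score = img$image_score[match(starts, img$window_start)],
    index_score = idx_val,
    hours_since_xray = img$hours_since_xray[match(starts, img$window_start)],
    hours_since_admit = starts + w,
    stringsAsFactors = FALSE
  )
  out$label <- if (grid$task == "low_risk") {
    as.integer(ever)
  } else {
    as.integer(ever && det <= grid$horizon_hours)
  }
  out <- out[!is.na(out$image_score) & !is.na(out$index_score), , drop = FALSE]
  if (nrow(out) == 0) {
    warning(sprintf("hospitalization %s: no valid prediction windows",
                    hosp$hosp_id), call. = FALSE)
    return(empty_instances())
  }
  rownames(out) <- NULL
  out
}

empty_instances <- function() {
  data.frame(hosp_id = character(0), window_start = numeric(0),
             image_score = numeric(0), index_score = numeric(0),
             hours_since_xray = numeric(0), hours_since_admit = numeric(0),
             label = integer(0), stringsAsFactors = FALSE)
}

#' Build prediction instances for a whole cohort
#'
#' Applies [make_instances()] to every hospitalization in a (filtered)
#' cohort and binds the results.
#'
#' @param cohort a `cohort` that already passed [apply_inclusion_filters()].
#' @param grid a [grid_spec()].
#' @param quiet suppress per-hospitalization warnings about empty grids.
#' @return A data frame of prediction instances across the cohort.
#' @export
build_instances <- function(cohort, grid, quiet = TRUE) {
  h <- cohort$hospitalizations
  xr_split <- split(cohort$xrays, cohort$xrays$hosp_id)
  idx_split <- split(cohort$index_scores, cohort$index_scores$hosp_id)
  rows <- lapply(seq_len(nrow(h)), function(i) {
    id <- h$hosp_id[i]
    xr <- xr_split[[id]]
    idx <- idx_split[[id]]
    if (is.null(xr) || is.null(idx)) return(empty_instances())
    call <- quote(make_instances(h[i, , drop = FALSE], idx$time, idx$score,
                                 xr$time, xr$image_score, grid))
    if (quiet) suppressWarnings(eval(call)) else eval(call)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-horizon deterioration labels
#'
#' Binary labels for deterioration within each horizon of 12, 24, 48, 72, 96
#' and 120 hours after a reference time, plus an "any" label for
#' deterioration at any point during the hospitalization.
#'
#' @param deterioration_time event time in hours, or `NA` if the
#'   hospitalization never deteriorates.
#' @param reference_time time the labels are anchored to (hours, `>= 0`).
#' @param horizons horizons in hours.
#' @return Named integer vector over the horizons plus `"any"`; horizon
#'   labels are 1 iff the event time lies in
#'   `(reference_time, reference_time + horizon]`.
#' @export
make_horizon_labels <- function(deterioration_time, reference_time = 0,
                                horizons = c(12, 24, 48, 72, 96, 120)) {
  check_scalar(reference_time, "reference_time", 0)
  det <- deterioration_time
  lab <- if (is.na(det)) {
    rep(0L, length(horizons))
  } else {
    as.integer(det > reference_time & det <= reference_time + horizons)
  }
  stats::setNames(c(lab, as.integer(!is.na(det))), c(horizons, "any"))
}
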