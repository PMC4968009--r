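#' Telemetry track series
#'
#' Container for one individual's location time series: strictly increasing
#' timestamps (epoch seconds) and a K-dimensional planar coordinate per
#' record (meters), K in 1:3. This is the signal whose periodicity the rest
#' of the package analyses.
#'
#' @param times numeric vector of epoch seconds, strictly increasing.
#' @param coords numeric vector (K = 1) or N x K matrix of planar
#'   coordinates in meters.
#' @param id individual identifier.
#' @param dim_names axis labels; defaults to `"x"`, `"y"`, `"z"`.
#' @return An object of class `"track"`: a list with elements `id`,
#'   `times`, `coords` (always an N x K matrix) and `dim_names`.
#' @examples
#' tr <- track_series(times = (0:99) * 3600,
#'                    coords = cbind(cumsum(rnorm(100)), cumsum(rnorm(100))))
#' tr
#' @export
track_series <- function(times, coords, id = "track", dim_names = NULL) {
  times <- as.numeric(times)
  if (is.null(dim(coords))) coords <- matrix(as.numeric(coords), ncol = 1L)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(times)
  if (nrow(coords) != n)
    stop("'times' and 'coords' must have the same number of records")
  if (n >= 2 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing (no duplicate timestamps)")
  if (!all(is.finite(times)))
    stop("non-finite timestamps")
  if (!all(is.finite(coords)))
    stop("every record must have finite coordinates in all dimensions")
  k <- ncol(coords)
  if (!(k %in% 1:3)) stop("coordinate dimension K must be 1, 2 or 3")
  if (is.null(dim_names)) dim_names <- c("x", "y", "z")[seq_len(k)]
  if (length(dim_names) != k) stop("'dim_names' must have length K")
  colnames(coords) <- dim_names
  structure(list(id = as.character(id), times = times, coords = coords,
                 dim_names = dim_names),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<track> id=%s  records=%d  K=%d (%s)\n",
              x$id, n, ncol(x$coords), paste(x$dim_names, collapse = ",")))
  if (n >= 2) {
    dur <- x$times[n] - x$times[1]
    cat(sprintf("  span %.6g s (%.3g days), median interval %.6g s\n",
                dur, dur / 86400, stats::median(diff(x$times))))
  }
  invisible(x)
}

#' @export
length.track <- function(x) length(x$times)

# lower median: the smaller of the two central order statistics for even
# counts, so that a gappy or duty-cycled schedule keeps its intended
# (finest) interval rather than an average of two interval classes
lower_median <- function(x) unname(stats::quantile(x, 0.5, type = 1))

#' Build the even sampling grid and schedule function of a track
#'
#' Constructs the regular time grid \{t_j\} underlying an (intendedly) even
#' sampling design, the binary schedule function `w` marking which grid
#' cells hold a recorded fix, and the gridded signal `wX` (zeros at missing
#' cells). The grid interval defaults to the median of the successive
#' sampling intervals; `res_time` refines it by an integer factor so that
#' fixes with small timing jitter land closer to a grid cell.
#'
#' Records are snapped to the nearest grid cell (maximum snapping error
#' `dt/2` by construction). If two records snap to the same cell the
#' earlier one is kept and a warning is issued.
#'
#' @param track a [track_series()] object with at least 2 records.
#' @param res_time integer >= 1; temporal refinement factor of the grid.
#' @return An object of class `"sample_grid"`: list with `t1`, `dt`, `n`,
#'   `w` (0/1 vector of length `n`), `wX` (`n` x K matrix), `duration`
#'   (`(n-1)*dt`), `res_time`, `dim_names`, `id`.
#' @examples
#' tr <- track_series(c(0, 1, 3) * 3600, rnorm(3))
#' g <- build_sample_grid(tr)
#' g$w  # 1 1 0 1 : the fix at 2 h is missing
#' @export
build_sample_grid <- function(track, res_time = 1L) {
  stopifnot(inherits(track, "track"))
  res_time <- as.integer(res_time)
  if (is.na(res_time) || res_time < 1L) stop("'res_time' must be an integer >= 1")
  times <- track$times
  if (length(times) < 2L) stop("need at least 2 records to build a grid")
  dt <- lower_median(diff(times)) / res_time
  if (!(dt > 0)) stop("degenerate sampling interval")
  t1 <- times[1L]
  cells <- as.integer(round((times - t1) / dt)) + 1L
  n <- max(cells)
  k <- ncol(track$coords)
  w <- integer(n)
  wX <- matrix(0, n, k, dimnames = list(NULL, track$dim_names))
  dup <- duplicated(cells)
  if (any(dup)) {
    warning(sprintf("%d record(s) snapped to an already-occupied grid cell; keeping the earlier record", sum(dup)))
  }
  keep <- !dup
  w[cells[keep]] <- 1L
  wX[cells[keep], ] <- track$coords[keep, , drop = FALSE]
  structure(list(t1 = t1, dt = dt, n = n, w = w, wX = wX,
                 duration = (n - 1L) * dt, res_time = res_time,
                 dim_names = track$dim_names, id = track$id),
            class = "sample_grid")
}

#' @export
print.sample_grid <- function(x, ...) {
  cat(sprintf("<sample_grid> N=%d  dt=%.6g s  records=%d (%.1f%% of cells)  res_time=%d\n",
              x$n, x$dt, sum(x$w), 100 * mean(x$w), x$res_time))
  invisible(x)
}

# grid cell timestamps
grid_times <- function(grid) grid$t1 + (seq_len(grid$n) - 1) * grid$dt

#' Movement-speed (activity) series of a track
#'
#' Computes the scalar activity signal used for rest/activity-cycle
#' analysis: the length of each recorded step divided by the duration of
#' the corresponding time interval, timestamped at the interval midpoint.
#'
#' @param track a [track_series()] object with at least 2 records.
#' @return An object of class `"activity"`: list with `times` (interval
#'   midpoints, s) and `speed` (m/s), one entry per consecutive pair of
#'   records.
#' @export
compute_speed_series <- function(track) {
  stopifnot(inherits(track, "track"))
  n <- length(track$times)
  if (n < 2L) stop("need at least 2 records to compute speeds")
  dtv <- diff(track$times)
  if (any(dtv <= 0)) stop("duplicate timestamps give zero-length intervals")
  steps <- sqrt(rowSums(diff(track$coords)^2))
  structure(list(times = track$times[-n] + dtv / 2,
                 speed = as.numeric(steps) / dtv,
                 id = track$id),
            class = "activity")
}

#' @export
print.activity <- function(x, ...) {
  cat(sprintf("<activity> id=%s  steps=%d  mean speed %.4g m/s\n",
              x$id, length(x$speed), mean(x$speed)))
  invisible(x)
}

#' Resample a track onto another individual's sampling schedule
#'
#' Retains only the records that fall within `tolerance` of an occupied
#' cell of a template schedule, after shifting the template so that the
#' two series start at the same time. This reproduces the classical
#' manipulation of imposing one animal's pattern of missing fixes onto
#' another animal's complete record, to demonstrate schedule-induced
#' artefacts.
#'
#' @param track a [track_series()] object.
#' @param template a [build_sample_grid()] object supplying the schedule.
#' @param tolerance maximum absolute time offset (s) from an occupied cell.
#' @return A [track_series()] object (possibly empty, with a warning).
#' @export
resample_to_schedule <- function(track, template, tolerance) {
  stopifnot(inherits(track, "track"), inherits(template, "sample_grid"))
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  occ <- which(template$w == 1L)
  if (length(occ) == 0L) {
    warning("template schedule has no occupied cells; returning empty track")
    return(structure(list(id = track$id, times = numeric(0),
                          coords = track$coords[0, , drop = FALSE],
                          dim_names = track$dim_names), class = "track"))
  }
  tocc <- grid_times(template)[occ]
  tocc <- tocc - tocc[1L] + track$times[1L]  # align start times
  # distance of each record to nearest occupied template time
  idx <- findInterval(track$times, tocc)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(tocc))
  dist <- pmin(abs(track$times - tocc[lo]), abs(track$times - tocc[hi]))
  keep <- dist <= tolerance
  if (!any(keep)) warning("no records within tolerance of the template schedule")
  structure(list(id = track$id, times = track$times[keep],
                 coords = track$coords[keep, , drop = FALSE],
                 dim_names = track$dim_names),
            class = "track")
}
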