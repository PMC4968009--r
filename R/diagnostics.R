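#' Rescale a periodogram to a maximum of zero (log scale)
#'
#' Replaces the power values by `log10(power) - max(log10(power))`, so
#' that the maximum is exactly 0 and values are in decades below the
#' peak. This puts a data periodogram and a schedule periodogram on a
#' common scale for visual or automated comparison; the transform is
#' monotone, so peak ordering is preserved.
#'
#' @param pgram a `"periodogram"` object with at least one finite,
#'   positive power value.
#' @return A `"periodogram"` object on the rescaled (log10) scale, with
#'   `meta$rescaled = TRUE`.
#' @export
rescale_zero_max <- function(pgram) {
  stopifnot(inherits(pgram, "periodogram"))
  p <- pgram$power
  if (!any(is.finite(p) & p > 0)) stop("all power values are zero or non-finite")
  lp <- log10(pmax(pgram$power_by_dim, 0))
  lcomb <- log10(pmax(p, 0))
  shift <- max(lcomb[is.finite(lcomb)])
  out <- pgram
  out$power_by_dim <- lp - shift
  out$power <- lcomb - shift
  out$meta$rescaled <- TRUE
  out
}

# log10-prominence of the local maximum at index i: height above the
# higher of the two flanking minima, walking outward while descending
peak_prominence <- function(logp, i) {
  n <- length(logp)
  l <- i
  while (l > 1L && logp[l - 1L] <= logp[l]) l <- l - 1L
  r <- i
  while (r < n && logp[r + 1L] <= logp[r]) r <- r + 1L
  left <- if (l == i) logp[i] else min(logp[l:i])
  right <- if (r == i) logp[i] else min(logp[i:r])
  logp[i] - max(if (l == i) -Inf else left, if (r == i) -Inf else right,
                na.rm = FALSE)
}

#' Flag a candidate periodicity as a sampling-schedule artefact
#'
#' Automated version of the visual diagnostic: after zero-max rescaling,
#' a peak near the target period in the data periodogram is suspected to
#' be artefactual if the periodogram of the sampling schedule has a
#' local maximum at the same period (within the frequency resolution
#' `df`) with log10-prominence at least `prominence_threshold` decades
#' that also stands at least 1.5 decades above the schedule spectrum's
#' median level (raw prominence alone is routinely exceeded by isolated
#' noise ordinates, whose flanking minima dip far down).
#' A raised flag indicates a risk of false positive created by the
#' schedule; it does not prove the absence of a true periodic pattern,
#' since a genuine periodicity can be superimposed on an artefactual
#' one.
#'
#' @param data_pgram periodogram of the location series.
#' @param sched_pgram periodogram of the schedule, from
#'   [schedule_periodogram()], on the same frequency grid.
#' @param period candidate period (s).
#' @param prominence_threshold minimum schedule-peak prominence in
#'   decades (default 0.5).
#' @return An object of class `"diagnostic_report"`: list with `period`,
#'   `data_peak` and `schedule_peak` (rescaled, <= 0),
#'   `schedule_peak_is_local_max`, `schedule_peak_prominence`,
#'   `artefact_suspected` and `caveat`.
#' @export
artefact_flag <- function(data_pgram, sched_pgram, period,
                          prominence_threshold = 0.5) {
  stopifnot(inherits(data_pgram, "periodogram"),
            inherits(sched_pgram, "periodogram"))
  fd <- data_pgram$freqs$freqs
  fs <- sched_pgram$freqs$freqs
  if (length(fd) != length(fs) || max(abs(fd - fs)) > 1e-9 * max(fd))
    stop("periodograms are on incompatible frequency grids")
  rd <- rescale_zero_max(data_pgram)
  if (!any(is.finite(sched_pgram$power) & sched_pgram$power > 0)) {
    # complete sampling: the schedule periodogram is identically zero and
    # can never explain a data peak
    f0 <- 1 / period
    df0 <- data_pgram$freqs$df
    if (is.na(df0)) df0 <- diff(fd[1:2])
    win0 <- which(abs(fd - f0) <= df0)
    if (!length(win0)) win0 <- which.min(abs(fd - f0))
    return(structure(list(period = period,
                          data_peak = max(rd$power[win0]),
                          schedule_peak = -Inf,
                          schedule_peak_is_local_max = FALSE,
                          schedule_peak_prominence = 0,
                          artefact_suspected = FALSE,
                          caveat = paste("A raised flag indicates risk of a",
                                         "schedule-induced false positive; it does not prove",
                                         "the absence of a true periodic pattern.")),
                     class = "diagnostic_report"))
  }
  rs <- rescale_zero_max(sched_pgram)
  f0 <- 1 / period
  df <- data_pgram$freqs$df
  if (is.na(df)) df <- diff(fd[1:2])
  win <- which(abs(fd - f0) <= df)
  if (!length(win)) win <- which.min(abs(fd - f0))
  sp <- rs$power
  n <- length(sp)
  is_lmax <- vapply(win, function(i) {
    (i == 1L || sp[i] > sp[i - 1L]) && (i == n || sp[i] > sp[i + 1L])
  }, TRUE)
  prom <- vapply(win, function(i) peak_prominence(sp, i), 0)
  sched_peak_is_local_max <- any(is_lmax)
  # an isolated noise ordinate easily shows >0.5 decades of raw prominence
  # (periodogram ordinates are exponential, so flanking minima dip far
  # down); a true schedule line must also stand far above the schedule
  # spectrum's typical level — noise bins sit within about a decade of the
  # median, a genuine duty-cycle/daily line several decades above it
  med <- stats::median(sp[is.finite(sp)])
  suspected <- any(is_lmax & prom >= prominence_threshold &
                     (sp[win] - med) >= 1.5)
  structure(list(period = period,
                 data_peak = max(rd$power[win]),
                 schedule_peak = max(sp[win]),
                 schedule_peak_is_local_max = sched_peak_is_local_max,
                 schedule_peak_prominence = if (any(is_lmax)) max(prom[is_lmax]) else 0,
                 artefact_suspected = suspected,
                 caveat = paste("A raised flag indicates risk of a schedule-induced",
                                "false positive; it does not prove the absence of",
                                "a true periodic pattern.")),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report> period %.6g s (%.4g days)\n",
              x$period, x$period / 86400))
  cat(sprintf("  data periodogram (rescaled): %.3f decades below max\n",
              -x$data_peak))
  cat(sprintf("  schedule periodogram: local max = %s, prominence %.3f decades\n",
              x$schedule_peak_is_local_max, x$schedule_peak_prominence))
  cat(sprintf("  artefact suspected: %s\n", x$artefact_suspected))
  cat(" ", x$caveat, "\n")
  invisible(x)
}

#' Overlay plot of data and schedule periodograms
#'
#' Plots the zero-max rescaled data periodogram alongside the rescaled
#' schedule periodogram on a log period axis. A peak present in both at
#' the same period signals an artefactual periodicity.
#'
#' @param data_pgram,sched_pgram as in [artefact_flag()].
#' @param period optional period (s) to mark with a vertical line.
#' @param ... passed to [plot()].
#' @export
plot_diagnostic <- function(data_pgram, sched_pgram, period = NULL, ...) {
  rd <- rescale_zero_max(data_pgram)
  rs <- rescale_zero_max(sched_pgram)
  per <- 1 / rd$freqs$freqs / 86400
  ok <- is.finite(rd$power) & is.finite(rs$power)
  plot(per[ok], rd$power[ok], log = "x", type = "l",
       xlab = "period (days)", ylab = "rescaled log10 power", ...)
  graphics::lines(per[ok], rs$power[ok], col = "red")
  if (!is.null(period)) graphics::abline(v = period / 86400, lty = 2)
  graphics::legend("bottomright", c("data", "sampling schedule"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(NULL)
}
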