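#' Log-log spectral slope of a track's periodogram
#'
#' Measures the slope of `log10(power)` against `log10(period)` of a
#' track's Lomb-Scargle periodogram over a period band, the quantity that
#' identifies the autocorrelation regime of an aperiodic movement model
#' (0 in a flat, white-like regime; 2 in a Brownian regime; 4 in a
#' velocity-autocorrelated regime, with transitions near period
#' `2*pi*tau`).
#'
#' For diffusive tracks (BM- or IOU-like, spectral slope >= 2) the raw
#' rectangular-window periodogram is leakage-limited: power from the
#' random-walk trend floods the steep tail through the window-kernel
#' sidelobes, and no measured slope can exceed 2. `prewhiten = TRUE`
#' therefore first-differences the coordinates, computes the LSP of the
#' (stationary) increment series, and recolors by the exact inverse
#' transfer function `1 / (4 sin^2(pi f dt))` — the standard prewhitening
#' remedy for steep spectra. Prewhitening should be off in flat regimes,
#' where differencing digs an artificial low-frequency valley that
#' reverse-leaks.
#'
#' The fit optionally averages `log10(power)` in log-spaced period bins
#' (suppressing the `1/D`-scale oscillations) and weights each bin by
#' its ordinate count, which keeps the slope estimate unbiased.
#'
#' @param track a [track_series()] object on a (near-)even grid.
#' @param period_range numeric length-2: the period band (s) over which
#'   to fit.
#' @param prewhiten difference-and-recolor before fitting (see above).
#' @param bins number of log-spaced period bins, or `NULL` for an
#'   unbinned fit.
#' @param dim which coordinate dimension to use (default 1).
#' @return list with `slope`, `intercept`, `n_ordinates`, and the fitted
#'   band.
#' @export
lsp_slope <- function(track, period_range, prewhiten = FALSE, bins = NULL,
                      dim = 1L) {
  stopifnot(inherits(track, "track"), length(period_range) == 2)
  if (prewhiten) {
    y <- diff(track$coords[, dim])
    track <- track_series(track$times[-1], y, id = track$id)
    dim <- 1L
  }
  grid <- build_sample_grid(track)
  pg <- suppressMessages(fast_lsp(grid))
  f <- pg$freqs$freqs
  pow <- pg$power_by_dim[, dim]
  if (prewhiten) pow <- pow / (4 * sin(pi * f * grid$dt)^2)
  per <- 1 / f
  sel <- per > min(period_range) & per < max(period_range) & pow > 0
  if (sum(sel) < 5) stop("fewer than 5 periodogram ordinates in the period band")
  x <- log10(per[sel])
  y <- log10(pow[sel])
  if (!is.null(bins)) {
    b <- cut(x, bins)
    cnt <- as.numeric(tapply(x, b, length))
    xb <- as.numeric(tapply(x, b, mean))
    yb <- as.numeric(tapply(y, b, mean))  # mean of logs: constant bias, slope unbiased
    ok <- !is.na(xb)
    fit <- stats::lm.wfit(cbind(1, xb[ok]), yb[ok], w = cnt[ok])
  } else {
    fit <- stats::lm.fit(cbind(1, x), y)
  }
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n_ordinates = sum(sel), period_range = sort(period_range),
       prewhitened = prewhiten)
}
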