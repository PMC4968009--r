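#' Frequency grid for a periodogram
#'
#' Builds the set of probe frequencies for a sampling grid: multiples of
#' the base resolution `df = 1/(N*dt)` divided by the oversampling factor
#' `res_freq`, from the lowest resolvable frequency up to (and including)
#' the Nyquist frequency `F = 1/(2*dt)`. Zero frequency is excluded.
#'
#' @param grid a [build_sample_grid()] object.
#' @param res_freq integer >= 1; frequency oversampling factor.
#' @return An object of class `"frequency_grid"`: list with `freqs` (1/s,
#'   strictly increasing), `nyquist`, `df` (base resolution) and
#'   `res_freq`.
#' @export
frequency_grid <- function(grid, res_freq = 1L) {
  stopifnot(inherits(grid, "sample_grid"))
  res_freq <- as.integer(res_freq)
  if (is.na(res_freq) || res_freq < 1L) stop("'res_freq' must be an integer >= 1")
  n <- grid$n
  dt <- grid$dt
  df <- 1 / (n * dt)
  m <- seq_len(floor(res_freq * n / 2))
  structure(list(freqs = m * df / res_freq, nyquist = 1 / (2 * dt),
                 df = df, res_freq = res_freq),
            class = "frequency_grid")
}

# map requested frequencies onto integer FFT bin multiples m of
# df/res_freq; error if they are off-grid
freq_bins <- function(grid, fgrid) {
  step <- 1 / (grid$n * grid$dt * fgrid$res_freq)
  m <- fgrid$freqs / step
  mi <- round(m)
  if (any(abs(m - mi) > 1e-6))
    stop("frequency grid is not commensurate with the sampling grid; rebuild it with frequency_grid()")
  as.integer(mi)
}

new_periodogram <- function(fgrid, power_by_dim, n_effective, meta) {
  power_by_dim <- as.matrix(power_by_dim)
  structure(list(freqs = fgrid,
                 power_by_dim = power_by_dim,
                 power = rowMeans(power_by_dim),
                 n_effective = n_effective,
                 meta = meta),
            class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  f <- x$freqs$freqs
  imax <- which.max(x$power)
  cat(sprintf("<periodogram> %d frequencies in [%.4g, %.4g] 1/s  K=%d  n_eff=%s\n",
              length(f), f[1], f[length(f)], ncol(x$power_by_dim),
              format(x$n_effective)))
  cat(sprintf("  global maximum at period %.6g s (%.4g days), power %.6g\n",
              1 / f[imax], 1 / f[imax] / 86400, x$power[imax]))
  invisible(x)
}

#' Fast FFT-based Lomb-Scargle periodogram
#'
#' Computes the least-squares (Lomb-Scargle) periodogram of a gridded,
#' possibly gappy signal exactly, using only fast Fourier transforms. With
#' `W = DFT\{w\}` and `G_k = DFT\{wX_k\}` (after subtracting the
#' per-dimension weighted mean of the observed values), the periodogram of
#' dimension k at frequency f is
#' \deqn{LSP^{(k)}(f) = \frac{W(0)\,|G_k(f)|^2 -
#'   \mathrm{Re}\!\left(W(2f)\,\overline{G_k(f)}^2\right)}
#'   {W(0)^2 - |W(2f)|^2},}
#' and the combined periodogram is the arithmetic mean over dimensions.
#' Both transforms are evaluated on a zero-padded grid of length
#' `res_freq * N`, on which every probe frequency `f` and its double
#' `2f` fall on exact FFT bins (`2f` wraps modulo the `1/dt`
#' periodicity of the DFT); the whole computation is O(N log N). When the sampling is complete
#' (`w == 1` everywhere) the result reduces to the classical DFT
#' periodogram. At frequencies where the denominator underflows (e.g. the
#' exact Nyquist bin) the power is evaluated by the exact least-squares
#' fit instead, with a message.
#'
#' @param grid a [build_sample_grid()] object with at least 3 records.
#' @param fgrid a [frequency_grid()] for the same grid; defaults to
#'   `frequency_grid(grid)`.
#' @return A `"periodogram"` object: list with `freqs`
#'   (the frequency grid), `power_by_dim` (matrix, one column per
#'   dimension), `power` (mean over dimensions), `n_effective`
#'   (`sum(w)`) and `meta`.
#' @seealso [lsq_lsp()] for the O(N^2) reference implementation,
#'   [dft_periodogram()] for complete series.
#' @examples
#' tr <- track_series((0:511) * 3600,
#'                    sin(2 * pi * (0:511) / 24) + rnorm(512, sd = 0.5))
#' pg <- fast_lsp(build_sample_grid(tr))
#' print(pg)  # global maximum near the 24 h period
#' @export
fast_lsp <- function(grid, fgrid = frequency_grid(grid)) {
  stopifnot(inherits(grid, "sample_grid"), inherits(fgrid, "frequency_grid"))
  w <- as.numeric(grid$w)
  n <- grid$n
  if (sum(w) < 3) stop("need at least 3 recorded fixes")
  k <- ncol(grid$wX)
  m <- freq_bins(grid, fgrid)
  # all probe frequencies m*df/res_freq and their doubles live on the
  # res_freq*N transform grid (2f wraps modulo the 1/dt periodicity)
  pad <- fgrid$res_freq * n
  # center by the weighted mean of observed values, per dimension
  xbar <- colSums(grid$wX) / sum(w)
  wXc <- grid$wX - outer(w, xbar)
  wpad <- c(w, numeric(pad - n))
  Xpad <- rbind(wXc, matrix(0, pad - n, k))
  W <- stats::fft(wpad)
  G <- stats::mvfft(Xpad)
  W0 <- sum(w)
  idx_f <- m + 1L
  idx_2f <- (2L * m) %% pad + 1L
  W2 <- W[idx_2f]
  den <- W0^2 - Mod(W2)^2
  Gf <- G[idx_f, , drop = FALSE]
  num <- W0 * Mod(Gf)^2 - Re(W2 * Conj(Gf)^2)
  power <- num / den
  bad <- which(!(abs(den) > 1e-12 * W0^2))
  if (length(bad)) {
    # the exact Nyquist bin is always degenerate (the sine component
    # vanishes); only unexpected interior degeneracies are worth a message
    unexpected <- sum(abs(fgrid$freqs[bad] - fgrid$nyquist) >
                        1e-12 * fgrid$nyquist)
    if (unexpected > 0)
      message(sprintf("denominator underflow at %d frequency bin(s); using exact least-squares values there", unexpected))
    tg <- grid_times(grid)
    obs <- grid$w == 1L
    ref <- lsq_lsp(tg[obs], grid$wX[obs, , drop = FALSE],
                   freqs = fgrid$freqs[bad])
    power[bad, ] <- ref$power_by_dim
  }
  new_periodogram(fgrid, power, sum(w),
                  meta = list(id = grid$id, n = n, dt = grid$dt,
                              res_time = grid$res_time,
                              res_freq = fgrid$res_freq))
}

#' Classical DFT periodogram of a complete series
#'
#' The standard periodogram `P(f) = |DFT\{X\}(f)|^2 / N` per dimension
#' (mean over dimensions combined), defined only for complete, evenly
#' sampled series. At the exact Nyquist bin the least-squares convention
#' is used (half the classical ordinate; the sine component vanishes
#' there), so that [fast_lsp()] and `dft_periodogram()` agree at every
#' probe frequency.
#'
#' @inheritParams fast_lsp
#' @return A `"periodogram"` object.
#' @export
dft_periodogram <- function(grid, fgrid = frequency_grid(grid)) {
  stopifnot(inherits(grid, "sample_grid"), inherits(fgrid, "frequency_grid"))
  if (any(grid$w != 1L))
    stop("series has missing records; use fast_lsp() instead")
  n <- grid$n
  k <- ncol(grid$wX)
  m <- freq_bins(grid, fgrid)
  pad <- fgrid$res_freq * n
  Xc <- sweep(grid$wX, 2, colMeans(grid$wX))
  G <- stats::mvfft(rbind(Xc, matrix(0, pad - n, k)))
  power <- Mod(G[m + 1L, , drop = FALSE])^2 / n
  at_nyquist <- abs(fgrid$freqs - fgrid$nyquist) < 1e-12 * fgrid$nyquist
  power[at_nyquist, ] <- power[at_nyquist, ] / 2
  new_periodogram(fgrid, power, n,
                  meta = list(id = grid$id, n = n, dt = grid$dt,
                              res_time = grid$res_time,
                              res_freq = fgrid$res_freq))
}

#' Periodogram of the sampling schedule
#'
#' The Lomb-Scargle periodogram of the binary schedule function `w`
#' itself (mean-subtracted), on the same frequency grid as the data
#' periodogram. Peaks in this periodogram reveal periodic structure in
#' the way fixes were recorded or missed — the raw material of
#' artefactual periodicities.
#'
#' @inheritParams fast_lsp
#' @return A `"periodogram"` object (one dimension).
#' @seealso [artefact_flag()]
#' @export
schedule_periodogram <- function(grid, fgrid = frequency_grid(grid)) {
  stopifnot(inherits(grid, "sample_grid"))
  wgrid <- structure(list(t1 = grid$t1, dt = grid$dt, n = grid$n,
                          w = rep(1L, grid$n),
                          wX = matrix(as.numeric(grid$w), ncol = 1,
                                      dimnames = list(NULL, "w")),
                          duration = grid$duration, res_time = grid$res_time,
                          dim_names = "w", id = paste0(grid$id, ":schedule")),
                     class = "sample_grid")
  dft_periodogram(wgrid, fgrid)
}

#' Average periodograms across individuals
#'
#' Combines periodograms from several individuals assumed to share the
#' same periodic behavior, to augment sample size. Each periodogram is
#' normalized by its mean power (individuals differ in movement
#' variance), interpolated onto the coarsest common frequency grid, and
#' averaged with weights proportional to each individual's number of
#' recorded fixes. Nyquist ranges that do not fully overlap are truncated
#' to the common band with a warning.
#'
#' @param periodograms a non-empty list of `"periodogram"` objects.
#' @return A `"periodogram"` object (combined power only; per-dimension
#'   powers are not retained across individuals).
#' @export
combine_individuals <- function(periodograms) {
  if (!length(periodograms)) stop("empty list of periodograms")
  stopifnot(all(vapply(periodograms, inherits, TRUE, "periodogram")))
  if (length(periodograms) == 1L) {
    p <- periodograms[[1L]]
    norm <- mean(p$power)
    return(new_periodogram(p$freqs, p$power_by_dim / norm, p$n_effective,
                           meta = c(p$meta, list(individuals = 1L))))
  }
  spacing <- vapply(periodograms, function(p) p$freqs$df / p$freqs$res_freq, 0)
  nyq <- vapply(periodograms, function(p) p$freqs$nyquist, 0)
  if (max(nyq) > min(nyq) * (1 + 1e-9))
    warning("individuals have different Nyquist frequencies; truncating to the common band")
  base <- periodograms[[which.max(spacing)]]$freqs
  fout <- base$freqs[base$freqs <= min(nyq) * (1 + 1e-12)]
  fgrid_out <- structure(list(freqs = fout, nyquist = min(nyq),
                              df = base$df, res_freq = base$res_freq),
                         class = "frequency_grid")
  wts <- vapply(periodograms, function(p) p$n_effective, 0)
  acc <- numeric(length(fout))
  for (i in seq_along(periodograms)) {
    p <- periodograms[[i]]
    pi_norm <- p$power / mean(p$power)
    yi <- stats::approx(p$freqs$freqs, pi_norm, xout = fout, rule = 2)$y
    acc <- acc + wts[i] * yi
  }
  new_periodogram(fgrid_out, matrix(acc / sum(wts), ncol = 1,
                                    dimnames = list(NULL, "combined")),
                  n_effective = sum(wts),
                  meta = list(individuals = length(periodograms),
                              ids = vapply(periodograms,
                                           function(p) as.character(p$meta$id %||% ""), "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local maxima of a periodogram
#'
#' Extracts the local maxima of the combined periodogram and coarsens
#' them by merging maxima closer than `1/D` on the frequency scale (the
#' natural resolution limit set by the study duration `D`; oscillations
#' finer than that carry no information), keeping the highest of each
#' merged cluster. The fundamental period is the period of the global
#' maximum.
#'
#' @param pgram a `"periodogram"` object.
#' @param study_duration total study duration `D` in seconds.
#' @return An object of class `"spectral_summary"`: list with
#'   `peak_periods` (s, sorted by decreasing power), `peak_powers`,
#'   `fundamental` (s) and `peak_freqs`.
#' @export
local_maxima <- function(pgram, study_duration) {
  stopifnot(inherits(pgram, "periodogram"), study_duration > 0)
  p <- pgram$power
  f <- pgram$freqs$freqs
  nf <- length(p)
  if (nf == 1L) {
    cand <- 1L
  } else {
    interior <- which(p[-c(1L, nf)] > p[-c(nf - 1L, nf)] &
                        p[-c(1L, nf)] > p[-c(1L, 2L)]) + 1L
    cand <- interior
    if (p[1L] > p[2L]) cand <- c(1L, cand)
    if (p[nf] > p[nf - 1L]) cand <- c(cand, nf)
  }
  if (!length(cand)) cand <- which.max(p)
  cand <- cand[order(p[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(f[i] - f[keep]) >= 1 / study_duration))
      keep <- c(keep, i)
  }
  structure(list(peak_periods = 1 / f[keep], peak_powers = p[keep],
                 peak_freqs = f[keep], fundamental = 1 / f[keep[1L]],
                 study_duration = study_duration),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %d peak(s); fundamental period %.6g s (%.4g days)\n",
              length(x$peak_periods), x$fundamental, x$fundamental / 86400))
  invisible(x)
}

#' Classify periodogram peaks as harmonics or independent periods
#'
#' A harmonic is a peak whose period divides the fundamental period (the
#' period of the highest peak) by an integer, with lower power than the
#' fundamental. Non-fundamental peaks that fail this test are independent
#' periods. The signal is labelled mono-periodic when every
#' non-fundamental peak is a harmonic, and multi-periodic otherwise; in
#' particular a peak at a longer period than the fundamental (a high
#' short-period peak dominating a long-period one) always makes the
#' signal multi-periodic.
#'
#' @param summary a [local_maxima()] result with at least one peak.
#' @param tolerance fractional tolerance on the integer period ratio
#'   (default 0.05).
#' @return list with `labels` (character per peak: `"fundamental"`,
#'   `"harmonic"`, `"independent-period"`) and `signal`
#'   (`"mono-periodic"` or `"multi-periodic"`).
#' @export
classify_harmonics <- function(summary, tolerance = 0.05) {
  stopifnot(inherits(summary, "spectral_summary"),
            length(summary$peak_periods) >= 1L)
  Tf <- summary$fundamental
  Pf <- summary$peak_powers[1L]
  labels <- character(length(summary$peak_periods))
  labels[1L] <- "fundamental"
  if (length(labels) > 1L) {
    for (i in 2L:length(labels)) {
      Ti <- summary$peak_periods[i]
      ratio <- Tf / Ti
      kint <- round(ratio)
      # absolute remainder: T_fund = k * T_i within `tolerance` of an integer
      is_harm <- kint >= 1 && abs(ratio - kint) <= tolerance &&
        summary$peak_powers[i] < Pf && Ti <= Tf * (1 + tolerance)
      labels[i] <- if (is_harm) "harmonic" else "independent-period"
    }
  }
  list(labels = labels,
       signal = if (all(labels %in% c("fundamental", "harmonic")))
         "mono-periodic" else "multi-periodic")
}

#' Plot a periodogram on log-log period scale
#'
#' @param x a `"periodogram"` object.
#' @param max if `TRUE`, plot only local maxima (coarsened at the `1/D`
#'   resolution), suppressing the artefactual fine oscillations.
#' @param add overlay on an existing plot.
#' @param study_duration duration used for the `max = TRUE` coarsening;
#'   defaults to `(n-1)*dt` from the metadata.
#' @param ... further arguments passed to [plot()]/[lines()].
#' @export
plot.periodogram <- function(x, max = FALSE, add = FALSE,
                             study_duration = NULL, ...) {
  per <- 1 / x$freqs$freqs
  pow <- x$power
  if (isTRUE(max)) {
    if (is.null(study_duration))
      study_duration <- (x$meta$n - 1) * x$meta$dt
    sm <- local_maxima(x, study_duration)
    ord <- order(sm$peak_periods)
    per <- sm$peak_periods[ord]; pow <- sm$peak_powers[ord]
  }
  pos <- pow > 0
  if (add) {
    graphics::lines(per[pos] / 86400, pow[pos], ...)
  } else {
    plot(per[pos] / 86400, pow[pos], log = "xy", type = "l",
         xlab = "period (days)", ylab = "power", ...)
  }
  invisible(x)
}
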