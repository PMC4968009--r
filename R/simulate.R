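#' Specify an aperiodic continuous-time movement model
#'
#' The four standard Gaussian movement models used as aperiodic background
#' (null) processes: Brownian motion (`"bm"`), the Ornstein-Uhlenbeck
#' position process (`"ou"`), the integrated OU / OU-velocity process
#' (`"iou"`) and the OUF process with autocorrelation in both position
#' and velocity (`"ouf"`). `sigma` is the long-run diffusion rate
#' (m^2/s) for `bm` and `iou`, and the stationary positional variance
#' (m^2, per dimension) for `ou` and `ouf`. For `iou` the stationary
#' velocity variance is `sigma / (2 * tau_vel)`, so the model converges
#' to BM with rate `sigma` as `tau_vel -> 0`.
#'
#' @param family one of `"bm"`, `"ou"`, `"iou"`, `"ouf"`.
#' @param sigma variance or diffusion rate, see above; > 0.
#' @param tau_pos position autocorrelation timescale (s); `ou`, `ouf`.
#' @param tau_vel velocity autocorrelation timescale (s); `iou`, `ouf`.
#'   For `ouf`, `tau_pos > tau_vel` is required.
#' @param mean optional [periodic_mean()] added to the stochastic path.
#' @return An object of class `"movement_model"`.
#' @export
movement_model <- function(family = c("bm", "ou", "iou", "ouf"),
                           sigma, tau_pos = NULL, tau_vel = NULL,
                           mean = NULL) {
  family <- match.arg(tolower(family), c("bm", "ou", "iou", "ouf"))
  if (!(is.numeric(sigma) && sigma > 0)) stop("'sigma' must be > 0")
  need_pos <- family %in% c("ou", "ouf")
  need_vel <- family %in% c("iou", "ouf")
  if (need_pos && !(is.numeric(tau_pos) && tau_pos > 0))
    stop("'tau_pos' must be > 0 for family ", family)
  if (need_vel && !(is.numeric(tau_vel) && tau_vel > 0))
    stop("'tau_vel' must be > 0 for family ", family)
  if (family == "ouf" && !(tau_pos > tau_vel))
    stop("OUF requires tau_pos > tau_vel")
  if (!is.null(mean) && !inherits(mean, "periodic_mean"))
    stop("'mean' must be a periodic_mean() object")
  structure(list(family = family, sigma = sigma,
                 tau_pos = if (need_pos) tau_pos else NULL,
                 tau_vel = if (need_vel) tau_vel else NULL,
                 mean = mean),
            class = "movement_model")
}

#' @export
print.movement_model <- function(x, ...) {
  cat(sprintf("<movement_model> %s  sigma=%.6g%s%s%s\n", toupper(x$family),
              x$sigma,
              if (!is.null(x$tau_pos)) sprintf("  tau_pos=%.6g s", x$tau_pos) else "",
              if (!is.null(x$tau_vel)) sprintf("  tau_vel=%.6g s", x$tau_vel) else "",
              if (!is.null(x$mean)) sprintf("  + periodic mean (T=%.6g s, %s)",
                                            x$mean$period, x$mean$waveform) else ""))
  invisible(x)
}

#' Periodic deterministic mean component
#'
#' A repeating mean pattern superimposed on the stochastic movement:
#' a per-dimension sinusoid, an ellipse (dimension 1 on cosine, dimension
#' 2 on sine), or a constant-speed traversal of a square loop — the
#' latter two being concrete non-sinusoidal repeated patterns that
#' activate harmonic series in the periodogram.
#'
#' @param period repeat period (s), > 0.
#' @param amplitude amplitude (m), one value per dimension (recycled);
#'   >= 0. For `"square-loop"` the half-width of the square.
#' @param waveform `"sinusoid"`, `"ellipse"` or `"square-loop"`.
#' @param phase phase offset (radians).
#' @return An object of class `"periodic_mean"`.
#' @export
periodic_mean <- function(period, amplitude, waveform = c("sinusoid", "ellipse", "square-loop"),
                          phase = 0) {
  waveform <- match.arg(waveform)
  if (!(period > 0)) stop("'period' must be > 0")
  if (any(amplitude < 0)) stop("'amplitude' must be >= 0")
  structure(list(period = period, amplitude = amplitude,
                 waveform = waveform, phase = phase),
            class = "periodic_mean")
}

periodic_mean_values <- function(mean, times, k) {
  amp <- rep_len(mean$amplitude, k)
  u <- 2 * pi * times / mean$period + mean$phase
  out <- matrix(0, length(times), k)
  if (mean$waveform == "sinusoid") {
    for (j in seq_len(k)) out[, j] <- amp[j] * sin(u)
  } else if (mean$waveform == "ellipse") {
    if (k < 2) stop("'ellipse' waveform needs K >= 2")
    out[, 1] <- amp[1] * cos(u)
    out[, 2] <- amp[2] * sin(u)
  } else { # square-loop: constant-speed traversal of the square perimeter
    if (k < 2) stop("'square-loop' waveform needs K >= 2")
    a <- amp[1]
    s <- (u / (2 * pi)) %% 1  # position along perimeter in [0,1)
    seg <- floor(s * 4)
    r <- s * 4 - seg          # position within the side
    x <- numeric(length(s)); y <- numeric(length(s))
    x[seg == 0] <- a;                 y[seg == 0] <- a * (2 * r[seg == 0] - 1)
    x[seg == 1] <- a * (1 - 2 * r[seg == 1]); y[seg == 1] <- a
    x[seg == 2] <- -a;                y[seg == 2] <- a * (1 - 2 * r[seg == 2])
    x[seg == 3] <- a * (2 * r[seg == 3] - 1); y[seg == 3] <- -a
    out[, 1] <- x; out[, 2] <- y
  }
  out
}

#' Simulate a track from a movement model
#'
#' Exact Gaussian simulation at arbitrary (irregular) times by
#' per-dimension Markov recursion: the OU position process uses its exact
#' AR(1) transition, BM uses independent Gaussian increments, and the
#' IOU/OUF models use the exact 2-state (position, velocity) Gaussian
#' transition per interval. OU and OUF start in their stationary
#' distribution; BM and IOU start at the origin (IOU with stationary
#' velocity). An optional periodic mean is added afterwards. The same
#' seed always reproduces the same track.
#'
#' @param spec a [movement_model()] object.
#' @param grid_times simulation times (s), strictly increasing.
#' @param K number of spatial dimensions (1-3).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param id identifier for the returned track.
#' @return A [track_series()] object.
#' @export
simulate_track <- function(spec, grid_times, K = 2L, seed = NULL, id = "sim") {
  stopifnot(inherits(spec, "movement_model"))
  t <- as.numeric(grid_times)
  if (any(diff(t) <= 0)) stop("'grid_times' must be strictly increasing")
  K <- as.integer(K)
  if (!(K %in% 1:3)) stop("K must be 1, 2 or 3")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(t)
  X <- switch(spec$family,
    bm = {
      dts <- diff(t)
      inc <- matrix(stats::rnorm((n - 1) * K), n - 1, K) *
        sqrt(spec$sigma * dts)
      apply(rbind(matrix(0, 1, K), inc), 2, cumsum)
    },
    ou = sim_ou_cpp(t, spec$sigma, spec$tau_pos,
                    matrix(stats::rnorm(n * K), n, K)),
    iou = sim_iou_cpp(t, spec$sigma, spec$tau_vel,
                      matrix(stats::rnorm(n * K), n, K),
                      matrix(stats::rnorm(n * K), n, K)),
    ouf = sim_ouf_cpp(t, spec$sigma, spec$tau_pos, spec$tau_vel,
                      matrix(stats::rnorm(n * K), n, K),
                      matrix(stats::rnorm(n * K), n, K)))
  X <- as.matrix(X)
  if (!is.null(spec$mean)) X <- X + periodic_mean_values(spec$mean, t, K)
  track_series(t, X, id = id)
}

#' Specify a structured-missingness scheme
#'
#' Patterns of missing fixes typical of telemetry: none, i.i.d. random
#' thinning, deterministic duty cycling (`on_len` recorded cells followed
#' by `off_len` missing cells, repeating), or temporally autocorrelated
#' gaps (a two-state Markov keep/drop chain with persistence `p_stay` and
#' marginal retention `p_keep`).
#'
#' @param kind `"none"`, `"iid"`, `"duty_cycle"` or `"autocorrelated"`.
#' @param p_keep retention probability in `[0,1]` (`iid`,
#'   `autocorrelated`).
#' @param on_len,off_len cell counts >= 1 (`duty_cycle`).
#' @param p_stay Markov persistence in `[0,1]` (`autocorrelated`).
#' @return An object of class `"missingness_spec"`.
#' @export
missingness_spec <- function(kind = c("none", "iid", "duty_cycle", "autocorrelated"),
                             p_keep = 0.5, on_len = 1L, off_len = 1L,
                             p_stay = 0.9) {
  kind <- match.arg(kind)
  if (p_keep < 0 || p_keep > 1) stop("'p_keep' must be in [0,1]")
  if (p_stay < 0 || p_stay > 1) stop("'p_stay' must be in [0,1]")
  if (on_len < 1 || off_len < 1) stop("duty-cycle lengths must be >= 1")
  structure(list(kind = kind, p_keep = p_keep,
                 on_len = as.integer(on_len), off_len = as.integer(off_len),
                 p_stay = p_stay),
            class = "missingness_spec")
}

#' Apply a missingness scheme to a track
#'
#' Subsets the records of a track according to a [missingness_spec()].
#' Duty cycling is deterministic (cells are indexed on the track's median
#' sampling interval from its first record); i.i.d. and autocorrelated
#' thinning use the seed.
#'
#' @param track a [track_series()] object.
#' @param mspec a [missingness_spec()] object.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [track_series()] object with at least 3 records (error
#'   otherwise).
#' @export
apply_missingness <- function(track, mspec, seed = NULL) {
  stopifnot(inherits(track, "track"), inherits(mspec, "missingness_spec"))
  if (mspec$kind == "none") return(track)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(track$times)
  keep <- switch(mspec$kind,
    iid = stats::rbinom(n, 1L, mspec$p_keep) == 1L,
    duty_cycle = {
      dt <- lower_median(diff(track$times))
      cell <- round((track$times - track$times[1L]) / dt)
      (cell %% (mspec$on_len + mspec$off_len)) < mspec$on_len
    },
    autocorrelated = {
      # two-state chain with stationary marginal p_keep and persistence
      # p_stay: switch probabilities scaled by (1 - p_stay)
      s <- logical(n)
      s[1L] <- stats::runif(1) < mspec$p_keep
      p_kk <- 1 - (1 - mspec$p_stay) * (1 - mspec$p_keep)  # keep -> keep
      p_dk <- (1 - mspec$p_stay) * mspec$p_keep            # drop -> keep
      u <- stats::runif(n)
      for (j in 2:n) s[j] <- u[j] < (if (s[j - 1L]) p_kk else p_dk)
      s
    })
  if (sum(keep) < 3L)
    stop("missingness scheme retains fewer than 3 records")
  structure(list(id = track$id, times = track$times[keep],
                 coords = track$coords[keep, , drop = FALSE],
                 dim_names = track$dim_names),
            class = "track")
}

#' Theoretical periodogram shape of an aperiodic movement model
#'
#' The spectral density of the model on a frequency grid, on the scale of
#' the periodogram's expectation: a Lorentzian for OU, `f^-2` for BM,
#' and products of Lorentzian factors for IOU and OUF. The log-log slope
#' against period is 0 in a model's flat regime, 2 in its BM-like regime
#' and 4 in its velocity-autocorrelated regime, with regime transitions
#' at periods `2*pi*tau`. If `dt` is supplied the density is divided by
#' `dt`, matching the expectation scale of the discrete periodogram of a
#' series sampled at that interval.
#'
#' @param spec an aperiodic [movement_model()] (no periodic mean).
#' @param freqs frequencies (1/s).
#' @param dt optional sampling interval (s) for periodogram scaling.
#' @return numeric vector of theoretical power values.
#' @export
theoretical_lsp <- function(spec, freqs, dt = NULL) {
  stopifnot(inherits(spec, "movement_model"))
  if (!is.null(spec$mean)) stop("theoretical shape is defined for aperiodic models")
  om <- 2 * pi * freqs
  S <- switch(spec$family,
    bm = spec$sigma / om^2,
    ou = {
      lp <- 1 / spec$tau_pos
      2 * spec$sigma * lp / (lp^2 + om^2)
    },
    iou = spec$sigma / (om^2 * (1 + (om * spec$tau_vel)^2)),
    ouf = {
      lp <- 1 / spec$tau_pos; lv <- 1 / spec$tau_vel
      2 * spec$sigma * lp * lv * (lp + lv) / ((lp^2 + om^2) * (lv^2 + om^2))
    })
  if (!is.null(dt)) S <- S / dt
  S
}
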