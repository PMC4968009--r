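#' Exact least-squares Lomb-Scargle periodogram (reference implementation)
#'
#' Direct O(N^2) evaluation of the Lomb-Scargle periodogram from its
#' defining least-squares problem: at each frequency f the data are fit to
#' `A e^{2 pi i f t} + conj(A) e^{-2 pi i f t}` by weighted least squares
#' (2x2 normal equations in Re A, Im A per dimension), and the power is
#' half the explained sum of squares. This works at arbitrary (un-snapped)
#' record times and arbitrary frequencies, and serves as the correctness
#' certificate for [fast_lsp()]; it is far too slow for routine use above
#' a few thousand records.
#'
#' @param times record times (s), any spacing.
#' @param values N x K matrix (or vector) of coordinates.
#' @param weights 0/1 vector marking retained records; default all 1.
#' @param freqs frequencies (1/s) at which to evaluate the periodogram.
#' @param center subtract the weighted per-dimension mean first (the same
#'   centering [fast_lsp()] applies). Default `TRUE`.
#' @return A `"periodogram"` object.
#' @export
lsq_lsp <- function(times, values, weights = NULL, freqs, center = TRUE) {
  times <- as.numeric(times)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  n <- length(times)
  stopifnot(nrow(values) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (sum(weights > 0) < 3) stop("need at least 3 weighted records")
  obs <- weights > 0
  t <- times[obs]
  X <- values[obs, , drop = FALSE]
  if (center) X <- sweep(X, 2, colMeans(X))
  k <- ncol(X)
  power <- matrix(0, length(freqs), k)
  sing <- 0L
  for (i in seq_along(freqs)) {
    fit <- lsq_fit_centered(t, X, freqs[i])
    power[i, ] <- fit$power
    sing <- sing + fit$singular
  }
  if (sing > 0)
    warning(sprintf("singular normal equations at %d frequency/dimension case(s); power set to 0 there", sing))
  fgrid <- structure(list(freqs = freqs, nyquist = NA_real_, df = NA_real_,
                          res_freq = NA_integer_),
                     class = "frequency_grid")
  new_periodogram(fgrid, power, length(t),
                  meta = list(id = "lsq_lsp", n = n, dt = NA_real_,
                              res_time = NA_integer_, res_freq = NA_integer_))
}

# core least-squares solve at one frequency for pre-centered observed data
lsq_fit_centered <- function(t, X, f) {
  th <- 2 * pi * f * t
  cth <- cos(th); sth <- sin(th)
  # design columns for the real parameters (a, b) = (Re A, Im A):
  # fitted value = 2 a cos(theta) - 2 b sin(theta)
  Suu <- 4 * sum(cth^2)
  Svv <- 4 * sum(sth^2)
  Suv <- -4 * sum(cth * sth)
  k <- ncol(X)
  ReG <- as.numeric(crossprod(cth, X))   # sum X cos
  ImG <- -as.numeric(crossprod(sth, X))  # DFT convention e^{-i theta}
  rhs_u <- 2 * ReG
  rhs_v <- 2 * ImG
  det <- Suu * Svv - Suv^2
  singular <- 0L
  if (abs(det) > 1e-12 * (Suu + Svv)^2) {
    a <- (Svv * rhs_u - Suv * rhs_v) / det
    b <- (Suu * rhs_v - Suv * rhs_u) / det
  } else {
    # rank-1 design (e.g. f = 0 or exact Nyquist on an even grid):
    # minimum-norm least squares along the dominant direction
    if (Suu + Svv < 1e-300) {
      a <- b <- numeric(k); singular <- k
    } else if (Suu >= Svv) {
      a <- rhs_u / Suu; b <- numeric(k)
    } else {
      a <- numeric(k); b <- rhs_v / Svv
    }
  }
  amplitude <- complex(real = a, imaginary = b)
  # explained sum of squares / 2 = a ReG' + b ImG' with rhs = 2 G parts
  power <- a * rhs_u / 2 + b * rhs_v / 2
  power <- pmax(power, 0)
  cost <- colSums(X^2) - 2 * power
  list(amplitude = amplitude, power = power, cost = pmax(cost, 0),
       singular = singular)
}

#' Least-squares sinusoid fit at a single frequency
#'
#' Exposes the per-frequency fit behind [lsq_lsp()]: the complex
#' amplitude, the residual cost, and the resulting periodogram power, for
#' each dimension.
#'
#' @inheritParams lsq_lsp
#' @param f a single frequency (1/s).
#' @return list with `amplitude` (complex, per dimension), `cost`
#'   (residual weighted sum of squares), `power`.
#' @export
lsq_fit <- function(times, values, weights = NULL, f, center = TRUE) {
  times <- as.numeric(times)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  if (is.null(weights)) weights <- rep(1, length(times))
  obs <- weights > 0
  t <- times[obs]
  X <- values[obs, , drop = FALSE]
  if (center) X <- sweep(X, 2, colMeans(X))
  lsq_fit_centered(t, X, f)
}
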