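# shared fixtures and independent oracles, all generated in code

DAY <- 86400
HOUR <- 3600

# complete hourly track with the given signal vector(s)
hourly_track <- function(x, id = "fix") {
  x <- as.matrix(x)
  track_series((seq_len(nrow(x)) - 1) * HOUR, x, id = id)
}

# closed-form model covariance matrices (the dense oracles used to certify
# both the simulators and the state-space likelihoods)
model_cov <- function(family, t, sigma, tau_pos = NULL, tau_vel = NULL) {
  d <- abs(outer(t, t, "-"))
  switch(family,
    bm = sigma * outer(t - t[1], t - t[1], pmin),
    ou = sigma * exp(-d / tau_pos),
    ouf = sigma * (tau_pos * exp(-d / tau_pos) - tau_vel * exp(-d / tau_vel)) /
      (tau_pos - tau_vel),
    iou = {
      sv <- sigma / (2 * tau_vel); l <- 1 / tau_vel
      tt <- t - t[1]
      s <- outer(tt, tt, pmin); b <- outer(tt, tt, pmax)
      (sv / l^2) * (2 * l * s - 1 + exp(-l * outer(tt, rep(0, length(tt)), "+")) +
                      t(exp(-l * outer(tt, rep(0, length(tt)), "+"))) -
                      exp(-l * (b - s)))
    })
}

# dense-covariance log-likelihood oracle, same convention as the package:
# conditioned on the first record; stationary mean profiled numerically
dense_loglik <- function(family, t, Y, sigma, tau_pos = NULL, tau_vel = NULL) {
  Y <- as.matrix(Y)
  S <- model_cov(family, t, sigma, tau_pos, tau_vel)
  n <- length(t)
  ll_dim <- function(y) {
    if (family %in% c("bm", "iou")) {
      yc <- y - y[1]
      Sc <- S[-1, -1, drop = FALSE]
      return(-0.5 * (determinant(Sc)$modulus +
                       t(yc[-1]) %*% solve(Sc, yc[-1]) + (n - 1) * log(2 * pi)))
    }
    f <- function(mu) {
      cm <- mu + S[-1, 1] / S[1, 1] * (y[1] - mu)
      Sc <- S[-1, -1] - S[-1, 1] %*% t(S[1, -1]) / S[1, 1]
      -0.5 * (determinant(Sc)$modulus +
                t(y[-1] - cm) %*% solve(Sc, y[-1] - cm) + (n - 1) * log(2 * pi))
    }
    r <- max(stats::sd(y), sqrt(sigma)) * 20
    opt <- stats::optimize(function(m) -f(m), c(mean(y) - r, mean(y) + r))
    f(opt$minimum)
  }
  sum(apply(Y, 2, function(y) as.numeric(ll_dim(y))))
}

# malfunctioning-collar schedule: day/night-modulated Markov gap chain,
# producing temporally autocorrelated missingness with a daily structure
faulty_collar_template <- function(track, seed, p_day = 0.95, p_night = 0.2,
                                   p_stay = 0.85) {
  set.seed(seed)
  hod <- (round(track$times / HOUR) %% 24)
  keep <- logical(length(track$times))
  state <- TRUE
  for (j in seq_along(keep)) {
    p_target <- if (hod[j] < 12) p_day else p_night
    p <- if (state) 1 - (1 - p_stay) * (1 - p_target) else (1 - p_stay) * p_target
    state <- stats::runif(1) < p
    keep[j] <- state
  }
  track_series(track$times[keep], track$coords[keep, , drop = FALSE],
               id = "faulty-collar")
}

# visibility of a spectral bump at `period`: mean power in a +-4*df window
# around the period, in decades above the surrounding background ring
peak_visibility <- function(track, period) {
  g <- build_sample_grid(track)
  fg <- frequency_grid(g)
  p <- suppressMessages(fast_lsp(g, fg))
  f <- fg$freqs; df <- fg$df
  win <- abs(f - 1 / period) <= 4 * df
  ring <- abs(f - 1 / period) > 8 * df & abs(f - 1 / period) <= 30 * df
  log10(mean(p$power[win])) - log10(mean(p$power[ring]))
}

# normalized maximum deviation between two periodograms
max_rel_err <- function(a, b) {
  max(abs(a$power_by_dim - b$power_by_dim)) / max(abs(b$power_by_dim))
}
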