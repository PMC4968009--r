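test_that("model specification validates parameters", {
  expect_error(movement_model("ou", sigma = -1, tau_pos = 1), "sigma")
  expect_error(movement_model("ou", sigma = 1), "tau_pos")
  expect_error(movement_model("iou", sigma = 1), "tau_vel")
  expect_error(movement_model("ouf", sigma = 1, tau_pos = 1, tau_vel = 2),
               "tau_pos > tau_vel")
  expect_s3_class(movement_model("bm", 1), "movement_model")
})

test_that("simulation is reproducible and respects the white-noise limit", {
  t <- (0:999) * HOUR
  a <- simulate_track(movement_model("ou", 2, tau_pos = 5 * HOUR), t,
                      K = 2, seed = 42)
  b <- simulate_track(movement_model("ou", 2, tau_pos = 5 * HOUR), t,
                      K = 2, seed = 42)
  expect_identical(a$coords, b$coords)
  # tau << dt: consecutive fixes decorrelate (white limit)
  w <- simulate_track(movement_model("ou", 1, tau_pos = 1), t, K = 1, seed = 3)
  x <- w$coords[, 1]
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 3 / sqrt(length(x)))
})

test_that("OU sample autocovariance matches the exponential model", {
  tau <- 10 * HOUR
  sig <- 4
  n <- 1e5
  tr <- simulate_track(movement_model("ou", sig, tau_pos = tau),
                       (0:(n - 1)) * HOUR, K = 1, seed = 11)
  x <- tr$coords[, 1]
  for (lag in c(1, 5, 10, 20)) {
    emp <- mean(x[-seq_len(lag)] * x[seq_len(n - lag)])
    theo <- sig * exp(-lag * HOUR / tau)
    # se of the autocovariance under strong correlation: ~ sigma^2
    # sqrt(4 tau / (N dt))
    se <- sig * sqrt(4 * tau / (n * HOUR))
    expect_lt(abs(emp - theo), 3 * se)
  }
})

test_that("short-track covariance matches the closed form for every family", {
  # 1e4 replicates of N=8 tracks; empirical covariance vs model covariance
  t8 <- c(0, 1, 2.5, 4, 5, 7, 8, 10) * HOUR
  cases <- list(
    list(fam = "bm", sigma = 1 / HOUR),
    list(fam = "ou", sigma = 2, tau_pos = 4 * HOUR),
    list(fam = "iou", sigma = 1 / HOUR, tau_vel = 3 * HOUR),
    list(fam = "ouf", sigma = 2, tau_pos = 6 * HOUR, tau_vel = 1.5 * HOUR))
  nrep <- 1e4
  for (cs in cases) {
    spec <- movement_model(cs$fam, cs$sigma, tau_pos = cs$tau_pos,
                           tau_vel = cs$tau_vel)
    set.seed(777)
    X <- vapply(seq_len(nrep),
                function(i) simulate_track(spec, t8, K = 1)$coords[, 1],
                numeric(8))
    emp <- tcrossprod(X - rowMeans(X)) / nrep
    theo <- model_cov(cs$fam, t8, cs$sigma, cs$tau_pos, cs$tau_vel)
    if (cs$fam %in% c("ou", "ouf")) {
      # stationary families: compare raw second moments (mean is zero)
      emp <- tcrossprod(X) / nrep
    } else {
      # nonstationary families start at the origin; remove the zero row/col
      theo <- theo
      emp <- tcrossprod(X) / nrep
    }
    scale <- max(abs(theo))
    mc_se <- scale * 3.5 / sqrt(nrep)
    expect_lt(max(abs(emp - theo)), 5 * mc_se + 0.02 * scale,
              label = paste("covariance mismatch for", cs$fam))
  }
})

test_that("periodic mean components repeat with the requested period", {
  t <- (0:479) * HOUR
  for (wf in c("sinusoid", "ellipse", "square-loop")) {
    m <- periodic_mean(DAY, 100, wf)
    v <- movelsp:::periodic_mean_values(m, t, 2)
    expect_equal(v[1:24, ], v[25:48, ], tolerance = 1e-12)
    expect_lte(max(abs(v)), 100 + 1e-9)
  }
  # square loop traverses at constant speed: equal steps
  m <- periodic_mean(DAY, 100, "square-loop")
  v <- movelsp:::periodic_mean_values(m, seq(0, DAY, length.out = 401), 2)
  steps <- sqrt(rowSums(diff(v)^2))
  expect_lt(diff(range(steps)), 1e-6 * mean(steps))
  # sinusoid injected on OU noise is recovered by the periodogram
  spec <- movement_model("ou", 0.5, tau_pos = 3 * HOUR,
                         mean = periodic_mean(DAY, 3, "sinusoid"))
  tr <- simulate_track(spec, t, K = 1, seed = 5)
  pg <- suppressMessages(fast_lsp(build_sample_grid(tr)))
  expect_equal(1 / pg$freqs$freqs[which.max(pg$power)], DAY, tolerance = 0.05)
})

test_that("missingness schemes thin records as specified", {
  t <- (0:9599) * HOUR  # a whole number of 24 h duty cycles
  tr <- simulate_track(movement_model("bm", 1), t, K = 1, seed = 8)
  # none: identity
  expect_identical(apply_missingness(tr, missingness_spec("none")), tr)
  # duty cycle 12 on / 12 off: exactly half, in 12 h blocks
  dc <- apply_missingness(tr, missingness_spec("duty_cycle", on_len = 12,
                                               off_len = 12))
  expect_equal(length(dc$times), 4800L)
  hod <- (dc$times / HOUR) %% 24
  expect_true(all(hod < 12))
  # iid p=0.5: binomial bound
  iid <- apply_missingness(tr, missingness_spec("iid", p_keep = 0.5), seed = 2)
  frac <- length(iid$times) / length(t)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / length(t)))
  # autocorrelated gaps: marginal retention near p_keep, runs longer than iid
  ac <- apply_missingness(tr, missingness_spec("autocorrelated", p_keep = 0.5,
                                               p_stay = 0.95), seed = 3)
  frac_ac <- length(ac$times) / length(t)
  expect_lt(abs(frac_ac - 0.5), 0.1)
  keep_vec <- t %in% ac$times
  runs <- rle(keep_vec)$lengths
  expect_gt(mean(runs), 3)  # iid runs average 2
  # refusing to keep fewer than 3 records
  small <- track_series(c(0, 1, 2, 3) * HOUR, rnorm(4))
  expect_error(apply_missingness(small, missingness_spec("iid", p_keep = 0.01),
                                 seed = 1), "fewer than 3")
})

test_that("theoretical periodogram shapes have the advertised slopes and knees", {
  slope_at <- function(spec, per) {
    # local log-log slope of power vs period by finite differences
    f1 <- 1 / (per * 1.01); f0 <- 1 / per
    s <- theoretical_lsp(spec, c(f0, f1))
    (log10(s[2]) - log10(s[1])) / (log10(per * 1.01) - log10(per))
  }
  ou <- movement_model("ou", 1, tau_pos = 10 * HOUR)
  expect_equal(slope_at(ou, 1e6 * HOUR), 0, tolerance = 0.01)
  expect_equal(slope_at(ou, 1e-3 * HOUR), 2, tolerance = 0.01)
  iou <- movement_model("iou", 1, tau_vel = 10 * HOUR)
  expect_equal(slope_at(iou, 1e-3 * HOUR), 4, tolerance = 0.01)
  expect_equal(slope_at(iou, 1e6 * HOUR), 2, tolerance = 0.01)
  bm <- movement_model("bm", 1)
  expect_equal(slope_at(bm, HOUR), 2, tolerance = 1e-6)
  expect_equal(slope_at(bm, 1000 * HOUR), 2, tolerance = 1e-6)
  # knee: the OU asymptotes S(0) and 2*sigma/(tau*omega^2) cross at 2*pi*tau
  tau <- 10 * HOUR
  flat <- theoretical_lsp(ou, 1e-12)          # low-frequency plateau
  f_knee <- 1 / (2 * pi * tau)
  steep <- 2 * 1 / (tau * (2 * pi * f_knee)^2)  # high-frequency asymptote
  expect_equal(steep, flat, tolerance = 1e-9)
  # OUF slope ladder: 0 (long) -> 2 (mid) -> 4 (short)
  ouf <- movement_model("ouf", 1, tau_pos = 100 * HOUR, tau_vel = HOUR)
  expect_equal(slope_at(ouf, 1e7 * HOUR), 0, tolerance = 0.01)
  expect_equal(slope_at(ouf, 2 * pi * 10 * HOUR), 2, tolerance = 0.15)
  expect_equal(slope_at(ouf, 1e-3 * HOUR), 4, tolerance = 0.01)
})
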