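test_that("frequency grid follows the Nyquist and resolution rules", {
  tr <- hourly_track(rnorm(1000))
  g <- build_sample_grid(tr)
  fg <- frequency_grid(g, 1)
  expect_equal(fg$nyquist, 0.5 / HOUR)
  expect_equal(fg$df, 1e-3 / HOUR)
  expect_length(fg$freqs, 500)
  expect_true(all(fg$freqs > 0 & fg$freqs <= fg$nyquist + 1e-15))
  expect_equal(diff(fg$freqs), rep(fg$df, 499))
  # oversampling doubles the count, same Nyquist
  fg2 <- frequency_grid(g, 2)
  expect_length(fg2$freqs, 1000)
  expect_equal(fg2$nyquist, fg$nyquist)
  expect_equal(diff(fg2$freqs)[1], fg$df / 2)
  # minimal grid
  g2 <- build_sample_grid(track_series(c(0, 1), c(0, 1)))
  expect_equal(frequency_grid(g2)$freqs, 0.5)
  expect_error(frequency_grid(g, 0), "res_freq")
})

test_that("fast LSP equals the least-squares oracle on gappy grids", {
  # property over random schedules, signals, dimensions, oversampling
  set.seed(101)
  for (case in 1:8) {
    n <- sample(c(64, 200, 333, 512), 1)
    k <- sample(1:3, 1)
    rf <- sample(1:2, 1)
    x <- matrix(as.numeric(arima.sim(list(ar = runif(1, -0.5, 0.95)), n * k)),
                ncol = k)
    keep <- runif(n) < runif(1, 0.4, 0.9)
    keep[1] <- TRUE
    tr <- track_series(((0:(n - 1)) * HOUR)[keep], x[keep, , drop = FALSE])
    g <- build_sample_grid(tr)
    fg <- frequency_grid(g, rf)
    pf <- suppressMessages(fast_lsp(g, fg))
    obs <- g$w == 1
    po <- lsq_lsp(movelsp:::grid_times(g)[obs], g$wX[obs, , drop = FALSE],
                  freqs = fg$freqs)
    expect_lt(max_rel_err(pf, po), 1e-8)
    # non-negativity of the combined power
    expect_true(all(pf$power >= -1e-9 * max(pf$power)))
    # combined power is the mean over dimensions
    expect_equal(pf$power, rowMeans(pf$power_by_dim))
  }
})

test_that("fast LSP reduces to the DFT periodogram for complete data", {
  set.seed(7)
  for (n in c(128, 255)) {
    x <- cbind(as.numeric(arima.sim(list(ar = 0.8), n)), rnorm(n))
    g <- build_sample_grid(hourly_track(x))
    fg <- frequency_grid(g, 1)
    pf <- fast_lsp(g, fg)
    pd <- dft_periodogram(g, fg)
    expect_lt(max_rel_err(pf, pd), 1e-10)
  }
  # missing data refuse the DFT route
  trg <- track_series(c(0, 1, 3, 4) * HOUR, rnorm(4))
  expect_error(dft_periodogram(build_sample_grid(trg)), "fast_lsp")
})

test_that("DFT periodogram basics: zero signal, pure tone, variance scale", {
  g <- build_sample_grid(hourly_track(rep(3, 64)))
  expect_true(all(dft_periodogram(g)$power < 1e-20))
  # tone at an exact grid frequency concentrates in one bin
  n <- 128
  tone <- cos(2 * pi * 8 * (0:(n - 1)) / n)
  pg <- dft_periodogram(build_sample_grid(hourly_track(tone)))
  expect_equal(which.max(pg$power), 8L)
  expect_lt(sort(pg$power, decreasing = TRUE)[2] / max(pg$power), 1e-20)
  # white noise: mean power ~ variance, cross-checked against naive O(N^2) sum
  set.seed(12)
  x <- rnorm(n)
  pgw <- dft_periodogram(build_sample_grid(hourly_track(x)))
  xc <- x - mean(x)
  naive <- vapply(pgw$freqs$freqs, function(f) {
    Mod(sum(xc * exp(-2i * pi * f * (0:(n - 1)) * HOUR)))^2 / n
  }, 0)
  naive[length(naive)] <- naive[length(naive)] / 2  # least-squares Nyquist convention
  expect_equal(pgw$power, naive, tolerance = 1e-10)
  expect_equal(mean(pgw$power[-length(naive)]), var(x), tolerance = 0.35)
})

test_that("fast LSP recovers an injected daily tone under 30% missingness", {
  set.seed(33)
  n <- 512
  x <- sin(2 * pi * (0:(n - 1)) / 24)
  keep <- runif(n) < 0.7
  tr <- track_series(((0:(n - 1)) * HOUR)[keep], x[keep])
  pg <- suppressMessages(fast_lsp(build_sample_grid(tr)))
  peak <- 1 / pg$freqs$freqs[which.max(pg$power)]
  expect_lt(abs(peak - DAY) / DAY, 0.1)
})

test_that("schedule periodogram exposes periodic duty cycling", {
  # constant schedule: zero power
  g <- build_sample_grid(hourly_track(rnorm(200)))
  expect_true(all(schedule_periodogram(g)$power < 1e-20))
  # 12 h on / 12 h off duty cycle on an hourly grid peaks at 24 h,
  # cross-checked against the least-squares fit of the schedule itself
  n <- 480
  w <- rep(c(rep(1, 12), rep(0, 12)), n / 24)
  tr <- track_series(((0:(n - 1)) * HOUR)[w == 1], rnorm(sum(w)))
  g2 <- build_sample_grid(tr)
  fg2 <- frequency_grid(g2)
  sp <- schedule_periodogram(g2, fg2)
  expect_lt(abs(1 / sp$freqs$freqs[which.max(sp$power)] - DAY) / DAY, 0.06)
  po <- lsq_lsp((0:(g2$n - 1)) * HOUR, g2$w, freqs = fg2$freqs)
  expect_lt(max_rel_err(sp, po), 1e-8)
  # iid thinning: no outstanding schedule peak beyond Monte-Carlo extremes
  set.seed(55)
  n3 <- 1024
  w3 <- rbinom(n3, 1, 0.5)
  w3[1] <- 1L
  tr3 <- track_series(((0:(n3 - 1)) * HOUR)[w3 == 1], rnorm(sum(w3)))
  g3 <- build_sample_grid(tr3)
  sp3 <- schedule_periodogram(g3, frequency_grid(g3))
  mc_max <- replicate(50, {
    wmc <- rbinom(g3$n, 1, mean(g3$w))
    max(dft_periodogram(build_sample_grid(hourly_track(wmc)))$power)
  })
  expect_lt(max(sp3$power), max(mc_max) * 1.5)
})

test_that("multi-individual averaging sharpens a shared daily peak", {
  # single element and idempotence
  set.seed(9)
  g <- build_sample_grid(hourly_track(rnorm(128)))
  p <- dft_periodogram(g)
  c1 <- combine_individuals(list(p))
  expect_equal(c1$power, p$power / mean(p$power))
  c2 <- combine_individuals(list(p, p))
  expect_equal(c2$power, p$power / mean(p$power), tolerance = 1e-12)
  # 8 individuals sharing a 24 h mean over OUF noise
  n <- 720
  spec <- movement_model("ouf", 1e5, tau_pos = 20 * HOUR, tau_vel = HOUR,
                         mean = periodic_mean(DAY, 250, "sinusoid"))
  pgs <- lapply(1:8, function(i) {
    tr <- simulate_track(spec, (0:(n - 1)) * HOUR, K = 2, seed = 700 + i)
    suppressMessages(fast_lsp(build_sample_grid(tr)))
  })
  comb <- combine_individuals(pgs)
  prom_at_day <- function(pg) {
    f <- pg$freqs$freqs
    i <- which.min(abs(f - 1 / DAY))
    ring <- abs(f - 1 / DAY) <= 20 * pg$freqs$df & abs(f - 1 / DAY) > 2 * pg$freqs$df
    log10(pg$power[i] / mean(pg$power[ring]))
  }
  singles <- vapply(pgs, prom_at_day, 0)
  expect_gt(prom_at_day(comb), stats::median(singles))
})

test_that("local maxima are coarsened at the 1/D resolution", {
  # monotone periodogram: only the boundary maximum
  fg <- structure(list(freqs = (1:50) / (100 * HOUR), nyquist = 0.5 / HOUR,
                       df = 1 / (100 * HOUR), res_freq = 1L),
                  class = "frequency_grid")
  mono <- movelsp:::new_periodogram(fg, matrix(50:1, ncol = 1), 100,
                                    list(n = 100, dt = HOUR))
  sm <- local_maxima(mono, 100 * HOUR)
  expect_equal(sm$peak_freqs, fg$freqs[1])
  # two well-separated tones are both kept
  set.seed(21)
  n <- 960
  x <- sin(2 * pi * (0:(n - 1)) / 24) + 0.9 * sin(2 * pi * (0:(n - 1)) / 12 + 1)
  pg <- dft_periodogram(build_sample_grid(hourly_track(x)))
  sm2 <- local_maxima(pg, (n - 1) * HOUR)
  tops <- sort(sm2$peak_periods[1:2])
  expect_equal(tops, c(12, 24) * HOUR, tolerance = 0.05)
  expect_equal(sm2$fundamental, DAY, tolerance = 0.05)
  # noisy aperiodic periodogram: retained maxima respect the 1/D gap
  tr <- simulate_track(movement_model("ouf", 1, tau_pos = 30 * HOUR,
                                      tau_vel = 2 * HOUR),
                       (0:2159) * HOUR, K = 2, seed = 77)
  g <- build_sample_grid(tr)
  D <- 90 * DAY
  sm3 <- local_maxima(suppressMessages(fast_lsp(g)), D)
  if (length(sm3$peak_freqs) > 1) {
    gaps <- abs(outer(sm3$peak_freqs, sm3$peak_freqs, "-"))
    expect_true(all(gaps[upper.tri(gaps)] >= 1 / D - 1e-15))
  }
})

test_that("harmonic classification follows the integer-multiple rules", {
  mk <- function(periods, powers) {
    structure(list(peak_periods = periods, peak_powers = powers,
                   peak_freqs = 1 / periods, fundamental = periods[1],
                   study_duration = 100 * DAY), class = "spectral_summary")
  }
  # 24 h fundamental with 12 h and 8 h harmonics: mono-periodic
  r <- classify_harmonics(mk(c(24, 12, 8) * HOUR, c(10, 6, 3)))
  expect_equal(r$labels, c("fundamental", "harmonic", "harmonic"))
  expect_equal(r$signal, "mono-periodic")
  # 29.5 d and 24 h: not integer multiples -> multi-periodic
  r2 <- classify_harmonics(mk(c(29.5 * DAY, DAY), c(10, 6)))
  expect_equal(r2$labels[2], "independent-period")
  expect_equal(r2$signal, "multi-periodic")
  # short-period peak above a long-period peak: multi-periodic
  r3 <- classify_harmonics(mk(c(HOUR, DAY), c(10, 6)))
  expect_equal(r3$signal, "multi-periodic")
})

test_that("peak width grows as the square of the period at fixed N*dt", {
  # an injected tone's half-maximum width on the period scale follows
  # dT ~ T^2/(N dt): widths at 24 h and 48 h differ by ~4x
  n <- 4096
  width_at <- function(Tper) {
    x <- sin(2 * pi * (0:(n - 1)) / (Tper / HOUR))
    g <- build_sample_grid(hourly_track(x))
    fg <- frequency_grid(g, 8)
    pg <- fast_lsp(g, fg)
    per <- 1 / fg$freqs
    half <- pg$power >= max(pg$power) / 2
    win <- abs(per - Tper) < Tper / 4
    diff(range(per[half & win]))
  }
  w24 <- width_at(24 * HOUR)
  w48 <- width_at(48 * HOUR)
  ratio <- w48 / w24
  expect_gt(ratio, 4 / 1.6)
  expect_lt(ratio, 4 * 1.6)
})

# the N log N runtime-scaling property is exercised in test-acceptance.R
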