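#' Read telemetry tracks from a delimited text file
#'
#' Reads Movebank-style CSV/TSV telemetry (one row per fix, possibly
#' several individuals interleaved) into a list of [track_series()]
#' objects, one per individual, sorted by time. Default column names are
#' the Movebank conventions (`individual-local-identifier`, `timestamp`,
#' `location-long`, `location-lat`); planar input may instead provide `x`
#' and `y` columns in meters. Geographic coordinates are projected to
#' planar meters with an equirectangular tangent-plane projection
#' centred on each individual's median location (adequate for
#' home-range-scale extents; expect distortion beyond a few hundred km).
#' Duplicate timestamps within an individual are dropped with a warning;
#' unparseable rows are reported with their line numbers.
#'
#' @param path file path.
#' @param column_map optional named list overriding column names; any of
#'   `id`, `time`, `lon`, `lat`, `x`, `y`.
#' @param sep field separator (default `","`).
#' @return A named list of [track_series()] objects.
#' @export
read_tracks <- function(path, column_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty file: ", path)
  cm <- list(id = "individual-local-identifier", time = "timestamp",
             lon = "location-long", lat = "location-lat", x = "x", y = "y")
  cm[names(column_map)] <- column_map
  pick <- function(key) if (cm[[key]] %in% names(df)) df[[cm[[key]]]] else NULL
  id <- pick("id")
  if (is.null(id)) id <- rep("track", nrow(df))
  tm_raw <- pick("time")
  if (is.null(tm_raw)) stop("timestamp column '", cm$time, "' not found")
  if (is.numeric(tm_raw)) {
    tm <- as.numeric(tm_raw)
  } else {
    tm <- as.numeric(as.POSIXct(tm_raw, tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                               "%Y-%m-%dT%H:%M:%OS",
                                               "%Y-%m-%d %H:%M:%OS",
                                               "%Y-%m-%d")))
  }
  lon <- pick("lon"); lat <- pick("lat")
  geographic <- !is.null(lon) && !is.null(lat)
  if (geographic) {
    cx <- as.numeric(lon); cy <- as.numeric(lat)
  } else {
    cx <- as.numeric(pick("x")); cy0 <- pick("y")
    cy <- if (is.null(cy0)) NULL else as.numeric(cy0)
    if (is.null(cx)) stop("no coordinate columns found (need lon/lat or x/y)")
  }
  bad <- !is.finite(tm) | !is.finite(cx)
  if (!is.null(cy)) bad <- bad | !is.finite(cy)
  bad <- which(bad)
  if (length(bad))
    stop("unparseable rows (file line numbers, counting the header): ",
         paste(utils::head(bad + 1L, 20), collapse = ", "))
  out <- list()
  for (ind in unique(id)) {
    sel <- which(id == ind)
    sel <- sel[order(tm[sel])]
    dup <- duplicated(tm[sel])
    if (any(dup)) {
      warning(sprintf("individual %s: dropping %d duplicate timestamp(s)",
                      ind, sum(dup)))
      sel <- sel[!dup]
    }
    if (geographic) {
      xy <- project_tangent(cx[sel], cy[sel])
    } else {
      xy <- if (is.null(cy)) cbind(x = cx[sel]) else cbind(x = cx[sel], y = cy[sel])
    }
    out[[as.character(ind)]] <- track_series(tm[sel], xy, id = ind)
  }
  out
}

# equirectangular tangent-plane projection centred on the median location
project_tangent <- function(lon, lat) {
  R <- 6378137
  lon0 <- stats::median(lon); lat0 <- stats::median(lat)
  cbind(x = R * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180,
        y = R * (lat - lat0) * pi / 180)
}

#' Write / read a periodogram as delimited text
#'
#' The file holds one metadata header line (`# movelsp-periodogram N=...
#' dt=... nw=... res_freq=...`) followed by a CSV table with columns
#' `period_s`, `frequency_per_s`, `power` and `power_dim_1..K`, at full
#' double precision so that a read/write round trip reproduces the
#' numeric content exactly.
#'
#' @param pgram a `"periodogram"` object.
#' @param path output file path.
#' @return `write_periodogram()` returns `path` invisibly;
#'   `read_periodogram()` returns a `"periodogram"` object.
#' @export
write_periodogram <- function(pgram, path) {
  stopifnot(inherits(pgram, "periodogram"))
  k <- ncol(pgram$power_by_dim)
  hdr <- sprintf("# movelsp-periodogram N=%s dt=%.17g nw=%s res_freq=%s nyquist=%.17g df=%.17g",
                 format(pgram$meta$n), pgram$meta$dt,
                 format(pgram$n_effective), format(pgram$freqs$res_freq),
                 pgram$freqs$nyquist, pgram$freqs$df)
  tab <- cbind(period_s = 1 / pgram$freqs$freqs,
               frequency_per_s = pgram$freqs$freqs,
               power = pgram$power,
               pgram$power_by_dim)
  colnames(tab)[-(1:3)] <- paste0("power_dim_", seq_len(k))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(tab), collapse = ","), con)
  writeLines(apply(tab, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")), con)
  invisible(path)
}

#' @rdname write_periodogram
#' @export
read_periodogram <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# movelsp-periodogram"))
    stop("not a movelsp periodogram file: ", path)
  meta_kv <- strsplit(sub("^# movelsp-periodogram ", "", hdr), " ")[[1]]
  kv <- strsplit(meta_kv, "=")
  meta <- stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                          vapply(kv, `[`, "", 1))
  tab <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  dims <- grep("^power_dim_", names(tab))
  fgrid <- structure(list(freqs = tab$frequency_per_s,
                          nyquist = meta$nyquist, df = meta$df,
                          res_freq = as.integer(meta$res_freq)),
                     class = "frequency_grid")
  new_periodogram(fgrid, as.matrix(tab[, dims, drop = FALSE]),
                  n_effective = meta$nw,
                  meta = list(id = "file", n = as.integer(meta$N),
                              dt = meta$dt, res_time = NA_integer_,
                              res_freq = as.integer(meta$res_freq)))
}

#' Write a periodicity test result as structured text
#'
#' Key-value lines; a p-value of exactly 0 is rendered as
#' `< 1/n_sims` in the display field (the raw proportion is also kept).
#'
#' @param result a `"periodicity_test"` object.
#' @param path output file path.
#' @param histogram optional path for a two-column CSV of the null power
#'   sample.
#' @return `path`, invisibly.
#' @export
write_test_result <- function(result, path, histogram = NULL) {
  stopifnot(inherits(result, "periodicity_test"))
  lines <- c(
    "movelsp-periodicity-test",
    sprintf("period_s: %.17g", result$period),
    sprintf("observed_power: %.17g", result$observed_power),
    sprintf("n_sims: %d", result$n_sims),
    sprintf("seed: %d", result$seed),
    sprintf("null_family: %s", result$null_model$spec$family),
    sprintf("p_value: %.17g", result$p_value),
    sprintf("p_value_display: %s", format_p_value(result$p_value, result$n_sims)))
  writeLines(lines, path)
  if (!is.null(histogram)) {
    utils::write.csv(data.frame(sim = seq_along(result$null_powers),
                                null_power = result$null_powers),
                     histogram, row.names = FALSE)
  }
  invisible(path)
}

#' Write a track as Movebank-style CSV
#'
#' Planar coordinates are written as `x`/`y` columns (meters) together
#' with the numeric epoch timestamp.
#'
#' @param track a [track_series()] object (or list of them).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(track, path) {
  if (inherits(track, "track")) track <- list(track)
  rows <- do.call(rbind, lapply(track, function(tr) {
    data.frame(`individual-local-identifier` = tr$id,
               timestamp = sprintf("%.17g", tr$times),
               tr$coords, check.names = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
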