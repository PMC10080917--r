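#' Configuration for AIS bounds detection
#'
#' Collects the tunable constants of the profile-processing chain:
#' rolling-ball background subtraction, first-order Savitzky-Golay
#' smoothing, and the half-of-range threshold rule.
#'
#' The rolling-ball radius is dimensionless (measured in profile samples),
#' so its useful value scales with the sampling density: the ball must be
#' wider than the widest genuine AIS span or the opening absorbs the AIS
#' into the background estimate. At the default sampling of 0.2 µm per
#' sample an AIS can span 200+ samples, hence the default radius of 250
#' samples; when profiles are exported at a coarser per-pixel scale
#' (about 1 µm/sample), a radius of 50 plays the same role.
#'
#' @param rolling_ball_radius Ball radius in samples (>= 1).
#' @param savgol_window Odd window length in samples, > `savgol_polyorder`.
#' @param savgol_polyorder Polynomial order of the smoothing fit; the
#'   method uses first-order (linear) fits.
#' @param threshold_fraction Fraction of the baseline-to-maximum range that
#'   defines the AIS span; the method uses 0.5 (half-maximum above
#'   baseline).
#' @param min_prominence_fraction Detectability floor in (0, 1): when the
#'   smoothed dynamic range is below this fraction of `max(maximum, 1)`
#'   intensity units the profile is reported `undetermined` (the explicit
#'   stand-in for "too weak to call" cells).
#' @return A `bounds_config` list.
#' @export
bounds_config <- function(rolling_ball_radius = 250,
                          savgol_window = 11,
                          savgol_polyorder = 1,
                          threshold_fraction = 0.5,
                          min_prominence_fraction = 0.1) {
  cfg <- list(
    rolling_ball_radius = as.integer(rolling_ball_radius),
    savgol_window = as.integer(savgol_window),
    savgol_polyorder = as.integer(savgol_polyorder),
    threshold_fraction = threshold_fraction,
    min_prominence_fraction = min_prominence_fraction
  )
  problems <- character()
  if (is.na(cfg$rolling_ball_radius) || cfg$rolling_ball_radius < 1) {
    problems <- c(problems, "`rolling_ball_radius` must be >= 1 sample")
  }
  if (is.na(cfg$savgol_window) || cfg$savgol_window %% 2 == 0 ||
      cfg$savgol_window <= cfg$savgol_polyorder) {
    problems <- c(problems, "`savgol_window` must be odd and > `savgol_polyorder`")
  }
  if (cfg$savgol_polyorder < 0) {
    problems <- c(problems, "`savgol_polyorder` must be >= 0")
  }
  if (!is.numeric(cfg$threshold_fraction) || cfg$threshold_fraction <= 0 ||
      cfg$threshold_fraction >= 1) {
    problems <- c(problems, "`threshold_fraction` must lie in (0, 1)")
  }
  if (!is.numeric(cfg$min_prominence_fraction) ||
      cfg$min_prominence_fraction < 0 || cfg$min_prominence_fraction >= 1) {
    problems <- c(problems, "`min_prominence_fraction` must lie in [0, 1)")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid bounds configuration:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  structure(cfg, class = "bounds_config")
}

#' One-dimensional rolling-ball background
#'
#' Estimates the slowly varying baseline of a profile as the grayscale
#' opening (erosion followed by dilation) of the signal with a ball
#' structuring element: a semicircle spanning `radius` samples whose
#' vertical semi-axis equals the profile's dynamic range (the element
#' scales with image intensity, as in the classic rolling-ball
#' implementations). This makes the subtraction exactly invariant to
#' additive offsets and positive gain. Subtracting the result removes
#' broad background while preserving features narrower than the ball.
#' Edges are padded by replication to avoid spurious troughs in the
#' estimate.
#'
#' @param intensities Numeric vector (length >= 2, finite).
#' @param radius Ball radius in samples (>= 1).
#' @return Background vector of the same length, everywhere <= the signal.
#' @export
#' @examples
#' x <- c(rep(0, 20), 100, rep(0, 20)) # single-sample spike
#' range(rolling_ball_background(x, 10)) # background ignores the spike
rolling_ball_background <- function(intensities, radius) {
  x <- as.numeric(intensities)
  n <- length(x)
  if (n < 2) abort("`intensities` must have length >= 2.")
  if (any(!is.finite(x))) abort("`intensities` must be finite.")
  r <- as.integer(radius)
  if (is.na(r) || r < 1) abort("`radius` must be >= 1 sample.")

  lo <- min(x)
  rng <- max(x) - lo
  if (rng == 0) return(x) # flat signal: the opening is the signal itself
  g <- (x - lo) * (r / rng) # normalized so the ball aspect is fixed

  ball <- sqrt(r^2 - (-r:r)^2) - r # semicircle, apex 0 at the center
  clamp_idx <- function(i) pmin(pmax(i, 1L), n)

  # erosion over the padded domain (1 - r) .. (n + r), replication padding
  pos <- (1L - r):(n + r)
  ero <- rep(Inf, length(pos))
  for (k in seq_along(ball)) {
    j <- k - r - 1L
    ero <- pmin(ero, g[clamp_idx(pos + j)] - ball[k])
  }
  # dilation back onto 1..n
  bg <- rep(-Inf, n)
  base <- seq_len(n) + r # index of position i within `ero`
  for (k in seq_along(ball)) {
    j <- k - r - 1L
    bg <- pmax(bg, ero[base + j] + ball[k])
  }
  bg <- bg * (rng / r) + lo
  # the opening is <= the signal in exact arithmetic; guard the last ulp
  pmin(bg, x)
}

#' Savitzky-Golay smoothing
#'
#' Each output sample is the centre value of the least-squares polynomial of
#' order `polyorder` fitted over a window of `window` samples centred on it.
#' Near the edges the window is truncated to the available samples and the
#' fit is evaluated at the sample position (no padding, no reflection).
#'
#' @param intensities Numeric vector, length >= `window`.
#' @param window Odd window length in samples.
#' @param polyorder Polynomial order, < `window`.
#' @return Smoothed vector of the same length.
#' @export
savgol_smooth <- function(intensities, window = 11, polyorder = 1) {
  x <- as.numeric(intensities)
  n <- length(x)
  w <- as.integer(window)
  p <- as.integer(polyorder)
  if (is.na(w) || w %% 2 == 0) abort("`window` must be an odd integer.")
  if (is.na(p) || p < 0 || p >= w) abort("`polyorder` must satisfy 0 <= polyorder < window.")
  if (w > n) abort("`window` must not exceed the profile length.")
  h <- (w - 1L) / 2L

  out <- numeric(n)
  # interior: convolution with the centre-row pseudoinverse weights
  A <- outer(-h:h, 0:p, `^`)
  w0 <- solve(crossprod(A), t(A))[1, ]
  interior <- (h + 1L):(n - h)
  conv <- stats::filter(x, w0, sides = 2)
  out[interior] <- conv[interior]
  # edges: truncated-window least squares evaluated at the sample
  edge <- c(seq_len(h), (n - h + 1L):n)
  for (i in edge) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    tt <- (lo:hi) - i
    Ai <- outer(tt, 0:p, `^`)
    beta <- solve(crossprod(Ai), crossprod(Ai, x[lo:hi]))
    out[i] <- beta[1]
  }
  out
}

#' Detect AIS bounds on a smoothed profile
#'
#' Applies the half-of-range rule: with `baseline` the minimum and `M` the
#' maximum of the smoothed profile, the AIS is the maximal contiguous run of
#' samples strictly above `baseline + threshold_fraction * (M - baseline)`
#' that contains the global maximum (first-occurring maximum on ties). If
#' the dynamic range is below the detectability floor the profile is
#' `undetermined`. Other supra-threshold runs are counted (`n_extra_runs`,
#' a diagnostic for multi-like profiles) but never measured.
#'
#' @param smoothed Numeric vector, the processed profile.
#' @param distances Strictly increasing sample positions in µm, same length.
#' @param config A [bounds_config()].
#' @param neuron_id,localization_class Carried through to the output row.
#' @return A one-row tibble: `neuron_id`, `localization_class`, `status`
#'   (`"determined"`/`"undetermined"`), `start_um`, `length_um`
#'   (span of the run including one sampling step), `peak_intensity`,
#'   `n_extra_runs`.
#' @export
detect_bounds <- function(smoothed, distances, config = bounds_config(),
                          neuron_id = NA_character_,
                          localization_class = NA_character_) {
  y <- as.numeric(smoothed)
  d <- as.numeric(distances)
  n <- length(y)
  if (n == 0) abort("Empty profile.")
  if (length(d) != n) abort("`smoothed` and `distances` must have the same length.")
  if (n < config$savgol_window) {
    abort("Profile shorter than the smoothing window.")
  }

  undetermined <- function(n_extra = 0L) {
    tibble(
      neuron_id = as.character(neuron_id),
      localization_class = as.character(localization_class),
      status = "undetermined",
      start_um = NA_real_, length_um = NA_real_,
      peak_intensity = NA_real_, n_extra_runs = n_extra
    )
  }

  baseline <- min(y)
  m <- max(y)
  if ((m - baseline) < config$min_prominence_fraction * max(m, 1)) {
    return(undetermined())
  }
  tau <- baseline + config$threshold_fraction * (m - baseline)
  above <- y > tau
  if (!any(above)) {
    return(undetermined())
  }
  run_id <- cumsum(c(1L, diff(above) != 0))
  peak <- which.max(y) # first-occurring maximum on ties
  peak_run <- run_id[peak]
  in_run <- which(run_id == peak_run & above)
  n_runs <- length(unique(run_id[above]))

  step <- median(diff(d))
  tibble(
    neuron_id = as.character(neuron_id),
    localization_class = as.character(localization_class),
    status = "determined",
    start_um = d[in_run[1]],
    length_um = d[in_run[length(in_run)]] - d[in_run[1]] + step,
    peak_intensity = m,
    n_extra_runs = n_runs - 1L
  )
}

#' Quantify AIS geometry from arc-length profiles
#'
#' Full measurement chain for one or more neurons: rolling-ball background
#' subtraction, Savitzky-Golay smoothing, then half-of-range bounds
#' detection. Additive offsets are removed by the background subtraction and
#' the threshold is range-relative, so the detected geometry is invariant to
#' `a * intensity + b` transformations with `a > 0`.
#'
#' @param profiles Profile tibble (columns `neuron_id`,
#'   `localization_class`, `distance_um`, `intensity`), one or more neurons.
#' @param config A [bounds_config()].
#' @return A measurement tibble, one row per neuron, in the [detect_bounds()]
#'   schema.
#' @export
quantify_ais <- function(profiles, config = bounds_config()) {
  need <- c("distance_um", "intensity")
  if (!all(need %in% names(profiles))) {
    abort("`profiles` needs `distance_um` and `intensity` columns.")
  }
  if (any(!is.finite(profiles$intensity))) abort("Profile intensities must be finite.")
  if (!"neuron_id" %in% names(profiles)) profiles$neuron_id <- "profile"
  if (!"localization_class" %in% names(profiles)) {
    profiles$localization_class <- NA_character_
  }
  profiles |>
    dplyr::group_split(.data$neuron_id) |>
    purrr::map(function(pr) {
      residual <- pr$intensity -
        rolling_ball_background(pr$intensity, config$rolling_ball_radius)
      smoothed <- savgol_smooth(residual, config$savgol_window,
                                config$savgol_polyorder)
      detect_bounds(smoothed, pr$distance_um, config,
                    neuron_id = pr$neuron_id[1],
                    localization_class = pr$localization_class[1])
    }) |>
    purrr::list_rbind()
}

#' Intermediate curves of the measurement chain
#'
#' Returns raw, background, residual and smoothed traces for one neuron, in
#' long-friendly wide format; convenient for plotting the Fig-3-style
#' shaded-span illustration with [plot_profile()].
#'
#' @inheritParams quantify_ais
#' @return Tibble with columns `distance_um`, `raw`, `background`,
#'   `residual`, `smoothed`.
#' @export
pipeline_curves <- function(profiles, config = bounds_config()) {
  if (length(unique(profiles$neuron_id %||% "p")) > 1) {
    abort("`pipeline_curves()` expects a single neuron.")
  }
  bg <- rolling_ball_background(profiles$intensity, config$rolling_ball_radius)
  residual <- profiles$intensity - bg
  tibble(
    distance_um = profiles$distance_um,
    raw = profiles$intensity,
    background = bg,
    residual = residual,
    smoothed = savgol_smooth(residual, config$savgol_window, config$savgol_polyorder)
  )
}

#' Read and write measurement tables
#'
#' CSV schema: `neuron_id`, `localization_class`, `status`, `start_um`,
#' `length_um`, `peak_intensity`, `n_extra_runs`, `config_hash`.
#'
#' @param path File path.
#' @return `read_measurements_csv()` returns the measurements tibble.
#' @export
read_measurements_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_measurements_csv
#' @param measurements Measurement tibble from [quantify_ais()].
#' @param config The [bounds_config()] used, recorded as a hash column.
#' @export
write_measurements_csv <- function(measurements, path, config = bounds_config()) {
  measurements$config_hash <- config_hash(config)
  readr::write_csv(measurements, path, progress = FALSE)
  invisible(path)
}

#' Hash a configuration object
#'
#' MD5 of the canonical JSON serialization; recorded in output tables and
#' manifests so measurements are traceable to the exact settings.
#'
#' @param config Any list-like configuration.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.function(x)) {
    paste(deparse(x), collapse = "\n")
  } else {
    unclass(x)
  }
}
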