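test_that("rolling-ball background matches flat, spike and oracle cases", {
  # flat signal: opening is the signal itself, zero residual
  expect_equal(rolling_ball_background(rep(3.7, 80), 50), rep(3.7, 80))

  # single-sample spike never enters the background (up to the sampling
  # curvature of the discrete ball, sqrt(r^2 - 1) - r + 1 ~ 0.01 at r = 50)
  x <- rep(0, 101)
  x[51] <- 100
  bg <- rolling_ball_background(x, 50)
  expect_lt(max(abs(bg)), 0.05)
  expect_gt((x - bg)[51], 99.9)

  # seeded sawtooth vs explicit min/max window-scan oracle, elementwise
  set.seed(41)
  s <- (0:199 %% 23) * 3 + rnorm(200)
  expect_equal(rolling_ball_background(s, 10), oracle_rolling_ball(s, 10),
               tolerance = 1e-12)

  expect_error(rolling_ball_background(c(1, NA, 3), 5), "finite")
  expect_error(rolling_ball_background(5, 3), "length")
})

test_that("rolling-ball background stays below the signal and shifts with offsets", {
  set.seed(42)
  x <- abs(rnorm(300, 50, 20))
  bg <- rolling_ball_background(x, 30)
  expect_true(all(bg <= x + 1e-12))
  # grayscale opening commutes with additive offsets
  expect_equal(rolling_ball_background(x + 250, 30), bg + 250, tolerance = 1e-9)
})

test_that("Savitzky-Golay smoothing reproduces polynomials and the lm oracle", {
  x <- seq(0, 10, length.out = 60)
  lin <- 3 * x + 2
  expect_equal(savgol_smooth(lin, 11, 1), lin, tolerance = 1e-9)
  expect_equal(savgol_smooth(rep(4, 30), 7, 1), rep(4, 30))

  # seeded noisy step vs per-window least-squares line fits (lm oracle)
  set.seed(43)
  v <- c(rep(0, 40), rep(10, 40)) + rnorm(80)
  expect_equal(savgol_smooth(v, 11, 1), oracle_savgol(v, 11, 1),
               tolerance = 1e-9)
  # quadratic fit follows the same contract
  expect_equal(savgol_smooth(v, 11, 2), oracle_savgol(v, 11, 2),
               tolerance = 1e-9)

  expect_error(savgol_smooth(v, 10, 1), "odd")
  expect_error(savgol_smooth(v, 81, 1), "exceed")
  expect_error(savgol_smooth(v, 11, 11), "polyorder")
})

test_that("detect_bounds finds the half-of-range span of simple shapes", {
  d <- (0:199) * 0.2
  # rectangular pulse over samples [30, 70): crossings at the pulse edges
  y <- numeric(200)
  y[31:70] <- 100
  m <- detect_bounds(y, d)
  expect_equal(m$status, "determined")
  expect_equal(m$start_um, 6.0, tolerance = 0.2)
  expect_equal(m$length_um, 8.0, tolerance = 0.2)
  expect_equal(m$peak_intensity, 100)

  # flat profile: zero dynamic range
  expect_equal(detect_bounds(rep(5, 200), d)$status, "undetermined")

  # triangular bump apex h at p = 20 um, half-base w = 8 um: FWHM = w
  p <- 20
  w <- 8
  tri <- pmax(0, 1 - abs(d - p) / w) * 120
  m <- detect_bounds(tri, d)
  expect_equal(m$start_um, p - w / 2, tolerance = 0.2)
  expect_equal(m$length_um, w, tolerance = 0.2)
})

test_that("detect_bounds picks the run containing the first global maximum", {
  d <- (0:199) * 0.2
  y <- numeric(200)
  y[21:40] <- 80    # secondary run
  y[101:140] <- 100 # run holding the global maximum
  m <- detect_bounds(y, d)
  expect_equal(m$start_um, d[101])
  expect_equal(m$n_extra_runs, 1L)

  # tie on the maximum: the first-occurring one decides
  y2 <- numeric(200)
  y2[21:30] <- 100
  y2[101:140] <- 100
  m2 <- detect_bounds(y2, d)
  expect_equal(m2$start_um, d[21])

  expect_error(detect_bounds(numeric(0), numeric(0)), "Empty")
})

test_that("detected bounds agree with an exhaustive threshold-scan oracle", {
  cfg <- bounds_config()
  sim <- simulate_profiles(12, seed = 44)
  for (pr in dplyr::group_split(sim$profiles, neuron_id)) {
    residual <- pr$intensity -
      rolling_ball_background(pr$intensity, cfg$rolling_ball_radius)
    sm <- savgol_smooth(residual, cfg$savgol_window, cfg$savgol_polyorder)
    m <- detect_bounds(sm, pr$distance_um, cfg)
    # oracle: scan every sample against tau, no vectorized shortcuts
    tau <- min(sm) + 0.5 * (max(sm) - min(sm))
    peak <- which.max(sm)
    i0 <- peak
    while (i0 > 1 && sm[i0 - 1] > tau) i0 <- i0 - 1
    i1 <- peak
    while (i1 < length(sm) && sm[i1 + 1] > tau) i1 <- i1 + 1
    expect_equal(m$start_um, pr$distance_um[i0])
    expect_equal(m$length_um,
                 pr$distance_um[i1] - pr$distance_um[i0] + 0.2,
                 tolerance = 1e-9)
  }
})

test_that("quantify_ais recovers noiseless truth and honours the prominence floor", {
  cfg <- noiseless_config()
  sim <- simulate_profiles(6, cfg, seed = 45)
  m <- quantify_ais(sim$profiles) |>
    dplyr::left_join(sim$truth, by = c("neuron_id", "localization_class"))
  expect_true(all(m$status == "determined"))
  expect_true(all(abs(m$start_um - m$true_start_um) <= 0.4))
  expect_true(all(abs(m$length_um - m$true_length_um) <= 0.8))

  # dynamic range below the detectability floor
  d <- (0:199) * 0.2
  dim_p <- tibble::tibble(neuron_id = "dim", distance_um = d,
                          intensity = 0.05 * ais_shape(d, 5, 15))
  expect_equal(quantify_ais(dim_p)$status, "undetermined")
})

test_that("AIS geometry is invariant to offsets and positive scaling", {
  sim <- simulate_profiles(5, seed = 46)
  base <- quantify_ais(sim$profiles)
  plus <- quantify_ais(dplyr::mutate(sim$profiles, intensity = intensity + 500))
  times <- quantify_ais(dplyr::mutate(sim$profiles, intensity = intensity * 3))
  expect_equal(plus$start_um, base$start_um)
  expect_equal(plus$length_um, base$length_um)
  expect_equal(times$start_um, base$start_um)
  expect_equal(times$length_um, base$length_um)
  # peak intensity scales with gain up to the ball's fixed vertical
  # curvature (the structuring element does not rescale with the signal)
  expect_equal(times$peak_intensity, base$peak_intensity * 3, tolerance = 0.05)
})

test_that("detected length is non-decreasing in true length at fixed noise", {
  cfg <- generator_config()
  lengths <- seq(5, 40, by = 5)
  detected <- vapply(lengths, function(L) {
    set.seed(47) # same noise realization for every sweep point
    d <- seq(0, 5 + L + 10, by = 0.2)
    clean <- 100 * ais_shape(d, 5, L)
    v <- rpois(length(d), clean * 5) / 5 + rnorm(length(d), 0, 2) + 20
    m <- quantify_ais(tibble::tibble(neuron_id = "s", distance_um = d,
                                     intensity = pmax(v, 0)))
    m$length_um
  }, numeric(1))
  expect_true(all(diff(detected) >= 0))
  expect_equal(detected, lengths, tolerance = 0.1)
})

test_that("undetermined fraction rises to one as amplitude vanishes", {
  # detectability is an absolute floor (in intensity units), so the
  # degradation sweep uses sub-unit read noise
  cfg <- generator_config(
    noise = noise_model(background_level = 0, background_gradient = c(0, 0),
                        poisson_scale = 0, gaussian_sigma = 0.03)
  )
  amps <- c(5, 1, 0.3, 0.05, 0.01)
  undet <- vapply(amps, function(a) {
    cfg_a <- generator_config(ais_amplitude = a, noise = cfg$noise)
    sim <- simulate_profiles(20, cfg_a, seed = 48)
    mean(quantify_ais(sim$profiles)$status == "undetermined")
  }, numeric(1))
  expect_true(all(diff(undet) >= 0)) # monotone in decreasing amplitude
  expect_equal(undet[1], 0)
  expect_equal(undet[length(undet)], 1)
})

test_that("measurement tables round-trip through CSV with a config hash", {
  sim <- simulate_profiles(3, seed = 49)
  m <- quantify_ais(sim$profiles)
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(m, f)
  back <- read_measurements_csv(f)
  expect_equal(back$start_um, m$start_um)
  expect_equal(unique(back$config_hash), config_hash(bounds_config()))
})

test_that("bounds configuration is validated", {
  expect_error(bounds_config(rolling_ball_radius = 0), "rolling_ball_radius")
  expect_error(bounds_config(savgol_window = 10), "savgol_window")
  expect_error(bounds_config(threshold_fraction = 1.2), "threshold_fraction")
  expect_error(bounds_config(min_prominence_fraction = 1), "min_prominence")
})
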