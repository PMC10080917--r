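test_that("noiseless renders place marker signal exactly on the AIS span", {
  cfg <- noiseless_config()
  sim <- simulate_neuron(cfg, seed = 51, "c1")
  tr <- sim$truth
  ais <- purrr::detect(tr$neurites, ~ .x$is_ais)

  expect_true(all(sim$scene$marker >= 0))
  # extract the noiseless marker profile along the ground-truth trace:
  # positive strictly inside the span, zero beyond the cosine shoulders
  trs <- traces_from_neuron(tr)
  trs <- trs[trs$neuron_id == trs$neuron_id[1], ]
  p <- extract_profile(sim$scene$marker, trs, tr$pixel_size)
  w <- 0.1 * ais$ais_length_um
  inside <- p$distance_um > ais$ais_start_um + w &
    p$distance_um < ais$ais_start_um + ais$ais_length_um - w
  outside <- p$distance_um < ais$ais_start_um - w - 0.5 |
    p$distance_um > ais$ais_start_um + ais$ais_length_um + w + 0.5
  expect_true(all(p$intensity[inside] > 0))
  expect_true(all(p$intensity[outside] == 0))
  # fill channel covers soma and neurites
  expect_gt(sim$scene$fill[round(tr$soma_center_px[2]) + 1,
                           round(tr$soma_center_px[1]) + 1], 99)
})

test_that("simulation is bit-identical under a repeated seed", {
  a <- simulate_neuron(generator_config(), seed = 52, "c")
  b <- simulate_neuron(generator_config(), seed = 52, "c")
  expect_identical(a$scene$fill, b$scene$fill)
  expect_identical(a$scene$marker, b$scene$marker)
  expect_identical(truth_table(a$truth), truth_table(b$truth))
  c_ <- simulate_neuron(generator_config(), seed = 53, "c")
  expect_false(identical(a$scene$fill, c_$scene$fill))
})

test_that("Poisson stage preserves the mean (Monte-Carlo oracle)", {
  nm <- noise_model(background_level = 0, background_gradient = c(0, 0),
                    poisson_scale = 10, gaussian_sigma = 0)
  clean <- structure(list(fill = matrix(50, 100, 100),
                          marker = matrix(50, 100, 100), pixel_size = 0.2),
                     class = "ais_scene")
  noisy <- add_scene_noise(clean, nm, seed = 54)
  expect_equal(mean(noisy$fill), 50, tolerance = 0.01)
  # quantized to 1/poisson_scale
  expect_true(all(abs(noisy$fill * 10 - round(noisy$fill * 10)) < 1e-9))
})

test_that("generator invariants hold across seeded draws", {
  cfg <- generator_config()
  for (seed in 55:74) {
    tt <- truth_table(simulate_neuron(cfg, seed, "x")$truth)
    ais_rows <- dplyr::filter(tt, is_ais)
    cls <- tt$localization_class[1]
    expect_true(all(ais_rows$ais_start_um >= 0))
    expect_true(all(ais_rows$ais_length_um > 0))
    # class <-> number of AIS-bearing neurites
    expect_equal(nrow(ais_rows) >= 2, cls == "multi")
    if (cls == "acd") {
      expect_true(ais_rows$ais_start_um[1] > ais_rows$branch_point_um[1])
    }
  }
})

test_that("localization class frequencies match configured probabilities", {
  probs <- c(direct = 0.593, acd = 0.353, multi = 0.054)
  sim <- simulate_profiles(1000, generator_config(class_probs = probs), seed = 75)
  counts <- table(factor(sim$truth$localization_class,
                         levels = names(probs)))
  for (cl in names(probs)) {
    ci <- qbinom(c(0.005, 0.995), 1000, probs[[cl]])
    expect_gte(counts[[cl]], ci[1])
    expect_lte(counts[[cl]], ci[2])
  }
})

test_that("ground truth round-trips through CSV", {
  sims <- simulate_cohort(4, generator_config(), seed = 76)
  tt <- truth_table(purrr::map(sims, "truth"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(tt, f)
  back <- read_truth_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(tt), tolerance = 0)
})

test_that("scene TIFFs round-trip at float precision", {
  sim <- simulate_neuron(generator_config(), seed = 77)
  f <- withr::local_tempfile(fileext = ".tif")
  write_scene_tiff(sim$scene, f)
  back <- read_scene_tiff(f, pixel_size = 0.2)
  expect_equal(back$fill, sim$scene$fill, tolerance = 1e-6)
  expect_equal(back$marker, sim$scene$marker, tolerance = 1e-6)
})

test_that("a null axonopathy effect changes nothing", {
  sim <- simulate_neuron(generator_config(), seed = 78, "c")
  nul <- apply_axonopathy(
    sim$truth,
    axonopathy_effect(ais_start_shift = 0, varicosity_count = 0,
                      varicosity_amplitude = 0,
                      distal_attenuation_fraction = 0),
    config = generator_config()
  )
  expect_identical(nul$scene$fill, sim$scene$fill)
  expect_identical(nul$scene$marker, sim$scene$marker)
  expect_equal(truth_table(nul$truth)$ais_start_um,
               truth_table(sim$truth)$ais_start_um)
})

test_that("the start shift is exact arithmetic with clamping flagged", {
  sim <- simulate_neuron(generator_config(), seed = 79, "c")
  tt0 <- dplyr::filter(truth_table(sim$truth), is_ais)
  sh <- apply_axonopathy(sim$truth, axonopathy_effect(ais_start_shift = 2),
                         config = generator_config())
  tt1 <- dplyr::filter(truth_table(sh$truth), is_ais)
  expect_equal(tt1$ais_start_um, pmax(tt0$ais_start_um - 2, 0))
  expect_equal(tt1$ais_length_um, tt0$ais_length_um)

  big <- apply_axonopathy(sim$truth, axonopathy_effect(ais_start_shift = 100),
                          config = generator_config())
  expect_true(big$truth$clamped)
  expect_equal(dplyr::filter(truth_table(big$truth), is_ais)$ais_start_um[1], 0)

  expect_error(axonopathy_effect(ais_start_shift = -1), "ais_start_shift")
  expect_error(axonopathy_effect(distal_attenuation_fraction = 2), "attenuation")
})

test_that("varicosity bumps appear as countable fill-channel maxima", {
  cfg <- noiseless_config()
  sim <- simulate_neuron(cfg, seed = 80, "c")
  eff <- axonopathy_effect(ais_start_shift = 0, varicosity_count = 4,
                           varicosity_amplitude = 60,
                           distal_attenuation_fraction = 0)
  tr <- apply_axonopathy(sim$truth, eff, config = cfg)
  trs <- traces_from_neuron(tr$truth)
  trs <- trs[grepl(tr$truth$varicosities$neurite_id, trs$neuron_id), ]
  p <- extract_profile(tr$scene$fill, trs, tr$truth$pixel_size)
  # peak-count oracle on the noiseless profile: samples that are the
  # maximum of their +/- 4-sample neighbourhood and rise clearly above the
  # neurite stroke baseline, distal to the AIS
  ais <- purrr::detect(tr$truth$neurites, ~ .x$is_ais)
  distal <- p$distance_um > ais$ais_start_um + ais$ais_length_um
  v <- p$intensity
  is_window_max <- vapply(seq_along(v), function(i) {
    w <- v[max(1, i - 4):min(length(v), i + 4)]
    v[i] == max(w) && sum(w == v[i]) == 1
  }, logical(1))
  peaks <- which(distal & v > 110 & is_window_max)
  expect_equal(length(peaks), 4)
  expect_equal(sort(p$distance_um[peaks]), sort(tr$truth$varicosities$arcs_um),
               tolerance = 0.05)
})

test_that("distal fill intensity is non-increasing in the attenuation fraction", {
  cfg <- noiseless_config()
  sim <- simulate_neuron(cfg, seed = 81, "c")
  ais <- purrr::detect(sim$truth$neurites, ~ .x$is_ais)
  distal_mean <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    tr <- apply_axonopathy(
      sim$truth,
      axonopathy_effect(ais_start_shift = 0, varicosity_count = 0,
                        distal_attenuation_fraction = f),
      config = cfg
    )
    p <- extract_profile(tr$scene$fill, traces_from_neuron(tr$truth),
                         tr$truth$pixel_size)
    mean(p$intensity[p$distance_um > ais$ais_start_um + ais$ais_length_um + 1])
  }, numeric(1))
  expect_true(all(diff(distal_mean) <= 0))
  expect_lt(distal_mean[5], distal_mean[1] / 4)
})

test_that("an AIS span exceeding its neurite is rejected by name", {
  cfg <- noiseless_config()
  sim <- simulate_neuron(cfg, seed = 82, "c")
  bad <- sim$truth
  i <- which(purrr::map_lgl(bad$neurites, "is_ais"))[1]
  bad$neurites[[i]]$ais_length_um <- bad$neurites[[i]]$length_um + 10
  expect_error(render_scene(bad), bad$neurites[[i]]$neurite_id)
  expect_error(generator_config(pixel_size = 0), "pixel_size")
})
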