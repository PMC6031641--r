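test_that("tag model enforces its length ordering", {
  expect_error(tag_geometry_model(length_min_nm = 0), "length_min")
  expect_error(tag_geometry_model(length_min_nm = 10, length_max_nm = 5),
               "length_min")
  expect_error(tag_geometry_model(length_max_nm = 30), "length_max")
})

test_that("degenerate orientation laws give closed-form distances", {
  m_perp <- tag_geometry_model(length_min_nm = 10, length_max_nm = 10,
                               orientation_law = "perpendicular")
  # degenerate sample: the FWHM summary legitimately warns
  ds <- suppressWarnings(simulate_detected_distances(m_perp, 500, seed = 4))
  expect_equal(ds$distances, rep(10, 500))

  # hemisphere-uniform, single length L: distance = L * U(0,1)
  m_hemi <- tag_geometry_model(length_min_nm = 10, length_max_nm = 10,
                               orientation_law = "hemisphere")
  ds2 <- simulate_detected_distances(m_hemi, 2e4, seed = 4)
  se <- 10 / sqrt(12) / sqrt(2e4)
  expect_lt(abs(ds2$mean - 5), 3 * se)
  expect_true(all(ds2$distances >= 0 & ds2$distances <= 10))
})

test_that("simulation respects the theoretical maximum and is reproducible", {
  ds1 <- simulate_detected_distances(tag_geometry_model(), 1e4, seed = 7)
  ds2 <- simulate_detected_distances(tag_geometry_model(), 1e4, seed = 7)
  expect_identical(ds1$distances, ds2$distances)
  expect_lte(max(ds1$distances), 22)
  expect_lte(max(ds1$distances), 18)  # lengths are capped at 18 nm
})

test_that("summaries recover the model median", {
  # perpendicular + uniform lengths: distance ~ U(7, 18), median 12.5
  m <- tag_geometry_model(orientation_law = "perpendicular")
  ds <- simulate_detected_distances(m, 1e5, seed = 9)
  expect_lt(abs(ds$median - 12.5) / 12.5, 0.02)
})

test_that("discrete length states draw only the configured lengths", {
  m <- tag_geometry_model(n_length_states = 3,
                          orientation_law = "perpendicular")
  ds <- simulate_detected_distances(m, 1000, seed = 2)
  expect_setequal(unique(ds$distances), c(7, 12.5, 18))
})

test_that("FWHM matches closed forms for known distributions", {
  set.seed(23)
  g <- rnorm(1e5, mean = 50, sd = 3)
  expect_lt(abs(fwhm(g) - 2.355 * 3) / (2.355 * 3), 0.05)

  u <- runif(1e5, 7, 18)
  expect_lt(abs(fwhm(u) - 11) / 11, 0.10)

  expect_warning(w <- fwhm(rep(4, 100)), "identical")
  expect_equal(as.numeric(w), 0)
  expect_true(is.numeric(attr(fwhm(g), "bandwidth")))
})

test_that("measured distances equal constructed offsets and reflect cleanly", {
  p <- data.frame(x = seq(100, 900, by = 100), y = rep(312, 9))
  ann <- straight_annotation(y_nm = 300, particles = p)
  ds <- measure_distances(ann)
  expect_equal(ds$distances, rep(12, 9))
  expect_equal(attr(ds, "n_excluded"), 0L)

  # mirror the scene about the membrane line: the mirrored particles land on
  # the extracellular side and are excluded
  pm <- data.frame(x = p$x, y = 600 - p$y)
  annm <- straight_annotation(y_nm = 300, particles = pm)
  dsm <- measure_distances(annm)
  expect_equal(dsm$n, 0L)
  expect_equal(attr(dsm, "n_excluded"), 9L)

  # flipping the side convention restores them, with identical distances
  ct <- membrane_contour(rbind(c(0, 300), c(1000, 300)),
                         side_convention = "right")
  annf <- micrograph_annotation(image_frame(1000, 1000, 1), list(ct), pm)
  expect_equal(measure_distances(annf)$distances, ds$distances)
})

test_that("generated distances match the measurement pipeline", {
  # anchored tags at uniform 7-18 nm, perpendicular: measured median should
  # sit near the configured law's median over seeds
  tm <- tag_geometry_model(orientation_law = "perpendicular")
  cfg <- scene_config(cytoplasm_density = 0, membrane_density = 0,
                      coat_density = 0, n_pits = 1,
                      tag_model_pit = tm, tag_model_distal = tm,
                      anchored_rate_pit = 0.3, anchored_rate_distal = 0.05)
  meds <- vapply(1:10, function(s) {
    sc <- generate_scene(cfg, seed = 700 + s)
    measure_distances(sc$annotation)$median
  }, 0)
  se <- sd(meds) / sqrt(length(meds))
  expect_lt(abs(mean(meds) - 12.5), 3 * se + 0.5)
})

test_that("SNR recovers constructed disc amplitudes and nulls", {
  set.seed(55)
  mk_patch <- function(a, s) {
    img <- matrix(rnorm(41 * 41, sd = s), 41, 41)
    dx <- seq_len(41) - 21
    disc <- sqrt(outer(dx^2, dx^2, "+")) <= 3.5
    img[disc] <- img[disc] + a
    img
  }
  snrs <- vapply(1:100, function(i)
    particle_snr(mk_patch(5, 1), c(21, 21))$snr, 0)
  expect_lt(abs(mean(snrs) - 5) / 5, 0.10)

  nulls <- vapply(1:100, function(i)
    particle_snr(mk_patch(0, 1), c(21, 21))$snr, 0)
  expect_lt(mean(abs(nulls)), 0.3)

  flat <- particle_snr(matrix(7, 41, 41), c(21, 21))
  expect_true(is.na(flat$snr))
  expect_equal(flat$signal, flat$background)

  expect_error(particle_snr(matrix(0, 41, 41), c(21, 21), r_signal = 8),
               "r_signal < r_bg_inner")
  expect_error(particle_snr(matrix(0, 20, 20), c(2, 2)), "inside the patch")
})
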