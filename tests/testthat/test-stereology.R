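test_that("grid points are the interior intersections, never on the perimeter", {
  f <- image_frame(700, 500, 1)
  gp <- grid_points(f)
  expect_equal(nrow(gp), 24L)
  expect_equal(sort(unique(gp[, "x"])), seq(100, 600, by = 100))
  expect_equal(sort(unique(gp[, "y"])), seq(100, 400, by = 100))
  expect_true(all(gp[, "x"] > 0 & gp[, "x"] < 700))
  expect_true(all(gp[, "y"] > 0 & gp[, "y"] < 500))

  # integer upscaling multiplies all coordinates
  f3 <- image_frame(2100, 1500, 1)
  expect_equal(grid_points(f3), grid_points(f) * 3)
  # scale arrives through nm_per_px as well
  expect_equal(grid_points(image_frame(700, 500, 2)), grid_points(f) * 2)
})

test_that("point fractions partition to 1 and track area fractions", {
  # membrane near the top edge: every grid point is deep cytoplasm
  ann <- straight_annotation(y_nm = 40)
  fr <- point_compartment_fractions(list(ann))
  expect_equal(sum(fr$fractions), 1)
  expect_equal(unname(fr$fractions[["cytoplasm"]]), 1)

  # straight membranes at random depths: pooled proximal point fraction
  # matches the band-area fraction within binomial error
  set.seed(13)
  anns <- lapply(1:150, function(i) straight_annotation(y_nm = runif(1, 150, 750)))
  fr2 <- point_compartment_fractions(anns)
  prox <- fr2$counts[["membrane"]] + fr2$counts[["coat"]]
  intr <- prox + fr2$counts[["cytoplasm"]]
  # per image: proximal area 1000 x 50, intracellular 1000 x (1050 - y)
  a_prox <- 1000 * 50
  a_intr <- mean(vapply(anns, function(a)
    1000 * (1000 - a$contours[[1]]$vertices[1, 2]) + a_prox * 0, 0)) * 1
  p_true <- a_prox / a_intr
  se <- sqrt(p_true * (1 - p_true) / intr)
  expect_lt(abs(prox / intr - p_true), 3 * se)
})

test_that("expected counts scale fractions to the observed total", {
  expect_equal(expected_counts(c(cytoplasm = 0.5, membrane = 0, coat = 0.5), 10),
               c(cytoplasm = 5, membrane = 0, coat = 5))
  expect_equal(sum(expected_counts(c(cytoplasm = 0.2, membrane = 0.1,
                                     coat = 0.1, extracellular = 0.6), 27)),
               27)
  expect_equal(expected_counts(c(cytoplasm = 0.7, membrane = 0.2, coat = 0.1), 0),
               c(cytoplasm = 0, membrane = 0, coat = 0))
})

test_that("Yates statistic matches chisq.test and is swap-invariant", {
  set.seed(19)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 12) + 1, 2, 2)
    ours <- yates_chi2_2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))$statistic
    expect_equal(ours, unname(ref), tolerance = 1e-12)
    expect_equal(yates_chi2_2x2(tab[2:1, ]), ours)
    expect_equal(yates_chi2_2x2(tab[, 2:1]), ours)
  }
  # identical rows: correction clamps at zero
  expect_equal(yates_chi2_2x2(rbind(c(10, 5), c(10, 5))), 0)
  expect_error(yates_chi2_2x2(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(yates_chi2_2x2(rbind(c(1, 0), c(2, 0))), "margin")
})

test_that("df = 1 upper tail is a proper survival function", {
  expect_equal(chi2_sf_df1(0), 1)
  expect_error(chi2_sf_df1(-1), "non-negative")
  # monotone decreasing and consistent with simulation at a few points
  xs <- c(0.5, 1, 3.84, 10)
  p <- chi2_sf_df1(xs)
  expect_true(all(diff(p) < 0))
  expect_equal(p[3], 0.05, tolerance = 0.005)
})

test_that("RLI is 1 with zero chi-squared when observed equals expected", {
  fr <- c(cytoplasm = 0.5, membrane = 0.25, coat = 0.25)
  rep_ <- rli_report(c(cytoplasm = 12, membrane = 6, coat = 6), fr)
  expect_equal(unname(rep_$rli), c(1, 1, 1))
  expect_equal(rep_$chi2, 0)
  expect_equal(rep_$p_value, 1)
  expect_equal(sum(rep_$expected), sum(rep_$observed))
})

test_that("stereology table reports one labeled row per experiment", {
  set.seed(41)
  anns <- c(
    lapply(1:3, function(i) {
      a <- generate_scene(scene_config(cytoplasm_density = 300,
                                       membrane_density = 300,
                                       coat_density = 300, grid_nm = 6),
                          seed = 200 + i, experiment_id = "expA",
                          image_index = i)$annotation
      a
    }))
  st <- stereology_table(anns)
  expect_equal(nrow(st), 1L)
  expect_equal(st$n_images, 3L)
  expect_equal(st$obs_total, st$obs_cyto + st$obs_mem + st$obs_coat)
  expect_equal(st$exp_total, st$obs_total)
  expect_true(is.finite(st$chi2) && st$p_value > 0 && st$p_value <= 1)
})

test_that("null simulation output carries counts consistent with its ratios", {
  r <- simulate_rli_null(6, n_images = 6, mean_total = 40, seed = 5)
  expect_equal(nrow(r), 6L)
  expect_equal(r$rli_cyto, r$obs_cyto / r$exp_cyto)
  expect_equal(r$total, r$obs_cyto + r$obs_mem + r$obs_coat)
  expect_true(all(abs(r$exp_cyto + r$exp_mem + r$exp_coat - r$total) < 1e-9))
})
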