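test_that("zone rule classifies the canonical cases", {
  ann <- straight_annotation(y_nm = 300, coat = rbind(c(400, 600)))
  pts <- rbind(c(100, 360),   # 60 nm below membrane, cytoplasmic
               c(500, 325),   # 25 nm, foot at arc 500 inside the coat
               c(100, 325),   # 25 nm, foot outside the coat
               c(100, 350),   # exactly 50 nm: closed interval -> proximal
               c(100, 100))   # above the membrane
  lab <- as.character(classify_particles(ann, pts))
  expect_equal(lab, c("cytoplasm", "coat", "membrane", "membrane",
                      "extracellular"))
})

test_that("classification agrees with a dense-sampling brute force", {
  set.seed(31)
  sc <- generate_scene(scene_config(cytoplasm_density = 0,
                                    membrane_density = 0, coat_density = 0),
                       seed = 31)
  ann <- sc$annotation
  w <- ann$frame$width_px * ann$frame$nm_per_px
  pts <- cbind(runif(300, 0, w), runif(300, 0, w))
  fast <- as.character(classify_particles(ann, pts))
  ct <- ann$contours[[1]]
  for (i in seq_len(nrow(pts))) {
    bc <- brute_closest(contour_vertices(ct), pts[i, ], n_per_seg = 400)
    # exclude points within 0.5 nm of the zone boundary or a coat edge
    near_zone <- abs(bc$dist - 50) < 0.5
    near_edge <- !is.null(ct$coat_intervals) &&
      any(abs(bc$arc - as.vector(ct$coat_intervals)) < 0.5)
    if (near_zone || near_edge) next
    expect_equal(fast[i], brute_classify(ann, pts[i, ], n_per_seg = 400))
  }
})

test_that("classification counts are permutation-invariant", {
  set.seed(8)
  ann <- straight_annotation(coat = rbind(c(200, 300)))
  pts <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
  t1 <- table(classify_particles(ann, pts))
  t2 <- table(classify_particles(ann, pts[sample(200), ]))
  expect_equal(t1, t2)
})

test_that("region areas match analytic oracles and conserve the frame", {
  # straight membrane across a 1000 x 1000 frame: proximal band = L x 50
  ann <- straight_annotation(y_nm = 300)
  g <- region_geometry(ann, grid_nm = 2)
  prox <- sum(g$area_um2[g$region %in% c("membrane", "coat")])
  expect_equal(prox * 1e6, 1000 * 50, tolerance = 0.01)
  expect_equal(g$area_um2[g$region == "extracellular"] * 1e6, 1000 * 300,
               tolerance = 0.01)
  expect_equal(sum(g$area_um2) * 1e6, 1000 * 1000)  # exact conservation
  expect_equal(g$volume_um3, g$area_um2 * 70 / 1e3)

  # coated half of a circular membrane, cytoplasm outside: the coated band
  # is a half annulus with area pi/2 ((r+50)^2 - r^2) (curvature-corrected
  # arc x 50)
  f <- image_frame(600, 600, 1)
  ct <- circle_contour(300, 300, 50, n = 500, coat_half = TRUE)
  ann2 <- micrograph_annotation(f, list(ct))
  g2 <- region_geometry(ann2, grid_nm = 2)
  half_annulus <- pi / 2 * ((100)^2 - 50^2)
  expect_equal(g2$area_um2[g2$region == "coat"] * 1e6, half_annulus,
               tolerance = 0.02)
  expect_equal(g2$area_um2[g2$region == "membrane"] * 1e6, half_annulus,
               tolerance = 0.02)
  # the circle interior is extracellular
  expect_equal(g2$area_um2[g2$region == "extracellular"] * 1e6, pi * 50^2,
               tolerance = 0.02)
})

test_that("densities pool counts and volumes, and scale with thickness", {
  set.seed(12)
  p <- data.frame(x = runif(40, 0, 1000), y = runif(40, 351, 1000))
  ann70 <- straight_annotation(y_nm = 300, particles = p)
  ann140 <- straight_annotation(y_nm = 300, particles = p, thickness = 140)
  d70 <- density_table(list(ann70), grid_nm = 5)$table
  d140 <- density_table(list(ann140), grid_nm = 5)$table
  expect_equal(d70$density[d70$region == "cytoplasm"],
               2 * d140$density[d140$region == "cytoplasm"])
  expect_equal(d70$count, d140$count)

  # zero particles: densities 0 wherever the region exists, enrichment
  # undefined (the plain membrane has no coated region, so coat volume is 0
  # and its density is reported as missing)
  d0 <- density_table(list(straight_annotation()), grid_nm = 5)$table
  expect_true(all(d0$density[d0$volume_um3 > 0] == 0))
  expect_true(is.na(d0$density[d0$region == "coat"]))
  expect_true(all(is.na(d0$fold_enrichment)))
})

test_that("scene densities are recovered from generated scenes", {
  # parameter recovery at a reduced density regime for speed; the published
  # regime is exercised in the acceptance suite
  cfg <- scene_config(cytoplasm_density = 150, membrane_density = 0,
                      coat_density = 1500, grid_nm = 5)
  anns <- lapply(1:8, function(s)
    generate_scene(cfg, seed = 100 + s, image_index = s)$annotation)
  tab <- density_table(anns, grid_nm = 5)$table
  for (rg in c("cytoplasm", "coat")) {
    row <- tab[tab$region == rg, ]
    se <- sqrt(row$count) / row$volume_um3
    truth <- if (rg == "cytoplasm") 150 else 1500
    expect_lt(abs(row$density - truth), 3 * se + 1e-9)
  }
})

test_that("group comparison behaves at the null and under separation", {
  # equal groups: F = 0, no rejection
  d <- data.frame(density = rep(c(1, 2, 3), 3),
                  group = rep(c("a", "b", "c"), each = 3))
  res <- compare_conditions(d)
  expect_gt(res$omnibus_p, 0.99)

  # clear separation: all pairwise p < 0.01
  set.seed(2)
  d2 <- data.frame(density = c(rnorm(8, 0), rnorm(8, 50), rnorm(8, 100)),
                   group = rep(c("a", "b", "c"), each = 8))
  res2 <- compare_conditions(d2)
  expect_lt(res2$omnibus_p, 1e-6)
  expect_true(all(res2$pairwise$p_adj < 0.01))

  expect_error(compare_conditions(data.frame(density = 1:3,
                                             group = c("a", "a", "b"))),
               "at least 2 observations")
})

test_that("ANOVA type-I error is calibrated", {
  set.seed(77)
  rej <- replicate(1000, {
    d <- data.frame(density = rnorm(24),
                    group = rep(c("a", "b", "c"), each = 8))
    compare_conditions(d)$omnibus_p < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})
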