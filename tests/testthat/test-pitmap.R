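# A hand-built pit scene: straight flanks with a semicircular pit of radius
# 50 between arc marks, cytoplasm below.
pit_annotation <- function(particles = NULL) {
  t <- seq(0, pi, length.out = 65)
  arc <- cbind(500 - 50 * cos(t), 400 + 50 * sin(t))
  v <- rbind(c(0, 400), arc, c(1000, 400))
  cum <- c(0, cumsum(sqrt(rowSums(diff(v)^2))))
  marks <- c(cum[2], cum[2 + 64])
  ct <- membrane_contour(v, coat_intervals = rbind(marks), pit_marks = marks)
  micrograph_annotation(image_frame(1000, 1000, 1), list(ct),
                        particles = particles)
}

test_that("pit particles are normalized by arc position, distal by offset", {
  # apex particle: foot at the pit midpoint -> s = 0.5
  p <- data.frame(x = c(500, 0, 900), y = c(470, 410, 430))
  res <- classify_and_normalize(pit_annotation(), p)
  expect_equal(as.character(res$label), c("pit", "distal", "distal"))
  expect_equal(res$s[1], 0.5, tolerance = 1e-3)
  expect_true(res$distal_offset_nm[2] < 0)   # before the pit start
  expect_true(res$distal_offset_nm[3] > 0)   # past the pit end
  expect_equal(res$proximity[1], 20, tolerance = 0.1)
})

test_that("a foot exactly at the pit start is labeled pit with s = 0", {
  ann <- pit_annotation()
  # a particle sitting exactly on the pit-start vertex (450, 400): the foot
  # arc equals the pit start, and the closed-interval rule labels it pit
  res <- classify_and_normalize(ann, rbind(c(450, 400)))
  expect_equal(as.character(res$label), "pit")
  expect_equal(res$s, 0, tolerance = 1e-9)
  expect_equal(res$proximity, 0)
})

test_that("labels and s agree with a dense-sampling oracle", {
  set.seed(61)
  ann <- pit_annotation()
  ct <- ann$contours[[1]]
  marks <- ct$pit_marks
  pit_len <- marks[2] - marks[1]
  pts <- cbind(runif(60, 50, 950), runif(60, 405, 600))
  res <- classify_and_normalize(ann, pts)
  for (i in seq_len(nrow(pts))) {
    bc <- brute_closest(contour_vertices(ct), pts[i, ], n_per_seg = 2000)
    if (min(abs(bc$arc - marks)) < 0.5) next  # skip edge-ambiguous feet
    want <- if (bc$arc >= marks[1] && bc$arc <= marks[2]) "pit" else "distal"
    expect_equal(as.character(res$label[i]), want)
    if (want == "pit")
      expect_lt(abs(res$s[i] - (bc$arc - marks[1]) / pit_len), 1e-3)
  }
})

test_that("classification is invariant under rigid motions", {
  set.seed(67)
  ann <- pit_annotation()
  ct <- ann$contours[[1]]
  pts <- cbind(runif(40, 100, 900), runif(40, 405, 650))
  base <- classify_and_normalize(ct, pts)
  v2 <- rotate_points(contour_vertices(ct), 0.8, c(300, -100))
  ct2 <- membrane_contour(v2, coat_intervals = ct$coat_intervals,
                          pit_marks = ct$pit_marks)
  moved <- classify_and_normalize(ct2, rotate_points(pts, 0.8, c(300, -100)))
  expect_equal(as.character(moved$label), as.character(base$label))
  expect_equal(moved$proximity, base$proximity, tolerance = 1e-9)
  expect_equal(moved$s, base$s, tolerance = 1e-9)
})

test_that("idealized projection mirrors every particle and keeps proximity", {
  ann <- pit_annotation()
  p <- data.frame(x = c(500, 463, 800), y = c(475, 430, 415))
  pm <- classify_and_normalize(ann, p)
  proj <- idealized_projection(pm)
  expect_equal(nrow(proj), 2L * nrow(pm))

  # apex particle with proximity p sits exactly p beyond the apex on axis
  apex <- proj[proj$label == "pit" & !proj$mirror, ][1, ]
  expect_equal(apex$x, 0, tolerance = 1e-6)
  expect_equal(apex$y, -(50 + pm$proximity[1]), tolerance = 1e-6)

  # pit points: radial distance to the model arc equals the proximity
  pit_rows <- proj[proj$label == "pit", ]
  expect_equal(sqrt(pit_rows$x^2 + pit_rows$y^2) - 50, pit_rows$proximity,
               tolerance = 1e-9)
  # distal points: vertical distance to the flank equals the proximity
  d_rows <- proj[proj$label == "distal", ]
  expect_equal(-d_rows$y, d_rows$proximity, tolerance = 1e-9)
  expect_true(all(abs(d_rows$x) >= 50))

  # mirror symmetry is exact
  expect_equal(proj$x[seq_len(nrow(pm))], -proj$x[nrow(pm) + seq_len(nrow(pm))])
})

test_that("proximity comparison is symmetric and guards small groups", {
  pm <- data.frame(label = factor(rep(c("pit", "distal"), each = 6),
                                  levels = c("pit", "distal")),
                   proximity = c(rnorm(6, 17), rnorm(6, 7)))
  res <- proximity_comparison(pm)
  expect_equal(res$difference,
               mean(pm$proximity[1:6]) - mean(pm$proximity[7:12]))
  swapped <- pm
  swapped$label <- factor(rev(as.character(pm$label)),
                          levels = c("pit", "distal"))
  res2 <- proximity_comparison(swapped)
  expect_equal(res2$difference, -res$difference)
  expect_equal(res2$p_value, res$p_value)

  same <- data.frame(label = factor(rep(c("pit", "distal"), each = 8),
                                    levels = c("pit", "distal")),
                     proximity = rep(rnorm(8), 2))
  expect_gt(proximity_comparison(same)$p_value, 0.99)
  expect_error(proximity_comparison(pm[c(1, 7:12), ]), "at least 2")
})

test_that("per-image frequencies conserve counts and order anchor rates", {
  cfg <- scene_config(cytoplasm_density = 0, membrane_density = 0,
                      coat_density = 0, n_pits = 1,
                      anchored_rate_pit = 0.2, anchored_rate_distal = 0.014)
  ordered <- logical(20)
  for (s in 1:20) {
    sc <- generate_scene(cfg, seed = 800 + s)
    pmap <- classify_and_normalize(sc$annotation)
    fq <- frequency_per_region(pmap)
    expect_equal(fq$n_pit + fq$n_distal, nrow(pmap))
    ordered[s] <- fq$rate_pit_per_nm > fq$rate_distal_per_nm
  }
  expect_gte(mean(ordered), 0.95)

  empty <- classify_and_normalize(pit_annotation(),
                                  matrix(numeric(0), ncol = 2))
  fq0 <- frequency_per_region(empty)
  expect_equal(fq0$n_pit, 0L)
  expect_equal(fq0$n_distal, 0L)
})

test_that("pit/distal labels recover generator truth end to end", {
  cfg <- scene_config(cytoplasm_density = 0, membrane_density = 0,
                      coat_density = 0, n_pits = 1,
                      anchored_rate_pit = 0.2, anchored_rate_distal = 0.02)
  agree <- total <- 0
  for (s in 1:10) {
    sc <- generate_scene(cfg, seed = 900 + s)
    pmap <- classify_and_normalize(sc$annotation)
    truth_lab <- ifelse(sc$truth$region_true == "coat", "pit", "distal")
    agree <- agree + sum(as.character(pmap$label) == truth_lab[pmap$particle])
    total <- total + nrow(pmap)
  }
  expect_gte(agree / total, 0.98)
})

test_that("missing pit marks raise an informative error", {
  ann <- straight_annotation(particles = data.frame(x = 1, y = 400))
  expect_error(classify_and_normalize(ann), "pit_marks")
})
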