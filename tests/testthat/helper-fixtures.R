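# Fixtures and independent oracles, built in code.

# A frame with a straight horizontal membrane at depth y_nm (cytoplasm
# below), optionally with coat intervals / pit marks in arc length.
straight_annotation <- function(y_nm = 300, width_px = 1000, height_px = 1000,
                                nm_per_px = 1, coat = NULL, pit = NULL,
                                particles = NULL, thickness = 70) {
  f <- image_frame(width_px, height_px, nm_per_px, thickness)
  w <- width_px * nm_per_px
  ct <- membrane_contour(rbind(c(0, y_nm), c(w, y_nm)),
                         coat_intervals = coat, pit_marks = pit,
                         side_convention = "left")
  micrograph_annotation(f, list(ct), particles = particles)
}

# Closed circular contour of radius r (polygon, n vertices); traversed
# counter-clockwise in standard orientation so the outside is the "right"
# side. With side_convention = "right" the cytoplasm is outside the circle.
circle_contour <- function(cx, cy, r, n = 400, coat_half = FALSE) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  v <- cbind(cx + r * cos(t), cy + r * sin(t))
  total <- sum(sqrt(rowSums(diff(v)^2)))
  membrane_contour(v,
                   coat_intervals = if (coat_half) rbind(c(0, total / 2)),
                   side_convention = "right")
}

# Independent brute-force oracle: minimum distance from a point to a
# polyline by dense sampling along every segment, plus the arc position of
# the best sample. Uses only the vertex matrix, not the package kernel.
brute_closest <- function(vertices, p, n_per_seg = 3000) {
  best <- Inf; best_arc <- NA_real_; cum <- 0
  for (i in seq_len(nrow(vertices) - 1)) {
    a <- vertices[i, ]; b <- vertices[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = n_per_seg)
    px <- a[1] + tt * (b[1] - a[1]); py <- a[2] + tt * (b[2] - a[2])
    d <- sqrt((px - p[1])^2 + (py - p[2])^2)
    j <- which.min(d)
    if (d[j] < best) { best <- d[j]; best_arc <- cum + tt[j] * len }
    cum <- cum + len
  }
  list(dist = best, arc = best_arc)
}

# Independent brute-force region classifier built on brute_closest and a
# sign test against the membrane, for a single-contour annotation.
brute_classify <- function(ann, p, zone_nm = 50, n_per_seg = 3000) {
  ct <- ann$contours[[1]]
  v <- contour_vertices(ct)
  bc <- brute_closest(v, p, n_per_seg)
  # side by cross product at the nearest vertex pair bracketing the foot
  cum <- c(0, cumsum(sqrt(rowSums(diff(v)^2))))
  i <- max(1, min(nrow(v) - 1, findInterval(bc$arc, cum)))
  d <- v[i + 1, ] - v[i, ]
  cr <- d[1] * (p[2] - v[i, 2]) - d[2] * (p[1] - v[i, 1])
  left_is_cyto <- is.null(ct$side_convention) || ct$side_convention == "left"
  cyto <- if (left_is_cyto) cr >= 0 else cr <= 0
  if (!cyto) return("extracellular")
  if (bc$dist > zone_nm) return("cytoplasm")
  iv <- ct$coat_intervals
  if (!is.null(iv) &&
      any(bc$arc >= iv[, 1] & bc$arc <= iv[, 2])) "coat" else "membrane"
}

rotate_points <- function(m, theta, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(m %*% t(R), 2, shift, "+")
}
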