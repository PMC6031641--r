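# Labeling resolution: perpendicular tag-to-membrane distances, detection
# simulation under a tag-geometry model, KDE FWHM and per-particle SNR.

#' Tag-geometry model for the labeling-resolution simulation
#'
#' A membrane-anchored tag whose particle sits at the end of a linker of
#' variable length (conformational length states spanning
#' `length_min_nm`..`length_max_nm`, at most `length_max_theoretical_nm`,
#' the fully extended colinear arrangement). Orientation is drawn about the
#' membrane normal with membrane exclusion (the tag cannot penetrate the
#' membrane half-space):
#' * `"perpendicular"` - always along the normal;
#' * `"hemisphere"` - uniform over the cytoplasmic hemisphere;
#' * `"cone"` - uniform in solid angle within `cone_half_angle_deg` of the
#'   normal (the default, half-angle 45 degrees, a steric compromise between
#'   the flexible linker and the bulk of the particle/membrane).
#'
#' @param length_min_nm,length_max_nm Range of tag length states (nm);
#'   defaults 7 and 18.
#' @param length_max_theoretical_nm Hard upper bound (nm), default 22.
#' @param n_length_states Number of discrete length states, or `Inf`
#'   (default) for a continuous uniform law over the range.
#' @param orientation_law One of `"cone"`, `"hemisphere"`, `"perpendicular"`.
#' @param cone_half_angle_deg Cone half-angle in degrees (for `"cone"`).
#' @param section_thickness_nm EM section thickness (nm), default 70.
#' @return List of class `tag_geometry_model`.
#' @export
tag_geometry_model <- function(length_min_nm = 7, length_max_nm = 18,
                               length_max_theoretical_nm = 22,
                               n_length_states = Inf,
                               orientation_law = c("cone", "hemisphere",
                                                   "perpendicular"),
                               cone_half_angle_deg = 45,
                               section_thickness_nm = 70) {
  if (!(length_min_nm > 0 && length_min_nm <= length_max_nm &&
        length_max_nm <= length_max_theoretical_nm))
    stop("need 0 < length_min <= length_max <= length_max_theoretical")
  orientation_law <- match.arg(orientation_law)
  structure(list(length_min_nm = length_min_nm,
                 length_max_nm = length_max_nm,
                 length_max_theoretical_nm = length_max_theoretical_nm,
                 n_length_states = n_length_states,
                 orientation_law = orientation_law,
                 cone_half_angle_deg = cone_half_angle_deg,
                 section_thickness_nm = section_thickness_nm),
            class = "tag_geometry_model")
}

# Draw n (length, cos-theta, distance) samples; uses the caller's RNG stream.
.rtag_draw <- function(model, n) {
  L <- if (is.finite(model$n_length_states)) {
    states <- if (model$n_length_states == 1) model$length_min_nm
      else seq(model$length_min_nm, model$length_max_nm,
               length.out = model$n_length_states)
    sample(states, n, replace = TRUE)
  } else stats::runif(n, model$length_min_nm, model$length_max_nm)
  cmin <- switch(model$orientation_law,
                 perpendicular = 1,
                 hemisphere = 0,
                 cone = cos(model$cone_half_angle_deg * pi / 180))
  # uniform in solid angle between the normal and the exclusion bound
  cth <- if (cmin == 1) rep(1, n) else stats::runif(n, cmin, 1)
  list(length = L, cos_theta = cth, distance = L * cth)
}

#' Simulate detected tag-to-membrane distances in EM sections
#'
#' Per draw: a tag length is sampled from the length-state law and an
#' orientation from the orientation law (with membrane exclusion); the
#' particle is placed in 3-D relative to an anchor at a uniformly random
#' depth inside a section of the model's thickness, and the draw is accepted
#' only if the particle centre falls inside the section. The recorded value
#' is the in-plane perpendicular distance to the membrane trace.
#'
#' @param model A [tag_geometry_model()].
#' @param n_draws Number of accepted draws to return.
#' @param seed Integer seed (bit-for-bit reproducible).
#' @return Object of class `distance_sample`: list with `distances` (nm),
#'   `median`, `mean`, `fwhm`, `n` and `model`.
#' @export
simulate_detected_distances <- function(model = tag_geometry_model(),
                                        n_draws, seed = 1) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  set.seed(seed)
  thick <- model$section_thickness_nm
  out <- numeric(0)
  while (length(out) < n_draws) {
    m <- as.integer(min(2e6, max(1024, 1.3 * (n_draws - length(out)))))
    d <- .rtag_draw(model, m)
    sth <- sqrt(pmax(0, 1 - d$cos_theta^2))
    phi <- stats::runif(m, 0, 2 * pi)
    dz <- d$length * sth * sin(phi)         # through-section displacement
    z0 <- stats::runif(m, 0, thick)          # anchor depth in the section
    keep <- (z0 + dz) >= 0 & (z0 + dz) <= thick
    out <- c(out, d$distance[keep])
  }
  distance_sample(out[seq_len(n_draws)], model = model)
}

#' Bundle distances with summary statistics
#'
#' @param distances Non-negative distances (nm).
#' @param model Optional [tag_geometry_model()] metadata.
#' @return Object of class `distance_sample`.
#' @export
distance_sample <- function(distances, model = NULL) {
  if (any(distances < 0)) stop("distances must be non-negative")
  structure(list(distances = distances, n = length(distances),
                 median = stats::median(distances), mean = mean(distances),
                 fwhm = if (length(distances) >= 50) fwhm(distances)
                        else NA_real_,
                 model = model),
            class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat(sprintf(
    "<distance_sample> n = %d, median = %.2f nm, mean = %.2f nm, FWHM = %s nm\n",
    x$n, x$median, x$mean,
    if (is.na(x$fwhm)) "NA" else sprintf("%.2f", x$fwhm)))
  invisible(x)
}

#' Measure perpendicular particle-to-membrane distances
#'
#' Closest-approach proximity for every particle on the cytoplasmic side;
#' extracellular-side particles are excluded and counted.
#'
#' @param annotations A [micrograph_annotation()] or list of them.
#' @return A `distance_sample` with an `n_excluded` attribute.
#' @export
measure_distances <- function(annotations) {
  if (inherits(annotations, "micrograph_annotation"))
    annotations <- list(annotations)
  d <- numeric(0); excluded <- 0L
  for (a in annotations) {
    if (!length(a$contours)) stop("annotation has no contours")
    p <- a$particles
    if (!nrow(p)) next
    r <- .closest_to_contours(p$x, p$y, a$contours)
    keep <- r$side >= 0
    d <- c(d, r$dist[keep])
    excluded <- excluded + sum(!keep)
  }
  out <- distance_sample(d)
  attr(out, "n_excluded") <- excluded
  out
}

#' Full width at half maximum of a distance distribution
#'
#' Width between the outermost crossings of half the modal height of a
#' Gaussian kernel-density estimate. The bandwidth (default: Silverman-type
#' rule, `stats::bw.nrd0`) is recorded in the result.
#'
#' @param x Numeric sample (or a `distance_sample`).
#' @param bw Kernel bandwidth; default Silverman-type (`"nrd0"`).
#' @return Width (same units as `x`) with attribute `bandwidth`.
#' @export
fwhm <- function(x, bw = "nrd0") {
  if (inherits(x, "distance_sample")) x <- x$distances
  if (length(unique(x)) == 1L) {
    warning("all values identical; FWHM is 0")
    return(structure(0, bandwidth = 0))
  }
  d <- stats::density(x, bw = bw)
  hm <- max(d$y) / 2
  above <- d$y >= hm
  i1 <- which(above)[1L]; i2 <- max(which(above))
  # linear interpolation at the outermost half-height crossings
  xl <- if (i1 > 1L)
    d$x[i1 - 1L] + (hm - d$y[i1 - 1L]) / (d$y[i1] - d$y[i1 - 1L]) *
      (d$x[i1] - d$x[i1 - 1L]) else d$x[1L]
  xr <- if (i2 < length(d$x))
    d$x[i2] + (d$y[i2] - hm) / (d$y[i2] - d$y[i2 + 1L]) *
      (d$x[i2 + 1L] - d$x[i2]) else d$x[length(d$x)]
  structure(xr - xl, bandwidth = d$bw)
}

#' Per-particle signal-to-noise ratio
#'
#' SNR = |mean(signal disc) - mean(background annulus)| / SD(annulus), with
#' the disc of radius `r_signal` centred on the particle and the annulus
#' between `r_bg_inner` and `r_bg_outer`. Default radii: 3.5 nm (half the
#' 7 nm nominal particle diameter) and a 7-14 nm annulus, converted to
#' pixels via `nm_per_px`.
#'
#' @param img Numeric matrix (image patch).
#' @param center Length-2 (x, y) centre in pixels.
#' @param r_signal,r_bg_inner,r_bg_outer Radii in nm.
#' @param nm_per_px Pixel size (nm); radii are divided by this.
#' @return data.frame with `signal`, `background`, `background_sd`, `snr`
#'   (`NA` when the annulus SD is 0) and pixel counts.
#' @export
particle_snr <- function(img, center, r_signal = 3.5, r_bg_inner = 7,
                         r_bg_outer = 14, nm_per_px = 1) {
  if (!(r_signal < r_bg_inner && r_bg_inner < r_bg_outer))
    stop("need r_signal < r_bg_inner < r_bg_outer")
  rs <- r_signal / nm_per_px; ri <- r_bg_inner / nm_per_px
  ro <- r_bg_outer / nm_per_px
  if (center[1L] - ro < 0.5 || center[1L] + ro > nrow(img) + 0.5 ||
      center[2L] - ro < 0.5 || center[2L] + ro > ncol(img) + 0.5)
    stop("background annulus must lie fully inside the patch")
  dx <- seq_len(nrow(img)) - center[1L]
  dy <- seq_len(ncol(img)) - center[2L]
  rr <- sqrt(outer(dx^2, dy^2, "+"))
  disc <- rr <= rs
  ann <- rr >= ri & rr <= ro
  sig <- mean(img[disc]); bg <- mean(img[ann]); bsd <- stats::sd(img[ann])
  data.frame(signal = sig, background = bg, background_sd = bsd,
             snr = if (bsd > 0) abs(sig - bg) / bsd else NA_real_,
             n_signal_px = sum(disc), n_background_px = sum(ann))
}
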