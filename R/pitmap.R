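# Nanoscale mapping of membrane-attached particles around coated pits:
# normalized arc positions, pit/distal classification, proximity statistics
# and idealized-pit spatial averaging.

#' Classify particles against a pit and normalize their arc positions
#'
#' For every cytoplasmic-side particle, the closest-approach foot on the
#' contour is computed; the particle is labeled `pit` when the foot lies in
#' the closed `[pit start, pit end]` arc interval and `distal` otherwise.
#' Pit particles get a normalized arc position
#' `s = (foot - pit start) / pit contour length` in `[0, 1]`; distal
#' particles get a signed arc offset to the nearest pit edge (negative before
#' the pit start, positive past the pit end). Non-cytoplasmic particles are
#' excluded and counted.
#'
#' @param annotation A [micrograph_annotation()] whose first contour carries
#'   `pit_marks`, or a [membrane_contour()] with `pit_marks` plus `particles`.
#' @param particles Optional n x 2 points (nm); defaults to the annotation's
#'   particles.
#' @return data.frame of class `pit_map` with columns `particle`, `label`,
#'   `s`, `distal_offset_nm`, `proximity`, `foot_arc`; attributes
#'   `pit_length_nm`, `distal_length_nm`, `n_excluded`.
#' @export
classify_and_normalize <- function(annotation, particles = NULL) {
  if (inherits(annotation, "membrane_contour")) {
    contour <- annotation
    if (is.null(particles)) stop("supply particles with a bare contour")
  } else {
    if (!length(annotation$contours)) stop("annotation has no contours")
    contour <- annotation$contours[[1L]]
    if (is.null(particles)) particles <- annotation$particles
  }
  if (is.null(contour$pit_marks))
    stop("contour has no pit_marks; set them in the metadata")
  if (is.data.frame(particles)) particles <- cbind(particles$x, particles$y)
  particles <- matrix(as.numeric(particles), ncol = 2L)
  pm <- contour$pit_marks
  pit_len <- pm[2L] - pm[1L]
  total <- arc_length(contour)
  r <- closest_approach(contour, particles)
  keep <- r$side != "extracellular"
  n_excluded <- sum(!keep)
  r <- r[keep, , drop = FALSE]
  idx <- which(keep)
  in_pit <- r$foot_arc >= pm[1L] & r$foot_arc <= pm[2L]
  s <- ifelse(in_pit, (r$foot_arc - pm[1L]) / pit_len, NA_real_)
  off <- ifelse(in_pit, NA_real_,
                ifelse(r$foot_arc < pm[1L], r$foot_arc - pm[1L],
                       r$foot_arc - pm[2L]))
  out <- data.frame(particle = idx,
                    label = factor(ifelse(in_pit, "pit", "distal"),
                                   levels = c("pit", "distal")),
                    s = s, distal_offset_nm = off,
                    proximity = r$proximity, foot_arc = r$foot_arc)
  class(out) <- c("pit_map", "data.frame")
  attr(out, "pit_length_nm") <- pit_len
  attr(out, "distal_length_nm") <- total - pit_len
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Project a pit map onto an idealized coated pit
#'
#' Particles are mapped onto a standard pit: a semicircular invagination of
#' the given diameter with flat flanks. Pit particles sit at their normalized
#' arc fraction `s` along the semicircle, offset outward (cytoplasmic side)
#' along the local normal by their measured proximity; distal particles sit
#' on the flanks at their arc offset, offset by their proximity. Every
#' particle is duplicated by mirror symmetry about the pit axis, so `n` input
#' rows give exactly `2n` output points. In the output frame the pit axis is
#' `x = 0`, the flank membrane is `y = 0`, and the pit invaginates toward
#' negative `y` (apex at `(0, -radius)`); the cytoplasmic side is below the
#' profile.
#'
#' @param pitmap A `pit_map` from [classify_and_normalize()].
#' @param pit_diameter_nm Idealized pit diameter (default 100 nm).
#' @return data.frame with `x`, `y` (nm), `label`, `proximity`, `mirror`.
#' @export
idealized_projection <- function(pitmap, pit_diameter_nm = 100) {
  r <- pit_diameter_nm / 2
  n <- nrow(pitmap)
  if (!n) return(data.frame(x = numeric(0), y = numeric(0),
                            label = factor(character(0),
                                           levels = c("pit", "distal")),
                            proximity = numeric(0), mirror = logical(0)))
  x <- numeric(n); y <- numeric(n)
  pit <- pitmap$label == "pit"
  # arc position s in [0,1]: s = 0 at (-r, 0), s = 0.5 at the apex (0, -r)
  th <- pitmap$s[pit] * pi
  px <- -r * cos(th); py <- -r * sin(th)
  prox <- pitmap$proximity
  x[pit] <- px * (1 + prox[pit] / r)   # radial outward offset
  y[pit] <- py * (1 + prox[pit] / r)
  off <- pitmap$distal_offset_nm[!pit]
  x[!pit] <- sign(off) * (r + abs(off))
  y[!pit] <- -prox[!pit]
  out <- data.frame(x = c(x, -x), y = c(y, y),
                    label = rep(pitmap$label, 2L),
                    proximity = rep(prox, 2L),
                    mirror = rep(c(FALSE, TRUE), each = n))
  out
}

#' Compare membrane proximity between pit and distal particles
#'
#' Group means +/- SD and a two-sided Welch (unequal-variance) t-test.
#'
#' @param pitmap A `pit_map` (or any data.frame with `label` and
#'   `proximity`), or a concatenation of several via `rbind`.
#' @return List with `summary` (per-label n, mean, sd), `difference`
#'   (pit mean - distal mean) and `p_value`.
#' @export
proximity_comparison <- function(pitmap) {
  g <- split(pitmap$proximity, pitmap$label)
  if (any(lengths(g) < 2L))
    stop("need at least 2 particles in each of pit and distal")
  smry <- data.frame(label = names(g), n = lengths(g),
                     mean = vapply(g, mean, 0),
                     sd = vapply(g, stats::sd, 0), row.names = NULL)
  tt <- stats::t.test(g$pit, g$distal, var.equal = FALSE)
  list(summary = smry, difference = mean(g$pit) - mean(g$distal),
       p_value = tt$p.value)
}

#' Per-image pit and distal particle frequencies
#'
#' Raw per-image counts per label, plus rates per unit arc length (pit arc
#' vs analyzed distal arc), with the normalizing arc lengths recorded.
#'
#' @param pitmaps A list of `pit_map` objects (one per image).
#' @return data.frame with one row per image: counts, arc lengths and
#'   per-nm rates.
#' @export
frequency_per_region <- function(pitmaps) {
  if (inherits(pitmaps, "pit_map")) pitmaps <- list(pitmaps)
  rows <- lapply(seq_along(pitmaps), function(i) {
    pm <- pitmaps[[i]]
    tb <- table(pm$label)
    pl <- attr(pm, "pit_length_nm"); dl <- attr(pm, "distal_length_nm")
    data.frame(image = i,
               n_pit = as.integer(tb[["pit"]]),
               n_distal = as.integer(tb[["distal"]]),
               pit_arc_nm = pl, distal_arc_nm = dl,
               rate_pit_per_nm = tb[["pit"]] / pl,
               rate_distal_per_nm = tb[["distal"]] / dl)
  })
  do.call(rbind, rows)
}
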