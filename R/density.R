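# Compartment classification, region areas/volumes and particle densities.

#' Compartment labels used throughout the package
#'
#' `cytoplasm`: cytoplasmic side, > `zone_nm` from any membrane.
#' `membrane`: membrane-proximal (within the zone) but uncoated.
#' `coat`: membrane-proximal with the nearest-point arc position inside a
#' coat interval. `extracellular`: the non-cytoplasmic side.
#' @export
REGIONS <- c("cytoplasm", "membrane", "coat", "extracellular")

# Is arc position s inside any closed interval of the k x 2 matrix iv?
.in_intervals <- function(s, iv) {
  if (is.null(iv) || !nrow(iv)) return(rep(FALSE, length(s)))
  hit <- rep(FALSE, length(s))
  for (r in seq_len(nrow(iv)))
    hit <- hit | (s >= iv[r, 1L] & s <= iv[r, 2L])
  hit
}

# Vectorised classification of arbitrary points against an annotation's
# contours. Returns a factor with levels REGIONS.
.classify_points <- function(annotation, px, py, zone_nm = 50) {
  if (!length(annotation$contours)) stop("annotation has no contours")
  r <- .closest_to_contours(px, py, annotation$contours)
  lab <- rep("extracellular", length(px))
  cyto <- r$side >= 0   # on-membrane (proximity 0) counts as membrane-proximal
  prox <- cyto & r$dist <= zone_nm
  lab[cyto & !prox] <- "cytoplasm"
  coated <- rep(FALSE, length(px))
  for (k in seq_along(annotation$contours)) {
    iv <- annotation$contours[[k]]$coat_intervals
    w <- prox & r$contour == k
    if (any(w)) coated[w] <- .in_intervals(r$arc[w], iv)
  }
  lab[prox & !coated] <- "membrane"
  lab[prox & coated] <- "coat"
  factor(lab, levels = REGIONS)
}

#' Classify particles into membrane compartments
#'
#' Applies the zone rule: a particle is membrane-proximal if it lies on the
#' cytoplasmic side within `zone_nm` (default 50 nm, closed interval) of a
#' membrane contour; membrane-proximal particles are `coat` when the
#' nearest-point (foot) arc position falls inside a coat interval, otherwise
#' `membrane`; cytoplasmic-side particles beyond the zone are `cytoplasm`;
#' everything on the other side is `extracellular`.
#'
#' @param annotation A [micrograph_annotation()] with at least one contour.
#' @param particles Optional n x 2 matrix / data.frame of points (nm);
#'   defaults to the annotation's own particles.
#' @param zone_nm Membrane-proximal zone width in nm.
#' @return Factor of compartment labels (levels [REGIONS]).
#' @export
classify_particles <- function(annotation, particles = NULL, zone_nm = 50) {
  if (is.null(particles)) particles <- annotation$particles
  if (is.data.frame(particles)) particles <- cbind(particles$x, particles$y)
  particles <- matrix(as.numeric(particles), ncol = 2L)
  if (!nrow(particles)) return(factor(character(0), levels = REGIONS))
  .classify_points(annotation, particles[, 1L], particles[, 2L], zone_nm)
}

#' Per-compartment areas and volumes of a micrograph
#'
#' Areas are computed by midpoint-grid quadrature: the frame is covered by a
#' regular grid of cell centres at `grid_nm` spacing and every centre is
#' classified with the same rule as [classify_particles()], so region areas
#' and particle counts are mutually consistent by construction. Volumes
#' multiply areas by the section thickness. Compartment areas sum exactly to
#' the frame area.
#'
#' @param annotation A [micrograph_annotation()].
#' @param zone_nm Membrane-proximal zone width (nm).
#' @param grid_nm Target quadrature spacing (nm); the actual spacing divides
#'   the frame exactly.
#' @return data.frame with `region`, `area_um2`, `volume_um3`.
#' @export
region_geometry <- function(annotation, zone_nm = 50, grid_nm = 4) {
  w <- frame_width_nm(annotation$frame)
  h <- frame_height_nm(annotation$frame)
  nx <- max(1L, round(w / grid_nm)); ny <- max(1L, round(h / grid_nm))
  hx <- w / nx; hy <- h / ny
  cx <- (seq_len(nx) - 0.5) * hx
  cy <- (seq_len(ny) - 0.5) * hy
  gx <- rep(cx, times = ny); gy <- rep(cy, each = nx)
  lab <- .classify_points(annotation, gx, gy, zone_nm)
  counts <- table(lab)
  area_nm2 <- as.numeric(counts) * hx * hy
  data.frame(region = factor(names(counts), levels = REGIONS),
             area_um2 = area_nm2 / 1e6,
             volume_um3 = area_nm2 / 1e6 *
               annotation$frame$section_thickness_nm / 1e3)
}

#' Observed particle counts per compartment
#'
#' @param annotations List of [micrograph_annotation()] objects (one
#'   experiment).
#' @param zone_nm Membrane-proximal zone width (nm).
#' @return data.frame with one row per experiment: `experiment_id`,
#'   `n_images`, counts `cytoplasm`, `membrane`, `coat`, `extracellular` and
#'   `total` (intracellular compartments only, as tallied in labeling tables).
#' @export
region_tally <- function(annotations, zone_nm = 50) {
  if (inherits(annotations, "micrograph_annotation"))
    annotations <- list(annotations)
  ids <- vapply(annotations, function(a) a$experiment_id, "")
  out <- lapply(unique(ids), function(id) {
    anns <- annotations[ids == id]
    cnt <- stats::setNames(rep(0L, length(REGIONS)), REGIONS)
    for (a in anns) {
      tb <- table(classify_particles(a, zone_nm = zone_nm))
      cnt[names(tb)] <- cnt[names(tb)] + as.integer(tb)
    }
    data.frame(experiment_id = id, n_images = length(anns),
               cytoplasm = cnt[["cytoplasm"]], membrane = cnt[["membrane"]],
               coat = cnt[["coat"]], extracellular = cnt[["extracellular"]],
               total = cnt[["cytoplasm"]] + cnt[["membrane"]] + cnt[["coat"]])
  })
  do.call(rbind, out)
}

#' Particle densities per compartment and condition
#'
#' Counts and volumes are pooled over all images of a condition before
#' division (density = pooled count / pooled volume). Extracellular-side
#' particles are excluded from densities. `fold_enrichment` is the coat /
#' cytoplasm density ratio, reported as `NA` when the cytoplasm density is 0.
#'
#' @param annotations List of [micrograph_annotation()] objects.
#' @param zone_nm Membrane-proximal zone width (nm).
#' @param grid_nm Quadrature spacing for [region_geometry()].
#' @return List with `$table` (condition x region densities) and
#'   `$per_image` (per-image densities, for group comparisons).
#' @export
density_table <- function(annotations, zone_nm = 50, grid_nm = 4) {
  if (inherits(annotations, "micrograph_annotation"))
    annotations <- list(annotations)
  conds <- vapply(annotations, function(a) a$condition, "")
  intracell <- c("cytoplasm", "membrane", "coat")
  per_image <- list(); rows <- list()
  for (cond in unique(conds)) {
    anns <- annotations[conds == cond]
    vol <- stats::setNames(rep(0, 3L), intracell)
    area <- vol
    cnt <- stats::setNames(rep(0L, 3L), intracell)
    for (a in anns) {
      g <- region_geometry(a, zone_nm = zone_nm, grid_nm = grid_nm)
      tb <- table(classify_particles(a, zone_nm = zone_nm))
      for (rg in intracell) {
        vi <- g$volume_um3[g$region == rg]
        vi <- if (length(vi)) vi else 0
        ci <- if (rg %in% names(tb)) as.integer(tb[[rg]]) else 0L
        vol[rg] <- vol[rg] + vi
        area[rg] <- area[rg] + (if (length(g$area_um2[g$region == rg]))
          g$area_um2[g$region == rg] else 0)
        cnt[rg] <- cnt[rg] + ci
        per_image[[length(per_image) + 1L]] <- data.frame(
          condition = cond, experiment_id = a$experiment_id,
          image_index = a$image_index, region = rg, count = ci,
          volume_um3 = vi,
          density = if (vi > 0) ci / vi else NA_real_)
      }
    }
    if (all(vol == 0)) stop("zero pooled volume for condition ", cond)
    dens <- ifelse(vol > 0, cnt / vol, NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, region = intracell, n_images = length(anns),
      area_um2 = as.numeric(area), volume_um3 = as.numeric(vol),
      count = as.integer(cnt), density = as.numeric(dens),
      fold_enrichment = if (!is.na(dens[["cytoplasm"]]) &&
                            dens[["cytoplasm"]] > 0)
        dens[["coat"]] / dens[["cytoplasm"]] else NA_real_)
  }
  list(table = do.call(rbind, rows), per_image = do.call(rbind, per_image))
}

#' Compare per-image densities across groups
#'
#' One-way ANOVA across groups with Tukey HSD post-hoc pairwise comparisons,
#' as used for scatter-dot density comparisons between conditions and
#' compartments.
#'
#' @param densities data.frame with a numeric value column and a grouping
#'   column.
#' @param value,group Column names.
#' @return List with `omnibus_p`, the fitted `aov` and a data.frame of
#'   pairwise Tukey-adjusted p-values.
#' @export
compare_conditions <- function(densities, value = "density",
                               group = "group") {
  y <- densities[[value]]; g <- factor(densities[[group]])
  ok <- !is.na(y)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  ns <- table(g)
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  fit <- stats::aov(y ~ g)
  omnibus_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(comparison = rownames(tk),
                         diff = tk[, "diff"], p_adj = tk[, "p adj"],
                         row.names = NULL)
  list(omnibus_p = omnibus_p, fit = fit, pairwise = pairwise)
}
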