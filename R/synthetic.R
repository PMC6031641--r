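# Synthetic annotated scenes and two-channel kinetics stacks with known
# ground truth. Annotations (not pixels) are the contract for the EM stages.

# Random membrane profile spanning the frame: a horizontal polyline at a
# random depth with n_pits coated-pit invaginations. Each pit is a
# semicircular crown (radius pit_radius_nm, flagged as coated) joined
# smoothly to the flat membrane by tangent-continuous shoulder fillets of
# radius shoulder_nm (uncoated neck). The fillet radius is kept at or above
# the maximum tag length so a tag displaced along the local crown normal is
# always nearest its own anchor. The depth range spans whole grid-row
# periods and pits are placed by uniform dart throwing, so membrane features
# sit at uniformly distributed offsets relative to any deterministic overlay
# grid (as in real micrographs, where framing is arbitrary).
.random_membrane <- function(frame, n_pits = 4, pit_radius_nm = 50,
                             shoulder_nm = 25,
                             y_frac_range = c(0.2, 0.8), n_arc = 16L,
                             x_period_nm = NULL) {
  w <- frame_width_nm(frame); h <- frame_height_nm(frame)
  r <- pit_radius_nm; rs <- shoulder_nm
  y0 <- stats::runif(1L, y_frac_range[1L], y_frac_range[2L]) * h
  half <- r + rs
  margin <- half + 25
  n_pits <- as.integer(n_pits)
  sep <- 2 * half + 10
  # with x_period_nm set, pits live on a circular domain spanning a whole
  # number of periods: a stationary hard-core process, exactly uniform
  # modulo the period (removes any beat between pit positions and a
  # deterministic overlay grid of that period)
  span <- w - 2 * margin
  Lx <- if (is.null(x_period_nm)) span
        else max(1, floor(span / x_period_nm)) * x_period_nm
  centers <- numeric(0)
  tries <- 0L
  while (length(centers) < n_pits && tries < 500L) {
    cand <- stats::runif(1L, margin, margin + Lx)
    d <- abs(centers - cand)
    if (!is.null(x_period_nm)) d <- pmin(d, Lx - d)
    if (!length(centers) || min(d) >= sep)
      centers <- c(centers, cand)
    tries <- tries + 1L
  }
  centers <- sort(centers)
  .membrane_with_pits(0, w, y0, centers, r, rs, n_arc)
}

# Build a pit-bearing membrane polyline from x_start to x_end at depth y0,
# with semicircular crowns (radius r, coated) at the given centers joined
# by shoulder fillets (radius rs, uncoated). Cytoplasm on the left.
.membrane_with_pits <- function(x_start, x_end, y0, centers, r, rs,
                                n_arc = 16L) {
  half <- r + rs
  n_pits <- length(centers)
  # shoulders are concave from the cytoplasmic side, so chords cut inside
  # the smooth fillet by d*(1 - cos(turn)); 24 chords per quarter turn keep
  # that below 0.04 nm for the longest tags
  n_sh <- 24L
  verts <- matrix(c(x_start, y0), ncol = 2L)
  crown_idx <- matrix(0L, nrow = n_pits, ncol = 2L)
  for (k in seq_len(n_pits)) {
    xc <- centers[k]
    # left shoulder: quarter turn from the flank down to a vertical tangent
    phi <- seq(-pi / 2, 0, length.out = n_sh + 1L)
    sh_l <- cbind(xc - half + rs * cos(phi), y0 + rs + rs * sin(phi))
    verts <- rbind(verts, sh_l)
    crown_idx[k, 1L] <- nrow(verts)
    # crown: half turn through the pit bottom
    t <- seq(pi, 2 * pi, length.out = n_arc + 1L)
    crown <- cbind(xc + r * cos(t), y0 + rs - r * sin(t))
    verts <- rbind(verts, crown[-1L, , drop = FALSE])
    crown_idx[k, 2L] <- nrow(verts)
    # right shoulder, mirror of the left
    phi <- seq(pi, 3 * pi / 2, length.out = n_sh + 1L)
    sh_r <- cbind(xc + half + rs * cos(phi), y0 + rs + rs * sin(phi))
    verts <- rbind(verts, sh_r[-1L, , drop = FALSE])
  }
  verts <- rbind(verts, c(x_end, y0))
  cum <- c(0, cumsum(sqrt(rowSums(diff(verts)^2))))
  coat <- if (n_pits > 0)
    cbind(cum[crown_idx[, 1L]], cum[crown_idx[, 2L]]) else NULL
  membrane_contour(verts, coat_intervals = coat,
                   pit_marks = if (n_pits > 0) coat[1L, ],
                   side_convention = "left")
}

# Rejection-sample n points uniformly over the union of the given regions.
.sample_region_points <- function(annotation, n, regions, zone_nm = 50,
                                  max_tries = 60L) {
  w <- frame_width_nm(annotation$frame); h <- frame_height_nm(annotation$frame)
  got <- matrix(numeric(0), ncol = 2L)
  batch <- max(4L * n, 256L)
  for (it in seq_len(max_tries)) {
    if (nrow(got) >= n) break
    px <- stats::runif(batch, 0, w); py <- stats::runif(batch, 0, h)
    lab <- .classify_points(annotation, px, py, zone_nm)
    keep <- lab %in% regions
    got <- rbind(got, cbind(px[keep], py[keep]))
    acc <- max(mean(keep), 1e-3)
    batch <- as.integer(min(2e5, max(256, 1.5 * (n - nrow(got)) / acc)))
  }
  if (nrow(got) < n)
    stop("could not place points in region(s) ", paste(regions, collapse = ","),
         " (region may have zero area)")
  got[seq_len(n), , drop = FALSE]
}

#' Configuration of a synthetic annotated scene
#'
#' Defaults reproduce the measured labeling regime of ferritin-tagged
#' clathrin: cytoplasmic density 72.5 and coated-zone density 1308.6
#' particles per um^3, with semicircular coated pits of 50 nm radius (100 nm
#' diameter) on a membrane profile spanning the frame.
#'
#' @param frame An [image_frame()]; default 400 x 400 px at 3 nm/px, 70 nm
#'   sections.
#' @param cytoplasm_density,membrane_density,coat_density Volumetric particle
#'   densities (particles/um^3) for the cytoplasm, uncoated membrane-proximal
#'   and coated membrane-proximal regions.
#' @param n_pits Number of coated-pit invaginations.
#' @param pit_radius_nm Pit radius (nm).
#' @param tag_model_pit,tag_model_distal [tag_geometry_model()]s used to draw
#'   membrane-anchored tag displacements at pits (extended conformation,
#'   longer) and on uncoated membrane (kinked conformation, shorter).
#' @param anchored_rate_pit,anchored_rate_distal Anchor rates for
#'   membrane-attached tags, per nm of coated / uncoated arc length.
#' @param zone_nm Membrane-proximal zone width (nm).
#' @param grid_nm Quadrature spacing for region areas.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(frame = image_frame(400, 400, 3),
                         cytoplasm_density = 72.5,
                         membrane_density = 100,
                         coat_density = 1308.6,
                         n_pits = 4, pit_radius_nm = 50,
                         tag_model_pit = tag_geometry_model(
                           length_min_nm = 18, length_max_nm = 18,
                           cone_half_angle_deg = 25),
                         tag_model_distal = tag_geometry_model(
                           length_min_nm = 7.5, length_max_nm = 7.5,
                           cone_half_angle_deg = 25),
                         anchored_rate_pit = 0,
                         anchored_rate_distal = 0,
                         zone_nm = 50, grid_nm = 4) {
  if (any(c(cytoplasm_density, membrane_density, coat_density) < 0))
    stop("densities must be non-negative")
  if (pit_radius_nm <= 0) stop("pit_radius_nm must be positive")
  structure(list(frame = frame, cytoplasm_density = cytoplasm_density,
                 membrane_density = membrane_density,
                 coat_density = coat_density, n_pits = n_pits,
                 pit_radius_nm = pit_radius_nm,
                 tag_model_pit = tag_model_pit,
                 tag_model_distal = tag_model_distal,
                 anchored_rate_pit = anchored_rate_pit,
                 anchored_rate_distal = anchored_rate_distal,
                 zone_nm = zone_nm, grid_nm = grid_nm),
            class = "scene_config")
}

# Complement of the coat intervals within [0, total].
.uncoated_intervals <- function(contour) {
  total <- arc_length(contour)
  iv <- contour$coat_intervals
  if (is.null(iv) || !nrow(iv)) return(matrix(c(0, total), ncol = 2L))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  starts <- c(0, iv[, 2L]); ends <- c(iv[, 1L], total)
  keep <- ends > starts
  cbind(starts[keep], ends[keep])
}

.sample_in_intervals <- function(iv, n) {
  len <- iv[, 2L] - iv[, 1L]
  if (sum(len) <= 0 || n == 0L) return(numeric(0))
  k <- sample.int(nrow(iv), n, replace = TRUE, prob = len)
  stats::runif(n, iv[k, 1L], iv[k, 2L])
}

#' Generate a synthetic annotated micrograph with ground truth
#'
#' Builds a membrane profile with coated-pit invaginations, places volumetric
#' particles per region with Poisson counts (mean = density x region volume,
#' volume = area x section thickness; placement uniform in area) and places
#' membrane-anchored tag particles at anchor points drawn along coated /
#' uncoated arcs, displaced toward the cytoplasmic side by a draw from the
#' corresponding tag-geometry model.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; a fixed seed gives an identical scene.
#' @param condition,experiment_id,image_index Labels for the annotation.
#' @return List with `$annotation` ([micrograph_annotation()]) and `$truth`
#'   (data.frame: one row per particle with `region_true`, `anchored`,
#'   `anchor_arc`, `tag_length`, `detected_distance`, `conformation`).
#' @export
generate_scene <- function(config = scene_config(), seed = 1,
                           condition = "rapamycin", experiment_id = "sim1",
                           image_index = 0L) {
  set.seed(seed)
  frame <- config$frame
  ct <- .random_membrane(frame, n_pits = config$n_pits,
                         pit_radius_nm = config$pit_radius_nm)
  ann <- micrograph_annotation(frame, list(ct), condition = condition,
                               experiment_id = experiment_id,
                               image_index = image_index)
  dens <- c(cytoplasm = config$cytoplasm_density,
            membrane = config$membrane_density,
            coat = config$coat_density)
  pts <- list(); truth <- list()
  if (any(dens > 0)) {
    g <- region_geometry(ann, zone_nm = config$zone_nm,
                         grid_nm = config$grid_nm)
    vol <- stats::setNames(rep(0, 3L), names(dens))
    hit <- match(names(dens), as.character(g$region))
    vol[!is.na(hit)] <- g$volume_um3[hit[!is.na(hit)]]
    mu <- dens * vol
    if (sum(mu) > 1e6)
      stop("configured densities imply > 1e6 particles per image; ",
           "reduce densities or frame size")
    for (rg in names(dens)) {
      n <- stats::rpois(1L, mu[[rg]])
      if (!n) next
      p <- .sample_region_points(ann, n, rg, zone_nm = config$zone_nm)
      pts[[length(pts) + 1L]] <- p
      truth[[length(truth) + 1L]] <- data.frame(
        region_true = rg, anchored = FALSE, anchor_arc = NA_real_,
        tag_length = NA_real_, detected_distance = NA_real_,
        conformation = NA_character_, count = n)[rep(1L, n), ]
    }
  }
  # membrane-anchored tags
  coat_iv <- ct$coat_intervals
  unc_iv <- .uncoated_intervals(ct)
  place_anchored <- function(iv, rate, model, region_true, conformation) {
    arc_total <- if (is.null(iv)) 0 else sum(iv[, 2L] - iv[, 1L])
    n <- if (arc_total > 0 && rate > 0) stats::rpois(1L, rate * arc_total) else 0L
    if (!n) return(NULL)
    s <- .sample_in_intervals(iv, n)
    draw <- .rtag_draw(model, n)
    base <- .point_at_arc(ct, s)
    nrm <- .normal_at_arc(ct, s)
    p <- base + draw$distance * nrm
    pts[[length(pts) + 1L]] <<- p
    truth[[length(truth) + 1L]] <<- data.frame(
      region_true = region_true, anchored = TRUE, anchor_arc = s,
      tag_length = draw$length, detected_distance = draw$distance,
      conformation = conformation, count = n)
    invisible(NULL)
  }
  place_anchored(coat_iv, config$anchored_rate_pit, config$tag_model_pit,
                 "coat", "extended")
  place_anchored(unc_iv, config$anchored_rate_distal, config$tag_model_distal,
                 "membrane", "kinked")
  particles <- if (length(pts)) {
    m <- do.call(rbind, pts)
    data.frame(x = pmin(pmax(m[, 1L], 0), frame_width_nm(frame)),
               y = pmin(pmax(m[, 2L], 0), frame_height_nm(frame)),
               diameter_nm = 7)
  } else NULL
  ann$particles <- if (is.null(particles))
    data.frame(x = numeric(0), y = numeric(0), diameter_nm = numeric(0))
  else particles
  truth <- if (length(truth)) {
    tr <- do.call(rbind, truth)
    tr$count <- NULL
    rownames(tr) <- NULL
    tr
  } else data.frame(region_true = character(0), anchored = logical(0),
                    anchor_arc = numeric(0), tag_length = numeric(0),
                    detected_distance = numeric(0),
                    conformation = character(0))
  list(annotation = ann, truth = truth)
}

#' Write a synthetic scene to disk
#'
#' Point file (model2point dialect), key-value metadata and ground-truth CSV.
#'
#' @param scene Output of [generate_scene()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the written paths.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, paste0(stem, ".pts"))
  mp <- file.path(dir, paste0(stem, ".meta"))
  tp <- file.path(dir, paste0(stem, "_truth.csv"))
  write_point_file(scene$annotation, pp)
  write_image_metadata(scene$annotation, mp)
  utils::write.csv(scene$truth, tp, row.names = FALSE)
  invisible(c(points = pp, metadata = mp, truth = tp))
}

#' Generate a synthetic two-channel kinetics stack
#'
#' Channel 1 (reference, GFP-like) carries persistent Gaussian spots over a
#' non-zero background; channel 2 (tag, mCherry-like) steps from baseline to
#' baseline + amplitude at the stimulus onset at the same spots, with
#' additive Gaussian noise in both channels. The channel-2 spot gain is drawn
#' from a diffuse pool (total channel-2 intensity is conserved across the
#' onset), mimicking recruitment rather than creation of signal.
#'
#' @param n_frames Number of timepoints.
#' @param n_spots Number of spots.
#' @param onset_frame Stimulus onset (first responding frame).
#' @param response_amplitude True background-subtracted channel ratio at the
#'   spots after onset (channel-2 spot amplitude = this x channel-1 spot
#'   amplitude, so shared spot shape cancels in the ratio).
#' @param noise_sd Additive Gaussian noise SD (both channels).
#' @param dim Frame side length in pixels; the default 256 px with 8 spots
#'   gives a spot coverage of about 1 percent of the frame, as in live-cell
#'   images where diffraction-limited spots are sparse on the cell area.
#' @param spot_sigma_px,spot_amp1,bg1,bg2 Spot width, channel-1 spot
#'   amplitude and channel baselines.
#' @param seed Integer seed.
#' @return List with `ch1`, `ch2` (dim x dim x n_frames arrays) and `truth`
#'   (spot centres, amplitude, onset frame).
#' @export
generate_kinetics_stack <- function(n_frames = 30, n_spots = 8,
                                    onset_frame = 10,
                                    response_amplitude = 0.4, noise_sd = 2,
                                    dim = 256, spot_sigma_px = 2,
                                    spot_amp1 = 50, bg1 = 10, bg2 = 8,
                                    seed = 1) {
  if (onset_frame < 1 || onset_frame > n_frames)
    stop("onset_frame must lie within the stack")
  if (response_amplitude < 0) stop("response_amplitude must be >= 0")
  set.seed(seed)
  sep <- 6 * spot_sigma_px
  if (n_spots * (sep + 2)^2 > dim^2)
    stop("spot count exceeds frame capacity")
  margin <- 3 * spot_sigma_px + 1
  centers <- matrix(numeric(0), ncol = 2L)
  tries <- 0L
  while (nrow(centers) < n_spots) {
    cand <- stats::runif(2L, margin, dim - margin)
    if (!nrow(centers) ||
        min(sqrt(rowSums(sweep(centers, 2L, cand)^2))) >= sep)
      centers <- rbind(centers, cand)
    tries <- tries + 1L
    if (tries > 10000L) stop("spot count exceeds frame capacity")
  }
  xs <- seq_len(dim)
  spot_img <- matrix(0, dim, dim)
  for (k in seq_len(n_spots)) {
    gx <- exp(-(xs - centers[k, 1L])^2 / (2 * spot_sigma_px^2))
    gy <- exp(-(xs - centers[k, 2L])^2 / (2 * spot_sigma_px^2))
    spot_img <- spot_img + outer(gx, gy)
  }
  amp2 <- response_amplitude * spot_amp1
  pool_drain <- amp2 * sum(spot_img) / dim^2  # conserved channel-2 total
  ch1 <- array(0, c(dim, dim, n_frames))
  ch2 <- array(0, c(dim, dim, n_frames))
  for (t in seq_len(n_frames)) {
    on <- t >= onset_frame
    ch1[, , t] <- bg1 + spot_amp1 * spot_img +
      stats::rnorm(dim^2, sd = noise_sd)
    ch2[, , t] <- (bg2 - if (on) pool_drain else 0) +
      (if (on) amp2 else 0) * spot_img +
      stats::rnorm(dim^2, sd = noise_sd)
  }
  list(ch1 = ch1, ch2 = ch2,
       truth = list(spots = data.frame(x = centers[, 1L], y = centers[, 2L]),
                    amplitude = response_amplitude,
                    onset_frame = onset_frame, n_frames = n_frames,
                    bg1 = bg1, bg2 = bg2))
}
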