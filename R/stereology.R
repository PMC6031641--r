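# Relative labeling intensity (RLI) stereology: grid-point expectation,
# expected-count scaling and Yates-corrected chi-squared testing.
# Following the point-counting approach of Mayhew & Lucocq for immuno-EM.

#' Interior test points of the stereology grid
#'
#' An `n_vertical` x `n_horizontal` line grid is overlaid on the image with
#' its outer lines on the image perimeter; the interior intersections (by
#' default (8-2) x (6-2) = 24 points) are the test points.
#'
#' @param frame An [image_frame()].
#' @param n_vertical,n_horizontal Number of vertical / horizontal grid lines.
#' @return m x 2 matrix of (x, y) points in nm.
#' @examples
#' f <- image_frame(700, 500, nm_per_px = 1)
#' grid_points(f)  # x in 100..600, y in 100..400, 24 points
#' @export
grid_points <- function(frame, n_vertical = 8, n_horizontal = 6) {
  w <- frame_width_nm(frame); h <- frame_height_nm(frame)
  xs <- (seq_len(n_vertical - 2L)) * w / (n_vertical - 1L)
  ys <- (seq_len(n_horizontal - 2L)) * h / (n_horizontal - 1L)
  cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
}

#' Grid-point compartment fractions
#'
#' Classifies every interior grid point of every image with the same rule as
#' [classify_particles()] and pools the tallies over images. Fractions sum to
#' 1 over all four compartments (including extracellular).
#'
#' @param annotations List of [micrograph_annotation()] objects.
#' @param zone_nm Membrane-proximal zone width (nm).
#' @param n_vertical,n_horizontal Grid line counts.
#' @return List with `counts` (named integer vector over [REGIONS]),
#'   `fractions` and `n_points`.
#' @export
point_compartment_fractions <- function(annotations, zone_nm = 50,
                                        n_vertical = 8, n_horizontal = 6) {
  if (inherits(annotations, "micrograph_annotation"))
    annotations <- list(annotations)
  cnt <- stats::setNames(rep(0L, length(REGIONS)), REGIONS)
  for (a in annotations) {
    gp <- grid_points(a$frame, n_vertical, n_horizontal)
    tb <- table(classify_particles(a, particles = gp, zone_nm = zone_nm))
    cnt[names(tb)] <- cnt[names(tb)] + as.integer(tb)
  }
  n <- sum(cnt)
  list(counts = cnt, fractions = cnt / n, n_points = n)
}

#' Expected particle counts from grid-point fractions
#'
#' Grid-point fractions over the intracellular compartments (cytoplasm,
#' membrane, coat; extracellular points are dropped and the fractions
#' renormalized) are scaled to the total number of observed particles, so the
#' expected counts sum exactly to the observed total.
#'
#' @param fractions Named fractions (or the list from
#'   [point_compartment_fractions()]).
#' @param total_observed Total observed particle count.
#' @return Named numeric vector of expected counts for cytoplasm, membrane
#'   and coat.
#' @export
expected_counts <- function(fractions, total_observed) {
  if (is.list(fractions)) fractions <- fractions$fractions
  intracell <- c("cytoplasm", "membrane", "coat")
  f <- fractions[intracell]
  if (total_observed == 0) return(stats::setNames(rep(0, 3L), intracell))
  s <- sum(f)
  if (s <= 0) stop("no intracellular grid points")
  stats::setNames(as.numeric(f) / s * total_observed, intracell)
}

#' Yates-corrected chi-squared statistic for a 2 x 2 table
#'
#' Pearson's chi-squared with Yates' continuity correction:
#' \eqn{\chi^2 = \sum (\max(|O - E| - 0.5, 0))^2 / E}, with expectations from
#' the row/column margins. df = 1.
#'
#' @param tab 2 x 2 numeric matrix (all cells >= 0).
#' @return The statistic (a single number).
#' @export
yates_chi2_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  if (any(tab < 0)) stop("cells must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0)) stop("degenerate margin: row ", which(rs == 0)[1L],
                         " sums to zero")
  if (any(cs == 0)) stop("degenerate margin: column ", which(cs == 0)[1L],
                         " sums to zero")
  e <- outer(rs, cs) / n
  sum(pmax(abs(tab - e) - 0.5, 0)^2 / e)
}

#' Upper-tail chi-squared probability, df = 1
#'
#' @param x Statistic value(s), >= 0.
#' @return p = P(X >= x) for X ~ chi-squared(1).
#' @examples
#' chi2_sf_df1(0)       # 1
#' chi2_sf_df1(38.531)  # ~5.39e-10
#' @export
chi2_sf_df1 <- function(x) {
  if (any(x < 0)) stop("x must be non-negative")
  stats::pchisq(x, df = 1, lower.tail = FALSE)
}

#' Relative labeling intensity report for one experiment
#'
#' RLI per compartment is observed / expected (NA when expected is 0). The
#' chi-squared test is on the 2 x 2 {observed, expected} x {cytoplasm, coat}
#' table with Yates correction, df = 1.
#'
#' @param tally One-row data.frame from [region_tally()], or a named vector
#'   of observed counts (`cytoplasm`, `membrane`, `coat`).
#' @param fractions Output of [point_compartment_fractions()] (or named
#'   fractions vector).
#' @return List with `observed`, `expected`, `rli`, `chi2`, `df`, `p_value`.
#' @export
rli_report <- function(tally, fractions) {
  intracell <- c("cytoplasm", "membrane", "coat")
  obs <- if (is.data.frame(tally))
    stats::setNames(as.numeric(tally[1L, intracell]), intracell)
  else as.numeric(tally[intracell]) |> stats::setNames(intracell)
  exp <- expected_counts(fractions, sum(obs))
  rli <- ifelse(exp > 0, obs / exp, NA_real_)
  names(rli) <- intracell
  tab <- rbind(observed = c(obs[["cytoplasm"]], obs[["coat"]]),
               expected = c(exp[["cytoplasm"]], exp[["coat"]]))
  chi2 <- yates_chi2_2x2(tab)
  list(observed = obs, expected = exp, rli = rli, chi2 = chi2, df = 1L,
       p_value = chi2_sf_df1(chi2))
}

#' Labeling-table report across experiments
#'
#' One row per experiment: image count, observed counts per compartment,
#' expected (grid-scaled) counts, the Yates chi-squared (cytoplasm vs coat)
#' and its p-value.
#'
#' @param annotations List of [micrograph_annotation()] objects spanning one
#'   or more experiments (grouped by `experiment_id`).
#' @param zone_nm Membrane-proximal zone width (nm).
#' @return data.frame shaped like a labeling-distribution table.
#' @export
stereology_table <- function(annotations, zone_nm = 50) {
  if (inherits(annotations, "micrograph_annotation"))
    annotations <- list(annotations)
  ids <- vapply(annotations, function(a) a$experiment_id, "")
  out <- lapply(unique(ids), function(id) {
    anns <- annotations[ids == id]
    tl <- region_tally(anns, zone_nm = zone_nm)
    fr <- point_compartment_fractions(anns, zone_nm = zone_nm)
    rep_ <- rli_report(tl, fr)
    data.frame(experiment_id = id,
               condition = anns[[1L]]$condition,
               n_images = length(anns),
               obs_cyto = rep_$observed[["cytoplasm"]],
               obs_mem = rep_$observed[["membrane"]],
               obs_coat = rep_$observed[["coat"]],
               obs_total = sum(rep_$observed),
               exp_cyto = rep_$expected[["cytoplasm"]],
               exp_mem = rep_$expected[["membrane"]],
               exp_coat = rep_$expected[["coat"]],
               exp_total = sum(rep_$expected),
               rli_cyto = rep_$rli[["cytoplasm"]],
               rli_mem = rep_$rli[["membrane"]],
               rli_coat = rep_$rli[["coat"]],
               chi2 = rep_$chi2, p_value = rep_$p_value)
  })
  do.call(rbind, out)
}

#' Null-calibration simulation of the RLI test
#'
#' Simulates experiments in which particles are placed uniformly over the
#' intracellular area of randomly generated membrane scenes (the same spatial
#' law that the grid points sample), then runs the full observed-vs-expected
#' pipeline on each. Used to check the type-I error of the Yates test and
#' that RLI is centred on 1 under the null.
#'
#' Scenes are thin cell profiles (lamellae) fully contained in the frame: a
#' pit-bearing plasma membrane at a random depth and a parallel membrane
#' `lamella_nm` deeper, cytoplasm between them and extracellular outside.
#' Keeping the whole intracellular space inside the span covered by the
#' interior grid rows matters: grid points with the outer lines on the
#' perimeter never sample the outermost half-spacing margins of the frame,
#' so a cell extending into those margins would bias the expected fractions.
#'
#' @param n_experiments Number of simulated experiments.
#' @param n_images Micrographs per experiment.
#' @param mean_total Poisson mean of the total particle count per experiment.
#' @param frame Shared [image_frame()] (default 500 x 500 px at 3 nm/px).
#' @param n_pits Poisson mean of coated pits per image.
#' @param pit_radius_nm Pit radius.
#' @param lamella_nm Cytoplasm thickness between the two membranes.
#' @param zone_nm Membrane-proximal zone width (nm).
#' @param seed Integer seed.
#' @return data.frame with one row per experiment: chi2, p_value, RLI per
#'   compartment, and the observed / expected counts behind them (for pooled
#'   ratio estimation across replicates).
#' @export
simulate_rli_null <- function(n_experiments, n_images = 20, mean_total = 80,
                              frame = image_frame(500, 500, 3),
                              n_pits = 6, pit_radius_nm = 50,
                              lamella_nm = 600, zone_nm = 50,
                              seed = 1) {
  set.seed(seed)
  h <- frame_height_nm(frame)
  # membrane depth uniform over whole grid-row periods, with the lamella and
  # its pits inside the rows' covered span
  row_sp <- h / 5
  y_lo <- row_sp / 2 + zone_nm
  y_hi <- y_lo + row_sp
  if (y_hi + lamella_nm > h - row_sp / 2 - zone_nm)
    stop("lamella does not fit inside the grid-covered span")
  res <- vector("list", n_experiments)
  for (e in seq_len(n_experiments)) {
    anns <- vector("list", n_images)
    w <- frame_width_nm(frame)
    rs <- 25; half <- pit_radius_nm + rs
    for (i in seq_len(n_images)) {
      y0 <- stats::runif(1L, y_lo, y_hi)
      # pits on a circular (wrap-around) domain of the full frame width:
      # an x-stationary hard-core process, so pits can sit anywhere in the
      # frame (including cut by its edge) exactly as in real micrographs
      n_p <- stats::rpois(1L, n_pits)
      centers <- numeric(0); tries <- 0L
      while (length(centers) < n_p && tries < 500L) {
        cand <- stats::runif(1L, 0, w)
        d <- abs(centers - cand); d <- pmin(d, w - d)
        if (!length(centers) || min(d) >= 2 * half + 10)
          centers <- c(centers, cand)
        tries <- tries + 1L
      }
      ext <- 2 * half + 100
      reps <- c(centers,
                centers[centers >= w - ext] - w,
                centers[centers <= ext] + w)
      reps <- sort(reps[reps > -ext - half & reps < w + ext + half])
      ct <- .membrane_with_pits(-ext - 2 * half, w + ext + 2 * half, y0,
                                reps, pit_radius_nm, rs)
      yb <- y0 + lamella_nm
      ct_bot <- membrane_contour(rbind(c(-ext, yb), c(w + ext, yb)),
                                 side_convention = "right")
      anns[[i]] <- micrograph_annotation(frame, list(ct, ct_bot),
                                         experiment_id = "null",
                                         image_index = i)
    }
    n_total <- stats::rpois(1L, mean_total)
    # place particles uniformly over the pooled intracellular area:
    # propose (image, point-in-frame) pairs and accept intracellular hits,
    # so images contribute in proportion to their intracellular area
    w <- frame_width_nm(frame); h <- frame_height_nm(frame)
    placed <- 0L
    while (placed < n_total) {
      m <- max(256L, 3L * (n_total - placed))
      img <- sample.int(n_images, m, replace = TRUE)
      px <- stats::runif(m, 0, w); py <- stats::runif(m, 0, h)
      for (i in unique(img)) {
        wi <- which(img == i)
        lab <- .classify_points(anns[[i]], px[wi], py[wi], zone_nm)
        keep <- wi[lab != "extracellular"]
        if (placed >= n_total || !length(keep)) next
        keep <- keep[seq_len(min(length(keep), n_total - placed))]
        anns[[i]]$particles <- rbind(
          anns[[i]]$particles,
          data.frame(x = px[keep], y = py[keep], diameter_nm = 7))
        placed <- placed + length(keep)
      }
    }
    tl <- region_tally(anns, zone_nm = zone_nm)
    fr <- point_compartment_fractions(anns, zone_nm = zone_nm)
    rp <- rli_report(tl, fr)
    res[[e]] <- data.frame(chi2 = rp$chi2, p_value = rp$p_value,
                           rli_cyto = rp$rli[["cytoplasm"]],
                           rli_mem = rp$rli[["membrane"]],
                           rli_coat = rp$rli[["coat"]],
                           obs_cyto = rp$observed[["cytoplasm"]],
                           obs_mem = rp$observed[["membrane"]],
                           obs_coat = rp$observed[["coat"]],
                           exp_cyto = rp$expected[["cytoplasm"]],
                           exp_mem = rp$expected[["membrane"]],
                           exp_coat = rp$expected[["coat"]],
                           total = sum(rp$observed))
  }
  do.call(rbind, res)
}
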