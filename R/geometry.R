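# Planar geometry kernel: arc length, closest approach and sidedness for
# open polylines (segmented membrane profiles). All coordinates in nm.

# Precompute per-segment quantities for a vertex matrix (n x 2).
.seg_table <- function(v) {
  n <- nrow(v)
  if (n < 2L) stop("contour needs at least 2 vertices")
  ax <- v[-n, 1L]; ay <- v[-n, 2L]
  dx <- v[-1L, 1L] - ax; dy <- v[-1L, 2L] - ay
  len <- sqrt(dx^2 + dy^2)
  if (all(len == 0)) stop("degenerate contour: all vertices identical")
  list(ax = ax, ay = ay, dx = dx, dy = dy, len = len, len2 = len^2,
       cum0 = c(0, cumsum(len))[seq_len(n - 1L)], total = sum(len))
}

#' Arc length along a membrane contour
#'
#' Total polyline length, or the cumulative arc length up to a vertex index.
#' Also validates that an arc position lies on the contour.
#'
#' @param contour A [membrane_contour()].
#' @param to Optional. Either an integer vertex index (cumulative length up to
#'   that vertex) or, with `position = TRUE`, an arc-length position to
#'   validate and return.
#' @param position Interpret `to` as an arc-length position rather than a
#'   vertex index.
#' @return Length in nm.
#' @examples
#' sq <- membrane_contour(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
#' arc_length(sq)          # 30
#' arc_length(sq, to = 2)  # 10
#' @export
arc_length <- function(contour, to = NULL, position = FALSE) {
  v <- contour_vertices(contour)
  st <- .seg_table(v)
  if (is.null(to)) return(st$total)
  if (position) {
    if (to < 0 || to > st$total)
      stop(sprintf("arc position %g outside [0, %g]", to, st$total))
    return(to)
  }
  to <- as.integer(to)
  if (to < 1L || to > nrow(v)) stop("vertex index out of range")
  c(0, cumsum(st$len))[to]
}

# Point on the contour at arc position s (vectorised over s).
.point_at_arc <- function(contour, s) {
  v <- contour_vertices(contour)
  st <- .seg_table(v)
  s <- pmin(pmax(s, 0), st$total)
  brk <- c(st$cum0, st$total)
  i <- findInterval(s, brk, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(st$ax))
  t <- ifelse(st$len[i] > 0, (s - st$cum0[i]) / st$len[i], 0)
  cbind(st$ax[i] + t * st$dx[i], st$ay[i] + t * st$dy[i])
}

# Unit normal pointing toward the cytoplasmic side at arc position s.
.normal_at_arc <- function(contour, s) {
  v <- contour_vertices(contour)
  st <- .seg_table(v)
  s <- pmin(pmax(s, 0), st$total)
  brk <- c(st$cum0, st$total)
  i <- findInterval(s, brk, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(st$ax))
  nx <- -st$dy[i] / st$len[i]
  ny <- st$dx[i] / st$len[i]
  # (-dy, dx) is the positive-cross-product ("left") side; flip if needed
  if (identical(attr_side(contour), "right")) { nx <- -nx; ny <- -ny }
  cbind(nx, ny)
}

attr_side <- function(contour) {
  sc <- contour$side_convention
  if (is.null(sc)) "left" else sc
}

# Vectorised closest approach of many points to one polyline.
# Returns data.frame(dist, arc, side) where side is the sign of the cross
# product of the winning segment direction with the point offset
# (+1 = "left" side, -1 = "right", 0 = on the membrane).
.closest_to_polyline <- function(px, py, v, chunk = 20000L) {
  st <- .seg_table(v)
  n <- length(px)
  out_d <- numeric(n); out_a <- numeric(n); out_s <- numeric(n)
  if (n == 0L) return(data.frame(dist = out_d, arc = out_a, side = out_s))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    x <- px[lo:hi]; y <- py[lo:hi]
    # matrices: points in rows, segments in columns
    rx <- outer(x, st$ax, "-")
    ry <- outer(y, st$ay, "-")
    tt <- sweep(rx, 2L, st$dx, "*") + sweep(ry, 2L, st$dy, "*")
    tt <- sweep(tt, 2L, pmax(st$len2, .Machine$double.eps), "/")
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    fx <- rx - sweep(tt, 2L, st$dx, "*")
    fy <- ry - sweep(tt, 2L, st$dy, "*")
    d2 <- fx^2 + fy^2
    j <- max.col(-d2, ties.method = "first")
    ij <- cbind(seq_along(x), j)
    out_d[lo:hi] <- sqrt(d2[ij])
    out_a[lo:hi] <- st$cum0[j] + tt[ij] * st$len[j]
    cross <- st$dx[j] * ry[ij] - st$dy[j] * rx[ij]
    out_s[lo:hi] <- sign(cross)
  }
  data.frame(dist = out_d, arc = out_a, side = out_s)
}

# Closest approach of many points to a list of contours; returns the winning
# contour index as well. side is reported as cytoplasmic (+1) / extracellular
# (-1) / on-membrane (0) after applying each contour's side convention.
.closest_to_contours <- function(px, py, contours, chunk = 20000L) {
  stopifnot(length(contours) >= 1L)
  best <- NULL
  for (k in seq_along(contours)) {
    ck <- contours[[k]]
    r <- .closest_to_polyline(px, py, contour_vertices(ck), chunk = chunk)
    if (identical(attr_side(ck), "right")) r$side <- -r$side
    r$contour <- rep(k, nrow(r))
    if (is.null(best)) best <- r else {
      w <- r$dist < best$dist
      best[w, ] <- r[w, ]
    }
  }
  best$side[best$dist == 0] <- 0
  best
}

#' Closest approach of a point to a membrane contour
#'
#' Minimum Euclidean distance from a point to a segmented membrane polyline,
#' together with the arc-length position of the nearest membrane point (the
#' "foot") and which side of the membrane the point lies on.
#'
#' @param contour A [membrane_contour()].
#' @param point Numeric length-2 vector (x, y) in nm, or an n x 2 matrix.
#' @return A data.frame with one row per point: `proximity` (nm), `foot_arc`
#'   (nm along the contour) and `side` (`"cytoplasmic"`, `"extracellular"` or
#'   `"on_membrane"`), using the contour's `side_convention`.
#' @examples
#' m <- membrane_contour(rbind(c(0, 0), c(100, 0)))
#' closest_approach(m, c(50, 25))  # proximity 25, cytoplasmic
#' @export
closest_approach <- function(contour, point) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 2L)
  r <- .closest_to_contours(p[, 1L], p[, 2L], list(contour))
  data.frame(
    proximity = r$dist,
    foot_arc = r$arc,
    side = c("extracellular", "on_membrane", "cytoplasmic")[r$side + 2L]
  )
}
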