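# Domain types and coordinate-file I/O for annotated electron micrographs.

#' Physical calibration of one micrograph
#'
#' @param width_px,height_px Image size in pixels (>= 1).
#' @param nm_per_px Pixel size in nm (> 0).
#' @param section_thickness_nm Ultrathin-section thickness in nm; 70 nm is the
#'   conventional serial-section thickness and the default.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(width_px, height_px, nm_per_px,
                        section_thickness_nm = 70) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px < 1L || height_px < 1L) stop("frame must be at least 1 x 1 px")
  if (nm_per_px <= 0) stop("nm_per_px must be positive")
  if (section_thickness_nm <= 0) stop("section_thickness_nm must be positive")
  structure(list(width_px = width_px, height_px = height_px,
                 nm_per_px = nm_per_px,
                 section_thickness_nm = section_thickness_nm),
            class = "image_frame")
}

frame_width_nm <- function(frame) frame$width_px * frame$nm_per_px
frame_height_nm <- function(frame) frame$height_px * frame$nm_per_px

#' A segmented membrane profile
#'
#' An ordered 2-D polyline in nm with optional clathrin-coat intervals and
#' pit marks, both expressed as arc-length positions so they survive
#' resampling of the polyline.
#'
#' @param vertices n x 2 numeric matrix of (x, y) in nm, n >= 2.
#' @param coat_intervals k x 2 matrix of arc-length ranges `[s0, s1]` flagged
#'   as coated; pairwise non-overlapping and within `[0, total length]`.
#' @param pit_marks Optional numeric pair (pit start, pit end) in arc length.
#' @param side_convention `"left"` (default) if the cytoplasm lies on the left
#'   of the directed polyline (positive cross product of segment direction
#'   with point offset), `"right"` to flip.
#' @return An object of class `membrane_contour`.
#' @export
membrane_contour <- function(vertices, coat_intervals = NULL, pit_marks = NULL,
                             side_convention = c("left", "right")) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(vertices) < 2L || ncol(vertices) != 2L)
    stop("vertices must be an n x 2 matrix with n >= 2")
  side_convention <- match.arg(side_convention)
  total <- sum(sqrt(rowSums(diff(vertices)^2)))
  if (!is.null(coat_intervals)) {
    coat_intervals <- matrix(as.numeric(coat_intervals), ncol = 2L)
    if (any(coat_intervals < -1e-9) || any(coat_intervals > total + 1e-9))
      stop("coat intervals must lie within [0, total arc length]")
    if (any(coat_intervals[, 2L] < coat_intervals[, 1L]))
      stop("coat interval end precedes its start")
    o <- order(coat_intervals[, 1L])
    ci <- coat_intervals[o, , drop = FALSE]
    if (nrow(ci) > 1L && any(ci[-1L, 1L] < ci[-nrow(ci), 2L]))
      stop("coat intervals must be pairwise non-overlapping")
  }
  if (!is.null(pit_marks)) {
    pit_marks <- as.numeric(pit_marks)
    if (length(pit_marks) != 2L || pit_marks[1L] >= pit_marks[2L])
      stop("pit_marks must be (start, end) with start < end")
    if (pit_marks[1L] < -1e-9 || pit_marks[2L] > total + 1e-9)
      stop("pit_marks must lie within [0, total arc length]")
  }
  structure(list(vertices = vertices, coat_intervals = coat_intervals,
                 pit_marks = pit_marks, side_convention = side_convention),
            class = "membrane_contour")
}

#' @export
contour_vertices <- function(contour) {
  if (inherits(contour, "membrane_contour")) contour$vertices
  else as.matrix(contour)
}

#' One annotated micrograph
#'
#' @param frame An [image_frame()].
#' @param contours List of [membrane_contour()] objects.
#' @param particles data.frame with columns `x`, `y` (nm) and optionally
#'   `diameter_nm` (default 7, the nominal particle diameter).
#' @param condition,experiment_id Labels (e.g. "control" / "rapamycin").
#' @param image_index Serial-section / image index (from the z column of
#'   point files).
#' @return An object of class `micrograph_annotation`.
#' @export
micrograph_annotation <- function(frame, contours = list(),
                                  particles = NULL,
                                  condition = "unspecified",
                                  experiment_id = "exp1",
                                  image_index = 0L) {
  stopifnot(inherits(frame, "image_frame"))
  if (is.null(particles))
    particles <- data.frame(x = numeric(0), y = numeric(0),
                            diameter_nm = numeric(0))
  if (is.null(particles$diameter_nm))
    particles$diameter_nm <- rep(7, nrow(particles))
  if (any(particles$diameter_nm <= 0)) stop("particle diameter must be > 0")
  w <- frame_width_nm(frame); h <- frame_height_nm(frame)
  if (nrow(particles) &&
      (any(particles$x < 0 | particles$x > w) ||
       any(particles$y < 0 | particles$y > h)))
    stop("particle centers must lie within the frame bounds (nm)")
  structure(list(frame = frame, contours = contours, particles = particles,
                 condition = condition, experiment_id = experiment_id,
                 image_index = as.integer(image_index)),
            class = "micrograph_annotation")
}

#' @export
print.micrograph_annotation <- function(x, ...) {
  cat(sprintf(
    "<micrograph_annotation> %s / %s (z = %d): %d contour(s), %d particle(s), %d x %d px @ %g nm/px\n",
    x$experiment_id, x$condition, x$image_index, length(x$contours),
    nrow(x$particles), x$frame$width_px, x$frame$height_px, x$frame$nm_per_px))
  invisible(x)
}

# ---- point-file dialect ----------------------------------------------------
# Whitespace-separated "object contour x y z" records, one point per line;
# '#' comment lines ignored. Object 1 holds membrane contours, object 2 holds
# particle markers (one point per particle). The z column is the serial
# section / image index; one annotation is returned per distinct z.

MEMBRANE_OBJECT <- 1L
PARTICLE_OBJECT <- 2L

#' Read a model2point-style coordinate file
#'
#' Parses whitespace-delimited records (object id, contour id, x, y, z) into
#' one [micrograph_annotation()] per image (distinct z value). Object id 1
#' carries membrane contours (points grouped by contour id in file order);
#' object id 2 carries particle markers. Pixel coordinates are converted to nm
#' using the frame calibration.
#'
#' @param path File path, or a character vector of lines (via `text`).
#' @param frame An [image_frame()] supplying nm/px; or a list of metadata as
#'   returned by [read_image_metadata()].
#' @param text Optional character vector of lines instead of `path`.
#' @param condition,experiment_id Labels attached to every returned
#'   annotation (overridden by metadata if `frame` is a metadata list).
#' @return A list of `micrograph_annotation` objects, ordered by image index.
#' @export
read_point_file <- function(path = NULL, frame, text = NULL,
                            condition = "unspecified", experiment_id = "exp1") {
  meta <- NULL
  if (!inherits(frame, "image_frame")) {
    meta <- frame
    frame <- meta$frame
    if (!is.null(meta$condition)) condition <- meta$condition
    if (!is.null(meta$experiment_id)) experiment_id <- meta$experiment_id
  }
  lines <- if (is.null(text)) readLines(path) else text
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(list())
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop(sprintf("malformed line %d: expected at least 5 fields, got %d",
                 idx[which(nf < 5L)[1L]], min(nf)))
  m <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(fields, `[`, 1:5))), ncol = 5L,
           byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    stop(sprintf("malformed line %d: non-numeric field", idx[bad]))
  }
  obj <- as.integer(m[, 1L])
  known <- c(MEMBRANE_OBJECT, PARTICLE_OBJECT)
  if (any(!obj %in% known))
    stop(sprintf("unknown object id %d (admissible ids: %s)",
                 obj[which(!obj %in% known)[1L]],
                 paste(known, collapse = ", ")))
  z <- as.integer(round(m[, 5L]))
  px <- frame$nm_per_px
  out <- list()
  for (zi in sort(unique(z))) {
    sel <- z == zi
    contours <- list()
    mrows <- which(sel & obj == MEMBRANE_OBJECT)
    if (length(mrows)) {
      for (cid in unique(m[mrows, 2L])) {
        cr <- mrows[m[mrows, 2L] == cid]
        v <- cbind(m[cr, 3L], m[cr, 4L]) * px
        contours[[length(contours) + 1L]] <- membrane_contour(v)
      }
    }
    prows <- which(sel & obj == PARTICLE_OBJECT)
    particles <- data.frame(x = m[prows, 3L] * px, y = m[prows, 4L] * px)
    ann <- micrograph_annotation(frame, contours, particles,
                                 condition = condition,
                                 experiment_id = experiment_id,
                                 image_index = zi)
    # re-attach coat intervals / pit marks / side convention from metadata
    if (!is.null(meta)) ann <- .apply_metadata(ann, meta)
    out[[length(out) + 1L]] <- ann
  }
  out
}

#' Write annotations to a model2point-style coordinate file
#'
#' Inverse of [read_point_file()]: coordinates are converted back from nm to
#' pixels. Coat intervals, pit marks and side conventions live in the
#' companion metadata file ([write_image_metadata()]), not in the point file.
#'
#' @param annotations A `micrograph_annotation` or list of them.
#' @param path Output path; omit to return the lines invisibly.
#' @param digits Numeric precision for coordinates.
#' @export
write_point_file <- function(annotations, path = NULL, digits = 6) {
  if (inherits(annotations, "micrograph_annotation"))
    annotations <- list(annotations)
  lines <- character(0)
  for (ann in annotations) {
    px <- ann$frame$nm_per_px
    z <- ann$image_index
    for (ci in seq_along(ann$contours)) {
      v <- contour_vertices(ann$contours[[ci]]) / px
      lines <- c(lines, sprintf("%d %d %.*g %.*g %d", MEMBRANE_OBJECT, ci,
                                digits, v[, 1L], digits, v[, 2L], z))
    }
    p <- ann$particles
    if (nrow(p))
      lines <- c(lines, sprintf("%d %d %.*g %.*g %d", PARTICLE_OBJECT,
                                seq_len(nrow(p)), digits, p$x / px,
                                digits, p$y / px, z))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# ---- per-image metadata (flat key-value config) ----------------------------

#' Read per-image metadata from a flat key-value file
#'
#' Lines of the form `key = value`; `#` comments ignored. Recognised keys:
#' `width_px`, `height_px`, `nm_per_px`, `section_thickness_nm`, `condition`,
#' `experiment_id`, `side_convention`, `coat_intervals` (comma-separated
#' `s0:s1` arc-length pairs, nm) and `pit_marks` (`s0:s1`).
#'
#' @param path File path, or `text` lines.
#' @param text Optional character vector of lines.
#' @return A list with an `image_frame` in `$frame` plus the other fields.
#' @export
read_image_metadata <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2L)) stop("metadata lines must be 'key = value'")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(k, d = NULL) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  chr <- function(k, d = NULL) if (k %in% names(vals)) trimws(vals[[k]]) else d
  pairs <- function(k) {
    if (!k %in% names(vals)) return(NULL)
    ps <- strsplit(strsplit(vals[[k]], ",")[[1L]], ":")
    matrix(as.numeric(unlist(ps)), ncol = 2L, byrow = TRUE)
  }
  frame <- image_frame(num("width_px"), num("height_px"), num("nm_per_px"),
                       num("section_thickness_nm", 70))
  list(frame = frame,
       condition = chr("condition", "unspecified"),
       experiment_id = chr("experiment_id", "exp1"),
       side_convention = chr("side_convention", "left"),
       coat_intervals = pairs("coat_intervals"),
       pit_marks = if (!is.null(pairs("pit_marks"))) pairs("pit_marks")[1L, ])
}

#' Write per-image metadata as a flat key-value file
#'
#' @param annotation A `micrograph_annotation` (first contour's coat
#'   intervals / pit marks / side convention are recorded).
#' @param path Output path; omit to return lines invisibly.
#' @export
write_image_metadata <- function(annotation, path = NULL) {
  f <- annotation$frame
  lines <- c(sprintf("width_px = %d", f$width_px),
             sprintf("height_px = %d", f$height_px),
             sprintf("nm_per_px = %g", f$nm_per_px),
             sprintf("section_thickness_nm = %g", f$section_thickness_nm),
             sprintf("condition = %s", annotation$condition),
             sprintf("experiment_id = %s", annotation$experiment_id))
  if (length(annotation$contours)) {
    ct <- annotation$contours[[1L]]
    lines <- c(lines, sprintf("side_convention = %s", attr_side(ct)))
    if (!is.null(ct$coat_intervals))
      lines <- c(lines, sprintf("coat_intervals = %s", paste(
        sprintf("%g:%g", ct$coat_intervals[, 1L], ct$coat_intervals[, 2L]),
        collapse = ",")))
    if (!is.null(ct$pit_marks))
      lines <- c(lines, sprintf("pit_marks = %g:%g", ct$pit_marks[1L],
                                ct$pit_marks[2L]))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# Attach metadata-carried contour attributes to the first contour.
.apply_metadata <- function(ann, meta) {
  if (!length(ann$contours)) return(ann)
  ct <- ann$contours[[1L]]
  ann$contours[[1L]] <- membrane_contour(
    contour_vertices(ct),
    coat_intervals = meta$coat_intervals,
    pit_marks = meta$pit_marks,
    side_convention = if (is.null(meta$side_convention)) "left"
                      else meta$side_convention)
  for (k in seq_along(ann$contours)[-1L]) {
    ck <- ann$contours[[k]]
    ann$contours[[k]] <- membrane_contour(
      contour_vertices(ck),
      side_convention = if (is.null(meta$side_convention)) "left"
                        else meta$side_convention)
  }
  ann
}
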