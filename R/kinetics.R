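# Live-cell tagging kinetics: spot detection on binarized frames,
# background-subtracted channel ratios per spot, median-zeroed traces and
# the randomized-channel control.

#' Detect spots in a single-channel frame
#'
#' Binarizes the frame (default: Otsu threshold) and labels connected
#' components; components smaller than `min_area` pixels are discarded.
#'
#' @param frame Numeric matrix.
#' @param threshold `"otsu"` or a numeric threshold.
#' @param min_area Minimum component area in pixels (default 4, suppressing
#'   single-pixel noise).
#' @return Integer label matrix (0 = background); a blank frame gives zero
#'   spots, not an error.
#' @export
detect_spots <- function(frame, threshold = "otsu", min_area = 4) {
  rng <- range(frame)
  if (rng[1L] == rng[2L]) return(matrix(0L, nrow(frame), ncol(frame)))
  th <- if (identical(threshold, "otsu"))
    EBImage::otsu(frame, range = rng) else as.numeric(threshold)
  lab <- EBImage::bwlabel(frame > th)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    lab[!(lab %in% keep)] <- 0L
    # compact labels
    if (length(keep)) {
      map <- integer(max(lab)); map[keep] <- seq_along(keep)
      lab[lab > 0] <- map[lab[lab > 0]]
    }
  }
  matrix(as.integer(lab), nrow(frame), ncol(frame))
}

# Robust background: mode of the intensity distribution over non-spot pixels
# (KDE peak).
.background_mode <- function(frame, label_mask) {
  v <- frame[label_mask == 0L]
  if (!length(v)) v <- as.vector(frame)
  if (length(unique(v)) == 1L) return(v[1L])
  d <- stats::density(v)
  d$x[which.max(d$y)]
}

#' Tagging-kinetics trace from a two-channel stack
#'
#' Spots are detected per frame on the reference channel; each spot's ratio
#' of background-subtracted mean intensities
#' `(mean ch2 - bg2) / (mean ch1 - bg1)` is computed (background = per-frame
#' per-channel mode of the non-spot pixels); the per-frame value is the
#' median over spots; the trace is shifted so its pre-onset median is exactly
#' 0. Spots whose denominator is <= 0 are skipped and counted.
#'
#' @param ch1,ch2 dim x dim x T arrays (reference and tag channels), or a
#'   list with `$ch1`/`$ch2` (e.g. from [generate_kinetics_stack()]).
#' @param onset_frame Stimulus onset (first responding frame).
#' @param threshold,min_area Passed to [detect_spots()].
#' @return data.frame of class `kinetics_trace`: `frame`, `ratio` (raw
#'   per-frame median), `value` (median-zeroed), `n_spots`, `n_skipped`;
#'   attribute `onset_frame`.
#' @export
ratio_trace <- function(ch1, ch2 = NULL, onset_frame,
                        threshold = "otsu", min_area = 4) {
  if (is.list(ch1) && is.null(ch2)) { ch2 <- ch1$ch2; ch1 <- ch1$ch1 }
  stopifnot(identical(dim(ch1), dim(ch2)))
  nt <- dim(ch1)[3L]
  if (onset_frame < 1 || onset_frame > nt) stop("onset_frame outside stack")
  ratio <- rep(NA_real_, nt); nsp <- integer(nt); nsk <- integer(nt)
  for (t in seq_len(nt)) {
    f1 <- ch1[, , t]; f2 <- ch2[, , t]
    lab <- detect_spots(f1, threshold = threshold, min_area = min_area)
    k <- max(lab)
    nsp[t] <- k
    if (!k) next
    bg1 <- .background_mode(f1, lab)
    bg2 <- .background_mode(f2, lab)
    m1 <- vapply(seq_len(k), function(j) mean(f1[lab == j]), 0) - bg1
    m2 <- vapply(seq_len(k), function(j) mean(f2[lab == j]), 0) - bg2
    ok <- m1 > 0
    nsk[t] <- sum(!ok)
    if (any(ok)) ratio[t] <- stats::median(m2[ok] / m1[ok])
  }
  pre <- ratio[seq_len(onset_frame - 1L)]
  shift <- stats::median(pre, na.rm = TRUE)
  out <- data.frame(frame = seq_len(nt), ratio = ratio,
                    value = ratio - shift, n_spots = nsp, n_skipped = nsk)
  class(out) <- c("kinetics_trace", "data.frame")
  attr(out, "onset_frame") <- onset_frame
  out
}

#' Randomized-channel control trace
#'
#' The tag channel is permuted pixel-wise within each frame (fixed seed),
#' then analysed exactly as [ratio_trace()]. A responding stack should give a
#' flat control trace.
#'
#' @inheritParams ratio_trace
#' @param seed Integer seed for the permutation.
#' @export
randomized_control <- function(ch1, ch2 = NULL, onset_frame, seed = 1,
                               threshold = "otsu", min_area = 4) {
  if (is.list(ch1) && is.null(ch2)) { ch2 <- ch1$ch2; ch1 <- ch1$ch1 }
  set.seed(seed)
  perm <- ch2
  npx <- prod(dim(ch2)[1:2])
  for (t in seq_len(dim(ch2)[3L])) {
    f <- ch2[, , t]
    perm[, , t] <- matrix(f[sample.int(npx)], dim(ch2)[1L], dim(ch2)[2L])
  }
  ratio_trace(ch1, perm, onset_frame, threshold = threshold,
              min_area = min_area)
}

#' Average kinetics traces across cells
#'
#' @param traces List of `kinetics_trace` objects of equal length (one per
#'   cell).
#' @return data.frame with `frame`, `mean`, `sem`, `n`.
#' @export
average_traces <- function(traces) {
  vals <- vapply(traces, function(tr) tr$value, numeric(nrow(traces[[1L]])))
  vals <- matrix(vals, ncol = length(traces))
  data.frame(frame = traces[[1L]]$frame,
             mean = rowMeans(vals, na.rm = TRUE),
             sem = apply(vals, 1L, function(v)
               stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
             n = apply(vals, 1L, function(v) sum(!is.na(v))))
}
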