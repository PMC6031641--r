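# Multi-page grayscale TIFF I/O for two-channel kinetics stacks.

#' Write a two-channel kinetics stack as multi-page TIFFs
#'
#' One float multi-page grayscale TIFF per channel (`ch1.tif`, `ch2.tif`),
#' one page per timepoint. Intensities are stored as 32-bit floats scaled by
#' `scale` into [0, 1) for TIFF compatibility.
#'
#' @param stack List with `ch1`/`ch2` arrays (e.g. from
#'   [generate_kinetics_stack()]).
#' @param dir Output directory (created if needed).
#' @param scale,offset Affine map `(x + offset) / scale` applied before
#'   writing (noise can make raw intensities negative; TIFF floats must lie
#'   in [0, 1]). Inverted on read from the recorded metadata.
#' @return Invisibly, the written paths.
#' @export
write_kinetics_stack <- function(stack, dir, scale = 2048, offset = 512) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for stack I/O")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("ch1.tif", "ch2.tif"))
  for (k in 1:2) {
    a <- (stack[[paste0("ch", k)]] + offset) / scale
    if (any(a < 0) || any(a >= 1))
      stop("intensities outside the storable range; adjust scale/offset")
    pages <- lapply(seq_len(dim(a)[3L]), function(t) a[, , t])
    tiff::writeTIFF(pages, paths[k], bits.per.sample = 32L)
  }
  writeLines(c(sprintf("scale = %g", scale), sprintf("offset = %g", offset)),
             file.path(dir, "stack.meta"))
  invisible(paths)
}

#' Read a two-channel kinetics stack written by [write_kinetics_stack()]
#'
#' @param dir Directory holding `ch1.tif`, `ch2.tif` and `stack.meta`.
#' @return List with `ch1` and `ch2` arrays.
#' @export
read_kinetics_stack <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for stack I/O")
  meta <- file.path(dir, "stack.meta")
  kv <- if (file.exists(meta)) read_run_config(meta) else list()
  scale <- if (is.null(kv$scale)) 1 else kv$scale
  offset <- if (is.null(kv$offset)) 0 else kv$offset
  out <- lapply(1:2, function(k) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("ch%d.tif", k)),
                            all = TRUE)
    simplify2array(pages) * scale - offset
  })
  names(out) <- c("ch1", "ch2")
  out
}
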