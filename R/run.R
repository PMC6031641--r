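# Pipeline orchestration: flat key-value run configs, stage dispatch and
# provenance manifests. A thin command-line wrapper over these functions
# lives in inst/cli/clemquant.R.

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value`; `#` comments ignored. Values are
#' auto-typed (numeric where possible). Defaults follow the conventional
#' analysis parameters: 50 nm membrane-proximal zone, 70 nm sections,
#' tag length states 7-18 nm (max 22), 100 nm idealized pit, 8 x 6 grid.
#'
#' @param path File path (or `text` lines).
#' @param text Optional character vector of lines.
#' @return Named list of parameters merged over the defaults.
#' @export
read_run_config <- function(path = NULL, text = NULL) {
  defaults <- list(zone_nm = 50, section_thickness_nm = 70,
                   length_min_nm = 7, length_max_nm = 18,
                   length_max_theoretical_nm = 22,
                   pit_diameter_nm = 100, n_vertical = 8, n_horizontal = 6,
                   grid_nm = 4, min_area = 4, seed = 1)
  if (is.null(path) && is.null(text)) return(defaults)
  lines <- if (is.null(text)) readLines(path) else text
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "\\s*=\\s*")[[1L]]
    if (length(kv) != 2L) stop("config lines must be 'key = value': ", ln)
    val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    defaults[[trimws(kv[1L])]] <- if (!is.na(num)) num else val
  }
  defaults
}

.write_manifest <- function(out_dir, stage, config, seed) {
  lines <- c(sprintf("stage = %s", stage),
             sprintf("seed = %d", seed),
             sprintf("package_version = %s",
                     as.character(utils::packageVersion("clemquant"))),
             sprintf("r_version = %s", R.version.string),
             sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(config), function(k)
               sprintf("config.%s = %s", k,
                       paste(format(config[[k]]), collapse = ",")), ""))
  writeLines(lines, file.path(out_dir, "run_manifest.txt"))
}

.load_annotations <- function(input) {
  # input: a directory of paired <stem>.pts / <stem>.meta files
  pts <- list.files(input, pattern = "\\.pts$", full.names = TRUE)
  if (!length(pts)) stop("no .pts point files found in ", input)
  anns <- list()
  for (p in pts) {
    meta_path <- sub("\\.pts$", ".meta", p)
    if (!file.exists(meta_path)) stop("missing metadata file ", meta_path)
    meta <- read_image_metadata(meta_path)
    anns <- c(anns, read_point_file(p, meta))
  }
  anns
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic scene written as point file + metadata +
#' ground truth), `density`, `stereology` (labeling-table report),
#' `resolution` (detection simulation + FWHM), `pitmap`, `kinetics`.
#' Every run writes its outputs as comma-separated tables plus a
#' `run_manifest.txt` provenance record (stage, seed, package and R
#' versions, config) in `out_dir`.
#'
#' @param stage Stage name.
#' @param input Input directory of scenes (stages reading annotations) or a
#'   kinetics stack list (stage `kinetics`).
#' @param out_dir Output directory (created).
#' @param config Parameter list from [read_run_config()] (or `NULL` for
#'   defaults).
#' @param seed Integer seed; all stage randomness flows from it.
#' @return Invisibly, a list of result objects; files on disk in `out_dir`.
#' @export
run_stage <- function(stage, input = NULL, out_dir = "clemquant_out",
                      config = NULL, seed = NULL) {
  stages <- c("simulate", "density", "stereology", "resolution", "pitmap",
              "kinetics")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; usage: one of ",
         paste(stages, collapse = " | "))
  if (is.null(config)) config <- read_run_config()
  if (is.null(seed)) seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(stage,
    simulate = {
      sc <- generate_scene(scene_config(grid_nm = config$grid_nm,
                                        zone_nm = config$zone_nm),
                           seed = seed)
      write_scene(sc, out_dir)
      sc
    },
    density = {
      anns <- .load_annotations(input)
      dt <- density_table(anns, zone_nm = config$zone_nm,
                          grid_nm = config$grid_nm)
      utils::write.csv(dt$table, file.path(out_dir, "density_table.csv"),
                       row.names = FALSE)
      utils::write.csv(dt$per_image,
                       file.path(out_dir, "density_per_image.csv"),
                       row.names = FALSE)
      dt
    },
    stereology = {
      anns <- .load_annotations(input)
      st <- stereology_table(anns, zone_nm = config$zone_nm)
      utils::write.csv(st, file.path(out_dir, "stereology_table.csv"),
                       row.names = FALSE)
      st
    },
    resolution = {
      model <- tag_geometry_model(
        length_min_nm = config$length_min_nm,
        length_max_nm = config$length_max_nm,
        length_max_theoretical_nm = config$length_max_theoretical_nm,
        section_thickness_nm = config$section_thickness_nm)
      n <- if (!is.null(config$n_draws)) config$n_draws else 1e5
      ds <- simulate_detected_distances(model, n_draws = n, seed = seed)
      smry <- data.frame(n = ds$n, median_nm = ds$median, mean_nm = ds$mean,
                         fwhm_nm = ds$fwhm,
                         bandwidth = attr(fwhm(ds), "bandwidth"))
      utils::write.csv(smry, file.path(out_dir, "resolution_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(distance_nm = ds$distances),
                       file.path(out_dir, "simulated_distances.csv"),
                       row.names = FALSE)
      ds
    },
    pitmap = {
      anns <- .load_annotations(input)
      pms <- lapply(anns, classify_and_normalize)
      all_pm <- do.call(rbind, pms)
      utils::write.csv(all_pm, file.path(out_dir, "pit_map.csv"),
                       row.names = FALSE)
      proj <- idealized_projection(all_pm,
                                   pit_diameter_nm = config$pit_diameter_nm)
      utils::write.csv(proj, file.path(out_dir, "idealized_pit.csv"),
                       row.names = FALSE)
      utils::write.csv(frequency_per_region(pms),
                       file.path(out_dir, "pit_frequency.csv"),
                       row.names = FALSE)
      list(pitmaps = pms, projection = proj)
    },
    kinetics = {
      stack <- if (is.list(input) && !is.null(input$ch1)) input
        else if (is.character(input) && dir.exists(input))
          read_kinetics_stack(input)
        else stop("kinetics stage expects a stack list with $ch1/$ch2 ",
                  "or a directory with ch1.tif/ch2.tif")
      onset <- if (!is.null(config$onset_frame)) config$onset_frame
        else stop("config needs onset_frame for the kinetics stage")
      tr <- ratio_trace(stack, onset_frame = onset,
                        min_area = config$min_area)
      ctl <- randomized_control(stack, onset_frame = onset, seed = seed,
                                min_area = config$min_area)
      utils::write.csv(tr, file.path(out_dir, "kinetics_trace.csv"),
                       row.names = FALSE)
      utils::write.csv(ctl, file.path(out_dir, "kinetics_control.csv"),
                       row.names = FALSE)
      list(trace = tr, control = ctl)
    })
  .write_manifest(out_dir, stage, config, seed)
  invisible(res)
}
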