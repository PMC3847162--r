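#' Read a colony area table
#'
#' Reads a delimited table of tracked colony areas (columns `colony_id`,
#' `time_h`, `area_px`; centroid columns `cx`, `cy` and ground-truth columns
#' are carried through when present) and validates it: malformed values,
#' duplicated `(colony_id, time_h)` rows and non-increasing times within a
#' colony are reported with the offending line numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated track tibble.
#' @export
read_area_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "growthdyn_io_error")
  }
  # base read.csv: strtod parsing is correctly rounded, so tables written
  # with 17 significant digits round-trip bit-identically
  raw <- tibble::as_tibble(utils::read.csv(path))
  # measurement columns are doubles even when a file holds whole numbers
  for (col in intersect(c("time_h", "area_px", "true_rate", "a0",
                          "cx", "cy"), names(raw))) {
    raw[[col]] <- as.double(raw[[col]])
  }
  required <- c("colony_id", "time_h", "area_px")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "growthdyn_io_error")
  }
  line_of <- function(i) i + 1L  # header occupies line 1
  bad <- which(!complete.cases(raw[required]) |
                 !is.finite(raw$time_h) | !is.finite(raw$area_px))
  if (length(bad) > 0) {
    abort(sprintf("malformed row(s) at line(s) %s.",
                  paste(line_of(bad), collapse = ", ")),
          class = "growthdyn_io_error")
  }
  if (any(raw$area_px <= 0)) {
    abort(sprintf("non-positive area(s) at line(s) %s.",
                  paste(line_of(which(raw$area_px <= 0)), collapse = ", ")),
          class = "growthdyn_io_error")
  }
  dup <- duplicated(raw[c("colony_id", "time_h")])
  if (any(dup)) {
    abort(sprintf("duplicated (colony_id, time_h) at line(s) %s.",
                  paste(line_of(which(dup)), collapse = ", ")),
          class = "growthdyn_io_error")
  }
  nonmono <- raw |>
    dplyr::mutate(.line = dplyr::row_number()) |>
    dplyr::group_by(.data$colony_id) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$time_h <= dplyr::lag(.data$time_h)) |>
    dplyr::pull(".line")
  if (length(nonmono) > 0) {
    abort(sprintf("non-increasing time within a colony at line(s) %s.",
                  paste(line_of(nonmono), collapse = ", ")),
          class = "growthdyn_io_error")
  }
  raw
}

#' Write a colony area table
#'
#' Writes tracks as CSV with full double precision (17 significant digits)
#' so that reading the file back reproduces the numbers bit-identically.
#'
#' @param tracks Track tibble (`colony_id`, `time_h`, `area_px`, ...).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(tracks, path) {
  stopifnot(all(c("colony_id", "time_h", "area_px") %in% names(tracks)))
  out <- dplyr::mutate(tracks, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a time-lapse image stack
#'
#' Accepts a multi-frame TIFF, a glob pattern, or a vector of single-frame
#' TIFF/PNG paths. File sequences are ordered by the number embedded in the
#' file name (so `frame2` sorts before `frame10`), not lexicographically.
#' All frames must share one shape.
#'
#' @param path A file path, glob pattern, or character vector of paths.
#' @return A list of numeric matrices, one per frame, in acquisition order.
#' @export
read_image_stack <- function(path) {
  paths <- if (length(path) == 1 && grepl("[*?]", path)) {
    Sys.glob(path)
  } else {
    path
  }
  if (length(paths) == 0) {
    abort("no input: the glob matched no files.",
          class = "growthdyn_io_error")
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("no such file(s): %s", paste(missing, collapse = ", ")),
          class = "growthdyn_io_error")
  }
  as_frame <- function(x) {
    if (length(dim(x)) == 3) x <- x[, , 1]
    matrix(as.numeric(x), nrow(x), ncol(x))
  }
  frames <- if (length(paths) == 1 && grepl("\\.tiff?$", paths,
                                            ignore.case = TRUE)) {
    lapply(tiff::readTIFF(paths, all = TRUE), as_frame)
  } else {
    nums <- suppressWarnings(as.numeric(sub(
      ".*?(\\d+)\\D*$", "\\1", basename(paths), perl = TRUE)))
    if (!any(is.na(nums)) && length(paths) > 1) {
      paths <- paths[order(nums)]
    }
    lapply(paths, function(p) {
      if (grepl("\\.png$", p, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE)) {
          abort("reading PNG needs the png package.",
                class = "growthdyn_io_error")
        }
        as_frame(png::readPNG(p))
      } else {
        as_frame(tiff::readTIFF(p))
      }
    })
  }
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(shapes)) != 1) {
    abort(sprintf("mixed frame shapes: %s.",
                  paste(unique(shapes), collapse = " vs ")),
          class = "growthdyn_io_error")
  }
  frames
}

#' Write frames as a multi-frame TIFF
#'
#' Intensities are clamped to `[0, 1]`.
#'
#' @param frames List of numeric matrices.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) > 0)
  clamped <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(clamped, path, bits.per.sample = 16)
  invisible(path)
}

#' Run the synthetic study pipeline end to end
#'
#' Binds the stages into one seeded, reproducible run: `synth` generates
#' growth rates and colony trajectories; `fit_growth` fits and gates them
#' and summarizes the rate distribution; `simulate` runs the
#' lineage-selection Monte Carlo; `scale` generates a fluorescence snapshot
#' family, measures its collapse and fits the variance-mean law; `assay`
#' generates plate counts and estimates the fraction adapted. `all` runs
#' everything. Outputs are CSV tables and JSON summaries plus a manifest
#' recording the resolved configuration, the seed and the package version;
#' identical config and seed give byte-identical outputs.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognized entries: `stages` (character vector, default `"all"`),
#'   `seed` (default 1), and parameter blocks `generator`, `simulator`,
#'   `scaling` (`means`, `law`, `n_cells`, `shape`), `assay`
#'   (`frac_adapted`, `n_plated`, ...), `fit` (arguments of
#'   [fit_exponential()]), plus `input_area_table` to run `fit_growth` on an
#'   existing CSV instead of synthetic tracks.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of in-memory stage results; files are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("growthdyn_")) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("synth", "simulate", "fit_growth", "scale", "assay")
  stages <- config$stages %||% "all"
  if (identical(stages, "all")) stages <- known
  unknown <- setdiff(stages, known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown stage(s): %s (known: %s).",
                  paste(unknown, collapse = ", "),
                  paste(known, collapse = ", ")),
          class = "growthdyn_usage_error")
  }
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  wjson <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  gen_args <- config$generator %||% list()
  gen_args$seed <- substream_seed(seed, "synth")
  cfg <- do.call(generator_config, gen_args)

  if (any(c("synth", "fit_growth") %in% stages) &&
      is.null(config$input_area_table)) {
    rates <- gen_growth_rates(cfg)
    tracks <- gen_colony_trajectories(rates, cfg)
    res$rates <- rates
    res$tracks <- tracks
    if ("synth" %in% stages) {
      write_area_table(tracks, file.path(out_dir, "tracks.csv"))
      readr::write_csv(rates, file.path(out_dir, "growth_rates.csv"),
                       progress = FALSE)
    }
  }

  if ("fit_growth" %in% stages) {
    tracks <- if (!is.null(config$input_area_table)) {
      read_area_table(config$input_area_table)
    } else {
      res$tracks
    }
    fit_args <- config$fit %||% list()
    fits <- do.call(fit_colonies, c(list(tracks), fit_args))
    fits <- apply_exclusions(fits, tracks)
    summ <- summarize_rates(fits, seed = substream_seed(seed, "summarize"),
                            min_n = config$min_n %||% 100)
    res$fits <- fits
    res$rate_distribution <- summ
    readr::write_csv(fits, file.path(out_dir, "fits.csv"), progress = FALSE)
    readr::write_csv(attr(fits, "review_queue"),
                     file.path(out_dir, "review_queue.csv"),
                     progress = FALSE)
    readr::write_csv(summ$histogram, file.path(out_dir, "histogram.csv"),
                     progress = FALSE)
    wjson(c(as.list(glance(summ)),
            list(fraction_exponential = fraction_exponential(fits))),
          "rate_summary.json")
  }

  if ("simulate" %in% stages) {
    sim_args <- config$simulator %||% list(horizon_generations = 5)
    sim_args$seed <- substream_seed(seed, "simulate")
    traj <- simulate_population(do.call(sim_config, sim_args))
    res$trajectory <- traj
    readr::write_csv(tidy(traj), file.path(out_dir, "trajectory.csv"),
                     progress = FALSE)
    wjson(as.list(glance(traj)), "simulation_summary.json")
  }

  if ("scale" %in% stages) {
    sc <- config$scaling %||% list()
    means <- sc$means %||% seq(100, 1000, length.out = 8)
    law <- do.call(quadratic_law, as.list(sc$law %||% c(0, 1478, 0.48)))
    snaps <- gen_fluorescence_snapshots(
      means, law, shape = sc$shape %||% "lognormal",
      n_cells = sc$n_cells %||% 5000L,
      seed = substream_seed(seed, "scale"))
    cd <- collapse_distance(snaps)
    vm <- fit_variance_mean(snapshot_moments(snaps))
    res$snapshots <- snaps
    res$collapse <- cd
    res$varmean <- vm
    readr::write_csv(snapshot_moments(snaps),
                     file.path(out_dir, "snapshot_moments.csv"),
                     progress = FALSE)
    wjson(list(max_collapse_distance = cd$max_distance,
               ks_null_05 = ks_critical(min(cd$n_per_snapshot)),
               varmean = as.list(glance(vm))[c("a", "b", "c")]),
          "scaling_summary.json")
  }

  if ("assay" %in% stages) {
    aa <- config$assay %||% list()
    counts <- gen_plate_counts(
      frac_adapted = aa$frac_adapted %||% 0.1,
      n_plated = aa$n_plated %||% 200L,
      n_glu_plates = aa$n_glu_plates %||% 3L,
      n_ypd_plates = aa$n_ypd_plates %||% 2L,
      plating_efficiency = aa$plating_efficiency %||% 1,
      seed = substream_seed(seed, "assay"))
    fr <- fraction_adapted(counts)
    res$plate_counts <- counts
    res$fraction_adapted <- fr
    readr::write_csv(counts, file.path(out_dir, "plate_counts.csv"),
                     progress = FALSE)
    readr::write_csv(fr, file.path(out_dir, "fraction_adapted.csv"),
                     progress = FALSE)
  }

  manifest <- list(
    package = "growthdyn",
    version = as.character(utils::packageVersion("growthdyn")),
    seed = seed,
    stages = stages,
    units = list(time = "hours", rate = "1/hour", area = "pixels"),
    config = config
  )
  wjson(manifest, "manifest.json")
  res$out_dir <- out_dir
  invisible(res)
}
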