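#' Configuration for the synthetic-data generators
#'
#' Bundles the parameters shared by the growth-rate, colony-trajectory and
#' image generators. Defaults describe a broad-distribution ("rewired
#' phase-IV"-like) population imaged hourly for 24 h: a mean instantaneous
#' rate of `log(2)/8.4` per hour (a mean division time of 8.4 h), a
#' coefficient of variation of 0.3, and a single-cell footprint of 45 pixels.
#' The 25-frame window spans just under three generations at the mean rate,
#' the longest stretch over which a single-exponent fit is still meaningful
#' for these cells.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_cells Number of cells / colony founders to generate.
#' @param mean_rate Mean instantaneous growth rate of the growing
#'   subpopulation, in 1/hour.
#' @param cv Coefficient of variation (sigma/mu) of the growing
#'   subpopulation's rates; must be >= 0.
#' @param frac_nongrower Fraction of cells that do not grow at all, in
#'   `[0, 1]`.
#' @param noise_cv Multiplicative (log-normal) measurement noise scale on
#'   colony areas; the SD of the per-frame relative area error.
#' @param frame_interval Time between frames, hours.
#' @param n_frames Number of frames per trajectory; at least 3 (an
#'   exponential fit needs three points).
#' @param image_shape Integer vector `c(rows, cols)` of rendered frames, in
#'   pixels.
#' @param cell_area_px Area of a single cell, in pixels.
#' @return A validated list of class `generator_config`.
#' @export
#' @examples
#' generator_config(seed = 1, n_cells = 10)
generator_config <- function(seed = 1L,
                             n_cells = 500L,
                             mean_rate = log(2) / 8.4,
                             cv = 0.3,
                             frac_nongrower = 0,
                             noise_cv = 0.05,
                             frame_interval = 1,
                             n_frames = 25L,
                             image_shape = c(512L, 512L),
                             cell_area_px = 45) {
  check_number(seed, "seed")
  check_count(n_cells, "n_cells")
  check_number(mean_rate, "mean_rate")
  check_number(cv, "cv", lower = 0)
  check_number(frac_nongrower, "frac_nongrower", lower = 0, upper = 1)
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(frame_interval, "frame_interval", lower = 1e-12)
  check_count(n_frames, "n_frames", lower = 3)
  if (length(image_shape) != 2 || any(image_shape < 8)) {
    abort("`image_shape` must be two pixel dimensions >= 8.",
          class = "growthdyn_config_error")
  }
  check_number(cell_area_px, "cell_area_px", lower = 1e-12)
  structure(
    list(seed = as.integer(seed), n_cells = as.integer(n_cells),
         mean_rate = mean_rate, cv = cv, frac_nongrower = frac_nongrower,
         noise_cv = noise_cv, frame_interval = frame_interval,
         n_frames = as.integer(n_frames),
         image_shape = as.integer(image_shape), cell_area_px = cell_area_px),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d cells, mean rate %.4f /h (division time %.2f h), CV %.2f\n",
              x$n_cells, x$mean_rate, log(2) / x$mean_rate, x$cv))
  cat(sprintf("  non-growers %.1f%%, area noise CV %.2f\n",
              100 * x$frac_nongrower, x$noise_cv))
  cat(sprintf("  %d frames every %g h, image %dx%d px, cell %g px\n",
              x$n_frames, x$frame_interval, x$image_shape[1],
              x$image_shape[2], x$cell_area_px))
  invisible(x)
}

#' Draw a population of single-cell growth rates
#'
#' Rates of the growing subpopulation are Gaussian with mean
#' `config$mean_rate` and SD `cv * mean_rate`. A `frac_nongrower` share of
#' cells is sampled (binomially) as non-growers with rate exactly 0. Gaussian
#' draws that land at or below zero are reclassified as non-growers rather
#' than resampled, preserving the configured Gaussian over the growing tail;
#' such cells carry `reclassified = TRUE`.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per cell: `cell_id`, `rate` (1/hour),
#'   `class` (`"grower"` or `"nongrower"`), `reclassified`. The config is
#'   attached as attribute `"config"`.
#' @export
#' @examples
#' gen_growth_rates(generator_config(seed = 1, n_cells = 5))
gen_growth_rates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(substream_seed(config$seed, "growth_rates"), {
    n <- config$n_cells
    nongrower <- runif(n) < config$frac_nongrower
    rate <- rnorm(n, config$mean_rate, config$cv * abs(config$mean_rate))
    reclassified <- !nongrower & rate <= 0
    rate[nongrower | reclassified] <- 0
    out <- tibble::tibble(
      cell_id = seq_len(n),
      rate = rate,
      class = ifelse(rate > 0, "grower", "nongrower"),
      reclassified = reclassified
    )
    attr(out, "config") <- config
    out
  })
}

#' Generate synthetic colony-area trajectories
#'
#' Each growing cell founds a microcolony whose area follows
#' `A0 * exp(r * t)` with i.i.d. multiplicative log-normal noise of scale
#' `noise_cv` applied per frame; non-growers keep a constant mean area under
#' the same noise. Initial areas default to a log-normal scatter around the
#' single-cell footprint `cell_area_px`. The generating rate and initial area
#' are carried in the output so downstream stages always have a recovery
#' target.
#'
#' @param rates A tibble from [gen_growth_rates()], or any data frame with
#'   columns `cell_id` and `rate`.
#' @param config A [generator_config()].
#' @param a0 Optional vector of initial areas (pixels), one per cell;
#'   defaults to log-normal around `config$cell_area_px`.
#' @return A long tibble: `colony_id`, `time_h`, `area_px`, plus ground truth
#'   `true_rate` and `a0`.
#' @export
#' @examples
#' cfg <- generator_config(seed = 1, n_cells = 3, n_frames = 5)
#' gen_colony_trajectories(gen_growth_rates(cfg), cfg)
gen_colony_trajectories <- function(rates, config, a0 = NULL) {
  stopifnot(inherits(config, "generator_config"))
  stopifnot(all(c("cell_id", "rate") %in% names(rates)))
  n <- nrow(rates)
  with_seed(substream_seed(config$seed, "colony_trajectories"), {
    if (is.null(a0)) {
      a0 <- rlnorm(n, meanlog = log(config$cell_area_px), sdlog = 0.15)
    }
    stopifnot(length(a0) == n, all(a0 > 0))
    t_h <- (seq_len(config$n_frames) - 1) * config$frame_interval
    out <- tidyr::expand_grid(
      idx = seq_len(n),
      time_h = t_h
    )
    out$colony_id <- rates$cell_id[out$idx]
    out$true_rate <- rates$rate[out$idx]
    out$a0 <- a0[out$idx]
    noise <- if (config$noise_cv > 0) {
      exp(rnorm(nrow(out), 0, config$noise_cv))
    } else {
      1
    }
    out$area_px <- out$a0 * exp(out$true_rate * out$time_h) * noise
    dplyr::select(out, "colony_id", "time_h", "area_px", "true_rate", "a0")
  })
}

#' Render colony trajectories as a synthetic image stack
#'
#' Each colony is drawn as a filled disk of the trajectory's area at a fixed
#' centroid, on a noisy background. Ground-truth label masks are emitted
#' alongside the frames. Colonies are laid out on a grid spaced by their
#' largest final radius unless explicit centroids are supplied. Pairs of
#' disks that come closer than `proximity_px` (edge to edge) in any frame are
#' flagged, exercising the downstream proximity-exclusion rule.
#'
#' @param tracks Long tibble from [gen_colony_trajectories()] (columns
#'   `colony_id`, `time_h`, `area_px`).
#' @param config A [generator_config()]; `image_shape` bounds the field.
#' @param centroids Optional 2-column matrix (x, y in pixels) of colony
#'   centres, one row per colony in `sort(unique(colony_id))` order.
#' @param proximity_px Edge-to-edge distance (pixels) below which two
#'   colonies are flagged as overlapping/too close.
#' @param fg,bg Foreground and background intensities.
#' @param pixel_noise_sd SD of additive Gaussian pixel noise.
#' @return A list of class `microcolony_stack`: `frames` (list of numeric
#'   matrices), `masks` (list of integer label matrices), `truth` (tibble of
#'   per-frame centroid, nominal area and rasterized mask area), `overlaps`
#'   (tibble of flagged pairs), `times` (hours).
#' @export
gen_microcolony_images <- function(tracks, config, centroids = NULL,
                                   proximity_px = 2, fg = 0.9, bg = 0.1,
                                   pixel_noise_sd = 0.02) {
  stopifnot(inherits(config, "generator_config"))
  ids <- sort(unique(tracks$colony_id))
  n <- length(ids)
  shp <- config$image_shape
  times <- sort(unique(tracks$time_h))
  wide <- tracks |>
    dplyr::select("colony_id", "time_h", "area_px") |>
    dplyr::arrange(.data$colony_id, .data$time_h)
  rmax <- if (n == 0) {
    tibble::tibble(colony_id = integer(), r = double())
  } else {
    wide |>
      dplyr::group_by(.data$colony_id) |>
      dplyr::summarise(r = sqrt(max(.data$area_px) / pi), .groups = "drop")
  }
  if (is.null(centroids) && n == 0) {
    centroids <- matrix(0, 0, 2)
  }
  if (is.null(centroids)) {
    pitch <- 2 * max(rmax$r) + proximity_px + 4
    per_row <- max(1L, floor((shp[2] - pitch) / pitch))
    gx <- pitch * (((seq_len(n) - 1) %% per_row) + 1)
    gy <- pitch * (((seq_len(n) - 1) %/% per_row) + 1)
    centroids <- cbind(gx, gy)
  }
  stopifnot(nrow(centroids) == n)
  if (any(centroids[, 1] + rmax$r > shp[2] | centroids[, 1] - rmax$r < 1 |
          centroids[, 2] + rmax$r > shp[1] | centroids[, 2] - rmax$r < 1)) {
    abort("colony footprints do not fit inside `image_shape`.",
          class = "growthdyn_config_error")
  }

  col_idx <- matrix(rep(seq_len(shp[2]), each = shp[1]), nrow = shp[1])
  row_idx <- matrix(rep(seq_len(shp[1]), times = shp[2]), nrow = shp[1])

  frames <- vector("list", length(times))
  masks <- vector("list", length(times))
  truth <- vector("list", length(times))
  overlaps <- list()

  with_seed(substream_seed(config$seed, "microcolony_images"), {
    for (k in seq_along(times)) {
      areas <- wide$area_px[wide$time_h == times[k]]
      radii <- sqrt(areas / pi)
      mask <- matrix(0L, shp[1], shp[2])
      for (i in seq_len(n)) {
        inside <- (col_idx - centroids[i, 1])^2 +
          (row_idx - centroids[i, 2])^2 <= radii[i]^2
        mask[inside] <- ids[i]
      }
      img <- ifelse(mask > 0, fg, bg) +
        rnorm(shp[1] * shp[2], 0, pixel_noise_sd)
      frames[[k]] <- matrix(img, shp[1], shp[2])
      masks[[k]] <- mask
      truth[[k]] <- tibble::tibble(
        frame = k, time_h = times[k], colony_id = ids,
        cx = centroids[, 1], cy = centroids[, 2],
        area_px = areas,
        mask_area = tabulate(mask, nbins = max(ids))[ids]
      )
      if (n > 1) {
        d <- as.matrix(stats::dist(centroids))
        edge <- outer(radii, radii, "+") + proximity_px
        pair <- which(d < edge & upper.tri(d), arr.ind = TRUE)
        if (nrow(pair) > 0) {
          overlaps[[length(overlaps) + 1]] <- tibble::tibble(
            frame = k, colony_a = ids[pair[, 1]], colony_b = ids[pair[, 2]]
          )
        }
      }
    }
  })

  structure(
    list(frames = frames, masks = masks,
         truth = dplyr::bind_rows(truth),
         overlaps = if (length(overlaps)) dplyr::bind_rows(overlaps) else
           tibble::tibble(frame = integer(), colony_a = integer(),
                          colony_b = integer()),
         times = times, centroids = centroids),
    class = "microcolony_stack"
  )
}

#' @export
print.microcolony_stack <- function(x, ...) {
  cat(sprintf("<microcolony_stack> %d frames of %dx%d px, %d colonies, %d flagged pairs\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              length(unique(x$truth$colony_id)),
              nrow(unique(x$overlaps[c("colony_a", "colony_b")]))))
  invisible(x)
}

#' Generate a family of fixed-shape fluorescence snapshots
#'
#' Emulates single-cell fluorescence distributions whose shape is preserved
#' over time while mean and variance move along a quadratic variance-mean
#' law: every snapshot is one fixed standardized base shape, affinely
#' rescaled to the requested mean and to `variance_law(mean)`. Such a family
#' collapses onto a single curve when each snapshot is standardized
#' (mean-subtracted, SD-divided). The base shape is a right-skewed
#' standardized log-normal by default; real protein distributions are
#' right-skewed but their analytic form is not modelled.
#'
#' @param means Numeric vector of requested snapshot means (arbitrary
#'   fluorescence units).
#' @param variance_law A [quadratic_law()] (or coefficient vector
#'   `c(a, b, c)`) giving variance as a function of mean.
#' @param shape Base shape: `"lognormal"` (right-skewed) or `"gaussian"`.
#' @param n_cells Cells per snapshot.
#' @param seed Integer seed.
#' @param sdlog Shape parameter of the log-normal base (ignored for
#'   `"gaussian"`).
#' @return A long tibble: `snapshot`, `target_mean`, `target_variance`,
#'   `value`.
#' @export
#' @examples
#' gen_fluorescence_snapshots(c(10, 20), quadratic_law(0, 1, 0.1),
#'                            n_cells = 100, seed = 1)
gen_fluorescence_snapshots <- function(means, variance_law,
                                       shape = c("lognormal", "gaussian"),
                                       n_cells = 40000L, seed = 1L,
                                       sdlog = 0.5) {
  shape <- match.arg(shape)
  if (!inherits(variance_law, "quadratic_law")) {
    variance_law <- quadratic_law(variance_law[1], variance_law[2],
                                  variance_law[3])
  }
  check_count(n_cells, "n_cells")
  v <- predict(variance_law, means)
  if (any(v <= 0)) {
    abort("`variance_law` must be positive over the requested means.",
          class = "growthdyn_generation_error")
  }
  with_seed(substream_seed(seed, "fluorescence_snapshots"), {
    purrr::map2_dfr(seq_along(means), means, function(i, mu) {
      z <- switch(shape,
        lognormal = {
          x <- rlnorm(n_cells, 0, sdlog)
          m <- exp(sdlog^2 / 2)
          s <- sqrt((exp(sdlog^2) - 1) * exp(sdlog^2))
          (x - m) / s
        },
        gaussian = rnorm(n_cells)
      )
      tibble::tibble(snapshot = i, target_mean = mu, target_variance = v[i],
                     value = mu + sqrt(v[i]) * z)
    })
  })
}

#' Generate synthetic plating-assay colony counts
#'
#' Emulates the selective/rich plating protocol: cells from a culture are
#' dispersed on selective (glucose, no histidine) and rich (YPD) agar plates
#' and the colonies counted. Per-plate counts are Poisson around the expected
#' number of colonies; adapted cells form colonies on both media,
#' non-adapted cells only on rich medium. `frac_adapted` may exceed 1 (up to
#' 1.2) to emulate counting fluctuations that push the downstream ratio
#' estimator above one.
#'
#' @param frac_adapted Fraction of plated cells able to form a colony on
#'   selective medium, in `[0, 1.2]`.
#' @param n_plated Cells dispersed per plate.
#' @param n_glu_plates,n_ypd_plates Number of selective / rich plates
#'   (defaults 3 and 2).
#' @param plating_efficiency Fraction of cells forming a colony on rich
#'   medium, in `[0, 1.2]`.
#' @param seed Integer seed.
#' @param time_label Optional label carried through (e.g. hours since medium
#'   switch).
#' @return A tibble: `time_label`, `medium` (`"glucose"` or `"ypd"`),
#'   `plate`, `count`, `n_plated`.
#' @export
#' @examples
#' gen_plate_counts(frac_adapted = 0.1, n_plated = 200, seed = 1)
gen_plate_counts <- function(frac_adapted, n_plated = 200L,
                             n_glu_plates = 3L, n_ypd_plates = 2L,
                             plating_efficiency = 1, seed = 1L,
                             time_label = NA_real_) {
  check_number(frac_adapted, "frac_adapted", lower = 0, upper = 1.2)
  check_number(plating_efficiency, "plating_efficiency", lower = 0,
               upper = 1.2)
  check_count(n_plated, "n_plated")
  check_count(n_glu_plates, "n_glu_plates")
  check_count(n_ypd_plates, "n_ypd_plates")
  with_seed(substream_seed(seed, "plate_counts"), {
    lam_ypd <- n_plated * plating_efficiency
    lam_glu <- lam_ypd * frac_adapted
    tibble::tibble(
      time_label = time_label,
      medium = rep(c("glucose", "ypd"), c(n_glu_plates, n_ypd_plates)),
      plate = c(seq_len(n_glu_plates), seq_len(n_ypd_plates)),
      count = c(rpois(n_glu_plates, lam_glu), rpois(n_ypd_plates, lam_ypd)),
      n_plated = as.integer(n_plated)
    )
  })
}
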