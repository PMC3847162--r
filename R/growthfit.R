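#' Segment one bright-field frame into colony regions
#'
#' Default backend: Gaussian smoothing, Otsu thresholding and
#' connected-component labelling (via EBImage), followed by a minimum-area
#' filter. Areas and centroids are computed from the label matrix. The
#' backend is deliberately simple — colony morphology carries no information
#' downstream, only per-colony area and centroid do — and the rest of the
#' pipeline equally accepts pre-extracted area tables
#' ([read_area_table()]).
#'
#' @param image Single-channel 2-D numeric matrix (rows = y, columns = x).
#' @param min_area Minimum region area in pixels; smaller components are
#'   dropped as debris.
#' @param smooth_sigma SD (pixels) of the Gaussian pre-filter; 0 disables.
#' @param threshold `"otsu"` or a numeric intensity cutoff.
#' @return A tibble with one row per region: `region`, `area_px`, `cx`, `cy`
#'   (pixel coordinates, `cx` along columns). A blank (constant) frame gives
#'   zero rows.
#' @export
segment_frame <- function(image, min_area = 10, smooth_sigma = 2,
                          threshold = "otsu") {
  stopifnot(is.matrix(image), is.numeric(image))
  empty <- tibble::tibble(region = integer(), area_px = double(),
                          cx = double(), cy = double())
  if (diff(range(image)) < .Machine$double.eps^0.5) {
    return(empty)
  }
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("segment_frame needs the EBImage package; alternatively supply pre-extracted area tables.")
  }
  img <- image
  if (smooth_sigma > 0) {
    img <- EBImage::gblur(img, sigma = smooth_sigma)
  }
  rng <- range(img)
  scaled <- (img - rng[1]) / (rng[2] - rng[1])
  cut <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(scaled))
  } else {
    (threshold - rng[1]) / (rng[2] - rng[1])
  }
  labels <- EBImage::bwlabel(scaled > cut)
  lab <- as.integer(labels)
  if (all(lab == 0)) {
    return(empty)
  }
  rows <- matrix(rep(seq_len(nrow(image)), times = ncol(image)),
                 nrow = nrow(image))
  cols <- matrix(rep(seq_len(ncol(image)), each = nrow(image)),
                 nrow = nrow(image))
  keep <- lab > 0
  out <- tibble::tibble(lab = lab[keep], row = rows[keep], col = cols[keep]) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(area_px = dplyr::n(), cx = mean(.data$col),
                     cy = mean(.data$row), .groups = "drop") |>
    dplyr::filter(.data$area_px >= min_area) |>
    dplyr::arrange(.data$cy, .data$cx)
  tibble::tibble(region = seq_len(nrow(out)), area_px = as.double(out$area_px),
                 cx = out$cx, cy = out$cy)
}

#' Track colonies across frames by centroid correlation
#'
#' Greedy nearest-centroid matching: region pairs across consecutive frames
#' are linked in order of increasing centroid displacement, subject to a
#' maximum displacement per frame (default: one mean colony radius in the
#' first frame). Equidistant candidates are resolved deterministically by
#' smallest area difference. Unmatched new regions start new tracks; a track
#' whose head finds no free region is flagged `lost` — and both tracks are
#' flagged `merged` when the lost head's nearest region was claimed by
#' another track (two colonies have grown into one region). Tracks whose
#' colony ever comes within `edge_margin` plus its own radius of the field
#' border are flagged `edge_proximal`.
#'
#' @param regions A list of per-frame region tibbles from [segment_frame()],
#'   or one tibble with a `frame` column.
#' @param times Frame acquisition times in hours (default `0, 1, 2, ...`).
#' @param max_displacement Maximum centroid displacement per frame, pixels.
#' @param field_shape `c(rows, cols)` of the field of view, needed for edge
#'   flags (skipped when `NULL`).
#' @param edge_margin Distance (pixels) from the border that counts as "too
#'   close to the edge".
#' @return A long tibble: `colony_id`, `frame`, `time_h`, `area_px`, `cx`,
#'   `cy`, and per-colony flags `edge_proximal`, `merged`, `lost` (constant
#'   within a colony).
#' @export
track_colonies <- function(regions, times = NULL, max_displacement = NULL,
                           field_shape = NULL, edge_margin = 5) {
  if (is.data.frame(regions)) {
    stopifnot("frame" %in% names(regions))
    regions <- split(regions, regions$frame)
  }
  n_frames <- length(regions)
  if (n_frames < 2) {
    abort("tracking needs at least 2 frames.",
          class = "growthdyn_config_error")
  }
  times <- times %||% (seq_len(n_frames) - 1)
  stopifnot(length(times) == n_frames)

  first <- regions[[1]]
  if (is.null(max_displacement)) {
    max_displacement <- if (nrow(first) > 0) {
      mean(sqrt(first$area_px / pi))
    } else {
      10
    }
  }

  next_id <- 0L
  heads <- tibble::tibble(colony_id = integer(), cx = double(),
                          cy = double(), area_px = double())
  obs <- list()
  flags <- new.env(parent = emptyenv())
  set_flag <- function(id, what) {
    key <- as.character(id)
    f <- get0(key, envir = flags,
              ifnotfound = c(edge_proximal = FALSE, merged = FALSE,
                             lost = FALSE))
    f[what] <- TRUE
    assign(key, f, envir = flags)
  }
  add_obs <- function(id, k, reg_row) {
    obs[[length(obs) + 1]] <<- tibble::tibble(
      colony_id = id, frame = k, time_h = times[k],
      area_px = reg_row$area_px, cx = reg_row$cx, cy = reg_row$cy)
  }

  for (k in seq_len(n_frames)) {
    regs <- regions[[k]]
    if (k == 1 || nrow(heads) == 0) {
      assigned_region <- integer(0)
      matched_head <- integer(0)
    } else {
      d <- outer(heads$cx, regs$cx %||% double(0), "-")^2 +
        outer(heads$cy, regs$cy %||% double(0), "-")^2
      d <- sqrt(d)
      ad <- abs(outer(heads$area_px, regs$area_px, "-"))
      matched_head <- integer(0)
      assigned_region <- integer(0)
      if (length(d) > 0) {
        repeat {
          d_open <- d
          if (length(matched_head)) d_open[matched_head, ] <- Inf
          if (length(assigned_region)) d_open[, assigned_region] <- Inf
          dmin <- min(d_open)
          if (!is.finite(dmin) || dmin > max_displacement) break
          cand <- which(d_open <= dmin + 1e-9, arr.ind = TRUE)
          # deterministic tie-break: smallest area difference
          pick <- cand[order(ad[cand], cand[, 1], cand[, 2])[1], , drop = TRUE]
          matched_head <- c(matched_head, pick[1])
          assigned_region <- c(assigned_region, pick[2])
          add_obs(heads$colony_id[pick[1]], k, regs[pick[2], ])
        }
      }
      # heads left behind: lost; if their nearest region was claimed by
      # another track the two colonies have merged into one region
      for (h in setdiff(seq_len(nrow(heads)), matched_head)) {
        set_flag(heads$colony_id[h], "lost")
        if (ncol(d) > 0) {
          nearest <- which.min(d[h, ])
          if (d[h, nearest] <= max_displacement &&
              nearest %in% assigned_region) {
            winner <- matched_head[match(nearest, assigned_region)]
            set_flag(heads$colony_id[h], "merged")
            set_flag(heads$colony_id[winner], "merged")
          }
        }
      }
    }
    # unmatched regions found new tracks
    new_regions <- setdiff(seq_len(nrow(regs)), assigned_region)
    new_ids <- integer(0)
    for (j in new_regions) {
      next_id <- next_id + 1L
      new_ids <- c(new_ids, next_id)
      add_obs(next_id, k, regs[j, ])
    }
    # rebuild heads from this frame's observations
    live <- c(if (length(matched_head)) heads$colony_id[matched_head],
              new_ids)
    this_frame <- dplyr::bind_rows(obs) |>
      dplyr::filter(.data$frame == k, .data$colony_id %in% live)
    heads <- tibble::tibble(colony_id = this_frame$colony_id,
                            cx = this_frame$cx, cy = this_frame$cy,
                            area_px = this_frame$area_px)
    # edge proximity
    if (!is.null(field_shape)) {
      r <- sqrt(this_frame$area_px / pi)
      near <- this_frame$cx - r < edge_margin |
        this_frame$cy - r < edge_margin |
        this_frame$cx + r > field_shape[2] - edge_margin |
        this_frame$cy + r > field_shape[1] - edge_margin
      for (id in this_frame$colony_id[near]) set_flag(id, "edge_proximal")
    }
  }

  out <- dplyr::bind_rows(obs) |> dplyr::arrange(.data$colony_id, .data$frame)
  fl <- purrr::map_dfr(unique(out$colony_id), function(id) {
    f <- get0(as.character(id), envir = flags,
              ifnotfound = c(edge_proximal = FALSE, merged = FALSE,
                             lost = FALSE))
    tibble::tibble(colony_id = id, edge_proximal = f[["edge_proximal"]],
                   merged = f[["merged"]], lost = f[["lost"]])
  })
  dplyr::left_join(out, fl, by = "colony_id")
}

#' Fit an exponential growth curve to one colony's area trajectory
#'
#' Fits the two-parameter model `area = A * exp(B * t)` by least squares on
#' the area scale (Levenberg-Marquardt), initialized from a log-linear OLS
#' fit; `B` is the colony's instantaneous growth rate in 1/hour. The
#' goodness-of-fit statistic is `Rsq = 1 - SS_res / SS_tot`, also on the
#' area scale, and fits are gated strictly: `Rsq > rsq_threshold` is
#' accepted, anything at or below is `rejected_rsq`. Trajectories longer
#' than about `window_generations` doublings of the (initializer-estimated)
#' rate are windowed from the start so that the fit measures an
#' instantaneous, single-exponent rate. A constant-area trajectory has no
#' variance to explain (`SS_tot = 0`): it is classified `non_growing` with
#' `B = 0` and undefined Rsq.
#'
#' @param track Tibble with columns `time_h` and `area_px` for one colony
#'   (strictly increasing times, positive areas, >= 3 frames).
#' @param rsq_threshold Acceptance gate on Rsq (strict inequality).
#' @param window_generations Cap on trajectory length, in doublings of the
#'   fitted rate.
#' @param fit_scale `"area"` (nonlinear fit, the default) or `"log"`
#'   (log-linear OLS only).
#' @return A one-row tibble: `colony_id` (if present), `a`, `b`, `rsq`,
#'   `n_frames_used`, `status`, `rejection_reason`.
#' @export
#' @examples
#' tr <- tibble::tibble(time_h = 0:12, area_px = 1.59 * exp(0.216 * 0:12))
#' fit_exponential(tr)
fit_exponential <- function(track, rsq_threshold = 0.95,
                            window_generations = 3,
                            fit_scale = c("area", "log")) {
  fit_scale <- match.arg(fit_scale)
  stopifnot(all(c("time_h", "area_px") %in% names(track)))
  id <- if ("colony_id" %in% names(track)) track$colony_id[1] else NA_integer_
  t <- track$time_h
  y <- track$area_px
  if (length(t) < 3) {
    abort("an exponential fit needs at least 3 frames.",
          class = "growthdyn_config_error")
  }
  if (any(diff(t) <= 0)) {
    abort("frame times must be strictly increasing.",
          class = "growthdyn_config_error")
  }
  if (any(y <= 0)) {
    abort("areas must be positive.", class = "growthdyn_config_error")
  }
  row <- function(a, b, rsq, n_used, status, reason = NA_character_) {
    tibble::tibble(colony_id = id, a = a, b = b, rsq = rsq,
                   n_frames_used = n_used, status = status,
                   rejection_reason = reason)
  }
  if (diff(range(y)) < .Machine$double.eps^0.5 * max(y)) {
    return(row(mean(y), 0, NA_real_, length(t), "non_growing",
               "constant area (SS_tot = 0)"))
  }

  init <- lm(log(y) ~ t)
  b0 <- unname(coef(init)[2])
  a0 <- exp(unname(coef(init)[1]))

  # instantaneous-rate window: keep ~window_generations doublings
  keep <- rep(TRUE, length(t))
  if (b0 > 0) {
    cap <- window_generations * log(2) / b0
    keep <- (t - t[1]) <= cap + 1e-9
    if (sum(keep) < 3) keep[seq_len(3)] <- TRUE
  }
  tw <- t[keep]
  yw <- y[keep]
  if (sum(keep) < length(t)) {
    init <- lm(log(yw) ~ tw)
    b0 <- unname(coef(init)[2])
    a0 <- exp(unname(coef(init)[1]))
  }

  if (fit_scale == "log") {
    fitted_y <- exp(predict(init))
    a <- a0
    b <- b0
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(yw ~ A * exp(B * tw), start = list(A = a0, B = b0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      a <- a0
      b <- b0
      fitted_y <- a * exp(b * tw)
    } else {
      a <- unname(coef(fit)[["A"]])
      b <- unname(coef(fit)[["B"]])
      fitted_y <- predict(fit)
    }
  }
  ss_res <- sum((yw - fitted_y)^2)
  ss_tot <- sum((yw - mean(yw))^2)
  rsq <- 1 - ss_res / ss_tot
  if (rsq > rsq_threshold) {
    row(a, b, rsq, sum(keep), "accepted")
  } else {
    row(a, b, rsq, sum(keep), "rejected_rsq",
        sprintf("Rsq = %.3f <= %.2f", rsq, rsq_threshold))
  }
}

#' Fit every colony in a track table
#'
#' Applies [fit_exponential()] per colony.
#'
#' @param tracks Long tibble with `colony_id`, `time_h`, `area_px`.
#' @param ... Passed to [fit_exponential()].
#' @return A tibble of fits, one row per colony.
#' @export
fit_colonies <- function(tracks, ...) {
  stopifnot(all(c("colony_id", "time_h", "area_px") %in% names(tracks)))
  tracks |>
    dplyr::group_by(.data$colony_id) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_exponential(df, ...)
      dplyr::select(f, -"colony_id")
    }) |>
    dplyr::ungroup()
}

#' Apply edge and proximity exclusions to fitted colonies
#'
#' Colonies flagged `edge_proximal` or `merged` are excluded regardless of
#' fit quality (`rejected_exclusion`). Sub-threshold fits keep their
#' `rejected_rsq` status; they are additionally collected into a review
#' queue (attribute `"review_queue"`) mirroring a manual re-examination step
#' that this pipeline deliberately does not automate — conservative and
#' reproducible.
#'
#' @param fits Tibble of fits from [fit_colonies()].
#' @param tracks Optional track tibble carrying `edge_proximal` / `merged`
#'   flag columns (as produced by [track_colonies()]).
#' @param flags Optional explicit per-colony flag tibble (`colony_id`,
#'   `edge_proximal`, `merged`); overrides `tracks`.
#' @return The fits tibble with final `status`, with the review queue
#'   attached as attribute `"review_queue"`.
#' @export
apply_exclusions <- function(fits, tracks = NULL, flags = NULL) {
  if (is.null(flags)) {
    if (!is.null(tracks) &&
        all(c("edge_proximal", "merged") %in% names(tracks))) {
      flags <- tracks |>
        dplyr::distinct(.data$colony_id, .data$edge_proximal, .data$merged)
    } else {
      flags <- tibble::tibble(colony_id = fits$colony_id,
                              edge_proximal = FALSE, merged = FALSE)
    }
  }
  out <- dplyr::left_join(fits, flags, by = "colony_id") |>
    dplyr::mutate(
      edge_proximal = dplyr::coalesce(.data$edge_proximal, FALSE),
      merged = dplyr::coalesce(.data$merged, FALSE),
      excluded = .data$edge_proximal | .data$merged,
      rejection_reason = dplyr::if_else(
        .data$excluded,
        dplyr::if_else(.data$edge_proximal, "too close to field edge",
                       "grew too close to another colony"),
        .data$rejection_reason),
      status = dplyr::if_else(.data$excluded, "rejected_exclusion",
                              .data$status)
    ) |>
    dplyr::select(-"edge_proximal", -"merged", -"excluded")
  attr(out, "review_queue") <- dplyr::filter(out,
                                             .data$status == "rejected_rsq")
  out
}

#' Summarize an accepted growth-rate distribution
#'
#' Builds the histogram of accepted instantaneous rates with per-bin
#' bootstrap errors, reports mean, SD, SEM (= SD/sqrt(n)) and CV
#' (= SD/mean) with a bootstrap SE on the CV, and runs a
#' subsample-convergence diagnostic: the mean of random subsets should
#' converge to the full mean within one SEM as the subset grows, indicating
#' the sample is large enough to represent the distribution.
#'
#' @param fits Tibble of fits with final statuses.
#' @param n_bins Number of histogram bins.
#' @param bootstrap_reps Bootstrap resamples for per-bin and CV errors.
#' @param seed Integer seed for the bootstrap.
#' @param min_n Fewer accepted fits than this raises a warning (not an
#'   error); distributions with at least ~100 colonies are considered
#'   reliable.
#' @return An object of class `rate_distribution`: list with `rates`,
#'   `histogram` (tibble `bin_lo`, `bin_hi`, `count`, `boot_sd`), `mean`,
#'   `sd`, `sem`, `cv`, `cv_se`, `n`, `convergence` (tibble `subset_n`,
#'   `subset_mean`).
#' @export
summarize_rates <- function(fits, n_bins = 20, bootstrap_reps = 200,
                            seed = 1L, min_n = 100) {
  rates <- fits$b[fits$status == "accepted"]
  n <- length(rates)
  if (n == 0) {
    abort("no accepted fits to summarize.", class = "growthdyn_config_error")
  }
  if (n < min_n) {
    warn(sprintf("only %d accepted fits (fewer than %d); summary statistics may be unreliable.",
                 n, min_n))
  }
  m <- mean(rates)
  s <- if (n > 1) sd(rates) else 0
  with_seed(substream_seed(seed, "summarize_rates"), {
    if (s == 0) {
      breaks <- c(m - 0.5, m + 0.5)
    } else {
      breaks <- seq(min(rates), max(rates), length.out = n_bins + 1)
      breaks[1] <- breaks[1] - 1e-12
    }
    counts <- as.double(table(cut(rates, breaks, include.lowest = TRUE)))
    boot_counts <- matrix(0, bootstrap_reps, length(counts))
    boot_cv <- numeric(bootstrap_reps)
    for (r in seq_len(bootstrap_reps)) {
      res <- sample(rates, n, replace = TRUE)
      boot_counts[r, ] <- as.double(table(cut(res, breaks,
                                              include.lowest = TRUE)))
      boot_cv[r] <- if (mean(res) != 0) sd(res) / mean(res) else NA_real_
    }
    conv_sizes <- unique(pmax(2, round(n * seq(0.1, 1, by = 0.1))))
    convergence <- purrr::map_dfr(conv_sizes, function(k) {
      tibble::tibble(subset_n = k, subset_mean = mean(sample(rates, k)))
    })
    structure(
      list(rates = rates,
           histogram = tibble::tibble(bin_lo = head(breaks, -1),
                                      bin_hi = tail(breaks, -1),
                                      count = counts,
                                      boot_sd = apply(boot_counts, 2, sd)),
           mean = m, sd = s, sem = s / sqrt(n),
           cv = if (m != 0) s / m else NA_real_,
           cv_se = sd(boot_cv, na.rm = TRUE),
           n = n, convergence = convergence),
      class = "rate_distribution"
    )
  })
}

#' @export
print.rate_distribution <- function(x, ...) {
  cat(sprintf("<rate_distribution> n = %d accepted colonies\n", x$n))
  cat(sprintf("  mean %.4f /h +/- %.4f (SEM), sd %.4f, CV %.3f +/- %.3f\n",
              x$mean, x$sem, x$sd, x$cv, x$cv_se))
  cat(sprintf("  mean division time %.2f h\n", log(2) / x$mean))
  invisible(x)
}

#' @rdname summarize_rates
#' @param x,object A `rate_distribution`.
#' @param ... Unused.
#' @method tidy rate_distribution
#' @export
tidy.rate_distribution <- function(x, ...) {
  x$histogram
}

#' @rdname summarize_rates
#' @method glance rate_distribution
#' @export
glance.rate_distribution <- function(x, ...) {
  tibble::tibble(n = x$n, mean = x$mean, sd = x$sd, sem = x$sem, cv = x$cv,
                 cv_se = x$cv_se, division_time_h = log(2) / x$mean)
}

#' @rdname summarize_rates
#' @method autoplot rate_distribution
#' @export
autoplot.rate_distribution <- function(object, ...) {
  h <- object$histogram
  h$mid <- (h$bin_lo + h$bin_hi) / 2
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue", colour = "grey30",
                      width = (h$bin_hi - h$bin_lo) * 0.95) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$count - .data$boot_sd,
                                        ymax = .data$count + .data$boot_sd),
                           width = 0) +
    ggplot2::labs(x = "instantaneous growth rate (1/h)", y = "colonies",
                  title = sprintf("n = %d, mean = %.3f /h, CV = %.2f",
                                  object$n, object$mean, object$cv)) +
    ggplot2::theme_minimal()
}

#' Fraction of colonies growing exponentially
#'
#' Accepted fits divided by all non-excluded fits (accepted + non-growing +
#' sub-threshold); edge/proximity exclusions are removed from the
#' denominator because they say nothing about the colony's growth mode.
#'
#' @param fits Tibble of fits with final statuses.
#' @return A single fraction in `[0, 1]`.
#' @export
fraction_exponential <- function(fits) {
  denom <- sum(fits$status %in% c("accepted", "non_growing", "rejected_rsq"))
  if (denom == 0) {
    abort("no non-excluded fits.", class = "growthdyn_config_error")
  }
  sum(fits$status == "accepted") / denom
}
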