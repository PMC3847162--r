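#' Quadratic variance-versus-mean law
#'
#' `variance = a + b * mean + c * mean^2`. Families of fixed-shape
#' distributions whose spread follows such a law collapse onto one curve
#' under standardization; the law is both a generator input
#' ([gen_fluorescence_snapshots()]) and the object returned by
#' [fit_variance_mean()].
#'
#' @param a Intercept (units^2).
#' @param b Linear coefficient (units).
#' @param c Quadratic coefficient (dimensionless).
#' @return An object of class `quadratic_law`.
#' @export
#' @examples
#' law <- quadratic_law(-5.39, 1478, 0.48)
#' predict(law, c(100, 1000))
quadratic_law <- function(a, b, c) {
  check_number(a, "a")
  check_number(b, "b")
  check_number(c, "c")
  structure(list(a = a, b = b, c = c), class = "quadratic_law")
}

#' @rdname quadratic_law
#' @param object A `quadratic_law`.
#' @param newdata Numeric vector of means.
#' @param ... Unused.
#' @export
predict.quadratic_law <- function(object, newdata, ...) {
  object$a + object$b * newdata + object$c * newdata^2
}

#' @export
print.quadratic_law <- function(x, ...) {
  cat(sprintf("<quadratic_law> variance = %.4g + %.4g*mean + %.4g*mean^2\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Standardize a sample (subtract the mean, divide by the SD)
#'
#' The scaling transform behind distribution collapse: affinely related
#' samples become identical after standardization, so a family of snapshots
#' that share one base shape superimposes onto a single curve.
#'
#' @param x Numeric vector with positive SD.
#' @return A numeric vector with mean 0 and SD 1.
#' @export
#' @examples
#' z <- standardize(rnorm(100, 50, 5))
#' c(mean(z), sd(z))
standardize <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot standardize a degenerate (zero-SD) sample.",
          class = "growthdyn_degenerate_error")
  }
  (x - mean(x)) / s
}

#' Standardize snapshots of a long value table, group-wise
#'
#' @param data Long tibble of snapshot values.
#' @param value Column of single-cell values.
#' @param group Column identifying the snapshot.
#' @return `data` with an added `standardized` column.
#' @export
standardize_snapshots <- function(data, value = "value",
                                  group = "snapshot") {
  stopifnot(all(c(value, group) %in% names(data)))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::mutate(standardized = standardize(.data[[value]])) |>
    dplyr::ungroup()
}

#' Per-snapshot moments of a long value table
#'
#' @inheritParams standardize_snapshots
#' @return A tibble with one row per snapshot: group column(s), `n`, `mean`,
#'   `sd`, `variance`.
#' @export
snapshot_moments <- function(data, value = "value", group = "snapshot") {
  stopifnot(all(c(value, group) %in% names(data)))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data[[value]]),
                     sd = sd(.data[[value]]),
                     variance = var(.data[[value]]), .groups = "drop")
}

#' Quantify the scaling collapse of a snapshot family
#'
#' Standardizes every snapshot and computes the pairwise two-sample
#' Kolmogorov-Smirnov statistic (or Cramer-von Mises, rescaled to a
#' comparable magnitude) between standardized empirical distributions. A
#' family drawn from one base shape gives distances at the KS sampling-noise
#' floor; genuinely different shapes stand far above it. The summary is the
#' maximum pairwise distance.
#'
#' @inheritParams standardize_snapshots
#' @param method `"ks"` (default) or `"cvm"`.
#' @return An object of class `collapse_distance`: list with `pairs` (tibble
#'   `group_a`, `group_b`, `distance`), `matrix`, `max_distance`, `method`,
#'   `n_per_snapshot`.
#' @export
#' @examples
#' snaps <- gen_fluorescence_snapshots(c(10, 20, 40), quadratic_law(0, 1, 0.1),
#'                                     n_cells = 500, seed = 1)
#' collapse_distance(snaps)$max_distance
collapse_distance <- function(data, value = "value", group = "snapshot",
                              method = c("ks", "cvm")) {
  method <- match.arg(method)
  stopifnot(all(c(value, group) %in% names(data)))
  groups <- split(data[[value]], data[[group]])
  if (length(groups) < 2) {
    abort("need at least 2 snapshots.", class = "growthdyn_config_error")
  }
  z <- purrr::map(groups, standardize)
  ids <- names(groups)
  k <- length(ids)
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      d <- if (method == "ks") {
        # direct sup|F1 - F2| over the pooled sample: exact under ties
        pooled <- sort(c(z[[i]], z[[j]]))
        max(abs(stats::ecdf(z[[i]])(pooled) - stats::ecdf(z[[j]])(pooled)))
      } else {
        # two-sample Cramer-von Mises statistic, normalized per sample
        nx <- length(z[[i]])
        ny <- length(z[[j]])
        pooled <- sort(c(z[[i]], z[[j]]))
        fx <- stats::ecdf(z[[i]])(pooled)
        fy <- stats::ecdf(z[[j]])(pooled)
        sqrt(sum((fx - fy)^2) * nx * ny / (nx + ny)^2)
      }
      d <- unname(d)
      m[i, j] <- m[j, i] <- d
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        group_a = ids[i], group_b = ids[j], distance = d)
    }
  }
  structure(
    list(pairs = dplyr::bind_rows(pairs), matrix = m,
         max_distance = max(m), method = method,
         n_per_snapshot = lengths(groups)),
    class = "collapse_distance"
  )
}

#' @export
print.collapse_distance <- function(x, ...) {
  cat(sprintf("<collapse_distance> %d snapshots, %s metric, max distance %.4f\n",
              ncol(x$matrix), toupper(x$method), x$max_distance))
  invisible(x)
}

#' @rdname collapse_distance
#' @param x A `collapse_distance`.
#' @param ... Unused.
#' @method tidy collapse_distance
#' @export
tidy.collapse_distance <- function(x, ...) {
  x$pairs
}

#' Critical value of the two-sample KS statistic
#'
#' Asymptotic null quantile `c(alpha) * sqrt((n + m) / (n * m))` with
#' `c(alpha) = sqrt(-log(alpha / 2) / 2)`; the sampling-noise floor against
#' which a measured collapse distance is judged.
#'
#' @param n,m Sample sizes.
#' @param alpha Significance level.
#' @return The critical KS distance.
#' @export
ks_critical <- function(n, m = n, alpha = 0.05) {
  sqrt(-log(alpha / 2) / 2) * sqrt((n + m) / (n * m))
}

#' Fit the variance-versus-mean quadratic law
#'
#' Ordinary least squares of snapshot variance on `(1, mean, mean^2)`
#' (unweighted by default; supply `weights` for heteroscedastic fits), or on
#' `(1, mean)` when the quadratic term is suppressed for model comparison.
#'
#' @param data Tibble with one row per snapshot, or a long value table (in
#'   which case moments are computed with [snapshot_moments()]).
#' @param mean_col,var_col Column names of the per-snapshot mean and
#'   variance.
#' @param quadratic Set `FALSE` to constrain the quadratic coefficient to 0.
#' @param weights Optional OLS weights.
#' @return An object of class `varmean_fit`: list with `law`
#'   ([quadratic_law()]), `fit` (the underlying `lm`), `data`.
#' @export
#' @examples
#' law <- quadratic_law(-5.39, 1478, 0.48)
#' pts <- tibble::tibble(mean = seq(100, 1000, length.out = 10),
#'                       variance = predict(law, seq(100, 1000,
#'                                                   length.out = 10)))
#' coef(fit_variance_mean(pts)$fit)
fit_variance_mean <- function(data, mean_col = "mean", var_col = "variance",
                              quadratic = TRUE, weights = NULL) {
  if (!all(c(mean_col, var_col) %in% names(data)) &&
      all(c("snapshot", "value") %in% names(data))) {
    data <- snapshot_moments(data)
  }
  stopifnot(all(c(mean_col, var_col) %in% names(data)))
  df <- tibble::tibble(m = data[[mean_col]], v = data[[var_col]])
  need <- if (quadratic) 4 else 3
  if (nrow(df) < need) {
    abort(sprintf("need at least %d snapshots.", need),
          class = "growthdyn_config_error")
  }
  if (length(unique(df$m)) < (if (quadratic) 3 else 2)) {
    abort("degenerate design: snapshot means are not distinct enough.",
          class = "growthdyn_fit_error")
  }
  fit <- if (quadratic) {
    lm(v ~ m + I(m^2), data = df, weights = weights)
  } else {
    lm(v ~ m, data = df, weights = weights)
  }
  cf <- coef(fit)
  law <- quadratic_law(unname(cf[1]), unname(cf[2]),
                       if (quadratic) unname(cf[3]) else 0)
  structure(list(law = law, fit = fit, data = df, quadratic = quadratic),
            class = "varmean_fit")
}

#' @export
print.varmean_fit <- function(x, ...) {
  print(x$law)
  cat(sprintf("  fitted on %d snapshots, residual SD %.4g\n",
              nrow(x$data), sqrt(mean(resid(x$fit)^2))))
  invisible(x)
}

#' @rdname fit_variance_mean
#' @param x,object A `varmean_fit`.
#' @param ... Unused.
#' @method tidy varmean_fit
#' @export
tidy.varmean_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("a", "b", "c")[seq_len(nrow(s))],
                 estimate = s[, 1], std_error = s[, 2])
}

#' @rdname fit_variance_mean
#' @method glance varmean_fit
#' @export
glance.varmean_fit <- function(x, ...) {
  tibble::tibble(a = x$law$a, b = x$law$b, c = x$law$c,
                 r_squared = summary(x$fit)$r.squared,
                 sigma = summary(x$fit)$sigma, n = nrow(x$data))
}

#' @rdname fit_variance_mean
#' @method autoplot varmean_fit
#' @export
autoplot.varmean_fit <- function(object, ...) {
  grid <- tibble::tibble(m = seq(min(object$data$m), max(object$data$m),
                                 length.out = 200))
  grid$v <- predict(object$law, grid$m)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$m, y = .data$v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "snapshot mean", y = "snapshot variance",
                  title = sprintf("variance = %.3g + %.3g m + %.3g m^2",
                                  object$law$a, object$law$b,
                                  object$law$c)) +
    ggplot2::theme_minimal()
}

#' Windowed coefficient of variation of a time series
#'
#' Splits a series into consecutive windows of fixed duration and reports
#' sigma/mu per window — the statistic used to compare fluctuation
#' magnitudes between background and adaptation-phase stretches of a
#' density or expression record.
#'
#' @param data Tibble with time and value columns, or a numeric vector (then
#'   `dt` supplies the sampling interval).
#' @param window Window duration, in the series' time units.
#' @param time_col,value_col Column names.
#' @param dt Sampling interval when `data` is a bare vector.
#' @return A tibble: `window`, `t_start`, `t_mid`, `n`, `mean`, `sd`, `cv`.
#' @export
windowed_cv <- function(data, window, time_col = "time", value_col = "value",
                        dt = 1) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- tibble::tibble(time = (seq_along(data) - 1) * dt, value = data)
    time_col <- "time"
    value_col <- "value"
  }
  stopifnot(all(c(time_col, value_col) %in% names(data)))
  tt <- data[[time_col]]
  vv <- data[[value_col]]
  if (any(vv < 0)) {
    warn("negative values: sigma/mu is hard to interpret for sign-changing series.")
  }
  span <- diff(range(tt))
  if (window >= span) {
    abort("`window` must be shorter than the series span.",
          class = "growthdyn_config_error")
  }
  idx <- floor((tt - min(tt)) / window)
  # a final sliver shorter than half a window joins the previous one
  tibble::tibble(window = idx, t = tt, v = vv) |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(t_start = min(.data$t), t_mid = mean(.data$t),
                     n = dplyr::n(), mean = mean(.data$v),
                     sd = if (dplyr::n() > 1) sd(.data$v) else 0,
                     .groups = "drop") |>
    dplyr::mutate(cv = .data$sd / .data$mean)
}

#' Autocorrelation time of a uniformly sampled series
#'
#' The first lag at which the autocorrelation of the mean-removed series
#' drops below 1/e, linearly interpolated between lags. Distinguishes fast
#' "noise-like" fluctuations (about one sampling interval) from slow
#' relaxation over many generations.
#'
#' @param x Numeric series, uniformly sampled, at least 50 points.
#' @param dt Sampling interval (hours).
#' @param generation_time Optional generation time (hours); adds the result
#'   in generations.
#' @return A one-row tibble: `tau` (same units as `dt`), `tau_lags`, and
#'   `tau_generations` when `generation_time` is given.
#' @export
autocorrelation_time <- function(x, dt = 1, generation_time = NULL) {
  stopifnot(is.numeric(x))
  if (length(x) < 50) {
    abort("need at least 50 samples.", class = "growthdyn_config_error")
  }
  if (sd(x) == 0) {
    abort("autocorrelation time is undefined for a constant series.",
          class = "growthdyn_degenerate_error")
  }
  rho <- as.numeric(acf(x - mean(x), lag.max = length(x) - 2,
                        plot = FALSE)$acf)
  target <- exp(-1)
  below <- which(rho < target)
  if (length(below) == 0) {
    tau_lag <- NA_real_
  } else {
    k <- below[1]  # 1-based: rho[1] is lag 0
    if (k == 1) {
      tau_lag <- 0
    } else {
      frac <- (rho[k - 1] - target) / (rho[k - 1] - rho[k])
      tau_lag <- (k - 2) + frac
    }
  }
  out <- tibble::tibble(tau = tau_lag * dt, tau_lags = tau_lag)
  if (!is.null(generation_time)) {
    out$tau_generations <- out$tau / generation_time
  }
  out
}
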