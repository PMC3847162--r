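#' Configuration for the lineage-selection simulator
#'
#' Describes a clonal population founded by `n_founders` cells whose
#' instantaneous growth rates are drawn from a Gaussian with mean
#' `founder_mean_rate` and coefficient of variation `founder_cv`. Under
#' `"stable"` inheritance a founder's rate is passed unchanged to all
#' descendants (the selection null model); under `"switching"` each cell
#' re-draws its rate at exponentially distributed waiting times with rate
#' `switch_rate`, a minimal model of a metastable phenotype.
#'
#' Two engines are available. The default `"lineage"` engine propagates
#' per-founder lineage frequencies as exact exponentials between protocol
#' events, with stochasticity entering only at dilution sampling and
#' switching events; it handles astronomically large populations because only
#' frequencies and a log population size are stored. The `"agent"` engine
#' simulates every cell individually (divisions as Bernoulli events per time
#' step) and is intended for cross-validation at up to ~10^4 founders.
#'
#' Time is dimensionless by default (rates in inverse simulation time);
#' protocols that need wall-clock units interpret times as hours.
#'
#' @param n_founders Number of founder cells (>= 1).
#' @param founder_mean_rate Mean founder growth rate (1/time).
#' @param founder_cv Coefficient of variation of founder rates (>= 0).
#' @param inheritance `"stable"` or `"switching"`.
#' @param switch_rate Switching-mode rate of phenotype re-draws, per cell per
#'   unit time.
#' @param redraw Switching-mode redraw distribution: `"founder"` re-draws
#'   from the founder Gaussian (exploration without drift); `"ou"` re-draws
#'   locally around the switching cell's current rate
#'   (an Ornstein-Uhlenbeck-flavoured extension).
#' @param ou_sd SD of local re-draws when `redraw = "ou"`.
#' @param protocol `"none"`, `"serial_dilution"` or `"chemostat"`.
#' @param dilution_interval Hours between serial-dilution transfers.
#' @param dilution_range Two-element range of dilution factors; each transfer
#'   draws a factor uniformly from it (use equal endpoints for a fixed
#'   factor).
#' @param min_transfer Minimum number of cells that must survive a transfer;
#'   fewer aborts the protocol (the bottleneck guard).
#' @param chemostat_rate Chemostat dilution rate (1/hour).
#' @param horizon_time,horizon_generations Stop after this much time and/or
#'   this many population doublings (whichever comes first; at least one
#'   required).
#' @param checkpoint_interval Time between recorded checkpoints (also the
#'   integration step for switching and the agent engine).
#' @param engine `"lineage"` or `"agent"`.
#' @param stochastic If `FALSE`, run in deterministic expectation mode: no
#'   sampling anywhere (dilutions scale sizes exactly, switching moves
#'   expected mass). Founder rates are still drawn unless `founder_rates` is
#'   supplied.
#' @param founder_rates Optional explicit founder rates (overrides the
#'   Gaussian draw).
#' @param founder_sizes Optional initial lineage sizes (default: 1 cell
#'   each).
#' @param max_new_lineages Cap on new rate classes created per step by
#'   switching in the lineage engine (switch events are pooled beyond it).
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' sim_config(n_founders = 100, horizon_generations = 3)
sim_config <- function(n_founders = 1000L,
                       founder_mean_rate = 1,
                       founder_cv = 0.3,
                       inheritance = c("stable", "switching"),
                       switch_rate = 0,
                       redraw = c("founder", "ou"),
                       ou_sd = NULL,
                       protocol = c("none", "serial_dilution", "chemostat"),
                       dilution_interval = 12,
                       dilution_range = c(10, 50),
                       min_transfer = 1e5,
                       chemostat_rate = 0.18,
                       horizon_time = NULL,
                       horizon_generations = NULL,
                       checkpoint_interval = 0.1,
                       engine = c("lineage", "agent"),
                       stochastic = TRUE,
                       founder_rates = NULL,
                       founder_sizes = NULL,
                       max_new_lineages = 100L,
                       seed = 1L) {
  inheritance <- match.arg(inheritance)
  redraw <- match.arg(redraw)
  protocol <- match.arg(protocol)
  engine <- match.arg(engine)
  check_count(n_founders, "n_founders")
  check_number(founder_mean_rate, "founder_mean_rate")
  check_number(founder_cv, "founder_cv", lower = 0)
  check_number(switch_rate, "switch_rate", lower = 0)
  check_number(min_transfer, "min_transfer", lower = 1)
  check_number(checkpoint_interval, "checkpoint_interval", lower = 1e-9)
  if (is.null(horizon_time) && is.null(horizon_generations)) {
    abort("supply `horizon_time` and/or `horizon_generations`.",
          class = "growthdyn_config_error")
  }
  if (!is.null(horizon_time)) check_number(horizon_time, "horizon_time",
                                           lower = 0)
  if (!is.null(horizon_generations)) {
    check_number(horizon_generations, "horizon_generations", lower = 0)
  }
  if (protocol == "serial_dilution") {
    check_number(dilution_interval, "dilution_interval", lower = 1e-9)
    if (length(dilution_range) != 2 || any(dilution_range <= 1) ||
        dilution_range[1] > dilution_range[2]) {
      abort("`dilution_range` must be an increasing pair of factors > 1.",
            class = "growthdyn_config_error")
    }
  }
  if (inheritance == "switching" && switch_rate <= 0) {
    abort("switching inheritance needs `switch_rate` > 0.",
          class = "growthdyn_config_error")
  }
  if (!is.null(founder_rates) && length(founder_rates) != n_founders) {
    abort("`founder_rates` must have length `n_founders`.",
          class = "growthdyn_config_error")
  }
  if (!is.null(founder_sizes) &&
      (length(founder_sizes) != n_founders || any(founder_sizes <= 0))) {
    abort("`founder_sizes` must be positive, one per founder.",
          class = "growthdyn_config_error")
  }
  structure(
    list(n_founders = as.integer(n_founders),
         founder_mean_rate = founder_mean_rate, founder_cv = founder_cv,
         inheritance = inheritance, switch_rate = switch_rate,
         redraw = redraw,
         ou_sd = ou_sd %||% (founder_cv * abs(founder_mean_rate) / 2),
         protocol = protocol, dilution_interval = dilution_interval,
         dilution_range = dilution_range, min_transfer = min_transfer,
         chemostat_rate = chemostat_rate, horizon_time = horizon_time,
         horizon_generations = horizon_generations,
         checkpoint_interval = checkpoint_interval, engine = engine,
         stochastic = isTRUE(stochastic), founder_rates = founder_rates,
         founder_sizes = founder_sizes,
         max_new_lineages = as.integer(max_new_lineages),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Closed-form selection oracle for Gaussian founder rates
#'
#' For a population founded by infinitely many lineages with rates
#' `r ~ N(mu0, sigma0^2)` growing as `exp(r t)` under stable inheritance, the
#' exponentially weighted (population) rate distribution at time `t` is again
#' Gaussian: completing the square in `exp(r t) * phi(r)` shifts the mean to
#' `mu0 + sigma0^2 * t` and leaves the SD at `sigma0`. The mean therefore
#' increases linearly in time with slope equal to the rate variance —
#' Fisher's fundamental theorem for this model.
#'
#' @param mu0 Founder mean rate.
#' @param sigma0 Founder rate SD (>= 0).
#' @param t Time (vectorised).
#' @return A tibble with columns `t`, `mean`, `sd`.
#' @export
#' @examples
#' gaussian_tilt_moments(1, 0.3, c(0, 1, 2))
gaussian_tilt_moments <- function(mu0, sigma0, t) {
  check_number(mu0, "mu0")
  check_number(sigma0, "sigma0", lower = 0)
  tibble::tibble(t = t, mean = mu0 + sigma0^2 * t, sd = sigma0)
}

#' Exact selection weights for a finite set of lineages
#'
#' Deterministic expectation-mode moments of the population rate at time
#' `t`: lineage `i` carries weight `w0_i * exp(r_i t)`. The weighted mean and
#' SD are the finite-founder analogue of [gaussian_tilt_moments()].
#'
#' @param rates Lineage growth rates.
#' @param t Time (vectorised).
#' @param weights Initial lineage sizes (default equal).
#' @return A tibble with columns `t`, `mean`, `sd`.
#' @export
lineage_tilt_moments <- function(rates, t, weights = NULL) {
  weights <- weights %||% rep(1, length(rates))
  stopifnot(length(weights) == length(rates))
  purrr::map_dfr(t, function(tt) {
    lw <- log(weights) + rates * tt
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    m <- sum(w * rates)
    tibble::tibble(t = tt, mean = m, sd = sqrt(sum(w * (rates - m)^2)))
  })
}

#' Dilute a population by multinomial bottleneck sampling
#'
#' Models one serial-dilution transfer: `round(N / factor)` survivors are
#' drawn multinomially across lineages, so expected lineage frequencies are
#' unchanged while small lineages can stochastically die out. For very large
#' populations (more than `1e7` survivors) sampling noise is negligible and
#' sizes are scaled exactly.
#'
#' @param sizes Positive lineage sizes (cells).
#' @param factor Dilution factor (> 1).
#' @param min_transfer Minimum surviving cells; fewer raises a protocol
#'   violation (the anti-bottleneck guard).
#' @param stochastic Set `FALSE` to scale deterministically regardless of
#'   size.
#' @param seed Optional seed for the draw (uses the ambient RNG stream if
#'   `NULL`).
#' @return Numeric vector of post-dilution lineage sizes.
#' @export
#' @examples
#' apply_dilution(c(6e5, 4e5), factor = 10, seed = 1)
apply_dilution <- function(sizes, factor, min_transfer = 1,
                           stochastic = TRUE, seed = NULL) {
  stopifnot(is.numeric(sizes), all(sizes >= 0), any(sizes > 0))
  check_number(factor, "factor")
  if (factor <= 1) {
    abort("`factor` must be > 1.", class = "growthdyn_config_error")
  }
  n_total <- sum(sizes)
  n_surv <- round(n_total / factor)
  if (n_surv < 1 || n_surv < min_transfer) {
    abort(sprintf(
      "dilution by %g leaves %s cells, below the transfer minimum (%s).",
      factor, format(n_surv, big.mark = ","),
      format(min_transfer, big.mark = ",")),
      class = "growthdyn_protocol_violation")
  }
  draw <- function() {
    if (!stochastic || n_surv > 1e7) {
      sizes / factor
    } else {
      as.numeric(rmultinom(1, size = n_surv, prob = sizes / n_total))
    }
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a population of heritable growth-rate phenotypes under selection
#'
#' Runs the Monte Carlo model described by a [sim_config()]: founder rates
#' are drawn once, lineages grow exponentially at their own rates, and
#' faster lineages take over the population. Checkpoints record population
#' size, mean rate, rate SD, the generation counter (log2 of the cumulative
#' growth factor, dilutions excluded), and the fraction of cells with
#' positive rate. In stable mode per-founder lineage frequencies are kept at
#' every checkpoint for takeover analysis.
#'
#' @param config A [sim_config()].
#' @return A `popsim_trajectory`: a tibble of checkpoints with attributes
#'   `founder_rates`, `lineage_freq` (checkpoint x founder matrix, stable
#'   mode), `status` (`"completed"`, `"extinct"` or `"protocol_violation"`)
#'   and `config`.
#' @export
#' @examples
#' traj <- simulate_population(sim_config(n_founders = 200,
#'                                        horizon_generations = 3,
#'                                        checkpoint_interval = 0.25))
#' glance(traj)
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "popsim"), {
    if (config$engine == "lineage") {
      simulate_lineage_engine(config)
    } else {
      simulate_agent_engine(config)
    }
  })
}

# lineage engine: frequencies + log population size -------------------------

simulate_lineage_engine <- function(config) {
  n <- config$n_founders
  rates <- config$founder_rates %||%
    rnorm(n, config$founder_mean_rate,
          config$founder_cv * abs(config$founder_mean_rate))
  sizes0 <- config$founder_sizes %||% rep(1, n)
  orig_rates <- rates
  founder_of <- seq_len(n)

  freq <- sizes0 / sum(sizes0)
  log_size <- log(sum(sizes0))
  dt <- config$checkpoint_interval
  cum_log_growth <- 0
  t_now <- 0
  status <- "completed"
  track_lineages <- config$inheritance == "stable"

  t_max <- config$horizon_time %||% Inf
  g_max <- config$horizon_generations %||% Inf
  max_steps <- 2e6L

  rows <- list()
  freq_rows <- list()
  record <- function() {
    m <- sum(freq * rates)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      time = t_now,
      size = exp(log_size),
      mean_rate = m,
      sd_rate = sqrt(max(0, sum(freq * (rates - m)^2))),
      generations = cum_log_growth / log(2),
      frac_growing = sum(freq[rates > 0])
    )
    if (track_lineages) {
      f <- numeric(n)
      agg <- tapply(freq, founder_of, sum)
      f[as.integer(names(agg))] <- agg
      freq_rows[[length(freq_rows) + 1]] <<- f
    }
  }
  record()

  next_dilution <- if (config$protocol == "serial_dilution") {
    config$dilution_interval
  } else {
    Inf
  }

  for (step in seq_len(max_steps)) {
    if (t_now >= t_max - 1e-12 || cum_log_growth / log(2) >= g_max - 1e-12) {
      break
    }
    # exponential growth over dt (exact in expectation)
    w <- freq * exp(rates * dt)
    gsum <- sum(w)
    freq <- w / gsum
    log_size <- log_size + log(gsum)
    cum_log_growth <- cum_log_growth + log(gsum)
    if (config$protocol == "chemostat") {
      log_size <- log_size - config$chemostat_rate * dt
    }
    t_now <- step * dt  # not cumulative addition: keeps times exact

    # metastable switching: move mass into freshly drawn rate classes
    if (config$inheritance == "switching") {
      p <- 1 - exp(-config$switch_rate * dt)
      pop <- exp(log_size)
      counts <- freq * pop * p
      if (config$stochastic) {
        small <- counts < 1e7
        counts[small] <- pmin(rpois(sum(small), counts[small]),
                              freq[small] * pop)
      }
      total <- sum(counts)
      if (total > 0) {
        m_new <- min(config$max_new_lineages, max(1L, round(total)))
        src <- sample.int(length(freq), m_new, replace = TRUE,
                          prob = pmax(counts, 1e-300))
        new_rates <- switch(config$redraw,
          founder = rnorm(m_new, config$founder_mean_rate,
                          config$founder_cv * abs(config$founder_mean_rate)),
          ou = rnorm(m_new, rates[src], config$ou_sd)
        )
        freq <- c(freq - counts / pop, rep((total / pop) / m_new, m_new))
        freq <- pmax(freq, 0)
        freq <- freq / sum(freq)
        rates <- c(rates, new_rates)
        founder_of <- c(founder_of, founder_of[src])
      }
    }

    # serial-dilution bottleneck
    if (t_now >= next_dilution - 1e-9) {
      next_dilution <- next_dilution + config$dilution_interval
      factor <- if (config$stochastic) {
        runif(1, config$dilution_range[1], config$dilution_range[2])
      } else {
        mean(config$dilution_range)
      }
      sizes_abs <- freq * exp(log_size)
      res <- tryCatch(
        apply_dilution(sizes_abs, factor,
                       min_transfer = config$min_transfer,
                       stochastic = config$stochastic),
        growthdyn_protocol_violation = function(e) e
      )
      if (inherits(res, "condition")) {
        status <- "protocol_violation"
        record()
        break
      }
      if (sum(res) == 0) {
        status <- "extinct"
        record()
        break
      }
      keep <- res > 0
      rates <- rates[keep]
      founder_of <- founder_of[keep]
      freq <- res[keep] / sum(res)
      log_size <- log(sum(res))
    }
    record()
  }

  new_popsim_trajectory(dplyr::bind_rows(rows),
                        founder_rates = orig_rates,
                        lineage_freq = if (track_lineages) {
                          do.call(rbind, freq_rows)
                        } else {
                          NULL
                        },
                        status = status, config = config)
}

# agent engine: one record per cell ------------------------------------------

simulate_agent_engine <- function(config) {
  n <- config$n_founders
  rates <- config$founder_rates %||%
    rnorm(n, config$founder_mean_rate,
          config$founder_cv * abs(config$founder_mean_rate))
  orig_rates <- rates
  founder <- seq_len(n)
  if (!is.null(config$founder_sizes)) {
    reps <- round(config$founder_sizes)
    rates <- rep(rates, reps)
    founder <- rep(founder, reps)
  }
  dt <- config$checkpoint_interval
  t_now <- 0
  cum_log_growth <- 0
  status <- "completed"
  t_max <- config$horizon_time %||% Inf
  g_max <- config$horizon_generations %||% Inf

  rows <- list()
  freq_rows <- list()
  record <- function() {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      time = t_now, size = length(rates),
      mean_rate = mean(rates),
      sd_rate = if (length(rates) > 1) stats::sd(rates) else 0,
      generations = cum_log_growth / log(2),
      frac_growing = mean(rates > 0)
    )
    f <- tabulate(founder, nbins = n) / length(founder)
    freq_rows[[length(freq_rows) + 1]] <<- f
  }
  record()

  next_dilution <- if (config$protocol == "serial_dilution") {
    config$dilution_interval
  } else {
    Inf
  }

  step <- 0L
  while (t_now < t_max - 1e-12 && cum_log_growth / log(2) < g_max - 1e-12) {
    if (length(rates) > 2e6) {
      abort("agent engine exceeded 2e6 cells; use the lineage engine.",
            class = "growthdyn_config_error")
    }
    # exact pure-birth (Yule) step: a cell of rate r leaves a geometric
    # number of descendants with mean exp(r dt), so growth is unbiased for
    # any step size
    grow <- rates > 0
    n_desc <- rep(1L, length(rates))
    if (config$stochastic) {
      n_desc[grow] <- 1L + rgeom(sum(grow), exp(-rates[grow] * dt))
    } else {
      n_desc[grow] <- round(exp(rates[grow] * dt))
    }
    n_before <- length(rates)
    rates <- rep(rates, n_desc)
    founder <- rep(founder, n_desc)
    cum_log_growth <- cum_log_growth + log(length(rates) / n_before)
    step <- step + 1L
    t_now <- step * dt

    if (config$inheritance == "switching") {
      p_sw <- 1 - exp(-config$switch_rate * dt)
      sw <- runif(length(rates)) < p_sw
      if (any(sw)) {
        rates[sw] <- switch(config$redraw,
          founder = rnorm(sum(sw), config$founder_mean_rate,
                          config$founder_cv * abs(config$founder_mean_rate)),
          ou = rnorm(sum(sw), rates[sw], config$ou_sd)
        )
      }
    }

    if (t_now >= next_dilution - 1e-9) {
      next_dilution <- next_dilution + config$dilution_interval
      factor <- runif(1, config$dilution_range[1], config$dilution_range[2])
      n_surv <- round(length(rates) / factor)
      if (n_surv < 1 || n_surv < config$min_transfer) {
        status <- "protocol_violation"
        record()
        break
      }
      keep <- sample.int(length(rates), n_surv)
      rates <- rates[keep]
      founder <- founder[keep]
    }
    record()
  }

  new_popsim_trajectory(dplyr::bind_rows(rows),
                        founder_rates = orig_rates, status = status,
                        lineage_freq = do.call(rbind, freq_rows),
                        config = config)
}

new_popsim_trajectory <- function(checkpoints, founder_rates, lineage_freq,
                                  status, config) {
  structure(checkpoints,
            founder_rates = founder_rates, lineage_freq = lineage_freq,
            status = status, config = config,
            class = c("popsim_trajectory", class(checkpoints)))
}

#' @export
print.popsim_trajectory <- function(x, ...) {
  last <- x[nrow(x), ]
  cat(sprintf(
    "<popsim_trajectory> %d checkpoints to t = %g (g = %.2f), status: %s\n",
    nrow(x), last$time, last$generations, attr(x, "status")))
  cat(sprintf("  mean rate %.4f -> %.4f, sd %.4f -> %.4f\n",
              x$mean_rate[1], last$mean_rate, x$sd_rate[1], last$sd_rate))
  NextMethod()
}

#' @rdname simulate_population
#' @param x,object A `popsim_trajectory`.
#' @param ... Unused.
#' @method tidy popsim_trajectory
#' @export
tidy.popsim_trajectory <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname simulate_population
#' @method glance popsim_trajectory
#' @export
glance.popsim_trajectory <- function(x, ...) {
  last <- x[nrow(x), ]
  tibble::tibble(
    status = attr(x, "status"),
    n_checkpoints = nrow(x),
    final_time = last$time,
    final_generations = last$generations,
    initial_mean_rate = x$mean_rate[1],
    final_mean_rate = last$mean_rate,
    rel_rate_change = (last$mean_rate - x$mean_rate[1]) / x$mean_rate[1],
    final_sd_rate = last$sd_rate,
    final_frac_growing = last$frac_growing
  )
}

#' Generations until the fastest founders take over the population
#'
#' Operationalizes "takeover" for a stable-inheritance trajectory: the first
#' generation count at which the combined frequency of lineages descending
#' from the `top_fraction` fastest founders exceeds 50% of the population.
#' The crossing is linearly interpolated between checkpoints.
#'
#' @param traj A `popsim_trajectory` with lineage frequencies (stable mode).
#' @param top_fraction Fraction of founders, ranked by rate, that counts as
#'   "the fastest" (default the top decile).
#' @param threshold Population share that defines takeover (default 0.5).
#' @return A one-row tibble: `reached`, `generations`, `time`,
#'   `top_fraction`, `threshold`. `generations`/`time` are `NA` when takeover
#'   is not reached within the trajectory.
#' @export
takeover_time <- function(traj, top_fraction = 0.1, threshold = 0.5) {
  stopifnot(inherits(traj, "popsim_trajectory"))
  check_number(top_fraction, "top_fraction", lower = 1e-12, upper = 1)
  freq <- attr(traj, "lineage_freq")
  rates <- attr(traj, "founder_rates")
  if (is.null(freq)) {
    abort("takeover_time needs a stable-inheritance trajectory with lineage frequencies.",
          class = "growthdyn_config_error")
  }
  n <- ncol(freq)
  top <- order(rates[seq_len(n)], decreasing = TRUE)[
    seq_len(max(1L, ceiling(top_fraction * n)))]
  share <- rowSums(freq[, top, drop = FALSE])
  cross <- which(share > threshold)
  if (length(cross) == 0) {
    return(tibble::tibble(reached = FALSE, generations = NA_real_,
                          time = NA_real_, top_fraction = top_fraction,
                          threshold = threshold))
  }
  k <- cross[1]
  if (k == 1) {
    g <- traj$generations[1]
    tt <- traj$time[1]
  } else {
    # linear interpolation of the share crossing between checkpoints
    w <- (threshold - share[k - 1]) / (share[k] - share[k - 1])
    g <- traj$generations[k - 1] +
      w * (traj$generations[k] - traj$generations[k - 1])
    tt <- traj$time[k - 1] + w * (traj$time[k] - traj$time[k - 1])
  }
  tibble::tibble(reached = TRUE, generations = g, time = tt,
                 top_fraction = top_fraction, threshold = threshold)
}
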