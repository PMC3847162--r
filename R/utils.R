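#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in a multi-stage run flows from one global seed. Each stage
#' draws from its own substream, derived deterministically from the global
#' seed and the stage name, so adding or reordering stages never perturbs the
#' randomness of the others.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"synth"`, `"simulate"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "synth")
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- as.double(seed) %% 2147483647
  for (k in seq_along(codes)) {
    h <- (h * 31 + codes[k] * k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# shared argument checks ------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "growthdyn_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  check_number(x, name, lower = lower)
  if (x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "growthdyn_config_error")
  }
  invisible(as.integer(x))
}
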