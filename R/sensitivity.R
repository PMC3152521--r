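#' Triangular uncertainty parameter
#'
#' A three-point (low, mode, high) specification for an uncertain model
#' input, used when only a plausible range and a best guess are available.
#' A degenerate parameter with `low == mode == high` is permitted and
#' represents an input held fixed (the zero-variance limit).
#'
#' @param low,mode,high numbers with `low <= mode <= high`.
#' @param target name of the model input this parameter perturbs.
#' @param group optional sibling-group label; parameters sharing a group
#'   are renormalised to sum to 1 after sampling (used for the branch
#'   probabilities of a chance node).
#' @return A `triangular_param` object.
#' @export
triangular_param <- function(low, mode, high, target = NA_character_,
                             group = NA_character_) {
  stop_if_not_number(low, "low"); stop_if_not_number(mode, "mode")
  stop_if_not_number(high, "high")
  if (!(low <= mode && mode <= high)) {
    stop("need low <= mode <= high", call. = FALSE)
  }
  structure(list(low = low, mode = mode, high = high,
                 target = as.character(target), group = as.character(group)),
            class = "triangular_param")
}

#' Default symmetric range around a base case
#'
#' Builds the standard triangular range used for inputs whose uncertainty
#' is otherwise unquantified: the base case is the mode and the limits sit
#' `fraction` below and above it (25% by default).
#'
#' @param base base-case value (the mode).
#' @param fraction relative half-width, strictly inside `(0, 1)`.
#' @inheritParams triangular_param
#' @return A [triangular_param()]. A zero base yields a degenerate
#'   parameter and a warning, since a relative range cannot spread it.
#' @export
#' @examples
#' make_default_range(100)  # (75, 100, 125)
make_default_range <- function(base, fraction = 0.25,
                               target = NA_character_,
                               group = NA_character_) {
  stop_if_not_number(base, "base")
  stop_if_not_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (base == 0) {
    warning("zero base gives a degenerate (zero-width) range", call. = FALSE)
    return(triangular_param(0, 0, 0, target = target, group = group))
  }
  lo <- base * (1 - fraction)
  hi <- base * (1 + fraction)
  if (base < 0) { tmp <- lo; lo <- hi; hi <- tmp }
  triangular_param(lo, base, hi, target = target, group = group)
}

#' Sample a triangular distribution by inverse CDF
#'
#' Maps uniform deviates `u` through the triangular inverse CDF: for
#' `u <= (mode - low) / (high - low)` the draw is
#' `low + sqrt(u * (high - low) * (mode - low))`, otherwise
#' `high - sqrt((1 - u) * (high - low) * (high - mode))`. Draws always lie
#' in `[low, high]`; a degenerate parameter returns its single value.
#'
#' @param param a [triangular_param()].
#' @param u uniform deviates in `[0, 1]` (vectorised).
#' @return Numeric vector of draws, same length as `u`.
#' @export
#' @examples
#' p <- triangular_param(75, 100, 125)
#' sample_triangular(p, c(0, 0.5, 1))  # 75, 100, 125
sample_triangular <- function(param, u) {
  stopifnot(inherits(param, "triangular_param"))
  if (!is.numeric(u) || anyNA(u) || any(u < 0 | u > 1)) {
    stop("`u` must be numeric in [0, 1]", call. = FALSE)
  }
  lo <- param$low; mo <- param$mode; hi <- param$high
  if (hi == lo) return(rep(lo, length(u)))
  fc <- (mo - lo) / (hi - lo)
  out <- numeric(length(u))
  left <- u <= fc
  out[left] <- lo + sqrt(u[left] * (hi - lo) * (mo - lo))
  out[!left] <- hi - sqrt((1 - u[!left]) * (hi - lo) * (hi - mo))
  out
}

#' Moments of a triangular distribution
#'
#' Analytic mean `(low + mode + high) / 3` and standard deviation, used as
#' independent checks on the sampler.
#'
#' @param param a [triangular_param()].
#' @return A single number.
#' @export
triangular_mean <- function(param) {
  stopifnot(inherits(param, "triangular_param"))
  (param$low + param$mode + param$high) / 3
}

#' @rdname triangular_mean
#' @export
triangular_sd <- function(param) {
  stopifnot(inherits(param, "triangular_param"))
  a <- param$low; c <- param$mode; b <- param$high
  sqrt((a^2 + b^2 + c^2 - a * b - a * c - b * c) / 18)
}

#' Monte Carlo simulation specification
#'
#' Bundles the iteration count, the random seed and the list of uncertain
#' parameters. Every [triangular_param()] must carry a `target` name; the
#' targets label the columns of the sampled draw matrix.
#'
#' @param n_iterations number of model evaluations (default 10000).
#' @param seed integer RNG seed; fixes the entire simulation.
#' @param params list of [triangular_param()] objects.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(n_iterations = 10000L, seed = 1L,
                            params = list()) {
  stop_if_not_number(n_iterations, "n_iterations")
  if (n_iterations < 1) stop("`n_iterations` must be >= 1", call. = FALSE)
  stop_if_not_number(seed, "seed")
  if (!all(vapply(params, inherits, logical(1), "triangular_param"))) {
    stop("`params` must be a list of triangular_param objects", call. = FALSE)
  }
  targets <- vapply(params, function(p) p$target, character(1))
  if (length(params) > 0L && (anyNA(targets) || anyDuplicated(targets))) {
    stop("every parameter needs a unique non-NA `target`", call. = FALSE)
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), params = params),
            class = "simulation_spec")
}

#' Run a Monte Carlo probabilistic sensitivity analysis
#'
#' Draws `n_iterations` parameter sets from the triangular distributions
#' of `spec` and propagates each through `model`. One seeded generator
#' stream is used and parameters are sampled in their list order within
#' each iteration, so identical specifications reproduce identical results
#' bit for bit. After sampling, parameters that share a `group` (sibling
#' branch probabilities of a chance node) are renormalised to sum to 1;
#' iterations in which a renormalised probability leaves `[0, 1]` are
#' counted in `n_invalid` and flagged, never silently dropped.
#'
#' @param model a function. It receives the draw matrix (rows =
#'   iterations, columns named by parameter target) and must return a
#'   numeric matrix of per-iteration outputs if it carries attribute
#'   `vectorised = TRUE`; otherwise it is called once per iteration with a
#'   named numeric vector and must return a named numeric vector.
#' @param spec a [simulation_spec()].
#' @return A `simulation_result`: list with `samples` (iterations x
#'   outputs matrix), `mean` (per output), `n_invalid`, `invalid` (logical
#'   flag per iteration), `n_iterations` and `seed`.
#' @export
run_monte_carlo <- function(model, spec) {
  stopifnot(is.function(model), inherits(spec, "simulation_spec"))
  n <- spec$n_iterations
  params <- spec$params
  np <- length(params)
  if (np == 0L) stop("`spec` contains no parameters", call. = FALSE)
  targets <- vapply(params, function(p) p$target, character(1))

  set.seed(spec$seed)
  # one stream; each iteration consumes np deviates in parameter order
  u <- matrix(stats::runif(n * np), nrow = n, ncol = np, byrow = TRUE)
  draws <- matrix(0, nrow = n, ncol = np, dimnames = list(NULL, targets))
  for (j in seq_len(np)) draws[, j] <- sample_triangular(params[[j]], u[, j])

  groups <- vapply(params, function(p) p$group, character(1))
  invalid <- rep(FALSE, n)
  for (g in unique(groups[!is.na(groups)])) {
    idx <- which(!is.na(groups) & groups == g)
    s <- rowSums(draws[, idx, drop = FALSE])
    draws[, idx] <- draws[, idx, drop = FALSE] / s
    bad <- apply(draws[, idx, drop = FALSE] < 0 |
                   draws[, idx, drop = FALSE] > 1, 1L, any)
    invalid <- invalid | bad
  }
  if (any(invalid)) {
    warning(sprintf("%d iteration(s) produced invalid branch probabilities",
                    sum(invalid)), call. = FALSE)
  }

  if (isTRUE(attr(model, "vectorised"))) {
    samples <- model(draws)
  } else {
    rows <- lapply(seq_len(n), function(i) model(draws[i, ]))
    samples <- do.call(rbind, rows)
  }
  samples <- as.matrix(samples)
  if (nrow(samples) != n) {
    stop("model returned a wrong number of iterations", call. = FALSE)
  }

  structure(list(samples = samples, mean = colMeans(samples),
                 n_invalid = sum(invalid), invalid = invalid,
                 n_iterations = n, seed = spec$seed),
            class = "simulation_result")
}

#' Summarise a Monte Carlo result
#'
#' Empirical central interval and mean per output. Quantiles use linear
#' interpolation between order statistics (`stats::quantile()` type 7), a
#' convention fixed so that results are reproducible; `interval = 0.90`
#' returns the 5th and 95th percentiles, `interval = 1` the range.
#'
#' @param result a `simulation_result` from [run_monte_carlo()].
#' @param interval central probability mass in `(0, 1]`.
#' @return Data frame with one row per output: `output`, `mean`, `lower`,
#'   `upper`.
#' @export
summarise_psa <- function(result, interval = 0.90) {
  stopifnot(inherits(result, "simulation_result"))
  stop_if_not_number(interval, "interval")
  if (interval <= 0 || interval > 1) {
    stop("`interval` must lie in (0, 1]", call. = FALSE)
  }
  if (nrow(result$samples) == 0L) stop("no samples to summarise", call. = FALSE)
  alpha <- (1 - interval) / 2
  qs <- apply(result$samples, 2L, stats::quantile,
              probs = c(alpha, 1 - alpha), type = 7, names = FALSE)
  data.frame(
    output = colnames(result$samples),
    mean = unname(result$mean),
    lower = qs[1L, ],
    upper = qs[2L, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<Monte Carlo simulation> %d iterations, seed %d\n",
              x$n_iterations, x$seed))
  if (x$n_invalid > 0) {
    cat(sprintf("  %d iteration(s) flagged invalid\n", x$n_invalid))
  }
  print(summarise_psa(x))
  invisible(x)
}
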