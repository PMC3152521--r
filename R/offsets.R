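#' Per-capita health expenditure
#'
#' National personal medical services spend divided by population. Both
#' arguments are in millions, so the units cancel and the result is
#' dollars per person.
#'
#' @param total_spend_m national spend in $ millions (>= 0).
#' @param population_m population in millions (> 0).
#' @return Dollars per capita.
#' @export
#' @examples
#' per_capita_cost(15313, 4.292)  # about 3568
per_capita_cost <- function(total_spend_m, population_m) {
  stop_if_not_number(total_spend_m, "total_spend_m")
  stop_if_not_number(population_m, "population_m")
  if (total_spend_m < 0) stop("`total_spend_m` must be non-negative", call. = FALSE)
  if (population_m <= 0) stop("`population_m` must be positive", call. = FALSE)
  total_spend_m / population_m
}

#' Split per-capita health costs between insomniacs and good sleepers
#'
#' The all-population per-capita health cost `TP` is a prevalence-weighted
#' mixture of the insomniac mean `X` and the non-insomniac mean `Y`:
#' `TP = Ip * X + (1 - Ip) * Y` with `X = R * Y`, where `Ip` is the
#' insomnia prevalence and `R` the insomniac to non-insomniac cost ratio.
#' Solving the mixture identity gives `Y = TP / (1 + Ip * (R - 1))`. The
#' per-capita cost avoided by successful treatment is `delta = X - Y`.
#'
#' @param tp all-population per-capita cost ($).
#' @param ip insomnia prevalence in `[0, 1]`.
#' @param r cost ratio (> 0); e.g. `1.18` for an 18% cost excess.
#' @return A `population_health_costs` object: list with elements `tp`,
#'   `ip`, `r`, `y` (non-insomniac mean), `x` (insomniac mean) and `delta`
#'   (`x - y`, the avoidable per-capita cost).
#' @export
#' @examples
#' split_costs(3567.8, 0.13, 1.18)
split_costs <- function(tp, ip, r) {
  stop_if_not_number(tp, "tp"); stop_if_not_number(ip, "ip")
  stop_if_not_number(r, "r")
  if (ip < 0 || ip > 1) stop("`ip` must lie in [0, 1]", call. = FALSE)
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  if (tp < 0) stop("`tp` must be non-negative", call. = FALSE)
  y <- tp / (1 + ip * (r - 1))
  x <- r * y
  delta <- x - y
  structure(list(tp = tp, ip = ip, r = r, y = y, x = x, delta = delta),
            class = "population_health_costs")
}

#' Recover the cost ratio from a split
#'
#' Inverse check for [split_costs()]: `X / Y` round-trips to the ratio the
#' split was built from, to machine precision.
#'
#' @param costs a `population_health_costs` object.
#' @return The ratio `x / y`.
#' @export
recover_ratio <- function(costs) {
  stopifnot(inherits(costs, "population_health_costs"))
  if (costs$y <= 0) stop("non-insomniac mean `y` must be positive", call. = FALSE)
  costs$x / costs$y
}

#' @export
print.population_health_costs <- function(x, ...) {
  cat("Population health-cost split ($ per capita)\n")
  cat(sprintf("  all-population mean (TP)   %10.2f\n", x$tp))
  cat(sprintf("  prevalence (Ip)            %10.3f\n", x$ip))
  cat(sprintf("  cost ratio (R)             %10.3f\n", x$r))
  cat(sprintf("  non-insomniac mean (Y)     %10.2f\n", x$y))
  cat(sprintf("  insomniac mean (X)         %10.2f\n", x$x))
  cat(sprintf("  avoidable cost (X - Y)     %10.2f\n", x$delta))
  invisible(x)
}
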