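#' Convert SF-36 domain scores to a utility
#'
#' The physical-functioning and mental-health SF-36 domains (each scored
#' 0-100) are rescaled to 0-1 and averaged, giving a single utility-like
#' index comparable with EQ-5D utilities.
#'
#' @param physical physical-functioning score in `[0, 100]`.
#' @param mental mental-health score in `[0, 100]`.
#' @return Utility in `[0, 1]`. Vectorised over both arguments.
#' @export
#' @examples
#' sf36_to_utility(60, 40)  # 0.5
sf36_to_utility <- function(physical, mental) {
  if (!is.numeric(physical) || !is.numeric(mental)) {
    stop("scores must be numeric", call. = FALSE)
  }
  if (any(physical < 0 | physical > 100, na.rm = FALSE) ||
      any(mental < 0 | mental > 100, na.rm = FALSE) ||
      anyNA(physical) || anyNA(mental)) {
    stop("SF-36 scores must lie in [0, 100]", call. = FALSE)
  }
  (physical / 100 + mental / 100) / 2
}

#' QALY-gain specification (low / base / high)
#'
#' The one-year utility gain attached to successful treatment, as a
#' three-point specification used both for the base case and as the
#' triangular range of the sensitivity analysis.
#'
#' @param low,base,high utilities with `0 <= low <= base <= high`.
#' @return A `qaly_gain_spec` object.
#' @export
qaly_gain_spec <- function(low, base, high) {
  stop_if_not_number(low, "low"); stop_if_not_number(base, "base")
  stop_if_not_number(high, "high")
  if (low < 0) stop("`low` must be non-negative", call. = FALSE)
  if (!(low <= base && base <= high)) {
    stop("need low <= base <= high", call. = FALSE)
  }
  structure(list(low = low, base = base, high = high), class = "qaly_gain_spec")
}

#' Combine utility-difference observations into a QALY-gain spec
#'
#' Pools utility differences (clinician EQ-5D assessments and literature
#' SF-36 derived values) into a single dataset: the base case is the mean,
#' the high value is the maximum, and the low value is taken as 0 — the
#' conservative assumption that treatment might yield no utility gain.
#'
#' @param values numeric vector of utility differences in `[-1, 1]`;
#'   must be non-empty.
#' @return A [qaly_gain_spec()].
#' @export
#' @examples
#' combine_utility_dataset(c(0.078, 0.373, 0.02))
combine_utility_dataset <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  if (any(values < -1 | values > 1)) {
    stop("utility differences must lie in [-1, 1]", call. = FALSE)
  }
  qaly_gain_spec(low = 0, base = mean(values), high = max(values))
}

#' Population scaling parameters
#'
#' The at-risk population (millions), insomnia prevalence and proportion
#' of sufferers who seek treatment; their product is the number treated.
#'
#' @param at_risk_m at-risk population in millions (> 0).
#' @param prevalence proportion in `[0, 1]`.
#' @param p_seek proportion in `[0, 1]`.
#' @return A `population_scaling` object.
#' @export
population_scaling <- function(at_risk_m, prevalence, p_seek) {
  stop_if_not_number(at_risk_m, "at_risk_m")
  stop_if_not_number(prevalence, "prevalence")
  stop_if_not_number(p_seek, "p_seek")
  if (at_risk_m <= 0) stop("`at_risk_m` must be positive", call. = FALSE)
  if (prevalence < 0 || prevalence > 1 || p_seek < 0 || p_seek > 1) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(at_risk_m = at_risk_m, prevalence = prevalence,
                 p_seek = p_seek),
            class = "population_scaling")
}

#' Economic evaluation of treatment versus no treatment
#'
#' Combines the per-person treatment cost, the per-person health costs
#' avoided by successful treatment, the QALY gain and the population
#' scaling into the full evaluation: net benefit per person, cost per
#' QALY, and national totals. The number treated is
#' `at_risk * prevalence * p_seek` (millions), and every national total is
#' the per-person value times the number treated, computed at full
#' precision before any reporting rounding.
#'
#' @param cost_per_person treatment cost, dollars (>= 0).
#' @param avoided_per_person health costs avoided, dollars (>= 0).
#' @param qaly_gain utility gain per person treated; a number or a
#'   [qaly_gain_spec()] (its base case is used). Must be non-negative; a
#'   zero gain leaves `cost_per_qaly` as `NA` with a warning rather than
#'   returning an infinity.
#' @param scaling a [population_scaling()].
#' @return An `evaluation_result`: list with per-person values
#'   (`cost_per_person`, `avoided_per_person`, `net_benefit_per_person`,
#'   `qaly_gain`, `cost_per_qaly`) and national values in millions
#'   (`n_treated_m`, `total_cost_m`, `total_avoided_m`,
#'   `total_net_benefit_m`, `total_qaly_m`).
#' @export
#' @examples
#' evaluate_treatment(145, 627.52, 0.157,
#'                    population_scaling(2.317, 0.13, 0.15))
evaluate_treatment <- function(cost_per_person, avoided_per_person,
                               qaly_gain, scaling) {
  stop_if_not_number(cost_per_person, "cost_per_person")
  stop_if_not_number(avoided_per_person, "avoided_per_person")
  stopifnot(inherits(scaling, "population_scaling"))
  if (inherits(qaly_gain, "qaly_gain_spec")) qaly_gain <- qaly_gain$base
  stop_if_not_number(qaly_gain, "qaly_gain")
  if (cost_per_person < 0 || avoided_per_person < 0) {
    stop("dollar inputs must be non-negative", call. = FALSE)
  }
  if (qaly_gain < 0) stop("`qaly_gain` must be non-negative", call. = FALSE)

  n_treated <- scaling$at_risk_m * scaling$prevalence * scaling$p_seek
  net <- avoided_per_person - cost_per_person
  if (qaly_gain == 0) {
    warning("`qaly_gain` is zero: cost per QALY is undefined", call. = FALSE)
    cpq <- NA_real_
  } else {
    cpq <- net / qaly_gain
  }

  structure(list(
    cost_per_person = cost_per_person,
    avoided_per_person = avoided_per_person,
    net_benefit_per_person = net,
    qaly_gain = qaly_gain,
    cost_per_qaly = cpq,
    n_treated_m = n_treated,
    total_cost_m = cost_per_person * n_treated,
    total_avoided_m = avoided_per_person * n_treated,
    total_net_benefit_m = net * n_treated,
    total_qaly_m = qaly_gain * n_treated,
    scaling = scaling
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  s <- x$scaling
  cat("Economic evaluation of treatment versus no treatment\n")
  cat(sprintf("  %-34s %12s %12s\n", "", "per person", "national (M)"))
  cat(sprintf("  %-34s %12s %12.3f\n", "At-risk population (M)", "", s$at_risk_m))
  cat(sprintf("  %-34s %12s %12.1f%%\n", "Prevalence of insomnia", "",
              100 * s$prevalence))
  cat(sprintf("  %-34s %12s %12.1f%%\n", "Proportion seeking treatment", "",
              100 * s$p_seek))
  cat(sprintf("  %-34s %12s %12.3f\n", "Number seeking treatment (M)", "",
              x$n_treated_m))
  cat(sprintf("  %-34s %12.0f %12.1f\n", "Costs incurred ($)",
              round_half_up(x$cost_per_person), x$total_cost_m))
  cat(sprintf("  %-34s %12.0f %12.1f\n", "Costs avoided ($)",
              round_half_up(x$avoided_per_person), x$total_avoided_m))
  cat(sprintf("  %-34s %12.0f %12.1f\n", "Net benefit ($)",
              round_half_up(x$net_benefit_per_person), x$total_net_benefit_m))
  cat(sprintf("  %-34s %12.3f %12.3f\n", "QALYs gained", x$qaly_gain,
              x$total_qaly_m))
  if (!is.na(x$cost_per_qaly)) {
    cat(sprintf("  %-34s %12.0f\n", "Net benefit per QALY gained ($)",
                round_half_up(x$cost_per_qaly)))
  }
  invisible(x)
}

#' @export
as.data.frame.evaluation_result <- function(x, ...) {
  data.frame(
    quantity = c("cost_per_person", "avoided_per_person",
                 "net_benefit_per_person", "qaly_gain", "cost_per_qaly",
                 "n_treated_m", "total_cost_m", "total_avoided_m",
                 "total_net_benefit_m", "total_qaly_m"),
    value = c(x$cost_per_person, x$avoided_per_person,
              x$net_benefit_per_person, x$qaly_gain, x$cost_per_qaly,
              x$n_treated_m, x$total_cost_m, x$total_avoided_m,
              x$total_net_benefit_m, x$total_qaly_m),
    stringsAsFactors = FALSE
  )
}
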