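#' Run configuration
#'
#' Resolves, checks and parses every input of an end-to-end run before
#' any computation starts: the unit cost table, the utilisation matrix,
#' the parameter file, the probability completion and the simulation
#' settings. File arguments may be `NULL` (packaged copies) or paths; a
#' missing or unparsable file fails here, not mid-run.
#'
#' @param unit_costs,utilisation,params optional file paths (CSV, CSV,
#'   YAML); `NULL` uses the packaged copies.
#' @param completion `"default"`, `"calibrated"`, or a
#'   [probability_completion()] object.
#' @param seek_split `"external"` (care-seeking handled by population
#'   scaling; tree cost is per person treated) or `"in_tree"`.
#' @param n_iterations,seed,fraction simulation settings; `NULL` values
#'   fall back to the parameter file / packaged defaults.
#' @param currency_label label stamped on all written reports.
#' @return A `run_config` object with parsed inputs.
#' @export
run_config <- function(unit_costs = NULL, utilisation = NULL, params = NULL,
                       completion = "default",
                       seek_split = c("external", "in_tree"),
                       n_iterations = NULL, seed = 42L, fraction = NULL,
                       currency_label = "NZD 2009, GST-exclusive") {
  seek_split <- match.arg(seek_split)
  for (p in c(unit_costs, utilisation, params)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("input file does not exist: %s", p), call. = FALSE)
    }
  }
  uc <- read_unit_costs(unit_costs)
  um <- read_utilisation(utilisation)
  pl <- nz_model_params(params)

  if (is.character(completion)) {
    completion <- switch(
      match.arg(completion, c("default", "calibrated")),
      default = default_completion(
        build_first_contact(unlist(pl$first_contact_raw))),
      calibrated = calibrate_completion(
        costs = uc, matrix = um,
        first_contact = build_first_contact(unlist(pl$first_contact_raw)))
    )
  }
  stopifnot(inherits(completion, "probability_completion"))

  structure(list(
    unit_costs = uc, utilisation = um, params = pl,
    completion = completion, seek_split = seek_split,
    n_iterations = as.integer(n_iterations %||%
                                pl$simulation$n_iterations %||% 10000L),
    seed = as.integer(seed),
    fraction = fraction %||% pl$simulation$default_fraction %||% 0.25,
    currency_label = currency_label
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose top-level keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file does not exist: %s", path), call. = FALSE)
  }
  do.call(run_config, yaml::read_yaml(path))
}

#' Deterministic base-case evaluation
#'
#' Runs the full deterministic model: builds the tree from the
#' configuration's completion, enumerates and costs every pathway,
#' computes per-entry-branch mean costs, splits the national per-capita
#' health cost to obtain the avoided-cost offset, and scales to the
#' national population. When `out_dir` is given, writes `pathways.csv`,
#' `branch_means.csv`, `evaluation.csv` and a plain-text `report.txt`
#' that also logs the modelling conventions in effect.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if needed).
#' @return An `insomod_run`: list with `pathways` (leaf, path,
#'   probability, cost, entry branch), `branch_means`, `tree_cost`
#'   (expected cost per person treated), `health` (the
#'   population-health-cost split), `evaluation` (an
#'   `evaluation_result`), `findings` and `provenance`.
#' @export
run_deterministic <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ec <- build_event_costs(config$utilisation, config$unit_costs)
  tree <- build_insomnia_tree(config$completion,
                              seek_split = config$seek_split,
                              p_seek = config$params$scaling$p_seek)
  findings <- validate_tree(tree, tolerance = 1e-6, event_ids = names(ec))
  if (nrow(findings) > 0L) {
    stop("model validation failed:\n",
         paste(sprintf("- [%s] %s: %s", findings$type, findings$node_id,
                       findings$message), collapse = "\n"),
         call. = FALSE)
  }
  paths <- enumerate_pathways(tree, ec)

  # entry branch = child of the "seek" node on each pathway
  entry_of <- function(p) {
    i <- match("seek", p)
    if (!is.na(i) && length(p) > i) p[[i + 1L]] else NA_character_
  }
  paths$entry <- vapply(paths$path, entry_of, character(1))

  seek_paths <- paths[!is.na(paths$entry), , drop = FALSE]
  p_seek_total <- sum(seek_paths$probability)
  branch_means <- do.call(rbind, lapply(split(seek_paths, seek_paths$entry),
    function(d) data.frame(entry = d$entry[1L],
                           probability = sum(d$probability) / p_seek_total,
                           mean_cost = sum(d$probability * d$cost) /
                             sum(d$probability))))
  branch_means <- branch_means[order(branch_means$entry), , drop = FALSE]
  rownames(branch_means) <- NULL

  # expected cost per person treated: with the external seek split this is
  # the tree cost itself; with the in-tree split, condition on seeking
  tree_cost <- if (config$seek_split == "external") {
    expected_tree_cost(paths, tolerance = 1e-6)
  } else {
    sum(seek_paths$probability * seek_paths$cost) / p_seek_total
  }

  hc <- config$params$health_costs
  sc <- config$params$scaling
  tp <- per_capita_cost(hc$personal_medical_services_m,
                        hc$population_all_ages_m)
  health <- split_costs(tp, sc$prevalence, 1 + hc$cost_increase_mean)
  qaly <- qaly_gain_spec(config$params$utility$low,
                         config$params$utility$base,
                         config$params$utility$high)
  evaluation <- evaluate_treatment(
    tree_cost, health$delta, qaly,
    population_scaling(sc$at_risk_m, sc$prevalence, sc$p_seek))

  run <- structure(list(
    pathways = paths, branch_means = branch_means, tree_cost = tree_cost,
    health = health, evaluation = evaluation, qaly = qaly,
    findings = findings, provenance = attr(tree, "provenance"),
    config = config
  ), class = "insomod_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# internal: write deterministic-run outputs
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pw <- run$pathways
  pw_out <- data.frame(
    leaf = pw$leaf,
    path = vapply(pw$path, paste, character(1), collapse = " -> "),
    entry = pw$entry,
    probability = pw$probability,
    cost = pw$cost,
    cost_reported = round_half_up(pw$cost)
  )
  utils::write.csv(pw_out, file.path(out_dir, "pathways.csv"),
                   row.names = FALSE)
  utils::write.csv(run$branch_means, file.path(out_dir, "branch_means.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$evaluation),
                   file.path(out_dir, "evaluation.csv"), row.names = FALSE)

  con <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Insomnia treatment evaluation - deterministic base case")
  w("Currency: %s", run$config$currency_label)
  w("")
  w("Expected treatment cost per person treated: $%.2f (reported $%.0f)",
    run$tree_cost, round_half_up(run$tree_cost))
  w("Per-capita health cost avoided by successful treatment: $%.2f",
    run$health$delta)
  w("")
  out <- utils::capture.output(print(run$evaluation))
  writeLines(out, con)
  w("")
  w("Branch probability provenance: %s",
    paste(sprintf("%s=%s", names(run$provenance), run$provenance),
          collapse = ", "))
  w("Conventions in effect: probability-weighted expected cost; sibling")
  w("probabilities renormalised after sampling; reported dollars rounded")
  w("half away from zero; quantiles by linear interpolation (type 7).")
  invisible(out_dir)
}

#' Probabilistic sensitivity run
#'
#' Builds the stochastic model from the configuration, runs the Monte
#' Carlo simulation and summarises the 90% interval of the headline
#' outputs, echoing the deterministic base case for comparison. When
#' `out_dir` is given, writes `psa_summary.csv` (and `psa_samples.csv`
#' when `write_samples = TRUE`).
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param write_samples also write the raw per-iteration samples.
#' @param interval central interval mass (default 0.90).
#' @return An `insomod_psa_run`: list with `result`
#'   (a `simulation_result`), `summary`, `deterministic` (the matching
#'   [run_deterministic()] output) and `flags` (character; non-empty when
#'   the iteration count is too small for stable percentiles).
#' @export
run_psa <- function(config = run_config(), out_dir = NULL,
                    write_samples = FALSE, interval = 0.90) {
  stopifnot(inherits(config, "run_config"))
  psa <- insomnia_psa_model(costs = config$unit_costs,
                            matrix = config$utilisation,
                            params = config$params,
                            completion = config$completion,
                            fraction = config$fraction)
  spec <- simulation_spec(n_iterations = config$n_iterations,
                          seed = config$seed, params = psa$params)
  result <- run_monte_carlo(psa$model, spec)
  summary <- summarise_psa(result, interval = interval)
  det <- run_deterministic(config)
  det_vals <- c(cost_per_person = det$tree_cost,
                avoided_per_person = det$health$delta,
                net_benefit_per_person = det$evaluation$net_benefit_per_person,
                national_net_benefit_m = det$evaluation$total_net_benefit_m,
                net_benefit_per_qaly = det$evaluation$cost_per_qaly)
  summary$base_case <- unname(det_vals[summary$output])

  flags <- character()
  if (config$n_iterations < 1000L) {
    flags <- c(flags, sprintf(
      "only %d iterations: percentile estimates are unstable",
      config$n_iterations))
  }
  if (result$n_invalid > 0L) {
    flags <- c(flags, sprintf("%d invalid iteration(s)", result$n_invalid))
  }

  run <- structure(list(result = result, summary = summary,
                        deterministic = det, flags = flags,
                        interval = interval, config = config),
                   class = "insomod_psa_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "psa_summary.csv"),
                     row.names = FALSE)
    if (write_samples) {
      utils::write.csv(as.data.frame(result$samples),
                       file.path(out_dir, "psa_samples.csv"),
                       row.names = FALSE)
    }
  }
  run
}

#' @export
print.insomod_run <- function(x, ...) {
  cat(sprintf("Deterministic evaluation (%s)\n", x$config$currency_label))
  cat(sprintf("  expected cost per person treated: $%.2f\n", x$tree_cost))
  cat("  branch mean costs:\n")
  for (i in seq_len(nrow(x$branch_means))) {
    cat(sprintf("    entry %-3s $%8.2f  (p = %.3f)\n",
                x$branch_means$entry[i], x$branch_means$mean_cost[i],
                x$branch_means$probability[i]))
  }
  print(x$evaluation)
  invisible(x)
}

#' @export
print.insomod_psa_run <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations, seed %d\n",
              x$result$n_iterations, x$result$seed))
  for (f in x$flags) cat("  NOTE:", f, "\n")
  df <- x$summary
  cat(sprintf("  %d%% intervals:\n", round(100 * x$interval)))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("    %-26s mean %10.1f  [%10.1f, %10.1f]  base %10.1f\n",
                df$output[i], df$mean[i], df$lower[i], df$upper[i],
                df$base_case[i]))
  }
  invisible(x)
}
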