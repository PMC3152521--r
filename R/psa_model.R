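#' Probabilistic sensitivity model for the packaged evaluation
#'
#' Builds the stochastic version of the full evaluation: every unit cost
#' and every nonzero utilisation volume gets a symmetric triangular range
#' of relative half-width `fraction` around its base case (25% by
#' default), every downstream branch probability gets the same treatment
#' with per-chance-node renormalisation so sibling branches still sum
#' to 1, the insomniac cost excess is sampled from its literature
#' triangular range (5%, 18%, 25%), the QALY gain from its (low, base,
#' high) specification, and the prevalence and care-seeking proportions
#' from symmetric ranges. All inputs are sampled independently.
#'
#' Parameters are laid out in a fixed, documented order — unit costs
#' (cost-table order), volumes (matrix row then column order), branch
#' probabilities (depth-first tree order), cost excess, QALY gain,
#' prevalence, care-seeking proportion — so a seeded run is exactly
#' reproducible. With `fraction = 0` every parameter is degenerate and
#' each iteration reproduces the deterministic base case bit for bit.
#'
#' @param costs a [unit_cost_table()].
#' @param matrix a [utilisation_matrix()].
#' @param params parameter list, see [nz_model_params()].
#' @param completion a [probability_completion()].
#' @param fraction relative half-width of the symmetric ranges; `0` for
#'   the zero-variance limit.
#' @param vary character subset of
#'   `c("unit_costs", "volumes", "probabilities", "cost_increase",
#'   "qaly", "prevalence", "p_seek")`; inputs not listed are held at
#'   their base case. Defaults to all.
#' @return An `insomod_psa_model`: list with `params` (triangular
#'   parameters ready for [simulation_spec()]), `model` (vectorised
#'   closure mapping a draw matrix to per-iteration outputs
#'   `cost_per_person`, `avoided_per_person`, `net_benefit_per_person`,
#'   `national_net_benefit_m`, `net_benefit_per_qaly`) and `base`
#'   (named base-case draw vector).
#' @export
insomnia_psa_model <- function(costs = read_unit_costs(),
                               matrix = read_utilisation(),
                               params = nz_model_params(),
                               completion = default_completion(),
                               fraction = 0.25,
                               vary = c("unit_costs", "volumes",
                                        "probabilities", "cost_increase",
                                        "qaly", "prevalence", "p_seek")) {
  stopifnot(inherits(costs, "unit_cost_table"),
            inherits(matrix, "utilisation_matrix"),
            inherits(completion, "probability_completion"))
  vary <- match.arg(vary, several.ok = TRUE)
  stop_if_not_number(fraction, "fraction")
  if (fraction < 0 || fraction >= 1) {
    stop("`fraction` must lie in [0, 1)", call. = FALSE)
  }

  tri <- function(base, target, group = NA_character_, on = TRUE) {
    if (fraction == 0 || !on || base == 0) {
      triangular_param(base, base, base, target = target, group = group)
    } else {
      make_default_range(base, fraction, target = target, group = group)
    }
  }

  tree <- build_insomnia_tree(completion, seek_split = "external")
  vm <- volume_matrix(matrix)
  uc <- unit_cost_vector(costs)

  plist <- list()
  add <- function(p) plist[[length(plist) + 1L]] <<- p

  # 1. unit costs, cost-table order
  for (r in names(uc)) {
    add(tri(uc[[r]], paste0("uc:", r), on = "unit_costs" %in% vary))
  }
  # 2. nonzero volumes, row-major in matrix order
  cells <- list()
  for (e in rownames(vm)) {
    for (r in colnames(vm)) {
      if (vm[e, r] > 0) {
        tgt <- paste0("vol:", e, ":", r)
        cells[[length(cells) + 1L]] <- list(event = e, resource = r,
                                            target = tgt)
        add(tri(vm[e, r], tgt, on = "volumes" %in% vary))
      }
    }
  }
  # 3. branch probabilities, depth-first, grouped by parent chance node
  branch_params <- character()  # target name per non-root node id
  for (item in flatten_tree(tree)) {
    node <- item$node
    if (node$kind != "chance") next
    for (ch in node$children) {
      tgt <- paste0("p:", ch$id)
      branch_params[[ch$id]] <- tgt
      add(tri(ch$p, tgt, group = node$id, on = "probabilities" %in% vary))
    }
  }
  # 4. insomniac cost excess: literature triangular range, not +/-25%
  hc <- params$health_costs
  if (fraction == 0 || !"cost_increase" %in% vary) {
    add(triangular_param(hc$cost_increase_mean, hc$cost_increase_mean,
                         hc$cost_increase_mean, target = "cost_increase"))
  } else {
    add(triangular_param(hc$cost_increase_low, hc$cost_increase_mean,
                         hc$cost_increase_high, target = "cost_increase"))
  }
  # 5. QALY gain: (low, base, high) specification
  ut <- params$utility
  if (fraction == 0 || !"qaly" %in% vary) {
    add(triangular_param(ut$base, ut$base, ut$base, target = "qaly"))
  } else {
    add(triangular_param(ut$low, ut$base, ut$high, target = "qaly"))
  }
  # 6.-7. prevalence and care seeking
  sc <- params$scaling
  add(tri(sc$prevalence, "prevalence", on = "prevalence" %in% vary))
  add(tri(sc$p_seek, "p_seek", on = "p_seek" %in% vary))

  targets <- vapply(plist, function(p) p$target, character(1))
  base <- stats::setNames(vapply(plist, function(p) p$mode, numeric(1)),
                          targets)

  # precompute pathway structure once (depth-first leaf order)
  paths <- enumerate_pathway_structure(tree)
  event_ids <- matrix$event_id
  cells_by_event <- split(cells, vapply(cells, `[[`, character(1), "event"))
  tp <- per_capita_cost(hc$personal_medical_services_m,
                        hc$population_all_ages_m)
  at_risk <- sc$at_risk_m

  model <- function(draws) {
    n <- nrow(draws)
    # event costs: contributions summed in resource-column order, matching
    # event_cost()'s accumulation
    C <- base::matrix(0, nrow = n, ncol = length(event_ids),
                      dimnames = list(NULL, event_ids))
    for (e in names(cells_by_event)) {
      cls <- cells_by_event[[e]]
      contrib <- vapply(cls, function(cl) {
        draws[, cl$target] * draws[, paste0("uc:", cl$resource)]
      }, numeric(n))
      contrib <- base::matrix(contrib, nrow = n)
      C[, e] <- rowSums(contrib)
    }
    # pathway costs and probabilities, accumulated in visit order
    np <- length(paths)
    path_cost <- base::matrix(0, n, np)
    path_prob <- base::matrix(1, n, np)
    for (k in seq_len(np)) {
      pk <- paths[[k]]
      acc_c <- rep(0, n)
      for (e in pk$events) acc_c <- acc_c + C[, e]
      path_cost[, k] <- acc_c
      acc_p <- rep(1, n)
      for (b in pk$branches) acc_p <- acc_p * draws[, branch_params[[b]]]
      path_prob[, k] <- acc_p
    }
    cost <- rowSums(path_prob * path_cost)

    prev <- draws[, "prevalence"]
    r <- 1 + draws[, "cost_increase"]
    y <- tp / (1 + prev * (r - 1))
    x <- r * y
    delta <- x - y
    net <- delta - cost
    n_treated <- at_risk * prev * draws[, "p_seek"]
    national <- net * n_treated
    per_qaly <- net / draws[, "qaly"]

    cbind(cost_per_person = cost,
          avoided_per_person = delta,
          net_benefit_per_person = net,
          national_net_benefit_m = national,
          net_benefit_per_qaly = per_qaly)
  }
  attr(model, "vectorised") <- TRUE

  structure(list(params = plist, model = model, base = base,
                 fraction = fraction, vary = vary,
                 provenance = completion$provenance),
            class = "insomod_psa_model")
}

# internal: per-leaf event and branch-node id lists in depth-first order
enumerate_pathway_structure <- function(tree) {
  paths <- list()
  walk <- function(node, events, branches, is_root) {
    if (!is.null(node$event)) events <- c(events, node$event)
    if (!is_root) branches <- c(branches, node$id)
    if (node$kind == "end") {
      paths[[length(paths) + 1L]] <<- list(leaf = node$id, events = events,
                                           branches = branches)
    } else {
      for (ch in node$children) walk(ch, events, branches, FALSE)
    }
  }
  walk(tree$root, character(), character(), TRUE)
  paths
}
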