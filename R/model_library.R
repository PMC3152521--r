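#' Packaged model parameters
#'
#' Reads the parameter file shipped with the package: national health-cost
#' inputs, population scaling, the utility-gain specification, the raw
#' first-contact survey percentages and the simulation defaults.
#'
#' @param path YAML file; `NULL` for the packaged copy.
#' @return A named list.
#' @export
nz_model_params <- function(path = NULL) {
  yaml::read_yaml(path %||% insomod_file("model_params.yaml"))
}

#' Raw first-contact survey percentages
#'
#' The percentage of insomnia sufferers approaching each provider type in
#' the first instance, from a UK patient survey. Respondents could name
#' several providers, so the percentages need not sum to 100.
#'
#' @return Named numeric vector of percentages.
#' @export
stinson_percentages <- function() {
  unlist(nz_model_params()$first_contact_raw)
}

# provider categories of the model, in entry-branch order 1..5
.entry_categories <- c("pharmacist", "general_practitioner",
                       "health_practitioner", "psychologist",
                       "alternative_health_practitioner")
.entry_nodes <- c(pharmacist = "1", general_practitioner = "2",
                  health_practitioner = "3", psychologist = "4",
                  alternative_health_practitioner = "5")

#' First-contact provider distribution
#'
#' Maps raw survey percentages onto the five entry branches of the model
#' and normalises. Nurses and counsellors are grouped under "health
#' practitioner"; herbalists, acupuncturists and hypnotists under
#' "alternative health practitioner". Psychiatrists have no entry branch
#' in the model and are dropped before normalisation. Because the source
#' survey allowed multiple answers, the retained categories are
#' renormalised to sum to 1.
#'
#' @param raw named numeric vector of non-negative percentages; names may
#'   be the nine survey categories, the five model categories, or a mix.
#' @return A `first_contact_distribution`: list with `proportions` (named
#'   by the five model categories, summing to 1) and `raw`.
#' @export
#' @examples
#' build_first_contact(stinson_percentages())
build_first_contact <- function(raw = stinson_percentages()) {
  if (!is.numeric(raw) || is.null(names(raw))) {
    stop("`raw` must be a named numeric vector", call. = FALSE)
  }
  if (any(raw < 0) || anyNA(raw)) {
    stop("percentages must be non-negative and non-missing", call. = FALSE)
  }
  grouping <- c(
    pharmacist = "pharmacist",
    general_practitioner = "general_practitioner",
    psychologist = "psychologist",
    nurse = "health_practitioner",
    counsellor = "health_practitioner",
    health_practitioner = "health_practitioner",
    herbalist = "alternative_health_practitioner",
    acupuncturist = "alternative_health_practitioner",
    hypnotist = "alternative_health_practitioner",
    alternative_health_practitioner = "alternative_health_practitioner",
    psychiatrist = NA_character_  # no entry branch in the model
  )
  unknown <- setdiff(names(raw), names(grouping))
  if (length(unknown) > 0L) {
    stop("unknown provider categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mapped <- grouping[names(raw)]
  keep <- !is.na(mapped)
  grouped <- tapply(raw[keep], factor(mapped[keep], levels = .entry_categories),
                    sum, default = 0)
  grouped <- as.numeric(grouped)
  names(grouped) <- .entry_categories
  total <- sum(grouped)
  if (total <= 0) stop("all retained percentages are zero", call. = FALSE)
  props <- grouped / total
  # pin the floating-point sum to exactly 1 through the last category
  props[length(props)] <- 1 - sum(props[-length(props)])
  structure(list(proportions = props, raw = raw),
            class = "first_contact_distribution")
}

#' Probability completion for the packaged tree
#'
#' A completion assigns, to every chance node of the pathway tree, the
#' branch probabilities of its children. The published model only prints
#' the first-contact proportions, so downstream assignments are synthetic
#' stand-ins and carry a provenance flag that propagates to all outputs.
#' Each assignment is normalised so its floating-point sum is exactly 1.
#'
#' @param assignments named list; element `"<chance node id>"` is a named
#'   numeric vector of child branch probabilities.
#' @param provenance character vector (recycled) labelling each
#'   assignment: `"paper_first_contact"`, `"synthetic"` or
#'   `"synthetic_calibrated"`.
#' @return A `probability_completion` object.
#' @export
probability_completion <- function(assignments, provenance = "synthetic") {
  stopifnot(is.list(assignments), !is.null(names(assignments)))
  provenance <- rep_len(as.character(provenance), length(assignments))
  names(provenance) <- names(assignments)
  assignments <- lapply(assignments, function(p) {
    if (!is.numeric(p) || is.null(names(p))) {
      stop("each assignment must be a named numeric vector", call. = FALSE)
    }
    if (any(p < 0) || anyNA(p)) {
      stop("branch probabilities must be non-negative", call. = FALSE)
    }
    s <- sum(p)
    if (s <= 0) stop("assignment sums to zero", call. = FALSE)
    p <- p / s
    p[length(p)] <- 1 - sum(p[-length(p)])
    p
  })
  structure(list(assignments = assignments, provenance = provenance),
            class = "probability_completion")
}

# fixed structural map of the five entry branches (used by completions
# and by the calibration helper)
.branch_structure <- list(
  "1" = list(children = c("1.1", "1.2"), refer = "1.1", success = "1.2"),
  "2" = list(no_action = "2.1", treat = "2.2", success = "2.2.1",
             refer = "2.2.2",
             options = c("2.2.2.1", "2.2.2.2", "2.2.2.3")),
  "3" = list(no_action = "3.1", treat = "3.2", success = "3.2.1",
             refer = "3.2.2",
             options = c("3.2.2.1", "3.2.2.2", "3.2.2.3", "3.2.2.4")),
  "4" = list(no_action = "4.1", treat = "4.2", success = "4.2.1",
             refer = "4.2.2",
             options = c("4.2.2.1", "4.2.2.2", "4.2.2.3", "4.2.2.4")),
  "5" = list(no_action = "5.1", treat = "5.2", success = "5.2.2",
             refer = "5.2.3",
             options = c("5.2.3.1", "5.2.3.2", "5.2.3.3"))
)

# assemble a completion from per-branch (p_treat, p_refer) pairs plus a
# first-contact distribution; uniform split across referral options
completion_from_rates <- function(rates, first_contact, provenance) {
  fc <- first_contact$proportions
  assignments <- list(
    seek = stats::setNames(as.numeric(fc[.entry_categories]),
                           .entry_nodes[.entry_categories])
  )
  prov <- c(seek = "paper_first_contact")
  # pharmacist branch has a single refer/success split
  p1 <- rates[["1"]]
  assignments[["1"]] <- c("1.1" = p1$p_refer, "1.2" = 1 - p1$p_refer)
  prov["1"] <- provenance
  for (b in c("2", "3", "4", "5")) {
    st <- .branch_structure[[b]]
    r <- rates[[b]]
    assignments[[b]] <- stats::setNames(c(1 - r$p_treat, r$p_treat),
                                        c(st$no_action, st$treat))
    assignments[[st$treat]] <- stats::setNames(c(1 - r$p_refer, r$p_refer),
                                               c(st$success, st$refer))
    k <- length(st$options)
    assignments[[st$refer]] <- stats::setNames(rep(1 / k, k), st$options)
    prov[c(b, st$treat, st$refer)] <- provenance
  }
  probability_completion(assignments, provenance = prov[names(assignments)])
}

#' Default synthetic probability completion
#'
#' Placeholder branch probabilities chosen so the packaged model runs end
#' to end: the first-contact split uses the survey-derived distribution
#' (the one published input), and every downstream split uses documented
#' round numbers — 30% of pharmacist patients referred on, an 80% chance
#' of receiving treatment at the other entry providers, a 40% chance of
#' on-referral after treatment, and a uniform split across referral
#' options. These are not estimates of the unpublished probabilities;
#' every assignment except the first contact is flagged `"synthetic"`.
#'
#' @param first_contact a [build_first_contact()] result.
#' @return A [probability_completion()].
#' @export
default_completion <- function(first_contact = build_first_contact()) {
  stopifnot(inherits(first_contact, "first_contact_distribution"))
  rates <- list(
    "1" = list(p_refer = 0.3),
    "2" = list(p_treat = 0.8, p_refer = 0.4),
    "3" = list(p_treat = 0.8, p_refer = 0.4),
    "4" = list(p_treat = 0.8, p_refer = 0.4),
    "5" = list(p_treat = 0.8, p_refer = 0.4)
  )
  completion_from_rates(rates, first_contact, "synthetic")
}

#' Random synthetic probability completion
#'
#' Draws every downstream assignment uniformly from the probability
#' simplex (the first-contact split stays at the survey-derived
#' distribution). Useful for property testing: any draw yields a valid
#' tree.
#'
#' @param seed integer seed; fixes the draw.
#' @param first_contact a [build_first_contact()] result.
#' @return A [probability_completion()] flagged `"synthetic"`.
#' @export
random_completion <- function(seed, first_contact = build_first_contact()) {
  stop_if_not_number(seed, "seed")
  set.seed(as.integer(seed))
  topo <- insomnia_topology()
  assignments <- list()
  prov <- character()
  for (item in flatten_tree(topo)) {
    node <- item$node
    if (node$kind != "chance") next
    kids <- vapply(node$children, function(ch) ch$id, character(1))
    if (node$id == "seek") {
      assignments[[node$id]] <-
        stats::setNames(as.numeric(first_contact$proportions[.entry_categories]),
                        .entry_nodes[.entry_categories])
      prov[node$id] <- "paper_first_contact"
    } else {
      g <- stats::rgamma(length(kids), shape = 1)
      assignments[[node$id]] <- stats::setNames(g / sum(g), kids)
      prov[node$id] <- "synthetic"
    }
  }
  probability_completion(assignments, provenance = prov[names(assignments)])
}

#' Calibrated probability completion (reverse-engineered)
#'
#' Searches for downstream branch probabilities that reproduce the
#' published per-entry-branch mean treatment costs ($36 pharmacist, $98
#' GP, $213 health practitioner, $134 psychologist, $280 alternative
#' practitioner). Within each entry branch the mean cost is an affine
#' function of the treat and refer probabilities, so the match is solved
#' in closed form: referral options are split uniformly, the treatment
#' probability defaults to 0.5, and the on-referral probability is solved
#' from the target; where that leaves `[0, 1]`, the referral probability
#' is fixed at 0.25 and the treatment probability is solved instead.
#'
#' This is explicit reverse-engineering of unpublished inputs from
#' published outputs — a consistency reconstruction, not ground truth —
#' and every downstream assignment is flagged `"synthetic_calibrated"`.
#'
#' @param branch_means named numeric vector of target mean costs for entry
#'   nodes `"1"`..`"5"`.
#' @param costs,matrix unit cost table and utilisation matrix (packaged
#'   copies by default).
#' @param first_contact a [build_first_contact()] result.
#' @param p_treat default treatment probability tried first.
#' @return A [probability_completion()].
#' @export
calibrate_completion <- function(branch_means = c("1" = 36, "2" = 98,
                                                  "3" = 213, "4" = 134,
                                                  "5" = 280),
                                 costs = read_unit_costs(),
                                 matrix = read_utilisation(),
                                 first_contact = build_first_contact(),
                                 p_treat = 0.5) {
  ec <- build_event_costs(matrix, costs)
  need <- names(.branch_structure)
  if (!all(need %in% names(branch_means))) {
    stop("`branch_means` must name entry branches ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rates <- list()
  for (b in need) {
    st <- .branch_structure[[b]]
    target <- branch_means[[b]]
    entry_cost <- ec[[b]]
    if (b == "1") {
      pr <- (target - entry_cost) / ec[[st$refer]]
      if (pr < 0 || pr > 1) {
        stop("cannot calibrate pharmacist branch to its target mean",
             call. = FALSE)
      }
      rates[[b]] <- list(p_refer = pr)
      next
    }
    treat_cost <- ec[[st$treat]]
    refer_mean <- mean(ec[st$options])
    needed <- target - entry_cost
    if (needed < 0) stop(sprintf("branch %s target below its entry cost", b),
                         call. = FALSE)
    pt <- p_treat
    pr <- (needed / pt - treat_cost) / refer_mean
    if (pr < 0 || pr > 1) {
      pr <- 0.25
      pt <- needed / (treat_cost + pr * refer_mean)
      if (pt <= 0 || pt > 1) {
        stop(sprintf("cannot calibrate branch %s to its target mean", b),
             call. = FALSE)
      }
    }
    rates[[b]] <- list(p_treat = pt, p_refer = pr)
  }
  completion_from_rates(rates, first_contact, "synthetic_calibrated")
}

#' Packaged tree topology
#'
#' The treatment-pathway tree with branch probabilities left blank below
#' the root, read from the YAML file shipped under `extdata`.
#'
#' @return An `insomod_tree` whose non-root probabilities are `NA`.
#' @export
insomnia_topology <- function() {
  read_tree_yaml(insomod_file("insomnia_tree.yaml"))
}

#' Build the packaged insomnia treatment tree
#'
#' Applies a probability completion to the packaged topology. By default
#' the tree models the population *seeking treatment* (`seek_split =
#' "external"`): its expected cost is the average cost per person treated
#' and the care-seeking proportion enters through [population_scaling()].
#' With `seek_split = "in_tree"` a root chance node is added that sends
#' `1 - p_seek` of the at-risk insomniac population to a zero-cost
#' "do not seek treatment" end node.
#'
#' @param completion a [probability_completion()] covering every chance
#'   node of the topology; missing nodes raise an error naming them.
#' @param seek_split where the care-seeking split lives (see above).
#' @param p_seek proportion seeking treatment (used by `"in_tree"` only).
#' @return A validated `insomod_tree` with attribute `"provenance"`
#'   carrying the completion's per-node provenance flags.
#' @export
#' @examples
#' tree <- build_insomnia_tree(default_completion())
build_insomnia_tree <- function(completion = default_completion(),
                                seek_split = c("external", "in_tree"),
                                p_seek = 0.15) {
  stopifnot(inherits(completion, "probability_completion"))
  seek_split <- match.arg(seek_split)
  topo <- insomnia_topology()

  missing <- character()
  apply_completion <- function(node) {
    if (node$kind == "chance") {
      assign <- completion$assignments[[node$id]]
      if (is.null(assign)) {
        missing <<- c(missing, node$id)
      } else {
        node$children <- lapply(node$children, function(ch) {
          if (!ch$id %in% names(assign)) {
            stop(sprintf("completion for node '%s' lacks child '%s'",
                         node$id, ch$id), call. = FALSE)
          }
          ch$p <- assign[[ch$id]]
          ch
        })
      }
      node$children <- lapply(node$children, apply_completion)
    }
    node
  }
  root <- apply_completion(topo$root)
  if (length(missing) > 0L) {
    stop("completion missing assignments for chance node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  root$p <- 1

  if (seek_split == "in_tree") {
    stop_if_not_number(p_seek, "p_seek")
    if (p_seek < 0 || p_seek > 1) stop("`p_seek` must lie in [0, 1]",
                                       call. = FALSE)
    seek_node <- root
    seek_node$p <- p_seek
    root <- tree_node("root", "chance", p = 1, children = list(
      tree_node("no_treatment", "end", p = 1 - p_seek,
                event = "no_treatment"),
      seek_node
    ))
  }

  tree <- tree_model(root, name = topo$name,
                     currency_year = topo$currency_year)
  findings <- validate_tree(tree, tolerance = 1e-9)
  if (nrow(findings) > 0L) {
    stop("completed tree failed validation:\n",
         paste(sprintf("- [%s] %s: %s", findings$type, findings$node_id,
                       findings$message), collapse = "\n"),
         call. = FALSE)
  }
  attr(tree, "provenance") <- completion$provenance
  tree
}

#' Generate a random decision tree with event costs
#'
#' Property-test fixture generator: builds a random tree of at most
#' `depth` levels whose chance nodes branch into at most `max_branching`
#' children with probabilities drawn uniformly from the simplex, and
#' attaches an independent non-negative random cost to every node's
#' event. `depth = 1` yields a single end node. Reproducible under
#' `seed`.
#'
#' @param depth maximum number of levels (>= 1).
#' @param max_branching maximum children per chance node (>= 2 unless
#'   `depth` is 1).
#' @param seed integer seed.
#' @return List with elements `tree` (an `insomod_tree`) and
#'   `event_costs` (named numeric vector covering every node).
#' @export
generate_random_tree <- function(depth, max_branching = 4L, seed = 1L) {
  stop_if_not_number(depth, "depth")
  stop_if_not_number(max_branching, "max_branching")
  if (depth < 1) stop("`depth` must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  counter <- 0L
  costs <- numeric()
  build <- function(level, p) {
    counter <<- counter + 1L
    id <- paste0("n", counter)
    costs[[id]] <<- stats::runif(1, 0, 100)
    terminal <- level >= depth || (level > 1L && stats::runif(1) < 0.3)
    if (terminal) {
      tree_node(id, "end", p = p, event = id)
    } else {
      k <- if (max_branching >= 2L) sample(2:max_branching, 1L) else 1L
      g <- stats::rgamma(k, shape = 1)
      ps <- g / sum(g)
      ps[k] <- 1 - sum(ps[-k])
      children <- lapply(seq_len(k), function(i) build(level + 1L, ps[i]))
      tree_node(id, "chance", p = p, event = id, children = children)
    }
  }
  root <- build(1L, 1)
  list(tree = tree_model(root, name = sprintf("random tree (seed %d)",
                                              as.integer(seed))),
       event_costs = costs)
}

#' @export
print.probability_completion <- function(x, ...) {
  cat(sprintf("<probability completion> %d chance-node assignments\n",
              length(x$assignments)))
  tab <- table(x$provenance)
  for (p in names(tab)) cat(sprintf("  %s: %d\n", p, tab[[p]]))
  invisible(x)
}

#' @export
print.first_contact_distribution <- function(x, ...) {
  cat("First-contact provider distribution\n")
  for (nm in names(x$proportions)) {
    cat(sprintf("  %-33s %6.3f\n", nm, x$proportions[[nm]]))
  }
  invisible(x)
}
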