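#' Create a decision-tree node
#'
#' A node is either a *chance* node (at least one child branch, each child
#' carrying the probability of its branch) or an *end* node (a pathway
#' terminus with no children). `p` is the probability of taking the branch
#' that enters this node from its parent; the root carries `p = 1`.
#' `event` names a row of a utilisation matrix and may be `NULL` for purely
#' structural nodes, which contribute zero cost.
#'
#' @param id unique node label (character; coerced).
#' @param kind `"chance"` or `"end"`.
#' @param p branch probability in `[0, 1]` (`NA` for "to be completed").
#' @param event event id costed via the utilisation matrix, or `NULL`.
#' @param children list of `tree_node` objects (chance nodes only).
#' @return An object of class `insomod_node`.
#' @seealso [tree_model()], [validate_tree()]
#' @export
#' @examples
#' leaf <- tree_node("a", "end", p = 1)
tree_node <- function(id, kind = c("chance", "end"), p = NA_real_,
                      event = NULL, children = list()) {
  kind <- match.arg(kind)
  id <- as.character(id)
  if (length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("`id` must be a single non-empty string", call. = FALSE)
  }
  if (length(p) != 1L || !is.numeric(p)) {
    stop("`p` must be a single numeric value (possibly NA)", call. = FALSE)
  }
  if (!is.null(event)) event <- as.character(event)
  if (kind == "end" && length(children) > 0L) {
    stop(sprintf("end node '%s' cannot have children", id), call. = FALSE)
  }
  if (!all(vapply(children, inherits, logical(1), "insomod_node"))) {
    stop("`children` must be a list of tree_node objects", call. = FALSE)
  }
  structure(
    list(id = id, kind = kind, p = as.numeric(p), event = event,
         children = children),
    class = "insomod_node"
  )
}

#' Create a decision-tree model
#'
#' Wraps a root [tree_node()] together with a model name and the currency
#' year its costs are expressed in.
#'
#' @param root the root `tree_node`; its branch probability must be 1.
#' @param name model name.
#' @param currency_year integer year the model's costs are valued in.
#' @return An object of class `insomod_tree`.
#' @export
#' @examples
#' t <- tree_model(tree_node("root", "end", p = 1), name = "degenerate")
tree_model <- function(root, name = "decision tree", currency_year = 2009L) {
  if (!inherits(root, "insomod_node")) {
    stop("`root` must be a tree_node", call. = FALSE)
  }
  structure(
    list(root = root, name = as.character(name),
         currency_year = as.integer(currency_year)),
    class = "insomod_tree"
  )
}

# internal: preorder flatten; returns list of list(node, parent, depth)
flatten_tree <- function(tree) {
  out <- list()
  walk <- function(node, parent, depth) {
    out[[length(out) + 1L]] <<- list(node = node, parent = parent, depth = depth)
    for (ch in node$children) walk(ch, node$id, depth + 1L)
  }
  walk(tree$root, NA_character_, 1L)
  out
}

# internal: ids in preorder
tree_ids <- function(tree) {
  vapply(flatten_tree(tree), function(x) x$node$id, character(1))
}

#' Validate a decision tree
#'
#' Checks the probability semantics of a decision tree: every branch
#' probability lies in `[0, 1]`, the root enters with probability 1, and
#' the child probabilities of every chance node sum to 1 within
#' `tolerance`. Structural defects (duplicate node ids, chance nodes with
#' no children) are reported as findings of type `"structure"`, distinct
#' from `"probability"` findings. If `event_ids` is supplied, event
#' references that do not resolve are reported as type `"event"`.
#'
#' @param tree an `insomod_tree`.
#' @param tolerance allowed absolute deviation of sibling-probability sums
#'   from 1. Defaults to `1e-9`, appropriate for trees built in code; use
#'   a looser value such as `1e-6` for hand-entered configurations.
#' @param event_ids optional character vector of resolvable event ids.
#' @return A data frame with columns `node_id`, `type`
#'   (`structure`/`probability`/`event`) and `message`; zero rows iff the
#'   tree is valid.
#' @export
#' @examples
#' n <- tree_node("r", "chance", 1, children = list(
#'   tree_node("a", "end", 0.6), tree_node("b", "end", 0.3)))
#' validate_tree(tree_model(n))  # one finding: sums to 0.9
validate_tree <- function(tree, tolerance = 1e-9, event_ids = NULL) {
  stopifnot(inherits(tree, "insomod_tree"))
  stop_if_not_number(tolerance, "tolerance")
  if (tolerance <= 0) stop("`tolerance` must be positive", call. = FALSE)
  findings <- list()
  add <- function(node_id, type, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(node_id = node_id, type = type, message = message,
                 stringsAsFactors = FALSE)
  }

  flat <- flatten_tree(tree)
  ids <- vapply(flat, function(x) x$node$id, character(1))
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add(d, "structure", "duplicate node id")

  root <- tree$root
  if (is.na(root$p) || abs(root$p - 1) > tolerance) {
    add(root$id, "probability",
        sprintf("root branch probability is %s, expected 1",
                format(root$p)))
  }

  for (item in flat) {
    node <- item$node
    if (is.na(node$p)) {
      add(node$id, "probability", "branch probability is missing (NA)")
    } else if (node$p < 0 || node$p > 1) {
      add(node$id, "probability",
          sprintf("branch probability %g outside [0, 1]", node$p))
    }
    if (node$kind == "chance") {
      if (length(node$children) == 0L) {
        add(node$id, "structure", "chance node has no children")
      } else {
        ps <- vapply(node$children, function(ch) ch$p, numeric(1))
        if (anyNA(ps)) {
          add(node$id, "probability",
              "child branch probabilities contain NA")
        } else if (abs(sum(ps) - 1) > tolerance) {
          add(node$id, "probability",
              sprintf("child branch probabilities sum to %.10g, not 1",
                      sum(ps)))
        }
      }
    }
    if (!is.null(event_ids) && !is.null(node$event) &&
        !(node$event %in% event_ids)) {
      add(node$id, "event",
          sprintf("event '%s' not found among supplied event ids",
                  node$event))
    }
  }

  if (length(findings) == 0L) {
    data.frame(node_id = character(), type = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
}

#' Enumerate root-to-leaf pathways
#'
#' Walks the tree depth first and returns one pathway per end node. A
#' pathway's probability is the product of the branch probabilities along
#' it, and its cost is the sum of the event costs of the nodes it visits
#' (nodes with a `NULL` event contribute nothing). The tree is validated
#' first; any finding, including an event id missing from `event_costs`,
#' aborts with an informative error.
#'
#' @param tree an `insomod_tree`.
#' @param event_costs named numeric vector mapping event ids to dollars,
#'   e.g. from [build_event_costs()].
#' @param tolerance validation tolerance, see [validate_tree()].
#' @return A data frame with one row per leaf: `leaf` (leaf node id),
#'   `path` (list column of node-id vectors), `probability`, `cost`.
#'   Pathway probabilities sum to 1 within `tolerance`.
#' @export
#' @examples
#' n <- tree_node("r", "chance", 1, children = list(
#'   tree_node("a", "end", 0.5, event = "a"),
#'   tree_node("b", "end", 0.5, event = "b")))
#' enumerate_pathways(tree_model(n), c(a = 10, b = 20))
enumerate_pathways <- function(tree, event_costs, tolerance = 1e-9) {
  stopifnot(inherits(tree, "insomod_tree"))
  if (is.null(names(event_costs)) && length(event_costs) > 0L) {
    stop("`event_costs` must be a named numeric vector", call. = FALSE)
  }
  findings <- validate_tree(tree, tolerance, event_ids = names(event_costs))
  if (nrow(findings) > 0L) {
    stop("tree failed validation:\n",
         paste(sprintf("- [%s] %s: %s", findings$type, findings$node_id,
                       findings$message), collapse = "\n"),
         call. = FALSE)
  }

  leaves <- list()
  # probability and cost accumulate sequentially in visit order so that the
  # result is bit-identical to the vectorised PSA engine's arithmetic
  walk <- function(node, ids, prob, cost) {
    ids <- c(ids, node$id)
    prob <- prob * node$p
    if (!is.null(node$event)) cost <- cost + event_costs[[node$event]]
    if (node$kind == "end") {
      leaves[[length(leaves) + 1L]] <<-
        list(leaf = node$id, path = ids, probability = prob, cost = cost)
    } else {
      for (ch in node$children) walk(ch, ids, prob, cost)
    }
  }
  walk(tree$root, character(), 1, 0)

  data.frame(
    leaf = vapply(leaves, `[[`, character(1), "leaf"),
    path = I(lapply(leaves, `[[`, "path")),
    probability = vapply(leaves, `[[`, numeric(1), "probability"),
    cost = vapply(leaves, `[[`, numeric(1), "cost"),
    stringsAsFactors = FALSE
  )
}

#' Expected cost of a decision tree
#'
#' The probability-weighted sum of pathway costs,
#' \eqn{\sum_k p_k c_k}{sum(p_k * c_k)} — the average cost per person
#' entering the tree. Pathway probabilities must sum to 1 within
#' `tolerance` (conservation), otherwise an error is raised.
#'
#' @param pathways a pathway data frame from [enumerate_pathways()], or
#'   any data frame with `probability` and `cost` columns.
#' @param tolerance allowed deviation of the probability total from 1.
#' @return Expected cost in dollars (single number).
#' @export
#' @examples
#' expected_tree_cost(data.frame(probability = c(0.5, 0.5), cost = c(10, 20)))
expected_tree_cost <- function(pathways, tolerance = 1e-9) {
  stopifnot(is.data.frame(pathways),
            all(c("probability", "cost") %in% names(pathways)))
  s <- sum(pathways$probability)
  if (abs(s - 1) > tolerance) {
    stop(sprintf(
      "pathway probabilities sum to %.10g, not 1 (conservation violated)", s),
      call. = FALSE)
  }
  sum(pathways$probability * pathways$cost)
}

# ---- YAML serialisation ------------------------------------------------

node_to_list <- function(node) {
  out <- list(id = node$id, kind = node$kind)
  if (!is.na(node$p)) out$p <- node$p
  if (!is.null(node$event)) out$event <- node$event
  if (length(node$children) > 0L) {
    out$children <- lapply(node$children, node_to_list)
  }
  out
}

node_from_list <- function(x) {
  tree_node(
    id = as.character(x$id),
    kind = x$kind,
    p = if (is.null(x$p)) NA_real_ else as.numeric(x$p),
    event = if (is.null(x$event)) NULL else as.character(x$event),
    children = lapply(x$children %||% list(), node_from_list)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write decision trees as YAML
#'
#' Trees are serialised as nested mappings with keys `id`, `kind`, `p`,
#' `event` and `children`; a missing `p` (to be supplied later by a
#' probability completion) is simply omitted. Reading and writing
#' round-trip to an identical tree. Node and event ids are coerced to
#' character on read, so dotted labels such as `"2.2.2.1"` survive.
#'
#' @param path file path.
#' @param tree an `insomod_tree`.
#' @return `read_tree_yaml()` returns an `insomod_tree`;
#'   `write_tree_yaml()` returns `path` invisibly.
#' @export
read_tree_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$root)) stop("tree YAML must have a `root` mapping", call. = FALSE)
  tree_model(node_from_list(x$root),
             name = x$name %||% "decision tree",
             currency_year = x$currency_year %||% 2009L)
}

#' @rdname read_tree_yaml
#' @export
write_tree_yaml <- function(tree, path) {
  stopifnot(inherits(tree, "insomod_tree"))
  yaml::write_yaml(
    list(name = tree$name, currency_year = tree$currency_year,
         root = node_to_list(tree$root)),
    path,
    precision = 17  # probabilities must survive the round trip exactly
  )
  invisible(path)
}

#' @export
print.insomod_tree <- function(x, ...) {
  cat(sprintf("<decision tree> %s (NZD %d)\n", x$name, x$currency_year))
  show <- function(node, indent) {
    marker <- if (node$kind == "chance") "o" else "<"
    p <- if (is.na(node$p)) "p=?" else sprintf("p=%.4g", node$p)
    cat(sprintf("%s%s %s [%s]%s\n", strrep("  ", indent), marker, node$id, p,
                if (is.null(node$event)) "" else paste0(" event=", node$event)))
    for (ch in node$children) show(ch, indent + 1L)
  }
  show(x$root, 0L)
  invisible(x)
}
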