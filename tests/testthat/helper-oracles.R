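# Independent oracle: expected tree cost by direct depth-first recursion,
# E[node] = event_cost(node) + sum_children p_child * E[child].
# Deliberately does not share code with enumerate_pathways()/
# expected_tree_cost(), which roll the expectation up from pathways.
recursive_expected_cost <- function(tree, event_costs) {
  rec <- function(node) {
    own <- if (is.null(node$event)) 0 else event_costs[[node$event]]
    if (node$kind == "end") return(own)
    kids <- vapply(node$children, function(ch) ch$p * rec(ch), numeric(1))
    own + sum(kids)
  }
  rec(tree$root)
}

# preorder node ids without relying on package internals
tree_ids_for_test <- function(tree) {
  ids <- character()
  walk <- function(node) {
    ids <<- c(ids, node$id)
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  ids
}

# small two-leaf tree used across tests
two_leaf_tree <- function(p1 = 0.5, e1 = "a", e2 = "b") {
  tree_model(tree_node("r", "chance", 1, children = list(
    tree_node("a", "end", p1, event = e1),
    tree_node("b", "end", 1 - p1, event = e2)
  )))
}
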