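test_that("a degenerate single-end-node tree validates cleanly", {
  t <- tree_model(tree_node("only", "end", p = 1, event = "e"))
  expect_identical(nrow(validate_tree(t)), 0L)
})

test_that("validation reports probability non-conservation with the sum", {
  t <- tree_model(tree_node("r", "chance", 1, children = list(
    tree_node("a", "end", 0.6), tree_node("b", "end", 0.3))))
  f <- validate_tree(t)
  expect_identical(nrow(f), 1L)
  expect_identical(f$type, "probability")
  expect_match(f$message, "sum to 0.9")
})

test_that("structural defects are findings distinct from probability ones", {
  dup <- tree_model(tree_node("r", "chance", 1, children = list(
    tree_node("x", "end", 0.5), tree_node("x", "end", 0.5))))
  f <- validate_tree(dup)
  expect_true("structure" %in% f$type)

  childless <- tree_model(tree_node("r", "chance", 1))
  expect_true("structure" %in% validate_tree(childless)$type)

  # out-of-range and missing probabilities are probability findings
  bad_p <- tree_model(tree_node("r", "chance", 1, children = list(
    tree_node("a", "end", 1.5), tree_node("b", "end", -0.5))))
  expect_true(all(validate_tree(bad_p)$type == "probability"))

  # end nodes reject children outright
  expect_error(tree_node("e", "end", 1, children = list(tree_node("c", "end", 1))),
               "cannot have children")
})

test_that("unresolvable event references are reported when ids supplied", {
  t <- tree_model(tree_node("r", "end", 1, event = "ghost"))
  f <- validate_tree(t, event_ids = c("real"))
  expect_identical(f$type, "event")
  expect_match(f$message, "ghost")
})

test_that("two-leaf enumeration yields the expected pathways", {
  p <- enumerate_pathways(two_leaf_tree(), c(a = 10, b = 20))
  expect_identical(p$leaf, c("a", "b"))
  expect_equal(p$probability, c(0.5, 0.5))
  expect_equal(p$cost, c(10, 20))
  expect_equal(expected_tree_cost(p), 15)
})

test_that("structural nodes with no event contribute zero cost", {
  t <- tree_model(tree_node("r", "chance", 1, children = list(
    tree_node("mid", "chance", 1, children = list(
      tree_node("leaf", "end", 1, event = "e"))))))
  p <- enumerate_pathways(t, c(e = 7))
  expect_equal(p$cost, 7)
  expect_equal(p$probability, 1)
})

test_that("a missing event cost aborts naming the event", {
  expect_error(enumerate_pathways(two_leaf_tree(e2 = "nope"), c(a = 1)),
               "nope")
})

test_that("expected_tree_cost enforces probability conservation", {
  expect_equal(expected_tree_cost(data.frame(probability = 1, cost = 50)), 50)
  bad <- data.frame(probability = c(0.5, 0.4), cost = c(1, 2))
  expect_error(expected_tree_cost(bad), "conservation")
  # invariant under reordering
  p <- data.frame(probability = c(0.3, 0.7), cost = c(10, 100))
  expect_equal(expected_tree_cost(p), expected_tree_cost(p[2:1, ]))
})

test_that("pathway rollup matches the recursive expectation oracle on random trees", {
  for (seed in 1:25) {
    g <- generate_random_tree(depth = 5, max_branching = 4, seed = seed)
    p <- enumerate_pathways(g$tree, g$event_costs)
    expect_equal(sum(p$probability), 1, tolerance = 1e-12)
    expect_equal(expected_tree_cost(p),
                 recursive_expected_cost(g$tree, g$event_costs),
                 tolerance = 1e-10)
  }
})

test_that("pathway and expected costs are linear in event costs", {
  g <- generate_random_tree(depth = 4, max_branching = 3, seed = 99)
  p1 <- enumerate_pathways(g$tree, g$event_costs)
  k <- 3.7
  p2 <- enumerate_pathways(g$tree, g$event_costs * k)
  expect_equal(p2$cost, k * p1$cost)
  expect_equal(expected_tree_cost(p2), k * expected_tree_cost(p1))
})

test_that("a zero-cost zero-probability branch leaves the expected cost unchanged", {
  t1 <- two_leaf_tree()
  t2 <- tree_model(tree_node("r", "chance", 1, children = list(
    tree_node("a", "end", 0.5, event = "a"),
    tree_node("b", "end", 0.5, event = "b"),
    tree_node("ghostly", "end", 0, event = "z"))))
  ec <- c(a = 10, b = 20, z = 0)
  expect_equal(expected_tree_cost(enumerate_pathways(t2, ec)),
               expected_tree_cost(enumerate_pathways(t1, ec)))
})

test_that("YAML round-trip is the identity on tree content", {
  g <- generate_random_tree(depth = 4, max_branching = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tree_yaml(g$tree, path)
  back <- read_tree_yaml(path)
  expect_identical(back, g$tree)
  # and a second round trip writes identical text
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_tree_yaml(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("dotted node ids survive YAML serialisation as character", {
  t <- tree_model(tree_node("2.2", "chance", 1, event = "2.2",
                            children = list(
                              tree_node("2.2.1", "end", 0.5),
                              tree_node("2.2.10", "end", 0.5))))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tree_yaml(t, path)
  back <- read_tree_yaml(path)
  expect_identical(tree_ids_for_test(back), c("2.2", "2.2.1", "2.2.10"))
})
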