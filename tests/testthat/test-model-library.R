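test_that("first-contact grouping pools nurses/counsellors and drops psychiatrists", {
  fc <- build_first_contact(stinson_percentages())
  p <- fc$proportions
  # raw groupings before normalisation: 3.5 + 10.6 and 8.2 + 8.2 + 4.7,
  # over a retained total of 100.0 exactly
  expect_equal(unname(p["health_practitioner"]), 14.1 / 100)
  expect_equal(unname(p["alternative_health_practitioner"]), 21.1 / 100)
  expect_equal(unname(p["pharmacist"]), 0.165)
  expect_equal(unname(p["general_practitioner"]), 0.412)
  expect_equal(sum(p), 1)
})

test_that("first-contact edge cases normalise correctly", {
  one <- build_first_contact(c(pharmacist = 12))
  expect_equal(unname(one$proportions["pharmacist"]), 1)
  uni <- build_first_contact(stats::setNames(
    rep(20, 5), c("pharmacist", "general_practitioner", "psychologist",
                  "health_practitioner", "alternative_health_practitioner")))
  expect_equal(unname(uni$proportions), rep(0.2, 5))
  expect_error(build_first_contact(c(pharmacist = 0)), "zero")
  expect_error(build_first_contact(c(wizard = 5)), "unknown")
})

test_that("any valid completion yields a validating packaged tree", {
  for (comp in list(default_completion(), random_completion(31),
                    calibrate_completion())) {
    tree <- build_insomnia_tree(comp)
    expect_identical(nrow(validate_tree(tree, 1e-9)), 0L)
  }
  # in-tree care-seeking split also validates and adds the no-treatment leaf
  t2 <- build_insomnia_tree(default_completion(), seek_split = "in_tree",
                            p_seek = 0.15)
  expect_identical(nrow(validate_tree(t2, 1e-9)), 0L)
  expect_true("no_treatment" %in% tree_ids_for_test(t2))
})

test_that("an incomplete or inconsistent completion is rejected by name", {
  comp <- default_completion()
  comp$assignments[["3.2"]] <- NULL
  expect_error(build_insomnia_tree(comp), "3\\.2")
  # an assignment that cannot be normalised is caught at construction
  expect_error(probability_completion(list(x = c(a = 0, b = 0))), "zero")
  expect_error(probability_completion(list(x = c(a = -1, b = 2))),
               "non-negative")
})

test_that("the packaged topology contains every published pathway endpoint", {
  ec <- build_event_costs(read_utilisation(), read_unit_costs())
  tree <- build_insomnia_tree(default_completion())
  p <- enumerate_pathways(tree, ec)
  # the four worked pathway costs exist as root-to-leaf paths
  expect_equal(round_half_up(p$cost[p$leaf == "1.2"]), 33)
  expect_equal(round_half_up(p$cost[p$leaf == "2.2.2.2"]), 434)
  expect_equal(round_half_up(p$cost[p$leaf == "3.2.2.2"]), 502)
  expect_equal(round_half_up(p$cost[p$leaf == "3.2.2.1"]), 562)
  expect_setequal(setdiff(read_utilisation()$event_id, "no_treatment"),
                  tree_ids_for_test(tree))
})

test_that("collapsing every split onto success leaves only first-visit costs", {
  # success-probability-1 completion: expected cost is the probability-
  # weighted entry event cost
  comp <- default_completion()
  comp$assignments[["1"]] <- c("1.1" = 0, "1.2" = 1)
  for (b in c("2", "3", "4", "5")) {
    kids <- names(comp$assignments[[b]])
    comp$assignments[[b]] <- stats::setNames(c(1, 0), kids)  # no further action
  }
  ec <- build_event_costs(read_utilisation(), read_unit_costs())
  tree <- build_insomnia_tree(comp)
  got <- expected_tree_cost(enumerate_pathways(tree, ec), 1e-6)
  fc <- build_first_contact()$proportions
  entry_costs <- ec[c("1", "2", "3", "4", "5")]
  expect_equal(got, sum(unname(fc) * unname(entry_costs)))
})

test_that("calibration reproduces the published per-branch mean costs", {
  run <- run_deterministic(run_config(completion = "calibrated"))
  bm <- stats::setNames(run$branch_means$mean_cost, run$branch_means$entry)
  expect_equal(bm, c("1" = 36, "2" = 98, "3" = 213, "4" = 134, "5" = 280),
               tolerance = 1e-9)
  # provenance flags mark the reverse-engineered assignments
  expect_true(all(run$provenance[names(run$provenance) != "seek"] ==
                    "synthetic_calibrated"))
  expect_identical(unname(run$provenance["seek"]), "paper_first_contact")
})

test_that("random tree generation is reproducible and honours depth 1", {
  g1 <- generate_random_tree(4, 3, seed = 10)
  g2 <- generate_random_tree(4, 3, seed = 10)
  expect_identical(g1$tree, g2$tree)
  expect_identical(g1$event_costs, g2$event_costs)
  g3 <- generate_random_tree(4, 3, seed = 11)
  expect_false(identical(g1$tree, g3$tree))

  d1 <- generate_random_tree(1, 4, seed = 2)
  expect_identical(d1$tree$root$kind, "end")
  p <- enumerate_pathways(d1$tree, d1$event_costs)
  expect_equal(expected_tree_cost(p), unname(d1$event_costs["n1"]))
})
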