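uc <- read_unit_costs()
um <- read_utilisation()

test_that("the packaged unit cost table carries the published estimates", {
  v <- unit_cost_vector(uc)
  expect_equal(unname(v[c("gp", "specialist_initial", "specialist_followup",
                          "psychologist", "health_practitioner",
                          "alternative_health_practitioner", "prescription",
                          "nonprescription", "transport")]),
               c(48.89, 222.22, 99.56, 88.89, 120.00, 75.56, 6.42, 16.00,
                 16.71))
})

test_that("event costs are volume-weighted sums of unit costs", {
  # GP first visit: one consultation plus one round trip
  expect_equal(event_cost("2", um, uc), 48.89 + 16.71)
  # specialist referral: initial + follow-up + prescription + two trips
  expect_equal(event_cost("2.2.2.2", um, uc), 222.22 + 99.56 + 6.42 + 33.42)
  # pharmacist first visit: OTC product plus travel
  expect_equal(event_cost("1", um, uc), 32.71)
  # an expected half-course of a prescription contributes half its cost
  expect_equal(event_cost("3.2", um, uc), 0.5 * 6.42)
  # all-zero rows are valid zero-cost events
  expect_identical(event_cost("2.2.1", um, uc), 0)
})

test_that("build_event_costs covers every event and agrees with event_cost", {
  ec <- build_event_costs(um, uc)
  expect_setequal(names(ec), um$event_id)
  for (e in c("1", "1.1", "3.2.2.4", "5.2", "no_treatment")) {
    expect_identical(ec[[e]], event_cost(e, um, uc))
  }
})

test_that("unpriced resources raise a lookup error naming them", {
  um2 <- utilisation_matrix(data.frame(event_id = "x", label = "x",
                                       moonbeam = 1))
  expect_error(event_cost("x", um2, uc), "moonbeam")
  expect_error(build_event_costs(um2, uc), "moonbeam")
  expect_error(event_cost("absent", um, uc), "absent")
})

test_that("event costs are additive over merged events and homogeneous in unit costs", {
  # additivity: volumes of a merged event are the sums of its parts
  part1 <- utilisation_matrix(data.frame(event_id = "a", label = "a",
                                         gp = 1, transport = 2))
  part2 <- utilisation_matrix(data.frame(event_id = "b", label = "b",
                                         gp = 0.5, transport = 1))
  merged <- utilisation_matrix(data.frame(event_id = "m", label = "m",
                                          gp = 1.5, transport = 3))
  expect_equal(event_cost("m", merged, uc),
               event_cost("a", part1, uc) + event_cost("b", part2, uc))
  # homogeneity: scaling all unit costs scales every event cost
  uc2 <- unit_cost_table(transform(as.data.frame(uc),
                                   unit_cost = unit_cost * 2.5))
  ec1 <- build_event_costs(um, uc)
  ec2 <- build_event_costs(um, uc2)
  expect_equal(ec2, 2.5 * ec1)
})

test_that("transport unit cost is rate times round-trip distance", {
  expect_equal(transport_unit_cost(0.56, 29.83), 16.7048)
  expect_equal(transport_unit_cost(1, 1), 1)
  expect_error(transport_unit_cost(0.56, 0), "positive")
  expect_error(transport_unit_cost(-1, 10), "positive")
})

test_that("malformed costing inputs are rejected", {
  expect_error(unit_cost_table(data.frame(resource_id = c("a", "a"),
                                          label = "x", unit_cost = 1,
                                          year = 2009)), "duplicate")
  expect_error(unit_cost_table(data.frame(resource_id = "a", label = "x",
                                          unit_cost = -1, year = 2009)),
               "non-negative")
  expect_error(utilisation_matrix(data.frame(event_id = "e", label = "l",
                                             gp = -2)), "negative")
})
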