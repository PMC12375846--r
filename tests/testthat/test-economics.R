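test_that("discounting follows the age-45 reference convention", {
  expect_equal(discount_value(100, 0, 0.03), 100)
  expect_equal(discount_value(100, 17, 0), 100)
  expect_equal(discount_value(100, 10, 0.03), 100 / 1.03^10)
  # events before the reference clamp to time zero
  expect_equal(discount_value(100, -5, 0.03), 100)
  expect_error(discount_value(100, 1, -0.01), ">= 0")
})

test_that("the multiplicative utility model combines background and states", {
  u <- utility_inputs()
  bg <- background_utility_at <- utility_at_age(u, 50)
  expect_equal(utility_at_age(u, 50, character()), bg)
  # a state with utility 1 leaves the background unchanged
  u1 <- u
  u1$states$utility[u1$states$state == "as"] <- 1
  expect_equal(utility_at_age(u1, 50, "as"), bg)
  expect_equal(utility_at_age(u, 60, c("biopsy", "as")),
               utility_at_age(u, 60) * 0.90 * 0.97)
  expect_error(utility_at_age(u, 50, "spa_day"), "unknown health state")
})

test_that("event costs accumulate and discount like a hand ledger", {
  costs <- cost_schedule()
  expect_equal(unname(accumulate_costs(data.frame(person_id = integer(),
                                                  age = numeric(),
                                                  event = character(),
                                                  type = character()),
                                       NULL, costs, 0.03)),
               c(0, 0))

  # three PSA tests at 25.61 euros, undiscounted
  r <- data.frame(person_id = 1, age = c(50, 55, 60), event = "psa_test",
                  type = NA_character_)
  expect_equal(unname(accumulate_costs(r, NULL, costs, 0)[1]), 76.83)

  # mixed record against an explicit event-by-event recomputation
  r <- data.frame(
    person_id = 1,
    age = c(50, 50, 52, 52, 55),
    event = c("psa_test", "mri", "biopsy", "dre_test", "biopsy"),
    type = c(NA, NA, "combined", NA, "systematic")
  )
  want_undisc <- 25.61 + 500 + 1250 + 15 + 650
  want_disc <- 25.61 / 1.03^5 + 500 / 1.03^5 + 1250 / 1.03^7 +
    15 / 1.03^7 + 650 / 1.03^10
  got <- accumulate_costs(r, NULL, costs, 0.03)
  expect_equal(unname(got), c(want_undisc, want_disc))

  bad <- data.frame(person_id = 1, age = 50, event = "biopsy", type = "laser")
  expect_error(accumulate_costs(bad, NULL, costs, 0), "no cost entry")
})

test_that("QALY integration reduces to life-years under unit utilities", {
  flat <- utility_inputs()
  flat$background$utility[] <- 1
  flat$states$utility[] <- 1
  hist <- list(person_id = 1, actual_dx_age = NA_real_, stage_at_dx = NULL,
               grade_category = NA_character_, cancer_death_age = NA_real_,
               death_age = 83.4, other_cause_death_age = 83.4)
  empty <- data.frame(person_id = integer(), age = numeric(),
                      event = character(), type = character())
  q <- accumulate_qalys(empty, hist, flat, 0)
  expect_equal(unname(q["ly_undisc"]), 83.4 - 45)
  expect_equal(unname(q["qaly_undisc"]), 83.4 - 45)

  q3 <- accumulate_qalys(empty, hist, flat, 0.03)
  expect_lt(q3[["ly_disc"]], q3[["ly_undisc"]])
  expect_lt(q3[["qaly_disc"]], q3[["qaly_undisc"]])

  # one 0.9-utility state lasting a year knocks off exactly 0.1 QALYs
  one_state <- flat
  one_state$states$utility[one_state$states$state == "biopsy"] <- 0.9
  one_state$states$duration_years[one_state$states$state == "biopsy"] <- 1
  r <- data.frame(person_id = 1, age = 50, event = "biopsy",
                  type = "systematic")
  q <- accumulate_qalys(r, hist, one_state, 0)
  expect_equal(unname(q["qaly_undisc"]), unname(q["ly_undisc"]) - 0.1)
})

test_that("cohort economics: QALY <= LY, discounting shrinks, costs are linear", {
  co <- fixture_cohort(3000, 42)
  scr <- run_screening_cohort(co, strategy_preset("psa_ras_45_70_mri"))
  econ <- compute_economics(scr)
  expect_true(all(econ$qaly_undisc <= econ$ly_undisc + 1e-9))
  expect_true(all(econ$qaly_disc <= econ$ly_disc + 1e-9))
  expect_true(all(econ$ly_disc <= econ$ly_undisc + 1e-9))
  expect_true(all(econ$cost_disc <= econ$cost_undisc + 1e-9))

  # doubling the MRI unit cost doubles exactly the MRI component
  econ2 <- compute_economics(scr, cost_schedule(mri = 1000))
  c1 <- attr(econ, "cost_components")
  c2 <- attr(econ2, "cost_components")
  expect_equal(c2[["mri"]], 2 * c1[["mri"]])
  others <- setdiff(names(c1), "mri")
  expect_equal(c2[others], c1[others])
  expect_equal(sum(econ2$cost_disc) - sum(econ$cost_disc), c1[["mri"]])
})

test_that("swapping the utility set changes QALYs only", {
  co <- fixture_cohort(3000, 42)
  scr <- run_screening_cohort(co, strategy_preset("psa_ras_50_70_nomri"))
  porpus <- compute_economics(scr, utilities = utility_inputs("porpus_u"))
  eq5d <- compute_economics(scr, utilities = utility_inputs("eq5d"))
  expect_identical(porpus$ly_undisc, eq5d$ly_undisc)
  expect_identical(porpus$ly_disc, eq5d$ly_disc)
  expect_identical(porpus$cost_disc, eq5d$cost_disc)
  expect_false(isTRUE(all.equal(porpus$qaly_disc, eq5d$qaly_disc)))
  expect_true(all(eq5d$qaly_disc <= porpus$qaly_disc + 1e-9))
})
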