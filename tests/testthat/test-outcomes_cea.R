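test_that("overdiagnosis is screen detection the man would never have known about", {
  mk <- function(mode, cf, oc) list(dx_mode = mode,
                                    counterfactual_clinical_dx_age = cf,
                                    other_cause_death_age = oc)
  expect_false(count_overdiagnosis(mk("clinical", 62, 80)))
  expect_true(count_overdiagnosis(mk("screen", 62, 60)))
  expect_false(count_overdiagnosis(mk("screen", 58, 80)))
  expect_true(count_overdiagnosis(mk("screen", NA, 80)))
})

test_that("per-100k summaries scale correctly and are duplication-invariant", {
  co <- fixture_cohort(3000, 42)
  res <- run_strategy(co, "psa_ras_50_60_nomri", run_config())
  out <- summarize_per_100k(res)
  ident <- summarize_per_100k(res, scale_n = res$n)
  expect_equal(ident$n_dx_total, sum(res$persons$dx_mode != "none"))
  expect_equal(out$n_dx_total, ident$n_dx_total * 1e5 / res$n)

  # duplicating every person leaves the per-100k outcome unchanged
  dup <- res
  p2 <- res$persons
  p2$person_id <- p2$person_id + res$n
  e2 <- res$events
  e2$person_id <- e2$person_id + res$n
  ec2 <- res$economics
  ec2$person_id <- ec2$person_id + res$n
  dup$persons <- rbind(res$persons, p2)
  dup$events <- rbind(res$events, e2)
  dup$economics <- rbind(res$economics, ec2)
  dup$n <- 2L * res$n
  expect_equal(summarize_per_100k(dup), out)

  expect_error(summarize_per_100k(list(persons = NULL, n = 0)), "empty")
})

test_that("conservation holds in simulated outcomes", {
  co <- fixture_cohort(3000, 42)
  for (nm in c("no_screening", "dre_45_75", "psa_ras_45_70_mri")) {
    out <- run_and_summarize(co, nm)
    expect_equal(out$n_dx_total, out$n_dx_clinical + out$n_dx_screen)
    expect_equal(out$n_biopsies_total,
                 out$n_biopsies_clinical + out$n_biopsies_screen)
    expect_lte(out$n_overdiagnosed, out$n_dx_screen)
    if (nm == "no_screening") {
      expect_equal(out$n_dx_screen + out$n_biopsies_screen +
                     out$n_psa_tests + out$n_mri, 0)
    }
  }
})

test_that("reductions against a reference reproduce the table convention", {
  ref <- list(n_biopsies_screen = 151125, n_overdiagnosed = 2468)
  x <- list(n_biopsies_screen = 12727, n_overdiagnosed = 314)
  r <- reduction_vs_reference(x, ref, "n_biopsies_screen")
  expect_equal(r$absolute, 138398)
  expect_equal(r$percent, 92)
  r <- reduction_vs_reference(x, ref, "n_overdiagnosed")
  expect_equal(r$absolute, 2154)
  expect_equal(r$percent, 87)
  same <- reduction_vs_reference(ref, ref, "n_overdiagnosed")
  expect_equal(c(same$absolute, same$percent), c(0, 0))
  zero <- reduction_vs_reference(x, list(n_biopsies_screen = 0),
                                 "n_biopsies_screen")
  expect_true(is.na(zero$percent))
})

test_that("the efficiency frontier handles trivial dominance and ordering", {
  two <- data.frame(strategy = c("a", "b"), effect = c(2, 1), cost = c(1, 2))
  fr <- efficiency_frontier(two, "effect", "cost")
  expect_identical(fr$efficient$strategy, "a")
  expect_identical(fr$dominated$strategy, "b")
  expect_identical(fr$dominated$label, "strictly_dominated")
  expect_error(efficiency_frontier(two[1, ], "effect", "cost"), "at least 2")

  # invariant to the input ordering of strategies
  d <- data.frame(strategy = letters[1:6],
                  effect = c(5, 3, 8, 1, 9, 7),
                  cost = c(4, 1, 9, 2, 20, 6))
  f1 <- efficiency_frontier(d, "effect", "cost")
  f2 <- efficiency_frontier(d[sample(6), ], "effect", "cost")
  expect_equal(f1$efficient, f2$efficient)
})

test_that("frontier matches an independent greedy construction on random instances", {
  set.seed(99)
  for (i in 1:500) {
    k <- sample(2:12, 1)
    d <- data.frame(
      strategy = paste0("s", seq_len(k)),
      effect = round(stats::runif(k, 0, 10), sample(0:2, 1)),
      cost = round(stats::rnorm(k, 5, 3), sample(0:2, 1))
    )
    fr <- efficiency_frontier(d, "effect", "cost")
    expect_identical(sort(fr$efficient$strategy), frontier_oracle(d))
    # ICERs strictly increase along the frontier
    ic <- fr$efficient$icer[-1]
    expect_true(all(diff(ic) > 0) || length(ic) < 2)
    # the least-cost strategy opens the frontier
    expect_equal(fr$efficient$cost[1], min(d$cost))
  }
})

test_that("CEAC probabilities count net-monetary-benefit winners", {
  d <- data.frame(iteration = 1, strategy = c("a", "b"),
                  cost = c(5, 10), effect = c(1, 2))
  cc <- ceac_from_draws(d, c(0, 10))
  expect_equal(cc$probability, c(1, 0, 0, 1))

  # lambda = 0: the cheapest strategy wins with probability 1
  set.seed(3)
  n_iter <- 60
  d <- do.call(rbind, lapply(seq_len(n_iter), function(i) {
    data.frame(iteration = i, strategy = c("a", "b", "c"),
               cost = stats::rnorm(3, c(5, 8, 11)),
               effect = stats::rnorm(3, c(1, 1.5, 1.8), 0.2))
  }))
  grid <- c(0, 2, 5, 20)
  cc <- ceac_from_draws(d, grid)

  # independent recount of winners, iteration by iteration
  for (lam in grid) {
    p <- sapply(c("a", "b", "c"), function(s) {
      wins <- 0
      for (i in seq_len(n_iter)) {
        di <- d[d$iteration == i, ]
        nmb <- lam * di$effect - di$cost
        if (di$strategy[which.max(nmb)] == s) wins <- wins + 1
      }
      wins / n_iter
    })
    got <- cc$probability[cc$wtp == lam]
    expect_equal(got, unname(p))
    expect_equal(sum(got), 1)
  }
  expect_error(ceac_from_draws(d, numeric()), "empty")
})
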