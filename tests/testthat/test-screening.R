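test_that("strategy presets encode the policy definitions", {
  s <- strategy_preset("psa_ras_50_60_nomri")
  expect_equal(s$start_age, 50)
  expect_equal(s$stop_age, 60)
  expect_equal(s$workup_threshold, 3)
  expect_equal(s$risk_bands$interval_years[1:2], c(5, 2))
  expect_equal(s$risk_bands$upper[1:2], c(1.5, 3))
  expect_false(s$mri_triage)
  expect_identical(s$biopsy_type_on_workup, "systematic")

  d <- strategy_preset("dre_45_75")
  expect_identical(d$primary_test, "dre")
  expect_equal(c(d$start_age, d$stop_age, d$dre_interval), c(45, 75, 1))
  expect_identical(d$symptomatic_workup, "systematic")

  ns <- strategy_preset("no_screening")
  expect_identical(ns$primary_test, "none")
  expect_identical(ns$symptomatic_workup, "mri_combined")

  m <- strategy_preset("psa_ras_45_70_mri")
  expect_true(m$mri_triage)
  expect_identical(m$biopsy_type_on_workup, "combined")
  expect_equal(c(m$start_age, m$stop_age), c(45, 70))

  expect_error(strategy_preset("psa_every_day"), "valid presets")
  expect_length(list_strategy_presets(), 10L)
})

test_that("next_invitation follows the risk bands and the stop-age rule", {
  s <- strategy_preset("psa_ras_50_60_nomri")
  expect_equal(next_invitation(s), 50)
  expect_equal(next_invitation(s, 50, 1.0), 55)
  expect_equal(next_invitation(s, 50, 2.0), 52)
  expect_true(is.na(next_invitation(s, 58, 1.0)))  # 5y overshoots stop 60
  expect_equal(next_invitation(s, 58, 2.0), 60)    # lands exactly on stop
  expect_error(next_invitation(s, 50, -1), "non-negative")
})

test_that("active-surveillance schedule truncates and paces correctly", {
  s <- active_surveillance_schedule(60, 60.5)
  expect_equal(s$age[s$event == "as_psa_dre"], c(60, 60.25))
  expect_equal(sum(s$event == "as_mri_biopsy"), 0)

  s <- active_surveillance_schedule(60, 63)
  v <- s$age[s$event == "as_psa_dre"] - 60
  expect_equal(v, c(seq(0, 1.75, 0.25), 2, 2.5))

  # closed-form biopsy count over a 10-year course:
  # 1.5 and 3 in the first three years, then 6 and 9
  s <- active_surveillance_schedule(60, 75)
  expect_equal(s$age[s$event == "as_mri_biopsy"] - 60, c(1.5, 3, 6, 9))
})

test_that("degenerate participation reduces any strategy to invitations only", {
  co <- fixture_cohort(3000, 42)
  st <- strategy_preset("psa_ras_50_60_mri")
  st$participation[] <- 0
  scr <- run_screening_cohort(co, st)
  expect_true(all(scr$events$event[scr$events$origin %in% "screen"] == "invitation"))
  expect_equal(sum(scr$persons$dx_mode == "screen"), 0)

  ns <- run_screening_cohort(co, strategy_preset("no_screening"))
  expect_identical(scr$persons$dx_age, ns$persons$dx_age)
  expect_identical(scr$persons$death_age, ns$persons$death_age)
})

test_that("the PSA threshold gates the whole workup cascade", {
  # a man whose measured PSA stays below the threshold at every screen
  # must have no screen-initiated biopsy and no screen detection
  co <- fixture_cohort(3000, 42)
  scr <- run_screening_cohort(co, strategy_preset("psa_ras_50_70_nomri"))
  ev <- scr$events
  psa_max <- tapply(ev$value[ev$event == "psa_test"],
                    ev$person_id[ev$event == "psa_test"], max)
  low <- as.integer(names(psa_max))[psa_max < 3]
  expect_gt(length(low), 100)
  bx <- ev$person_id[ev$event == "biopsy" & ev$origin %in% "screen"]
  expect_length(intersect(low, bx), 0)
  expect_length(intersect(low, scr$persons$person_id[
    scr$persons$dx_mode == "screen"]), 0)
})

test_that("perfect tests and full participation detect every qualifying case", {
  co <- fixture_cohort(3000, 42)
  st <- strategy_preset("psa_ras_50_70_nomri")
  st$participation[] <- 1
  tests <- default_test_profiles()
  tests$biopsy_systematic$sens_by_grade[] <- 1
  scr <- run_screening_cohort(co, st, tests)

  ev <- scr$events
  psa <- ev[ev$event == "psa_test", ]
  P <- co$persons
  onset <- P$onset_age[psa$person_id]
  qualifying <- psa$value >= 3 & !is.na(onset) & psa$age > onset
  first_qual <- tapply(psa$age[qualifying], psa$person_id[qualifying], min)
  det <- scr$persons[scr$persons$dx_mode == "screen", ]
  expect_setequal(det$person_id, as.integer(names(first_qual)))
  expect_equal(det$dx_age[match(as.integer(names(first_qual)),
                                det$person_id)],
               as.numeric(first_qual), ignore_attr = TRUE)
})

test_that("MRI-triage strategies never biopsy without a same-age screen MRI", {
  co <- fixture_cohort(3000, 42)
  scr <- run_screening_cohort(co, strategy_preset("psa_ras_45_70_mri"))
  ev <- scr$events
  bx <- ev[ev$event == "biopsy" & ev$origin == "screen", ]
  mri <- ev[ev$event == "mri" & ev$origin == "screen", ]
  expect_true(all(paste(bx$person_id, bx$age) %in%
                    paste(mri$person_id, mri$age)))
  expect_true(all(bx$type == "combined"))
})

test_that("screening respects stop age, death, and diagnosis conservation", {
  co <- fixture_cohort(3000, 42)
  for (nm in c("dre_45_75", "psa_ras_45_70_mri", "psa_ras_50_60_nomri")) {
    st <- strategy_preset(nm)
    scr <- run_screening_cohort(co, st)
    ev <- scr$events
    scr_ev <- ev[ev$origin %in% "screen", ]
    expect_lte(max(scr_ev$age), st$stop_age)
    expect_true(all(ev$age <= scr$persons$death_age[
      match(ev$person_id, scr$persons$person_id)] + 1e-9))
    p <- scr$persons
    expect_equal(sum(p$dx_mode != "none"),
                 sum(p$dx_mode == "screen") + sum(p$dx_mode == "clinical"))
    expect_true(all(p$overdiagnosed[p$dx_mode != "screen"] == FALSE))
  }
})

test_that("the screening engine matches an independent per-person cascade calculator", {
  co <- fixture_cohort(2000, 42)
  st <- strategy_preset("psa_ras_50_60_nomri")
  scr <- run_screening_cohort(co, st)
  P <- co$persons
  part <- st$participation

  # plain per-person reimplementation of the cascade on the same uniforms
  n_tests <- n_bx <- integer(co$n)
  dx_age <- rep(NA_real_, co$n)
  for (i in seq_len(co$n)) {
    cf <- ifelse(is.na(P$cf_dx_age[i]), Inf, P$cf_dx_age[i])
    a <- 50; k <- 1; naive <- TRUE
    while (a <= 60 && a < P$oc_death_age[i] && a < cf && is.na(dx_age[i])) {
      attends <- co$u_first[i] < part[["first_screen"]] &&
        (naive || co$u_rescreen[i, k] < part[["rescreen"]])
      interval <- st$recall_interval
      if (attends) {
        naive <- FALSE
        cancer <- !is.na(P$onset_age[i]) && a > P$onset_age[i]
        lp <- P$psa_int[i] + P$psa_slope[i] * (a - 35) +
          (if (cancer) P$psa_accel[i] * (a - P$onset_age[i]) else 0)
        psa <- exp(lp + 0.30 * co$z_noise[i, k])
        n_tests[i] <- n_tests[i] + 1L
        interval <- if (psa < 1.5) 5 else 2
        if (psa >= 3 && co$u_biopsy_accept[i, k] < part[["biopsy"]]) {
          n_bx[i] <- n_bx[i] + 1L
          sens <- if (cancer)
            default_test_profiles()$biopsy_systematic$sens_by_grade[P$grade[i]]
          else 0
          if (co$u_detect[i, k] < sens) dx_age[i] <- a
        }
      }
      a <- a + interval; k <- k + 1
    }
  }
  ev <- scr$events
  expect_equal(unname(n_tests),
               unname(tabulate(ev$person_id[ev$event == "psa_test"], co$n)))
  expect_equal(unname(n_bx),
               unname(tabulate(ev$person_id[ev$event == "biopsy" &
                                              ev$origin == "screen"], co$n)))
  sd_engine <- scr$persons$dx_age
  sd_engine[scr$persons$dx_mode != "screen"] <- NA
  expect_equal(unname(sd_engine), dx_age)
})

test_that("single-person screening is reproducible and consistent", {
  p <- nh_params()
  h <- simulate_natural_course(p, default_lt, 17, 5)
  st <- strategy_preset("psa_ras_45_70_nomri")
  r1 <- run_screening(h, st, params = p, life_table = default_lt, seed = 5)
  r2 <- run_screening(h, st, params = p, life_table = default_lt, seed = 5)
  expect_identical(r1, r2)
  person <- attr(r1, "person")
  expect_equal(person$oc_death_age, h$other_cause_death_age)

  expect_error(run_screening_cohort(fixture_cohort(3000, 42),
                                    strategy_preset("psa_ras_45_70_mri"),
                                    tests = list(biopsy_combined = list(
                                      sens_by_grade = c(1, 1, 1)))),
               "MRI")
})

test_that("strategies round-trip through YAML", {
  st <- strategy_preset("psa_ras_45_70_mri")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_strategy(st, f)
  expect_equal(unclass(read_strategy(f)), unclass(st))
})
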