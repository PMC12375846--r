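test_that("PSA growth is piecewise log-linear, continuous at onset", {
  p <- nh_params()

  # continuity: with and without the post-onset term at the onset age
  at_onset <- psa_at_age(p, onset_age = 55, grade_category = "gs_gt7", age = 55)
  no_onset <- psa_at_age(p, age = 55)
  expect_equal(at_onset, no_onset)

  # closed form: pre-onset log-PSA difference over 10 years is 10 * slope
  lp <- log(psa_at_age(p, age = c(50, 60)))
  expect_equal(diff(lp), 10 * p$psa_pre_onset_slope)

  # independently coded closed-form evaluation (onset 55, GS>7, age 60,
  # person effects 0.1 / 0.001)
  got <- psa_at_age(p, person_effects = c(0.1, 0.001), onset_age = 55,
                    grade_category = "gs_gt7", age = 60)
  want <- exp(log(0.8) + 0.1 + (0.02 + 0.001) * (60 - 35) + (0.25 - 0.02) * 5)
  expect_equal(got, unname(want))

  expect_error(psa_at_age(p, age = -1), "non-negative")
  bad <- p
  bad$psa_pre_onset_slope <- -0.1
  expect_error(psa_at_age(bad, age = 50), "slope")
  expect_error(validate_nh_params(unclass(bad)), "slope")
})

test_that("18 disease states enumerate and earlier stages dominate in survival", {
  st <- disease_states()
  expect_identical(nrow(st), 18L)
  expect_identical(nrow(unique(st)), 18L)

  p <- nh_params()
  tt <- seq(0, 30, by = 0.5)
  for (g in grade_levels()) {
    s <- sapply(1:3, function(tc) survival_probability(p, tc, FALSE, g, tt))
    sm <- survival_probability(p, 2, TRUE, g, tt)
    expect_true(all(diff(t(s)) <= 1e-12))      # S(T1) >= S(T2) >= S(T3)
    expect_true(all(s[, 3] >= sm - 1e-12))      # localized dominates metastatic
  }
})

test_that("single life histories are deterministic and respect invariants", {
  p <- nh_params()
  h1 <- simulate_natural_course(p, default_lt, person_id = 3, seed = 11)
  h2 <- simulate_natural_course(p, default_lt, person_id = 3, seed = 11)
  expect_identical(h1, h2)

  # degenerate onset hazard: no disease, death straight from the life table
  p0 <- nh_params(onset_hazard_params = list(shape = 2, scale = Inf))
  h0 <- simulate_natural_course(p0, default_lt, 1, 5)
  expect_true(is.na(h0$onset_age))
  expect_identical(h0$dx_mode, "none")
  expect_equal(h0$death_age, h0$other_cause_death_age)

  for (i in 1:40) {
    h <- simulate_natural_course(p, default_lt, i, 7)
    expect_equal(h$death_age,
                 min(h$other_cause_death_age, h$cancer_death_age, na.rm = TRUE))
    if (!is.na(h$actual_dx_age)) expect_lte(h$actual_dx_age, h$death_age)
    if (!is.null(h$state_trajectory)) {
      expect_true(!is.unsorted(h$state_trajectory$age, strictly = TRUE))
    }
  }
})

test_that("with cancer disabled, death ages reproduce the life table (KS)", {
  p0 <- nh_params(onset_hazard_params = list(shape = 2, scale = Inf))
  co <- simulate_cohort(p0, default_lt, 50000, 123)
  x <- co$persons$clin_death_age
  rates <- default_lt$mortality_rate
  ages <- default_lt$age
  cum <- c(0, cumsum(rates))
  pdeath <- function(q) {
    i <- pmin(findInterval(q, c(ages, max(ages) + 1)), length(rates))
    1 - exp(-(cum[i] + (q - ages[i]) * rates[i]))
  }
  # deaths are administratively censored at 105; compare the uncensored
  # part against the conditional distribution
  pcond <- function(q) pdeath(q) / pdeath(105)
  ks <- suppressWarnings(stats::ks.test(x[x < 105], pcond))
  expect_gt(ks$p.value, 0.01)
})

test_that("grade mixture marginal matches the configured age-linked probabilities", {
  p <- nh_params()
  co <- simulate_cohort(p, default_lt, 100000, 77)
  P <- co$persons
  on <- !is.na(P$onset_age)
  expected <- colMeans(grade_probs(p, P$onset_age[on]))
  observed <- tabulate(P$grade[on], 3) / sum(on)
  se <- sqrt(expected * (1 - expected) / sum(on))
  expect_true(all(abs(observed - expected) < 3 * se))
})

test_that("clinical incidence matches numerical integration of the same hazards", {
  # homogeneous-person parameterization (no random effects, no metastasis
  # multiplier, no old-age attenuation) so the at-risk diagnosis rate has a
  # 1-D integral representation over onset age
  p <- nh_params(psa_intercept_sd = 0, psa_slope_sd = 0,
                 clinical_dx_params = list(rate_per_ngml = 0.012,
                                           met_multiplier = 1,
                                           age_attn_start = 75,
                                           age_attn_rate = 0))
  n <- 50000
  co <- simulate_cohort(p, default_lt, n, 42)
  P <- co$persons
  dx <- ifelse(is.na(P$cf_dx_age), Inf, P$cf_dx_age)
  death <- pmin(P$oc_death_age,
                ifelse(is.na(P$clin_cancer_death_age), Inf,
                       P$clin_cancer_death_age))
  atrisk_end <- pmin(dx, death)

  k <- p$onset_hazard_params$shape
  lam <- p$onset_hazard_params$scale
  f_on <- function(s) {
    t <- s - 35
    (k / lam) * (t / lam)^(k - 1) * exp(-(t / lam)^k)
  }
  S_on <- function(s) exp(-((s - 35) / lam)^k)
  base <- log(p$psa_baseline_level)
  pre <- p$psa_pre_onset_slope
  rate <- p$clinical_dx_params$rate_per_ngml
  post <- p$psa_post_onset_slope_by_grade

  for (a in seq(50, 75, 5)) {
    cases <- sum(dx >= a & dx < a + 5 & is.finite(dx) & dx < death)
    py <- sum(pmin(pmax(atrisk_end - a, 0), 5))
    emp <- cases / py
    amid <- a + 2.5
    sgrid <- seq(35.05, amid, by = 0.1)
    gp <- grade_probs(p, sgrid)
    num <- den <- 0
    for (g in 1:3) {
      b <- post[g]
      u <- amid - sgrid
      rate0 <- rate * exp(base + pre * (sgrid - 35))
      H <- rate0 / b * (exp(b * u) - 1)
      num <- num + sum(f_on(sgrid) * gp[, g] * rate0 * exp(b * u) * exp(-H)) * 0.1
      den <- den + sum(f_on(sgrid) * gp[, g] * exp(-H)) * 0.1
    }
    oracle <- num / (S_on(amid) + den)
    se <- sqrt(cases) / py
    expect_lt(abs(emp - oracle), 3 * se)
  }
})

test_that("stage-shift survival keeps the common-random-number contract", {
  p <- nh_params()
  co <- simulate_cohort(p, default_lt, 5000, 3)
  P <- co$persons
  idx <- which(!is.na(P$cf_dx_age) & !is.na(P$clin_cancer_death_age))[1:10]
  for (i in idx) {
    h <- list(person_id = i,
              counterfactual_clinical_dx_age = P$cf_dx_age[i],
              other_cause_death_age = P$oc_death_age[i],
              grade_category = grade_levels()[P$grade[i]],
              u_surv = P$u_surv[i])
    # detection at the unchanged stage reproduces the clinical death age
    same <- stage_shift_survival(p, h, P$cf_dx_age[i],
                                 list(t_category = P$cf_t_cat[i],
                                      metastasis = P$cf_met[i]))
    expect_equal(same, P$clin_cancer_death_age[i])
    # detection at stage T1 non-metastatic can only postpone death
    earlier <- stage_shift_survival(p, h, P$cf_dx_age[i] - 1,
                                    list(t_category = 1, metastasis = FALSE))
    expect_true(is.na(earlier) || earlier >= same)
    # contract violation: screen detection after the counterfactual
    expect_error(
      stage_shift_survival(p, h, P$cf_dx_age[i] + 1,
                           list(t_category = 1, metastasis = FALSE)),
      "counterfactual")
  }
})

test_that("screen detection never shortens survival across a whole cohort", {
  co <- fixture_cohort(5000, 42)
  scr <- run_screening_cohort(co, strategy_preset("dre_45_75"))
  s <- scr$persons$dx_mode == "screen"
  clin <- co$persons$clin_cancer_death_age[s]
  scrd <- scr$persons$cancer_death_age[s]
  # NA means no cancer death in the screened world
  expect_true(all(is.na(scrd) | is.na(clin) | scrd >= clin - 1e-9))
  lead <- scr$persons$lead_time
  expect_true(all(is.na(lead) | lead >= 0))
})

test_that("natural-history parameters round-trip through YAML", {
  p <- nh_params()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_nh_params(p, f)
  p2 <- read_nh_params(f)
  expect_equal(unclass(p), unclass(p2))
})
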