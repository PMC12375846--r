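#' Grade category labels
#'
#' Histological grade is modelled in three ordered categories: Gleason
#' score below 7 (ISUP grade group 1), equal to 7, and above 7.
#'
#' @return Character vector of the three grade labels.
#' @export
grade_levels <- function() c("gs_lt7", "gs_7", "gs_gt7")

#' Enumerate the preclinical/clinical disease states
#'
#' Disease extent is modelled as 3 ordered local-extent (T) levels crossed
#' with a metastasis indicator and 3 grade categories, giving 18 states.
#'
#' @return data.frame with columns `t_category`, `metastasis`,
#'   `grade_category` (18 rows).
#' @export
disease_states <- function() {
  st <- expand.grid(
    t_category = 1:3,
    metastasis = c(FALSE, TRUE),
    grade_category = grade_levels(),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  st <- st[order(st$grade_category, st$metastasis, st$t_category), ]
  rownames(st) <- NULL
  st
}

default_survival_params <- function() {
  base_cure <- c(gs_lt7 = 0.905, gs_7 = 0.78, gs_gt7 = 0.60)
  base_rate <- c(gs_lt7 = 0.05, gs_7 = 0.08, gs_gt7 = 0.12)
  t_cure_mult <- c(1, 0.93, 0.82)
  t_rate_mult <- c(1, 1.4, 2.0)
  met_cure <- c(gs_lt7 = 0.08, gs_7 = 0.05, gs_gt7 = 0.02)
  met_rate <- c(gs_lt7 = 0.20, gs_7 = 0.25, gs_gt7 = 0.30)
  st <- disease_states()
  g <- st$grade_category
  cure <- ifelse(st$metastasis, met_cure[g],
                 base_cure[g] * t_cure_mult[st$t_category])
  rate <- ifelse(st$metastasis, met_rate[g],
                 base_rate[g] * t_rate_mult[st$t_category])
  out <- data.frame(st, cure_fraction = unname(cure), excess_rate = unname(rate))
  rownames(out) <- NULL
  out
}

#' Natural-history parameter set
#'
#' Bundles every parameter of the disease model: the Weibull age-dependence
#' of preclinical onset, the age-linked grade mixture, the piecewise
#' log-linear PSA growth model with person-level random effects, the
#' exponential state-progression clocks, the PSA-scaled clinical-diagnosis
#' hazard, and the per-state cure-fraction survival curves.
#'
#' PSA grows log-linearly with age from a baseline level at age 35 and
#' accelerates after disease onset by a grade-specific increment, so the
#' post-onset slope always dominates the pre-onset slope. Onset follows a
#' Weibull hazard in years since age 35. Local extent progresses
#' T1 -> T2 -> T3 via exponential clocks; a parallel exponential clock
#' governs metastatic spread. Clinical presentation occurs with a hazard
#' proportional to the (noise-free) PSA level, multiplied after metastasis.
#' Cause-specific survival after diagnosis follows a cure-fraction model
#' \eqn{S(t) = c + (1 - c) e^{-r t}} per stage-grade state.
#'
#' @param onset_hazard_params list(shape, scale): Weibull shape and scale
#'   (years since 35) of preclinical onset. `scale = Inf` disables onset.
#' @param grade_mixture_params list(int_gs7, int_gsgt7, age_slope,
#'   severity_gt7): multinomial-logit intercepts for GS=7 and GS>7 relative
#'   to GS<7 plus a shared log-odds slope per year of onset age (centred at
#'   60), steepened by `severity_gt7` for the GS>7 category.
#' @param psa_baseline_level Median PSA (ng/mL) at age 35.
#' @param psa_pre_onset_slope Pre-onset log-PSA slope per year.
#' @param psa_post_onset_slope_by_grade Named vector of post-onset log-PSA
#'   slopes per year, one per grade; must dominate the pre-onset slope.
#' @param psa_intercept_sd,psa_slope_sd SDs of person-level deviations of
#'   the log-PSA intercept and slope.
#' @param noise_sd Log-PSA measurement noise SD per test.
#' @param progression_rate_params list(t2_rate, t3_rate, met_rate), each a
#'   length-3 per-grade vector of exponential rates per year.
#' @param clinical_dx_params list(rate_per_ngml, met_multiplier,
#'   age_attn_start, age_attn_rate): clinical presentation hazard per year
#'   per ng/mL of mean PSA, its multiplier once metastatic, and an old-age
#'   attenuation (diagnostic intensity declines exponentially at
#'   `age_attn_rate` per year beyond `age_attn_start`, reproducing the
#'   registry incidence decline in the very old).
#' @param survival_params 18-row data.frame (`t_category`, `metastasis`,
#'   `grade_category`, `cure_fraction`, `excess_rate`).
#' @return A validated object of class `nh_params`.
#' @export
nh_params <- function(
    onset_hazard_params = list(shape = 1.8, scale = 95),
    grade_mixture_params = list(int_gs7 = -0.3, int_gsgt7 = -0.7,
                                age_slope = 0.03, severity_gt7 = 1.5),
    psa_baseline_level = 0.8,
    psa_pre_onset_slope = 0.02,
    psa_post_onset_slope_by_grade = c(gs_lt7 = 0.12, gs_7 = 0.18, gs_gt7 = 0.25),
    psa_intercept_sd = 0.55,
    psa_slope_sd = 0.005,
    noise_sd = 0.30,
    progression_rate_params = list(
      t2_rate = c(gs_lt7 = 0.07, gs_7 = 0.11, gs_gt7 = 0.18),
      t3_rate = c(gs_lt7 = 0.06, gs_7 = 0.10, gs_gt7 = 0.16),
      met_rate = c(gs_lt7 = 0.005, gs_7 = 0.012, gs_gt7 = 0.035)
    ),
    clinical_dx_params = list(rate_per_ngml = 0.012, met_multiplier = 25,
                              age_attn_start = 75, age_attn_rate = 0.35),
    survival_params = default_survival_params()) {
  p <- list(
    onset_hazard_params = onset_hazard_params,
    grade_mixture_params = grade_mixture_params,
    psa_baseline_level = psa_baseline_level,
    psa_pre_onset_slope = psa_pre_onset_slope,
    psa_post_onset_slope_by_grade = psa_post_onset_slope_by_grade,
    psa_intercept_sd = psa_intercept_sd,
    psa_slope_sd = psa_slope_sd,
    noise_sd = noise_sd,
    progression_rate_params = progression_rate_params,
    clinical_dx_params = clinical_dx_params,
    survival_params = survival_params
  )
  validate_nh_params(p)
}

#' @rdname nh_params
#' @param p A list with the `nh_params` fields.
#' @export
validate_nh_params <- function(p) {
  with(p, {
    assert_nonneg(c(onset_hazard_params$shape, psa_baseline_level,
                    psa_intercept_sd, psa_slope_sd, noise_sd,
                    clinical_dx_params$rate_per_ngml,
                    clinical_dx_params$met_multiplier),
                  "natural-history rates/SDs")
    if (onset_hazard_params$scale <= 0) stop("onset scale must be > 0", call. = FALSE)
    for (nm in c("t2_rate", "t3_rate", "met_rate")) {
      assert_nonneg(progression_rate_params[[nm]], nm)
      stopifnot(length(progression_rate_params[[nm]]) == 3L)
    }
    if (psa_pre_onset_slope < 0 ||
        any(psa_post_onset_slope_by_grade < psa_pre_onset_slope)) {
      stop("post-onset PSA slopes must be >= the pre-onset slope (>= 0)",
           call. = FALSE)
    }
  })
  sp <- p$survival_params
  if (nrow(sp) != 18L) stop("survival_params must enumerate all 18 states", call. = FALSE)
  assert_prob(sp$cure_fraction, "cure_fraction")
  assert_nonneg(sp$excess_rate, "excess_rate")
  structure(p, class = "nh_params")
}

#' Age-dependent grade mixture probabilities
#'
#' @param params `nh_params`.
#' @param age Onset ages (vectorized).
#' @return Matrix (length(age) x 3) of probabilities over
#'   [grade_levels()]; rows sum to 1.
#' @export
grade_probs <- function(params, age) {
  g <- params$grade_mixture_params
  eta7 <- g$int_gs7 + g$age_slope * (age - 60)
  etag <- g$int_gsgt7 + g$severity_gt7 * g$age_slope * (age - 60)
  denom <- 1 + exp(eta7) + exp(etag)
  m <- cbind(1 / denom, exp(eta7) / denom, exp(etag) / denom)
  colnames(m) <- grade_levels()
  m
}

#' PSA level at a given age
#'
#' Piecewise log-linear: log-PSA rises at the (person-adjusted) pre-onset
#' slope from the age-35 baseline and switches to the grade-specific
#' post-onset slope at disease onset, continuously. Measurement noise is
#' multiplicative on the natural scale (additive on log-PSA).
#'
#' @param params `nh_params`.
#' @param person_effects Numeric `c(intercept, slope)` deviations on the
#'   log scale (defaults to the population mean person).
#' @param onset_age Onset age in years, or `NULL`/`NA` if disease-free.
#' @param grade_category One of [grade_levels()] (required with onset).
#' @param age Age in years (vectorized).
#' @param with_noise Apply measurement noise?
#' @param noise_z Optional standard-normal noise draws (for reproducible
#'   measurement error); drawn internally when `NULL` and `with_noise`.
#' @return PSA level(s) in ng/mL.
#' @export
psa_at_age <- function(params, person_effects = c(0, 0), onset_age = NULL,
                       grade_category = NULL, age, with_noise = FALSE,
                       noise_z = NULL) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  if (params$psa_pre_onset_slope < 0 ||
      any(params$psa_post_onset_slope_by_grade < 0)) {
    stop("PSA slopes must be non-negative", call. = FALSE)
  }
  slope <- params$psa_pre_onset_slope + person_effects[2]
  lp <- log(params$psa_baseline_level) + person_effects[1] + slope * (age - 35)
  if (!is.null(onset_age) && length(onset_age) && !is.na(onset_age)) {
    accel <- params$psa_post_onset_slope_by_grade[[grade_category]] -
      params$psa_pre_onset_slope
    lp <- lp + accel * pmax(0, age - onset_age)
  }
  if (with_noise) {
    z <- noise_z %||% stats::rnorm(length(lp))
    lp <- lp + params$noise_sd * z
  }
  exp(lp)
}

#' Cause-specific survival probability for a disease state
#'
#' Evaluates the cure-fraction survival curve
#' \eqn{S(t) = c + (1 - c) e^{-r t}} of the given stage-grade state.
#'
#' @param params `nh_params`.
#' @param t_category Local extent level (1-3).
#' @param metastasis Logical metastasis flag.
#' @param grade_category One of [grade_levels()].
#' @param time Years since the survival clock start (vectorized).
#' @return Survival probabilities.
#' @export
survival_probability <- function(params, t_category, metastasis,
                                 grade_category, time) {
  sp <- params$survival_params
  row <- sp[sp$t_category == t_category & sp$metastasis == metastasis &
              sp$grade_category == grade_category, ]
  if (nrow(row) != 1L) stop("unknown disease state", call. = FALSE)
  row$cure_fraction + (1 - row$cure_fraction) * exp(-row$excess_rate * time)
}

# Inverse-CDF survival draw sharing one uniform per person (common random
# numbers): cured if u <= c, else exponential tail. Monotone in the state's
# severity for a fixed u, which makes the per-person stage-shift benefit
# deterministic in sign.
draw_survival_time <- function(params, t_category, metastasis,
                               grade_category, u) {
  sp <- params$survival_params
  key <- paste(sp$t_category, sp$metastasis, sp$grade_category)
  idx <- match(paste(t_category, metastasis, grade_category), key)
  cure <- sp$cure_fraction[idx]
  rate <- sp$excess_rate[idx]
  out <- rep(Inf, length(u))
  hit <- !is.na(idx) & u > cure
  out[hit] <- -log((u[hit] - cure[hit]) / (1 - cure[hit])) / rate[hit]
  out[is.na(idx)] <- NA_real_
  out
}

## ---- cohort simulation ------------------------------------------------

#' Simulate the natural (unscreened) life course of a cohort
#'
#' Draws, for `n` men alive at age 35: other-cause death from the life
#' table; preclinical onset from the Weibull hazard; grade from the
#' age-linked mixture; person-level PSA effects; exponential
#' state-progression clocks; the counterfactual clinical diagnosis age by
#' closed-form inversion of the PSA-scaled presentation hazard; and
#' cause-specific survival after clinical diagnosis. Also pre-draws the
#' per-person, per-screening-round uniforms that every screening strategy
#' reuses, so strategies share common random numbers.
#'
#' @param params `nh_params`.
#' @param life_table A `life_table` covering ages 35-105.
#' @param n Number of persons.
#' @param seed Master seed for the cohort.
#' @param max_rounds Screening rounds covered by the pre-drawn uniforms
#'   (31 covers annual screening from 45 to 75).
#' @return An `nh_cohort` list: `persons` data.frame, screening uniform
#'   matrices, `params`, `life_table`, `seed`.
#' @export
simulate_cohort <- function(params, life_table, n, seed, max_rounds = 31L) {
  life_table <- validate_life_table(life_table)
  set.seed(derive_seed(seed, "cohort"))
  persons <- draw_natural_histories(params, life_table, n)
  cohort <- list(
    n = n,
    persons = persons,
    params = params,
    life_table = life_table,
    seed = seed,
    max_rounds = max_rounds,
    u_first = stats::runif(n),
    u_surv = persons$u_surv,
    z_noise = matrix(stats::rnorm(n * max_rounds), n, max_rounds),
    u_rescreen = matrix(stats::runif(n * max_rounds), n, max_rounds),
    u_biopsy_accept = matrix(stats::runif(n * max_rounds), n, max_rounds),
    u_detect = matrix(stats::runif(n * max_rounds), n, max_rounds),
    u_dre = matrix(stats::runif(n * max_rounds), n, max_rounds),
    u_mri = matrix(stats::runif(n * max_rounds), n, max_rounds)
  )
  class(cohort) <- "nh_cohort"
  cohort
}

# Vectorized draws of the person-level natural history (no screening).
# Must be called with the RNG state already set.
draw_natural_histories <- function(params, life_table, n) {
  oh <- params$onset_hazard_params
  pr <- params$progression_rate_params
  dx <- params$clinical_dx_params

  oc_death <- pmin(draw_death_age(life_table, stats::runif(n), 35), 105)

  u_on <- stats::runif(n)
  onset <- if (is.finite(oh$scale)) {
    35 + oh$scale * (-log(1 - u_on))^(1 / oh$shape)
  } else rep(Inf, n)
  has_onset <- onset < 105

  u_grade <- stats::runif(n)
  gp <- grade_probs(params, pmin(onset, 104))
  grade <- 1L + (u_grade > gp[, 1]) + (u_grade > gp[, 1] + gp[, 2])
  grade[!has_onset] <- NA_integer_

  z_int <- stats::rnorm(n)
  z_slope <- stats::rnorm(n)
  psa_int <- log(params$psa_baseline_level) + params$psa_intercept_sd * z_int
  psa_slope <- pmax(params$psa_pre_onset_slope +
                      params$psa_slope_sd * z_slope, 1e-4)

  gidx <- ifelse(has_onset, grade, 1L)
  accel <- pmax(params$psa_post_onset_slope_by_grade[gidx] -
                  params$psa_pre_onset_slope, 0)

  t_t2 <- stats::rexp(n) / pr$t2_rate[gidx]
  t_t3 <- t_t2 + stats::rexp(n) / pr$t3_rate[gidx]
  t_met <- pmin(stats::rexp(n) / pr$met_rate[gidx], 500)

  # closed-form inversion of the cumulative presentation hazard: the mean
  # PSA is exp(a + b u) in time-since-onset u, with a metastasis multiplier
  # after t_met and an exponential old-age attenuation beyond
  # age_attn_start; the hazard is piecewise C exp(K u), so the cumulative
  # hazard inverts analytically piece by piece
  u_dx <- stats::runif(n)
  a_on <- psa_int + psa_slope * (pmin(onset, 105) - 35)
  b <- pmax(psa_slope + accel, 1e-3)
  rate0 <- dx$rate_per_ngml * exp(a_on)
  e_dx <- -log(u_dx)
  u_time <- invert_dx_hazard(
    e_dx, rate0, b,
    t_met = t_met,
    met_mult = dx$met_multiplier,
    t_attn = pmax((dx$age_attn_start %||% Inf) - pmin(onset, 105), 0),
    attn_rate = dx$age_attn_rate %||% 0
  )
  cf_dx <- ifelse(has_onset, onset + u_time, Inf)
  cf_dx[cf_dx >= pmin(oc_death, 105)] <- Inf

  has_cf <- is.finite(cf_dx)
  t_at_dx <- cf_dx - onset
  cf_t_cat <- 1L + (t_at_dx >= t_t2) + (t_at_dx >= t_t3)
  cf_met <- t_at_dx >= t_met
  cf_t_cat[!has_cf] <- NA_integer_
  cf_met[!has_cf] <- NA

  u_surv <- stats::runif(n)
  surv_t <- rep(Inf, n)
  surv_t[has_cf] <- draw_survival_time(
    params, cf_t_cat[has_cf], cf_met[has_cf],
    grade_levels()[grade[has_cf]], u_surv[has_cf]
  )
  clin_cancer_death <- ifelse(has_cf, cf_dx + surv_t, Inf)
  clin_death <- pmin(oc_death, clin_cancer_death)
  clin_cancer_death[clin_cancer_death > oc_death] <- Inf

  data.frame(
    person_id = seq_len(n),
    oc_death_age = oc_death,
    onset_age = ifelse(has_onset, onset, NA_real_),
    grade = grade,
    psa_int = psa_int,
    psa_slope = psa_slope,
    psa_accel = ifelse(has_onset, accel, NA_real_),
    t_t2 = t_t2,
    t_t3 = t_t3,
    t_met = t_met,
    cf_dx_age = ifelse(has_cf, cf_dx, NA_real_),
    cf_t_cat = cf_t_cat,
    cf_met = cf_met,
    clin_cancer_death_age = ifelse(is.finite(clin_cancer_death),
                                   clin_cancer_death, NA_real_),
    clin_death_age = clin_death,
    u_surv = u_surv
  )
}

# Vectorized inversion of a piecewise log-linear presentation hazard
# h(u) = rate0 * exp(b u) * met_mult^[u >= t_met] * exp(-attn_rate (u - t_attn)_+).
# On each piece the hazard is C exp(K u); the cumulative hazard is summed
# piecewise and inverted at the exponential draws `e`. Returns Inf where
# the total cumulative hazard never reaches the draw.
invert_dx_hazard <- function(e, rate0, b, t_met, met_mult, t_attn, attn_rate) {
  n <- length(e)
  cap <- 500
  t_met <- pmin(t_met, cap)
  t_attn <- pmin(t_attn, cap)
  s1 <- pmin(t_met, t_attn)
  s2 <- pmax(t_met, t_attn)
  bounds <- cbind(0, s1, s2, cap)
  sol <- rep(Inf, n)
  acc <- numeric(n)       # cumulative hazard up to the current piece
  done <- rep(FALSE, n)
  for (j in 1:3) {
    lo <- bounds[, j]
    hi <- bounds[, j + 1]
    mid <- (lo + hi) / 2
    met_on <- mid >= t_met
    attn_on <- mid >= t_attn
    K <- b - ifelse(attn_on, attn_rate, 0)
    K[abs(K) < 1e-9] <- 1e-9
    C <- rate0 * ifelse(met_on, met_mult, 1) *
      exp(ifelse(attn_on, attn_rate * t_attn, 0))
    dH <- C / K * (exp(K * hi) - exp(K * lo))
    dH[hi <= lo] <- 0
    hit <- !done & e <= acc + dH & hi > lo
    if (any(hit)) {
      arg <- exp(K[hit] * lo[hit]) + K[hit] * (e[hit] - acc[hit]) / C[hit]
      sol[hit] <- log(arg) / K[hit]
      done[hit] <- TRUE
    }
    acc <- acc + dH
  }
  sol
}

# T category and metastasis status of a person's disease at a given age
# (vectorized over persons); ages must be >= onset for cancer carriers.
stage_at_age <- function(persons, idx, age) {
  t <- age - persons$onset_age[idx]
  list(
    t_category = 1L + (t >= persons$t_t2[idx]) + (t >= persons$t_t3[idx]),
    metastasis = t >= persons$t_met[idx]
  )
}

#' Simulate one man's natural life course
#'
#' Single-person wrapper around the cohort engine using a per-person
#' random substream, so the same `(person_id, seed)` pair always
#' reproduces the identical life history.
#'
#' @inheritParams simulate_cohort
#' @param person_id Integer person identifier.
#' @return A `life_history` list: onset, grade, state trajectory,
#'   counterfactual clinical diagnosis age, death ages, PSA person effects.
#' @export
simulate_natural_course <- function(params, life_table, person_id, seed) {
  key <- derive_seed(seed, "person", person_id)
  life_table <- validate_life_table(life_table)
  set.seed(key)
  p <- draw_natural_histories(params, life_table, 1L)

  death_age <- p$clin_death_age
  traj <- NULL
  if (!is.na(p$onset_age) && p$onset_age < death_age) {
    ages <- c(p$onset_age, p$onset_age + p$t_t2, p$onset_age + p$t_t3)
    tcat <- 1:3
    keep <- ages < death_age
    traj <- data.frame(age = ages[keep], t_category = tcat[keep])
    met_age <- p$onset_age + p$t_met
    traj$metastasis <- rep(FALSE, nrow(traj))
    if (met_age < death_age) {
      traj <- rbind(traj, data.frame(
        age = met_age,
        t_category = max(tcat[keep][ages[keep] <= met_age]),
        metastasis = TRUE
      ))
      traj <- traj[order(traj$age), ]
      traj$metastasis <- cumsum(traj$age >= met_age) > 0
    }
  }

  has_dx <- !is.na(p$cf_dx_age) && p$cf_dx_age <= death_age
  structure(list(
    person_id = person_id,
    random_stream_key = key,
    onset_age = if (!is.na(p$onset_age)) p$onset_age else NA_real_,
    grade_category = if (!is.na(p$grade)) grade_levels()[p$grade] else NA_character_,
    state_trajectory = traj,
    counterfactual_clinical_dx_age = p$cf_dx_age,
    actual_dx_age = if (has_dx) p$cf_dx_age else NA_real_,
    dx_mode = if (has_dx) "clinical" else "none",
    stage_at_dx = if (has_dx) list(t_category = p$cf_t_cat,
                                   metastasis = p$cf_met,
                                   grade_category = grade_levels()[p$grade])
                  else NULL,
    other_cause_death_age = p$oc_death_age,
    cancer_death_age = p$clin_cancer_death_age,
    death_age = death_age,
    psa_person_effects = c(
      intercept = p$psa_int - log(params$psa_baseline_level),
      slope = p$psa_slope - params$psa_pre_onset_slope
    ),
    u_surv = p$u_surv
  ), class = "life_history")
}

#' Stage-shift survival after screen detection
#'
#' Assigns the cause-specific survival of the (earlier) stage observed at
#' screen detection, with the survival clock starting at the end of the
#' lead time, i.e. at the counterfactual clinical diagnosis age. The
#' survival uniform is shared with the clinical-world draw (common random
#' numbers), so detection at an unchanged stage reproduces the clinical
#' cancer death age exactly, and detection at an earlier stage can only
#' postpone it.
#'
#' @param params `nh_params`.
#' @param history A `life_history`.
#' @param screen_dx_age Age at screen detection; must not exceed the
#'   counterfactual clinical diagnosis age.
#' @param stage_at_screen_dx list(t_category, metastasis) at detection.
#' @param seed Optional seed used only if the history carries no stored
#'   survival uniform.
#' @return Cancer death age, or `NA` if the cancer never causes death
#'   before other-cause death (cure or overdiagnosed case).
#' @export
stage_shift_survival <- function(params, history, screen_dx_age,
                                 stage_at_screen_dx, seed = NULL) {
  cf <- history$counterfactual_clinical_dx_age
  if (!is.na(cf) && screen_dx_age > cf + 1e-9) {
    stop("screen_dx_age must not exceed the counterfactual clinical diagnosis age",
         call. = FALSE)
  }
  if (is.na(cf)) return(NA_real_)  # never clinically diagnosed: no cancer death
  u <- history$u_surv
  if (is.null(u)) {
    set.seed(derive_seed(seed %||% 1L, "stage_shift", history$person_id))
    u <- stats::runif(1)
  }
  ts <- draw_survival_time(params, stage_at_screen_dx$t_category,
                           stage_at_screen_dx$metastasis,
                           history$grade_category, u)
  death <- cf + ts
  if (!is.finite(death) || death >= history$other_cause_death_age) NA_real_ else death
}

## ---- config round-trip ------------------------------------------------

#' Read / write natural-history parameters as YAML
#'
#' Flat key-value serialization with keys matching the `nh_params` field
#' names; the survival table is stored as parallel per-state vectors.
#'
#' @param params `nh_params`.
#' @param path YAML file path.
#' @export
write_nh_params <- function(params, path) {
  x <- unclass(params)
  x$survival_params <- as.list(x$survival_params)
  x$psa_post_onset_slope_by_grade <- as.list(x$psa_post_onset_slope_by_grade)
  x$progression_rate_params <- lapply(x$progression_rate_params, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_nh_params
#' @export
read_nh_params <- function(path) {
  x <- yaml::read_yaml(path)
  x$survival_params <- data.frame(
    t_category = x$survival_params$t_category,
    metastasis = x$survival_params$metastasis,
    grade_category = x$survival_params$grade_category,
    cure_fraction = x$survival_params$cure_fraction,
    excess_rate = x$survival_params$excess_rate
  )
  for (nm in c("psa_post_onset_slope_by_grade")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  for (nm in c("t2_rate", "t3_rate", "met_rate")) {
    x$progression_rate_params[[nm]] <- unlist(x$progression_rate_params[[nm]])
  }
  validate_nh_params(x)
}
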