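#' Screening test performance profiles
#'
#' Sensitivity/specificity of the screening and diagnostic tests. The DRE
#' profile applies to preclinical cancer of any grade; the MRI profile
#' distinguishes clinically significant (GS >= 7) from insignificant
#' disease, which is what lets MRI triage cut overdiagnosis; biopsy
#' sensitivity is grade-specific, with combined (systematic + targeted)
#' biopsy more sensitive for significant and less sensitive for
#' insignificant cancer than systematic biopsy alone. Values are
#' literature-informed defaults and fully configurable.
#'
#' @return Named list of test profiles.
#' @export
default_test_profiles <- function() {
  list(
    dre = list(sensitivity = 0.55, specificity = 0.92),
    mri = list(sens_significant = 0.90, sens_insignificant = 0.45,
               specificity = 0.75),
    biopsy_systematic = list(sens_by_grade = c(gs_lt7 = 0.70, gs_7 = 0.88,
                                               gs_gt7 = 0.90)),
    biopsy_combined = list(sens_by_grade = c(gs_lt7 = 0.60, gs_7 = 0.95,
                                             gs_gt7 = 0.97))
  )
}

validate_test_profiles <- function(tests) {
  assert_prob(unlist(tests), "test characteristics")
  tests
}

#' Define a screening strategy
#'
#' @param name Strategy label.
#' @param primary_test `"psa"`, `"dre"` or `"none"`.
#' @param start_age,stop_age First/last age at which invitations are issued.
#' @param risk_bands data.frame(`upper`, `interval_years`): ordered PSA
#'   upper cutoffs (last must be `Inf`) with the rescreen interval applied
#'   to each band. An `Inf` interval means no further rescreening from that
#'   band.
#' @param workup_threshold PSA (ng/mL) triggering diagnostic work-up.
#' @param mri_triage Use MRI as a reflex test before biopsy?
#' @param biopsy_type_on_workup `"systematic"` or `"combined"`.
#' @param dre_interval Years between DREs (DRE strategies).
#' @param recall_interval Re-invitation interval for invitees without a
#'   current PSA value (non-attenders).
#' @param participation Named probabilities `first_screen` (ever-attender
#'   share), `rescreen` (per invitation), `biopsy` (per referral).
#' @param symptomatic_workup Diagnostic pathway of symptomatic
#'   presentations in this arm: `"mri_combined"` or `"systematic"`.
#' @return Object of class `strategy_definition`.
#' @export
strategy_definition <- function(name, primary_test = c("psa", "dre", "none"),
                                start_age = 50, stop_age = 60,
                                risk_bands = data.frame(
                                  upper = c(1.5, 3, Inf),
                                  interval_years = c(5, 2, 2)),
                                workup_threshold = 3,
                                mri_triage = FALSE,
                                biopsy_type_on_workup = c("systematic", "combined"),
                                dre_interval = 1,
                                recall_interval = 5,
                                participation = c(first_screen = 0.75,
                                                  rescreen = 0.95,
                                                  biopsy = 0.65),
                                symptomatic_workup = c("systematic", "mri_combined")) {
  primary_test <- match.arg(primary_test)
  biopsy_type_on_workup <- match.arg(biopsy_type_on_workup)
  symptomatic_workup <- match.arg(symptomatic_workup)
  if (primary_test != "none" && start_age >= stop_age) {
    stop("start_age must be below stop_age", call. = FALSE)
  }
  if (is.unsorted(risk_bands$upper, strictly = TRUE)) {
    stop("risk-band cutoffs must be strictly increasing", call. = FALSE)
  }
  assert_prob(participation, "participation")
  structure(list(
    name = name, primary_test = primary_test,
    start_age = start_age, stop_age = stop_age,
    risk_bands = risk_bands, workup_threshold = workup_threshold,
    mri_triage = mri_triage, biopsy_type_on_workup = biopsy_type_on_workup,
    dre_interval = dre_interval, recall_interval = recall_interval,
    participation = participation, symptomatic_workup = symptomatic_workup
  ), class = "strategy_definition")
}

#' Built-in screening strategy presets
#'
#' The ten base-case strategies: no screening; annual DRE at ages 45-75
#' with suspicious findings referred to systematic biopsy; and eight PSA
#' risk-adaptive strategies (start 45 or 50, stop 60 or 70, with or
#' without MRI triage) using a 3 ng/mL biopsy threshold and rescreen
#' intervals of 5 years below 1.5 ng/mL and 2 years for 1.5-2.99 ng/mL.
#' Symptomatic cases are worked up with MRI plus combined biopsy in the
#' no-screening and MRI arms, and with systematic biopsy otherwise.
#'
#' @param name Preset name; see [list_strategy_presets()].
#' @return A `strategy_definition`.
#' @export
strategy_preset <- function(name) {
  presets <- list_strategy_presets()
  if (!name %in% presets) {
    stop(sprintf("unknown strategy '%s'; valid presets: %s",
                 name, paste(presets, collapse = ", ")), call. = FALSE)
  }
  if (name == "no_screening") {
    return(strategy_definition(name, primary_test = "none",
                               symptomatic_workup = "mri_combined"))
  }
  if (name == "dre_45_75") {
    return(strategy_definition(name, primary_test = "dre",
                               start_age = 45, stop_age = 75,
                               dre_interval = 1, recall_interval = 1,
                               biopsy_type_on_workup = "systematic",
                               symptomatic_workup = "systematic"))
  }
  m <- regmatches(name, regexec("^psa_ras_(\\d+)_(\\d+)_(mri|nomri)$", name))[[1]]
  mri <- m[4] == "mri"
  strategy_definition(
    name, primary_test = "psa",
    start_age = as.numeric(m[2]), stop_age = as.numeric(m[3]),
    mri_triage = mri,
    biopsy_type_on_workup = if (mri) "combined" else "systematic",
    symptomatic_workup = if (mri) "mri_combined" else "systematic"
  )
}

#' @rdname strategy_preset
#' @export
list_strategy_presets <- function() {
  c("no_screening", "dre_45_75",
    paste0("psa_ras_", rep(c(45, 50), each = 4), "_",
           rep(rep(c(60, 70), each = 2), 2), "_", c("mri", "nomri")))
}

band_interval <- function(strategy, psa) {
  rb <- strategy$risk_bands
  band <- findInterval(psa, utils::head(rb$upper, -1)) + 1L
  rb$interval_years[band]
}

#' Next screening invitation age under a risk-adaptive schedule
#'
#' The rescreen interval is looked up from the PSA risk band of the last
#' measurement; the first invitation is issued at the strategy's start
#' age. An interval that overshoots the stop age yields no further
#' invitation.
#'
#' @param strategy `strategy_definition`.
#' @param last_screen_age Age at the last attended screen (`NULL` for the
#'   first invitation).
#' @param last_psa PSA at the last screen (ng/mL).
#' @return Next invitation age, or `NA` if screening is over.
#' @export
next_invitation <- function(strategy, last_screen_age = NULL, last_psa = NULL) {
  if (is.null(last_screen_age)) return(strategy$start_age)
  if (!is.null(last_psa) && any(last_psa < 0)) {
    stop("PSA must be non-negative", call. = FALSE)
  }
  interval <- if (strategy$primary_test == "dre") {
    strategy$dre_interval
  } else if (is.null(last_psa)) {
    strategy$recall_interval
  } else {
    band_interval(strategy, last_psa)
  }
  nxt <- last_screen_age + interval
  if (!is.finite(nxt) || nxt > strategy$stop_age) NA_real_ else nxt
}

#' Active-surveillance monitoring schedule
#'
#' PSA + DRE visits every 3 months for the first 2 years after diagnosis,
#' then every 6 months; MRI with combined biopsy at 18-month spacing for
#' the first 3 years and 3-yearly thereafter. Events are truncated
#' strictly before death (or the configured AS duration).
#'
#' @param dx_age Diagnosis age.
#' @param death_age Death age (`> dx_age`).
#' @param config See [as_config()].
#' @return data.frame(`age`, `event`) with events `as_psa_dre` and
#'   `as_mri_biopsy`.
#' @export
active_surveillance_schedule <- function(dx_age, death_age, config = as_config()) {
  stopifnot(dx_age < death_age)
  horizon <- min(death_age - dx_age, config$duration)
  quarterly <- seq(0, config$intensive_years - config$intensive_step,
                   by = config$intensive_step)
  later <- seq(config$intensive_years, 200, by = config$later_step)
  visits <- c(quarterly, later)
  visits <- visits[visits < horizon]
  bx_early <- seq(config$biopsy_interval_early, config$biopsy_early_years,
                  by = config$biopsy_interval_early)
  bx_late <- seq(config$biopsy_early_years + config$biopsy_interval_late, 200,
                 by = config$biopsy_interval_late)
  bx <- c(bx_early, bx_late)
  bx <- bx[bx < horizon]
  out <- rbind(
    data.frame(age = dx_age + visits, event = "as_psa_dre"),
    if (length(bx)) data.frame(age = dx_age + bx, event = "as_mri_biopsy")
  )
  out[order(out$age), , drop = FALSE]
}

#' @rdname active_surveillance_schedule
#' @param intensive_years,intensive_step,later_step PSA+DRE visit spacing.
#' @param biopsy_interval_early,biopsy_early_years,biopsy_interval_late
#'   MRI + combined-biopsy spacing.
#' @param duration Maximum AS duration in years.
#' @export
as_config <- function(intensive_years = 2, intensive_step = 0.25,
                      later_step = 0.5, biopsy_interval_early = 1.5,
                      biopsy_early_years = 3, biopsy_interval_late = 3,
                      duration = 10) {
  list(intensive_years = intensive_years, intensive_step = intensive_step,
       later_step = later_step, biopsy_interval_early = biopsy_interval_early,
       biopsy_early_years = biopsy_early_years,
       biopsy_interval_late = biopsy_interval_late, duration = duration)
}

#' Treatment-assignment rules
#'
#' Assigns the management pathway at diagnosis from grade, stage and age:
#' metastatic disease receives androgen deprivation / chemotherapy;
#' localized GS < 7 goes to active surveillance up to `as_max_age` and
#' watchful waiting beyond; localized GS >= 7 receives radical treatment
#' up to `radical_max_age` and hormonal therapy beyond. Shipped as a
#' configurable default.
#'
#' @param as_max_age Oldest age for active surveillance.
#' @param radical_max_age Oldest age for radical treatment.
#' @export
treatment_rules <- function(as_max_age = 75, radical_max_age = 80) {
  list(as_max_age = as_max_age, radical_max_age = radical_max_age)
}

assign_treatment <- function(grade, metastasis, age, rules = treatment_rules()) {
  out <- rep(NA_character_, length(grade))
  known <- !is.na(grade) & !is.na(age)
  met <- known & !is.na(metastasis) & metastasis
  out[met] <- "adt"
  loc <- known & !met
  g1 <- loc & grade == 1L
  g2 <- loc & grade >= 2L
  out[g1 & age <= rules$as_max_age] <- "as"
  out[g1 & age > rules$as_max_age] <- "watchful"
  out[g2 & age <= rules$radical_max_age] <- "radical"
  out[g2 & age > rules$radical_max_age] <- "adt"
  out
}

## ---- the cohort screening engine --------------------------------------

#' Apply a screening strategy to a simulated cohort
#'
#' Runs the full screening cascade for every person: invitations on the
#' strategy's risk-adaptive schedule, participation draws (ever-attender,
#' per-invitation rescreen acceptance, per-referral biopsy acceptance),
#' the test cascade (PSA [-> MRI] -> biopsy, or DRE -> biopsy), detection
#' per the test profiles given the true underlying state, symptomatic
#' presentations with the arm-appropriate work-up, stage-shift survival
#' for screen-detected cancers, treatment assignment, and
#' active-surveillance monitoring events. All randomness comes from the
#' uniforms pre-drawn in [simulate_cohort()], so different strategies (and
#' cost scenarios) share common random numbers.
#'
#' @param cohort An `nh_cohort`.
#' @param strategy A `strategy_definition`.
#' @param tests Test profiles, see [default_test_profiles()].
#' @param rules Treatment rules, see [treatment_rules()].
#' @param as_cfg Active-surveillance configuration.
#' @return A `screened_cohort`: tidy `events` table (person_id, age,
#'   event, type, origin, value) and augmented `persons` table with
#'   diagnosis, treatment, overdiagnosis, lead time and death fields.
#' @export
run_screening_cohort <- function(cohort, strategy,
                                 tests = default_test_profiles(),
                                 rules = treatment_rules(),
                                 as_cfg = as_config()) {
  tests <- validate_test_profiles(tests)
  P <- cohort$persons
  n <- cohort$n
  st <- strategy
  if (st$primary_test == "psa" && is.null(tests[[paste0("biopsy_", st$biopsy_type_on_workup)]])) {
    stop("missing biopsy test profile for this strategy", call. = FALSE)
  }
  if (st$primary_test == "dre" && is.null(tests$dre)) {
    stop("missing DRE test profile", call. = FALSE)
  }
  if (st$mri_triage && is.null(tests$mri)) {
    stop("missing MRI test profile", call. = FALSE)
  }
  part <- st$participation
  cf <- ifelse(is.na(P$cf_dx_age), Inf, P$cf_dx_age)
  noise_sd <- cohort$params$noise_sd

  ev <- list()
  emit <- function(id, age, event, type = NA_character_,
                   origin = NA_character_, value = NA_real_) {
    if (!length(id)) return(invisible())
    ev[[length(ev) + 1L]] <<- data.frame(
      person_id = id, age = age, event = event, type = type,
      origin = origin, value = value, stringsAsFactors = FALSE)
  }

  screen_dx_age <- rep(NA_real_, n)
  screen_t_cat <- rep(NA_integer_, n)
  screen_met <- rep(NA, n)

  if (st$primary_test != "none") {
    ever <- cohort$u_first < part[["first_screen"]]
    next_age <- rep(as.numeric(st$start_age), n)
    k <- rep(1L, n)
    naive <- rep(TRUE, n)  # has not yet attended a screen
    guard <- 0L
    repeat {
      guard <- guard + 1L
      idx <- which(is.na(screen_dx_age) &
                     next_age <= st$stop_age + 1e-9 &
                     next_age < P$oc_death_age & next_age < cf)
      if (!length(idx) || guard > 200L) break
      A <- next_age[idx]
      kk <- pmin(k[idx], cohort$max_rounds)
      ucol <- cbind(idx, kk)
      emit(idx, A, "invitation", origin = "screen")
      attend <- ever[idx] &
        (naive[idx] | cohort$u_rescreen[ucol] < part[["rescreen"]])
      interval <- rep(st$recall_interval, length(idx))
      detected <- rep(FALSE, length(idx))

      ia <- which(attend)
      if (length(ia)) {
        pid <- idx[ia]
        Aa <- A[ia]
        naive[pid] <- FALSE
        cancer <- !is.na(P$onset_age[pid]) & Aa > P$onset_age[pid]
        grade <- P$grade[pid]

        if (st$primary_test == "psa") {
          lp <- P$psa_int[pid] + P$psa_slope[pid] * (Aa - 35) +
            ifelse(cancer, P$psa_accel[pid] * (Aa - P$onset_age[pid]), 0)
          psa <- exp(lp + noise_sd * cohort$z_noise[ucol[ia, , drop = FALSE]])
          emit(pid, Aa, "psa_test", origin = "screen", value = psa)
          interval[ia] <- band_interval(st, psa)
          pos <- psa >= st$workup_threshold
          offer <- pos
          if (st$mri_triage) {
            sig <- cancer & grade >= 2L
            p_mri <- ifelse(!cancer, 1 - tests$mri$specificity,
                            ifelse(sig, tests$mri$sens_significant,
                                   tests$mri$sens_insignificant))
            mri_pos <- cohort$u_mri[ucol[ia, , drop = FALSE]] < p_mri
            im <- which(pos)
            emit(pid[im], Aa[im], "mri", origin = "screen")
            offer <- pos & mri_pos
          }
          btype <- st$biopsy_type_on_workup
        } else {
          emit(pid, Aa, "dre_test", origin = "screen")
          p_pos <- ifelse(cancer, tests$dre$sensitivity,
                          1 - tests$dre$specificity)
          pos <- cohort$u_dre[ucol[ia, , drop = FALSE]] < p_pos
          # a positive DRE triggers a reflex PSA test (cost only)
          ip <- which(pos)
          if (length(ip)) {
            lp <- P$psa_int[pid[ip]] + P$psa_slope[pid[ip]] * (Aa[ip] - 35) +
              ifelse(cancer[ip],
                     P$psa_accel[pid[ip]] * (Aa[ip] - P$onset_age[pid[ip]]), 0)
            psa_r <- exp(lp + noise_sd * cohort$z_noise[ucol[ia[ip], , drop = FALSE]])
            emit(pid[ip], Aa[ip], "psa_test", origin = "screen", value = psa_r)
          }
          interval[ia] <- st$dre_interval
          offer <- pos
          btype <- "systematic"
        }

        acc <- offer & cohort$u_biopsy_accept[ucol[ia, , drop = FALSE]] < part[["biopsy"]]
        ib <- which(acc)
        emit(pid[ib], Aa[ib], "biopsy", type = btype, origin = "screen")
        sens <- tests[[paste0("biopsy_", btype)]]$sens_by_grade
        p_det <- ifelse(cancer, sens[ifelse(is.na(grade), 1L, grade)], 0)
        det <- acc & cohort$u_detect[ucol[ia, , drop = FALSE]] < p_det
        detected[ia] <- det
      }

      d <- which(detected)
      if (length(d)) {
        pid <- idx[d]
        screen_dx_age[pid] <- A[d]
        stg <- stage_at_age(P, pid, A[d])
        screen_t_cat[pid] <- stg$t_category
        screen_met[pid] <- stg$metastasis
        emit(pid, A[d], "screen_dx", origin = "screen")
      }
      next_age[idx] <- A + interval
      k[idx] <- k[idx] + 1L
    }
  }

  ## symptomatic presentations (not pre-empted by screen detection)
  clin <- which(is.na(screen_dx_age) & is.finite(cf))
  if (length(clin)) {
    Ac <- cf[clin]
    if (st$symptomatic_workup == "mri_combined") {
      emit(clin, Ac, "mri_diagnostic", origin = "clinical")
      emit(clin, Ac, "biopsy", type = "combined", origin = "clinical")
    } else {
      emit(clin, Ac, "biopsy", type = "systematic", origin = "clinical")
    }
    emit(clin, Ac, "clinical_dx", origin = "clinical")
  }

  ## assemble person-level outcomes
  dx_mode <- rep("none", n)
  dx_mode[clin] <- "clinical"
  dx_mode[!is.na(screen_dx_age)] <- "screen"
  dx_age <- ifelse(dx_mode == "screen", screen_dx_age,
                   ifelse(dx_mode == "clinical", cf, NA_real_))
  dx_t_cat <- ifelse(dx_mode == "screen", screen_t_cat, P$cf_t_cat)
  dx_met <- ifelse(dx_mode == "screen", screen_met, P$cf_met)
  dx_t_cat[dx_mode == "none"] <- NA_integer_
  dx_met[dx_mode == "none"] <- NA

  ## stage-shift survival for screen-detected cancers: survival of the
  ## stage at detection, clock starting at the counterfactual clinical
  ## diagnosis (end of lead time), shared survival uniform
  cancer_death <- ifelse(is.na(P$clin_cancer_death_age), Inf,
                         P$clin_cancer_death_age)
  scr <- which(dx_mode == "screen" & is.finite(cf))
  if (length(scr)) {
    ts <- draw_survival_time(cohort$params, screen_t_cat[scr], screen_met[scr],
                             grade_levels()[P$grade[scr]], P$u_surv[scr])
    cd <- cf[scr] + ts
    cd[cd >= P$oc_death_age[scr]] <- Inf
    cancer_death[scr] <- cd
  }
  cancer_death[dx_mode == "screen" & !is.finite(cf)] <- Inf  # overdiagnosed
  death_age <- pmin(P$oc_death_age, cancer_death)
  pca_death <- is.finite(cancer_death) & cancer_death <= P$oc_death_age

  overdx <- dx_mode == "screen" & !is.finite(cf)
  lead_time <- ifelse(dx_mode == "screen" & is.finite(cf),
                      cf - screen_dx_age, NA_real_)

  treatment <- assign_treatment(P$grade, dx_met, dx_age, rules)
  treatment[dx_mode == "none"] <- NA_character_
  emit(which(!is.na(treatment) & treatment != "watchful"),
       dx_age[!is.na(treatment) & treatment != "watchful"],
       "treatment_start",
       type = treatment[!is.na(treatment) & treatment != "watchful"])

  ## active-surveillance monitoring events
  ias <- which(!is.na(treatment) & treatment == "as" & dx_age < death_age)
  as_end <- rep(NA_real_, n)
  if (length(ias)) {
    as_end[ias] <- pmin(death_age[ias], dx_age[ias] + as_cfg$duration)
    sched <- lapply(ias, function(i) {
      s <- active_surveillance_schedule(dx_age[i], death_age[i], as_cfg)
      s$person_id <- i
      s
    })
    sched <- do.call(rbind, sched)
    vis <- sched[sched$event == "as_psa_dre", ]
    bx <- sched[sched$event == "as_mri_biopsy", ]
    emit(vis$person_id, vis$age, "as_visit", origin = "as")
    emit(bx$person_id, bx$age, "mri", origin = "as")
    emit(bx$person_id, bx$age, "biopsy", type = "combined", origin = "as")
  }

  ## metastatic phase start (for ongoing-cost accrual): metastatic at
  ## diagnosis starts immediately; otherwise only cancers that actually
  ## progress to a cancer death enter a terminal metastatic phase (treated
  ## cancers that are cured do not progress)
  met_start <- rep(NA_real_, n)
  dxd <- dx_mode != "none"
  met_at_dx <- dxd & !is.na(dx_met) & dx_met
  met_start[met_at_dx] <- dx_age[met_at_dx]
  prog <- dxd & !is.na(dx_met) & !dx_met & pca_death
  met_start[prog] <- pmax(dx_age[prog], cancer_death[prog] - 3)

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(person_id = integer(), age = numeric(), event = character(),
               type = character(), origin = character(), value = numeric())
  events <- events[order(events$person_id, events$age), , drop = FALSE]
  rownames(events) <- NULL

  persons <- data.frame(
    person_id = P$person_id,
    oc_death_age = P$oc_death_age,
    onset_age = P$onset_age,
    grade = P$grade,
    cf_dx_age = P$cf_dx_age,
    dx_age = dx_age, dx_mode = dx_mode,
    dx_t_cat = dx_t_cat, dx_met = dx_met,
    treatment = treatment, as_end = as_end, met_start = met_start,
    cancer_death_age = ifelse(is.finite(cancer_death), cancer_death, NA_real_),
    death_age = death_age, pca_death = pca_death,
    overdiagnosed = overdx, lead_time = lead_time,
    stringsAsFactors = FALSE
  )
  structure(list(strategy = st, events = events, persons = persons, n = n),
            class = "screened_cohort")
}

#' Apply a screening strategy to one life history
#'
#' Single-person counterpart of [run_screening_cohort()]; replays the
#' person's random substream so the result is reproducible from
#' `(person_id, seed)`.
#'
#' @param history A `life_history` from [simulate_natural_course()].
#' @param strategy A `strategy_definition`.
#' @param tests Test profiles.
#' @param params,life_table The natural-history parameters and life table
#'   used to simulate the history.
#' @param seed Master seed (same one passed to [simulate_natural_course()]).
#' @return The person's `ScreeningRecord` event data.frame; the augmented
#'   person row is attached as attribute `"person"`.
#' @export
run_screening <- function(history, strategy, tests = default_test_profiles(),
                          params, life_table, seed) {
  set.seed(history$random_stream_key %||% derive_seed(seed, "person",
                                                      history$person_id))
  persons <- draw_natural_histories(params, validate_life_table(life_table), 1L)
  max_rounds <- 31L
  cohort <- list(
    n = 1L, persons = persons, params = params, life_table = life_table,
    seed = seed, max_rounds = max_rounds,
    u_first = stats::runif(1),
    u_surv = persons$u_surv,
    z_noise = matrix(stats::rnorm(max_rounds), 1),
    u_rescreen = matrix(stats::runif(max_rounds), 1),
    u_biopsy_accept = matrix(stats::runif(max_rounds), 1),
    u_detect = matrix(stats::runif(max_rounds), 1),
    u_dre = matrix(stats::runif(max_rounds), 1),
    u_mri = matrix(stats::runif(max_rounds), 1)
  )
  class(cohort) <- "nh_cohort"
  out <- run_screening_cohort(cohort, strategy, tests)
  rec <- out$events
  attr(rec, "person") <- out$persons
  rec
}

## ---- strategy config round-trip ---------------------------------------

#' Read / write a strategy definition as YAML
#' @param strategy A `strategy_definition`.
#' @param path YAML file path.
#' @export
write_strategy <- function(strategy, path) {
  x <- unclass(strategy)
  x$risk_bands <- as.list(x$risk_bands)
  x$participation <- as.list(x$participation)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_strategy
#' @export
read_strategy <- function(path) {
  x <- yaml::read_yaml(path)
  rb <- data.frame(upper = unlist(x$risk_bands$upper),
                   interval_years = unlist(x$risk_bands$interval_years))
  rb$upper[is.na(rb$upper) | rb$upper == ".inf"] <- Inf
  strategy_definition(
    name = x$name, primary_test = x$primary_test,
    start_age = x$start_age, stop_age = x$stop_age,
    risk_bands = rb, workup_threshold = x$workup_threshold,
    mri_triage = x$mri_triage, biopsy_type_on_workup = x$biopsy_type_on_workup,
    dre_interval = x$dre_interval, recall_interval = x$recall_interval,
    participation = unlist(x$participation),
    symptomatic_workup = x$symptomatic_workup
  )
}
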