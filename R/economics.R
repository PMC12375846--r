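#' Unit-cost schedule (2023 euros)
#'
#' Per-event and per-year direct healthcare costs from the statutory
#' health insurance perspective. The PSA test cost (25.61) and the
#' base-case MRI cost (500) are fixed from the German fee-for-service
#' setting; the remaining values are documented placeholder defaults in
#' the same price year, all configurable.
#'
#' @param ... Named overrides of individual unit costs.
#' @return Named list of unit costs, class `cost_schedule`.
#' @export
cost_schedule <- function(...) {
  costs <- list(
    invitation = 0,
    psa_test = 25.61,
    dre_test = 15,
    mri = 500,
    biopsy_systematic = 650,
    biopsy_combined = 1250,
    as_visit = 60,
    radical_treatment = 9000,
    adt_chemo_per_year = 5000,
    palliative_per_year = 20000,
    followup_per_year = 120
  )
  over <- list(...)
  bad <- setdiff(names(over), names(costs))
  if (length(bad)) stop("unknown cost item(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  costs[names(over)] <- over
  assert_nonneg(unlist(costs), "costs")
  structure(costs, class = "cost_schedule")
}

#' Health-state utility inputs
#'
#' Age-specific background utilities (population norms, linearly
#' interpolated) and per-state utility weights with their durations, under
#' a multiplicative model: the utility at an age is the background utility
#' times the product of all active state utilities. Two utility sets are
#' shipped: the disease-specific `porpus_u` base case and a generally
#' lower generic `eq5d` set. States with `NA` duration are ongoing phases
#' whose length is determined by the disease course.
#'
#' @param set_name `"porpus_u"` or `"eq5d"`.
#' @return List with `set_name`, `background` (data.frame age/utility) and
#'   `states` (data.frame state/utility/duration_years), class
#'   `utility_inputs`.
#' @export
utility_inputs <- function(set_name = c("porpus_u", "eq5d")) {
  set_name <- match.arg(set_name)
  background <- data.frame(
    age = c(35, 45, 55, 65, 75, 85, 95, 105),
    utility = c(0.95, 0.93, 0.91, 0.87, 0.82, 0.74, 0.65, 0.55)
  )
  states <- data.frame(
    state = c("screen_attend", "biopsy", "diagnosis", "as", "watchful",
              "radical_tx", "post_tx", "met", "terminal"),
    utility = c(0.99, 0.90, 0.80, 0.97, 0.97, 0.75, 0.95, 0.80, 0.40),
    duration_years = c(1 / 52, 3 / 52, 1 / 12, NA, NA, 1, 9, NA, 0.5)
  )
  if (set_name == "eq5d") {
    states$utility <- c(0.99, 0.87, 0.77, 0.95, 0.95, 0.71, 0.92, 0.75, 0.35)
  }
  assert_prob(background$utility, "background utilities")
  assert_prob(states$utility, "state utilities")
  structure(list(set_name = set_name, background = background,
                 states = states), class = "utility_inputs")
}

#' Discount a value to present value at age 45
#'
#' Events are discounted annually from a fixed reference of age 45; event
#' times before the reference are clamped to time zero (no negative
#' discounting).
#'
#' @param amount Amount(s) to discount.
#' @param event_time_years_from_age_45 Time(s) in years since age 45.
#' @param annual_rate Annual discount rate (e.g. 0.03).
#' @return Discounted amount(s).
#' @export
discount_value <- function(amount, event_time_years_from_age_45, annual_rate) {
  if (annual_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  amount / (1 + annual_rate)^pmax(event_time_years_from_age_45, 0)
}

background_utility_at <- function(inputs, age) {
  stats::approx(inputs$background$age, inputs$background$utility,
                xout = age, rule = 2)$y
}

state_utility <- function(inputs, state) {
  i <- match(state, inputs$states$state)
  if (any(is.na(i))) {
    stop("unknown health state(s): ",
         paste(state[is.na(i)], collapse = ", "), call. = FALSE)
  }
  inputs$states$utility[i]
}

state_duration <- function(inputs, state) {
  inputs$states$duration_years[match(state, inputs$states$state)]
}

#' Utility at an age under the multiplicative model
#'
#' @param inputs `utility_inputs`.
#' @param age Age in years.
#' @param active_states Character vector of active state names (possibly
#'   empty).
#' @return Utility in `[0, 1]`: background times the product of active
#'   state utilities.
#' @export
utility_at_age <- function(inputs, age, active_states = character()) {
  u <- background_utility_at(inputs, age)
  if (length(active_states)) u <- u * prod(state_utility(inputs, active_states))
  u
}

## ---- cohort economics engine ------------------------------------------

# Disjoint disease-phase intervals per person, ordered by clinical
# priority (terminal > metastatic > primary treatment pathway). Returns a
# list of (start, end, state, cost_key) interval sets, each a vector pair.
build_phases <- function(persons, inputs) {
  inf <- function(x) ifelse(is.na(x), Inf, x)
  dx <- inf(persons$dx_age)
  death <- persons$death_age
  term_dur <- state_duration(inputs, "terminal")
  terminal_start <- ifelse(persons$pca_death %in% TRUE,
                           pmax(death - term_dur, dx), Inf)
  met_s <- inf(persons$met_start)
  met_s[!is.na(persons$treatment) & persons$treatment == "adt" &
          is.na(persons$met_start)] <- dx[!is.na(persons$treatment) &
                                            persons$treatment == "adt" &
                                            is.na(persons$met_start)]
  tr <- persons$treatment
  is_tr <- function(x) !is.na(tr) & tr == x
  cap <- pmin(met_s, terminal_start, death)
  phases <- list(
    list(state = "as", cost_key = NA_character_,
         start = ifelse(is_tr("as"), dx, Inf),
         end = ifelse(is_tr("as"), pmin(inf(persons$as_end), cap), Inf)),
    list(state = "watchful", cost_key = NA_character_,
         start = ifelse(is_tr("watchful"), dx, Inf),
         end = ifelse(is_tr("watchful"), cap, Inf)),
    list(state = "radical_tx", cost_key = NA_character_,
         start = ifelse(is_tr("radical"), dx, Inf),
         end = ifelse(is_tr("radical"), pmin(dx + 1, cap), Inf)),
    list(state = "post_tx", cost_key = "followup_per_year",
         start = ifelse(is_tr("radical"), pmin(dx + 1, cap), Inf),
         end = ifelse(is_tr("radical"),
                      pmin(dx + 1 + state_duration(inputs, "post_tx"), cap),
                      Inf)),
    list(state = "met", cost_key = "adt_chemo_per_year",
         start = ifelse(is.finite(met_s), pmin(met_s, death), Inf),
         end = ifelse(is.finite(met_s), pmin(terminal_start, death), Inf)),
    list(state = "terminal", cost_key = "palliative_per_year",
         start = ifelse(is.finite(terminal_start),
                        pmin(terminal_start, death), Inf),
         end = ifelse(is.finite(terminal_start), death, Inf))
  )
  lapply(phases, function(p) {
    p$end <- pmax(p$end, p$start)
    p
  })
}

# Core person-level economics: life-years, QALYs and costs, discounted and
# undiscounted, from an augmented persons table and its tidy event log.
econ_engine <- function(persons, events, costs, utilities, rate,
                        ref_age = 45, max_age = 105) {
  n <- nrow(persons)
  death <- persons$death_age
  phases <- build_phases(persons, utilities)
  phase_u <- vapply(phases, function(p) state_utility(utilities, p$state), 0)

  ly_u <- ly_d <- qaly_u <- qaly_d <- cost_u <- cost_d <- numeric(n)
  comp_d <- stats::setNames(numeric(length(costs)), names(costs))
  years <- seq(ref_age, max_age - 1)
  for (y in years) {
    frac <- clamp(death - y, 0, 1)
    disc <- 1 / (1 + rate)^(y + 0.5 - ref_age)
    bg <- background_utility_at(utilities, y + 0.5)
    q <- bg * frac
    cost_y <- numeric(n)
    for (j in seq_along(phases)) {
      p <- phases[[j]]
      ov <- clamp(pmin(p$end, y + 1) - pmax(p$start, y), 0, 1)
      q <- q - bg * ov * (1 - phase_u[j])
      if (!is.na(p$cost_key)) {
        cost_y <- cost_y + costs[[p$cost_key]] * ov
        comp_d[p$cost_key] <- comp_d[p$cost_key] +
          sum(costs[[p$cost_key]] * ov) * disc
      }
    }
    ly_u <- ly_u + frac
    ly_d <- ly_d + frac * disc
    qaly_u <- qaly_u + q
    qaly_d <- qaly_d + q * disc
    cost_u <- cost_u + cost_y
    cost_d <- cost_d + cost_y * disc
  }

  if (nrow(events)) {
    key <- event_cost_key(events)
    known <- !is.na(key)
    missing_cost <- setdiff(key[known], names(costs))
    if (length(missing_cost)) {
      stop("no cost entry for event kind(s): ",
           paste(missing_cost, collapse = ", "), call. = FALSE)
    }
    unit <- unlist(costs)[key]
    unit[is.na(key)] <- 0
    disc_ev <- 1 / (1 + rate)^pmax(events$age - ref_age, 0)
    cu <- rowsum(unit, events$person_id)
    cd <- rowsum(unit * disc_ev, events$person_id)
    pid <- as.integer(rownames(cu))
    m <- match(pid, persons$person_id)
    cost_u[m] <- cost_u[m] + cu[, 1]
    cost_d[m] <- cost_d[m] + cd[, 1]
    for (k in unique(key[known])) {
      comp_d[k] <- comp_d[k] + sum((unit * disc_ev)[known & key == k])
    }

    ## short event-triggered disutility rectangles (biopsy, diagnosis),
    ## applied against the background utility
    dis_state <- ifelse(events$event == "biopsy", "biopsy",
                 ifelse(events$event %in% c("screen_dx", "clinical_dx"),
                        "diagnosis", NA_character_))
    ie <- which(!is.na(dis_state))
    if (length(ie)) {
      m2 <- match(events$person_id[ie], persons$person_id)
      dur <- pmin(state_duration(utilities, dis_state[ie]),
                  pmax(death[m2] - events$age[ie], 0))
      loss <- background_utility_at(utilities, events$age[ie]) *
        (1 - state_utility(utilities, dis_state[ie])) * dur
      loss_d <- loss / (1 + rate)^pmax(events$age[ie] - ref_age, 0)
      lu <- rowsum(loss, events$person_id[ie])
      ld <- rowsum(loss_d, events$person_id[ie])
      m3 <- match(as.integer(rownames(lu)), persons$person_id)
      qaly_u[m3] <- qaly_u[m3] - lu[, 1]
      qaly_d[m3] <- qaly_d[m3] - ld[, 1]
    }
  }

  out <- data.frame(
    person_id = persons$person_id,
    ly_undisc = ly_u, ly_disc = ly_d,
    qaly_undisc = qaly_u, qaly_disc = qaly_d,
    cost_undisc = cost_u, cost_disc = cost_d
  )
  attr(out, "cost_components") <- comp_d
  out
}

# Maps an event row to the unit-cost key charged for it; NA = free event.
event_cost_key <- function(events) {
  key <- rep(NA_character_, nrow(events))
  key[events$event == "psa_test"] <- "psa_test"
  key[events$event == "dre_test"] <- "dre_test"
  key[events$event %in% c("mri", "mri_diagnostic")] <- "mri"
  key[events$event == "biopsy"] <-
    paste0("biopsy_", events$type[events$event == "biopsy"])
  key[events$event == "as_visit"] <- "as_visit"
  key[events$event == "treatment_start" &
        events$type %in% "radical"] <- "radical_treatment"
  key
}

#' Costs and QALYs for a screened cohort
#'
#' Attaches unit costs to every logged event, accrues phase-based ongoing
#' costs (follow-up, androgen deprivation / chemotherapy, terminal
#' palliative care) over the disease phases, and integrates background and
#' state utilities over each person's lifespan from age 45, discounted
#' annually.
#'
#' @param screened A `screened_cohort` from [run_screening_cohort()].
#' @param costs A `cost_schedule`.
#' @param utilities A `utility_inputs`.
#' @param discount_rate Annual discount rate.
#' @return Per-person data.frame (`ly_undisc`, `ly_disc`, `qaly_undisc`,
#'   `qaly_disc`, `cost_undisc`, `cost_disc`) with a `cost_components`
#'   attribute of discounted totals per unit-cost key.
#' @export
compute_economics <- function(screened, costs = cost_schedule(),
                              utilities = utility_inputs(),
                              discount_rate = 0.03) {
  econ_engine(screened$persons, screened$events, costs, utilities,
              discount_rate)
}

as_person_row <- function(history) {
  if (is.data.frame(history)) return(history)
  dx_age <- history$actual_dx_age %||% NA_real_
  stage <- history$stage_at_dx
  grade <- match(history$grade_category, grade_levels())
  met <- if (!is.null(stage)) stage$metastasis else NA
  treatment <- if (!is.na(dx_age)) {
    assign_treatment(grade, met, dx_age)
  } else NA_character_
  cancer_death <- history$cancer_death_age %||% NA_real_
  data.frame(
    person_id = history$person_id %||% 1L,
    dx_age = dx_age,
    treatment = treatment,
    as_end = if (!is.na(dx_age) && identical(treatment, "as"))
      min(history$death_age, dx_age + as_config()$duration) else NA_real_,
    met_start = if (!is.na(dx_age) && isTRUE(met)) dx_age else NA_real_,
    death_age = history$death_age,
    pca_death = !is.na(cancer_death) && cancer_death <= history$death_age,
    stringsAsFactors = FALSE
  )
}

#' Accumulate costs for one person's screening record
#'
#' Sums per-event costs over a `ScreeningRecord` event log plus the
#' phase-based ongoing costs implied by the person's disease course,
#' discounted from age 45.
#'
#' @param record Event data.frame (`person_id`, `age`, `event`, `type`).
#' @param history A `life_history` or an augmented person row; `NULL` for
#'   a disease-free person (event costs only).
#' @param costs `cost_schedule`.
#' @param rate Annual discount rate.
#' @return Named vector `c(undiscounted, discounted)` in euros.
#' @export
accumulate_costs <- function(record, history = NULL, costs = cost_schedule(),
                             rate = 0.03) {
  persons <- person_row_or_default(record, history)
  res <- econ_engine(persons, normalize_record(record), costs,
                     utility_inputs(), rate)
  c(undiscounted = sum(res$cost_undisc), discounted = sum(res$cost_disc))
}

#' Accumulate life-years and QALYs for one person
#'
#' Integrates (quality-adjusted) survival from age 45 to death, applying
#' state utilities over their configured durations after each triggering
#' event and over the ongoing disease phases.
#'
#' @inheritParams accumulate_costs
#' @param inputs `utility_inputs`.
#' @return Named vector `c(ly_undisc, ly_disc, qaly_undisc, qaly_disc)`.
#' @export
accumulate_qalys <- function(record, history = NULL,
                             inputs = utility_inputs(), rate = 0.03) {
  persons <- person_row_or_default(record, history)
  res <- econ_engine(persons, normalize_record(record), cost_schedule(),
                     inputs, rate)
  c(ly_undisc = sum(res$ly_undisc), ly_disc = sum(res$ly_disc),
    qaly_undisc = sum(res$qaly_undisc), qaly_disc = sum(res$qaly_disc))
}

person_row_or_default <- function(record, history) {
  if (is.null(history)) {
    pid <- if (nrow(record)) record$person_id[1] else 1L
    return(data.frame(person_id = pid, dx_age = NA_real_,
                      treatment = NA_character_, as_end = NA_real_,
                      met_start = NA_real_, death_age = 105,
                      pca_death = FALSE, stringsAsFactors = FALSE))
  }
  as_person_row(history)
}

normalize_record <- function(record) {
  rec <- as.data.frame(record)
  if (!nrow(rec)) {
    return(data.frame(person_id = integer(), age = numeric(),
                      event = character(), type = character(),
                      origin = character(), value = numeric()))
  }
  if (is.null(rec$type)) rec$type <- NA_character_
  if (is.null(rec$origin)) rec$origin <- NA_character_
  if (is.null(rec$value)) rec$value <- NA_real_
  rec
}
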