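#' Registry-style calibration targets
#'
#' Age-group prostate-cancer incidence (cases and person-years) plus the
#' grade-category distribution among diagnoses per age group, optionally
#' with cancer-mortality rates for validation. The CSV schema is
#' `age_low, age_high, cases, person_years, p_gs_lt7, p_gs_7, p_gs_gt7`
#' (plus optional `mortality_cases`).
#'
#' @param targets data.frame in the schema above.
#' @return Validated `calibration_targets` data.frame.
#' @export
calibration_targets <- function(targets) {
  need <- c("age_low", "age_high", "cases", "person_years",
            "p_gs_lt7", "p_gs_7", "p_gs_gt7")
  if (!all(need %in% names(targets))) {
    stop("targets must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(targets$person_years <= 0)) {
    stop("person-year denominators must be > 0", call. = FALSE)
  }
  assert_nonneg(targets$cases, "cases")
  psum <- targets$p_gs_lt7 + targets$p_gs_7 + targets$p_gs_gt7
  if (any(abs(psum - 1) > 1e-6)) {
    stop("grade proportions must sum to 1 in every age group", call. = FALSE)
  }
  targets <- targets[order(targets$age_low), , drop = FALSE]
  class(targets) <- c("calibration_targets", "data.frame")
  targets
}

#' @rdname calibration_targets
#' @param path CSV path.
#' @export
read_calibration_targets <- function(path) {
  calibration_targets(utils::read.csv(path))
}

#' @rdname calibration_targets
#' @export
write_calibration_targets <- function(targets, path) {
  utils::write.csv(as.data.frame(targets), path, row.names = FALSE)
  invisible(path)
}

#' Background (opportunistic) screening configuration for calibration
#'
#' Registry incidence reflects the statutory annual-DRE offer, so the
#' calibration cohort is simulated with an opportunistic annual DRE of
#' configurable uptake (the uptake itself is an assumption, not a
#' registry quantity).
#'
#' @param uptake Annual probability of taking the DRE offer.
#' @param start_age,stop_age Ages of DRE availability.
#' @param sensitivity,specificity DRE test characteristics.
#' @param biopsy_sens_by_grade Grade-specific systematic-biopsy
#'   sensitivity after a suspicious DRE.
#' @export
background_screening <- function(uptake = 0.2, start_age = 45, stop_age = 75,
                                 sensitivity = 0.55, specificity = 0.92,
                                 biopsy_sens_by_grade =
                                   c(gs_lt7 = 0.70, gs_7 = 0.88, gs_gt7 = 0.90)) {
  assert_prob(c(uptake, sensitivity, specificity, biopsy_sens_by_grade),
              "background screening probabilities")
  list(uptake = uptake, start_age = start_age, stop_age = stop_age,
       sensitivity = sensitivity, specificity = specificity,
       biopsy_sens_by_grade = biopsy_sens_by_grade)
}

# Lightweight annual-DRE background screen over a natural-history persons
# table: returns the screen-detection age (NA if none). Runs under common
# random numbers keyed by `seed`, independent of the cohort stream.
simulate_background_dre <- function(persons, bg, seed) {
  n <- nrow(persons)
  set.seed(derive_seed(seed, "background_dre"))
  det_age <- rep(NA_real_, n)
  cf <- ifelse(is.na(persons$cf_dx_age), Inf, persons$cf_dx_age)
  for (a in seq(bg$start_age, bg$stop_age)) {
    u_at <- stats::runif(n)
    u_pos <- stats::runif(n)
    u_det <- stats::runif(n)
    open <- is.na(det_age) & a < persons$oc_death_age & a < cf
    attend <- open & u_at < bg$uptake
    cancer <- attend & !is.na(persons$onset_age) & a > persons$onset_age
    pos <- (cancer & u_pos < bg$sensitivity)
    g <- ifelse(is.na(persons$grade), 1L, persons$grade)
    det <- pos & u_det < bg$biopsy_sens_by_grade[g]
    det_age[det] <- a
  }
  det_age
}

# Age-group incidence and grade mix implied by a simulated cohort under
# background screening. Denominators are total person-years alive in each
# age group (registry convention).
model_rates <- function(persons, det_age, groups) {
  dx_age <- pmin(ifelse(is.na(persons$cf_dx_age), Inf, persons$cf_dx_age),
                 ifelse(is.na(det_age), Inf, det_age))
  death <- pmin(persons$oc_death_age,
                ifelse(is.na(persons$clin_cancer_death_age), Inf,
                       persons$clin_cancer_death_age))
  pca <- !is.na(persons$clin_cancer_death_age) &
    persons$clin_cancer_death_age <= persons$oc_death_age
  out <- lapply(seq_len(nrow(groups)), function(i) {
    lo <- groups$age_low[i]; hi <- groups$age_high[i]
    py <- sum(clamp(death - lo, 0, hi - lo))
    in_grp <- is.finite(dx_age) & dx_age >= lo & dx_age < hi & dx_age < death
    ncase <- sum(in_grp)
    gr <- tabulate(persons$grade[in_grp], nbins = 3)
    data.frame(age_low = lo, age_high = hi, cases = ncase, person_years = py,
               n_gs_lt7 = gr[1], n_gs_7 = gr[2], n_gs_gt7 = gr[3],
               pca_deaths = sum(pca & death >= lo & death < hi))
  })
  do.call(rbind, out)
}

#' Model-implied registry rates under background screening
#'
#' Simulates a cohort from the given parameters under background DRE
#' screening (common random numbers keyed by `seed`) and tabulates
#' age-group diagnosis counts, person-years and grade counts — the model
#' side of the calibration deviance.
#'
#' @inheritParams calibration_loss
#' @param age_groups data.frame(age_low, age_high).
#' @return data.frame (`age_low`, `age_high`, `cases`, `person_years`,
#'   `n_gs_lt7`, `n_gs_7`, `n_gs_gt7`).
#' @export
simulate_registry_rates <- function(params, age_groups,
                                    bg = background_screening(),
                                    n_sim = 1e5, seed = 1,
                                    life_table = make_life_table()) {
  set.seed(derive_seed(seed, "calibration_cohort"))
  persons <- draw_natural_histories(params, validate_life_table(life_table),
                                    n_sim)
  det_age <- simulate_background_dre(persons, bg, seed)
  model_rates(persons, det_age, age_groups)
}

#' Calibration loss: Poisson + multinomial deviance against targets
#'
#' Simulates a cohort under the given natural-history parameters and
#' background DRE screening, computes model age-group incidence and grade
#' proportions, and returns the summed Poisson deviance of the target
#' case counts against model-implied expected counts plus the multinomial
#' deviance of the target grade counts against model grade proportions.
#' Every evaluation reuses the same random numbers (seeded internally
#' from `seed`), making the objective deterministic in the parameters.
#'
#' @param params `nh_params` to evaluate.
#' @param targets `calibration_targets`.
#' @param bg [background_screening()] configuration.
#' @param n_sim Cohort size per evaluation.
#' @param seed Seed shared across evaluations (common random numbers).
#' @param life_table Life table used for the simulated cohort.
#' @return Scalar deviance.
#' @export
calibration_loss <- function(params, targets, bg = background_screening(),
                             n_sim = 1e5, seed = 1,
                             life_table = make_life_table()) {
  targets <- calibration_targets(targets)
  mr <- simulate_registry_rates(params, targets, bg, n_sim, seed, life_table)

  ## Poisson deviance on case counts at the registry person-years
  mu <- pmax(mr$cases / pmax(mr$person_years, 1), 1e-8) * targets$person_years
  obs <- targets$cases
  dev_pois <- 2 * sum(ifelse(obs > 0, obs * log(obs / mu), 0) - (obs - mu))

  ## multinomial deviance on the grade split
  pm <- cbind(mr$n_gs_lt7, mr$n_gs_7, mr$n_gs_gt7)
  pm <- pm / pmax(rowSums(pm), 1)
  pm <- pmax(pm, 1e-6)
  pm <- pm / rowSums(pm)
  obs_g <- targets$cases * cbind(targets$p_gs_lt7, targets$p_gs_7,
                                 targets$p_gs_gt7)
  phat <- obs_g / pmax(rowSums(obs_g), 1e-12)
  dev_multi <- 2 * sum(ifelse(obs_g > 0, obs_g * log(pmax(phat, 1e-12) / pm), 0))

  dev_pois + dev_multi
}

#' Fit onset and grade-mixture parameters to registry targets
#'
#' Derivative-free (Nelder-Mead) minimization of [calibration_loss()] over
#' the identifiable free-parameter subset: the Weibull onset shape and
#' scale (log-parameterized) and the two grade-mixture intercepts. All
#' other natural-history parameters stay fixed at their input values.
#' Common random numbers across evaluations keep the objective smooth in
#' the parameters. Grade intercepts are initialized analytically from the
#' pooled target grade proportions.
#'
#' @param targets `calibration_targets`.
#' @param bg [background_screening()] configuration.
#' @param base_params Starting `nh_params` (fixed components are taken
#'   from here).
#' @param optimizer_config list(maxit, reltol, n_sim).
#' @param seed Seed for the common-random-number evaluations.
#' @param life_table Life table.
#' @param free Character subset of `c("onset", "grade")` to fit; an empty
#'   subset returns the inputs with a single loss evaluation.
#' @return list(params, loss, trace, convergence, counts).
#' @export
fit_natural_history <- function(targets, bg = background_screening(),
                                base_params = nh_params(),
                                optimizer_config = list(maxit = 150,
                                                        reltol = 1e-4,
                                                        n_sim = 1e5),
                                seed = 1, life_table = make_life_table(),
                                free = c("onset", "grade")) {
  targets <- calibration_targets(targets)
  n_sim <- optimizer_config$n_sim %||% 1e5
  if (!length(free)) {
    loss <- calibration_loss(base_params, targets, bg, n_sim, seed, life_table)
    return(list(params = base_params, loss = loss, trace = loss,
                convergence = 0L, counts = c(`function` = 1L)))
  }

  ## analytic initialization of the grade intercepts from pooled targets
  pooled <- colSums(targets$cases * cbind(targets$p_gs_lt7, targets$p_gs_7,
                                          targets$p_gs_gt7))
  pooled <- pmax(pooled / sum(pooled), 1e-3)
  gm <- base_params$grade_mixture_params
  init_grade <- c(log(pooled[2] / pooled[1]), log(pooled[3] / pooled[1]))

  theta0 <- c()
  if ("onset" %in% free) {
    theta0 <- c(theta0, log_shape = log(base_params$onset_hazard_params$shape),
                log_scale = log(base_params$onset_hazard_params$scale))
  }
  if ("grade" %in% free) {
    theta0 <- c(theta0, int_gs7 = unname(init_grade[1]),
                int_gsgt7 = unname(init_grade[2]))
  }

  apply_theta <- function(theta) {
    p <- base_params
    if ("onset" %in% free) {
      p$onset_hazard_params$shape <- exp(theta[["log_shape"]])
      p$onset_hazard_params$scale <- exp(theta[["log_scale"]])
    }
    if ("grade" %in% free) {
      p$grade_mixture_params$int_gs7 <- theta[["int_gs7"]]
      p$grade_mixture_params$int_gsgt7 <- theta[["int_gsgt7"]]
    }
    validate_nh_params(p)
  }

  trace <- numeric(0)
  obj <- function(theta) {
    l <- calibration_loss(apply_theta(theta), targets, bg, n_sim, seed,
                          life_table)
    trace[length(trace) + 1L] <<- l
    l
  }
  ## Nelder-Mead with restarts: re-seeding the simplex at the incumbent
  ## recovers from premature simplex collapse on the Monte-Carlo surface
  maxit <- optimizer_config$maxit %||% 150
  restarts <- optimizer_config$restarts %||% 3
  reltol <- optimizer_config$reltol %||% 1e-4
  best <- list(par = theta0, value = Inf, convergence = 1L,
               counts = c(`function` = 0L))
  for (r in seq_len(restarts)) {
    fit <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = ceiling(maxit / restarts),
                                       reltol = reltol))
    if (fit$value <= best$value) {
      best <- fit
    }
  }
  list(params = apply_theta(best$par), loss = best$value, trace = trace,
       convergence = best$convergence, counts = c(`function` = length(trace)))
}

#' Validate fitted parameters against cancer-mortality targets
#'
#' Simulates a cohort under the fitted parameters and background
#' screening and tabulates age-group prostate-cancer mortality with
#' Poisson Monte-Carlo intervals next to the observed target rates. No
#' fitting takes place.
#'
#' @param params Fitted `nh_params`.
#' @param mortality_targets data.frame (`age_low`, `age_high`, `cases`,
#'   `person_years`) of observed cancer deaths; may be empty.
#' @param bg Background screening configuration.
#' @param n_sim Cohort size.
#' @param seed Seed.
#' @param life_table Life table.
#' @param conf Confidence level of the Monte-Carlo intervals.
#' @return data.frame with observed and model rates per 100,000
#'   person-years and model interval bounds.
#' @export
validate_mortality <- function(params, mortality_targets,
                               bg = background_screening(), n_sim = 1e5,
                               seed = 1, life_table = make_life_table(),
                               conf = 0.95) {
  if (is.null(mortality_targets) || !nrow(mortality_targets)) {
    return(data.frame(age_low = numeric(), age_high = numeric(),
                      observed_rate = numeric(), model_rate = numeric(),
                      model_lo = numeric(), model_hi = numeric()))
  }
  set.seed(derive_seed(seed, "validation_cohort"))
  persons <- draw_natural_histories(params, validate_life_table(life_table),
                                    n_sim)
  death <- pmin(persons$oc_death_age,
                ifelse(is.na(persons$clin_cancer_death_age), Inf,
                       persons$clin_cancer_death_age))
  pca <- !is.na(persons$clin_cancer_death_age) &
    persons$clin_cancer_death_age <= persons$oc_death_age
  alpha <- (1 - conf) / 2
  out <- lapply(seq_len(nrow(mortality_targets)), function(i) {
    lo <- mortality_targets$age_low[i]; hi <- mortality_targets$age_high[i]
    py <- sum(clamp(death - lo, 0, hi - lo))
    k <- sum(pca & death >= lo & death < hi)
    rate <- 1e5 * k / py
    ci <- 1e5 * stats::qgamma(c(alpha, 1 - alpha), shape = c(k, k + 1)) / py
    data.frame(age_low = lo, age_high = hi,
               observed_rate = 1e5 * mortality_targets$cases[i] /
                 mortality_targets$person_years[i],
               model_rate = rate, model_lo = ci[1], model_hi = ci[2])
  })
  do.call(rbind, out)
}
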