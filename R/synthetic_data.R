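#' Configuration of the synthetic-data generator
#'
#' Bundles everything needed to emulate the external inputs of the
#' analysis: an all-cause life table (Gompertz-Makeham), a ground-truth
#' natural-history parameter set, registry-scale person-year denominators
#' per 5-year age group, and Poisson noise on case counts. The generated
#' targets emulate national-registry age-specific incidence and grade
#' distributions observed under opportunistic annual-DRE screening.
#'
#' @param seed Generator seed.
#' @param life_table_params list(makeham, gompertz_b, gompertz_theta).
#' @param true_natural_history Ground-truth `nh_params`.
#' @param age_groups data.frame(age_low, age_high); default 5-year groups
#'   40-85.
#' @param person_years_per_group Registry person-years per age group.
#' @param noise Apply Poisson noise to case counts?
#' @param n_sim Cohort size used to tabulate model rates.
#' @param background [background_screening()] configuration in force when
#'   the registry data were "observed".
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 20140601,
                             life_table_params = list(makeham = 8e-4,
                                                      gompertz_b = 3e-5,
                                                      gompertz_theta = 0.092),
                             true_natural_history = nh_params(),
                             age_groups = data.frame(
                               age_low = seq(40, 80, 5),
                               age_high = seq(45, 85, 5)),
                             person_years_per_group = 1e7,
                             noise = TRUE,
                             n_sim = 2e5,
                             background = background_screening()) {
  stopifnot(all(person_years_per_group > 0))
  structure(list(seed = seed, life_table_params = life_table_params,
                 true_natural_history = true_natural_history,
                 age_groups = age_groups,
                 person_years_per_group = person_years_per_group,
                 noise = noise, n_sim = n_sim, background = background),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @param config A `synthetic_config`.
#' @return For `synthetic_life_table`, a `life_table` built from the
#'   configured Gompertz-Makeham coefficients.
#' @export
synthetic_life_table <- function(config = synthetic_config()) {
  lp <- config$life_table_params
  make_life_table(lp$makeham, lp$gompertz_b, lp$gompertz_theta)
}

#' Generate registry-style calibration and validation targets
#'
#' Simulates a large cohort from the configured ground-truth parameters
#' under background DRE screening, tabulates age-group incidence, grade
#' proportions and cancer mortality, rescales counts to the configured
#' registry person-years, and (optionally) adds Poisson sampling noise to
#' the case counts. The generating truth is attached as an attribute so
#' parameter-recovery experiments can close the loop.
#'
#' @param config A `synthetic_config`.
#' @return A `calibration_targets` data.frame with an extra
#'   `mortality_cases` column and attributes `truth` (the generating
#'   `nh_params`) and `mortality` (validation table).
#' @export
make_registry_targets <- function(config = synthetic_config()) {
  lt <- synthetic_life_table(config)
  params <- config$true_natural_history
  mr <- simulate_registry_rates(params, config$age_groups, config$background,
                                n_sim = config$n_sim, seed = config$seed,
                                life_table = lt)

  py <- rep_len(config$person_years_per_group, nrow(mr))
  expected <- mr$cases / pmax(mr$person_years, 1) * py
  set.seed(derive_seed(config$seed, "registry_noise"))
  cases <- if (config$noise) stats::rpois(length(expected), expected) else
    round(expected)
  gr <- cbind(mr$n_gs_lt7, mr$n_gs_7, mr$n_gs_gt7)
  p <- gr / pmax(rowSums(gr), 1)

  ## cancer mortality per age group, rescaled to the registry denominators
  mort <- mr$pca_deaths / pmax(mr$person_years, 1)
  mort_cases <- if (config$noise) stats::rpois(length(mort), mort * py) else
    round(mort * py)

  out <- data.frame(
    age_low = mr$age_low, age_high = mr$age_high,
    cases = cases, person_years = py,
    p_gs_lt7 = p[, 1], p_gs_7 = p[, 2], p_gs_gt7 = p[, 3],
    mortality_cases = mort_cases
  )
  ## degenerate groups with no diagnoses keep a uniform grade mix
  empty <- rowSums(gr) == 0
  out[empty, c("p_gs_lt7", "p_gs_7", "p_gs_gt7")] <- 1 / 3
  out <- calibration_targets(out)
  attr(out, "truth") <- params
  attr(out, "mortality") <- data.frame(
    age_low = mr$age_low, age_high = mr$age_high,
    cases = mort_cases, person_years = py
  )
  out
}
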