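#' Deterministic scenario specification
#'
#' A named set of overrides, each a dotted configuration path mapped to a
#' replacement value; paths must resolve against the base configuration.
#'
#' @param name Scenario label.
#' @param overrides Named list: path -> value.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = list()) {
  structure(list(name = name, overrides = overrides), class = "scenario_spec")
}

#' Shipped deterministic-sensitivity scenarios
#'
#' The preset scenario set: reduced MRI cost (120 euros per scan, scenario
#' 1); no rescreening below 1.5 ng/mL with a 4 ng/mL biopsy threshold
#' (scenario 2) or with the 3 ng/mL threshold kept (scenario 3); discount
#' rates of 0 and 5 percent; the EQ-5D utility swap; DRE stopping at 70;
#' MRI cost halved; raised androgen-deprivation/chemotherapy costs; and
#' low/high participation variants.
#'
#' @return Named list of `scenario_spec` objects.
#' @export
scenario_presets <- function() {
  list(
    base = scenario_spec("base"),
    scenario1_mri_120 = scenario_spec("scenario1_mri_120",
                                      list(costs.mri = 120)),
    scenario2_threshold4_no_low_rescreen = scenario_spec(
      "scenario2_threshold4_no_low_rescreen",
      list(screening.psa_low_band_interval = Inf,
           screening.psa_workup_threshold = 4)),
    scenario3_no_low_rescreen = scenario_spec(
      "scenario3_no_low_rescreen",
      list(screening.psa_low_band_interval = Inf)),
    discount_0 = scenario_spec("discount_0", list(discount_rate = 0)),
    discount_5 = scenario_spec("discount_5", list(discount_rate = 0.05)),
    eq5d_utilities = scenario_spec("eq5d_utilities",
                                   list(utility_set = "eq5d")),
    dre_stop_70 = scenario_spec("dre_stop_70",
                                list(screening.dre_stop_age = 70)),
    mri_cost_half = scenario_spec("mri_cost_half", list(costs.mri = 250)),
    adt_chemo_high = scenario_spec("adt_chemo_high",
                                   list(costs.adt_chemo_per_year = 15000)),
    participation_low = scenario_spec(
      "participation_low",
      list(participation.first_screen = 0.5, participation.rescreen = 0.8,
           participation.biopsy = 0.5)),
    participation_high = scenario_spec(
      "participation_high",
      list(participation.first_screen = 1, participation.rescreen = 1,
           participation.biopsy = 1))
  )
}

apply_scenario <- function(config, scenario) {
  for (p in names(scenario$overrides)) {
    config <- set_config_path(config, p, scenario$overrides[[p]])
  }
  config
}

#' Run the deterministic sensitivity analysis
#'
#' Evaluates every scenario on the same simulated cohort (common random
#' numbers), so outcome differences between a scenario and the base case
#' are attributable purely to the overridden parameters; scenarios that
#' touch only costs or utilities leave every count outcome bit-identical.
#'
#' @param base_config A `run_config`.
#' @param scenarios list of `scenario_spec`s (default: the shipped
#'   presets).
#' @return data.frame of per-100,000 outcomes with a `scenario` column.
#' @export
run_dsa <- function(base_config = run_config(),
                    scenarios = scenario_presets()) {
  cohort <- simulate_cohort(base_config$nh, config_life_table(base_config),
                            base_config$n_persons, base_config$master_seed)
  out <- lapply(scenarios, function(sc) {
    cfg <- apply_scenario(base_config, sc)
    res <- run_strategies(cfg, cohort = cohort)
    cbind(scenario = sc$name, res$outcomes, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sampling distributions for the probabilistic sensitivity analysis
#'
#' Beta distributions for probabilities and utilities, gamma for costs,
#' parameterized by mean and coefficient of variation. The means are the
#' base-case values; the spreads are documented assumptions informed by
#' the deterministic ranges where available.
#'
#' @return list of parameter entries (`path`, `dist`, `mean`, `cv`).
#' @export
psa_distributions_default <- function() {
  par <- function(path, dist, mean, cv) list(path = path, dist = dist,
                                             mean = mean, cv = cv)
  list(
    par("costs.mri", "gamma", 500, 0.2),
    par("costs.psa_test", "gamma", 25.61, 0.1),
    par("costs.biopsy_systematic", "gamma", 650, 0.2),
    par("costs.biopsy_combined", "gamma", 1250, 0.2),
    par("costs.radical_treatment", "gamma", 9000, 0.2),
    par("costs.adt_chemo_per_year", "gamma", 5000, 0.2),
    par("costs.palliative_per_year", "gamma", 20000, 0.2),
    par("participation.first_screen", "beta", 0.75, 0.10),
    par("participation.rescreen", "beta", 0.95, 0.03),
    par("participation.biopsy", "beta", 0.65, 0.10),
    par("tests.dre.sensitivity", "beta", 0.55, 0.10),
    par("tests.dre.specificity", "beta", 0.92, 0.02),
    par("tests.mri.sens_significant", "beta", 0.90, 0.04),
    par("tests.mri.sens_insignificant", "beta", 0.45, 0.10),
    par("tests.mri.specificity", "beta", 0.75, 0.05),
    par("state_utilities.biopsy", "beta", 0.90, 0.03),
    par("state_utilities.diagnosis", "beta", 0.80, 0.05),
    par("state_utilities.as", "beta", 0.97, 0.01),
    par("state_utilities.radical_tx", "beta", 0.75, 0.05),
    par("state_utilities.post_tx", "beta", 0.95, 0.02),
    par("state_utilities.met", "beta", 0.80, 0.05),
    par("state_utilities.terminal", "beta", 0.40, 0.10)
  )
}

draw_psa_param <- function(entry) {
  m <- entry$mean
  s <- entry$cv * m
  if (s == 0) return(m)
  if (entry$dist == "beta") {
    v <- s^2
    if (v >= m * (1 - m)) stop("beta variance too large for mean ", m,
                               call. = FALSE)
    k <- m * (1 - m) / v - 1
    stats::rbeta(1, m * k, (1 - m) * k)
  } else if (entry$dist == "gamma") {
    shape <- 1 / entry$cv^2
    stats::rgamma(1, shape = shape, scale = m / shape)
  } else {
    stop("unknown distribution '", entry$dist, "'", call. = FALSE)
  }
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws one joint parameter set per iteration (test characteristics,
#' participation, costs, health-state utilities -- natural-history
#' parameters stay fixed), reruns every strategy on a shared cohort, and
#' records the discounted per-person cost and QALYs. The reference
#' configuration in the source analysis is 1000 iterations of one million
#' men; the default here is a desk-scale reduction, configurable upward.
#'
#' @param base_config A `run_config`.
#' @param dists Parameter entries (see [psa_distributions_default()]).
#' @param n_iter Number of iterations.
#' @param cohort_n Cohort size per iteration.
#' @param seed Seed for the parameter draws.
#' @param wtp_grid Willingness-to-pay grid (euros per QALY) for the CEAC.
#' @return list(`draws` data.frame (iteration, strategy, cost, effect),
#'   `ceac` data.frame from [ceac_from_draws()]).
#' @export
run_probabilistic <- function(base_config = run_config(),
                              dists = psa_distributions_default(),
                              n_iter = 200, cohort_n = 1e5, seed = 1,
                              wtp_grid = seq(0, 450000, by = 25000)) {
  stopifnot(n_iter >= 1)
  cfg0 <- base_config
  cfg0$n_persons <- cohort_n
  cohort <- simulate_cohort(cfg0$nh, config_life_table(cfg0), cohort_n,
                            cfg0$master_seed)
  draws <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(derive_seed(seed, "psa_iteration", i))
    cfg <- cfg0
    for (entry in dists) {
      cfg <- set_config_path(cfg, entry$path, draw_psa_param(entry))
    }
    res <- run_strategies(cfg, cohort = cohort)
    draws[[i]] <- data.frame(
      iteration = i,
      strategy = res$outcomes$strategy,
      cost = res$outcomes$cost_disc_meur * 1e6 / 1e5,   # euros per person
      effect = res$outcomes$qaly_disc / 1e5,            # QALYs per person
      stringsAsFactors = FALSE
    )
  }
  draws <- do.call(rbind, draws)
  list(draws = draws, ceac = ceac_from_draws(draws, wtp_grid))
}
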