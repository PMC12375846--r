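#' Assemble a full analysis configuration
#'
#' The declarative configuration driving the whole pipeline: cohort size
#' and master seed, the strategy set, natural-history parameters, life
#' table coefficients, test profiles, participation rates, unit costs,
#' utility set and discount rate, plus the screening-policy knobs the
#' scenario analyses move (low-risk rescreen interval, biopsy threshold,
#' DRE stopping age).
#'
#' @param strategies Character preset names (see [list_strategy_presets()])
#'   or `strategy_definition` objects.
#' @param n_persons Cohort size.
#' @param master_seed Master seed; spawns all substreams.
#' @param discount_rate Annual discount rate.
#' @param costs `cost_schedule` (as list).
#' @param utility_set `"porpus_u"` or `"eq5d"`.
#' @param state_utilities Named list of health-state utilities overriding
#'   the PORPUS-U defaults (used by the probabilistic analysis).
#' @param tests Test profiles.
#' @param participation Named list `first_screen`, `rescreen`, `biopsy`.
#' @param nh `nh_params`.
#' @param life_table_params Gompertz-Makeham coefficients.
#' @param screening list(psa_low_band_interval, psa_workup_threshold,
#'   dre_stop_age) applied to the presets.
#' @return list of class `run_config`.
#' @export
run_config <- function(strategies = list_strategy_presets(),
                       n_persons = 1e4, master_seed = 1,
                       discount_rate = 0.03,
                       costs = cost_schedule(),
                       utility_set = "porpus_u",
                       state_utilities = as.list(stats::setNames(
                         utility_inputs("porpus_u")$states$utility,
                         utility_inputs("porpus_u")$states$state)),
                       tests = default_test_profiles(),
                       participation = list(first_screen = 0.75,
                                            rescreen = 0.95, biopsy = 0.65),
                       nh = nh_params(),
                       life_table_params = list(makeham = 8e-4,
                                                gompertz_b = 3e-5,
                                                gompertz_theta = 0.092),
                       screening = list(psa_low_band_interval = 5,
                                        psa_workup_threshold = 3,
                                        dre_stop_age = 75)) {
  stopifnot(n_persons >= 1)
  structure(list(strategies = strategies, n_persons = n_persons,
                 master_seed = master_seed, discount_rate = discount_rate,
                 costs = costs, utility_set = utility_set,
                 state_utilities = state_utilities, tests = tests,
                 participation = participation, nh = nh,
                 life_table_params = life_table_params,
                 screening = screening),
            class = "run_config")
}

materialize_strategy <- function(x, config) {
  st <- if (inherits(x, "strategy_definition")) x else strategy_preset(x)
  st$participation <- c(first_screen = config$participation$first_screen,
                        rescreen = config$participation$rescreen,
                        biopsy = config$participation$biopsy)
  sc <- config$screening
  if (st$primary_test == "psa") {
    st$risk_bands$interval_years[1] <- sc$psa_low_band_interval
    st$risk_bands$upper[2] <- sc$psa_workup_threshold
    st$workup_threshold <- sc$psa_workup_threshold
  }
  if (st$primary_test == "dre") st$stop_age <- sc$dre_stop_age
  st
}

materialize_utilities <- function(config) {
  u <- utility_inputs(config$utility_set)
  if (config$utility_set == "porpus_u" && length(config$state_utilities)) {
    i <- match(names(config$state_utilities), u$states$state)
    u$states$utility[i[!is.na(i)]] <-
      unlist(config$state_utilities)[!is.na(i)]
  }
  u
}

config_life_table <- function(config) {
  lp <- config$life_table_params
  make_life_table(lp$makeham, lp$gompertz_b, lp$gompertz_theta)
}

#' Simulate, screen and cost one strategy on a shared cohort
#'
#' @param cohort An `nh_cohort` from [simulate_cohort()].
#' @param strategy Strategy name or `strategy_definition`.
#' @param config A `run_config`.
#' @return A `screened_cohort` with an `economics` per-person table
#'   attached.
#' @export
run_strategy <- function(cohort, strategy, config = run_config()) {
  st <- materialize_strategy(strategy, config)
  screened <- run_screening_cohort(cohort, st, config$tests)
  screened$economics <- compute_economics(
    screened, do.call(cost_schedule, config$costs),
    materialize_utilities(config), config$discount_rate)
  screened
}

#' Run all configured strategies on one shared cohort
#'
#' Simulates the cohort once from the master seed, applies every strategy
#' under common random numbers, and summarizes each to a per-100,000
#' outcome row.
#'
#' @param config A `run_config`.
#' @param cohort Optional pre-simulated `nh_cohort` (reused across
#'   scenario evaluations).
#' @param keep_results Keep the per-strategy `screened_cohort` objects?
#' @return list(`outcomes` data.frame, `results` (optional), `cohort`).
#' @export
run_strategies <- function(config, cohort = NULL, keep_results = FALSE) {
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$nh, config_life_table(config),
                              config$n_persons, config$master_seed)
  }
  results <- lapply(config$strategies, run_strategy,
                    cohort = cohort, config = config)
  outcomes <- do.call(rbind, lapply(results, summarize_per_100k))
  rownames(outcomes) <- NULL
  list(outcomes = outcomes,
       results = if (keep_results) results else NULL,
       cohort = cohort)
}

#' Execute the full comparison pipeline and write results to disk
#'
#' Runs simulate -> screen -> economics -> summarize -> frontier for every
#' configured strategy on a shared cohort, then writes the per-100,000
#' outcome table (CSV), the efficiency frontiers per effect measure
#' (JSON), and a run manifest carrying the master seed and a configuration
#' checksum, so any run can be reproduced exactly.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, list(outcomes, frontiers, paths).
#' @export
run_compare <- function(config = run_config(), out_dir = "results") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("simulating cohort of ", config$n_persons, " men (seed ",
          config$master_seed, ")")
  run <- run_strategies(config)
  message("screening complete for ", nrow(run$outcomes), " strategies")
  out <- run$outcomes

  frontiers <- list(
    qaly = efficiency_frontier(out, "qaly_disc", "cost_disc_meur"),
    ly = efficiency_frontier(out, "ly_disc", "cost_disc_meur")
  )
  out$deaths_averted <- max(out$n_pca_deaths) - out$n_pca_deaths
  frontiers$deaths <- efficiency_frontier(out, "deaths_averted",
                                          "cost_disc_meur")

  paths <- list(
    outcomes = file.path(out_dir, "outcomes.csv"),
    frontier = file.path(out_dir, "frontier.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(out, paths$outcomes, row.names = FALSE)
  jsonlite::write_json(
    lapply(frontiers, function(f) list(efficient = f$efficient,
                                       dominated = f$dominated)),
    paths$frontier, dataframe = "rows", auto_unbox = TRUE, digits = NA,
    na = "null")
  manifest <- list(master_seed = config$master_seed,
                   n_persons = config$n_persons,
                   config_checksum = config_checksum(config),
                   package_version = as.character(
                     utils::packageVersion("prostascreen")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  message("results written to ", normalizePath(out_dir))
  invisible(list(outcomes = out, frontiers = frontiers, paths = paths))
}

config_checksum <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% 2^31
}
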