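# Shared fixtures: everything is generated in code at test time.

default_lt <- make_life_table()

# one small shared cohort reused by cheap tests
fixture_cohort <- local({
  co <- NULL
  function(n = 3000, seed = 42) {
    if (is.null(co) || co$n != n || co$seed != seed) {
      co <<- simulate_cohort(nh_params(), default_lt, n, seed)
    }
    co
  }
})

run_and_summarize <- function(cohort, strategy_name, config = run_config()) {
  res <- run_strategy(cohort, strategy_name, config)
  summarize_per_100k(res)
}

# Published per-100,000 outcome counts (screening strategies only where the
# row applies); used by the comparison-arithmetic and conservation checks.
printed_counts <- function() {
  data.frame(
    strategy = c("psa_ras_50_60_nomri", "no_screening", "psa_ras_45_60_nomri",
                 "psa_ras_50_60_mri", "psa_ras_50_70_nomri", "psa_ras_45_60_mri",
                 "psa_ras_45_70_nomri", "psa_ras_50_70_mri", "psa_ras_45_70_mri",
                 "dre_45_75"),
    biopsies_total = c(29235, 19672, 28965, 20714, 62169, 20701, 60230,
                       26069, 25792, 161126),
    biopsies_clinical = c(16508, 19672, 16683, 17312, 12985, 17437, 13334,
                          14073, 14365, 10001),
    biopsies_screen = c(12727, NA, 12282, 3402, 49184, 3264, 46897, 11995,
                        11427, 151125),
    dx_total = c(10788, 10474, 10771, 10675, 11714, 10665, 11654, 11377,
                 11330, 12942),
    dx_clinical = c(8805, 10474, 8897, 9223, 6930, 9289, 7115, 7492, 7647,
                    5329),
    dx_screen = c(1983, 0, 1874, 1452, 4784, 1376, 4539, 3885, 3683, 7613),
    overdiagnosed = c(314, NA, 297, 202, 1240, 191, 1180, 903, 857, 2468),
    stringsAsFactors = FALSE
  )
}

# Published incremental (QALY, cost in millions) pairs vs no screening
printed_panel_c <- function() {
  data.frame(
    strategy = c("psa_ras_50_60_nomri", "no_screening", "psa_ras_45_60_nomri",
                 "psa_ras_50_60_mri", "psa_ras_50_70_nomri", "psa_ras_45_60_mri",
                 "psa_ras_45_70_nomri", "psa_ras_50_70_mri", "psa_ras_45_70_mri",
                 "dre_45_75"),
    deaths_averted = c(335, 0, 321, 248, 647, 240, 616, 540, 514, 939),
    ly = c(1430, 0, 1392, 1134, 2252, 1117, 2174, 1938, 1877, 3019),
    qaly = c(820, 0, 793, 708, 915, 692, 884, 961, 931, 456),
    cost = c(-1.2, 0, 1.9, 4.1, 6.5, 7.1, 9.3, 20.0, 22.3, 37.4),
    stringsAsFactors = FALSE
  )
}

# Independent greedy (gift-wrapping) frontier construction used as the
# oracle against the package's sequential-deletion implementation.
frontier_oracle <- function(d) {
  d <- d[order(d$cost, -d$effect, d$strategy), ]
  cur <- 1L
  eff_set <- d$strategy[1]
  repeat {
    cand <- which(d$effect > d$effect[cur] + 1e-12)
    if (!length(cand)) break
    icer <- (d$cost[cand] - d$cost[cur]) / (d$effect[cand] - d$effect[cur])
    best <- cand[order(icer, -d$effect[cand])][1]
    eff_set <- c(eff_set, d$strategy[best])
    cur <- best
  }
  sort(eff_set)
}
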