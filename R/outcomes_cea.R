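#' Overdiagnosis flag for a life history
#'
#' A screen-detected cancer is overdiagnosed when it would never have been
#' clinically diagnosed in the man's lifetime without screening: either no
#' counterfactual clinical diagnosis exists at all, or other-cause death
#' precedes it.
#'
#' @param history A `life_history` (or any list with `dx_mode`,
#'   `counterfactual_clinical_dx_age`, `other_cause_death_age`).
#' @return Logical flag.
#' @export
count_overdiagnosis <- function(history) {
  if (!identical(history$dx_mode, "screen")) return(FALSE)
  cf <- history$counterfactual_clinical_dx_age
  is.na(cf) || history$other_cause_death_age < cf
}

#' Per-100,000 strategy outcome table
#'
#' Scales person-level counts, life-years, QALYs and costs to a cohort of
#' 100,000 men. Event counts split screen-initiated from
#' clinically-initiated resource use (active-surveillance biopsies count
#' as clinically-initiated); diagnoses are stratified into localized
#' GS<7 / GS=7 / GS>7 and metastatic. Costs are reported in millions of
#' euros.
#'
#' @param strategy_result A `screened_cohort` with an `economics`
#'   component, as produced by [run_strategy()], or a list with `persons`,
#'   `events`, `economics` and `n`.
#' @param scale_n Reporting denominator (persons).
#' @return One-row data.frame of class `strategy_outcome`.
#' @export
summarize_per_100k <- function(strategy_result, scale_n = 1e5) {
  persons <- strategy_result$persons
  events <- strategy_result$events
  econ <- strategy_result$economics
  n <- strategy_result$n
  if (is.null(persons) || n < 1) stop("empty person results", call. = FALSE)
  f <- scale_n / n
  cnt <- function(x) sum(x, na.rm = TRUE) * f

  is_bx <- events$event == "biopsy"
  bx_screen <- is_bx & events$origin == "screen"
  bx_clin <- is_bx & events$origin %in% c("clinical", "as")
  dx_screen <- persons$dx_mode == "screen"
  dx_clin <- persons$dx_mode == "clinical"
  dxd <- dx_screen | dx_clin
  loc <- dxd & !is.na(persons$dx_met) & !persons$dx_met

  out <- data.frame(
    strategy = strategy_result$strategy$name %||% NA_character_,
    n_psa_tests = cnt(events$event == "psa_test"),
    n_dre_tests = cnt(events$event == "dre_test"),
    n_mri = cnt(events$event == "mri" & events$origin == "screen"),
    n_biopsies_total = cnt(bx_screen | bx_clin),
    n_biopsies_screen = cnt(bx_screen),
    n_biopsies_clinical = cnt(bx_clin),
    n_dx_total = cnt(dxd),
    n_dx_screen = cnt(dx_screen),
    n_dx_clinical = cnt(dx_clin),
    n_dx_localized_gs_lt7 = cnt(loc & persons$grade == 1L),
    n_dx_localized_gs_7 = cnt(loc & persons$grade == 2L),
    n_dx_localized_gs_gt7 = cnt(loc & persons$grade == 3L),
    n_dx_metastatic = cnt(dxd & !is.na(persons$dx_met) & persons$dx_met),
    n_overdiagnosed = cnt(persons$overdiagnosed),
    n_pca_deaths = cnt(persons$pca_death),
    ly_undisc = mean(econ$ly_undisc) * scale_n,
    ly_disc = mean(econ$ly_disc) * scale_n,
    qaly_undisc = mean(econ$qaly_undisc) * scale_n,
    qaly_disc = mean(econ$qaly_disc) * scale_n,
    cost_undisc_meur = mean(econ$cost_undisc) * scale_n / 1e6,
    cost_disc_meur = mean(econ$cost_disc) * scale_n / 1e6,
    stringsAsFactors = FALSE
  )
  class(out) <- c("strategy_outcome", "data.frame")
  out
}

#' Absolute and percentage reduction versus a reference strategy
#'
#' The table convention: reduction = reference minus comparator, with the
#' percentage rounded half-away-from-zero to an integer.
#'
#' @param outcome,reference_outcome `strategy_outcome` rows (or any lists
#'   with the named field).
#' @param field Outcome field to compare (e.g. `"n_biopsies_screen"`).
#' @return list(absolute, percent); `percent` is `NA` for a zero
#'   reference.
#' @export
reduction_vs_reference <- function(outcome, reference_outcome, field) {
  x <- outcome[[field]]
  ref <- reference_outcome[[field]]
  absolute <- ref - x
  percent <- if (isTRUE(ref == 0)) NA_real_ else
    round_half_away(100 * absolute / ref)
  list(absolute = absolute, percent = percent)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Efficiency frontier with incremental cost-effectiveness ratios
#'
#' Removes strictly dominated strategies (at least as costly and no more
#' effective than another) and extended-dominated strategies (whose
#' incremental cost-effectiveness ratio exceeds that of a later, more
#' effective strategy), then reports the efficient set ordered by effect
#' with pairwise ICERs. The least costly strategy anchors the frontier.
#' Ties in effect are broken by lower cost; exact ties collapse to one
#' representative.
#'
#' @param outcomes data.frame with one row per strategy (needs a
#'   `strategy` column) or a list of `strategy_outcome` rows.
#' @param effect_field,cost_field Column names of the effect and cost
#'   measures.
#' @return list of class `frontier_result`: `efficient` data.frame
#'   (strategy, effect, cost, icer), `dominated` data.frame (strategy,
#'   label in strictly_dominated / extended_dominated).
#' @export
efficiency_frontier <- function(outcomes, effect_field = "qaly_disc",
                                cost_field = "cost_disc_meur") {
  if (!is.data.frame(outcomes)) outcomes <- do.call(rbind, outcomes)
  if (nrow(outcomes) < 2) stop("need at least 2 strategies", call. = FALSE)
  d <- data.frame(strategy = outcomes$strategy,
                  effect = outcomes[[effect_field]],
                  cost = outcomes[[cost_field]],
                  stringsAsFactors = FALSE)
  d <- d[order(d$effect, d$cost, d$strategy), ]
  ## collapse exact ties to one representative
  dup <- duplicated(d[c("effect", "cost")])
  dominated <- data.frame(strategy = d$strategy[dup],
                          label = rep("strictly_dominated", sum(dup)),
                          stringsAsFactors = FALSE)
  d <- d[!dup, ]

  ## strict dominance: another strategy costs no more and is at least as
  ## effective (and differs)
  strict <- vapply(seq_len(nrow(d)), function(i) {
    any(d$cost <= d$cost[i] & d$effect >= d$effect[i] &
          (d$cost < d$cost[i] | d$effect > d$effect[i]))
  }, TRUE)
  dominated <- rbind(dominated,
                     data.frame(strategy = d$strategy[strict],
                                label = rep("strictly_dominated", sum(strict)),
                                stringsAsFactors = FALSE))
  d <- d[!strict, ]

  ## extended dominance: after ordering by effect, ICERs must be strictly
  ## increasing along the frontier
  repeat {
    if (nrow(d) < 3) break
    icer <- c(NA, diff(d$cost) / diff(d$effect))
    drop <- which(diff(icer[-1]) <= 0)  # icer[i+1] <= icer[i]
    if (!length(drop)) break
    i <- drop[1] + 1L  # the strategy whose ICER is not justified
    dominated <- rbind(dominated,
                       data.frame(strategy = d$strategy[i],
                                  label = "extended_dominated",
                                  stringsAsFactors = FALSE))
    d <- d[-i, ]
  }
  icer <- c(NA, diff(d$cost) / diff(d$effect))
  d$icer <- icer
  rownames(d) <- NULL
  structure(list(efficient = d, dominated = dominated,
                 effect_field = effect_field, cost_field = cost_field),
            class = "frontier_result")
}

#' Cost-effectiveness acceptability curves from probabilistic draws
#'
#' For each willingness-to-pay threshold, the probability (across
#' iterations) that each strategy maximizes net monetary benefit
#' \eqn{\lambda \cdot effect - cost}; ties within an iteration are split
#' equally.
#'
#' @param psa_draws data.frame with columns `iteration`, `strategy`,
#'   `cost`, `effect`.
#' @param wtp_grid Numeric willingness-to-pay thresholds (same units as
#'   `cost` per unit `effect`).
#' @return data.frame (`wtp`, `strategy`, `probability`); probabilities at
#'   each threshold sum to 1.
#' @export
ceac_from_draws <- function(psa_draws, wtp_grid) {
  if (!length(wtp_grid)) stop("empty willingness-to-pay grid", call. = FALSE)
  strategies <- unique(psa_draws$strategy)
  if (length(strategies) < 2 || !nrow(psa_draws)) {
    stop("need >= 2 strategies and >= 1 iteration", call. = FALSE)
  }
  iters <- unique(psa_draws$iteration)
  eff <- matrix(NA_real_, length(iters), length(strategies),
                dimnames = list(NULL, strategies))
  cst <- eff
  ii <- match(psa_draws$iteration, iters)
  jj <- match(psa_draws$strategy, strategies)
  eff[cbind(ii, jj)] <- psa_draws$effect
  cst[cbind(ii, jj)] <- psa_draws$cost
  out <- lapply(wtp_grid, function(lambda) {
    nmb <- lambda * eff - cst
    best <- nmb == apply(nmb, 1, max)
    p <- colMeans(best / rowSums(best))
    data.frame(wtp = lambda, strategy = strategies, probability = unname(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
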