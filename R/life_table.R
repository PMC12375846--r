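#' Construct a synthetic Gompertz-Makeham life table
#'
#' Generates an all-cause male life table on ages 35-105 with hazard
#' \eqn{\mu(x) = A + B e^{\theta x}}: a constant (Makeham) background term
#' plus an exponentially age-increasing (Gompertz) senescent term. The
#' default coefficients give a remaining life expectancy at age 45 of about
#' 34-35 years, in line with a contemporary German male cohort.
#'
#' @param makeham Constant hazard component (per person-year).
#' @param gompertz_b Gompertz scale coefficient.
#' @param gompertz_theta Gompertz log-slope per year of age.
#' @param ages Integer ages covered (half-open intervals `[a, a+1)`).
#' @return A data.frame with columns `age`, `mortality_rate`, of class
#'   `life_table`.
#' @export
make_life_table <- function(makeham = 8e-4, gompertz_b = 3e-5,
                            gompertz_theta = 0.092, ages = 35:105) {
  assert_nonneg(c(makeham, gompertz_b, gompertz_theta), "life table coefficients")
  lt <- data.frame(
    age = as.integer(ages),
    mortality_rate = makeham + gompertz_b * exp(gompertz_theta * ages)
  )
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Read / write a life table CSV
#'
#' The on-disk schema is `age, mortality_rate` with rates per person-year on
#' half-open one-year age intervals.
#'
#' @param path CSV file path.
#' @return `read_life_table` returns a validated `life_table` data.frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  validate_life_table(lt)
}

#' @rdname read_life_table
#' @param life_table A `life_table` data.frame.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table)[c("age", "mortality_rate")],
                   path, row.names = FALSE)
  invisible(path)
}

validate_life_table <- function(lt, min_age = 35, max_age = 105) {
  if (!all(c("age", "mortality_rate") %in% names(lt))) {
    stop("life table must have columns 'age' and 'mortality_rate'", call. = FALSE)
  }
  lt <- lt[order(lt$age), , drop = FALSE]
  if (min(lt$age) > min_age || max(lt$age) < max_age - 1) {
    stop(sprintf("life table must cover ages %d-%d", min_age, max_age), call. = FALSE)
  }
  assert_nonneg(lt$mortality_rate, "mortality_rate")
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Draw death ages from a life table by piecewise-exponential inversion
#'
#' Treats the annual mortality rates as a piecewise-constant hazard and
#' inverts the cumulative hazard at the supplied uniforms. Ages are
#' continuous; draws exceeding the table support are administratively
#' censored at the last covered age.
#'
#' @param life_table A `life_table` data.frame.
#' @param u Uniform(0,1) draws, one per person.
#' @param start_age Age at which persons are known alive.
#' @return Numeric death ages.
#' @export
draw_death_age <- function(life_table, u, start_age = 35) {
  lt <- life_table[life_table$age >= start_age, , drop = FALSE]
  rates <- lt$mortality_rate
  ages <- lt$age
  cumhaz <- c(0, cumsum(rates))
  e <- -log(1 - u)
  idx <- findInterval(e, cumhaz, rightmost.closed = FALSE)
  idx <- pmin(idx, length(rates))
  age <- ages[idx] + (e - cumhaz[idx]) / rates[idx]
  pmin(age, max(ages) + 1)
}

#' Remaining life expectancy implied by a life table
#'
#' Numerically integrates the piecewise-exponential survival curve.
#'
#' @inheritParams draw_death_age
#' @param at_age Conditioning age.
#' @return Expected years of life remaining at `at_age`.
#' @export
life_expectancy <- function(life_table, at_age = 45) {
  lt <- life_table[life_table$age >= at_age, , drop = FALSE]
  rates <- lt$mortality_rate
  surv_start <- exp(-c(0, cumsum(rates)))
  # integral of exp(-r t) over each 1-year piece, weighted by survival to
  # the piece start
  piece <- (1 - exp(-rates)) / rates
  sum(surv_start[seq_along(rates)] * piece)
}
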