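#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with a purpose label and an integer id so that each
#' simulation component (cohort draws, screening noise, calibration
#' evaluations, probabilistic-sensitivity iterations) uses an independent but
#' reproducible random stream. The result is always a valid 32-bit integer
#' seed.
#'
#' @param master_seed Integer master seed.
#' @param purpose Character label of the consuming component.
#' @param id Optional integer sub-index (e.g. person id or iteration).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, purpose = "default", id = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, is.finite(master_seed))
  h <- sum(utf8ToInt(as.character(purpose)) * (seq_along(utf8ToInt(as.character(purpose))) %% 31 + 1))
  # double-precision arithmetic stays exact below 2^53
  x <- (abs(master_seed) * 48271 + h * 69621 + abs(id) * 16807) %% (2^31 - 3)
  as.integer(x + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be non-negative and finite", name), call. = FALSE)
  }
  invisible(x)
}

#' Set a nested configuration value by dotted path
#'
#' Used by the scenario machinery: `"costs.mri"` resolves to
#' `config$costs$mri`. Errors if the path does not resolve against the
#' existing configuration, so scenario typos are caught before any
#' simulation runs.
#'
#' @param config A nested list.
#' @param path Dotted character path.
#' @param value Replacement value.
#' @return The modified list.
#' @export
set_config_path <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- config
  for (k in keys) {
    if (is.null(ref[[k]])) {
      stop(sprintf("override path '%s' does not resolve (missing '%s')", path, k),
           call. = FALSE)
    }
    ref <- ref[[k]]
  }
  config[[keys]] <- value
  config
}

get_config_path <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- config
  for (k in keys) ref <- ref[[k]]
  ref
}
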