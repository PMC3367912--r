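# Internal helpers: error classes, seeding, rounding conventions.

config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("oscmeg_config_error", "oscmeg_error")))
}

data_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("oscmeg_data_error", "oscmeg_error")))
}

estimation_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("oscmeg_estimation_error", "oscmeg_error")))
}

numerical_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("oscmeg_numerical_error", "oscmeg_error")))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores the
#' prior RNG state afterwards, so seeded internals never disturb a caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (base round() is round-half-even).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Deterministic seed fan-out: derive a sub-seed from a master seed and a
# stage/subject tag. Arithmetic stays below 2^31 and within double precision.
derive_seed <- function(master, stage, unit = 0L) {
  stage_code <- sum(utf8ToInt(as.character(stage))) %% 1000L
  s <- (as.numeric(master) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + stage_code * 10007 + as.numeric(unit) * 97 + 1) %% 2147483629)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
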