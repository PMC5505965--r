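#' Environment schedule and phenotype-to-fitness maps
#'
#' In the constant regime fitness simply equals phenotype. In the periodic
#' regime two environments, E1 and E2, alternate deterministically every
#' `period_n` generations (so each environment is experienced once every
#' `2 * period_n` generations). Fitness in E1 is the identity map
#' \eqn{f^1(x) = x}; fitness in E2 is the reflection around the midpoint m,
#' \eqn{f^2(x) = 2m - x}. The reflection preserves the phenotypic variance
#' and is an involution, so the two alleles keep equal mean fitness in their
#' respective preferred environments.
#'
#' @param regime `"constant"` or `"periodic"`.
#' @param period_n Generations per environment (periodic only), a positive
#'   integer.
#' @param initial_env `"E1"`, `"E2"`, or `"random"` (resolved once per
#'   replicate with probability 1/2 each).
#' @param m Reflection midpoint (periodic only).
#' @return An object of class `"fitness_model"`.
#' @examples
#' fm <- fitness_model("periodic", period_n = 20, initial_env = "E1", m = 0.7)
#' environment_at(fm, t = 40, resolved_initial = "E1")
#' fitness_of(0.9, "E2", fm)
#' @export
fitness_model <- function(regime = c("constant", "periodic"), period_n = NULL,
                          initial_env = c("E1", "E2", "random"), m = NULL) {
  regime <- match.arg(regime)
  initial_env <- match.arg(initial_env)
  if (regime == "periodic") {
    if (is.null(period_n) || !is.numeric(period_n) || period_n < 1 ||
        period_n != round(period_n))
      stop("periodic regime requires a positive integer 'period_n'")
    if (is.null(m) || !is.numeric(m) || !is.finite(m))
      stop("periodic regime requires the reflection midpoint 'm'")
    period_n <- as.integer(period_n)
  } else {
    period_n <- NA_integer_
    m <- NA_real_
  }
  structure(list(regime = regime, period_n = period_n,
                 initial_env = initial_env, m = m),
            class = "fitness_model")
}

#' Environment in effect at a given generation
#'
#' Pure function of the generation index, the period, and the resolved
#' initial environment: generation t lies in block `floor(t / period_n)`,
#' and even blocks carry the initial environment.
#'
#' @param model A periodic [fitness_model()].
#' @param t Generation index (0-based), non-negative.
#' @param resolved_initial `"E1"` or `"E2"`; the initial environment after
#'   any per-replicate randomization has been resolved.
#' @return `"E1"` or `"E2"`.
#' @export
environment_at <- function(model, t, resolved_initial = c("E1", "E2")) {
  stopifnot(inherits(model, "fitness_model"))
  if (model$regime == "constant") stop("no environment schedule")
  resolved_initial <- match.arg(resolved_initial)
  stopifnot(all(t >= 0), all(t == round(t)))
  even <- (floor(t / model$period_n) %% 2) == 0
  other <- if (resolved_initial == "E1") "E2" else "E1"
  ifelse(even, resolved_initial, other)
}

#' Map phenotype to fitness
#'
#' @param phenotype Positive phenotype value(s).
#' @param env `"constant"`, `"E1"` or `"E2"`.
#' @param model A [fitness_model()]; needed (for `m`) when `env = "E2"`.
#' @return Fitness value(s); always strictly positive, otherwise an error
#'   is thrown (the scenario is invalid).
#' @export
fitness_of <- function(phenotype, env = c("constant", "E1", "E2"), model = NULL) {
  env <- match.arg(env)
  w <- if (env == "E2") {
    stopifnot(inherits(model, "fitness_model"), is.finite(model$m))
    2 * model$m - phenotype
  } else {
    phenotype
  }
  if (any(w <= 0)) stop("non-positive fitness")
  w
}

#' @export
print.fitness_model <- function(x, ...) {
  if (x$regime == "constant") {
    cat("Fitness model: constant environment (fitness = phenotype)\n")
  } else {
    cat(sprintf(
      "Fitness model: periodic, n = %d generations per environment,\n  initial environment %s, reflection midpoint m = %g\n",
      x$period_n, x$initial_env, x$m))
  }
  invisible(x)
}
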