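#' Introduce a single plastic mutant into a resident population
#'
#' Builds the generation-0 state: N - 1 residents at the wild-type's fixed
#' phenotype and one invader. For a two-point invader the initial phenotype
#' is the lower or upper support point with probability 1/2 each (or forced
#' to one of them); for a continuous invader it is one fresh draw.
#'
#' If the fitness model's `initial_env` is `"random"`, the replicate's
#' initial environment is resolved here (one coin flip) and stamped on the
#' returned state as attribute `"env0"`.
#'
#' @param cfg A [sim_config()] with `N >= 2`.
#' @param forced_start `"random"` (default), or `"max"`/`"min"` to force a
#'   two-point invader to start at its upper/lower support point.
#' @return An object of class `"wf_population"`: list with `alleles`
#'   (length-N character vector of `"A"`/`"a"`), `phenotypes` (length-N
#'   positive numeric), and `generation` (0).
#' @export
introduce_mutant <- function(cfg, forced_start = c("random", "max", "min")) {
  stopifnot(inherits(cfg, "sim_config"))
  forced_start <- match.arg(forced_start)
  if (cfg$N < 2) stop("N must be >= 2 to introduce a mutant")
  if (forced_start != "random" && cfg$invader$kind != "two_point")
    stop("forced_start applies only to two_point invader distributions")

  env0 <- resolve_initial_env(cfg$fitness)
  phi0 <- switch(forced_start,
                 max = cfg$invader$mean + cfg$invader$sd,
                 min = cfg$invader$mean - cfg$invader$sd,
                 random = draw_phenotype(cfg$invader, 1L))
  state <- structure(
    list(alleles = c("a", rep("A", cfg$N - 1L)),
         phenotypes = c(phi0, rep(cfg$resident$mean, cfg$N - 1L)),
         generation = 0L),
    class = "wf_population")
  attr(state, "env0") <- env0
  state
}

# population fixed for the plastic allele, phenotypes at their stationary
# starting point (iid draws; one shared draw under global memory)
all_plastic_population <- function(cfg) {
  env0 <- resolve_initial_env(cfg$fitness)
  ph <- if (cfg$memory$mode == "global")
    rep(draw_phenotype(cfg$invader, 1L), cfg$N)
  else
    draw_phenotype(cfg$invader, cfg$N)
  state <- structure(
    list(alleles = rep("a", cfg$N), phenotypes = ph, generation = 0L),
    class = "wf_population")
  attr(state, "env0") <- env0
  state
}

#' Count copies of an allele in a population state
#'
#' @param state A `"wf_population"`.
#' @param allele `"a"` (default) or `"A"`.
#' @return Integer count.
#' @export
allele_count <- function(state, allele = "a") sum(state$alleles == allele)

#' Has the population absorbed?
#'
#' @param state A `"wf_population"`.
#' @return `TRUE` if either allele has fixed (the other is lost).
#' @export
is_absorbed <- function(state) {
  k <- allele_count(state, "a")
  k == 0L || k == length(state$alleles)
}

state_to_cpp <- function(state) {
  list(alleles = as.integer(state$alleles == "a"),
       phenotypes = state$phenotypes,
       generation = state$generation)
}

cpp_to_state <- function(res, env0) {
  state <- structure(
    list(alleles = c("A", "a")[res$alleles + 1L],
         phenotypes = res$phenotypes,
         generation = res$generation),
    class = "wf_population")
  attr(state, "env0") <- env0
  state
}

#' Advance the population by one Wright-Fisher generation
#'
#' The environment for the current generation index is determined first,
#' fitness is evaluated for every individual, N parents are sampled with
#' replacement with probability proportional to fitness, and phenotype
#' inheritance (or resampling) is applied to the offspring. Population size
#' is unchanged and the generation counter increments.
#'
#' @param state A `"wf_population"` (from [introduce_mutant()] or a previous
#'   step); must not be absorbed.
#' @param cfg The [sim_config()].
#' @return The next `"wf_population"` state.
#' @export
step_generation <- function(state, cfg) {
  stopifnot(inherits(state, "wf_population"), inherits(cfg, "sim_config"))
  if (is_absorbed(state)) stop("population absorbed")
  s <- state_to_cpp(state)
  env0 <- attr(state, "env0") %||% 0L
  res <- cpp_wf_step(s$alleles, s$phenotypes, s$generation, cpp_cfg(cfg, env0))
  cpp_to_state(res, env0)
}

#' Run a population to absorption
#'
#' Iterates [step_generation()] until the plastic allele fixes or is lost,
#' or until `cfg$max_generations` further generations have elapsed
#' (a discard).
#'
#' @param state A `"wf_population"`.
#' @param cfg The [sim_config()].
#' @return List with `outcome` (`"fixation"`, `"loss"`, or `"discard"`,
#'   from the plastic allele's point of view), `generation` (index at
#'   absorption or cutoff), and `steps` (generations simulated here).
#' @export
run_to_absorption <- function(state, cfg) {
  stopifnot(inherits(state, "wf_population"), inherits(cfg, "sim_config"))
  s <- state_to_cpp(state)
  env0 <- attr(state, "env0") %||% 0L
  res <- cpp_wf_run(s$alleles, s$phenotypes, s$generation, cpp_cfg(cfg, env0))
  list(outcome = c("loss", "fixation", "discard")[res$outcome + 1L],
       generation = res$generation,
       steps = res$steps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wf_population <- function(x, ...) {
  cat(sprintf("Wright-Fisher population: N = %d, generation %d, a-count %d\n",
              length(x$alleles), x$generation, allele_count(x, "a")))
  invisible(x)
}
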