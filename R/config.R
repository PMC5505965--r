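#' Full simulation scenario
#'
#' Bundles population size, the resident and invader phenotype
#' distributions, the memory model, the fitness model, and the Monte Carlo
#' protocol (replicate count, discard cutoff, master seed) into a validated
#' scenario object.
#'
#' Validation rejects scenarios in which any phenotype on either allele's
#' support could map to non-positive fitness under either environment,
#' switching mode with a non-two-point distribution, and periodic regimes
#' missing `period_n` or `m`.
#'
#' @param N Population size (>= 1; most operations require >= 2).
#' @param resident [phenotype_distribution()] of the wild-type allele A;
#'   must be degenerate. A bare number is accepted as shorthand for a
#'   degenerate distribution at that mean.
#' @param invader [phenotype_distribution()] of the plastic allele a.
#' @param memory A [memory_model()].
#' @param fitness A [fitness_model()].
#' @param max_generations Discard cutoff: replicates not absorbed after
#'   this many generations are discarded (default 10000).
#' @param n_replicates Ensemble size for Monte Carlo estimates
#'   (default 10000).
#' @param master_seed Integer master seed; replicate i uses the derived
#'   stream `set.seed((master_seed * 48271 + offset + i) mod 2147483629)`.
#' @param label Optional free-form scenario label.
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(
#'   N = 1000,
#'   resident = 0.8,
#'   invader = phenotype_distribution("two_point", mean = 0.8, sd = 0.1),
#'   memory = memory_model("individual", p = 0.9))
#' @export
sim_config <- function(N, resident, invader,
                       memory = memory_model("individual", p = 0.5),
                       fitness = fitness_model("constant"),
                       max_generations = 10000L, n_replicates = 10000L,
                       master_seed = 1L, label = NULL) {
  if (is.numeric(resident) && length(resident) == 1L)
    resident <- phenotype_distribution("degenerate", mean = resident)
  stopifnot(inherits(resident, "phenotype_distribution"),
            inherits(invader, "phenotype_distribution"),
            inherits(memory, "memory_model"),
            inherits(fitness, "fitness_model"))
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("N must be a positive integer")
  if (resident$kind != "degenerate")
    stop("the resident (wild-type) distribution must be degenerate")
  if (memory$mode == "switching" && invader$kind != "two_point")
    stop("switching mode requires a two_point invader distribution")
  if (max_generations < 1) stop("max_generations must be >= 1")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!is.numeric(master_seed) || master_seed != round(master_seed))
    stop("master_seed must be an integer")

  # all reachable fitness values must be strictly positive
  sup <- c(support(resident), support(invader))
  if (min(sup) <= 0) stop("non-positive fitness on support under E1/constant")
  if (fitness$regime == "periodic" && min(2 * fitness$m - sup) <= 0)
    stop("non-positive fitness on support under E2 (2m - phenotype <= 0)")

  structure(list(N = as.integer(N), resident = resident, invader = invader,
                 memory = memory, fitness = fitness,
                 max_generations = as.integer(max_generations),
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 label = label),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation scenario%s\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'")))
  cat(sprintf("  N = %d, replicates = %d, cutoff = %d generations, seed = %d\n",
              x$N, x$n_replicates, x$max_generations, x$master_seed))
  cat("  resident: "); print(x$resident)
  cat("  invader:  "); print(x$invader)
  cat("  "); print(x$memory)
  cat("  "); print(x$fitness)
  invisible(x)
}

# integer codes shared with the C++ core
mode_code <- c(individual = 0L, global = 1L, switching = 2L)
kind_code <- c(degenerate = 0L, two_point = 1L, uniform = 2L)

# flat list consumed by the C++ functions; env0 is the resolved initial
# environment (0 = E1, 1 = E2)
cpp_cfg <- function(cfg, env0 = 0L) {
  list(N = cfg$N,
       mode = mode_code[[cfg$memory$mode]],
       p = if (is.na(cfg$memory$p)) 0 else cfg$memory$p,
       q = if (is.na(cfg$memory$q)) 0 else cfg$memory$q,
       kind = kind_code[[cfg$invader$kind]],
       mean = cfg$invader$mean,
       sd = cfg$invader$sd,
       phiA = cfg$resident$mean,
       regime = if (cfg$fitness$regime == "periodic") 1L else 0L,
       period_n = if (is.na(cfg$fitness$period_n)) 1L else cfg$fitness$period_n,
       env0 = as.integer(env0),
       m = if (is.na(cfg$fitness$m)) 0 else cfg$fitness$m,
       max_gen = cfg$max_generations)
}

# Per-replicate derived stream: a documented counter-based scheme so that
# replicates are independent and individually reproducible. The master seed
# is scrambled once with the MINSTD multiplier (exact in doubles: the
# product stays below 2^53) so that nearby master seeds yield disjoint
# replicate streams rather than shifted copies of one another; the modulus
# is a prime below 2^31 so derived seeds stay valid R integers.
replicate_seed <- function(master_seed, counter) {
  h <- (as.double(master_seed) * 48271) %% 2147483629
  as.integer((h + as.double(counter)) %% 2147483629)
}

# Resolve the initial environment for one replicate. Must be called after
# the replicate's seed has been set; consumes one uniform draw only when
# initial_env == "random".
resolve_initial_env <- function(fitness) {
  if (fitness$regime == "constant") return(0L)
  switch(fitness$initial_env,
         E1 = 0L, E2 = 1L,
         random = if (stats::runif(1) < 0.5) 0L else 1L)
}
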