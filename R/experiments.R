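#' Monte Carlo fixation estimate
#'
#' Runs `cfg$n_replicates` independent replicates; each introduces a single
#' plastic mutant ([introduce_mutant()]) and simulates to absorption or the
#' discard cutoff. Replicate i uses the derived seed
#' `(master_seed + replicate_offset + i) mod 2147483629`, so any replicate
#' can be re-run in isolation.
#'
#' @param cfg A [sim_config()].
#' @param forced_start Passed to [introduce_mutant()]: `"random"`, `"max"`,
#'   or `"min"`.
#' @param replicate_offset Integer offset added to the replicate counter
#'   before seed derivation (used by sweeps to keep per-point streams
#'   disjoint).
#' @param n_replicates Ensemble size; defaults to `cfg$n_replicates`.
#' @return A `"fixation_estimate"`: list with `n_replicates`, `fixations`,
#'   `losses`, `discards`, `p_hat` (discards excluded), `ci95` (exact
#'   Clopper-Pearson 95\% interval), `mean_absorption_time`,
#'   `median_absorption_time`.
#' @examples
#' \donttest{
#' cfg <- sim_config(N = 100, resident = 0.8,
#'                   invader = phenotype_distribution("two_point", 0.8, 0.1),
#'                   memory = memory_model("individual", p = 0.9),
#'                   n_replicates = 2000, master_seed = 1)
#' estimate_fixation(cfg)
#' }
#' @export
estimate_fixation <- function(cfg, forced_start = "random",
                              replicate_offset = 0L,
                              n_replicates = cfg$n_replicates) {
  stopifnot(inherits(cfg, "sim_config"), n_replicates >= 1)
  if (cfg$N < 2) stop("N must be >= 2")
  validate_runnable(cfg)

  outcomes <- integer(n_replicates)
  times <- integer(n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(replicate_seed(cfg$master_seed, replicate_offset + i))
    state <- introduce_mutant(cfg, forced_start)
    s <- state_to_cpp(state)
    res <- cpp_wf_run(s$alleles, s$phenotypes, s$generation,
                      cpp_cfg(cfg, attr(state, "env0")))
    outcomes[i] <- res$outcome
    times[i] <- res$steps
  }
  fixation_estimate(outcomes, times, label = cfg$label)
}

# re-check positivity before running (a sim_config is validated at build
# time, but components may have been swapped by sweeps)
validate_runnable <- function(cfg) {
  sup <- c(support(cfg$resident), support(cfg$invader))
  if (min(sup) <= 0 ||
      (cfg$fitness$regime == "periodic" && min(2 * cfg$fitness$m - sup) <= 0))
    stop("invalid scenario: non-positive fitness reachable")
  invisible(cfg)
}

# outcomes coded as in the C++ core: 0 loss, 1 fixation, 2 discard
fixation_estimate <- function(outcomes, times, label = NULL) {
  fixations <- sum(outcomes == 1L)
  losses <- sum(outcomes == 0L)
  discards <- sum(outcomes == 2L)
  absorbed <- fixations + losses
  if (absorbed > 0) {
    p_hat <- fixations / absorbed
    ci95 <- as.numeric(binom.test(fixations, absorbed)$conf.int)
    t_abs <- times[outcomes != 2L]
    mean_t <- mean(t_abs)
    median_t <- median(t_abs)
  } else {
    p_hat <- NA_real_; ci95 <- c(NA_real_, NA_real_)
    mean_t <- NA_real_; median_t <- NA_real_
  }
  structure(list(n_replicates = length(outcomes),
                 fixations = fixations, losses = losses, discards = discards,
                 p_hat = p_hat, ci95 = ci95,
                 mean_absorption_time = mean_t,
                 median_absorption_time = median_t,
                 label = label),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("Fixation estimate%s: %d replicates\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$n_replicates))
  cat(sprintf("  fixations %d, losses %d, discards %d\n",
              x$fixations, x$losses, x$discards))
  cat(sprintf("  p_hat = %.5g  (95%% CI %.5g - %.5g)\n",
              x$p_hat, x$ci95[1], x$ci95[2]))
  cat(sprintf("  absorption time: mean %.1f, median %.1f generations\n",
              x$mean_absorption_time, x$median_absorption_time))
  invisible(x)
}

#' Counter-fixation probability of the wild type
#'
#' Estimates the fixation probability of a single wild-type A introduced
#' into a population fixed for the plastic allele. Each replicate burns in
#' an all-plastic population for `burn_in_generations` so the phenotype
#' distribution reaches its stationary state, replaces one uniformly chosen
#' individual with an A at the wild-type phenotype, and simulates to
#' absorption. The environment clock keeps running through the burn-in.
#'
#' @inheritParams estimate_fixation
#' @param burn_in_generations Burn-in length; defaults to 40 environmental
#'   periods (`40 * period_n`) in the periodic regime and `10 * N`
#'   generations in the constant regime.
#' @return A `"fixation_estimate"` for the A allele (fixation = A fixed).
#' @export
counter_fixation <- function(cfg, burn_in_generations = NULL,
                             replicate_offset = 0L,
                             n_replicates = cfg$n_replicates) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$N < 2) stop("N must be >= 2")
  validate_runnable(cfg)
  if (is.null(burn_in_generations))
    burn_in_generations <- if (cfg$fitness$regime == "periodic")
      40L * cfg$fitness$period_n else 10L * cfg$N
  if (burn_in_generations < 1) stop("burn_in_generations must be >= 1")

  outcomes <- integer(n_replicates)
  times <- integer(n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(replicate_seed(cfg$master_seed, replicate_offset + i))
    state <- all_plastic_population(cfg)
    env0 <- attr(state, "env0")
    s <- state_to_cpp(state)
    burned <- cpp_wf_steps(s$alleles, s$phenotypes, s$generation,
                           cpp_cfg(cfg, env0), burn_in_generations, FALSE)
    al <- burned$alleles
    ph <- burned$phenotypes
    j <- sample.int(cfg$N, 1L)
    al[j] <- 0L
    ph[j] <- cfg$resident$mean
    res <- cpp_wf_run(al, ph, burned$generation, cpp_cfg(cfg, env0))
    # outcome is reported for a; flip to A's point of view
    outcomes[i] <- if (res$outcome == 2L) 2L else 1L - res$outcome
    times[i] <- res$steps
  }
  fixation_estimate(outcomes, times, label = cfg$label)
}

#' Stationary geometric mean fitness of the plastic-fixed population
#'
#' Simulates a population fixed for the plastic allele to its stationary
#' phenotype distribution (burn-in), then records the population mean
#' fitness \eqn{\bar w_t} each generation over windows of one full
#' environmental cycle (2n generations in the periodic regime) and returns
#' the geometric mean \eqn{(\prod_t \bar w_t)^{1/2n}}, averaged over
#' `n_periods_averaged` consecutive windows and `n_replicates` independent
#' replicates.
#'
#' @inheritParams counter_fixation
#' @param n_periods_averaged Number of full environmental cycles recorded
#'   per replicate.
#' @param n_replicates Independent replicates (burn-ins); the default is
#'   far smaller than for fixation estimates because each replicate
#'   contributes `n_periods_averaged` windows of low-noise mean-fitness
#'   records.
#' @return The average stationary geometric mean fitness (scalar), with
#'   attributes `se` (standard error over windows) and `n_windows`.
#' @export
stationary_gm_fitness <- function(cfg, burn_in_generations = NULL,
                                  n_periods_averaged = 8L,
                                  n_replicates = 48L,
                                  replicate_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"), n_periods_averaged >= 1,
            n_replicates >= 1)
  validate_runnable(cfg)
  periodic <- cfg$fitness$regime == "periodic"
  window <- if (periodic) 2L * cfg$fitness$period_n else 1L
  if (is.null(burn_in_generations))
    burn_in_generations <- if (periodic) 40L * cfg$fitness$period_n
                           else 10L * cfg$N

  gms <- numeric(0)
  for (i in seq_len(n_replicates)) {
    set.seed(replicate_seed(cfg$master_seed, replicate_offset + i))
    state <- all_plastic_population(cfg)
    env0 <- attr(state, "env0")
    s <- state_to_cpp(state)
    burned <- cpp_wf_steps(s$alleles, s$phenotypes, s$generation,
                           cpp_cfg(cfg, env0), burn_in_generations, FALSE)
    rec <- cpp_wf_steps(burned$alleles, burned$phenotypes, burned$generation,
                        cpp_cfg(cfg, env0),
                        as.integer(window * n_periods_averaged), TRUE)
    wbar <- rec$mean_fitness
    if (any(wbar <= 0)) stop("non-positive mean fitness recorded")
    win <- matrix(wbar, nrow = window)
    gms <- c(gms, apply(win, 2L, geometric_mean))
  }
  structure(mean(gms),
            se = stats::sd(gms) / sqrt(length(gms)),
            n_windows = length(gms))
}

#' Geometric mean
#'
#' @param x Positive numeric vector.
#' @return `(prod(x))^(1/length(x))`, computed on the log scale.
#' @export
geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}
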