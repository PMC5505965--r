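# scenario builders shared across test files

two_point_cfg <- function(N = 100, p = 0.9, mean = 0.8, sd = 0.1,
                          mode = "individual", n_replicates = 2000,
                          master_seed = 1, ...) {
  sim_config(N = N, resident = mean,
             invader = phenotype_distribution("two_point", mean = mean, sd = sd),
             memory = memory_model(mode, p = p),
             n_replicates = n_replicates, master_seed = master_seed, ...)
}

neutral_cfg <- function(N = 100, n_replicates = 2000, master_seed = 1, ...) {
  sim_config(N = N, resident = 0.8,
             invader = phenotype_distribution("degenerate", mean = 0.8),
             memory = memory_model("individual", p = 0.5),
             n_replicates = n_replicates, master_seed = master_seed, ...)
}

# periodic setting with f1(Phi_A) = 0.6, m = 0.7, invader mean 0.8
periodic_cfg <- function(N = 200, n = 10, p = 0.8, kind = "uniform",
                         variance = 0.0033, initial_env = "random",
                         mode = "individual", q = NULL,
                         n_replicates = 2000, master_seed = 1, ...) {
  mem <- if (mode == "switching") memory_model("switching", q = q)
         else memory_model(mode, p = p)
  sim_config(N = N, resident = 0.6,
             invader = phenotype_distribution(kind, mean = 0.8,
                                              sd = sqrt(variance)),
             memory = mem,
             fitness = fitness_model("periodic", period_n = n,
                                     initial_env = initial_env, m = 0.7),
             n_replicates = n_replicates, master_seed = master_seed, ...)
}

# deterministic two-phenotype selection-mutation recursion, iterated to a
# fixed point: the independent oracle for balance_frequency()
balance_fixed_point <- function(mu, phi_min, phi_max, tol = 1e-14) {
  x <- 0.5
  repeat {
    xs <- x * phi_max / (x * phi_max + (1 - x) * phi_min)
    xn <- xs * (1 - mu) + (1 - xs) * mu
    if (abs(xn - x) < tol) return(xn)
    x <- xn
  }
}

# 3-SE binomial band around a known probability
within_3se <- function(p_hat, p0, n) abs(p_hat - p0) <= 3 * sqrt(p0 * (1 - p0) / n)
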