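#' Equilibrium frequency of the fitter phenotype within the plastic lineage
#'
#' For a two-point phenotype distribution, the two phenotypes inside the
#' a-lineage behave like two alleles under proportional selection with
#' symmetric "phenotypic mutation" at rate \eqn{\mu = (1 - p)/2}. At
#' mutation-selection balance the frequency of the fitter phenotype
#' \eqn{\Phi_{a,max}} within the lineage is the stable root of the balance
#' quadratic:
#' \deqn{f_{a,max} = \frac{\Phi_{max} - \Phi_{min} - \mu\Phi_{min} - \mu\Phi_{max}
#'   + \sqrt{4\Phi_{min}\mu(\Phi_{max} - \Phi_{min})
#'   + (\Phi_{min} - \Phi_{max} + \mu\Phi_{max} + \mu\Phi_{min})^2}}
#'   {2(\Phi_{max} - \Phi_{min})}.}
#'
#' The equivalent mean/sd parameterization (with
#' \eqn{E = (\Phi_{min}+\Phi_{max})/2}, \eqn{\sigma = (\Phi_{max}-\Phi_{min})/2})
#' is available via [balance_frequency_ms()]; the two agree to machine
#' precision.
#'
#' @param mu Phenotypic mutation rate in \[0, 1/2\].
#' @param phi_min,phi_max The two support points, `0 < phi_min < phi_max`.
#' @return The balance frequency, in \[1/2, 1\].
#' @seealso [plastic_fixation_probability()] for the full chain.
#' @export
balance_frequency <- function(mu, phi_min, phi_max) {
  stopifnot(all(mu >= 0), all(mu <= 0.5), all(phi_min > 0))
  if (any(phi_min >= phi_max)) {
    if (any(phi_min == phi_max)) stop("degenerate distribution")
    stop("phi_min must be < phi_max")
  }
  d <- phi_max - phi_min
  disc <- 4 * phi_min * mu * d + (phi_min - phi_max + mu * phi_max + mu * phi_min)^2
  (d - mu * phi_min - mu * phi_max + sqrt(disc)) / (2 * d)
}

#' @rdname balance_frequency
#' @param e_phi Mean phenotype \eqn{E(\Phi_a)}.
#' @param sigma Phenotypic standard deviation \eqn{\sigma_{\Phi_a}} (> 0).
#' @export
balance_frequency_ms <- function(mu, e_phi, sigma) {
  stopifnot(all(sigma > 0))
  disc <- (2 * e_phi * mu - 2 * sigma)^2 - 8 * sigma * (sigma * mu - e_phi * mu)
  (2 * sigma - 2 * e_phi * mu + sqrt(disc)) / (4 * sigma)
}

#' Effective selection coefficient of the plastic lineage
#'
#' The lineage's mean fitness at phenotype balance, relative to the
#' wild-type's fixed phenotype:
#' \deqn{s_a = \frac{\Phi_{min}(1 - f_{a,max}) + \Phi_{max} f_{a,max}}{\Phi_A} - 1.}
#'
#' @param f_a_max Balance frequency of the fitter phenotype, in \[0, 1\].
#' @param phi_min,phi_max Support points of the plastic allele.
#' @param phi_A Fixed phenotype of the wild-type; must be positive.
#' @return The effective selection coefficient (can be negative).
#' @export
effective_selection <- function(f_a_max, phi_min, phi_max, phi_A) {
  if (any(phi_A <= 0)) stop("phi_A must be positive")
  stopifnot(all(f_a_max >= 0), all(f_a_max <= 1))
  (phi_min * (1 - f_a_max) + phi_max * f_a_max) / phi_A - 1
}

#' Kimura fixation probability of a selected allele
#'
#' The diffusion approximation for the fixation probability of a single
#' copy with selection coefficient s in a haploid population of size N:
#' \deqn{P = \frac{1 - e^{-2s}}{1 - e^{-2Ns}},}
#' with the continuous limit 1/N returned for |s| < 1e-8 (both numerator
#' and denominator vanish there).
#'
#' @param s Selection coefficient.
#' @param N Population size, >= 2.
#' @return Fixation probability in \[0, 1\]; monotone increasing in s.
#' @export
kimura_fixation <- function(s, N) {
  stopifnot(is.numeric(s), N >= 2)
  ifelse(abs(s) < 1e-8, 1 / N,
         expm1(-2 * s) / expm1(-2 * N * s))
}

#' Probability of a phenotypic mutation before loss of the lineage
#'
#' A lineage introduced as one copy of the unfit phenotype decays roughly
#' as \eqn{e^{-st}} under selection coefficient -s, so its expected
#' cumulative copy count is \eqn{\sum_t X_t = 1 / (1 - e^{-s})}. The chance
#' that at least one offspring mutates phenotype before the lineage is lost
#' is then
#' \deqn{P(\eta) = 1 - (1 - \mu)^{1/(1 - e^{-s})}.}
#'
#' @param mu Phenotypic mutation rate in \[0, 1/2\].
#' @param s Decay coefficient, strictly positive (otherwise the cumulative
#'   copy count diverges).
#' @return Probability in \[0, 1\].
#' @export
loss_mutation_probability <- function(mu, s) {
  stopifnot(all(mu >= 0), all(mu <= 0.5))
  if (any(s <= 0)) stop("non-decaying lineage (s must be > 0)")
  1 - (1 - mu)^(1 / (-expm1(-s)))
}

#' Fixation probability of the plastic allele in a constant environment
#'
#' Composes the full approximation chain for a two-point plastic allele
#' introduced as a single copy with uniformly random initial phenotype:
#' \eqn{\mu = (1-p)/2}; the balance frequency of the fitter phenotype
#' ([balance_frequency()]); the effective selection coefficient
#' ([effective_selection()]); the Kimura fixation probability of a lineage
#' started at the fitter phenotype ([kimura_fixation()]); and the rescue
#' probability of a lineage started at the unfit phenotype
#' ([loss_mutation_probability()]). The result is
#' \deqn{P_f(a) = \tfrac12 P_f(a_{max}) + \tfrac12 P(\eta) P_f(a_{max})
#'             = \tfrac12\left(2 - (1-\mu)^{1/(1-e^{-s})}\right) P_f(a_{max}).}
#'
#' The decay coefficient s entering \eqn{P(\eta)} is, by default, the
#' selective disadvantage of the unfit phenotype against the resident,
#' \eqn{s = 1 - \Phi_{a,min}/\Phi_A}; set `s_loss = "abs_s_a"` to use
#' \eqn{|s_a|} instead.
#'
#' @param p Phenotypic memory in \[0, 1\].
#' @param dist A two-point [phenotype_distribution()] with `sd > 0`.
#' @param phi_A Fixed phenotype of the wild-type (> 0).
#' @param N Population size.
#' @param s_loss `"phi_min"` (default) or `"abs_s_a"`: which decay
#'   coefficient to use in the rescue probability.
#' @return An object of class `"balance_result"`: list with `p`, `mu`,
#'   `f_a_max`, `s_a`, `s_loss`, `p_eta`, `p_fix_max`, `p_fix_min`,
#'   `p_fix`, and `N`.
#' @examples
#' dist <- phenotype_distribution("two_point", mean = 0.8, sd = 0.1)
#' plastic_fixation_probability(0.9, dist, phi_A = 0.8, N = 1000)
#' @export
plastic_fixation_probability <- function(p, dist, phi_A, N,
                                         s_loss = c("phi_min", "abs_s_a")) {
  s_loss <- match.arg(s_loss)
  stopifnot(inherits(dist, "phenotype_distribution"))
  if (dist$kind != "two_point" || dist$sd <= 0)
    stop("the analytic chain requires a two_point distribution with sd > 0")
  stopifnot(p >= 0, p <= 1, phi_A > 0, N >= 2)

  phi_min <- dist$mean - dist$sd
  phi_max <- dist$mean + dist$sd
  mu <- (1 - p) / 2
  f_a_max <- balance_frequency(mu, phi_min, phi_max)
  s_a <- effective_selection(f_a_max, phi_min, phi_max, phi_A)
  p_fix_max <- kimura_fixation(s_a, N)
  s_dec <- switch(s_loss, phi_min = 1 - phi_min / phi_A, abs_s_a = abs(s_a))
  p_eta <- if (mu == 0) 0 else loss_mutation_probability(mu, s_dec)
  p_fix_min <- p_eta * p_fix_max
  structure(list(p = p, mu = mu, f_a_max = f_a_max, s_a = s_a,
                 s_loss = s_dec, p_eta = p_eta,
                 p_fix_max = p_fix_max, p_fix_min = p_fix_min,
                 p_fix = 0.5 * p_fix_max + 0.5 * p_eta * p_fix_max,
                 N = N),
            class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat(sprintf("Analytic fixation approximation (N = %d, p = %g)\n", x$N, x$p))
  cat(sprintf("  mu = %g, f_a_max = %.6f, s_a = %.6f\n", x$mu, x$f_a_max, x$s_a))
  cat(sprintf("  P(eta) = %.6f, P_f(a_max) = %.6g, P_f(a_min) = %.6g\n",
              x$p_eta, x$p_fix_max, x$p_fix_min))
  cat(sprintf("  P_f(a) = %.6g\n", x$p_fix))
  invisible(x)
}

#' Analytic fixation curve over a grid of memory values
#'
#' Convenience wrapper around [plastic_fixation_probability()] for plotting
#' or CSV export.
#'
#' @param p_values Vector of memory values in \[0, 1\].
#' @param mean,sd Mean and sd of the two-point invader distribution.
#' @param phi_A Wild-type phenotype.
#' @param N Population size.
#' @param s_loss Passed to [plastic_fixation_probability()].
#' @return A data.frame with columns `p`, `mu`, `f_a_max`, `s_a`, `p_eta`,
#'   `p_fix`.
#' @export
analytic_fixation_curve <- function(p_values, mean, sd, phi_A, N,
                                    s_loss = "phi_min") {
  dist <- phenotype_distribution("two_point", mean = mean, sd = sd)
  rows <- lapply(p_values, function(p) {
    r <- plastic_fixation_probability(p, dist, phi_A, N, s_loss)
    data.frame(p = p, mu = r$mu, f_a_max = r$f_a_max, s_a = r$s_a,
               p_eta = r$p_eta, p_fix = r$p_fix)
  })
  do.call(rbind, rows)
}
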