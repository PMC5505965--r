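#' Phenotype distribution of an allele
#'
#' Describes the random phenotype \eqn{\Phi} an allele can express. Fitness
#' is measured on the same (dimensionless) scale as phenotype, so the whole
#' support must be strictly positive. Three kinds are supported:
#'
#' * `"degenerate"`: a single fixed phenotype (the wild-type allele A, or a
#'   neutral control invader); requires `sd = 0`.
#' * `"two_point"`: two equiprobable phenotypes at `mean - sd` and
#'   `mean + sd` (the unique equiprobable two-point law with the given mean
#'   and variance).
#' * `"uniform"`: continuous uniform on
#'   \eqn{[mean - sd\sqrt{3},\; mean + sd\sqrt{3}]}.
#'
#' @param kind One of `"degenerate"`, `"two_point"`, `"uniform"`.
#' @param mean Mean phenotype; must be positive.
#' @param sd Phenotypic standard deviation \eqn{\sigma_\Phi}; must be 0 for
#'   `"degenerate"` and positive otherwise.
#' @return An object of class `"phenotype_distribution"` with fields
#'   `kind`, `mean`, `sd`.
#' @examples
#' phi_a <- phenotype_distribution("two_point", mean = 0.8, sd = 0.1)
#' support(phi_a)
#' @export
phenotype_distribution <- function(kind = c("two_point", "uniform", "degenerate"),
                                   mean, sd = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (mean <= 0) stop("phenotype mean must be > 0 (fitness equals phenotype)")
  if (sd < 0) stop("phenotype sd must be >= 0")
  if (kind == "degenerate" && sd != 0)
    stop("degenerate distribution requires sd = 0")
  if (kind != "degenerate" && sd == 0)
    stop(sprintf("kind '%s' requires sd > 0 (use 'degenerate' for a fixed phenotype)", kind))
  d <- structure(list(kind = kind, mean = mean, sd = sd),
                 class = "phenotype_distribution")
  if (min(support(d)) <= 0)
    stop("entire phenotype support must be strictly positive")
  d
}

#' Support of a phenotype distribution
#'
#' @param dist A [phenotype_distribution()].
#' @return For `"degenerate"` the single value; for `"two_point"` the two
#'   support points; for `"uniform"` the interval endpoints.
#' @export
support <- function(dist) {
  stopifnot(inherits(dist, "phenotype_distribution"))
  switch(dist$kind,
         degenerate = dist$mean,
         two_point  = c(dist$mean - dist$sd, dist$mean + dist$sd),
         uniform    = c(dist$mean - dist$sd * sqrt(3),
                        dist$mean + dist$sd * sqrt(3)))
}

#' Sample phenotypes
#'
#' Independent draws from a phenotype distribution, using R's RNG.
#'
#' @param dist A [phenotype_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_phenotype <- function(dist, n = 1L) {
  stopifnot(inherits(dist, "phenotype_distribution"), n >= 0)
  switch(dist$kind,
         degenerate = rep(dist$mean, n),
         two_point  = dist$mean + dist$sd * sign(stats::runif(n) - 0.5),
         uniform    = stats::runif(n,
                                   dist$mean - dist$sd * sqrt(3),
                                   dist$mean + dist$sd * sqrt(3)))
}

#' @export
print.phenotype_distribution <- function(x, ...) {
  cat(sprintf("Phenotype distribution: %s, mean %g, sd %g\n",
              x$kind, x$mean, x$sd))
  if (x$kind != "degenerate")
    cat(sprintf("  support: [%g, %g], variance %g\n",
                min(support(x)), max(support(x)), x$sd^2))
  invisible(x)
}
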