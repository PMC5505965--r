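#' Phenotype inheritance model for the plastic allele
#'
#' Three modes of phenotype transmission from an a-parent to its offspring:
#'
#' * `"individual"`: each offspring independently retains its parent's
#'   phenotype with probability `p` (the phenotypic memory) and otherwise
#'   redraws from the phenotype distribution.
#' * `"global"`: a single Bernoulli(`p`) per generation; on failure one
#'   shared fresh draw is assigned to every a-offspring, so the whole
#'   a-subpopulation expresses one phenotype at a time.
#' * `"switching"`: classic two-phenotype switch; each offspring flips to
#'   the other support point with probability `q`, independently (requires a
#'   two-point phenotype distribution).
#'
#' @param mode `"individual"`, `"global"`, or `"switching"`.
#' @param p Phenotypic memory in \[0, 1\] (individual/global modes).
#' @param q Per-generation switch probability in \[0, 1\] (switching mode).
#' @return An object of class `"memory_model"`.
#' @export
memory_model <- function(mode = c("individual", "global", "switching"),
                         p = NULL, q = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("individual", "global")) {
    if (is.null(p) || !is.numeric(p) || p < 0 || p > 1)
      stop(sprintf("mode '%s' requires phenotypic memory p in [0, 1]", mode))
    q <- NA_real_
  } else {
    if (is.null(q) || !is.numeric(q) || q < 0 || q > 1)
      stop("switching mode requires switch probability q in [0, 1]")
    p <- NA_real_
  }
  structure(list(mode = mode, p = p, q = q), class = "memory_model")
}

#' @export
print.memory_model <- function(x, ...) {
  lab <- switch(x$mode,
                individual = sprintf("individual memory, p = %g", x$p),
                global     = sprintf("global memory, p = %g", x$p),
                switching  = sprintf("two-phenotype switching, q = %g", x$q))
  cat("Memory model:", lab, "\n")
  invisible(x)
}
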