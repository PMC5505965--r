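#' Bundled scenario presets
#'
#' Ready-made scenario configurations shipped under
#' `inst/extdata/configs/`:
#'
#' * `"constant-two-point"`: constant environment, wild-type fixed at 0.8,
#'   two-point invader with mean 0.8 (Var = 0.01), N = 1000 — the standard
#'   constant-environment setting for memory sweeps.
#' * `"periodic-uniform"`: periodic environment with reflection midpoint
#'   m = 0.7, wild-type at 0.6 (so its two fitness values are 0.6 and 0.8),
#'   invader uniform on \[0.7, 0.9\] (Var = 0.0033), n = 20, random initial
#'   environment, N = 1000.
#' * `"periodic-uniform-e1"`: as above but the first environment is always
#'   E1 (used for variance sweeps where the starting environment is held
#'   fixed).
#' * `"periodic-switching"`: two-phenotype switching variant in the same
#'   periodic setting (two-point invader, Var = 0.0033, n = 10).
#'
#' @param name Preset name.
#' @param reduced If `TRUE`, return a desk-scale variant (N = 200,
#'   2000 replicates) suitable for quick exploration; the full-scale
#'   presets use N = 1000 and 10000 replicates.
#' @return A [sim_config()].
#' @export
scenario_preset <- function(name = c("constant-two-point", "periodic-uniform",
                                     "periodic-uniform-e1",
                                     "periodic-switching"),
                            reduced = FALSE) {
  name <- match.arg(name)
  path <- system.file("extdata", "configs", paste0(name, ".json"),
                      package = "phenomem", mustWork = TRUE)
  cfg <- suppressMessages(load_config(path))
  if (reduced) {
    cfg$N <- 200L
    cfg$n_replicates <- 2000L
  }
  cfg
}
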