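#' Read a scenario configuration from JSON or YAML
#'
#' The on-disk schema is a flat key-value document:
#' `N`, `memory_mode`, `p`, `q`, `regime`, `period_n`, `initial_env`,
#' `resident` (object with `mean`), `invader` (object with `kind`, `mean`,
#' `sd`), `m`, `max_generations`, `n_replicates`, `master_seed`, `label`.
#' Unknown keys are an error (no silent typo tolerance); missing required
#' keys are an error naming the field; every defaulted field is reported
#' with a message.
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml  = yaml::read_yaml(path),
                stop("unsupported config format '", ext, "' (use JSON or YAML)"))
  config_from_list(raw, source = path)
}

config_keys <- c("N", "memory_mode", "p", "q", "regime", "period_n",
                 "initial_env", "resident", "invader", "m",
                 "max_generations", "n_replicates", "master_seed", "label")

config_from_list <- function(raw, source = "config") {
  # YAML 1.1 parses a bare N key as the boolean FALSE; undo that
  names(raw)[names(raw) == "FALSE"] <- "N"
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0)
    stop("unknown config keys in ", source, ": ",
         paste(unknown, collapse = ", "))
  required <- c("N", "memory_mode", "regime", "resident", "invader")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("missing required config fields: ", paste(missing, collapse = ", "))
  if (is.null(raw$invader$kind) || is.null(raw$invader$mean))
    stop("invader must provide 'kind' and 'mean'")
  if (is.null(raw$resident$mean))
    stop("resident must provide 'mean'")

  default <- function(key, value) {
    if (is.null(raw[[key]])) {
      message(sprintf("config %s: using default %s = %s", source, key,
                      format(value)))
      value
    } else raw[[key]]
  }

  memory <- switch(raw$memory_mode,
                   individual = ,
                   global = memory_model(raw$memory_mode, p = raw$p),
                   switching = memory_model("switching", q = raw$q),
                   stop("unknown memory_mode: ", raw$memory_mode))
  fitness <- if (raw$regime == "periodic") {
    if (is.null(raw$period_n)) stop("periodic regime requires 'period_n'")
    if (is.null(raw$m)) stop("periodic regime requires 'm'")
    fitness_model("periodic", period_n = raw$period_n,
                  initial_env = default("initial_env", "E1"), m = raw$m)
  } else if (raw$regime == "constant") {
    fitness_model("constant")
  } else stop("unknown regime: ", raw$regime)

  invader <- phenotype_distribution(raw$invader$kind,
                                    mean = raw$invader$mean,
                                    sd = raw$invader$sd %||% 0)
  sim_config(N = raw$N,
             resident = phenotype_distribution("degenerate",
                                               mean = raw$resident$mean),
             invader = invader,
             memory = memory,
             fitness = fitness,
             max_generations = default("max_generations", 10000L),
             n_replicates = default("n_replicates", 10000L),
             master_seed = default("master_seed", 1L),
             label = raw$label)
}

# canonical flat representation; field order is fixed so that
# serialize -> parse -> serialize round-trips byte-identically
config_as_list <- function(cfg) {
  out <- list(N = cfg$N,
              memory_mode = cfg$memory$mode)
  if (cfg$memory$mode %in% c("individual", "global")) out$p <- cfg$memory$p
  if (cfg$memory$mode == "switching") out$q <- cfg$memory$q
  out$regime <- cfg$fitness$regime
  if (cfg$fitness$regime == "periodic") {
    out$period_n <- cfg$fitness$period_n
    out$initial_env <- cfg$fitness$initial_env
  }
  out$resident <- list(mean = cfg$resident$mean)
  out$invader <- list(kind = cfg$invader$kind, mean = cfg$invader$mean,
                      sd = cfg$invader$sd)
  if (cfg$fitness$regime == "periodic") out$m <- cfg$fitness$m
  out$max_generations <- cfg$max_generations
  out$n_replicates <- cfg$n_replicates
  out$master_seed <- cfg$master_seed
  if (!is.null(cfg$label)) out$label <- cfg$label
  out
}

#' Write a scenario configuration to canonical JSON
#'
#' @param cfg A [sim_config()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  json <- jsonlite::toJSON(config_as_list(cfg), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Hash identifying a (configuration, seed) pair
#'
#' A small deterministic string hash of the canonical JSON serialization
#' (which includes the master seed); two outputs with equal hashes were
#' produced by identical scenarios.
#'
#' @param cfg A [sim_config()].
#' @return An 8-character lowercase hex string.
#' @export
config_hash <- function(cfg) {
  s <- as.character(jsonlite::toJSON(config_as_list(cfg), auto_unbox = TRUE,
                                     digits = NA))
  h <- 5381
  for (b in as.integer(charToRaw(s)))
    h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write Monte Carlo results to CSV with a JSON sidecar
#'
#' Writes one CSV row per scenario or grid point with the columns
#' `scenario`, `parameter`, `fixations`, `losses`, `discards`, `p_hat`,
#' `ci_lo`, `ci_hi`, `mean_T_abs` (for geometric-mean-fitness sweeps the
#' objective value is carried in `p_hat` and the count columns are NA).
#' A sidecar `<path without ext>.meta.json` records the config hash, the
#' master seed, the package version, total discards, and a timestamp; all
#' sidecar fields except the timestamp are deterministic given
#' (config, seed).
#'
#' @param result A `"fixation_estimate"` or `"sweep_result"`.
#' @param path Output CSV path.
#' @param cfg The [sim_config()] that produced the result (for the hash and
#'   seed in the sidecar); optional.
#' @param scenario Scenario id string for the CSV; defaults to the config
#'   label or `"scenario"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, cfg = NULL, scenario = NULL) {
  scenario <- scenario %||% (if (!is.null(cfg)) cfg$label else NULL) %||%
    "scenario"
  row_of <- function(est, parameter) {
    if (inherits(est, "fixation_estimate")) {
      data.frame(scenario = scenario, parameter = parameter,
                 fixations = est$fixations, losses = est$losses,
                 discards = est$discards, p_hat = est$p_hat,
                 ci_lo = est$ci95[1], ci_hi = est$ci95[2],
                 mean_T_abs = est$mean_absorption_time)
    } else {  # scalar objective (gm fitness)
      data.frame(scenario = scenario, parameter = parameter,
                 fixations = NA_integer_, losses = NA_integer_,
                 discards = NA_integer_, p_hat = as.numeric(est),
                 ci_lo = NA_real_, ci_hi = NA_real_, mean_T_abs = NA_real_)
    }
  }
  if (inherits(result, "fixation_estimate")) {
    df <- row_of(result, NA_real_)
  } else if (inherits(result, "sweep_result")) {
    if (length(result$grid) == 0) stop("empty sweep: nothing to write")
    df <- do.call(rbind, Map(row_of, result$estimates, result$grid))
  } else stop("write_results expects a fixation_estimate or sweep_result")

  tryCatch(write.csv(df, path, row.names = FALSE),
           error = function(e) stop("failed to write ", path, ": ",
                                    conditionMessage(e)))
  meta <- list(scenario = scenario,
               config_hash = if (!is.null(cfg)) config_hash(cfg) else NA,
               master_seed = if (!is.null(cfg)) cfg$master_seed else NA,
               package_version = as.character(packageVersion("phenomem")),
               discards = if (inherits(result, "fixation_estimate"))
                 result$discards
               else sum(vapply(result$estimates, function(e)
                 if (inherits(e, "fixation_estimate")) e$discards else 0L,
                 integer(1))),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  meta_path <- paste0(tools::file_path_sans_ext(path), ".meta.json")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", na = "null"),
             meta_path)
  invisible(path)
}
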