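# Run configuration: a flat YAML dialect with the model parameter keys
# plus optional strategy / sweep / numerics / output blocks. Unknown keys
# are rejected with the offending key path.

MODEL_KEYS <- c("p_W", "p_B1", "m_C", "A", "TST_h",
                "r_Ww", "r_Bw", "r_Ws", "r_Bs")
STRATEGY_KEYS <- c("rho", "mai_target", "TST_h")
SWEEP_KEYS <- c("panel", "mai_grid", "tst_grid", "rho_grid", "a_grid",
                "pw_grid", "pb1_grid", "mc_values")
NUMERICS_KEYS <- c("r_bw_step", "r_bw_max", "match_tol_rel", "bd_interval")
OUTPUT_KEYS <- c("dir", "prefix")

default_config <- function() {
  structure(
    list(
      params = ea_params(),
      strategy = list(rho = 0.3, mai_target = 0.4, TST_h = 8),
      sweep = list(),
      numerics = list(r_bw_step = 0.02, r_bw_max = 10, match_tol_rel = 1e-4,
                      bd_interval = c(1e-6, 50)),
      output = list(dir = ".", prefix = "easleep")
    ),
    class = "ea_config"
  )
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    abort(sprintf("Unknown configuration key%s at %s: %s",
                  if (length(bad) > 1) "s" else "", where,
                  paste0("`", bad, "`", collapse = ", ")),
          class = "easleep_config_error")
  }
}

#' Read a run configuration
#'
#' Reads a YAML configuration file. Top-level keys are the model
#' parameters (`p_W`, `p_B1`, `m_C`, `A`, `TST_h`, `r_Ww`, `r_Bw`,
#' `r_Ws`, `r_Bs`) plus optional `strategy`, `sweep`, `numerics`, and
#' `output` blocks. Missing keys take the model's standard defaults; an
#' empty file yields the full default configuration. Unknown keys are
#' rejected with their key path; parameter values are validated (e.g.
#' `A < m_C`).
#'
#' @param path Path to a YAML file.
#' @return An object of class `ea_config`: list with `params`
#'   ([ea_params()]), `strategy`, `sweep`, `numerics`, `output`.
#' @examples
#' cfg <- file.path(tempdir(), "run.yml")
#' writeLines("TST_h: 8\nstrategy: {rho: 0.3, mai_target: 0.4}", cfg)
#' read_ea_config(cfg)
#' @export
read_ea_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys(raw, c(MODEL_KEYS, "strategy", "sweep", "numerics", "output"),
             "top level")
  cfg <- default_config()
  model <- raw[intersect(names(raw), MODEL_KEYS)]
  if (length(model)) {
    cfg$params <- tryCatch(
      do.call(ea_update, c(list(cfg$params), model)),
      error = function(e) {
        abort(sprintf("Invalid model parameters in %s: %s", path,
                      conditionMessage(e)),
              class = "easleep_config_error")
      }
    )
  }
  for (blk in c("strategy", "sweep", "numerics", "output")) {
    if (!is.null(raw[[blk]])) {
      allowed <- switch(blk, strategy = STRATEGY_KEYS, sweep = SWEEP_KEYS,
                        numerics = NUMERICS_KEYS, output = OUTPUT_KEYS)
      check_keys(raw[[blk]], allowed, blk)
      cfg[[blk]] <- modifyList(cfg[[blk]], raw[[blk]])
    }
  }
  if (!is.null(cfg$strategy$rho) &&
      (cfg$strategy$rho < 0 || cfg$strategy$rho > 1)) {
    abort("strategy/rho must lie in [0, 1].", class = "easleep_config_error")
  }
  if (!is.null(cfg$strategy$mai_target) &&
      (cfg$strategy$mai_target < 0 || cfg$strategy$mai_target > 1)) {
    abort("strategy/mai_target must lie in [0, 1].",
          class = "easleep_config_error")
  }
  cfg
}

#' Write a run configuration
#'
#' Serializes an `ea_config` (or the defaults) back to YAML so that a
#' configuration round-trips unchanged through [read_ea_config()].
#'
#' @param config An `ea_config` object, e.g. from [read_ea_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ea_config <- function(config, path) {
  stopifnot(inherits(config, "ea_config"))
  flat <- c(
    unclass(config$params)[MODEL_KEYS],
    list(strategy = config$strategy, sweep = config$sweep,
         numerics = config$numerics, output = config$output)
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}
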