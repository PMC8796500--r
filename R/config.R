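## Model configuration: a single structured file holds the transition
## table, both arms' parameters, run settings, the WTP threshold, the
## observed cost breakdown, and the PSA dispersion assumptions. Paths in
## `not_from_paper` flag documented placeholders (unpublished SPMS
## utilities/costs, cost dispersion).

#' Read and validate a model configuration file
#'
#' @param path Path to a YAML configuration (see the bundled
#'   `paper_base_case.yaml` for the schema).
#' @return A validated list of class `ms_model_config`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg <- validate_model_config(cfg)
  cfg
}

#' The bundled base-case configuration
#'
#' Encodes the published transition/death table, per-arm relapse
#' probabilities, per-(arm, band) utilities with SDs, the observed annual
#' cost breakdown, discount rates, the lifetime horizon and the 3x GDP
#' willingness-to-pay threshold, plus flagged placeholder values for the
#' unpublished SPMS inputs (shared across arms so they cancel in
#' incremental results).
#'
#' @return A validated `ms_model_config`.
#' @export
#' @examples
#' cfg <- base_case_config()
#' cfg$threshold
base_case_config <- function() {
  read_model_config(system.file("extdata", "paper_base_case.yaml",
                                package = "rrmscea", mustWork = TRUE))
}

.require_fields <- function(x, fields, where) {
  for (f in fields)
    if (is.null(x[[f]]))
      stop(sprintf("config schema violation: missing field '%s/%s'",
                   where, f), call. = FALSE)
}

#' Validate a model configuration
#'
#' Checks the schema and numeric invariants; errors name the offending
#' field with its full path.
#'
#' @param cfg A configuration list.
#' @return The config, classed `ms_model_config`.
#' @export
validate_model_config <- function(cfg) {
  .require_fields(cfg, c("threshold", "settings", "transition_table", "arms"),
                  "")
  .require_fields(cfg$threshold, c("gdp_per_capita", "multiplier"), "threshold")
  .require_fields(cfg$settings,
                  c("start_age", "max_age", "discount_rate_costs",
                    "discount_rate_outcomes", "start_distribution"),
                  "settings")
  .require_fields(cfg$transition_table, c("living_percent", "death_percent"),
                  "transition_table")
  for (s in edss_states()) {
    if (is.null(cfg$transition_table$living_percent[[s]]))
      stop(sprintf("config schema violation: missing field '%s'",
                   paste0("transition_table/living_percent/", s)),
           call. = FALSE)
    if (is.null(cfg$transition_table$death_percent[[s]]))
      stop(sprintf("config schema violation: missing field '%s'",
                   paste0("transition_table/death_percent/", s)),
           call. = FALSE)
  }
  for (a in arm_names()) {
    arm <- cfg$arms[[a]]
    if (is.null(arm))
      stop(sprintf("config schema violation: missing field 'arms/%s'", a),
           call. = FALSE)
    .require_fields(arm, c("annual_relapse_prob", "drug_cost_annual",
                           "other_cost", "utilities"), paste0("arms/", a))
    for (s in edss_states()) {
      for (fld in c("utilities", "other_cost")) {
        if (is.null(arm[[fld]][[s]]))
          stop(sprintf("config schema violation: missing field 'arms/%s/%s/%s'",
                       a, fld, s), call. = FALSE)
      }
    }
    if (arm$annual_relapse_prob < 0 || arm$annual_relapse_prob > 1)
      .fail_field(paste0("arms/", a, "/annual_relapse_prob"),
                  "must lie in [0, 1]")
    if (any(unlist(arm$utilities) > 1))
      .fail_field(paste0("arms/", a, "/utilities"), "must be at most 1")
    if (arm$drug_cost_annual < 0 || any(unlist(arm$other_cost) < 0))
      .fail_field(paste0("arms/", a, "/costs"), "must be nonnegative")
  }
  structure(cfg, class = c("ms_model_config", "list"))
}

#' Turn a configuration into model objects
#'
#' @param cfg An `ms_model_config`.
#' @return A list: `tt` ([transition_table()]), `arms` (named list of
#'   [arm_parameters()]), `settings` ([model_settings()]), `threshold`
#'   ([wtp_threshold()]).
#' @export
config_objects <- function(cfg) {
  lp <- do.call(rbind, lapply(edss_states(), function(s)
    as.numeric(cfg$transition_table$living_percent[[s]])))
  dp <- vapply(edss_states(), function(s)
    as.numeric(cfg$transition_table$death_percent[[s]]), numeric(1))
  tt <- transition_table(lp, dp)
  arms <- lapply(arm_names(), function(a) {
    arm <- cfg$arms[[a]]
    arm_parameters(
      name = a,
      annual_relapse_prob = arm$annual_relapse_prob,
      state_utilities = unlist(arm$utilities)[edss_states()],
      drug_cost_annual = arm$drug_cost_annual,
      other_cost = unlist(arm$other_cost)[edss_states()]
    )
  })
  names(arms) <- arm_names()
  st <- cfg$settings
  settings <- model_settings(
    start_age = st$start_age, max_age = st$max_age,
    discount_rate_costs = st$discount_rate_costs,
    discount_rate_outcomes = st$discount_rate_outcomes,
    start_distribution = unlist(st$start_distribution)[edss_states()],
    survival_floor = if (is.null(st$survival_floor)) 1e-6 else
      st$survival_floor,
    half_cycle_correction = isTRUE(st$half_cycle_correction),
    discount_first_cycle = isTRUE(st$discount_first_cycle)
  )
  list(tt = tt, arms = arms, settings = settings,
       threshold = wtp_threshold(cfg$threshold$gdp_per_capita,
                                 cfg$threshold$multiplier))
}

#' Observed cost breakdown as cost lines
#'
#' Converts the configuration's observed mean annual costs (one mean per
#' arm, category and item) into a cost-lines data frame with one
#' pseudo-patient per arm, suitable for [aggregate_costs()].
#'
#' @param cfg An `ms_model_config` with an `observed_annual_costs` block.
#' @return Data frame: patient_id, arm, category, item, amount.
#' @export
observed_cost_lines <- function(cfg) {
  oc <- cfg$observed_annual_costs
  if (is.null(oc))
    stop("config has no observed_annual_costs block", call. = FALSE)
  out <- list()
  for (a in names(oc)) {
    for (cat in names(oc[[a]])) {
      items <- oc[[a]][[cat]]
      out[[length(out) + 1L]] <- data.frame(
        patient_id = paste0("mean-", a), arm = a, category = cat,
        item = names(items), amount = as.numeric(unlist(items)),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Get or set a configuration entry by path
#'
#' Paths are slash-separated (state names contain dots, so `/` is the
#' separator), e.g. `"arms/rituximab/utilities/EDSS 0-2.5"`.
#'
#' @param cfg An `ms_model_config`.
#' @param path Slash-separated path string.
#' @param value Replacement value (for `config_set`).
#' @return `config_get`: the entry. `config_set`: the modified config.
#' @export
config_get <- function(cfg, path) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  for (k in keys) {
    cfg <- cfg[[k]]
    if (is.null(cfg))
      stop(sprintf("config path not found: '%s' (at '%s')", path, k),
           call. = FALSE)
  }
  cfg
}

#' @rdname config_get
#' @export
config_set <- function(cfg, path, value) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  set_rec <- function(x, keys) {
    if (is.null(x[[keys[1]]]))
      stop(sprintf("config path not found: '%s' (at '%s')", path, keys[1]),
           call. = FALSE)
    if (length(keys) == 1L) x[[keys[1]]] <- value
    else x[[keys[1]]] <- set_rec(x[[keys[1]]], keys[-1])
    x
  }
  set_rec(cfg, keys)
}
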