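## Annual-cycle Markov cohort engine over four EDSS bands plus death.
## Published transition tables print conditional living-to-living
## percentages (rows ~ 100) next to a separate per-state annual death
## probability, so a full row-stochastic matrix is composed as: death
## first, then survivors distributed proportionally to the renormalised
## living row.

#' Convert an event rate to a per-period transition probability
#'
#' Uses the standard exponential relation p = 1 - exp(-r t) for a constant
#' rate r over period t.
#'
#' @param rate Nonnegative event rate per unit time.
#' @param t Period length (default one cycle).
#' @return Probability in [0, 1).
#' @export
#' @examples
#' rate_to_prob(0.5)  # 0.3934693
rate_to_prob <- function(rate, t = 1) {
  if (any(rate < 0)) stop("rate must be nonnegative", call. = FALSE)
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  1 - exp(-rate * t)
}

#' Discount a value to present value
#'
#' @param value Numeric (negative values pass through, for incremental
#'   arithmetic).
#' @param rate Nonnegative annual discount rate.
#' @param cycle_index Cycle number (0 = no discounting).
#' @return `value / (1 + rate)^cycle_index`.
#' @export
discount <- function(value, rate, cycle_index) {
  if (any(rate < 0)) stop("rate must be nonnegative", call. = FALSE)
  value / (1 + rate)^cycle_index
}

#' Annual transition table: living rows plus death column
#'
#' @param living_percent 4x4 numeric matrix of living-to-living transition
#'   percentages (rows = from-state, columns = to-state, ordered as
#'   [edss_states()]). Each row must sum to 100 within 0.05; rows inside
#'   that slack are renormalised, larger deviations are rejected.
#' @param death_percent Length-4 numeric: annual probability of death (%)
#'   from each living state.
#' @return An object of class `transition_table`.
#' @export
transition_table <- function(living_percent, death_percent) {
  living_percent <- as.matrix(living_percent)
  if (!all(dim(living_percent) == c(4, 4)))
    .fail_field("living_percent", "must be a 4x4 matrix")
  if (any(living_percent < 0))
    .fail_field("living_percent", "entries must be nonnegative")
  rs <- rowSums(living_percent)
  if (any(abs(rs - 100) > 0.05))
    .fail_field("living_percent",
                sprintf("row sums must be 100 +/- 0.05 (got %s)",
                        paste(round(rs, 4), collapse = ", ")))
  if (length(death_percent) != 4 || any(death_percent < 0) ||
      any(death_percent > 100))
    .fail_field("death_percent", "must be 4 probabilities in [0, 100] percent")
  dimnames(living_percent) <- list(edss_states(), edss_states())
  structure(list(living_percent = living_percent,
                 death_percent = setNames(death_percent, edss_states())),
            class = "transition_table")
}

#' Compose the full 5x5 row-stochastic transition matrix
#'
#' For each living state s with annual death probability d_s, the
#' composed row is P(s -> Death) = d_s and
#' P(s -> j) = (1 - d_s) * p_sj / sum_k p_sk over the living columns.
#' Death is absorbing.
#'
#' @param tt A [transition_table()].
#' @return 5x5 matrix (rows/cols: the four EDSS states then Death); every
#'   row sums to 1 within 1e-12.
#' @export
build_transition_matrix <- function(tt) {
  stopifnot(inherits(tt, "transition_table"))
  d <- tt$death_percent / 100
  liv <- tt$living_percent / rowSums(tt$living_percent)  # renormalise
  M <- matrix(0, 5, 5,
              dimnames = list(c(edss_states(), death_state()),
                              c(edss_states(), death_state())))
  M[1:4, 1:4] <- (1 - d) * liv
  M[1:4, 5] <- d
  M[5, 5] <- 1
  stopifnot(all(abs(rowSums(M) - 1) < 1e-12))
  M
}

#' Per-arm model parameters
#'
#' @param name Arm label.
#' @param annual_relapse_prob Annual probability of relapse while the
#'   disease-modifying therapy (DMT) is active.
#' @param state_utilities Named utility per living state (at most 1).
#' @param drug_cost_annual Annual DMT acquisition/administration cost
#'   (PPP$), incurred only in `dmt_active_states`.
#' @param other_cost Named annual non-drug cost per living state (PPP$).
#' @param dmt_active_states States in which DMT is given (default the
#'   RRMS bands; therapy stops at secondary progression).
#' @return An object of class `arm_parameters`.
#' @export
arm_parameters <- function(name, annual_relapse_prob, state_utilities,
                           drug_cost_annual, other_cost,
                           dmt_active_states = rrms_states()) {
  if (annual_relapse_prob < 0 || annual_relapse_prob > 1)
    .fail_field("annual_relapse_prob", "must lie in [0, 1]")
  for (fld in c("state_utilities", "other_cost")) {
    v <- get(fld)
    if (!all(edss_states() %in% names(v)))
      .fail_field(fld, "must be named over all four EDSS states")
  }
  if (any(state_utilities > 1))
    .fail_field("state_utilities", "utilities must be at most 1")
  if (drug_cost_annual < 0 || any(other_cost < 0))
    .fail_field("drug_cost_annual/other_cost", "costs must be nonnegative")
  if (!all(dmt_active_states %in% edss_states()))
    .fail_field("dmt_active_states", "must be a subset of the EDSS states")
  structure(list(name = name, annual_relapse_prob = annual_relapse_prob,
                 state_utilities = state_utilities[edss_states()],
                 drug_cost_annual = drug_cost_annual,
                 other_cost = other_cost[edss_states()],
                 dmt_active_states = dmt_active_states),
            class = "arm_parameters")
}

#' Run settings for the cohort model
#'
#' @param start_age Cohort age at model entry (years; default 34).
#' @param max_age Age at which the horizon ends (default 100, i.e. a
#'   lifetime horizon of 66 annual cycles from age 34).
#' @param discount_rate_costs Annual discount rate for costs (default 0.058).
#' @param discount_rate_outcomes Annual discount rate for QALYs and
#'   relapses (default 0.03).
#' @param start_distribution Named occupancy over living states at entry
#'   (default: everyone in EDSS 0-2.5); must sum to 1.
#' @param survival_floor Stop cycling when living occupancy falls below
#'   this (default 1e-6).
#' @param half_cycle_correction Accrue on the average of cycle-start and
#'   cycle-end occupancy (default FALSE: cycle-start occupancy).
#' @param discount_first_cycle If TRUE the first cycle is discounted one
#'   period; default FALSE (first cycle undiscounted, factor (1+r)^0).
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(start_age = 34, max_age = 100,
                           discount_rate_costs = 0.058,
                           discount_rate_outcomes = 0.03,
                           start_distribution =
                             setNames(c(1, 0, 0, 0), edss_states()),
                           survival_floor = 1e-6,
                           half_cycle_correction = FALSE,
                           discount_first_cycle = FALSE) {
  if (discount_rate_costs < 0 || discount_rate_outcomes < 0)
    .fail_field("discount_rate", "rates must be nonnegative")
  if (max_age <= start_age)
    .fail_field("max_age", "must exceed start_age")
  if (!all(edss_states() %in% names(start_distribution)))
    .fail_field("start_distribution", "must be named over the EDSS states")
  if (abs(sum(start_distribution) - 1) > 1e-9 || any(start_distribution < 0))
    .fail_field("start_distribution", "must be a distribution summing to 1")
  structure(list(start_age = start_age, max_age = max_age,
                 cycle_length = 1,
                 discount_rate_costs = discount_rate_costs,
                 discount_rate_outcomes = discount_rate_outcomes,
                 start_distribution = start_distribution[edss_states()],
                 survival_floor = survival_floor,
                 half_cycle_correction = half_cycle_correction,
                 discount_first_cycle = discount_first_cycle),
            class = "model_settings")
}

## lean engine shared by run_cohort() and the PSA loop.
## M: 5x5 matrix; u, cost_state, relapse_state: per living state accrual
## weights. Returns per-cycle matrices of occupancy and accruals.
.run_engine <- function(M, u, cost_state, relapse_state, settings) {
  n_cycles <- settings$max_age - settings$start_age
  occ <- c(settings$start_distribution, 0)  # death mass last
  disc_c <- 1 / (1 + settings$discount_rate_costs)
  disc_o <- 1 / (1 + settings$discount_rate_outcomes)
  k0 <- if (settings$discount_first_cycle) 1L else 0L
  rows <- vector("list", n_cycles)
  for (k in seq_len(n_cycles) - 1L) {
    living <- occ[1:4]
    if (sum(living) < settings$survival_floor) break
    w <- living
    if (settings$half_cycle_correction) {
      nxt <- as.numeric(occ %*% M)
      w <- (living + nxt[1:4]) / 2
    }
    qaly <- sum(w * u)
    cost <- sum(w * cost_state)
    rel <- sum(w * relapse_state)
    fc <- disc_c^(k + k0); fo <- disc_o^(k + k0)
    rows[[k + 1L]] <- c(cycle = k, age = settings$start_age + k,
                        occ[1:5],
                        cost = cost, cost_disc = cost * fc,
                        qaly = qaly, qaly_disc = qaly * fo,
                        relapses = rel, relapses_disc = rel * fo,
                        life_years = sum(living))
    occ <- as.numeric(occ %*% M)
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Run the lifetime Markov cohort model for one arm
#'
#' Starting from the entry distribution, the cohort is propagated through
#' annual cycles (`occupancy_{k+1} = occupancy_k %*% M`). During cycle k
#' the cohort accrues, weighted by cycle-start occupancy (or the
#' half-cycle average if enabled):
#' utilities (QALYs), state costs (non-drug cost everywhere, drug cost
#' only in DMT-active states) and expected relapses (relapse probability
#' applied to RRMS occupancy while DMT is active). Costs are discounted
#' at the cost rate, QALYs and relapses at the outcome rate, with factor
#' `(1+r)^-k` and k starting at 0 unless `discount_first_cycle`. The run
#' stops at `max_age` or when living occupancy drops below
#' `survival_floor`.
#'
#' @param tt A [transition_table()].
#' @param arm An [arm_parameters()].
#' @param settings A [model_settings()].
#' @return A list of class `cohort_run` with elements `trace` (data frame
#'   of per-cycle occupancies and accruals) and `result` (an
#'   [arm_result()] with discounted totals).
#' @export
run_cohort <- function(tt, arm, settings = model_settings()) {
  stopifnot(inherits(arm, "arm_parameters"),
            inherits(settings, "model_settings"))
  M <- build_transition_matrix(tt)
  if (any(abs(rowSums(M) - 1) > 1e-9))
    stop("transition matrix is not row-stochastic", call. = FALSE)
  u <- arm$state_utilities
  dmt <- edss_states() %in% arm$dmt_active_states
  cost_state <- arm$other_cost + arm$drug_cost_annual * dmt
  relapse_state <- arm$annual_relapse_prob *
    (edss_states() %in% rrms_states() & dmt)
  tr <- .run_engine(M, u, cost_state, relapse_state, settings)
  trace <- as.data.frame(tr)
  names(trace) <- c("cycle", "age", edss_states(), death_state(),
                    "cost", "cost_disc", "qaly", "qaly_disc",
                    "relapses", "relapses_disc", "life_years")
  res <- arm_result(name = arm$name,
                    cost = sum(trace$cost_disc),
                    qaly = sum(trace$qaly_disc),
                    relapses = sum(trace$relapses_disc),
                    life_years = sum(trace$life_years),
                    cost_undiscounted = sum(trace$cost),
                    qaly_undiscounted = sum(trace$qaly))
  structure(list(trace = trace, result = res), class = "cohort_run")
}

#' Lifetime results for one arm
#'
#' Container for an arm's discounted totals; also used to enter published
#' arm-level results directly into [compare_strategies()].
#'
#' @param name Arm label.
#' @param cost Total discounted cost (PPP$).
#' @param qaly Total discounted QALYs.
#' @param relapses Total discounted expected relapses.
#' @param life_years Undiscounted life years.
#' @param cost_undiscounted,qaly_undiscounted Optional undiscounted totals.
#' @return An object of class `arm_result`.
#' @export
arm_result <- function(name, cost, qaly, relapses = NA_real_,
                       life_years = NA_real_,
                       cost_undiscounted = NA_real_,
                       qaly_undiscounted = NA_real_) {
  if (cost < 0 || qaly < 0)
    .fail_field("cost/qaly", "must be nonnegative")
  structure(list(name = name, cost = cost, qaly = qaly, relapses = relapses,
                 life_years = life_years,
                 cost_undiscounted = cost_undiscounted,
                 qaly_undiscounted = qaly_undiscounted),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result '%s'>  cost %.2f PPP$, %.3f QALYs, %.3f relapses\n",
              x$name, x$cost, x$qaly, x$relapses))
  invisible(x)
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("<cohort_run>  %d cycles\n", nrow(x$trace)))
  print(x$result)
  invisible(x)
}
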