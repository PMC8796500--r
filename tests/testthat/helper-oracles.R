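# Independent oracles used across tests: none of these call the engine
# path they check.

# occupancy after n cycles by explicit matrix power
matrix_power_occupancy <- function(M, start, n) {
  occ <- c(start, 0)
  P <- diag(nrow(M))
  for (i in seq_len(n)) P <- P %*% M
  as.numeric(occ %*% P)
}

# individual-level microsimulation of the same annual-cycle process:
# each of n patients walks the transition matrix; QALYs accrue on the
# cycle-start state, discounted at the outcome rate with the first cycle
# undiscounted. Returns the per-patient discounted QALY vector.
microsim_qalys <- function(M, u, settings, n, seed) {
  set.seed(seed)
  n_cycles <- settings$max_age - settings$start_age
  cum <- t(apply(M, 1, cumsum))
  state <- sample(1:4, n, replace = TRUE,
                  prob = as.numeric(settings$start_distribution))
  uu <- c(as.numeric(u), 0)
  disc <- (1 + settings$discount_rate_outcomes)^-(seq_len(n_cycles) - 1L)
  q <- numeric(n)
  for (k in seq_len(n_cycles)) {
    if (all(state == 5L)) break
    q <- q + disc[k] * uu[state]
    r <- runif(n)
    nxt <- state
    for (s in 1:4) {
      idx <- which(state == s)
      if (length(idx)) nxt[idx] <- findInterval(r[idx], cum[s, ]) + 1L
    }
    state <- nxt
  }
  q
}

# a transition table with no transitions and no death (identity process)
identity_transition_table <- function() {
  transition_table(diag(4) * 100, rep(0, 4))
}

# small flat arm: utility u everywhere, no costs, no relapses
flat_arm <- function(name = "flat", u = 1) {
  arm_parameters(name, 0, setNames(rep(u, 4), edss_states()), 0,
                 setNames(rep(0, 4), edss_states()))
}

base_tt <- function() {
  cfg <- base_case_config()
  config_objects(cfg)$tt
}

# hand-built PSA sample frame from per-iteration (cost, qaly) pairs
fake_psa <- function(cost_nat, qaly_nat, cost_rit, qaly_rit) {
  data.frame(cost_natalizumab = cost_nat, qaly_natalizumab = qaly_nat,
             cost_rituximab = cost_rit, qaly_rituximab = qaly_rit)
}
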