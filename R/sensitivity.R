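## Parameter uncertainty: method-of-moments beta/gamma fitting,
## second-order Monte-Carlo (PSA) rerunning the full cohort model per
## draw, cost-effectiveness acceptability curves, cost-effectiveness
## plane summaries, and a one-way +/-20% tornado analysis.

#' Fit a beta distribution by the method of moments
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy sd^2 < mean (1 - mean).
#' @return Named numeric `c(shape1, shape2)` whose distribution has the
#'   requested mean and sd exactly.
#' @export
#' @examples
#' beta_from_moments(0.833, 0.125)
beta_from_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1)
    stop("beta mean must lie strictly in (0, 1)", call. = FALSE)
  if (sd <= 0) stop("beta sd must be positive", call. = FALSE)
  if (sd^2 >= mean * (1 - mean))
    stop(sprintf(
      "infeasible beta moments: sd^2 = %.4g >= mean(1-mean) = %.4g",
      sd^2, mean * (1 - mean)), call. = FALSE)
  k <- mean * (1 - mean) / sd^2 - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Fit a gamma distribution by the method of moments
#'
#' @param mean Positive mean.
#' @param sd Positive standard deviation.
#' @return Named numeric `c(shape, scale)` with the requested moments.
#' @export
#' @examples
#' gamma_from_moments(36058.08, 7211.616)  # shape 25
gamma_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0)
    stop("gamma mean and sd must be positive", call. = FALSE)
  c(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Probabilistic sensitivity analysis configuration
#'
#' @param n_iterations Monte-Carlo trials (default 5000).
#' @param seed Master seed; all parameter draws derive from it in a fixed
#'   order before any model evaluation, so results are independent of
#'   iteration execution order.
#' @param cost_cv Coefficient of variation applied to every cost
#'   parameter (`NULL`: take from the model config's psa block, default
#'   0.2). Cost dispersions are an assumption, not an observed quantity.
#' @param thresholds Nonnegative, sorted willingness-to-pay grid for the
#'   acceptability curve.
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(n_iterations = 5000, seed = 1L, cost_cv = NULL,
                       thresholds = seq(0, 80000, by = 2000)) {
  if (n_iterations < 1) .fail_field("n_iterations", "must be >= 1")
  if (any(thresholds < 0)) .fail_field("thresholds", "must be nonnegative")
  if (is.unsorted(thresholds)) .fail_field("thresholds", "must be sorted")
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), cost_cv = cost_cv,
                 thresholds = thresholds),
            class = "psa_config")
}

## draw n values with the given moments; sd = 0 means a fixed parameter
.draw_beta <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  p <- beta_from_moments(mean, sd)
  rbeta(n, p[["shape1"]], p[["shape2"]])
}
.draw_gamma <- function(n, mean, sd) {
  if (mean <= 0 || sd <= 0) return(rep(mean, n))
  p <- gamma_from_moments(mean, sd)
  rgamma(n, shape = p[["shape"]], scale = p[["scale"]])
}

#' Run the probabilistic sensitivity analysis
#'
#' Every utility is drawn from a beta distribution (method-of-moments fit
#' to its mean/SD: the observed per-(arm, band) SDs for the RRMS states,
#' the configured placeholder SDs for the SPMS states) and every cost
#' parameter (per-arm annual drug cost and per-state non-drug cost) from
#' a gamma distribution with the configured coefficient of variation.
#' Transition and relapse probabilities are not sampled. Each iteration
#' reruns the full lifetime Markov model for both arms with its drawn
#' parameter set. All draws are taken vectorised from the master seed
#' before any model run, making the sample collection deterministic given
#' the seed. A parameter with SD 0 (or CV 0) stays fixed at its mean, so
#' the PSA degenerates to the base case as dispersions shrink to zero.
#'
#' @param cfg An `ms_model_config`.
#' @param psa A [psa_config()].
#' @return An object of class `psa_result`: a data frame of samples (one
#'   row per iteration: drawn parameters, per-arm discounted cost and
#'   QALYs, `delta_cost` and `delta_qaly` for rituximab minus
#'   natalizumab), with the config threshold in attribute `threshold`.
#' @export
run_psa <- function(cfg, psa = psa_config()) {
  obj <- config_objects(cfg)
  n <- psa$n_iterations
  cv <- psa$cost_cv
  if (is.null(cv)) cv <- if (!is.null(cfg$psa$cost_cv)) cfg$psa$cost_cv else 0.2
  spms_sd <- unlist(cfg$psa$spms_utility_sd)
  M <- build_transition_matrix(obj$tt)

  set.seed(psa$seed)
  draws <- list()
  for (a in arm_names()) {
    arm <- cfg$arms[[a]]
    usd <- unlist(arm$utility_sd)
    if (is.null(usd)) usd <- numeric(0)
    for (s in edss_states()) {
      sdev <- if (s %in% rrms_states()) {
        if (is.na(usd[s])) 0 else usd[[s]]
      } else {
        if (is.null(spms_sd) || is.na(spms_sd[s])) 0 else spms_sd[[s]]
      }
      draws[[paste0("u_", a, "_", s)]] <-
        .draw_beta(n, arm$utilities[[s]], sdev)
    }
    draws[[paste0("drug_cost_", a)]] <-
      .draw_gamma(n, arm$drug_cost_annual, cv * arm$drug_cost_annual)
    for (s in edss_states())
      draws[[paste0("other_cost_", a, "_", s)]] <-
        .draw_gamma(n, arm$other_cost[[s]], cv * arm$other_cost[[s]])
  }

  out <- matrix(NA_real_, nrow = n, ncol = 4,
                dimnames = list(NULL, c("cost_natalizumab",
                                        "qaly_natalizumab",
                                        "cost_rituximab", "qaly_rituximab")))
  dmt <- edss_states() %in% rrms_states()
  for (i in seq_len(n)) {
    for (a in arm_names()) {
      u <- vapply(edss_states(), function(s)
        draws[[paste0("u_", a, "_", s)]][i], numeric(1))
      oc <- vapply(edss_states(), function(s)
        draws[[paste0("other_cost_", a, "_", s)]][i], numeric(1))
      cost_state <- oc + draws[[paste0("drug_cost_", a)]][i] * dmt
      relapse_state <- cfg$arms[[a]]$annual_relapse_prob * dmt
      tr <- .run_engine(M, u, cost_state, relapse_state, obj$settings)
      out[i, paste0("cost_", a)] <- sum(tr[, "cost_disc"])
      out[i, paste0("qaly_", a)] <- sum(tr[, "qaly_disc"])
    }
  }
  samples <- cbind(data.frame(iteration = seq_len(n)),
                   as.data.frame(draws, check.names = FALSE),
                   as.data.frame(out))
  samples$delta_cost <- samples$cost_rituximab - samples$cost_natalizumab
  samples$delta_qaly <- samples$qaly_rituximab - samples$qaly_natalizumab
  structure(samples,
            class = c("psa_result", "data.frame"),
            strategies = arm_names(),
            threshold = obj$threshold$value,
            seed = psa$seed, cost_cv = cv,
            thresholds = psa$thresholds)
}

.psa_samples <- function(samples) {
  if (inherits(samples, "psa_result") || is.data.frame(samples)) {
    need <- c("cost_natalizumab", "qaly_natalizumab",
              "cost_rituximab", "qaly_rituximab")
    if (!all(need %in% names(samples)))
      stop("samples need columns ", paste(need, collapse = ", "),
           call. = FALSE)
    samples
  } else stop("expected a psa_result or data frame of samples", call. = FALSE)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which each strategy has the higher net monetary benefit
#' (QALYs x threshold - cost). Ties are split equally, so the two
#' strategies' fractions sum to 1 at every threshold.
#'
#' @param samples A [run_psa()] result (or equivalent data frame).
#' @param thresholds Nonempty numeric vector of thresholds; defaults to
#'   the grid stored on the `psa_result`.
#' @return Data frame: threshold, p_rituximab, p_natalizumab.
#' @export
ceac <- function(samples, thresholds = attr(samples, "thresholds")) {
  s <- .psa_samples(samples)
  if (is.null(thresholds) || length(thresholds) == 0)
    stop("thresholds must be a nonempty numeric vector", call. = FALSE)
  if (nrow(s) == 0) stop("no PSA samples", call. = FALSE)
  res <- vapply(thresholds, function(lambda) {
    dnmb <- (s$qaly_rituximab - s$qaly_natalizumab) * lambda -
      (s$cost_rituximab - s$cost_natalizumab)
    mean(dnmb > 0) + 0.5 * mean(dnmb == 0)
  }, numeric(1))
  data.frame(threshold = thresholds, p_rituximab = res,
             p_natalizumab = 1 - res)
}

#' Cost-effectiveness plane summary
#'
#' Quadrant proportions of the (incremental QALY, incremental cost) cloud
#' for rituximab vs natalizumab, and the proportion of points in the
#' acceptance region (below the threshold ray, i.e. positive incremental
#' net monetary benefit; ties split equally). Points on a quadrant
#' boundary are classified with "more effective" meaning delta QALY >= 0
#' and "cheaper" meaning delta cost <= 0.
#'
#' @param samples A [run_psa()] result (or equivalent data frame).
#' @param threshold Willingness-to-pay value; defaults to the threshold
#'   stored on the `psa_result`.
#' @return A list of class `ce_plane` with `quadrants` (named
#'   proportions summing to 1), `acceptance_prop`, `threshold` and the
#'   point cloud `points` (delta_qaly, delta_cost).
#' @export
ce_plane <- function(samples, threshold = attr(samples, "threshold")) {
  s <- .psa_samples(samples)
  if (nrow(s) == 0) stop("no PSA samples", call. = FALSE)
  de <- s$qaly_rituximab - s$qaly_natalizumab
  dc <- s$cost_rituximab - s$cost_natalizumab
  quadrants <- c(
    more_effective_cheaper  = mean(de >= 0 & dc <= 0),
    more_effective_costlier = mean(de >= 0 & dc > 0),
    less_effective_cheaper  = mean(de < 0 & dc <= 0),
    less_effective_costlier = mean(de < 0 & dc > 0)
  )
  lambda <- .as_threshold(threshold)
  dnmb <- de * lambda - dc
  structure(list(
    quadrants = quadrants,
    acceptance_prop = mean(dnmb > 0) + 0.5 * mean(dnmb == 0),
    threshold = lambda,
    points = data.frame(delta_qaly = de, delta_cost = dc)
  ), class = "ce_plane")
}

#' @export
print.ce_plane <- function(x, ...) {
  cat("<ce_plane>  quadrant proportions:\n")
  print(round(x$quadrants, 4))
  cat(sprintf("  acceptance (below threshold %.0f): %.2f%%\n",
              x$threshold, 100 * x$acceptance_prop))
  invisible(x)
}

#' Default tornado parameter list
#'
#' Every cost entry (annual drug cost, per-state non-drug cost) and every
#' state utility of both arms, as slash-separated config paths.
#'
#' @param cfg An `ms_model_config`.
#' @return Character vector of config paths.
#' @export
tornado_parameters <- function(cfg) {
  unlist(lapply(arm_names(), function(a) c(
    sprintf("arms/%s/drug_cost_annual", a),
    sprintf("arms/%s/other_cost/%s", a, edss_states()),
    sprintf("arms/%s/utilities/%s", a, edss_states())
  )))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter is set in turn to base x (1 - pct) and base x (1 + pct)
#' holding everything else at base case, and the full model is rerun for
#' both arms. Because the base-case ICER is negative (rituximab
#' dominates) and negative ICERs are not rankable, both the incremental
#' cost and the incremental net monetary benefit (rituximab minus
#' natalizumab) are reported; bars are sorted by the incremental-NMB
#' swing. Perturbed utilities are capped at 1 with a warning.
#'
#' @param cfg An `ms_model_config`.
#' @param parameters Config paths to vary; default [tornado_parameters()].
#' @param pct Relative perturbation (default 0.20).
#' @return A data frame of class `tornado_result`, sorted by descending
#'   bar width: parameter, low_value, high_value, delta_cost_low/high,
#'   inc_nmb_low/high, width.
#' @export
tornado <- function(cfg, parameters = tornado_parameters(cfg), pct = 0.20) {
  if (pct <= 0) .fail_field("pct", "must be positive")
  eval_cfg <- function(cc) {
    obj <- config_objects(cc)
    rr <- run_cohort(obj$tt, obj$arms$rituximab, obj$settings)$result
    rn <- run_cohort(obj$tt, obj$arms$natalizumab, obj$settings)$result
    lambda <- obj$threshold$value
    c(delta_cost = rr$cost - rn$cost,
      inc_nmb = (rr$qaly - rn$qaly) * lambda - (rr$cost - rn$cost))
  }
  base <- eval_cfg(cfg)
  rows <- lapply(parameters, function(p) {
    bv <- config_get(cfg, p)
    if (!is.numeric(bv) || length(bv) != 1)
      stop("tornado parameter must address a scalar: ", p, call. = FALSE)
    vals <- bv * c(1 - pct, 1 + pct)
    is_util <- grepl("/utilities/", p, fixed = TRUE)
    if (is_util && any(vals > 1)) {
      warning(sprintf("perturbed utility for '%s' capped at 1", p),
              call. = FALSE)
      vals <- pmin(vals, 1)
    }
    lo <- eval_cfg(config_set(cfg, p, vals[1]))
    hi <- eval_cfg(config_set(cfg, p, vals[2]))
    data.frame(parameter = p, low_value = vals[1], high_value = vals[2],
               delta_cost_low = lo[["delta_cost"]],
               delta_cost_high = hi[["delta_cost"]],
               inc_nmb_low = lo[["inc_nmb"]],
               inc_nmb_high = hi[["inc_nmb"]],
               width = abs(hi[["inc_nmb"]] - lo[["inc_nmb"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "baseline") <- base
  attr(out, "pct") <- pct
  class(out) <- c("tornado_result", "data.frame")
  out
}
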