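## Incremental cost-effectiveness arithmetic for a two-strategy
## comparison: deltas, ICER or dominance verdict, and net monetary
## benefit at a willingness-to-pay threshold.

#' Willingness-to-pay threshold as a multiple of per-capita GDP
#'
#' Following the WHO-CHOICE convention for settings without an explicit
#' threshold: one to three times per-capita GDP per QALY.
#'
#' @param gdp_per_capita Per-capita GDP (PPP$; 2019 value 12,547).
#' @param multiplier GDP multiple (default 3).
#' @return An object of class `wtp_threshold` with fields
#'   `gdp_per_capita`, `multiplier`, `value`.
#' @export
#' @examples
#' wtp_threshold(12547, 3)$value  # 37641
wtp_threshold <- function(gdp_per_capita = 12547, multiplier = 3) {
  if (gdp_per_capita <= 0) .fail_field("gdp_per_capita", "must be positive")
  if (multiplier <= 0) .fail_field("multiplier", "must be positive")
  structure(list(gdp_per_capita = gdp_per_capita, multiplier = multiplier,
                 value = gdp_per_capita * multiplier),
            class = "wtp_threshold")
}

.as_threshold <- function(threshold) {
  if (inherits(threshold, "wtp_threshold")) threshold$value
  else as.numeric(threshold)
}

#' Compare two strategies: incremental cost-utility
#'
#' Computes delta cost = cost_a - cost_b and delta effect =
#' effect_a - effect_b (QALYs). Strategy `a` is *dominant* when it is
#' cheaper and more effective (negative delta cost, positive delta
#' effect), *dominated* in the mirrored case; otherwise the ICER
#' delta-cost / delta-effect is compared with the threshold, with the
#' verdict decided by net monetary benefit (NMB = effect x threshold -
#' cost): `icer_below_threshold` when a's NMB is higher, otherwise
#' `icer_above_threshold`. Equal results give `indeterminate`; equal
#' effects with unequal costs are decided on cost alone with the ICER
#' undefined.
#'
#' @param a,b [arm_result()] objects (a is the candidate, b the
#'   comparator).
#' @param threshold A [wtp_threshold()] or numeric threshold (PPP$/QALY).
#' @return An object of class `cea_result` with fields `delta_cost`,
#'   `delta_effect`, `icer`, `verdict`, `nmb` (named, both arms),
#'   `threshold`, and display-rounded `delta_cost_display` (nearest
#'   dollar) and `delta_effect_display` (3 decimals).
#' @export
compare_strategies <- function(a, b, threshold = wtp_threshold()) {
  stopifnot(inherits(a, "arm_result"), inherits(b, "arm_result"))
  lambda <- .as_threshold(threshold)
  dc <- a$cost - b$cost
  de <- a$qaly - b$qaly
  if (!is.finite(dc) || !is.finite(de))
    stop("arm results must be finite", call. = FALSE)
  nmb <- c(a$qaly * lambda - a$cost, b$qaly * lambda - b$cost)
  names(nmb) <- c(a$name, b$name)
  icer <- NA_real_
  if (dc == 0 && de == 0) {
    verdict <- "indeterminate"
  } else if (dc < 0 && de > 0) {
    verdict <- "dominant"
  } else if (dc > 0 && de < 0) {
    verdict <- "dominated"
  } else if (de == 0) {
    verdict <- if (dc < 0) "dominant" else "dominated"  # decided on cost alone
  } else {
    icer <- dc / de
    verdict <- if (nmb[1] > nmb[2]) "icer_below_threshold"
               else "icer_above_threshold"
  }
  structure(list(
    strategy = a$name, comparator = b$name,
    delta_cost = dc, delta_effect = de, icer = icer, verdict = verdict,
    nmb = nmb, threshold = lambda,
    delta_cost_display = round(dc), delta_effect_display = round(de, 3)
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result>  %s vs %s\n", x$strategy, x$comparator))
  cat(sprintf("  incremental cost   %12.0f PPP$\n", x$delta_cost_display))
  cat(sprintf("  incremental QALYs  %12.3f\n", x$delta_effect_display))
  cat(sprintf("  ICER               %12s\n",
              if (is.na(x$icer)) "-" else sprintf("%.0f", x$icer)))
  cat(sprintf("  verdict            %12s (threshold %.0f PPP$/QALY)\n",
              x$verdict, x$threshold))
  invisible(x)
}
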