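## Estimation of model inputs from patient-level records: per-stratum
## EQ-5D-3L utilities, pooled annualised relapse rates, and societal cost
## aggregation mirroring the DMC / DNMC / IC breakdown.

#' Convert Iranian Rials to purchasing-power-parity dollars
#'
#' @param amount_rials Nonnegative amount(s) in Rials.
#' @param rate Rials per PPP dollar (2019 rate: 22,075).
#' @return Amount(s) in PPP dollars.
#' @export
#' @examples
#' ppp_convert(22075)  # 1
ppp_convert <- function(amount_rials, rate = 22075) {
  if (any(amount_rials < 0))
    stop("amount_rials must be nonnegative", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  amount_rials / rate
}

#' Summarise utilities per arm and EDSS band
#'
#' Scores every patient's EQ-5D-3L code against the value set and reports
#' per-(arm, band) sample mean, sample SD (n-1 denominator) and n. A
#' stratum with a single patient gets SD 0 and `sd_undefined = TRUE`; an
#' arm missing one of the RRMS bands triggers a warning and the stratum
#' is omitted.
#'
#' @param cohort An `ms_cohort` (or a data frame shaped like its
#'   `patients` element).
#' @param vs An `eq5d_value_set`.
#' @return Data frame: arm, band, mean, sd, n, sd_undefined.
#' @export
summarize_utilities <- function(cohort, vs) {
  p <- if (inherits(cohort, "ms_cohort")) cohort$patients else cohort
  if (nrow(p) == 0) stop("no patient records", call. = FALSE)
  p$utility <- vapply(p$eq5d_code, score_eq5d, numeric(1), vs = vs)
  out <- do.call(rbind, lapply(split(p, list(p$arm, p$edss_band), drop = TRUE),
    function(g) data.frame(
      arm = g$arm[1], band = g$edss_band[1],
      mean = mean(g$utility),
      sd = if (nrow(g) > 1) sd(g$utility) else 0,
      n = nrow(g),
      sd_undefined = nrow(g) < 2,
      stringsAsFactors = FALSE
    )))
  expected <- expand.grid(arm = unique(p$arm), band = rrms_states(),
                          stringsAsFactors = FALSE)
  miss <- !paste(expected$arm, expected$band) %in% paste(out$arm, out$band)
  if (any(miss))
    warning("empty strata omitted: ",
            paste(expected$arm[miss], expected$band[miss], collapse = "; "),
            call. = FALSE)
  out <- out[order(out$arm, out$band), ]
  rownames(out) <- NULL
  out
}

#' Pooled annualised relapse rate per arm
#'
#' Implements the pooled person-time estimator: total relapses across all
#' patients of an arm divided by their total years of drug use. The
#' additional division by the number of patients described alongside the
#' estimator in some protocols yields a per-patient share rather than a
#' rate; it is available behind `per_patient = TRUE` but off by default
#' because the reported relapse summaries are on the rate scale.
#'
#' @param cohort An `ms_cohort` (or patients data frame).
#' @param per_patient Divide the pooled rate by the arm's patient count.
#' @return Named numeric, one rate per arm.
#' @export
mean_relapse_rate <- function(cohort, per_patient = FALSE) {
  p <- if (inherits(cohort, "ms_cohort")) cohort$patients else cohort
  if (nrow(p) == 0) stop("no patient records: empty arm", call. = FALSE)
  if (any(p$years_on_drug <= 0))
    stop("years_on_drug must be positive", call. = FALSE)
  vapply(split(p, p$arm), function(g) {
    r <- sum(g$relapse_count) / sum(g$years_on_drug)
    if (per_patient) r <- r / nrow(g)
    r
  }, numeric(1))
}

.COST_CATEGORIES <- c("DMC", "DNMC", "IC")

#' Aggregate cost lines into a societal cost breakdown
#'
#' Computes, per arm, item-level mean annual costs per patient, category
#' subtotals (DMC, DNMC, IC), grand total, and percentage shares at two
#' levels: each item within its category and each category within the
#' grand total. An item absent for a patient contributes zero to that
#' patient's total, so the item mean is sum(amount) / n patients.
#'
#' @param cohort An `ms_cohort`, or a data frame of cost lines with
#'   columns patient_id, arm, category, item, amount.
#' @return A named list (one element per arm) of `cost_breakdown`
#'   objects, each a list with elements `items` (category, item, mean,
#'   share_in_category_pct), `categories` (category, subtotal,
#'   share_of_total_pct), `grand_total`, `n_patients` and `zero_total`.
#' @export
aggregate_costs <- function(cohort) {
  if (inherits(cohort, "ms_cohort")) {
    cl <- merge(cohort$cost_lines,
                cohort$patients[, c("patient_id", "arm")], by = "patient_id")
    n_by_arm <- table(cohort$patients$arm)
  } else {
    cl <- cohort
    if (!all(c("patient_id", "arm", "category", "item", "amount") %in% names(cl)))
      stop("cost lines need columns patient_id, arm, category, item, amount",
           call. = FALSE)
    n_by_arm <- vapply(split(cl, cl$arm),
                       function(g) length(unique(g$patient_id)), numeric(1))
  }
  bad <- setdiff(unique(cl$category), .COST_CATEGORIES)
  if (length(bad))
    stop("unknown cost category: ", paste(bad, collapse = ", "), call. = FALSE)
  lapply(split(cl, cl$arm), function(g) {
    n <- as.numeric(n_by_arm[[g$arm[1]]])
    it <- aggregate(amount ~ category + item, data = g, FUN = sum)
    it$mean <- it$amount / n
    it$amount <- NULL
    it$category <- factor(it$category, levels = .COST_CATEGORIES)
    it <- it[order(it$category, it$item), ]
    cat_sub <- vapply(split(it$mean, it$category), sum, numeric(1))
    cat_sub[is.na(cat_sub)] <- 0
    grand <- sum(cat_sub)
    zero <- grand <= 0
    it$share_in_category_pct <- if (zero) 0 else
      100 * it$mean / cat_sub[as.character(it$category)]
    it$share_in_category_pct[cat_sub[as.character(it$category)] == 0] <- 0
    cats <- data.frame(
      category = .COST_CATEGORIES,
      subtotal = as.numeric(cat_sub[.COST_CATEGORIES]),
      share_of_total_pct = if (zero) rep(0, 3) else
        100 * as.numeric(cat_sub[.COST_CATEGORIES]) / grand,
      stringsAsFactors = FALSE
    )
    rownames(it) <- NULL
    it$category <- as.character(it$category)
    structure(list(arm = g$arm[1], items = it, categories = cats,
                   grand_total = grand, n_patients = n, zero_total = zero),
              class = "cost_breakdown")
  })
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown '%s'>  n = %d patients, total %.2f PPP$/yr\n",
              x$arm, x$n_patients, x$grand_total))
  df <- x$categories
  df$subtotal <- round(df$subtotal, 2)
  df$share_of_total_pct <- round(df$share_of_total_pct, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
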