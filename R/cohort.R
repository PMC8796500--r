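## Synthetic patient-level cohort with the statistical structure of the
## study sample: 60 patients per arm, 74.17% female, arm-specific age
## distributions, EQ-5D-3L codes realising per-(arm, EDSS band) utility
## targets, Poisson relapse counts matching per-band annualised relapse
## rates, and micro-costed annual cost lines (count x unit price).

#' Default per-(arm, band) utility targets
#'
#' Observed mean and SD of EQ-5D-3L utilities per arm and EDSS band in the
#' study sample, used as generation targets.
#' @return Data frame with columns arm, band, mean, sd.
#' @export
default_utility_targets <- function() {
  data.frame(
    arm  = rep(arm_names(), each = 2),
    band = rep(rrms_states(), 2),
    mean = c(0.754, 0.530, 0.833, 0.621),
    sd   = c(0.186, 0.120, 0.125, 0.097),
    stringsAsFactors = FALSE
  )
}

#' Default per-(arm, band) annualised relapse-rate targets
#' @return Data frame with columns arm, band, mean, sd.
#' @export
default_relapse_targets <- function() {
  data.frame(
    arm  = rep(arm_names(), each = 2),
    band = rep(rrms_states(), 2),
    mean = c(1.024, 1.667, 0.313, 1.727),
    sd   = c(1.506, 1.782, 0.528, 0.905),
    stringsAsFactors = FALSE
  )
}

#' Default annual cost menu (item, annual count, unit price)
#'
#' Micro-costing menu per arm: direct medical items as annual use counts
#' times 2019 unit prices in PPP dollars; direct non-medical and indirect
#' (human-capital productivity loss) items as precomputed annual amounts
#' (count 1). Amounts are annual per patient.
#'
#' @return Data frame with columns arm, category (DMC/DNMC/IC), item,
#'   count, unit_price.
#' @export
default_cost_menu <- function() {
  nat <- data.frame(
    arm = "natalizumab",
    category = c(rep("DMC", 9), rep("DNMC", 4), rep("IC", 3)),
    item = c("Physicians' Visits", "Main Medicines", "Complete Blood Counts",
             "Biochemistry Tests", "JC Virus Test", "MRI",
             "Supplementary Medicines", "Physiotherapy & Other Services",
             "Hospitalization & Surgeries",
             "Transportation", "Accommodation", "Meals",
             "Purchasing Auxiliary Tools",
             "Income Lost (Outpatient Visits)",
             "Income Lost (Hospitalization)", "Patient's Family Costs"),
    count = c(6, 12, 2, 2, 2, 1, 1, 1, 1, rep(1, 7)),
    unit_price = c(44, 2745, 30, 30, 73, 500, 695.69, 0, 241.60,
                   441.72, 53.14, 53.14, 117.70,
                   282.83, 79.27, 117.48),
    stringsAsFactors = FALSE
  )
  rit <- data.frame(
    arm = "rituximab",
    category = c(rep("DMC", 11), rep("DNMC", 2), rep("IC", 3)),
    item = c("Physicians' Visits", "Main Medicines", "Complete Blood Counts",
             "Biochemistry Tests", "Urinalysis Tests", "Tuberculin Skin Test",
             "Serology Test", "MRI", "Supplementary Medicines",
             "Physiotherapy & Other Services", "Hospitalization & Surgeries",
             "Transportation", "Purchasing Auxiliary Tools",
             "Income Lost (Outpatient Visits)",
             "Income Lost (Hospitalization)", "Patient's Family Costs"),
    count = c(2, 2, 2, 2, 2, 1, 1, 3, 1, 1, 1, rep(1, 5)),
    unit_price = c(44, 1019, 30, 30, 25, 25, 25, 500, 421.64, 647.27, 56.04,
                   27.94, 13.18,
                   254.72, 64.40, 107.08),
    stringsAsFactors = FALSE
  )
  rbind(nat, rit)
}

#' Specification for synthetic cohort generation
#'
#' Defaults emulate the study sample: 60 patients per arm, 74.17% female,
#' ages Normal(33.4, 7.27) for natalizumab and Normal(34.92, 5.94) for
#' rituximab truncated to 18-65 years, all patients enrolled in EDSS band
#' 0-2.5 (configurable mix), utilities and relapse rates targeting the
#' observed per-(arm, band) summaries, and annual cost lines from the
#' micro-costing menu with small multiplicative noise.
#'
#' @param n_per_arm Patients per arm (default 60).
#' @param female_fraction Probability a patient is female (default 0.7417).
#' @param age_mean_by_arm,age_sd_by_arm Named numeric (per arm), years.
#' @param edss_band_probs Named probabilities over [rrms_states()] for the
#'   enrollment band; must sum to 1.
#' @param utility_targets,relapse_targets Data frames as returned by
#'   [default_utility_targets()] / [default_relapse_targets()].
#' @param cost_menu Data frame as returned by [default_cost_menu()].
#' @param cost_noise_sdlog SD (log scale) of the mean-one multiplicative
#'   lognormal noise applied to each cost line (default 0.1).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A validated object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_arm = 60,
                        female_fraction = 0.7417,
                        age_mean_by_arm = c(natalizumab = 33.4, rituximab = 34.92),
                        age_sd_by_arm = c(natalizumab = 7.27, rituximab = 5.94),
                        edss_band_probs = c("EDSS 0-2.5" = 1, "EDSS 3-5.5" = 0),
                        utility_targets = default_utility_targets(),
                        relapse_targets = default_relapse_targets(),
                        cost_menu = default_cost_menu(),
                        cost_noise_sdlog = 0.1,
                        seed = 1L) {
  spec <- structure(list(
    n_per_arm = n_per_arm, female_fraction = female_fraction,
    age_mean_by_arm = age_mean_by_arm, age_sd_by_arm = age_sd_by_arm,
    edss_band_probs = edss_band_probs, utility_targets = utility_targets,
    relapse_targets = relapse_targets, cost_menu = cost_menu,
    cost_noise_sdlog = cost_noise_sdlog, seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#' @param spec A `cohort_spec`.
#' @return The spec, invisibly; errors name the offending field.
#' @export
validate_cohort_spec <- function(spec) {
  if (!is.numeric(spec$n_per_arm) || length(spec$n_per_arm) != 1 ||
      spec$n_per_arm < 0 || spec$n_per_arm != round(spec$n_per_arm))
    .fail_field("n_per_arm", "must be a single nonnegative integer")
  if (spec$female_fraction < 0 || spec$female_fraction > 1)
    .fail_field("female_fraction", "must lie in [0, 1]")
  for (a in arm_names()) {
    if (is.na(spec$age_mean_by_arm[a]))
      .fail_field("age_mean_by_arm", sprintf("missing arm '%s'", a))
    if (is.na(spec$age_sd_by_arm[a]) || spec$age_sd_by_arm[a] <= 0)
      .fail_field("age_sd_by_arm", sprintf("SD for arm '%s' must be > 0", a))
  }
  if (abs(sum(spec$edss_band_probs) - 1) > 1e-9)
    .fail_field("edss_band_probs", "must sum to 1 (within 1e-9)")
  if (any(spec$edss_band_probs < 0))
    .fail_field("edss_band_probs", "must be nonnegative")
  if (!all(names(spec$edss_band_probs) %in% rrms_states()))
    .fail_field("edss_band_probs", "names must be RRMS bands")
  for (tgt in c("utility_targets", "relapse_targets")) {
    df <- spec[[tgt]]
    if (!all(c("arm", "band", "mean", "sd") %in% names(df)))
      .fail_field(tgt, "needs columns arm, band, mean, sd")
    if (any(df$sd < 0)) .fail_field(tgt, "SDs must be nonnegative")
  }
  if (any(spec$utility_targets$mean > 1))
    .fail_field("utility_targets", "means must be at most 1")
  cm <- spec$cost_menu
  if (any(cm$count < 0)) .fail_field("cost_menu", "counts must be >= 0")
  if (any(cm$unit_price < 0)) .fail_field("cost_menu", "unit prices must be >= 0")
  if (!all(cm$category %in% c("DMC", "DNMC", "IC")))
    .fail_field("cost_menu", "categories must be DMC, DNMC or IC")
  invisible(spec)
}

.truncnorm <- function(n, mean, sd, lo, hi) {
  ## draw-until-inside; fine for mild truncation
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

## mean of Normal(mu, sd) truncated to [lo, hi]
.truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

## truncated-normal draws whose TRUNCATED mean equals `target`: the
## location parameter is solved for, so truncation does not bias the
## generated sample means away from the study targets
.truncnorm_calibrated <- function(n, target, sd, lo, hi) {
  if (sd <= 1e-8) return(rep(min(max(target, lo), hi), n))
  f <- function(mu) .truncnorm_mean(mu, sd, lo, hi) - target
  lo_mu <- target - 8 * sd; hi_mu <- target + 8 * sd
  if (f(hi_mu) < 0) mu <- hi_mu
  else if (f(lo_mu) > 0) mu <- lo_mu
  else mu <- stats::uniroot(f, c(lo_mu, hi_mu), tol = 1e-10)$root
  .truncnorm(n, mu, sd, lo, hi)
}

## map target utility draws to nearest code under the value set
.nearest_code <- function(u, vs) {
  ord <- order(vs$scores)
  s <- vs$scores[ord]
  codes <- names(s)
  i <- findInterval(u, s, all.inside = TRUE)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(s))
  pick <- ifelse(abs(u - s[lo]) <= abs(s[hi] - u), lo, hi)
  codes[pick]
}

#' Generate a synthetic patient-level cohort
#'
#' Deterministic given `spec$seed`. Utility targets are realised by
#' drawing a target utility from a truncated normal and selecting the
#' EQ-5D-3L code whose value-set score is closest, so the scoring path is
#' exercised downstream. Relapse counts are Poisson with mean
#' rate x years-on-drug, where years-on-drug is 1 + Exponential(mean 2)
#' truncated at 10 (the study enrolled only patients with at least one
#' year of drug use). Cost lines are count x unit price with mean-one
#' multiplicative lognormal noise.
#'
#' @param spec A [cohort_spec()].
#' @param vs Value set used to realise utility targets (default the
#'   bundled synthetic test set).
#' @return An object of class `ms_cohort`: a list with data frames
#'   `patients` (patient_id, arm, age, sex, edss_band, eq5d_code,
#'   relapse_count, years_on_drug) and `cost_lines` (patient_id, category,
#'   item, amount).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_arm = 5, seed = 1))
#' coh$patients
generate_cohort <- function(spec, vs = synthetic_value_set()) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  smin <- min(vs$scores)
  pats <- list(); lines <- list()
  for (a in arm_names()) {
    n <- spec$n_per_arm
    if (n == 0) next
    id <- sprintf("%s-%03d", substr(a, 1, 3), seq_len(n))
    age <- .truncnorm_calibrated(n, spec$age_mean_by_arm[[a]],
                                 spec$age_sd_by_arm[[a]], 18, 65)
    sex <- ifelse(runif(n) < spec$female_fraction, "F", "M")
    band <- sample(names(spec$edss_band_probs), n, replace = TRUE,
                   prob = spec$edss_band_probs)
    ut <- spec$utility_targets[spec$utility_targets$arm == a, ]
    um <- setNames(ut$mean, ut$band); us <- setNames(ut$sd, ut$band)
    utarget <- numeric(n)
    for (b in unique(band)) {
      idx <- which(band == b)
      utarget[idx] <- .truncnorm_calibrated(length(idx), um[[b]], us[[b]],
                                            smin, 1)
    }
    code <- .nearest_code(utarget, vs)
    years <- pmin(1 + rexp(n, rate = 1 / 2), 10)
    rt <- spec$relapse_targets[spec$relapse_targets$arm == a, ]
    rm_ <- setNames(rt$mean, rt$band)
    relapse <- rpois(n, lambda = rm_[band] * years)
    pats[[a]] <- data.frame(
      patient_id = id, arm = a, age = age, sex = sex, edss_band = band,
      eq5d_code = code, relapse_count = relapse, years_on_drug = years,
      stringsAsFactors = FALSE
    )
    menu <- spec$cost_menu[spec$cost_menu$arm == a, ]
    k <- nrow(menu)
    sdl <- spec$cost_noise_sdlog
    noise <- rlnorm(n * k, meanlog = -sdl^2 / 2, sdlog = sdl)
    lines[[a]] <- data.frame(
      patient_id = rep(id, each = k),
      category = rep(menu$category, n),
      item = rep(menu$item, n),
      amount = rep(menu$count * menu$unit_price, n) * noise,
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    patients = if (length(pats)) do.call(rbind, unname(pats)) else
      data.frame(patient_id = character(), arm = character(),
                 age = numeric(), sex = character(), edss_band = character(),
                 eq5d_code = character(), relapse_count = integer(),
                 years_on_drug = numeric(), stringsAsFactors = FALSE),
    cost_lines = if (length(lines)) do.call(rbind, unname(lines)) else
      data.frame(patient_id = character(), category = character(),
                 item = character(), amount = numeric(),
                 stringsAsFactors = FALSE)
  ), class = "ms_cohort")
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf("<ms_cohort>  %d patients (%s), %d cost lines\n",
              nrow(x$patients),
              paste(sprintf("%s: %d", names(table(x$patients$arm)),
                            table(x$patients$arm)), collapse = ", "),
              nrow(x$cost_lines)))
  invisible(x)
}

## full-precision numeric formatting so write/read round-trips exactly
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a cohort to delimited text files
#'
#' Writes two UTF-8 tab-separated files: `<stem>.patients.tsv` (one row
#' per patient) and `<stem>.costs.tsv` (long format, one cost line per
#' row, keyed by patient_id). Numeric fields are written at full precision
#' so that [read_cohort()] reproduces the cohort exactly.
#'
#' @param cohort An `ms_cohort`.
#' @param stem Path stem for the two output files.
#' @return The two file paths, invisibly.
#' @export
write_cohort <- function(cohort, stem) {
  stopifnot(inherits(cohort, "ms_cohort"))
  p <- cohort$patients
  p$age <- .fmt_num(p$age)
  p$years_on_drug <- .fmt_num(p$years_on_drug)
  cl <- cohort$cost_lines
  cl$amount <- .fmt_num(cl$amount)
  fp <- paste0(stem, ".patients.tsv")
  fc <- paste0(stem, ".costs.tsv")
  write.table(p, fp, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  write.table(cl, fc, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(c(patients = fp, costs = fc))
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates every row; a malformed row raises a parse error naming the
#' file, line number and offending value.
#'
#' @param stem Path stem used in [write_cohort()].
#' @return An `ms_cohort`.
#' @export
read_cohort <- function(stem) {
  fp <- paste0(stem, ".patients.tsv")
  fc <- paste0(stem, ".costs.tsv")
  for (f in c(fp, fc)) if (!file.exists(f))
    stop("cohort file not found: ", f, call. = FALSE)
  p <- read.delim(fp, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character",
                                 eq5d_code = "character"))
  cl <- read.delim(fc, stringsAsFactors = FALSE,
                   colClasses = c(patient_id = "character"))
  ## stable column types even for header-only files
  p$arm <- as.character(p$arm); p$sex <- as.character(p$sex)
  p$edss_band <- as.character(p$edss_band)
  p$age <- as.numeric(p$age); p$years_on_drug <- as.numeric(p$years_on_drug)
  p$relapse_count <- as.integer(p$relapse_count)
  cl$category <- as.character(cl$category); cl$item <- as.character(cl$item)
  cl$amount <- as.numeric(cl$amount)
  if (nrow(p)) {
    for (i in seq_len(nrow(p))) {
      line <- i + 1L  # header is line 1
      code <- p$eq5d_code[i]
      if (!grepl("^[123]{5}$", code)) {
        bad <- regmatches(code, regexpr("[^123]", code))
        stop(sprintf(
          "%s line %d: malformed eq5d_code '%s'%s", basename(fp), line, code,
          if (length(bad)) sprintf(" (invalid level '%s')", bad) else ""),
          call. = FALSE)
      }
      if (!p$arm[i] %in% arm_names())
        stop(sprintf("%s line %d: unknown arm '%s'", basename(fp), line,
                     p$arm[i]), call. = FALSE)
      if (is.na(p$years_on_drug[i]) || p$years_on_drug[i] < 1)
        stop(sprintf("%s line %d: years_on_drug must be >= 1", basename(fp),
                     line), call. = FALSE)
      if (is.na(p$relapse_count[i]) || p$relapse_count[i] < 0)
        stop(sprintf("%s line %d: relapse_count must be >= 0", basename(fp),
                     line), call. = FALSE)
    }
  }
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      line <- i + 1L
      if (!cl$category[i] %in% c("DMC", "DNMC", "IC"))
        stop(sprintf("%s line %d: unknown cost category '%s'", basename(fc),
                     line, cl$category[i]), call. = FALSE)
      if (is.na(cl$amount[i]) || cl$amount[i] < 0)
        stop(sprintf("%s line %d: cost amount must be >= 0", basename(fc),
                     line), call. = FALSE)
    }
  }
  structure(list(patients = p, cost_lines = cl), class = "ms_cohort")
}
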