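vs <- synthetic_value_set()

make_patients <- function(arm, codes, band = "EDSS 0-2.5",
                          relapses = 0, years = 1) {
  n <- length(codes)
  data.frame(patient_id = paste0(arm, seq_len(n)), arm = arm,
             age = 30, sex = "F", edss_band = band, eq5d_code = codes,
             relapse_count = rep_len(relapses, n),
             years_on_drug = rep_len(years, n), stringsAsFactors = FALSE)
}

test_that("utility summaries use the sample SD and flag singletons", {
  # two codes with known scores: hand-computed mean and n-1 SD
  u1 <- score_eq5d("21111", vs); u2 <- score_eq5d("31111", vs)
  p <- make_patients("rituximab", c("21111", "31111"))
  s <- suppressWarnings(summarize_utilities(p, vs))  # one band only
  expect_equal(s$mean, (u1 + u2) / 2)
  expect_equal(s$sd, sqrt(((u1 - (u1 + u2) / 2)^2 + (u2 - (u1 + u2) / 2)^2)))
  expect_equal(s$n, 2)

  # the canonical two-point case: utilities 0.4 and 0.6 via a custom set
  vs2 <- value_set(setNames(ifelse(eq5d_codes() == "11111", 1,
                                   ifelse(eq5d_codes() == "22222", 0.4,
                                          ifelse(eq5d_codes() == "33333",
                                                 0.6, 0.5))),
                            eq5d_codes()), "two-point")
  p2 <- make_patients("rituximab", c("22222", "33333"))
  s2 <- suppressWarnings(summarize_utilities(p2, vs2))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$sd, 0.1414214, tolerance = 1e-6)

  # single record: SD reported 0 and flagged; missing stratum warned
  expect_warning(summarize_utilities(make_patients("rituximab", "21111"), vs),
                 "omitted")
  s1 <- suppressWarnings(
    summarize_utilities(make_patients("rituximab", "21111"), vs))
  expect_equal(s1$sd, 0)
  expect_true(s1$sd_undefined)
})

test_that("utility means always lie inside the value set's range", {
  for (seed in 1:3) {
    coh <- generate_cohort(cohort_spec(n_per_arm = 30, seed = seed,
                                       edss_band_probs =
                                         c("EDSS 0-2.5" = 0.5,
                                           "EDSS 3-5.5" = 0.5)), vs)
    s <- summarize_utilities(coh, vs)
    expect_true(all(s$mean >= min(vs$scores) & s$mean <= max(vs$scores)))
    expect_true(all(s$sd >= 0) && all(s$n >= 1))
  }
})

test_that("the pooled relapse-rate estimator matches its definition", {
  # one patient, 2 relapses in 2 years
  expect_equal(unname(mean_relapse_rate(
    make_patients("rituximab", "11111", relapses = 2, years = 2))), 1.0)
  # (3/2yr) and (1/2yr) pool to 4/4 = 1
  p <- make_patients("rituximab", c("11111", "11111"),
                     relapses = c(3, 1), years = 2)
  expect_equal(unname(mean_relapse_rate(p)), 1.0)
  # per-patient variant divides by n
  expect_equal(unname(mean_relapse_rate(p, per_patient = TRUE)), 0.5)
  # zero relapses
  expect_equal(unname(mean_relapse_rate(
    make_patients("rituximab", c("11111", "11111")))), 0)
  # invariant to patient ordering
  p2 <- make_patients("natalizumab", rep("11111", 4),
                      relapses = c(0, 1, 2, 5), years = c(1, 2, 3, 4))
  expect_equal(mean_relapse_rate(p2), mean_relapse_rate(p2[4:1, ]))
  # merging two patients with identical rates leaves the pooled rate fixed
  p3 <- make_patients("natalizumab", rep("11111", 2), relapses = 2, years = 2)
  p4 <- make_patients("natalizumab", "11111", relapses = 4, years = 4)
  expect_equal(mean_relapse_rate(p3), mean_relapse_rate(p4))
  # empty input errors
  expect_error(mean_relapse_rate(p3[0, ]), "empty")
})

test_that("cost aggregation is additive and validates categories", {
  coh <- generate_cohort(cohort_spec(n_per_arm = 20, seed = 6))
  whole <- aggregate_costs(coh)
  # split the cohort in two and pool: weighted item means must agree
  ids <- coh$patients$patient_id
  half <- ids[seq(1, length(ids), by = 2)]
  c1 <- list(patients = coh$patients[coh$patients$patient_id %in% half, ],
             cost_lines = coh$cost_lines[coh$cost_lines$patient_id %in% half, ])
  c2 <- list(patients = coh$patients[!coh$patients$patient_id %in% half, ],
             cost_lines = coh$cost_lines[!coh$cost_lines$patient_id %in% half, ])
  class(c1) <- class(c2) <- "ms_cohort"
  b1 <- aggregate_costs(c1); b2 <- aggregate_costs(c2)
  for (a in arm_names()) {
    n1 <- b1[[a]]$n_patients; n2 <- b2[[a]]$n_patients
    pooled <- (b1[[a]]$grand_total * n1 + b2[[a]]$grand_total * n2) / (n1 + n2)
    expect_equal(pooled, whole[[a]]$grand_total)
  }
  # internal consistency: subtotals match item sums, shares sum to 100
  for (a in arm_names()) {
    b <- whole[[a]]
    for (cat in c("DMC", "DNMC", "IC")) {
      expect_equal(sum(b$items$mean[b$items$category == cat]),
                   b$categories$subtotal[b$categories$category == cat],
                   tolerance = 1e-9)
      expect_equal(sum(b$items$share_in_category_pct[b$items$category == cat]),
                   100, tolerance = 0.1)
    }
    expect_equal(sum(b$categories$subtotal), b$grand_total, tolerance = 1e-9)
    expect_equal(sum(b$categories$share_of_total_pct), 100, tolerance = 0.1)
  }

  # unknown category label errors
  bad <- coh$cost_lines
  bad$arm <- "rituximab"
  bad$category[1] <- "OOPS"
  expect_error(aggregate_costs(bad), "OOPS")
})

test_that("degenerate cost inputs are handled", {
  # single item of 100 in DMC only: 100% shares
  one <- data.frame(patient_id = "p1", arm = "rituximab", category = "DMC",
                    item = "x", amount = 100, stringsAsFactors = FALSE)
  b <- aggregate_costs(one)$rituximab
  expect_equal(b$items$share_in_category_pct, 100)
  expect_equal(b$categories$share_of_total_pct[b$categories$category == "DMC"],
               100)
  expect_equal(b$grand_total, 100)
  # all-zero lines: zero totals, flagged, shares 0
  z <- one; z$amount <- 0
  bz <- aggregate_costs(z)$rituximab
  expect_true(bz$zero_total)
  expect_equal(bz$grand_total, 0)
  expect_equal(bz$items$share_in_category_pct, 0)
})

test_that("PPP conversion divides by the 2019 rate", {
  expect_equal(ppp_convert(22075), 1)
  expect_equal(ppp_convert(0), 0)
  expect_equal(ppp_convert(44150), 2)
  expect_error(ppp_convert(-1), "nonnegative")
})
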