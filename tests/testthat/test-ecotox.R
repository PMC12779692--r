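test_that("acute classification bands match the standard table", {
  expect_equal(as.character(classify_toxicity(150)), "not_harmful")
  expect_equal(as.character(classify_toxicity(50)), "harmful")
  expect_equal(as.character(classify_toxicity(2.511)), "toxic")
  expect_equal(as.character(classify_toxicity(0.263)), "very_toxic")
  expect_equal(as.character(classify_toxicity(0.903)), "very_toxic")
  # boundaries fall in the more-toxic adjacent class
  expect_equal(as.character(classify_toxicity(c(100, 10, 1))),
               c("harmful", "toxic", "very_toxic"))
})

test_that("chronic classification bands match, with the (10,100] gap flagged", {
  expect_equal(as.character(classify_toxicity(0.047, chronic = TRUE)), "very_toxic")
  expect_equal(as.character(classify_toxicity(0.098, chronic = TRUE)), "very_toxic")
  expect_equal(as.character(classify_toxicity(0.5, chronic = TRUE)), "toxic")
  expect_equal(as.character(classify_toxicity(5, chronic = TRUE)), "harmful")
  expect_equal(as.character(classify_toxicity(150, chronic = TRUE)), "not_harmful")
  expect_warning(cls <- classify_toxicity(50, chronic = TRUE),
                 class = "silicotox_chronic_gap")
  expect_equal(as.character(cls), "not_harmful")
  expect_equal(as.character(classify_toxicity(c(10, 1, 0.1), chronic = TRUE)),
               c("harmful", "toxic", "very_toxic"))
})

test_that("all reported fixture concentrations classify as reported", {
  fix <- tscz_toxicity_fixture()
  got <- as.character(classify_toxicity(fix$concentration, chronic = fix$chronic))
  expect_equal(got, fix$reported_class)
})

test_that("classification is a total monotone step function of concentration", {
  set.seed(21)
  for (chronic in c(FALSE, TRUE)) {
    conc <- sort(10^runif(200, -3, 3))
    cls <- suppressWarnings(classify_toxicity(conc, chronic = chronic))
    sev <- match(as.character(cls),
                 c("very_toxic", "toxic", "harmful", "not_harmful"))
    expect_true(all(diff(sev) >= 0))  # severity never increases with conc
  }
  expect_error(classify_toxicity(0), "positive")
  expect_error(classify_toxicity(-1), "positive")
})

test_that("LC50 prediction follows the log-linear model and unit conversion", {
  cf <- list(endpoint_id = "e", m = 0, b = 0, kow_domain_max = 5)
  est <- predict_lc50(log_kow = 3.7, molecular_weight = 1, coeff = cf)
  expect_equal(est$concentration_mg_l, 1)

  cf2 <- list(endpoint_id = "e", m = -1, b = 0, kow_domain_max = 5)
  est2 <- predict_lc50(2, 100, cf2)
  expect_equal(est2$lc50_mmol_l, 0.01)
  expect_equal(est2$concentration_mg_l, 1.0)
  expect_equal(as.character(est2$tox_class), "very_toxic")

  # brute-force oracle over a random (m, b, logKow, MW) grid
  set.seed(9)
  for (i in 1:20) {
    m <- runif(1, -2, 1); b <- runif(1, -1, 2)
    lk <- runif(1, 0, 6); mw <- runif(1, 50, 500)
    est <- predict_lc50(lk, mw,
                        list(endpoint_id = "e", m = m, b = b, kow_domain_max = 5))
    expect_equal(est$concentration_mg_l, 10^(m * lk + b) * mw, tolerance = 1e-12)
  }

  expect_error(predict_lc50(2, 100, list(endpoint_id = "e", m = -1)), "missing")
})

test_that("prediction flags solubility excess and domain violations", {
  cf <- list(endpoint_id = "e", m = 0, b = 1, kow_domain_max = 5)
  est <- predict_lc50(5.385, 100, cf, solubility = 10)  # 1000 mg/L predicted
  expect_true(est$exceeds_solubility)
  expect_true(est$outside_kow_domain)
  est2 <- predict_lc50(4.2, 100, cf, solubility = 5000)
  expect_false(est2$exceeds_solubility)
  expect_false(est2$outside_kow_domain)
  # monotone in logKow with the sign of m
  cfn <- list(endpoint_id = "e", m = -0.8, b = 1, kow_domain_max = 5)
  concs <- vapply(c(1, 2, 3, 4), function(lk)
    predict_lc50(lk, 100, cfn)$concentration_mg_l, numeric(1))
  expect_true(all(diff(concs) < 0))
})

test_that("narcotic activity is the LC50/solubility ratio with supersaturation flag", {
  expect_equal(narcosis_activity(1, 2)$activity, 0.5)
  at <- narcosis_activity(3, 3)
  expect_equal(at$activity, 1)
  expect_false(at$supersaturated)
  expect_true(narcosis_activity(5, 3)$supersaturated)
  expect_error(narcosis_activity(1, 0), "positive")
})

test_that("HC5 follows its closed form", {
  expect_equal(hc5(4.52 / 1.05), 1.0, tolerance = 1e-12)
  expect_equal(hc5(0), 10^4.52)
  set.seed(13)
  lk <- runif(25, 0, 7)
  expect_equal(hc5(lk), 10^(-(-4.52 + 1.05 * lk)), tolerance = 1e-12)
})

test_that("chronic value is the symmetric geometric mean of NOEC and LOEC", {
  expect_equal(chronic_value(3, 3), 3)
  expect_equal(round(chronic_value(0.1, 1.0), 5), 0.31623)
  set.seed(17)
  a <- 10^runif(30, -2, 2); b <- 10^runif(30, -2, 2)
  expect_equal(chronic_value(a, b), sqrt(a * b), tolerance = 1e-12)
  expect_equal(chronic_value(a, b), chronic_value(b, a))
  expect_true(all(chronic_value(a, b) >= pmin(a, b) - 1e-12))
  expect_true(all(chronic_value(a, b) <= pmax(a, b) + 1e-12))
  expect_error(chronic_value(0, 1), "positive")
})

test_that("bioconcentration factor matches the uptake/elimination balance", {
  expect_equal(bcf(l_b = 0, k1 = 2, k2 = 2, phi = 1)$bcf, 2)
  expect_equal(bcf(l_b = 0.3, k1 = 10, k2 = 1, phi = 0)$bcf, 0.7)
  set.seed(19)
  for (i in 1:20) {
    lb <- runif(1, 0, 0.5); k1 <- runif(1, 0, 2000)
    ks <- runif(4, 0.01, 1); phi <- runif(1)
    got <- bcf(lb, k1, ks[1], ks[2], ks[3], ks[4], phi)
    expect_equal(got$bcf, (1 - lb) + k1 * phi / sum(ks), tolerance = 1e-12)
    expect_gte(got$bcf, 1 - lb)
  }
  expect_true(bcf(0, k1 = 6000, k2 = 1, phi = 1)$bioaccumulative)
  expect_false(bcf(0, k1 = 100, k2 = 1, phi = 1)$bioaccumulative)
  expect_error(bcf(0, 1, 0), "positive")
})

test_that("lipophilicity and applicability flags use strict thresholds", {
  f <- lipophilicity_flags(c(4.2, 5.385, 3.0, 5.0))
  expect_equal(f$lipophilic, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(f$outside_fish_daphnia_domain, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("the shipped QSAR coefficient configuration loads and is complete", {
  cfs <- read_qsar_coefficients()
  expect_gte(length(cfs), 2)
  for (cf in cfs) {
    expect_true(all(c("endpoint_id", "m", "b", "kow_domain_max", "chronic")
                    %in% names(cf)))
  }
  expect_true(any(vapply(cfs, function(x) isTRUE(x$chronic), logical(1))))
})
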