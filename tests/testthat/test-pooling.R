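fx <- egf_glioma_studies()

test_that("cochran_q on degenerate and hand-computed inputs", {
  none <- cochran_q(make_effects(rep(0.3, 3), rep(0.1, 3)))
  expect_equal(none$q, 0)
  expect_equal(none$tau_squared, 0)
  expect_equal(none$i_squared, 0)
  expect_equal(none$p_value, 1)

  # theta_hat = 0.5, Q = 0.25 + 0.25
  two <- cochran_q(make_effects(c(0, 1), c(1, 1)))
  expect_equal(two$q, 0.5)
  expect_equal(two$df, 1L)

  expect_error(cochran_q(make_effects(0.2, 0.1)),
               class = "snpmeta_insufficient_studies")
})

test_that("overall heterogeneity matches the published Q-test p-values", {
  # published values are printed to 3 decimals; compare to half a ULP
  expect_lt(abs(cochran_q(fixture_effects("AA_vs_GG"))$p_value - 0.001), 0.0005)
  expect_lt(abs(cochran_q(fixture_effects("GA_vs_GG"))$p_value - 0.016), 0.0005)
  expect_lt(abs(cochran_q(fixture_effects("dominant"))$p_value - 0.002), 0.0005)
  expect_lt(abs(cochran_q(fixture_effects("recessive"))$p_value - 0.024), 0.0005)
})

test_that("Mantel-Haenszel pooling: k = 1 reduction and published subgroups", {
  single <- build_contingency(fx$studies[[1]], "dominant")
  pooled <- pool_mantel_haenszel(list(single))
  expect_equal(pooled$or_pooled, 96 * 141 / (179 * 64), tolerance = 1e-12)
  expect_equal(pooled$k, 1L)
  expect_null(pooled$heterogeneity)

  eth <- vapply(fx$studies, function(s) s$ethnicity, character(1))
  asian <- lapply(fx$studies[eth == "Asian"], build_contingency, model = "AA_vs_GG")
  asian_pool <- pool_mantel_haenszel(asian)
  expect_equal(asian_pool$or_pooled, 1.63, tolerance = 0.005)
  expect_equal(asian_pool$ci_low, 1.20, tolerance = 0.005)
  expect_equal(asian_pool$ci_high, 2.21, tolerance = 0.005)

  cauc <- lapply(fx$studies[eth == "Caucasian"], build_contingency, model = "AA_vs_GG")
  expect_equal(pool_mantel_haenszel(cauc)$or_pooled, 0.66, tolerance = 0.005)

  expect_error(pool_mantel_haenszel(list()), class = "snpmeta_insufficient_studies")
})

test_that("DerSimonian-Laird pooling: reductions and published overall values", {
  # tau^2 = 0 => identical to the fixed inverse-variance pool
  eff <- make_effects(c(0.28, 0.30, 0.32), c(0.2, 0.1, 0.15))
  dl <- pool_dersimonian_laird(eff)
  expect_equal(dl$heterogeneity$tau_squared, 0)
  w <- 1 / eff$se^2
  expect_equal(dl$log_or, sum(w * eff$log_or) / sum(w), tolerance = 1e-12)
  expect_equal(dl$se, 1 / sqrt(sum(w)), tolerance = 1e-12)

  overall <- pool_dersimonian_laird(fixture_effects("AA_vs_GG"))
  expect_equal(overall$or_pooled, 0.95, tolerance = 0.005)
  expect_equal(overall$ci_low, 0.62, tolerance = 0.005)
  expect_equal(overall$ci_high, 1.45, tolerance = 0.005)
  expect_equal(pool_dersimonian_laird(fixture_effects("recessive"))$or_pooled,
               1.04, tolerance = 0.005)

  expect_error(pool_dersimonian_laird(make_effects(0.1, 0.2)),
               class = "snpmeta_insufficient_studies")
})

test_that("select_and_pool applies the strict p > alpha rule", {
  eth <- vapply(fx$studies, function(s) s$ethnicity, character(1))
  asian <- fx[eth == "Asian"]
  expect_identical(select_and_pool(asian, "AA_vs_GG")$method,
                   "mantel_haenszel_fixed")
  expect_identical(select_and_pool(fx, "AA_vs_GG")$method,
                   "dersimonian_laird_random")
  expect_identical(select_and_pool(identical_collection(2), "dominant")$method,
                   "mantel_haenszel_fixed")  # Q = 0 => p = 1
  expect_error(select_and_pool(fx[1], "dominant"),
               class = "snpmeta_insufficient_studies")
  expect_error(select_and_pool(fx, "dominant", alpha_het = 1.2),
               class = "snpmeta_validation_error")
})

test_that("stratified analysis reproduces the published subgroup rows", {
  eth_dom <- stratified_analysis(fx, "ethnicity", "dominant")
  expect_equal(eth_dom$Asian$or_pooled, 1.31, tolerance = 0.005)
  expect_equal(eth_dom$Caucasian$or_pooled, 0.73, tolerance = 0.005)
  expect_identical(eth_dom$Asian$method, "mantel_haenszel_fixed")
  expect_identical(eth_dom$Asian$stratum_label, "Asian")

  src_hom <- stratified_analysis(fx, "control_source", "AA_vs_GG")
  expect_equal(src_hom$Population$or_pooled, 1.11, tolerance = 0.005)
  expect_equal(src_hom$Hospital$or_pooled, 0.87, tolerance = 0.005)

  # a single-stratum collection reduces to the unstratified pool
  eth <- vapply(fx$studies, function(s) s$ethnicity, character(1))
  asian <- fx[eth == "Asian"]
  only <- stratified_analysis(asian, "ethnicity", "recessive")
  expect_length(only, 1)
  expect_equal(only$Asian$or_pooled,
               select_and_pool(asian, "recessive")$or_pooled, tolerance = 1e-12)

  lone <- study_collection(c(asian$studies[1], fx$studies[eth == "Caucasian"]))
  expect_error(stratified_analysis(lone, "ethnicity", "dominant"),
               "Asian", class = "snpmeta_insufficient_studies")
})

test_that("pooled estimates are order-invariant and scale-consistent", {
  set.seed(303)
  for (model in genetic_models()) {
    base <- select_and_pool(fx, model)
    perm <- select_and_pool(fx[sample(7)], model)
    expect_equal(perm$or_pooled, base$or_pooled, tolerance = 1e-12)
    expect_equal(perm$ci_low, base$ci_low, tolerance = 1e-12)
    expect_equal(perm$heterogeneity$q, base$heterogeneity$q, tolerance = 1e-12)
    # exp of the pooled log estimate is the pooled OR; CI brackets it
    expect_equal(exp(base$log_or), base$or_pooled)
    expect_true(base$ci_low <= base$or_pooled && base$or_pooled <= base$ci_high)
    expect_equal(sum(base$weights), 1, tolerance = 1e-9)
    expect_true(all(base$weights >= 0))
  }
})

test_that("MH agrees with the fixed inverse-variance pool on large homogeneous tables", {
  set.seed(404)
  for (rep in 1:10) {
    k <- 8
    tables <- lapply(seq_len(k), function(i) {
      b <- sample(20:200, 1); d <- sample(20:200, 1)
      or <- 1.4
      a <- round(or * b * sample(20:200, 1) / d); c_ <- sample(20:200, 1)
      a <- round(or * b * c_ / d)
      list(a = max(a, 20), b = b, c = c_, d = d, study_label = paste0("t", i))
    })
    mh <- pool_mantel_haenszel(tables)$or_pooled
    eff <- do.call(rbind, lapply(tables, function(t) {
      e <- log_odds_ratio(t)
      data.frame(study = t$study_label, log_or = e$log_or, se = e$se)
    }))
    w <- 1 / eff$se^2
    iv <- exp(sum(w * eff$log_or) / sum(w))
    expect_lt(abs(mh - iv) / iv, 0.02)
  }
})
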