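test_that("parameter sampling honours spec kinds, truncation and seeding", {
  specs <- list(a = dist_spec("point", value = 3),
                b = dist_spec("uniform", min = 1, max = 1),
                c = dist_spec("normal", mean = 15, sd = 2.3, lower = 0))
  d1 <- sample_parameters(specs, 1000, seed = 9)
  expect_true(all(d1$a == 3))
  expect_true(all(d1$b == 1))
  expect_true(all(d1$c > 0))
  expect_length(d1$c, 1000)
  d2 <- sample_parameters(specs, 1000, seed = 9)
  expect_identical(d1, d2)
  d3 <- sample_parameters(specs, 1000, seed = 10)
  expect_false(identical(d1$c, d3$c))
  # truncation that excludes essentially all mass fails loudly
  bad <- list(x = dist_spec("normal", mean = 0, sd = 1, lower = 50))
  expect_error(sample_parameters(bad, 10, seed = 1), "mass")
})

test_that("point-mass Monte Carlo equals the deterministic model exactly", {
  refs <- point_bundle()
  tab <- make_soil_table()
  det <- risk_totals(assess_risk(tab, refs, "child"))
  draws <- sample_parameters(refs$exposure$child, 500, seed = 4)
  for (site in tab$sites) {
    mc <- run_mc(tab$values[site, ], draws, refs, "soil")
    expect_equal(unique(mc$nri_samples),
                 det$nri_total[det$site == site])
    expect_equal(unique(mc$cri_samples),
                 det$cri_total[det$site == site])
    expect_equal(unname(mc$nri_summary["sd"]), 0)
  }
})

test_that("zero concentrations simulate to zero risk and zero exceedance", {
  refs <- default_reference_bundle()
  draws <- sample_parameters(refs$exposure$child, 200, seed = 2)
  conc <- stats::setNames(rep(0, 10), pte_elements)
  mc <- run_mc(conc, draws, refs, "soil")
  expect_true(all(mc$nri_samples == 0))
  expect_true(all(mc$cri_samples == 0))
  expect_equal(mc$p_exceed_nri, 0)
  expect_equal(mc$p_exceed_cri, 0)
})

test_that("exceedance probability is an exact strict-inequality count", {
  expect_equal(exceedance_probability(c(0.5, 1.5, 2.5, 0.9), 1), 0.5)
  expect_equal(exceedance_probability(c(0.1, 0.2), 1), 0)
  expect_equal(exceedance_probability(c(2, 3), 1), 1)
  # threshold value itself does not count as exceedance
  expect_equal(exceedance_probability(c(1, 1, 2), 1), 1 / 3)
  expect_error(exceedance_probability(numeric(0), 1), "empty")
  # constructed vector: 6400 of 10000 above 1e-4
  x <- c(rep(2e-4, 6400), rep(5e-5, 3600))
  expect_equal(exceedance_probability(x, 1e-4), 0.64)
  # monotone: p_exceed never increases with the threshold
  set.seed(1)
  samples <- rlnorm(5000)
  thresholds <- sort(runif(20, 0, 5))
  p <- vapply(thresholds, function(t) exceedance_probability(samples, t), 0)
  expect_true(all(diff(p) <= 0))
})

test_that("MC mean converges to the deterministic value when only EF varies", {
  refs <- point_bundle()
  refs$exposure$child$ef <- dist_spec("uniform", min = 335, max = 365)
  tab <- make_soil_table()
  det <- risk_totals(assess_risk(tab, refs, "child"))  # central EF = 350
  draws <- sample_parameters(refs$exposure$child, 10000, seed = 31)
  mc <- run_mc(tab$values[1, ], draws, refs, "soil")
  se <- mc$nri_summary["sd"] / sqrt(10000)
  expect_lt(abs(mc$nri_summary["mean"] - det$nri_total[det$site == tab$sites[1]]),
            3 * se)
})

test_that("per-site simulations are reproducible and order-independent", {
  refs <- default_reference_bundle()
  tab <- make_soil_table(n_sites = 3)
  a <- mc_assess(tab, refs, "child", n_iter = 300, seed = 5)
  b <- mc_assess(tab, refs, "child", n_iter = 300, seed = 5)
  expect_identical(a$summary, b$summary)
  expect_identical(a$sites[[1]]$nri_samples, b$sites[[1]]$nri_samples)
  # reordering sites leaves every per-site result unchanged
  tab_rev <- sample_table(tab$values[rev(tab$sites), ], "soil")
  c <- mc_assess(tab_rev, refs, "child", n_iter = 300, seed = 5)
  expect_identical(a$sites[["S2"]]$nri_samples, c$sites[["S2"]]$nri_samples)
  # pooled probabilities lie between the per-site extremes
  expect_gte(a$pooled$p_exceed_cri, min(a$summary$p_exceed_cri))
  expect_lte(a$pooled$p_exceed_cri, max(a$summary$p_exceed_cri))
})

test_that("sensitivity attributes output variance to the driving parameters", {
  specs <- list(bw = dist_spec("normal", mean = 15, sd = 2.3, lower = 0),
                ef = dist_spec("uniform", min = 335, max = 365),
                ed = dist_spec("point", value = 6))
  draws <- sample_parameters(specs, 2000, seed = 8)
  # output an exact copy of the only varying parameter: 100%, the rest 0
  only_ef <- sample_parameters(list(ef = specs$ef, ed = specs$ed), 2000, 8)
  s1 <- sensitivity(only_ef, only_ef$ef)
  expect_equal(s1$contribution[s1$parameter == "ef"], 100)
  expect_equal(s1$contribution[s1$parameter == "ed"], 0)
  # monotone inverse of BW: rho = -1, contribution -100%
  s2 <- sensitivity(list(bw = draws$bw), 1 / draws$bw)
  expect_equal(s2$contribution, -100)
  # absolute contributions sum to 100
  out <- draws$ef / draws$bw
  s3 <- sensitivity(draws, out)
  expect_equal(sum(abs(s3$contribution)), 100)
  # invariance to monotone rescaling of the output
  s4 <- sensitivity(draws, log(out))
  expect_equal(s3$contribution, s4$contribution)
  expect_error(sensitivity(list(ed = draws$ed), draws$ed), "constant")
})

test_that("default child soil sensitivity gives BW a negative contribution", {
  refs <- default_reference_bundle()
  tab <- make_soil_table()
  sens <- mc_sensitivity(tab, refs, "child", n_iter = 4000, seed = 13)
  expect_lt(sens$nri$contribution[sens$nri$parameter == "bw"], 0)
  expect_lt(sens$cri$contribution[sens$cri$parameter == "bw"], 0)
  # ingestion rate is the dominant positive driver under the default spread
  expect_equal(sens$nri$parameter[1], "r_ing_soil")
})
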