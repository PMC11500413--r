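test_that("tk_metrics: discrete Cmax/Tmax and trapezoid AUC", {
  m <- tk_metrics(c(0, 1, 2, 3), c(0, 2, 1, 0))
  expect_equal(m$cmax, 2); expect_equal(m$tmax, 1); expect_equal(m$auc, 3.0)

  cst <- tk_metrics(c(0, 2, 5, 10), rep(3, 4))
  expect_equal(cst$auc, 30); expect_equal(cst$tmax, 0)

  short <- tk_metrics(c(0, 1, 2), c(1, 2, 1))
  expect_false(short$valid)
  expect_match(short$reason, "fewer than 4")

  # AUC agrees with an independent piecewise integration oracle
  set.seed(31)
  t <- sort(stats::runif(40, 0, 24))
  v <- stats::runif(40, 0, 5)
  f <- stats::approxfun(t, v)
  oracle <- sum(vapply(seq_len(39), function(i)
    stats::integrate(f, t[i], t[i + 1])$value, numeric(1)))
  expect_equal(tk_metrics(t, v)$auc, oracle, tolerance = 1e-12)

  # inserting collinear points does not change the AUC
  t2 <- sort(c(t, (t[5] + t[6]) / 2))
  v2 <- f(t2)
  expect_equal(tk_metrics(t2, v2)$auc, tk_metrics(t, v)$auc,
               tolerance = 1e-12)
})

test_that("within-fold counting: worked ratios, inclusive bounds, "
          , {
  r <- c(0.1, 0.5, 1, 3, 6)
  expect_equal(within_fold_percent(r, 2), 40)
  expect_equal(within_fold_percent(r, 5), 60)
  expect_equal(within_fold_percent(5.0, 5), 100)   # boundary inclusive
  expect_equal(within_fold_percent(1 / 5, 5), 100)

  # antisymmetry: inverting all ratios leaves the percentages unchanged
  set.seed(13)
  for (i in 1:20) {
    rr <- exp(stats::rnorm(30, 0, 1.2))
    for (k in c(2, 5)) {
      expect_equal(within_fold_percent(rr, k), within_fold_percent(1 / rr, k))
    }
    expect_gte(within_fold_percent(rr, 5), within_fold_percent(rr, 2))
  }
})

test_that("fold_evaluation interpolates, excludes zeros and summarizes", {
  phys <- resolve_physiology(default_species_template("rat"), 0.25)
  model <- build_model(fixture_family("generic_otp", "rat"), phys)
  sim <- simulate_pbk(model, exposure_scenario("rat", 0.25, "oral", 1, 48))
  tt <- c(1, 2, 4, 8, 12, 24)
  pred <- stats::approx(sim$times, sim$conc$otp_generic$blood, tt)$y

  # identical observations -> 100% within both bands
  obs <- data.frame(study = "s1", chemical = "otp_generic",
                    matrix = "blood", time_h = tt, value = pred,
                    unit = "umol/L")
  fs <- fold_evaluation(sim, obs)
  expect_equal(fs$pct_within_2, 100)
  expect_equal(fs$pct_within_5, 100)
  # predicted metrics come from the dense grid, observed from the sparse
  # samples of the same curve, so the folds sit close to (not at) unity
  expect_equal(fs$metrics$cmax_fold, 1, tolerance = 0.05)
  expect_equal(fs$metrics$auc_fold, 1, tolerance = 0.05)

  # constructed fold pattern: factors 3 (within 5) and 10 (outside)
  obs2 <- obs
  obs2$value <- pred * c(3, 3, 10, 10, 1, 1)
  fs2 <- fold_evaluation(sim, obs2)
  expect_equal(fs2$pct_within_5, 100 * 4 / 6)
  expect_equal(fs2$pct_within_2, 100 * 2 / 6)

  # observed zeros are excluded and counted
  obs3 <- obs; obs3$value[1] <- 0
  fs3 <- fold_evaluation(sim, obs3)
  expect_identical(fs3$n_excluded_zero_observed, 1L)
  expect_equal(fs3$pct_within_5, 100)

  # unit mismatch rejected
  obs4 <- obs; obs4$unit <- "ng/mL"
  expect_error(fold_evaluation(sim, obs4), "unit mismatch")
  # unknown chemical rejected
  obs5 <- obs; obs5$chemical <- "mystery"
  expect_error(fold_evaluation(sim, obs5), "not simulated")
})

test_that("local sensitivity: dose coefficient, structural zeros, "
          , {
  phys <- resolve_physiology(default_species_template("rat"), 0.25)
  model <- build_model(fixture_family("generic_otp", "rat"), phys)
  scen <- exposure_scenario("rat", 0.25, "oral", dose = 0.001,
                            duration = 48)

  res <- local_sensitivity(model, scen,
                           parameters = c("dose", "kp_fat_metab_generic",
                                          "vmax_rxn1"))
  sc <- stats::setNames(res$coefficients$sc, res$coefficients$parameter)
  expect_equal(sc[["dose"]], 1, tolerance = 1e-3)
  # the metabolite's partitioning cannot reach the oxon metric
  expect_lt(abs(sc[["kp_fat_metab_generic"]]), 1e-6)
  # desulfuration capacity drives oxon formation
  expect_gt(sc[["vmax_rxn1"]], 0.5)
  expect_gt(res$baseline_metric, 0)

  # forward and central differences agree to first order
  fwd <- local_sensitivity(model, scen, parameters = "vmax_rxn1",
                           perturbation = 1e-4)
  cen <- local_sensitivity(model, scen, parameters = "vmax_rxn1",
                           perturbation = 1e-4, method = "central")
  expect_equal(fwd$coefficients$sc, cen$coefficients$sc, tolerance = 0.01)

  # no oxon member -> metric undefined
  model0 <- build_model(desulfuration_family(), phys)
  fam_no_opo <- compound_family("p_only",
    parent = list(descriptor = compound_descriptor(
      "p", "OTP", log_p = 2, molecular_weight = 300,
      charge_class = "neutral"), params = inert_params(ka = 1)))
  m_no <- build_model(fam_no_opo, phys)
  expect_error(local_sensitivity(m_no, scen), "no OPO member")
  expect_s3_class(local_sensitivity(model0, scen, parameters = "dose"),
                  "sensitivity_result")
})
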