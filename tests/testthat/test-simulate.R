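rat_phys <- resolve_physiology(default_species_template("rat"), 0.25)

test_that("closed system: IV dose with all clearances zero conserves dose", {
  model <- build_model(parent_only_family(), rat_phys)
  scen <- exposure_scenario("rat", 0.25, "iv", dose = 2, duration = 24)
  sim <- simulate_pbk(model, scen)
  totals <- rowSums(sim$amounts[, model$layout$name[model$layout$is_mass]])
  expect_equal(totals, rep(sim$dose_umol, length(sim$times)),
               tolerance = 1e-12)
  expect_identical(sim$mass_balance[1], 0)
})

test_that("one-compartment IV reduction matches the closed form", {
  V <- 0.8; CL <- 0.35; dose <- 5
  times <- seq(0, 20, 0.5)
  conc <- onecomp_solve(V, CL, dose, times) / V
  expect_equal(conc, dose / V * exp(-CL * times / V), tolerance = 1e-8)
})

test_that("gut-only oral simulation reproduces the absorbed-fraction "
          , {
  for (ka in c(0.3, 2)) {
    for (kt in c(2.11, 4.76)) {
      tmpl <- template_with(kt_si = kt)
      phys <- resolve_physiology(tmpl, 0.25)
      model <- build_model(parent_only_family(ka = ka), phys)
      scen <- exposure_scenario("rat", 0.25, "oral", dose = 1,
                                duration = 200, times = c(0, 100, 200))
      sim <- simulate_pbk(model, scen)
      body_states <- grep("^inert_parent_", model$layout$name, value = TRUE)
      absorbed <- sum(sim$amounts[3, body_states]) / sim$dose_umol
      expect_equal(absorbed, compute_fraction_absorbed(ka, kt),
                   tolerance = 1e-6)
      # everything not absorbed ends in feces
      expect_equal(unname(absorbed +
                            sim$amounts[3, "gut_feces"] / sim$dose_umol),
                   1, tolerance = 1e-6)
    }
  }
})

test_that("delayed oral absorption shifts the trajectory without "
          , {
  model <- build_model(fixture_family("generic_otp", "rat"), rat_phys)
  s0 <- simulate_pbk(model, exposure_scenario(
    "rat", 0.25, "oral", 1, 48, times = seq(0, 40, 0.5)))
  s1 <- simulate_pbk(model, exposure_scenario(
    "rat", 0.25, "oral", 1, 48, absorption_delay = 2,
    times = seq(2, 42, 0.5)))
  expect_equal(s1$conc$otp_generic$blood, s0$conc$otp_generic$blood,
               tolerance = 1e-10)
  # before the delay everything is zero
  s2 <- simulate_pbk(model, exposure_scenario(
    "rat", 0.25, "oral", 1, 48, absorption_delay = 2,
    times = c(0.5, 1, 1.5, 3, 6)))
  expect_true(all(s2$amounts[1:3, ] == 0))
  expect_true(all(s2$mass_balance[1:3] == 0))
})

test_that("mass balance error stays at round-off across the dose range", {
  for (fam in list(fixture_family("chlorfenvinphos", "rat"),
                   fixture_family("generic_otp", "rat"))) {
    model <- build_model(fam, rat_phys)
    for (dose in c(0.001, 1, 100)) {
      sim <- simulate_pbk(model, exposure_scenario("rat", 0.25, "oral",
                                                   dose, duration = 48))
      mb <- mass_balance_error(sim)
      limit <- if (dose < 0.01) 1e-8 else 1e-11
      expect_lt(mb$max_abs_error, limit)
      expect_identical(mb$error[1], 0)
    }
  }
})

test_that("amounts are non-negative and sinks non-decreasing", {
  model <- build_model(fixture_family("generic_otp", "rat"), rat_phys)
  sim <- simulate_pbk(model, exposure_scenario("rat", 0.25, "oral", 1, 48))
  expect_gt(min(sim$amounts), -1e-10)
  sinks <- sim$amounts[, grep("urine|feces|sink|extent",
                              colnames(sim$amounts))]
  expect_true(all(apply(sinks, 2, function(x) all(diff(x) >= -1e-10))))
})

test_that("dose linearity below saturation; supralinear AUC above", {
  model <- build_model(fixture_family("generic_otp", "rat"), rat_phys)
  run <- function(dose, duration = 48) {
    simulate_pbk(model, exposure_scenario("rat", 0.25, "oral", dose,
                                          duration = duration))
  }
  lo <- run(0.001); hi <- run(0.002)
  for (mn in names(lo$conc)) {
    expect_equal(max(hi$conc[[mn]]$blood) / max(lo$conc[[mn]]$blood), 2,
                 tolerance = 0.01)
    expect_equal(trapz(hi$times, hi$conc[[mn]]$blood) /
                   trapz(lo$times, lo$conc[[mn]]$blood), 2,
                 tolerance = 0.01)
  }
  # saturated regime: parent AUC more than doubles when the dose doubles
  s1 <- run(1000, 96); s2 <- run(2000, 96)
  ratio <- trapz(s2$times, s2$conc$otp_generic$blood) /
    trapz(s1$times, s1$conc$otp_generic$blood)
  expect_gt(ratio, 2.1)
})

test_that("cumulative metabolite formation equals cumulative parent "
          , {
  fam <- desulfuration_family()
  model <- build_model(fam, rat_phys)
  sim <- simulate_pbk(model, exposure_scenario("rat", 0.25, "oral", 1, 48))
  # the only OPO source is desulfuration: OPO present + excreted = extent
  opo_total <- rowSums(sim$amounts[, grep("^opo_x_", colnames(sim$amounts))])
  expect_equal(opo_total, sim$amounts[, "rxn1_extent"], tolerance = 1e-9)
})

test_that("scenario validation and mismatches are rejected", {
  model <- build_model(parent_only_family(), rat_phys)
  expect_error(exposure_scenario("rat", 0.25, "oral", -1, 24), "dose")
  expect_error(exposure_scenario("rat", 0.25, "oral", 1, 24,
                                 absorption_delay = 30), "delay")
  expect_error(simulate_pbk(model, exposure_scenario("human", 70, "iv", 1,
                                                     24)),
               "does not match")
  expect_error(simulate_pbk(model, exposure_scenario("rat", 0.3, "iv", 1,
                                                     24)),
               "body weight")
})
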