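test_that("fraction absorbed: closed form, limits, monotonicity", {
  expect_identical(compute_fraction_absorbed(0, 2.11), 0)
  expect_equal(compute_fraction_absorbed(4.76, 4.76), 1 - 2^-7)
  ka <- seq(0, 10, 0.25)
  fa <- compute_fraction_absorbed(ka, 2.11)
  expect_true(all(diff(fa) > 0))
  expect_true(all(fa >= 0 & fa < 1))
  expect_error(compute_fraction_absorbed(-1, 2), ">= 0")
  expect_error(compute_fraction_absorbed(1, 0), "> 0")
})

test_that("conjugate lumping: weighted averages and secretion factors", {
  mk <- function(fup, kp_liver = 1, ka = 0) {
    kp <- flat_kp(); kp[["liver"]] <- kp_liver
    kinetic_params(fup = fup, bpr = 1, kp = kp, ka = ka)
  }
  # 50/50 glucuronide/sulfate -> multiplier 0.5*1.6 + 0.5*5.5 = 3.55
  spec <- conjugate_spec(list(
    glucuronide = list(fraction = 0.5, params = mk(0.8, kp_liver = 2)),
    sulfate = list(fraction = 0.5, params = mk(0.2, kp_liver = 4))))
  lump <- lump_metabolite_forms(spec)
  expect_equal(lump$gfr_multiplier, 3.55)
  expect_equal(lump$params$fup, 0.5)
  expect_equal(lump$params$kp[["liver"]], 3)

  # single form: identity, multiplier = its secretion factor
  one <- lump_metabolite_forms(conjugate_spec(list(
    sulfate = list(fraction = 1, params = mk(0.3)))))
  expect_equal(one$gfr_multiplier, 5.5)
  expect_equal(one$params$fup, 0.3)

  # convexity: every effective parameter within the per-form range
  set.seed(42)
  for (i in 1:20) {
    w <- stats::runif(1)
    f1 <- stats::runif(1, 0.05, 1); f2 <- stats::runif(1, 0.05, 1)
    sp <- conjugate_spec(list(
      unconjugated = list(fraction = w, params = mk(f1)),
      glucuronide = list(fraction = 1 - w, params = mk(f2))))
    eff <- lump_metabolite_forms(sp)$params$fup
    expect_gte(eff, min(f1, f2)); expect_lte(eff, max(f1, f2))
  }

  expect_error(conjugate_spec(list(
    sulfate = list(fraction = 0.7, params = mk(0.3)))), "sum to 1")
  expect_error(conjugate_spec(list()), "at least one form")
})

test_that("Vmax in-vitro to in-vivo scaling", {
  # 32 mg microsomal protein/g liver, 10 g liver:
  # 0.46 nmol/min/mg * 32 * 10 * 0.06 = 8.832 umol/h
  tmpl <- template_with(
    microsomal_protein_per_g_liver = 32,
    tissue_volume_fractions = c(liver = 0.04, kidney = 0.007,
                                brain = 0.0057, fat = 0.07,
                                slowly_perfused = 0.65,
                                rapidly_perfused = 0.05, blood = 0.074))
  phys <- resolve_physiology(tmpl, 0.25)  # liver = 0.01 L = 10 g
  rx <- mm_reaction("p", "urinary_metabolite", "liver_microsome", 0.46, 5.91)
  expect_equal(scale_vmax(rx, phys), 8.832, tolerance = 1e-12)

  # zero rate scales to zero; doubling liver mass doubles capacity
  rx0 <- mm_reaction("p", "urinary_metabolite", "liver_microsome", 0, 5.91)
  expect_identical(scale_vmax(rx0, phys), 0)
  phys2 <- resolve_physiology(tmpl, 0.5)
  expect_equal(scale_vmax(rx, phys2), 2 * scale_vmax(rx, phys))

  # plasma site: per-mL rate times plasma volume in mL
  rxp <- mm_reaction("o", "hydrolysis_product", "plasma", 0.2, 20)
  plasma_ml <- phys$compartment_volumes[["blood"]] * 0.54 * 1000
  expect_equal(scale_vmax(rxp, phys), 0.2 * plasma_ml * 0.06)
})

test_that("Michaelis-Menten fitting: exact, noisy, and degenerate cases", {
  s <- c(1, 2, 5, 10, 20, 50)
  v <- 0.46 * s / (5.91 + s)
  fit <- fit_michaelis_menten(s, v)
  expect_equal(fit$vmax, 0.46, tolerance = 1e-6)
  expect_equal(fit$km, 5.91, tolerance = 1e-6)
  expect_true(all(is.finite(fit$se)))

  # duplicating every point leaves the estimates unchanged
  fit2 <- fit_michaelis_menten(c(s, s), c(v, v))
  expect_equal(fit2$vmax, fit$vmax, tolerance = 1e-10)
  expect_equal(fit2$km, fit$km, tolerance = 1e-10)

  expect_error(fit_michaelis_menten(s[1:3], v[1:3]), "at least 4")
  expect_error(fit_michaelis_menten(s, rep(0, 6)), "all rates are zero")
})

test_that("catalytic efficiency", {
  expect_equal(signif(catalytic_efficiency(0.46, 5.91), 3), 77.8)
  expect_equal(catalytic_efficiency(0.46, 5.91), 78.0, tolerance = 0.005)
  expect_equal(catalytic_efficiency(1, 1), 1000)
  expect_identical(catalytic_efficiency(0, 3), 0)
  expect_error(catalytic_efficiency(1, 0), "> 0")
})
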