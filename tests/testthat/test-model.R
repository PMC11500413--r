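test_that("state layout is a bijection and families are validated", {
  fam <- fixture_family("generic_otp", "rat")
  phys <- resolve_physiology(default_species_template("rat"), 0.25)
  model <- build_model(fam, phys)
  expect_false(any(duplicated(model$layout$name)))
  # 10 gut + 3 members x 8 + 1 terminal sink + 4 extents
  expect_identical(nrow(model$layout), 10L + 3L * 8L + 1L + 4L)
  expect_identical(sum(!model$layout$is_mass), 4L)

  # invalid wiring is rejected at family construction
  otp <- compound_descriptor("p", "OTP", log_p = 2, molecular_weight = 300,
                             charge_class = "neutral")
  met <- compound_descriptor("m", "urinary_metabolite", log_p = 0,
                             molecular_weight = 150,
                             charge_class = "neutral")
  expect_error(compound_family("bad",
    parent = list(descriptor = otp, params = inert_params()),
    reactions = list(mm_reaction("p", "nonexistent", "liver_microsome",
                                 1, 1))),
    "neither a family member nor a terminal sink")
  expect_error(compound_family("bad",
    parent = list(descriptor = otp, params = inert_params()),
    metabolites = list(list(descriptor = met, params = inert_params())),
    reactions = list(mm_reaction("m", "urinary_metabolite",
                                 "liver_microsome", 1, 1))),
    "cannot be a reaction substrate")
  expect_error(compound_family("bad",
    parent = list(descriptor = otp, params = inert_params()),
    reactions = list(mm_reaction("p", "hydrolysis_product", "plasma",
                                 1, 1))),
    "PON1")
})

test_that("total molar mass is a linear invariant of the RHS", {
  fam <- fixture_family("generic_otp", "rat")
  phys <- resolve_physiology(default_species_template("rat"), 0.25)
  model <- build_model(fam, phys)
  mass <- model$layout$is_mass
  set.seed(7)
  for (i in 1:200) {
    y <- stats::runif(nrow(model$layout), 0, 10)
    dy <- pbk_rhs(model, y)
    expect_lt(abs(sum(dy[mass])), 1e-12 * sum(abs(dy[mass])))
  }
})

test_that("metabolite formation mirrors substrate consumption 1:1", {
  fam <- desulfuration_family()
  phys <- resolve_physiology(default_species_template("rat"), 0.25)
  model <- build_model(fam, phys)
  opo_states <- grep("^opo_x_", model$layout$name, value = TRUE)
  set.seed(11)
  for (i in 1:50) {
    y <- stats::runif(nrow(model$layout), 0, 5)
    dy <- pbk_rhs(model, y)
    v <- dy[["rxn1_extent"]]  # instantaneous desulfuration rate
    # all OPO inflow comes from that single reaction
    expect_equal(sum(dy[opo_states]), v, tolerance = 1e-12)
    expect_gt(v, 0)
  }
})

test_that("a degenerate parent-only IV model reduces to distribution plus "
          , {
  fam <- parent_only_family(gfr_multiplier = 1, fup = 0.5)
  phys <- resolve_physiology(default_species_template("rat"), 0.25)
  model <- build_model(fam, phys)
  expect_identical(nrow(model$enc$reactions), 0L)
  y <- stats::setNames(numeric(nrow(model$layout)), model$layout$name)
  y["inert_parent_blood"] <- 1
  dy <- pbk_rhs(model, y)
  # only tissue uptake and renal excretion move mass out of blood
  expect_gt(dy[["inert_parent_urine"]], 0)
  expect_equal(dy[["inert_parent_urine"]],
               phys$GFR * 0.5 * (1 / phys$compartment_volumes[["blood"]]))
  expect_true(all(dy[grep("^gut_", names(dy))] == 0))
})
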