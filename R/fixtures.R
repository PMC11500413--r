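#' Built-in compound families
#'
#' Two self-contained example families so the simulator runs end-to-end
#' without external data.
#'
#' `"chlorfenvinphos"`: an oxon-type (P=O) OP dosed directly, with hepatic
#' CYP450-mediated oxidative dealkylation to des-ethyl-chlorfenvinphos.  The
#' Michaelis-Menten parameters are the measured liver-microsome incubation
#' values: Vmax 0.46 (rat) / 0.57 (human) nmol/min/mg microsomal protein and
#' Km 5.91 (rat) / 6.36 (human) uM.  Plasma PON1 hydrolysis is omitted
#' (reported minimal for this compound).  Absorption: ka 1.0 1/h in rat
#' (supplied per-study for rats) and the fitted generic human value
#' 0.1 1/h.
#'
#' `"generic_otp"`: a synthetic organothiophosphate triad
#' (parent OTP, oxon OPO, one lumped urinary metabolite with 50/50
#' glucuronide/sulfate conjugation, hence a GFR secretion multiplier of
#' 0.5 x 1.6 + 0.5 x 5.5 = 3.55) with round-number kinetics, used by the
#' test-suite and as a template for new compounds.
#'
#' @param which `"chlorfenvinphos"` or `"generic_otp"`.
#' @param species `"rat"` or `"human"` (selects the measured incubation
#'   parameters and the absorption rate constant).
#' @return A [compound_family()].
#' @export
fixture_family <- function(which = c("chlorfenvinphos", "generic_otp"),
                           species = c("rat", "human")) {
  which <- match.arg(which)
  species <- match.arg(species)
  ka <- if (species == "rat") 1.0 else 0.1

  if (which == "chlorfenvinphos") {
    cvp <- compound_descriptor("chlorfenvinphos", "OPO", log_p = 3.81,
                               molecular_weight = 359.57,
                               charge_class = "neutral")
    dcvp <- compound_descriptor("desethyl_chlorfenvinphos",
                                "urinary_metabolite", log_p = 2.2,
                                molecular_weight = 331.52,
                                charge_class = "acid", pka = 1.9)
    vmax <- if (species == "rat") 0.46 else 0.57
    km <- if (species == "rat") 5.91 else 6.36
    return(compound_family(
      name = "chlorfenvinphos",
      parent = list(descriptor = cvp,
                    params = derive_kinetic_params(cvp, ka = ka)),
      metabolites = list(list(descriptor = dcvp,
                              params = derive_kinetic_params(dcvp))),
      reactions = list(
        mm_reaction("chlorfenvinphos", "desethyl_chlorfenvinphos",
                    "liver_microsome", vmax_invitro = vmax, km = km,
                    species = species))))
  }

  otp <- compound_descriptor("otp_generic", "OTP", log_p = 4.0,
                             molecular_weight = 350, charge_class = "neutral")
  opo <- compound_descriptor("opo_generic", "OPO", log_p = 3.0,
                             molecular_weight = 334, charge_class = "neutral")
  met <- compound_descriptor("metab_generic", "urinary_metabolite",
                             log_p = 1.0, molecular_weight = 150,
                             charge_class = "acid", pka = 4.5)
  gluc <- compound_descriptor("metab_generic_gluc", "urinary_metabolite",
                              log_p = -0.5, molecular_weight = 326,
                              charge_class = "acid", pka = 3.2)
  sulf <- compound_descriptor("metab_generic_sulf", "urinary_metabolite",
                              log_p = -0.2, molecular_weight = 230,
                              charge_class = "acid", pka = 2.0)
  lumped <- lump_metabolite_forms(conjugate_spec(list(
    glucuronide = list(fraction = 0.5,
                       params = derive_kinetic_params(gluc)),
    sulfate = list(fraction = 0.5,
                   params = derive_kinetic_params(sulf)))))
  compound_family(
    name = "generic_otp",
    parent = list(descriptor = otp,
                  params = derive_kinetic_params(otp, ka = ka)),
    oxon = list(descriptor = opo,
                params = derive_kinetic_params(opo)),
    metabolites = list(list(descriptor = met, params = lumped$params)),
    reactions = list(
      mm_reaction("otp_generic", "opo_generic", "liver_microsome",
                  vmax_invitro = 0.5, km = 5, species = species),
      mm_reaction("otp_generic", "metab_generic", "liver_microsome",
                  vmax_invitro = 0.3, km = 10, species = species),
      mm_reaction("opo_generic", "metab_generic", "liver_microsome",
                  vmax_invitro = 0.2, km = 8, species = species),
      mm_reaction("opo_generic", "hydrolysis_product", "plasma",
                  vmax_invitro = 0.2, km = 20, species = species)))
}

#' Generate all example/fixture files into a directory
#'
#' Emits, deterministically for a given seed:
#' \itemize{
#'   \item `species_rat.json`, `species_human.json`: the default physiology
#'     templates;
#'   \item `family_chlorfenvinphos_rat.json` / `_human.json`: the measured
#'     incubation-parameterized family;
#'   \item `family_generic_otp_rat.json`: the synthetic test triad;
#'   \item `scenario_oral_rat_1mgkg.json`: a 1 mg/kg single oral rat dose;
#'   \item `observed_synthetic_chlorfenvinphos_rat.tsv`: a SYNTHETIC
#'     observed series -- model predictions sampled at sparse times with
#'     seeded multiplicative lognormal noise -- for exercising
#'     [fold_evaluation()]; not in vivo data;
#'   \item `incubation_synthetic_rat.tsv`: SYNTHETIC incubation rates from
#'     the measured (Vmax, Km) with small seeded noise, for exercising
#'     [fit_michaelis_menten()].
#' }
#'
#' @param output_dir Writable directory (created if absent).
#' @param seed RNG seed controlling the synthetic noise.
#' @param noise_sdlog Lognormal sdlog of the synthetic observed series
#'   (default 0.5).
#' @return Invisible character vector of the written paths.
#' @export
generate_fixtures <- function(output_dir, seed = 20260910,
                              noise_sdlog = 0.5) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(p) { paths <<- c(paths, p); p }

  write_species_template_json(default_species_template("rat"),
                              emit(file.path(output_dir, "species_rat.json")))
  write_species_template_json(default_species_template("human"),
                              emit(file.path(output_dir, "species_human.json")))
  write_family_json(fixture_family("chlorfenvinphos", "rat"),
                    emit(file.path(output_dir,
                                   "family_chlorfenvinphos_rat.json")))
  write_family_json(fixture_family("chlorfenvinphos", "human"),
                    emit(file.path(output_dir,
                                   "family_chlorfenvinphos_human.json")))
  write_family_json(fixture_family("generic_otp", "rat"),
                    emit(file.path(output_dir,
                                   "family_generic_otp_rat.json")))
  scen <- exposure_scenario("rat", body_weight = 0.25, route = "oral",
                            dose = 1, duration = 48)
  write_scenario_json(scen,
                      emit(file.path(output_dir,
                                     "scenario_oral_rat_1mgkg.json")))

  # synthetic observed series from the model itself + lognormal noise
  fam <- fixture_family("chlorfenvinphos", "rat")
  phys <- resolve_physiology(default_species_template("rat"), 0.25)
  sim <- simulate_pbk(build_model(fam, phys), scen,
                      rtol = 1e-8, atol = 1e-10)
  obs_times <- c(0.5, 1, 2, 4, 6, 8, 12, 24)
  set.seed(seed)
  noise <- function(n) exp(stats::rnorm(n, 0, noise_sdlog))
  blood <- stats::approx(sim$times, sim$conc$chlorfenvinphos$blood,
                         obs_times)$y * noise(length(obs_times))
  urine <- stats::approx(sim$times,
                         sim$conc$desethyl_chlorfenvinphos$urine_umol,
                         obs_times)$y * noise(length(obs_times))
  obs <- data.frame(
    study = "synthetic_fixture", chemical = rep(
      c("chlorfenvinphos", "desethyl_chlorfenvinphos"),
      each = length(obs_times)),
    matrix = rep(c("blood", "urine"), each = length(obs_times)),
    time_h = rep(obs_times, 2), value = c(blood, urine),
    unit = rep(c("umol/L", "umol"), each = length(obs_times)),
    route = "oral", dose_mg_per_kg = 1, bw_kg = 0.25)
  write_observed_series(
    obs, emit(file.path(output_dir,
                        "observed_synthetic_chlorfenvinphos_rat.tsv")))

  conc <- c(1, 2, 5, 10, 20, 50)
  rate <- 0.46 * conc / (5.91 + conc) *
    exp(stats::rnorm(length(conc), 0, 0.03))
  inc <- data.frame(substrate_conc_uM = conc, rate_nmol_min_mg = rate)
  utils::write.table(inc,
                     emit(file.path(output_dir, "incubation_synthetic_rat.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
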