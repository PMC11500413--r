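# Shared deterministic model-building helpers.  Everything is constructed in
# code; no fixture files are read from disk.

flat_kp <- function(value = 1) {
  stats::setNames(rep(value, length(PBK_COMPARTMENTS)), PBK_COMPARTMENTS)
}

inert_params <- function(ka = 0, fup = 1, bpr = 1, kp = flat_kp(),
                         gfr_multiplier = 0) {
  kinetic_params(fup = fup, bpr = bpr, kp = kp, ka = ka,
                 gfr_multiplier = gfr_multiplier)
}

# parent-only family with unit partitioning and (by default) zero clearance
parent_only_family <- function(ka = 0, ...) {
  compound_family(
    "inert",
    parent = list(
      descriptor = compound_descriptor("inert_parent", "OPO", log_p = 1,
                                       molecular_weight = 100,
                                       charge_class = "neutral"),
      params = inert_params(ka = ka, ...)))
}

# copy of the default rat template with selected fields overridden
template_with <- function(..., base = default_species_template("rat")) {
  do.call(species_template, utils::modifyList(unclass(base), list(...)))
}

# minimal OTP -> OPO family with a single desulfuration reaction
desulfuration_family <- function(vmax = 0.5, km = 5) {
  otp <- compound_descriptor("otp_x", "OTP", log_p = 2,
                             molecular_weight = 300, charge_class = "neutral")
  opo <- compound_descriptor("opo_x", "OPO", log_p = 1.5,
                             molecular_weight = 284, charge_class = "neutral")
  compound_family(
    "desulf_only",
    parent = list(descriptor = otp, params = inert_params(ka = 1, fup = 0.5)),
    oxon = list(descriptor = opo, params = inert_params(fup = 0.5)),
    reactions = list(mm_reaction("otp_x", "opo_x", "liver_microsome",
                                 vmax_invitro = vmax, km = km)))
}

# raw single-compartment model (blood + urine) for closed-form oracles
onecomp_solve <- function(V, CL, dose, times, rtol = 1e-10, atol = 1e-12) {
  enc <- list(
    n_states = 2L,
    gut = list(present = FALSE),
    species = matrix(c(0, V, 1, CL / V), nrow = 1,
                     dimnames = list(NULL, c("blood_idx", "V_blood",
                                             "urine_idx", "renal_coeff"))),
    tissues = matrix(numeric(0), ncol = 5),
    reactions = matrix(numeric(0), ncol = 7))
  sol <- pbkop:::.pbk_solve(c(dose, 0), 0, times, enc, rtol, atol, 1e6)
  stopifnot(isTRUE(sol$success))
  sol$y[, 1]
}

trapz <- function(t, v) sum(diff(t) * (v[-length(v)] + v[-1]) / 2)
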