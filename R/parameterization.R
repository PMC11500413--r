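#' Compound-specific kinetic parameter bundle
#'
#' @param fup Fraction unbound in plasma, (0, 1].
#' @param bpr Blood:plasma concentration ratio, > 0.
#' @param kp Named numeric vector of tissue:plasma partition coefficients
#'   over the perfused compartments; all > 0.
#' @param ka First-order intestinal absorption rate constant, 1/h, >= 0
#'   (only meaningful for the orally dosed species).
#' @param gfr_multiplier Renal secretion multiplier on the passive GFR
#'   clearance (> 1 encodes active tubular secretion of conjugates),
#'   default 1.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(fup, bpr, kp, ka = 0, gfr_multiplier = 1) {
  if (!is.numeric(fup) || fup <= 0 || fup > 1) stop("fup must be in (0, 1]")
  if (!is.numeric(bpr) || bpr <= 0) stop("bpr must be > 0")
  kp <- kp[PBK_COMPARTMENTS]
  if (anyNA(kp)) {
    stop("kp must name every perfused compartment: ",
         paste(PBK_COMPARTMENTS, collapse = ", "))
  }
  if (any(kp <= 0)) stop("all partition coefficients must be > 0")
  if (!is.numeric(ka) || ka < 0) stop("ka must be >= 0 (1/h)")
  if (!is.numeric(gfr_multiplier) || gfr_multiplier < 0) {
    stop("gfr_multiplier must be >= 0")
  }
  structure(list(fup = as.numeric(fup), bpr = as.numeric(bpr),
                 kp = kp, ka = as.numeric(ka),
                 gfr_multiplier = as.numeric(gfr_multiplier)),
            class = "kinetic_params")
}

#' Derive kinetic parameters for a species by running the QSPR chain
#'
#' Convenience wrapper: fup from [predict_fraction_unbound()], BPR from
#' [predict_bpr()], Kp from [predict_partition_coefficients()] (method chosen
#' by role: charge-aware QSPR for urinary metabolites, lipid-partitioning
#' QSPR for parents and oxons, matching the model's use of each).
#'
#' @param descriptor A [compound_descriptor()].
#' @param ka Absorption rate constant (1/h) for the dosed species; default 0.
#' @param bpr_override Optional measured BPR.
#' @param gfr_multiplier Renal secretion multiplier; default 1.
#' @return A [kinetic_params()].
#' @export
derive_kinetic_params <- function(descriptor, ka = 0, bpr_override = NULL,
                                  gfr_multiplier = 1) {
  fup <- predict_fraction_unbound(descriptor)
  bpr <- predict_bpr(descriptor, override = bpr_override)
  method <- if (descriptor$role == "urinary_metabolite") {
    "rodgers_rowland"
  } else {
    "berezhkovskiy"
  }
  kp <- predict_partition_coefficients(descriptor, fup, method = method)
  kinetic_params(fup = fup, bpr = bpr, kp = kp, ka = ka,
                 gfr_multiplier = gfr_multiplier)
}

#' Conjugate composition of a urinary metabolite
#'
#' A urinary metabolite circulates as a mixture of its unconjugated form and
#' glucuronide/sulfate conjugates.  The model lumps these into one simulated
#' species; this object states the mixture.  Default secretion factors encode
#' the cross-species observation that glucuronide and sulfate conjugates are
#' cleared about 1.6 and 5.5 times faster than glomerular filtration.
#'
#' @param forms Named list mapping form label (`unconjugated`, `glucuronide`,
#'   `sulfate`) to a list with elements `fraction` (weights, must sum to 1)
#'   and `params` (a [kinetic_params()] for that form).
#' @param secretion_factors Named numeric vector of per-form GFR multipliers;
#'   defaults `c(unconjugated = 1, glucuronide = 1.6, sulfate = 5.5)`.
#' @return Object of class `conjugate_spec`.
#' @export
conjugate_spec <- function(forms,
                           secretion_factors = c(unconjugated = 1,
                                                 glucuronide = 1.6,
                                                 sulfate = 5.5)) {
  if (length(forms) == 0) stop("conjugate_spec requires at least one form")
  allowed <- c("unconjugated", "glucuronide", "sulfate")
  if (!all(names(forms) %in% allowed)) {
    stop("form labels must be among: ", paste(allowed, collapse = ", "))
  }
  fr <- vapply(forms, function(f) f$fraction, numeric(1))
  if (any(fr < 0)) stop("form fractions must be >= 0")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("form fractions must sum to 1 (got ", sum(fr), ")")
  }
  if (!all(names(forms) %in% names(secretion_factors))) {
    stop("every form needs a secretion factor")
  }
  for (f in forms) stopifnot(inherits(f$params, "kinetic_params"))
  structure(list(forms = forms, secretion_factors = secretion_factors),
            class = "conjugate_spec")
}

#' Lump conjugated and unconjugated metabolite forms into one species
#'
#' Every scalar parameter (fup, BPR, ka) and each tissue's Kp of the lumped
#' species is the fraction-weighted average over the forms; the effective GFR
#' multiplier is the weighted average of the per-form secretion factors.
#' Consequence: every effective parameter lies within the per-form range
#' (convex combination).
#'
#' @param spec A [conjugate_spec()].
#' @return List with `params` (effective [kinetic_params()]) and
#'   `gfr_multiplier` (also stored inside `params`).
#' @export
lump_metabolite_forms <- function(spec) {
  stopifnot(inherits(spec, "conjugate_spec"))
  fr <- vapply(spec$forms, function(f) f$fraction, numeric(1))
  wavg <- function(get) sum(fr * vapply(spec$forms, get, numeric(1)))
  fup <- wavg(function(f) f$params$fup)
  bpr <- wavg(function(f) f$params$bpr)
  ka <- wavg(function(f) f$params$ka)
  kp <- colSums(fr * do.call(rbind, lapply(spec$forms,
                                           function(f) f$params$kp)))
  mult <- sum(fr * spec$secretion_factors[names(spec$forms)])
  params <- kinetic_params(fup = fup, bpr = bpr, kp = kp, ka = ka,
                           gfr_multiplier = mult)
  list(params = params, gfr_multiplier = mult)
}

#' Fraction of an oral dose absorbed across the small intestine
#'
#' Closed form for first-order absorption competing with transit through `n`
#' equal small-intestine segments in series: each segment passes a fraction
#' `kt / (kt + ka)` onward, so
#' `fa = 1 - (1 + ka / kt_si)^(-n)`.
#'
#' `kt_si` is the per-segment transit rate, the same quantity that appears in
#' the species template and the gut ODEs (mean small-intestinal residence
#' time is `n / kt_si`).  Writings that express the same result in terms of
#' the whole-intestine transit rate `kt* = kt_si / n` read
#' `fa = 1 - (1 + ka / (n kt*))^(-n)`; both forms are identical.
#'
#' @param ka Absorption rate constant, 1/h, >= 0.
#' @param kt_si Per-segment small-intestinal transit rate, 1/h, > 0.
#' @param n_segments Number of segments (default 7).
#' @return fa in \[0, 1); 0 iff `ka = 0`; strictly increasing in `ka`.
#' @examples
#' compute_fraction_absorbed(4.76, 4.76)  # 1 - 2^-7 = 0.9921875
#' @export
compute_fraction_absorbed <- function(ka, kt_si, n_segments = 7) {
  if (!is.numeric(ka) || any(ka < 0)) stop("ka must be >= 0")
  if (!is.numeric(kt_si) || any(kt_si <= 0)) stop("kt_si must be > 0")
  1 - (1 + ka / kt_si)^(-n_segments)
}

#' In vitro Michaelis-Menten reaction
#'
#' One enzymatic reaction of the metabolic scheme, parameterized by in vitro
#' incubation kinetics.  Hepatic sites (`liver_microsome`, `liver_cytosol`)
#' carry Vmax in nmol/min/mg protein; the `plasma` site (PON1) in
#' nmol/min/mL plasma.  Products name another family member, or one of the
#' terminal sinks `"urinary_metabolite"` / `"hydrolysis_product"` when the
#' product is not itself simulated.
#'
#' @param substrate Substrate species name.
#' @param product Product species name or terminal sink label.
#' @param enzyme_site `"liver_microsome"`, `"liver_cytosol"` or `"plasma"`.
#' @param vmax_invitro nmol/min/mg protein (hepatic) or nmol/min/mL (plasma);
#'   >= 0.
#' @param km Michaelis constant, uM; > 0.
#' @param species Species the incubation was performed in (informational).
#' @return Object of class `mm_reaction`.
#' @export
mm_reaction <- function(substrate, product,
                        enzyme_site = c("liver_microsome", "liver_cytosol",
                                        "plasma"),
                        vmax_invitro, km, species = NA_character_) {
  enzyme_site <- match.arg(enzyme_site)
  if (!is.numeric(vmax_invitro) || is.na(vmax_invitro) || vmax_invitro < 0) {
    stop("vmax_invitro must be >= 0 for reaction ", substrate, " -> ", product)
  }
  if (!is.numeric(km) || is.na(km) || km <= 0) {
    stop("km must be > 0 (uM) for reaction ", substrate, " -> ", product)
  }
  structure(list(substrate = substrate, product = product,
                 enzyme_site = enzyme_site,
                 vmax_invitro = as.numeric(vmax_invitro),
                 km = as.numeric(km), species = species),
            class = "mm_reaction")
}

#' Scale an in vitro Vmax to a whole-organ in vivo capacity
#'
#' Hepatic sites: `Vmax_invivo = Vmax_invitro x (mg protein / g liver) x
#' (g liver) x 60/1000` converting nmol/min to umol/h.  Plasma site: per-mL
#' rate times plasma volume in mL, same time/amount conversion.  Km is taken
#' as identical in vitro and in vivo.
#'
#' @param reaction An [mm_reaction()].
#' @param physiology A [resolve_physiology()] result.
#' @return Vmax in vivo, umol/h.
#' @examples
#' phys <- resolve_physiology(default_species_template("rat"), 0.25)
#' rx <- mm_reaction("parent", "metabolite", "liver_microsome", 0.46, 5.91)
#' scale_vmax(rx, phys)
#' @export
scale_vmax <- function(reaction, physiology) {
  stopifnot(inherits(reaction, "mm_reaction"),
            inherits(physiology, "resolved_physiology"))
  liver_g <- physiology$compartment_volumes[["liver"]] * 1000  # 1 kg/L
  factor <- switch(reaction$enzyme_site,
    liver_microsome = physiology$microsomal_protein_per_g_liver * liver_g,
    liver_cytosol = physiology$cytosolic_protein_per_g_liver * liver_g,
    plasma = physiology$compartment_volumes[["blood"]] *
      physiology$plasma_fraction_of_blood * 1000,  # mL plasma
    stop("unknown enzyme site: ", reaction$enzyme_site))
  reaction$vmax_invitro * factor * 60 / 1000
}

#' Fit Michaelis-Menten kinetics to incubation data
#'
#' Untransformed nonlinear least squares of `v = Vmax * S / (Km + S)` (no
#' Lineweaver-Burk linearization).  Starting values from the observed rate
#' plateau and the concentration nearest half-plateau; bounded below at small
#' positive values via `nls(algorithm = "port")`.
#'
#' @param substrate_conc Substrate concentrations, uM; at least 4 points
#'   spanning below and above the apparent Km.
#' @param rate Observed rates (nmol/min/mg or nmol/min/mL), >= 0.
#' @return List with `vmax`, `km`, `se` (named standard errors), `fit` (the
#'   `nls` object) and `convergence` message.
#' @export
fit_michaelis_menten <- function(substrate_conc, rate) {
  if (length(substrate_conc) != length(rate)) {
    stop("substrate_conc and rate must have equal length")
  }
  if (length(substrate_conc) < 4) {
    stop("at least 4 concentration points are required")
  }
  if (any(rate < 0)) stop("rates must be >= 0")
  if (all(rate == 0)) stop("all rates are zero; nothing to fit")
  dat <- data.frame(S = substrate_conc, v = rate)
  v0 <- max(rate)
  km0 <- substrate_conc[which.min(abs(rate - v0 / 2))]
  if (km0 <= 0) km0 <- stats::median(substrate_conc[substrate_conc > 0])
  fit <- tryCatch(
    stats::nls(v ~ Vmax * S / (Km + S), data = dat,
               start = list(Vmax = v0, Km = km0),
               lower = c(Vmax = 1e-12, Km = 1e-12),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, tol = 1e-12,
                                            warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # robust fallback: direct SSR minimization on log parameters (nls/port
    # occasionally reports false convergence on noisy small-n designs)
    ssr <- function(lp) {
      pred <- exp(lp[1]) * dat$S / (exp(lp[2]) + dat$S)
      sum((dat$v - pred)^2)
    }
    opt <- stats::optim(log(c(v0, km0)), ssr, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (opt$convergence != 0) {
      stop("Michaelis-Menten fit did not converge: ", conditionMessage(fit),
           "; fallback optimizer code ", opt$convergence,
           " (n = ", nrow(dat), ", rate range ",
           paste(signif(range(rate), 3), collapse = "-"), ")")
    }
    est <- c(Vmax = exp(opt$par[1]), Km = exp(opt$par[2]))
    conv <- "converged (direct SSR fallback)"
    fit <- NULL
  } else {
    est <- stats::coef(fit)
    conv <- fit$convInfo$stopMessage %||% "converged"
  }
  # residual-based standard errors from the model Jacobian at the optimum
  se <- tryCatch({
    J <- cbind(dat$S / (est[["Km"]] + dat$S),
               -est[["Vmax"]] * dat$S / (est[["Km"]] + dat$S)^2)
    resid <- dat$v - est[["Vmax"]] * dat$S / (est[["Km"]] + dat$S)
    s2 <- sum(resid^2) / (nrow(dat) - 2)
    sqrt(diag(s2 * solve(crossprod(J))))
  }, error = function(e) c(NA_real_, NA_real_))
  list(vmax = unname(est[["Vmax"]]), km = unname(est[["Km"]]),
       se = c(vmax = se[1], km = se[2]),
       fit = fit, convergence = conv)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Catalytic efficiency Vmax/Km
#'
#' `Vmax` in nmol/min/mg protein and `Km` in uM give `Vmax/Km` in
#' mL/min/mg; the conventional reporting unit is uL/min/mg, hence the
#' factor 1000.
#'
#' @param vmax nmol/min/mg protein (>= 0).
#' @param km uM (> 0).
#' @return Catalytic efficiency, uL/min/mg protein.
#' @examples
#' catalytic_efficiency(0.46, 5.91)  # ~78 uL/min/mg
#' @export
catalytic_efficiency <- function(vmax, km) {
  if (!is.numeric(km) || any(km <= 0)) stop("km must be > 0")
  if (!is.numeric(vmax) || any(vmax < 0)) stop("vmax must be >= 0")
  vmax / km * 1000
}
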