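#' Chemical species descriptor
#'
#' Describes one chemical species of a compound family: the parent
#' organothiophosphate (`"OTP"`), its bioactive oxon (`"OPO"`), or a
#' hydrophilic urinary metabolite (`"urinary_metabolite"`).  The descriptor
#' carries the physicochemical inputs consumed by the QSPRs.
#'
#' @param name Species name (free text, must be unique within a family).
#' @param role One of `"OTP"`, `"OPO"`, `"urinary_metabolite"`.
#' @param log_p Octanol:water log partition coefficient (unitless).
#' @param molecular_weight g/mol, > 0.
#' @param charge_class `"neutral"`, `"acid"` or `"base"` at physiological pH.
#' @param pka Acid/base dissociation constant matching `charge_class`;
#'   optional (`NA`) for neutral compounds.
#' @return Object of class `compound_descriptor`.
#' @export
compound_descriptor <- function(name, role, log_p, molecular_weight,
                                charge_class = c("neutral", "acid", "base"),
                                pka = NA_real_) {
  role <- match.arg(role, c("OTP", "OPO", "urinary_metabolite"))
  charge_class <- match.arg(charge_class)
  if (!is.numeric(molecular_weight) || molecular_weight <= 0) {
    stop("molecular_weight must be > 0 (g/mol)")
  }
  if (!is.numeric(log_p) || !is.finite(log_p)) {
    stop("log_p is required and must be finite")
  }
  structure(list(name = name, role = role, log_p = log_p,
                 molecular_weight = molecular_weight,
                 charge_class = charge_class, pka = as.numeric(pka)),
            class = "compound_descriptor")
}

#' Distribution coefficient at physiological pH
#'
#' logD at the given pH from logP and a monoprotic pKa:
#' acids are corrected by `-log10(1 + 10^(pH - pKa))`, bases by
#' `-log10(1 + 10^(pKa - pH))`; neutral compounds return logP unchanged.
#' Missing pKa on an ionizable class falls back to logP with a warning.
#' @param descriptor A [compound_descriptor()].
#' @param ph pH (default 7.4, plasma).
#' @return logD (unitless).
#' @export
log_d <- function(descriptor, ph = 7.4) {
  lp <- descriptor$log_p
  cc <- descriptor$charge_class
  if (cc == "neutral") return(lp)
  if (is.na(descriptor$pka)) {
    warning("pKa missing for ", cc, " compound '", descriptor$name,
            "'; using logP as logD")
    return(lp)
  }
  if (cc == "acid") lp - log10(1 + 10^(ph - descriptor$pka))
  else lp - log10(1 + 10^(descriptor$pka - ph))
}

#' Default coefficients of the plasma-protein-binding QSPR
#'
#' The fraction unbound in plasma is modelled as a logistic function of the
#' pH 7.4 distribution coefficient with class-specific coefficients:
#' `fup = 1 / (1 + 10^(a + b * logD))`.  The class-specific
#' lipophilicity-regression structure follows the published
#' plasma-protein-binding QSPR family used for this model class; the default
#' coefficients below are editable calibration constants chosen to reproduce
#' typical binding magnitudes (see vignette), not values printed in any
#' single source.
#' @return Named list of `c(a, b)` per charge class.
#' @export
fup_qspr_coefficients <- function() {
  list(neutral = c(a = -0.51, b = 0.50),
       acid    = c(a =  0.06, b = 0.43),
       base    = c(a = -0.40, b = 0.42))
}

#' Predict fraction unbound in plasma from lipophilicity
#'
#' `fup = 1 / (1 + 10^(a + b * logD7.4))` with class-specific `(a, b)`
#' (see [fup_qspr_coefficients()]).  With `b > 0` the prediction is strictly
#' decreasing in logP within a charge class and tends to 1 as logP tends to
#' minus infinity.
#'
#' @param descriptor A [compound_descriptor()]; `log_p` is required.
#' @param coefficients Coefficient list as returned by
#'   [fup_qspr_coefficients()].
#' @return fup, a fraction in (0, 1].
#' @export
predict_fraction_unbound <- function(descriptor,
                                     coefficients = fup_qspr_coefficients()) {
  if (is.null(descriptor$log_p) || !is.finite(descriptor$log_p)) {
    stop("log_p is required to predict the fraction unbound")
  }
  cf <- coefficients[[descriptor$charge_class]]
  if (is.null(cf)) stop("no fup coefficients for class ", descriptor$charge_class)
  ld <- log_d(descriptor)
  1 / (1 + 10^(cf[["a"]] + cf[["b"]] * ld))
}

#' Blood-to-plasma concentration ratio
#'
#' In the absence of measured data the BPR defaults to 1 for neutral and
#' basic compounds and 0.55 for acids (acids are largely excluded from
#' erythrocytes, so whole-blood concentration is roughly the plasma fraction
#' of blood).  A measured value can be passed through as `override`.
#'
#' @param descriptor A [compound_descriptor()].
#' @param override Optional positive measured BPR; returned unchanged.
#' @return BPR (unitless, > 0).
#' @export
predict_bpr <- function(descriptor, override = NULL) {
  if (!is.null(override)) {
    if (!is.numeric(override) || length(override) != 1 || override <= 0) {
      stop("BPR override must be a single positive number")
    }
    return(as.numeric(override))
  }
  if (descriptor$charge_class == "acid") 0.55 else 1.0
}

#' Tissue composition table for the perfusion-limited compartments
#'
#' Fractional volumes of water (`vw`), neutral lipid (`vnl`) and phospholipid
#' (`vph`) per tissue plus plasma, used by the Berezhkovskiy-type partition
#' QSPR.  Standard rodent reference values; editable defaults.
#' @return data.frame with row names over compartments plus `"plasma"`.
#' @export
tissue_composition_bere <- function() {
  data.frame(
    vw  = c(liver = 0.705, kidney = 0.783, brain = 0.788, fat = 0.120,
            slowly_perfused = 0.756, rapidly_perfused = 0.779,
            plasma = 0.960),
    vnl = c(liver = 0.0138, kidney = 0.0123, brain = 0.0392, fat = 0.853,
            slowly_perfused = 0.0100, rapidly_perfused = 0.0115,
            plasma = 0.00147),
    vph = c(liver = 0.0303, kidney = 0.0284, brain = 0.0533, fat = 0.002,
            slowly_perfused = 0.0090, rapidly_perfused = 0.0166,
            plasma = 0.00083))
}

#' Tissue composition and albumin ratios for the charge-aware partition QSPR
#'
#' Extracellular water (`f_ew`), intracellular water (`f_iw`), neutral lipid
#' (`f_nl`), neutral phospholipid (`f_np`) fractional tissue volumes and
#' tissue:plasma albumin concentration ratios (`albumin_ratio`).  Standard
#' rodent reference values; editable defaults.  Plasma lipid fractions and
#' the water pH values are carried as attributes.
#' @return data.frame with attributes `plasma_nl`, `plasma_np`, `ph_iw`,
#'   `ph_plasma`.
#' @export
tissue_composition_rr <- function() {
  out <- data.frame(
    f_ew = c(liver = 0.161, kidney = 0.273, brain = 0.162, fat = 0.135,
             slowly_perfused = 0.118, rapidly_perfused = 0.336),
    f_iw = c(liver = 0.573, kidney = 0.483, brain = 0.620, fat = 0.017,
             slowly_perfused = 0.630, rapidly_perfused = 0.446),
    f_nl = c(liver = 0.0135, kidney = 0.0121, brain = 0.0391, fat = 0.853,
             slowly_perfused = 0.0100, rapidly_perfused = 0.0220),
    f_np = c(liver = 0.0238, kidney = 0.0240, brain = 0.0015, fat = 0.0016,
             slowly_perfused = 0.0072, rapidly_perfused = 0.0128),
    albumin_ratio = c(liver = 0.086, kidney = 0.130, brain = 0.048,
                      fat = 0.049, slowly_perfused = 0.064,
                      rapidly_perfused = 0.212))
  attr(out, "plasma_nl") <- 0.0023
  attr(out, "plasma_np") <- 0.0013
  attr(out, "ph_iw") <- 7.0
  attr(out, "ph_plasma") <- 7.4
  out
}

#' Predict tissue:plasma partition coefficients
#'
#' Two tissue-composition QSPRs are provided.  `"berezhkovskiy"` (used for
#' the lipophilic parents and oxons) partitions the neutral molecule between
#' tissue and plasma lipids and water, with the unbound fractions dividing
#' the aqueous terms only:
#' \deqn{K_p = \frac{P(V_{nl,t} + 0.3 V_{ph,t}) + (V_{w,t} + 0.7 V_{ph,t})/f_{u,t}}
#'                  {P(V_{nl,p} + 0.3 V_{ph,p}) + (V_{w,p} + 0.7 V_{ph,p})/f_{u,p}}}
#' with `P = 10^logD7.4`, `fut = 1/(1 + ((1-fup)/fup)/2)` for non-adipose
#' tissues and `fut = 1` for fat.  `"rodgers_rowland"` (used for the charged
#' urinary metabolites) computes the unbound tissue:plasma ratio `Kpu` from
#' extracellular/intracellular water with Henderson-Hasselbalch ionization,
#' neutral-species lipid partitioning, and albumin-ratio-scaled extracellular
#' protein binding inferred from `fup`; `Kp = Kpu * fup`.  Strong bases are
#' handled with the same weak-base equation (no acidic-phospholipid
#' association term), a documented limitation acceptable here because the
#' charged species in OP families are acids.
#'
#' @param descriptor A [compound_descriptor()].
#' @param fup Fraction unbound in plasma, in (0, 1].
#' @param method `"berezhkovskiy"` or `"rodgers_rowland"`.
#' @param composition Optional composition table overriding the defaults
#'   ([tissue_composition_bere()] / [tissue_composition_rr()]).
#' @return Named numeric vector of Kp over the perfused compartments; all
#'   values > 0.
#' @export
predict_partition_coefficients <- function(descriptor, fup,
                                           method = c("berezhkovskiy",
                                                      "rodgers_rowland"),
                                           composition = NULL) {
  method <- match.arg(method)
  if (!is.numeric(fup) || length(fup) != 1 || fup <= 0 || fup > 1) {
    stop("fup must be a single value in (0, 1]")
  }
  if (method == "berezhkovskiy") {
    tc <- if (is.null(composition)) tissue_composition_bere() else composition
    P <- 10^log_d(descriptor)
    fut <- 1 / (1 + ((1 - fup) / fup) / 2)
    denom <- P * (tc["plasma", "vnl"] + 0.3 * tc["plasma", "vph"]) +
      (tc["plasma", "vw"] + 0.7 * tc["plasma", "vph"]) / fup
    kp <- vapply(PBK_COMPARTMENTS, function(t) {
      fu_t <- if (t == "fat") 1 else fut
      num <- P * (tc[t, "vnl"] + 0.3 * tc[t, "vph"]) +
        (tc[t, "vw"] + 0.7 * tc[t, "vph"]) / fu_t
      num / denom
    }, numeric(1))
    return(kp)
  }

  # rodgers_rowland
  if (descriptor$charge_class != "neutral" && is.na(descriptor$pka)) {
    stop("rodgers_rowland requires a pKa for ", descriptor$charge_class,
         " compound '", descriptor$name, "'")
  }
  tc <- if (is.null(composition)) tissue_composition_rr() else composition
  ph_iw <- attr(tc, "ph_iw")
  ph_p <- attr(tc, "ph_plasma")
  P <- 10^descriptor$log_p
  ion <- function(ph) {
    switch(descriptor$charge_class,
           neutral = 1,
           acid = 1 + 10^(ph - descriptor$pka),
           base = 1 + 10^(descriptor$pka - ph))
  }
  X <- ion(ph_iw)   # total:neutral in intracellular water
  Y <- ion(ph_p)    # total:neutral in plasma water
  lip_p <- (P * attr(tc, "plasma_nl") +
              (0.3 * P + 0.7) * attr(tc, "plasma_np")) / Y
  ka_pr <- max(0, 1 / fup - 1 - lip_p)  # albumin association, plasma units
  kp <- vapply(PBK_COMPARTMENTS, function(t) {
    lip_t <- (P * tc[t, "f_nl"] + (0.3 * P + 0.7) * tc[t, "f_np"]) / Y
    kpu <- tc[t, "f_ew"] + (X / Y) * tc[t, "f_iw"] + lip_t +
      tc[t, "albumin_ratio"] * ka_pr
    kpu * fup
  }, numeric(1))
  kp
}
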