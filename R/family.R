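#' Compound family: the chemical species and reactions of one OP pesticide
#'
#' A family wires together the dosed parent compound (an organothiophosphate
#' or an oxon-type OP), optionally its bioactive oxon, one or more lumped
#' urinary metabolites, and the Michaelis-Menten reactions connecting them:
#' CYP450-mediated oxidative desulfuration (OTP to OPO) and oxidative
#' cleavage (OTP/OPO to urinary metabolite) in the liver, and PON1-mediated
#' hydrolysis of the oxon in liver and plasma.  Urinary metabolites undergo
#' no further metabolism.  A reaction product that is not itself simulated is
#' routed to a terminal mass sink (`"urinary_metabolite"` or
#' `"hydrolysis_product"`).
#'
#' @param name Family label.
#' @param parent List with `descriptor` ([compound_descriptor()], role
#'   `"OTP"` or `"OPO"`) and `params` ([kinetic_params()]).
#' @param oxon Optional list like `parent` with role `"OPO"`.
#' @param metabolites List of lists like `parent` with role
#'   `"urinary_metabolite"` (already conjugate-lumped, see
#'   [lump_metabolite_forms()]).
#' @param reactions List of [mm_reaction()].
#' @return Object of class `compound_family`.
#' @export
compound_family <- function(name, parent, oxon = NULL, metabolites = list(),
                            reactions = list()) {
  members <- list()
  add_member <- function(m, slot, roles) {
    stopifnot(inherits(m$descriptor, "compound_descriptor"),
              inherits(m$params, "kinetic_params"))
    if (!m$descriptor$role %in% roles) {
      stop(slot, " member '", m$descriptor$name, "' must have role ",
           paste(roles, collapse = " or "), ", got ", m$descriptor$role)
    }
    if (m$descriptor$name %in% names(members)) {
      stop("duplicate member name: ", m$descriptor$name)
    }
    members[[m$descriptor$name]] <<- c(m, list(slot = slot))
  }
  add_member(parent, "parent", c("OTP", "OPO"))
  if (!is.null(oxon)) add_member(oxon, "oxon", "OPO")
  for (met in metabolites) add_member(met, "metabolite", "urinary_metabolite")

  terminal <- c("urinary_metabolite", "hydrolysis_product")
  for (rx in reactions) {
    stopifnot(inherits(rx, "mm_reaction"))
    sub <- members[[rx$substrate]]
    if (is.null(sub)) {
      stop("reaction substrate '", rx$substrate, "' is not a family member")
    }
    if (sub$descriptor$role == "urinary_metabolite") {
      stop("urinary metabolite '", rx$substrate,
           "' cannot be a reaction substrate")
    }
    if (sub$descriptor$role == "OTP" && rx$enzyme_site == "plasma") {
      stop("plasma (PON1) metabolism is not modeled for OTP substrate '",
           rx$substrate, "'")
    }
    if (!(rx$product %in% names(members) || rx$product %in% terminal)) {
      stop("reaction product '", rx$product,
           "' resolves to neither a family member nor a terminal sink (",
           paste(terminal, collapse = ", "), ")")
    }
    if (rx$product %in% names(members)) {
      prole <- members[[rx$product]]$descriptor$role
      srole <- sub$descriptor$role
      ok <- (srole == "OTP" && prole %in% c("OPO", "urinary_metabolite")) ||
        (srole == "OPO" && prole == "urinary_metabolite")
      if (!ok) {
        stop("reaction ", rx$substrate, " -> ", rx$product,
             " violates the metabolic scheme (", srole, " -> ", prole, ")")
      }
    }
  }
  structure(list(name = name, members = members, reactions = reactions),
            class = "compound_family")
}

#' @export
print.compound_family <- function(x, ...) {
  cat("Compound family:", x$name, "\n")
  for (m in x$members) {
    cat(sprintf("  [%s] %s (%s, MW %.1f, logP %.2f, fup %.3g, BPR %.3g)\n",
                m$slot, m$descriptor$name, m$descriptor$role,
                m$descriptor$molecular_weight, m$descriptor$log_p,
                m$params$fup, m$params$bpr))
  }
  for (rx in x$reactions) {
    cat(sprintf("  %s -> %s [%s] Vmax %.3g, Km %.3g uM\n", rx$substrate,
                rx$product, rx$enzyme_site, rx$vmax_invitro, rx$km))
  }
  invisible(x)
}
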