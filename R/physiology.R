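#' Species physiology templates and body-weight resolution
#'
#' A `species_template` holds the species-level physiology of the PBK model as
#' body-weight-relative quantities: tissue volumes as fractions of body weight
#' (1 kg tissue is taken as 1 L), blood flows as fractions of cardiac output,
#' an allometric cardiac-output coefficient, a linear glomerular-filtration
#' coefficient, gut transit rates, and in-vitro-to-in-vivo protein scaling
#' factors.  [resolve_physiology()] turns a template plus a body weight into
#' absolute volumes (L), flows (L/h) and clearances (L/h).
#'
#' The shipped defaults ([default_species_template()]) are standard adult
#' reference physiology assembled from the usual literature compilations and
#' are deliberately editable: they are defaults, not measured values for any
#' particular study population.  Rat values lean male, human values lean
#' Caucasian adult male; no sex-specific templates are provided.
#'
#' @param species_id `"rat"` or `"human"` (free text allowed for custom
#'   templates).
#' @param reference_body_weight Reference adult body weight, kg.
#' @param tissue_volume_fractions Named numeric vector, fraction of body weight
#'   per compartment; names must be exactly the model compartments
#'   (liver, kidney, brain, fat, slowly_perfused, rapidly_perfused) plus
#'   `blood`.
#' @param tissue_flow_fractions Named numeric vector over the perfused
#'   compartments (everything except `blood`), fractions of cardiac output.
#'   Normalized to sum to one at resolution.
#' @param cardiac_output_coeff Cardiac output coefficient, L/h per
#'   kg^`allometric_exponent`.
#' @param allometric_exponent Exponent for cardiac-output scaling (default
#'   0.74).
#' @param gfr_coeff Glomerular filtration rate, L/h per kg body weight (linear
#'   scaling).
#' @param GER Gastric emptying rate, 1/h.
#' @param kt_si Small-intestine segment transit rate, 1/h (seven segments in
#'   series, so total small-intestinal transit time is `7 / kt_si`).
#' @param kt_col Colon-to-feces transit rate, 1/h.
#' @param microsomal_protein_per_g_liver mg microsomal protein per g liver.
#' @param cytosolic_protein_per_g_liver mg cytosolic protein per g liver.
#' @param plasma_fraction_of_blood Plasma volume fraction of whole blood
#'   (1 - hematocrit).
#' @return An object of class `species_template`.
#' @seealso [resolve_physiology()], [default_species_template()]
#' @export
species_template <- function(species_id,
                             reference_body_weight,
                             tissue_volume_fractions,
                             tissue_flow_fractions,
                             cardiac_output_coeff,
                             gfr_coeff,
                             GER,
                             kt_si,
                             kt_col,
                             microsomal_protein_per_g_liver,
                             cytosolic_protein_per_g_liver,
                             plasma_fraction_of_blood,
                             allometric_exponent = 0.74) {
  vol_names <- c(PBK_COMPARTMENTS, "blood")
  tissue_volume_fractions <- tissue_volume_fractions[vol_names]
  if (anyNA(tissue_volume_fractions)) {
    stop("tissue_volume_fractions must name every compartment: ",
         paste(vol_names, collapse = ", "))
  }
  tissue_flow_fractions <- tissue_flow_fractions[PBK_COMPARTMENTS]
  if (anyNA(tissue_flow_fractions)) {
    stop("tissue_flow_fractions must name every perfused compartment: ",
         paste(PBK_COMPARTMENTS, collapse = ", "))
  }
  if (any(tissue_volume_fractions <= 0) || any(tissue_volume_fractions >= 1)) {
    stop("all tissue volume fractions must lie in (0, 1)")
  }
  if (sum(tissue_volume_fractions) > 1) {
    stop("tissue volume fractions sum to more than 1 (",
         round(sum(tissue_volume_fractions), 4), ")")
  }
  if (any(tissue_flow_fractions <= 0) || any(tissue_flow_fractions >= 1)) {
    stop("all tissue flow fractions must lie in (0, 1)")
  }
  rates <- c(cardiac_output_coeff = cardiac_output_coeff, gfr_coeff = gfr_coeff,
             GER = GER, kt_si = kt_si, kt_col = kt_col,
             microsomal_protein_per_g_liver = microsomal_protein_per_g_liver,
             cytosolic_protein_per_g_liver = cytosolic_protein_per_g_liver,
             plasma_fraction_of_blood = plasma_fraction_of_blood)
  if (any(rates <= 0)) {
    stop("all rates and scaling factors must be > 0; offending: ",
         paste(names(rates)[rates <= 0], collapse = ", "))
  }
  if (plasma_fraction_of_blood >= 1) {
    stop("plasma_fraction_of_blood must be < 1")
  }
  structure(
    list(species_id = species_id,
         reference_body_weight = reference_body_weight,
         tissue_volume_fractions = tissue_volume_fractions,
         tissue_flow_fractions = tissue_flow_fractions,
         cardiac_output_coeff = cardiac_output_coeff,
         allometric_exponent = allometric_exponent,
         gfr_coeff = gfr_coeff,
         GER = GER, kt_si = kt_si, kt_col = kt_col,
         microsomal_protein_per_g_liver = microsomal_protein_per_g_liver,
         cytosolic_protein_per_g_liver = cytosolic_protein_per_g_liver,
         plasma_fraction_of_blood = plasma_fraction_of_blood),
    class = "species_template")
}

#' Perfused model compartments (excluding blood)
#'
#' Order is load-bearing: the state layout, partition-coefficient maps and
#' tissue-composition tables all follow it.
#' @export
PBK_COMPARTMENTS <- c("liver", "kidney", "brain", "fat",
                      "slowly_perfused", "rapidly_perfused")

#' Default physiology templates for rat and human
#'
#' Editable defaults drawn from standard reference-physiology compilations;
#' see the package vignette for the provenance of each field.  Gut transit:
#' seven small-intestine segments give total transit times of about 1.5 h
#' (rat) and 3.3 h (human); gastric emptying half-life about 15 min in both.
#'
#' @param species `"rat"` or `"human"`.
#' @return A [species_template()].
#' @export
default_species_template <- function(species = c("rat", "human")) {
  species <- match.arg(species)
  if (species == "rat") {
    species_template(
      species_id = "rat",
      reference_body_weight = 0.25,
      tissue_volume_fractions = c(liver = 0.034, kidney = 0.007,
                                  brain = 0.0057, fat = 0.07,
                                  slowly_perfused = 0.65,
                                  rapidly_perfused = 0.05, blood = 0.074),
      tissue_flow_fractions = c(liver = 0.174, kidney = 0.141, brain = 0.02,
                                fat = 0.07, slowly_perfused = 0.314,
                                rapidly_perfused = 0.281),
      cardiac_output_coeff = 14.1,   # L/h/kg^0.74
      gfr_coeff = 0.62,              # L/h/kg
      GER = 2.77,                    # 1/h
      kt_si = 4.76,                  # 1/h (7 segments, ~1.5 h SI transit)
      kt_col = 0.25,                 # 1/h
      microsomal_protein_per_g_liver = 32,
      cytosolic_protein_per_g_liver = 80.7,
      plasma_fraction_of_blood = 0.54)
  } else {
    species_template(
      species_id = "human",
      reference_body_weight = 70,
      tissue_volume_fractions = c(liver = 0.026, kidney = 0.0044,
                                  brain = 0.02, fat = 0.19,
                                  slowly_perfused = 0.56,
                                  rapidly_perfused = 0.04, blood = 0.079),
      tissue_flow_fractions = c(liver = 0.227, kidney = 0.175, brain = 0.114,
                                fat = 0.052, slowly_perfused = 0.242,
                                rapidly_perfused = 0.19),
      cardiac_output_coeff = 15.0,
      gfr_coeff = 0.103,
      GER = 2.77,
      kt_si = 2.11,                  # ~3.3 h SI transit
      kt_col = 0.055,
      microsomal_protein_per_g_liver = 32,
      cytosolic_protein_per_g_liver = 80.7,
      plasma_fraction_of_blood = 0.55)
  }
}

#' Resolve a species template to absolute physiology at a body weight
#'
#' Volumes are `fraction x BW` (tissue density 1 kg/L), cardiac output is
#' `coeff x BW^exponent`, tissue flows are normalized flow fractions times
#' cardiac output (so they sum to cardiac output exactly), and GFR scales
#' linearly with body weight.
#'
#' @param template A [species_template()].
#' @param body_weight Body weight, kg; must be > 0.
#' @return An object of class `resolved_physiology` with elements
#'   `compartment_volumes` (L, including `blood`), `compartment_flows` (L/h),
#'   `cardiac_output` (L/h), `GFR` (L/h), the gut rates and protein scaling
#'   factors carried through, and `body_weight`.
#' @examples
#' phys <- resolve_physiology(default_species_template("rat"), 0.25)
#' phys$compartment_volumes[["liver"]]  # 0.034 * 0.25 = 0.0085 L
#' @export
resolve_physiology <- function(template, body_weight) {
  stopifnot(inherits(template, "species_template"))
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("body_weight must be a single positive number (kg)")
  }
  volumes <- template$tissue_volume_fractions * body_weight
  co <- template$cardiac_output_coeff * body_weight^template$allometric_exponent
  ff <- template$tissue_flow_fractions / sum(template$tissue_flow_fractions)
  flows <- ff * co
  structure(
    list(species_id = template$species_id,
         body_weight = body_weight,
         compartment_volumes = volumes,
         compartment_flows = flows,
         cardiac_output = co,
         GFR = template$gfr_coeff * body_weight,
         GER = template$GER,
         kt_si = template$kt_si,
         kt_col = template$kt_col,
         microsomal_protein_per_g_liver = template$microsomal_protein_per_g_liver,
         cytosolic_protein_per_g_liver = template$cytosolic_protein_per_g_liver,
         plasma_fraction_of_blood = template$plasma_fraction_of_blood,
         template = template),
    class = "resolved_physiology")
}

#' @export
print.resolved_physiology <- function(x, ...) {
  cat("Resolved physiology:", x$species_id, "at", x$body_weight, "kg\n")
  cat("  cardiac output:", signif(x$cardiac_output, 4), "L/h;  GFR:",
      signif(x$GFR, 4), "L/h\n")
  cat("  volumes (L):",
      paste(names(x$compartment_volumes),
            signif(x$compartment_volumes, 3), collapse = ", "), "\n")
  cat("  flows (L/h):",
      paste(names(x$compartment_flows),
            signif(x$compartment_flows, 3), collapse = ", "), "\n")
  invisible(x)
}
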