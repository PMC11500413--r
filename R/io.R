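#' @useDynLib pbkop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# JSON config round-trips.  Schema version 1; all units are carried in field
# names or documented here: volumes L, flows L/h, rates 1/h, doses mg/kg,
# Vmax nmol/min/mg (hepatic) or nmol/min/mL (plasma), Km uM.

descriptor_to_list <- function(d) {
  list(name = d$name, role = d$role, log_p = d$log_p,
       molecular_weight = d$molecular_weight, charge_class = d$charge_class,
       pka = if (is.na(d$pka)) NULL else d$pka)
}

params_to_list <- function(p) {
  list(fup = p$fup, bpr = p$bpr, kp = as.list(p$kp), ka = p$ka,
       gfr_multiplier = p$gfr_multiplier)
}

member_from_list <- function(x) {
  d <- x$descriptor
  desc <- compound_descriptor(name = d$name, role = d$role, log_p = d$log_p,
                              molecular_weight = d$molecular_weight,
                              charge_class = d$charge_class,
                              pka = d$pka %||% NA_real_)
  params <- if (identical(x$params, "derive")) {
    opts <- x$derive %||% list()
    derive_kinetic_params(desc, ka = opts$ka %||% 0,
                          bpr_override = opts$bpr_override,
                          gfr_multiplier = opts$gfr_multiplier %||% 1)
  } else {
    p <- x$params
    kinetic_params(fup = p$fup, bpr = p$bpr, kp = unlist(p$kp),
                   ka = p$ka %||% 0,
                   gfr_multiplier = p$gfr_multiplier %||% 1)
  }
  list(descriptor = desc, params = params)
}

#' Write / read a compound family as a JSON config
#'
#' @param family A [compound_family()].
#' @param path File path.
#' @return `read_family_json` returns a [compound_family()];
#'   `write_family_json` returns `path` invisibly.
#' @export
write_family_json <- function(family, path) {
  stopifnot(inherits(family, "compound_family"))
  members <- lapply(family$members, function(m) {
    list(slot = m$slot, descriptor = descriptor_to_list(m$descriptor),
         params = params_to_list(m$params))
  })
  names(members) <- NULL
  reactions <- lapply(family$reactions, function(rx) {
    list(substrate = rx$substrate, product = rx$product,
         enzyme_site = rx$enzyme_site, vmax_invitro = rx$vmax_invitro,
         km = rx$km,
         species = if (is.na(rx$species)) NULL else rx$species)
  })
  jsonlite::write_json(
    list(schema_version = 1, name = family$name, members = members,
         reactions = reactions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_family_json
#' @export
read_family_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$schema_version, 1L) && !identical(x$schema_version, 1)) {
    stop("unsupported family schema version: ", x$schema_version)
  }
  parent <- NULL; oxon <- NULL; metabolites <- list()
  for (m in x$members) {
    mem <- member_from_list(m)
    switch(m$slot,
           parent = parent <- mem,
           oxon = oxon <- mem,
           metabolite = metabolites[[length(metabolites) + 1L]] <- mem,
           stop("unknown member slot: ", m$slot))
  }
  if (is.null(parent)) stop("family config has no parent member")
  reactions <- lapply(x$reactions, function(rx) {
    if (is.null(rx$km)) {
      stop("reaction ", rx$substrate %||% "?", " -> ", rx$product %||% "?",
           " is missing Km")
    }
    if (is.null(rx$vmax_invitro)) {
      stop("reaction ", rx$substrate %||% "?", " -> ", rx$product %||% "?",
           " is missing Vmax")
    }
    mm_reaction(substrate = rx$substrate, product = rx$product,
                enzyme_site = rx$enzyme_site,
                vmax_invitro = rx$vmax_invitro, km = rx$km,
                species = rx$species %||% NA_character_)
  })
  compound_family(name = x$name, parent = parent, oxon = oxon,
                  metabolites = metabolites, reactions = reactions)
}

#' Write / read an exposure scenario as a JSON config
#'
#' @param scenario An [exposure_scenario()].
#' @param path File path.
#' @export
write_scenario_json <- function(scenario, path) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  jsonlite::write_json(
    list(schema_version = 1, species = scenario$species,
         body_weight_kg = scenario$body_weight, route = scenario$route,
         dose_mg_per_kg = scenario$dose, duration_h = scenario$duration,
         absorption_delay_h = scenario$absorption_delay,
         n_output_times = length(scenario$times),
         comparison_mode = scenario$comparison_mode),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  exposure_scenario(
    species = x$species, body_weight = x$body_weight_kg, route = x$route,
    dose = x$dose_mg_per_kg, duration = x$duration_h,
    absorption_delay = x$absorption_delay_h %||% 0,
    times = seq(0, x$duration_h, length.out = x$n_output_times %||% 481),
    comparison_mode = x$comparison_mode %||% "total")
}

#' Write / read a species physiology template as a JSON config
#'
#' @param template A [species_template()].
#' @param path File path.
#' @export
write_species_template_json <- function(template, path) {
  stopifnot(inherits(template, "species_template"))
  x <- unclass(template)
  x$tissue_volume_fractions <- as.list(x$tissue_volume_fractions)
  x$tissue_flow_fractions <- as.list(x$tissue_flow_fractions)
  jsonlite::write_json(c(list(schema_version = 1), x), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_species_template_json
#' @export
read_species_template_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  species_template(
    species_id = x$species_id,
    reference_body_weight = x$reference_body_weight,
    tissue_volume_fractions = unlist(x$tissue_volume_fractions),
    tissue_flow_fractions = unlist(x$tissue_flow_fractions),
    cardiac_output_coeff = x$cardiac_output_coeff,
    gfr_coeff = x$gfr_coeff, GER = x$GER, kt_si = x$kt_si,
    kt_col = x$kt_col,
    microsomal_protein_per_g_liver = x$microsomal_protein_per_g_liver,
    cytosolic_protein_per_g_liver = x$cytosolic_protein_per_g_liver,
    plasma_fraction_of_blood = x$plasma_fraction_of_blood,
    allometric_exponent = x$allometric_exponent %||% 0.74)
}

#' Read / write observed concentration-excretion tables (TSV)
#'
#' Column schema: `study`, `chemical`, `matrix` (blood|plasma|urine),
#' `time_h`, `value`, `unit` (umol/L for blood/plasma, umol for urine), and
#' optionally `route`, `dose_mg_per_kg`, `bw_kg`.
#' @param path TSV file path.
#' @param df Observed table.
#' @export
read_observed_series <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_observed_series(df)
}

#' @rdname read_observed_series
#' @export
write_observed_series <- function(df, path) {
  as_observed_series(as.data.frame(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a simulation as a tidy TSV table
#'
#' @param result A [simulate_pbk()] result.
#' @param path File path.
#' @export
write_simulation_result <- function(result, path) {
  df <- as.data.frame(result)
  df$value <- formatC(df$value, digits = 15, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
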