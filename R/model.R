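#' Assemble the PBK ODE system for a compound family in one species
#'
#' Builds the state layout and the encoded right-hand side consumed by the
#' compiled solver.  States (all molar amounts, umol):
#' \itemize{
#'   \item shared gut states of the orally dosed parent: stomach, seven
#'     small-intestine segments, colon, feces;
#'   \item per chemical species: the six perfusion-limited tissues, blood,
#'     and cumulative urine;
#'   \item one terminal mass sink per reaction product that is not itself
#'     simulated;
#'   \item one auxiliary cumulative-extent state per reaction (flagged
#'     non-mass: the transferred moles are already counted in the product or
#'     sink state).
#' }
#' The RHS: first-order gut transit with absorption from every
#' small-intestine segment into the parent's liver; flow-limited tissue
#' exchange `dA_T/dt = Q_T (C_blood - C_T / (Kp_T / BPR))`; Michaelis-Menten
#' reaction rates `v = Vmax C / (Km + C)` driven by the unbound (default) or
#' total plasma-equivalent concentration at the enzyme site, each appearing
#' as an equal-magnitude inflow to the product (1:1 molar); renal filtration
#' `GFR x fup x C_plasma x gfr_multiplier` into cumulative urine.  Summed
#' over the mass-carrying states the RHS is identically zero, so total molar
#' mass is a linear invariant.
#'
#' @param family A [compound_family()].
#' @param physiology A [resolve_physiology()] result.
#' @param driving `"unbound"` (default) or `"total"`: whether Michaelis-Menten
#'   rates are driven by the unbound or the total plasma-equivalent
#'   concentration at the enzyme site.  Unbound is the default because the in
#'   vitro incubations from which Km is carried over are effectively
#'   free-drug systems.
#' @return Object of class `pbk_model`.
#' @export
build_model <- function(family, physiology,
                        driving = c("unbound", "total")) {
  stopifnot(inherits(family, "compound_family"),
            inherits(physiology, "resolved_physiology"))
  driving <- match.arg(driving)

  members <- family$members
  vols <- physiology$compartment_volumes
  flows <- physiology$compartment_flows
  v_blood <- vols[["blood"]]

  # ---- state layout -------------------------------------------------------
  layout <- data.frame(name = character(), member = character(),
                       compartment = character(), is_mass = logical(),
                       stringsAsFactors = FALSE)
  add_state <- function(name, member, compartment, is_mass = TRUE) {
    layout[nrow(layout) + 1L, ] <<- list(name, member, compartment, is_mass)
  }
  gut_names <- c("gut_stomach", paste0("gut_si", 1:7), "gut_colon",
                 "gut_feces")
  parent_name <- names(members)[vapply(members, function(m)
    m$slot == "parent", logical(1))]
  for (g in gut_names) add_state(g, parent_name, g)
  for (mn in names(members)) {
    for (comp in c(PBK_COMPARTMENTS, "blood", "urine")) {
      add_state(paste0(mn, "_", comp), mn, comp)
    }
  }
  terminal <- c("urinary_metabolite", "hydrolysis_product")
  sink_of <- character()
  for (rx in family$reactions) {
    if (rx$product %in% terminal) {
      sn <- paste0("sink_", rx$product, "_from_", rx$substrate)
      if (!sn %in% layout$name) add_state(sn, rx$substrate, "sink")
      sink_of[paste(rx$substrate, rx$product)] <- sn
    }
  }
  for (i in seq_along(family$reactions)) {
    add_state(sprintf("rxn%d_extent", i), family$reactions[[i]]$substrate,
              "extent", is_mass = FALSE)
  }
  sidx <- function(name) match(name, layout$name) - 1L  # 0-based for C++

  # ---- species (distribution + renal) table ------------------------------
  nm <- names(members)
  species_mat <- matrix(0, nrow = length(nm), ncol = 4,
                        dimnames = list(nm, c("blood_idx", "V_blood",
                                              "urine_idx", "renal_coeff")))
  tissue_rows <- list()
  for (i in seq_along(nm)) {
    p <- members[[nm[i]]]$params
    species_mat[i, ] <- c(sidx(paste0(nm[i], "_blood")), v_blood,
                          sidx(paste0(nm[i], "_urine")),
                          physiology$GFR * p$fup * p$gfr_multiplier /
                            (p$bpr * v_blood))
    for (tis in PBK_COMPARTMENTS) {
      tissue_rows[[length(tissue_rows) + 1L]] <-
        c(i - 1L, sidx(paste0(nm[i], "_", tis)), vols[[tis]], flows[[tis]],
          p$kp[[tis]] / p$bpr)
    }
  }
  tissue_mat <- do.call(rbind, tissue_rows)
  colnames(tissue_mat) <- c("species", "idx", "V", "Q", "KpB")

  # ---- reactions ----------------------------------------------------------
  rxn_rows <- list()
  vmax_invivo <- numeric(length(family$reactions))
  for (i in seq_along(family$reactions)) {
    rx <- family$reactions[[i]]
    sub <- members[[rx$substrate]]
    vmax_invivo[i] <- scale_vmax(rx, physiology)
    hepatic <- rx$enzyme_site != "plasma"
    if (hepatic) {
      src <- sidx(paste0(rx$substrate, "_liver"))
      drv_state <- src
      v_liver <- vols[["liver"]]
      kp_liver <- sub$params$kp[["liver"]]
      drv_coeff <- if (driving == "unbound") {
        sub$params$fup / (v_liver * kp_liver)
      } else {
        1 / (v_liver * kp_liver)
      }
    } else {
      src <- sidx(paste0(rx$substrate, "_blood"))
      drv_state <- src
      drv_coeff <- if (driving == "unbound") {
        sub$params$fup / (v_blood * sub$params$bpr)
      } else {
        1 / (v_blood * sub$params$bpr)
      }
    }
    dst <- if (rx$product %in% names(members)) {
      if (hepatic) sidx(paste0(rx$product, "_liver"))
      else sidx(paste0(rx$product, "_blood"))
    } else {
      sidx(sink_of[[paste(rx$substrate, rx$product)]])
    }
    rxn_rows[[i]] <- c(src, dst, sidx(sprintf("rxn%d_extent", i)),
                       drv_state, drv_coeff, vmax_invivo[i], rx$km)
  }
  rxn_mat <- if (length(rxn_rows)) do.call(rbind, rxn_rows) else
    matrix(numeric(0), ncol = 7)
  colnames(rxn_mat) <- c("src", "dst", "extent", "drv_state", "drv_coeff",
                         "vmax", "km")

  enc <- list(
    n_states = nrow(layout),
    gut = list(present = TRUE,
               idx = vapply(gut_names, sidx, integer(1)),
               liver_in = sidx(paste0(parent_name, "_liver")),
               ger = physiology$GER, kt_si = physiology$kt_si,
               kt_col = physiology$kt_col,
               ka = members[[parent_name]]$params$ka),
    species = species_mat,
    tissues = tissue_mat,
    reactions = rxn_mat)

  structure(list(family = family, physiology = physiology,
                 driving = driving, layout = layout, enc = enc,
                 parent = parent_name, vmax_invivo = vmax_invivo),
            class = "pbk_model")
}

#' Evaluate the model right-hand side at a state point
#'
#' Mainly for verification: conservation and stoichiometry checks.
#' @param model A [build_model()] result.
#' @param state Named or unnamed numeric vector of amounts (umol), length
#'   and order per `model$layout`.
#' @return Named numeric vector of derivatives (umol/h).
#' @export
pbk_rhs <- function(model, state) {
  stopifnot(inherits(model, "pbk_model"))
  if (!is.null(names(state))) state <- state[model$layout$name]
  dy <- .pbk_rhs_eval(as.numeric(state), model$enc)
  names(dy) <- model$layout$name
  dy
}

#' @export
print.pbk_model <- function(x, ...) {
  cat("PBK model:", x$family$name, "in", x$physiology$species_id, "at",
      x$physiology$body_weight, "kg\n")
  cat("  states:", nrow(x$layout), " (",
      sum(x$layout$is_mass), "mass-carrying )\n")
  cat("  members:", paste(names(x$family$members), collapse = ", "), "\n")
  if (length(x$vmax_invivo)) {
    cat("  in vivo Vmax (umol/h):",
        paste(signif(x$vmax_invivo, 4), collapse = ", "), "\n")
  }
  cat("  MM driving concentration:", x$driving, "\n")
  invisible(x)
}
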