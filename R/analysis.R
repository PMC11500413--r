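#' Toxicokinetic summary metrics of a concentration-time series
#'
#' Cmax and Tmax are taken from the discrete series (first maximum); AUC is
#' the linear trapezoid between the first and last observation.  Following
#' the evaluation convention, metrics are only computed for series with at
#' least four points; shorter series return an invalid object carrying the
#' reason.
#'
#' @param times Observation times, h, strictly increasing.
#' @param values Concentrations (or cumulative amounts for urine), >= 0.
#' @return Object of class `tk_metrics`: `cmax`, `tmax` (h), `auc`
#'   (value x h), `n`, `valid`, `reason`.
#' @export
tk_metrics <- function(times, values) {
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (length(times) < 4) {
    return(structure(list(cmax = NA_real_, tmax = NA_real_, auc = NA_real_,
                          n = length(times), valid = FALSE,
                          reason = "fewer than 4 data points"),
                     class = "tk_metrics"))
  }
  i <- which.max(values)
  auc <- sum(diff(times) * (values[-length(values)] + values[-1]) / 2)
  structure(list(cmax = values[i], tmax = times[i], auc = auc,
                 n = length(times), valid = TRUE, reason = NA_character_),
            class = "tk_metrics")
}

#' @export
print.tk_metrics <- function(x, ...) {
  if (!x$valid) {
    cat("TK metrics withheld:", x$reason, "(n =", x$n, ")\n")
  } else {
    cat(sprintf("Cmax %.4g at Tmax %.3g h; AUC %.4g (n = %d)\n",
                x$cmax, x$tmax, x$auc, x$n))
  }
  invisible(x)
}

#' Percent of fold ratios within a k-fold band
#'
#' A ratio is within k-fold when `1/k <= ratio <= k`, bounds inclusive (a
#' ratio of exactly 5 counts as within 5-fold).
#' @param ratios Positive predicted/observed ratios.
#' @param k Fold limit (> 1).
#' @return Percentage in \[0, 100\].
#' @export
within_fold_percent <- function(ratios, k) {
  if (length(ratios) == 0) return(NA_real_)
  100 * mean(ratios >= 1 / k & ratios <= k)
}

#' Validate an observed concentration/excretion-time table
#'
#' Required columns: `study`, `chemical`, `matrix` (`blood`, `plasma` or
#' `urine`), `time_h`, `value`, `unit` (`umol/L` for blood/plasma, `umol`
#' for urine).  Optional: `route`, `dose_mg_per_kg`, `bw_kg`.
#' @param df data.frame.
#' @return The validated data.frame (invisibly classed `observed_series`).
#' @export
as_observed_series <- function(df) {
  need <- c("study", "chemical", "matrix", "time_h", "value", "unit")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("observed series lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(df$matrix %in% c("blood", "plasma", "urine"))) {
    stop("matrix must be one of blood, plasma, urine")
  }
  expected_unit <- ifelse(df$matrix == "urine", "umol", "umol/L")
  bad <- df$unit != expected_unit
  if (any(bad)) {
    stop("unit mismatch: ", df$matrix[bad][1], " rows must carry '",
         expected_unit[bad][1], "', got '", df$unit[bad][1], "'")
  }
  if (any(df$value < 0)) stop("observed values must be >= 0")
  for (g in split(df, interaction(df$study, df$chemical, df$matrix,
                                  drop = TRUE))) {
    if (is.unsorted(g$time_h, strictly = TRUE)) {
      stop("times must be strictly increasing within ",
           g$study[1], "/", g$chemical[1], "/", g$matrix[1])
    }
  }
  class(df) <- c("observed_series", class(df))
  invisible(df)
}

#' Predicted-versus-observed fold evaluation
#'
#' Interpolates the simulated series linearly onto the observed time points
#' (matching chemical and matrix; under the scenario's `"unbound"` comparison
#' mode blood and plasma observations are compared against the simulated
#' free-blood and unbound-plasma series), forms per-point
#' `ratio = predicted / observed`, and summarizes the percentage of points
#' within 2-fold and 5-fold (bounds inclusive), pooled and per matrix.
#' Observed zeros and points where the prediction is exactly zero (e.g.
#' before a delayed absorption phase) are excluded and counted.  For every
#' study/chemical/matrix group with at least four points, fold differences
#' of Cmax, Tmax and AUC (predicted over observed) are reported as well.
#'
#' @param predicted A [simulate_pbk()] result.
#' @param observed An [as_observed_series()]-valid data.frame.
#' @param comparison_mode Override of the scenario's comparison mode.
#' @return Object of class `fold_summary`: `ratios` (per-point table),
#'   `pct_within_2`, `pct_within_5`, `per_matrix`, `metrics` (per-group TK
#'   fold differences), `n_excluded_zero_observed`,
#'   `n_excluded_zero_predicted`.
#' @export
fold_evaluation <- function(predicted, observed, comparison_mode = NULL) {
  stopifnot(inherits(predicted, "pbk_simulation"))
  observed <- as_observed_series(as.data.frame(observed))
  mode <- comparison_mode %||% predicted$scenario$comparison_mode
  series_col <- function(matrix) {
    switch(matrix,
           blood = if (mode == "unbound") "blood_free" else "blood",
           plasma = if (mode == "unbound") "plasma_unbound" else "plasma",
           urine = "urine_umol")
  }
  rows <- list()
  metric_rows <- list()
  for (g in split(observed, interaction(observed$study, observed$chemical,
                                        observed$matrix, drop = TRUE))) {
    chem <- g$chemical[1]
    if (!chem %in% names(predicted$conc)) {
      stop("observed chemical '", chem, "' is not simulated by this model")
    }
    cc <- predicted$conc[[chem]]
    col <- series_col(g$matrix[1])
    if (min(g$time_h) < min(cc$time) || max(g$time_h) > max(cc$time)) {
      stop("observed times for ", g$study[1], "/", chem,
           " fall outside the simulated grid")
    }
    pred <- stats::approx(cc$time, cc[[col]], xout = g$time_h)$y
    rows[[length(rows) + 1L]] <- data.frame(
      study = g$study[1], chemical = chem, matrix = g$matrix[1],
      time_h = g$time_h, predicted = pred, observed = g$value)
    if (nrow(g) >= 4) {
      keep <- cc$time >= min(g$time_h) & cc$time <= max(g$time_h)
      pm <- tk_metrics(cc$time[keep], cc[[col]][keep])
      om <- tk_metrics(g$time_h, g$value)
      if (pm$valid && om$valid) {
        metric_rows[[length(metric_rows) + 1L]] <- data.frame(
          study = g$study[1], chemical = chem, matrix = g$matrix[1],
          cmax_fold = pm$cmax / om$cmax,
          tmax_fold = if (om$tmax > 0) pm$tmax / om$tmax else NA_real_,
          auc_fold = pm$auc / om$auc)
      }
    }
  }
  pts <- do.call(rbind, rows)
  zero_obs <- pts$observed == 0
  zero_pred <- !zero_obs & pts$predicted == 0
  valid <- !zero_obs & !zero_pred
  if (!any(valid)) stop("no valid points: all excluded as zeros")
  pts$ratio <- NA_real_
  pts$ratio[valid] <- pts$predicted[valid] / pts$observed[valid]
  vr <- pts$ratio[valid]
  per_matrix <- do.call(rbind, lapply(split(vr, pts$matrix[valid]),
    function(r) data.frame(n = length(r),
                           pct_within_2 = within_fold_percent(r, 2),
                           pct_within_5 = within_fold_percent(r, 5))))
  per_matrix$matrix <- rownames(per_matrix)
  rownames(per_matrix) <- NULL
  structure(list(ratios = pts,
                 pct_within_2 = within_fold_percent(vr, 2),
                 pct_within_5 = within_fold_percent(vr, 5),
                 per_matrix = per_matrix[, c("matrix", "n", "pct_within_2",
                                             "pct_within_5")],
                 metrics = if (length(metric_rows))
                   do.call(rbind, metric_rows) else NULL,
                 n_excluded_zero_observed = sum(zero_obs),
                 n_excluded_zero_predicted = sum(zero_pred),
                 comparison_mode = mode),
            class = "fold_summary")
}

#' @export
print.fold_summary <- function(x, ...) {
  cat(sprintf(
    "Fold evaluation (%s mode): %.1f%% within 2-fold, %.1f%% within 5-fold (n = %d",
    x$comparison_mode, x$pct_within_2, x$pct_within_5,
    sum(!is.na(x$ratios$ratio))))
  cat(sprintf("; excluded: %d zero observed, %d zero predicted)\n",
              x$n_excluded_zero_observed, x$n_excluded_zero_predicted))
  print(x$per_matrix)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Local sensitivity analysis

#' Names of the scalar parameters exposed to sensitivity analysis
#'
#' @param model A [build_model()] result.
#' @return Character vector of parameter names resolvable by
#'   [local_sensitivity()].
#' @export
sensitivity_parameters <- function(model) {
  stopifnot(inherits(model, "pbk_model"))
  tmpl_scalars <- c("cardiac_output_coeff", "gfr_coeff", "GER", "kt_si",
                    "kt_col", "microsomal_protein_per_g_liver",
                    "cytosolic_protein_per_g_liver",
                    "plasma_fraction_of_blood")
  out <- c("dose", "body_weight", tmpl_scalars,
           paste0("vf_", c(PBK_COMPARTMENTS, "blood")),
           paste0("ff_", PBK_COMPARTMENTS))
  for (mn in names(model$family$members)) {
    m <- model$family$members[[mn]]
    out <- c(out, paste0(c("fup_", "bpr_", "gfr_multiplier_"), mn),
             paste0("kp_", PBK_COMPARTMENTS, "_", mn))
    if (m$slot == "parent" && m$params$ka > 0) {
      out <- c(out, paste0("ka_", mn))
    }
  }
  if (length(model$family$reactions)) {
    out <- c(out, paste0("vmax_rxn", seq_along(model$family$reactions)),
             paste0("km_rxn", seq_along(model$family$reactions)))
  }
  out
}

# Apply a multiplicative factor to one named parameter of the modelling
# context (template / family / scenario); returns the perturbed context.
perturb_context <- function(ctx, param, factor) {
  hit <- FALSE
  bump <- function(x) { hit <<- TRUE; x * factor }
  if (param == "dose") {
    ctx$scenario$dose <- bump(ctx$scenario$dose)
  } else if (param == "body_weight") {
    ctx$scenario$body_weight <- bump(ctx$scenario$body_weight)
  } else if (param %in% names(ctx$template) &&
             is.numeric(ctx$template[[param]]) &&
             length(ctx$template[[param]]) == 1) {
    ctx$template[[param]] <- bump(ctx$template[[param]])
  } else if (grepl("^vf_", param)) {
    comp <- sub("^vf_", "", param)
    ctx$template$tissue_volume_fractions[[comp]] <-
      bump(ctx$template$tissue_volume_fractions[[comp]])
  } else if (grepl("^ff_", param)) {
    comp <- sub("^ff_", "", param)
    ctx$template$tissue_flow_fractions[[comp]] <-
      bump(ctx$template$tissue_flow_fractions[[comp]])
  } else if (grepl("^(vmax|km)_rxn[0-9]+$", param)) {
    i <- as.integer(sub("^.*_rxn", "", param))
    field <- if (grepl("^vmax", param)) "vmax_invitro" else "km"
    ctx$family$reactions[[i]][[field]] <-
      bump(ctx$family$reactions[[i]][[field]])
  } else {
    for (mn in names(ctx$family$members)) {
      suffix <- paste0("_", mn)
      if (!endsWith(param, suffix)) next
      stem <- substr(param, 1, nchar(param) - nchar(suffix))
      if (stem %in% c("fup", "bpr", "gfr_multiplier", "ka")) {
        ctx$family$members[[mn]]$params[[stem]] <-
          bump(ctx$family$members[[mn]]$params[[stem]])
      } else if (grepl("^kp_", stem)) {
        tis <- sub("^kp_", "", stem)
        ctx$family$members[[mn]]$params$kp[[tis]] <-
          bump(ctx$family$members[[mn]]$params$kp[[tis]])
      }
      break
    }
  }
  if (!hit) stop("cannot resolve sensitivity parameter '", param, "'")
  ctx
}

run_context <- function(ctx, rtol, atol) {
  phys <- resolve_physiology(ctx$template, ctx$scenario$body_weight)
  model <- build_model(ctx$family, phys, driving = ctx$driving)
  simulate_pbk(model, ctx$scenario, rtol = rtol, atol = atol)
}

#' Local sensitivity of peak free oxon blood concentration
#'
#' Normalized sensitivity coefficients
#' `SC = ((C(P (1 + d)) - C(P)) / C(P)) / d` for each parameter, where `C`
#' is the maximum over time of the free (unbound) blood concentration of the
#' oxon-role species, `fup/BPR x C_blood` -- the exposure metric tied to
#' acetylcholinesterase inhibition.  The default perturbation is 1%
#' (forward difference); a central difference is available for
#' verification.  Model and physiology are rebuilt from perturbed inputs for
#' every evaluation, so physiological and compound parameters propagate
#' through the full QSPR-free parameter chain (volumes, flows, scaled Vmax).
#'
#' @param model A [build_model()] result.
#' @param scenario An [exposure_scenario()] (the reference analysis uses a
#'   single oral dose of 1 mg/kg, below Km for all reactions).
#' @param parameters Parameter names (see [sensitivity_parameters()]);
#'   default all.
#' @param perturbation Relative perturbation `d` (default 0.01).
#' @param method `"forward"` (default) or `"central"`.
#' @param rtol,atol Solver tolerances (defaults relaxed relative to
#'   [simulate_pbk()] because finite differences at 1% do not resolve below
#'   1e-8 anyway).
#' @return Object of class `sensitivity_result`: data.frame `coefficients`
#'   (`parameter`, `sc`), `baseline_metric` (umol/L), `oxon`, `perturbation`,
#'   `method`.
#' @export
local_sensitivity <- function(model, scenario, parameters = NULL,
                              perturbation = 0.01,
                              method = c("forward", "central"),
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "pbk_model"))
  method <- match.arg(method)
  roles <- vapply(model$family$members,
                  function(m) m$descriptor$role, character(1))
  opo <- names(roles)[roles == "OPO"]
  if (length(opo) == 0) {
    stop("family has no OPO member; the sensitivity metric ",
         "(maximum free oxon blood concentration) is undefined")
  }
  opo <- opo[1]
  metric <- function(sim) max(sim$conc[[opo]]$blood_free)
  ctx <- list(template = model$physiology$template, family = model$family,
              scenario = scenario, driving = model$driving)
  base <- metric(run_context(ctx, rtol, atol))
  if (is.null(parameters)) parameters <- sensitivity_parameters(model)
  if (base <= 0) {
    warning("baseline metric is zero (no oxon formed); SC undefined")
    sc <- rep(NA_real_, length(parameters))
  } else {
    sc <- vapply(parameters, function(p) {
      up <- metric(run_context(perturb_context(ctx, p, 1 + perturbation),
                               rtol, atol))
      if (method == "forward") {
        ((up - base) / base) / perturbation
      } else {
        dn <- metric(run_context(perturb_context(ctx, p, 1 - perturbation),
                                 rtol, atol))
        ((up - dn) / base) / (2 * perturbation)
      }
    }, numeric(1))
  }
  structure(list(coefficients = data.frame(parameter = parameters,
                                           sc = unname(sc)),
                 baseline_metric = base, oxon = opo,
                 perturbation = perturbation, method = method),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Local sensitivity of max free", x$oxon, "blood concentration\n")
  cat("  baseline:", signif(x$baseline_metric, 5), "umol/L;",
      x$method, "difference at", 100 * x$perturbation, "%\n")
  cf <- x$coefficients[order(-abs(x$coefficients$sc)), ]
  print(utils::head(cf, 15), row.names = FALSE)
  if (nrow(cf) > 15) cat("  ...", nrow(cf) - 15, "more\n")
  invisible(x)
}
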