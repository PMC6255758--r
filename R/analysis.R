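# Post-processing: compartment summaries, cross-mode comparisons, and the
# anterior-posterior quadriceps surrogate scale sweep.

#' Per-compartment tissue response over the stance phase
#'
#' Summarizes each time step per compartment over the contacting cartilage
#' columns (tissue `"cartilage"`, traction > 0): contact pressure, contact
#' area, compressive logarithmic strain, maximum principal total stress and
#' depth-averaged pore pressure. Steps in which a compartment has no
#' cartilage contact get `NA` summaries (not zeros) and area 0.
#'
#' The maximum principal total stress per column is the largest of the three
#' normal stresses under uniaxial-strain kinematics,
#' `max(C13 e - p, C33 e - p)` with `e` the (negative) engineering axial
#' strain and `p` the depth-averaged pore pressure; tensile in-plane totals
#' are possible near contact onset.
#'
#' @param sim A `knee_sim` from [simulate_stance()].
#' @param config Run configuration (material constants for the stress
#'   reconstruction).
#' @return A tibble with one row per step x compartment: `step`,
#'   `stance_fraction`, `compartment`, `contact_area_mm2`,
#'   `mean_pressure_MPa`, `peak_pressure_MPa`, `mean_log_strain`,
#'   `min_log_strain` (most compressive), `max_principal_stress_MPa`,
#'   `mean_pore_pressure_MPa`.
#' @export
compartment_response <- function(sim, config = default_config()) {
  stopifnot(inherits(sim, "knee_sim"))
  mc <- config$materials$cartilage
  cart <- material_tipe(mc$E_p, mc$E_t, mc$nu_p, mc$nu_tp, mc$G_t,
                        mc$permeability_k, mc$e0)
  cm <- confined_moduli(cart)
  cols <- sim$columns
  is_cart <- cols$tissue == "cartilage"

  purrr::map_dfr(seq_along(sim$fields), function(j) {
    fld <- sim$fields[[j]]
    purrr::map_dfr(c("medial", "lateral"), function(side) {
      sel <- is_cart & cols$compartment == side & fld$traction > 0
      n <- sum(sel)
      if (n == 0) {
        return(tibble::tibble(
          step = sim$steps$step[j],
          stance_fraction = sim$steps$stance_fraction[j],
          compartment = side, n_contact = 0L, contact_area_mm2 = 0,
          mean_pressure_MPa = NA_real_, peak_pressure_MPa = NA_real_,
          mean_log_strain = NA_real_, min_log_strain = NA_real_,
          max_principal_stress_MPa = NA_real_,
          mean_pore_pressure_MPa = NA_real_
        ))
      }
      Tr <- fld$traction[sel]
      eps <- -fld$w_cart[sel] / cols$h0[sel]       # engineering, negative
      log_eps <- log1p(eps)
      p <- fld$p_mean[sel]
      s_max <- pmax(cm$C13 * eps - p, cm$M_t * eps - p)
      tibble::tibble(
        step = sim$steps$step[j],
        stance_fraction = sim$steps$stance_fraction[j],
        compartment = side, n_contact = n,
        contact_area_mm2 = sum(cols$area[sel]),
        mean_pressure_MPa = mean(Tr), peak_pressure_MPa = max(Tr),
        mean_log_strain = mean(log_eps), min_log_strain = min(log_eps),
        max_principal_stress_MPa = max(s_max),
        mean_pore_pressure_MPa = mean(p)
      )
    })
  })
}

# variables compared between two simulations (steps-table columns)
comparison_variables <- c(
  t_ap_mm = "tx_mm", t_dp_mm = "ty_mm", t_ml_mm = "tz_mm",
  vv_deg = "vv_deg", ie_deg = "ie_deg",
  R_axial_BW = "R_axial_BW", R_ap_BW = "R_ap_BW", R_ml_BW = "R_ml_BW"
)

#' Compare two stance simulations
#'
#' Aligns two `knee_sim` runs on stance fraction (linear interpolation of
#' the second onto the first when the step grids differ) and reports, for
#' the femoral translations, free rotations and contact reactions, the mean
#' and maximum absolute difference and the RMS difference over stance;
#' contact-field snapshots (per-column traction for both runs) are stored at
#' 20%, 50% and 80% of stance when the two runs share a column tessellation.
#'
#' @param sim_a,sim_b `knee_sim` objects (e.g. two driving modes).
#' @param snapshot_at Stance fractions for field snapshots.
#' @return An object of class `knee_comparison`: list with `metrics`
#'   (tibble: `variable`, `mean_abs_diff`, `max_abs_diff`, `rms_diff`,
#'   `ref_rms`), `snapshots` (tibble of per-column tractions or `NULL`),
#'   `series` (the aligned per-step differences) and the two mode
#'   identifiers.
#' @export
compare_models <- function(sim_a, sim_b, snapshot_at = c(0.2, 0.5, 0.8)) {
  stopifnot(inherits(sim_a, "knee_sim"), inherits(sim_b, "knee_sim"))
  sa <- sim_a$steps
  sb <- sim_b$steps
  if (!nrow(sa) || !nrow(sb)) {
    stop("cannot compare: a simulation has no completed steps", call. = FALSE)
  }
  tt <- sa$stance_fraction[sa$stance_fraction <= max(sb$stance_fraction)]
  series <- tibble::tibble(stance_fraction = tt)
  for (nm in names(comparison_variables)) {
    cn <- comparison_variables[[nm]]
    va <- sa[[cn]][seq_along(tt)]
    vb <- stats::approx(sb$stance_fraction, sb[[cn]], xout = tt,
                        rule = 2)$y
    series[[paste0(nm, "_a")]] <- va
    series[[paste0(nm, "_b")]] <- vb
    series[[paste0(nm, "_diff")]] <- vb - va
  }
  metrics <- purrr::map_dfr(names(comparison_variables), function(nm) {
    d <- series[[paste0(nm, "_diff")]]
    va <- series[[paste0(nm, "_a")]]
    tibble::tibble(variable = nm,
                   mean_abs_diff = mean(abs(d)),
                   max_abs_diff = max(abs(d)),
                   rms_diff = sqrt(mean(d^2)),
                   ref_rms = sqrt(mean(va^2)))
  })

  snapshots <- NULL
  if (nrow(sim_a$columns) == nrow(sim_b$columns) &&
      isTRUE(all.equal(sim_a$columns$x, sim_b$columns$x))) {
    snapshots <- purrr::map_dfr(snapshot_at, function(f) {
      ja <- which.min(abs(sa$stance_fraction - f))
      jb <- which.min(abs(sb$stance_fraction - f))
      tibble::tibble(
        stance_fraction = f,
        x = sim_a$columns$x, z = sim_a$columns$z,
        compartment = sim_a$columns$compartment,
        tissue = sim_a$columns$tissue,
        traction_a_MPa = sim_a$fields[[ja]]$traction,
        traction_b_MPa = sim_b$fields[[jb]]$traction
      )
    })
    snapshots$traction_diff_MPa <-
      snapshots$traction_b_MPa - snapshots$traction_a_MPa
  }

  structure(list(metrics = metrics, snapshots = snapshots, series = series,
                 mode_a = sim_a$mode$model_id, mode_b = sim_b$mode$model_id),
            class = "knee_comparison")
}

#' @export
print.knee_comparison <- function(x, ...) {
  cat("<knee_comparison> mode", x$mode_a, "vs", x$mode_b, "\n")
  print(as.data.frame(x$metrics), digits = 4)
  invisible(x)
}

# scalar discrepancy of a comparison: equal-weight mean over translations
# and reactions of the mean absolute difference, each normalized by the RMS
# of the reference series (so millimetres and body weights are commensurable)
comparison_discrepancy <- function(cmp,
                                   variables = c("t_ap_mm", "t_dp_mm",
                                                 "t_ml_mm", "R_axial_BW",
                                                 "R_ap_BW", "R_ml_BW")) {
  m <- cmp$metrics[cmp$metrics$variable %in% variables, ]
  mean(m$mean_abs_diff / pmax(m$ref_rms, 1e-9))
}

#' Sweep the anterior-posterior quadriceps surrogate scale
#'
#' Runs the surrogate-driven mode D over a grid of scale factors and scores
#' each run against a reference simulation with a scalar discrepancy: the
#' equal-weight mean, over the three femoral translations and three contact
#' reactions, of the mean absolute difference normalized by the reference
#' RMS of that variable.
#'
#' @param geometry A `knee_geometry_set` (or variant-B `knee_geometry`).
#' @param gait A `gait_series`.
#' @param reference A `knee_sim` to score against (any mode).
#' @param scales Grid of surrogate scale factors.
#' @param config Run configuration.
#' @return A tibble of class `qf_sweep` with columns `qf_scale` and
#'   `discrepancy` plus per-variable mean absolute differences; attribute
#'   `best` holds the grid scale with the smallest discrepancy.
#' @export
qf_scale_sweep <- function(geometry, gait, reference,
                           scales = seq(0, 1.5, by = 0.1),
                           config = default_config()) {
  stopifnot(inherits(reference, "knee_sim"))
  out <- purrr::map_dfr(scales, function(s) {
    mode <- driving_mode("D", qf_scale = s,
                         moment_scale = config$solver$moment_scale)
    sim <- simulate_stance(geometry, gait, mode, config)
    if (!is.na(sim$failed_at)) {
      return(tibble::tibble(qf_scale = s, discrepancy = NA_real_))
    }
    cmp <- compare_models(reference, sim)
    wide <- stats::setNames(as.list(cmp$metrics$mean_abs_diff),
                            paste0("mad_", cmp$metrics$variable))
    dplyr::bind_cols(tibble::tibble(qf_scale = s,
                                    discrepancy = comparison_discrepancy(cmp)),
                     tibble::as_tibble(wide))
  })
  attr(out, "best") <- out$qf_scale[which.min(out$discrepancy)]
  class(out) <- c("qf_sweep", class(out))
  out
}
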