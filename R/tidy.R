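# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stance simulation
#'
#' One row per time step with the pose, reactions and contact counts (the
#' `steps` tibble, minus solver diagnostics).
#'
#' @param x A `knee_sim`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy knee_sim
#' @export
tidy.knee_sim <- function(x, ...) {
  dplyr::select(x$steps, -dplyr::any_of(c("iterations", "force_residual_BW",
                                          "moment_residual_BWmm",
                                          "complementarity")))
}

#' Glance at a stance simulation
#'
#' One-row summary: mode, steps completed, peak reactions, worst residuals.
#'
#' @param x A `knee_sim`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance knee_sim
#' @export
glance.knee_sim <- function(x, ...) {
  s <- x$steps
  tibble::tibble(
    mode = x$mode$model_id,
    n_steps = x$n_steps,
    steps_completed = nrow(s),
    failed = !is.na(x$failed_at),
    peak_axial_BW = if (nrow(s)) max(s$R_axial_BW) else NA_real_,
    peak_ap_BW = if (nrow(s)) max(abs(s$R_ap_BW)) else NA_real_,
    ie_range_deg = if (nrow(s)) diff(range(s$ie_deg)) else NA_real_,
    max_force_residual_BW = if (nrow(s)) max(s$force_residual_BW) else NA_real_,
    max_complementarity = if (nrow(s)) max(s$complementarity) else NA_real_
  )
}

#' Tidy a model comparison
#'
#' The per-variable difference metrics of a [compare_models()] result.
#'
#' @param x A `knee_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy knee_comparison
#' @export
tidy.knee_comparison <- function(x, ...) {
  dplyr::mutate(x$metrics, mode_a = x$mode_a, mode_b = x$mode_b, .before = 1)
}

#' Glance at a model comparison
#'
#' One-row scalar summary: the normalized discrepancy plus the largest
#' kinematic and reaction differences.
#'
#' @param x A `knee_comparison`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance knee_comparison
#' @export
glance.knee_comparison <- function(x, ...) {
  m <- x$metrics
  pick <- function(v, col) m[[col]][m$variable == v]
  tibble::tibble(
    mode_a = x$mode_a, mode_b = x$mode_b,
    discrepancy = comparison_discrepancy(x),
    max_ie_diff_deg = pick("ie_deg", "max_abs_diff"),
    max_axial_diff_BW = pick("R_axial_BW", "max_abs_diff"),
    rms_axial_diff_BW = pick("R_axial_BW", "rms_diff")
  )
}
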