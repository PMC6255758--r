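# The four driving modes.
#
# A: kinetic, complex geometry -- flexion-extension prescribed, scaled
#    internal-external and varus-valgus moments applied, translational
#    forces applied, quadriceps through the patellar mechanism.
# B: kinetic-kinematic, complex geometry -- flexion-extension and
#    internal-external prescribed, varus-valgus free (no applied moment by
#    default), forces and quadriceps as in A.
# C: kinetic-kinematic, simplified geometry -- forces and rotations only.
# D: as C plus the anterior-posterior quadriceps component added to the
#    anterior-posterior translational force (scale s, default 1).

#' Construct a driving mode
#'
#' @param model_id One of "A", "B", "C", "D".
#' @param qf_scale Scaling of the anterior-posterior quadriceps surrogate
#'   force in mode D (dimensionless; 1 reproduces the full component).
#' @param moment_scale Fraction of the measured moments applied in the
#'   kinetic mode (default 0.5: muscles assumed to absorb half).
#' @param vv_moment_in_B Apply the scaled varus-valgus moment in mode B while
#'   leaving the rotation free (default `FALSE`).
#' @return An object of class `driving_mode`.
#' @examples
#' driving_mode("C")
#' driving_mode("D", qf_scale = 0.7)
#' @export
driving_mode <- function(model_id = c("A", "B", "C", "D"), qf_scale = 1,
                         moment_scale = 0.5, vv_moment_in_B = FALSE) {
  model_id <- match.arg(model_id)
  spec <- switch(model_id,
    A = list(geometry_variant = "A", prescribed = "fe",
             moments = c(ie = moment_scale, vv = moment_scale),
             quadriceps = "patella_mechanism"),
    B = list(geometry_variant = "A", prescribed = c("fe", "ie"),
             moments = if (vv_moment_in_B) c(vv = moment_scale) else
               c(vv = 0)[0],
             quadriceps = "patella_mechanism"),
    C = list(geometry_variant = "B", prescribed = c("fe", "ie"),
             moments = c(vv = 0)[0], quadriceps = "none"),
    D = list(geometry_variant = "B", prescribed = c("fe", "ie"),
             moments = c(vv = 0)[0], quadriceps = "ap_surrogate")
  )
  structure(c(list(model_id = model_id, qf_scale = qf_scale,
                   moment_scale = moment_scale), spec),
            class = "driving_mode")
}

#' @export
print.driving_mode <- function(x, ...) {
  cat("<driving_mode ", x$model_id, "> geometry ", x$geometry_variant,
      "; prescribed rotations: ", paste(x$prescribed, collapse = ", "),
      "; applied moments: ",
      if (length(x$moments)) paste(names(x$moments), "x", x$moments,
                                   collapse = ", ") else "none",
      "; quadriceps: ", x$quadriceps,
      if (x$quadriceps == "ap_surrogate") paste0(" (s = ", x$qf_scale, ")"),
      "\n", sep = "")
  invisible(x)
}
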