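# Synthetic stance-phase gait inputs.
#
# Emulates the structure of motion-capture-derived knee loading during the
# stance phase of gait (time-normalized 0-100%): a double-peaked axial
# force, smooth flexion-extension and internal-external rotation curves,
# varus-valgus and internal-external moments, and a quadriceps force with
# its main peak in early stance. All waveforms are sums of Gaussian bumps,
# hence C1-smooth; seeded smooth noise can be superimposed. Forces are in
# body weight (BW), moments in N mm per BW, rotations in degrees.

gauss_bump <- function(t, center, width, amp) {
  amp * exp(-(t - center)^2 / (2 * width^2))
}

softplus_floor <- function(x, floor = 0, sharp = 50) {
  floor + log1p(exp(sharp * (x - floor))) / sharp
}

smooth_noise <- function(t, scale, n_bumps = 6L) {
  if (scale <= 0) return(rep(0, length(t)))
  centers <- stats::runif(n_bumps, 0.05, 0.95)
  widths <- stats::runif(n_bumps, 0.06, 0.18)
  amps <- stats::rnorm(n_bumps, 0, scale)
  out <- rep(0, length(t))
  for (i in seq_len(n_bumps)) out <- out + gauss_bump(t, centers[i], widths[i], amps[i])
  out
}

#' Generate synthetic stance-phase gait input waveforms
#'
#' Returns a tibble on a uniform stance-fraction grid with translational
#' forces (BW), internal-external and varus-valgus moments (N mm/BW),
#' flexion-extension and internal-external rotations (deg) and the
#' quadriceps force magnitude (BW). The distal-proximal force is
#' double-peaked (defaults at 20% and 80% of stance, the first/second peak
#' loads); the quadriceps force peaks in early stance. Deterministic for a
#' fixed seed.
#'
#' @param gait_config Gait section of the run configuration
#'   (see [default_config()]); gives peak magnitudes/timings, noise level,
#'   grid size and body weight.
#' @param seed Integer seed for the smooth noise.
#' @return A tibble of class `gait_series` with columns `stance_fraction`,
#'   `F_ap_BW`, `F_ml_BW`, `F_dp_BW`, `M_ie_Nmm_per_BW`, `M_vv_Nmm_per_BW`,
#'   `theta_fe_deg`, `theta_ie_deg`, `QF_BW` and attribute `body_weight`
#'   (N).
#' @examples
#' gait <- generate_gait(seed = 1)
#' dplyr::slice_max(gait, F_dp_BW, n = 1)
#' @export
generate_gait <- function(gait_config = default_config()$gait, seed = 1L) {
  gcfg <- gait_config
  pk <- c(gcfg$dp_peak1_time, gcfg$dp_peak2_time, gcfg$qf_peak_time)
  if (any(pk <= 0 | pk >= 1)) {
    stop("peak times must lie strictly inside (0, 1)", call. = FALSE)
  }
  t <- seq(0, 1, length.out = gcfg$n_grid)
  nl <- gcfg$noise_level

  with_preserved_seed(seed, {
    F_dp <- gcfg$dp_baseline +
      gauss_bump(t, gcfg$dp_peak1_time, gcfg$dp_width, gcfg$dp_peak1) +
      gauss_bump(t, gcfg$dp_peak2_time, gcfg$dp_width, gcfg$dp_peak2) +
      smooth_noise(t, nl * gcfg$dp_peak1)
    F_dp <- softplus_floor(F_dp, 0.01)

    F_ap <- gauss_bump(t, 0.15, 0.10, gcfg$ap_peak1) +
      gauss_bump(t, 0.75, 0.12, gcfg$ap_peak2) +
      smooth_noise(t, nl * abs(gcfg$ap_peak1))

    F_ml <- gauss_bump(t, 0.25, 0.18, gcfg$ml_peak) +
      gauss_bump(t, 0.75, 0.15, gcfg$ml_peak * 0.8) +
      smooth_noise(t, nl * abs(gcfg$ml_peak))

    M_vv <- gauss_bump(t, 0.22, 0.14, gcfg$vv_moment_peak1) +
      gauss_bump(t, 0.78, 0.13, gcfg$vv_moment_peak2) +
      smooth_noise(t, nl * gcfg$vv_moment_peak1)

    M_ie <- gauss_bump(t, 0.40, 0.20, gcfg$ie_moment_peak) +
      gauss_bump(t, 0.85, 0.10, -0.4 * gcfg$ie_moment_peak) +
      smooth_noise(t, nl * abs(gcfg$ie_moment_peak))

    theta_fe <- gcfg$fe_baseline +
      gauss_bump(t, 0.15, 0.10, gcfg$fe_early_peak) +
      gauss_bump(t, 1.00, 0.16, gcfg$fe_toeoff) +
      smooth_noise(t, nl * gcfg$fe_early_peak)

    theta_ie <- gcfg$ie_baseline +
      gauss_bump(t, 0.20, 0.15, gcfg$ie_early_peak) +
      gauss_bump(t, 0.90, 0.12, gcfg$ie_late_peak) +
      smooth_noise(t, nl * abs(gcfg$ie_early_peak))

    QF <- gcfg$qf_baseline +
      gauss_bump(t, gcfg$qf_peak_time, 0.10, gcfg$qf_peak) +
      gauss_bump(t, 0.78, 0.14, gcfg$qf_late_peak) +
      smooth_noise(t, nl * gcfg$qf_peak)
    QF <- softplus_floor(QF, 0.01)

    out <- tibble::tibble(
      stance_fraction = t,
      F_ap_BW = F_ap, F_ml_BW = F_ml, F_dp_BW = F_dp,
      M_ie_Nmm_per_BW = M_ie, M_vv_Nmm_per_BW = M_vv,
      theta_fe_deg = theta_fe, theta_ie_deg = theta_ie,
      QF_BW = QF
    )
    attr(out, "body_weight") <- gcfg$body_weight
    class(out) <- c("gait_series", class(out))
    out
  })
}

gait_columns <- c("stance_fraction", "F_ap_BW", "F_ml_BW", "F_dp_BW",
                  "M_ie_Nmm_per_BW", "M_vv_Nmm_per_BW",
                  "theta_fe_deg", "theta_ie_deg", "QF_BW")

#' Interpolate a gait series onto arbitrary stance fractions
#'
#' Linear interpolation of every waveform.
#'
#' @param gait A `gait_series` tibble.
#' @param t Stance fractions in `[0, 1]`.
#' @return A tibble with the same columns at the requested fractions.
#' @export
interpolate_gait <- function(gait, t) {
  out <- tibble::tibble(stance_fraction = t)
  for (cn in setdiff(gait_columns, "stance_fraction")) {
    out[[cn]] <- stats::approx(gait$stance_fraction, gait[[cn]], xout = t,
                               rule = 2)$y
  }
  attr(out, "body_weight") <- attr(gait, "body_weight")
  class(out) <- c("gait_series", class(out))
  out
}

#' Decompose the quadriceps force into anterior-posterior and
#' distal-proximal components
#'
#' Projects the quadriceps force magnitude along its line of action -- the
#' direction from the patellar reference toward the quadriceps reference
#' point posed at the current flexion angle -- onto the tibial
#' anterior-posterior and distal-proximal axes. The medial-lateral remainder
#' is discarded, so `QF_ap^2 + QF_dp^2 <= QF^2`.
#'
#' @param QF Quadriceps force magnitude (BW); vectorized.
#' @param theta_fe Flexion angle (deg); vectorized with `QF`.
#' @param geometry A `knee_geometry` with a patella block, or a
#'   `knee_geometry_set` (variant A is used).
#' @return Tibble with columns `QF_ap` and `QF_dp` (BW; anterior positive,
#'   proximal positive).
#' @export
decompose_quadriceps <- function(QF, theta_fe, geometry) {
  if (inherits(geometry, "knee_geometry_set")) geometry <- geometry$A
  pat <- geometry$patella
  if (is.null(pat)) stop("geometry has no patellar mechanism", call. = FALSE)
  stopifnot(all(QF >= 0), length(QF) == length(theta_fe))
  n <- length(QF)
  ap <- dp <- numeric(n)
  for (i in seq_len(n)) {
    q <- c(0, 0, 0, deg2rad(theta_fe[i]), 0, 0)
    rpq <- as.numeric(pose_points(matrix(pat$rp_quad, 1), q, geometry$rp_femur))
    u <- rpq - pat$ref
    L <- sqrt(sum(u^2))
    if (L < 1e-9) stop("zero-length quadriceps line of action", call. = FALSE)
    u <- u / L
    ap[i] <- QF[i] * u[1]
    dp[i] <- QF[i] * u[2]
  }
  tibble::tibble(QF_ap = ap, QF_dp = dp)
}
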