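# Independent closed-form and brute-force reference solutions used by the
# test fixtures. These deliberately share no code with the solver or the
# column discretization: the consolidation solution is the classical series,
# the uniaxial-strain stress comes straight from the compliance matrix, and
# the one-DOF equilibrium is a bracketed root search on the force balance.

#' Terzaghi consolidation series solution
#'
#' Excess pore pressure in a layer of thickness `H` drained at `z = 0` and
#' impermeable at `z = H`, after a step load `p0` at `t = 0`:
#' `p(z,t) = (4 p0/pi) sum 1/(2j+1) sin((2j+1) pi z / (2H))
#'  exp(-(2j+1)^2 pi^2 c_v t / (4 H^2))`.
#'
#' @param z Distance from the drained boundary (mm); vectorized.
#' @param t Time since load application (s); scalar.
#' @param p0 Step load / initial excess pressure (MPa).
#' @param c_v Consolidation coefficient (mm^2/s), `M_t * k`.
#' @param H Drainage path length (mm).
#' @param n_terms Number of series terms.
#' @return Pore pressure at `z` (MPa).
#' @export
terzaghi_pressure <- function(z, t, p0, c_v, H, n_terms = 200L) {
  stopifnot(t >= 0, H > 0, c_v > 0)
  if (t == 0) return(rep(p0, length(z)))
  j <- seq_len(n_terms) - 1L
  odd <- 2 * j + 1
  out <- numeric(length(z))
  for (i in seq_along(z)) {
    out[i] <- sum(4 * p0 / (pi * odd) * sin(odd * pi * z[i] / (2 * H)) *
                    exp(-odd^2 * pi^2 * c_v * t / (4 * H^2)))
  }
  out
}

#' Average degree of consolidation (series solution)
#'
#' Fraction of the step-load settlement completed at time `t`.
#'
#' @inheritParams terzaghi_pressure
#' @return Scalar in `[0, 1]`.
#' @export
terzaghi_consolidation_degree <- function(t, c_v, H, n_terms = 200L) {
  j <- seq_len(n_terms) - 1L
  odd <- 2 * j + 1
  1 - sum(8 / (pi^2 * odd^2) * exp(-odd^2 * pi^2 * c_v * t / (4 * H^2)))
}

#' Closed-form uniaxial-strain stress state
#'
#' Total stress tensor (tension positive, Voigt diagonal) of a transversely
#' isotropic column held at zero lateral strain with axial strain `eps` and
#' uniform pore pressure `p`, computed directly from the inverted compliance.
#'
#' @param mat A transversely isotropic material.
#' @param eps Axial (out-of-plane) engineering strain; negative in
#'   compression.
#' @param p Pore pressure (MPa), compression-carrying.
#' @return Named list: `sigma` (length-3 principal total stresses, in-plane,
#'   in-plane, axial), `max_principal` (MPa).
#' @export
uniaxial_strain_stress <- function(mat, eps, p = 0) {
  E_p <- mat$E_p; E_t <- mat$E_t
  nu_p <- mat$nu_p; nu_tp <- mat$nu_tp
  S <- matrix(c(1 / E_p, -nu_p / E_p, -nu_tp / E_t,
                -nu_p / E_p, 1 / E_p, -nu_tp / E_t,
                -nu_tp / E_t, -nu_tp / E_t, 1 / E_t), 3, 3)
  C <- solve(S)
  sig_eff <- C %*% c(0, 0, eps)
  sigma <- as.numeric(sig_eff) - p
  list(sigma = sigma, max_principal = max(eigen(diag(sigma),
                                                symmetric = TRUE,
                                                only.values = TRUE)$values))
}

#' Brute-force equilibrium of a one-DOF spring system
#'
#' Finds the displacement at which a tension-only spring balances an applied
#' force by bisection on the force residual, independent of the Newton
#' solver.
#'
#' @param k Spring stiffness (N/mm).
#' @param slack_length Slack length (mm).
#' @param anchor_distance Distance between anchors at zero displacement (mm);
#'   displacement stretches the spring further.
#' @param force Applied force along the spring axis (N), stretching positive.
#' @param bracket Search interval for the displacement (mm).
#' @return Displacement (mm) at equilibrium.
#' @export
brute_force_spring_equilibrium <- function(k, slack_length, anchor_distance,
                                           force,
                                           bracket = c(-100, 100)) {
  resid <- function(u) {
    len <- anchor_distance + u
    tension <- k * max(0, len - slack_length)
    force - tension
  }
  stats::uniroot(resid, interval = bracket, tol = 1e-12)$root
}
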