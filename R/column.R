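# One-dimensional poroelastic consolidation columns.
#
# Each contact column is a through-thickness discretization of cartilage in
# uniaxial (confined) strain: axial kinematics are prescribed by the contact
# overlap, lateral strain is zero, the articular surface is drained (zero
# pore pressure) and the cartilage-bone interface is impermeable. Quasi-
# static equilibrium makes the total axial stress uniform through the depth,
# which reduces Biot consolidation to a single pressure diffusion problem
# coupled to the overlap through an integral constraint:
#
#   eps(y,t) = (sigma_tot(t) + p(y,t)) / M_t          (effective stress law)
#   d eps/dt = k d^2 p / dy^2                          (Darcy + continuity)
#   integral eps dy = -overlap                         (prescribed kinematics)
#
# with M_t the out-of-plane confined modulus (C33 of the drained stiffness)
# and k the permeability in mm^2/(MPa s). Backward-Euler time stepping gives,
# for a fixed state, a surface traction that is affine in the new overlap:
# T(w) = alpha + beta * w. The contact solver exploits this: alpha/beta are
# extracted once per time step and the Newton iteration sees a piecewise
# affine (complementarity-clipped) foundation law.

# Assemble the backward-Euler system matrix for one column.
# Unknowns: (p_1 .. p_{m-1}, sigma_tot); p at m equally spaced nodes from the
# bone interface (node 1, impermeable) to the articular surface (node m,
# drained, p_m = 0 eliminated).
column_system_matrix <- function(h0, n_layers, M_t, k_mm, dt) {
  m <- n_layers + 1L
  dy <- h0 / n_layers
  A <- matrix(0, m, m)
  cdt <- 1 / (M_t * dt)
  kd2 <- k_mm / dy^2
  for (j in seq_len(m - 1L)) {
    A[j, j] <- A[j, j] + cdt
    A[j, m] <- A[j, m] + cdt     # sigma column
    if (j == 1L) {
      A[1, 1] <- A[1, 1] + 2 * kd2
      if (m > 2L) A[1, 2] <- A[1, 2] - 2 * kd2
    } else {
      A[j, j - 1L] <- A[j, j - 1L] - kd2
      A[j, j] <- A[j, j] + 2 * kd2
      if (j + 1L <= m - 1L) A[j, j + 1L] <- A[j, j + 1L] - kd2
      # neighbour at node m is the drained boundary, p_m = 0
    }
  }
  # kinematic constraint row: trapezoid integral of p plus sigma * h = -M w
  A[m, 1] <- dy / 2
  if (m > 2L) A[m, 2:(m - 1L)] <- dy
  A[m, m] <- h0
  A
}

#' Initialize the state of a poroelastic contact column
#'
#' @param thickness0 Undeformed cartilage thickness (mm).
#' @param depth_layers Number of through-thickness sub-layers (default 3,
#'   mirroring three depth-wise cartilage element layers; refine for
#'   convergence studies).
#' @return An object of class `column_state` with zero pore pressure, zero
#'   stress and zero overlap.
#' @export
new_column_state <- function(thickness0, depth_layers = 3L) {
  stopifnot(thickness0 > 0, depth_layers >= 1L)
  structure(
    list(thickness0 = thickness0, depth_layers = as.integer(depth_layers),
         pore_pressure = rep(0, depth_layers),      # nodes 1..m-1
         sigma = 0, overlap = 0, time = 0),
    class = "column_state"
  )
}

#' Advance one column by one implicit consolidation time step
#'
#' Solves one backward-Euler step of the confined-compression consolidation
#' problem with the new overlap prescribed, and returns the updated state
#' together with the compressive surface traction (axial effective stress
#' plus pore pressure).
#'
#' @param state A [new_column_state()] object.
#' @param mat A [material_tipe()] cartilage material.
#' @param new_overlap Prescribed surface compression at the end of the step
#'   (mm), >= 0.
#' @param dt Step duration (s), > 0.
#' @return List with `state` (updated `column_state`) and `traction`
#'   (compressive surface traction, MPa).
#' @examples
#' cart <- material_tipe(24, 0.46, 0.42, 0.06, 12, 1, 4)
#' st <- new_column_state(3, depth_layers = 8)
#' out <- column_consolidation_step(st, cart, new_overlap = 0.1, dt = 0.01)
#' out$traction
#' @export
column_consolidation_step <- function(state, mat, new_overlap, dt) {
  stopifnot(inherits(state, "column_state"))
  if (!is.finite(new_overlap) || new_overlap < 0) {
    stop("new_overlap must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  M_t <- confined_moduli(mat)$M_t
  n <- state$depth_layers
  m <- n + 1L
  A <- column_system_matrix(state$thickness0, n, M_t, mat$k_mm, dt)
  b <- c((state$pore_pressure + state$sigma) / (M_t * dt),
         -M_t * new_overlap)
  u <- tryCatch(solve(A, b), error = function(e) {
    stop("implicit consolidation step failed to solve (", conditionMessage(e),
         "); reduce dt or increase depth_layers", call. = FALSE)
  })
  state$pore_pressure <- u[seq_len(m - 1L)]
  state$sigma <- u[m]
  state$overlap <- new_overlap
  state$time <- state$time + dt
  list(state = state, traction = -state$sigma)
}

#' Depth-averaged pore pressure of a column state
#'
#' Trapezoidal average over the through-thickness nodes (the drained surface
#' node is zero by construction).
#'
#' @param state A `column_state`.
#' @return Scalar average pore pressure (MPa).
#' @export
column_mean_pressure <- function(state) {
  p <- c(state$pore_pressure, 0)
  m <- length(p)
  wts <- c(0.5, rep(1, m - 2L), 0.5)
  sum(p * wts) / (m - 1L)
}

# ---------------------------------------------------------------------------
# Vectorized column bank used by the joint solver.
#
# All columns share the material, layer count and time step, but have
# individual thicknesses (hence individual system matrices). The inverse of
# each small system matrix is precomputed once per simulation; per time step
# the affine coefficients T(w) = alpha + beta * w are read off, and the
# commit is a batched matrix-vector product.

column_bank <- function(h0, mat, n_layers, dt, k_series = NULL) {
  N <- length(h0)
  m <- n_layers + 1L
  M_t <- confined_moduli(mat)$M_t
  Ainv <- array(0, dim = c(m, m, N))
  for (i in seq_len(N)) {
    Ainv[, , i] <- solve(column_system_matrix(h0[i], n_layers, M_t, mat$k_mm, dt))
  }
  beta <- M_t * Ainv[m, m, ]           # undrained-per-step foundation stiffness
  if (is.null(k_series)) k_series <- rep(Inf, N)
  gamma <- 1 / (1 + beta / k_series)   # series compliance of meniscus spacer
  list(
    N = N, m = m, h0 = h0, dt = dt, M_t = M_t, C13 = confined_moduli(mat)$C13,
    Ainv = Ainv, beta = beta, k_series = k_series, gamma = gamma,
    # last-row blocks used for the per-step affine offset
    arow = matrix(Ainv[m, seq_len(m - 1L), ], nrow = m - 1L, ncol = N),
    p = matrix(0, m - 1L, N), sigma = rep(0, N), w_cart = rep(0, N),
    time = 0
  )
}

# Affine traction offsets for the current bank state: cartilage-side
# traction is alpha + beta * w_cart for the step about to be taken.
bank_alpha <- function(bank) {
  cdt <- 1 / (bank$M_t * bank$dt)
  -colSums(bank$arow * (bank$p + rep(bank$sigma, each = bank$m - 1L))) * cdt
}

# Effective traction of the cartilage+spacer stack at total overlap w
# (vector), given precomputed alpha. Complementarity-clipped at zero.
bank_traction <- function(bank, alpha, w) {
  pmax(0, bank$gamma * (alpha + bank$beta * w))
}

# Residual gap for the complementarity check: zero when in contact,
# clearance to the free-swelling surface otherwise.
bank_gap <- function(bank, alpha, w) {
  w0 <- -alpha / bank$beta
  pmax(0, w0 - w)
}

# Commit one consolidation step at total overlaps w (vector). Columns out of
# contact relax at zero traction (free swelling).
bank_commit <- function(bank, alpha, w) {
  traction <- bank_traction(bank, alpha, w)
  w0 <- -alpha / bank$beta
  w_cart <- ifelse(bank$gamma * (alpha + bank$beta * w) > 0,
                   w - traction / bank$k_series, w0)
  m <- bank$m
  cdt <- 1 / (bank$M_t * bank$dt)
  b <- rbind((bank$p + rep(bank$sigma, each = m - 1L)) * cdt,
             -bank$M_t * w_cart)
  u <- matrix(0, m, bank$N)
  for (j in seq_len(m)) {
    acc <- 0
    for (kk in seq_len(m)) acc <- acc + bank$Ainv[j, kk, ] * b[kk, ]
    u[j, ] <- acc
  }
  bank$p <- u[seq_len(m - 1L), , drop = FALSE]
  bank$sigma <- u[m, ]
  bank$w_cart <- w_cart
  bank$time <- bank$time + bank$dt
  bank
}

# Depth-averaged pore pressures for all columns (trapezoid; surface node 0).
bank_mean_pressure <- function(bank) {
  m <- bank$m
  if (m == 2L) return(bank$p[1, ] * 0.5 / (m - 1L))
  wts <- c(0.5, rep(1, m - 2L))
  colSums(bank$p * wts) / (m - 1L)
}
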