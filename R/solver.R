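# Quasi-static 6-DOF femur equilibrium against the poroelastic contact
# columns, prestrained ligament springs, meniscal spacers and (geometry A)
# the point-patella extensor mechanism, run as a three-step protocol:
# (1) bring the surfaces into first contact, (2) rotate to the initial
# orientation and apply the initial loads, (3) march the stance-phase
# inputs with consolidation time stepping.

#' Assemble a solvable joint system
#'
#' Combines one geometry variant with the material configuration into the
#' internal system object used by [solve_equilibrium()] and
#' [simulate_stance()]: consolidation column bank, ligament springs with
#' slack lengths frozen at the reference (imaging) pose, meniscal series
#' stiffnesses (wedge compression in series with the lumped horn/hoop
#' restraint), and the patellar mechanism when present.
#'
#' @param geometry A `knee_geometry` (one variant; pass `$A` or `$B` of a
#'   [build_geometry()] result).
#' @param config Run configuration (see [default_config()]).
#' @param dt Consolidation time-step duration (s); defaults to
#'   `stance_duration / n_steps`.
#' @return An object of class `knee_system`.
#' @export
assemble_system <- function(geometry, config = default_config(), dt = NULL) {
  stopifnot(inherits(geometry, "knee_geometry"))
  mcfg <- config$materials
  scfg <- config$solver
  if (is.null(dt)) dt <- scfg$stance_duration / scfg$n_steps
  cart <- material_tipe(mcfg$cartilage$E_p, mcfg$cartilage$E_t,
                        mcfg$cartilage$nu_p, mcfg$cartilage$nu_tp,
                        mcfg$cartilage$G_t, mcfg$cartilage$permeability_k,
                        mcfg$cartilage$e0)
  men <- material_tie(mcfg$meniscus$E_p, mcfg$meniscus$E_t,
                      mcfg$meniscus$nu_p, mcfg$meniscus$nu_tp,
                      mcfg$meniscus$G_t)

  cols <- geometry$columns
  # meniscal load path: wedge confined compression in series with the
  # horn/hoop restraint (two horns of k_horn per meniscus, distributed over
  # the ring area of that compartment)
  k_series <- rep(Inf, nrow(cols))
  C33_men <- confined_moduli(men)$M_t
  for (side in c("medial", "lateral")) {
    idx <- which(cols$tissue == "meniscus" & cols$compartment == side)
    if (!length(idx)) next
    ring_area <- sum(cols$area[idx])
    k_horn_area <- 2 * mcfg$horn$stiffness_k / ring_area   # MPa/mm
    k_wedge <- C33_men / config$geometry$meniscus$body_height
    k_series[idx] <- 1 / (1 / k_wedge + 1 / k_horn_area)
  }
  bank <- column_bank(cols$h0, cart, scfg$depth_layers, dt, k_series)

  ligaments <- lapply(names(geometry$insertions), function(nm) {
    pts <- geometry$insertions[[nm]]
    L_ref <- sqrt(sum((pts$tibia - pts$femur)^2))
    list(lig = spring_ligament(nm, mcfg[[nm]]$stiffness_k,
                               mcfg[[nm]]$prestrain, L_ref,
                               endpoints = c(paste0(nm, "_femur"),
                                             paste0(nm, "_tibia"))),
         femur = pts$femur, tibia = pts$tibia)
  })
  names(ligaments) <- names(geometry$insertions)

  patella <- NULL
  if (!is.null(geometry$patella)) {
    gp <- geometry$patella
    pt_ref <- sqrt(sum((gp$ref - gp$tuberosity)^2))
    patella <- list(
      ref = gp$ref, rp_quad = gp$rp_quad, tuberosity = gp$tuberosity,
      trochlea_center = gp$trochlea_center,
      trochlea_radius = gp$trochlea_radius,
      k_pf = gp$contact_stiffness,
      k_reg = gp$regularization_stiffness,
      pt = spring_ligament("PT", mcfg$PT$stiffness_k, mcfg$PT$prestrain,
                           pt_ref),
      qt = list(stiffness_k = mcfg$QT$stiffness_k,
                prestrain = mcfg$QT$prestrain),  # recorded; see vignette
      trusses = list(
        MPFL = list(lig = truss_ligament("MPFL", mcfg$MPFL$E,
                                         mcfg$MPFL$cross_section_area,
                                         sqrt(sum((gp$ref - gp$mpfl_femur)^2)),
                                         nu = mcfg$MPFL$nu),
                    femur = gp$mpfl_femur),
        LPFL = list(lig = truss_ligament("LPFL", mcfg$LPFL$E,
                                         mcfg$LPFL$cross_section_area,
                                         sqrt(sum((gp$ref - gp$lpfl_femur)^2)),
                                         nu = mcfg$LPFL$nu),
                    femur = gp$lpfl_femur)
      )
    )
  }

  structure(
    list(columns = cols, bank = bank, condyles = geometry$condyles,
         rp = geometry$rp_femur, ligaments = ligaments, patella = patella,
         quad = list(rp_quad = config$geometry$patella$rp_quad,
                     ref = config$geometry$patella$ref),
         body_weight = config$gait$body_weight, dt = dt,
         variant = geometry$variant,
         tol_force = scfg$tol_force_bw, tol_moment = scfg$tol_moment_bwmm,
         max_iter = scfg$max_iter),
    class = "knee_system"
  )
}

#' Minimal joint system constructor (for reduced test problems)
#'
#' Builds a bare `knee_system` from explicit parts; any part may be omitted.
#' Used to exercise the equilibrium solver on systems as small as a single
#' spring with one free translation.
#'
#' @param ligaments List of `list(lig = spring_ligament(...), femur =, tibia =)`.
#' @param columns,bank,condyles Optional contact field parts.
#' @param rp Femoral reference point.
#' @param body_weight Body weight (N) used for residual scaling.
#' @param ... Further fields (tolerances etc.).
#' @return A `knee_system`.
#' @export
knee_system <- function(ligaments = list(), columns = NULL, bank = NULL,
                        condyles = NULL, rp = c(0, 0, 0), body_weight = 700,
                        ...) {
  extra <- list(...)
  base <- list(columns = columns, bank = bank, condyles = condyles, rp = rp,
               ligaments = ligaments, patella = NULL,
               body_weight = body_weight, dt = 0.01, variant = "B",
               tol_force = 1e-10, tol_moment = 1e-10, max_iter = 80L)
  base[names(extra)] <- extra
  structure(base, class = "knee_system")
}

# ---------------------------------------------------------------------------
# residual assembly

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# vertical overlaps of all columns under pose q (positive = penetration of
# the undeformed surfaces)
column_overlaps <- function(sys, q) {
  if (is.null(sys$columns)) return(numeric(0))
  cols <- sys$columns
  ov <- rep(-1e6, nrow(cols))
  R <- cardan_matrix(q[4], q[5], q[6])
  for (cd in sys$condyles) {
    ctr <- as.numeric(pose_points(matrix(cd$center, 1), q, sys$rp))
    Q <- R %*% diag(1 / cd$semi^2) %*% t(R)
    dx <- cols$x - ctr[1]
    dz <- cols$z - ctr[3]
    a <- Q[2, 2]
    b <- 2 * (Q[1, 2] * dx + Q[2, 3] * dz)
    cc <- Q[1, 1] * dx^2 + Q[3, 3] * dz^2 + 2 * Q[1, 3] * dx * dz - 1
    disc <- b^2 - 4 * a * cc
    hit <- disc > 0
    if (any(hit)) {
      y_low <- ctr[2] + (-b[hit] - sqrt(disc[hit])) / (2 * a)
      ov[hit] <- pmax(ov[hit], cols$y_top[hit] - y_low)
    }
  }
  ov
}

# patellar point equilibrium; returns position, element forces and the
# femur-side reactions. QF_vec in N (tibia frame).
solve_patella <- function(sys, q, QF_vec, warm = NULL) {
  pat <- sys$patella
  rpq <- as.numeric(pose_points(matrix(pat$rp_quad, 1), q, sys$rp))
  ref_posed <- as.numeric(pose_points(matrix(pat$ref, 1), q, sys$rp))
  ctr <- as.numeric(pose_points(matrix(pat$trochlea_center, 1), q, sys$rp))
  tf <- lapply(pat$trusses, function(tr)
    as.numeric(pose_points(matrix(tr$femur, 1), q, sys$rp)))

  resid <- function(p) {
    r <- QF_vec
    # patellar tendon to the fixed tibial tuberosity
    d <- pat$tuberosity - p
    L <- sqrt(sum(d^2))
    r <- r + spring_force(pat$pt, L) * d / L
    # trochlear contact patch
    dc <- p - ctr
    dist <- sqrt(sum(dc^2))
    o <- pat$trochlea_radius - dist
    if (o > 0) r <- r + pat$k_pf * o * dc / dist
    # patellofemoral ligament trusses
    for (i in seq_along(pat$trusses)) {
      dtr <- tf[[i]] - p
      Lt <- sqrt(sum(dtr^2))
      r <- r + truss_force(pat$trusses[[i]]$lig, Lt) * dtr / Lt
    }
    # weak centering spring (removes the all-slack singularity)
    r + pat$k_reg * (ref_posed - p)
  }

  # every patellar force derives from a potential (tension-only springs,
  # penalty contact, constant muscle pull), so globalize by energy descent
  # before the Newton polish; gradient of `energy` is -resid
  energy <- function(p) {
    d <- pat$tuberosity - p
    L <- sqrt(sum(d^2))
    e <- -sum(QF_vec * p) +
      0.5 * pat$pt$stiffness_k * max(0, L - pat$pt$slack_length)^2
    dc <- p - ctr
    o <- pat$trochlea_radius - sqrt(sum(dc^2))
    if (o > 0) e <- e + 0.5 * pat$k_pf * o^2
    for (i in seq_along(pat$trusses)) {
      lg <- pat$trusses[[i]]$lig
      Lt <- sqrt(sum((tf[[i]] - p)^2))
      e <- e + 0.5 * lg$E * lg$cross_section_area / lg$reference_length *
        max(0, Lt - lg$reference_length)^2
    }
    e + 0.5 * pat$k_reg * sum((ref_posed - p)^2)
  }

  newton_polish <- function(p, tol = 1e-9, max_it = 40L) {
    r <- resid(p)
    it <- 0L
    while (max(abs(r)) > tol && it < max_it) {
      J <- matrix(0, 3, 3)
      h <- 1e-6
      for (j in 1:3) {
        pp <- p
        pp[j] <- pp[j] + h
        J[, j] <- (resid(pp) - r) / h
      }
      dp <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(dp)) break
      lam <- 1
      repeat {
        pn <- p + lam * dp
        rn <- resid(pn)
        if (sum(rn^2) < sum(r^2) || lam < 1e-4) break
        lam <- lam / 2
      }
      if (sum(rn^2) >= sum(r^2)) break  # stalled on a force-law kink
      p <- pn
      r <- rn
      it <- it + 1L
    }
    list(p = p, r = r, it = it)
  }

  p <- if (!is.null(warm)) warm else ref_posed
  np <- newton_polish(p)
  if (max(abs(np$r)) > 1e-8) {
    opt <- stats::optim(np$p, energy, gr = function(p) -resid(p),
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    np <- newton_polish(opt$par)
  }
  p <- np$p
  r <- np$r
  it <- np$it
  if (max(abs(r)) > 1e-6) {
    stop("patellar equilibrium did not converge (residual ",
         signif(max(abs(r)), 3), " N)", call. = FALSE)
  }

  # femur-side reactions
  fF <- numeric(3)
  fM <- numeric(3)
  rp_cur <- sys$rp + q[1:3]
  dc <- p - ctr
  dist <- sqrt(sum(dc^2))
  o <- pat$trochlea_radius - dist
  troch_force <- 0
  if (o > 0) {
    Fc_pat <- pat$k_pf * o * dc / dist          # on the patella
    cp <- ctr + dc / dist * pat$trochlea_radius # contact point on the trochlea
    fF <- fF - Fc_pat
    fM <- fM + cross3(cp - rp_cur, -Fc_pat)
    troch_force <- pat$k_pf * o
  }
  for (i in seq_along(pat$trusses)) {
    dtr <- tf[[i]] - p
    Lt <- sqrt(sum(dtr^2))
    Tt <- truss_force(pat$trusses[[i]]$lig, Lt)
    Ff <- Tt * (p - tf[[i]]) / Lt                # pulls the femur point
    fF <- fF + Ff
    fM <- fM + cross3(tf[[i]] - rp_cur, Ff)
  }
  Freg <- -pat$k_reg * (ref_posed - p)           # reaction on the femur
  fF <- fF + Freg
  fM <- fM + cross3(ref_posed - rp_cur, Freg)

  d <- pat$tuberosity - p
  list(pos = p, residual = max(abs(r)), iterations = it,
       femur_force = fF, femur_moment = fM,
       pt_tension = spring_force(pat$pt, sqrt(sum(d^2))),
       trochlea_force = troch_force)
}

# full residual at pose q. loads: list(F = N (3), M = N*mm (3),
# QF_vec = N (3) or NULL). alpha: per-column affine offsets for this step.
femur_residual <- function(sys, q, loads, alpha, pat_env = NULL) {
  rp_cur <- sys$rp + q[1:3]
  F <- loads$F
  M <- loads$M

  Tvec <- numeric(0)
  w_n <- numeric(0)
  if (!is.null(sys$columns)) {
    cols <- sys$columns
    ov <- column_overlaps(sys, q)
    w_n <- ov * cols$ny
    Tvec <- bank_traction(sys$bank, alpha, w_n)
    TA <- Tvec * cols$area
    Fc <- c(sum(TA * cols$nx), sum(TA * cols$ny), sum(TA * cols$nz))
    rx <- cols$x - rp_cur[1]
    ry <- cols$y_top - rp_cur[2]
    rz <- cols$z - rp_cur[3]
    Mc <- c(sum(ry * TA * cols$nz - rz * TA * cols$ny),
            sum(rz * TA * cols$nx - rx * TA * cols$nz),
            sum(rx * TA * cols$ny - ry * TA * cols$nx))
    F <- F + Fc
    M <- M + Mc
  }

  for (lg in sys$ligaments) {
    pf <- as.numeric(pose_points(matrix(lg$femur, 1), q, sys$rp))
    d <- lg$tibia - pf
    L <- sqrt(sum(d^2))
    Tl <- spring_force(lg$lig, L)
    if (Tl > 0) {
      Fl <- Tl * d / L
      F <- F + Fl
      M <- M + cross3(pf - rp_cur, Fl)
    }
  }

  pat_sol <- NULL
  if (!is.null(sys$patella)) {
    warm <- if (!is.null(pat_env)) pat_env$pos else NULL
    QF_vec <- if (is.null(loads$QF_vec)) c(0, 0, 0) else loads$QF_vec
    pat_sol <- solve_patella(sys, q, QF_vec, warm = warm)
    if (!is.null(pat_env)) pat_env$pos <- pat_sol$pos
    F <- F + pat_sol$femur_force
    M <- M + pat_sol$femur_moment
  }

  list(res = c(F, M), traction = Tvec, w_n = w_n, patella = pat_sol)
}

# map free DOF names/indices to residual components:
# tx,ty,tz -> force x,y,z; vv -> moment x; ie -> moment y; fe -> moment z
dof_residual_index <- c(tx = 1, ty = 2, tz = 3, fe = 6, vv = 4, ie = 5)

#' Solve quasi-static equilibrium of the femur for the free DOFs
#'
#' Damped Newton iteration on the residual (applied loads + contact column
#' tractions + ligament and patellar forces, reduced to the femoral
#' reference point) over the free degrees of freedom, with a
#' finite-difference Jacobian. Contact is frictionless (tractions along the
#' column normals) and compressive-only.
#'
#' @param sys A `knee_system` ([assemble_system()] or [knee_system()]).
#' @param q0 Starting pose `(tx, ty, tz, fe, vv, ie)`; prescribed entries are
#'   held at their values in `q0`.
#' @param loads List with `F` (applied force, N), `M` (applied moment about
#'   the femoral reference point, N mm) and optionally `QF_vec` (quadriceps
#'   force on the patella, N).
#' @param free Character vector of free DOF names among
#'   `c("tx","ty","tz","fe","vv","ie")`.
#' @param alpha Per-column affine traction offsets for the current
#'   consolidation step (default: computed from the bank state).
#' @param pat_env Optional environment carrying the patellar warm start.
#' @return List with the solved pose `q`, `converged`, residual norms,
#'   iteration count, and the final full evaluation (`traction`, `w_n`,
#'   `patella`).
#' @export
solve_equilibrium <- function(sys, q0, loads,
                              free = c("tx", "ty", "tz", "vv"),
                              alpha = NULL, pat_env = NULL) {
  if (is.null(alpha) && !is.null(sys$bank)) alpha <- bank_alpha(sys$bank)
  if (is.null(pat_env)) pat_env <- new.env()
  bw <- sys$body_weight
  fi <- match(free, pose_names)
  if (anyNA(fi)) stop("unknown DOF name in `free`", call. = FALSE)
  ri <- dof_residual_index[free]
  is_rot <- fi >= 4
  tol <- ifelse(is_rot, sys$tol_moment, sys$tol_force) * bw
  fd_h <- ifelse(is_rot, 1e-7, 1e-6)

  q <- q0
  ev <- femur_residual(sys, q, loads, alpha, pat_env)
  r <- ev$res[ri]
  it <- 0L
  while (any(abs(r) > tol) && it < sys$max_iter) {
    J <- matrix(0, length(ri), length(fi))
    for (j in seq_along(fi)) {
      qp <- q
      qp[fi[j]] <- qp[fi[j]] + fd_h[j]
      rp <- femur_residual(sys, qp, loads, alpha, pat_env)$res[ri]
      J[, j] <- (rp - r) / fd_h[j]
    }
    dq <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dq)) {
      cn <- sqrt(colSums(J^2))
      stop("singular equilibrium Jacobian; unconstrained DOF: ",
           free[which.min(cn)], call. = FALSE)
    }
    lam <- 1
    repeat {
      qn <- q
      qn[fi] <- qn[fi] + lam * dq
      evn <- femur_residual(sys, qn, loads, alpha, pat_env)
      rn <- evn$res[ri]
      if (sum((rn / tol)^2) < sum((r / tol)^2) || lam < 1e-6) break
      lam <- lam / 2
    }
    q <- qn
    ev <- evn
    r <- rn
    it <- it + 1L
  }
  converged <- all(abs(r) <= tol)
  if (!converged) {
    stop("equilibrium Newton iteration did not converge after ", it,
         " iterations; residual trace (scaled): ",
         paste(signif(r / tol, 3), collapse = ", "), call. = FALSE)
  }
  fres <- if (any(!is_rot)) max(abs(r[!is_rot])) / bw else 0
  mres <- if (any(is_rot)) max(abs(r[is_rot])) / bw else 0
  list(q = q, converged = converged, iterations = it,
       force_residual_bw = fres, moment_residual_bwmm = mres,
       residual = ev$res, traction = ev$traction, w_n = ev$w_n,
       patella = ev$patella)
}

# ---------------------------------------------------------------------------
# three-step loading protocol

#' Bring the femur into first contact with the tibial surfaces
#'
#' Translates the femur distally (along -y) from the reference pose until
#' the first contact column touches, so the net contact reaction is zero
#' (below the settle tolerance by construction).
#'
#' @param geometry A `knee_geometry`.
#' @param config Run configuration.
#' @return A list of class `knee_state` with the pose `q`, the stance time
#'   (`t = 0`) and the settle translation.
#' @export
settle_contact <- function(geometry, config = default_config()) {
  g0 <- geometry_gaps(geometry, rep(0, 6))
  gmin <- min(g0)
  if (!is.finite(gmin)) {
    stop("no contact achievable: every column lies outside the condyle ",
         "footprints", call. = FALSE)
  }
  q <- c(0, -max(gmin, 0), 0, 0, 0, 0)
  structure(list(q = q, t = 0, settle_translation = q[2]),
            class = "knee_state")
}

# loads (N, N mm, tibia frame) for one interpolated gait row under a mode
assemble_loads <- function(sys, mode, row) {
  bw <- sys$body_weight
  F_ap <- row$F_ap_BW
  if (identical(mode$quadriceps, "ap_surrogate")) {
    qd <- decompose_quadriceps_sys(sys, row$QF_BW, row$theta_fe_deg)
    F_ap <- F_ap + mode$qf_scale * qd$QF_ap
  }
  F <- bw * c(F_ap, -row$F_dp_BW, row$F_ml_BW)
  M <- c(0, 0, 0)
  if ("vv" %in% names(mode$moments)) {
    M[1] <- M[1] + bw * mode$moments[["vv"]] * row$M_vv_Nmm_per_BW
  }
  if ("ie" %in% names(mode$moments)) {
    M[2] <- M[2] + bw * mode$moments[["ie"]] * row$M_ie_Nmm_per_BW
  }
  QF_vec <- NULL
  if (identical(mode$quadriceps, "patella_mechanism")) {
    qd <- decompose_quadriceps_sys(sys, row$QF_BW, row$theta_fe_deg)
    QF_vec <- bw * c(qd$QF_ap, qd$QF_dp, 0)
  }
  list(F = F, M = M, QF_vec = QF_vec)
}

# quadriceps decomposition from system fields; the line of action is shared
# by all modes (configured patellar attachment points), so the mode-D
# surrogate uses exactly the components that the mode-A mechanism sees
decompose_quadriceps_sys <- function(sys, QF, theta_fe) {
  pat <- if (!is.null(sys$patella)) sys$patella else sys$quad
  R <- cardan_matrix(deg2rad(theta_fe), 0, 0)
  rpq <- as.numeric(R %*% (pat$rp_quad - sys$rp)) + sys$rp
  u <- rpq - pat$ref
  u <- u / sqrt(sum(u^2))
  list(QF_ap = QF * u[1], QF_dp = QF * u[2])
}

free_dofs <- function(mode) {
  setdiff(c("tx", "ty", "tz", "fe", "vv", "ie"), mode$prescribed)
}

# tibial contact reactions (BW), anterior/lateral positive, compression
# positive
contact_reactions <- function(sys, traction) {
  cols <- sys$columns
  TA <- traction * cols$area
  bw <- sys$body_weight
  c(R_axial_BW = sum(TA * cols$ny) / bw,
    R_ap_BW = -sum(TA * cols$nx) / bw,
    R_ml_BW = -sum(TA * cols$nz) / bw)
}

#' Rotate and load the joint to its initial stance state
#'
#' Ramps the stance-onset rotations and loads onto the settled joint in a
#' fixed number of increments (quasi-static; one consolidation commit at the
#' end), returning the state from which the stance march starts.
#'
#' @param sys A `knee_system` from [assemble_system()].
#' @param state A `knee_state` from [settle_contact()].
#' @param gait A `gait_series`.
#' @param mode A [driving_mode()].
#' @param config Run configuration.
#' @return An updated `knee_state` (pose, committed column bank inside
#'   `sys`, patellar warm start); the modified system is attached as
#'   `state$sys`.
#' @export
apply_initial_state <- function(sys, state, gait, mode,
                                config = default_config()) {
  row0 <- interpolate_gait(gait, 0)
  n_inc <- config$solver$init_increments
  free <- free_dofs(mode)
  pat_env <- new.env()
  q <- state$q
  alpha <- bank_alpha(sys$bank)
  sol <- NULL
  for (k in seq_len(n_inc)) {
    f <- k / n_inc
    row <- row0
    for (cn in setdiff(gait_columns, "stance_fraction")) {
      row[[cn]] <- f * row0[[cn]]
    }
    loads <- assemble_loads(sys, mode, row)
    q[4] <- deg2rad(f * row0$theta_fe_deg)
    if ("ie" %in% mode$prescribed) q[6] <- deg2rad(f * row0$theta_ie_deg)
    sol <- solve_equilibrium(sys, q, loads, free = free, alpha = alpha,
                             pat_env = pat_env)
    q <- sol$q
  }
  sys$bank <- bank_commit(sys$bank, alpha, sol$w_n)
  structure(list(q = q, t = 0, settle_translation = state$settle_translation,
                 sys = sys, pat_env = pat_env, sol = sol),
            class = "knee_state")
}

#' Simulate the stance phase under a driving mode
#'
#' Runs the full protocol -- settle to first contact, ramp the initial
#' state, then march the stance-phase inputs with backward-Euler
#' consolidation of the contact columns -- and records pose, reactions,
#' contact fields and convergence diagnostics at every step.
#'
#' @param geometry A `knee_geometry_set` or single `knee_geometry`; with a
#'   set, the variant required by the mode is used.
#' @param gait A `gait_series` from [generate_gait()].
#' @param mode A [driving_mode()].
#' @param config Run configuration (see [default_config()]); `solver$n_steps`
#'   sets the march resolution.
#' @return An object of class `knee_sim`: a list with `steps` (tibble, one
#'   row per time step: stance fraction, pose, contact reactions in BW,
#'   per-compartment contact counts, residual norms, complementarity), a
#'   `fields` list of per-step column records (traction, cartilage
#'   compression, mean pore pressure), the column table, mode, and run
#'   metadata. On a solver failure the steps completed so far are returned
#'   with `failed_at` set.
#' @examples
#' \dontrun{
#' geo <- build_geometry(seed = 1)
#' gait <- generate_gait(seed = 1)
#' sim <- simulate_stance(geo, gait, driving_mode("C"))
#' sim$steps
#' }
#' @export
simulate_stance <- function(geometry, gait, mode,
                            config = default_config()) {
  if (inherits(geometry, "knee_geometry_set")) {
    geometry <- geometry[[mode$geometry_variant]]
  }
  stopifnot(inherits(geometry, "knee_geometry"),
            inherits(mode, "driving_mode"))
  scfg <- config$solver
  n_steps <- scfg$n_steps
  dt <- scfg$stance_duration / n_steps
  sys <- assemble_system(geometry, config, dt = dt)
  if (identical(mode$quadriceps, "patella_mechanism") &&
      is.null(sys$patella)) {
    stop("mode ", mode$model_id, " requires geometry variant A ",
         "(patellar mechanism)", call. = FALSE)
  }

  st <- settle_contact(geometry, config)
  st <- apply_initial_state(sys, st, gait, mode, config)
  sys <- st$sys
  q <- st$q
  pat_env <- st$pat_env
  free <- free_dofs(mode)
  cols <- sys$columns
  cart_med <- cols$tissue == "cartilage" & cols$compartment == "medial"
  cart_lat <- cols$tissue == "cartilage" & cols$compartment == "lateral"

  rows <- vector("list", n_steps)
  fields <- vector("list", n_steps)
  failed_at <- NA_integer_

  for (j in seq_len(n_steps)) {
    t_j <- j / n_steps
    row <- interpolate_gait(gait, t_j)
    q[4] <- deg2rad(row$theta_fe_deg)
    if ("ie" %in% mode$prescribed) q[6] <- deg2rad(row$theta_ie_deg)
    loads <- assemble_loads(sys, mode, row)
    alpha <- bank_alpha(sys$bank)
    sol <- tryCatch(
      solve_equilibrium(sys, q, loads, free = free, alpha = alpha,
                        pat_env = pat_env),
      error = function(e) e
    )
    if (inherits(sol, "error")) {
      failed_at <- j
      warning("stance march failed at step ", j, " (t = ", signif(t_j, 3),
              "): ", conditionMessage(sol), call. = FALSE)
      break
    }
    q <- sol$q
    gaps <- bank_gap(sys$bank, alpha, sol$w_n)
    comp <- if (length(gaps)) max(sol$traction * gaps) else 0
    sys$bank <- bank_commit(sys$bank, alpha, sol$w_n)
    p_mean <- bank_mean_pressure(sys$bank)
    in_contact <- sol$traction > 0

    reac <- contact_reactions(sys, sol$traction)
    rows[[j]] <- tibble::tibble(
      step = j, stance_fraction = t_j,
      tx_mm = q[1], ty_mm = q[2], tz_mm = q[3],
      fe_deg = rad2deg(q[4]), vv_deg = rad2deg(q[5]), ie_deg = rad2deg(q[6]),
      R_axial_BW = reac[["R_axial_BW"]], R_ap_BW = reac[["R_ap_BW"]],
      R_ml_BW = reac[["R_ml_BW"]],
      contact_n_medial = sum(in_contact & cart_med),
      contact_n_lateral = sum(in_contact & cart_lat),
      patella_x = if (!is.null(sol$patella)) sol$patella$pos[1] else NA_real_,
      patella_y = if (!is.null(sol$patella)) sol$patella$pos[2] else NA_real_,
      pt_tension_N = if (!is.null(sol$patella)) sol$patella$pt_tension else
        NA_real_,
      iterations = sol$iterations,
      force_residual_BW = sol$force_residual_bw,
      moment_residual_BWmm = sol$moment_residual_bwmm,
      complementarity = comp
    )
    fields[[j]] <- list(traction = sol$traction,
                        w_cart = sys$bank$w_cart,
                        p_mean = p_mean)
  }

  done <- if (is.na(failed_at)) n_steps else failed_at - 1L
  structure(
    list(steps = dplyr::bind_rows(rows[seq_len(done)]),
         fields = fields[seq_len(done)],
         columns = cols, mode = mode, n_steps = n_steps, dt = dt,
         body_weight = sys$body_weight,
         settle_translation = st$settle_translation,
         initial_q = st$q, failed_at = failed_at,
         config_hash = config_hash(config)),
    class = "knee_sim"
  )
}

#' @export
print.knee_sim <- function(x, ...) {
  cat("<knee_sim> mode ", x$mode$model_id, ", ", nrow(x$steps), "/",
      x$n_steps, " steps (dt = ", signif(x$dt, 3), " s)\n", sep = "")
  if (!is.na(x$failed_at)) cat("  ! failed at step", x$failed_at, "\n")
  if (nrow(x$steps)) {
    cat("  peak axial reaction:", signif(max(x$steps$R_axial_BW), 4), "BW\n")
  }
  invisible(x)
}
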