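# reduced systems for the equilibrium solver

test_that("one-spring system equilibrium matches the brute-force oracle", {
  # vertical spring from femur point (0, 10, 0) to tibia point (0, -20, 0),
  # pulled by an external +y force; only ty free
  lig <- list(lig = spring_ligament("ACL", 380, 0.05, 30),
              femur = c(0, 10, 0), tibia = c(0, -20, 0))
  sys <- knee_system(ligaments = list(ACL = lig), rp = c(0, 10, 0))
  # spring pulls the femur down; external force F up; solve
  F_up <- 150
  sol <- solve_equilibrium(sys, rep(0, 6),
                           loads = list(F = c(0, F_up, 0), M = c(0, 0, 0)),
                           free = "ty")
  # oracle: spring anchored 30mm apart, slack 30/1.05; femur moves -u
  slack <- 30 / 1.05
  u <- brute_force_spring_equilibrium(380, slack, 30, F_up)
  expect_equal(sol$q[2], u, tolerance = 1e-8)
})

test_that("unconstrained degrees of freedom produce a named singular-Jacobian error", {
  # no contact and no ligaments: nothing resists any motion
  sys <- knee_system(ligaments = list())
  expect_error(
    solve_equilibrium(sys, rep(0, 6),
                      loads = list(F = c(0, 5, 0), M = c(0, 0, 0)),
                      free = "ty"),
    "unconstrained DOF: ty")
})

test_that("mirror-symmetric joint under pure axial load stays symmetric", {
  cfg <- default_config()
  cfg$geometry$symmetric <- TRUE
  cfg$geometry$column_spacing <- 2
  geo <- build_geometry(cfg$geometry, seed = 1)
  sys <- assemble_system(geo$B, cfg, dt = 0.01)
  st <- settle_contact(geo$B, cfg)
  sol <- solve_equilibrium(sys, st$q,
                           loads = list(F = c(0, -700, 0), M = c(0, 0, 0)),
                           free = c("ty", "vv"))
  expect_lt(abs(sol$q[5]), 1e-10)          # varus-valgus exactly zero
  reac <- kneedrive:::contact_reactions(sys, sol$traction)
  expect_lt(abs(reac[["R_ml_BW"]]), 1e-8)  # no medio-lateral reaction
  expect_equal(reac[["R_axial_BW"]], 1 +
    sum(purrr::map_dbl(sys$ligaments, function(lg) {
      pf <- lg$femur + sol$q[1:3]
      d <- lg$tibia - pf
      L <- sqrt(sum(d^2))
      -spring_force(lg$lig, L) * d[2] / L
    })) / 700, tolerance = 1e-7)           # contact balances load + ligaments
})

test_that("settle_contact reaches first touch with zero reaction", {
  geo <- build_geometry(seed = 1)
  st <- settle_contact(geo$B)
  g <- geometry_gaps(geo$B, st$q)
  expect_equal(min(g), 0, tolerance = 1e-9)
  expect_lte(st$q[2], 0)
})

test_that("simulate_stance converges with tight residuals on a short march", {
  cfg <- default_config()
  cfg$geometry$column_spacing <- 2
  cfg$solver$n_steps <- 10L
  geo <- build_geometry(cfg$geometry, seed = 1)
  gait <- generate_gait(cfg$gait, seed = 1)
  sim <- simulate_stance(geo, gait, driving_mode("C"), cfg)
  expect_s3_class(sim, "knee_sim")
  expect_true(is.na(sim$failed_at))
  expect_equal(nrow(sim$steps), 10L)
  expect_lt(max(sim$steps$force_residual_BW), 1e-7)
  expect_lt(max(sim$steps$moment_residual_BWmm), 1e-7)
  expect_lt(max(sim$steps$complementarity), 1e-10)
  expect_true(all(sim$steps$R_axial_BW > 0))
  # prescribed rotations are honored exactly
  gi <- interpolate_gait(gait, sim$steps$stance_fraction)
  expect_equal(sim$steps$fe_deg, gi$theta_fe_deg, tolerance = 1e-12)
  expect_equal(sim$steps$ie_deg, gi$theta_ie_deg, tolerance = 1e-12)
})

test_that("kinetic mode requires the patellar geometry variant", {
  cfg <- default_config()
  cfg$geometry$column_spacing <- 2
  geo <- build_geometry(cfg$geometry, seed = 1)
  gait <- generate_gait(cfg$gait, seed = 1)
  expect_error(simulate_stance(geo$B, gait, driving_mode("A"), cfg),
               "variant A")
})

test_that("patellar point equilibrium balances to machine precision", {
  cfg <- default_config()
  geo <- build_geometry(cfg$geometry, seed = 1)
  sys <- assemble_system(geo$A, cfg, dt = 0.01)
  ps <- kneedrive:::solve_patella(sys, rep(0, 6), QF_vec = c(-300, 900, 0))
  expect_lt(ps$residual, 1e-8)
  # force transmitted to the femur equals muscle + patellar tendon pull
  tub <- sys$patella$tuberosity
  d <- tub - ps$pos
  L <- sqrt(sum(d^2))
  expect_equal(ps$femur_force,
               c(-300, 900, 0) + spring_force(sys$patella$pt, L) * d / L,
               tolerance = 1e-6)
})
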