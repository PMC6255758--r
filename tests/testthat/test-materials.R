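test_that("elasticity operator is symmetric positive definite for the default tissues", {
  cart <- material_tipe(24, 0.46, 0.42, 0.06, 12, 1, 4)
  men <- material_tie(20, 159.6, 0.3, 0.01, 50)
  for (m in list(cart, men)) {
    C <- tipe_elasticity_matrix(m)
    expect_equal(C, t(C))
    expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("confined modulus matches a direct compliance inversion", {
  cart <- material_tipe(24, 0.46, 0.42, 0.06, 12, 1, 4)
  # uniaxial strain: solve the 3x3 normal-stress block directly
  S <- matrix(c(1 / 24, -0.42 / 24, -0.06 / 0.46,
                -0.42 / 24, 1 / 24, -0.06 / 0.46,
                -0.06 / 0.46, -0.06 / 0.46, 1 / 0.46), 3, 3)
  C3 <- solve(S)
  cm <- kneedrive:::confined_moduli(cart)
  expect_equal(cm$M_t, C3[3, 3], tolerance = 1e-12)
  expect_equal(cm$C13, C3[1, 3], tolerance = 1e-12)
})

test_that("inadmissible parameter sets are rejected with a thermodynamic message", {
  expect_error(material_tipe(24, 0.46, 0.42, 0.49, 12, 1, 4),
               "thermodynamic admissibility")
  expect_error(material_tipe(24, 0.46, 0.6, 0.06, 12, 1, 4),
               "Poisson")
})

test_that("permeability is converted to mm^2/(MPa s)", {
  cart <- material_tipe(24, 0.46, 0.42, 0.06, 12, 1, 4)
  expect_equal(cart$k_mm, 1e-3)
  expect_equal(cart$porosity, 4 / 5)
})

test_that("bilinear spring law: prestrain, slack, tension-only", {
  acl <- spring_ligament("ACL", 380, 0.05, reference_length = 31.5)
  expect_equal(acl$slack_length, 31.5 / 1.05)
  expect_equal(spring_force(acl, 31.5), 380 * (31.5 - 31.5 / 1.05))
  expect_equal(spring_force(acl, 20), 0)
  expect_error(spring_force(acl, 0), "degenerate geometry")
})

test_that("spring equilibrium matches the brute-force oracle", {
  k <- 380
  L_ref <- 30
  slack <- L_ref / 1.05
  for (F in c(0, 120, 377)) {
    u <- brute_force_spring_equilibrium(k, slack, anchor_distance = L_ref,
                                        force = F + k * (L_ref - slack))
    expect_equal(spring_force(spring_ligament("x", k, 0.05, L_ref),
                              L_ref + u),
                 F + k * (L_ref - slack), tolerance = 1e-9)
  }
})

test_that("truss law is linear in tension and zero in compression", {
  tr <- truss_ligament("MPFL", 19.1, 10, reference_length = 40)
  expect_equal(truss_force(tr, 42), 19.1 * 10 * 2 / 40)
  expect_equal(truss_force(tr, 38), 0)
})
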