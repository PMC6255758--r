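cart <- material_tipe(24, 0.46, 0.42, 0.06, 12, 1, 4)
cm <- kneedrive:::confined_moduli(cart)

test_that("instantaneous (one-step) response shows the undrained stiffening", {
  st <- new_column_state(3, depth_layers = 8)
  out <- column_consolidation_step(st, cart, new_overlap = 0.1, dt = 1e-4)
  # near-undrained: traction far above the drained value
  expect_gt(out$traction, 5 * cm$M_t * 0.1 / 3)
  # pore pressure carries almost all of the load away from the surface
  expect_gt(out$state$pore_pressure[1] / out$traction, 0.95)
})

test_that("long-time traction relaxes to the drained confined stiffness", {
  st <- new_column_state(3, depth_layers = 8)
  t_char <- 3^2 / (cart$k_mm * cm$M_t)
  for (i in 1:80) {
    out <- column_consolidation_step(st, cart, 0.1, dt = t_char / 2)
    st <- out$state
  }
  expect_equal(out$traction, cm$M_t * 0.1 / 3, tolerance = 1e-10)
  expect_lt(max(abs(st$pore_pressure)), 1e-12)
})

test_that("column state advances time and validates inputs", {
  st <- new_column_state(2)
  expect_error(column_consolidation_step(st, cart, -0.1, 0.01), "overlap")
  expect_error(column_consolidation_step(st, cart, 0.1, 0), "dt")
  out <- column_consolidation_step(st, cart, 0.05, 0.01)
  expect_equal(out$state$time, 0.01)
})

test_that("the vectorized bank reproduces the scalar column step", {
  h0 <- c(2, 3.4)
  dt <- 0.006
  bank <- kneedrive:::column_bank(h0, cart, 3L, dt, c(Inf, Inf))
  w <- c(0.05, 0.12)
  a <- kneedrive:::bank_alpha(bank)
  Tb <- kneedrive:::bank_traction(bank, a, w)
  bank2 <- kneedrive:::bank_commit(bank, a, w)
  for (i in 1:2) {
    st <- new_column_state(h0[i], 3L)
    out <- column_consolidation_step(st, cart, w[i], dt)
    expect_equal(Tb[i], out$traction, tolerance = 1e-12)
    expect_equal(bank2$p[, i], out$state$pore_pressure, tolerance = 1e-12)
  }
  # second step from committed state
  a2 <- kneedrive:::bank_alpha(bank2)
  Tb2 <- kneedrive:::bank_traction(bank2, a2, w * 1.5)
  for (i in 1:2) {
    st <- new_column_state(h0[i], 3L)
    st <- column_consolidation_step(st, cart, w[i], dt)$state
    out <- column_consolidation_step(st, cart, 1.5 * w[i], dt)
    expect_equal(Tb2[i], out$traction, tolerance = 1e-11)
  }
})

test_that("bank traction and gap satisfy complementarity by construction", {
  bank <- kneedrive:::column_bank(c(2, 2, 2), cart, 3L, 0.01, rep(Inf, 3))
  a <- kneedrive:::bank_alpha(bank)
  w <- c(-0.5, 0, 0.1)   # separated, touching, compressed
  Tr <- kneedrive:::bank_traction(bank, a, w)
  g <- kneedrive:::bank_gap(bank, a, w)
  expect_true(all(Tr >= 0))
  expect_true(all(g >= 0))
  expect_true(all(Tr * g == 0))
  expect_equal(Tr[1], 0)
  expect_gt(Tr[3], 0)
})

test_that("meniscal series compliance softens the column response", {
  bank_stiff <- kneedrive:::column_bank(2, cart, 3L, 0.01, Inf)
  bank_soft <- kneedrive:::column_bank(2, cart, 3L, 0.01, 0.5)
  a1 <- kneedrive:::bank_alpha(bank_stiff)
  a2 <- kneedrive:::bank_alpha(bank_soft)
  T1 <- kneedrive:::bank_traction(bank_stiff, a1, 0.1)
  T2 <- kneedrive:::bank_traction(bank_soft, a2, 0.1)
  expect_lt(T2, T1)
  # committed cartilage compression excludes the spacer deflection
  b2 <- kneedrive:::bank_commit(bank_soft, a2, 0.1)
  expect_equal(b2$w_cart, 0.1 - T2 / 0.5, tolerance = 1e-12)
})

test_that("depth-averaged pore pressure matches the trapezoid of the nodes", {
  st <- new_column_state(3, 4L)
  st <- column_consolidation_step(st, cart, 0.08, 0.05)$state
  p <- c(st$pore_pressure, 0)
  expect_equal(column_mean_pressure(st),
               sum((p[-1] + p[-5]) / 2) / 4, tolerance = 1e-12)
})
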