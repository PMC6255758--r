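test_that("gait series has the documented schema and grid", {
  g <- generate_gait(seed = 1)
  expect_s3_class(g, "gait_series")
  expect_named(g, kneedrive:::gait_columns)
  expect_equal(nrow(g), 101L)
  expect_equal(range(g$stance_fraction), c(0, 1))
  expect_equal(attr(g, "body_weight"), 700)
})

test_that("waveforms are deterministic in the seed and smooth", {
  expect_identical(generate_gait(seed = 4), generate_gait(seed = 4))
  expect_false(identical(generate_gait(seed = 4), generate_gait(seed = 5)))
  g <- generate_gait(seed = 1)
  # C1-smoothness proxy: bounded second differences
  d2 <- diff(diff(g$F_dp_BW))
  expect_lt(max(abs(d2)), 0.05)
})

test_that("axial force is double-peaked and strictly positive", {
  cfg <- default_config()$gait
  cfg$noise_level <- 0
  g <- generate_gait(cfg, seed = 1)
  expect_true(all(g$F_dp_BW > 0))
  pk1 <- g$stance_fraction[which.max(g$F_dp_BW * (g$stance_fraction < 0.5))]
  pk2 <- g$stance_fraction[which.max(g$F_dp_BW * (g$stance_fraction > 0.5))]
  expect_equal(pk1, cfg$dp_peak1_time, tolerance = 0.03)
  expect_equal(pk2, cfg$dp_peak2_time, tolerance = 0.03)
  mid <- g$F_dp_BW[g$stance_fraction == 0.5]
  expect_lt(mid, 0.8 * max(g$F_dp_BW))
})

test_that("invalid peak timing is rejected", {
  cfg <- default_config()$gait
  cfg$dp_peak1_time <- 1.2
  expect_error(generate_gait(cfg), "peak times")
})

test_that("interpolation hits grid values exactly and clamps outside", {
  g <- generate_gait(seed = 2)
  gi <- interpolate_gait(g, c(0, 0.37, 1))
  expect_equal(gi$F_dp_BW[1], g$F_dp_BW[1])
  expect_equal(gi$F_dp_BW[3], g$F_dp_BW[101])
  lo <- interpolate_gait(g, -0.5)
  expect_equal(lo$QF_BW, g$QF_BW[1])
})

test_that("quadriceps decomposition conserves magnitude bounds and flexion trend", {
  geo <- build_geometry(seed = 1)
  qd <- decompose_quadriceps(c(1, 1), c(0, 40), geo)
  expect_true(all(qd$QF_ap^2 + qd$QF_dp^2 <= 1 + 1e-12))
  expect_true(all(qd$QF_dp > 0))      # quadriceps pulls proximally
  expect_true(all(qd$QF_ap < 0))      # and posteriorly toward the shaft
  # more flexion tilts the line of action further posterior
  expect_lt(qd$QF_ap[2], qd$QF_ap[1])
  expect_equal(decompose_quadriceps(0, 10, geo)$QF_ap, 0)
})
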