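coarse_cfg <- function(n_steps = 10L) {
  cfg <- default_config()
  cfg$geometry$column_spacing <- 2
  cfg$solver$n_steps <- n_steps
  cfg
}

test_that("compartment response summarizes contacting cartilage only", {
  cfg <- coarse_cfg()
  geo <- build_geometry(cfg$geometry, seed = 1)
  gait <- generate_gait(cfg$gait, seed = 1)
  sim <- simulate_stance(geo, gait, driving_mode("C"), cfg)
  cr <- compartment_response(sim, cfg)
  expect_equal(nrow(cr), 2L * nrow(sim$steps))
  expect_setequal(unique(cr$compartment), c("medial", "lateral"))
  # area equals count x spacing^2
  expect_equal(cr$contact_area_mm2, cr$n_contact * 4)
  # strains are compressive, pressures positive where contact exists
  has <- cr$n_contact > 0
  expect_true(all(cr$min_log_strain[has] < 0))
  expect_true(all(cr$peak_pressure_MPa[has] > 0))
  expect_true(all(cr$mean_pore_pressure_MPa[has] >= 0))
  # maximum principal stress reproduces the closed-form uniaxial oracle
  j <- which(has)[1]
  fld <- sim$fields[[cr$step[j]]]
  cols <- sim$columns
  sel <- cols$tissue == "cartilage" & cols$compartment == cr$compartment[j] &
    fld$traction > 0
  mat <- material_tipe(24, 0.46, 0.42, 0.06, 12, 1, 4)
  smax <- purrr::map_dbl(which(sel), function(i) {
    uniaxial_strain_stress(mat, -fld$w_cart[i] / cols$h0[i],
                           fld$p_mean[i])$max_principal
  })
  expect_equal(cr$max_principal_stress_MPa[j], max(smax), tolerance = 1e-10)
})

test_that("empty contact yields NA summaries, not zeros", {
  cfg <- coarse_cfg()
  geo <- build_geometry(cfg$geometry, seed = 1)
  gait <- generate_gait(cfg$gait, seed = 1)
  sim <- simulate_stance(geo, gait, driving_mode("C"), cfg)
  # fabricate a step with no contact
  sim$fields[[1]]$traction <- rep(0, nrow(sim$columns))
  cr <- compartment_response(sim, cfg)
  r1 <- cr[cr$step == sim$steps$step[1], ]
  expect_true(all(is.na(r1$mean_pressure_MPa)))
  expect_true(all(r1$contact_area_mm2 == 0))
})

test_that("comparison of a run with itself is exactly zero", {
  cfg <- coarse_cfg()
  geo <- build_geometry(cfg$geometry, seed = 2)
  gait <- generate_gait(cfg$gait, seed = 2)
  sim <- simulate_stance(geo, gait, driving_mode("C"), cfg)
  cmp <- compare_models(sim, sim)
  expect_true(all(cmp$metrics$mean_abs_diff == 0))
  expect_true(all(cmp$metrics$max_abs_diff == 0))
  expect_true(all(cmp$metrics$rms_diff == 0))
  expect_true(all(cmp$snapshots$traction_diff_MPa == 0))
  expect_equal(kneedrive:::comparison_discrepancy(cmp), 0)
})

test_that("comparison metrics capture an injected offset", {
  cfg <- coarse_cfg()
  geo <- build_geometry(cfg$geometry, seed = 2)
  gait <- generate_gait(cfg$gait, seed = 2)
  sim <- simulate_stance(geo, gait, driving_mode("C"), cfg)
  sim2 <- sim
  sim2$steps$R_axial_BW <- sim2$steps$R_axial_BW + 0.05
  cmp <- compare_models(sim, sim2)
  m <- cmp$metrics
  expect_equal(m$mean_abs_diff[m$variable == "R_axial_BW"], 0.05)
  expect_equal(m$max_abs_diff[m$variable == "R_axial_BW"], 0.05)
  expect_equal(m$mean_abs_diff[m$variable == "R_ap_BW"], 0)
})

test_that("tidiers return well-formed tibbles", {
  cfg <- coarse_cfg(5L)
  geo <- build_geometry(cfg$geometry, seed = 1)
  gait <- generate_gait(cfg$gait, seed = 1)
  sim <- simulate_stance(geo, gait, driving_mode("C"), cfg)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_false("iterations" %in% names(td))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$mode, "C")
  expect_false(gl$failed)
  cmp <- compare_models(sim, sim)
  expect_equal(glance(cmp)$discrepancy, 0)
  expect_s3_class(tidy(cmp), "tbl_df")
})
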