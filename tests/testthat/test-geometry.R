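test_that("geometry generation is deterministic in the seed", {
  g1 <- build_geometry(seed = 11)
  g2 <- build_geometry(seed = 11)
  g3 <- build_geometry(seed = 12)
  expect_identical(g1$B$columns, g2$B$columns)
  expect_identical(g1$B$condyles, g2$B$condyles)
  expect_false(identical(g1$B$condyles, g3$B$condyles))
})

test_that("geometry generation leaves the global RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(build_geometry(seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("variants share surfaces; only A carries the patellar mechanism", {
  g <- build_geometry(seed = 1)
  expect_identical(g$A$columns, g$B$columns)
  expect_identical(g$A$condyles, g$B$condyles)
  expect_null(g$B$patella)
  expect_false(is.null(g$A$patella))
})

test_that("cartilage thickness respects the configured band", {
  cfg <- default_config()$geometry
  g <- build_geometry(cfg, seed = 3)
  expect_true(all(g$B$columns$h0 >= cfg$cartilage$thickness_min))
  expect_true(all(g$B$columns$h0 <= cfg$cartilage$thickness_max))
})

test_that("meniscus occupies the outer annulus with a wedge profile", {
  g <- build_geometry(seed = 2)
  cols <- g$B$columns
  men <- cols[cols$tissue == "meniscus", ]
  cart <- cols[cols$tissue == "cartilage", ]
  expect_true(all(men$wedge >= 0))
  expect_true(all(cart$wedge == 0))
  expect_gt(nrow(men), 0)
  # wedge grows outward
  expect_gt(max(men$wedge), 0.5)
})

test_that("symmetric flag yields a mirror-symmetric joint", {
  cfg <- default_config()$geometry
  cfg$symmetric <- TRUE
  g <- build_geometry(cfg, seed = 7)
  cm <- g$B$condyles$medial
  cl <- g$B$condyles$lateral
  expect_equal(cm$center * c(1, 1, -1), cl$center)
  expect_equal(cm$semi, cl$semi)
  expect_equal(g$B$insertions$MCL$femur * c(1, 1, -1), g$B$insertions$LCL$femur)
  expect_equal(g$B$insertions$ACL$femur[3], 0)
})

test_that("reference-pose interpenetration is rejected", {
  cfg <- default_config()$geometry
  cfg$condyle$center_y <- 10   # far below the auto-placed height
  expect_error(build_geometry(cfg, seed = 1), "interpenetrate")
})

test_that("gaps are non-negative at the reference pose and close under -y translation", {
  g <- build_geometry(seed = 1)
  g0 <- geometry_gaps(g$B, rep(0, 6))
  expect_gte(min(g0), 0)
  gmin <- min(g0)
  g1 <- geometry_gaps(g$B, c(0, -gmin - 0.2, 0, 0, 0, 0))
  expect_lt(min(g1), 0)
})
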