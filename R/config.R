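# Run configuration: defaults, YAML I/O, schema validation, hashing.
#
# Every default is either a literature-reported constant (cartilage/meniscus
# material parameters, ligament stiffnesses and prestrains, horn spring
# constant, moment scaling) or a declared modelling choice of this package
# (geometry dimensions, waveform magnitudes, solver tolerances); the methods
# vignette documents which is which.

#' Default run configuration
#'
#' Nested list with sections `materials`, `geometry`, `gait`, `solver`,
#' `modes`, `seed` and `output_dir`. Material constants: cartilage is
#' transversely isotropic poroelastic (in-plane modulus 24 MPa, out-of-plane
#' 0.46 MPa, permeability 1e-15 m^4/(N s), void ratio 4), menisci
#' transversely isotropic elastic; cruciate/collateral ligaments are
#' bilinear springs (ACL 380, PCL 200, MCL/LCL 100 N/mm) with 5% (cruciate)
#' and 4% (collateral/tendon) prestrain; quadriceps and patellar tendons 475
#' and 545 N/mm; meniscal horns 350 N/mm each; MPFL/LPFL elastic trusses
#' (19.1 / 17 MPa, area 10 mm^2). Moments in the kinetic mode are scaled by
#' 0.5 (muscles assumed to absorb half).
#'
#' @return A named nested list.
#' @export
default_config <- function() {
  list(
    materials = list(
      cartilage = list(E_p = 24, E_t = 0.46, nu_p = 0.42, nu_tp = 0.06,
                       G_t = 12, permeability_k = 1, e0 = 4),
      meniscus = list(E_p = 20, E_t = 159.6, nu_p = 0.3, nu_tp = 0.01,
                      G_t = 50),
      ACL = list(stiffness_k = 380, prestrain = 0.05),
      PCL = list(stiffness_k = 200, prestrain = 0.05),
      MCL = list(stiffness_k = 100, prestrain = 0.04),
      LCL = list(stiffness_k = 100, prestrain = 0.04),
      QT = list(stiffness_k = 475, prestrain = 0.04),
      PT = list(stiffness_k = 545, prestrain = 0.04),
      horn = list(stiffness_k = 350),
      MPFL = list(E = 19.1, nu = 0.499, cross_section_area = 10),
      LPFL = list(E = 17, nu = 0.499, cross_section_area = 10)
    ),
    geometry = list(
      symmetric = FALSE,
      jitter_rel = 0.03,
      jitter_mm = 0.5,
      column_spacing = 1.0,
      compartment_offset = 22,
      gap_tolerance = 1e-9,
      initial_gap = 0.5,
      plateau = list(rx = 19, rz = 13, posterior_slope_deg = 7,
                     dish_radius_medial = 70, dish_radius_lateral = 90),
      cartilage = list(thickness_center = 3.4, thickness_edge = 2.0,
                       thickness_min = 1.5, thickness_max = 4.0),
      meniscus = list(inner_frac = 0.6, wedge_height = 3.0, body_height = 6.0),
      condyle = list(semi_ap = 30, semi_dp = 26, semi_ml = 24,
                     center_x = -2, center_y = NA),
      epicondyle = list(y = 12, z = 40),
      insertions = list(
        ACL = list(femur = c(-6, 18, 4), tibia = c(8, 0, 0)),
        PCL = list(femur = c(4, 16, -4), tibia = c(-10, -2, 0)),
        MCL = list(femur = c(0, 12, -40), tibia = c(0, -55, -38)),
        LCL = list(femur = c(0, 12, 40), tibia = c(-3, -50, 42))
      ),
      patella = list(
        ref = c(35, 25, 0), rp_quad = c(15, 80, 0),
        tuberosity = c(28, -30, 0),
        trochlea_center = c(12, 28, 0), trochlea_radius = 22,
        contact_stiffness = 400, regularization_stiffness = 0.1,
        mpfl_femur = c(5, 20, -25), lpfl_femur = c(5, 20, 25)
      )
    ),
    gait = list(
      n_grid = 101L,
      body_weight = 700,
      noise_level = 0.05,
      dp_peak1 = 1.1, dp_peak2 = 1.0, dp_baseline = 0.15,
      dp_peak1_time = 0.20, dp_peak2_time = 0.80, dp_width = 0.12,
      ap_peak1 = -0.15, ap_peak2 = 0.12, ml_peak = 0.10,
      vv_moment_peak1 = 40, vv_moment_peak2 = 32,
      ie_moment_peak = 10,
      fe_baseline = 5, fe_early_peak = 13, fe_toeoff = 30,
      ie_baseline = 1, ie_early_peak = 4, ie_late_peak = -4,
      qf_baseline = 0.2, qf_peak = 2.2, qf_late_peak = 0.4,
      qf_peak_time = 0.18
    ),
    solver = list(
      n_steps = 100L,
      stance_duration = 0.6,
      depth_layers = 3L,
      settle_tolerance = 1.0,
      tol_force_bw = 1e-8,
      tol_moment_bwmm = 1e-8,
      max_iter = 80L,
      init_increments = 40L,
      moment_scale = 0.5,
      qf_scale = 1.0,
      vv_moment_in_B = FALSE,
      cardan = "fe-vv-ie"
    ),
    modes = c("A", "B", "C", "D"),
    seed = 1L,
    output_dir = "kneedrive-out"
  )
}

#' Read or write a run configuration as YAML
#'
#' `read_config()` loads a YAML file, merges it over the defaults and
#' validates it; unknown keys are rejected with their full field path.
#'
#' @param path File path.
#' @param config Configuration list (for writing).
#' @return `read_config()` returns the validated configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), raw, path = character())
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# recursive merge of user values over defaults; unknown keys rejected.
merge_config <- function(base, user, path) {
  if (is.null(user)) return(base)
  if (!is.list(base) || !is.list(user) || is.null(names(user))) return(user)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown configuration key: ",
         paste(c(path, unknown[1]), collapse = "."), call. = FALSE)
  }
  for (nm in names(user)) {
    base[[nm]] <- merge_config(base[[nm]], user[[nm]], c(path, nm))
  }
  base
}

#' Validate a run configuration
#'
#' Checks types and physical ranges of the key fields; errors name the full
#' field path (e.g. `materials.ACL.stiffness_k`).
#'
#' @param config Configuration list.
#' @return The configuration, invisibly, if valid.
#' @export
validate_config <- function(config) {
  fail <- function(path, why) {
    stop("invalid configuration at ", path, ": ", why, call. = FALSE)
  }
  need_pos <- function(x, path) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      fail(path, "must be a positive number")
    }
  }
  need_nonneg <- function(x, path) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
      fail(path, "must be a non-negative number")
    }
  }
  m <- config$materials
  for (lg in c("ACL", "PCL", "MCL", "LCL", "QT", "PT")) {
    need_pos(m[[lg]]$stiffness_k, paste0("materials.", lg, ".stiffness_k"))
    need_nonneg(m[[lg]]$prestrain, paste0("materials.", lg, ".prestrain"))
  }
  need_pos(m$horn$stiffness_k, "materials.horn.stiffness_k")
  for (tr in c("MPFL", "LPFL")) {
    need_pos(m[[tr]]$E, paste0("materials.", tr, ".E"))
    need_pos(m[[tr]]$cross_section_area,
             paste0("materials.", tr, ".cross_section_area"))
  }
  for (f in c("E_p", "E_t", "G_t", "permeability_k", "e0")) {
    need_pos(m$cartilage[[f]], paste0("materials.cartilage.", f))
  }
  for (f in c("E_p", "E_t", "G_t")) {
    need_pos(m$meniscus[[f]], paste0("materials.meniscus.", f))
  }
  for (tis in c("cartilage", "meniscus")) {
    for (f in c("nu_p", "nu_tp")) {
      v <- m[[tis]][[f]]
      if (!is.numeric(v) || v <= -1 || v >= 0.5) {
        fail(paste0("materials.", tis, ".", f), "must lie in (-1, 0.5)")
      }
    }
  }
  g <- config$geometry
  need_pos(g$column_spacing, "geometry.column_spacing")
  need_pos(g$cartilage$thickness_center, "geometry.cartilage.thickness_center")
  need_pos(g$initial_gap, "geometry.initial_gap")
  s <- config$solver
  need_pos(s$stance_duration, "solver.stance_duration")
  need_pos(s$tol_force_bw, "solver.tol_force_bw")
  if (!is.numeric(s$n_steps) || s$n_steps < 1) fail("solver.n_steps", "must be >= 1")
  if (!is.numeric(s$depth_layers) || s$depth_layers < 1) {
    fail("solver.depth_layers", "must be >= 1")
  }
  need_nonneg(s$qf_scale, "solver.qf_scale")
  gt <- config$gait
  need_pos(gt$body_weight, "gait.body_weight")
  need_nonneg(gt$noise_level, "gait.noise_level")
  if (!is.numeric(gt$n_grid) || gt$n_grid < 3) fail("gait.n_grid", "must be >= 3")
  bad_mode <- setdiff(config$modes, c("A", "B", "C", "D"))
  if (length(bad_mode)) fail("modes", paste("unknown mode", bad_mode[1]))
  invisible(config)
}

#' Hash of a run configuration
#'
#' Stable content hash used in run manifests; changes iff any
#' scientifically relevant configuration value changes. The output
#' directory is excluded, so runs of the same study written to different
#' places produce identical manifests.
#'
#' @param config Configuration list.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  config$output_dir <- NULL
  rlang::hash(config)
}
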