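# Small deterministic fixtures with analytically known answers, used by the
# test suite and exported so users can regenerate them.

#' Generate a named verification fixture
#'
#' Each fixture is a small, deterministic dataset with an analytically known
#' answer:
#'
#' * `"single_column_step_load"`: confined-compression consolidation of one
#'   cartilage column under a step compression; table of analytic
#'   centre/interface pore pressures and consolidation degree at 20 time
#'   points (series solution).
#' * `"one_dof_spring"`: a prestrained spring pulled by a range of axial
#'   forces; table of closed-form equilibrium elongations.
#' * `"two_sphere_symmetric"`: a mirror-symmetric joint geometry (symmetry
#'   flag on) with the facts that make symmetry checkable: paired column
#'   coordinates and the expected zero medio-lateral reaction under
#'   symmetric load.
#'
#' @param name Fixture name.
#' @param seed Seed for fixtures with generated geometry.
#' @return A list of class `knee_fixture` with `name`, `data` (tibble) and
#'   `meta` (named list of scalar parameters).
#' @examples
#' fx <- make_fixture("one_dof_spring")
#' fx$data
#' @export
make_fixture <- function(name = c("single_column_step_load", "one_dof_spring",
                                  "two_sphere_symmetric"), seed = 1L) {
  name <- match.arg(name)
  fx <- switch(name,
    single_column_step_load = {
      mat <- material_tipe(24, 0.46, 0.42, 0.06, 12, 1, 4)
      cm <- confined_moduli(mat)
      h <- 3                       # mm, drainage path (surface-drained)
      T0 <- 0.05                   # MPa step traction, held constant
      c_v <- mat$k_mm * cm$M_t     # consolidation coefficient, mm^2/s
      t_char <- h^2 / c_v
      times <- t_char * 10^seq(-1.3, 0.1, length.out = 20)
      data <- tibble::tibble(
        time_s = times,
        p_interface_MPa = purrr::map_dbl(times, ~terzaghi_pressure(h, .x, T0, c_v, h)),
        p_mid_MPa = purrr::map_dbl(times, ~terzaghi_pressure(h / 2, .x, T0, c_v, h)),
        consolidation_degree = purrr::map_dbl(
          times, ~terzaghi_consolidation_degree(.x, c_v, h))
      )
      list(data = data,
           meta = list(thickness_mm = h, step_traction_MPa = T0,
                       M_t_MPa = cm$M_t, k_mm2_per_MPa_s = mat$k_mm,
                       c_v_mm2_per_s = c_v, t_char_s = t_char))
    },
    one_dof_spring = {
      k <- 380
      L_ref <- 30
      prestrain <- 0.05
      slack <- L_ref / (1 + prestrain)
      forces <- seq(0, 400, by = 50)
      # pulling along the spring axis from the reference length:
      # equilibrium length L satisfies k (L - slack) = F + k (L_ref - slack)
      data <- tibble::tibble(
        force_N = forces,
        length_mm = L_ref + forces / k,
        tension_N = k * (L_ref + forces / k - slack)
      )
      list(data = data,
           meta = list(stiffness_k = k, reference_length = L_ref,
                       prestrain = prestrain, slack_length = slack))
    },
    two_sphere_symmetric = {
      cfg <- default_config()$geometry
      cfg$symmetric <- TRUE
      geo <- build_geometry(cfg, seed = seed)
      cols <- geo$B$columns
      data <- dplyr::count(cols, .data$compartment, .data$tissue)
      list(data = data,
           meta = list(seed = seed, n_columns = nrow(cols),
                       expected_R_ml_BW = 0,
                       medial_center_z = geo$B$condyles$medial$center[3],
                       lateral_center_z = geo$B$condyles$lateral$center[3]))
    }
  )
  structure(c(list(name = name), fx), class = "knee_fixture")
}

#' Write a fixture to disk as text
#'
#' Writes `<name>.csv` (the data table) and `<name>.json` (the metadata).
#'
#' @param fixture A [make_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "knee_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(fixture$name, ".csv"))
  js <- file.path(dir, paste0(fixture$name, ".json"))
  readr::write_csv(fixture$data, csv)
  jsonlite::write_json(fixture$meta, js, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(csv, js))
}
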