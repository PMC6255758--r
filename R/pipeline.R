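# End-to-end pipeline: generate inputs, run the requested driving modes,
# post-process, and write a reproducible set of text artifacts.

#' Read and write gait input CSV files
#'
#' The on-disk schema matches the columns of [generate_gait()]. Reading
#' validates the schema: all required columns present, `stance_fraction`
#' strictly increasing in `[0, 1]` (errors name the offending row), and
#' unknown extra columns trigger a warning (they are preserved).
#'
#' @param path CSV file path.
#' @param gait A `gait_series` tibble (for writing).
#' @param body_weight Body weight (N) attached on read.
#' @return `read_gait_csv()` returns a `gait_series` tibble.
#' @export
read_gait_csv <- function(path, body_weight = default_config()$gait$body_weight) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(gait_columns, names(df))
  if (length(missing)) {
    stop("gait file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), gait_columns)
  if (length(extra)) {
    warning("gait file has unrecognized column(s), preserved as-is: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  t <- df$stance_fraction
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stop("stance_fraction must be strictly increasing; violation at row ",
         bad[1] + 1L, call. = FALSE)
  }
  if (t[1] < 0 || t[length(t)] > 1) {
    stop("stance_fraction must lie within [0, 1]", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "body_weight") <- body_weight
  class(out) <- c("gait_series", class(out))
  out
}

#' @rdname read_gait_csv
#' @export
write_gait_csv <- function(gait, path) {
  out <- as.data.frame(gait)
  # full precision so a write/read round trip is lossless to ~1e-15
  readr::write_csv(tibble::as_tibble(lapply(out, identity)), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# legacy-ASCII VTK POLYDATA writer for contact maps (point data on the
# column grid); plain text, viewable in ParaView

write_vtk_contact_map <- function(sim, step_index, path) {
  cols <- sim$columns
  fld <- sim$fields[[step_index]]
  n <- nrow(cols)
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("tibiofemoral contact map, stance fraction ",
     format(sim$steps$stance_fraction[step_index]))
  wl("ASCII")
  wl("DATASET POLYDATA")
  wl("POINTS ", n, " float")
  pts <- cbind(cols$x, cols$y_top, cols$z)
  writeLines(apply(format(pts, trim = TRUE, digits = 8), 1, paste,
                   collapse = " "), con)
  wl("VERTICES ", n, " ", 2L * n)
  writeLines(paste(1L, seq_len(n) - 1L), con)
  wl("POINT_DATA ", n)
  scalar <- function(name, v) {
    wl("SCALARS ", name, " float 1")
    wl("LOOKUP_TABLE default")
    writeLines(format(v, trim = TRUE, digits = 8), con)
  }
  scalar("traction_MPa", fld$traction)
  scalar("cartilage_compression_mm", fld$w_cart)
  scalar("pore_pressure_MPa", fld$p_mean)
  scalar("tissue_meniscus", as.numeric(cols$tissue == "meniscus"))
  invisible(path)
}

#' Run the full study pipeline and write its artifacts
#'
#' Generates (or reads) the gait inputs, builds the geometry, simulates the
#' requested driving modes, post-processes, and writes a deterministic set
#' of text artifacts to the output directory:
#' `gait.csv`, `steps_<mode>.csv`, `compartment_<mode>.csv`, pairwise
#' `comparison_metrics.csv`, contact maps `contact_<mode>_<pct>.vtk` at 20,
#' 50 and 80% of stance, and `manifest.json` (package version, seed,
#' configuration hash, file list). No timestamps are written, so repeated
#' runs with the same seed and configuration are byte-identical.
#'
#' @param config Run configuration; `config$modes` selects the modes and
#'   `config$output_dir` the destination.
#' @param seed Seed for geometry and gait generation (defaults to
#'   `config$seed`).
#' @param gait Optional externally supplied `gait_series` (e.g. from
#'   [read_gait_csv()]); when `NULL` one is generated.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the simulations (`sims`), comparisons
#'   (`comparisons`), the gait table and the manifest.
#' @export
run_pipeline <- function(config = default_config(), seed = config$seed,
                         gait = NULL, quiet = FALSE) {
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  geo <- build_geometry(config$geometry, seed = seed)
  if (is.null(gait)) gait <- generate_gait(config$gait, seed = seed)
  files <- character(0)
  pth <- function(...) file.path(config$output_dir, paste0(...))

  write_gait_csv(gait, pth("gait.csv"))
  files <- c(files, "gait.csv")

  sims <- list()
  for (m in config$modes) {
    say("simulating mode ", m, " ...")
    mode <- driving_mode(m, qf_scale = config$solver$qf_scale,
                         moment_scale = config$solver$moment_scale,
                         vv_moment_in_B = config$solver$vv_moment_in_B)
    sim <- simulate_stance(geo, gait, mode, config)
    sims[[m]] <- sim
    readr::write_csv(sim$steps, pth("steps_", m, ".csv"))
    readr::write_csv(compartment_response(sim, config),
                     pth("compartment_", m, ".csv"))
    files <- c(files, paste0("steps_", m, ".csv"),
               paste0("compartment_", m, ".csv"))
    for (f in c(0.2, 0.5, 0.8)) {
      j <- which.min(abs(sim$steps$stance_fraction - f))
      if (!length(j)) next
      fn <- paste0("contact_", m, "_", round(100 * f), ".vtk")
      write_vtk_contact_map(sim, j, pth(fn))
      files <- c(files, fn)
    }
  }

  comparisons <- list()
  ids <- names(sims)
  if (length(ids) > 1) {
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    metrics <- purrr::map_dfr(pairs, function(pr) {
      cmp <- compare_models(sims[[pr[1]]], sims[[pr[2]]])
      comparisons[[paste(pr, collapse = "")]] <<- cmp
      dplyr::mutate(cmp$metrics, mode_a = pr[1], mode_b = pr[2],
                    .before = 1)
    })
    readr::write_csv(metrics, pth("comparison_metrics.csv"))
    files <- c(files, "comparison_metrics.csv")
  }

  manifest <- list(
    package = "kneedrive",
    version = tryCatch(as.character(utils::packageVersion("kneedrive")),
                       error = function(e) "dev"),
    seed = seed,
    config_hash = config_hash(config),
    modes = as.list(config$modes),
    n_steps = config$solver$n_steps,
    columns = nrow(geo$B$columns),
    files = as.list(sort(files))
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(sims = sims, comparisons = comparisons, gait = gait,
                 geometry = geo, manifest = manifest))
}
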