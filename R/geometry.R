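# Parametric knee geometry generator.
#
# Stands in for MRI segmentation: ellipsoidal femoral condyles over dished,
# posteriorly sloped tibial plateau patches tessellated into contact
# columns, annular meniscal wedge spacers, and named ligament insertion
# points. Geometry A carries the patellar mechanism (point patella,
# trochlear patch, quadriceps/patellar tendon attachments, MPFL/LPFL);
# Geometry B shares the identical tibiofemoral surfaces without it.
#
# Frame: tibia-fixed, +x anterior, +y proximal, +z lateral (right knee);
# lengths mm. The femur frame coincides with the tibia frame at the
# reference (imaging) pose.

with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

jit_rel <- function(x, sd) x * (1 + stats::rnorm(length(x), 0, sd))
jit_abs <- function(x, sd) x + stats::rnorm(length(x), 0, sd)

#' Generate a parametric knee geometry (variants A and B)
#'
#' Builds the tibiofemoral surfaces, contact-column tessellation, meniscal
#' wedge annuli, ligament insertion points and reference points for one
#' synthetic knee. Both geometry variants are returned from a single call:
#' variant A includes the patellar mechanism, variant B does not; their
#' tibiofemoral surfaces are shared exactly, so differences between driving
#' modes that use the two variants are attributable solely to the patella.
#'
#' The generator is deterministic for a fixed seed; the seed drives small
#' jitters of radii, thicknesses and insertion points (mirrored when the
#' symmetry flag is set).
#'
#' @param geo_config Geometry section of the run configuration
#'   (see [default_config()]).
#' @param seed Integer seed.
#' @return An object of class `knee_geometry_set` with elements `A` and `B`
#'   (each class `knee_geometry`), plus `seed` and the config used.
#' @examples
#' geo <- build_geometry(seed = 7)
#' nrow(geo$B$columns)
#' @export
build_geometry <- function(geo_config = default_config()$geometry, seed = 1L) {
  gc <- geo_config
  stopifnot(gc$column_spacing > 0, gc$condyle$semi_ap > 0,
            gc$cartilage$thickness_center > 0)

  with_preserved_seed(seed, {
    jr <- gc$jitter_rel
    jm <- gc$jitter_mm

    semi_m <- jit_rel(c(gc$condyle$semi_ap, gc$condyle$semi_dp,
                        gc$condyle$semi_ml), jr)
    semi_l <- if (isTRUE(gc$symmetric)) semi_m else
      jit_rel(c(gc$condyle$semi_ap, gc$condyle$semi_dp, gc$condyle$semi_ml), jr)
    dish_m <- jit_rel(gc$plateau$dish_radius_medial, jr)
    dish_l <- if (isTRUE(gc$symmetric)) dish_m else
      jit_rel(gc$plateau$dish_radius_lateral, jr)
    th_c <- jit_rel(gc$cartilage$thickness_center, jr)
    th_e <- jit_rel(gc$cartilage$thickness_edge, jr)
    cx <- jit_abs(gc$condyle$center_x, jm / 2)

    ins0 <- gc$insertions
    if (isTRUE(gc$symmetric)) {
      # central structures on the midline, collaterals mirrored exactly
      ins0$ACL$femur[3] <- 0; ins0$ACL$tibia[3] <- 0
      ins0$PCL$femur[3] <- 0; ins0$PCL$tibia[3] <- 0
      ins0$LCL$femur <- ins0$MCL$femur * c(1, 1, -1)
      ins0$LCL$tibia <- ins0$MCL$tibia * c(1, 1, -1)
    }
    jit_pt <- function(p) jit_abs(p, jm)
    insertions <- ins0
    if (isTRUE(gc$symmetric)) {
      jf <- jit_pt(ins0$MCL$femur); jt <- jit_pt(ins0$MCL$tibia)
      insertions$MCL$femur <- jf; insertions$MCL$tibia <- jt
      insertions$LCL$femur <- jf * c(1, 1, -1)
      insertions$LCL$tibia <- jt * c(1, 1, -1)
      for (nm in c("ACL", "PCL")) {
        insertions[[nm]]$femur <- jit_pt(ins0[[nm]]$femur) * c(1, 1, 0)
        insertions[[nm]]$tibia <- jit_pt(ins0[[nm]]$tibia) * c(1, 1, 0)
      }
    } else {
      for (nm in names(ins0)) {
        insertions[[nm]]$femur <- jit_pt(ins0[[nm]]$femur)
        insertions[[nm]]$tibia <- jit_pt(ins0[[nm]]$tibia)
      }
    }

    # ---- contact columns ---------------------------------------------------
    slope <- tan(deg2rad(gc$plateau$posterior_slope_deg))
    off <- gc$compartment_offset
    one_compartment <- function(side, z_c, dish_R) {
      sp <- gc$column_spacing
      rx <- gc$plateau$rx; rz <- gc$plateau$rz
      xs <- seq(-rx, rx, by = sp)
      zs <- seq(-rz, rz, by = sp)
      g <- expand.grid(x = xs, dz = zs)
      rho <- sqrt((g$x / rx)^2 + (g$dz / rz)^2)
      keep <- rho <= 1
      g <- g[keep, ]; rho <- rho[keep]
      z <- z_c + g$dz
      y_dish <- (g$x^2 + g$dz^2) / (2 * dish_R)
      y_bone <- slope * g$x + y_dish
      h0 <- pmin(pmax(th_c - (th_c - th_e) * rho^2,
                      gc$cartilage$thickness_min), gc$cartilage$thickness_max)
      fi <- gc$meniscus$inner_frac
      men <- rho >= fi
      wedge <- ifelse(men, gc$meniscus$wedge_height * (rho - fi) / (1 - fi), 0)
      # outward surface normal from the bone surface gradient
      gx <- slope + g$x / dish_R
      gz <- g$dz / dish_R
      nn <- sqrt(gx^2 + gz^2 + 1)
      tibble::tibble(
        x = g$x, z = z,
        y_bone = y_bone, y_top = y_bone + h0 + wedge,
        h0 = h0, wedge = wedge,
        nx = -gx / nn, ny = 1 / nn, nz = -gz / nn,
        area = sp^2,
        tissue = ifelse(men, "meniscus", "cartilage"),
        compartment = side
      )
    }
    columns <- dplyr::bind_rows(
      one_compartment("medial", -off, dish_m),
      one_compartment("lateral", off, dish_l)
    )

    # ---- condyles ----------------------------------------------------------
    rp_femur <- c(0, gc$epicondyle$y, 0)
    place_condyle <- function(side, z_c, semi) {
      cols <- columns[columns$compartment == side, ]
      dx <- (cols$x - cx) / semi[1]
      dz <- (cols$z - z_c) / semi[3]
      s2 <- 1 - dx^2 - dz^2
      under <- s2 > 0
      if (!any(under)) stop("condyle footprint misses the plateau", call. = FALSE)
      need <- cols$y_top[under] + semi[2] * sqrt(s2[under])
      cy_fixed <- gc$condyle$center_y
      cy <- if (!is.null(cy_fixed) && !is.na(cy_fixed)) cy_fixed else
        max(need) + gc$initial_gap
      list(center = c(cx, cy, z_c), semi = semi)
    }
    condyles <- list(
      medial = place_condyle("medial", -off, semi_m),
      lateral = place_condyle("lateral", off, semi_l)
    )

    geomB <- structure(
      list(columns = columns, condyles = condyles, rp_femur = rp_femur,
           epicondyles = rbind(c(0, gc$epicondyle$y, -gc$epicondyle$z),
                               c(0, gc$epicondyle$y, gc$epicondyle$z)),
           insertions = insertions, patella = NULL, variant = "B",
           config = gc, seed = seed),
      class = "knee_geometry"
    )

    # reference-pose interpenetration check (only meaningful if center_y fixed)
    g0 <- geometry_gaps(geomB, q = rep(0, 6))
    if (min(g0, na.rm = TRUE) < -gc$gap_tolerance) {
      stop("condyle and plateau interpenetrate at the reference pose (",
           signif(min(g0, na.rm = TRUE), 4), " mm)", call. = FALSE)
    }

    pat <- gc$patella
    geomA <- geomB
    geomA$variant <- "A"
    geomA$patella <- list(
      ref = pat$ref, rp_quad = pat$rp_quad, tuberosity = pat$tuberosity,
      trochlea_center = pat$trochlea_center,
      trochlea_radius = pat$trochlea_radius,
      contact_stiffness = pat$contact_stiffness,
      regularization_stiffness = pat$regularization_stiffness,
      mpfl_femur = pat$mpfl_femur, lpfl_femur = pat$lpfl_femur
    )
    class(geomA) <- "knee_geometry"

    structure(list(A = geomA, B = geomB, seed = seed, config = gc),
              class = "knee_geometry_set")
  })
}

#' Vertical gaps between the posed femoral condyles and the contact columns
#'
#' For each column, the clearance (positive) or interpenetration (negative)
#' between the lower surface of the nearer posed condyle ellipsoid and the
#' column's undeformed top, measured along the vertical. Columns outside
#' both condyle footprints get `Inf`.
#'
#' @param geom A `knee_geometry`.
#' @param q Femur pose `(tx, ty, tz, fe, vv, ie)`, mm / radians.
#' @return Numeric vector of gaps (mm), one per column.
#' @export
geometry_gaps <- function(geom, q = rep(0, 6)) {
  cols <- geom$columns
  gap <- rep(Inf, nrow(cols))
  R <- cardan_matrix(q[4], q[5], q[6])
  for (cd in geom$condyles) {
    ctr <- as.numeric(pose_points(matrix(cd$center, 1), q, geom$rp_femur))
    Q <- R %*% diag(1 / cd$semi^2) %*% t(R)
    dx <- cols$x - ctr[1]
    dz <- cols$z - ctr[3]
    a <- Q[2, 2]
    b <- 2 * (Q[1, 2] * dx + Q[2, 3] * dz)
    cc <- Q[1, 1] * dx^2 + Q[3, 3] * dz^2 + 2 * Q[1, 3] * dx * dz - 1
    disc <- b^2 - 4 * a * cc
    hit <- disc > 0
    y_low <- rep(Inf, nrow(cols))
    y_low[hit] <- ctr[2] + (-b[hit] - sqrt(disc[hit])) / (2 * a)
    gap <- pmin(gap, y_low - cols$y_top)
  }
  gap
}

#' @export
print.knee_geometry_set <- function(x, ...) {
  cat("<knee_geometry_set> seed", x$seed, "\n")
  cat("  columns:", nrow(x$B$columns), "(",
      sum(x$B$columns$tissue == "meniscus"), "meniscal )\n")
  cat("  variants: A (patella mechanism), B (tibiofemoral only)\n")
  invisible(x)
}
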