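# Rigid-body pose of the femur relative to the tibia.
#
# Tibia-fixed, right-handed frame: +x anterior, +y proximal, +z lateral
# (modeled right knee). Rotations follow a Cardan sequence
# flexion-extension (about z) -> varus-valgus (about x) ->
# internal-external (about y), applied about the femoral reference point.

rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}

rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}

rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Cardan rotation matrix for a femur pose
#'
#' Builds the rotation matrix for the fixed Cardan sequence
#' flexion-extension (z) -> varus-valgus (x) -> internal-external (y).
#'
#' @param fe,vv,ie Rotations in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
cardan_matrix <- function(fe, vv, ie) {
  rot_z(fe) %*% rot_x(vv) %*% rot_y(ie)
}

# Pose vector convention used throughout the solver:
# q = (tx, ty, tz, fe, vv, ie); translations mm, rotations rad.
pose_names <- c("tx", "ty", "tz", "fe", "vv", "ie")

#' Transform femur-frame points to the tibia frame under a pose
#'
#' Points rotate about the femoral reference point `rp` and then translate.
#'
#' @param pts Numeric matrix (n x 3) of points in the femur reference frame
#'   (which coincides with the tibia frame at the reference pose).
#' @param q Pose vector `(tx, ty, tz, fe, vv, ie)`, mm and radians.
#' @param rp Femoral reference point (length-3), femur frame.
#' @return n x 3 matrix of posed points.
#' @keywords internal
pose_points <- function(pts, q, rp) {
  pts <- matrix(pts, ncol = 3)
  R <- cardan_matrix(q[4], q[5], q[6])
  centered <- sweep(pts, 2, rp)
  posed <- centered %*% t(R)
  sweep(posed, 2, rp + q[1:3], FUN = "+")
}
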