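#' Analytic proton-like beam model
#'
#' Each beam deposits `weight * L(r_perp) * Z(d)` at a point, where `L` is a
#' Gaussian in the perpendicular distance to the beam axis and `Z` is a 1-D
#' spread-out-Bragg-peak-like depth profile: a linear proximal ramp rising to
#' a plateau of height 1 over `[R - M, R]`, held at 1 up to the effective
#' range `R * range_scale`, then a half-logistic distal falloff. Depth is
#' measured along the beam direction with the beam isocenter placed at
#' mid-plateau (`d = R - M/2`), so an unshifted beam covers its target with
#' the flat part of the profile and the distal edge sits just beyond it.
#'
#' This is the simplest model whose DVH metrics respond to rigid setup
#' errors (through `L` and the plateau edges) and to fractional range
#' scaling (through the distal falloff) — the two handles the uncertainty
#' scenarios perturb. Heterogeneity, scatter and the nuclear halo are
#' deliberately ignored.
#'
#' @param direction unit 3-vector, beam travel direction in the patient frame.
#' @param isocenter 3-vector (mm), point the beam is aimed at.
#' @param nominal_range_mm depth R of the distal end of the plateau (mm).
#' @param modulation_mm plateau length M (mm), `0 <= M < R`.
#' @param lateral_sigma_mm Gaussian penumbra sigma (mm).
#' @param falloff_sigma_mm distal falloff steepness s (mm); the 50% depth is
#'   `R * range_scale + s * log(3) / 2`.
#' @param weight nonnegative beam weight (Gy at mid-plateau on axis).
#' @param entrance_fraction proximal ramp start value as a fraction of the
#'   plateau (typical SOBP entrance-to-plateau ratio).
#' @return an object of class `beam_spec`.
#' @export
beam_spec <- function(direction, isocenter, nominal_range_mm, modulation_mm,
                      lateral_sigma_mm, falloff_sigma_mm, weight = 1,
                      entrance_fraction = 0.7) {
  direction <- as.numeric(direction)
  if (length(direction) != 3L || abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("beam direction must be a unit 3-vector (|direction| = 1 within 1e-9)",
         call. = FALSE)
  if (!(nominal_range_mm > modulation_mm) || modulation_mm < 0)
    stop("need nominal_range_mm > modulation_mm >= 0", call. = FALSE)
  if (lateral_sigma_mm <= 0 || falloff_sigma_mm <= 0)
    stop("sigmas must be > 0", call. = FALSE)
  if (weight < 0) stop("weight must be nonnegative", call. = FALSE)
  structure(list(direction = direction, isocenter = as.numeric(isocenter),
                 nominal_range_mm = nominal_range_mm,
                 modulation_mm = modulation_mm,
                 lateral_sigma_mm = lateral_sigma_mm,
                 falloff_sigma_mm = falloff_sigma_mm,
                 weight = weight, entrance_fraction = entrance_fraction),
            class = "beam_spec")
}

#' A 6-DOF per-fraction setup error
#'
#' Translations are in mm along left-right (tx), anterior-posterior (ty) and
#' superior-inferior (tz); rotations are in degrees about the plan isocenter,
#' applied as intrinsic rotations in the order yaw (about z), pitch (about x),
#' roll (about y).
#'
#' @param tx,ty,tz translations (mm).
#' @param yaw,pitch,roll rotations (degrees), each in (-180, 180].
#' @return an object of class `fraction_shift`.
#' @export
fraction_shift <- function(tx = 0, ty = 0, tz = 0, yaw = 0, pitch = 0, roll = 0) {
  v <- c(tx = tx, ty = ty, tz = tz, yaw = yaw, pitch = pitch, roll = roll)
  if (any(!is.finite(v))) stop("shift components must be finite", call. = FALSE)
  if (any(v[4:6] <= -180 | v[4:6] > 180))
    stop("rotations must lie in (-180, 180] degrees", call. = FALSE)
  structure(as.list(v), class = "fraction_shift")
}

#' Rotation matrix of a 6-DOF shift
#'
#' Intrinsic yaw (z) -> pitch (x) -> roll (y); composed as
#' `Rz(yaw) %*% Rx(pitch) %*% Ry(roll)`.
#' @param shift a [fraction_shift()].
#' @return a 3 x 3 rotation matrix.
#' @export
shift_rotation_matrix <- function(shift) {
  d2r <- pi / 180
  cy <- cos(shift$yaw * d2r);  sy <- sin(shift$yaw * d2r)
  cp <- cos(shift$pitch * d2r); sp <- sin(shift$pitch * d2r)
  cr <- cos(shift$roll * d2r); sr <- sin(shift$roll * d2r)
  Rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cp, sp, 0, -sp, cp), 3, 3)
  Ry <- matrix(c(cr, 0, -sr, 0, 1, 0, sr, 0, cr), 3, 3)
  Rz %*% Rx %*% Ry
}

# depth profile Z(d); vectorized over d
depth_profile <- function(d, R, M, range_scale, s, p0) {
  R_eff <- R * range_scale
  plateau_start <- R - M
  base <- if (plateau_start > 0) {
    p0 + (1 - p0) * pmin(pmax(d / plateau_start, 0), 1)
  } else rep(1, length(d))
  distal <- ifelse(d <= R_eff, 1, 2 / (1 + exp(2 * (d - R_eff) / s)))
  base * distal
}

#' Evaluate the analytic dose at arbitrary points
#'
#' The setup error is applied as a rigid transform of the anatomy with beams
#' fixed: a point at patient coordinate `p` is evaluated at room coordinate
#' `Rmat (p - iso) + iso + t`. Dose is computed analytically at transformed
#' points, so there is no resampling/interpolation error.
#'
#' @param points N x 3 matrix of patient-frame positions (mm).
#' @param beams list of [beam_spec()]; an empty list yields zero dose.
#' @param shift a [fraction_shift()] (default: none).
#' @param range_scale multiplicative range perturbation, in `[0.8, 1.2]`.
#' @param isocenter plan isocenter (mm) about which rotations act.
#' @return numeric vector of doses (Gy), one per point.
#' @export
compute_dose_at <- function(points, beams, shift = fraction_shift(),
                            range_scale = 1, isocenter = c(0, 0, 0)) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  if (!inherits(shift, "fraction_shift")) stop("`shift` must be a fraction_shift")
  if (range_scale < 0.8 || range_scale > 1.2)
    stop("range_scale must lie in [0.8, 1.2]", call. = FALSE)
  dose <- numeric(nrow(points))
  if (length(beams) == 0L) return(dose)
  Rmat <- shift_rotation_matrix(shift)
  tvec <- c(shift$tx, shift$ty, shift$tz)
  y <- sweep(sweep(points, 2, isocenter) %*% t(Rmat), 2, isocenter + tvec, "+")
  for (b in beams) {
    if (!inherits(b, "beam_spec")) stop("beams must be beam_spec objects")
    if (b$weight == 0) next
    v <- sweep(y, 2, b$isocenter)
    dal <- drop(v %*% b$direction)
    d <- dal + b$nominal_range_mm - b$modulation_mm / 2
    r2 <- pmax(rowSums(v^2) - dal^2, 0)
    L <- exp(-r2 / (2 * b$lateral_sigma_mm^2))
    Z <- depth_profile(d, b$nominal_range_mm, b$modulation_mm, range_scale,
                       b$falloff_sigma_mm, b$entrance_fraction)
    dose <- dose + b$weight * L * Z
  }
  dose
}

#' Compute a dose grid for a phantom
#'
#' @param phantom an [build_phantom()] result.
#' @param beams list of [beam_spec()].
#' @inheritParams compute_dose_at
#' @return numeric array of doses (Gy) with `dim = phantom$grid$shape`.
#' @export
compute_dose <- function(phantom, beams, shift = fraction_shift(),
                         range_scale = 1, isocenter = c(0, 0, 0)) {
  stopifnot(inherits(phantom, "rt_phantom"))
  d <- compute_dose_at(voxel_centers(phantom$grid), beams, shift, range_scale,
                       isocenter)
  array(d, dim = phantom$grid$shape)
}

#' Normalize a plan to its primary prescription
#'
#' Rescales all beam weights by one global factor so that the nominal
#' (zero-shift, unit range scale) D95 of the primary target equals its
#' prescription. Since dose is linear in the weights the post-normalization
#' D95 is exact up to floating point.
#'
#' @param phantom an `rt_phantom`.
#' @param beams list of [beam_spec()].
#' @param primary the primary target [rt_structure()] (defaults to the
#'   phantom's `primary_target` structure).
#' @param isocenter plan isocenter (mm).
#' @return list(beams, scale): the rescaled beams and the factor applied.
#' @export
normalize_plan <- function(phantom, beams, primary = NULL,
                           isocenter = c(0, 0, 0)) {
  if (is.null(primary)) {
    roles <- vapply(phantom$structures, function(s) s$role, character(1))
    primary <- phantom$structures[[which(roles == "primary_target")[1]]]
  }
  pts <- voxel_centers(phantom$grid)[as.vector(primary$mask), , drop = FALSE]
  nominal <- compute_dose_at(pts, beams, isocenter = isocenter)
  if (all(nominal == 0))
    stop("normalization error: nominal dose is zero on the primary target",
         call. = FALSE)
  d95 <- d_at_volume_values(nominal, 95)
  scale <- primary$prescription_Gy / d95
  beams <- lapply(beams, function(b) { b$weight <- b$weight * scale; b })
  list(beams = beams, scale = scale)
}
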