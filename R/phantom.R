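#' Structures and synthetic phantoms
#'
#' A `rt_structure` couples a name, an analysis role and a binary voxel mask.
#' Targets carry a prescription dose (the D_Rx used to scale fractional dose
#' deviations) and are assessed with D95/V100; organs at risk (OARs) are
#' assessed with their max or mean dose.
#'
#' @param name structure name.
#' @param role one of `"primary_target"`, `"secondary_target"`, `"oar"`.
#' @param mask logical/0-1 array on the phantom grid; must be nonempty.
#' @param prescription_Gy prescription dose in Gy; required (> 0) for targets,
#'   must be absent/NA for OARs.
#' @param metric_kind `"target_D95_V100"` (forced for targets), `"oar_max"`
#'   or `"oar_mean"`.
#' @return an object of class `rt_structure`.
#' @export
rt_structure <- function(name, role, mask, prescription_Gy = NA_real_,
                         metric_kind = NULL) {
  role <- match.arg(role, c("primary_target", "secondary_target", "oar"))
  is_target <- role != "oar"
  if (is.null(metric_kind))
    metric_kind <- if (is_target) "target_D95_V100" else "oar_max"
  metric_kind <- match.arg(metric_kind, c("target_D95_V100", "oar_max", "oar_mean"))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask))
    stop(sprintf("structure '%s' has an empty mask at this grid resolution", name),
         call. = FALSE)
  if (is_target) {
    if (!isTRUE(prescription_Gy > 0))
      stop(sprintf("target '%s' requires prescription_Gy > 0", name), call. = FALSE)
    if (metric_kind != "target_D95_V100")
      stop("targets use metric_kind 'target_D95_V100'", call. = FALSE)
  } else if (isTRUE(prescription_Gy > 0)) {
    stop(sprintf("OAR '%s' must not carry a prescription", name), call. = FALSE)
  }
  structure(list(name = name, role = role, mask = mask,
                 prescription_Gy = prescription_Gy, metric_kind = metric_kind),
            class = "rt_structure")
}

# point-in-solid predicates, vectorized over an N x 3 matrix of mm points
solid_ellipsoid <- function(p, center, radii) {
  rowSums(sweep(sweep(p, 2, center), 2, radii, "/")^2) <= 1
}

solid_zcylinder <- function(p, center, radius, half_length) {
  dx <- p[, 1] - center[1]; dy <- p[, 2] - center[2]; dz <- p[, 3] - center[3]
  (dx^2 + dy^2 <= radius^2) & (abs(dz) <= half_length)
}

# capsule along z: cylinder with hemispherical caps
solid_zcapsule <- function(p, center, radius, half_length) {
  dx <- p[, 1] - center[1]; dy <- p[, 2] - center[2]; dz <- p[, 3] - center[3]
  dzc <- pmax(abs(dz) - half_length, 0)
  dx^2 + dy^2 + dzc^2 <= radius^2
}

mask_from_predicate <- function(grid, pred) {
  inside <- pred(voxel_centers(grid))
  array(inside, dim = grid$shape)
}

#' Build a synthetic head-and-neck phantom
#'
#' Constructs a voxel phantom emulating the geometry that drives setup/range
#' sensitivity in head-and-neck proton plans: a compact primary CTV centred
#' at the isocenter, optionally an elongated superior-inferior nodal CTV
#' offset laterally (a capsule standing in for a nodal chain), a posterior
#' cord-like cylindrical OAR (max-dose metric) and two lateral parotid-like
#' ellipsoidal OARs (mean-dose metric).
#'
#' @param config list with elements:
#'   \describe{
#'     \item{grid}{list(shape, spacing, origin?) passed to [grid_spec()].}
#'     \item{primary}{list(name?, center, radii, prescription_Gy).}
#'     \item{secondary}{optional list(name?, center, radius, half_length,
#'       prescription_Gy); omit or NULL for a primary-only phantom.}
#'     \item{oars}{optional list of lists(name, shape = "ellipsoid"|"zcylinder",
#'       center, radii or radius/half_length, metric = "max"|"mean").}
#'   }
#' @return an object of class `rt_phantom`: list(grid, structures) where
#'   structures is a named list of [rt_structure()].
#' @export
build_phantom <- function(config) {
  g <- config$grid
  grid <- grid_spec(g$shape, g$spacing, g$origin)

  structures <- list()
  p <- config$primary
  if (is.null(p)) stop("config must specify a primary target", call. = FALSE)
  pm <- mask_from_predicate(grid, function(pt) solid_ellipsoid(pt, p$center, p$radii))
  if (!any(pm))
    stop(sprintf("structure '%s' is empty at this grid resolution",
                 p$name %||% "CTV_primary"), call. = FALSE)
  structures[[1]] <- rt_structure(p$name %||% "CTV_primary", "primary_target",
                                  pm, p$prescription_Gy)

  s <- config$secondary
  if (!is.null(s)) {
    sm <- mask_from_predicate(grid, function(pt)
      solid_zcapsule(pt, s$center, s$radius, s$half_length))
    if (!any(sm))
      stop(sprintf("structure '%s' is empty at this grid resolution",
                   s$name %||% "CTV_nodal"), call. = FALSE)
    structures[[length(structures) + 1L]] <-
      rt_structure(s$name %||% "CTV_nodal", "secondary_target", sm,
                   s$prescription_Gy)
  }

  for (o in config$oars %||% list()) {
    om <- switch(o$shape %||% "ellipsoid",
      ellipsoid = mask_from_predicate(grid, function(pt)
        solid_ellipsoid(pt, o$center, o$radii)),
      zcylinder = mask_from_predicate(grid, function(pt)
        solid_zcylinder(pt, o$center, o$radius, o$half_length)),
      stop("unknown OAR shape: ", o$shape, call. = FALSE))
    if (!any(om))
      stop(sprintf("structure '%s' is empty at this grid resolution", o$name),
           call. = FALSE)
    structures[[length(structures) + 1L]] <-
      rt_structure(o$name, "oar", om,
                   metric_kind = paste0("oar_", o$metric %||% "max"))
  }

  names(structures) <- vapply(structures, function(s) s$name, character(1))
  structure(list(grid = grid, structures = structures), class = "rt_phantom")
}

#' @export
print.rt_phantom <- function(x, ...) {
  cat("rt_phantom:\n"); print(x$grid)
  for (s in x$structures)
    cat(sprintf("  %-14s %-16s %6d voxels%s\n", s$name, s$role, sum(s$mask),
                if (s$role != "oar") sprintf("  Rx %.1f Gy", s$prescription_Gy) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
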