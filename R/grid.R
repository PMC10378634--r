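#' Voxel grid geometry
#'
#' A `grid_spec` describes a regular 3-D voxel grid in the patient frame:
#' x = left-right, y = anterior-posterior, z = superior-inferior, all in mm.
#' `origin` is the position of the centre of voxel (1,1,1).
#'
#' @param shape integer vector of length 3, number of voxels per axis (>= 1).
#' @param spacing numeric vector of length 3, voxel spacing in mm (> 0).
#' @param origin numeric vector of length 3, mm position of the first voxel
#'   centre. Default centres the grid on the coordinate origin.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 integers >= 1", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  if (is.null(origin)) origin <- -(shape - 1L) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel-centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return an N x 3 matrix of voxel-centre positions (mm), N = prod(shape),
#'   rows in R array order (first index fastest).
#' @export
voxel_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g)
  dimnames(m) <- NULL
  m
}

#' @rdname voxel_centers
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

grids_identical <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Write / read a scalar grid as plain text
#'
#' Dose grids and masks are stored in a two-file plain-text format: a JSON
#' header (`<path>.json`) carrying shape/spacing/origin and the value kind,
#' and a flat one-value-per-line table (`<path>.txt`) in R array order
#' (first index fastest). This keeps the pipeline dependency-light and
#' byte-reproducible.
#'
#' @param values numeric array with `dim == grid$shape` (or a vector of
#'   length `prod(grid$shape)`).
#' @param grid a [grid_spec()].
#' @param path file stem; `.json` and `.txt` are appended.
#' @param kind free-text value kind recorded in the header
#'   (e.g. "dose_Gy", "mask").
#' @return `write_grid_text()` returns `path` invisibly; `read_grid_text()`
#'   returns a list with `grid`, `values` (array) and `kind`.
#' @export
write_grid_text <- function(values, grid, path, kind = "dose_Gy") {
  stopifnot(inherits(grid, "grid_spec"))
  v <- as.numeric(values)
  if (length(v) != prod(grid$shape))
    stop("values length does not match grid shape", call. = FALSE)
  hdr <- list(format = "rtrobust-grid-v1", kind = kind,
              shape = grid$shape, spacing = grid$spacing, origin = grid$origin)
  jsonlite::write_json(hdr, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(sprintf("%.17g", v), paste0(path, ".txt"))
  invisible(path)
}

#' @rdname write_grid_text
#' @export
read_grid_text <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(hdr$format, "rtrobust-grid-v1"))
    stop("not an rtrobust grid header: ", path, call. = FALSE)
  grid <- grid_spec(hdr$shape, hdr$spacing, hdr$origin)
  v <- as.numeric(readLines(paste0(path, ".txt")))
  if (length(v) != prod(grid$shape))
    stop("grid value table length mismatch in ", path, call. = FALSE)
  list(grid = grid, values = array(v, dim = grid$shape), kind = hdr$kind)
}
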