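#' Daily setup-error distribution
#'
#' Per-axis independent Gaussians for the six degrees of freedom of a daily
#' setup error. Translation SDs are in mm, rotation SDs in degrees.
#'
#' @param sd_trans_mm length-3 (or scalar) SDs for tx, ty, tz.
#' @param sd_rot_deg length-3 (or scalar) SDs for yaw, pitch, roll.
#' @param mean_trans_mm,mean_rot_deg per-axis means (default 0).
#' @return an object of class `shift_distribution`.
#' @export
shift_distribution <- function(sd_trans_mm = c(2, 2, 2),
                               sd_rot_deg = c(1, 1, 1),
                               mean_trans_mm = c(0, 0, 0),
                               mean_rot_deg = c(0, 0, 0)) {
  rep3 <- function(v) if (length(v) == 1L) rep(as.numeric(v), 3) else as.numeric(v)
  d <- list(sd_trans_mm = rep3(sd_trans_mm), sd_rot_deg = rep3(sd_rot_deg),
            mean_trans_mm = rep3(mean_trans_mm), mean_rot_deg = rep3(mean_rot_deg))
  if (any(vapply(d, length, 1L) != 3L)) stop("axis parameters must have length 3")
  if (any(d$sd_trans_mm < 0) || any(d$sd_rot_deg < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(d, class = "shift_distribution")
}

#' Sample daily 6-DOF setup errors
#'
#' @param n number of fractions (>= 1).
#' @param dist a [shift_distribution()].
#' @param seed optional integer; when given, sampling is wrapped in a local
#'   RNG scope so the caller's RNG state is untouched and the draw is
#'   reproducible.
#' @return a list of `n` [fraction_shift()] objects.
#' @export
sample_fraction_shifts <- function(n, dist, seed = NULL) {
  if (!isTRUE(n >= 1)) stop("n must be >= 1", call. = FALSE)
  stopifnot(inherits(dist, "shift_distribution"))
  draw <- function() {
    tr <- stats::rnorm(3, dist$mean_trans_mm, dist$sd_trans_mm)
    ro <- stats::rnorm(3, dist$mean_rot_deg, dist$sd_rot_deg)
    fraction_shift(tr[1], tr[2], tr[3], yaw = ro[1], pitch = ro[2], roll = ro[3])
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  replicate(n, draw(), simplify = FALSE)
}

#' Translational magnitude of a setup error
#'
#' Euclidean norm of the (tx, ty, tz) translations in mm. Rotations are
#' excluded: mixing degrees and millimetres in one norm is dimensionally
#' unsound, and reported combined shift statistics do not state a conversion.
#'
#' @param shift a [fraction_shift()].
#' @return scalar magnitude (mm).
#' @export
shift_magnitude <- function(shift) {
  sqrt(shift$tx^2 + shift$ty^2 + shift$tz^2)
}

shifts_to_df <- function(shifts, patient = NA_character_) {
  data.frame(
    patient = patient,
    fraction = seq_along(shifts),
    tx_mm = vapply(shifts, `[[`, 0, "tx"),
    ty_mm = vapply(shifts, `[[`, 0, "ty"),
    tz_mm = vapply(shifts, `[[`, 0, "tz"),
    yaw_deg = vapply(shifts, `[[`, 0, "yaw"),
    roll_deg = vapply(shifts, `[[`, 0, "roll"),
    pitch_deg = vapply(shifts, `[[`, 0, "pitch"),
    stringsAsFactors = FALSE
  )
}

#' Write / read a per-fraction shift log
#'
#' CSV with header `patient,fraction,tx_mm,ty_mm,tz_mm,yaw_deg,roll_deg,pitch_deg`.
#'
#' @param log data.frame with the columns above (as produced by [run_cohort()]).
#' @param path CSV path.
#' @return `read_shift_log()` returns the data.frame; rows are validated and
#'   per-patient fraction indices are checked for gaps.
#' @export
write_shift_log <- function(log, path) {
  cols <- c("patient", "fraction", "tx_mm", "ty_mm", "tz_mm",
            "yaw_deg", "roll_deg", "pitch_deg")
  stopifnot(all(cols %in% names(log)))
  utils::write.csv(log[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shift_log
#' @export
read_shift_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("patient", "fraction", "tx_mm", "ty_mm", "tz_mm",
            "yaw_deg", "roll_deg", "pitch_deg")
  if (!all(cols %in% names(log)))
    stop("shift log is missing columns: ",
         paste(setdiff(cols, names(log)), collapse = ", "), call. = FALSE)
  for (p in unique(log$patient)) {
    fr <- sort(log$fraction[log$patient == p])
    want <- seq_len(max(fr))
    gaps <- setdiff(want, fr)
    if (length(gaps))
      stop(sprintf("shift log gap: patient %s missing fraction(s) %s",
                   p, paste(gaps, collapse = ", ")), call. = FALSE)
  }
  log
}

shift_from_row <- function(row) {
  fraction_shift(row$tx_mm, row$ty_mm, row$tz_mm,
                 yaw = row$yaw_deg, pitch = row$pitch_deg, roll = row$roll_deg)
}
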