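#' Dose-volume histogram metrics
#'
#' All metrics are computed directly from the list of voxel doses inside a
#' structure mask (every voxel carries equal weight on a uniform grid); the
#' binned cumulative curve exists only for plotting and export.
#'
#' Conventions, stated once and pinned by tests:
#' * `d_at_volume(p)` is the largest dose d such that at least p% of voxels
#'   receive >= d, linearly interpolated between the descending order
#'   statistics bracketing the fractional rank `p * N / 100`.
#' * `v_at_dose(t)` counts voxels with dose >= t (ties covered), no
#'   partial-voxel interpolation.
#' * `Dmax` is the single hottest voxel (no D0.03cc smoothing).
#' @name dvh
NULL

mask_doses <- function(dose, mask, name = "structure") {
  if (is.null(mask) || !any(mask))
    stop(sprintf("empty mask for '%s'", name), call. = FALSE)
  as.numeric(dose[as.logical(mask)])
}

# rank-interpolated dose at volume, on a bare dose vector
d_at_volume_values <- function(doses, p_pct) {
  if (!(p_pct > 0 && p_pct <= 100)) stop("p_pct must lie in (0, 100]", call. = FALSE)
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  r <- p_pct * n / 100
  if (r <= 1) return(s[1])
  k <- floor(r)
  if (k >= n) return(s[n])
  frac <- r - k
  if (frac == 0) s[k] else s[k] + frac * (s[k + 1] - s[k])
}

#' @describeIn dvh dose (Gy) received by at least `p_pct` percent of the
#'   structure volume; `D95 = d_at_volume(dose, mask, 95)`.
#' @param dose numeric dose array/vector (Gy).
#' @param mask logical mask conformal with `dose`.
#' @param p_pct volume percentage in (0, 100].
#' @export
d_at_volume <- function(dose, mask, p_pct, name = "structure") {
  d_at_volume_values(mask_doses(dose, mask, name), p_pct)
}

#' @describeIn dvh percent of the structure volume receiving at least
#'   `threshold_Gy`; `V100 = v_at_dose(dose, mask, prescription)`.
#' @param threshold_Gy dose threshold (Gy), >= 0.
#' @export
v_at_dose <- function(dose, mask, threshold_Gy, name = "structure") {
  if (threshold_Gy < 0) stop("threshold must be >= 0", call. = FALSE)
  d <- mask_doses(dose, mask, name)
  100 * sum(d >= threshold_Gy) / length(d)
}

#' @describeIn dvh OAR summary dose: `kind = "max"` for the hottest voxel,
#'   `"mean"` for the arithmetic mean over the mask.
#' @param kind `"max"` or `"mean"`.
#' @export
oar_metric <- function(dose, mask, kind = c("max", "mean"), name = "structure") {
  kind <- match.arg(kind)
  d <- mask_doses(dose, mask, name)
  if (kind == "max") max(d) else mean(d)
}

#' @describeIn dvh all four scalar metrics at once; returns a list with
#'   `D95_Gy`, `V100_pct` (needs `prescription_Gy`), `Dmax_Gy`, `Dmean_Gy`.
#' @param prescription_Gy prescription used as the V100 threshold; NA skips V100.
#' @export
dvh_metrics <- function(dose, mask, prescription_Gy = NA_real_,
                        name = "structure") {
  d <- mask_doses(dose, mask, name)
  list(
    D95_Gy = d_at_volume_values(d, 95),
    V100_pct = if (is.na(prescription_Gy)) NA_real_
               else 100 * sum(d >= prescription_Gy) / length(d),
    Dmax_Gy = max(d),
    Dmean_Gy = mean(d)
  )
}

#' Cumulative DVH curve
#'
#' Volume-weighted cumulative histogram: for each dose edge, the percent of
#' structure volume receiving at least that dose. Edges run from 0 to just
#' above Dmax in steps of `bin_width_Gy`.
#'
#' @inheritParams d_at_volume
#' @param bin_width_Gy histogram bin width (> 0).
#' @return list(dose_edges, cumulative_volume_pct) of equal length.
#' @export
cumulative_dvh <- function(dose, mask, bin_width_Gy = 0.1, name = "structure") {
  if (!(bin_width_Gy > 0)) stop("bin_width_Gy must be > 0", call. = FALSE)
  d <- mask_doses(dose, mask, name)
  edges <- seq(0, max(d) + bin_width_Gy, by = bin_width_Gy)
  vol <- vapply(edges, function(e) 100 * sum(d >= e) / length(d), numeric(1))
  list(dose_edges = edges, cumulative_volume_pct = vol)
}

#' Export DVH curves as CSV
#'
#' Long format with header `structure,dose_Gy,volume_pct`.
#'
#' @param curves named list of [cumulative_dvh()] results.
#' @param path CSV path.
#' @export
write_dvh_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(names(curves), function(nm) {
    c <- curves[[nm]]
    data.frame(structure = nm, dose_Gy = c$dose_edges,
               volume_pct = c$cumulative_volume_pct)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
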