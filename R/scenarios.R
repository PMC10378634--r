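#' Setup/range uncertainty scenarios
#'
#' Robust evaluation perturbs the plan by rigid isocenter shifts of magnitude
#' S (the setup uncertainty) and by multiplicative range scaling 1 +/- delta
#' (the range uncertainty). The default scenario set is the common
#' 21-scenario treatment-planning-system convention: the Cartesian product of
#' the 7 shift vectors {0, +/-S x, +/-S y, +/-S z} with the 3 range scales
#' {1-delta, 1, 1+delta}. Two variants are selectable: `"reduced15"` pairs
#' the 7 shifts with the two extreme range scales only, plus the nominal
#' scenario; `"corners27"` uses 26 corner/axis shift directions (each
#' normalized to magnitude S) plus zero, times the 3 range scales.
#' Rotational uncertainty is not part of scenario bands; rotations enter only
#' through daily fraction errors.
#'
#' @param S_mm setup uncertainty magnitude (mm), >= 0.
#' @param range_delta relative range uncertainty, in [0, 0.2].
#' @param variant scenario-set variant.
#' @return a data.frame with columns `sx, sy, sz` (mm) and `range_scale`;
#'   duplicated scenarios (e.g. at S = 0) are removed; the nominal scenario
#'   is always the first row.
#' @export
enumerate_scenarios <- function(S_mm, range_delta = 0.035,
                                variant = c("product21", "reduced15", "corners27")) {
  variant <- match.arg(variant)
  if (S_mm < 0) stop("S_mm must be >= 0", call. = FALSE)
  if (range_delta < 0 || range_delta > 0.2)
    stop("range_delta must lie in [0, 0.2]", call. = FALSE)

  axis_shifts <- rbind(c(0, 0, 0),
                       S_mm * rbind(diag(3), -diag(3)))
  scales <- c(1 - range_delta, 1, 1 + range_delta)

  sc <- switch(variant,
    product21 = {
      g <- expand.grid(i = seq_len(nrow(axis_shifts)), s = scales)
      cbind(axis_shifts[g$i, , drop = FALSE], g$s)
    },
    reduced15 = {
      g <- expand.grid(i = seq_len(nrow(axis_shifts)),
                       s = c(1 - range_delta, 1 + range_delta))
      rbind(c(0, 0, 0, 1), cbind(axis_shifts[g$i, , drop = FALSE], g$s))
    },
    corners27 = {
      dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
      dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
      dirs <- dirs / sqrt(rowSums(dirs^2))
      shifts <- rbind(c(0, 0, 0), S_mm * dirs)
      g <- expand.grid(i = seq_len(nrow(shifts)), s = scales)
      cbind(shifts[g$i, , drop = FALSE], g$s)
    })

  df <- data.frame(sx = sc[, 1], sy = sc[, 2], sz = sc[, 3], range_scale = sc[, 4])
  nominal <- with(df, sx == 0 & sy == 0 & sz == 0 & range_scale == 1)
  df <- rbind(df[nominal, ][1, ], df[!nominal, ])
  df <- df[!duplicated(df), ]
  rownames(df) <- NULL
  df
}

metric_value <- function(dose_values, st) {
  switch(st$metric_kind,
    target_D95_V100 = list(
      D95 = d_at_volume_values(dose_values, 95),
      V100 = 100 * mean(dose_values >= st$prescription_Gy)),
    oar_max = list(Dmax = max(dose_values)),
    oar_mean = list(Dmean = mean(dose_values)))
}

#' Robustness band of a metric over uncertainty scenarios
#'
#' Evaluates a structure's metric(s) under every scenario (dose recomputed
#' analytically at the structure's voxels under the scenario shift and range
#' scale) and returns the min-max envelope plus the nominal value. The
#' nominal scenario must be in the set, so `band_min <= nominal <= band_max`
#' by construction.
#'
#' @param phantom an `rt_phantom`.
#' @param beams normalized beam list.
#' @param st an [rt_structure()].
#' @param scenarios data.frame from [enumerate_scenarios()].
#' @param setup_mm the setup uncertainty S the scenarios encode (bookkeeping).
#' @param isocenter plan isocenter.
#' @return data.frame with one row per metric for the structure:
#'   `structure, metric, setup_mm, band_min, band_max, nominal`.
#' @export
compute_band <- function(phantom, beams, st, scenarios, setup_mm = NA_real_,
                         isocenter = c(0, 0, 0)) {
  if (nrow(scenarios) < 1) stop("scenarios must be nonempty", call. = FALSE)
  if (!any(scenarios$sx == 0 & scenarios$sy == 0 & scenarios$sz == 0 &
           scenarios$range_scale == 1))
    stop("scenario set must include the nominal scenario", call. = FALSE)
  pts <- voxel_centers(phantom$grid)[as.vector(st$mask), , drop = FALSE]
  vals <- NULL
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    sh <- fraction_shift(sc$sx, sc$sy, sc$sz)
    d <- compute_dose_at(pts, beams, sh, sc$range_scale, isocenter)
    m <- unlist(metric_value(d, st))
    vals <- rbind(vals, m)
  }
  nominal_i <- which(scenarios$sx == 0 & scenarios$sy == 0 &
                     scenarios$sz == 0 & scenarios$range_scale == 1)[1]
  data.frame(
    structure = st$name, metric = colnames(vals), setup_mm = setup_mm,
    band_min = apply(vals, 2, min), band_max = apply(vals, 2, max),
    nominal = vals[nominal_i, ], row.names = NULL, stringsAsFactors = FALSE)
}

#' Bands for every structure of a plan
#'
#' @inheritParams compute_band
#' @param setups vector of setup uncertainties S (mm), e.g. `c(3, 5)`.
#' @param range_delta relative range uncertainty.
#' @param variant scenario-set variant, see [enumerate_scenarios()].
#' @return row-bound data.frame of [compute_band()] results for all
#'   structures at all setup settings.
#' @export
compute_bands <- function(phantom, beams, setups = c(3, 5), range_delta = 0.035,
                          variant = "product21", isocenter = c(0, 0, 0)) {
  out <- NULL
  for (S in setups) {
    scen <- enumerate_scenarios(S, range_delta, variant)
    for (st in phantom$structures)
      out <- rbind(out, compute_band(phantom, beams, st, scen, S, isocenter))
  }
  out
}

#' Band membership of a value
#'
#' Closed-interval comparison: values exactly on a bound count as inside.
#'
#' @param value metric value.
#' @param band_min,band_max band bounds (`band_min <= band_max`).
#' @return `"inside"`, `"below"` or `"above"`.
#' @export
within_band <- function(value, band_min, band_max) {
  if (band_min > band_max) stop("invalid band: band_min > band_max", call. = FALSE)
  if (value < band_min) "below" else if (value > band_max) "above" else "inside"
}

#' Export a band table as CSV
#'
#' Header `patient,structure,metric,setup_mm,band_min,band_max,nominal`.
#' @param bands band data.frame carrying a `patient` column.
#' @param path CSV path.
#' @export
write_band_csv <- function(bands, path) {
  cols <- c("patient", "structure", "metric", "setup_mm",
            "band_min", "band_max", "nominal")
  utils::write.csv(bands[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
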