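#' Fractional dose deviation (percent of prescription)
#'
#' How far a fraction's D95 falls outside its robustness band, as a percent
#' of the target prescription: 0 inside the closed band, otherwise
#' `100 * max(D_fx - D_Rmax, D_Rmin - D_fx) / D_Rx`. The deviation is a
#' nonnegative magnitude: for any out-of-band value exactly one of the two
#' arguments is positive, and in-band values clamp to zero.
#'
#' @param D_fx fraction D95 (Gy).
#' @param D_Rmin,D_Rmax band bounds (Gy), `D_Rmin <= D_Rmax`.
#' @param D_Rx prescription (Gy), > 0.
#' @return deviation in percent of prescription (>= 0).
#' @export
fractional_dose_deviation <- function(D_fx, D_Rmin, D_Rmax, D_Rx) {
  if (!isTRUE(D_Rx > 0)) stop("prescription D_Rx must be > 0", call. = FALSE)
  if (D_Rmin > D_Rmax) stop("invalid band: D_Rmin > D_Rmax", call. = FALSE)
  100 * max(D_fx - D_Rmax, D_Rmin - D_fx, 0) / D_Rx
}

#' Fractional volumetric deviation (percentage points)
#'
#' How far a fraction's V100 falls outside its robustness band, in
#' percentage points of volume: 0 inside the closed band, otherwise the
#' positive excursion beyond the nearest violated bound.
#'
#' @param V_fx fraction V100 (percent).
#' @param V_Rmin,V_Rmax band bounds (percent), `V_Rmin <= V_Rmax`.
#' @return deviation in percentage points (>= 0).
#' @export
fractional_volume_deviation <- function(V_fx, V_Rmin, V_Rmax) {
  vals <- c(V_fx, V_Rmin, V_Rmax)
  if (any(vals < 0 | vals > 100))
    stop("volume values must lie in [0, 100] percent", call. = FALSE)
  if (V_Rmin > V_Rmax) stop("invalid band: V_Rmin > V_Rmax", call. = FALSE)
  max(V_fx - V_Rmax, V_Rmin - V_fx, 0)
}

# band rows for one structure/metric/setup; errors if missing
band_row <- function(bands, structure, metric, setup_mm) {
  r <- bands[bands$structure == structure & bands$metric == metric &
             bands$setup_mm == setup_mm, ]
  if (nrow(r) != 1L)
    stop(sprintf("missing band for %s/%s at %g mm", structure, metric, setup_mm),
         call. = FALSE)
  r
}

#' Evaluate one treatment fraction against robustness bands
#'
#' Recomputes the fraction's dose with the full 6-DOF daily setup error at
#' unit range scale (range error is a planning uncertainty, not a daily
#' observable here), extracts every structure's metric(s), and emits one
#' record per structure/metric/setup setting. Target deviations use the
#' prescription-scaled dose rule for D95 and percentage points for V100;
#' OAR excursions are reported in Gy beyond the violated bound.
#'
#' @param phantom an `rt_phantom`.
#' @param beams normalized beams.
#' @param bands band table from [compute_bands()].
#' @param shift the fraction's [fraction_shift()].
#' @param setups setup settings (mm) to judge against.
#' @param isocenter plan isocenter.
#' @return data.frame with columns `structure, metric, setup_mm, value,
#'   band_min, band_max, status, deviation`.
#' @export
evaluate_fraction <- function(phantom, beams, bands, shift, setups = c(3, 5),
                              isocenter = c(0, 0, 0)) {
  vox <- voxel_centers(phantom$grid)
  out <- NULL
  for (st in phantom$structures) {
    pts <- vox[as.vector(st$mask), , drop = FALSE]
    d <- compute_dose_at(pts, beams, shift, range_scale = 1, isocenter)
    mv <- unlist(metric_value(d, st))
    for (metric in names(mv)) {
      for (S in setups) {
        b <- band_row(bands, st$name, metric, S)
        status <- within_band(mv[[metric]], b$band_min, b$band_max)
        dev <- if (metric == "D95") {
          fractional_dose_deviation(mv[[metric]], b$band_min, b$band_max,
                                    st$prescription_Gy)
        } else if (metric == "V100") {
          fractional_volume_deviation(mv[[metric]], b$band_min, b$band_max)
        } else {
          max(mv[[metric]] - b$band_max, b$band_min - mv[[metric]], 0)
        }
        out <- rbind(out, data.frame(
          structure = st$name, metric = metric, setup_mm = S,
          value = mv[[metric]], band_min = b$band_min, band_max = b$band_max,
          status = status, deviation = dev, stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

tier_of <- function(role) {
  c(primary_target = "primary", secondary_target = "secondary", oar = "oar")[role]
}

#' Summarize deviation records
#'
#' Aggregates per-fraction records by arbitrary grouping columns (typically
#' class, target tier and setup setting): the percent of records outside
#' their band, the percent below band for targets, and the mean/min/max
#' deviation over out-of-band records only (out-of-band averaging is the
#' reporting convention; set `include_zeros = TRUE` to average over all
#' records instead, for sensitivity analysis). Groups with no out-of-band
#' record report 0 deviation with `n_outside = 0`.
#'
#' @param records data.frame of deviation records (needs `status` and
#'   `deviation`; grouping columns as named in `by`).
#' @param by character vector of grouping column names.
#' @param include_zeros average deviations over all records, not just
#'   out-of-band ones.
#' @return one row per group: `n, n_outside, pct_outside, pct_below,
#'   mean_deviation, min_deviation, max_deviation`.
#' @export
summarize_deviations <- function(records, by = c("class", "tier", "setup_mm"),
                                 include_zeros = FALSE) {
  if (nrow(records) == 0) stop("no records to summarize", call. = FALSE)
  miss <- setdiff(by, names(records))
  if (length(miss)) stop("missing grouping columns: ", paste(miss, collapse = ", "))
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  out <- NULL
  for (k in levels(key)) {
    g <- records[key == k, ]
    outside <- g$status != "inside"
    devs <- if (include_zeros) g$deviation else g$deviation[outside]
    row <- cbind(
      g[1, by, drop = FALSE],
      data.frame(
        n = nrow(g), n_outside = sum(outside),
        pct_outside = 100 * mean(outside),
        pct_below = 100 * mean(g$status == "below"),
        mean_deviation = if (length(devs)) mean(devs) else 0,
        min_deviation = if (length(devs)) min(devs) else 0,
        max_deviation = if (length(devs)) max(devs) else 0))
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Export per-fraction deviation records as CSV
#'
#' Header `patient,fraction,structure,metric,setup_mm,value,band_min,band_max,status,deviation`.
#' @param records record data.frame carrying `patient` and `fraction`.
#' @param path CSV path.
#' @export
write_record_csv <- function(records, path) {
  cols <- c("patient", "fraction", "structure", "metric", "setup_mm",
            "value", "band_min", "band_max", "status", "deviation")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
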