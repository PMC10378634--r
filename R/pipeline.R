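#' FNV-1a hash of a configuration
#'
#' 32-bit FNV-1a over the canonical JSON serialization of the config;
#' embedded in JSON outputs and the run manifest so artifacts can be traced
#' to the exact configuration that produced them.
#'
#' @param config any jsonlite-serializable object.
#' @return an 8-character lowercase hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  # exact 32-bit FNV-1a in doubles: split the multiply to stay below 2^53
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- xor32(h, b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# 32-bit xor for nonnegative doubles < 2^32
xor32 <- function(a, b) {
  r <- 0; bit <- 1
  for (i in 1:32) {
    r <- r + bit * as.numeric(xor(a %% 2 >= 1, b %% 2 >= 1))
    a <- a %/% 2; b <- b %/% 2; bit <- bit * 2
    if (a == 0 && b == 0) break
  }
  r
}

#' Run the full daily-robustness pipeline on a synthetic cohort
#'
#' Cohort generation, plan normalization, scenario-band construction at each
#' setup setting, per-fraction 6-DOF evaluation, deviation summaries and
#' cohort statistics; optionally writes all tabular artifacts (CSV/JSON) and
#' band/deviation figures to `outdir`. Deterministic for a fixed config seed.
#'
#' @param config cohort configuration (default [default_cohort_config()]).
#' @param outdir output directory, or NULL to skip writing.
#' @param figures also write PNG figures (requires `outdir`).
#' @return invisibly, a result bundle: list(config, hash, cohort, bands,
#'   shift_log, records, summary, stats).
#' @export
run_cohort <- function(config = default_cohort_config(), outdir = NULL,
                       figures = TRUE) {
  hash <- config_hash(config)
  cohort <- build_cohort(config)

  bands_by_class <- list()
  bands <- NULL; records <- NULL; shift_log <- NULL
  for (pt in cohort) {
    cls <- pt$class
    if (is.null(bands_by_class[[cls]])) {
      bands_by_class[[cls]] <- compute_bands(
        pt$plan$phantom, pt$plan$beams, setups = config$setups_mm,
        range_delta = config$range_delta, variant = config$scenario_variant,
        isocenter = pt$plan$isocenter)
    }
    b <- bands_by_class[[cls]]
    bands <- rbind(bands, cbind(patient = pt$id, b))
    shift_log <- rbind(shift_log, shifts_to_df(pt$shifts, pt$id))

    roles <- vapply(pt$plan$phantom$structures, function(s) s$role, character(1))
    for (fx in seq_along(pt$shifts)) {
      rec <- evaluate_fraction(pt$plan$phantom, pt$plan$beams, b,
                               pt$shifts[[fx]], setups = config$setups_mm,
                               isocenter = pt$plan$isocenter)
      rec <- cbind(patient = pt$id, fraction = fx, class = cls,
                   tier = unname(tier_of(roles[rec$structure])), rec)
      records <- rbind(records, rec)
    }
  }

  summary <- summarize_deviations(records, by = c("class", "tier", "metric", "setup_mm"))
  stats <- cohort_statistics(records, shift_log, cohort, config)

  res <- list(config = config, hash = hash, cohort = cohort, bands = bands,
              shift_log = shift_log, records = records, summary = summary,
              stats = stats)
  if (!is.null(outdir)) write_run_outputs(res, outdir, figures = figures)
  invisible(res)
}

# the paper-shaped statistical comparisons on a finished run
cohort_statistics <- function(records, shift_log, cohort, config) {
  classes <- vapply(cohort, function(p) p$class, character(1))
  out <- list(shifts = shift_comparisons(shift_log, classes))

  tgt <- records[records$tier != "oar", ]
  for (S in config$setups_mm) {
    for (m in c("D95", "V100")) {
      r <- tgt[tgt$metric == m & tgt$setup_mm == S & tgt$status != "inside", ]
      po <- r$deviation[r$class == "PO"]; pnn <- r$deviation[r$class == "PNN"]
      key <- sprintf("%s_dev_PO_vs_PNN_%gmm", m, S)
      out[[key]] <- if (length(po) >= 2 && length(pnn) >= 2)
        two_sample_ttest(po, pnn, groups = key) else NULL
      rp <- tgt[tgt$metric == m & tgt$setup_mm == S & tgt$status != "inside" &
                tgt$class == "PNN", ]
      pri <- rp$deviation[rp$tier == "primary"]
      sec <- rp$deviation[rp$tier == "secondary"]
      key2 <- sprintf("%s_dev_primary_vs_secondary_%gmm", m, S)
      out[[key2]] <- if (length(pri) >= 2 && length(sec) >= 2)
        two_sample_ttest(pri, sec, groups = key2) else NULL
    }
  }

  # paired one-sided: per-patient % of records within robustness, 3 vs 5 mm
  S3 <- config$setups_mm[1]; S5 <- config$setups_mm[length(config$setups_mm)]
  pw <- function(S) vapply(split(records[records$setup_mm == S, ],
                                 records$patient[records$setup_mm == S]),
                           function(g) 100 * mean(g$status == "inside"),
                           numeric(1))
  w3 <- pw(S3); w5 <- pw(S5)
  out$within_robustness_3_vs_5 <- paired_one_sided_ttest(
    w3, w5[names(w3)], alternative = "less",
    groups = sprintf("within@%gmm vs within@%gmm", S3, S5))
  out
}

write_run_outputs <- function(res, outdir, figures = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  jsonlite::write_json(c(list(config_hash = res$hash), res$config),
                       fp("cohort_config.json"), auto_unbox = TRUE, digits = NA)
  write_shift_log(res$shift_log, fp("shift_log.csv"))
  write_band_csv(res$bands, fp("bands.csv"))
  write_record_csv(res$records, fp("records.csv"))
  utils::write.csv(res$summary, fp("summary.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(config_hash = res$hash, summary = res$summary),
                       fp("summary.json"), auto_unbox = TRUE, digits = NA)
  write_stats_json(c(list(config_hash = res$hash),
                     stats_to_list(res$stats[!vapply(res$stats, is.null, TRUE)])),
                   fp("stats.json"))
  jsonlite::write_json(
    list(config_hash = res$hash,
         files = c("cohort_config.json", "shift_log.csv", "bands.csv",
                   "records.csv", "summary.csv", "summary.json", "stats.json")),
    fp("manifest.json"), auto_unbox = TRUE, digits = NA)
  if (figures) {
    plot_bands_png(res, fp("band_plot.png"))
    plot_deviations_png(res, fp("deviation_plot.png"))
  }
  invisible(outdir)
}

# band envelopes + nominal, targets only, one panel per metric
plot_bands_png <- function(res, path) {
  b <- res$bands[res$bands$metric %in% c("D95", "V100"), ]
  grDevices::png(path, width = 900, height = 450)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2), mar = c(8, 4, 2, 1))
  for (m in c("D95", "V100")) {
    bm <- b[b$metric == m, ]
    lab <- paste(bm$patient, bm$structure, paste0(bm$setup_mm, "mm"))
    ylim <- range(bm$band_min, bm$band_max)
    graphics::plot(seq_len(nrow(bm)), bm$nominal, ylim = ylim, pch = 19,
                   xaxt = "n", xlab = "", main = m,
                   ylab = if (m == "D95") "Gy" else "% volume")
    graphics::arrows(seq_len(nrow(bm)), bm$band_min, seq_len(nrow(bm)),
                     bm$band_max, angle = 90, code = 3, length = 0.03)
    graphics::axis(1, at = seq_len(nrow(bm)), labels = lab, las = 2, cex.axis = 0.6)
  }
  invisible(path)
}

# out-of-band deviations per patient/tier at each setup setting
plot_deviations_png <- function(res, path) {
  r <- res$records[res$records$tier != "oar" & res$records$status != "inside", ]
  grDevices::png(path, width = 900, height = 450)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2), mar = c(6, 4, 2, 1))
  for (m in c("D95", "V100")) {
    rm_ <- r[r$metric == m, ]
    if (nrow(rm_) == 0) { graphics::plot.new(); next }
    grp <- interaction(rm_$patient, rm_$tier, rm_$setup_mm, drop = TRUE)
    graphics::boxplot(rm_$deviation ~ grp, las = 2, cex.axis = 0.6,
                      main = paste(m, "out-of-band deviation"),
                      ylab = if (m == "D95") "% of prescription" else "points")
  }
  invisible(path)
}

#' Import externally computed pipeline inputs
#'
#' Lets users substitute real recomputed fraction doses for the analytic toy
#' model. The metadata JSON names, relative to its own directory: the
#' structure masks (grid text format, see [write_grid_text()]), per-fraction
#' dose grid stems, a shift-log CSV, and either a precomputed band CSV or
#' per-scenario dose grid stems per setup setting from which bands are
#' derived. All grids must share one geometry.
#'
#' @param meta_path path to the metadata JSON.
#' @return list(phantom, fraction_doses, bands, shift_log, patient).
#' @export
import_external <- function(meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  base <- dirname(meta_path)
  rp <- function(f) file.path(base, f)

  grid <- NULL
  structures <- list()
  sdf <- meta$structures
  for (i in seq_len(nrow(sdf))) {
    s <- sdf[i, ]
    g <- read_grid_text(rp(s$mask))
    if (is.null(grid)) grid <- g$grid
    else if (!grids_identical(grid, g$grid))
      stop(sprintf(
        "geometry mismatch for mask '%s': %s vs %s", s$name,
        paste(deparse(unclass(g$grid)), collapse = ""),
        paste(deparse(unclass(grid)), collapse = "")), call. = FALSE)
    structures[[s$name]] <- rt_structure(
      s$name, s$role, g$values != 0,
      prescription_Gy = if (s$role == "oar") NA_real_ else s$prescription_Gy,
      metric_kind = if (s$role == "oar") paste0("oar_", s$metric) else NULL)
  }
  phantom <- structure(list(grid = grid, structures = structures),
                       class = "rt_phantom")

  fraction_doses <- lapply(meta$fraction_dose, function(stem) {
    g <- read_grid_text(rp(stem))
    if (!grids_identical(grid, g$grid))
      stop(sprintf("geometry mismatch for dose grid '%s'", stem), call. = FALSE)
    g$values
  })

  bands <- if (!is.null(meta$bands_csv)) {
    utils::read.csv(rp(meta$bands_csv), stringsAsFactors = FALSE)
  } else if (!is.null(meta$scenario_dose)) {
    # the first scenario grid per setting is taken as the nominal scenario
    bb <- NULL
    for (S in names(meta$scenario_dose)) {
      vals <- NULL
      for (stem in meta$scenario_dose[[S]]) {
        g <- read_grid_text(rp(stem))
        if (!grids_identical(grid, g$grid))
          stop(sprintf("geometry mismatch for scenario grid '%s'", stem),
               call. = FALSE)
        row <- NULL
        for (st in structures)
          row <- c(row, unlist(metric_value(g$values[st$mask], st)))
        vals <- rbind(vals, row)
      }
      per_st <- lapply(structures, function(st)
        names(metric_value(c(0, 0), st)))
      bb <- rbind(bb, data.frame(
        structure = rep(names(structures), lengths(per_st)),
        metric = unlist(per_st, use.names = FALSE),
        setup_mm = as.numeric(S),
        band_min = apply(vals, 2, min), band_max = apply(vals, 2, max),
        nominal = vals[1, ], row.names = NULL, stringsAsFactors = FALSE))
    }
    bb
  } else stop("metadata must supply bands_csv or scenario_dose", call. = FALSE)

  shift_log <- if (!is.null(meta$shifts_csv)) read_shift_log(rp(meta$shifts_csv))
               else NULL
  if (!is.null(shift_log) &&
      length(fraction_doses) != nrow(shift_log))
    stop(sprintf("shift log has %d rows but %d fraction dose grids supplied",
                 nrow(shift_log), length(fraction_doses)), call. = FALSE)

  list(phantom = phantom, fraction_doses = fraction_doses, bands = bands,
       shift_log = shift_log, patient = meta$patient %||% "imported")
}

#' Evaluate imported fraction dose grids against bands
#'
#' The imported analogue of [evaluate_fraction()]: metrics are read off the
#' supplied per-fraction dose grids rather than recomputed from the analytic
#' model.
#'
#' @param imp result of [import_external()].
#' @param setups setup settings to judge against (default: those present in
#'   the imported band table).
#' @return record data.frame as in [evaluate_fraction()], plus `patient` and
#'   `fraction` columns.
#' @export
evaluate_imported <- function(imp, setups = NULL) {
  if (is.null(setups)) setups <- sort(unique(imp$bands$setup_mm))
  out <- NULL
  for (fx in seq_along(imp$fraction_doses)) {
    dose <- imp$fraction_doses[[fx]]
    for (st in imp$phantom$structures) {
      mv <- unlist(metric_value(dose[st$mask], st))
      for (metric in names(mv)) for (S in setups) {
        b <- band_row(imp$bands, st$name, metric, S)
        status <- within_band(mv[[metric]], b$band_min, b$band_max)
        dev <- if (metric == "D95")
          fractional_dose_deviation(mv[[metric]], b$band_min, b$band_max,
                                    st$prescription_Gy)
        else if (metric == "V100")
          fractional_volume_deviation(mv[[metric]], b$band_min, b$band_max)
        else max(mv[[metric]] - b$band_max, b$band_min - mv[[metric]], 0)
        out <- rbind(out, data.frame(
          patient = imp$patient, fraction = fx, structure = st$name,
          metric = metric, setup_mm = S, value = mv[[metric]],
          band_min = b$band_min, band_max = b$band_max, status = status,
          deviation = dev, stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Export one patient of a run in the external-input format
#'
#' Writes masks, per-fraction dose grids, the shift log, the band table and
#' a metadata JSON so that [import_external()] round-trips.
#'
#' @param res a [run_cohort()] result bundle.
#' @param patient patient id to export.
#' @param dir output directory.
#' @param fractions which fractions to export (default all).
#' @return the metadata JSON path.
#' @export
export_patient_external <- function(res, patient, dir, fractions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- res$cohort[[patient]]
  if (is.null(pt)) stop("unknown patient: ", patient, call. = FALSE)
  if (is.null(fractions)) fractions <- seq_along(pt$shifts)
  ph <- pt$plan$phantom

  sdf <- NULL
  for (st in ph$structures) {
    stem <- paste0("mask_", st$name)
    write_grid_text(as.numeric(st$mask), ph$grid, file.path(dir, stem), "mask")
    sdf <- rbind(sdf, data.frame(
      name = st$name, role = st$role, mask = stem,
      prescription_Gy = st$prescription_Gy,
      metric = sub("oar_", "", st$metric_kind), stringsAsFactors = FALSE))
  }
  stems <- character(0)
  for (fx in fractions) {
    stem <- sprintf("dose_fx%03d", fx)
    d <- compute_dose(ph, pt$plan$beams, pt$shifts[[fx]], 1, pt$plan$isocenter)
    write_grid_text(d, ph$grid, file.path(dir, stem), "dose_Gy")
    stems <- c(stems, stem)
  }
  b <- res$bands[res$bands$patient == patient, ]
  utils::write.csv(b[, c("structure", "metric", "setup_mm",
                         "band_min", "band_max", "nominal")],
                   file.path(dir, "bands.csv"), row.names = FALSE, quote = FALSE)
  log <- res$shift_log[res$shift_log$patient == patient &
                       res$shift_log$fraction %in% fractions, ]
  log$fraction <- seq_len(nrow(log))
  write_shift_log(log, file.path(dir, "shifts.csv"))
  meta <- list(patient = patient, structures = sdf, fraction_dose = stems,
               bands_csv = "bands.csv", shifts_csv = "shifts.csv")
  mp <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  mp
}
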