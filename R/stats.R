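#' Classical Student's t-tests for cohort comparisons
#'
#' Implemented from the closed-form pooled-variance formulas so the package
#' carries its own statistical contract; base R's `t.test` is used only as an
#' independent oracle in the test suite. Equal-variance Student's t is the
#' default (a Welch option exists); no multiple-testing correction is applied.
#' @name cohort_stats
NULL

rt_stat <- function(test, groups, statistic, df, p_value, sided, paired) {
  structure(list(test = test, groups = groups, statistic = statistic,
                 df = df, p_value = p_value, sided = sided, paired = paired),
            class = "rt_stat")
}

#' @export
print.rt_stat <- function(x, ...) {
  cat(sprintf("%s [%s]: t = %.4f, df = %.4g, p = %.4g (%s-sided%s)\n",
              x$test, x$groups, x$statistic, x$df, x$p_value, x$sided,
              if (x$paired) ", paired" else ""))
  invisible(x)
}

#' @describeIn cohort_stats two-sample Student's t-test.
#' @param a,b numeric samples (each n >= 2).
#' @param sided `"two"` (default), `"greater"` (mean(a) > mean(b)) or
#'   `"less"`.
#' @param welch use the Welch unequal-variance form.
#' @param groups label for reporting.
#' @return an `rt_stat` with statistic, df, p-value.
#' @export
two_sample_ttest <- function(a, b, sided = c("two", "greater", "less"),
                             welch = FALSE, groups = "a vs b") {
  sided <- match.arg(sided)
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2) stop("degenerate sample in group 'a' (n < 2)", call. = FALSE)
  if (nb < 2) stop("degenerate sample in group 'b' (n < 2)", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    se2a <- va / na; se2b <- vb / nb
    if (se2a + se2b == 0) stop("zero variance in both groups", call. = FALSE)
    tstat <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) stop("zero pooled variance across groups", call. = FALSE)
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  p <- switch(sided,
    two = 2 * stats::pt(-abs(tstat), df),
    greater = stats::pt(tstat, df, lower.tail = FALSE),
    less = stats::pt(tstat, df))
  rt_stat(if (welch) "Welch t" else "Student t", groups, tstat, df, p,
          if (sided == "two") "two" else "one", paired = FALSE)
}

#' @describeIn cohort_stats one-sided paired Student's t-test on x - y.
#' @param x,y paired samples of equal length >= 2.
#' @param alternative `"less"` (default; mean(x) < mean(y)) or `"greater"`.
#' @export
paired_one_sided_ttest <- function(x, y, alternative = c("less", "greater"),
                                   groups = "x vs y") {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  sd_d <- stats::sd(d)
  tstat <- if (sd_d == 0) {
    if (all(d == 0)) 0
    else stop("degenerate pairs: constant nonzero differences", call. = FALSE)
  } else mean(d) / (sd_d / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
    less = stats::pt(tstat, df),
    greater = stats::pt(tstat, df, lower.tail = FALSE))
  rt_stat("paired Student t", groups, tstat, df, p, "one", paired = TRUE)
}

#' @describeIn cohort_stats comparisons on a per-fraction shift log:
#'   (i) two-sample test of translational shift magnitudes between the two
#'   patient classes, and (ii) a paired-by-patient test of mean magnitude in
#'   the first vs second half of each treatment course. Classes with fewer
#'   than 2 patients skip the class test with a warning.
#' @param shift_log data.frame as written by [write_shift_log()].
#' @param classes named character vector mapping patient id -> class
#'   (`"PO"` / `"PNN"`).
#' @export
shift_comparisons <- function(shift_log, classes) {
  mag <- sqrt(shift_log$tx_mm^2 + shift_log$ty_mm^2 + shift_log$tz_mm^2)
  cls <- classes[shift_log$patient]
  res <- list()
  if (all(table(classes) >= 2)) {
    res$class_magnitude <- two_sample_ttest(mag[cls == "PO"], mag[cls == "PNN"],
                                            groups = "PO vs PNN shift magnitude")
  } else {
    warning("a patient class has < 2 patients; class magnitude test skipped")
  }
  per_patient <- lapply(split(seq_len(nrow(shift_log)), shift_log$patient),
    function(idx) {
      m <- mag[idx][order(shift_log$fraction[idx])]
      h <- floor(length(m) / 2)
      c(first = mean(m[seq_len(h)]), second = mean(m[(h + 1):length(m)]))
    })
  halves <- do.call(rbind, per_patient)
  res$course_halves <- {
    d <- halves[, "first"] - halves[, "second"]
    n <- nrow(halves)
    tstat <- if (stats::sd(d) == 0) 0 else mean(d) / (stats::sd(d) / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), n - 1)
    rt_stat("paired Student t", "first vs second half magnitude",
            tstat, n - 1, p, "two", paired = TRUE)
  }
  res
}

stats_to_list <- function(stats) {
  if (inherits(stats, "rt_stat")) return(unclass(stats))
  if (!is.list(stats)) return(stats)
  lapply(stats, stats_to_list)
}

#' Write a stats report as JSON
#' @param stats (possibly nested) list of `rt_stat` results.
#' @param path JSON path.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(stats_to_list(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
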