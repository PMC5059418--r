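#' Extract an ion chromatogram at ppm tolerance
#'
#' Sums, per qualifying scan, the intensities of all centroid peaks within
#' `target_mz * ppm_tol * 1e-6` of the target m/z. For MS2 extraction the
#' scans are restricted to one SWATH window so that only fragments of
#' co-isolated precursors contribute.
#'
#' @param run A [spectrum_run()].
#' @param target_mz Target m/z.
#' @param ppm_tol Mass tolerance in ppm (default 20).
#' @param rt_range Optional `c(lo, hi)` retention-time restriction (minutes,
#'   inclusive); `NULL` keeps all scans.
#' @param level MS level, 1 or 2.
#' @param window 0-based SWATH window index (required for `level = 2`).
#' @return An object of class `chromatogram`: data frame `(rt, intensity)`
#'   with attributes `target_mz`, `ppm_tol`, `source` and `empty_rt_range`
#'   (flag set when no scan falls in `rt_range`).
#' @export
extract_xic <- function(run, target_mz, ppm_tol = 20, rt_range = NULL,
                        level = 2L, window = NULL) {
  stopifnot(inherits(run, "spectrum_run"), target_mz > 0, ppm_tol >= 0)
  level <- as.integer(level)
  h <- run$header
  sel <- h$ms_level == level
  if (level == 2L) {
    if (is.null(window)) stop("MS2 extraction requires a window index")
    sel <- sel & !is.na(h$window) & h$window == as.integer(window)
  }
  if (!is.null(rt_range)) {
    stopifnot(length(rt_range) == 2L, rt_range[1] <= rt_range[2])
    sel <- sel & h$rt >= rt_range[1] & h$rt <= rt_range[2]
  }
  idx <- which(sel)
  tol <- target_mz * ppm_tol * 1e-6
  ints <- vapply(idx, function(i) {
    p <- run$peaks[[i]]
    if (!nrow(p)) return(0)
    lo <- findInterval(target_mz - tol, p[, 1L]) + 1L
    hi <- findInterval(target_mz + tol, p[, 1L])
    if (hi < lo) 0 else sum(p[lo:hi, 2L])
  }, 0)
  out <- data.frame(rt = h$rt[idx], intensity = ints)
  structure(out, class = c("chromatogram", "data.frame"),
            target_mz = target_mz, ppm_tol = ppm_tol,
            source = if (level == 1L) "MS1" else paste0("MS2@", window),
            empty_rt_range = !is.null(rt_range) && nrow(out) == 0L)
}

#' Integrate a chromatographic peak between retention-time borders
#'
#' Trapezoidal integration of intensity over retention time, restricted to
#' the inclusive border interval, on the native cycle-time grid (no
#' smoothing or interpolation).
#'
#' @param chrom A [extract_xic()] chromatogram, or any data frame with `rt`
#'   and `intensity` columns.
#' @param rt_borders `c(lo, hi)` in minutes, `lo <= hi`.
#' @return A list of class `peak_area`: `area` (intensity x minutes),
#'   `rt_borders`, `n_points`, `apex_rt` and `low_points` flag (fewer than 2
#'   points in range, area reported as 0).
#' @export
integrate_peak <- function(chrom, rt_borders) {
  stopifnot(length(rt_borders) == 2L)
  if (rt_borders[1] > rt_borders[2]) stop("rt_borders must be ordered")
  sel <- chrom$rt >= rt_borders[1] & chrom$rt <= rt_borders[2]
  rt <- chrom$rt[sel]; int <- chrom$intensity[sel]
  if (length(rt) < 2L) {
    return(structure(list(area = 0, rt_borders = rt_borders,
                          n_points = length(rt),
                          apex_rt = if (length(rt)) rt[which.max(int)] else NA_real_,
                          low_points = TRUE),
                     class = "peak_area"))
  }
  structure(list(area = pracma::trapz(rt, int), rt_borders = rt_borders,
                 n_points = length(rt), apex_rt = rt[which.max(int)],
                 low_points = FALSE),
            class = "peak_area")
}

#' @export
print.peak_area <- function(x, ...) {
  cat("peak_area: ", signif(x$area, 6), " (", x$n_points, " points, RT ",
      round(x$rt_borders[1], 2), "-", round(x$rt_borders[2], 2),
      if (x$low_points) ", LOW POINTS", ")\n", sep = "")
  invisible(x)
}

#' MS1 isotope peak areas for a precursor
#'
#' Extracts and integrates MS1 XICs for the first `n_isotopes` isotopic
#' peaks (M, M+1, ...) of an acyl peptide's precursor, spaced by
#' 1.0033548/charge. The monoisotopic (M) area is the highest-ranked
#' precursor signal used for MS1-based occupancy.
#'
#' @param run A [spectrum_run()].
#' @param peptide An [acyl_peptide()].
#' @param n_isotopes Number of isotopes (default 3: M, M+1, M+2).
#' @param ppm_tol ppm tolerance (default 20).
#' @param rt_borders Integration borders (minutes).
#' @return List of [integrate_peak()] results ordered by isotope index,
#'   with an `isotope_mz` attribute.
#' @export
ms1_isotope_areas <- function(run, peptide, n_isotopes = 3L, ppm_tol = 20,
                              rt_borders) {
  stopifnot(n_isotopes >= 1L)
  mz0 <- precursor_mz(peptide)
  z <- peptide$charge
  mzs <- mz0 + (seq_len(n_isotopes) - 1L) * .C13_SPACING / z
  out <- lapply(mzs, function(m)
    integrate_peak(extract_xic(run, m, ppm_tol, rt_range = rt_borders,
                               level = 1L), rt_borders))
  attr(out, "isotope_mz") <- mzs
  out
}
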