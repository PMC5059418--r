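#' Construct an in-memory spectrum run
#'
#' A `spectrum_run` holds an ordered list of centroided scans: a header data
#' frame (MS level, retention time in minutes, SWATH window index and
#' isolation bounds for MS2) plus one two-column peak matrix (m/z,
#' intensity) per scan. It is the common currency of the XIC layer: both
#' [read_run()] and the simulator produce it.
#'
#' @param header Data frame with columns `ms_level` (1 or 2), `rt` (minutes,
#'   non-decreasing), `window` (0-based index, `NA` for MS1), `iso_lower`,
#'   `iso_upper` (isolation bounds, `NA` for MS1).
#' @param peaks List of numeric matrices with columns m/z (ascending) and
#'   intensity, one per header row.
#' @param source Optional provenance string (file path or "simulated").
#' @return An object of class `spectrum_run`.
#' @export
spectrum_run <- function(header, peaks, source = "in-memory") {
  stopifnot(is.data.frame(header), is.list(peaks),
            nrow(header) == length(peaks))
  need <- c("ms_level", "rt", "window", "iso_lower", "iso_upper")
  miss <- setdiff(need, names(header))
  if (length(miss)) stop("header missing columns: ", paste(miss, collapse = ", "))
  if (is.unsorted(header$rt)) stop("retention times must be non-decreasing")
  for (i in seq_along(peaks)) {
    p <- peaks[[i]]
    if (!is.matrix(p) || ncol(p) != 2L)
      stop("scan ", i, ": peaks must be a 2-column matrix")
    if (nrow(p) > 1L && is.unsorted(p[, 1L]))
      peaks[[i]] <- p[order(p[, 1L]), , drop = FALSE]
    if (any(peaks[[i]][, 2L] < 0)) stop("scan ", i, ": negative intensity")
  }
  structure(list(header = header, peaks = peaks, source = source),
            class = "spectrum_run")
}

#' @export
print.spectrum_run <- function(x, ...) {
  h <- x$header
  cat("spectrum_run (", x$source, "): ", nrow(h), " scans, ",
      sum(h$ms_level == 1L), " MS1 / ", sum(h$ms_level == 2L), " MS2, RT ",
      round(min(h$rt), 2), "-", round(max(h$rt), 2), " min",
      if (any(h$ms_level == 2L))
        paste0(", ", length(unique(stats::na.omit(h$window))), " windows"),
      "\n", sep = "")
  invisible(x)
}

#' Read an mzML/mzXML run into a spectrum run
#'
#' Reads centroided MS1 + SWATH MS2 scans via mzR. MS2 scans are mapped to
#' SWATH window indices from their isolation-window metadata when present;
#' when a scheme is supplied, the isolation-window midpoint is matched to
#' the scheme window containing it. Files lacking isolation metadata require
#' a scheme, in which case MS2 scans are assigned by cycle order (the i-th
#' MS2 scan after each MS1 scan gets window i-1). Retention times are
#' converted from seconds to minutes.
#'
#' @param path mzML or mzXML file.
#' @param scheme Optional [swath_scheme()].
#' @return A [spectrum_run()].
#' @export
read_run <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop("run file not found: ", path)
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(ms), add = TRUE)
  hd <- mzR::header(ms)
  if (!nrow(hd)) stop("no spectra in ", path)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  pk <- lapply(pk, function(p) {
    p <- as.matrix(p); colnames(p) <- c("mz", "intensity"); p
  })
  rt <- hd$retentionTime / 60
  lvl <- as.integer(hd$msLevel)
  iso_lo <- iso_up <- rep(NA_real_, nrow(hd))
  win <- rep(NA_integer_, nrow(hd))
  is2 <- lvl == 2L
  has_iso <- is2 & !is.na(hd$isolationWindowTargetMZ)
  iso_lo[has_iso] <- hd$isolationWindowTargetMZ[has_iso] -
    hd$isolationWindowLowerOffset[has_iso]
  iso_up[has_iso] <- hd$isolationWindowTargetMZ[has_iso] +
    hd$isolationWindowUpperOffset[has_iso]
  if (any(is2)) {
    if (any(has_iso)) {
      if (!is.null(scheme)) {
        win[has_iso] <- assign_window(
          (iso_lo[has_iso] + iso_up[has_iso]) / 2, scheme)
      } else {
        # no scheme: index distinct isolation windows in ascending m/z order
        key <- paste(round(iso_lo, 4), round(iso_up, 4))
        uk <- unique(key[has_iso])
        uk <- uk[order(iso_lo[has_iso][match(uk, key[has_iso])])]
        win[has_iso] <- match(key[has_iso], uk) - 1L
      }
    } else {
      if (is.null(scheme))
        stop("MS2 scans carry no isolation-window metadata and no scheme ",
             "was supplied")
      cycle <- cumsum(lvl == 1L)
      for (cy in unique(cycle)) {
        sel <- which(is2 & cycle == cy)
        win[sel] <- seq_along(sel) - 1L
      }
      wdf <- scheme$windows
      ok <- !is.na(win) & win < nrow(wdf)
      iso_lo[is2 & ok] <- wdf$lower[win[is2 & ok] + 1L]
      iso_up[is2 & ok] <- wdf$upper[win[is2 & ok] + 1L]
    }
  }
  spectrum_run(
    data.frame(ms_level = lvl, rt = rt, window = win,
               iso_lower = iso_lo, iso_upper = iso_up),
    pk, source = path)
}

#' Write a spectrum run to mzML
#'
#' @param run A [spectrum_run()].
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "spectrum_run"))
  h <- run$header
  n <- nrow(h)
  pk <- run$peaks
  npk <- vapply(pk, nrow, 0L)
  safe <- function(f, default) vapply(pk, function(p)
    if (nrow(p)) f(p) else default, 0)
  iso_mid <- (h$iso_lower + h$iso_upper) / 2
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = h$ms_level,
    polarity = rep(1L, n), peaksCount = npk,
    totIonCurrent = safe(function(p) sum(p[, 2]), 0),
    retentionTime = h$rt * 60,
    basePeakMZ = safe(function(p) p[which.max(p[, 2]), 1], 0),
    basePeakIntensity = safe(function(p) max(p[, 2]), 0),
    collisionEnergy = ifelse(h$ms_level == 2L, 30, NA_real_),
    ionisationEnergy = rep(0, n),
    lowMZ = safe(function(p) min(p[, 1]), 0),
    highMZ = safe(function(p) max(p[, 1]), 0),
    precursorScanNum = NA_integer_,
    precursorMZ = ifelse(h$ms_level == 2L, iso_mid, NA_real_),
    precursorCharge = ifelse(h$ms_level == 2L, 0L, NA_integer_),
    precursorIntensity = ifelse(h$ms_level == 2L, 0, NA_real_),
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_, mergedResultEndScanNum = NA_integer_,
    injectionTime = ifelse(h$ms_level == 2L, 0.045, 0.25),
    filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = iso_mid,
    isolationWindowLowerOffset = iso_mid - h$iso_lower,
    isolationWindowUpperOffset = h$iso_upper - iso_mid,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  # mzR requires at least one peak per spectrum; pad empty scans
  pk <- lapply(pk, function(p) {
    if (nrow(p)) unname(p) else matrix(c(400, 0), ncol = 2)
  })
  hdr$peaksCount <- pmax(npk, 1L)
  mzR::writeMSData(pk, file = path, header = hdr)
  invisible(path)
}
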