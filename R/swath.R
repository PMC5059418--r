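#' Construct a SWATH isolation window scheme
#'
#' A scheme is an ordered list of precursor isolation windows (lower, upper
#' m/z), possibly overlapping by a fixed amount (the SCIEX convention is a
#' 1 m/z overlap between neighbours). The overlap is split equally between
#' neighbouring windows, giving effective, de-overlapped half-open intervals
#' that tile the scheme range: a precursor m/z is assigned to exactly one
#' window, and an m/z falling exactly on an effective boundary goes to the
#' higher-index window.
#'
#' @param lower,upper Numeric vectors of window bounds (m/z), same length,
#'   sorted by `lower`.
#' @return An object of class `swath_scheme` with fields `windows` (data
#'   frame: `index` 0-based, `lower`, `upper`, `eff_lower`, `eff_upper`),
#'   `overlap` and `range`.
#' @export
swath_scheme <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == length(upper),
            length(lower) >= 1L)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("non-numeric window bounds")
  bad <- which(lower >= upper)
  if (length(bad))
    stop("window ", bad[1], ": lower bound ", lower[bad[1]],
         " not below upper bound ", upper[bad[1]])
  if (is.unsorted(lower))
    stop("windows not sorted by lower bound")
  n <- length(lower)
  if (n > 1L) {
    gap <- which(lower[-1L] > upper[-n])
    if (length(gap))
      stop("gap between window ", gap[1] - 1L, " and window ", gap[1],
           " (", upper[gap[1]], " to ", lower[gap[1] + 1L], ")")
    overlap <- max(0, stats::median(upper[-n] - lower[-1L]))
  } else overlap <- 0
  # effective boundaries: scheme edges outside, overlap midpoints inside
  if (n > 1L) inner <- (upper[-n] + lower[-1L]) / 2 else inner <- numeric()
  eff_lower <- c(lower[1L], inner)
  eff_upper <- c(inner, upper[n])
  structure(
    list(
      windows = data.frame(index = seq_len(n) - 1L, lower = lower,
                           upper = upper, eff_lower = eff_lower,
                           eff_upper = eff_upper),
      overlap = overlap,
      range = c(lower[1L], upper[n])
    ),
    class = "swath_scheme"
  )
}

#' @export
print.swath_scheme <- function(x, ...) {
  cat("swath_scheme: ", nrow(x$windows), " windows over m/z ",
      x$range[1], "-", x$range[2], ", overlap ", signif(x$overlap, 4),
      "\n", sep = "")
  invisible(x)
}

#' Load a SWATH window scheme from a text file
#'
#' Expects two numeric columns (lower and upper window m/z) per line,
#' whitespace- or tab-separated, with an optional single header line. The
#' overlap is inferred as the median of upper_i - lower_(i+1), clamped at 0.
#'
#' @param path Window definition file.
#' @return A [swath_scheme()].
#' @export
load_window_scheme <- function(path) {
  if (!file.exists(path)) stop("window scheme file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty window scheme file: ", path)
  parse_line <- function(l) suppressWarnings(
    as.numeric(strsplit(trimws(l), "[\t ,]+")[[1]]))
  first <- parse_line(lines[1])
  skip_header <- anyNA(first) || length(first) < 2L
  body <- if (skip_header) lines[-1L] else lines
  offset <- if (skip_header) 1L else 0L
  if (!length(body)) stop("no window rows in ", path)
  lo <- up <- numeric(length(body))
  for (i in seq_along(body)) {
    v <- parse_line(body[i])
    if (length(v) < 2L || anyNA(v[1:2]))
      stop("line ", i + offset, ": expected two numeric columns")
    lo[i] <- v[1]; up[i] <- v[2]
    if (lo[i] >= up[i])
      stop("line ", i + offset, ": lower bound ", lo[i],
           " not below upper bound ", up[i])
  }
  if (is.unsorted(lo)) stop("window definitions not sorted by lower bound")
  swath_scheme(lo, up)
}

#' Write a window scheme in the same dialect read by [load_window_scheme()]
#'
#' @param scheme A [swath_scheme()].
#' @param path Output path.
#' @export
write_window_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "swath_scheme"))
  utils::write.table(
    data.frame(lower_mz = scheme$windows$lower, upper_mz = scheme$windows$upper),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign precursor m/z values to SWATH windows
#'
#' Deterministic assignment against the effective (de-overlapped) half-open
#' intervals `[eff_lower, eff_upper)`; a boundary m/z goes to the
#' higher-index window, an m/z outside the scheme range to `NA`.
#'
#' @param mz Numeric vector of precursor m/z.
#' @param scheme A [swath_scheme()].
#' @return Integer vector of 0-based window indices (`NA` = outside range).
#' @export
assign_window <- function(mz, scheme) {
  stopifnot(inherits(scheme, "swath_scheme"))
  b <- c(scheme$windows$eff_lower, scheme$range[2])
  i <- findInterval(mz, b)                 # [b_i, b_{i+1})
  i[i < 1L | i > nrow(scheme$windows) | mz >= scheme$range[2]] <- NA_integer_
  as.integer(i - 1L)
}

#' Check that a light/heavy precursor pair is co-isolated
#'
#' Fragment-level L/(L+H) quantification requires the light and heavy
#' precursors to be sampled in the same SWATH isolation window so that their
#' fragments appear in the same MS2 scans.
#'
#' @param light_mz,heavy_mz Precursor m/z of the light and heavy species.
#' @param scheme A [swath_scheme()].
#' @return List with `co_isolated` (logical), `light_window`, `heavy_window`
#'   (0-based indices or `NA`).
#' @export
co_isolated <- function(light_mz, heavy_mz, scheme) {
  wl <- assign_window(light_mz, scheme)
  wh <- assign_window(heavy_mz, scheme)
  list(co_isolated = !is.na(wl) && !is.na(wh) && wl == wh,
       light_window = wl, heavy_window = wh)
}

#' Default 64-window variable SWATH scheme over m/z 400-1250
#'
#' A deterministic variable-width scheme emulating vendor variable-window
#' acquisition: narrow windows where tryptic/Glu-C precursor density is
#' highest (around m/z 500-800) and wide windows at the range edges, with a
#' 1 m/z overlap between neighbours. Widths stay within 5-90 m/z.
#'
#' @param n Number of windows (default 64).
#' @param mz_range Scheme range (default `c(400, 1250)`).
#' @param overlap Overlap between neighbouring windows (default 1 m/z).
#' @return A [swath_scheme()].
#' @export
default_window_scheme <- function(n = 64L, mz_range = c(400, 1250),
                                  overlap = 1) {
  n <- as.integer(n)
  # precursor-density model: lognormal-like bump peaking near m/z 650
  grid <- seq(mz_range[1], mz_range[2], length.out = 4096L)
  dens <- stats::dnorm(grid, mean = 650, sd = 160) + 0.25 / diff(mz_range)
  cdf <- cumsum(dens); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  breaks <- stats::approx(cdf, grid, xout = seq(0, 1, length.out = n + 1L))$y
  # enforce a 5 m/z minimum width, then rescale to the full range
  w <- pmax(diff(breaks), 5)
  w <- w * diff(mz_range) / sum(w)
  breaks <- mz_range[1] + c(0, cumsum(w))
  lower <- breaks[-(n + 1L)] - overlap / 2
  upper <- breaks[-1L] + overlap / 2
  lower[1L] <- mz_range[1]; upper[n] <- mz_range[2]
  swath_scheme(round(lower, 4), round(upper, 4))
}
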