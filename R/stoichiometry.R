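#' Construct a quantification target
#'
#' One quantification task: an acyl peptide, the protein-level site numbers
#' of its modified lysines, the precursor charge, the retention-time borders
#' for peak integration, and the source run.
#'
#' @param sequence Peptide sequence.
#' @param peptide_positions 1-based positions of the acyl lysines within the
#'   peptide (strictly increasing).
#' @param site_numbers Protein-level residue numbers of the same lysines;
#'   must differ from `peptide_positions` by a constant offset. Defaults to
#'   the peptide positions.
#' @param protein Protein identifier.
#' @param family `"acetyl"` or `"succinyl"`.
#' @param charge Precursor charge.
#' @param rt_borders `c(lo, hi)` integration borders in minutes.
#' @param run_file Source run file name.
#' @return An object of class `target_entry`.
#' @export
target_entry <- function(sequence, peptide_positions, site_numbers = NULL,
                         protein = "", family = c("acetyl", "succinyl"),
                         charge = 2L, rt_borders = c(0, Inf), run_file = "") {
  family <- match.arg(family)
  peptide_positions <- as.integer(peptide_positions)
  if (is.null(site_numbers)) site_numbers <- peptide_positions
  site_numbers <- as.integer(site_numbers)
  if (length(site_numbers) != length(peptide_positions))
    stop("site_numbers and peptide_positions differ in length")
  off <- site_numbers - peptide_positions
  if (length(off) > 1L && length(unique(off)) != 1L)
    stop("protein site numbers inconsistent with peptide positions ",
         "(offsets differ)")
  # validates K-at-site, ordering, range
  pep <- acyl_peptide(sequence, peptide_positions, "light", family, charge)
  stopifnot(length(rt_borders) == 2L, rt_borders[1] <= rt_borders[2])
  structure(list(sequence = sequence, protein = protein,
                 peptide_positions = peptide_positions,
                 site_numbers = site_numbers, family = family,
                 charge = as.integer(charge),
                 rt_borders = as.numeric(rt_borders), run_file = run_file,
                 peptide = pep),
            class = "target_entry")
}

#' Read a target table TSV
#'
#' Columns: `sequence`, `protein`, `site_numbers`, `peptide_positions`
#' (semicolon-separated for multi-K peptides), `family`, `charge`,
#' `rt_start`, `rt_end`, `run_file`.
#'
#' @param path TSV path.
#' @return List of [target_entry()] objects.
#' @export
read_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "protein", "site_numbers", "peptide_positions",
            "family", "charge", "rt_start", "rt_end", "run_file")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("target table missing columns: ",
                         paste(miss, collapse = ", "))
  split_int <- function(x) as.integer(strsplit(as.character(x), ";")[[1]])
  lapply(seq_len(nrow(df)), function(i)
    target_entry(df$sequence[i], split_int(df$peptide_positions[i]),
                 split_int(df$site_numbers[i]), df$protein[i],
                 df$family[i], df$charge[i],
                 c(df$rt_start[i], df$rt_end[i]), df$run_file[i]))
}

#' Write a target table TSV
#'
#' @param targets List of [target_entry()] objects.
#' @param path Output path.
#' @export
write_targets <- function(targets, path) {
  df <- do.call(rbind, lapply(targets, function(t) data.frame(
    sequence = t$sequence, protein = t$protein,
    site_numbers = paste(t$site_numbers, collapse = ";"),
    peptide_positions = paste(t$peptide_positions, collapse = ";"),
    family = t$family, charge = t$charge,
    rt_start = t$rt_borders[1], rt_end = t$rt_borders[2],
    run_file = t$run_file, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Differentiating fragment ions for an acyl site
#'
#' A differentiating ion is a b- or y-ion whose m/z differs between the
#' light and heavy peptide forms because it contains the modified lysine.
#' In strict mode only fragments containing exactly the requested site are
#' returned: for a single-K peptide these are all b_i with i >= site and all
#' y_j with j > length - site; for a multi-K peptide, the b-ion run that
#' isolates the first site and the y-ion run that isolates the last site.
#' Extended mode adds multi-site fragments together with their full
#' label-count m/z ladder (`mz_ladder[k+1]` = m/z with k heavy sites), which
#' the middle-site solver of [quantify_multisite()] consumes.
#'
#' @param peptide An [acyl_peptide()].
#' @param site Peptide-level position of an acyl site.
#' @param mode `"strict"` or `"extended"`.
#' @param fragment_charges Fragment charges (default 1).
#' @return Data frame with `series`, `index`, `charge`, `n_sites`,
#'   `site_rank` (1-based rank of `site` within the fragment's contained
#'   sites) and list-column `mz_ladder`.
#' @export
differentiating_ions <- function(peptide, site, mode = c("strict", "extended"),
                                 fragment_charges = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(peptide, "acyl_peptide"))
  site <- as.integer(site)
  if (!site %in% peptide$sites)
    stop("position ", site, " is not an acyl site of this peptide")
  fam <- acyl_family(peptide$family)
  base <- acyl_peptide(peptide$sequence, peptide$sites,
                       "light", peptide$family, peptide$charge)
  fr <- fragment_ions(base, charges = fragment_charges)
  keep <- vapply(fr$sites, function(s)
    site %in% s && (mode == "extended" || length(s) == 1L), TRUE)
  fr <- fr[keep, , drop = FALSE]
  if (!nrow(fr)) {
    out <- data.frame(series = character(), index = integer(),
                      charge = integer(), n_sites = integer(),
                      site_rank = integer(), stringsAsFactors = FALSE)
    out$mz_ladder <- I(list())
    return(out)
  }
  n_sites <- vapply(fr$sites, length, 0L)
  out <- data.frame(series = fr$series, index = fr$index, charge = fr$charge,
                    n_sites = n_sites,
                    site_rank = vapply(fr$sites, function(s)
                      match(site, s), 0L),
                    stringsAsFactors = FALSE)
  out$mz_ladder <- I(Map(function(mz0, m, z)
    mz0 + (0:m) * fam$pair_delta / z, fr$mz, n_sites, fr$charge))
  rownames(out) <- NULL
  out
}

.frag_id <- function(df) paste0(df$series, df$index, "^", df$charge)

## lower-of-central median: deterministic at even counts
.median_low <- function(x) {
  x <- sort(x)
  x[(length(x) + 1L) %/% 2L]
}

## extract + integrate one channel of one fragment
.channel_area <- function(run, mz, ppm_tol, borders, window) {
  integrate_peak(
    extract_xic(run, mz, ppm_tol, rt_range = borders, level = 2L,
                window = window),
    borders)$area
}

.empty_site_result <- function(target, site, qc) {
  fr <- data.frame(series = character(), index = integer(),
                   charge = integer(), mz_light = numeric(),
                   mz_heavy = numeric(), light_area = numeric(),
                   heavy_area = numeric(), ratio = numeric(),
                   pass = logical(), rank = integer(),
                   stringsAsFactors = FALSE)
  structure(list(target = target, site = site,
                 site_number = target$site_numbers[
                   match(site, target$peptide_positions)],
                 fragments = fr, median_ratio = NA_real_,
                 rank1_ratio = NA_real_, co_isolated = FALSE,
                 window = NA_integer_, qc = qc),
            class = "site_stoichiometry")
}

#' @export
print.site_stoichiometry <- function(x, ...) {
  cat("site_stoichiometry: ", x$target$sequence, " K", x$site_number,
      " (", x$target$family, ")\n", sep = "")
  cat("  median L/(L+H): ", signif(x$median_ratio, 4),
      "   rank-1: ", signif(x$rank1_ratio, 4), "\n", sep = "")
  cat("  fragments passing: ", sum(x$fragments$pass), "/",
      nrow(x$fragments),
      if (length(x$qc)) paste0("   QC: ", paste(x$qc, collapse = "; ")),
      "\n", sep = "")
  invisible(x)
}

#' Quantify occupancy of one acyl site from SWATH MS2 fragments
#'
#' Implements the fragment-level occupancy calculation: verify that the
#' light and heavy precursors are co-isolated in the same SWATH window,
#' extract light and heavy XICs for every strict differentiating fragment
#' ion from that window within the target's retention-time borders,
#' integrate, apply the minimum-area filter (a fragment is kept when either
#' its heavy or its light area reaches the threshold -- the light fallback
#' covers very high-stoichiometry sites whose heavy signal is weak), and
#' compute per-fragment L/(L+H). The median over passing fragments and the
#' rank-1 fragment ratio are reported; rank 1 is the passing fragment with
#' the largest light+heavy summed area unless a library-style rank table is
#' supplied.
#'
#' @param run A [spectrum_run()].
#' @param scheme A [swath_scheme()].
#' @param target A [target_entry()].
#' @param site Peptide-level site position (default: the target's only
#'   site).
#' @param ppm_tol ppm tolerance (default 20).
#' @param min_heavy_area Minimum peak area threshold (default 1000).
#' @param mode `"strict"` (default) or `"extended"` fragment selection; only
#'   strict single-site fragments are ratioed here.
#' @param fragment_charges Fragment charges (default 1).
#' @param ranks Optional data frame (`series`, `index`, `charge`, `rank`)
#'   emulating spectral-library fragment ranking.
#' @param purity Optional heavy-reagent isotopic purity in (0, 1]; when
#'   supplied, ratios are corrected for the 1-p light-signal floor
#'   (occupancies are otherwise upper-limit values).
#' @return A `site_stoichiometry` object.
#' @export
quantify_site <- function(run, scheme, target, site = NULL, ppm_tol = 20,
                          min_heavy_area = 1000, mode = "strict",
                          fragment_charges = 1L, ranks = NULL,
                          purity = NULL) {
  stopifnot(inherits(target, "target_entry"))
  if (is.null(site)) {
    if (length(target$peptide_positions) != 1L)
      stop("site must be given for multi-site targets")
    site <- target$peptide_positions
  }
  fam <- acyl_family(target$family)
  k <- length(target$peptide_positions)
  # all label permutations share k+1 distinct precursor m/z values
  light_pep <- acyl_peptide(target$sequence, target$peptide_positions,
                            "light", target$family, target$charge)
  prec <- precursor_mz(light_pep) +
    (0:k) * fam$pair_delta / target$charge
  wins <- assign_window(prec, scheme)
  if (anyNA(wins) || length(unique(wins)) != 1L)
    return(.empty_site_result(target, site,
                              "co-isolation failure: precursor pair split across windows"))
  window <- wins[1]
  di <- differentiating_ions(light_pep, site, mode = "strict",
                             fragment_charges = fragment_charges)
  if (!nrow(di))
    return(.empty_site_result(target, site, "no differentiating fragments"))
  borders <- target$rt_borders
  mz_light <- vapply(di$mz_ladder, `[`, 0, 1L)
  mz_heavy <- vapply(di$mz_ladder, `[`, 0, 2L)
  la <- vapply(mz_light, .channel_area, 0, ppm_tol, borders, window, run = run)
  ha <- vapply(mz_heavy, .channel_area, 0, ppm_tol, borders, window, run = run)
  pass <- ha >= min_heavy_area | la >= min_heavy_area
  ratio <- ifelse(pass, la / (la + ha), NA_real_)
  if (!is.null(purity)) {
    stopifnot(purity > 0, purity <= 1)
    ratio <- pmin(1, pmax(0, (ratio - (1 - purity)) / purity))
  }
  fr <- data.frame(series = di$series, index = di$index, charge = di$charge,
                   mz_light = mz_light, mz_heavy = mz_heavy,
                   light_area = la, heavy_area = ha, ratio = ratio,
                   pass = pass, stringsAsFactors = FALSE)
  fr$rank <- NA_integer_
  qc <- character()
  if (!any(pass)) {
    qc <- "no fragments above threshold"
    med <- r1 <- NA_real_
  } else {
    if (!is.null(ranks)) {
      key <- .frag_id(fr); rkey <- .frag_id(ranks)
      fr$rank <- ranks$rank[match(key, rkey)]
      ord <- order(fr$rank)
    } else {
      ord <- order(-(fr$light_area + fr$heavy_area))
    }
    fr$rank[ord] <- seq_len(nrow(fr))
    passing <- fr[fr$pass, , drop = FALSE]
    med <- .median_low(passing$ratio)
    r1 <- passing$ratio[which.min(passing$rank)]
  }
  structure(list(target = target, site = site,
                 site_number = target$site_numbers[
                   match(site, target$peptide_positions)],
                 fragments = fr, median_ratio = med, rank1_ratio = r1,
                 co_isolated = TRUE, window = window, qc = qc),
            class = "site_stoichiometry")
}

## label-count ladder probabilities under per-site independence:
## coefficients of prod_i (theta_i + (1 - theta_i) x)
.ladder_probs <- function(thetas) {
  p <- 1
  for (th in thetas) p <- stats::convolve(p, rev(c(th, 1 - th)), type = "open")
  p
}

#' Quantify occupancy for peptides with two or three acyl lysines
#'
#' The first lysine is quantified from its strict differentiating b-ions and
#' the last from its strict y-ions (fragments containing exactly one site).
#' For three-lysine peptides no single-site fragment isolates the middle
#' lysine; its occupancy is estimated in extended mode from the label-count
#' ladders of multi-site fragments, modelling per-site label states as
#' independent and solving for the middle occupancy by least squares given
#' the b-/y-derived flanking estimates. Middle-site results carry an
#' "extended-mode estimate" QC note. Co-isolation of every label
#' permutation (e.g. LL, mixed and HH species) in one window is required.
#'
#' @inheritParams quantify_site
#' @return List of `site_stoichiometry` objects, one per site in peptide
#'   order.
#' @export
quantify_multisite <- function(run, scheme, target, ppm_tol = 20,
                               min_heavy_area = 1000, fragment_charges = 1L,
                               ranks = NULL, purity = NULL) {
  stopifnot(inherits(target, "target_entry"))
  sites <- target$peptide_positions
  k <- length(sites)
  if (k < 2L || k > 3L)
    stop("quantify_multisite handles 2 or 3 acyl sites (got ", k, ")")
  res <- lapply(sites, function(s)
    quantify_site(run, scheme, target, site = s, ppm_tol = ppm_tol,
                  min_heavy_area = min_heavy_area,
                  fragment_charges = fragment_charges, ranks = ranks,
                  purity = purity))
  names(res) <- paste0("K", target$site_numbers)
  if (k == 3L) {
    res[[2]] <- .estimate_middle_site(run, scheme, target, res,
                                      ppm_tol, min_heavy_area,
                                      fragment_charges)
  }
  res
}

.estimate_middle_site <- function(run, scheme, target, res, ppm_tol,
                                  min_heavy_area, fragment_charges) {
  sites <- target$peptide_positions
  th1 <- res[[1]]$median_ratio
  th3 <- res[[3]]$median_ratio
  mid <- sites[2]
  if (is.na(th1) || is.na(th3) || !res[[1]]$co_isolated)
    return(.empty_site_result(target, mid,
                              "middle site: flanking estimates unavailable"))
  light_pep <- acyl_peptide(target$sequence, sites, "light",
                            target$family, target$charge)
  di <- differentiating_ions(light_pep, mid, mode = "extended",
                             fragment_charges = fragment_charges)
  di <- di[di$n_sites >= 2L, , drop = FALSE]
  if (!nrow(di))
    return(.empty_site_result(target, mid, "middle site: no multi-site fragments"))
  window <- res[[1]]$window
  borders <- target$rt_borders
  # observed normalized label-count ladders, one per usable fragment
  obs <- list(); mods <- list()
  base <- fragment_ions(light_pep, charges = fragment_charges)
  base_id <- .frag_id(base)
  for (i in seq_len(nrow(di))) {
    areas <- vapply(di$mz_ladder[[i]], .channel_area, 0,
                    ppm_tol, borders, window, run = run)
    if (max(areas) < min_heavy_area) next
    contained <- base$sites[[match(.frag_id(di[i, ]), base_id)]]
    obs[[length(obs) + 1L]] <- areas / sum(areas)
    mods[[length(mods) + 1L]] <- contained
  }
  if (!length(obs))
    return(.empty_site_result(target, mid,
                              "middle site: no multi-site fragments above threshold"))
  known <- c(th1, NA, th3); names(known) <- as.character(sites)
  objective <- function(th2) {
    known[2] <- th2
    sum(vapply(seq_along(obs), function(j) {
      p <- .ladder_probs(known[as.character(mods[[j]])])
      sum((obs[[j]] - p)^2)
    }, 0))
  }
  opt <- stats::optimize(objective, c(0, 1), tol = 1e-10)
  out <- .empty_site_result(target, mid, character())
  out$median_ratio <- out$rank1_ratio <- opt$minimum
  out$co_isolated <- TRUE
  out$window <- window
  out$qc <- "extended-mode estimate (label-independence model)"
  out
}

#' MS1 precursor-level occupancy (for comparison with MS2)
#'
#' Occupancy from the monoisotopic (highest-ranked) light and heavy
#' precursor XIC areas, L/(L+H); the top-`n_isotopes` areas per channel are
#' retained in the report. Only single-site targets are supported: with
#' multiple lysines the mixed label permutations share precursor m/z and
#' cannot be differentiated at the MS1 level.
#'
#' @param run A [spectrum_run()].
#' @param target A single-site [target_entry()].
#' @param ppm_tol ppm tolerance (default 20).
#' @param n_isotopes Isotopes per channel (default 3: M, M+1, M+2).
#' @return List with `occupancy`, `light_areas`, `heavy_areas` (numeric
#'   vectors, M first), and `qc`.
#' @export
ms1_stoichiometry <- function(run, target, ppm_tol = 20, n_isotopes = 3L) {
  stopifnot(inherits(target, "target_entry"))
  if (length(target$peptide_positions) != 1L)
    stop("MS1 occupancy is undefined for multi-site peptides: mixed light/",
         "heavy permutations share precursor m/z and cannot be separated; ",
         "use quantify_multisite")
  lp <- acyl_peptide(target$sequence, target$peptide_positions, "light",
                     target$family, target$charge)
  hp <- acyl_peptide(target$sequence, target$peptide_positions, "heavy",
                     target$family, target$charge)
  la <- ms1_isotope_areas(run, lp, n_isotopes, ppm_tol, target$rt_borders)
  ha <- ms1_isotope_areas(run, hp, n_isotopes, ppm_tol, target$rt_borders)
  lv <- vapply(la, `[[`, 0, "area")
  hv <- vapply(ha, `[[`, 0, "area")
  if (lv[1] + hv[1] <= 0)
    return(list(occupancy = NA_real_, light_areas = lv, heavy_areas = hv,
                qc = "both precursor channels empty"))
  list(occupancy = lv[1] / (lv[1] + hv[1]), light_areas = lv,
       heavy_areas = hv, qc = character())
}

#' Flatten site results to fragment- and site-level tables
#'
#' @param results List of `site_stoichiometry` objects.
#' @return List with data frames `fragments` (one row per target, site and
#'   fragment) and `sites` (one summary row per target site).
#' @export
stoichiometry_tables <- function(results) {
  frag <- list(); site <- list()
  for (r in results) {
    t <- r$target
    base <- data.frame(sequence = t$sequence, protein = t$protein,
                       site_number = r$site_number, family = t$family,
                       charge = t$charge, run_file = t$run_file,
                       stringsAsFactors = FALSE)
    if (nrow(r$fragments))
      frag[[length(frag) + 1L]] <- cbind(base[rep(1L, nrow(r$fragments)), ],
                                         r$fragments, row.names = NULL)
    site[[length(site) + 1L]] <- cbind(base, data.frame(
      median_ratio = r$median_ratio, rank1_ratio = r$rank1_ratio,
      n_passing = sum(r$fragments$pass), co_isolated = r$co_isolated,
      window = r$window,
      qc = paste(r$qc, collapse = "; "), stringsAsFactors = FALSE),
      row.names = NULL)
  }
  list(fragments = if (length(frag)) do.call(rbind, frag) else NULL,
       sites = do.call(rbind, site))
}
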