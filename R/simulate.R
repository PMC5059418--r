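#' Specify one simulated acyl peptide
#'
#' Describes a light/heavy acyl peptide pair for the SWATH simulator: the
#' per-site true occupancy is the fraction of molecules carrying the
#' endogenous (light) acyl group, i.e. the quantity L/(L+H) estimates.
#'
#' @param sequence Peptide sequence (uppercase).
#' @param sites Acyl-site positions (1-based, K residues).
#' @param occupancy True light occupancy per site, in `[0, 1]` (recycled).
#' @param family `"acetyl"` or `"succinyl"`.
#' @param charge Precursor charge.
#' @param abundance Total precursor abundance (XIC area units,
#'   intensity x minutes).
#' @param rt_apex Elution apex (minutes).
#' @param rt_sd Gaussian elution peak standard deviation (minutes).
#' @param fragment_intensities Optional named vector of relative fragment
#'   intensities (names like `"b3^1"`, `"y5^1"`); defaults to a smooth
#'   deterministic ladder profile peaking at mid-sequence ions.
#' @return An object of class `sim_peptide`.
#' @export
sim_peptide <- function(sequence, sites, occupancy, family = "acetyl",
                        charge = 2L, abundance = 1e6, rt_apex = 10,
                        rt_sd = 0.08, fragment_intensities = NULL) {
  occupancy <- rep_len(occupancy, length(sites))
  stopifnot(all(occupancy >= 0), all(occupancy <= 1),
            abundance > 0, rt_sd > 0)
  # validates sequence, sites, charge
  acyl_peptide(sequence, sites, "light", family, charge)
  structure(list(sequence = sequence, sites = as.integer(sites),
                 occupancy = occupancy, family = family,
                 charge = as.integer(charge), abundance = abundance,
                 rt_apex = rt_apex, rt_sd = rt_sd,
                 fragment_intensities = fragment_intensities),
            class = "sim_peptide")
}

#' Specify a SWATH simulation scenario
#'
#' Collects everything the generator needs to emit a run: the peptides, the
#' window scheme, acquisition timing, the noise model, and the chemistry
#' parameters (heavy-reagent isotopic purity and labelling completeness).
#' With purity p, each chemically labelled site carries the light mass with
#' probability 1-p, which puts a floor of about 1-p on apparent occupancy;
#' with completeness c, a fraction 1-c of chemically targeted lysines stays
#' unmodified and contributes to neither channel.
#'
#' @param peptides List of [sim_peptide()] objects.
#' @param scheme A [swath_scheme()]; default [default_window_scheme()].
#' @param cycle_time Acquisition cycle time in seconds (default 3.2: one
#'   MS1 scan plus one MS2 scan per window per cycle).
#' @param purity Heavy-reagent isotopic purity in (0, 1] (default 1).
#' @param completeness Chemical labelling completeness in (0, 1] (default
#'   1).
#' @param noise `"none"` or `"poisson"`: with `"poisson"`, every generated
#'   stick intensity is replaced by a Poisson draw with that mean.
#' @param baseline_peaks Number of random baseline peaks added per scan
#'   (default 0).
#' @param baseline_intensity Mean intensity of baseline peaks (exponential
#'   draw).
#' @param interferences Optional data frame with columns `level` ("MS1" or
#'   "MS2"), `mz`, `rt_apex`, `rt_sd`, `intensity` (area units) and
#'   `window` (0-based, MS2 only) describing injected interfering signals.
#' @param ms2_yield Fraction of precursor abundance converted to summed
#'   fragment signal (default 0.5).
#' @param rt_range Optional run retention-time range `c(lo, hi)` (minutes);
#'   default covers every peptide apex +/- 5 sd.
#' @param emit_all_windows Emit an MS2 scan for every scheme window each
#'   cycle (default TRUE, as on the instrument); FALSE restricts scans to
#'   windows containing simulated signal, for compact test runs.
#' @param seed Integer seed driving all randomness (recorded in the ground
#'   truth).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(peptides, scheme = default_window_scheme(),
                         cycle_time = 3.2, purity = 1, completeness = 1,
                         noise = c("none", "poisson"), baseline_peaks = 0L,
                         baseline_intensity = 50, interferences = NULL,
                         ms2_yield = 0.5, rt_range = NULL,
                         emit_all_windows = TRUE, seed = 1L) {
  noise <- match.arg(noise)
  if (inherits(peptides, "sim_peptide")) peptides <- list(peptides)
  stopifnot(all(vapply(peptides, inherits, TRUE, "sim_peptide")),
            inherits(scheme, "swath_scheme"), cycle_time > 0)
  if (!(purity > 0 && purity <= 1)) stop("purity must be in (0, 1]")
  if (!(completeness > 0 && completeness <= 1))
    stop("completeness must be in (0, 1]")
  if (!is.null(interferences)) {
    need <- c("level", "mz", "rt_apex", "rt_sd", "intensity")
    miss <- setdiff(need, names(interferences))
    if (length(miss)) stop("interferences missing columns: ",
                           paste(miss, collapse = ", "))
    if (is.null(interferences$window)) interferences$window <- NA_integer_
  }
  structure(list(peptides = peptides, scheme = scheme,
                 cycle_time = cycle_time, purity = purity,
                 completeness = completeness, noise = noise,
                 baseline_peaks = as.integer(baseline_peaks),
                 baseline_intensity = baseline_intensity,
                 interferences = interferences, ms2_yield = ms2_yield,
                 rt_range = rt_range, emit_all_windows = emit_all_windows,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

## default relative fragment intensity profile: smooth triangular ladder
.default_fragment_intensities <- function(n) {
  idx <- seq_len(n - 1L)
  prof <- 0.25 + pmin(idx, n - idx) / n
  c(stats::setNames(prof, paste0("b", idx, "^1")),
    stats::setNames(prof, paste0("y", idx, "^1")))
}

## neutral mass and fragment m/z for one label-state vector, where states
## may be "light", "heavy" or "unmod" (residual unlabelled lysine)
.species_masses <- function(sequence, sites, states, family, charge) {
  tab <- residue_mass_table()
  res <- strsplit(sequence, "")[[1]]
  fam <- acyl_family(family)
  d <- numeric(length(res))
  d[res == "C"] <- .mod_delta("carbamidomethyl")
  if (length(sites))
    d[sites] <- d[sites] + vapply(states, function(s)
      switch(s, light = fam$delta_light, heavy = fam$delta_heavy, unmod = 0),
      0)
  rm <- tab$residues[res] + d
  n <- length(res)
  fwd <- cumsum(rm)
  mass <- fwd[n] + tab$water
  idx <- seq_len(n - 1L)
  list(
    mass = mass,
    prec_mz = (mass + charge * tab$proton) / charge,
    frag_mz = c(
      stats::setNames((fwd[idx] + tab$proton) / 1, paste0("b", idx, "^1")),
      stats::setNames((fwd[n] - fwd[n - idx] + tab$water + tab$proton) / 1,
                      paste0("y", idx, "^1")))
  )
}

## enumerate label-state species with expected-fraction weights
.enumerate_species <- function(pep, purity, completeness) {
  k <- length(pep$sites)
  states <- c("light", "heavy", if (completeness < 1) "unmod")
  grid <- do.call(expand.grid,
                  c(rep(list(states), k), stringsAsFactors = FALSE))
  w <- rep(1, nrow(grid))
  for (i in seq_len(k)) {
    th <- pep$occupancy[i]
    p_state <- c(light = th + (1 - th) * completeness * (1 - purity),
                 heavy = (1 - th) * completeness * purity,
                 unmod = (1 - th) * (1 - completeness))
    w <- w * p_state[grid[[i]]]
  }
  keep <- w > 1e-12
  list(states = grid[keep, , drop = FALSE], weight = unname(w[keep]))
}

## averagine-style Poisson isotope envelope (first n isotopes)
.isotope_envelope <- function(mass, n = 4L) {
  lambda <- 5.47e-4 * mass
  e <- stats::dpois(0:(n - 1L), lambda)
  e / sum(e)
}

#' Generate a synthetic SWATH run
#'
#' Emits a complete acquisition: MS1 scans carrying the light and heavy
#' precursor isotope envelopes of every label-state species (envelope from
#' a Poisson averagine-style approximation, first 4 isotopes; reagent
#' purity folded into the species weights) and MS2 scans per SWATH window
#' carrying the b/y fragment ladders of every label permutation weighted by
#' per-site occupancy, purity and labelling completeness. Elution peaks are
#' Gaussian in retention time on the cycle-time grid; spectra are centroid
#' sticks. Optional Poisson noise, baseline peaks, and injected
#' interferences. All randomness derives from the scenario seed; the
#' ground-truth record is sufficient to recompute every expected peak area
#' in closed form (species XIC area = abundance x weight x isotope
#' fraction).
#'
#' @param scenario A [sim_scenario()].
#' @param dir Optional output directory; when given, writes `run.mzML`,
#'   `windows.tsv`, `targets.tsv` and `truth.json` and returns their paths
#'   in `files`.
#' @return List with `run` (a [spectrum_run()]), `scheme`, `targets` (list
#'   of [target_entry()]), `truth` (ground-truth record) and `files`.
#' @export
simulate_run <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(scenario$seed)
  sc <- scenario$scheme
  peps <- scenario$peptides
  rng <- scenario$rt_range
  if (is.null(rng)) {
    lo <- min(vapply(peps, function(p) p$rt_apex - 5 * p$rt_sd, 0))
    hi <- max(vapply(peps, function(p) p$rt_apex + 5 * p$rt_sd, 0))
    if (!is.null(scenario$interferences)) {
      lo <- min(lo, scenario$interferences$rt_apex -
                  5 * scenario$interferences$rt_sd)
      hi <- max(hi, scenario$interferences$rt_apex +
                  5 * scenario$interferences$rt_sd)
    }
    rng <- c(max(0, lo), hi)
  }
  cyc <- scenario$cycle_time / 60
  cycles <- seq(rng[1], rng[2], by = cyc)

  # --- enumerate species, their windows and stick templates ---
  truth_peps <- list(); excluded <- character()
  all_species <- list()
  for (ip in seq_along(peps)) {
    p <- peps[[ip]]
    en <- .enumerate_species(p, scenario$purity, scenario$completeness)
    fint <- p$fragment_intensities
    if (is.null(fint))
      fint <- .default_fragment_intensities(nchar(p$sequence))
    fint <- fint / sum(fint)
    spl <- list()
    for (is in seq_len(nrow(en$states))) {
      st <- as.character(unlist(en$states[is, ]))
      sm <- .species_masses(p$sequence, p$sites, st, p$family, p$charge)
      win <- assign_window(sm$prec_mz, sc)
      spl[[is]] <- list(states = st, weight = en$weight[is],
                        mass = sm$mass, prec_mz = sm$prec_mz,
                        window = win, frag_mz = sm$frag_mz[names(fint)],
                        envelope = .isotope_envelope(sm$mass),
                        charge = p$charge, abundance = p$abundance,
                        rt_apex = p$rt_apex, rt_sd = p$rt_sd,
                        frag_rel = fint)
    }
    wins <- vapply(spl, function(s)
      if (is.na(s$window)) -1L else s$window, 0L)
    if (any(wins < 0L)) {
      excluded <- c(excluded, p$sequence)
      warning("peptide ", p$sequence,
              " has precursor species outside the window scheme; excluded")
      next
    }
    truth_peps[[length(truth_peps) + 1L]] <- list(
      sequence = p$sequence, sites = p$sites, occupancy = p$occupancy,
      family = p$family, charge = p$charge, abundance = p$abundance,
      rt_apex = p$rt_apex, rt_sd = p$rt_sd,
      species = data.frame(
        states = vapply(spl, function(s) paste(s$states, collapse = ""), ""),
        weight = vapply(spl, `[[`, 0, "weight"),
        prec_mz = vapply(spl, `[[`, 0, "prec_mz"),
        window = vapply(spl, `[[`, 0L, "window"),
        ms1_area = vapply(spl, function(s) s$abundance * s$weight, 0),
        stringsAsFactors = FALSE),
      shape_by_cycle = stats::dnorm(cycles, p$rt_apex, p$rt_sd))
    all_species <- c(all_species, spl)
  }

  active_windows <- sort(unique(c(
    vapply(all_species, `[[`, 0L, "window"),
    if (!is.null(scenario$interferences))
      as.integer(stats::na.omit(
        scenario$interferences$window[scenario$interferences$level == "MS2"]))
  )))
  win_idx <- if (scenario$emit_all_windows)
    sc$windows$index else active_windows

  interf <- scenario$interferences
  noisy <- scenario$noise == "poisson"
  nb <- scenario$baseline_peaks
  scan_offsets <- c(0, (0.25 + 0.045 * seq_along(win_idx)) / 60)

  # precompute elution shapes (cycles x species) and window grouping
  shape <- vapply(all_species, function(s)
    stats::dnorm(cycles, s$rt_apex, s$rt_sd), numeric(length(cycles)))
  if (length(cycles) == 1L) shape <- matrix(shape, nrow = 1L)
  peak_height <- vapply(all_species, function(s)
    s$abundance * s$weight, 0)
  by_win <- split(seq_along(all_species),
                  vapply(all_species, `[[`, 0L, "window"))

  header <- list(); peaks <- list(); sn <- 0L
  add_scan <- function(rt, lvl, win, ilo, iup, mz, int) {
    sn <<- sn + 1L
    if (noisy && length(int)) int <- stats::rpois(length(int), int)
    if (nb > 0L) {
      lo <- if (lvl == 1L) sc$range[1] else 100
      hi <- if (lvl == 1L) sc$range[2] else 1400
      mz <- c(mz, stats::runif(nb, lo, hi))
      int <- c(int, stats::rexp(nb, 1 / scenario$baseline_intensity))
    }
    keep <- int > 0
    o <- order(mz[keep])
    header[[sn]] <<- data.frame(ms_level = lvl, rt = rt, window = win,
                                iso_lower = ilo, iso_upper = iup)
    peaks[[sn]] <<- cbind(mz = mz[keep][o], intensity = int[keep][o])
  }

  sticks_interf <- function(lvl, win, t) {
    if (is.null(interf)) return(NULL)
    sel <- interf$level == (if (lvl == 1L) "MS1" else "MS2") &
      (lvl == 1L | (!is.na(interf$window) & interf$window == win))
    if (!any(sel)) return(NULL)
    i <- interf[sel, , drop = FALSE]
    cbind(i$mz, i$intensity * stats::dnorm(t, i$rt_apex, i$rt_sd))
  }

  for (ci in seq_along(cycles)) {
    t <- cycles[ci]
    # MS1 scan
    mz <- numeric(); int <- numeric()
    for (k in which(peak_height * shape[ci, ] > 1e-6)) {
      s <- all_species[[k]]
      h <- peak_height[k] * shape[ci, k]
      mz <- c(mz, s$prec_mz + (0:3) * .C13_SPACING / s$charge)
      int <- c(int, h * s$envelope)
    }
    si <- sticks_interf(1L, NA, t)
    if (!is.null(si)) { mz <- c(mz, si[, 1]); int <- c(int, si[, 2]) }
    add_scan(t, 1L, NA_integer_, NA_real_, NA_real_, mz, int)
    # MS2 scans
    for (j in seq_along(win_idx)) {
      w <- win_idx[j]
      mz <- numeric(); int <- numeric()
      for (k in by_win[[as.character(w)]]) {
        h <- peak_height[k] * scenario$ms2_yield * shape[ci, k]
        if (h < 1e-6) next
        s <- all_species[[k]]
        mz <- c(mz, s$frag_mz)
        int <- c(int, h * s$frag_rel)
      }
      si <- sticks_interf(2L, w, t)
      if (!is.null(si)) { mz <- c(mz, si[, 1]); int <- c(int, si[, 2]) }
      wrow <- sc$windows[sc$windows$index == w, ]
      add_scan(t + scan_offsets[j + 1L], 2L, w, wrow$lower, wrow$upper,
               mz, int)
    }
  }

  run <- spectrum_run(do.call(rbind, header), peaks, source = "simulated")
  targets <- lapply(truth_peps, function(tp)
    target_entry(tp$sequence, tp$sites, protein = "SYNTHETIC",
                 family = tp$family, charge = tp$charge,
                 rt_borders = c(tp$rt_apex - 4 * tp$rt_sd,
                                tp$rt_apex + 4 * tp$rt_sd),
                 run_file = "run.mzML"))
  truth <- list(seed = scenario$seed, purity = scenario$purity,
                completeness = scenario$completeness,
                cycle_rt = cycles, peptides = truth_peps,
                excluded = excluded)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(mzml = file.path(dir, "run.mzML"),
                  windows = file.path(dir, "windows.tsv"),
                  targets = file.path(dir, "targets.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_run(run, files$mzml)
    write_window_scheme(sc, files$windows)
    write_targets(targets, files$targets)
    jsonlite::write_json(
      list(seed = truth$seed, purity = truth$purity,
           completeness = truth$completeness, excluded = truth$excluded,
           peptides = lapply(truth_peps, function(tp)
             tp[c("sequence", "sites", "occupancy", "family", "charge",
                  "abundance", "rt_apex", "rt_sd", "species")])),
      files$truth, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  }
  list(run = run, scheme = sc, targets = targets, truth = truth,
       files = files)
}

## deterministic synthetic peptide panel: single-K, Glu-C-like (ends in E),
## precursors inside the default scheme range at z=2 with the light/heavy
## pair co-isolated (the same pre-check target building applies to real
## peptides)
.synthetic_peptide_panel <- function(n, family = "succinyl") {
  aa <- c("A", "G", "L", "V", "S", "T", "F", "N", "Q", "I", "P", "R")
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(1799L)
  scheme <- default_window_scheme()
  fam <- acyl_family(family)
  out <- character(0); sites <- integer(0)
  while (length(out) < n) {
    len <- sample(8:12, 1)
    kpos <- sample(2:(len - 2), 1)
    res <- sample(aa, len, replace = TRUE)
    res[kpos] <- "K"; res[len] <- "E"
    seqs <- paste(res, collapse = "")
    lmz <- precursor_mz(acyl_peptide(seqs, kpos, "light", family, 2L))
    hmz <- lmz + fam$pair_delta / 2
    if (lmz > 405 && hmz < 1245 && !seqs %in% out &&
        co_isolated(lmz, hmz, scheme)$co_isolated) {
      out <- c(out, seqs); sites <- c(sites, kpos)
    }
  }
  data.frame(sequence = out, site = sites, stringsAsFactors = FALSE)
}

#' Dilution-series scenario of defined light fractions
#'
#' Emulates the defined-mixture validation design: a panel of 18 acyl
#' peptides measured at each of several defined light-modification
#' fractions (e.g. 0, 1, 10, 50 and 100 percent). The separate mixtures are
#' laid out as consecutive retention-time blocks of one scenario, one block
#' per fraction, so a single simulated run carries the whole dilution
#' curve. The peptide panel is synthetic (deterministic single-K sequences;
#' no real protein sequence is bundled).
#'
#' @param light_fractions Numeric vector of defined light fractions in
#'   `[0, 1]`.
#' @param n_peptides Panel size (default 18).
#' @param family Acyl family (default `"succinyl"`).
#' @param purity Heavy-reagent isotopic purity (default 0.98, the reported
#'   purity of the d4 succinylation reagent).
#' @param noise Noise model passed to [sim_scenario()] (default
#'   `"poisson"`).
#' @param seed Scenario seed.
#' @return A [sim_scenario()]; empty `light_fractions` gives a scenario
#'   with no peptides.
#' @export
bsa_mixture_scenario <- function(light_fractions, n_peptides = 18L,
                                 family = "succinyl", purity = 0.98,
                                 noise = "poisson", seed = 1L) {
  stopifnot(all(light_fractions >= 0), all(light_fractions <= 1))
  panel <- .synthetic_peptide_panel(n_peptides, family)
  peps <- list()
  block_len <- n_peptides * 0.35 + 1
  for (fi in seq_along(light_fractions)) {
    t0 <- 1 + (fi - 1) * block_len
    for (j in seq_len(n_peptides)) {
      peps[[length(peps) + 1L]] <- sim_peptide(
        panel$sequence[j], panel$site[j],
        occupancy = light_fractions[fi], family = family,
        abundance = 1e6, rt_apex = t0 + (j - 1) * 0.35, rt_sd = 0.05)
    }
  }
  sim_scenario(peps, purity = purity, noise = noise,
               emit_all_windows = FALSE, seed = seed)
}
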