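#' Monoisotopic residue mass table
#'
#' Standard monoisotopic residue (amino-acid minus water) masses for the 20
#' proteinogenic amino acids, together with the water and proton masses used
#' throughout the package. All values in Da.
#'
#' @return A list with elements `residues` (named numeric vector, one-letter
#'   codes), `water` and `proton`.
#' @export
#' @examples
#' residue_mass_table()$residues[["K"]]
residue_mass_table <- function() {
  list(
    residues = c(
      G = 57.02146372, A = 71.03711379, S = 87.03202840, P = 97.05276385,
      V = 99.06841391, T = 101.04767846, C = 103.00918448, L = 113.08406398,
      I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
      K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
      F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
    ),
    water  = 18.0105646863,
    proton = 1.00727646688
  )
}

## C12->C13 spacing used for isotope envelopes / MS1 isotope XICs
.C13_SPACING <- 1.0033548378

#' Built-in modification specifications
#'
#' Monoisotopic mass deltas for the fixed and variable modifications of the
#' acylation-stoichiometry workflow: carbamidomethylation of cysteine (fixed),
#' and the light/heavy acyl pairs on lysine. Heavy acetyl is the d3 form
#' installed by acetic anhydride-d6; heavy succinyl the d4 form installed by
#' succinic anhydride-d4.
#'
#' @return A data frame with columns `name`, `target` (residue code), `delta`
#'   (Da) and `partner` (isotopic counterpart, `NA` for unpaired mods).
#' @export
modification_specs <- function() {
  data.frame(
    name    = c("carbamidomethyl", "acetyl", "acetyl_d3", "succinyl", "succinyl_d4"),
    target  = c("C", "K", "K", "K", "K"),
    delta   = c(57.021464, 42.010565, 45.029395, 100.016044, 104.041152),
    partner = c(NA, "acetyl_d3", "acetyl", "succinyl_d4", "succinyl"),
    stringsAsFactors = FALSE
  )
}

#' Light/heavy modification pair for an acyl family
#'
#' @param family `"acetyl"` or `"succinyl"`.
#' @return List with `light`, `heavy` (modification names), their `delta`
#'   masses and `pair_delta` = heavy minus light (3.018830 Da for acetyl,
#'   4.025108 Da for succinyl).
#' @export
acyl_family <- function(family = c("acetyl", "succinyl")) {
  family <- match.arg(family)
  specs <- modification_specs()
  light <- family
  heavy <- specs$partner[specs$name == family]
  dl <- specs$delta[specs$name == light]
  dh <- specs$delta[specs$name == heavy]
  list(family = family, light = light, heavy = heavy,
       delta_light = dl, delta_heavy = dh, pair_delta = dh - dl)
}

.mod_delta <- function(name) {
  specs <- modification_specs()
  i <- match(name, specs$name)
  if (anyNA(i)) stop("unknown modification: ", paste(name[is.na(i)], collapse = ", "))
  specs$delta[i]
}

#' Construct an acyl peptide
#'
#' An `acyl_peptide` couples a peptide sequence with its fixed modifications
#' (carbamidomethyl on every cysteine, applied automatically), the positions
#' of acyl-modified lysines, the per-site label state (light = endogenous
#' acyl, heavy = chemically installed isotope-labelled acyl) and the
#' precursor charge.
#'
#' @param sequence Uppercase one-letter peptide sequence.
#' @param sites Integer vector of 1-based acyl-site positions (must be K),
#'   strictly increasing. May be empty.
#' @param labels Character vector, `"light"`/`"heavy"` per site; a single
#'   value is recycled.
#' @param family Acyl family, `"acetyl"` or `"succinyl"`.
#' @param charge Precursor charge (positive integer).
#' @return An object of class `acyl_peptide`.
#' @export
#' @examples
#' p <- acyl_peptide("TYVPKAFDE", sites = 5, labels = "light", charge = 2)
#' precursor_mz(p)
acyl_peptide <- function(sequence, sites = integer(), labels = "light",
                         family = c("acetyl", "succinyl"), charge = 2L) {
  family <- match.arg(family)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  tab <- residue_mass_table()$residues
  bad <- which(!res %in% names(tab))
  if (length(bad))
    stop("non-residue character '", res[bad[1]], "' at position ", bad[1])
  sites <- as.integer(sites)
  if (length(sites)) {
    if (any(sites < 1L) || any(sites > length(res)))
      stop("acyl site position out of range")
    if (is.unsorted(sites, strictly = TRUE))
      stop("acyl site positions must be strictly increasing")
    if (any(res[sites] != "K"))
      stop("acyl site on non-K residue at position ",
           sites[which(res[sites] != "K")[1]])
  }
  labels <- rep_len(labels, length(sites))
  if (length(labels) && !all(labels %in% c("light", "heavy")))
    stop("labels must be 'light' or 'heavy'")
  charge <- as.integer(charge)
  if (charge < 1L) stop("charge must be a positive integer")
  structure(
    list(sequence = sequence, residues = res, sites = sites,
         labels = labels, family = family, charge = charge),
    class = "acyl_peptide"
  )
}

#' @export
print.acyl_peptide <- function(x, ...) {
  lab <- if (length(x$sites))
    paste(sprintf("K%d:%s", x$sites, x$labels), collapse = " ") else "none"
  cat("acyl_peptide ", x$sequence, " (", x$family, ", z=", x$charge,
      ", sites: ", lab, ")\n", sep = "")
  invisible(x)
}

## per-residue modification deltas (fixed cam on C + acyl per label state)
.residue_mod_deltas <- function(pep) {
  fam <- acyl_family(pep$family)
  d <- numeric(length(pep$residues))
  d[pep$residues == "C"] <- .mod_delta("carbamidomethyl")
  if (length(pep$sites))
    d[pep$sites] <- d[pep$sites] +
      ifelse(pep$labels == "light", fam$delta_light, fam$delta_heavy)
  d
}

#' Monoisotopic neutral mass of an acyl peptide
#'
#' Sum of residue masses plus water plus all modification deltas (fixed
#' carbamidomethyl and per-site acyl masses according to label state).
#'
#' @param peptide An [acyl_peptide()].
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mono_mass <- function(peptide) {
  stopifnot(inherits(peptide, "acyl_peptide"))
  tab <- residue_mass_table()
  sum(tab$residues[peptide$residues]) + tab$water +
    sum(.residue_mod_deltas(peptide))
}

#' Precursor m/z from neutral mass and charge
#'
#' @param x Neutral monoisotopic mass (Da) or an [acyl_peptide()] (whose
#'   charge is used when `charge` is missing).
#' @param charge Positive integer charge.
#' @return (mass + charge * proton) / charge.
#' @export
precursor_mz <- function(x, charge = NULL) {
  if (inherits(x, "acyl_peptide")) {
    if (is.null(charge)) charge <- x$charge
    x <- peptide_mono_mass(x)
  }
  charge <- as.integer(charge)
  if (any(charge < 1L)) stop("charge must be >= 1")
  (x + charge * residue_mass_table()$proton) / charge
}

#' Theoretical b- and y-fragment ions of an acyl peptide
#'
#' Enumerates b_i and y_j ions for i, j in 1..(length-1) (the full-length
#' b_n/y_n species are excluded: they are not observable as distinct
#' fragments). Modification masses are placed on the fragment that contains
#' the modified residue; each fragment records which acyl sites it contains
#' and their label states, which is what makes an ion "differentiating"
#' (light and heavy forms differ in m/z) or "common" (no site contained).
#'
#' @param peptide An [acyl_peptide()].
#' @param series Subset of `c("b", "y")`.
#' @param charges Integer vector of fragment charges (default 1).
#' @return Data frame with columns `series`, `index`, `charge`, `mz`,
#'   `sites` (list of contained acyl-site positions) and `labels` (list of
#'   their label states).
#' @export
fragment_ions <- function(peptide, series = c("b", "y"), charges = 1L) {
  stopifnot(inherits(peptide, "acyl_peptide"))
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  charges <- as.integer(charges)
  if (any(charges < 1L)) stop("fragment charges must be >= 1")
  tab <- residue_mass_table()
  n <- length(peptide$residues)
  if (n < 2L) return(.empty_fragment_df())
  rm <- tab$residues[peptide$residues] + .residue_mod_deltas(peptide)
  fwd <- cumsum(rm)                       # b_i neutral residue sum
  out <- list()
  site_of <- function(pos) {
    i <- match(pos, peptide$sites)
    list(pos = peptide$sites[i], lab = peptide$labels[i])
  }
  for (z in charges) {
    if ("b" %in% series) {
      idx <- seq_len(n - 1L)
      mzs <- (fwd[idx] + z * tab$proton) / z
      cs <- lapply(idx, function(i) peptide$sites[peptide$sites <= i])
      out[[length(out) + 1L]] <- data.frame(
        series = "b", index = idx, charge = z, mz = mzs,
        stringsAsFactors = FALSE
      ) |> .add_site_cols(cs, peptide)
    }
    if ("y" %in% series) {
      idx <- seq_len(n - 1L)
      rev_sum <- fwd[n] - fwd[n - idx]    # sum of last j residues
      mzs <- (rev_sum + tab$water + z * tab$proton) / z
      cs <- lapply(idx, function(j) peptide$sites[peptide$sites > n - j])
      out[[length(out) + 1L]] <- data.frame(
        series = "y", index = idx, charge = z, mz = mzs,
        stringsAsFactors = FALSE
      ) |> .add_site_cols(cs, peptide)
    }
  }
  do.call(rbind, out)
}

.add_site_cols <- function(df, contained, peptide) {
  df$sites <- I(contained)
  df$labels <- I(lapply(contained, function(s)
    peptide$labels[match(s, peptide$sites)]))
  df
}

.empty_fragment_df <- function() {
  data.frame(series = character(), index = integer(), charge = integer(),
             mz = numeric(), sites = I(list()), labels = I(list()),
             stringsAsFactors = FALSE)
}

#' In-silico Glu-C digestion
#'
#' Cleaves a protein strictly C-terminal to glutamate (E) and aspartate (D),
#' the specificity used for per-acylated proteins: unlike trypsin, Glu-C is
#' unaffected by lysine acylation. With `max_missed_cleavages = 0` the
#' peptides partition the protein; with k missed cleavages every contiguous
#' join of up to k+1 fully cleaved peptides is also returned.
#'
#' @param protein_sequence Uppercase protein sequence.
#' @param max_missed_cleavages Non-negative integer (default 0).
#' @param cleave_after Residues defining the cleavage rule (C-terminal side);
#'   default `c("E", "D")`. A generic hook for other proteases.
#' @return Data frame with columns `peptide`, `start`, `end` (1-based,
#'   inclusive protein coordinates) and `missed` (number of missed
#'   cleavages).
#' @export
#' @examples
#' digest_gluc("ACDEFG")
digest_gluc <- function(protein_sequence, max_missed_cleavages = 0L,
                        cleave_after = c("E", "D")) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L,
            nzchar(protein_sequence))
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  if (max_missed_cleavages < 0L) stop("max_missed_cleavages must be >= 0")
  res <- strsplit(protein_sequence, "")[[1]]
  tab <- residue_mass_table()$residues
  bad <- which(!res %in% names(tab))
  if (length(bad))
    stop("non-residue character '", res[bad[1]], "' at position ", bad[1])
  n <- length(res)
  cut <- which(res %in% cleave_after)     # cleave after these positions
  ends <- unique(c(cut, n))
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  k <- length(starts)
  out <- list()
  for (m in 0:max_missed_cleavages) {
    if (m + 1L > k) break
    i <- seq_len(k - m)
    s <- starts[i]; e <- ends[i + m]
    out[[m + 1L]] <- data.frame(
      peptide = substring(protein_sequence, s, e),
      start = s, end = e, missed = m, stringsAsFactors = FALSE
    )
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences (names from the
#'   first token of each description line).
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  seqs
}
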