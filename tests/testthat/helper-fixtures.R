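# shared fixtures: built in code at test time

tiny_scheme <- function() swath_scheme(c(400, 409, 419), c(410, 420, 430))

# random peptide with at least one K, returned as list(sequence, sites)
random_k_peptide <- function(len = NULL, n_sites = 1L) {
  aa <- c("A", "G", "L", "V", "S", "T", "F", "N", "Q", "I", "P", "R",
          "D", "E", "Y", "W", "H", "M", "C")
  if (is.null(len)) len <- sample(6:15, 1)
  len <- max(len, n_sites * 2 + 1)
  res <- sample(aa, len, replace = TRUE)
  sites <- sort(sample(seq_len(len), n_sites))
  res[sites] <- "K"
  list(sequence = paste(res, collapse = ""), sites = sites)
}

# an MS2-only run with flat chromatograms: one scan every 0.05 min over
# [0, 1], so the trapezoidal XIC area of a channel equals its stick height
flat_ms2_run <- function(channels, scheme, window = 0L,
                         rt = seq(0, 1, by = 0.05)) {
  w <- scheme$windows[scheme$windows$index == window, ]
  o <- order(channels$mz)
  pk <- lapply(rt, function(t)
    cbind(mz = channels$mz[o], intensity = channels$height[o]))
  spectrum_run(
    data.frame(ms_level = 2L, rt = rt, window = window,
               iso_lower = w$lower, iso_upper = w$upper),
    pk, source = "fixture")
}

# fast single-peptide noise-free simulation
quick_sim <- function(peptides, ..., seed = 1L) {
  if (inherits(peptides, "sim_peptide")) peptides <- list(peptides)
  simulate_run(sim_scenario(peptides, noise = "none",
                            emit_all_windows = FALSE, seed = seed, ...))
}
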