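test_that("residue mass table covers the 20 residues with standard constants", {
  tab <- residue_mass_table()
  expect_length(tab$residues, 20)
  expect_true(all(tab$residues > 0))
  expect_lt(abs(tab$water - 18.010565), 1e-6)
  expect_lt(abs(tab$proton - 1.007276), 1e-6)
})

test_that("acyl label pairs carry the expected mass shifts", {
  ac <- acyl_family("acetyl")
  su <- acyl_family("succinyl")
  expect_lt(abs(ac$pair_delta - 3.018830), 1e-5)
  expect_lt(abs(su$pair_delta - 4.025107), 1e-5)
})

test_that("Glu-C digestion cleaves after E and D and partitions the protein", {
  d <- digest_gluc("ACDEFG")
  expect_equal(d$peptide, c("ACD", "E", "FG"))
  expect_equal(d$start, c(1L, 4L, 5L))
  expect_equal(d$end, c(3L, 4L, 6L))

  expect_equal(digest_gluc("KKKK")$peptide, "KKKK")

  d2 <- digest_gluc("MEGFKRIAED")
  expect_true(any(d2$peptide == "GFKRIAE" & d2$start == 3 & d2$end == 9))

  # partition property on random proteins
  set.seed(5)
  for (i in 1:25) {
    prot <- random_k_peptide(len = sample(20:80, 1))$sequence
    d <- digest_gluc(prot)
    expect_identical(paste(d$peptide, collapse = ""), prot)
    expect_identical(d$start, c(1L, head(d$end, -1) + 1L))
  }
})

test_that("missed cleavages return all contiguous joins", {
  d <- digest_gluc("ACDEFG", max_missed_cleavages = 2)
  expect_setequal(d$peptide[d$missed == 1], c("ACDE", "EFG"))
  expect_setequal(d$peptide[d$missed == 2], "ACDEFG")
  # joins of <= k+1 zero-missed peptides, brute force
  base <- digest_gluc("ACDEFG")$peptide
  joins <- c(paste0(base[1], base[2]), paste0(base[2], base[3]))
  expect_setequal(d$peptide[d$missed == 1], joins)
})

test_that("digestion rejects non-residue characters with position", {
  expect_error(digest_gluc("ACXDE"), "position 3")
})

test_that("peptide monoisotopic masses match independent summation", {
  # frozen values from direct residue + modification mass summation
  p1 <- acyl_peptide("TYVPKAFDE", 5, "light", "acetyl", 2)
  expect_lt(abs(peptide_mono_mass(p1) - 1110.523), 1e-3)

  p2 <- acyl_peptide("FCKAFNAKTDSIE", c(3, 8), "light", "acetyl", 2)
  expect_lt(abs(peptide_mono_mass(p2) - 1613.740), 1e-3)

  g <- acyl_peptide("G", integer(), charge = 1)
  expect_lt(abs(peptide_mono_mass(g) - 75.032), 1e-3)
})

test_that("acyl sites must sit on lysine", {
  expect_error(acyl_peptide("TYVPKAFDE", 4), "non-K")
  expect_error(acyl_peptide("TYVPKAFDE", 10), "out of range")
  expect_error(acyl_peptide("TYVPKAFDE", 5, charge = 0), "charge")
})

test_that("precursor m/z follows the proton convention", {
  expect_lt(abs(precursor_mz(1000, 1) - 1001.007276), 1e-6)
  expect_lt(abs(precursor_mz(1000, 2) - 501.007276), 1e-6)
  expect_error(precursor_mz(1000, 0), "charge")
})

test_that("fragment ions place modifications and sites correctly", {
  # y5 of GFKacRIAE contains the site; frozen from residue-mass summation
  p <- acyl_peptide("GFKRIAE", 3, "light", "acetyl", 2)
  fr <- fragment_ions(p)
  y5 <- fr[fr$series == "y" & fr$index == 5, ]
  expect_lt(abs(y5$mz - 658.39), 0.011)
  expect_equal(y5$sites[[1]], 3L)
  # y2 (AE) contains no site: identical m/z for light and heavy peptides
  ph <- acyl_peptide("GFKRIAE", 3, "heavy", "acetyl", 2)
  frh <- fragment_ions(ph)
  y2l <- fr$mz[fr$series == "y" & fr$index == 2]
  y2h <- frh$mz[frh$series == "y" & frh$index == 2]
  expect_equal(y2l, y2h, tolerance = 1e-9)
  # full-length ions excluded
  expect_false(any(fr$index == nchar("GFKRIAE")))
})

test_that("b/y complementarity: neutral(b_i) + neutral(y_{n-i}) = M", {
  tab <- residue_mass_table()
  set.seed(11)
  for (rep in 1:20) {
    rp <- random_k_peptide(n_sites = sample(1:2, 1))
    pep <- acyl_peptide(rp$sequence, rp$sites,
                        sample(c("light", "heavy"), length(rp$sites), TRUE))
    m <- peptide_mono_mass(pep)
    fr <- fragment_ions(pep)
    n <- nchar(rp$sequence)
    for (i in seq_len(n - 1)) {
      b <- fr$mz[fr$series == "b" & fr$index == i] - tab$proton
      y <- fr$mz[fr$series == "y" & fr$index == n - i] - tab$proton
      expect_lt(abs(b + y - m), 1e-6)
    }
  }
})

test_that("contained sites equal brute-force span intersection", {
  set.seed(21)
  for (rep in 1:50) {
    rp <- random_k_peptide(n_sites = sample(1:3, 1))
    pep <- acyl_peptide(rp$sequence, rp$sites)
    fr <- fragment_ions(pep)
    n <- nchar(rp$sequence)
    for (i in seq_len(nrow(fr))) {
      span <- if (fr$series[i] == "b") seq_len(fr$index[i])
              else (n - fr$index[i] + 1):n
      expect_identical(fr$sites[[i]], intersect(rp$sites, span))
    }
  }
})

test_that("heavy-minus-light precursor shift equals sites x pair delta / z", {
  set.seed(31)
  for (rep in 1:200) {
    rp <- random_k_peptide(n_sites = sample(1:3, 1))
    fam <- sample(c("acetyl", "succinyl"), 1)
    z <- sample(1:3, 1)
    lp <- acyl_peptide(rp$sequence, rp$sites, "light", fam, z)
    hp <- acyl_peptide(rp$sequence, rp$sites, "heavy", fam, z)
    delta <- acyl_family(fam)$pair_delta
    expect_lt(abs((precursor_mz(hp) - precursor_mz(lp)) -
                    length(rp$sites) * delta / z), 1e-5)
  }
})

test_that("FASTA reading feeds digestion", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1 test protein", "MEGFKRIAED"), fa)
  seqs <- read_fasta(fa)
  expect_identical(names(seqs), "prot1")
  expect_true("GFKRIAE" %in% digest_gluc(seqs[[1]])$peptide)
})
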