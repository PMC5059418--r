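test_that("strict differentiating sets match the worked single-K examples", {
  # K at 3 of a length-7 peptide: b3..b6 and y5, y6
  p <- acyl_peptide("GFKRIAE", 3, "light", "acetyl", 2)
  d <- differentiating_ions(p, 3)
  expect_setequal(paste0(d$series, d$index),
                  c("b3", "b4", "b5", "b6", "y5", "y6"))
  # N-terminal K: only b-ions can isolate it
  p2 <- acyl_peptide("KIVIANRGE", 1, "light", "acetyl", 2)
  d2 <- differentiating_ions(p2, 1)
  expect_setequal(paste0(d2$series, d2$index), paste0("b", 1:8))
  expect_true("b3" %in% paste0(d2$series, d2$index))
})

test_that("strict sets isolate first/last site of a two-K peptide", {
  p <- acyl_peptide("FCKAFNAKTDSIE", c(3, 8), "light", "acetyl", 2)
  d3 <- differentiating_ions(p, 3)
  expect_setequal(paste0(d3$series, d3$index), paste0("b", 3:7))
  d8 <- differentiating_ions(p, 8)
  expect_setequal(paste0(d8$series, d8$index), paste0("y", 6:10))
  expect_error(differentiating_ions(p, 5), "not an acyl site")
})

test_that("extended mode adds multi-site fragments with full label ladders", {
  p <- acyl_peptide("FCKAFNAKTDSIE", c(3, 8), "light", "acetyl", 2)
  d <- differentiating_ions(p, 8, mode = "extended")
  b8 <- d[d$series == "b" & d$index == 8, ]
  expect_equal(b8$n_sites, 2L)
  expect_length(b8$mz_ladder[[1]], 3)
  expect_equal(diff(b8$mz_ladder[[1]]),
               rep(acyl_family("acetyl")$pair_delta, 2), tolerance = 1e-9)
})

test_that("strict sets match brute-force enumeration on random peptides", {
  set.seed(17)
  for (rep in 1:1000) {
    rp <- random_k_peptide(n_sites = sample(1:3, 1))
    pep <- acyl_peptide(rp$sequence, rp$sites)
    fr <- fragment_ions(pep)
    site <- rp$sites[sample(length(rp$sites), 1)]
    want <- fr[vapply(fr$sites, function(s) identical(s, site), TRUE), ]
    got <- differentiating_ions(pep, site)
    expect_identical(paste0(got$series, got$index, "^", got$charge),
                     paste0(want$series, want$index, "^", want$charge))
  }
})

test_that("b7 of the two-K peptide separates light and heavy first-site forms", {
  p <- acyl_peptide("FCKAFNAKTDSIE", c(3, 8), "light", "acetyl", 2)
  d <- differentiating_ions(p, 3)
  b7 <- d[d$series == "b" & d$index == 7, ]
  expect_lt(abs(b7$mz_ladder[[1]][1] - 881.4), 0.06)
  expect_lt(abs(b7$mz_ladder[[1]][2] - 884.4), 0.06)
})

test_that("threshold filter, light fallback and ratio arithmetic are exact", {
  # flat chromatograms: channel area == stick height; threshold 1000
  scheme <- swath_scheme(550, 562)
  p <- acyl_peptide("TYVPKAFDE", 5, "light", "acetyl", 2)
  d <- differentiating_ions(p, 5)
  mzl <- function(s, i) d$mz_ladder[[which(d$series == s & d$index == i)]][1]
  mzh <- function(s, i) d$mz_ladder[[which(d$series == s & d$index == i)]][2]
  channels <- data.frame(
    mz = c(mzl("b", 5), mzh("b", 5),    # light 2000, heavy 500: fallback keeps it
           mzh("b", 6),                 # light 0, heavy 50000: ratio 0
           mzl("y", 5), mzh("y", 5),    # light = heavy = 20000: ratio 0.5
           mzl("y", 6), mzh("y", 6)),   # both below threshold: dropped
    height = c(2000, 500, 50000, 20000, 20000, 800, 900))
  run <- flat_ms2_run(channels, scheme, window = 0L)
  tg <- target_entry("TYVPKAFDE", 5, family = "acetyl", charge = 2,
                     rt_borders = c(0, 1))
  r <- quantify_site(run, scheme, tg, min_heavy_area = 1000)
  fr <- r$fragments
  id <- paste0(fr$series, fr$index)
  expect_equal(fr$ratio[id == "b5"], 0.8)     # 2000/(2000+500)
  expect_true(fr$pass[id == "b5"])            # light fallback
  expect_equal(fr$ratio[id == "b6"], 0.0)
  expect_equal(fr$ratio[id == "y5"], 0.5)
  expect_false(fr$pass[id == "y6"])
  # median over passing {0, 0.5, 0.8} and rank-1 by summed area (b6)
  expect_equal(r$median_ratio, 0.5)
  expect_equal(r$rank1_ratio, 0.0)
  expect_true(all(fr$ratio[fr$pass] >= 0 & fr$ratio[fr$pass] <= 1))
})

test_that("median is order-invariant and uses the lower central value", {
  expect_equal(acylstoich:::.median_low(c(0.4, 0.1, 0.3, 0.2)), 0.2)
  expect_equal(acylstoich:::.median_low(c(0.3, 0.1, 0.2)), 0.2)
  set.seed(2)
  x <- runif(7)
  expect_equal(acylstoich:::.median_low(x),
               acylstoich:::.median_low(sample(x)))
})

test_that("a user-supplied rank table overrides area-based ranking", {
  scheme <- swath_scheme(550, 562)
  p <- acyl_peptide("TYVPKAFDE", 5, "light", "acetyl", 2)
  d <- differentiating_ions(p, 5)
  lad <- function(s, i) d$mz_ladder[[which(d$series == s & d$index == i)]]
  channels <- data.frame(mz = c(lad("b", 5), lad("y", 5)),
                         height = c(8000, 2000, 3000, 3000))
  run <- flat_ms2_run(channels, scheme, window = 0L)
  tg <- target_entry("TYVPKAFDE", 5, family = "acetyl", charge = 2,
                     rt_borders = c(0, 1))
  # by area, b5 (10000) would be rank 1; the rank table promotes y5
  ranks <- data.frame(series = c("y", "b"), index = c(5L, 5L),
                      charge = 1L, rank = c(1L, 2L))
  r <- quantify_site(run, scheme, tg, ranks = ranks)
  expect_equal(r$rank1_ratio, 0.5)
  r2 <- quantify_site(run, scheme, tg)
  expect_equal(r2$rank1_ratio, 0.8)
})

test_that("co-isolation failure yields a flagged empty result", {
  scheme <- swath_scheme(c(550, 557), c(557.5, 565))  # boundary splits the pair
  tg <- target_entry("TYVPKAFDE", 5, family = "acetyl", charge = 2,
                     rt_borders = c(0, 1))
  run <- flat_ms2_run(data.frame(mz = 600, height = 1), scheme, window = 0L)
  r <- quantify_site(run, scheme, tg)
  expect_false(r$co_isolated)
  expect_true(is.na(r$median_ratio))
  expect_match(r$qc, "co-isolation")
})

test_that("all-noise runs report no fragments above threshold", {
  scheme <- swath_scheme(550, 562)
  run <- flat_ms2_run(data.frame(mz = 556.5, height = 5), scheme, window = 0L)
  tg <- target_entry("TYVPKAFDE", 5, family = "acetyl", charge = 2,
                     rt_borders = c(0, 1))
  r <- quantify_site(run, scheme, tg, min_heavy_area = 1000)
  expect_true(is.na(r$median_ratio))
  expect_match(r$qc, "threshold")
})

test_that("noise-free simulator truth is recovered exactly per fragment", {
  sim <- quick_sim(sim_peptide("TYVPKAFDE", 5, 0.37, rt_apex = 1))
  r <- quantify_site(sim$run, sim$scheme, sim$targets[[1]])
  expect_true(all(abs(r$fragments$ratio[r$fragments$pass] - 0.37) <= 1e-6))
  expect_lt(abs(r$median_ratio - 0.37), 1e-6)
})

test_that("very low occupancy with strong heavy signal is recovered", {
  sim <- quick_sim(sim_peptide("TYVPKAFDE", 5, 0.005, abundance = 2e6,
                               rt_apex = 1))
  r <- quantify_site(sim$run, sim$scheme, sim$targets[[1]])
  expect_lt(abs(r$median_ratio - 0.005), 1e-6)
})

test_that("two equal-occupancy sites are symmetric and exact without noise", {
  sim <- quick_sim(sim_peptide("FCKAFNAKTDSIE", c(3, 8), c(0.5, 0.5),
                               rt_apex = 1))
  rs <- quantify_multisite(sim$run, sim$scheme, sim$targets[[1]])
  expect_lt(abs(rs[[1]]$median_ratio - 0.5), 1e-9)
  expect_lt(abs(rs[[2]]$median_ratio - 0.5), 1e-9)
})

test_that("three-site middle occupancy solves under label independence", {
  sim <- quick_sim(sim_peptide("ASGSKPAKGFAAKTSE", c(5, 8, 13),
                               c(0.1, 0.3, 0.7), rt_apex = 1))
  rs <- quantify_multisite(sim$run, sim$scheme, sim$targets[[1]])
  expect_lt(abs(rs[[1]]$median_ratio - 0.1), 1e-6)
  expect_lt(abs(rs[[2]]$median_ratio - 0.3), 1e-6)
  expect_lt(abs(rs[[3]]$median_ratio - 0.7), 1e-6)
  expect_match(rs[[2]]$qc, "extended-mode")
})

test_that("MS1 stoichiometry recovers noise-free truth and refuses multi-K", {
  sim <- quick_sim(sim_peptide("TYVPKAFDE", 5, 0.10, rt_apex = 1))
  m <- ms1_stoichiometry(sim$run, sim$targets[[1]])
  expect_lt(abs(m$occupancy - 0.10), 2e-3)
  expect_length(m$light_areas, 3)
  tg2 <- target_entry("FCKAFNAKTDSIE", c(3, 8), family = "acetyl",
                      charge = 2, rt_borders = c(0, 2))
  expect_error(ms1_stoichiometry(sim$run, tg2), "multi-site")
  # both channels empty -> flagged NA
  tg3 <- target_entry("GFKRIAE", 3, family = "acetyl", charge = 2,
                      rt_borders = c(0.5, 1.5))
  m3 <- ms1_stoichiometry(sim$run, tg3)
  expect_true(is.na(m3$occupancy))
  expect_match(m3$qc, "empty")
})

test_that("target tables round-trip and validate site mapping", {
  tg <- target_entry("FCKAFNAKTDSIE", c(3, 8), site_numbers = c(40, 45),
                     protein = "RL11", family = "acetyl", charge = 2,
                     rt_borders = c(10, 12), run_file = "run.mzML")
  f <- tempfile(fileext = ".tsv")
  write_targets(list(tg), f)
  back <- read_targets(f)[[1]]
  expect_equal(back$site_numbers, c(40L, 45L))
  expect_equal(back$peptide_positions, c(3L, 8L))
  expect_equal(back$rt_borders, c(10, 12))
  expect_error(target_entry("FCKAFNAKTDSIE", c(3, 8),
                            site_numbers = c(40, 46)), "inconsistent")
})
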