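---
title: "Quantifying lysine acylation stoichiometry from SWATH fragment ions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lysine acylation stoichiometry from SWATH fragment ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylstoich)
```

## The measurement model

The package quantifies, per lysine residue, the fraction of a protein
population carrying an endogenous acyl modification. The chemistry
guarantees a closed two-state system: exhaustive in-vitro acylation with
an isotope-labelled anhydride converts every unmodified lysine to the
heavy form, so each lysine is either endogenously light or chemically
heavy, and occupancy is the binomial parameter

$$\theta = \frac{L}{L + H}$$

estimated from light and heavy signal areas. Because the labels are
chemically identical, light and heavy peptides co-elute (deuterium
retention shifts are below the integration-border resolution and are not
modelled), and because the mass difference per site (3.018830 Da acetyl,
4.025107 Da succinyl) is small relative to SWATH window widths, both
precursors are normally co-isolated and fragmented together. The estimator
therefore works entirely inside one SWATH window: for each
*differentiating* fragment ion — a b- or y-ion containing the modified
lysine — the light and heavy XIC areas are integrated over the same
retention-time borders and ratioed. Common fragment ions (no site
contained) carry no label information and are ignored.

Assumptions worth stating explicitly:

* **Co-isolation.** Light and heavy precursors must fall in the same
  effective window; the pipeline checks this first and refuses (with a QC
  flag) rather than quantify across windows. Pairs that straddle a window
  boundary are a real loss mode of the method, not an error of it.
* **Shared elution.** Light and heavy areas are always integrated over one
  RT border pair, so ratios are robust to modest peak-shape variation.
* **Label closure.** Everything not endogenously modified is assumed
  chemically labelled. Incomplete labelling removes signal from the heavy
  channel (biasing $\theta$ upward); the simulator exposes a
  `completeness` parameter to study exactly this bias.
* **Reagent purity.** A heavy reagent of isotopic purity $p$ deposits
  light-mass labels with probability $1-p$, flooring the apparent
  occupancy near $1-p$ (about 2% for the d4 succinic anhydride, 1% for the
  d6 acetic anhydride). Reported occupancies are therefore upper-limit
  values; `quantify_site(purity = )` optionally divides this floor out,
  but the default reports the uncorrected value.

## Pipeline and parameters

`quantify_site()` runs, per target site: co-isolation check, strict
differentiating-ion enumeration, per-fragment light/heavy XIC extraction
and trapezoidal integration, the area filter, and the ratio summaries.
The tunable parameters, their defaults and the reasoning:

* **ppm tolerance, 20 ppm.** Suited to the ~15,000 fragment-ion
  resolution of the qTOF acquisitions the workflow targets. At 20 ppm the
  light M+3 isotope (3.0103 Da) and the heavy acetyl monoisotope
  (3.0188 Da) are resolved at singly charged m/z above ~430; for doubly
  charged precursors below ~860 m/z the MS1 heavy channel can absorb a
  small light M+3 contribution. No isotope-overlap deconvolution is
  performed; the simulator's 4-isotope envelopes let the resulting MS1
  bias be measured directly (it is well below the MS1 interference
  effects that motivate fragment-level quantification in the first
  place).
* **Minimum heavy area, 1000 intensity·min.** Excludes ratios computed
  from noise-level ions. The filter is two-sided in the sense of the
  original rule: a fragment whose heavy area fails the threshold is kept
  if its *light* area passes, which preserves exactly the
  high-stoichiometry sites whose heavy signal is legitimately weak.
  Ratios from fragments failing both channels are undefined, never 0/0.
* **Fragment charges, 1+.** All worked fragment examples in the source
  material are singly charged; higher charges are available via
  `fragment_charges`.
* **Rank-1 definition.** The original workflow ranks fragments by
  spectral-library intensity; identification and library building are out
  of scope here, so rank 1 defaults to the passing fragment with the
  largest light+heavy summed area — a proxy for "best ion statistics" —
  and a user-supplied rank table can restore library ranking exactly.
* **Median, lower-central.** With an even number of passing fragments the
  lower of the two central ratios is reported, keeping the summary a
  value that was actually observed and the computation deterministic.
  The median is taken over threshold-passing fragments only.

## Multi-lysine peptides

Precursor m/z cannot apportion occupancy between two lysines on one
peptide: the two singly-mixed species (light/heavy and heavy/light) are
isobaric. Fragments can. For a two-lysine peptide the strict b-ion run
(ions containing only the first lysine) quantifies the first site and the
strict y-ion run the second; this is the default. For three lysines no
single-site fragment isolates the middle residue, so the middle occupancy
is estimated in *extended mode*: each multi-site fragment's label-count
ladder (m/z base + k·delta for k heavy sites) is modelled as the
coefficient vector of $\prod_i(\theta_i + (1-\theta_i)x)$ — per-site label
states treated as independent — and the middle $\theta$ is found by least
squares on [0, 1] given the b-/y-derived flanking estimates. This
independence model is an extension beyond the published two-lysine rule
and every middle-site result carries an "extended-mode" QC note. On
noise-free synthetic data it is exactly identifiable (the tests require
agreement to 1e-6); on real data its accuracy degrades with correlated
modification states, which the model ignores by construction.

## SWATH window handling

Window schemes are ordered (lower, upper) pairs with a constant overlap
(1 m/z in the vendor convention), inferred on load as the median of
consecutive overlaps. The overlap is split equally between neighbours —
the vendor tools do not publish their split rule, and an equal split is
the only symmetric deterministic choice — giving effective half-open
intervals $[b_{i-1}, b_i)$ that tile the range; a precursor exactly on a
boundary goes to the higher-index window. Each precursor is assigned to
exactly one window; merging signal from two overlapping windows is not
attempted.

## The simulator

`simulate_run()` emits a complete acquisition on the 3.2 s cycle grid
(one MS1 scan plus one MS2 scan per 64-window variable scheme per cycle):
Gaussian elution profiles sampled as centroid sticks, precursor isotope
envelopes from a Poisson averagine-style approximation (first 4 isotopes,
rate 5.47e-4 per Da — sufficient to exercise the M+3/M+4 overlap question
at qTOF resolution, not a fine-structure model), and per-window fragment
ladders for every label-state species. Reagent purity and labelling
completeness enter as expected species weights (the exact convolution of
independent per-site label states), so the ground-truth record can state
every expected XIC area in closed form: species area = abundance ×
species weight (× isotope fraction at MS1, × fragment share × MS2 yield
at MS2). Randomness is confined to the noise model — Poisson draws on
stick intensities plus optional exponential baseline peaks — and derives
entirely from the scenario seed.

What the simulator deliberately does **not** emulate: profile-mode peak
shapes, chromatographic drift between runs, deuterium retention shifts,
correlated multi-site label states, fragment isotope envelopes, and
real-world interference density. Passing the recovery suites therefore
demonstrates that the *pipeline arithmetic* is unbiased and
noise-robust under the stated acquisition geometry — not that real
samples are free of interferences; the interference machinery exists
precisely to inject such effects explicitly (`interferences =` places
arbitrary MS1/MS2 signals at chosen m/z and RT offsets, reproducing the
MS1-inflation phenomenon while fragment-level values stay put).

The dilution-series generator (`bsa_mixture_scenario()`) mirrors the
defined-mixture validation design: an 18-peptide panel at each defined
light fraction. The panel is synthetic — deterministic single-lysine
Glu-C-like sequences filtered for co-isolation under the default scheme —
because bundling a real protein sequence adds nothing the arithmetic
needs. The separate mixtures are laid out as disjoint retention-time
blocks of one run; with purity 0.98 the recovered means follow
$\theta + (1-\theta)(1-p)$, the floor-at-$1-p$, slope-1 line that the
real measurements show.

## Numerical choices and degenerate inputs

* Trapezoidal integration on the native cycle-time grid, borders
  inclusive, no smoothing or interpolation: determinism over cosmetics.
  Fewer than two points inside the borders yields area 0 with a
  `low_points` flag rather than an extrapolated value.
* An empty RT intersection between borders and run is a flagged empty
  chromatogram, not an error — one stale target must not kill a batch.
* Retention time is minutes everywhere; mzML seconds are converted on
  read. mzML is the read/write dialect (mzXML read-only).
* Full-length $b_n$/$y_n$ ions are excluded from enumeration: they are
  not observable as distinct fragments.
* All randomized tests fix their seeds; the middle-site optimizer uses
  `optimize()` at tolerance 1e-10 on the closed interval [0, 1].

Test problem sizes: property suites run 1000 random peptides for the
label-shift and differentiating-set invariants and 10,000 random m/z for
window assignment; the stochastic suites use 10-24 peptides per run with
5 seeds for the purity floor and single runs for recovery and the
dilution series — sizes chosen so the full suite exercises every claim at
the stated tolerances while staying comfortably interactive.

## Known limitations

* Occupancies are upper limits: other unaccounted lysine modifications at
  the same site, incomplete labelling, and reagent impurity all push the
  estimate upward.
* No peptide identification, FDR control, spectral-library construction,
  cross-run normalization or protein-level rollup — the package begins at
  a validated target list and ends at per-site ratios.
* MS1-based occupancy is provided for comparison only and refuses
  multi-lysine targets on principle.
* The three-lysine middle-site estimate rests on the label-independence
  assumption stated above.
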