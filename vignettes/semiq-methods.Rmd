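---
title: "Methods: semi-targeted quantification, batch optimization and spectral curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-targeted quantification, batch optimization and spectral curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiq)
```

## Scope and model of the data

`semiq` quantifies a predefined list of compounds — each with an accurate
m/z and an expected retention time (RT) — in centroided LC-MS/MS runs
acquired by data-dependent acquisition (DDA). This is *semi-targeted*
analysis: no untargeted feature finding is attempted, and compounds
without a library entry are invisible to the engine. The ingest format is
mzML; all retention times are converted to seconds on reading, and
profile-mode data are rejected rather than centroided.

The engine treats each (compound, file) pair independently up to the
batch-optimization stage. Its unit of evidence is the extracted ion
chromatogram (EIC): the per-MS1-scan sum of all centroid intensities
within a symmetric, inclusive ppm window around the target m/z. Summing
(rather than taking the maximum of) in-window centroids makes extraction
robust against centroid splitting; the cost per spectrum is logarithmic
because centroids are binary-searched in the ascending m/z array. Missing
scans are never interpolated: every downstream step operates on the scan
grid as acquired.

## The eight-step quantification chain

1. **EIC extraction** (`extract_eic`) — default tolerance 20 ppm. The
   default is a deliberate compromise for time-of-flight and Orbitrap
   class data; tighter tolerances only help if mass calibration is
   better than the isotope spacing divided by the mass range in use.
2. **Smoothing** (`smooth_eic`) — four methods: moving mean, Gaussian
   kernel, Savitzky-Golay (default, window 7 scans, order 2), and loess.
   Savitzky-Golay is the default because it preserves peak height and
   width to second order, which matters when the apex intensity feeds
   the S/N criterion. Edges are handled by truncating the window to
   available points; negative outputs of the polynomial methods are
   clipped to zero so smoothed traces remain valid intensity vectors.
3. **Noise estimation** (`estimate_noise`) — three methods: scaled MAD
   (default; `1.4826 * median(|I - median(I)|)`), the mean of the lower
   intensity half, and the minimum standard deviation over
   non-overlapping 11-scan windows. We use *disjoint* windows in the
   third method: with stride-1 windows the minimum of ~190 strongly
   overlapping standard deviations concentrates near the extreme order
   statistic and systematically halves the estimate. All estimators are
   floored at 1.0 intensity unit so S/N is always finite, and all are
   scale-equivariant above the floor.
4. **Peak selection** (`select_peaks`) — three methods: local maxima
   (default), sign change of the first difference, and a Mexican-hat
   continuous wavelet transform with ridge linking over scales 2–16
   scans. All methods require the smoothed apex to reach
   `snr_min * noise` and at least three scans of support; overlapping
   candidates are merged keeping the higher apex (ties to the earlier
   RT). Boundary rules per method: nearest local minimum or first point
   below 5 % of the apex (local maxima); first difference below
   `deriv_eps * apex` (derivative); ±2 scales around the best ridge
   coefficient, clipped to local minima (CWT).
5. **Integration** (`integrate_peak`) — trapezoidal sum of the *raw*
   trace between the bounds, either as-is or minus a straight-line
   baseline joining the boundary intensities (default). The S/N of the
   peak is the raw apex over the EIC noise level.
6. **Screening** (`screen_peak`) — five independent criteria: S/N ≥ 3,
   apex ≥ 1000, |apex RT − calibrated expected RT| ≤ 30 s, width within
   [2, 90] s, and left/right half-width ratio within [1/5, 5].
   Screening annotates candidates with the names of failed criteria and
   never deletes them, so batch optimization and manual annotations can
   overrule it later.
7. **Identification** (`identify_peak`) — three strategies of rising
   stringency: `mz_rt` (mass is enforced by the extraction window, RT
   and S/N by the screen flags), `mz_rt_ms1` (adds an isotope-envelope
   score threshold, default 0.5), `mz_rt_ms2` (adds a spectral-library
   match threshold, default 0.7). The isotope model estimates the carbon
   count as `mz * 0.0455` and expects an M+1/M ratio of `n_C * 0.0108`;
   it needs no molecular formula and is deliberately coarse — a
   plausibility check, not an elemental-composition test. All DDA MS2
   scans whose precursor falls within 0.5 Da of the target and whose RT
   lies inside the peak are scored against every reference entry of the
   compound and the best combination wins; scoring only the apex-nearest
   scan is available through the same machinery but best-of-window is
   the default because DDA rarely samples the apex exactly.
8. **Batch optimization** — described next.

## Batch optimization

**RT calibration.** If an internal-standard (IS) library is supplied,
the IS compounds are detected per file with the same chain (RT tolerance
relaxed twofold) and the (expected, observed) anchor pairs define a
monotone piecewise-linear map: observed times are first monotonized by
pool-adjacent-violators, interpolation runs through the anchors, and the
map extrapolates with slope 1 beyond them. Fewer than two anchors yield
the identity. Flat segments can appear when anchors are pooled, so the
map is guaranteed nondecreasing rather than strictly increasing.

**Cross-file alignment.** For each compound, the file-wise best
candidate (fewest screen flags, then highest S/N) votes with its apex
RT; the median is the consensus. Every file then re-selects the
candidate nearest the consensus — overriding its local best — and files
whose nearest candidate is farther than 30 s are marked inconsistent
(status `unknown`). Voting and re-selection happen in the
calibration-corrected frame (each file's calibration shift is subtracted
first); otherwise inter-file drift systematically drags the consensus
away from every file's true peak.

**RT-pattern refinement.** Compounds eluting close together share drift.
Per file, each cleanly detected compound contributes a shift
`delta = apex - calibrated expected RT`; a compound's local reference
shift is the median over neighbours within 120 s of library RT (at
least three required, otherwise the file's global median). Deviating
from the local shift by more than 20 s triggers re-selection toward
`expected + local shift`, and demotion to `unknown` when no candidate
fits. The procedure runs exactly once; because a corrected selection
deviates from the local shift by at most the tolerance, a second
application is a no-op, which the tests assert.

**Statuses.** `pass` = clean flags, consistent, identified, not demoted;
`unknown` = candidates exist but the selection is flagged, inconsistent,
unidentified or demoted; `fail` = no candidate at all. Only `pass` cells
carry areas in the wide quantification report; the long report
enumerates every (compound, file) cell with its status and evidence.
Manual inspection is represented by an annotations CSV
(`compound,file,status[,rt_start,rt_end]`) that overrides statuses and
optionally re-integrates over edited bounds with the identical
integrator — this file contract replaces an interactive review UI so the
inspect-modify-export loop stays scriptable and testable.

## Spectral matching and curation

Fragments are paired greedily by nearest m/z within the fragment
tolerance (default 0.02 Da), each fragment used at most once, ties
toward the lower-m/z reference fragment. Seven sub-scores in [0, 1] are
combined as a weighted mean (all weights default to 1): squared cosine
on square-root intensities, the same on `mz^2 * sqrt(I)` mass-weighted
vectors, spectral-entropy similarity, matched fraction of query and of
reference fragments, matched fraction of reference intensity, and mean
relative mass accuracy of the matched pairs. Identical spectra score 1
in every component and disjoint spectra 0; the cosine and entropy
components are symmetric under query/reference exchange while the two
match fractions swap.

Curation harvests, for every approved `pass` cell, the in-peak MS2 scan
nearest the apex, and stamps it with instrument type, collision energy,
ionization mode and source run (`"unknown"` where the run does not
record a field — metadata is never fabricated). Approving a non-pass
cell is an error by design: curation presupposes an inspected result.
Consensus building clusters fragments by single linkage with the
fragment tolerance, keeps clusters present in at least half the
replicates, uses intensity-weighted mean m/z and median intensity, and
renormalizes to a base peak of 100. Libraries round-trip through MSP
(metadata in a `Comment:` line of `key=value` pairs; unknown keys are
preserved) and export to MGF; both writers sort entries by compound and
precursor so output is byte-stable.

## The synthetic generator and what it does (not) show

`simulate_run` builds DDA runs from a fully specified design: Gaussian
elution profiles, a one-parameter isotope envelope (the same carbon
model the identification step uses), a constant baseline with additive
Gaussian noise clipped at zero, per-centroid mass jitter in ppm, and
top-N MS2 triggering with a 20 s dynamic exclusion. Ground truth
(including the analytic peak area `abundance * sigma * sqrt(2*pi)`) is
emitted alongside. Gaussian — not exponentially modified Gaussian —
shapes are the default so the analytic truth stays exact.

`simulate_benchmark_pair` emulates a two-mixture design in which seven
compound groups are mixed at SB:SA concentration ratios 1/16, 1/4, 1/2,
1, 2, 4 and 16. Defaults are desk-scale: 20 compounds per group
(140 total) in two 600 s runs at 1 Hz MS1, abundances log-uniform in
8e4–6e5, peak widths 3–6 s, noise sigma 50 on a baseline of 100, 2 ppm
mass jitter, and a 5 s RT drift on SB — sizes chosen so the full
generate-analyze-summarize cycle runs in seconds while every group,
including the 16-fold-diluted one, stays comfortably above the default
screening thresholds. Compound m/z values sit on a jittered 2 Th grid so
no monoisotopic or M+1 channel of one compound can invade another's
extraction window; real matrices violate this constantly, so passing the
benchmark says nothing about interference robustness. Likewise the
generator has no chemical noise, no saturation, no tailing and no
missing scans: recovery of the generating fold changes demonstrates that
the chain is unbiased under its own model assumptions, not that it is
immune to real-data pathologies.

## Numerical choices and degenerate inputs

Tolerance windows are inclusive on both sides. The noise floor of 1.0
intensity unit keeps S/N finite on blank traces. Candidate merging
breaks ties toward the earlier RT; fragment pairing toward the lower
reference m/z. Constant traces survive all four smoothers unchanged;
all-zero traces yield no candidates. Empty spectra score zero across all
seven match components with a warning rather than an error. Compound- or
file-level failures inside a batch are caught and recorded as `fail`
cells; they never abort the run. Overviews serialize to JSON with a
caller-suppliable timestamp, so identical inputs (including the
timestamp argument) produce byte-identical files — the reproducibility
contract the tests enforce.

## Known limitations

Co-eluting isomers sharing one EIC are not deconvolved; the crude carbon
model misranks halogenated or sulfur-rich compounds; the MSP dialect is
the NIST-style subset described above; and cross-batch normalization of
multiple Overviews is out of scope.
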