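---
title: "Preprocessing exhaled-breath TD-GC/q-MS data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessing exhaled-breath TD-GC/q-MS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Untargeted breath volatilomics by TD-GC/q-MS produces profile-mode,
unit-resolution EI chromatograms: for every sample, thousands of scans, each
a vector of intensities over the acquisition m/z range. Before any group
comparison can run, this raw signal must become a compound-by-sample matrix.
Two preprocessing philosophies coexist. The *feature-centric* route detects
individual ion peaks (one m/z at one retention time), aligns and groups them
across samples, and only afterwards assembles co-eluting features into
pseudo-compounds. The *compound-centric* route deconvolves overlapping
elution profiles directly and extracts one spectrum and area per compound.
Each has a known weakness — the first struggles to say *which compound* a
feature belongs to; the second can invent or split compounds. `vocpipe`
implements both and then cross-validates them: a compound is trusted only
when both routes see it, and each route repairs the other's weakness (the
feature route contributes accurately quantified intensities, the
deconvolution route contributes library-searchable spectra).

# Approach 1: matched-filter peak picking

All signal is first binned to unit mass (intensity at observed m/z $x$
accrues to $\lfloor x + 0.5\rfloor$), the natural resolution of a single
quadrupole. `smooth_and_baseline()` applies a centred moving average
(default window 5 scans) and subtracts a rolling low-quantile baseline
(default: 25th percentile over 401 scans ≈ 2 min), clipped at zero. A
quantile of 0 disables baseline subtraction, so window 1 / quantile 0 is the
identity — useful for testing and for pre-corrected data.

`detect_peaks()` convolves each EIC with a zero-area Mexican-hat kernel (the
negative-normalized second derivative of a Gaussian) whose width is set by
`fwhm` (default 0.05 min = 3 s, matching the expected chromatographic peak
width). Local maxima of the filter response above `snr` (default 5) times a
robust per-EIC noise scale (1.4826 × MAD of the response) become features;
the integration window runs between the response's zero crossings, and the
feature's intensity is the maximum raw intensity in that window (the *maxo*
convention). The matched filter's sign structure separates overlapping peaks
whenever the response shows two maxima.

`align_retention_times()` corrects between-run retention drift in two
passes: a coarse pass (bandwidth 0.5 min) estimates each sample's gross
median shift — this is what absorbs a column change — and a fine pass
re-clusters the coarsely corrected features (bandwidth `rt_bw`, default
2 s), keeping as anchors the groups present in ≥ 90 % of samples with
residual spread ≤ 2 × fwhm. A loess curve (degree 1, span 0.75; linear or
constant fit when anchors are few) of total deviation versus retention time
is inverted per sample. Anchor medians are left in place, so aligned and
unaligned cohorts share a coordinate system.

`group_features()` clusters retention times within each unit mass by
single-linkage with cut height `rt_bw`: a cluster covering at least
`minfrac` (default 0.5) of the samples becomes a cross-sample feature group,
one member per sample (nearest the cluster median). `fill_missing()` then
reads, for every (group, sample) hole, the retention-corrected EIC inside
the group's integration envelope and records its maximum — so the final
matrix has no missing cells and gap-filled values follow the same maxo
convention as detected ones. Gap filling never alters detected values.

Pseudo-compounds ("clique compounds") come from a per-sample similarity
network: two features are connected iff they co-elute (|ΔRT| ≤ 0.05 min) and
the cosine of their raw EIC shapes over the union of their windows is ≥ 0.8.
Fragments of one compound share the compound's elution profile, so their
cosine approaches 1; profiles ~2 σ apart fall below the gate. Connected
components are the per-sample groups. Because this grouping is inherently
per-sample, the package reconciles it across the cohort by **majority
vote**: two feature groups belong to the same clique compound iff they are
co-clustered in more than half of the samples where both are detected. The
reconciliation rule is this package's own design choice (the per-sample
grouping idiom it generalizes leaves cohort-level consolidation open); the
vote's support fraction is reported per compound.

# Approach 2: segment-wise deconvolution

The oven program has three ramps (default: 35 °C held 10 min; 3 °C/min to
121 °C, i.e. until 38.67 min; 20 °C/min to 270 °C, until 46.12 min), and the
chromatographic peak behaviour differs enough between ramps that each
segment is deconvolved independently (`segment_run()`; a boundary scan
belongs to the earlier segment).

`deconvolve()` floors intensities below `noise_threshold` (default 300
abundance units — the denoising/baseline step), lightly smooths each EIC and
collects its local maxima. Apex retention times clustering within one
`peak_sigma` (default 0.02 min) across at least `min_ions` (default 4)
distinct ions announce a candidate compound at the cluster's median apex —
a local-covariance style detection that resolves co-eluting compounds with
disjoint fragment sets down to ~2 σ separation, where the total ion current
is still unimodal. Each candidate's width is estimated from the dominant
ion's full width at half maximum (clipped to 0.6–3 × `peak_sigma`), so peaks
broader or narrower than nominal keep their ions. An EIC joins a candidate
when its correlation with the candidate's Gaussian elution model, over the
ion's visible (above-threshold) support, is ≥ `cor_gate` (default 0.9);
the apex contribution of each member ion is then solved by non-negative
least squares against the models of *all* window-overlapping candidates,
which unmixes shared fragments. Spectra are rescaled to base peak = 1000;
the compound's area is the elution-model area times the summed ion loadings.

`align_compounds()` clusters compounds across samples greedily by descending
area: a compound joins a cluster iff its shift-corrected retention time is
within `rt_tol` (0.05 min) of the cluster and its spectral cosine with the
cluster consensus is ≥ `min_spectral_dot` (0.7), one member per sample; the
per-sample shifts come from a first greedy pass at a wide (0.2 min)
tolerance. The consensus spectrum is the area-weighted mean, base peak 1000.
`recover_missing()` integrates, for each compound absent from a sample, the
sample's EICs of the compound's three most intense ions over the consensus
window (± 3 σ, shifted into the sample's coordinates) and scales up by the
consensus weight of the remaining ions.

# Connecting the approaches

Features and compound ions are declared *the same signal* when they share
the unit m/z and agree in retention time within ± 0.05 min. Each clique
compound receives a relative-intensity spectrum by the three-step protocol:
average each member feature across the whole set of samples; give 1000 to
the highest average (ties: both get 1000, the formula applied verbatim);
scale the rest proportionally. Both spectra types are embedded as vectors
with **412 positions** covering the integer m/z comparison range 38–450 and
scaled to unit Euclidean norm, so the dot product is a cosine in [0, 1].
Two decisions deserve note:

* *412 versus 413.* The inclusive integer range 38–450 holds 413 values; the
  fixed vector length of 412 is reproduced exactly by implementing the range
  half-open, [38, 450). The alternative (inclusive range, 413 positions)
  would change nothing else in the pipeline; the bounds are configurable.
* *Normalization makes the dot product bounded.* A raw dot product of
  intensity vectors is unbounded; only unit-norm scaling yields a similarity
  in [0, 1]. Vectors are therefore normalized at construction, and an
  all-zero spectrum is flagged rather than normalized.

Every clique compound is compared with every deconvolved compound; a
deconvolved compound that is the **best** match of at least one clique
compound with a dot product **above 0.7** is a *filtered compound*
(arg-max ties break by smaller retention gap, then id). The features
previously matched to filtered compounds are the *filtered features* — the
second filter. Duplicates are flagged among any compound list by: dot
product > 0.8, same retention time ± 0.05 min, and, where per-sample areas
exist (the deconvolution side), area Pearson correlation > 0.75; the
clique side, for which no numeric rule is inherited, reuses the same
retention and dot thresholds. Deduplication keeps the larger total area
(deconvolution side) or the larger summed average intensity (clique side).

The filtered matrix is normalized per subset as
$\mathrm{norm}(f,s) = \log_{10} v(f,s) \,/\, \log_{10} D(f) \times 1000$.
The denominator "the feature's intensity values across all samples" admits
three readings — log of the sum (default), log of the mean, sum of logs —
all exposed via `normalize_matrix(denominator =)`; the sum is the only
reading that yields one number per feature with no further convention.
Zeros are floored to one abundance unit; a feature whose denominator is not
positive is dropped with a warning.

# Identification

The match factor is 100 × the weighted cosine of two spectra over the union
of their ions, with NIST-style weights $m^1 I^{0.5}$ — chosen because it is
the standard library-search statistic with the two required endpoint
properties (100 iff proportional, 0 iff disjoint). Candidate entries must
exceed the 80 % floor and sit within 5 points of the best; at most 450 are
kept. Retention indices use van den Dool–Kratz piecewise-linear
interpolation with RI(Cn) ≡ 100 n (the universal convention for
temperature-programmed GC; the source procedure names no formula);
extrapolation beyond the anchor span is flagged. RI error is
$100\,|RI_q - RI_e| / RI_e$ (entry-referenced; the denominator convention is
a declared choice). Entries with RI error above 20 % are discarded; the
lowest RI error wins, match factor breaking ties; with no qualifying RI the
highest match factor wins and the ranking basis is recorded as `mf_only`.

`anchor_alkanes()` builds anchors from samples with six filters applied in
order: (1) match factor > 95 against any C7–C24 alkane entry; (2) per
alkane, compounds within 5 match-factor points of that alkane's best;
(3) the alkane's molecular ion (m/z = 14 n + 2) must be present in the
deconvolved spectrum; (4) cross-approach confirmation — a detected feature
at that m/z within ± 0.05 min; (5) the lowest-retention compound per alkane
(match factor breaks ties); (6) outliers off the retention-versus-carbon
line removed at 3 × MAD of linear-fit residuals (skipped when the residual
scale is below numeric noise, 1 µmin). Whether the "5 points" here and the
"5 %" of the general search are one rule is unknowable from the source;
they are separate configuration keys (`mf_points`, `mf_window`).

# The synthetic cohort generator

`simulate_cohort()` emulates the features of the target data that the
pipeline must handle, with known ground truth:

* Gaussian elution (amplitude form, σ default 0.02 min) over the three-ramp
  program, scans every 0.005 min — about 20 scans across a peak, enough for
  matched filtering to be meaningful; the instrument's true scan rate is not
  documented in the emulated acquisition, so this is a stated default.
* unit-mass EI spectra with 5–25 fragments in m/z 38–450, base peak 1000,
  molecular ion recorded; log-normal abundances across samples (median
  5 × 10⁴, σ_log 0.5 — positive and heavy-tailed, the standard intensity
  model in metabolomics);
* constant baseline (100) plus additive Gaussian detector noise (sd 50),
  truncated at zero;
* a constant +0.3 min retention shift for the second group (the column
  change between groups) plus per-compound, per-sample jitter
  (sd 0.02 min ≈ 1.2 s). The jitter level is set to make intragroup
  retention variation visible, the documented property of the emulated
  data that makes alignment necessary; it is also what occasionally splits
  a compound's features into retention-disjoint groups — the duplication
  phenomenon the merge step is designed to suppress;
* two ubiquitous sampling-bag artifacts (N,N-dimethylacetamide, phenol) in
  every breath and room-air run;
* per group: a C7–C30 n-alkane ladder run (retention linear in carbon
  number, which makes the RI grid exact and the anchor regression
  well-posed) and a 10-compound VOC standard run.

What the generator does **not** emulate: chemically realistic EI
fragmentation (spectra are random), peak tailing/fronting, detector
saturation, TD breakthrough, and correlated noise. Passing tests therefore
demonstrate the pipeline's *algorithmic* correctness on well-formed signals
— detection, alignment, unmixing, matching, thresholds, bookkeeping — not
robustness to pathological peak shapes.

# Numerical choices and degenerate inputs

* Unit-mass ties (x.5) round half up.
* The matched-filter noise scale and the anchor-outlier rule both use
  1.4826 × MAD (robust, standard).
* Retention-tolerance comparisons carry a 10⁻⁹ min epsilon so grid round-off
  cannot flip a boundary case; segment boundaries likewise.
* With fewer than two samples, alignment warns and returns identity warps;
  with no anchors it does the same. loess falls back to a linear fit if the
  fit degenerates.
* Empty runs, empty libraries, empty compound lists and all-zero spectra are
  explicit error or flagged-empty paths, not silent zeros.
* The match factor is clamped to [0, 100] against floating-point overshoot
  (the alkane filter's "> 95" and the candidate floor "> 80" are exclusive
  comparisons).
* The test suite and examples run the pipeline on a compressed three-ramp
  program (9 min, ~1 800 scans per run) with 6–8 compounds and 2–5 samples
  per subset; the full-scale seeded study (`demo_pipeline(seed = 1)`: two
  groups, 16 breath runs plus 4 standards on the 46-min program, 18 library
  compounds + 2 artifacts) is exercised once in the acceptance tests. These
  sizes are the package's chosen desk-scale study conditions.

# Known limitations

* **Duplicate-reduction inequality.** In the seeded full-scale study the
  filtered list's duplicate fraction (0) sits strictly below the clique
  side's raw fraction but *ties* the deconvolution side's, which is also 0.
  This is structural: a flagged deconvolution-side duplicate pair needs
  dot > 0.8 *and* ΔRT ≤ 0.05 min, a strict subset of the aligner's join
  criterion (dot ≥ 0.7, ΔRT ≤ 0.05 min), so any cross-sample pair that the
  duplicate detector could flag has already been merged during alignment;
  within-sample splits, the other possible source, do not occur because
  candidate detection clusters per-ion apexes and adapts to peak width. On
  real data — where deconvolution engines bin, split tailing peaks and
  over-segment — both raw lists duplicate freely and the filtered list's
  reduction is strict; on clean synthetic Gaussians the deconvolution route
  is already duplicate-free, so that half of the comparison is vacuous. The
  corresponding acceptance expectation is left failing rather than weakened.
* The majority-vote consolidation of per-sample cliques deliberately
  suppresses the sample-by-sample duplication that plagues per-sample
  grouping; cohort-level clique duplicates arise only from retention-split
  feature groups.
* Identification is putative annotation, not identification: with random
  synthetic spectra the match factor separates compounds sharply, which
  real isomer-rich libraries will not.
* The 412-position half-open range and the sum-then-log normalization
  denominator are declared conventions; both are configurable where the
  underlying convention is ambiguous.
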