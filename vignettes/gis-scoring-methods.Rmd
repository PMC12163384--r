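---
title: "Genomic instability scar scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic instability scar scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openhrd)
```

This vignette explains the models behind `openhrd`, the parameters a user
may want to adjust, the numerical choices made where the design was open,
and what the simulation-based validation does and does not demonstrate.

## The signal model

A tumor specimen is a mixture of tumor cells (fraction $\rho$, the purity)
and normal diploid cells (fraction $1-\rho$). A genomic segment with
allele-specific copy numbers $(n_A, n_B)$ in the tumor produces an expected
total intensity proportional to $2(1-\rho) + \rho\,(n_A+n_B)$. Arrays
compress this signal; we model the observed LogR of a segment as

$$ r = \gamma \log_2 \frac{2(1-\rho) + \rho\,(n_A+n_B)}{2(1-\rho) + \rho\,\psi}, $$

where $\psi$ is the average tumor copy number (ploidy) that normalizes the
track to zero, and $\gamma$ (default 0.55) is the platform compression
factor customary for SNP arrays. The B-allele frequency of a
germline-heterozygous probe is

$$ b = \frac{(1-\rho) + \rho\, n_B}{2(1-\rho) + \rho\,(n_A+n_B)}. $$

`segment_copy_numbers()` inverts this model exactly, and the simulator's
`render_probes()` is its exact algebraic forward evaluation — which is what
makes the purity/ploidy fit testable against ground truth.

## Segmentation

The original processing chain runs an allele-specific piecewise-constant
fit (ASPCF) with a penalty of 70 inside external software whose objective
is not published. `segment_track()` re-implements the role of that stage
with a defined objective: per chromosome it minimizes

$$ \sum_{\text{segments}} \left[ \frac{1}{\hat\sigma_r^2}\sum_i (r_i-\bar r)^2
 + \frac{1}{\hat\sigma_b^2}\sum_{i \in \text{het}} (m_i-\bar m)^2 \right]
 + \lambda \times \#\{\text{breakpoints}\}, $$

where $m_i = |b_i - 0.5| + 0.5$ is the mirrored BAF of informative probes
and $\lambda$ = 70 by default. The optimum is computed exactly by an
$O(n^2)$ dynamic program (compiled code), with a minimum segment length of
5 probes; chromosomes with fewer probes are emitted whole with a warning.

Standardizing residuals by robust noise estimates is essential: it puts the
penalty in units of noise variance, so 70 acts like a chi-squared evidence
threshold per breakpoint. On raw residual scales a penalty of 70 would
suppress every biologically real breakpoint at array noise levels, and in
the zero-noise limit nothing would ever split. The noise estimates are

* $\hat\sigma_r$: median absolute difference of consecutive same-chromosome
  LogR values, scaled to be consistent for Gaussian noise (the MAPD metric
  up to a constant);
* $\hat\sigma_b$: from homozygous probes, whose BAF sits at 0 or 1 with
  clipping — the squared distance to the nearest extreme has expectation
  $\sigma_b^2/2$.

Both are floored at $10^{-4}$ so that noiseless input still segments
exactly. Whether the external software's penalty of 70 is numerically
comparable to this objective cannot be verified without that software; the
default is kept nominally and behavior is validated on simulations.

### De-biasing the mirrored BAF

Folding BAF about 0.5 makes a perfectly balanced segment look slightly
imbalanced, because $E|N(0,\sigma_b)| = \sigma_b\sqrt{2/\pi} > 0$. Left
uncorrected this biased the purity fit upward by 0.05–0.10 at default noise.
Each segment's allelic imbalance is therefore estimated as
$\hat\Delta = \sqrt{\max(\overline{(b_i-0.5)^2} - \hat\sigma_b^2,\, 0)}$,
which is unbiased for the fold and exact at zero noise; the reported
`mean_mbaf` is $0.5 + \hat\Delta$.

## Purity/ploidy grid search

`grid_search()` scores every $(\rho, \psi)$ on a grid
($\rho$: 0.10–1.00 by 0.01, covering the 20% pathology acceptance minimum
with margin; $\psi$: 1.0–5.4 by 0.05) by the length-weighted squared
distance of the continuous $(n_A, n_B)$ of BAF-informative segments to
their nearest non-negative integers. The full surface is returned and can
be drawn as the "sunrise" heatmap.

Two well-known identifiability issues are handled explicitly:

* **Affine degeneracies.** Mapping every state $n \mapsto k n + m$
  (integers $k \ge 1$, $m \ge 0$) yields another parameter pair with
  identical residuals at higher ploidy — $k=2, m=0$ is the genome-doubling
  ambiguity, and $k=1, m=1$ exists whenever $\rho < 0.5$. On a coarse grid
  an image can even fit *better* than the truth when its $\psi$ happens to
  lie nearer a grid value. Near-optimal candidates are therefore re-scored
  after local continuous refinement of $(\rho, \psi)$ (Nelder–Mead within
  ±1.5 grid steps), which restores the exact tie, and a tiny additive
  preference ($10^{-6}$ per ploidy unit, $10^{-9}$ toward higher purity)
  resolves it toward the parsimonious solution. The reported parameters are
  the grid point nearest the winning basin's optimum.
* **Flat balanced profiles.** A normal diploid genome constrains neither
  $\rho$ nor $\psi$; when all informative segments are balanced and the
  LogR range is negligible the fit is flagged `non_identifiable` and the
  pipeline insists on a manual `fix_rho`/`fix_psi`, mirroring the analyst
  confirmation step of the original platform.

A pathologist tumor-content estimate, when provided, down-ranks grid
solutions whose purity deviates beyond a tolerance band (default ±0.15) by
inflating their distance — solutions are never excluded, so a confidently
wrong estimate cannot hide a clearly better fit.

`fit_profile()` rounds to non-negative integers (clamping negatives to zero
with a count of clamped values), orders alleles as major ≥ minor, extends
the outermost segments to the chromosome ends, and merges equal-state
neighbours. Segments without informative probes (e.g. male sex chromosomes)
get their rounded total split as evenly as the integer allows.

## Scar rules

All three rules run on the integer profile against the bundled hg19
coordinate model (chromosome lengths and centromere spans; this package
uses the UCSC centromere annotations, and a user table can be substituted).
Telomeres are taken as the first/last base of each chromosome, with no
subtelomeric buffer. Chromosome X is scored by default (configurable), and
Y only for XY samples.

* **LOH** — maximal runs of segments with $n_{minor} = 0$ and
  $n_{major} \ge 1$; homozygous deletions (0,0) inside a run do not break
  it but contribute no length, and data gaps under 3 Mb are bridged. A run
  counts when its summed length exceeds 15 Mb (strict, per the rule's
  "greater than" phrasing) and it does not span the whole chromosome.
* **LST** — per chromosome arm (breaks never span the centromere):
  segments shorter than 3 Mb are deleted one at a time (shortest first),
  merging equal-state flanks over the removed interval, until stable; a
  break is then an adjacent pair in different states with both segments
  ≥ 10 Mb (inclusive, per "minimum size") and an inter-segment gap below
  3 Mb. The 3 Mb figure is used both as the smoothing threshold and the
  maximum gap at a counted break.
* **TAI** — maximal runs of equal imbalance status
  ($n_{major} \ne n_{minor}$); an imbalanced run counts when it touches the
  first or last covered base of a chromosome, does not cross the centromere,
  is at least `tai_min_len` long (default 0), and does not cover the whole
  chromosome.

The whole-chromosome exclusions for LOH and TAI follow the scar literature
this family of rules descends from (whole-chromosome events reflect
aneuploidy rather than recombination-deficient repair) and can be switched
off in `scar_config()`. The GIS score is the plain sum of the three counts.

## Calibration, threshold and agreement

Raw GIS scores are aligned to the reference assay's scale by ordinary least
squares (`reference ~ m·raw + b`). Corrected scores are kept continuous for
thresholding — the classification rule is corrected ≥ 42, inclusive — and a
display value rounded half-away-from-zero is reported separately.

Positive/negative/overall percent agreement use Wilson score intervals
(no continuity correction) at 95%. PPA and NPA are margined on the **test**
assay — PPA is the share of test-positive samples confirmed by the
reference — because that orientation is the one under which the published
validation statistics are internally consistent; it is stated prominently
since the reference-margined convention is also common.

## The simulator

`sim_config()`/`inject_scars()`/`render_probes()` emulate a clonal tumor on
a diploid (or re-based) background with probes every 100 kb, 25% of them
germline-heterozygous, and Gaussian noise (LogR SD 0.12, BAF SD 0.03 —
values typical of FFPE array data; purity defaults to 0.6, a common
pathology estimate well above the 20% acceptance minimum). Each injected
event is constructed to qualify under exactly one scar rule:

* LOH events straddle the centromere (total span 16–21 Mb; each arm
  overhang is 6.5–9 Mb, i.e. under the 10 Mb LST flank and away from any
  telomere);
* LST events are balanced terminal gains of 12–30 Mb on a q arm (one state
  transition with ≥ 10 Mb flanks, no imbalance);
* TAI events are single-allele terminal gains of 5.5–9.5 Mb (imbalanced and
  telomere-touching, but too short for their boundary to count as an LST).

Each event occupies its own autosome, which more than satisfies the 20 Mb
separation constraint; requests beyond 22 events, or TAI on an allelically
imbalanced (odd-ploidy) baseline, are rejected as infeasible. One RNG
stream per run is seeded from the configuration.

What passing the simulation suite shows: the segmentation, fit and scar
stages invert the package's own forward model, exactly at zero noise and
stably at realistic noise. What it does not show: robustness to FFPE wave
and GC artifacts, subclonality, probe-density variation, or mis-specified
noise models — none of which the generator emulates. Real-array behavior
is anchored instead by the published validation statistics that the
calibration/agreement module reproduces.

## Problem sizes and determinism

The test suite and the acceptance script use full-genome simulations
(~31,000 probes) with 10 zero-noise round-trip seeds, 15–20 noisy
replicates for grid recovery and GIS error, a 50-replicate GIS regression,
1,000 random draws for signal-model inversion, 200 random toy profiles for
the brute-force scar oracle, and exhaustive segmentation enumeration up to
30 probes. All stochastic tests fix seeds; identical inputs and
configuration produce byte-identical JSON reports.

## Known limitations

* ndSNPQC is vendor-defined inside proprietary software and has no
  published formula; it is accepted as an externally supplied value and
  only compared against its threshold (26).
* Raw CEL parsing and array normalization are out of scope; the pipeline
  starts from per-probe LogR/BAF tracks.
* No subclonal (non-integer) copy-number states and no multi-sample joint
  fitting.
* Near the 42-point threshold, assay calls are sensitive to single GIS
  points; the published validation itself shows occasional discordance
  there, and the continuous corrected score should be inspected for
  borderline samples.
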