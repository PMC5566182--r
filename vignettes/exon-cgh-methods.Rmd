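---
title: "Methods: exon-centric aCGH design, simulation, calling and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exon-centric aCGH design, simulation, calling and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonCGH)
```

## The problem

Exon-targeted array comparative genomic hybridization (aCGH) measures,
for every oligonucleotide probe, the log2 ratio of test versus reference
DNA hybridization intensity. A diploid locus sits near 0; a heterozygous
single-copy gain (3 copies) sits near `log2(3/2) = +0.58`; a heterozygous
deletion (1 copy) near `log2(1/2) = -1`. Concentrating 1–2 probes on
every exon of a clinically curated gene panel makes single- and
multi-exon copy-number variants (CNVs) visible at a resolution that
whole-genome arrays cannot reach, at the cost of leaving everything
outside the panel unobserved.

exonCGH implements the full desk-side workflow around such a platform:
isothermal probe-panel design with coverage accounting, a probe-level
signal simulator, two-tier interval-score CNV calling with call
integration, single-probe exon-level calling clustered by disease panel,
and qPCR dosage validation by the delta-delta-Ct method.

## Probe design

Probes are ~60-mers selected per exon from sliding candidate windows.
Each candidate gets a nearest-neighbor melting temperature (unified
thermodynamic parameter set; duplex initiation terms; entropic salt
correction `0.368 (N-1) ln[Na+]`; strand term `R ln(Ct/4)`). The ionic
and oligo concentrations are fixed design constants, 0.1 M Na+ and
0.25 uM total oligo, chosen so a balanced 60-mer melts near the 80 °C
isothermal design point; both are carried in `design_config()` and
therefore in any output metadata.

Candidate quality is a product of penalties — GC deviation from 50 %,
Tm deviation from target, homopolymer runs, self-complementarity — with
hard failures (non-ACGT bases, runs longer than 6, GC outside 30–70 %,
a self-complementary stretch of 12+ bases) zeroing the score.
"Specificity" is approximated by these sequence-intrinsic penalties only;
there is no genome-wide uniqueness search. That is a documented
simplification with a clear extension point (a k-mer uniqueness filter
would slot into `score_candidate()`).

Selection keeps up to 2 non-identical passing candidates per exon,
spread across the exon by binning the candidate range and taking each
bin's best scorer (ties go to the leftmost start, making the whole
design deterministic given genome and configuration). Exons with no
passing candidate fall back to genomic tiling: end-to-end placement at a
one-probe stride with the Tm tolerance doubled. Exons shorter than one
probe receive a single probe extended symmetrically into flanking
sequence; exons where even tiling fails (e.g. poly-N sequence) are
reported as uncovered rather than silently dropped.

Coverage accounting counts a target as covered when any probe overlaps
it by at least 1 bp, and prints coverage rounded half-up to a whole
percent. Median probe spacing is the median of start-to-start distances
between consecutive probes within each chromosome, pooled — the quantity
is not standardized, so it is documented here and computed exactly this
way everywhere in the package.

## The signal simulator

`simulate_signals()` draws each probe's ratio from
`Normal(log2(c/2), sigma_i)` with `sigma_i = sigma * jitter_i`, where the
per-probe jitter (default 0.8–1.2) emulates the per-probe error estimates
a feature-extraction pipeline reports. Copy number 0 maps to a floor of
-4 because `log2(0)` is undefined. Options add uniform outliers
(default probability 0.01 on ±2) and a sinusoidal wave artifact (off by
default — it is there to stress the caller, not because the caller
corrects it). The defaults (`sigma = 0.2`) correspond to a decent but not
pristine array.

What the simulator does *not* emulate: two-channel raw intensities and
dye effects, GC-correlated waves tied to real genome sequence, spatial
artifacts, and mosaic (non-integer) states. Tests passing on simulated
data therefore demonstrate the statistical machinery under the model's
assumptions — Gaussian probe noise around `log2(c/2)` — not performance
on any particular scanner's output.

qPCR simulation follows the ideal-doubling model: a locus at relative
dosage `q` crosses threshold `log2(q)` cycles early,
`Ct = baseline - log2(q) + noise`, with the reference locus and every
calibrator well at `q = 1`.

## CNV calling

Both calling tiers use one interval statistic: for probes `i..j`,
`S = |sum(u_k)| / sqrt(j - i + 1)`, with `u_k = r_k / sigma_hat` in the
global tier ("ADM-1-like") and `u_k = r_k / sigma_k` in the
probe-error-weighted tier ("ADM-2-like"). With uniform per-probe errors
the tiers coincide, which the tests assert. The true commercial ADM
internals are proprietary; this module implements the
published-in-outline statistic with a recursive maximal-interval search
and claims only the qualitative contract: the weighted tier is the
stricter filter, and integrating both recovers real calls that only one
tier finds.

The noise scale `sigma_hat` comes from the derivative log-ratio spread
(DLRS): `1.4826 * median(|diff(r)|) / sqrt(2)` per chromosome, pooled by
median — robust to the CNV segments themselves, which contribute only two
breakpoint differences each.

Search: per chromosome, find the highest-scoring contiguous interval
(exhaustive over all starts and lengths from `min_probes` = 3 up to a
cap), emit it if `S >= threshold_t`, and recurse independently on both
flanks. Ties break longest-then-leftmost. Emitted calls within one tier
can therefore never overlap. Significant intervals whose mean log2 ratio
lies inside (`loss_cut`, `gain_cut`) = (-0.30, +0.30) are discarded as
untyped; the cuts sit midway between noise and the heterozygous
amplitudes ±0.58/-1. The copy-number estimate is
`round(2 * 2^mean)` clamped to 0..8, mapping +0.58 to 3 and -1 to 1
exactly. `threshold_t` defaults to 6.0, a conventional
aberration-detection default, exposed in the configuration and written
into run metadata. On a 300-probe null array at this threshold, fewer
than 1 % of seeds produce any call.

Integration matches calls from the two tiers by reciprocal overlap
(>= 0.5 of both lengths, same chromosome, same type): matched pairs merge
into tier `"both"` (union interval, maximum score); unmatched calls stay
with tier `"single-algorithm"`, because a single-tier call can be a real
variant — the point of running both tiers is precisely not to let either
filter the other.

### Centralisation

Ratios must be centered so the diploid state sits at 0 before scoring.
The mode method locates the highest peak of a Gaussian kernel density
estimate (ties toward zero) and refines it to the mean of probes within
2 MAD of that peak. The refinement matters: the diploid peak of
`Normal(0, 0.2)` noise is flat on top, so a raw histogram bin or KDE
argmax wanders by several hundredths even at 2,000 probes, while the
clipped mean is efficient near the peak yet still excludes aberrant
segments. Measured on 20 seeded arrays with a 5 % CNV fraction, the
worst-case offset is 0.016 and the median 0.005, and the estimator stays
stable at a 20 % aberrant fraction. A median method is available for
degenerate inputs; an all-constant signal centers to zero and is flagged
`zero_spread`.

## Single-probe exon calling

Multi-probe calling ignores events supported by fewer than `min_probes`
probes, so single-exon CNVs covered by one or two probes vanish from
standard reports. The exon caller computes `z = r / sigma_i` per probe
and labels an exon `gain` (all `z >= 3`), `loss` (all `z <= -3`),
`normal`, or `uncovered` when no probe overlaps it — never `normal`, so
absence of evidence stays visible. The 3-SD default keeps the expected
number of false single-probe calls low at panel scale (about 0.3 % of
covered exons two-sided) while catching heterozygous deletions at
`|z| ~ 5` on a good array; it is configurable because the right
trade-off depends on how many strongly causative genes the panel
restricts to.

This mode is deliberately more sensitive *and* more false-positive-prone
than 3-probe calling — the test suite measures both rates on matched
simulations and asserts the ordering. By default, aberrant single-probe
statuses are reported only for genes flagged causative; on other genes
they are retained but marked suppressed (and logged) rather than deleted,
which supports using the mode as a validation strategy for externally
known imbalances. Aberrant calls are clustered by disease panel, with
shared genes appearing in every panel they belong to.

## qPCR validation

`relative_dosage()` computes, per sample,
`dCt = Ct_target - mean(Ct_reference)`, then
`ddCt = dCt_sample - dCt_calibrator` against a diploid calibrator, and
reports `RQ = 2^-ddCt` replicate-wise as mean and SD. Adding a constant
to every Ct cancels. Classification applies `loss <= 0.6`,
`0.8 <= normal <= 1.2`, `gain >= 1.4` on the RQ scale: the normal band
0.8–1.2 brackets 1 only on the `2^-ddCt` scale on which results are
reported, so the thresholds are interpreted there. The gaps
(0.6, 0.8) and (1.2, 1.4) yield an explicit `indeterminate` instead of a
forced call; indeterminate counts as discordant in concordance
accounting. Concordance matches each assayed locus to array calls by
interval overlap: gain–gain, loss–loss, or no-call–normal count as
concordant.

## Fixtures and problem sizes

Three bundled fixtures are built entirely in code: a ten-CNV case (six
gains, four losses at the published coordinates, with qPCR validation
loci at dosages 1.5 and 0.5), a single-gene case with a heterozygous
deletion of two adjacent exons of which one has no probe coverage, and a
negative control. Probe layouts and gene intervals inside them are
synthetic reconstructions; only the call coordinates, probe counts and
amplitudes are as printed. The ten-CNV fixture simulates at
`sigma = 0.1` — a high-quality clinical array — chosen analytically so
that its smallest record (3 probes at +0.58, expected score
`0.58 * sqrt(3) / 0.1 ~ 10`) clears the default threshold with margin;
at the generator default 0.2 that record's expected score (5.0) would sit
below a threshold of 6 by design, not by measurement error.

Test problem sizes are chosen to keep the whole suite near half a
minute: estimator-consistency checks at n = 10,000 probes,
oracle-equivalence up to 500 probes, detection-monotonicity at
3 amplitudes x 3 lengths with 100–200 seeded replicates of 120–150-probe
arrays, and 200-seed null-array batches at 300 probes.

## Known limitations

- No fuzzy-zero correction, GC-wave detrending, or mosaic-fraction
  estimation; the wave artifact exists in the simulator to demonstrate
  the limitation.
- Calls never span chromosomes, and the search cost is quadratic in the
  probes per chromosome (capped by `max_interval_probes`).
- The probe scorer does not model cross-hybridization or genome-wide
  uniqueness.
- Cytoband labels are not bundled; containment annotation requires a
  user-supplied interval database.
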