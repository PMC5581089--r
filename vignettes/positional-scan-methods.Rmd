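---
title: "Methods: positional enrichment scans and resistance quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positional enrichment scans and resistance quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistscan)
```

## The problem

When a cell line acquires drug resistance under continuous selection, one
recurrent mechanism is a genomic lesion — a deletion or loss of
heterozygosity — that silences every gene in a chromosomal neighbourhood at
once. On an expression array this leaves a characteristic footprint: a
cluster of co-located probes, often on both the miRNA and mRNA platforms,
all downregulated in the resistant subline. `resistscan` formalises the
search for that footprint and the quantification of the resistance
phenotype that motivates it.

## The region test

### Model

Let the *scan universe* be the N probes of one platform that carry both a
fold-change record and a cytoband assignment. Probe fold change is

$$\mathrm{fc}_i = \frac{\max(\bar x_i^{\mathrm{res}}, \epsilon)}
                      {\max(\bar x_i^{\mathrm{par}}, \epsilon)},$$

the ratio of arithmetic-mean linear intensities across replicates, with a
detection floor $\epsilon = 1$ intensity unit so the ratio is always
finite. A probe is *downregulated* when $\mathrm{fc}_i < 0.5$ and
*upregulated* when $\mathrm{fc}_i > 2$, both strict inequalities, so a
probe at exactly half intensity is not counted. Let K of the N universe
probes be downregulated.

For a region R of n probes with a of them downregulated, the null
hypothesis is that downregulated probes are exchangeable across the
genome, under which $a \sim \mathrm{Hypergeom}(N, K, n)$. The test is the
one-sided exact upper tail

$$p_R = \sum_{a' \ge a} \frac{\binom{K}{a'}\binom{N-K}{n-a'}}{\binom{N}{n}},$$

summed in log space (log-binomials via `lchoose`, combined with
log-sum-exp) so that tails of order 10⁻³⁰⁰ are still representable. The
test is one-sided by design: the biological question is an *excess* of
downregulation; a two-sided variant is available behind a flag and
delegates to `stats::fisher.test`.

A region is significant when $p_R \le \alpha$ with $\alpha = 2\times10^{-3}$
by default — an inclusive threshold, so a region landing exactly on the
boundary is called. No multiple-testing correction modifies the call (the
procedure is a fixed-threshold selection rule); Benjamini–Hochberg
q-values are emitted as an informational column.

### Assumptions and their limits

The hypergeometric null treats probes as exchangeable: it ignores
correlation between neighbouring probes of the same transcript and any
platform-specific intensity structure. Exchangeability makes the test
conservative for detecting a planted contiguous signal but means p-values
should be read as enrichment scores, not calibrated genome-wide error
rates. Regions are fixed cytobands (sub-band resolution, e.g. q22.32),
because named sub-bands are the natural reporting unit for this kind of
finding; bands with fewer than `min_probes = 2` probes are not tested
since a single probe cannot "cluster". The scan universe deliberately
excludes unassigned probes from both margins, keeping the 2×2 margins
consistent across regions.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 2×10⁻³ | significance threshold on the one-sided p |
| `fold_threshold` | 2 | fc < 1/threshold is "down", > threshold "up" |
| `min_probes` | 2 | minimum assigned probes for a band to be tested |
| `floor_intensity` | 1 | detection floor before the ratio (intensity units) |
| `sided` | "one" | enrichment-only tail vs classic two-sided |

### Coordinates and reporting

Coordinates are 0-based half-open internally, matching BED-style inputs;
reports are 1-based inclusive. A probe belongs to the band containing its
midpoint (probes are tiny relative to bands, so midpoint membership avoids
double counting); a midpoint exactly on a band boundary falls in the next
band by the half-open convention. Manhattan x-positions are band midpoints
offset by the summed lengths of preceding chromosomes in the order 1..22,
X, Y. Ties in "best region" ranking are broken by larger observed count a,
then lexical region id, making ranks deterministic.

## Dose-response and resistance ratios

Viability at concentration c is $(OD(c) - b)/(OD(0) - b)$ with b the plate
blank; values above 1 (growth stimulation) are kept because clipping would
bias the regression. The default IC50 estimator regresses viability on
log₁₀ concentration over a local window — the two concentrations
bracketing the 50% crossing plus their immediate neighbours, four points
when available — and solves the fitted line for viability 0.5. A local
line is used rather than a global one because dose ranges span two or more
decades and a single line fits the sigmoid poorly; the window makes the
"regression line" assumption locally true. A 4-parameter logistic
(`minpack.lm::nlsLM`, starting values from a logit-log regression) is
provided as the modern alternative and recovers noiseless logistic data
exactly; the two estimators agree within 15% on noiseless data with Hill
slopes in [0.8, 2].

If viability is still above 50% at the top concentration the IC50 is
censored as ">Cmax" (symmetrically "<Cmin" below); a censored numerator
propagates into a lower-bound resistance ratio rendered "> x", while a
censored denominator is an error because the ratio is then undefined.
Reported ratios are rounded half away from zero at a declared number of
decimals, so printed values are reproducible exactly (16.8/7.6 → 2.2 at
one decimal; 3.7/13.9 → 0.27 and 15.7/82.7 → 0.19 at two).

## qPCR relative quantification

Ct values are averaged on the Ct scale across replicates (the
conventional treatment), converted to quantities through an assay
standard curve $Q = 10^{(C_t - \mathrm{intercept})/\mathrm{slope}}$,
normalized against the reference assay (U6 for miRNA, GAPDH for mRNA),
and calibrated against a designated calibrator sample. When no curve
parameters are supplied, perfect-efficiency curves (slope −1/log₁₀2) are
assumed with a logged notice — the method then reduces exactly to
2^(−ΔΔCt), which is also the package's closed-form cross-check.
Efficiencies outside (0.8, 1.1) warn; outside (0, 1.5] they error.

## Seed matching

The seed is miRNA nucleotides 2–8 of the mature 5′ end. Site detection
works in DNA space (U→T): the 7mer-m8 site is the reverse complement of
the full seed; an 8mer additionally has an A immediately 3′ on the target
(opposite miRNA position 1); a 7mer-A1 matches the reverse complement of
seed nucleotides 2–7 followed by an A; a 6mer is that core match alone.
Each core-match locus is reported once with its maximal type, overlapping
loci are all reported, and 6mer reporting is off by default because only
7mer-and-better sites carry appreciable repression signal. Families are
grouped by exact seed identity — the mechanism behind "family members
behave alike" arguments.

## The synthetic-data generator

The generator emulates the structure of a paired-subline array study with
planted ground truth, so every downstream claim is testable end to end:

* **Genome**: 10 chromosomes × 10 contiguous bands of 10 Mb; 10 miRNA and
  10 mRNA probes per band (universe 1000 per platform, 100 regions). Band
  names follow a fixed sub-band vocabulary so the planted default locus is
  literally "9q22.32".
* **Expression**: baseline intensity per probe is log-normal
  (log₂ mean 8, sd 2 — a typical array dynamic range); each sample
  multiplies in log-normal replicate noise (log₂ sd 0.25). One parental
  and one resistant array per platform by default, matching the
  single-array-per-condition design the scan is meant for.
* **Signal**: the planted band's probes are divided by `effect_fold = 4`
  in the resistant condition on both platforms; a Bernoulli 5% subset of
  the remaining probes is spuriously downregulated 4-fold, emulating the
  genome-wide deregulation background that accompanies acquired
  resistance.
* **Dose-response**: 4-parameter logistic viability on an 8-point
  half-log grid from 0.1 to 316 μM, planted IC50s 7.6 μM (parental) and
  76 μM (resistant), Hill 1, 3 replicates, Gaussian viability noise
  sd 0.05; absorbances are blank + gain × viability.
* **UTRs**: background sequence is rejection-sampled so no accidental
  seed-core occurrence survives outside the planted loci, sites are
  inserted non-overlapping with guard bases that prevent accidental
  upgrade to a longer site type, and the whole sequence is re-scanned to
  verify the construction.

Every stage derives its own sub-seed deterministically from the master
`rng_seed`, so outputs are byte-identical across runs and stages can be
regenerated independently.

What the generator does *not* emulate: probe-level correlation within
transcripts, intensity-dependent variance, spatial array artifacts,
copy-number segments, or partial-penetrance deletions. Passing the
planted-recovery tests therefore shows the machinery is correct under an
idealised error model, not that real arrays of any particular platform
will yield the same power.

## Numerical choices and degenerate inputs

* Exact-test tails are log-sum-exp sums of `lchoose` terms; the result is
  clamped into (0, 1]. Against a direct enumeration of the hypergeometric
  pmf the implementation agrees to ~10⁻¹⁵ relative over every table with
  N ≤ 12.
* An all-zero probe (both conditions) gets fc = 1 and an
  `uninformative` flag rather than propagating 0/0.
* A viability point exactly at 50% short-circuits the regression and is
  returned as the IC50 (the crossing is attained, not interpolated).
* Non-monotone viability with several 50% crossings uses the lowest
  crossing and warns.
* Empty cytoband files parse to an empty map with a warning; overlapping
  bands are a hard error naming the offending pair; probes on
  chromosomes without bands are left unassigned, counted, and excluded
  from the scan universe.
* TSV writers render doubles at 17 significant digits so write→read
  round-trips are bit-identical.

## Problem sizes used in the checks

The bundled checks run the default scenario (universe 1000, 100 regions)
over 100 seeds for planted recovery and 200 seeds for null calibration,
100 seeds for noisy IC50 recovery, and the exhaustive exact-test sweep
over all 2×2 tables with N ≤ 12 (1820 tables). These sizes give binomial
resolution of a few percent on recovery rates while keeping a full run in
the order of a minute.

## Known limitations

The scan assumes pre-normalized linear intensities and performs no array
normalization of its own; whether fold changes should be computed on
linear or log intensities is a genuine modelling choice, and the linear
convention used here is declared rather than derived. The fixed-threshold
selection rule is intentionally faithful to common practice in this study
design but is not a calibrated multiple-testing procedure. IC50s from the
local-line estimator carry a small systematic bias (a few percent) when
the true curve is logistic, which is why the 4PL estimator is the
reference for recovery checks. Seed matching deliberately stops at site
detection: no context scoring, conservation, or thermodynamics.
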