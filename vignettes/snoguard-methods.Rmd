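---
title: "Methods: snoRNA-guided methylation and tRNA fragmentation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snoRNA-guided methylation and tRNA fragmentation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoguard)
```

# Scope and model

`snoguard` implements the computational chain used to establish that a
C/D-box snoRNA 2′-O-methylates a tRNA and thereby protects it from
site-specific cleavage into a tRNA-derived fragment (tRF). The chain
has five parts: reference handling with C/D-box annotation, antisense
duplex prediction with methylation-site placement, tRF profiling from
small-RNA reads, RTL-Q-based methylation quantification, and the qPCR
expression indices used to compare conditions. A synthetic-data module
generates inputs with the statistical structure these analyses assume,
so the whole chain is testable without sequencing or qPCR data.

# Duplex prediction and the +5 rule

C/D-box snoRNAs carry two antisense elements, directly upstream of the
D and D′ boxes, that are free of ribonucleoproteins and hybridize to
target RNAs by Watson–Crick base-pairing. `find_duplex_hits()` scans
every target window antiparallel to the element (element 5′ end
against the window 3′ end) and reports windows whose longest
contiguous run of Watson–Crick pairs reaches `min_core` (default 7 nt)
with all mismatches confined to the outermost
`max_terminal_mismatches` (default 2) positions at each element end.
This reflects guide-duplex geometry: a clamped central core with outer
nucleotides allowed to fray. G:U wobble pairs count as mismatches by
default (`allow_wobble = TRUE` relaxes this), because guide
recognition is defined by strict Watson–Crick pairing.

The methylated nucleotide is the target base paired with the element
residue five positions upstream of the adjacent box. We count from 1
at the residue immediately before the box (the element's 3′-most
position), the standard convention; the "+5" residue is therefore
element position L − 4 and, by the antiparallel pairing map, the
target position `target_start + 4`. When that element position is a
mismatch the site is unplaceable and reported absent with reason
"unpaired at +5".

Box motifs themselves (C: RUGAUGA; D and D′: CUGA, D′ tolerating one
mismatch; D = last match, D′ = first internal match after the C box)
are the standard C/D-box consensus definitions. The packaged snoRNA
fixture additionally ships a pre-annotated box table, so fixture-based
results never depend on motif calling; a test asserts the two agree.

# tRF profiling

Read assignment is exact full-length substring matching against the
mature tRNA references — a deliberate desk-scale replacement for a
genome aligner that makes results reproducible and dependency-free.
Uniquely matching reads are assigned first and define per-reference
expression; multi-mapping reads are then rescued, whole-count, to the
reference with the highest unique-read count (single assignment), with
lexicographic id as tie-break. The procedure is invariant to read
input order. Reads shorter than 15 nt are dropped and counted.

Fragments group reads by (parent, start, end); calls shorter than
45 nt are tRFs, the rest mature/precursor. Names use 1-based inclusive
coordinates on the bare mature sequence (no 3′ CCA), so "tRF 47-64"
has length 18. Analytics: RPM (count / assigned library × 10⁶), a
length histogram over 18–45 nt with small (18–29) and large (30–45)
classes, per-position coverage (5′→3′; reverse for 3′→5′ display),
and fragment-family shares where a family is the canonical fragment
plus 3′ extensions up to +2 nt — matching the three observed sizes of
a ragged 3′ terminus. All denominators are explicit arguments.

# RTL-Q and the EMF

Reverse transcription at low dNTP concentration pauses at a
2′-O-methylated ribose for a primer placed downstream of the site
(R_D) but not for a primer on the site (R_U), and no pausing occurs at
high dNTP concentration. The estimated methylated fraction is

EMF = (Ct_lowRD − Ct_highRD) − (Ct_lowRU − Ct_highRU),

with EMF > 0 calling methylation present. The score is invariant to a
common Ct shift (loading) and antisymmetric under swapping primer
roles; both are tested. Replicates with any Ct at or beyond the
45-cycle detection ceiling (configurable) are excluded; aggregation is
the mean of replicate EMFs with its standard error. No amplification
-efficiency correction is applied — the assay is raw Ct arithmetic —
so EMF is a score, not a calibrated stoichiometric fraction.

# Expression indices and tests

`relative_expression_dct()` is the 2^−ΔCt method against a reference
RNA (U6 in the motivating assays); a multi-reference variant averages
reference Cts, equivalent to a geometric mean on the linear scale.
`fragmentation_ratio()` divides the mature tRNA's absolute Ct by the
tRF's Ct: since lower Ct means more template, a larger ratio means
more fragment relative to its mature tRNA. Group comparisons are
two-tailed t tests — unpaired (Student, pooled variance), paired, or
ratio-paired. "Ratio paired" is implemented as a paired t test on
log-transformed values, the natural reading when effects are
multiplicative; the source assays do not define it further. Verdicts
use p < 0.05 (significant) and 0.05 ≤ p < 0.1 (trend), both
configurable. Zero-variance degeneracies, where `t.test()` refuses,
are resolved analytically: identical groups give t = 0, p = 1; a
constant nonzero difference gives p = 0. No multiple-testing
correction is applied by default, matching the assays emulated.

# The synthetic-data generator

`cleavage_profile()` defines the generative model: each molecule draws
a methylation state (Bernoulli m), stays intact with probability
`intact_fraction`, or is cleaved at one of the weighted cut sites; on
methylated molecules the protected site — the one whose 3′ boundary
abuts the methylation position — has its weight multiplied by
`protection_factor`. Fragment 3′ ends are extended by Uniform{0..2}
nt. This is phenomenological: it encodes the direction and location of
methylation-dependent protection, not nuclease kinetics. It also omits
sequencing error, adapters, UMIs and pre-tRNA processing, so passing
recovery tests demonstrates internal consistency of the pipeline, not
robustness to real-library artefacts.

The packaged condition profiles share cut sites 1–30, 28–45 and 47–64
with weights 10 : 6 : 19 and protection factor f = 368/893 ≈ 0.412,
and differ only in the methylated fraction: m = 0.2 for `af25_low`
(snoRNA knocked down; knockdown reduces but does not abolish
methylation) and m = 0.9 for `af25_high` (overexpressed). These values
solve the closed-form mixture share

share = (1 − m)·w_p/(w_p + W) + m·f·w_p/(f·w_p + W)

for 47–64 family shares of exactly 50 % and 35 % of tRFs in the two
conditions — the regime the pipeline is meant to resolve. The
expectation is implemented in `expected_fragment_share()` and tested
against the documented fixture values and by simulation recovery
within three binomial standard errors. Stress-variant profiles change
only an abundance multiplier (hypoxia 2.0, oxidative 1.6, starvation
1.0), emulating expression directionality without a kinetic stress
model.

The RTL-Q simulator gives the low-dNTP R_D reaction a template yield
of (1 − m) + m·2^−δ, so the expected EMF is −log2((1 − m) + m·2^−δ):
0 when m = 0 and δ when m = 1. For m = 0.5, δ = 4 this evaluates to
−log2(0.53125) ≈ 0.9125. qPCR Cts follow the standard log2-linear
response Ct = base − log2(abundance) + N(0, sd), default base 25 and
sd 0.2 cycles — typical technical replicate noise. FASTQ is written
with constant quality 'I' since qualities are ignored downstream.
Identical seeds reproduce reads, FASTQ bytes and Ct draws exactly.

# Fixtures

The tRNA and snoRNA fixture sequences are synthetic reconstructions
(the motivating figures are schematic). They carry every documented
structural feature: an 85-nt leucine tRNA (anticodon UAA) with the
AACCCCA guide-pairing core at positions 62–68 and unique fragment
substrings; a mouse/human pair differing at one D-arm position; a
62-nt snoRNA with C box at 5–11, D′ box at 26–29, D box at 54–57 and a
9-nt D′-adjacent element whose two outer residues mismatch the target
by construction. The predicted 2′Ome site (position 65) abuts the
47–64 fragment boundary — the geometry of cleavage just upstream of a
protected site. Coordinates count the bare mature sequence; whether
published fragment coordinates assume a CCA-appended sequence is
ambiguous, and the bare convention is this package's fixed choice
(`append_cca` exists for CCA-counted references).

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere and survive FASTA
  round-trips.
* DNA input (T) is silently converted to RNA (U); mixed case is
  folded; any other character errors with its position.
* Duplex ties (equal core length) break by smallest target start.
* Degenerate full protection (all available cut-site weights zero for
  a methylation class) leaves those molecules intact rather than
  failing: a molecule with no available cleavage site is uncleaved.
* Per-stage pipeline seeds derive deterministically from the master
  seed; manifests contain no timestamps so reruns are byte-identical.
* Default problem sizes: module tests simulate 2 000–20 000 reads;
  share-recovery validation uses 100 000 reads per condition and the
  EMF grid uses 12 replicates per (m, δ) point — sizes at which
  three-standard-error bands are a few tenths of a percent or cycle,
  chosen as comfortably diagnostic for desk-scale validation.

# Limitations

Exact-match assignment cannot place reads with sequencing errors or
non-templated additions; the profiler consequently understates
abundance on real libraries relative to a mismatch-tolerant aligner.
Duplex scoring is combinatorial (no thermodynamics), appropriate for
short guide elements but not for ranking marginal sites. EMF is a
relative score; converting it to an absolute methylated fraction would
require calibration the underlying assay does not provide. The
simulator's protection model is directional, not mechanistic, and
class-level RPM summaries depend on which references are supplied —
the package does not quantify microRNA/piRNA/snRNA classes beyond
counting assigned reads.
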