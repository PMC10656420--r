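---
title: "Boundary, census and inversion inference on sex chromosomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary, census and inversion inference on sex chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parcensus)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, what the simulator does and
does not emulate, and the design choices made where the design was open.

## The inference problem

A male mammal's X and Y share a pseudoautosomal region (PAR) and diverge
beyond the pseudoautosomal boundary (PAB). Three observable signatures
localize the PAB on an X assembly:

1. **Homology transition.** Alignments from Y-derived sequence (an MSY
   assembly, Y-side BAC clones) stop at the PAB while X-derived
   alignments continue. The PAB is "where the alignment stopped".
2. **Depth step.** Male reads cover the PAR at twice the X-specific
   depth, because PAR reads from both haplotypes co-map. Past the PAB
   the depth falls to ~50 % of the PAR-side baseline.
3. **Read drop-offs.** Y-origin reads entering the PAR terminate their X
   alignments at a common coordinate.

The package implements all three, plus the census machinery for tandem
and dispersed repeats and inversion demarcation from synteny blocks.

## Models and estimators

### Homology-transition boundary

Segments of each source class (Y-derived, X-derived) are filtered to
identity ≥ `tier_hi` (default 90 %) and length ≥ `min_hit_len` (1 kb) and
merged per class across gaps ≤ `merge_gap` (5 kb). The PAR-anchored Y
block is the merged Y interval nearest the PAR end of the target; the
boundary is its **right end, i.e. the last pseudoautosomal base**. The
call additionally requires X homology extending ≥ `flank` (10 kb) beyond
the boundary, distinguishing a true transition from the target simply
ending. When the printed convention of an external coordinate is unknown
(last shared base vs first specific base), comparisons should allow ±1.

`merge_gap` is the resolution limit: fragmented or jittered alignment
endpoints move the call by at most the largest bridged gap, which the
recovery tests confirm (exact on clean evidence, ≤ `merge_gap` under
1 kb endpoint jitter).

### Depth changepoint

Window depths $y_1,\dots,y_n$ (window = 1 kb by default) are treated as
Poisson counts. For a breakpoint $b$ the two-mean log-likelihood with
side-wise MLEs $\hat\lambda_1, \hat\lambda_2$ is

$$\ell(b) = S_1\log\hat\lambda_1 - n_1\hat\lambda_1
          + S_2\log\hat\lambda_2 - n_2\hat\lambda_2,$$

with $S$, $n$ the side sums and counts. The estimator scans **all**
breakpoints via cumulative sums (so it is exact likelihood, not a greedy
search — the test suite checks it against an independent brute-force
scan), takes the leftmost argmax on ties, and reports
$\Delta\ell = \ell(\hat b) - \ell_0$ against the single-mean null. A call
requires $\Delta\ell \ge$ `changepoint_min_delta_loglik` (default 10,
roughly a $\chi^2_1$ far tail; depth tracks are long, so power is not the
issue — the threshold guards against spurious steps on flat tracks). The
ratio is $\hat\lambda_2/\hat\lambda_1$, i.e. relative to the **PAR-side
baseline**, matching the "drops to ~50 %" convention. Fractional window
means are accepted as quasi-Poisson counts; window size trades resolution
against noise and 1 kb puts single-window error well below the ~2 kb
accuracy the synthetic benchmark demands.

Where X–Y homology decays gradually rather than abruptly, a step is the
wrong shape. The **ramp model** fits a flat–linear–flat profile by least
squares over a coarse-to-fine $(s, e)$ grid and reports the transition
interval and flat-level ratio. Model `"auto"` fits both and prefers the
ramp when an F-like statistic (residual improvement per extra parameter)
exceeds `ramp_f_threshold` (default 20). No principled criterion exists
for this choice in the motivating data — the threshold is exposed rather
than hidden.

### Drop-off clustering

Alignment right-ends are single-linkage clustered with tolerance `tol`
(50 bp); clusters of ≥ `min_reads` (5) are reported. Ends within `tol`
of the target end are uninformative (the read, not the homology, ran
out) and are excluded when the target length is supplied.

### Exon linkage and promoter scan

An exon is present in an assembly iff one merged segment set covers
≥ 80 % of it at ≥ 90 % identity; presence in X and Y assemblies maps to
pseudoautosomal / X-specific / Y-specific / absent. The TATA scanner
matches the IUPAC word `TATAWAW` on the forward strand in a 100-bp
upstream window; `distance_upstream` is anchor − motif start in 1-based
coordinates, so a motif 35 bases before an exon reports 35.

### Repeat census

* **Period inference:** distances between consecutive occurrences of
  repeated k-mers (k = 21) are histogrammed in 100-bp bins within
  `[min_period, max_period]`; the modal bin must carry ≥ 20 % of the
  recurrence distances, else "not tandem". The reported period is the
  modal bin's center of mass, accurate to ~±100 bp at percent-level
  copy divergence.
* **Copy enumeration:** the monomer is mapped to both strands of each
  target with the built-in anchor aligner **without repeat masking**
  (the query is an explicit monomer; masking is for whole-genome
  chaining). Hits < `min_hit_len` are dropped — this is the stated 1-kb
  rule, and it means planted copies shorter than 1 kb are invisible by
  design. Same-strand hits with compatible monomer coordinates ≤ 100 bp
  apart are chained into one copy; `full` means monomer coverage ≥
  `full_frac` = 0.9. "Full vs partial" has no standard definition; 0.9
  is this package's, configurable and prominently documented. Array
  spans cluster copies ≤ 50 kb apart.
* **Tiers:** high ≥ 90 %, low < 85 %, mid between — the empirical split
  between X-linked and autosomal amplicon copies.
* **Identity:** global Needleman–Wunsch (match +1, mismatch −1, gap −2);
  identity = matches / alignment columns, gap columns counting against
  identity. Whether external tools count gaps the same way is not
  assumed — ingested identities are preserved as reported.
* **Neighbor joining:** canonical Saitou–Nei on the Q criterion; ties
  broken by lowest label-index pair; negative branch lengths clamped to
  zero; output unrooted (no outgroup, no midpoint rooting). On additive
  matrices the tree metric is reproduced exactly (tested to 1e−9), and
  the topology agrees with an independent reference implementation.

### Anchor aligner

`anchor_map` is deliberately not a general aligner: exact shared k-mers
(k = 15; target k-mers occurring > 100 times masked, except in the
census) are grouped by target locality, split into diagonal bands
(forward: $t-q$; reverse: $t+q$; band width 100 bp), and chained along
the query with gaps ≤ 1 kb; ties resolve leftmost. Identity is estimated
from anchor density as $100\,f^{1/k}$ with $f$ the anchored fraction of
the span — for i.i.d. substitutions $\mathbb E[f] = (1-p)^k$, so the
estimator is consistent and empirically within ±3 points on
substitution-only data. Its documented limit is ~10 % substitution
divergence and no affine-gap extension; beyond that, use a real aligner
and ingest PAF/BLAST6.

### Synteny and inversions

Blocks chain same-orientation segments collinear on both axes within
`max_gap` (50 kb); segments < 100 bp are discarded first, because chance
k-mer collisions between unrelated sequence would otherwise seed
fabricated blocks. Inversions are maximal reverse-orientation runs;
breakpoints are the run's outermost reference bases, resolution-limited
to ±`max_gap`; a gap ≤ `max_gap` inside a run (e.g. an unassembled
centromere inside a pericentric inversion) does not split the call.

## The simulator and what it does not show

The generator emulates the statistical structure the estimators assume:
an X/Y pair with a shared PAR (within-species PAR-X/PAR-Y identity is
not an empirically measured quantity; the default divergence 0.001 —
99.9 % — is a free parameter and is flagged as such), independent random
sex-specific tails, a three-exon PAB-spanning gene with exons 1–2
Y-specific and exon 3 pseudoautosomal, a TATAWAW word planted 35 bp
upstream of exon 3, ~8 kb monomer arrays with full and prefix-partial
copies, amplicon tiers at ~98 % and ~80 % identity, large inversions,
and Poisson-sampled long reads (count mean = depth × length / mean read
length) with i.i.d. substitution errors. Between-species divergence
defaults to 2 %, the sister-equid scale.

Deliberate simplifications: substitutions only by default (indel-free
arithmetic keeps planted coordinates exact; an indel stress mode exists
in the mutation rate machinery but is not the default), uniform base
composition, no segmental duplications or satellite background, no
quality scores or FASTQ realism, no Hi-C/optical-map evidence, and the
two-haplotype male design only. Passing the synthetic suite therefore
demonstrates correctness of the inference layer under its stated
assumptions — not robustness to assembly error, indel-rich alignment, or
real repeat heterogeneity. Coordinates are 1-based inclusive everywhere
(the R/Bioconductor convention), except BED output which is 0-based
half-open per that format's standard; the PAB is always the last
pseudoautosomal base.

Determinism: every generator threads a single seed (`withr::with_seed`),
so identical configuration and seed give byte-identical sequences, reads
and truth; no global RNG state leaks.

## Problem sizes

The shipped analyses and tests run at desk scale by choice: PAR 100–200
kb with 150–300 kb tails and 30–40× reads for boundary work; 8 kb
monomers in arrays of ~10–15 copies (2 kb monomers for the 50-seed
recovery sweeps); a 5 Mb scaffold with 250 amplicon copies; 0.7–1.4 Mb
chromosomes with 170–180 kb inversions (a 1:100 scale analogue of an
~18 Mb pericentric inversion). These sizes exercise every code path with
comfortable statistical margins — e.g. ~4,000 reads give a depth track
whose changepoint standard error is a fraction of a window.

## Known limitations

* The anchor aligner's identity estimate degrades above ~10 %
  divergence and near segment ends (anchor loss), and partial-copy
  boundaries are k-mer-resolution estimates, not base-exact.
* Copy counts depend on the chaining rule (≤ 100 bp gaps, compatible
  monomer offsets); a raw-hit count from an external BLAST run can
  legitimately differ on real data.
* The ramp/step model choice is threshold-based, not inferential; for
  borderline gradual boundaries report both fits.
* `enumerate_copies` assumes the monomer is a faithful representative;
  no consensus polishing or higher-order-repeat inference is attempted.
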