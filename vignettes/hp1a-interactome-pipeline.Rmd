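---
title: "Methods: motif scanning, peak co-localization and border calling in hp1tools"
author: "hp1tools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif scanning, peak co-localization and border calling in hp1tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hp1tools)
```

hp1tools implements three analyses used to characterize the interactome
of Drosophila heterochromatin protein 1a (HP1a): scanning candidate
interactor proteins for chromoshadow-domain (CSD) binding pentapeptides,
testing whether two ChIP-seq peak sets co-localize more (or less) than
chance, and locating the heterochromatin–euchromatin "epigenomic
border" on a chromosome arm from binned peak summit heights. This
vignette is the package's account of each method: the model, the
parameters that matter, the numerical conventions, and what the
synthetic-data generators do and do not emulate.

## 1. Pentapeptide motif scanning

HP1 proteins dimerize through their C-terminal chromoshadow domain, and
the CSD dimer interface binds partner proteins carrying the pentapeptide
**PxVxL** (P, any residue, V, any residue, L). Degenerate variants that
keep the V and L anchors but change the first anchor — **LxVxL** and
**CxVxL** — also bind. `scan_protein()` tests every length-5 window of a
sequence against each requested class.

Conventions, and why:

* **Wildcards exclude ambiguity codes.** Positions 2 and 4 accept any of
  the 20 standard residues, never X, B, Z or U, and anchors accept only
  the literal residue (B is not treated as "D or N"). An unknown residue
  is not evidence of a motif; counting it would inflate hit rates.
* **All matches are reported**, including overlapping windows and
  multiple motifs per protein — proteins carrying several candidate
  binding sites are biologically meaningful (alternative or simultaneous
  partners), so deduplication is left to the caller. No window can match
  two classes at once because the position-1 anchors (P, L, C) are
  distinct; a test asserts this.
* **Flanks.** The residues at the −1 and +1 positions around the
  pentapeptide modulate binding affinity, so each hit records them
  (`"-"` at a sequence edge).
* **Cohort percentages** (`summarize_cohort()`) count a protein once
  regardless of hit multiplicity and round to the nearest integer with
  ties away from zero — the convention under which 9 of 13 is 69% and
  30 of 86 is 35%.

Scanning is implemented with zero-width lookahead regular expressions
(so overlapping matches are all found); the test suite checks it for
exact equality against an independently written window-by-window
enumeration oracle on 1,000 random 500-residue sequences.

## 2. Peak co-localization with a randomization null

For a query peak set $Q$ and reference set $R$ on a shared genome, the
observed statistic is the number (and percentage) of query peaks with at
least 1 bp of intersection with any reference peak:

$$ X_{\mathrm{obs}} = \#\{\, q \in Q : \exists r \in R,\; |q \cap r| \ge 1 \,\}, \qquad
   \mathrm{pct} = 100\, X_{\mathrm{obs}} / |Q|. $$

A query peak counts once however many reference peaks it touches, and
intervals that merely abut (half-open adjacency in BED coordinates) do
not overlap. The ≥1 bp criterion is the weakest standard overlap
definition; `min_overlap` generalizes it.

**The null.** `permutation_test()` holds $Q$ fixed and randomizes $R$
$B$ times. Each reference peak keeps its chromosome and its length and
receives a new start drawn uniformly from the integer positions at which
it still fits; placements are independent and may overlap each other.
Keeping peaks on their own chromosome preserves per-chromosome peak
density, which differs systematically between chromosome arms. The null
statistic $X_1, \dots, X_B$ is the overlap count recomputed against each
randomized reference.

**Inference.** With $b$ the number of null draws at least as extreme as
$X_{\mathrm{obs}}$ under the chosen alternative,

$$ p = \frac{1 + b}{B + 1}, \qquad
   z = \frac{X_{\mathrm{obs}} - \bar X_{\mathrm{null}}}{s_{\mathrm{null}}}. $$

The add-one estimator means $p$ can never be exactly 0; when the null is
degenerate ($s_{\mathrm{null}} = 0$, e.g. a reference tiling the whole
genome) the z-score is flagged undefined while $p$ is still computed
from counts. The default alternative is two-sided (extremeness
$|X - \bar X_{\mathrm{null}}| \ge |X_{\mathrm{obs}} - \bar X_{\mathrm{null}}|$)
because both enrichment ($z > 0$) and depletion ($z < 0$, peaks
avoiding each other) occur in practice and are reported with this sign
convention. Defaults: `n_perm = 1000`; the seed is mandatory in reports
so every p-value is reproducible.

Direction matters: "42% of HP1a peaks co-localize with partner X" and
"42% of X peaks co-localize with HP1a" are different statistics when the
sets differ in size. The API makes query and reference explicit; swap
the arguments to get the other direction.

Two deliberate simplifications: no masking of assembly gaps or blacklist
regions (users of real genomes should pre-filter peaks; this keeps the
null exactly as stated and exactly testable), and no multiple-testing
correction across partners (raw p-values are reported; correct outside
if screening many partners).

**Implementation note.** The exported `overlap_stat()` uses
`GenomicRanges::countOverlaps()`. Inside the permutation loop the same
count is computed by a sorted-vector kernel (a query $[s,e)$ overlaps
some reference iff the number of reference starts $< e$ exceeds the
number of reference ends $\le s$), which avoids per-iteration GRanges
overhead. Tests assert that the kernel, `countOverlaps()`, and a
quadratic all-pairs oracle agree, and that the Monte-Carlo null mean
matches exhaustive placement enumeration on a small chromosome.

## 3. Epigenomic border calling

Pericentric heterochromatin carries dense, high HP1a ChIP-seq signal;
euchromatin does not. The border is called from peak **summit heights**
(signalValue at the summit position, in arbitrary units of the processed
track — typically log2 enrichment, treated as opaque):

1. `global_median_height()` — the median summit height over the whole
   peak set (even counts: mean of the two central values). This is the
   genome-wide reference level.
2. `bin_profile()` — fixed-width bins (default 0.5 Mb) laid from an
   origin (the centromere-proximal end of the arm) toward the telomere,
   in either coordinate direction. Summits, not whole intervals, are
   binned; formats without summits get midpoint imputation. Bins are
   half-open in scan order: a summit exactly on a boundary belongs to
   the higher-index (origin-distal) bin. Each bin records its peak count
   and median height; **empty bins get median 0** — a stretch with no
   peaks cannot be heterochromatin under this statistic, and 0 keeps the
   scan well-defined.
3. `call_border()` — scanning outward from the origin, the border is the
   **first bin whose median falls strictly below** the global median; a
   bin exactly at the median does not trigger ("decays below" is
   strict). If no bin qualifies the border is absent. `min_run` can
   require the drop to persist over several consecutive bins, but
   defaults to 1 (a single-threshold crossing, no smoothing).

The reported coordinate is the origin-proximal boundary of that bin (the
last coordinate known to be heterochromatin-adjacent); `report =
"end"`/`"midpoint"` give the symmetric choices, and reports carry both
bp and Mb (one decimal) — the granularity at which such borders are
usually quoted (e.g. 7.3 vs 7.4 Mb on Drosophila 2R between studies).
Origin and direction are explicit per-arm inputs because centromere
coordinates are assembly-specific and out of scope here.

`consensus_border()` compares calls from several tracks (e.g. HP1a,
Su(var)3-9, H3K9me3): agreement requires every pairwise distance within
a tolerance (default one bin) and every call present; the consensus
coordinate is the median of the positions.

**A degenerate case worth knowing.** On a synthetic two-level landscape
the genome-wide median equals the euchromatic level itself, so the
strict drop can never fire against a threshold computed from the same
single arm. In real data the genome-wide median (0.9 a.u. in the
motivating analysis) sits between the heterochromatic and euchromatic
arm medians because it pools all chromosomes and a broad height
distribution. The recovery tests therefore pass a threshold lying
between the two planted levels to `call_border()`, which is exactly how
the statistic is used in practice (threshold from the genome, profile
from one arm).

## 4. What the synthetic generators emulate

All three generators take an explicit seed, draw from a single private
RNG stream (the global RNG state is untouched), and emit their planted
truth, so expected pipeline outputs are exactly predictable.

* `generate_proteome()` — background residues uniform over the 20
  standard amino acids; planted motifs have fixed anchors and uniform
  wildcards. Whole proteins are **rejection-resampled until a full scan
  finds exactly the planted hits**, so incidental motifs (including
  windows straddling a planted motif's flanks) are excluded by
  construction and scanner tests are equality assertions, not
  probabilistic ones. With three classes the incidental-match rate is
  about $3 \times 20^{-3}$ per window, so acceptance probability per
  500-residue protein is roughly 0.8 and resampling is cheap. Protein
  lengths are Poisson around `length_mean` (default 500 residues, a
  typical protein scale). Not emulated: real amino-acid composition,
  domain structure, homology.
* `generate_peak_pair()` — reference peaks uniform over the genome
  (chromosome proportional to length); with overlap fraction $f$,
  exactly $\mathrm{round}(f \cdot n_{\mathrm{query}})$ query peaks are
  forced to intersect a uniformly chosen reference peak by ≥1 bp and the
  rest are rejection-placed to touch none, so the planted overlap count
  is exact, not expected. `overlap_frac = NULL` places the query
  independently — the configuration used to check type-I error
  calibration. Peak lengths are normal around `length_mean` (default
  300 bp, a typical ChIP-seq peak width; 15% CV, floored at 20 bp).
  Not emulated: chromatin-driven peak clustering, mappability, GC bias.
* `generate_landscape()` — a chromosome arm (default 25 Mb, about the
  size of arm 2R) with Poisson peak counts per 0.5-Mb bin (default mean
  20), summits uniform within bins, and heights normal with mean 3.0
  a.u. before the planted border (default 7.5 Mb) and 0.4 a.u. after,
  sd 0.3, truncated at a small positive floor. The step structure and
  levels mirror the observed decay of per-bin medians from ~3 a.u. in
  pericentric heterochromatin to ~0.4–0.5 a.u. in euchromatin. Not
  emulated: the gradual 1–2 bin shoulder sometimes seen at real borders,
  interspersed heterochromatin islands, coverage gaps.

Because the generators are idealized, passing tests demonstrate that the
implementations are correct under the stated models — uniform null,
independent placements, step-shaped borders — not that real tracks meet
those assumptions. On real data the same code applies but the null's
biological adequacy (e.g. unmasked assembly gaps) is the user's call.

## 5. Problem sizes and numerical choices in the checks

The package's property checks use sizes chosen to make the statistics
well-resolved while keeping a full run fast on one CPU: 1,000 random
500-residue proteins for oracle equivalence; 200 query / 200 reference
peaks for overlap exactness; 10,000 permutations against exhaustive
placement enumeration on a 1-kb toy chromosome; 200 independent null
peak pairs at 500 permutations each for calibration (the empirical
fraction of $p < 0.05$ is compared to the exact binomial 99% interval
around 0.05); and 100 seeded replicates of the noisy landscape
(recovery within one 0.5-Mb bin required in at least 95). The
calibration genome (two 400-kb chromosomes, 200 × 300-bp peaks per
side) is deliberately dense so that null overlap counts are far from
the zero-inflated regime, where the discreteness of a count statistic
would make any two-sided p-value coarse.

Internally, peak sets are `GRanges` (1-based, closed — the Bioconductor
convention) tied to a `Seqinfo` genome; all BED-family files keep their
native 0-based half-open convention and are converted exactly at the
I/O boundary. Reports are written as plain TSV or as a structured
variant with a `#%`-prefixed provenance block (inputs, parameters,
seed, tool version) above the identical rows.

## 6. Known limitations

* The motif model is presence/absence; no position-weight or affinity
  scoring, and no variants beyond PxVxL/LxVxL/CxVxL.
* The co-localization statistic is peak-level; base-pair-level measures
  (Jaccard) and distance-to-nearest tests are out of scope.
* The randomization does not mask gaps or blacklists, and reassignment
  across chromosomes is deliberately not offered.
* Border calling finds a single transition per scan; interspersed
  domains need segmentation methods (HMM/changepoint) that this
  statistic does not attempt.
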