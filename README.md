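# hp1tools

Reusable implementations of three computational analyses around the
Drosophila heterochromatin protein 1a (HP1a) interactome, for
epigenomics researchers working with protein sequences and ChIP-seq
peak calls:

1. **Motif scanning** — locate the chromoshadow-domain (CSD) binding
   pentapeptide **PxVxL** (P-any-V-any-L) and its degenerate variants
   **LxVxL** and **CxVxL** in protein sequences, with the −1/+1
   flanking residues, and summarize motif prevalence over cohorts of
   candidate interactors.
2. **Peak co-localization** — the percentage of query ChIP-seq peaks
   intersecting a reference peak set, with significance from a
   chromosome-aware randomization null: each reference peak keeps its
   chromosome and length and is replaced uniformly at random, giving an
   empirical p-value `p = (1 + b) / (n_perm + 1)` and z-score
   `z = (X_obs − mean(X_null)) / sd(X_null)` (z > 0 enrichment, z < 0
   depletion).
3. **Epigenomic border calling** — the heterochromatin–euchromatin
   transition on a chromosome arm, called by binning peak summit
   heights every 0.5 Mb from the centromere-proximal origin and marking
   the first bin whose median height decays strictly below the
   genome-wide median, with multi-track consensus (e.g. HP1a alongside
   Su(var)3-9 and H3K9me3).

Seeded synthetic-data generators (proteomes with planted motifs, peak
pairs with an exact planted overlap fraction, stepped peak-height
landscapes with a known border) emit their ground truth alongside, so
the whole pipeline is testable without external downloads.

Peak sets are `GenomicRanges::GRanges` objects tied to a
`GenomeInfoDb::Seqinfo` genome; proteins are `Biostrings::AAStringSet`
objects. Supported formats: FASTA, BED3/BED6, ENCODE narrowPeak,
chrom.sizes, TSV reports (plain or with a provenance header).

## Worked example

```r
library(hp1tools)

## 1. motif scanning -----------------------------------------------------
scan_protein("PAVALAVAL", id = "demo")
#>   protein_id motif_class start pentapeptide flank_minus1 flank_plus1
#> 1       demo       PxVxL     1        PAVAL            -           A
#> 2       demo       LxVxL     5        LAVAL            A           -
```

Two overlapping hits — a canonical PxVxL at residue 1 and a degenerate
LxVxL at residue 5 — both reported, with their flanking residues.

```r
## 2. co-localization ----------------------------------------------------
pp <- generate_peak_pair(synthetic_genome(), n_query = 200, n_ref = 200,
                         overlap_frac = 0.4, seed = 3)
permutation_test(pp$query, pp$ref, n_perm = 199, seed = 5)
#> permutation_result: 80/200 query peaks co-localize (40.0%)
#>   null 1.26 +/- 1.04 over 199 permutations (seed 5)
#>   z = 75.665, empirical p = 0.005 (two-sided)
```

The generator planted 40% overlap (exactly 80 of 200 query peaks);
under the randomization null barely more than one query peak overlaps
by chance, so the enrichment is overwhelming: p is at its floor of
1/(199+1) and z is large and positive.

```r
## 3. border calling -----------------------------------------------------
lsc <- generate_landscape(seed = 11)   # planted border at 7.5 Mb
prof <- bin_profile(lsc$peaks, "chr2R", origin = 0)
call_border(prof, global_median = 0.9)
#> border_call on chr2R (increasing from origin 0, 0.5-Mb bins):
#>   border at 7,500,000 bp (7.5 Mb); global median 0.9 a.u.
```

Binned medians sit near 3 a.u. through the simulated pericentric block
and fall to ~0.4 a.u. beyond it; the first bin strictly below the
0.9 a.u. reference level starts at 7.5 Mb — the planted border,
recovered exactly.

## Command line

A single executable wraps the same functions:

```sh
HP1TOOLS=$(Rscript -e 'cat(file.path(find.package("hp1tools"), "exec", "hp1tools"))')
Rscript $HP1TOOLS simulate landscape --seed 4 --out-prefix lsc
Rscript $HP1TOOLS call-border --peaks lsc.narrowPeak --genome lsc.chrom.sizes \
    --chrom chr2R --origin 0 --global-median 0.9 --out border.tsv
Rscript $HP1TOOLS colocalize --query-bed q.narrowPeak --ref-bed r.narrowPeak \
    --genome genome.chrom.sizes --n-perm 1000 --seed 7 --out coloc.tsv
Rscript $HP1TOOLS scan-motifs --fasta proteins.fa --out hits.tsv
```

All subcommands are byte-reproducible under a fixed `--seed`.

## Documentation

`vignettes/hp1a-interactome-pipeline.Rmd` describes the statistical
models, parameter defaults and their units, the conventions (strict
threshold crossing, half-open bins, add-one p-values, ambiguity-code
handling), what the synthetic generators do and do not emulate, and
known limitations.
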