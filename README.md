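# allokit

Curation toolkit for haplotype-resolved allotetraploid genome
assemblies.

Phased assemblies of allopolyploids keep every haplotype as a separate
sequence — for an allotetraploid, two subgenomes × two haplotypes.
That creates computational problems that collapsed-assembly pipelines
never face, and `allokit` implements the bespoke stages around them:

* **Allelic-unitig detection** — unitigs sharing the same single-copy
  protein marker (BUSCO-style orthologs, one expected hit per
  haplotype) are recorded as allelic; the marker copy-number histogram
  diagnoses phasing completeness (mode at 4 for a clean phased
  tetraploid).
* **Hi-C link pruning** — read pairs are dropped if either mate is
  secondary/supplementary (SAM flag mask 2304 = 256 + 2048), if
  `min(MAPQ) < 30`, or if the pair links two allelic unitigs. Without
  the third filter, allelic mis-mapped contacts drive the scaffolder
  into inter-haplotype misjoins.
* **Contact accounting** — unitig-level contact matrices, the
  inter-allelic contact fraction (exactly 0 after pruning when the
  marker set covers all allelic relations), and a deterministic
  average-linkage grouping used to score the pruning effect against
  truth with an adjusted Rand index.
* **Subgenome ancestry by coverage** — windowed read depth of
  candidate-progenitor alignments, per-source normalization,
  median-depth assignment with a margin threshold (indistinguishable
  progenitors are reported as a combined `"a+b"` label, not an error),
  and run-length switch detection that flags homoeologous exchanges
  and translocations as coverage-switch segments.
* **K-mer signatures** — canonical-k-mer sketches (optionally
  `scaled`-subsampled), pairwise similarity as presence/absence
  Jaccard ("composition") or abundance-weighted cosine ("frequency"),
  average-linkage dendrograms, and the **strict cut** validity check:
  a subgenome partition is correct iff no subgenome's chromosomes are
  split across clusters.
* **Curation tracks** — telomere-motif density (`TTTAGGG` and its
  reverse complement, both strands, overlapping matches counted) and
  maximal N-run gap intervals (length ≥ 10 bp by default), emitted as
  bedGraph/BED3.
* **Synthetic allotetraploid simulator** — generates genome, unitigs,
  marker hits, Hi-C pairs (with a planted allelic mis-link fraction),
  progenitor alignments, one planted homoeologous exchange and one
  terminal translocation, plus a complete truth set, so the whole
  pipeline is testable offline.

Formats: FASTA, PAF, 12-column tabular protein hits, name-sorted SAM
text or a 7-column pairs table for Hi-C, bedGraph/BED3 out. All
internal coordinates are 0-based half-open.

## Worked example

Simulate the default allotetraploid scenario (2 subgenomes × 2
haplotypes × 2 chromosomes of 500 kb, 10% inter-subgenome divergence,
1% heterozygosity, 200 single-copy markers, 50,000 Hi-C pairs of which
10% are allelic mis-links), build the allelic table, and prune:

```r
library(allokit)

cfg <- sim_config(seed = 1, planted_exchange = FALSE,
                  planted_translocation = FALSE)
sim <- simulate_allotetraploid(cfg)

hits <- best_hit_per_marker_unitig(sim$marker_hits)
tab  <- build_allelic_table(hits, ploidy = 4, min_identity = 75)
tab
#> Allelic-unitig table
#>   markers:        200
#>   allelic pairs:  325
#>   flagged (> ploidy 4): 0
copy_number_histogram(tab)
#>   copies n_markers
#> 1      4       200

res <- prune_pipeline(sim$hic_pairs, tab, mask = 2304, min_mapq = 30)
res$report
#> Hi-C prune report
#>   input pairs:      50000
#>   flag-removed:     0
#>   MAPQ-removed:     2000
#>   allelic-removed:  2952
#>   output pairs:     45048
```

Every marker is found exactly four times — once per haplotype — so the
histogram mode sits at the ploidy. The MAPQ filter catches the
mis-links that lost mapping quality; the allelic filter removes the
rest. The share of inter-unitig contact mass on allelic unitig pairs
confirms the cleanup:

```r
lens <- setNames(sim$truth$unitigs$end - sim$truth$unitigs$start,
                 sim$truth$unitigs$unitig_id)
inter_allelic_fraction(build_contact_matrix(sim$hic_pairs, lens), tab)
#> [1] 0.09904     # the planted 10% mis-link rate
inter_allelic_fraction(build_contact_matrix(res$pairs, lens), tab)
#> [1] 0           # nothing allelic survives pruning
```

Downstream, `assign_subgenomes()` / `detect_switches()` call subgenome
ancestry from progenitor read depth and flag the planted
rearrangements, and `sketch_set()` / `cluster_signatures()` /
`strict_cut_check()` reproduce the signature result that
abundance-weighted (frequency) k-mer clustering separates subgenomes
while presence/absence (composition) clustering pairs homologous
chromosomes instead. `run_synthetic_pipeline(run_config(seed = 1))`
chains all stages and writes a JSON report; the same stages are
scriptable from a shell via `exec/allokit` (subcommands `synth`,
`allelic-table`, `hic-prune`, `contact`, `ancestry`, `kmersig`,
`tracks`, `run-all`).

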