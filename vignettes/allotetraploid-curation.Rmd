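---
title: "Methods: Hi-C allelic pruning, subgenome ancestry, and k-mer signatures for phased allotetraploid assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hi-C allelic pruning, subgenome ancestry, and k-mer signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokit)
```

## The problem

A phased assembly of an allotetraploid keeps all four haplotypes (two
subgenomes × two haplotypes) as separate sequences. This creates two
bespoke computational problems that standard assembly pipelines do not
solve:

1. **Hi-C scaffolding is confused by allelic contacts.** A fraction of
   proximity-ligation read pairs mis-map between near-identical
   haplotypes. To a scaffolder these look like genuine long-range links
   between *allelic* unitigs — unitigs that represent the same locus on
   different haplotypes — and cause misjoins that collapse or shuffle
   haplotypes. The remedy is to detect allelic unitigs and remove the
   Hi-C pairs linking them before scaffolding.
2. **Subgenome identity is not written in the assembly.** Which
   chromosome came from which progenitor species must be inferred after
   the fact, here by two independent signals: windowed depth of
   candidate-progenitor reads aligned to the assembly, and genome-wide
   k-mer signatures.

`allokit` implements both, plus the curation tracks (telomere motif
density, N-gap intervals) used when inspecting a contact map by hand,
and a synthetic allotetraploid simulator so each stage can be tested
end to end without any external data.

## Allelic-unitig detection and Hi-C pruning

Single-copy protein markers (BUSCO-style orthologs, expected once per
haploid genome) are aligned to the unitigs; in a clean phased
tetraploid each marker hits four unitigs, one per haplotype. All
unitigs sharing a marker are recorded as allelic, and every unordered
pair within a marker's unitig set becomes an *allelic pair*.

Design choices, and why:

* **Markers hitting more unitigs than the ploidy are flagged and
  contribute no pairs.** Super-numerary hits indicate repeats or
  collapsed paralogy; pruning on them would remove genuine long-range
  links. The copy-number histogram (`copy_number_histogram()`) makes
  this visible: its mode sits at the ploidy when phasing worked.
* **A minimum percent identity of 75 (default) is applied to hits.**
  The threshold must tolerate cross-haplotype and cross-subgenome
  divergence (a marker's copies on the other subgenome can be ~10%
  diverged at the nucleotide level, much less at the protein level)
  while rejecting paralogous hits. It is exposed in the configuration.
* **Only direct pairwise co-occurrence counts; transitive closure is
  not taken.** Pruning acts on pairs of unitigs, so chaining markers
  into larger groups would only widen the removal set without evidence.

The pruning pipeline applies three pair-level filters in a fixed order,
attributing each removed pair to the first failing filter:

1. *flags*: drop a pair if either mate has any bit of the SAM mask 2304
   set (256 = secondary + 2048 = supplementary);
2. *MAPQ*: drop if `min(mapq1, mapq2) < 30`;
3. *allelic*: drop inter-unitig pairs whose unordered unitig pair is in
   the allelic table.

Removal is always pair-level (a half-pair is useless for scaffolding).
Pairs naming unitigs outside the assembly namespace are kept and
tallied rather than dropped — failing open avoids silently discarding
signal on namespace mismatches. The counters satisfy
`n_input = n_flag + n_mapq + n_allelic + n_output` on every input, and
pruning is idempotent.

The MAPQ stage is kept an explicit, optional filter (`min_mapq = 30`
default) even though scaffolders often apply their own threshold: an
explicit stage makes the removal accountable in the report.

## Quantifying the pruning effect

`build_contact_matrix()` aggregates pairs into a symmetric unitig-level
count matrix (diagonal = intra-unitig pairs).
`inter_allelic_fraction()` is the share of inter-unitig contact mass
that sits on allelic pairs: on a stream whose allelic relations are
fully covered by markers it drops to exactly zero after pruning.

`group_unitigs()` is a deliberately transparent proxy for scaffolder
behaviour, *not* a scaffolder: deterministic average-linkage
agglomerative clustering on the length-normalized similarity
`counts[i,j] / (len_i × len_j)` (standard Hi-C practice, preventing
long unitigs from dominating), cut at a chosen group count. Unitig ids
are sorted lexicographically before clustering so equal-similarity ties
break identically on every platform. Agreement with the true
chromosome of origin is scored with a pair-counting index
(`pair_agreement()`, the adjusted Rand index).

A caveat worth stating plainly: global average linkage at a known group
count is *more* robust to allelic mis-links than a real scaffolder's
greedy local joining. On simulated data the unpruned matrix is
sometimes grouped perfectly anyway; the improvement from pruning is
therefore assessed across replicate simulations, where the mean
agreement rises strictly after pruning. The test suite encodes exactly
this aggregate comparison.

## Coverage-based subgenome ancestry

Reads from candidate progenitor species are aligned to the assembly;
`windowed_depth()` computes mean per-base depth in uniform windows
(default 100 kb for chromosome-scale assemblies; the bundled synthetic
scenario uses 10 kb windows because its chromosomes are 0.5 Mb — both
are configuration values, and the window should be chosen so that the
smallest rearrangement of interest spans at least `min_segment`
windows).

**Normalization.** Each source's depths are divided by a per-source
constant so on-target windows sit near 1. The constant is the median
of the nonzero windows at or above that source's mean nonzero depth.
The obvious alternative — the plain median of nonzero windows — fails
in exactly the situation this package targets: with two balanced
subgenomes roughly half of a progenitor's windows are on-target (high
mode) and half off-target (low mode), so the plain median falls
unstably between the two modes and can swing the normalization
constant by the on/off depth ratio from replicate to replicate. Taking
the median of the at-or-above-mean windows locks onto the upper
(on-target) mode; for a uniform-depth source the two statistics
coincide. Assignment is scale-invariant either way.

**Assignment.** Per chromosome, sources are ranked by *median*
normalized depth (median, not mean — robust to repeat-driven pileups).
The best source is called when it exceeds the runner-up by the margin
threshold (default 2.0). Sources mutually within the margin but
jointly above the rest are reported as a combined `"a+b"` label: two
closely related diploid candidates can be genuinely indistinguishable
by coverage, and that either/or outcome is a first-class result, not
an error. When all sources are within the margin the call is
`"ambiguous"`.

**Switch detection.** Per window the dominant source is the argmax of
normalized depth (ties to the lexicographically first source); runs of
identical dominance shorter than `min_segment` windows (default 10)
are merged into the longer flanking run, and the remaining runs become
segments tiling the chromosome. A chromosome with more than one
distinct dominant source is a candidate rearrangement. Run-length
smoothing was chosen over a formal changepoint model because the
detection it replaces was visual; it is transparent, has one
parameter, and is easy to test. No quantitative rule separates a
homoeologous exchange from a translocation — both are emitted as
switch segments and interpretation is left to the caller. When two
sources form a combined label genome-wide, their tracks should be
summed (`combine_tracks()`) before switch detection, otherwise the
argmax alternates randomly between the two indistinguishable sources.

## K-mer signatures and the strict cut

`sketch()` collects canonical k-mers (lexicographic minimum of k-mer
and reverse complement; windows containing non-ACGT symbols skipped),
hashed with 64-bit FNV-1a under fixed constants so sketches reproduce
across runs and platforms. The top 53 bits of the hash are the sketch
value (exactly representable as an R double); with `scaled = s` only
hashes below `2^53 / s` are retained, a minhash-style subsample that
is a strict subset of the full sketch.

Two similarity modes mirror the with/without-abundance distinction of
minhash signature tooling:

* **composition** — presence/absence Jaccard `|A∩B| / |A∪B|`, defined
  as 0 when both sets are empty;
* **frequency** — cosine similarity of the abundance vectors over the
  union of k-mers.

Chromosomes are clustered by average linkage on `1 − similarity`
(leaves sorted lexicographically for deterministic ties). The **strict
cut** criterion then cuts the dendrogram into as many clusters as
there are subgenomes and passes if and only if no subgenome's
chromosomes are split across clusters; a cluster may contain several
whole subgenomes, but one split subgenome fails the check and the
offending chromosomes are reported.

The reporting grid of k-mer sizes used by default in tests is
`{21, 51, 81}`; the full published ladder (3–21 by 2, 21–161 by 10) is
available via `kmer_ladder()`.

## The synthetic allotetraploid

The simulator (`sim_config()` / `simulate_allotetraploid()`) is
first-class, tested code. Defaults define the standard scenario used
throughout the suite:

| parameter | default | meaning |
|---|---|---|
| `n_chromosomes_per_haplotype` | 2 | base chromosomes |
| `chromosome_length` | 500 kb | per base chromosome |
| `subgenome_divergence` | 0.10 | substitutions, ancestor → subgenome B |
| `haplotype_heterozygosity` | 0.01 | substitutions, backbone → haplotype 2 |
| `n_markers` | 200 | single-copy loci |
| `n_hic_pairs` | 50,000 | Hi-C pairs |
| `allelic_mislink_rate` | 0.10 | mis-mapped pair fraction |
| `contact_decay_exponent` | 1.0 | cis contact power law |
| `progenitor_depth` | 20× | on-target read depth |
| `offtarget_depth_ratio` | 0.1 | off-target/on-target depth |
| `mean_unitig` / `min_unitig` | 25 kb / 5 kb | fragmentation |

Structure and the reasoning behind the non-obvious choices:

* **Haplotype derivation.** Haplotype 1 *is* the subgenome backbone;
  haplotype 2 is the backbone mutated at the heterozygosity rate. The
  haplotype pair then differs at exactly the configured rate and the
  h1–h1 inter-subgenome Hamming distance equals the configured
  divergence — symmetric per-haplotype mutation would instead give
  divergence-plus-heterozygosity between subgenomes. Substitutions
  only, no indels: homologous coordinates are shared exactly across
  haplotypes, which makes mis-link placement and event planting exact
  bookkeeping rather than an alignment problem.
* **Dispersed repeats carry the subgenome signal for frequency-mode
  clustering.** Sixteen shared repeat families (400 bp) are inserted
  as exact copies genome-wide, but each family is amplified in one
  subgenome (10 vs 2 copies per chromosome); one low-copy
  chromosome-specific family (6 copies) is shared by all four copies
  of its base chromosome. This mirrors the real phenomenon: in a
  recent allopolyploid the *presence* of repeat families is shared,
  while their *abundance* profile tracks subgenome ancestry (as
  LTR-density patterns do in real assemblies). Without a repeat
  component, two random 500 kb chromosomes share essentially no
  81-mers and neither similarity mode could recover subgenomes at
  all. Composition-mode Jaccard is dominated by the single-copy
  fraction, so it pairs homologous haplotypes and then groups
  chromosome copies across subgenomes (via the chromosome-specific
  family) — reproducing the failure mode in which homologous pairs
  cluster but subgenomes do not.
* **Mis-links are anchored at single-copy marker loci**: both ends of
  a mis-mapped pair sit at the same marker locus on the two sister
  haplotypes of one subgenome. Mis-mapping concentrates where
  haplotypes are locally near-identical — which is exactly where
  conserved single-copy loci sit — and this guarantees that every
  planted mis-link joins a marker-covered allelic unitig pair, so the
  pruning stage can be scored exactly against the truth set. MAPQ for
  mis-links is a mixture (60 with probability 0.6, else uniform 0–29),
  reflecting that mis-mapped reads often, but not always, lose mapping
  quality.
* **Cis pairs are redrawn until they join two different unitigs.**
  Intra-unitig contacts carry no scaffolding information; emitting
  only inter-unitig contacts makes the expected inter-allelic fraction
  of the raw stream equal the configured mis-link rate, which is the
  property the contact module is tested against. Real pair streams of
  course contain intra-unitig pairs; the contact-matrix diagonal is
  exercised by hand-built fixtures instead.
* **Planted events.** The homoeologous exchange replaces the internal
  35–65% interval of one B-subgenome haplotype chromosome with the
  homoeologous A interval; the terminal translocation moves the first
  20% of one B chromosome onto the end of an A chromosome (donor
  shrinks, receiver grows). Progenitor alignments follow the *true*
  local ancestry of every interval, so both events are visible as
  coverage switches.
* **Fragmentation.** Unitig breakpoints are uniform; fragments under
  `min_unitig` merge into a neighbour, since assemblers do not emit
  tiny unitigs and zero-contact fragments would add noise. The mean
  unitig length of 25 kb keeps the unitig:chromosome length ratio
  (~1:20) near what phased assemblies show at full scale.

Every generator stage derives its own sub-seed from the master seed,
so each stage is individually reproducible and byte-identical across
reruns.

**What the simulator does not emulate** — and hence what passing tests
do not show about real data: read errors and indels; restriction-site
or ligation biases in Hi-C; collapsed or chimeric unitigs; repeat
landscapes with nested or diverged copies; intra-unitig contact mass;
more than two candidate progenitors per subgenome; assembly gaps
(curation-track code is tested on explicit fixtures instead).

## Numerical and interface conventions

* All internal coordinates are 0-based half-open; SAM's 1-based
  positions are converted at the reader boundary. Strand is ignored
  throughout (pruning and coverage logic are strand-agnostic).
* Hi-C pairs are accepted either as a name-sorted SAM text stream with
  exactly two records per read name, or as a dependency-free 7-column
  pairs table (which carries no flag field — flags read as 0).
* Degenerate inputs have defined results: empty pair streams produce
  zeroed reports; an all-`N` sequence yields an empty sketch with a
  warning; similarity of two empty sketches is 0; the inter-allelic
  fraction of a matrix with no inter-unitig mass is 0.
* bedGraph output never merges equal-valued adjacent windows, so the
  window grid round-trips bit-exactly.
* Problem sizes in the test-suite: 0.5 Mb chromosomes (4.2 Mb genome),
  50,000 Hi-C pairs, 200 markers, 10 kb ancestry windows, k = 81
  signatures on eight chromosomes, with replicate counts of 2–10
  depending on the check.

## Known limitations

* The allelic table is only as complete as the marker set: allelic
  unitig pairs in marker deserts are invisible to pruning.
* The contact grouping is a validation proxy; it says nothing about
  the ordering/orientation steps of a real scaffolder.
* Coverage ancestry cannot separate progenitors closer to each other
  than the margin threshold — by design it reports them as a combined
  label rather than guessing.
* The strict-cut outcome on real genomes depends on repeat content and
  k; the simulator demonstrates the mechanism, not the exact k range
  where real assemblies switch from failing to passing.
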