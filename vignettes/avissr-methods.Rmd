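---
title: "Methods: microsatellite mining, summary statistics and phylogenetic PCA in avissr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite mining, summary statistics and phylogenetic PCA in avissr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`avissr` characterizes microsatellites (SSRs, tandem repeats of 1–6 bp
motifs) genome-wide and compares repeat motif preferences across species
while accounting for their shared evolutionary history. This vignette is
the package's account of its methods: the detection model, the statistics,
the phylogenetic PCA, the synthetic-data generator that backs the test
suite, and the design decisions taken where conventions genuinely diverge.

## 1. Detection model

### Perfect SSRs

A perfect SSR (P-SSR) is a maximal uninterrupted tandem run of a
*primitive* motif — one that is not itself a repetition of a shorter unit —
whose repeat copy number (RCN) reaches the class threshold. The default
thresholds, 12, 7, 5, 4, 4 and 4 copies for mono- through hexanucleotide
motifs, are the detection standard used by genome surveys in birds and
other vertebrates; they are exposed in `detector_params()` and every test
treats them as behavioral boundaries (a run one copy short must yield
nothing).

The scanner (C++, single left-to-right pass) examines periods 1–6 at each
position, extends the maximal run for each period, and accepts the
*shortest primitive period* that meets its threshold; scanning resumes at
the end of an accepted locus. Consequences, all tested:

* a run of `ACACAC…` is a dinucleotide locus, never tetra (`ACAC` is not
  primitive);
* overlapping candidate runs resolve leftmost-first, and no base belongs
  to two perfect loci;
* a partial trailing copy is not counted: `length_bp == repeats ×
  motif_len` exactly, and the locus sequence is an exact tiling of its
  motif;
* runs never span `N`; any character outside `A,C,G,T,N` is an error
  naming its position.

The reference the scanner is tested against is a brute-force oracle built
on PCRE backreferences (`([ACGT]{p})\1{k-1,}` per period, with the same
shortest-period/leftmost resolution applied to the candidates and the
suffix after each accepted locus rescanned). The two routes share the
specification but no code.

### Imperfect SSRs

Genome surveys consistently find interrupted repeats (I-SSRs) to be the
most abundant SSR class, but there is no published algorithmic standard
for desk-scale re-implementation; `avissr` therefore adopts a
conventional, fully parameterized seed-and-extend scheme and documents it
as such. A *seed* is a perfect run with ≥ `seed_min_repeats` (3) copies
and ≥ `seed_min_length` (8) bases. Extension proceeds outward base by
base: +1 per match, −`mismatch_penalty` (1) per substitution,
−`gap_penalty` (2) per indel base, with a one-base lookahead classifying
each interruption as substitution, insertion or deletion. Extension stops
when more than `max_consecutive_edits` (3) edited positions occur in a
row, and a locus is reported when its score reaches `min_score` (10) and
it carries at least one edit — zero-edit runs belong to the perfect
detector.

Two termination rules keep extension honest, and both are design choices
of this package:

* **Terminal-segment rule.** An edit is committed into the locus only
  when a tandem segment of at least `seed_min_length` matching bases
  follows it. An interruption is evidence of an imperfect array only if
  the array demonstrably continues beyond it; without this rule, the
  flanks of any perfect locus would be annexed one chance match at a
  time.
* **X-drop.** Extension terminates when the running score falls
  `xdrop` (10) below the best committed score, the standard guard in
  seed-and-extend alignment against wandering through unrelated sequence
  toward a distant chance match.

So `A₈CA₈` is one 17 bp imperfect locus (score 8+8−1 = 15, one edit),
while `A₈CA₇` is nothing: the post-edit segment is one base short of
re-establishing the array. Exact agreement with any particular published
tool's imperfect calls is *not* claimed and is not an acceptance property;
the parameters are conventional defaults, not reverse-engineered values.

### Compound SSRs

Maximal chains of ≥ 2 perfect loci with adjacent gaps ≤ `compound_max_gap`
(10 bp, the documented default of the tool family this follows) become one
compound locus. Member loci are retained, and perfect loci absorbed into a
compound are flagged (`in_compound`) so that type proportions count each
genomic locus once; whether absorbed members should *also* count as
perfect is genuinely unsettled in the literature, so the statistics expose
`count_compound_members` to toggle it.

### Canonical motifs

Motifs equivalent under circular permutation and/or reverse
complementation are grouped as one microsatellite type. The class
representative is the lexicographic minimum over all rotations of the
motif and of its reverse complement; it is idempotent and invariant under
both group actions. Exhaustive enumeration gives 2, 4, 10, 33, 102 and
350 classes for k = 1..6, and the test suite re-derives these counts with
a union-find over the rotation/reverse-complement graph — a second route
with no shared code.

## 2. Genomic compartments and gene-end profiles

Annotation is read from GFF3 (gene → mRNA → exon/CDS with ID/Parent);
introns are always derived as gaps between consecutive exons of one
transcript, never read from the file. Three conventions are deliberate:

* **Longest transcript.** For multi-transcript genes the transcript with
  the largest summed exon length represents the gene; isoform-aware
  multi-labeling is out of scope.
* **Midpoint rule.** A locus is labeled by the compartment of its midpoint
  base, with precedence CDS > exon_noncoding > intron > intergenic. This
  gives every locus exactly one deterministic label; against a per-base
  majority oracle it agrees on ≥ 99% of random loci, and every
  disagreement straddles a compartment boundary. `exon_noncoding` keeps
  UTR exon distinct from CDS, since the survey convention reports exons
  and CDSs as separate compartments (the "exon" statistic is their union).
* **Ranks from both ends.** Exon and intron ranks count from the 5′ and
  the 3′ gene end honoring strand, so `rank5 + rank3 = n + 1` always;
  introns mirror the exon convention. The gene-end positional profile
  counts loci per rank up to `top_n` (default 30) from each end; flipping
  every gene's strand must swap the 5′ and 3′ profiles exactly, and does.

## 3. Summary statistics

All statistics operate on the locus table and are stratifiable by species,
motif-length class and compartment:

* type proportions (percent of P/I/C among loci, compound members counted
  once; percentages are of *locus counts*, the base-count alternative is
  noted but not used);
* abundance `loci/Mb = n × 10⁶ / L` and density `bp/Mb = Σlength × 10⁶ / L`,
  with genome length `L` including `N` bases (flag to exclude them is a
  possible extension; the simulator emits none);
* RCN histograms over integer copy numbers;
* CV of RCN = 100 × sd/mean, with the *sample* (n−1) standard deviation,
  reported in percent; cells with fewer than two loci are missing, not
  zero. The closed form `{2,4,6} → 50%` and scale invariance are test
  anchors;
* GC content of the concatenated locus spans, in [0,1] (AT-only motifs
  give exactly 0);
* motif preference matrices: species × canonical motif, in both loci/Mb
  and bp/Mb, full for di/tri classes and restricted to the top 25 motifs
  for tetra/penta/hexa. "Most common" is ranked by *mean abundance across
  species* (the metric is otherwise unspecified in survey practice), with
  lexicographic tie-break for determinism.

## 4. Phylogenetically-informed PCA

Species are not independent samples: under Brownian motion their expected
trait covariance is the tree variance–covariance matrix **C**, where
`C[i,j]` is the branch length shared from the root by tips i and j.
`tree_vcv()` computes **C** from node depths and MRCAs directly, and is
checked against `ape::vcv` on random trees.

`phylo_pca(X, C, mode)` then computes, from first principles:

* GLS ancestral mean `a = (1ᵀC⁻¹1)⁻¹ 1ᵀC⁻¹X`;
* evolutionary covariance `R = (X−1a)ᵀ C⁻¹ (X−1a)/(n−1)`, symmetrized;
* in `mode = "corr"`, traits are standardized by their GLS evolutionary
  standard deviations and R becomes a correlation matrix — scores are
  computed from the standardized data, following the convention of the
  reference implementation in the phylogenetics toolbox this is tested
  against;
* eigendecomposition of R, species scores `S = (X−1a)V`.

Numerical choices: `mode = "cov"` is the default (the survey convention
when none is stated); component signs are fixed so the largest-magnitude
loading of each axis is positive (PCA signs are arbitrary, reproducible
outputs are not); a numerically singular **C** — zero-length branches occur
in dated trees — is regularized by a ridge of `1e-8 × trace(C)/n` with a
message; `n ≤ m` warns of rank deficiency; non-finite trait values are an
error. Tested properties: with `C = I` the result equals ordinary PCA to
< 1e−8; eigenvalues sum to trace(R) and loadings are orthonormal; adding
a constant per trait changes only the mean; the single-trait eigenvalue is
the GLS variance; and over 500 Brownian simulations on an 80-tip tree the
mean estimated R recovers a generating covariance (entries 0.3–1) within
5% entrywise. Phylogenetic *signal* statistics (Pagel's λ, Blomberg's K)
are out of scope.

## 5. The synthetic-data generator

`generate_genome()` exists so that detection, annotation and statistics
can be validated against exhaustive ground truth. What it emulates:

* background sequence drawn i.i.d. at a configurable GC content (default
  0.42, a typical avian genome-wide value), *rejection-sampled* so that no
  unplanted run reaches either the perfect thresholds or the imperfect
  seed thresholds (8/4/3/3/3/3 copies) — the stricter of the two, so a
  clean background can seed neither class of call and the truth table is
  exhaustive;
* planted loci appearing verbatim at their stated coordinates: perfect
  arrays, imperfect arrays built by applying specified
  substitution/insertion/deletion edits to a perfect array, and compound
  arrangements of two threshold-passing arrays separated by a configurable
  gap (≥ 1 bp — at gap 0 the first member's run could extend into the
  second when phases align, making truth ambiguous);
* flanking bases pinned so a planted array can never extend into the
  background, and ≥ 20 bp spacing between plants so compound merging never
  occurs unless requested (an unstated convention in the tool family; the
  choice is flagged here);
* multi-exon gene models on both strands, emitted as standards-compliant
  GFF3 with CDS phase, plus a BED-like truth table (0-based half-open)
  whose region labels come from the generator's own midpoint computation —
  independent of the annotation module it validates.

Validation guards: planted loci may not overlap (error naming the pair);
an imperfect plant may not contain a perfect-threshold run (the truth
would be ambiguous); compound members must meet their class thresholds;
motifs must be primitive.

What it does *not* emulate: realistic chromosome size distributions,
transposable elements and other repeat families, sequencing error,
isochore/GC heterogeneity, and SSR length distributions shaped by real
mutation processes. Passing the recovery tests therefore shows the
pipeline is *correct on its own terms* — it finds exactly what is planted,
and nothing else, on a background engineered to be repeat-free — not that
its defaults are optimal on real assemblies.

`study_genome_spec()` fixes the study conditions used throughout the
tests and the acceptance script: one 100 kb sequence per species, four
5.4 kb five-exon genes at fixed positions on alternating strands, and 54
planted loci on a 1.75 kb grid crossing all compartments — six perfect
plants per motif-length class (copy numbers at threshold plus a small
binomial surplus), two imperfect plants per class (one interior
substitution, both segments below the perfect threshold and at or above
the seed threshold), and six compound plants. Motif identity is drawn
with species-specific log-normal weights (sd 1), which is the
between-species preference variation the comparative stage measures.
`generate_tree()` supplies a Yule (pure-birth) tree rescaled to unit
depth as the dated-phylogeny stand-in, and `simulate_bm_traits()` draws
matrix-normal Brownian traits (row covariance **C**, column covariance
`evo_cov`) for parameter-recovery checks.

## 6. Pipeline, configuration and outputs

`run_species()` produces a self-contained per-species directory (locus
TSV and BED, statistics TSVs, JSON manifest with input checksums and the
parameter echo); `run_comparative()` works from those files or in-memory
results and requires species identifiers to match tree tips exactly
(mismatches are reported as the asymmetric difference). `run_all()` reads
a YAML configuration:

```yaml
species:
  - id: s1
    simulate: {seed: 11}        # or: fasta: path.fa / gff: path.gff3
  - id: s2
    simulate: {seed: 12}
tree:
  simulate: {seed: 5}           # or a Newick path/string
classes: [2, 3, 4, 5, 6]
top_n_positional: 30
top_n_motifs: 25
mode: cov
out_dir: results/
```

Coordinates are 0-based half-open in memory and in the truth table;
human-facing TSVs are 1-based inclusive with column names that say so.
Outputs are deterministic functions of inputs and seed; reruns are
byte-identical.

## 7. Known limitations

* The imperfect-SSR algorithm is a documented convention, not a
  reproduction of any specific tool; loci with interruptions longer than
  `max_consecutive_edits` or weak terminal segments are deliberately
  split or trimmed.
* An imperfect locus may span a region that also contains a reported
  perfect locus (e.g. a long pure run with one flanking interruption);
  the two tables describe different models of the same sequence, and only
  compound membership is deduplicated in the type proportions.
* Satellites with units > 6 bp, primer design and cross-individual
  genotyping are out of scope.
* The midpoint rule undercounts compartment *overlap*: a locus straddling
  an exon boundary contributes to exactly one compartment.
* On real annotations with overlapping genes, a locus inside an exon of
  one gene and an intron of another counts in both gene-end profiles (one
  per feature type); the synthetic gene models do not overlap, so the
  recovery tests do not exercise that case.
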