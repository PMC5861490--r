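---
title: "vitring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vitring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitring)
```

`vitring` profiles microbial communities from 16S rRNA gene reads and
draws the result on a circle whose leaf order reflects phylogeny. This
vignette documents the models and procedures, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and
do not establish about real data.

## 1. Reference curation

Raw reference collections mix full-length and partial 16S genes,
flanking rRNA-operon context, and near-duplicate records. Curation
proceeds in fixed stages, each of which partitions its input into kept
and removed records (nothing is silently dropped; `build_refdb()` keeps
an audit table):

1. **Anchor trimming** (`trim_to_anchors()`). The 5' cut sits
   `five_prime_margin = 6` bases upstream of the first occurrence of
   the 8F primer motif `TTGATCCT`; the 3' cut at the end of the first
   anti-Shine–Dalgarno motif `CACCTCCTTN` downstream of it (`N`
   matches any base). Motif search uses the first exact occurrence,
   scanning left to right; the margin clamps at the sequence start.
   When a motif is missing, a caller-supplied already-trimmed *guide*
   sequence can substitute: the record is cut at the coordinates
   implied by its best local alignment to the guide, extended to the
   guide ends and clamped. A record with a 5' anchor but no 3' motif
   and no guide is trimmed on the 5' side only and kept to its end —
   flagging it untrimmable would discard an otherwise anchored record.
   Records with neither anchors nor a guide hit are flagged, not
   removed.
2. **Length filter** (`filter_by_length()`): keep 1120–1660 bp
   inclusive. The window brackets plausible nearly full-length genes
   after trimming.
3. **Homopolymer filter** (`filter_homopolymer()`): remove records with
   any single-base run of `max_run + 1 = 10` or more, the signature of
   pyrosequencing artifacts. Parameterizing the *longest tolerated*
   run (9) keeps the boundary explicit.
4. **Ordering and clustering** (`sort_for_clustering()`,
   `greedy_cluster()`). Greedy centroid clustering is order-dependent,
   so genus-classified records come first (longest first), then
   genus-`unclassified` records (longest first); length ties break by
   id so reruns are identical. Each record joins the first existing
   cluster whose representative aligns at ≥ 94 % identity with ≥ 0.9
   aligned coverage of both sequences, else founds a cluster. Identity
   is matches over all aligned columns (gaps included); coverage is the
   aligned span over each sequence's length. These definitions are the
   package's own — no attempt is made to reproduce any specific
   clustering tool bit for bit.
5. **Finalization** (`finalize_representatives()`): drop
   representatives flagged chimeric by **both** a de novo and a
   reference chimera screen (flags are inputs — chimera detection
   itself is out of scope), and representatives whose genus is
   `unclassified`. The two removal classes are assumed disjoint, which
   is what their bookkeeping arithmetic implies. A classified,
   unflagged representative is never removed.

For the phylum-level layout, `subsample_for_phylum_layout()` draws up
to 30 records per phylum (all records when fewer are available), and
per *class* within Proteobacteria, whose diversity would otherwise
swamp a single phylum sample. Sampling is uniform without replacement
and reproducible under a seed.

## 2. Distances, tree, and the circular layout

Pairwise distances on a fixed multiple alignment use Kimura's
two-parameter model: with transition fraction $P$ and transversion
fraction $Q$ over columns where both sequences have an unambiguous
base (pairwise deletion),

$$ d = -\tfrac12 \ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right]. $$

Saturated pairs (non-positive log argument) are replaced by 1.5× the
largest finite distance in the matrix and recorded in an attribute —
a sentinel that keeps them "very far" without breaking downstream
algebra. Multiple sequence alignment itself is an input: the package
consumes aligned FASTA and the simulator produces gap-free alignable
sequences, so no aligner is bundled.

The tree is standard neighbor joining (`ape::nj`); negative
branch-length estimates are clamped to zero. On additive matrices NJ
is exact, which the tests exploit: patristic distances of the
reconstructed tree reproduce random additive input matrices to 1e-9.

**Tree-topology scanning** (`tree_topology_scan()`) converts the tree
plus the distance matrix into a single leaf ordering. Rooted at the
chosen initial leaf, the most distant leaf is found by comparing
distances from the initial sequence; each subsequent pick is the most
distant unordered leaf within the *smallest ancestral clade* of the
last-chosen leaf that still contains unordered leaves. The far-to-near
emission is reversed and prefixed with the initial leaf. Distance ties
break by leaf id. Two deliberate choices:

* "Distance" defaults to the same matrix the tree was built from, with
  `use_tree_dist = TRUE` switching to patristic tree distances; both
  satisfy the worked six-leaf example, and the matrix is what the
  scan's description actually compares.
* The circle closes with the last-to-first distance: angles are
  $2\pi$ × cumulative gap fractions of the total (gaps + closing gap),
  so the layout has no arbitrary terminal whitespace. All-zero gap
  lists fall back to uniform spacing.

Taxon ring labels sit at the circular mean of member angles (direction
of the summed unit vectors), which handles wraparound across 0; an
antipodal-degenerate mean falls back to the smallest member angle.
Values within 1e-9 of $2\pi$ snap to 0.

## 3. Identity search

Indexing and searching are separate: `build_kmer_index()` records, for
every non-ambiguous k-mer of every reference, its reference and offset;
the index serializes to versioned JSON and reloads to byte-identical
search behavior. Default `k = 16`: long enough that random 150-mers
essentially never seed, short enough that reads at ≥ 90 % identity
almost surely contain an exact seed.

`identity_search()` counts shared seeds per reference and diagonal on
both strands (the query's reverse complement is searched explicitly),
then runs a banded affine-gap local alignment (Rcpp) around the most
seed-supported diagonal of the best candidates (`band_pad = 16`
absorbs indels up to that size). Scoring is match +1, mismatch −1, gap
open 2, gap extend 1 (a gap of length $L$ costs $2 + L$), identical to
the convention of `Biostrings::pairwiseAlignment`, which serves as the
independent full-DP oracle in the tests. Identity is matches over all
aligned columns including gaps; the single top hit is chosen by
identity, then alignment length, then reference id, and must pass
identity ≥ 80 % and alignment length ≥ 100 bp (the 100 bp default
matches the primary workflow; a 50 bp variant exists for short-read
experiments and is a plain argument). On substitution-mutated queries
the banded search reproduces the exhaustive DP identity exactly in the
test suite; with injected indels, equal-score co-optimal alignments can
differ by under one identity point, which is why the DP-agreement check
is run on the substitution regime.

The negative screen (`negative_screen()`) classifies reads against an
index of eukaryote 18S / mitochondrial rRNA with the *same* thresholds;
reads hitting both the positive and negative databases are excluded
from profiling. Note the consequence, exercised in the pipeline tests:
a 16S read whose genuine reference has a close relative in the negative
set is excluded too — sensitivity is traded for specificity exactly at
the stated thresholds.

## 4. Genus profiling and copy-number normalization

Reads with top-hit identity ≥ 94 % contribute one count to their
reference's genus; sub-threshold reads are reported as unassigned and
excluded from relative abundances (they cannot be confirmed as 16S).
Because shotgun read counts sample gene copies rather than genomes,
the profile can be normalized: each read's 16S copy number $c$ is
inherited from its top hit in a copy-number database (one sequence per
genome-sequenced species with its genomic 16S copy count, found with
the same 80 %/100 bp search), and the read contributes $1/c$ to its
genus. Reads with no copy-number hit fall back to $c = 1$ — no
down-weighting without evidence — and are flagged. Normalization never
changes the set of detected genera.

`leave_one_out_cn()` validates the nearest-neighbor assumption on a
given copy-number database: each record is searched against the
database rebuilt without it, and the inferred copy number is compared
to the truth as a fold error. On synthetic databases where copy number
is constant within clades the procedure is within twofold for every
record; a deliberately clade-discordant record exceeds twofold, which
is the failure mode expected for taxa whose copy number differs from
their relatives'. The headline accuracy of this procedure on a real
1505-species database depends on that database and is not reproduced
here; only the mechanism is.

## 5. Reconstruction of nearly full-length 16S genes

Reads sharing a top-hit reference form a bin (minus-strand reads are
reverse-complemented first). `assemble_bin()` merges greedily: at each
step the pair of contigs with the longest suffix–prefix overlap of at
least `min_overlap = 40` bp and mismatch rate ≤ `max_mismatch_rate =
0.02` is merged, until no admissible overlap remains; the final contig
sequence is the per-column majority vote over the read layout, and mean
coverage is total read bases over contig length (the definition is the
package's own, as "read coverage" admits several). A deterministic
greedy overlap-consensus assembler is adequate at desk scale and keeps
the pipeline self-contained; externally produced contigs can enter the
same downstream steps via `filter_contigs()` / `assign_species()`
directly. Contigs ≥ 800 bp with coverage ≥ 10× are kept; species names
are assigned at ≥ 97 % identity to a type-strain sequence, with equal
ties reported jointly. The species alignment must additionally span at
least half the contig (`min_span = 0.5`) so that a short perfect match
to a conserved motif cannot masquerade as a species call — local
alignment alone would otherwise report 100 % identity over a few dozen
bases. Contig ends are not trimmed of ITS or intergenic carry-over.

## 6. Sample comparison

Profiles restricted to ≥ 94 % assignments are compared pairwise at the
reference-cluster level (default) or genus level:

* Jaccard — shared support over union support (presence/absence only);
* Pearson — product-moment correlation of abundances on the label
  union (absent = 0);
* Yue–Clayton $\theta = \sum p_i q_i \big/ (\sum p_i^2 + \sum q_i^2 -
  \sum p_i q_i)$ — abundance-weighted, 1 iff the profiles are equal, 0
  for disjoint supports.

Undefined cases (empty profiles, zero variance, single shared label)
are `NA`, never coerced to 0.

## 7. Synthetic data: what it emulates and what it does not

`simulate_tree()` draws a random topology with exponential branch
lengths; `evolve_sequences()` runs forward K2P substitution along the
tree with defaults $\alpha = 0.5$, $\beta = 0.25$ per transversion, so
$\alpha + 2\beta = 1$ and branch lengths are expected substitutions per
site (distance estimates are then directly comparable to patristic
distances). Roots embed the two anchor motifs, held invariant so
trimming works on every descendant. `simulate_reads()` draws species
with probability ∝ molarity × copy number — the quantity shotgun
sequencing actually samples — with uniform start positions, random
strands, and substitution errors only. `make_contaminants()` produces
tRNA-like, 23S-like and random decoys unrelated to the references.

The simulator is substitution-only (no indels, no quality profile, no
chimeras, no compositional bias), produces gap-free alignable
references, and keeps the anchor region invariant. Passing tests
therefore demonstrate algorithmic correctness under the stated model,
not robustness to platform-specific artifacts; indel tolerance of the
search is tested separately with injected indels. One practical
caution encoded in the tests: generators given the *same* seed share
an RNG stream, so "unrelated" fixtures must use distinct seeds.

## 8. Problem sizes and determinism

The shipped tests and the acceptance script use desk-scale sizes chosen
as the smallest that exercise every code path with headroom: reference
sets of 2–10 sequences of ~1.4–1.5 kb, read sets of hundreds to a few
thousand 150 bp reads, 200 random search instances against an
exhaustive-DP oracle, additive matrices up to n = 8, and a ~12.5×
tiling of a single gene for reconstruction. Every stochastic step takes
an explicit seed, and the pipeline is a pure function of (inputs,
configuration, seed): rerunning writes byte-identical outputs, which
the tests assert file by file.

## 9. Known limitations

* No multiple sequence alignment, tree rooting by outgroup, or
  bootstrap support; the layout consumes a supplied alignment.
* The assembler is greedy overlap-consensus, not a de Bruijn graph; at
  very high error rates or with repeats it will fragment rather than
  misjoin (fragments are then removed by the length filter).
* Chimera detection and real reference databases (RDP-scale
  collections, real copy-number tables, curated negative sets) are
  inputs, not components.
* E-value statistics, protein search and GPU acceleration are out of
  scope; thresholds are plain identity/length cutoffs.
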