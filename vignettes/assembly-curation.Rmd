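---
title: "Curating and scaffolding an allotetraploid draft assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and scaffolding an allotetraploid draft assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrascaf)
```

## The problem

Allotetraploid genomes (AABB) carry two homoeologous subgenomes whose long
stretches of near-identical sequence make long-read contigs prone to
chimeric joins: a contig that concatenates two regions that are not adjacent
in the genome, often one from each subgenome. `tetrascaf` implements the
downstream half of a hybrid assembly workflow for such genomes:

1. **Optical-map curation** — digest the draft in silico with a nicking
   endonuclease, align the resulting label maps against an assembled optical
   genome map, score putative misjoins, and break sequences at soft-clip
   supported breakpoints.
2. **Mate-pair scaffolding** — join contigs supported by at least three
   insert-validated, uniquely mapped mate-pair links.
3. **Hi-C pseudomolecule construction** — cluster scaffolds into chromosome
   groups by contact frequency, order and orient them hierarchically, and
   emit chromosome sequences with an AGP placement table.
4. **Subgenome partitioning** — label every sequence A or B by diagnostic
   k-mer voting against the two ancestral diploid genomes.
5. **Reporting** — contiguity (N50/N90/L50), gap and GC statistics,
   per-chromosome anchoring tables, and the anchored / subgenome-separated
   percentages.

Every stage is exercised end-to-end on data from the package's own
simulator, which plants chimeras and records them as truth.

## The synthetic truth set

`sim_config()` fixes the study conditions. The defaults describe a toy
allotetraploid: two subgenomes of two 500-kb chromosomes each, derived from
two simulated ancestors. The ancestors differ by 3% point substitutions
(typical of the divergence between the two diploid progenitors of a young
allotetraploid); each subgenome adds 1% substitutions plus short (<= 5 bp)
indels at 5% of mutation events — enough to stress k-mer partitioning while
keeping coordinate bookkeeping exact, since all downstream coordinates live
on the subgenome chromosomes themselves.

```{r}
cfg <- sim_config(seed = 1)
cfg
```

The draft is made by cutting every chromosome into fragments
(Normal with mean 60 kb, truncated at 25 kb so each fragment carries a
handful of nick labels) and splicing five pairs of non-adjacent fragments
into chimeric contigs:

```{r}
truth <- make_draft_with_chimeras(simulate_truth(cfg), cfg)
truth
truth$chimeras[, c("draft_id", "junction", "chrom1", "chrom2")]
```

Four kinds of evidence are simulated against this truth:

* **Optical molecules** (`simulate_molecules()`): sampled at 40-fold
  coverage with mean length 220 kb; label positions get 2% multiplicative
  Gaussian sizing noise per interval (instrument error models for
  single-molecule maps are not standardized, so a proportional noise model
  was chosen once). A tenth of molecules are drawn to violate one of the
  standard retention filters (length > 150 kb, >= 8 labels, label SNR
  >= 3.0, intensity < 0.6) so that `filter_molecules()` has real work.
* **Mate pairs** (`simulate_mate_pairs()`): one 3-kb library (SD 300 bp,
  20,000 pairs, innie orientation) emitted as alignment records in draft
  coordinates. A pair drawn across a planted junction can never be placed
  concordantly inside the chimeric contig, so discordance at chimeras is a
  structural property of the generator, not a tuned rate.
* **Long-read alignments** (`simulate_long_read_clips()`): jittered even
  tiling at 10-fold coverage, mean read 15 kb. Reads crossing a planted
  junction are split there with ±60 bp jitter, leaving a cluster of
  soft-clip boundaries and zero spanning coverage at every chimera.
* **Hi-C contacts** (`simulate_contacts()`): 200,000 pairs; the
  intra-chromosomal separation follows a truncated power law with exponent
  1 (the canonical contact-decay slope), sampled with a uniform anchor and
  rejection at the chromosome end so that pair density is proportional to
  `(1+d)^-1` everywhere; 5% of pairs are uniform inter-chromosomal
  background, and 10%/2% of records carry low mapq / duplicate flags to
  exercise filtering.

The generator emulates the structure of real evidence, not its base-level
noise: there are no sequencing errors, no repeat-induced mapping ambiguity
beyond a 2% non-unique rate, and no optical-map assembly errors. Passing
tests therefore demonstrate that the decision rules and algorithms are
implemented correctly and recover planted truth under realistic geometry —
not that the pipeline is robust to every pathology of real data.

## Restriction-map alignment

`align_maps()` aligns two ordered label lists by dynamic programming over
label intervals. A matched interval contributes
`match_bonus - (residual / tol)^2` where `tol = max(500 bp, 5% of the
reference interval)`; skipped internal labels cost 3 per label on either
map; unmatched query end labels cost 1.5 each beyond the first at each end
(molecule ends are unreliable); reference labels outside the aligned span
are free, so placement is local on the reference and global on the query.
Both orientations are tried and ties prefer the forward orientation, then
the leftmost reference start. An alignment needs at least two matched
labels — one interval — to exist at all, and `fully_aligned` means every
query label is matched except at most one at each end, a tolerance for end
sizing artifacts.

The tolerance constants matter: they must accept the simulator's 2% sizing
noise (residual SD ~150 bp on a typical 8-kb interval) while rejecting the
chance matches that would otherwise let an alignment "walk across" a
chimeric junction. The defaults accept true intervals with penalty < 1 at
3 SD of noise and make a random junction-crossing match profitable only a
quarter of the time, which the split scan (below) then absorbs.

On maps with few labels the DP is checked against exhaustive enumeration of
every monotone matching (`align_score_bruteforce()`), an independent oracle
with the same scoring.

## Conflict detection and the decision rules

`detect_conflicts()` asks, for every draft sequence map, whether a
*two-placement* explanation beats the best single placement: for every
junction candidate between consecutive labels, the prefix and suffix maps
are aligned independently and the summed score is compared with the single
best alignment. For a clean contig the split always loses (it forfeits one
interval bonus); for a chimera the displaced half finds its true placement
and the split wins decisively. This is the label-resolution analogue of the
split-read criterion used in structural-variant calling. A second detector
flags runs of three or more consecutive intervals that all exceed the
sizing tolerance.

Each conflict junction is then evaluated by the standard curation rules:

* **Candidacy**: chimeric score >= 30% and more than two fully aligned
  molecules spanning the junction. The chimeric score is the percentage of
  window-overlapping molecules that fully align across the junction's 50-kb
  flanks. A junction with *no* local molecules scores 0 — absent optical
  evidence never triggers a break.
* **Confirmation**: the candidate is broken iff the mate-pair relationship
  of the 10-kb flanks is in disagreement (fewer than three concordant
  insert-validated bridging pairs) **or** fewer than five long reads fully
  span the junction.

Two implementation choices connect the rules into a working pipeline.
First, the junction coordinate coming out of map alignment is only accurate
to about one label interval (several kb), so before evaluating mate-pair
and spanning-read evidence the junction is *refined* to the consistent
soft-clip site: the median of the largest clip cluster (>= 3 boundaries
within 100 bp) within 25 kb of the coarse coordinate. Without a cluster the
coarse coordinate is kept, which is exactly what happens at a false
conflict on a clean contig. Second, a chimera whose half abuts the end of
an optical map cannot be spanned by molecules there, so the molecule
support is computed at both placements' inner boundaries and the stronger
side is used.

The sequence is broken at the refined coordinate; fragments are named
`{id}.1, {id}.2, ...` and total base count is conserved — both properties
are asserted by tests. On the default conditions the pipeline recovers
planted chimeras with recall and precision above 0.9 across 20 seeds, every
break lands within 2 kb of a planted junction, and a chimera-free draft is
never broken.

## Mate-pair scaffolding

`collect_links()` keeps pairs with both mates uniquely mapped and derives
which contig ends face each other from the mate strands (innie convention).
`filter_links_by_insert()` keeps links whose implied insert (the sum of
both mates' distances to their joined ends, i.e. assuming abutting contigs)
lies within the library mean ± 5 SD, boundary inclusive. `join_contigs()`
draws an edge between two contig ends only when a single library
contributes at least three such links — the threshold is deliberately not
summed across libraries, the conservative reading — and any end with two or
more competing supported partners joins nothing at all. What remains is a
set of simple paths (a cycle, should one arise, is opened at its weakest
edge); gaps are `round(mean(insert_mean - d_a - d_b))`, clamped at 10 bp.
Output order is deterministic and invariant to the input link order.

## Hi-C grouping, ordering, orientation

Contacts with mapq > 20 and no duplicate flag are aggregated in 50-kb bins;
intra- and inter-sequence submatrices are normalized separately by the
product of bin coverages and each class is rescaled to unit mean over its
nonzero entries. Scaffold-level clustering uses the length-normalized
contact frequency `links / (len_i * len_j)` under average-linkage
agglomeration cut at the requested number of groups (k is a parameter
because no absolute contact-frequency threshold generalizes across
datasets).

Within a group, ordering is hierarchical: the group is subclustered into
five subgroups, each subgroup is ordered by greedy chaining that extends
the current path at whichever end has the strongest remaining contact, each
ordered subgroup is collapsed into a super-bin, the super-bins are chained
the same way, and subgroups are flipped so the scaffold best connected to
the neighboring subgroup faces it. Orientation uses the contact-weighted
position gradient: contacts to scaffolds earlier in the order should attach
near a scaffold's left-facing end, so a scaffold whose mean contact
position toward its left neighbors exceeds that toward its right neighbors
is reversed; terminal scaffolds compare the gradient against their
midpoint. The whole solution is defined up to global reversal; the reported
direction starts at the lexicographically smaller terminal scaffold.

`build_pseudomolecules()` concatenates each ordered group with 100-N gaps
(reverse-complementing reversed scaffolds) and emits an AGP v2.1 table with
`proximity_ligation` evidence; reconstruction from the AGP reproduces the
emitted FASTA byte for byte. `heatmap_matrix()` lifts contacts to
pseudomolecule coordinates through the AGP, counts them in 500-kb windows
and reports `log2(count)` with empty bins masked (matching a 0-10 display
scale; `log2` of an empty bin is not a number worth plotting).

## Subgenome partitioning

Whole-genome alignment against the two progenitor genomes is replaced by
diagnostic k-mer voting, which tests the same signal — unique ancestral
sequence — at desk scale and deterministically. Canonical (strand-collapsed,
hence odd `k`) 21-mers unique to each ancestor form two disjoint diagnostic
sets; a sequence's votes are its canonical k-mer hits in each set and it is
labeled `A` when `votes_a >= 10` and `votes_a >= 2 * votes_b` (symmetric
for `B`), `ambiguous` when both sides clear the floor without a margin
winner, `unassigned` otherwise. The 10-vote floor and 2:1 margin keep false
assignments near zero at the toy divergences; a 10-kb windowed vote track
is retained because a cross-subgenome chimera shows as two disjoint vote
blocks. Swapping the ancestors swaps every label exactly, and
reverse-complementing a sequence never changes its votes.

## Reporting

`contiguity_stats()` computes N50/N90/L50/L90 from the cumulative length
distribution, GC% over non-N bases, and gaps as maximal N runs (length
>= 1). `chromosome_table()` reproduces the per-pseudochromosome layout of a
genome report — gap ratio and anchored percent at two decimals, half-up
rounding to match printed tables, totals recomputed from column sums —
and `anchoring_summary()` derives the anchored and subgenome-separated
percentages. `subgenome_table()` compares the two subgenomes over sequences
longer than 10 kb (strictly, so exactly 10,000 bp is excluded). The
bundled `reference_chromosome_stats()` table carries the published
per-chromosome lengths and gap sizes of the allotetraploid wild peanut
assembly so the arithmetic can be checked against printed values:

```{r}
chr <- reference_chromosome_stats()
summ <- anchoring_summary(chr)
summ$anchored_percent
summ$separated_percent
```

## Numerical choices and limitations

* Rounding in reports is half-up at two decimals, matching how the
  reference tables print.
* `align_maps()` tie-breaks prefer the forward orientation, then the
  leftmost reference start; `cluster_groups()` relies on `hclust`'s
  deterministic average-linkage merge order; `join_contigs()` sorts edges
  and paths lexicographically. Everything downstream of a fixed seed is
  byte-identical between runs.
* Each simulator operation draws from its own stream seeded by
  `config$seed` plus an operation tag, so stages can be regenerated
  independently.
* Problem sizes throughout (2-Mb genome, 20 seeds, 120 oracle map pairs)
  were chosen so the full test battery represents each claim with
  comfortable Monte-Carlo margins while remaining desk-scale; the genome
  structure, not its 2.7-Gb size, is what the pipeline's logic depends on.
* Chimeras whose smaller half carries fewer than two nick labels are
  invisible to optical conflict detection — with the default label density
  (one per ~8 kb) that is a few percent of planted junctions, and it is the
  dominant term in the residual recall gap.
* The 50-kb flank, >= 30% score, > 2 spanning molecules, ± 5 SD insert
  window, >= 3 links, mapq > 20, 50-kb bins, 20 groups, 5 subgroups and
  500-kb heatmap windows are the standard curation constants of this
  workflow and are exposed as parameters (`curation_thresholds()`,
  `hic_params()`), not hard-coded.
* Unresolved conflicts are simply kept and logged with their evidence;
  no manual-review step is modeled.
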