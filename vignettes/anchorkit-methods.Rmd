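---
title: "Methods: bait design, locus recovery and quartet mapping in anchorkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bait design, locus recovery and quartet mapping in anchorkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorkit)
```

anchorkit implements the computational core of an anchored-hybrid-enrichment
(AHE) phylogenomics workflow for protein-coding loci: designing a tiled bait
set from orthologous coding alignments, evaluating in-silico capture of those
targets from assembled contigs, codon-aware quality control of the recovered
locus alignments, assembly of completeness-filtered supermatrices with
gene-by-codon-position partitions, four-cluster likelihood mapping (FcLM) of
conflicting quartet signal, and support-based tree classification and
collapse.  Every step is exercised on synthetic data with recorded ground
truth generated by the `simulate_*` functions.

## Bait design from orthogroup alignments

The input for design is, per single-copy ortholog, a gapped amino-acid
alignment of the reference taxa plus the matching unaligned coding
sequences.  `thread_nucleotides()` rebuilds the codon-level alignment the way
Tranalign does: each residue is replaced by its codon, each gap by `---`.  A
terminal stop codon is stripped before threading; an internal stop, or any
residue whose codon does not translate to it, is an error rather than a
warning, because a bait designed over a mistranslated region is silently
wrong.

Conserved regions are found by a sliding window on the amino-acid alignment
(`score_conservation()`).  The published pipelines in this field reference a
design script rather than a statistic, so the statistic here is a deliberate
design choice: the score of a window is the mean, over its columns, of the
frequency of the modal residue among non-gap rows.  This is order-invariant,
invariant under bijective residue relabelling, cheap, and easy to verify
against brute force.  Defaults are a 20-residue window and a 0.7 threshold;
both are `design_params()` tunables.  A window containing any column with
gap fraction above 0.2 is ineligible regardless of score, because a bait
needs contiguous sequence to hybridise against.

Windows that pass are merged when overlapping or adjacent, converted to
nucleotide coordinates (×3, so excised regions always start on codon
boundaries), and dropped when shorter than 120 nt
(`min_target_len_nt`, chosen as a comfortable margin above the 100-nt bait).
`select_targets()` then applies the representation rule: a target is kept
when at least five reference taxa "represent" it.  Representation is
quantified as a non-gap fraction of at least 0.9 within the region — the
source workflows say only "representation", so the 0.9 floor is declared
here and configurable.

`tile_baits()` places 100-nt baits per represented taxon at a step of
`round(bait_len / tiling_factor)` — 87 nt at the published 1.15X tiling —
and adds one right-aligned bait when the last regular bait does not reach
the end, so coverage of every position is guaranteed and the realised
density approaches 1.15X from above on long targets.  The exact layout used
by bait vendors is proprietary; this arithmetic reproduces the stated
density and is deterministic.  Identical bait sequences arising from
near-identical taxa are deduplicated.  Whether the original kit tiled per
taxon or on a consensus is unstated; per-taxon tiling plus deduplication is
the more conservative choice (it can only add baits where taxa diverge).

## In-silico capture evaluation

`match_contigs()` mirrors the matching step of UCE/AHE pipelines: contigs
are matched to targets at a minimum 80% identity and 82% target coverage
(the conventional matching defaults), then two ambiguity filters run in a
fixed order: contigs matching two or more targets are discarded
(`multi_target`), then targets matched by two or more surviving contigs are
discarded (`multi_contig`).  "Two or more" counts distinct ids; secondary
hits to the same target never trigger a filter.  Coverage is measured on
the target, not the contig — the convention of the matching defaults being
reproduced — so a long genomic contig containing one complete target is a
clean hit.

The aligner behind `align_local()` requires a shared exact 15-mer seed
before any alignment is attempted (random sequence almost never shares one,
so decoys are rejected cheaply), and then computes an optimal local
alignment with affine gaps (+1/−1 match/mismatch, −2 open, −1 per gap
character).  The test suite checks the reported identity and coverage
against an independently written full Smith–Waterman dynamic program.

`reconcile_assemblies()` implements longest-fragment reconciliation across
assemblers: per target the accepted contig of maximal ungapped length wins,
with ties broken by the lexicographically smallest assembler name so reruns
are reproducible.

## Codon-aware locus QC

Manual alignment inspection is replaced by deterministic rules, all driven
by one resolved reading frame per locus.  `infer_reading_frame()` picks the
frame offset (0/1/2) minimising in-frame stop codons summed over rows
within the probe-matching core (the region matched during capture; the full
alignment when no core is recorded).  Codons containing gaps or `N` are not
counted.  If every row shows a stop in all three frames the locus is
flagged unresolvable and routed to a manual list rather than guessed at.

`detect_flanks()` places flank boundaries at the innermost column, outside
the core, showing any of the three demarcations used when such alignments
are inspected by eye: an in-frame stop codon in any row; a gap run whose
length is not divisible by 3; or a 10-codon window whose mean agreement
with the per-column amino-acid consensus falls below 0.5.  The consensus is
the modal amino acid over informative rows, ties broken alphabetically for
determinism.  `split_locus()` then trims the probe region to start at codon
position one (the 1–2 shifted columns join the left flank) and to a whole
number of codons.

`mask_frameshifts()` converts, within each row of the probe region, any
mod-3-breaking gap run *and everything downstream of it in that row* to
`N`.  When a later gap run restores the cumulative frame (an insertion
compensating a deletion), masking stops at the end of that run; otherwise
it runs to the end of the probe region.  The source convention says only
"downstream nucleotides affected by the frameshift"; masking to the
compensation point is the minimal faithful reading, and masking the gap
characters themselves keeps alignment dimensions fixed.  Finally,
`drop_short_and_outliers()` removes rows with fewer than 9 unambiguous
bases (counted as bases, not columns — the stricter reading) and rows whose
translated probe region agrees with the consensus on less than half of
comparable positions (contaminants and gross misalignments).  After QC,
every unmasked probe-region codon translates without stops; this is
asserted as an invariant in the tests, as is idempotence of the whole
pipeline.

## Supermatrices and partitions

`filter_by_completeness()` keeps a locus when at least
`ceiling(fraction × n_taxa)` taxa survived QC; `ceiling` implements a
strict "at least" when the product is fractional (30 taxa at 75% needs 23).
The 50% and 75% sets are nested by construction.  `concatenate_loci()`
concatenates in lexicographic locus order (deterministic, as concatenation
tools conventionally do), fills absent taxa with `?` (never `-`, which is
reserved for alignment gaps), appends flank blocks after all probe blocks
when requested, and keeps an exact coordinate map that round-trips through
the exported TSV.

`define_partitions()` emits three stride-3 partitions per probe locus
(`locus_pos1 = 1-300\3` and so on, 1-based inclusive as partition files
require) and one single `flanks` partition pooling all flank columns —
flanks carry no codon structure, so they are one candidate partition.
`drop_small_partitions()` prunes partitions below 80 columns, the size
below which downstream partitioned ML runs are known to fail; it is exposed
as a generic filter so it can also be applied to externally merged schemes.
`strip_third_positions()` deletes the saturated third positions from probe
blocks only (flanks untouched), after which translation is refused by
contract — amino acids must be taken before stripping.
`translate_matrix()` uses the standard code; codons containing `N` become
`X`, codons containing a gap become `-`, missing data stays `?`, and flanks
are excluded since amino-acid matrices carry no non-coding data.

## Four-cluster likelihood mapping

For four user-defined clusters, `run_fclm()` scores every one-per-cluster
quartet.  Per quartet the three unrooted topologies `ab|cd`, `ac|bd`,
`ad|bc` are each maximised over their five branch lengths with Felsenstein
pruning under JC69 (nucleotide) or the equal-rates Poisson model (amino
acid), and the posterior weights `exp(l_i − logsumexp(l))` are mapped onto
the 2-simplex.  Richer models are deliberately out of scope: region
proportions are driven by topology signal, and the two equal-rates models
keep the likelihood verifiable against an independent implementation
(the test suite checks exact agreement with `phangorn::pml` at fixed branch
lengths, and that the optimum dominates a coarse 5-D grid).

The optimiser is cyclic coordinate ascent with Brent's 1-D search per
branch: bounds `[1e-8, 10]`, deterministic start at 0.1, at most 100
sweeps, relative tolerance `1e-6`.  Two additional deterministic starts for
the internal branch (0.5 and 0.01) guard against a boundary local optimum
at internal length ~0 that coordinate ascent can otherwise fall into; the
best of the three is reported, so results are bit-reproducible.  Taxon
order within and between the pairs of a topology is canonicalised by name
before optimisation, making likelihoods exactly invariant under consistent
relabelling.  Columns with a gap or ambiguity in any of the four taxa are
skipped (complete-case deletion); a quartet with no usable column is
skipped and counted separately.

The seven regions of the simplex — three resolved corners, three
partly-resolved edges, one unresolved centre — are operationalised as
nearest attractor by Euclidean distance, with exact ties broken toward the
more resolved region.  The classical region boundaries are drawn slightly
differently in the original likelihood-mapping literature; the
nearest-attractor rule is equivalent at the attractors themselves, simple
to reason about, and declared openly here.

## Support classification and collapse

`classify_support()` implements the published thresholds: strong when both
UFB and SHT are ≥ 95 or LPP ≥ 0.95; otherwise moderate when UFB ≥ 95 and
SHT ≥ 80, or LPP ≥ 0.85; otherwise weak when exactly one of UFB ≥ 95 /
SHT ≥ 80 holds; otherwise none.  The prose those rules come from mixes
scales ("UFB ≥ 0.95" beside percent tables) and uses three classes in
figure legends; internally UFB/SHT are canonically percentages, LPP a
fraction, and `three_class = TRUE` folds moderate into weak for
figure-style reporting.  `collapse_low_support()` contracts internal edges
below 10 UFB into polytomies — the standard pre-coalescent step — by
rebuilding the newick recursively; children keep their own branch lengths
and the collapsed edge's length is discarded.

## What the simulators emulate, and what they do not

The generators produce the study conditions the tests run under:
orthogroups are a spacer–block–spacer coding layout evolved from a random
ancestral CDS along a star tree, with per-site uniform codon replacement at
rate 0.02 in the planted 60-codon conserved block and rate 1.0 in 40-codon
spacers — enough to pin amino-acid identity above 0.9 inside the block and
below 0.6 outside, which is what the window statistic responds to.  Each
orthogroup carries between 4 and 8 of the 8 reference taxa so the
5-of-8 selection rule is exercised on both sides.  Quartet alignments are
simulated under exact JC69 (uniform root, transition-probability sampling),
with the recovery condition set at internal branch 0.2, terminal branches
0.05 and 1000 sites.  Locus fixtures plant flank demarcations (stops,
mod-3 gap runs) and 1-nt frameshifts at recorded positions into otherwise
consensus-consistent alignments, so boundary recovery can be asserted
exactly: a fully random flank would trip the consensus rule immediately at
the core edge and hide the planted feature.

None of this emulates real capture data: there are no indel-rich
alignments, no sequencing error, no base-composition or rate heterogeneity,
no paralogy beyond the single planted copy, and substitution processes are
uniform rather than CTMC-realistic except in the quartet simulator.
Passing tests therefore demonstrate that the implemented rules behave
exactly as specified on inputs satisfying their assumptions — not that the
thresholds are optimal for any particular empirical dataset.

Problem sizes used by the test-suite and the acceptance script — 20
orthogroups of 8 taxa, 1000 random tiling lengths, 15 targets with 20
decoys, 100 loci over 4 assemblers, 50 QC loci, 200 loci × 30 taxa
matrices, 16 quartets of 1000 sites — are the package's chosen
verification scale: each is the smallest size at which the corresponding
rule has non-trivial room to fail.

## Conventions and degenerate inputs

* Coordinates are 1-based closed intervals everywhere in the R API, the
  native convention of R and its phylogenetics ecosystem; exported
  partition files are 1-based inclusive with stride notation, as partition
  files require.
* Consensus ties break alphabetically; reconciliation ties break by
  assembler name; frame ties break toward the reference profile, then the
  smallest offset; simplex ties break toward the more resolved region.
* Empty results are values, not errors: no conserved window, an empty
  flank, an empty match table are all legal.  Errors are reserved for
  contract violations (length mismatches, internal stops, duplicate ids,
  unannotated support where it is required).
* All simulators take a mandatory seed and restore the RNG state
  afterwards; identical seeds give byte-identical output.

## Known limitations

Ortholog inference, alignment construction (T-Coffee/MAFFT), block
trimming, read assembly, partitioned model selection and tree inference are
out of scope by design — the package prepares inputs for, and consumes
outputs of, the standard tools for those steps.  The FcLM models are
equal-rates only; the hooks for richer models are the `model` argument and
the `eqrates_pmatrix()` seam.  The aligner is a seed-gated optimal local
alignment, not a banded heuristic, so very long genome-scale subjects are
outside its intended use.
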