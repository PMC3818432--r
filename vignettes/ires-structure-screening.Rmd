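---
title: "Screening viral RNA for IRES elements by structure alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening viral RNA for IRES elements by structure alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iresscan)
```

## The screening problem

Internal ribosome entry sites (IRESs) recruit the ribosome cap-independently
through conserved RNA secondary and tertiary structure, not through primary
sequence. Viral IRESs fall into four structural classes, exemplified by the
intergenic-region IRES of cricket paralysis virus (group 1), the hepatitis C
virus IRES (group 2), the EMCV-type picornavirus IRES (group 3) and the
poliovirus-type IRES (group 4). Because family members diverge heavily in
sequence while keeping their paired core, sequence-level searches miss them;
`iresscan` instead screens by *structure*: fold locally, compare the predicted
structure to a group template, and threshold a normalized similarity score.

The pipeline is a three-stage screen:

1. **Local folding** (`scan_local`): windows of at most `L` nucleotides are
   folded to their minimum-energy nested structure.
2. **Structure alignment** (`align_structures`): each local candidate is
   globally aligned to each group template under an arc-annotated edit model,
   yielding the edit cost `DIST` and the alignment length `ALEN`. Because
   `DIST` grows with alignment length, the screen uses the ratio
   `R = ALEN / DIST`: template-like structure per unit edit cost. Identical
   structures have `DIST = 0` and receive an infinite `R`, which passes every
   threshold.
3. **Decision** (`decide_candidate`): a candidate is called for a group when
   `R` reaches the group's cut-off; in `r_plus_pk` mode an H-type pseudoknot
   (`detect_pseudoknot`) can rescue candidates just below the cut-off, or a
   calibrated two-feature discriminant can replace the rule.

The per-group cut-offs ship frozen at 1.61, 1.98, 1.87 and 1.58 for groups
1-4. They were derived by linear discriminant analysis of `R` distributions of
verified IRES elements against coding-sequence negatives, and
`fit_cutoff_1d` / `fit_lda_2d` re-implement that calibration for user data.
Recalibration never silently overwrites the frozen defaults; the `train` CLI
subcommand writes a new model file instead.

## Folding model

Two energy models are available, both restricted to the allowed pairs
`AU, UA, GC, CG, GU, UG` and a minimum hairpin loop of `min_loop = 3`
unpaired bases (hence the global invariant that every arc spans at least
four positions).

* `bp` scores -1 per base pair and 0 otherwise. It is base-pair maximisation
  expressed as an energy, and exists because it is exactly testable: the
  test suite checks it against exhaustive enumeration of all nested
  structures for sequences up to 14 nt.
* `nn` is a stacking-only nearest-neighbour model: pairs score 0 and each
  stack of adjacent pairs scores a tabulated stacking free energy in
  kcal/mol (packaged table `stack_energies.txt`, approximate literature
  values; unlisted stacks score 0; hairpin and internal loops score 0).
  This is deliberately not a full Turner loop model: a stacking-only model
  keeps the dynamic programming exactly self-consistent (the reported energy
  equals re-scoring the reported structure) while ranking contiguous helices
  realistically.

Ties are broken deterministically: lowest energy, then fewest pairs (so the
`nn` model never reports energy-neutral isolated pairs), then a fixed
traceback preference (the leftmost position pairs with its smallest
co-optimal partner, and stacked continuations are preferred inside a helix).
The fixed preference makes outputs platform-stable; it does not guarantee the
globally lexicographically-minimal arc set in rare co-optimal families, which
no test or downstream stage depends on.

`scan_local` interprets the published default `L = 250` as the maximum
candidate span, realized as a fold-window length: windows start at
`1, 1+step, ...` (default `step = 50`, configurable; the original tool's
true base-pair-span scan is a non-goal), a final window always covers the
tail, each window's structure is trimmed to its outermost arc, and trimmed
candidates overlapping by more than 50% of the shorter interval are
deduplicated keeping the lower energy (tie: earlier start). Windows folding
to the empty structure are suppressed — an unstructured window cannot be an
IRES candidate. The 50% overlap is measured against the shorter interval so
that a short candidate nested inside a long one counts as a duplicate.

The pipeline default is `energy = "nn"`: the stacking model recovers
contiguous designed helices much more reliably than plain pair maximisation,
which freely trades a real helix for scattered isolated pairs. `bp` remains
the reference mode for oracle testing.

## Arc-edit alignment and the R statistic

Structures are compared as arc-annotated sequences under six operations:
base match (cost 0), `base_mismatch` (1), `base_deletion` (1) on unpaired
columns; for arcs, `arc_mismatch` (1) when two aligned arcs differ in either
end base, and three dissolution operations when an arc is not aligned to an
arc: `arc_breaking` (1; both bases stay as unpaired columns),
`arc_altering` (1.5; one base is deleted), `arc_removing` (2; both bases are
deleted). The defaults follow the classical ordering
removing > altering > breaking, and published cut-offs are only meaningful
relative to a cost set, which every report header therefore records with a
checksum.

The aligner decomposes a dissolved arc's cost onto its two endpoints: a kept
endpoint charges `arc_breaking/2` plus the usual base cost, a deleted
endpoint charges `arc_removing/2`. This reproduces the three dissolution
operations exactly *iff* `arc_altering = (arc_breaking + arc_removing)/2`,
which holds for the defaults; `edit_costs()` validates the identity and
rejects other combinations rather than silently returning non-optimal
distances. Lifting the restriction would require coupling the two endpoint
fates across the alignment, which is what makes the general crossing-arc
problem hard; within the identity the alignment is solved exactly by a
decomposition over matched arc pairs (`G(x, y)` = optimal cost of aligning
arc `x` to arc `y` including their interiors, computed bottom-up over spans)
plus a prefix DP per interior window. `N` residues never pair, match only
`N`, and mismatch everything else.

`ALEN` is defined as the total number of columns of the optimal global
alignment, which makes `max(|a|,|b|) <= ALEN <= |a|+|b|` a testable
invariant. Whether the original comparison tool counted all columns or only
matched ones is not recoverable; the choice is declared here and the cut-offs
are recalibratable either way. Among co-optimal alignments the traceback
prefers arc matches, then substitutions, then deletions — deterministic,
though not a total lexicographic order over column lists.

One classical-sounding invariant is *not* true and is tested at its provable
bound instead: breaking one arc of the second structure can raise the
distance by up to `arc_breaking + 2*base_mismatch` (not just `arc_breaking`)
when the matched arcs' end bases disagreed on both sides.

## Pseudoknot detection

`detect_pseudoknot` searches the restricted H-type class: two helices
`(i+t, j-t)` and `(k+t, l-t)` with `i < k < j < l`, disjoint segments, each
at least `min_helix = 3` contiguous allowed pairs (the guard against
spurious 1-2 bp "helices"), every pair spanning at least four positions.
A configuration scores the sum of both helices' model energies and the best
configuration is reported as a pseudoknot when its score reaches
`pk_threshold`. The search enumerates all maximal complementary runs and all
inner truncations, so it is exhaustive over the class; the suite checks it
against a direct brute-force enumeration on sequences up to 30 nt.

Thresholds are mode-dependent. In `bp` mode the default is -6, i.e. at
least six pairs across the two helices (the comparison is `<=` so that the
six-pair case itself qualifies). In `nn` mode the default is -35 kcal/mol,
calibrated so that the call rate on uniform-random 250-nt windows falls in
the 10-35% band reported for negative (non-IRES) sequence sets in real
screens — a saturated detector would turn the rescue rule into a blanket
cut-off reduction. Because stability, not class membership, is what the
score measures, the detector runs only on the candidate interval the
classifier passes in, and only for candidates within `relax = 0.10` of a
cut-off (or above it); `--pk-all` forces detection everywhere.

The numeric "pseudoknot value" entering the two-feature discriminant is
ambiguous in principle (presence flag or energy), so `fit_lda_2d` accepts
either, defaulting to the flag.

## What the synthetic benchmark emulates

Real group templates are database entries; tests and examples must run
offline, so the package ships synthetic stand-ins
(`write_synthetic_templates`, frozen at seed 42 under
`inst/extdata/templates/`) with group-like architectures at realistic sizes
(152-198 nt): a compact two-domain layout with a free-standing hairpin
(CrPV-like), a long basal helix enclosing a multibranch (HCV-like), a large
branched domain (EMCV-like), and a series of separate stem-loops (PV-like).
Template realizations draw Watson-Crick pairs with a 10% GU fraction and
uniform loops; stem pairs are GC-biased (70% G:C), as in the
thermodynamically stable conserved helices of real IRES domains. The GC
bias is load-bearing: it is what makes a planted element the locally most
stable structure, so that the window-deduplication rule (keep the lower
energy) retains the planted window against a uniform-random background,
mirroring why stable IRES domains are what local folding finds in real
UTRs.

`make_synthetic_genome` plants a template realization at a seeded-random
offset in uniform-random background. The planted region keeps the
template's bases at paired positions — the family-conserved core — and
redraws loops uniformly, emulating a family member that conserves its
helices and diverges in loops. This is the regime in which the published
cut-offs are meaningful: such an element aligns to its template with mostly
matched arcs and loop-level mismatches, landing its `R` in the 2-3 range,
while random structured background aligns around 1.3-1.5.

What the generator does **not** emulate: natural base composition and
repeat structure, sequence homology beyond the paired core, tertiary
interactions, genuinely pseudoknotted templates (templates are nested by
construction; pseudoknots enter only through the detector), and the
database-scale negative sets behind the published specificity figures.
Passing the benchmark therefore shows the machinery separates
structure-conserved elements from random background at the published
operating points — not that it reproduces database-scale accuracies.

Negative controls are uniform-random genomes (`make_background_genome`) and
dinucleotide-preserving shuffles (`dinucleotide_shuffle`, an
Altschul-Erikson-style Eulerian-walk shuffle), the standard control for RNA
structure signals since folding stability depends on dinucleotide
composition.

## Calibration machinery

`fit_cutoff_1d` is Fisher LDA in one dimension: pooled within-class
variance, priors proportional to class sizes, boundary where the two class
discriminant scores are equal — the mean midpoint for balanced classes,
shifted by `s2 * log(n_neg/n_pos) / (mu_pos - mu_neg)` otherwise. Infinite
(perfect-match) scores are excluded from moment estimation. `fit_lda_2d` is
standard two-class LDA on `(R, pk)` with a warning fallback to the 1-D rule
when the pooled covariance is near-singular. Both are closed-form
implementations; the test suite cross-checks them against an independent
LDA implementation. The "accuracy rate" summary is implemented as the
arithmetic mean of sensitivity and specificity (balanced accuracy); that
this identity reproduces every published per-group accuracy from its
printed sensitivity/specificity pair is itself a tested property. Printed
percentages use half-up rounding to two decimals (`round()`'s half-even
rule disagrees with printed tables at values like 90.795).

## Problem sizes and numerical choices

The test suite and acceptance script use: exhaustive-enumeration folding
oracle on 200 sequences of length 5-14; exhaustive alignment oracle on 100
structure pairs of length 2-8; exhaustive pseudoknot oracle on 100
sequences of length 10-30; calibration recovery with 500 samples per class;
end-to-end planted-template recovery over 20 seeds on 800-nt genomes with
paired dinucleotide-shuffled controls; and a benchmark of 20 planted
positives plus 20 background negatives per group (the in-suite copy uses 6+6
per group). Floating-point ties in all DPs are resolved with an absolute
1e-9 tolerance; energies are plain doubles; determinism contracts
(`--reproducible` reports, seeded generators) are byte-exact.

Degenerate inputs: empty sequences fold to the empty structure at energy 0
and produce empty scans; empty structures align by pure deletion; records
longer than `max_input_len` (default 5000 nt, the web-service cap) are
skipped with a warning while the scan continues; a missing template group
is skipped with a warning; `evaluate_groups` marks single-class groups as
not evaluable rather than dividing by zero.

## Known limitations

* The folding stage approximates a true local-structure scan by stepped
  fixed windows; structures spanning a window boundary beyond `L` are
  invisible by design (`L` caps the candidate span).
* The `nn` model omits loop penalties; its absolute energies are not
  thermodynamic free energies and should only be ranked.
* Edit costs outside the half-sum family are rejected rather than solved.
* Alignment requires nested inputs; pseudoknotted candidates contribute
  through the separate detector feature only.
* The published database-scale accuracies depend on curated positive and
  negative collections that cannot be reproduced offline; the synthetic
  benchmark is a controlled stand-in, not a replication.
* Template files ship with the real standards' accession strings as opaque
  metadata only (the historical record lists variant accessions for two
  groups; the registry takes no side).
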