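---
title: "Molecule-resolved variant calling with structured UMIs: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecule-resolved variant calling with structured UMIs: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umivar)
```

## The model

An amplicon experiment with molecular barcoding has three layers, and
`umivar` models all three explicitly.

**Molecules.** A population of `n_molecules` original DNA molecules is
drawn from a small set of alleles with fixed frequencies: typically a
wild-type allele, an engineered spike-in SNV at 1e-2 to 1e-4, and
optionally large deletion/insertion/inversion alleles standing in for
repair outcomes. On top of its allele, each molecule independently
acquires somatic SNVs at a per-base rate of `somatic_snv_per_mb * 1e-6`,
placed only at positions that survive the allele's indels so that every
true edit has a reference coordinate.

**Barcoding and amplification.** Each molecule is tagged with a UMI drawn
*without replacement* from the structured-UMI space (the pattern's N
positions vary, fixed bases are constant), so simulated UMIs are
collision-free by construction; a `NNNNTGNNNN` pattern gives
4^8 = 65,536 distinct tags. Amplification is modeled as a *single*
substitution pass over the barcoded first copy at `pcr_per_base`
(default 6e-6/168 per base, a high-fidelity polymerase budget of about 6
errors per million 168-bp molecules). This is deliberate: the first copy
is the one error mode consensus cannot remove, because its errors
propagate to every read of the group, whereas later-cycle errors are
diluted far below any consensus threshold. Modeling the full amplification
tree would add cost without changing what the caller can see. A first-copy
error inside the UMI region itself is allowed and simply fragments the
group — the honest consequence of the mechanism.

**Sequencing.** Reads per molecule follow a negative binomial
(default mean 8, dispersion 3, matching typical per-group medians of 6–10
reads); each read receives independent per-base substitutions, insertions
and deletions. Platform archetypes: `nanopore` (sub 0.05, ins 0.03, del
0.04, full-length reads, strand Bernoulli(0.5)), `pacbio` (0.002 each),
`illumina` (sub 0.001, 150-bp paired ends). The Nanopore numbers are
calibration choices for a "raw long read" regime, not measurements.

## Why the pipeline is shaped this way

**Error-tolerant primer search.** Raw long reads carry indels at percent
rates, so a Hamming-only primer match would reject most reads (an indel
inside a 22-mer shifts everything downstream). The extractor therefore
finds the universal primer within a window of `1.5 * (primer + UMI)` bases
from each read end by edit distance (substitutions and indels both count
toward `max_primer_mismatches`, default 3 for long reads, 1 recommended
for short reads). The candidate UMI is the pattern-length stretch right
after the primer; the fixed pattern bases must match *exactly*. That
exactness is the point of a structured UMI: an indel upstream shifts the
frame and almost surely breaks the fixed bases, so structure acts as a
free quality check on the whole primer+UMI region.

**Exact-string grouping, no mismatch merging.** Misread UMIs scatter reads
into spurious low-count groups, which the `min_reads = 5` threshold
removes wholesale. Merging Hamming neighbours would recover some of those
reads but risks fusing two *true* molecules into one group — the one error
that consensus calling cannot undo. With a 65,536-tag space and hundreds
of molecules, true Hamming-1 pairs are rare but not negligible; we accept
the read loss instead of the fusion risk.

**Alignment: full DP, two-piece gaps, saturating long-gap cost.** At
amplicon scale (≤ ~8 kb) a full O(|q|·|r|) dynamic program is affordable,
so no seeding heuristics are used. Gaps cost
`min(gap_open + L*gap_extend, long_gap_open + L*long_gap_extend)` with
defaults 4+2L vs 24+0L. The long-gap extension of **zero** is a
considered choice: both query ends may be soft-clipped (residual adapter),
and any per-base long-gap charge eventually makes *clipping a flank*
cheaper than paying for a real deletion — a 5.5-kb deletion with a 0.6-kb
flank is exactly the kind of event that would silently vanish. With a
saturating cost, a contiguous deletion of any length survives as one `D`
run, while the affine short-gap piece still governs events under ~10 bp.
The mappability floor is `score >= 0.3 * match * read_length`; reads below
it are dropped as unmappable.

**Inversions by split realignment.** An inverted segment has no CIGAR
signature; it garbage-aligns (dense mismatches or a long soft clip). The
caller scans the primary alignment for internal low-identity stretches and
long clips (≥ 31 bp), realigns each candidate against the reverse
complement of the reference, and reports an inversion when the
minus-strand placement nests between plus-strand flank alignments of the
same read. Indel events inside a detected inversion interval are artifacts
of the garbage primary alignment and are suppressed.

**Consensus thresholds.** `consensus_fraction = 0.75` means a 5-read group
needs at least 4 concordant reads for an SNV. Both the callability gate
and the consensus denominator use *spanning* reads — those contributing a
base or a deletion at the position — rather than base calls alone. Gating
on base depth would let a single deletion error black out a position in a
5-read group about one time in five (per-base deletion error ~0.04),
destroying sensitivity exactly where molecule counts are scarce; while a
base-call denominator would let concordant substitution errors reach the
consensus fraction at positions thinned by deletions (three same-base
errors out of four remaining bases is 0.75). Counting a deletion read as
evidence against the SNV closes both failure modes at once. With per-base substitution
error e ≈ 0.05, the chance that 4 of 5 reads independently show the *same*
wrong base at the same position is of order 1e-6 per position, keeping the
expected spurious-SNV count well below one across hundreds of groups and a
~170-bp amplicon — consistent with zero observed spurious calls in our
seeded runs. SVs use a separate `sv_support_fraction = 0.6` because
breakpoint placement jitters between reads: the requirement is a matching
event (same kind, breakpoints within `breakpoint_tol = 10` bp) in 60% of
the group's reads, with per-read medians reported as the breakpoints. The
SV/small-indel boundary is at 31 bp (SVs are events > 30 bp); small indels
are left-aligned and called with the SNV consensus rule against the count
of reads spanning the position.

**Group filtering.** Three replacements for "low-confidence group"
heuristics, each aimed at a concrete failure mode: (1) mean
read-to-consensus identity < 0.7 drops groups of junk reads; (2) a UMI
collision (two molecules behind one tag) shows up as ≥ 3 near-even
conflicting positions whose minority reads are *the same subset* — random
errors don't repeat a subset, two genuine haplotypes do; (3) an SV
supported by an ambivalent fraction of reads (between `1 - 0.6` and
`0.6`, with at least two reads on each side) indicates a mixed group
rather than a variant. All three are configurable.

**Population statistics.** A variant's VAF is `supporting groups / total
eligible groups` — molecule counting, not read counting — with a Wilson
95% interval. The detection-power calculator inverts
`1 - (1-f)^n >= P` exactly: for f = 0.01 and P = 0.9 it returns 230 (the
commonly quoted 229 satisfies the bound only after rounding;
`1 - 0.99^229 = 0.8999`). Somatic load is
`1e6 * n_snvs / (n_groups * surveyed_length)`, with the surveyed length
supplied by the user because primer-covered bases (synthetic sequence)
must be excluded and primer layouts vary per design.

## What the simulator does and does not emulate

It emulates the parts of the data that drive the method's error budget:
per-molecule allele identity, UMI uniqueness and structure, first-copy PCR
error, per-read platform error including indels, strand mixture, paired
short reads, and read-count dispersion. Passing tests on simulated data
therefore demonstrate the *consensus machinery* — extraction, grouping,
alignment representation of large events, thresholds, merging, VAF
arithmetic — under realistic error rates.

It does **not** emulate homopolymer-dependent error (Nanopore's dominant
context effect), base-quality variation, chimera/template-switching
artifacts, or UMI cross-contamination between molecules. Results on real
data will differ most where those mechanisms matter: homopolymer-adjacent
small indels and chimera-driven false SVs. The group filter's ambivalence
rule is the main line of defense against the latter and is deliberately
conservative.

## Problem sizes used in validation

The automated checks run at desk scale, sized to preserve the relevant
regimes rather than the full sequencing throughput: a 168-bp amplicon with
~15,000 Nanopore-like reads funnels to ~300 eligible UMI groups (median 7
reads/group) for the 1:100 detection runs, repeated over 20 seeds; the
zero-error identity check uses a 2-kb amplicon with five allele classes
including a 600-bp deletion, a 120-bp insertion and a 200-bp inversion;
VAF-recovery runs use 600 and 5,000 molecules for f = 1e-2 and 1e-3; the
pooled-versus-grouped contrast uses 20,000 molecules with exactly two
spike-in copies (f = 1e-4). The n_molecules = 600 / mean-25-reads choice
for the noisy runs comes from the extraction arithmetic: with ~12%
per-base error, a read retains a perfectly read UMI with probability
~0.2, so 25 reads/molecule yields ~5 exact-UMI reads — reproducing the
observed funnel shape (raw reads → ~45% with UMI → ~300 eligible groups)
of a typical MinION amplicon run.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; 1-based only in VCF.
- DP tie-breaks prefer diagonal moves, then reference gaps, then query
  gaps; gap-state ties prefer extension. Ties between strands report `+`.
- `min_groups_for_detection` verifies the ceiling against both boundary
  inequalities to guard floating-point edge cases.
- Empty inputs produce empty-but-valid outputs (header-only VCF, zeroed
  manifest) rather than errors; an all-unmapped group is dropped with
  `pass_filter = FALSE`.
- Insertion merge keys use position and length (tolerance 10 bp); the
  reported insertion sequence is the member read's sequence of median
  length.
- Known limitation: recurrence clustering is single-linkage, so a dense
  ladder of SVs spaced just under the tolerance could chain into one
  cluster; with `breakpoint_tol = 10` and kilobase-scale events this has
  not been observed in testing.

## Session info

```{r}
sessionInfo()
```
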