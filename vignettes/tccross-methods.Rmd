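---
title: "Methods: cross-classification comparison of transporter families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-classification comparison of transporter families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tccross)
```

## The problem

Transport proteins are classified twice over: once by a transporter-specific
hierarchy (five-level TC numbers — class, subclass, family, subfamily,
transport system — with superfamily groupings layered on top), and once by a
general domain-family system in which profile models match protein regions
and homologous families are grouped into clans. The two systems disagree in
instructive ways: a family may exist in one and not the other, one family may
split across many of the other system's subfamilies, and unknown-function
domain families (DUFs/UPFs) may match proteins the transporter database has
already characterized. `tccross` implements the comparison machinery: finding
proteins classified in one system but invisible to the other, visualizing
family-level match structure, mapping superfamilies to clans, screening
candidate entries, and testing homology claims with a shuffle-based
Monte-Carlo score criterion.

Everything runs on plain TSV/FASTA interfaces, and a seeded synthetic
generator emits whole universes with planted ground truth, so every procedure
can be validated end to end without downloading either database.

## Missing-family discovery

`find_missing()` keeps assignments in a configurable set of TC classes
(default 1–5 and 8; class 9 holds systems of unknown mechanism and is
excluded), selects sequences with zero domain hits, and reduces redundancy to
one representative per four-level TC prefix. The representative rule — longest
sequence, ties broken by the lexicographically smallest id — is a
reproducibility choice; any deterministic rule serves, since the prefix
group, not the individual protein, is the unit of interest.

`expand_and_retain()` hands each representative to a search backend and
retains seeds whose match set reaches the retain threshold (default 100
matches after 2 iterations, inclusive, counting the query when present).
The backend is a pluggable contract `(query_id, refdb, iterations) -> ids`
so a real iterative profile search can be wired in. The shipped stand-in is
a transitive alignment search: a query matches a reference when their
overlap (ends-free) alignment score reaches 0.4 of the smaller self-score,
and each iteration re-queries with the newly matched set. Ends-free scoring
is the database-search convention and keeps tandem-repeat sequences from
being punished for their unaligned second unit. The 0.4 threshold sits in
the middle of the empirical gap between within-family score fractions
(≥ 0.63 on the default fixtures) and cross-family ones (≤ 0.25).

`rescan_iteration()` emulates rebuilding the model library after new
families are created: each member of a new family gains a full-length hit at
a sentinel E-value of 1e-30 (below every threshold used anywhere in the
toolkit), and the missing list is recomputed. Because a multi-subunit system
can hide a nonhomologous subunit behind a shared four-level prefix, one
round is not enough; iterating converges to a fixed point, and the missing
list is non-increasing along the way.

`match_unknown_function()` lists every DUF/UPF-flagged family that hits an
assigned sequence, with the TC families it touches — the cases where one
system already has the functional annotation the other lacks.

## The subclass match matrix

`build_matrix()` crosses the TC families (level 3) of one subclass with the
domain families that match their sequences at an E-value threshold (default
1e-5, inclusive). A cell holds the average number of hits per sequence:
total hits of that domain family over the TC family's sequences — counting
multiple hits per sequence, so tandem repeats can push the value above 1 —
divided by the number of sequences in the TC family. Cells are shaded on a
10-step light-to-dark ramp with `bin = min(floor(10 * fraction), 9)`;
values of 1 or more land in the top (0.9–1.0) bin. TC families with no
match keep an all-empty row, because an unrepresented family is itself a
finding.

The SVG written by `write_svg()` carries machine-readable attributes on
every cell (`data-row`, `data-col`, `data-fraction` at full precision,
`data-bin`) plus the complete row/column label lists on the root element.
`read_svg()` reconstructs the matrix from those attributes rather than from
geometry, which makes the hand-edit workflow robust: delete cells in a
vector editor, re-analyze, and exactly those cells are gone. Geometric
positions still follow row/column order, and pattern reports carry the SVG
x/y of each finding.

`find_patterns()` reports isolated cells and multi-hit rows/columns. The
isolation rule is read as "alone in its whole row and column" — a candidate
one-to-one family correspondence; the phrase could also be read as merely
lacking orthogonally adjacent neighbors, so an `"adjacent"` mode is
available behind a flag for dense matrices.

`repfam_view()` overlays domain hits on transmembrane topology: for each
hit, the number of predicted segments lying fully inside the hit envelope,
and per domain family the mean segments per hit. Containment (not partial
overlap) is the counting rule — conservative and stated in the report — since
partial-overlap semantics are not defined by the procedure this view
supports.

## Clan correspondence and candidate screening

`superfamily_to_clans()` collects the domain families matching any sequence
of a superfamily's member TC families (per-hit E-value cutoff, default
1e-25) and takes the most frequent clan among the clan-labeled matched
families. The dominant fraction is computed over labeled families only;
clanless matched families are reported as outliers and, when the dominant
fraction reaches the majority threshold (0.6, inclusive),
`propose_clan_changes()` emits one proposal per outlier — move to, or join,
the dominant clan. Ties produce no dominant clan and no proposals rather
than an arbitrary winner.

The candidate screen (`candidate_pipeline()`) looks in the opposite
direction: clans in which strictly more than half of the registered
families hit the superfamily (the two majority rules — ≥ 0.6 for the clan
table, > 0.5 here — are deliberately kept distinct), then families of those
clans that hit no assigned sequence at all. Each such family's
representative is aligned against every assigned sequence; the best match
(highest score, ties by smaller E-value then smaller id, so results are
order-invariant) is kept, and the verdict requires the candidate's
transmembrane-segment count to be within ±1 of its best match's and the
alignment E-value to fall inside [1e-7, 0.1], both ends inclusive. The
lower bound intentionally rejects near-identical matches: the screen hunts
distant relatives that would constitute genuinely new subfamilies. E-values
come from a Karlin–Altschul-style conversion of the raw alignment score
(gapped BLOSUM62 parameters lambda = 0.267, K = 0.041, bit scores floored
at 0) against the total residue count of the assigned database. On
desk-scale fixtures any planted true relative scores far below the 1e-7
bound, so the window's discriminating behavior is exercised against
synthesized evidence via `candidate_verdict()`, while the pipeline tests
assert that reported verdicts equal the rule applied to the reported
evidence trail.

## The homology criterion

`shuffle_z()` implements the significance rule used to justify superfamily
links: align the pair globally, realign one sequence against `n` independent
uniform permutations of the other (default 1000, the minimum for a
reportable verdict; fewer only in test mode), and express the real score in
standard deviations of that null. The verdict requires

* `z > 14` — strictly; a borderline score of 13.7 SD fails,
* at least 60 aligned residue pairs (gap columns excluded — the stricter of
  the two readings of "alignment length"), and
* at least 2 transmembrane segments aligned at equivalent positions.

Alignment is global Needleman–Wunsch/Gotoh with affine gaps (BLOSUM62,
open 8, extend 2, a gap of length L costing `open + L * extend`, end gaps
penalized), computed in compiled code with a fixed traceback tie preference
(diagonal, then up, then left), so alignments are deterministic. Ambiguity
codes map to `X`, which scores 0 against everything. Segment pairing
(`map_tms_pairs()`) counts a pair when the jointly-in-segment alignment
columns cover at least half the shorter segment, each segment used at most
once, greedily left to right.

Only one sequence is shuffled, preserving the other's composition exactly;
which one should not matter, and a test asserts the two z-scores agree
within Monte-Carlo error (|Δz| < 1.5 at n = 1000). Degenerate nulls (zero
variance, e.g. homopolymers) yield an explicitly indeterminate verdict
rather than an infinite z. Every verdict records its seed and shuffle
count; the shuffles use R's own RNG under a locally-set seed, and the
caller's RNG state is restored afterwards.

## The synthetic generator

`generate_fixture()` emits a universe of superfamilies × families ×
sequences (default 3 × 5 × 20), each family descended from a fresh ancestor
with a planted transmembrane architecture: 4 segments of 21 residues,
loops of 15–30 residues. Transmembrane stretches are drawn from strongly
hydrophobic residues {L, I, V, F} and loops from a ten-letter mildly
hydrophilic set {G, S, T, P, N, Q, Y, W, A, M} (mean Kyte–Doolittle ≈ −0.9).
These alphabets were chosen once, on hydropathy grounds: they make planted
topology recoverable by the standard sliding-window predictor (window 19,
threshold 1.6, minimum run 15, merge gap < 5) for every default-scale
sequence, and they give clean alignment-score contrast between common
descent and mere architectural similarity. Mutations resample from the
regional alphabet — transmembrane positions stay hydrophobic under
substitution, as in real membrane proteins.

Per-sequence features are planted independently: 10% of sequences are
orphans (TC number, no hits), 10% are tandem repeats (two domain units, two
hits, doubled segment counts), 20% of families carry DUF-style names, 10%
of families are registered under a wrong clan. Hit E-values follow the
deterministic law `10^(-30 * (1 - d))` in the realized divergence `d`, so
E-value filters bite meaningfully. The manifest records every planted fact
— orphan ids, true and registered clans, segment coordinates, per-sequence
divergence, candidate architecture deltas — and is the oracle every pipeline
test compares against. Indels are off by default (they complicate segment
bookkeeping without changing what the procedures consume); an indel mode
with loop-only indels exists for stress-testing the aligner.

What the generator does not emulate: real substitution processes (no
rate heterogeneity, no indel realism), profile-model search statistics
(hits are planted, not found), gathering thresholds, multi-component
systems with nonhomologous subunits sharing a TC number (representable in
the assignment table, not auto-generated), and the scale of real databases.
Passing tests therefore demonstrate that the procedures compute what they
claim on inputs with known truth — not that thresholds tuned for real data
keep their operating characteristics there.

## Problem sizes and reproducibility

The test suite and the acceptance script run the default 300-sequence
bundle, 100 + 100 sequence pairs at 1000 shuffles for the discrimination
check, 200 random matrices for the pattern oracle, and 50 random pairs for
the alignment oracle — sizes chosen so the whole suite completes in a couple
of minutes on one core while keeping every comparison against a planted or
brute-force oracle exact. The expansion stage is exercised at the canonical
retain threshold 100 (where the 20-member desk-scale families correctly
retain nothing) and at a fixture-scaled threshold 10 (where every planted
family qualifies); both expectations come from the manifest. All
randomness flows from explicit integer seeds; generation and verdicts
restore the caller's RNG state.

## Known limitations

* The stand-in search backend is transitive pairwise alignment, not a
  profile method; its 0.4 score-fraction threshold is calibrated to the
  generator's alphabets and will need recalibration for natural sequences.
* Karlin–Altschul parameters are fixed constants, not fitted to the scoring
  system per query; E-values are comparable within a run, approximate in
  absolute terms.
* The hydropathy predictor is a windowed stand-in: adequate for planted
  topologies and for counting, far from a real topology HMM on natural
  proteins; supplied annotations always take precedence.
* Isolation analysis treats the matrix as binary filled/empty; shading is
  not weighted in pattern detection.
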