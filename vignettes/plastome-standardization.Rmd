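---
title: "Standardizing and annotating plastid genomes with plastr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing and annotating plastid genomes with plastr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The plastome of most land plants is a circular molecule of roughly
120-170 kb with a conserved quadripartite organization: a large
single-copy region (LSC), a small single-copy region (SSC), and two
inverted-repeat copies (IRb, IRa) separating them.  De novo organelle
assemblers return this circle linearized at an arbitrary position, on an
arbitrary strand, and — because the two flip-flop isomers differing in SSC
orientation co-exist in plant cells — often as two candidate sequences.
Downstream work (annotation transfer, whole-plastome alignment,
submission) needs one canonical linear form: starting at LSC base 1, in
region order LSC-IRb-SSC-IRa, oriented like a chosen reference.

plastr implements that post-assembly toolchain: structure detection,
canonicalization, isomer selection, read-based correction of ambiguous
bases, reference-based annotation transfer with a multi-round identity
schedule, internal-stop QC, and GenBank / NCBI feature-table output, with
batch orchestration over many samples.  A synthetic plastome generator
with full ground truth makes every stage testable at desk scale.

## Inverted-repeat detection

`find_inverted_repeats()` compares the genome with its own reverse
complement.  The circle is handled by doubling the sequence and reducing
all coordinates modulo the genome length, the simplest correct treatment
of repeats spanning the origin.  Exact k-mer seeds between the doubled
forward strand and the reverse complement are grouped by anti-diagonal
and extended without gaps.

Extension scoring deserves a note.  A naive rule — "extend while the
running identity stays above the threshold" — lets a long, nearly exact
repeat bank a mismatch budget that can then carry the boundary tens of
bases into the single-copy regions (a 500 bp repeat at threshold 0.95 has
~20 spare mismatches when it reaches its true end).  plastr instead
scores matches +1 and mismatches -2 with an X-drop of 20 and reports the
*rightmost maximal-score* endpoint, so a boundary never ends in a
net-negative tail: random sequence past the true junction almost surely
drifts the score down, and a mutation within the last couple of bases of
a repeat costs at most that many bases of boundary precision.  The
reported pair must still satisfy the overall identity threshold, and with
`min_identity = 1` extension simply stops at the first mismatch.
Self-palindromic hits (copies overlapping on the circle) are discarded —
AT-rich plastome sequence is full of short spurious palindromes — and
duplicate discoveries from the doubled coordinates are collapsed.

Defaults are `min_length = 1000` and `min_identity = 0.99`: real plastome
IRs are 10-30 kb and near-identical, so anything shorter is noise.  The
seed length k defaults to 17 for genomes of 10 kb and above and scales
down (never above `min_length`) for the kilobase-scale test genomes.  The
test suite verifies the finder against an exhaustive substring-pair
oracle on random sequences.

## Quadripartite resolution and canonicalization

`resolve_quadripartite()` takes the longest inverted pair as the IRs; the
two arcs between the copies are the single-copy regions, the longer arc
is the LSC, and IRb is defined as the copy immediately clockwise of the
LSC, giving the circular order LSC-IRb-SSC-IRa.  The four intervals tile
the circle exactly.  Two degenerate cases are explicit conditions: no
qualifying repeat (`plastr_no_quadripartite`, e.g. IR-reduced conifers)
and equal-length arcs, which only a reference can disambiguate
(`plastr_ambiguous_structure`; with a reference, the arc more similar to
the reference LSC wins).

`canonicalize()` rotates the molecule so the string starts at LSC base 1;
between the two strand choices it keeps the one whose LSC has the higher
global-alignment identity to the reference LSC, and then flips the SSC in
place when its reverse complement matches the reference SSC better.  The
SSC flip touches exactly the SSC interval — junction bases belong to the
IRs.  Identity throughout is matching columns over alignment columns from
a unit-cost global alignment; ambiguity codes match only themselves, so
Ns never inflate a decision.  Ties keep the forward strand and the
unflipped SSC, which together with the deterministic repeat search makes
canonicalization idempotent and a class function: all sixteen isomer
transformations of a genome (rotations x strand flip x SSC flip)
canonicalize to one byte string.

When a structure cannot be resolved (no IR on either the target or the
reference), the pipeline falls back to whole-molecule orientation: it
finds the best-matching position of the reference's leading sequence on
either strand, rotates there, and records a warning.  Annotation still
proceeds.

## Candidate selection and ambiguous-base correction

When the assembler emits two candidates (SSC flip-flop isomers), each is
structure-resolved and the candidate whose native SSC orientation has the
higher forward identity to the reference SSC is kept.  More than two
candidates abort the sample — with an explicit condition rather than a
guess, mirroring the refusal to choose among ambiguous assemblies.

Ambiguous bases (any non-ACGT code) are corrected by read voting: for
each such position the k-mer flank immediately left and right (k = 21) is
matched exactly against every read on both strands, each anchored read
contributes the base it places at the position, votes from both flanks
are pooled, and the base is replaced only when at least `min_depth = 5`
votes agree at a `min_majority = 0.7` modal fraction.  Anything less
leaves the base unchanged with a warning in the report.  Positions
already in ACGT are never touched, and qualities are carried but not
used — the decision is a base-count vote.  The defaults are deliberately
conservative: at 30x coverage a true base collects dozens of votes, so
depth 5 / majority 0.7 only blocks genuinely conflicted positions (the
test suite pins a constructed 60/40 split as "leave unchanged").

Per sample the order is: select candidate, correct ambiguous bases,
resolve structure, canonicalize.  Correcting before canonicalization
keeps read-voting coordinates on the assembler's own sequence, so the
provenance log is stable; the final sequence is the same either way.

## Annotation transfer

`extract_reference_features()` turns each gene-level reference feature
into a template: the CDS/tRNA/rRNA segment structure in transcription
order, strand-applied segment sequences, qualifiers (gene, product,
codon_start, transl_table and anything else present are carried through),
and a trans-splicing flag for `order()` locations or mixed-strand
segments (the rps12 case).  Each IR-duplicated gene copy is its own
template, so both copies annotate independently.

`map_features()` searches each segment independently against the doubled
target on both strands, so hits wrap the origin.  Rounds of decreasing
identity are applied in order to still-unmapped templates — by default
(0.98 identity, 1.00 coverage), (0.90, 0.95), (0.80, 0.90) — a
configurable schedule in which later rounds rescue diverged features.
Hit discovery uses approximate pattern matching with an indel-tolerant
mismatch budget of `floor((1 - identity_r) * length)`, refined by a
unit-cost alignment that is global on the query, so boundaries come from
alignment ends and coverage is complete.  Among competing hits
(typically the two IR copies of a duplicated gene) the highest
identity x coverage wins; hits within 0.02 identity are treated as tied —
differences that small are mutation noise, not signal — and resolved by
consistency with the rotation offset and orientation implied by the
unambiguously mapped templates.  Mapping is per segment first because
multi-exon and trans-spliced genes move as parts, not blocks; a
consistency check on the assembled segment set guards the result.

`build_annotation()` emits per template a gene feature, the CDS/tRNA/rRNA
feature with its `join()`/`complement()`/`order()` location, exon
features (for multi-segment templates) and intron features derived as the
gaps between consecutive same-strand exons, sorted by coordinate.
Introns plus exons tile each feature's span exactly; trans-spliced
features keep reference segment order in an `order()` location and derive
no intron across strands.

`qc_internal_stops()` reassembles each CDS in transcription order,
honors `codon_start`, translates with the plastid/bacterial code
(table 11), and flags internal stops, lengths not divisible by three, and
missing terminal stops.  Flags are warnings, never edits: an internal
stop usually marks a boundary worth inspecting, and silent "fixes" are
exactly the failure mode this check exists to expose.

## The synthetic generator

`generate_plastome()` builds a canonical-order genome from uniform random
single-copy regions and one random IR planted forward as IRb and
reverse-complemented as IRa, then writes in a fixed, named gene set:
`toyA` (single-exon CDS), `toyB` (two-exon CDS with an intron),
`toyRps12` (trans-spliced CDS: one segment in the LSC on plus, one in the
SSC on minus), `toyTrn` (tRNA) and `toyIR` (CDS duplicated in both IRs,
mirrored).  All CDSs are clean ORFs under table 11, so the untouched
reference carries zero QC flags and a single planted in-frame stop is
exactly recoverable.  Region lengths are free above the minimums needed
to host the genes; the suite uses kilobase-scale genomes (LSC 2-4 kb, IR
0.3-0.8 kb, SSC 0.5-1 kb) so whole-pipeline properties run in seconds,
and full-scale generation remains possible.

One generator guarantee matters for exact testing: the two bases at each
single-copy region end are pinned to `A`, so extension of the planted IR
across any junction meets guaranteed mismatches and the planted pair is
the *unique maximal* inverted repeat.  Without this, a correct detector
would — with probability 1/4 per junction — legitimately report a repeat
one base longer than planted, and "exact boundary recovery" would be
unattainable by construction rather than by defect.

`transform_plastome()` produces the isomers (rotation, strand flip, SSC
flip); `mutate_plastome()` plants substitutions at an exact count
(`round(rate x eligible)`) drawn uniformly outside a configurable window
around feature-segment ends, optionally restricted to a region — exact
counts make divergence-threshold behaviour reproducible for any seed;
`inject_ambiguity()` replaces recorded positions with N;
`simulate_reads()` draws uniform fragments on the circle (insert 300 bp,
configurable) and emits proper FR pairs with optional substitution
errors.  Every generator is a pure function of its arguments including
the seed.

What the generator does not emulate — realistic base composition and
codon usage, indels, sequencing error profiles, coverage bias, repeat
families beyond the IR — bounds what green tests mean: they demonstrate
algorithmic correctness on the structural features of plastomes, not
robustness to every artifact of real sequencing data.  Real-data behaviour
is additionally constrained by conservative defaults (IR length and
identity floors, correction depth/majority) rather than by the test suite.

## Pipeline and batch behaviour

`run_sample()` creates `<prefix>/{logs,assembly,standardized,annotation}`,
runs candidates -> select -> correct -> structure -> canonicalize ->
annotate -> GenBank/tbl, writes one log per stage whose last line is
`SUCCESS` or `ERROR: ...`, and checks the final length against the
expected size range (a warning, not a failure).  Pre-assembled mode is
first class, so the core algorithms never require external binaries; the
fastp/assembler adapters shell out only when reads mode is configured
(trimmer subsampling defaults to 10,000,000 reads; assembler config
defaults: type chloro, k-mer 29, read length 151, insert 300,
paired-end).  `run_batch()` isolates failures per sample and marks a
sample complete only when every declared output exists and is non-empty.
No pipeline stage uses unseeded randomness, so a re-run reproduces
byte-identical outputs — down to a constant-format LOCUS line with no
embedded date.

The batch file dialect (whitespace-separated fields, `#` comments, one
sample per line) and the per-sample directory layout are this package's
own definitions, documented in `?parse_batch_file` and `?run_sample`.

## Numerical choices, in one place

* Coordinates are 0-based half-open internally; conversion to 1-based
  inclusive happens only in readers/writers.  One conversion boundary,
  no off-by-one drift.
* Repeat extension: match +1, mismatch -2, X-drop 20, rightmost argmax;
  `min_identity = 1` short-circuits to first mismatch.
* Identity metric everywhere: matching columns / alignment columns,
  unit-cost global alignment; ambiguity codes match nothing but
  themselves.
* Mapping near-tie tolerance: 0.02 identity; ties resolved by consensus
  rotation offset and orientation, then coordinate.
* Correction: k = 21, min_depth = 5, min_majority = 0.7; both flanks'
  votes pooled.
* Translation: NCBI table 11, `codon_start` honored.
* Test-scale structure parameters: `min_length = 100`, `min_identity = 1`
  for exact synthetic IRs, 0.95 when one IR copy carries 1% mutations.

## Limitations

* Direct (tandem) repeats are not searched; only inverted pairs.
* Linear molecules and IR-less plastomes have no quadripartite structure;
  they take the whole-molecule orientation fallback and are annotated
  without region provenance.
* The repeat finder's gapless extension will split a repeat containing an
  indel into two pairs; plastome IR pairs are effectively indel-free at
  the scales that matter here.
* Annotation transfer is reference-bound: genes absent from the reference
  are never discovered (no ab initio prediction, no tRNA scanning), and a
  reference mis-annotation transfers faithfully, flagged only if it
  breaks the reading frame.
* The feature table writer emits gene/CDS/tRNA/rRNA only; submission
  pipelines derive introns implicitly.
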