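---
title: "Reference-guided anchoring and its artifacts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided anchoring and its artifacts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromanchor)
```

## The procedure and its assumptions

`chromanchor` models the reference-guided stage of chromosome-level genome
assembly: scaffolds produced by a de-novo assembler are ordered, oriented
and concatenated into pseudo-chromosomes by alignment to a finished
reference genome. The package's thesis object of study is the bias this
stage introduces — anchored assemblies inherit the reference's chromosome
structure wherever scaffolds do not constrain it — together with the
breakpoint-provenance evidence that separates real rearrangements from
placement artifacts.

The anchoring model is deliberately minimal and fully specified:

1. **Seeds.** Maximal exact matches (MEMs) of length at least
   `min_seed_len` between scaffold and reference, on both strands, never
   spanning an N. The default `min_seed_len = 65` reads "seeds longer than
   64 bp" strictly. Seeds are anchored by unique probes: a seed survives
   the repeat filter iff at least one of its constituent probes occurs at
   most `max_occ` times in the reference (default 1). Unique anchors make
   chains placement-informative; the filter is configurable because the
   right setting depends on genome repetitiveness.
2. **Chains.** Per (reference sequence, strand), the maximum-score
   monotonic path of seeds — strictly increasing query starts, reference
   starts increasing (`+`) or decreasing (`-`) — by weighted
   longest-increasing-subsequence dynamic programming. The score is the
   summed seed lengths with the larger of the query and reference overlap
   between consecutive members counted once, keeping the score comparable
   to matched bases on either genome; the reference-side trimming is what
   prevents a duplicated segment from being absorbed into the syntenic
   backbone. Greedy extraction (best chain removed, DP repeated) assigns
   each seed to at most one chain. Tie-breaks everywhere are
   (higher score, query id, smaller reference start), for reproducibility.
   A gap penalty hook exists but defaults to 0 (pure monotonic paths).
3. **Chimera splitting.** A scaffold with two or more *significant* chains
   on different chromosomes, or on one chromosome at reference distance
   beyond `max(dist_base, 2 × scaffold length)`, is split at the midpoint
   of the query interval between the conflicting chains, snapped to the
   start of the nearest N-run inside that interval (an assembly gap is the
   natural break point). Significance is
   `score ≥ max(sig_abs, sig_frac × best score of the scaffold)` with
   defaults `sig_abs = 5 × min_seed_len` (absolute noise floor) and
   `sig_frac = 0.25` (captures genuinely competing locations). Parts are
   renamed `<id>-1`, `<id>-2`, … in coordinate order and re-chained.
4. **Placement.** All significant chains ranked by score are visited
   greedily; a chain is accepted when its scaffold is still unplaced and
   its reference span overlaps already-occupied spans by at most
   `ovl_frac = 0.2` of its own length (chain envelopes are fuzzy at the
   ends, so strict vacancy over-rejects). One placement per scaffold:
   scaffolds are physical units, and implicit multi-placement is forbidden
   except through explicit chimera splits.
5. **Emission.** Per reference chromosome, placed scaffolds are sorted by
   the integer median of their chain's seed reference midpoints (ties by
   scaffold id), `-` placements reverse-complemented, and joined with
   `gap_len = 100` bp N runs. Object coordinates are cumulative, so
   pseudo-chromosome lengths differ from the reference's. Chromosomes with
   no placement are omitted rather than fabricated as empty sequences;
   unplaced scaffolds are carried verbatim in an unplaced bin.

The SV caller reuses the same machinery one level up: chains between two
genomes are classified against the maximum-score colinear backbone of each
chromosome pair (computed by the same LIS recursion over chains).
Backbone members are syntenic; a chain whose reference interval overlaps
already-covered sequence by more than half is a duplication; an
opposite-strand chain filling a backbone gap *in both coordinate systems*
is an inversion (the both-systems condition separates in-place inversions
from inverted translocations); everything else is a translocation, with
`INVDP`/`INVTL` marking inverted variants. Calls shorter than `min_block`
are discarded and same-type neighbours closer than `min_block` merged. SV
length is measured on the reference span, matching how "1 Mbp or longer"
major-SV filters are applied to plotted reference blocks; the toy default
is `min_len = 10` kb.

This is intentionally **not** a re-implementation of a full SV annotator:
no base-level variants, no nested-variant graph — block-level calls in the
vocabulary of whole-genome synteny plots are sufficient for every analysis
the package performs, and block-merging distances of full annotators are
version-sensitive enough that exact call-count parity would be meaningless.

## Breakpoint provenance and linkage evidence

A breakpoint is classified by its distance to the nearest N-run edge and
the nearest AGP component boundary: `internal` when both exceed `d`,
otherwise `component_end` (priority) or `gap_adjacent`. The default
`d = 1000` bp reflects the kilobase scale of short-read-unresolvable
assembly gaps; it is configurable. Both 100 bp reconstruction gaps and
longer intra-scaffold assembly gaps count as non-internal, with the two
flavours distinguishable through the recorded distances.

Mate-pair linkage support counts pairs that are uniquely mapped, not
duplicates, and straddle the breakpoint with each mate at least
`min_offset = 1000` bp away, among pairs falling within an
`insert_max`-radius window of the endpoint. A non-internal endpoint with at
least `min_pairs = 3` spanning pairs is rescued. No published count exists
for how many spanning pairs "confirm" linkage; 3 is a declared default. A
call is `supported` when both endpoints are internal or every non-internal
endpoint is rescued, `suspect_artifact` when none is, `ambiguous` when
they disagree.

The reference-bias experiment anchors one contig set independently on two
references and scans both results against a comparison genome. Matches
between SV sets require the same type and ≥ 50% reciprocal overlap (the
standard deterministic criterion). The headline quantity is the
recapitulation fraction: the share of (reference vs comparison) major SVs
reproduced by (anchored-on-that-reference vs comparison). Contigs that do
not span any breakpoint recapitulate the reference's structure completely
(fraction 1); contigs that span every rearrangement hold their own
structure regardless of the reference.

## The simulator: what it emulates, and what it does not

`sim_config()` defines the study conditions: i.i.d. random chromosomes with
GC fraction 0.34 (a typical value for the plant genomes this workflow is
applied to), planted inversions / translocations / duplications with a
two-coordinate-system truth registry, fragmentation into contigs with
lengths ~ Normal(`frag_mean`, `frag_sd`) truncated at 200 bp, scaffolds of
1–3 contigs joined by 1000 bp N runs (deliberately different from the
100 bp reconstruction gaps, so the two gap kinds stay distinguishable in
tests), optional chimeric joins between chromosomes at a configurable rate,
and mate pairs with inserts uniform in 2000–5000 bp, the range of a
long-insert mate-pair library. Cut points can be forced onto rearrangement
breakpoints or suppressed around them — the lever that switches between the
"inheritance" and "resistance" regimes. A single integer seed drives every
stochastic operation through one documented generator; no function touches
global RNG state.

Random i.i.d. sequence is the simulator's strongest idealization: unique
65-mers are essentially guaranteed, so seeds are clean and every contig is
placeable. Real plant genomes are 50–70% repetitive, which thins unique
anchors, strands more scaffolds as unplaced, and makes chimera detection
harder. Passing tests on this simulator therefore demonstrate the *logic*
of anchoring bias and its diagnosis — erasure, fabrication, breakpoint
scars, pair rescue — not calibrated performance on repeat-rich genomes.
Read-level error models, polyploid subgenomes and repeat families are
explicitly out of scope. Overlapping or nested rearrangements are rejected
by construction so the truth registry stays unambiguous.

One condition is worth stating explicitly: a contig "spanning" an inversion
must carry more colinear flank than inverted interior, otherwise its best
chain is the inverted one and the whole contig is placed
reverse-complemented (erasing the inversion again, legitimately — the
evidence in the contig favours the flipped orientation). The replay's
default breakpoint margin therefore equals the longest planted inversion,
mirroring the real situation where inversions sit inside scaffolds far
longer than themselves.

## Numerical and implementation choices

* Internal coordinates are 0-based half-open everywhere; AGP v2.1 is
  1-based inclusive and PAF 0-based half-open, with conversions confined to
  the readers/writers. AGP gap rows are `scaffold`/`no` (unlinked,
  reference-inferred joins).
* Seed discovery hashes every probe to a 52-bit numeric key (two
  independent 26-bit modular polynomial hashes over packed 13-base
  strides, exact in doubles), merges diagonal runs of hits into MEMs, then
  string-verifies every assembled seed, with a character-level re-derivation
  fallback for the ~2^-52-probability hash collision. This keeps MEM
  semantics exact while allowing data.table joins on numeric keys at
  megabase scale.
* Even-count medians take the floor of the mean of the two central values:
  deterministic integers.
* `min_seed_len` below 16 is rejected as collision-prone; tests of the MEM
  engine use k = 20 for match density on kilobase sequences.
* Inversion nesting uses a boundary slack (default 200 bp) and tolerates
  chance micro-matches inside the gap up to the same slack in total length:
  at k = 65 such matches cannot occur, but at test-scale k they do.
* Degenerate inputs: empty queries anchor to an empty set with a warning;
  sequences shorter than the insert yield no pairs with a warning; break
  positions at a scaffold's ends, overlapping SV specs, non-contiguous AGP
  parts, duplicate FASTA ids and out-of-alphabet characters are hard errors
  naming the offender.

## Evaluation conditions

The acceptance suite and `scripts/acceptance.R` run at the following
problem sizes, chosen to exercise genome-scale behaviour while keeping a
full run in minutes on one CPU: chaining oracle on 500 random instances of
up to 15 seeds (exhaustive enumeration); MEM oracle on 200 mosaic pairs up
to 2 kb at k = 20; self-anchoring fixpoint on a 2 × 1 Mb reference cut into
~50 contigs; inversion recovery over 20 replicates of 2 × 1 Mb genomes with
1–3 planted inversions of 50–200 kb (boundary tolerance: one seed length
per side) plus SV-free controls; reference-structure inheritance over 20
replicates per fragmentation regime and the bias contrast at 2 × 300 kb;
and 100 simulated two-chromosome chimeras with unique flanks. The tests
assert exactly the quantities the script reports; no empirical claim in
this vignette goes beyond what they compute.

## Known limitations

Block-level SV calls only; greedy (not optimal) conflict resolution in
placement and chain extraction; no Hi-C or long-read evidence; no gap-size
estimation; repeat handling limited to the unique-anchor filter; the
uniqueness flag on simulated pairs is an idealization of aligner-specific
criteria (no secondary hit, adequate mapping quality). These bound what the
package can say about real assemblies — it diagnoses placement artifacts,
it does not re-assemble genomes.
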