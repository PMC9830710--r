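# chromanchor

Reference-guided pseudo-chromosome anchoring, chain-based structural-variant
detection, and diagnosis of anchoring artifacts — with a truth-tracked genome
simulator for testing all of it.

## The problem

Chromosome-level plant genome assemblies are often produced by anchoring
scaffolds onto an existing reference genome: exact-match seeds between each
scaffold and the reference are chained into maximal monotonic paths, chimeric
scaffolds (two significant mapping locations on different chromosomes, or
distant locations on one chromosome) are split, and scaffolds are greedily
assigned to vacant reference locations, ordered by the median reference
position of their best chain, and concatenated with fixed-length N gaps.

This procedure silently imports the *reference's* chromosome structure
wherever the scaffolds themselves do not constrain it. If two genomes truly
differ by an inversion but no scaffold spans the inversion's breakpoints, the
anchored assembly comes out colinear with the reference — the inversion is
erased (or, anchoring onto a rearranged reference, fabricated). Downstream
whole-genome comparisons then report rearrangements that are artifacts of
scaffold placement, not biology. The tell-tale signature is where the
breakpoints fall: a real rearrangement's endpoints traverse contiguously
assembled sequence, while a placement artifact's endpoints coincide with
assembly gaps or contig ends, and long-insert mate pairs spanning a gap can
rescue sequence whose placement is genuinely supported.

`chromanchor` implements the full loop needed to study this effect:

* **seed & chain engine** — maximal exact-match seeds (> 64 bp by default,
  unique anchors) found by hashed probe lookup and diagonal-run merging,
  chained by weighted longest-increasing-subsequence dynamic programming
  with overlap-trimmed scores (`build_index()`, `find_seeds()`,
  `chain_seeds()`);
* **anchoring** — chimera detection and splitting (`<id>-1`, `<id>-2`, …),
  greedy best-first placement onto vacant reference spans, and gapped
  pseudo-chromosome emission with full AGP provenance (`anchor_pipeline()`);
* **SV scanning** — block-level classification of chains against the
  colinear backbone into syntenic, inverted, translocated and duplicated
  regions, with the standard "1 Mbp or longer" major-SV filter
  (`genome_chains()`, `call_svs()`, `filter_major()`);
* **diagnosis** — breakpoint-provenance classification (internal /
  gap-adjacent / component-end), spanning mate-pair support, verdicts per
  call, and the two-reference re-anchoring contrast that measures how much
  of a reference's own structure an anchoring recapitulates
  (`classify_breakpoints()`, `spanning_pair_support()`, `sv_verdicts()`,
  `reference_bias_report()`);
* **simulator** — multi-chromosome random genomes, planted inversions /
  translocations / duplications with a ground-truth registry, fragmentation
  into gapped (optionally chimeric) scaffolds with exact provenance, and
  2–5 kbp-insert mate pairs (`simulate_reference()`, `apply_svs()`,
  `fragment_assembly()`, `simulate_mate_pairs()`);
* **replay** — the whole experiment under one seed with a checksummed
  output manifest (`replay_synthetic()`).

Everything is tidyverse-shaped: assemblies are `id`/`seq` tibbles, seeds,
chains, placements, AGP rows, SV calls and verdicts are tidy tables, results
have `tidy()`/`glance()`/`autoplot()` methods, and FASTA / AGP v2.1 / PAF /
TSV round-trip losslessly.

## Worked example

Plant a 30 kb inversion, fragment the derived genome so that contig ends
fall exactly on the inversion breakpoints, anchor the contigs back onto the
original reference, and watch the inversion disappear — leaving its scar at
a component end:

```r
library(chromanchor)

cfg <- sim_config(n_chrom = 2, chrom_len = 200000, frag_mean = 15000,
                  frag_sd = 4000, contigs_per_scaffold = c(1, 1), seed = 42)
ref     <- simulate_reference(cfg)
derived <- apply_svs(ref, sv_spec("INV", "chr01", 60000, 30000))
frags   <- fragment_assembly(derived$assembly, cfg,
                             forced_cuts = tibble::tibble(
                               seq = "chr01", pos = c(60000, 90000)))
anchored <- anchor_pipeline(frags$scaffolds, ref)
anchored
#> <pseudochrom_set> 2 pseudo-chromosome(s), 29 placed / 0 unplaced scaffold(s)
#>   chr01: 201300 bp
#>   chr02: 201400 bp

svs <- call_svs(genome_chains(anchored$assembly, ref, min_block = 5000),
                min_block = 5000)
svs[, c("type", "r_id", "r_start", "r_end", "length")]
#> # A tibble: 2 × 5
#>   type  r_id  r_start  r_end length
#> 1 SYN   chr01       0 200000 200000
#> 2 SYN   chr02       0 200000 200000
```

The planted inversion is gone: the anchored assembly is fully syntenic with
the reference, because every contig was placed back in reference order and
orientation. The erased breakpoint classifies as non-internal — the
signature that distinguishes placement artifacts from real rearrangements:

```r
loc <- breakpoint_on_object(60000, "chr01", frags, anchored)
classify_breakpoints(loc, gap_map(anchored$assembly), agp = anchored$agp)
#> # A tibble: 1 × 5
#>   seq_id   pos dist_gap dist_comp class
#> 1 chr01  60300        0         0 component_end
```

Had the fragmentation been forced to *span* the breakpoints instead
(`protect =` intervals around the inversion), the inversion survives
anchoring, is called `INV` at the planted coordinates, and both endpoints
classify internal with a `supported` verdict (`sv_verdicts()`).

A command-line wrapper with `simulate` / `anchor` / `svscan` / `diagnose` /
`replay` subcommands ships in `inst/cli/chromanchor.R`.

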