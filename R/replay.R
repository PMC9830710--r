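#' Configuration for the synthetic end-to-end replay
#'
#' One object drives the whole experiment: simulate a reference genome A,
#' derive a rearranged genome B, fragment B into scaffolds in two regimes
#' (contig ends forced onto the rearrangement breakpoints vs contigs forced
#' to span them), anchor B's scaffolds back onto A and onto a third genome
#' C (A plus one extra planted inversion), call and judge structural
#' variants, and run the reference-bias comparison.
#'
#' @param seed Master seed; sub-stage seeds are derived from it.
#' @param sim A [sim_config()] (its seed is overridden by `seed`).
#' @param anchor An [anchor_config()].
#' @param n_inversions Number of inversions planted in B.
#' @param inv_len_range Planted inversion length range (bp).
#' @param extra_inv_len Length of the single extra inversion distinguishing
#'   genome C from A.
#' @param n_pairs Mate pairs simulated on the scaffold assembly.
#' @param breakpoint_margin Margin (bp) kept cut-free around a spanned
#'   inversion. `NULL` (the default) uses the upper end of
#'   `inv_len_range`, so that a spanning contig's colinear flanks outweigh
#'   its inverted interior and the contig anchors in its true orientation —
#'   the regime of the real data, where inversions sit inside scaffolds far
#'   longer than themselves.
#' @param min_block,min_len SV-scan block size and major-SV length filter.
#' @return A `replay_config` list.
#' @export
replay_config <- function(seed = 1L, sim = sim_config(), anchor = anchor_config(),
                          n_inversions = 2L, inv_len_range = c(5e4, 2e5),
                          extra_inv_len = 1e5, n_pairs = 20000L,
                          breakpoint_margin = NULL, min_block = 5000,
                          min_len = 1e4) {
  sim$seed <- as.integer(seed)
  breakpoint_margin <- breakpoint_margin %||% ceiling(inv_len_range[[2]])
  structure(list(seed = as.integer(seed), sim = sim, anchor = anchor,
                 n_inversions = as.integer(n_inversions),
                 inv_len_range = inv_len_range,
                 extra_inv_len = as.integer(extra_inv_len),
                 n_pairs = as.integer(n_pairs),
                 breakpoint_margin = as.integer(breakpoint_margin),
                 min_block = min_block, min_len = min_len),
            class = c("replay_config", "list"))
}

#' Tool version, configuration hash and seed for report headers
#'
#' @param cfg Any configuration object.
#' @return Character vector of header lines (no timestamps, so identically
#'   configured runs emit byte-identical reports).
#' @export
version_and_provenance <- function(cfg) {
  c(sprintf("chromanchor %s", as.character(utils::packageVersion("chromanchor"))),
    sprintf("config_hash %s", rlang::hash(unclass(cfg))),
    sprintf("seed %s", cfg$seed %||% "NA"))
}

#' Replay the anchoring-bias experiment on synthetic data
#'
#' Runs the full synthetic study under one seed and, optionally, writes
#' every artifact plus a checksum manifest to a directory. The two
#' fragmentation regimes test the two directions of the reference-structure
#' inheritance mechanism: scaffolds cut at the rearrangement breakpoints are
#' re-arranged into the reference's structure (the rearrangements are
#' erased, leaving gap-adjacent endpoint signatures), while scaffolds
#' spanning the breakpoints carry their rearrangements through anchoring
#' (called with internal, mate-pair-supported endpoints).
#'
#' @param cfg A [replay_config()].
#' @param out_dir Optional output directory; on failure partial outputs are
#'   removed.
#' @return Invisibly, a list with the simulated genomes and truth, both
#'   anchoring results, SV calls and verdicts per regime, the
#'   [reference_bias_report()] and (when `out_dir` is given) the manifest.
#' @export
replay_synthetic <- function(cfg = replay_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "replay_config"))
  ref <- simulate_reference(cfg$sim)
  specs <- random_sv_specs(ref, cfg$n_inversions, "INV",
                           len_range = cfg$inv_len_range,
                           seed = cfg$seed + 101L)
  derived <- apply_svs(ref, specs)
  truth <- derived$truth$planted_svs
  bp_cuts <- tibble(seq = rep(truth$derived_chrom, 2L),
                    pos = c(truth$derived_start, truth$derived_end))
  m <- cfg$breakpoint_margin
  span_cuts <- tibble(seq = rep(truth$derived_chrom, 2L),
                      pos = pmax(0L, c(truth$derived_start - m,
                                       truth$derived_end + m)))
  protect <- tibble(seq = truth$derived_chrom,
                    start = truth$derived_start - m,
                    end = truth$derived_end + m)
  frag_avoid <- fragment_assembly(derived$assembly, cfg$sim,
                                  forced_cuts = bp_cuts,
                                  seed = cfg$seed + 202L)
  frag_span <- fragment_assembly(derived$assembly, cfg$sim,
                                 forced_cuts = span_cuts, protect = protect,
                                 seed = cfg$seed + 303L)
  anchored_avoid <- anchor_pipeline(frag_avoid$scaffolds, ref, cfg$anchor)
  anchored_span <- anchor_pipeline(frag_span$scaffolds, ref, cfg$anchor)
  scan <- function(asm) {
    call_svs(genome_chains(asm, ref, min_seed_len = cfg$anchor$min_seed_len,
                           max_occ = cfg$anchor$max_occ,
                           min_block = cfg$min_block),
             min_block = cfg$min_block)
  }
  svs_avoid <- scan(anchored_avoid$assembly)
  svs_span <- scan(anchored_span$assembly)
  pairs_span <- simulate_mate_pairs(frag_span$scaffolds, cfg$n_pairs, cfg$sim,
                                    seed = cfg$seed + 404L)
  pairs_lifted <- lift_pairs(pairs_span, anchored_span)
  verdicts_span <- sv_verdicts(filter_major(svs_span, cfg$min_len),
                               anchored_span$assembly,
                               agp = anchored_span$agp, pairs = pairs_lifted,
                               insert_max = cfg$sim$insert_max)
  verdicts_avoid <- sv_verdicts(filter_major(svs_avoid, cfg$min_len),
                                anchored_avoid$assembly,
                                agp = anchored_avoid$agp)
  # genome C: the reference plus one extra inversion, for the bias contrast
  extra <- random_sv_specs(ref, 1L, "INV",
                           len_range = rep(cfg$extra_inv_len, 2L),
                           seed = cfg$seed + 505L)
  genome_c <- apply_svs(ref, extra)
  bias <- reference_bias_report(frag_avoid$scaffolds, ref, genome_c$assembly,
                                ref, cfg = cfg$anchor,
                                min_block = cfg$min_block,
                                min_len = cfg$min_len)
  result <- list(cfg = cfg, reference = ref, derived = derived$assembly,
                 truth = derived$truth, genome_c = genome_c,
                 frag_avoid = frag_avoid, frag_span = frag_span,
                 anchored_avoid = anchored_avoid,
                 anchored_span = anchored_span,
                 svs_avoid = svs_avoid, svs_span = svs_span,
                 verdicts_avoid = verdicts_avoid,
                 verdicts_span = verdicts_span,
                 pairs_span = pairs_span, bias = bias)
  if (!is.null(out_dir)) {
    ok <- FALSE
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    on.exit(if (!ok) unlink(out_dir, recursive = TRUE), add = TRUE)
    hdr <- version_and_provenance(cfg)
    write_fasta(ref, file.path(out_dir, "reference.fa"))
    write_fasta(derived$assembly, file.path(out_dir, "derived.fa"))
    write_tsv_report(truth, file.path(out_dir, "planted_svs.tsv"), hdr)
    write_tsv_report(derived$truth$layout, file.path(out_dir, "layout.tsv"), hdr)
    write_fasta(frag_avoid$scaffolds, file.path(out_dir, "scaffolds_avoid.fa"))
    write_fasta(frag_span$scaffolds, file.path(out_dir, "scaffolds_span.fa"))
    write_agp(frag_avoid$agp, file.path(out_dir, "scaffolds_avoid.agp"), hdr)
    write_agp(frag_span$agp, file.path(out_dir, "scaffolds_span.agp"), hdr)
    write_pseudochrom_set(anchored_avoid, file.path(out_dir, "anchored_avoid"), hdr)
    write_pseudochrom_set(anchored_span, file.path(out_dir, "anchored_span"), hdr)
    write_tsv_report(svs_avoid, file.path(out_dir, "svs_avoid.tsv"), hdr)
    write_tsv_report(svs_span, file.path(out_dir, "svs_span.tsv"), hdr)
    write_tsv_report(verdicts_avoid, file.path(out_dir, "verdicts_avoid.tsv"), hdr)
    write_tsv_report(verdicts_span, file.path(out_dir, "verdicts_span.tsv"), hdr)
    write_pairs(pairs_span, file.path(out_dir, "pairs_span.tsv"), hdr)
    write_tsv_report(bias$recap, file.path(out_dir, "bias_recap.tsv"), hdr)
    yaml::write_yaml(unclass_deep(cfg), file.path(out_dir, "config.yaml"))
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          c("manifest.tsv", "run.log")))
    manifest <- tibble(file = files,
                       md5 = unname(tools::md5sum(file.path(out_dir, files))))
    write_tsv_report(manifest, file.path(out_dir, "manifest.tsv"))
    writeLines(c(hdr, sprintf("finished %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
               file.path(out_dir, "run.log"))
    result$manifest <- manifest
    ok <- TRUE
  }
  invisible(result)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Lift mate-pair coordinates from scaffolds to pseudo-chromosomes
#'
#' Maps pairs whose mates both lie on one placed scaffold through the AGP of
#' an anchoring result; pairs on unplaced scaffolds are dropped.
#'
#' @param pairs Pair tibble on scaffold coordinates.
#' @param pseudo A `pseudochrom_set`.
#' @return Pair tibble on pseudo-chromosome coordinates.
#' @export
lift_pairs <- function(pairs, pseudo) {
  w <- pseudo$agp[pseudo$agp$component_type == "W", ]
  map <- setNames(seq_len(nrow(w)), w$component_id)
  i1 <- map[pairs$seq1]
  keep <- !is.na(i1) & pairs$seq1 == pairs$seq2
  p <- pairs[keep, ]
  i <- i1[keep]
  comp_len <- w$component_end[i] - w$component_beg[i] + 1L
  fwd <- w$orientation[i] != "-"
  lift <- function(pos) {
    as.integer(ifelse(fwd, w$object_beg[i] - 1L + pos,
                      w$object_beg[i] - 1L + comp_len - 1L - pos))
  }
  p$pos1 <- lift(p$pos1)
  p$pos2 <- lift(p$pos2)
  p$seq1 <- w$object[i]
  p$seq2 <- w$object[i]
  p
}
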