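#' Classify breakpoints by assembly provenance
#'
#' For each (sequence, position), computes the distance to the nearest N-run
#' edge and to the nearest AGP component boundary, then classifies the
#' breakpoint: `internal` when both distances exceed `d` (a breakpoint inside
#' unambiguously assembled sequence supports a real rearrangement),
#' otherwise `component_end` (preferred when both are within `d`) or
#' `gap_adjacent` (the signature of a placement artifact or short
#' read-unresolved region).
#'
#' @param bps Tibble with columns `seq_id`, `pos` (0-based positions).
#' @param gapmap Gap map of the assembly (see [gap_map()]).
#' @param agp Optional AGP tibble describing the assembly's objects.
#' @param d Proximity window in bp (default 1000, a kb-scale window matching
#'   the length of short-read-unresolvable assembly gaps).
#' @return `bps` with added `dist_gap`, `dist_comp` (Inf when absent) and
#'   `class` columns.
#' @export
classify_breakpoints <- function(bps, gapmap, agp = NULL, d = 1000) {
  if (!all(c("seq_id", "pos") %in% names(bps))) {
    stopf("`bps` needs seq_id and pos columns")
  }
  dist_gap <- purrr::map_dbl(seq_len(nrow(bps)), function(i) {
    runs <- gapmap[gapmap$id == bps$seq_id[i], ]
    if (nrow(runs) == 0L) return(Inf)
    p <- bps$pos[i]
    inside <- runs$start <= p & p < runs$end
    if (any(inside)) return(0)
    min(abs(p - runs$start), abs(p - runs$end))
  })
  dist_comp <- purrr::map_dbl(seq_len(nrow(bps)), function(i) {
    if (is.null(agp)) return(Inf)
    part <- agp[agp$object == bps$seq_id[i] & agp$component_type == "W", ]
    if (nrow(part) == 0L) return(Inf)
    # 0-based component boundaries on the object
    edges <- unique(c(part$object_beg - 1L, part$object_end))
    min(abs(bps$pos[i] - edges))
  })
  bps |>
    mutate(dist_gap = dist_gap, dist_comp = dist_comp,
           class = case_when(
             pmin(dist_gap, dist_comp) > d ~ "internal",
             dist_comp <= d ~ "component_end",
             TRUE ~ "gap_adjacent"))
}

#' Count unique mate pairs spanning an interval
#'
#' Counts pairs with `unique = TRUE` and `duplicate = FALSE` whose mates lie
#' on the stated sequence, one strictly left of `start` and the other
#' strictly right of `end`, each at least `min_offset` bp away from its side
#' of the interval. Each pair id is counted once. This is the linkage
#' evidence used to support sequence placed across an assembly gap.
#'
#' @param pairs Pair tibble (see [simulate_mate_pairs()] / [read_pairs()]).
#' @param seq_id Sequence id.
#' @param start,end Interval (0-based half-open; `start == end` gives a
#'   point).
#' @param min_offset Minimal distance of each mate from the interval.
#' @return Integer count.
#' @export
spanning_pair_support <- function(pairs, seq_id, start, end,
                                  min_offset = 1000) {
  if (nrow(pairs) == 0L) return(0L)
  p <- pairs[pairs$unique & !pairs$duplicate &
               pairs$seq1 == seq_id & pairs$seq2 == seq_id, ]
  if (nrow(p) == 0L) return(0L)
  p <- p[!duplicated(p$pair_id), ]
  left <- pmin(p$pos1, p$pos2)
  right <- pmax(p$pos1, p$pos2)
  sum(left <= start - min_offset & right >= end + min_offset)
}

#' Judge structural-variant calls by breakpoint provenance and pair support
#'
#' Both endpoints of every call are classified with
#' [classify_breakpoints()]. When a pair table is supplied, non-internal
#' endpoints gather spanning-pair support counted among pairs whose mates
#' fall within a window of width `2 * insert_max` centred on the endpoint.
#' The verdict is `supported` when both endpoints are internal or every
#' non-internal endpoint has at least `min_pairs` spanning pairs;
#' `suspect_artifact` when pairs are absent or every non-internal endpoint
#' lacks support; `ambiguous` when non-internal endpoints disagree.
#'
#' @param svs SV-call tibble, with coordinates on `assembly`.
#' @param assembly The assembly carrying the breakpoints (`side = "query"`:
#'   the calls' query assembly; `side = "ref"`: their reference).
#' @param agp Optional AGP of that assembly.
#' @param pairs Optional pair tibble on the same coordinates.
#' @param d Proximity window for [classify_breakpoints()].
#' @param min_pairs Minimal spanning-pair count that rescues a non-internal
#'   endpoint (default 3).
#' @param insert_max Mate-pair insert upper bound, sets the support window.
#' @param min_offset Minimal mate offset for [spanning_pair_support()].
#' @param side Which side of the calls lives on `assembly`.
#' @return `svs` with endpoint classes, distances, support counts and a
#'   `verdict` column.
#' @export
sv_verdicts <- function(svs, assembly, agp = NULL, pairs = NULL, d = 1000,
                        min_pairs = 3, insert_max = 5000, min_offset = 1000,
                        side = c("query", "ref")) {
  side <- match.arg(side)
  id_col <- if (side == "query") "q_id" else "r_id"
  a_col <- if (side == "query") "q_start" else "r_start"
  b_col <- if (side == "query") "q_end" else "r_end"
  if (nrow(svs) == 0L) {
    return(svs |> mutate(start_class = character(0), end_class = character(0),
                         pair_support_start = integer(0),
                         pair_support_end = integer(0),
                         verdict = character(0)))
  }
  lens <- seq_lengths(assembly)
  if (!all(svs[[id_col]] %in% names(lens))) {
    stopf("sv coordinates reference sequence %s absent from the assembly",
          setdiff(svs[[id_col]], names(lens))[[1L]])
  }
  if (any(svs[[a_col]] < 0L | svs[[b_col]] > lens[svs[[id_col]]])) {
    stopf("sv coordinates out of bounds for the supplied assembly")
  }
  gm <- gap_map(assembly)
  bp <- tibble(seq_id = rep(svs[[id_col]], 2L),
               pos = c(svs[[a_col]], svs[[b_col]]))
  cls <- classify_breakpoints(bp, gm, agp = agp, d = d)
  n <- nrow(svs)
  start_cls <- cls[seq_len(n), ]
  end_cls <- cls[n + seq_len(n), ]
  support <- function(cl) {
    purrr::map_int(seq_len(n), function(i) {
      if (cl$class[i] == "internal" || is.null(pairs)) return(NA_integer_)
      pos <- cl$pos[i]
      win <- pairs[pairs$seq1 == cl$seq_id[i] & pairs$seq2 == cl$seq_id[i] &
                     pmin(pairs$pos1, pairs$pos2) >= pos - insert_max &
                     pmax(pairs$pos1, pairs$pos2) <= pos + insert_max, ]
      as.integer(spanning_pair_support(win, cl$seq_id[i], pos, pos,
                                       min_offset = min_offset))
    })
  }
  sup_s <- support(start_cls)
  sup_e <- support(end_cls)
  verdict <- purrr::map_chr(seq_len(n), function(i) {
    classes <- c(start_cls$class[i], end_cls$class[i])
    if (all(classes == "internal")) return("supported")
    sup <- c(sup_s[i], sup_e[i])[classes != "internal"]
    if (all(is.na(sup))) return("suspect_artifact")
    ok <- !is.na(sup) & sup >= min_pairs
    if (all(ok)) "supported" else if (any(ok)) "ambiguous" else "suspect_artifact"
  })
  svs |>
    mutate(start_class = start_cls$class, start_dist_gap = start_cls$dist_gap,
           start_dist_comp = start_cls$dist_comp,
           end_class = end_cls$class, end_dist_gap = end_cls$dist_gap,
           end_dist_comp = end_cls$dist_comp,
           pair_support_start = sup_s, pair_support_end = sup_e,
           verdict = verdict)
}

#' Locate a source-genome breakpoint on an anchored object
#'
#' Maps a breakpoint that coincides with a contig end (per the fragmentation
#' provenance map) through an anchoring AGP into object coordinates — the
#' position where an erased rearrangement leaves its scar. Returns `NA` when
#' the breakpoint is interior to every contig (nothing to find: the
#' rearrangement was carried, not erased).
#'
#' @param bp 0-based breakpoint position on the fragmented genome.
#' @param chrom Chromosome (of the fragmented genome) carrying it.
#' @param frag Fragmentation result from [fragment_assembly()] (provenance
#'   map plus scaffold AGP).
#' @param anchored `pseudochrom_set` from [anchor_pipeline()].
#' @return One-row tibble (`seq_id`, `pos`) on the anchored assembly, or a
#'   zero-row tibble when the breakpoint is contig-interior or its carrier
#'   is unplaced.
#' @export
breakpoint_on_object <- function(bp, chrom, frag, anchored) {
  none <- tibble(seq_id = character(), pos = integer())
  fm <- frag$frag_map
  hit_end <- fm[fm$src_seq == chrom & fm$src_end == bp, ]
  hit_start <- fm[fm$src_seq == chrom & fm$src_start == bp, ]
  resolve <- function(contig, at_src_end) {
    # contig -> 0-based junction coordinate on its scaffold
    srow <- frag$agp[frag$agp$component_type == "W" &
                       frag$agp$component_id == contig, ]
    if (nrow(srow) != 1L) return(NULL)
    scaffold <- srow$object
    pos_scf <- if (at_src_end) srow$object_end else srow$object_beg - 1L
    # scaffold -> post-split part, if the anchoring split it
    part <- scaffold
    pos_part <- pos_scf
    sp <- anchored$split_parts
    if (!is.null(sp) && scaffold %in% sp$scaffold &&
          !scaffold %in% sp$part) {
      prow <- sp[sp$scaffold == scaffold & sp$offset <= pos_scf &
                   pos_scf <= sp$offset + sp$length, ]
      if (nrow(prow) == 0L) return(NULL)
      prow <- prow[1L, ]
      part <- prow$part
      pos_part <- pos_scf - prow$offset
    }
    # part -> object coordinate through the anchoring AGP
    arow <- anchored$agp[anchored$agp$component_type == "W" &
                           anchored$agp$component_id == part, ]
    if (nrow(arow) != 1L) return(NULL)
    comp_len <- arow$component_end - arow$component_beg + 1L
    pos_obj <- if (identical(arow$orientation, "-")) {
      arow$object_beg - 1L + (comp_len - pos_part)
    } else {
      arow$object_beg - 1L + pos_part
    }
    tibble(seq_id = arow$object, pos = as.integer(pos_obj))
  }
  # try the contig ending at the breakpoint first; if its carrier is
  # unplaced, the contig starting there marks the same scar
  out <- NULL
  if (nrow(hit_end) > 0L) out <- resolve(hit_end$contig[[1L]], TRUE)
  if (is.null(out) && nrow(hit_start) > 0L) {
    out <- resolve(hit_start$contig[[1L]], FALSE)
  }
  out %||% none
}

#' Match two SV-call sets by reciprocal overlap
#'
#' Two calls match when they have the same type, the same reference
#' chromosome, and at least `min_recip` reciprocal overlap of their
#' reference intervals.
#'
#' @param a,b SV-call tibbles on a common reference coordinate system.
#' @param min_recip Reciprocal-overlap threshold (default 0.5).
#' @return `a` with a logical `matched` column and the index of the first
#'   matching row of `b` (`match_idx`, NA when unmatched).
#' @export
match_svs <- function(a, b, min_recip = 0.5) {
  matched <- purrr::map_int(seq_len(nrow(a)), function(i) {
    cand <- which(b$type == a$type[i] & b$r_id == a$r_id[i])
    for (j in cand) {
      ov <- min(a$r_end[i], b$r_end[j]) - max(a$r_start[i], b$r_start[j])
      if (ov <= 0) next
      if (ov >= min_recip * a$length[i] && ov >= min_recip * b$length[j]) {
        return(j)
      }
    }
    NA_integer_
  })
  a |> mutate(matched = !is.na(matched), match_idx = matched)
}

#' Reference-bias re-anchoring experiment
#'
#' Anchors one contig set independently on two references, calls major
#' structural variants of each result against a comparison genome, and
#' measures how much of each reference's own structure the corresponding
#' anchoring recapitulates: the fraction of major SVs in the direct
#' (reference vs comparison) scan that reappear (same type, >= 50%
#' reciprocal overlap) in the (anchored-on-that-reference vs comparison)
#' scan. A recapitulation fraction near 1 with contigs that do not span the
#' rearrangement breakpoints is the signature of anchoring reference bias:
#' the rearrangements belong to the reference, not the contigs.
#'
#' @param contigs Contig/scaffold assembly to anchor.
#' @param ref_a,ref_b Reference assemblies.
#' @param compare_to Comparison genome for the SV scans.
#' @param cfg An [anchor_config()].
#' @param min_block,min_len SV scan parameters (see [genome_chains()],
#'   [filter_major()]).
#' @param min_recip Reciprocal-overlap threshold for SV matching.
#' @return A `bias_report`: list with per-anchoring pseudo-chromosome sets,
#'   SV tables (`sv_anchored_a/b` and direct `sv_ref_a/b`), and `recap`, a
#'   tibble with one row per reference giving the recapitulation fraction.
#' @export
reference_bias_report <- function(contigs, ref_a, ref_b, compare_to,
                                  cfg = anchor_config(), min_block = 5000,
                                  min_len = 1e4, min_recip = 0.5) {
  anchored_a <- anchor_pipeline(contigs, ref_a, cfg)
  anchored_b <- anchor_pipeline(contigs, ref_b, cfg)
  scan <- function(asm) {
    filter_major(call_svs(genome_chains(asm, compare_to,
                                        min_seed_len = cfg$min_seed_len,
                                        max_occ = cfg$max_occ,
                                        min_block = min_block),
                          min_block = min_block), min_len)
  }
  sv_anch_a <- scan(anchored_a$assembly)
  sv_anch_b <- scan(anchored_b$assembly)
  sv_ref_a <- scan(ref_a)
  sv_ref_b <- scan(ref_b)
  recap_one <- function(ref_svs, anch_svs, label) {
    m <- if (nrow(ref_svs) > 0L) match_svs(ref_svs, anch_svs, min_recip) else
      ref_svs |> mutate(matched = logical(0), match_idx = integer(0))
    tibble(reference = label, n_ref_svs = nrow(ref_svs),
           n_recapitulated = sum(m$matched),
           recap_fraction = if (nrow(ref_svs) == 0L) NA_real_ else
             sum(m$matched) / nrow(ref_svs))
  }
  recap <- bind_rows(recap_one(sv_ref_a, sv_anch_a, "ref_a"),
                     recap_one(sv_ref_b, sv_anch_b, "ref_b"))
  structure(list(anchored_a = anchored_a, anchored_b = anchored_b,
                 sv_anchored_a = sv_anch_a, sv_anchored_b = sv_anch_b,
                 sv_ref_a = sv_ref_a, sv_ref_b = sv_ref_b, recap = recap,
                 min_len = min_len, min_recip = min_recip),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("<bias_report>\n")
  cat(sprintf("  major SVs vs comparison: anchored-on-A %d, anchored-on-B %d\n",
              nrow(x$sv_anchored_a), nrow(x$sv_anchored_b)))
  cat(sprintf("  direct reference SVs:    A %d, B %d\n",
              nrow(x$sv_ref_a), nrow(x$sv_ref_b)))
  print(x$recap)
  invisible(x)
}

#' Tidy a bias report into one SV table
#' @param x A `bias_report`.
#' @param ... Unused.
#' @return SV calls of both anchorings and both direct scans, tagged by
#'   `source`.
#' @export
tidy.bias_report <- function(x, ...) {
  bind_rows(
    x$sv_anchored_a |> mutate(source = "anchored_a"),
    x$sv_anchored_b |> mutate(source = "anchored_b"),
    x$sv_ref_a |> mutate(source = "ref_a"),
    x$sv_ref_b |> mutate(source = "ref_b"))
}

#' One-row-per-reference summary of a bias report
#' @param x A `bias_report`.
#' @param ... Unused.
#' @return The recapitulation tibble.
#' @export
glance.bias_report <- function(x, ...) x$recap
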