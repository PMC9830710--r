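#' Whole-genome chains between two assemblies
#'
#' Aligns every query chromosome against an index of the reference assembly
#' with the seed-and-chain engine (unique anchors), then discards chains
#' whose reference span is below `min_block`. The surviving chains are the
#' synteny blocks the SV caller classifies.
#'
#' @param query,reference Assembly tibbles.
#' @param min_seed_len Seed length (default 65).
#' @param max_occ Anchor repeat filter (default 1).
#' @param min_block Minimum chain reference span in bp (default 5000; use
#'   larger values at genome scale).
#' @param index Optional prebuilt [build_index()] of `reference` (its probe
#'   length overrides `min_seed_len`).
#' @return Chain tibble (see [chain_seeds()]).
#' @export
genome_chains <- function(query, reference, min_seed_len = 65, max_occ = 1,
                          min_block = 5000, index = NULL) {
  index <- index %||% build_index(reference, min_seed_len)
  chains <- assembly_chains(query, index, max_occ = max_occ)
  if (nrow(chains) == 0L) return(chains)
  chains[chains$r_end - chains$r_start >= min_block, ]
}

#' Classify chains into structural-variant calls
#'
#' For each query chromosome the dominant reference chromosome is the one
#' carrying the highest total chain score. The colinear backbone of that
#' pair is the maximum-score strand-consistent monotonic subset of its
#' chains (found with the same longest-increasing-subsequence machinery used
#' for seeds); backbone members are `SYN`. Every other chain is classified
#' against the backbone: chains whose reference interval overlaps
#' already-covered reference sequence by more than half their span are
#' duplications (`DUP`, strand `-`: `INVDP`); opposite-strand chains nesting
#' into a backbone gap are inversions (`INV`); chains on a non-dominant
#' chromosome pair or violating backbone order are translocations (`TRL`,
#' strand `-`: `INVTL`). Adjacent same-type calls separated by less than
#' `min_block` on both genomes are merged.
#'
#' @param chains Chain tibble from [genome_chains()].
#' @param min_block Merge distance and minimal block size (bp).
#' @param slack Boundary slack (bp) when testing nesting between backbone
#'   neighbours; defaults to one seed length below the smallest chain.
#' @return SV-call tibble: `type` (`SYN`/`INV`/`TRL`/`DUP`/`INVDP`/`INVTL`),
#'   `r_id`, `r_start`, `r_end`, `q_id`, `q_start`, `q_end`, `length`
#'   (reference-span length), `score`, `strand`. Deterministically ordered.
#' @export
call_svs <- function(chains, min_block = 5000, slack = 200) {
  empty <- tibble(type = character(), r_id = character(), r_start = integer(),
                  r_end = integer(), q_id = character(), q_start = integer(),
                  q_end = integer(), length = integer(), score = double(),
                  strand = character())
  if (nrow(chains) == 0L) return(empty)
  calls <- list()
  for (qid in unique(chains$q_id)) {
    qc <- chains[chains$q_id == qid, ]
    totals <- tapply(qc$score, qc$r_id, sum)
    dominant <- names(totals)[order(-totals, names(totals))][[1L]]
    dc <- qc[qc$r_id == dominant, ]
    backbone_idx <- colinear_backbone(dc)
    bb <- dc[backbone_idx, ]
    # coverage is tracked at seed level: a backbone chain's envelope can span
    # a gap (e.g. across an inversion) that its seeds do not cover
    bb_seeds <- bind_rows(bb$seeds)
    covered <- cbind(bb_seeds$r_start, bb_seeds$r_end)
    for (i in backbone_idx) {
      ch <- dc[i, ]
      calls[[length(calls) + 1L]] <- sv_row("SYN", ch)
    }
    rest <- bind_rows(dc[-backbone_idx, ], qc[qc$r_id != dominant, ])
    if (nrow(rest) > 0L) {
      rest <- rest[order(-rest$score, rest$r_id, rest$r_start), ]
      for (i in seq_len(nrow(rest))) {
        ch <- rest[i, ]
        span <- ch$r_end - ch$r_start
        type <- NULL
        if (ch$r_id == dominant) {
          ov <- interval_overlap_total(ch$r_start, ch$r_end, covered)
          if (ov > 0.5 * span) {
            type <- if (ch$strand == "-") "INVDP" else "DUP"
          } else if (ch$strand != backbone_strand(bb) &&
                     nests_in_backbone(ch, bb_seeds, backbone_strand(bb),
                                       slack)) {
            type <- "INV"
          } else {
            type <- if (ch$strand == "-") "INVTL" else "TRL"
          }
        } else {
          type <- if (ch$strand == "-") "INVTL" else "TRL"
        }
        if (ch$r_id == dominant) {
          covered <- rbind(covered, c(ch$r_start, ch$r_end))
        }
        calls[[length(calls) + 1L]] <- sv_row(type, ch)
      }
    }
  }
  out <- bind_rows(calls)
  out <- merge_adjacent_calls(out, min_block)
  out |> arrange(.data$q_id, .data$r_id, .data$r_start, .data$type)
}

sv_row <- function(type, ch) {
  tibble(type = type, r_id = ch$r_id, r_start = ch$r_start, r_end = ch$r_end,
         q_id = ch$q_id, q_start = ch$q_start, q_end = ch$q_end,
         length = ch$r_end - ch$r_start, score = ch$score, strand = ch$strand)
}

# maximum-score strand-consistent colinear subset of one (q,r) pair's chains,
# computed by the same weighted-LIS recursion used for seed chaining; returns
# row indices into `dc`.
colinear_backbone <- function(dc) {
  best <- list(score = -Inf, idx = integer(0))
  for (strand in intersect(c("+", "-"), unique(dc$strand))) {
    rows <- which(dc$strand == strand)
    g <- dc[rows, ]
    o <- order(g$q_start, g$r_start)
    g <- g[o, ]
    rows <- rows[o]
    n <- nrow(g)
    dp <- as.numeric(g$score)
    prev <- integer(n)
    neg <- strand == "-"
    if (n > 1L) {
      for (j in 2L:n) {
        for (i in 1L:(j - 1L)) {
          if (g$q_start[i] >= g$q_start[j]) next
          if (!neg && g$r_start[i] >= g$r_start[j]) next
          if (neg && g$r_start[i] <= g$r_start[j]) next
          # envelope overlap is trimmed exactly as in seed chaining, so a
          # chain nested in already-covered sequence cannot join the backbone
          q_ov <- g$q_end[i] - g$q_start[j]
          r_ov <- min(g$r_end[i], g$r_end[j]) - max(g$r_start[i], g$r_start[j])
          cand <- dp[i] + g$score[j] - max(0, q_ov, r_ov)
          if (cand > dp[j]) {
            dp[j] <- cand
            prev[j] <- i
          }
        }
      }
    }
    top <- which.max(dp)
    path <- integer(0)
    at <- top
    while (at != 0L) {
      path <- c(at, path)
      at <- prev[at]
    }
    if (dp[top] > best$score) best <- list(score = dp[top], idx = rows[path])
  }
  best$idx
}

backbone_strand <- function(bb) {
  if (nrow(bb) == 0L) "+" else bb$strand[[1L]]
}

# does chain `ch` fill a gap in the backbone's seed-level coverage, in place?
# An in-place inversion nests between its reference neighbours in BOTH
# coordinate systems; an inverted translocation does not.
nests_in_backbone <- function(ch, bb_seeds, bb_strand, slack) {
  if (nrow(bb_seeds) == 0L) return(FALSE)
  within_env <- ch$r_start >= min(bb_seeds$r_start) - slack &&
    ch$r_end <= max(bb_seeds$r_end) + slack
  if (!within_env) return(FALSE)
  is_prev <- bb_seeds$r_end <= ch$r_start + slack
  is_nxt <- bb_seeds$r_start >= ch$r_end - slack
  # chance micro-matches inside the gap must not veto nesting: violators may
  # carry at most `slack` bases in total
  if (sum(bb_seeds$length[!is_prev & !is_nxt]) > slack) return(FALSE)
  prev <- bb_seeds[is_prev, ]
  nxt <- bb_seeds[is_nxt, ]
  q_ok <- TRUE
  if (bb_strand == "+") {
    if (nrow(prev) > 0L) q_ok <- q_ok && max(prev$q_end) <= ch$q_start + slack
    if (nrow(nxt) > 0L) q_ok <- q_ok && min(nxt$q_start) >= ch$q_end - slack
  } else {
    if (nrow(prev) > 0L) q_ok <- q_ok && min(prev$q_start) >= ch$q_end - slack
    if (nrow(nxt) > 0L) q_ok <- q_ok && max(nxt$q_end) <= ch$q_start + slack
  }
  q_ok
}

merge_adjacent_calls <- function(calls, min_block) {
  if (nrow(calls) == 0L) return(calls)
  calls <- calls[order(calls$type, calls$q_id, calls$r_id, calls$strand,
                       calls$r_start), ]
  key <- paste(calls$type, calls$q_id, calls$r_id, calls$strand)
  newgrp <- c(TRUE, key[-1L] != key[-nrow(calls)] |
                calls$r_start[-1L] - calls$r_end[-nrow(calls)] >= min_block)
  grp <- cumsum(newgrp)
  calls |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    summarise(type = .data$type[[1L]], r_id = .data$r_id[[1L]],
              r_start = min(.data$r_start), r_end = max(.data$r_end),
              q_id = .data$q_id[[1L]], q_start = min(.data$q_start),
              q_end = max(.data$q_end), score = sum(.data$score),
              strand = .data$strand[[1L]], .groups = "drop") |>
    mutate(length = .data$r_end - .data$r_start) |>
    select("type", "r_id", "r_start", "r_end", "q_id", "q_start", "q_end",
           "length", "score", "strand")
}

#' Keep only major structural variants
#'
#' Retains non-syntenic calls whose reference-span length is `min_len` or
#' longer (boundary inclusive).
#'
#' @param svs SV-call tibble from [call_svs()].
#' @param min_len Length threshold in bp (default 1 Mb; use smaller values
#'   for toy genomes).
#' @return Filtered SV-call tibble.
#' @export
filter_major <- function(svs, min_len = 1e6) {
  svs[svs$type != "SYN" & svs$length >= min_len, ]
}

#' Assembly-vs-assembly structural variant scan
#'
#' Convenience composition of [genome_chains()], [call_svs()] and
#' [filter_major()].
#'
#' @inheritParams genome_chains
#' @param min_len Major-SV length filter (see [filter_major()]); `NULL`
#'   reports all calls.
#' @return SV-call tibble.
#' @export
scan_svs <- function(query, reference, min_seed_len = 65, max_occ = 1,
                     min_block = 5000, min_len = NULL) {
  chains <- genome_chains(query, reference, min_seed_len = min_seed_len,
                          max_occ = max_occ, min_block = min_block)
  svs <- call_svs(chains, min_block = min_block)
  if (is.null(min_len)) svs else filter_major(svs, min_len)
}
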