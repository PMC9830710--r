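#' Build an exact-match seed index over a reference assembly
#'
#' Indexes every k-length probe (k = `min_seed_len`) of the reference,
#' excluding probes containing `N`, and records per-probe occurrence counts
#' for repeat filtering. Lookups cover both strands: queries are probed
#' forward and reverse-complemented against the forward index.
#'
#' @param reference Assembly tibble.
#' @param min_seed_len Probe length; also the minimum reported seed length.
#'   Values below 16 are rejected as collision-prone.
#' @return A `seed_index` object.
#' @export
build_index <- function(reference, min_seed_len = 65) {
  validate_assembly(reference)
  if (nrow(reference) == 0L) stopf("reference is empty")
  min_seed_len <- as.integer(min_seed_len)
  if (min_seed_len < 16L) stopf("min_seed_len must be >= 16 (collision-prone below)")
  k <- min_seed_len
  tabs <- purrr::map2(reference$id, reference$seq, function(id, s) {
    h <- kmer_hashes(s, k)
    keep <- which(!is.na(h))
    if (length(keep) == 0L) return(NULL)
    data.table::data.table(kmer = h[keep], r_id = id, r0 = keep - 1L)
  })
  idx <- data.table::rbindlist(tabs)
  if (nrow(idx) > 0L) {
    data.table::setkeyv(idx, "kmer")
    idx[, n_occ := .N, by = "kmer"]
  }
  structure(list(k = k, kmers = idx, r_lens = seq_lengths(reference),
                 r_seqs = setNames(reference$seq, reference$id)),
            class = "seed_index")
}

# Map bases to 0..3 (N -> NA so that any window containing N hashes to NA).
base_codes <- local({
  codes <- rep(NA_integer_, 128L)
  codes[utf8ToInt("A")] <- 0L
  codes[utf8ToInt("C")] <- 1L
  codes[utf8ToInt("G")] <- 2L
  codes[utf8ToInt("T")] <- 3L
  function(s) codes[utf8ToInt(s)]
})

# Exact-width numeric hash of every k-window of `s`: two independent 26-bit
# modular polynomial hashes packed into one double (< 2^52, so all integer
# arithmetic below stays exact in doubles). Identical k-mers always collide;
# distinct k-mers collide with probability ~2^-52, and every seed assembled
# from hash hits is string-verified afterwards.
kmer_hashes <- function(s, k) {
  v <- as.double(base_codes(s))
  n <- length(v)
  m <- n - k + 1L
  if (m <= 0L) return(double(0))
  # pack strides of 13 bases (values < 4^13 = 2^26; h * 2^26 + seg < 2^53
  # stays exact in doubles)
  w <- min(13L, k)
  nw <- n - w + 1L
  pw <- v[seq_len(nw)]
  for (j in seq_len(w - 1L)) pw <- pw * 4 + v[(1L + j):(nw + j)]
  P1 <- 67108859; P2 <- 67108837
  h1 <- 0; h2 <- 0
  qw <- k %/% w
  for (b in seq_len(qw)) {
    off <- (b - 1L) * w
    seg <- pw[(1L + off):(m + off)]
    h1 <- (h1 * 67108864 + seg) %% P1
    h2 <- (h2 * 67108879 + seg) %% P2
  }
  rem <- k %% w
  if (rem > 0L) {
    for (j in seq_len(rem)) {
      off <- qw * w + j - 1L
      seg <- v[(1L + off):(m + off)]
      h1 <- (h1 * 4 + seg) %% P1
      h2 <- (h2 * 5 + seg) %% P2
    }
  }
  h1 * 67108864 + h2
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> k = %d, %d sequences, %d probes\n",
              x$k, length(x$r_lens), nrow(x$kmers)))
  invisible(x)
}

#' Find maximal exact-match seeds of a query against an indexed reference
#'
#' Reports every maximal exact match (MEM) of length at least the index's
#' probe length between each query sequence and the reference, on both
#' strands. A match is maximal when extension in either direction breaks it;
#' matches never span `N`. Seeds are assembled by merging diagonal runs of
#' probe hits, then filtered for repeats: a seed is kept iff the smallest
#' reference occurrence count among its probes is at most `max_occ`.
#'
#' @param query Assembly tibble (one or more sequences).
#' @param index A `seed_index` from [build_index()].
#' @param max_occ Repeat-filter threshold on probe occurrence counts in the
#'   reference (default 1: unique anchors only). Use `Inf` to disable.
#' @return Seed tibble with columns `q_id`, `q_len`, `q_start`, `q_end`,
#'   `r_id`, `r_len`, `r_start`, `r_end`, `strand`, `length`, sorted by
#'   (`q_id`, `q_start`, `r_id`, `r_start`). 0-based half-open coordinates;
#'   on strand `-` the query substring equals the reverse complement of the
#'   reference substring.
#' @export
find_seeds <- function(query, index, max_occ = 1) {
  validate_assembly(query)
  if (!inherits(index, "seed_index")) stopf("`index` must be a seed_index")
  k <- index$k
  out <- purrr::map2(query$id, query$seq, function(qid, qseq) {
    qlen <- nchar(qseq)
    one <- function(strand) {
      s <- if (strand == "+") qseq else revcomp(qseq)
      h <- kmer_hashes(s, k)
      starts <- which(!is.na(h)) - 1L
      if (length(starts) == 0L || nrow(index$kmers) == 0L) return(NULL)
      qdt <- data.table::data.table(kmer = h[starts + 1L], q0 = starts)
      hits <- index$kmers[qdt, on = "kmer", nomatch = NULL,
                          allow.cartesian = TRUE]
      if (nrow(hits) == 0L) return(NULL)
      hits[, diag := r0 - q0]
      data.table::setorderv(hits, c("r_id", "diag", "q0"))
      newrun <- c(TRUE, hits$r_id[-1L] != hits$r_id[-nrow(hits)] |
                    hits$diag[-1L] != hits$diag[-nrow(hits)] |
                    hits$q0[-1L] != hits$q0[-nrow(hits)] + 1L)
      hits[, run := cumsum(newrun)]
      runs <- hits[, .(q0 = min(q0), r0 = min(r0),
                       length = k + .N - 1L, min_occ = min(n_occ)),
                   by = c("r_id", "run")]
      runs <- runs[min_occ <= max_occ]
      if (nrow(runs) == 0L) return(NULL)
      runs <- verify_runs(runs, s, index$r_seqs, k)
      if (nrow(runs) == 0L) return(NULL)
      if (strand == "+") {
        tibble(q_id = qid, q_len = qlen,
               q_start = runs$q0, q_end = runs$q0 + runs$length,
               r_id = runs$r_id,
               r_len = unname(index$r_lens[runs$r_id]),
               r_start = runs$r0, r_end = runs$r0 + runs$length,
               strand = "+", length = runs$length)
      } else {
        tibble(q_id = qid, q_len = qlen,
               q_start = qlen - (runs$q0 + runs$length),
               q_end = qlen - runs$q0,
               r_id = runs$r_id,
               r_len = unname(index$r_lens[runs$r_id]),
               r_start = runs$r0, r_end = runs$r0 + runs$length,
               strand = "-", length = runs$length)
      }
    }
    bind_rows(one("+"), one("-"))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(q_id = character(), q_len = integer(), q_start = integer(),
                  q_end = integer(), r_id = character(), r_len = integer(),
                  r_start = integer(), r_end = integer(), strand = character(),
                  length = integer()))
  }
  out |>
    distinct() |>
    arrange(.data$q_id, .data$q_start, .data$r_id, .data$r_start, .data$strand)
}

# String-verify hash-assembled runs. Hash collisions (~2^-52 per probe pair)
# can in principle fabricate or corrupt a run; any run whose substrings
# disagree is re-derived by direct character comparison along its diagonal.
verify_runs <- function(runs, qseq, r_seqs, k) {
  qs <- substring(qseq, runs$q0 + 1L, runs$q0 + runs$length)
  rs <- substring(r_seqs[runs$r_id], runs$r0 + 1L, runs$r0 + runs$length)
  ok <- qs == rs
  if (all(ok)) return(runs)
  fixed <- purrr::map(which(!ok), function(i) {
    a <- base_codes(qs[i])
    b <- base_codes(rs[i])
    eq <- !is.na(a) & !is.na(b) & a == b
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= k)
    if (length(keep) == 0L) return(NULL)
    tibble(r_id = runs$r_id[i], run = runs$run[i],
           q0 = runs$q0[i] + begs[keep] - 1L,
           r0 = runs$r0[i] + begs[keep] - 1L,
           length = r$lengths[keep], min_occ = runs$min_occ[i])
  })
  bind_rows(runs[ok, ], bind_rows(fixed))
}

#' Chain seeds into maximal monotonic paths
#'
#' For each (reference sequence, strand) group of one query's seeds, computes
#' maximum-score monotonic chains by weighted longest-increasing-subsequence
#' dynamic programming: member seeds are strictly increasing in query start,
#' and strictly increasing (strand `+`) or strictly decreasing (strand `-`)
#' in reference start. The chain score is the summed seed lengths with
#' overlap between consecutive members counted once (the larger of the query
#' and reference overlap is trimmed, keeping the score comparable to matched
#' bases on either genome; a seed nested inside an already-chained reference
#' interval therefore starts its own chain instead of inflating the
#' backbone). Chains are
#' extracted greedily: the best chain is removed and the DP repeated on the
#' remaining seeds, so each seed belongs to at most one chain.
#'
#' @param seeds Seed tibble from [find_seeds()], all rows from one query
#'   sequence (mixed queries are a hard error).
#' @param gap_penalty Per-base penalty on the larger of the query/reference
#'   gap between consecutive members. 0 (the default) gives the pure
#'   monotonic-path score.
#' @return Chain tibble ranked by (score desc, query id, reference start),
#'   with columns `chain_id`, `q_id`, `q_len`, `r_id`, `r_len`, `strand`,
#'   `n_seeds`, `q_start`, `q_end`, `r_start`, `r_end`, `score`, `r_median`
#'   and a list-column `seeds` of member seed tables. `r_median` is the
#'   integer median of member seeds' reference midpoints (even counts: floor
#'   of the mean of the two central values).
#' @export
chain_seeds <- function(seeds, gap_penalty = 0) {
  empty <- tibble(chain_id = character(), q_id = character(),
                  q_len = integer(), r_id = character(), r_len = integer(),
                  strand = character(), n_seeds = integer(),
                  q_start = integer(), q_end = integer(),
                  r_start = integer(), r_end = integer(),
                  score = double(), r_median = integer(), seeds = list())
  if (nrow(seeds) == 0L) return(empty)
  if (length(unique(seeds$q_id)) > 1L) {
    stopf("chain_seeds expects seeds from a single query (got %d)",
          length(unique(seeds$q_id)))
  }
  groups <- split(seeds, paste(seeds$r_id, seeds$strand))
  chains <- purrr::map(groups, chain_group, gap_penalty = gap_penalty)
  chains <- bind_rows(chains)
  if (nrow(chains) == 0L) return(empty)
  chains <- chains |>
    arrange(desc(.data$score), .data$q_id, .data$r_id, .data$r_start,
            .data$strand) |>
    mutate(chain_id = sprintf("%s.c%d", .data$q_id, row_number()),
           .before = 1L)
  chains
}

# LIS-style DP with greedy best-chain extraction for one (r_id, strand) group.
chain_group <- function(g, gap_penalty = 0) {
  g <- g[order(g$q_start, g$r_start), ]
  neg <- g$strand[[1L]] == "-"
  m <- nrow(g)
  active <- rep(TRUE, m)
  out <- list()
  while (any(active)) {
    ids <- which(active)
    n <- length(ids)
    dp <- as.numeric(g$length[ids])
    prev <- integer(n)
    if (n > 1L) {
      for (j in 2L:n) {
        sj <- ids[j]
        for (i in 1L:(j - 1L)) {
          si <- ids[i]
          if (g$q_start[si] >= g$q_start[sj]) next
          if (!neg && g$r_start[si] >= g$r_start[sj]) next
          if (neg && g$r_start[si] <= g$r_start[sj]) next
          q_ov <- g$q_end[si] - g$q_start[sj]
          r_ov <- min(g$r_end[si], g$r_end[sj]) - max(g$r_start[si], g$r_start[sj])
          trim <- max(0L, q_ov, r_ov)
          pen <- 0
          if (gap_penalty > 0) {
            qg <- g$q_start[sj] - g$q_end[si]
            rg <- if (neg) g$r_start[si] - g$r_end[sj] else g$r_start[sj] - g$r_end[si]
            pen <- gap_penalty * max(qg, rg, 0L)
          }
          cand <- dp[i] - trim - pen + g$length[sj]
          if (cand > dp[j]) {
            dp[j] <- cand
            prev[j] <- i
          }
        }
      }
    }
    best <- which.max(dp)
    path <- integer(0)
    at <- best
    while (at != 0L) {
      path <- c(at, path)
      at <- prev[at]
    }
    members <- g[ids[path], ]
    mids <- (members$r_start + members$r_end) %/% 2L
    out[[length(out) + 1L]] <- tibble(
      q_id = members$q_id[[1L]], q_len = members$q_len[[1L]],
      r_id = members$r_id[[1L]], r_len = members$r_len[[1L]],
      strand = members$strand[[1L]], n_seeds = nrow(members),
      q_start = min(members$q_start), q_end = max(members$q_end),
      r_start = min(members$r_start), r_end = max(members$r_end),
      score = dp[best], r_median = int_median(mids),
      seeds = list(members))
    active[ids[path]] <- FALSE
  }
  bind_rows(out)
}

# Seeds + chains for every sequence of an assembly against one index, with
# globally re-ranked chain ids. The shared entry point for anchoring and
# genome-vs-genome scanning.
assembly_chains <- function(asm, index, max_occ = 1, gap_penalty = 0) {
  seeds <- find_seeds(asm, index, max_occ = max_occ)
  if (nrow(seeds) == 0L) return(chain_seeds(seeds))
  seeds |>
    split(factor(seeds$q_id, levels = unique(seeds$q_id))) |>
    purrr::map(chain_seeds, gap_penalty = gap_penalty) |>
    bind_rows()
}
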