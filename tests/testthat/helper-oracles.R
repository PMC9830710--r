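# Independent oracles and tiny fixture builders used across the suite.

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rc <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Quadratic maximal-exact-match enumeration by direct per-character diagonal
# scan -- independent of the k-mer hashing route used by find_seeds().
mem_oracle <- function(qseq, rseq, k) {
  code <- function(s) {
    v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    v
  }
  runs_one <- function(qv, rv) {
    nq <- length(qv)
    nr <- length(rv)
    out <- list()
    for (d in (-(nq - k)):(nr - k)) {
      qlo <- max(0L, -d)
      qhi <- min(nq - 1L, nr - 1L - d)
      if (qhi - qlo + 1L < k) next
      qi <- qlo:qhi
      eq <- !is.na(qv[qi + 1L]) & !is.na(rv[qi + d + 1L]) &
        qv[qi + 1L] == rv[qi + d + 1L]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      begs <- ends - r$lengths + 1L
      keep <- which(r$values & r$lengths >= k)
      for (j in keep) {
        out[[length(out) + 1L]] <- c(q0 = qlo + begs[j] - 1L,
                                     r0 = qlo + d + begs[j] - 1L,
                                     len = r$lengths[j])
      }
    }
    if (length(out) == 0L) return(NULL)
    m <- do.call(rbind, out)
    tibble::tibble(q0 = m[, "q0"], r0 = m[, "r0"], len = m[, "len"])
  }
  qlen <- nchar(qseq)
  fwd <- runs_one(code(qseq), code(rseq))
  rev <- runs_one(code(rc(qseq)), code(rseq))
  res <- list()
  if (!is.null(fwd)) {
    res[[1]] <- tibble::tibble(q_start = fwd$q0, q_end = fwd$q0 + fwd$len,
                               r_start = fwd$r0, r_end = fwd$r0 + fwd$len,
                               strand = "+", length = fwd$len)
  }
  if (!is.null(rev)) {
    res[[2]] <- tibble::tibble(q_start = qlen - (rev$q0 + rev$len),
                               q_end = qlen - rev$q0,
                               r_start = rev$r0, r_end = rev$r0 + rev$len,
                               strand = "-", length = rev$len)
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(out)
  dplyr::arrange(out, q_start, r_start, strand)
}

# Exhaustive enumeration of every strictly monotonic seed subset (per
# reference sequence and strand), scoring with query-overlap trimming;
# returns the best achievable chain score.
chain_score_oracle <- function(seeds) {
  best <- 0
  for (key in unique(paste(seeds$r_id, seeds$strand))) {
    g <- seeds[paste(seeds$r_id, seeds$strand) == key, ]
    g <- g[order(g$q_start, g$r_start), ]
    neg <- g$strand[[1]] == "-"
    n <- nrow(g)
    rec <- function(last, sc) {
      best <<- max(best, sc)
      if (last >= n) return()
      for (j in (last + 1L):n) {
        if (g$q_start[j] <= g$q_start[last]) next
        if (!neg && g$r_start[j] <= g$r_start[last]) next
        if (neg && g$r_start[j] >= g$r_start[last]) next
        q_ov <- g$q_end[last] - g$q_start[j]
        r_ov <- min(g$r_end[last], g$r_end[j]) -
          max(g$r_start[last], g$r_start[j])
        rec(j, sc + g$length[j] - max(0L, q_ov, r_ov))
      }
    }
    for (j in seq_len(n)) rec(j, g$length[j])
  }
  best
}

# random seed table for chaining tests
random_seeds <- function(n, q_id = "q") {
  q_start <- sort(sample.int(2000, n))
  len <- sample(20:120, n, replace = TRUE)
  tibble::tibble(q_id = q_id, q_len = 4000L, q_start = q_start,
                 q_end = q_start + len,
                 r_id = sample(c("r1", "r2"), n, replace = TRUE),
                 r_len = 4000L,
                 r_start = sample.int(3000, n),
                 r_end = 0L, strand = sample(c("+", "-"), n, replace = TRUE),
                 length = len) |>
    dplyr::mutate(r_end = r_start + length)
}

# one-row chain builder for anchoring-stage tests that construct chain
# tables by hand
mk_chain <- function(q_id, r_id, q_start, q_end, r_start, r_end,
                     strand = "+", score = q_end - q_start, q_len = 1e5,
                     r_len = 1e6, chain_id = paste0(q_id, ".c", r_id)) {
  tibble::tibble(chain_id = chain_id, q_id = q_id, q_len = as.integer(q_len),
                 r_id = r_id, r_len = as.integer(r_len), strand = strand,
                 n_seeds = 1L, q_start = as.integer(q_start),
                 q_end = as.integer(q_end), r_start = as.integer(r_start),
                 r_end = as.integer(r_end), score = score,
                 r_median = as.integer((r_start + r_end) %/% 2),
                 seeds = list(tibble::tibble(
                   q_id = q_id, q_len = as.integer(q_len),
                   q_start = as.integer(q_start), q_end = as.integer(q_end),
                   r_id = r_id, r_len = as.integer(r_len),
                   r_start = as.integer(r_start), r_end = as.integer(r_end),
                   strand = strand, length = as.integer(q_end - q_start))))
}
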