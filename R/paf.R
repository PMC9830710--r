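#' Export chains as PAF
#'
#' Writes the 12 mandatory PAF columns for a chain table, one line per chain,
#' for consumption by dot-plot viewers. Coordinates are 0-based half-open.
#' Column 10 (matches) is the chain score (summed seed match length after
#' overlap trimming), column 11 (block length) the chain's query span, and
#' column 12 (mapping quality) the constant 255.
#'
#' @param chains Chain tibble from [chain_seeds()] or [genome_chains()].
#' @param path Output path.
#' @param q_lens,r_lens Optional named vectors of sequence lengths; defaults
#'   to the `q_len`/`r_len` columns carried on the chain table. A chain
#'   referencing a sequence with no known length is a hard error.
#' @return `path`, invisibly.
#' @export
write_paf <- function(chains, path, q_lens = NULL, r_lens = NULL) {
  if (nrow(chains) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  ql <- if (is.null(q_lens)) chains$q_len else unname(q_lens[chains$q_id])
  rl <- if (is.null(r_lens)) chains$r_len else unname(r_lens[chains$r_id])
  if (any(is.na(ql))) {
    stopf("unknown query sequence %s", chains$q_id[is.na(ql)][[1L]])
  }
  if (any(is.na(rl))) {
    stopf("unknown target sequence %s", chains$r_id[is.na(rl)][[1L]])
  }
  lines <- paste(chains$q_id, ql, chains$q_start, chains$q_end, chains$strand,
                 chains$r_id, rl, chains$r_start, chains$r_end,
                 chains$score, chains$q_end - chains$q_start, 255L,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a 12-column PAF file into a chain-like tibble
#'
#' @param path Path to a PAF file.
#' @return Tibble with the chain columns used by [write_paf()].
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(q_id = character(), q_len = integer(), q_start = integer(),
                  q_end = integer(), strand = character(), r_id = character(),
                  r_len = integer(), r_start = integer(), r_end = integer(),
                  score = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    q_id = purrr::map_chr(f, 1L),
    q_len = as.integer(purrr::map_chr(f, 2L)),
    q_start = as.integer(purrr::map_chr(f, 3L)),
    q_end = as.integer(purrr::map_chr(f, 4L)),
    strand = purrr::map_chr(f, 5L),
    r_id = purrr::map_chr(f, 6L),
    r_len = as.integer(purrr::map_chr(f, 7L)),
    r_start = as.integer(purrr::map_chr(f, 8L)),
    r_end = as.integer(purrr::map_chr(f, 9L)),
    score = as.integer(purrr::map_chr(f, 10L))
  )
}
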