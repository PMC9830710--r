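#' Assemblies as tidy tables
#'
#' An assembly is represented throughout the package as a tibble with one row
#' per sequence and columns `id` (unique, whitespace-free), `desc` (the
#' remainder of the FASTA header, possibly `NA`) and `seq` (an uppercase
#' string over the alphabet `A`, `C`, `G`, `T`, `N`). All coordinates handled
#' on these sequences are 0-based half-open; conversions to the 1-based
#' inclusive AGP convention happen only in the AGP reader/writer.
#'
#' @param id Character vector of sequence identifiers.
#' @param seq Character vector of sequences (case-insensitive on input).
#' @param desc Optional character vector of header descriptions.
#' @param name Optional assembly name, stored as the `"name"` attribute.
#' @return A tibble with columns `id`, `desc`, `seq`.
#' @examples
#' asm <- assembly(c("chr1", "chr2"), c("ACGTACGT", "GGGTTTAA"))
#' seq_lengths(asm)
#' @export
assembly <- function(id, seq, desc = NA_character_, name = NULL) {
  out <- tibble(id = as.character(id),
                desc = rep_len(as.character(desc), length(id)),
                seq = toupper(as.character(seq)))
  validate_assembly(out)
  if (!is.null(name)) attr(out, "name") <- name
  out
}

validate_assembly <- function(asm) {
  if (!all(c("id", "seq") %in% names(asm))) {
    stopf("an assembly needs `id` and `seq` columns")
  }
  if (any(is.na(asm$id) | asm$id == "" | grepl("\\s", asm$id))) {
    stopf("sequence ids must be non-empty and contain no whitespace")
  }
  dup <- asm$id[duplicated(asm$id)]
  if (length(dup) > 0L) stopf("duplicate id %s", dup[[1L]])
  if (any(!nzchar(asm$seq))) {
    stopf("empty sequence for id %s", asm$id[!nzchar(asm$seq)][[1L]])
  }
  bad <- regexpr("[^ACGTN]", asm$seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[[1L]]
    stopf("illegal character '%s' in sequence %s at position %d",
          substr(asm$seq[i], bad[i], bad[i]), asm$id[i], bad[i])
  }
  invisible(asm)
}

#' Sequence lengths of an assembly
#' @param asm An assembly tibble.
#' @return Named integer vector of sequence lengths.
#' @export
seq_lengths <- function(asm) setNames(nchar(asm$seq), asm$id)

#' Read a FASTA file into an assembly tibble
#'
#' Headers are truncated at the first whitespace to form the `id`; the rest of
#' the header is kept in `desc`. Lowercase bases are folded to uppercase;
#' characters outside `ACGTN`, duplicate ids and empty sequences are hard
#' errors.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return An assembly tibble (see [assembly()]); the file's base name is
#'   stored in the `"name"` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  out <- assembly(ids, as.character(ss), desc = desc,
                  name = sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path)))
  out
}

#' Write an assembly tibble to FASTA
#'
#' @param asm Assembly tibble.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60).
#' @return `path`, invisibly. Round-trips through [read_fasta()] losslessly.
#' @export
write_fasta <- function(asm, path, wrap = 60) {
  validate_assembly(asm)
  if (nrow(asm) == 0L) {
    warnf("writing empty assembly to %s", path)
    file.create(path)
    return(invisible(path))
  }
  headers <- ifelse(is.na(asm$desc) | asm$desc == "", asm$id,
                    paste(asm$id, asm$desc))
  ss <- Biostrings::BStringSet(asm$seq)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = wrap)
  invisible(path)
}

#' Locate maximal N-runs (gaps) in an assembly
#'
#' Returns every maximal run of `N` characters per sequence, in 0-based
#' half-open coordinates. Runs are maximal by construction (flanked by non-N
#' or the sequence end), sorted and pairwise disjoint.
#'
#' @param asm Assembly tibble.
#' @return Tibble with columns `id`, `start`, `end` (one row per N-run).
#' @export
gap_map <- function(asm) {
  validate_assembly(asm)
  rows <- purrr::map2(asm$id, asm$seq, function(id, s) {
    m <- gregexpr("N+", s)[[1L]]
    if (m[[1L]] == -1L) return(NULL)
    tibble(id = id,
           start = as.integer(m) - 1L,
           end = as.integer(m) - 1L + attr(m, "match.length"))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(id = character(), start = integer(), end = integer())
  }
  out
}
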