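#' Anchoring configuration
#'
#' Parameters of the reference-guided pseudo-chromosome reconstruction.
#'
#' @param min_seed_len Minimum exact-match seed length (default 65: seeds
#'   strictly longer than 64 bp).
#' @param max_occ Repeat filter for seed anchors (see [find_seeds()]).
#' @param sig_abs Absolute chain-score floor for a "significant" mapping
#'   location; default `5 * min_seed_len`.
#' @param sig_frac A chain is also significant only if its score is at least
#'   this fraction of the scaffold's best chain score (default 0.25).
#' @param dist_base Base distance for "distant locations within the same
#'   chromosome"; the effective threshold per scaffold is
#'   `max(dist_base, 2 * scaffold length)`.
#' @param ovl_frac Tolerated fractional overlap of a chain's reference span
#'   with already-occupied reference intervals during placement.
#' @param gap_len Length of the N gap inserted between consecutive placed
#'   scaffolds on a pseudo-chromosome (default 100 bp).
#' @param gap_penalty Chaining gap penalty (default 0).
#' @return An `anchor_config` list.
#' @export
anchor_config <- function(min_seed_len = 65, max_occ = 1,
                          sig_abs = 5 * min_seed_len, sig_frac = 0.25,
                          dist_base = 1e6, ovl_frac = 0.2, gap_len = 100,
                          gap_penalty = 0) {
  structure(list(min_seed_len = as.integer(min_seed_len), max_occ = max_occ,
                 sig_abs = sig_abs, sig_frac = sig_frac,
                 dist_base = dist_base, ovl_frac = ovl_frac,
                 gap_len = as.integer(gap_len), gap_penalty = gap_penalty),
            class = c("anchor_config", "list"))
}

# significant chains per scaffold: score >= max(sig_abs, sig_frac * best)
significant_chains <- function(chains, sig_abs, sig_frac) {
  chains |>
    group_by(.data$q_id) |>
    filter(.data$score >= pmax(sig_abs, sig_frac * max(.data$score))) |>
    ungroup()
}

#' Detect chimeric scaffolds from their chains
#'
#' A scaffold is flagged chimeric when it has two or more significant chains
#' (score at least `max(sig_abs, sig_frac * best score)`) either on different
#' reference chromosomes, or on one chromosome with a gap between their
#' reference intervals exceeding the distance threshold
#' `max(dist_base, 2 * scaffold length)`. The break position is the midpoint
#' of the query interval between the two chains' query spans, snapped to the
#' start of the nearest N-run inside that interval when one exists.
#'
#' @param chains Chain tibble covering the scaffolds (all chains, not only
#'   significant ones).
#' @param gapmap Gap map of the scaffold assembly (see [gap_map()]), used for
#'   N-run snapping; may be `NULL`.
#' @param cfg An [anchor_config()].
#' @return Break-directive tibble: `scaffold`, `pos`, `reason`
#'   (`different_chromosomes` or `distant_same_chromosome`), `chain_left`,
#'   `chain_right`.
#' @export
detect_chimeras <- function(chains, gapmap = NULL, cfg = anchor_config()) {
  out <- tibble(scaffold = character(), pos = integer(), reason = character(),
                chain_left = character(), chain_right = character())
  if (nrow(chains) == 0L) return(out)
  sig <- significant_chains(chains, cfg$sig_abs, cfg$sig_frac)
  for (scf in unique(sig$q_id)) {
    cc <- sig[sig$q_id == scf, ]
    if (nrow(cc) < 2L) next
    cc <- cc[order(cc$q_start, cc$q_end), ]
    qlen <- cc$q_len[[1L]]
    dist_thresh <- max(cfg$dist_base, 2 * qlen)
    for (i in seq_len(nrow(cc) - 1L)) {
      a <- cc[i, ]
      b <- cc[i + 1L, ]
      reason <- NULL
      if (a$r_id != b$r_id) {
        reason <- "different_chromosomes"
      } else {
        ref_gap <- max(a$r_start, b$r_start) - min(a$r_end, b$r_end)
        if (ref_gap > dist_thresh) reason <- "distant_same_chromosome"
      }
      if (is.null(reason)) next
      lo <- min(a$q_end, b$q_start)
      hi <- max(a$q_end, b$q_start)
      pos <- (lo + hi) %/% 2L
      if (!is.null(gapmap)) {
        runs <- gapmap[gapmap$id == scf & gapmap$start >= lo &
                         gapmap$start < hi, ]
        if (nrow(runs) > 0L) {
          pos <- runs$start[which.min(abs(runs$start - pos))]
        }
      }
      pos <- min(max(pos, 1L), qlen - 1L)
      out <- bind_rows(out, tibble(scaffold = scf, pos = as.integer(pos),
                                   reason = reason, chain_left = a$chain_id,
                                   chain_right = b$chain_id))
    }
  }
  out |> distinct() |> arrange(.data$scaffold, .data$pos)
}

#' Split scaffolds at chimera break positions
#'
#' Parts are named `<id>-1`, `<id>-2`, ... in query-coordinate order;
#' concatenating the parts in order reproduces the original sequence exactly.
#' Scaffolds without a directive keep their name and sequence.
#'
#' @param asm Scaffold assembly tibble.
#' @param directives Break-directive tibble from [detect_chimeras()].
#' @return List with `assembly` (post-split) and `parts`, a provenance table
#'   (`part`, `scaffold`, `offset`, `length`).
#' @export
split_scaffolds <- function(asm, directives) {
  validate_assembly(asm)
  rows <- purrr::map(seq_len(nrow(asm)), function(i) {
    id <- asm$id[i]
    s <- asm$seq[i]
    n <- nchar(s)
    brk <- sort(unique(directives$pos[directives$scaffold == id]))
    if (length(brk) == 0L) {
      return(tibble(part = id, scaffold = id, offset = 0L, length = n, seq = s))
    }
    if (any(brk <= 0L | brk >= n)) {
      stopf("break position outside the interior of scaffold %s", id)
    }
    bounds <- c(0L, brk, n)
    tibble(part = sprintf("%s-%d", id, seq_len(length(bounds) - 1L)),
           scaffold = id,
           offset = bounds[-length(bounds)],
           length = diff(bounds),
           seq = substring(s, bounds[-length(bounds)] + 1L, bounds[-1L]))
  })
  parts <- bind_rows(rows)
  list(assembly = assembly(parts$part, parts$seq, name = attr(asm, "name")),
       parts = parts[, c("part", "scaffold", "offset", "length")])
}

#' Place scaffolds on reference chromosomes by greedy best-first iteration
#'
#' All significant chains are ranked by score (ties: query id, then smaller
#' reference start) and visited in order. A chain is accepted when its
#' scaffold is not yet placed and its reference span overlaps the union of
#' already-occupied spans on that chromosome by at most `ovl_frac` of its own
#' span; acceptance marks the span occupied. Scaffolds whose chains are all
#' inadmissible end up unplaced.
#'
#' @param chains Chain tibble (post-split scaffolds).
#' @param cfg An [anchor_config()].
#' @return Placement tibble: `scaffold`, `r_id`, `r_median`, `orientation`,
#'   `status` (`placed`/`unplaced`), `chain_id`, `score`, `r_start`, `r_end`.
#' @export
place_scaffolds <- function(chains, cfg = anchor_config()) {
  empty <- tibble(scaffold = character(), r_id = character(),
                  r_median = integer(), orientation = character(),
                  status = character(), chain_id = character(),
                  score = double(), r_start = integer(), r_end = integer())
  if (nrow(chains) == 0L) return(empty)
  sig <- significant_chains(chains, cfg$sig_abs, cfg$sig_frac) |>
    arrange(desc(.data$score), .data$q_id, .data$r_start, .data$r_id,
            .data$strand)
  occupied <- list()
  placed <- character(0)
  out <- list()
  for (i in seq_len(nrow(sig))) {
    ch <- sig[i, ]
    if (ch$q_id %in% placed) next
    occ <- occupied[[ch$r_id]]
    span <- ch$r_end - ch$r_start
    ov <- interval_overlap_total(ch$r_start, ch$r_end, occ)
    if (ov > cfg$ovl_frac * span) next
    occupied[[ch$r_id]] <- rbind(occ, c(ch$r_start, ch$r_end))
    placed <- c(placed, ch$q_id)
    out[[length(out) + 1L]] <- tibble(
      scaffold = ch$q_id, r_id = ch$r_id, r_median = ch$r_median,
      orientation = ch$strand, status = "placed", chain_id = ch$chain_id,
      score = ch$score, r_start = ch$r_start, r_end = ch$r_end)
  }
  res <- bind_rows(out)
  unplaced <- setdiff(unique(chains$q_id), placed)
  if (length(unplaced) > 0L) {
    res <- bind_rows(res, tibble(
      scaffold = unplaced, r_id = NA_character_, r_median = NA_integer_,
      orientation = NA_character_, status = "unplaced",
      chain_id = NA_character_, score = NA_real_, r_start = NA_integer_,
      r_end = NA_integer_))
  }
  if (nrow(res) == 0L) empty else res
}

#' Emit gapped pseudo-chromosomes from placements
#'
#' Per reference chromosome, placed scaffolds are sorted by their reference
#' median (ties: scaffold id), `-` placements reverse-complemented, and the
#' sequences joined with `gap_len`-bp N runs. AGP rows record every component
#' and gap; object coordinates are cumulative concatenation coordinates, so a
#' pseudo-chromosome's length generally differs from the reference
#' chromosome's. Reference chromosomes with no placement are omitted.
#' Unplaced scaffolds are carried unchanged in the unplaced bin.
#'
#' @param placements Placement tibble from [place_scaffolds()].
#' @param scaffolds Post-split scaffold assembly.
#' @param gap_len Reconstruction gap length (default 100 bp).
#' @return A `pseudochrom_set`: list with `assembly` (pseudo-chromosomes),
#'   `unplaced` (assembly tibble), `agp`, `placements`.
#' @export
build_pseudochromosomes <- function(placements, scaffolds, gap_len = 100) {
  validate_assembly(scaffolds)
  gap_len <- as.integer(gap_len)
  pl <- placements[placements$status == "placed", ]
  if (any(duplicated(pl$scaffold))) {
    stopf("scaffold %s placed more than once", pl$scaffold[duplicated(pl$scaffold)][[1L]])
  }
  if (!all(pl$scaffold %in% scaffolds$id)) {
    stopf("placement references unknown scaffold %s",
          setdiff(pl$scaffold, scaffolds$id)[[1L]])
  }
  seqs <- setNames(scaffolds$seq, scaffolds$id)
  objs <- list()
  agp_rows <- list()
  for (chrom in sort(unique(pl$r_id))) {
    p <- pl[pl$r_id == chrom, ]
    p <- p[order(p$r_median, p$scaffold), ]
    oriented <- ifelse(p$orientation == "-", revcomp(seqs[p$scaffold]),
                       seqs[p$scaffold])
    objs[[chrom]] <- paste(oriented, collapse = strrep("N", gap_len))
    clens <- nchar(oriented)
    pos <- 1L
    pn <- 1L
    parts <- list()
    for (j in seq_len(nrow(p))) {
      parts[[length(parts) + 1L]] <- tibble(
        object = chrom, object_beg = pos, object_end = pos + clens[j] - 1L,
        part_number = pn, component_type = "W",
        component_id = p$scaffold[j], component_beg = 1L,
        component_end = clens[j], orientation = p$orientation[j],
        gap_length = NA_integer_, gap_type = NA_character_,
        linkage = NA_character_)
      pos <- pos + clens[j]
      pn <- pn + 1L
      if (j < nrow(p)) {
        parts[[length(parts) + 1L]] <- tibble(
          object = chrom, object_beg = pos, object_end = pos + gap_len - 1L,
          part_number = pn, component_type = "N", component_id = NA_character_,
          component_beg = NA_integer_, component_end = NA_integer_,
          orientation = NA_character_, gap_length = gap_len,
          gap_type = "scaffold", linkage = "no")
        pos <- pos + gap_len
        pn <- pn + 1L
      }
    }
    agp_rows[[chrom]] <- bind_rows(parts)
  }
  missing <- setdiff(scaffolds$id, placements$scaffold)
  if (length(missing) > 0L) {
    # scaffolds with no admissible chain at all still need an unplaced entry
    placements <- bind_rows(placements, tibble(
      scaffold = missing, r_id = NA_character_, r_median = NA_integer_,
      orientation = NA_character_, status = "unplaced",
      chain_id = NA_character_, score = NA_real_, r_start = NA_integer_,
      r_end = NA_integer_))
  }
  unplaced_ids <- placements$scaffold[placements$status == "unplaced"]
  asm <- if (length(objs) > 0L) {
    assembly(names(objs), unlist(objs), name = "pseudochromosomes")
  } else {
    tibble(id = character(), desc = character(), seq = character())
  }
  unpl <- scaffolds[scaffolds$id %in% unplaced_ids, ]
  agp <- if (length(agp_rows) > 0L) validate_agp(bind_rows(agp_rows)) else
    read_agp_empty()
  structure(list(assembly = asm, unplaced = unpl, agp = agp,
                 placements = placements),
            class = "pseudochrom_set")
}

read_agp_empty <- function() {
  tibble(object = character(), object_beg = integer(), object_end = integer(),
         part_number = integer(), component_type = character(),
         component_id = character(), component_beg = integer(),
         component_end = integer(), orientation = character(),
         gap_length = integer(), gap_type = character(), linkage = character())
}

#' Reference-guided anchoring pipeline
#'
#' End-to-end pseudo-chromosome reconstruction: seed discovery and chaining
#' of every scaffold against the reference, chimera detection and splitting,
#' re-chaining of split parts, greedy placement, and gapped
#' pseudo-chromosome emission with AGP provenance. Deterministic given its
#' inputs and configuration.
#'
#' @param query Scaffold/contig assembly tibble to anchor.
#' @param reference Reference assembly tibble.
#' @param cfg An [anchor_config()].
#' @param index Optional prebuilt [build_index()] of `reference`.
#' @return A `pseudochrom_set` (see [build_pseudochromosomes()]) with extra
#'   elements `chains` (post-split chain table), `breaks` (chimera
#'   directives), `split_parts` (split provenance) and `cfg`.
#' @export
anchor_pipeline <- function(query, reference, cfg = anchor_config(),
                            index = NULL) {
  validate_assembly(query)
  validate_assembly(reference)
  if (nrow(query) == 0L) {
    warnf("empty query assembly; nothing to anchor")
    return(build_pseudochromosomes(place_scaffolds(chain_seeds(
      tibble(q_id = character(), q_len = integer(), q_start = integer(),
             q_end = integer(), r_id = character(), r_len = integer(),
             r_start = integer(), r_end = integer(), strand = character(),
             length = integer())), cfg), query, cfg$gap_len))
  }
  index <- index %||% build_index(reference, cfg$min_seed_len)
  chains <- assembly_chains(query, index, max_occ = cfg$max_occ,
                            gap_penalty = cfg$gap_penalty)
  breaks <- detect_chimeras(chains, gapmap = gap_map(query), cfg = cfg)
  sp <- split_scaffolds(query, breaks)
  if (nrow(breaks) > 0L) {
    touched <- unique(breaks$scaffold)
    kept <- chains[!chains$q_id %in% touched, ]
    new_parts <- sp$assembly[!sp$assembly$id %in% query$id, ]
    rechained <- assembly_chains(new_parts, index, max_occ = cfg$max_occ,
                                 gap_penalty = cfg$gap_penalty)
    chains <- bind_rows(kept, rechained)
  }
  placements <- place_scaffolds(chains, cfg)
  res <- build_pseudochromosomes(placements, sp$assembly, cfg$gap_len)
  res$chains <- chains
  res$breaks <- breaks
  res$split_parts <- sp$parts
  res$cfg <- cfg
  res
}

#' @export
print.pseudochrom_set <- function(x, ...) {
  npl <- sum(x$placements$status == "placed")
  cat(sprintf(paste0("<pseudochrom_set> %d pseudo-chromosome(s), ",
                     "%d placed / %d unplaced scaffold(s)\n"),
              nrow(x$assembly), npl, nrow(x$unplaced)))
  if (nrow(x$assembly) > 0L) {
    cat(sprintf("  %s: %d bp\n", x$assembly$id, nchar(x$assembly$seq)), sep = "")
  }
  invisible(x)
}

#' Tidy a pseudochrom_set into its placement table
#' @param x A `pseudochrom_set`.
#' @param ... Unused.
#' @return The placement tibble.
#' @export
tidy.pseudochrom_set <- function(x, ...) x$placements

#' One-row summary of an anchoring result
#' @param x A `pseudochrom_set`.
#' @param ... Unused.
#' @return Tibble: counts of pseudo-chromosomes, placed/unplaced scaffolds,
#'   chimera breaks, and total placed bases.
#' @export
glance.pseudochrom_set <- function(x, ...) {
  tibble(n_pseudo = nrow(x$assembly),
         n_placed = sum(x$placements$status == "placed"),
         n_unplaced = sum(x$placements$status == "unplaced"),
         n_breaks = if (is.null(x$breaks)) 0L else nrow(x$breaks),
         placed_bp = sum(nchar(x$assembly$seq)) -
           sum(x$agp$gap_length, na.rm = TRUE))
}

#' Write all artifacts of an anchoring run
#'
#' Emits `pseudo.fa`, `unplaced.fa`, `pseudo.agp`, `placements.tsv` and
#' `chains.paf` into a directory.
#'
#' @param x A `pseudochrom_set` from [anchor_pipeline()].
#' @param dir Output directory (created if needed).
#' @param header Optional `#` comment lines for the TSV report.
#' @return `dir`, invisibly.
#' @export
write_pseudochrom_set <- function(x, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(x$assembly, file.path(dir, "pseudo.fa"))
  write_fasta(x$unplaced, file.path(dir, "unplaced.fa"))
  write_agp(x$agp, file.path(dir, "pseudo.agp"), header = header)
  write_tsv_report(x$placements, file.path(dir, "placements.tsv"), header)
  if (!is.null(x$chains)) write_paf(x$chains, file.path(dir, "chains.paf"))
  invisible(dir)
}

# plain TSV with optional '#' comment header
write_tsv_report <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
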