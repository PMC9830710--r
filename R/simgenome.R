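#' Simulation configuration
#'
#' Bundles every knob of the synthetic-genome generator. All stochastic
#' operations read their parameters (and their seed) from this object; none
#' touch global RNG state, so a configuration fully determines every output.
#'
#' @param n_chrom Number of reference chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param gc GC fraction in (0, 1). Default 0.34, a typical plant-genome
#'   base composition.
#' @param frag_mean,frag_sd Contig length distribution (Normal, truncated at
#'   `min_contig`) used by [fragment_assembly()].
#' @param min_contig Minimum contig length (bp).
#' @param scaffold_gap_len Length of the N-run joining contigs inside a
#'   simulated scaffold (default 1000 bp). Deliberately different from the
#'   100 bp reconstruction gaps inserted by [build_pseudochromosomes()] so
#'   that assembly gaps and reconstruction gaps stay distinguishable.
#' @param contigs_per_scaffold Integer range (min, max) of contigs grouped
#'   into one scaffold.
#' @param chimera_rate Fraction of scaffolds made chimeric by joining
#'   material from two distant loci.
#' @param insert_min,insert_max Mate-pair insert range in bp (defaults 2000
#'   and 5000, a long-insert mate-pair library).
#' @param nonunique_frac,duplicate_frac Fractions of simulated pairs flagged
#'   as non-uniquely mapping / as PCR duplicates.
#' @param seed Integer seed driving every stochastic operation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chrom = 2L, chrom_len = 1e6, gc = 0.34,
                       frag_mean = 4e4, frag_sd = 1e4, min_contig = 200L,
                       scaffold_gap_len = 1000L,
                       contigs_per_scaffold = c(1L, 3L), chimera_rate = 0,
                       insert_min = 2000L, insert_max = 5000L,
                       nonunique_frac = 0.02, duplicate_frac = 0.02,
                       seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_len = as.integer(chrom_len),
              gc = gc, frag_mean = frag_mean, frag_sd = frag_sd,
              min_contig = as.integer(min_contig),
              scaffold_gap_len = as.integer(scaffold_gap_len),
              contigs_per_scaffold = as.integer(contigs_per_scaffold),
              chimera_rate = chimera_rate,
              insert_min = as.integer(insert_min),
              insert_max = as.integer(insert_max),
              nonunique_frac = nonunique_frac,
              duplicate_frac = duplicate_frac, seed = as.integer(seed))
  if (cfg$n_chrom < 1L) stopf("n_chrom must be positive")
  if (cfg$chrom_len < 1L) stopf("chrom_len must be positive")
  if (cfg$gc <= 0 || cfg$gc >= 1) stopf("gc must lie in (0, 1)")
  if (cfg$insert_min > cfg$insert_max) stopf("insert_min must be <= insert_max")
  if (cfg$chimera_rate < 0 || cfg$chimera_rate > 1) {
    stopf("chimera_rate must lie in [0, 1]")
  }
  if (any(c(cfg$frag_mean, cfg$frag_sd, cfg$scaffold_gap_len,
            cfg$min_contig, cfg$insert_min) <= 0)) {
    stopf("all lengths must be positive")
  }
  structure(cfg, class = c("sim_config", "list"))
}

#' Simulate a reference genome
#'
#' Draws `n_chrom` chromosomes of `chrom_len` i.i.d. bases with
#' P(G) + P(C) = `gc`, deterministically for a given seed.
#'
#' @param cfg A [sim_config()].
#' @return Assembly tibble with chromosomes `chr01`, `chr02`, ...
#' @export
simulate_reference <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  with_seed(cfg$seed, {
    seqs <- purrr::map_chr(seq_len(cfg$n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE,
                   prob = p), collapse = "")
    })
    assembly(sprintf("chr%02d", seq_len(cfg$n_chrom)), seqs, name = "reference")
  })
}

#' Specify planted structural variants
#'
#' @param type One of `"INV"`, `"TRL"`, `"DUP"`.
#' @param chrom Source chromosome id.
#' @param start 0-based start of the affected reference interval.
#' @param length Interval length (bp).
#' @param dest_chrom,dest_pos Destination for `TRL`/`DUP` (reference
#'   coordinates; must not fall inside any planted interval).
#' @return One-row sv-spec tibble; row-bind several to form a plan.
#' @export
sv_spec <- function(type, chrom, start, length,
                    dest_chrom = NA_character_, dest_pos = NA_integer_) {
  type <- match.arg(type, c("INV", "TRL", "DUP"))
  if (type != "INV" && (is.na(dest_chrom) || is.na(dest_pos))) {
    stopf("%s needs dest_chrom and dest_pos", type)
  }
  tibble(type = type, chrom = chrom, start = as.integer(start),
         length = as.integer(length), dest_chrom = as.character(dest_chrom),
         dest_pos = as.integer(dest_pos))
}

#' Randomly place non-overlapping structural variants
#'
#' @param ref Reference assembly.
#' @param n Number of events.
#' @param type Event type (recycled over `n`).
#' @param len_range Length range (min, max) in bp.
#' @param seed Integer seed.
#' @param margin Distance kept free of events at chromosome ends, between
#'   events, and around destination points.
#' @return sv-spec tibble with `n` rows.
#' @export
random_sv_specs <- function(ref, n, type = "INV", len_range = c(5e4, 2e5),
                            seed = 1L, margin = 2e4) {
  validate_assembly(ref)
  lens <- seq_lengths(ref)
  type <- rep_len(type, n)
  with_seed(seed, {
    taken <- tibble(chrom = character(), start = integer(), end = integer())
    specs <- vector("list", n)
    for (i in seq_len(n)) {
      for (attempt in 1:200) {
        chrom <- sample(names(lens), 1L)
        len <- as.integer(round(runif(1L, len_range[1L], len_range[2L])))
        if (lens[[chrom]] < len + 2L * margin) next
        start <- as.integer(floor(runif(1L, margin, lens[[chrom]] - len - margin)))
        clash <- taken$chrom == chrom &
          taken$start < start + len + margin & start < taken$end + margin
        if (any(clash)) next
        dest_chrom <- NA_character_
        dest_pos <- NA_integer_
        if (type[i] != "INV") {
          dest_chrom <- sample(setdiff(names(lens), chrom), 1L)
          repeat {
            dest_pos <- as.integer(floor(runif(1L, margin,
                                               lens[[dest_chrom]] - margin)))
            dclash <- taken$chrom == dest_chrom &
              taken$start - margin < dest_pos & dest_pos < taken$end + margin
            if (!any(dclash)) break
          }
        }
        taken <- bind_rows(taken, tibble(chrom = chrom, start = start,
                                         end = start + len))
        specs[[i]] <- sv_spec(type[i], chrom, start, len, dest_chrom, dest_pos)
        break
      }
      if (is.null(specs[[i]])) stopf("could not place event %d; genome too crowded", i)
    }
    bind_rows(specs)
  })
}

validate_sv_specs <- function(specs, lens) {
  if (nrow(specs) == 0L) return(invisible(specs))
  if (!all(specs$chrom %in% names(lens))) stopf("sv spec on unknown chromosome")
  end <- specs$start + specs$length
  if (any(specs$start < 0L | end > lens[specs$chrom] | specs$length <= 0L)) {
    stopf("sv interval out of bounds")
  }
  for (chrom in unique(specs$chrom)) {
    s <- specs[specs$chrom == chrom, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1L && any(s$start[-1L] < (s$start + s$length)[-nrow(s)])) {
      stopf("overlapping sv specs on %s", chrom)
    }
  }
  dst <- specs[!is.na(specs$dest_pos), ]
  if (nrow(dst) > 0L) {
    if (!all(dst$dest_chrom %in% names(lens))) stopf("sv dest on unknown chromosome")
    if (any(dst$dest_pos < 0L | dst$dest_pos > lens[dst$dest_chrom])) {
      stopf("sv dest_pos out of bounds")
    }
    inside <- purrr::map_lgl(seq_len(nrow(dst)), function(i) {
      any(specs$chrom == dst$dest_chrom[i] &
            specs$start < dst$dest_pos[i] &
            dst$dest_pos[i] < specs$start + specs$length)
    })
    if (any(inside)) stopf("sv dest_pos falls inside a planted interval")
  }
  invisible(specs)
}

#' Apply planted structural variants to a reference
#'
#' `INV` replaces a segment with its reverse complement, `TRL` excises a
#' segment and reinserts it at a stated position (possibly on another
#' chromosome), `DUP` inserts a copy of a segment at a stated position. The
#' returned truth registry records each event in both coordinate systems and
#' the full segment layout of every derived chromosome.
#'
#' @param ref Reference assembly.
#' @param sv_specs sv-spec tibble (see [sv_spec()]); intervals must be
#'   pairwise non-overlapping, destinations outside all intervals.
#' @return List with `assembly` (the derived genome) and `truth`, itself a
#'   list with `planted_svs` (type, reference interval, derived interval,
#'   strand-flip flag) and `layout` (the segment tiling of each derived
#'   chromosome in reference coordinates).
#' @export
apply_svs <- function(ref, sv_specs = NULL) {
  validate_assembly(ref)
  lens <- seq_lengths(ref)
  if (is.null(sv_specs) || nrow(sv_specs) == 0L) {
    layout <- tibble(derived_chrom = ref$id, part = 1L, src_chrom = ref$id,
                     src_start = 0L, src_end = unname(lens[ref$id]),
                     strand = "+", derived_start = 0L,
                     derived_end = unname(lens[ref$id]))
    return(list(assembly = ref,
                truth = list(planted_svs = empty_planted(), layout = layout)))
  }
  validate_sv_specs(sv_specs, lens)
  sv_specs$event <- seq_len(nrow(sv_specs))

  # Cut every chromosome at all event boundaries and destination points,
  # then manipulate segment lists; sequences are materialized at the end.
  cuts <- lapply(ref$id, function(chrom) {
    s <- sv_specs[sv_specs$chrom == chrom, ]
    d <- sv_specs[!is.na(sv_specs$dest_chrom) & sv_specs$dest_chrom == chrom, ]
    sort(unique(c(0L, lens[[chrom]], s$start, s$start + s$length, d$dest_pos)))
  })
  names(cuts) <- ref$id
  segs <- lapply(ref$id, function(chrom) {
    b <- cuts[[chrom]]
    tibble(src_chrom = chrom, src_start = b[-length(b)], src_end = b[-1L],
           strand = "+", tag = NA_integer_)
  })
  names(segs) <- ref$id

  seg_range <- function(chrom, start, end) {
    hit <- which(segs[[chrom]]$src_chrom == chrom &
                   segs[[chrom]]$strand == "+" &
                   is.na(segs[[chrom]]$tag) &
                   segs[[chrom]]$src_start >= start &
                   segs[[chrom]]$src_end <= end)
    if (length(hit) == 0L) stopf("internal: lost segment %s:[%d,%d)", chrom, start, end)
    hit
  }
  insert_at <- function(chrom, pos) {
    # index BEFORE which to insert, located by original coordinate
    sl <- segs[[chrom]]
    hit <- which(sl$src_chrom == chrom & sl$strand == "+" & is.na(sl$tag) &
                   sl$src_start == pos)
    if (length(hit) > 0L) hit[[1L]] else nrow(sl) + 1L
  }

  for (e in seq_len(nrow(sv_specs))) {
    ev <- sv_specs[e, ]
    end <- ev$start + ev$length
    idx <- seg_range(ev$chrom, ev$start, end)
    block <- segs[[ev$chrom]][idx, ]
    if (ev$type == "INV") {
      block <- block[rev(seq_len(nrow(block))), ]
      block$strand <- ifelse(block$strand == "+", "-", "+")
      block$tag <- ev$event
      segs[[ev$chrom]] <- bind_rows(
        segs[[ev$chrom]][seq_len(min(idx) - 1L), ], block,
        segs[[ev$chrom]][-seq_len(max(idx)), ])
    } else if (ev$type == "TRL") {
      block$tag <- ev$event
      segs[[ev$chrom]] <- segs[[ev$chrom]][-idx, ]
      at <- insert_at(ev$dest_chrom, ev$dest_pos)
      sl <- segs[[ev$dest_chrom]]
      segs[[ev$dest_chrom]] <- bind_rows(sl[seq_len(at - 1L), ], block,
                                         sl[-seq_len(at - 1L), ])
    } else { # DUP
      copy <- block
      copy$tag <- ev$event
      at <- insert_at(ev$dest_chrom, ev$dest_pos)
      sl <- segs[[ev$dest_chrom]]
      segs[[ev$dest_chrom]] <- bind_rows(sl[seq_len(at - 1L), ], copy,
                                         sl[-seq_len(at - 1L), ])
    }
  }

  ref_seq <- setNames(ref$seq, ref$id)
  layout <- purrr::imap(segs, function(sl, chrom) {
    w <- sl$src_end - sl$src_start
    off <- cumsum(c(0L, w))[seq_len(nrow(sl))]
    tibble(derived_chrom = chrom, part = seq_len(nrow(sl)),
           src_chrom = sl$src_chrom, src_start = sl$src_start,
           src_end = sl$src_end, strand = sl$strand, tag = sl$tag,
           derived_start = off, derived_end = off + w)
  }) |> bind_rows()

  derived_seqs <- purrr::map_chr(ref$id, function(chrom) {
    sl <- layout[layout$derived_chrom == chrom, ]
    pieces <- purrr::map_chr(seq_len(nrow(sl)), function(i) {
      s <- substr(ref_seq[[sl$src_chrom[i]]], sl$src_start[i] + 1L, sl$src_end[i])
      if (sl$strand[i] == "-") revcomp(s) else s
    })
    paste(pieces, collapse = "")
  })
  derived <- assembly(ref$id, derived_seqs, name = "derived")

  planted <- purrr::map(seq_len(nrow(sv_specs)), function(e) {
    ev <- sv_specs[e, ]
    hit <- layout[!is.na(layout$tag) & layout$tag == ev$event, ]
    tibble(type = ev$type, ref_chrom = ev$chrom, ref_start = ev$start,
           ref_end = ev$start + ev$length,
           derived_chrom = hit$derived_chrom[[1L]],
           derived_start = min(hit$derived_start),
           derived_end = max(hit$derived_end),
           strand_flip = ev$type == "INV")
  }) |> bind_rows()

  layout$tag <- NULL
  list(assembly = derived,
       truth = list(planted_svs = planted, layout = layout))
}

empty_planted <- function() {
  tibble(type = character(), ref_chrom = character(), ref_start = integer(),
         ref_end = integer(), derived_chrom = character(),
         derived_start = integer(), derived_end = integer(),
         strand_flip = logical())
}

#' Rebuild a derived genome from the reference and a truth layout
#'
#' Replays the recorded segment tiling; used to check that the truth registry
#' and the emitted derived genome agree exactly.
#'
#' @param ref Reference assembly.
#' @param layout `truth$layout` from [apply_svs()].
#' @return Assembly tibble.
#' @export
rebuild_from_layout <- function(ref, layout) {
  ref_seq <- setNames(ref$seq, ref$id)
  chroms <- unique(layout$derived_chrom)
  seqs <- purrr::map_chr(chroms, function(chrom) {
    sl <- layout[layout$derived_chrom == chrom, ]
    sl <- sl[order(sl$part), ]
    pieces <- purrr::map_chr(seq_len(nrow(sl)), function(i) {
      s <- substr(ref_seq[[sl$src_chrom[i]]], sl$src_start[i] + 1L, sl$src_end[i])
      if (sl$strand[i] == "-") revcomp(s) else s
    })
    paste(pieces, collapse = "")
  })
  assembly(chroms, seqs)
}

#' Fragment a genome into gapped scaffolds with known provenance
#'
#' Cuts each chromosome into contigs with lengths approximately
#' Normal(`frag_mean`, `frag_sd`) truncated at `min_contig`, groups
#' consecutive contigs into scaffolds joined by `scaffold_gap_len`-bp N runs,
#' and optionally makes a fraction of scaffolds chimeric by joining material
#' from two different chromosomes. Cut points can be forced at stated
#' positions (to place contig ends exactly at rearrangement breakpoints) and
#' suppressed inside protected intervals (to guarantee that one contig spans
#' a rearrangement).
#'
#' @param genome Assembly to fragment (typically a derived genome).
#' @param cfg A [sim_config()].
#' @param forced_cuts Optional tibble (`seq`, `pos`) of mandatory cut points.
#' @param protect Optional tibble (`seq`, `start`, `end`) of intervals in
#'   which no random cut is placed.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return List with `scaffolds` (assembly tibble), `agp` (scaffold tiling in
#'   contigs), `contigs` (assembly tibble), `frag_map` (contig provenance:
#'   contig, src_seq, src_start, src_end, orientation) and `chimera_joins`
#'   (scaffold, members, join coordinates and source chromosomes).
#' @export
fragment_assembly <- function(genome, cfg = sim_config(), forced_cuts = NULL,
                              protect = NULL, seed = NULL) {
  validate_assembly(genome)
  stopifnot(inherits(cfg, "sim_config"))
  seed <- seed %||% cfg$seed
  lens <- seq_lengths(genome)
  with_seed(seed, {
    frag_map <- purrr::map(genome$id, function(chrom) {
      n <- lens[[chrom]]
      pos <- 0L
      cutp <- c(0L)
      while (pos < n) {
        step <- max(cfg$min_contig,
                    as.integer(round(rnorm(1L, cfg$frag_mean, cfg$frag_sd))))
        pos <- min(pos + step, n)
        cutp <- c(cutp, pos)
      }
      if (!is.null(forced_cuts)) {
        fc <- forced_cuts[forced_cuts$seq == chrom, ]
        cutp <- c(cutp, as.integer(fc$pos))
      }
      cutp <- sort(unique(pmin(pmax(cutp, 0L), n)))
      if (!is.null(protect)) {
        pr <- protect[protect$seq == chrom, ]
        if (nrow(pr) > 0L) {
          forced <- c(0L, n, if (!is.null(forced_cuts))
            as.integer(forced_cuts$pos[forced_cuts$seq == chrom]))
          inside <- purrr::map_lgl(cutp, function(p) {
            any(pr$start < p & p < pr$end) && !(p %in% forced)
          })
          cutp <- cutp[!inside]
        }
      }
      tibble(src_seq = chrom, src_start = cutp[-length(cutp)],
             src_end = cutp[-1L], orientation = "+")
    }) |> bind_rows()
    frag_map <- frag_map[frag_map$src_end > frag_map$src_start, ]
    frag_map$contig <- sprintf("ctg%05d", seq_len(nrow(frag_map)))
    genome_seq <- setNames(genome$seq, genome$id)
    frag_map$seq <- substr(genome_seq[frag_map$src_seq],
                           frag_map$src_start + 1L, frag_map$src_end)

    # group consecutive same-chromosome contigs into scaffolds
    sizes <- integer(0)
    total <- nrow(frag_map)
    while (sum(sizes) < total) {
      sizes <- c(sizes, sample(cfg$contigs_per_scaffold[1L]:cfg$contigs_per_scaffold[2L], 1L))
    }
    grp <- rep(seq_along(sizes), sizes)[seq_len(total)]
    # never group across chromosomes
    chrom_break <- c(FALSE, frag_map$src_seq[-1L] != frag_map$src_seq[-total])
    grp <- cumsum(c(TRUE, diff(grp) != 0L | chrom_break[-1L]))
    frag_map$scaffold_grp <- grp

    groups <- split(seq_len(total), grp)
    # chimeras: merge pairs of scaffold groups from different chromosomes
    n_scf <- length(groups)
    chimera_joins <- tibble(scaffold = character(), members = character(),
                            join_pos = integer(), left_src = character(),
                            right_src = character())
    merge_pairs <- list()
    if (cfg$chimera_rate > 0 && n_scf >= 2L) {
      n_chim <- min(round(cfg$chimera_rate * n_scf), floor(n_scf / 2))
      if (n_chim > 0L) {
        chrom_of <- purrr::map_chr(groups, ~ frag_map$src_seq[.x[[1L]]])
        avail <- seq_len(n_scf)
        for (i in seq_len(n_chim)) {
          pool_a <- sample(avail, length(avail))
          pair <- NULL
          for (a in pool_a) {
            bs <- avail[chrom_of[avail] != chrom_of[[a]]]
            if (length(bs) > 0L) {
              pair <- c(a, bs[sample.int(length(bs), 1L)])
              break
            }
          }
          if (is.null(pair)) break
          merge_pairs[[length(merge_pairs) + 1L]] <- pair
          avail <- setdiff(avail, pair)
        }
      }
    }

    gap <- strrep("N", cfg$scaffold_gap_len)
    scaffold_of <- integer(total)
    scf_members <- groups
    if (length(merge_pairs) > 0L) {
      drop <- unlist(purrr::map(merge_pairs, ~ .x[[2L]]))
      for (p in merge_pairs) scf_members[[p[[1L]]]] <- c(groups[[p[[1L]]]], groups[[p[[2L]]]])
      scf_members <- scf_members[-drop]
    }
    scf_ids <- sprintf("scf%04d", seq_along(scf_members))
    agp_rows <- list()
    scf_seqs <- character(length(scf_members))
    for (s in seq_along(scf_members)) {
      mem <- scf_members[[s]]
      seqs <- frag_map$seq[mem]
      scf_seqs[s] <- paste(seqs, collapse = gap)
      clens <- nchar(seqs)
      pos <- 1L
      parts <- list()
      pn <- 1L
      for (j in seq_along(mem)) {
        parts[[length(parts) + 1L]] <- tibble(
          object = scf_ids[s], object_beg = pos, object_end = pos + clens[j] - 1L,
          part_number = pn, component_type = "W",
          component_id = frag_map$contig[mem[j]], component_beg = 1L,
          component_end = clens[j], orientation = "+",
          gap_length = NA_integer_, gap_type = NA_character_,
          linkage = NA_character_)
        pos <- pos + clens[j]
        pn <- pn + 1L
        if (j < length(mem)) {
          parts[[length(parts) + 1L]] <- tibble(
            object = scf_ids[s], object_beg = pos,
            object_end = pos + cfg$scaffold_gap_len - 1L, part_number = pn,
            component_type = "N", component_id = NA_character_,
            component_beg = NA_integer_, component_end = NA_integer_,
            orientation = NA_character_, gap_length = cfg$scaffold_gap_len,
            gap_type = "scaffold", linkage = "no")
          pos <- pos + cfg$scaffold_gap_len
          pn <- pn + 1L
        }
      }
      agp_rows[[s]] <- bind_rows(parts)
      # record chimera joins (members from >1 source chromosome)
      srcs <- frag_map$src_seq[mem]
      if (length(unique(srcs)) > 1L) {
        brk <- which(srcs[-1L] != srcs[-length(srcs)])
        for (b in brk) {
          join_pos <- sum(nchar(frag_map$seq[mem[seq_len(b)]])) +
            (b - 1L) * cfg$scaffold_gap_len
          chimera_joins <- bind_rows(chimera_joins, tibble(
            scaffold = scf_ids[s],
            members = paste(frag_map$contig[mem], collapse = ","),
            join_pos = as.integer(join_pos),
            left_src = srcs[b], right_src = srcs[b + 1L]))
        }
      }
    }
    scaffolds <- assembly(scf_ids, scf_seqs, name = "scaffolds")
    contigs <- assembly(frag_map$contig, frag_map$seq, name = "contigs")
    fm <- frag_map[, c("contig", "src_seq", "src_start", "src_end", "orientation")]
    list(scaffolds = scaffolds, agp = validate_agp(bind_rows(agp_rows)),
         contigs = contigs, frag_map = fm, chimera_joins = chimera_joins)
  })
}

#' Simulate gap-spanning mate pairs on an assembly
#'
#' Draws `n` pairs uniformly over the assembly (sequences weighted by
#' length), with inserts uniform in `[insert_min, insert_max]`. A fraction of
#' pairs is flagged non-unique and a fraction flagged duplicate, mirroring
#' the alignment filters (no secondary hit, not a PCR duplicate) applied to
#' real mate-pair libraries. Sequences shorter than the maximum insert are
#' skipped with a warning.
#'
#' @param asm Assembly tibble (typically scaffolds or pseudo-chromosomes).
#' @param n Total number of pairs.
#' @param cfg A [sim_config()] supplying insert range and flag fractions.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return Pair tibble: `pair_id`, `seq1`, `pos1`, `strand1`, `seq2`, `pos2`,
#'   `strand2`, `unique`, `duplicate`. Positions are 0-based points on the
#'   assembly.
#' @export
simulate_mate_pairs <- function(asm, n, cfg = sim_config(), seed = NULL) {
  validate_assembly(asm)
  stopifnot(n > 0)
  seed <- seed %||% cfg$seed
  lens <- seq_lengths(asm)
  usable <- lens > cfg$insert_max
  if (any(!usable)) {
    warnf("skipping %d sequence(s) shorter than insert_max (%d bp)",
          sum(!usable), cfg$insert_max)
  }
  lens <- lens[usable]
  if (length(lens) == 0L) {
    return(tibble(pair_id = character(), seq1 = character(), pos1 = integer(),
                  strand1 = character(), seq2 = character(), pos2 = integer(),
                  strand2 = character(), unique = logical(),
                  duplicate = logical()))
  }
  with_seed(seed, {
    seqs <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
    insert <- as.integer(floor(runif(n, cfg$insert_min, cfg$insert_max + 1)))
    insert <- pmin(insert, cfg$insert_max)
    start <- as.integer(floor(runif(n) * (lens[seqs] - insert)))
    tibble(pair_id = sprintf("pair%06d", seq_len(n)),
           seq1 = seqs, pos1 = start, strand1 = "+",
           seq2 = seqs, pos2 = start + insert, strand2 = "-",
           unique = runif(n) >= cfg$nonunique_frac,
           duplicate = runif(n) < cfg$duplicate_frac)
  })
}

#' Read / write the pair table as TSV
#' @param pairs Pair tibble (see [simulate_mate_pairs()]).
#' @param path File path.
#' @param header Optional `#` comment lines.
#' @return `path` (write) or the pair tibble (read).
#' @export
write_pairs <- function(pairs, path, header = NULL) {
  lines <- c(if (!is.null(header)) paste0("# ", header),
             paste(c("pair_id", "seq1", "pos1", "strand1", "seq2", "pos2",
                     "strand2", "unique", "duplicate"), collapse = "\t"),
             paste(pairs$pair_id, pairs$seq1, pairs$pos1, pairs$strand1,
                   pairs$seq2, pairs$pos2, pairs$strand2,
                   as.integer(pairs$unique), as.integer(pairs$duplicate),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  tibble(pair_id = as.character(df$pair_id),
         seq1 = as.character(df$seq1), pos1 = as.integer(df$pos1),
         strand1 = as.character(df$strand1),
         seq2 = as.character(df$seq2), pos2 = as.integer(df$pos2),
         strand2 = as.character(df$strand2),
         unique = as.logical(df$unique > 0 | df$unique == TRUE),
         duplicate = as.logical(df$duplicate > 0 | df$duplicate == TRUE))
}
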