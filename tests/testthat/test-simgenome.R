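small_cfg <- function(...) {
  sim_config(n_chrom = 2L, chrom_len = 40000L, frag_mean = 4000,
             frag_sd = 1000, ...)
}

test_that("simulation is fully deterministic given the config", {
  cfg <- small_cfg(seed = 7L)
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(a, b)
  fa <- fragment_assembly(a, cfg)
  fb <- fragment_assembly(a, cfg)
  expect_identical(fa, fb)
  pa <- simulate_mate_pairs(a, 500, cfg)
  pb <- simulate_mate_pairs(a, 500, cfg)
  expect_identical(pa, pb)
})

test_that("base composition matches the configured GC content", {
  ref <- simulate_reference(sim_config(n_chrom = 1L, chrom_len = 1e6,
                                       gc = 0.5, seed = 2L))
  gc_obs <- mean(strsplit(ref$seq, "")[[1]] %in% c("G", "C"))
  # 6-sigma binomial bound: sd = sqrt(0.25/1e6) = 5e-4
  expect_lt(abs(gc_obs - 0.5), 0.01)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(chrom_len = 0), "positive")
  expect_error(sim_config(insert_min = 6000, insert_max = 5000), "insert_min")
  expect_error(sim_config(chimera_rate = 1.5), "chimera_rate")
})

test_that("INV replaces a segment with its reverse complement", {
  ref <- simulate_reference(small_cfg(seed = 5L))
  d <- apply_svs(ref, sv_spec("INV", "chr01", 10000, 10000))
  expect_equal(substr(d$assembly$seq[[1]], 10001, 20000),
               rc(substr(ref$seq[[1]], 10001, 20000)))
  expect_equal(substr(d$assembly$seq[[1]], 1, 10000),
               substr(ref$seq[[1]], 1, 10000))
  expect_equal(substr(d$assembly$seq[[1]], 20001, 40000),
               substr(ref$seq[[1]], 20001, 40000))
  expect_identical(d$assembly$seq[[2]], ref$seq[[2]])
  tr <- d$truth$planted_svs
  expect_equal(tr$derived_start, 10000L)
  expect_equal(tr$derived_end, 20000L)
  expect_true(tr$strand_flip)
})

test_that("TRL and DUP conserve and extend bases as expected", {
  ref <- simulate_reference(small_cfg(seed = 6L))
  lens0 <- seq_lengths(ref)
  d <- apply_svs(ref, sv_spec("TRL", "chr01", 0, 5000, "chr02", 40000))
  lens1 <- seq_lengths(d$assembly)
  expect_equal(unname(lens1[["chr01"]]), unname(lens0[["chr01"]]) - 5000L)
  expect_equal(unname(lens1[["chr02"]]), unname(lens0[["chr02"]]) + 5000L)
  expect_equal(sum(lens1), sum(lens0))
  expect_equal(substr(d$assembly$seq[[2]], 40001, 45000),
               substr(ref$seq[[1]], 1, 5000))

  dup <- apply_svs(ref, sv_spec("DUP", "chr01", 1000, 2000, "chr02", 10000))
  expect_equal(sum(seq_lengths(dup$assembly)), sum(lens0) + 2000L)
  expect_equal(substr(dup$assembly$seq[[2]], 10001, 12000),
               substr(ref$seq[[1]], 1001, 3000))
  # source untouched
  expect_identical(dup$assembly$seq[[1]], ref$seq[[1]])
})

test_that("the truth layout replays to exactly the derived genome", {
  ref <- simulate_reference(small_cfg(seed = 8L))
  specs <- dplyr::bind_rows(
    sv_spec("INV", "chr01", 5000, 8000),
    sv_spec("TRL", "chr02", 20000, 4000, "chr01", 30000),
    sv_spec("DUP", "chr02", 1000, 2000, "chr01", 25000))
  d <- apply_svs(ref, specs)
  expect_identical(rebuild_from_layout(ref, d$truth$layout)$seq,
                   d$assembly$seq)
  # identity when no events
  d0 <- apply_svs(ref, NULL)
  expect_identical(d0$assembly$seq, ref$seq)
  expect_equal(nrow(d0$truth$planted_svs), 0L)
})

test_that("overlapping or out-of-bounds specs are hard errors", {
  ref <- simulate_reference(small_cfg(seed = 9L))
  expect_error(apply_svs(ref, dplyr::bind_rows(
    sv_spec("INV", "chr01", 1000, 5000),
    sv_spec("INV", "chr01", 4000, 5000))), "overlapping")
  expect_error(apply_svs(ref, sv_spec("INV", "chr01", 39000, 5000)),
               "out of bounds")
  expect_error(apply_svs(ref, sv_spec("DUP", "chr01", 1000, 2000,
                                      "chr01", 1500)), "inside")
})

test_that("fragmentation conserves bases and records true provenance", {
  cfg <- small_cfg(seed = 10L)
  ref <- simulate_reference(cfg)
  fr <- fragment_assembly(ref, cfg)
  # concatenating contigs per frag_map reproduces each chromosome
  for (chrom in ref$id) {
    fm <- fr$frag_map[fr$frag_map$src_seq == chrom, ]
    fm <- fm[order(fm$src_start), ]
    seqs <- setNames(fr$contigs$seq, fr$contigs$id)
    expect_identical(paste(seqs[fm$contig], collapse = ""),
                     ref$seq[ref$id == chrom])
    # contigs tile the chromosome exactly
    expect_equal(fm$src_start, c(0L, fm$src_end[-nrow(fm)]))
    expect_equal(fm$src_end[nrow(fm)], unname(seq_lengths(ref)[chrom]))
  }
  # non-N scaffold bases equal the genome's bases as a multiset
  scaff <- gsub("N", "", paste(fr$scaffolds$seq, collapse = ""))
  expect_identical(sort(strsplit(scaff, "")[[1]]),
                   sort(strsplit(paste(ref$seq, collapse = ""), "")[[1]]))
  # AGP reconstructs the scaffolds byte-for-byte
  rebuilt <- agp_build(fr$agp, fr$contigs)
  expect_identical(setNames(rebuilt$seq, rebuilt$id)[fr$scaffolds$id],
                   setNames(fr$scaffolds$seq, fr$scaffolds$id))
})

test_that("chimera rate zero keeps every scaffold colinear from one locus", {
  cfg <- small_cfg(seed = 11L, chimera_rate = 0)
  ref <- simulate_reference(cfg)
  fr <- fragment_assembly(ref, cfg)
  expect_equal(nrow(fr$chimera_joins), 0L)
  w <- fr$agp[fr$agp$component_type == "W", ]
  src <- setNames(fr$frag_map$src_seq, fr$frag_map$contig)
  per_scaffold <- tapply(src[w$component_id], w$object,
                         function(x) length(unique(x)))
  expect_true(all(per_scaffold == 1L))
})

test_that("requested chimeras join two chromosomes and are recorded", {
  cfg <- small_cfg(seed = 12L, chimera_rate = 0.2)
  ref <- simulate_reference(cfg)
  fr <- fragment_assembly(ref, cfg)
  expect_gt(nrow(fr$chimera_joins), 0L)
  for (i in seq_len(nrow(fr$chimera_joins))) {
    expect_true(fr$chimera_joins$left_src[i] != fr$chimera_joins$right_src[i])
  }
})

test_that("forced cuts land contig ends on breakpoints; protection spans them", {
  cfg <- small_cfg(seed = 13L)
  ref <- simulate_reference(cfg)
  d <- apply_svs(ref, sv_spec("INV", "chr01", 12000, 9000))
  tr <- d$truth$planted_svs
  cuts <- tibble::tibble(seq = rep(tr$derived_chrom, 2),
                         pos = c(tr$derived_start, tr$derived_end))
  fr <- fragment_assembly(d$assembly, cfg, forced_cuts = cuts)
  fm <- fr$frag_map
  spans_bp <- fm$src_seq == tr$derived_chrom &
    ((fm$src_start < tr$derived_start & fm$src_end > tr$derived_start) |
       (fm$src_start < tr$derived_end & fm$src_end > tr$derived_end))
  expect_false(any(spans_bp))

  pr <- tibble::tibble(seq = tr$derived_chrom, start = tr$derived_start - 2000,
                       end = tr$derived_end + 2000)
  cuts2 <- tibble::tibble(seq = rep(tr$derived_chrom, 2),
                          pos = c(tr$derived_start - 2000, tr$derived_end + 2000))
  fr2 <- fragment_assembly(d$assembly, cfg, forced_cuts = cuts2, protect = pr)
  fm2 <- fr2$frag_map
  contains <- fm2$src_seq == tr$derived_chrom &
    fm2$src_start <= tr$derived_start - 2000 &
    fm2$src_end >= tr$derived_end + 2000
  expect_equal(sum(contains), 1L)
})

test_that("mate pairs respect the configured insert range and flags", {
  cfg <- small_cfg(seed = 14L)
  ref <- simulate_reference(cfg)
  pairs <- simulate_mate_pairs(ref, 1000, cfg)
  ins <- abs(pairs$pos2 - pairs$pos1)
  expect_true(all(ins >= 2000 & ins <= 5000))
  expect_true(all(pairs$pos1 >= 0 &
                    pairs$pos2 <= seq_lengths(ref)[pairs$seq2]))

  cfg0 <- small_cfg(seed = 15L, nonunique_frac = 0, duplicate_frac = 0)
  p0 <- simulate_mate_pairs(ref, 200, cfg0)
  expect_true(all(p0$unique) && !any(p0$duplicate))

  short <- assembly("tiny", rand_dna(1500))
  expect_warning(p <- simulate_mate_pairs(short, 10, cfg),
                 "shorter than insert_max")
  expect_equal(nrow(p), 0L)
})

test_that("pair tables round-trip through TSV", {
  cfg <- small_cfg(seed = 16L)
  ref <- simulate_reference(cfg)
  pairs <- simulate_mate_pairs(ref, 50, cfg)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pairs, p, header = "test")
  back <- read_pairs(p)
  expect_identical(back, pairs)
})
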