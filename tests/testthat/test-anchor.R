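# chain fixtures are built by hand (mk_chain) so that the decision rules can
# be exercised in isolation from the alignment engine

test_that("chimera detection follows the significance and distance rules", {
  cfg <- anchor_config(sig_abs = 325, sig_frac = 0.25, dist_base = 1e6)

  one <- mk_chain("s1", "chr1", 0, 40000, 0, 40000, score = 40000)
  expect_equal(nrow(detect_chimeras(one, NULL, cfg)), 0L)

  two <- dplyr::bind_rows(
    mk_chain("s7", "chr1", 0, 40000, 0, 40000, score = 40000,
             chain_id = "c1"),
    mk_chain("s7", "chr2", 60000, 100000, 0, 40000, score = 40000,
             chain_id = "c2"))
  br <- detect_chimeras(two, NULL, cfg)
  expect_equal(br$pos, 50000L)
  expect_equal(br$reason, "different_chromosomes")

  gm <- tibble::tibble(id = "s7", start = 48000L, end = 49000L)
  br2 <- detect_chimeras(two, gm, cfg)
  expect_equal(br2$pos, 48000L)

  # same chromosome, reference intervals 0.1 Mb apart: below the threshold
  near <- dplyr::bind_rows(
    mk_chain("s2", "chr1", 0, 40000, 0, 40000, score = 40000),
    mk_chain("s2", "chr1", 60000, 100000, 140000, 180000, score = 40000,
             chain_id = "c2"))
  expect_equal(nrow(detect_chimeras(near, NULL, cfg)), 0L)

  # but far beyond it on the same chromosome is chimeric
  far <- dplyr::bind_rows(
    mk_chain("s3", "chr1", 0, 40000, 0, 40000, score = 40000),
    mk_chain("s3", "chr1", 60000, 100000, 5e6, 5e6 + 40000, score = 40000,
             chain_id = "c2"))
  expect_equal(detect_chimeras(far, NULL, cfg)$reason,
               "distant_same_chromosome")

  # an insignificant second chain does not trigger a break
  weak <- dplyr::bind_rows(
    mk_chain("s4", "chr1", 0, 40000, 0, 40000, score = 40000),
    mk_chain("s4", "chr2", 60000, 61000, 0, 1000, score = 1000,
             chain_id = "c2"))
  expect_equal(nrow(detect_chimeras(weak, NULL, cfg)), 0L)
})

test_that("splitting names parts in order and conserves the sequence", {
  set.seed(31)
  s <- rand_dna(100000)
  asm <- assembly("s7", s)
  dir <- tibble::tibble(scaffold = "s7", pos = 48000L,
                        reason = "different_chromosomes",
                        chain_left = "c1", chain_right = "c2")
  sp <- split_scaffolds(asm, dir)
  expect_equal(sp$assembly$id, c("s7-1", "s7-2"))
  expect_equal(nchar(sp$assembly$seq), c(48000L, 52000L))
  expect_identical(paste(sp$assembly$seq, collapse = ""), s)
  expect_equal(sp$parts$offset, c(0L, 48000L))

  none <- split_scaffolds(asm, dir[0, ])
  expect_identical(none$assembly$id, "s7")
  expect_identical(none$assembly$seq, s)

  expect_error(split_scaffolds(asm, dplyr::mutate(dir, pos = 0L)), "interior")
  expect_error(split_scaffolds(asm, dplyr::mutate(dir, pos = 100000L)),
               "interior")
})

test_that("greedy placement resolves span competition by score", {
  cfg <- anchor_config(sig_abs = 100, sig_frac = 0.25, ovl_frac = 0.2)
  chains <- dplyr::bind_rows(
    mk_chain("A", "chr1", 0, 1000, 5000, 6000, score = 1000, chain_id = "a1"),
    mk_chain("B", "chr1", 0, 800, 5100, 5900, score = 800, chain_id = "b1"),
    mk_chain("B", "chr1", 0, 700, 20000, 20700, score = 700, chain_id = "b2"))
  pl <- place_scaffolds(chains, cfg)
  expect_equal(pl$chain_id[pl$scaffold == "A"], "a1")
  expect_equal(pl$chain_id[pl$scaffold == "B"], "b2")
  expect_true(all(pl$status == "placed"))

  # disjoint spans: both placed, order key is the reference median
  disjoint <- dplyr::bind_rows(
    mk_chain("A", "chr1", 0, 1000, 50000, 51000, score = 1000),
    mk_chain("B", "chr1", 0, 1000, 1000, 2000, score = 900, chain_id = "b"))
  pl2 <- place_scaffolds(disjoint, cfg)
  expect_equal(pl2$scaffold[order(pl2$r_median)], c("B", "A"))

  # a scaffold whose best chain is below the absolute floor stays unplaced
  weak <- mk_chain("C", "chr1", 0, 50, 0, 50, score = 50)
  pl3 <- place_scaffolds(weak, cfg)
  expect_equal(pl3$status, "unplaced")
})

test_that("pseudo-chromosome emission produces the worked AGP example", {
  set.seed(32)
  s1 <- rand_dna(300)
  s2 <- rand_dna(400)
  scaff <- assembly(c("S1", "S2"), c(s1, s2))
  pl <- tibble::tibble(scaffold = c("S1", "S2"), r_id = "chr1",
                       r_median = c(10L, 500L), orientation = "+",
                       status = "placed", chain_id = c("c1", "c2"),
                       score = c(300, 400), r_start = c(0L, 400L),
                       r_end = c(300L, 800L))
  ps <- build_pseudochromosomes(pl, scaff, gap_len = 100)
  expect_equal(nchar(ps$assembly$seq), 800L)
  expect_equal(ps$agp$object_beg, c(1L, 301L, 401L))
  expect_equal(ps$agp$object_end, c(300L, 400L, 800L))
  expect_equal(ps$agp$component_type, c("W", "N", "W"))
  expect_equal(ps$agp$component_id, c("S1", NA, "S2"))
  expect_equal(ps$agp$gap_length[[2]], 100L)
  expect_identical(ps$assembly$seq, paste0(s1, strrep("N", 100), s2))
  # AGP rebuild is byte-identical
  expect_identical(agp_build(ps$agp, scaff)$seq, ps$assembly$seq)

  # single '-' placement equals the reverse complement
  neg <- build_pseudochromosomes(
    dplyr::mutate(pl[1, ], orientation = "-"), scaff, gap_len = 100)
  expect_identical(neg$assembly$seq, rc(s1))

  # median tie breaks by scaffold id
  tie <- build_pseudochromosomes(
    dplyr::mutate(pl, r_median = 10L), scaff, gap_len = 100)
  expect_equal(tie$agp$component_id[c(1, 3)], c("S1", "S2"))

  expect_error(build_pseudochromosomes(
    dplyr::bind_rows(pl, pl[1, ]), scaff), "more than once")
})

test_that("anchoring a clean fragmentation is a fixpoint of the reference", {
  cfg <- sim_config(n_chrom = 2L, chrom_len = 50000L, frag_mean = 5000,
                    frag_sd = 1000, contigs_per_scaffold = c(1L, 1L),
                    seed = 33L)
  ref <- simulate_reference(cfg)
  fr <- fragment_assembly(ref, cfg)
  acfg <- anchor_config(min_seed_len = 21)
  res <- anchor_pipeline(fr$scaffolds, ref, acfg)
  expect_equal(sum(res$placements$status == "unplaced"), 0L)
  expect_true(all(res$placements$orientation == "+"))
  expect_equal(res$assembly$id, ref$id)
  expect_identical(gsub("N", "", res$assembly$seq), ref$seq)
  # every query base appears exactly once across pseudo + unplaced
  emitted <- gsub("N", "", paste(c(res$assembly$seq, res$unplaced$seq),
                                 collapse = ""))
  query <- gsub("N", "", paste(fr$scaffolds$seq, collapse = ""))
  expect_identical(sort(strsplit(emitted, "")[[1]]),
                   sort(strsplit(query, "")[[1]]))
})

test_that("a two-chromosome chimera is split and both parts placed home", {
  cfg <- sim_config(n_chrom = 2L, chrom_len = 50000L, seed = 34L)
  ref <- simulate_reference(cfg)
  chim <- assembly("chi1", paste0(substr(ref$seq[[1]], 1, 20000),
                                  substr(ref$seq[[2]], 20001, 40000)))
  res <- anchor_pipeline(chim, ref, anchor_config(min_seed_len = 21))
  expect_equal(res$breaks$reason, "different_chromosomes")
  pl <- res$placements[res$placements$status == "placed", ]
  expect_setequal(pl$scaffold, c("chi1-1", "chi1-2"))
  expect_equal(pl$r_id[pl$scaffold == "chi1-1"], "chr01")
  expect_equal(pl$r_id[pl$scaffold == "chi1-2"], "chr02")
})

test_that("an empty query anchors to an empty set with a warning", {
  ref <- assembly("chr01", strrep("ACGT", 100))
  expect_warning(res <- anchor_pipeline(ref[0, ], ref), "empty query")
  expect_equal(nrow(res$assembly), 0L)
  expect_equal(nrow(res$placements), 0L)
})

test_that("reference structure is inherited or resisted by contig span", {
  # the central mechanism: an inversion whose breakpoints coincide with
  # contig ends is erased by anchoring; one spanned by a contig survives
  cfg <- sim_config(n_chrom = 1L, chrom_len = 60000L, frag_mean = 6000,
                    frag_sd = 1500, contigs_per_scaffold = c(1L, 1L),
                    seed = 35L)
  ref <- simulate_reference(cfg)
  d <- apply_svs(ref, sv_spec("INV", "chr01", 22000, 9000))
  tr <- d$truth$planted_svs
  acfg <- anchor_config(min_seed_len = 21)

  cuts <- tibble::tibble(seq = tr$derived_chrom,
                         pos = c(tr$derived_start, tr$derived_end))
  fr_avoid <- fragment_assembly(d$assembly, cfg, forced_cuts = cuts)
  res_avoid <- anchor_pipeline(fr_avoid$scaffolds, ref, acfg)
  expect_identical(gsub("N", "", res_avoid$assembly$seq), ref$seq)

  # spanning contig with colinear-majority flanks keeps its orientation
  pr <- tibble::tibble(seq = tr$derived_chrom, start = tr$derived_start - 8000,
                       end = tr$derived_end + 8000)
  cuts2 <- tibble::tibble(seq = rep(tr$derived_chrom, 2),
                          pos = c(pr$start, pr$end))
  fr_span <- fragment_assembly(d$assembly, cfg, forced_cuts = cuts2,
                               protect = pr)
  res_span <- anchor_pipeline(fr_span$scaffolds, ref, acfg)
  svs <- call_svs(genome_chains(res_span$assembly, ref, min_seed_len = 21,
                                min_block = 2000), min_block = 2000)
  inv <- svs[svs$type == "INV", ]
  expect_equal(nrow(inv), 1L)
  expect_lt(abs(inv$r_start - tr$ref_start), 21)
  expect_lt(abs(inv$r_end - tr$ref_end), 21)
})
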