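test_that("breakpoint classes follow distance to gaps and component ends", {
  gm <- tibble::tibble(id = "chrA", start = 10000L, end = 10100L)
  asm_len <- 20000L

  v <- classify_breakpoints(tibble::tibble(seq_id = "chrA", pos = 5000L), gm)
  expect_equal(v$class, "internal")
  expect_equal(v$dist_gap, 5000)
  expect_equal(v$dist_comp, Inf)

  v2 <- classify_breakpoints(tibble::tibble(seq_id = "chrA", pos = 10000L), gm)
  expect_equal(v2$class, "gap_adjacent")
  expect_equal(v2$dist_gap, 0)

  agp <- tibble::tibble(object = "chrA", object_beg = c(1L, 301L),
                        object_end = c(300L, 20000L), part_number = 1:2,
                        component_type = "W", component_id = c("c1", "c2"),
                        component_beg = 1L,
                        component_end = c(300L, 19700L), orientation = "+",
                        gap_length = NA_integer_, gap_type = NA_character_,
                        linkage = NA_character_)
  v3 <- classify_breakpoints(tibble::tibble(seq_id = "chrA", pos = 300L),
                             gm, agp = agp)
  expect_equal(v3$class, "component_end")
  expect_equal(v3$dist_comp, 0)

  # component_end takes priority when both are within d
  gm2 <- tibble::tibble(id = "chrA", start = 500L, end = 600L)
  v4 <- classify_breakpoints(tibble::tibble(seq_id = "chrA", pos = 400L),
                             gm2, agp = agp)
  expect_equal(v4$class, "component_end")
})

test_that("gap distances equal a naive linear scan over N-runs", {
  set.seed(51)
  for (i in 1:25) {
    chars <- sample(c("A", "C", "G", "T", "N"), 300, replace = TRUE,
                    prob = c(rep(0.225, 4), 0.1))
    chars[1] <- "A"
    s <- paste(chars, collapse = "")
    asm <- assembly("x", s)
    gm <- gap_map(asm)
    pos <- sample(0:299, 5)
    got <- classify_breakpoints(tibble::tibble(seq_id = "x", pos = pos), gm)
    isn <- chars == "N"
    naive <- vapply(pos, function(p) {
      if (!any(isn)) return(Inf)
      if (isn[p + 1]) return(0)
      edges <- c(which(diff(c(FALSE, isn)) == 1) - 1L,
                 which(diff(c(isn, FALSE)) == -1))
      min(abs(p - edges))
    }, numeric(1))
    expect_equal(got$dist_gap, naive)
  }
})

test_that("spanning-pair support counts unique non-duplicate straddlers once", {
  mkpair <- function(id, p1, p2, uni = TRUE, dup = FALSE, seq = "chrA") {
    tibble::tibble(pair_id = id, seq1 = seq, pos1 = p1, strand1 = "+",
                   seq2 = seq, pos2 = p2, strand2 = "-", unique = uni,
                   duplicate = dup)
  }
  pairs <- dplyr::bind_rows(
    purrr::map(1:6, ~ mkpair(paste0("u", .x), 2000L, 8000L)),
    purrr::map(1:2, ~ mkpair(paste0("n", .x), 2000L, 8000L, uni = FALSE)),
    purrr::map(1:2, ~ mkpair(paste0("d", .x), 2000L, 8000L, dup = TRUE)))
  expect_equal(spanning_pair_support(pairs, "chrA", 4000, 6000,
                                     min_offset = 1000), 6L)

  left <- mkpair("L", 1000L, 3000L)
  expect_equal(spanning_pair_support(left, "chrA", 4000, 6000), 0L)
  expect_equal(spanning_pair_support(pairs[0, ], "chrA", 4000, 6000), 0L)

  # order invariance and duplicated rows counted once
  shuffled <- pairs[sample(nrow(pairs)), ]
  doubled <- dplyr::bind_rows(pairs, pairs)
  expect_equal(spanning_pair_support(shuffled, "chrA", 4000, 6000), 6L)
  expect_equal(spanning_pair_support(doubled, "chrA", 4000, 6000), 6L)

  # oracle: naive filter-and-count
  set.seed(52)
  rnd <- mkpair(sprintf("p%03d", 1:200),
                sample(0:20000, 200, TRUE), sample(0:20000, 200, TRUE),
                uni = runif(200) > 0.2, dup = runif(200) < 0.2)
  naive <- sum(rnd$unique & !rnd$duplicate &
                 pmin(rnd$pos1, rnd$pos2) <= 9000 - 1000 &
                 pmax(rnd$pos1, rnd$pos2) >= 9500 + 1000)
  expect_equal(spanning_pair_support(rnd, "chrA", 9000, 9500), naive)
})

test_that("verdicts combine endpoint classes with pair support", {
  set.seed(53)
  seqs <- paste0(rand_dna(9000), strrep("N", 1000), rand_dna(10000))
  asm <- assembly("chrA", seqs)
  sv <- function(a, b) {
    tibble::tibble(type = "INV", r_id = "ref1", r_start = a, r_end = b,
                   q_id = "chrA", q_start = a, q_end = b,
                   length = b - a, score = 1, strand = "-")
  }
  # both endpoints internal -> supported without any pair evidence
  v <- sv_verdicts(sv(3000L, 15000L), asm)
  expect_equal(v$start_class, "internal")
  expect_equal(v$verdict, "supported")

  # one endpoint at the gap start, no pairs -> suspect artifact
  v2 <- sv_verdicts(sv(3000L, 9000L), asm)
  expect_equal(v2$end_class, "gap_adjacent")
  expect_equal(v2$verdict, "suspect_artifact")

  # sufficient spanning pairs across the gap endpoint rescue the call
  sup <- tibble::tibble(pair_id = sprintf("s%d", 1:6), seq1 = "chrA",
                        pos1 = 6500L, strand1 = "+", seq2 = "chrA",
                        pos2 = 11000L, strand2 = "-", unique = TRUE,
                        duplicate = FALSE)
  v3 <- sv_verdicts(sv(3000L, 9000L), asm, pairs = sup, min_pairs = 3)
  expect_equal(v3$pair_support_end, 6L)
  expect_equal(v3$verdict, "supported")

  # under-supported stays suspect; support threshold is min_pairs
  v4 <- sv_verdicts(sv(3000L, 9000L), asm, pairs = sup[1:2, ], min_pairs = 3)
  expect_equal(v4$verdict, "suspect_artifact")

  expect_error(sv_verdicts(sv(3000L, 99999L), asm), "out of bounds")
})

test_that("identical references produce identical anchorings and SV sets", {
  cfg <- sim_config(n_chrom = 2L, chrom_len = 40000L, frag_mean = 5000,
                    frag_sd = 1000, contigs_per_scaffold = c(1L, 1L),
                    seed = 54L)
  ref <- simulate_reference(cfg)
  fr <- fragment_assembly(ref, cfg)
  rep <- reference_bias_report(fr$scaffolds, ref, ref, ref,
                               cfg = anchor_config(min_seed_len = 21),
                               min_block = 2000, min_len = 4000)
  expect_identical(rep$sv_anchored_a, rep$sv_anchored_b)
  expect_identical(rep$anchored_a$assembly, rep$anchored_b$assembly)
})

test_that("a reference-only inversion is recapitulated by anchoring on it", {
  cfg <- sim_config(n_chrom = 1L, chrom_len = 60000L, frag_mean = 6000,
                    frag_sd = 1500, contigs_per_scaffold = c(1L, 1L),
                    seed = 55L)
  ref_a <- simulate_reference(cfg)
  inv <- sv_spec("INV", "chr01", 25000, 12000)
  ref_b <- apply_svs(ref_a, inv)$assembly
  # contigs colinear with A, cut exactly at B's inversion boundaries
  cuts <- tibble::tibble(seq = "chr01", pos = c(25000L, 37000L))
  fr <- fragment_assembly(ref_a, cfg, forced_cuts = cuts)
  rep <- reference_bias_report(fr$scaffolds, ref_a, ref_b, ref_a,
                               cfg = anchor_config(min_seed_len = 21),
                               min_block = 2000, min_len = 4000)
  expect_equal(nrow(rep$sv_anchored_a), 0L)
  inv_b <- rep$sv_anchored_b[rep$sv_anchored_b$type == "INV", ]
  expect_equal(nrow(inv_b), 1L)
  recap_b <- rep$recap[rep$recap$reference == "ref_b", ]
  expect_equal(recap_b$recap_fraction, 1)
  expect_equal(rep$recap$n_ref_svs[rep$recap$reference == "ref_a"], 0L)
})

test_that("tidy and glance expose the bias report tables", {
  cfg <- sim_config(n_chrom = 1L, chrom_len = 30000L, frag_mean = 5000,
                    frag_sd = 1000, contigs_per_scaffold = c(1L, 1L),
                    seed = 56L)
  ref <- simulate_reference(cfg)
  fr <- fragment_assembly(ref, cfg)
  rep <- reference_bias_report(fr$scaffolds, ref, ref, ref,
                               cfg = anchor_config(min_seed_len = 21),
                               min_block = 2000, min_len = 4000)
  expect_true(all(c("source") %in% names(tidy(rep))))
  expect_equal(nrow(glance(rep)), 2L)
})
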