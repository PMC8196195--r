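test_that("diagnostic positions are columns differing from every outgroup", {
  tgt <- data.frame(id = "t", seq = "ACGT")
  expect_equal(diagnostic_positions(tgt, data.frame(id = "o", seq = "ACGA"),
                                    aligned = TRUE)$positions, 3L)
  expect_length(diagnostic_positions(tgt, data.frame(id = "o", seq = "ACGT"),
                                     aligned = TRUE)$positions, 0)
  ## two outgroups: only the column differing from both is diagnostic
  tgt2 <- data.frame(id = "t", seq = "AAGGCCTT")
  outs <- data.frame(id = c("o1", "o2"), seq = c("AAGACCTT", "AAGTCCTT"))
  expect_equal(diagnostic_positions(tgt2, outs, aligned = TRUE)$positions, 3L)
  ## gap or N in any outgroup disqualifies the column
  outs2 <- data.frame(id = c("o1", "o2"), seq = c("AAG-CCTT", "AAGTCCTT"))
  expect_length(diagnostic_positions(tgt2, outs2, aligned = TRUE)$positions, 0)
  expect_error(diagnostic_positions(tgt, outs[0, ]), "outgroup")
})

test_that("unaligned inputs are anchored pairwise before column comparison", {
  ## outgroup has a 3 bp deletion; downstream columns must stay in register
  tgt <- data.frame(id = "t", seq = "ACGTACGTAAGGCCTTACGTACGT")
  out <- data.frame(id = "o", seq = "ACGTACGTAAGACTTACGTACGT")  # del + G->A
  dp <- diagnostic_positions(tgt, out, aligned = FALSE)
  expect_true(11L %in% dp$positions)
  expect_true(all(dp$positions < nchar(tgt$seq)))
})

test_that("toy L1Hs vs L1PA4 diagnostic columns include the engineered guide motif", {
  lib <- toy_consensus_library()
  dp <- diagnostic_positions(lib[lib$id == "L1Hs", ], lib[lib$id == "L1PA4", ],
                             aligned = TRUE)
  gd <- toy_guides()
  gpos <- gd$consensus_pos[gd$subfamily == "L1Hs"]
  in_guide <- dp$positions[dp$positions >= gpos & dp$positions < gpos + 23L]
  expect_equal(in_guide, gpos + 10:12)      # the ACA->GTG triplet
})

test_that("guide candidate enumeration requires a PAM and a diagnostic base", {
  tgt <- data.frame(id = "t", seq = paste0(strrep("A", 10), "CACACACACAC", "GG"))
  prof <- list(positions = 5L)
  cands <- enumerate_guide_candidates(tgt, prof)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$pam_side, "three_prime_NGG")
  expect_equal(cands$consensus_pos, 0L)
  expect_false(cands$diag_in_pam_GGCC)

  ## no GG or CC anywhere
  tgt2 <- data.frame(id = "t", seq = strrep("AT", 15))
  expect_equal(nrow(enumerate_guide_candidates(tgt2, list(positions = 3L))), 0L)
  ## shorter than the 23-mer window
  tgt3 <- data.frame(id = "t", seq = strrep("A", 22))
  expect_equal(nrow(enumerate_guide_candidates(tgt3, list(positions = 3L))), 0L)
  expect_error(enumerate_guide_candidates(tgt, prof, k = 20L), "23")

  ## diagnostic base on the PAM GG flags Tier0 eligibility
  seq <- paste0(strrep("T", 21), "GG")
  cands <- enumerate_guide_candidates(data.frame(id = "t", seq = seq),
                                      list(positions = 22L))
  expect_true(cands$diag_in_pam_GGCC)

  ## every candidate window contains >= 1 diagnostic position and a valid PAM
  lib <- toy_consensus_library()
  dp <- diagnostic_positions(lib[lib$id == "L1Hs", ], lib[lib$id == "L1PA4", ],
                             aligned = TRUE)
  cc <- enumerate_guide_candidates(lib[lib$id == "L1Hs", ], dp)
  expect_gt(nrow(cc), 0)
  expect_true(all(cc$n_diag >= 1))
  ok_pam <- ifelse(cc$pam_side == "three_prime_NGG",
                   substr(cc$seq23, 22, 23) == "GG",
                   substr(cc$seq23, 1, 2) == "CC")
  expect_true(all(ok_pam))
})

test_that("k-mer frequency equals the naive sliding-window count", {
  expect_equal(unname(count_kmer_frequency(data.frame(id = "g", seq = "AAAA"),
                                           "AA", both_strands = FALSE)), 3L)
  expect_equal(unname(count_kmer_frequency(data.frame(id = "g", seq = "AAAT"),
                                           "ATTT")), 1L)
  expect_equal(unname(count_kmer_frequency(data.frame(id = "g", seq = "GGGG"),
                                           "AA")), 0L)
  expect_error(count_kmer_frequency(data.frame(id = "g", seq = "ACGT"), "AN"),
               "N")
  set.seed(11)
  for (rep in 1:5) {
    g <- data.frame(id = "g", seq = random_dna_str(20000))
    kmers <- vapply(1:4, function(i) random_dna_str(6), character(1))
    got <- count_kmer_frequency(g, kmers)
    want <- vapply(kmers, function(k) oracle_kmer_count(g$seq, k), numeric(1))
    expect_equal(unname(got), unname(want))
  }
})

test_that("PAM-N substitution expands the wildcard position before counting", {
  ## genome contains TGG and CGG versions of the same site
  core <- strrep("ACGTC", 4)
  g <- data.frame(id = "g", seq = paste0(core, "TGG", "TTTT", core, "CGG"))
  km <- paste0(core, "TGG")
  plain <- count_kmer_frequency(g, km, both_strands = FALSE)
  expanded <- count_kmer_frequency(g, km, pam_substitution = TRUE,
                                   both_strands = FALSE)
  expect_equal(unname(plain), 1L)
  expect_equal(unname(expanded), 2L)
})

test_that("tier assignment follows the PAM-diagnostic and frequency rules", {
  cands <- data.frame(diag_in_pam_GGCC = c(TRUE, FALSE, FALSE),
                      genome_freq = c(999L, 150L, 300L))
  out <- assign_tier(cands, target_copy_count = 100L)
  expect_equal(out$tier, c("Tier0", "Tier1", "Tier2"))
  expect_error(assign_tier(cands, 0L), "positive")
})

test_that("ranking prefers low tier, many diagnostics, 3'-proximal position", {
  cands <- data.frame(seq23 = letters[1:4], pam_side = "three_prime_NGG",
                      consensus_pos = c(10L, 500L, 900L, 901L),
                      n_diag = c(1L, 5L, 2L, 2L), diag_hits = "0",
                      diag_in_pam_GGCC = FALSE, genome_freq = 1L,
                      tier = c("Tier1", "Tier1", "Tier0", "Tier1"))
  out <- rank_guides(cands, consensus_len = 1000L)
  ## Tier0 first regardless of other keys; then more diagnostics; then 3' end
  expect_equal(out$seq23, c("c", "b", "d", "a"))
  single <- cands[2, , drop = FALSE]
  expect_equal(rank_guides(single, 1000L), single)
  expect_error(rank_guides(cands[0, ], 1000L), "no candidates")
})

test_that("guide-bound classes match the exhaustive DP oracle and the quoted rules", {
  g23 <- random_dna_str(23)
  flank <- random_dna_str(60)
  expect_equal(classify_guide_match(g23, paste0(flank, g23, flank)), "lower")
  two_subs <- paste0(substr(g23, 1, 4), revcomp(substr(g23, 5, 6)),
                     substr(g23, 7, 23))
  cls2 <- classify_guide_match(g23, paste0(flank, two_subs, flank))
  expect_true(cls2 %in% c("lower", "intermediate"))
  expect_equal(cls2, oracle_guide_class(g23, paste0(flank, two_subs, flank)))
  expect_equal(classify_guide_match(g23, "ACGTACGTACGT"), "none")  # < 14 bp
  expect_error(classify_guide_match("ACGT", "ACGT"), "23")

  ## reverse-strand matches are counted
  expect_equal(classify_guide_match(g23, paste0(flank, revcomp(g23), flank)),
               "lower")
})

test_that("capture-bound summaries nest and agree with the per-copy oracle", {
  set.seed(7)
  guide <- random_dna_str(23)
  copies <- lapply(1:40, function(i) {
    n_ed <- sample(0:5, 1)
    el <- guide
    for (k in seq_len(n_ed)) {
      p <- sample(23, 1)
      substr(el, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(el, p, p)), 1)
    }
    paste0(random_dna_str(30), el, random_dna_str(30))
  })
  genome <- data.frame(id = "g", seq = paste(unlist(copies), collapse = ""))
  w <- nchar(copies[[1]])
  ann <- data.frame(ref_name = "g", start = (0:39) * w, end = (1:40) * w,
                    strand = "+", family = "L1", subfamily = "L1Hs")
  bs <- compute_capture_bounds(guide, genome, ann)
  classes <- vapply(copies, function(el) classify_guide_match(guide, el),
                    character(1))
  expect_equal(bs$n_lower, sum(classes == "lower"))
  expect_equal(bs$n_intermediate, sum(classes %in% c("lower", "intermediate")))
  expect_equal(bs$n_upper, sum(classes != "none"))
  expect_true(bs$n_lower <= bs$n_intermediate & bs$n_intermediate <= bs$n_upper)

  ## all copies exact -> every class equals the copy count
  genome2 <- data.frame(id = "g", seq = strrep(paste0(random_dna_str(20), guide,
                                                      random_dna_str(20)), 5))
  ann2 <- data.frame(ref_name = "g", start = (0:4) * 63L, end = (1:5) * 63L,
                     strand = "+", family = "L1", subfamily = "L1Hs")
  bs2 <- compute_capture_bounds(guide, genome2, ann2)
  expect_equal(unlist(bs2[, c("n_lower", "n_intermediate", "n_upper")],
                      use.names = FALSE), rep(5L, 3))

  ## empty element set -> empty summary; out-of-bounds feature errors
  expect_equal(nrow(compute_capture_bounds(guide, genome, ann[0, ])), 0L)
  bad <- ann[1, ]; bad$end <- nchar(genome$seq) + 10L
  expect_error(compute_capture_bounds(guide, genome, bad), "outside")
})
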