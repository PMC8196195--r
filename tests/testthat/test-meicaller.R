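mk_aln <- function(cigar, read_len, read_start, read_end, ref_start, ref_end,
                   strand = "+", id = "r1") {
  data.frame(read_id = id, read_len = read_len, read_start = read_start,
             read_end = read_end, strand = strand, ref_name = "chrT",
             ref_len = NA, ref_start = ref_start, ref_end = ref_end,
             mapq = 60L, cigar = cigar)
}

test_that("insertion signals come from long CIGAR insertions and terminal clips", {
  read <- strrep("A", 700)
  aln <- mk_aln("100M500I100M", 700L, 0L, 700L, 1000L, 1200L)
  sig <- extract_insertion_signals(aln, read)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$source, "cigar_insertion")
  expect_equal(sig$breakpoint, 1100L)
  expect_equal(sig$ins_len, 500L)

  ## plain match yields nothing
  expect_equal(nrow(extract_insertion_signals(mk_aln("200M", 200L, 0L, 200L,
                                                     0L, 200L), strrep("A", 200))),
               0L)

  ## 300S200M: leading soft clip becomes a 3'-junction signal at ref_start
  clip <- extract_insertion_signals(mk_aln("200M", 500L, 300L, 500L, 1000L,
                                           1200L), strrep("C", 500))
  expect_equal(clip$source, "soft_clip")
  expect_equal(clip$bk_type, "bp3")
  expect_equal(clip$breakpoint, 1000L)
  expect_equal(clip$ins_len, 300L)

  ## short insertions and clips fall below the thresholds
  small <- extract_insertion_signals(mk_aln("100M50I100M", 250L, 0L, 250L,
                                            0L, 200L), strrep("A", 250))
  expect_equal(nrow(small), 0L)

  ## CIGAR insertions inside masked read intervals are suppressed
  masked <- list(read_id = "r1", read_len = 700L,
                 masked = casmei:::iv(0L, 700L),
                 unmasked = casmei:::iv(integer(0), integer(0)))
  expect_equal(nrow(extract_insertion_signals(aln, read, masked)), 0L)
})

test_that("subfamily assignment identifies family, strand and 5' inversion", {
  lib <- toy_consensus_library(targets_only = TRUE)
  yb <- lib$seq[lib$id == "AluYb8"]
  asg <- assign_subfamily(yb, lib)
  expect_equal(asg$subfamily, "AluYb8")    # CAGTCCG-bearing consensus wins
  expect_equal(asg$strand, "+")

  asg_rc <- assign_subfamily(revcomp(yb), lib)
  expect_equal(asg_rc$subfamily, "AluYb8")
  expect_equal(asg_rc$strand, "-")

  l1 <- lib$seq[lib$id == "L1Hs"]
  twin <- paste0(revcomp(substr(l1, 1, 2500)), substr(l1, 2501, 6000))
  asg_tw <- assign_subfamily(twin, lib)
  expect_equal(asg_tw$subfamily, "L1Hs")
  expect_true(asg_tw$inverted5)
  expect_equal(asg_tw$strand, "+")         # strand follows the 3' half

  withr::with_seed(3, {
    unk <- assign_subfamily(random_dna_str(500), lib)
    expect_equal(unk$family, "unknown")
  })
})

test_that("TSD detection recovers the duplicated word across the junctions", {
  withr::with_seed(9, {
    tsd <- random_dna_str(12)
    f5 <- paste0(random_dna_str(30), tsd)
    f3 <- paste0(tsd, random_dna_str(30))
    expect_equal(detect_tsd(f5, f3), tsd)

    ## unrelated flanks: no duplication
    expect_true(is.na(detect_tsd(random_dna_str(40), random_dna_str(40))))

    ## one substitution within tolerance; the 3'-side word is returned
    tsd8 <- random_dna_str(8)
    tsd8_mut <- tsd8
    substr(tsd8_mut, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                      substr(tsd8, 4, 4))[1]
    got <- detect_tsd(paste0(random_dna_str(30), tsd8_mut),
                      paste0(tsd8, random_dna_str(30)))
    expect_equal(substr(got, 1, 8), tsd8)
  })
})

test_that("poly(A) measurement respects purity windows and strand", {
  expect_equal(detect_polya(paste0(strrep("CG", 25), strrep("A", 30))), 30L)
  expect_equal(detect_polya(paste0("CCCCC", strrep("A", 9))), 0L)
  ## A12-G-A12 with impure-window guard: tract is 25, not 26
  expect_equal(detect_polya(paste0("CCCCC", strrep("A", 12), "G",
                                   strrep("A", 12))), 25L)
  ## minus strand: leading T-tract reported as poly(A)
  expect_equal(detect_polya(paste0(strrep("T", 22), strrep("GC", 25)),
                            strand = "-"), 22L)
})

test_that("EN motif scoring counts Hamming matches to TTTT/AA", {
  expect_equal(detect_en_motif("TTTTAA"), 6L)
  expect_equal(detect_en_motif("GGGGGG"), 0L)
  ## TTTAAA vs TTTTAA: positions 1-3, 5 and 6 agree
  expect_equal(detect_en_motif("TTTAAA"), 5L)
  expect_equal(detect_en_motif("GTTAAG"), 3L)
  expect_equal(detect_en_motif("CGTTTTAACG"), 6L)  # centred window
  expect_error(detect_en_motif("TTT"), "6")
})

test_that("single-linkage clustering applies the support threshold", {
  sig <- function(bps, ids = paste0("r", seq_along(bps))) {
    data.frame(read_id = ids, ref_name = "chrT", strand = "+",
               source = "soft_clip", bk_type = "bp3", breakpoint = bps,
               ins_len = 300L, ins_seq = strrep("A", 300))
  }
  cl <- cluster_supporting_reads(sig(c(100L, 110L, 120L, 130L, 140L)))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$support, 5L)
  expect_equal(cl[[1]]$position, 120L)

  expect_length(cluster_supporting_reads(sig(c(100L, 110L, 120L))), 0L)

  two <- cluster_supporting_reads(sig(c(100L, 120L, 140L, 160L,
                                        1100L, 1120L, 1140L, 1160L)))
  expect_length(two, 2L)

  ## duplicate read ids count once toward support
  dup <- cluster_supporting_reads(sig(c(100L, 110L, 120L, 130L),
                                      ids = c("a", "a", "b", "c")))
  expect_length(dup, 0L)
})

test_that("genotype rule splits on the carrier fraction", {
  expect_equal(genotype_call(10, 10), "hom")
  expect_equal(genotype_call(5, 10), "het")
  expect_equal(genotype_call(1, 10), "unknown")
  expect_equal(genotype_call(8, 10), "hom")      # boundary f = 0.8
  expect_error(genotype_call(1, 0), "positive")
})

test_that("depth filter enforces the strict <2-fold pass region", {
  cov <- rep(10, 3000)
  cov[1251:1750] <- 25                       # 2.5x the flank median
  expect_false(apply_depth_filter(1500L, cov)$pass)
  cov[1251:1750] <- 12                       # 1.2x
  expect_true(apply_depth_filter(1500L, cov)$pass)
  cov[1251:1750] <- 20                       # exactly 2.0x fails
  expect_false(apply_depth_filter(1500L, cov)$pass)
  zero <- rep(0, 3000); zero[1251:1750] <- 5
  expect_equal(apply_depth_filter(1500L, zero)$reason, "no_flank_coverage")
})

test_that("calling returns nothing without implants or sufficient support", {
  fx <- cas9_fixture()
  ## reads from an implant-free donor: no non-reference calls
  cfg0 <- sim_config(genome_len = 300000L, nonref_n = 0L, reads_per_cut = 5,
                     error_sub = 0, error_ins = 0, error_del = 0)
  ref0 <- build_reference(cfg0, 42)
  donor0 <- implant_nonreference(ref0, cfg0, 42)
  run0 <- simulate_cas9_run(donor0, l1_guide()$guide, cfg0, 42)
  calls0 <- call_nonreference(run0$reads, run0$alignments, ref0$annotation,
                              ref0$consensus, ref0$genome)
  expect_equal(nrow(calls0[calls0$status == "non_reference", ]), 0L)

  ## no call is ever emitted below the support threshold
  calls <- call_nonreference(fx$run$reads, fx$run$alignments,
                             fx$ref$annotation, fx$ref$consensus,
                             fx$ref$genome, params = list(min_support = 6L))
  expect_true(all(calls$support >= 6L))
})

test_that("het and hom loci separate by the genotype rule at WGS depth", {
  fx <- wgs_fixture()
  calls <- call_nonreference(fx$run$reads, fx$run$alignments,
                             fx$ref$annotation, fx$ref$consensus, fx$ref$genome)
  truth <- fx$donor$loci
  m <- match(calls$position, truth$canonical_position)
  expect_true(all(!is.na(m)))
  concord <- mean(calls$genotype == ifelse(truth$zygosity[m] == "hom",
                                           "hom", "het"))
  expect_gte(concord, 0.9)
})
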