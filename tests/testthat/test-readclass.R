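mk_reads <- function(seqs, q = 30L) {
  data.frame(id = paste0("r", seq_along(seqs)), seq = seqs,
             qual = vapply(nchar(seqs), function(n) strrep(intToUtf8(33L + q), n),
                           character(1)),
             mean_q = as.numeric(q))
}

test_that("quality filter keeps reads with mean Q strictly above threshold", {
  reads <- mk_reads(c("ACGT", "ACGT", "ACGT"))
  reads$mean_q <- c(10, 2, 7)
  flt <- filter_reads(reads)
  expect_equal(flt$kept$id, "r1")          # Q-score > 7 is strict: 7.0 drops
  expect_equal(flt$dropped$id, c("r2", "r3"))
})

test_that("end scan localises consensus fragments to the correct read end", {
  lib <- toy_consensus_library(targets_only = TRUE)
  l1 <- lib$seq[lib$id == "L1Hs"]
  withr::with_seed(5, {
    flank <- random_dna_str(900)
    r5 <- mk_reads(paste0(substr(l1, 1, 100), flank))
    s5 <- scan_read_for_mei(r5, lib)
    expect_equal(s5$location, "end5")
    expect_equal(s5$family, "L1")

    r3 <- mk_reads(paste0(flank, substr(l1, 1001, 1100)))
    expect_equal(scan_read_for_mei(r3, lib)$location, "end3")

    rb <- mk_reads(paste0(substr(l1, 1, 100), flank, substr(l1, 2001, 2100)))
    expect_equal(scan_read_for_mei(rb, lib)$location, "both")

    rn <- mk_reads(random_dna_str(1000))
    expect_equal(scan_read_for_mei(rn, lib)$location, "none")

    ## interior-only fragments are 'middle' when interior scanning is on
    rm <- mk_reads(paste0(random_dna_str(400), substr(l1, 3001, 3200),
                          random_dna_str(400)))
    expect_equal(scan_read_for_mei(rm, lib, scan_interior = TRUE)$location,
                 "middle")
    expect_equal(scan_read_for_mei(rm, lib)$location, "none")
  })
  expect_error(scan_read_for_mei(mk_reads("ACGT"), lib[0, ]), "empty")
})

test_that("reads with a single terminal MEI fragment are never labelled both", {
  lib <- toy_consensus_library(targets_only = TRUE)
  l1 <- lib$seq[lib$id == "L1Hs"]
  index <- casmei:::build_scan_index(lib)
  withr::with_seed(6, {
    for (i in 1:20) {
      flank <- random_dna_str(sample(500:2000, 1))
      frag <- substr(l1, i * 150 + 1, i * 150 + 150)
      seq <- if (i %% 2) paste0(frag, flank) else paste0(flank, frag)
      s <- scan_read_for_mei(mk_reads(seq), lib, index = index)
      expect_true(s$location %in% c("end5", "end3"))
    }
  })
})

test_that("annotation projects through the CIGAR onto read coordinates", {
  ann <- data.frame(ref_name = "chrT", start = 1000L, end = 2000L,
                    strand = "+", family = "L1", subfamily = "L1Hs")
  ## read fully inside the element
  aln <- data.frame(read_id = "r", read_len = 500L, read_start = 0L,
                    read_end = 500L, strand = "+", ref_name = "chrT",
                    ref_len = NA, ref_start = 1100L, ref_end = 1600L,
                    mapq = 60L, cigar = "500M")
  mr <- project_annotation_to_read(aln, ann)
  expect_equal(mr$masked, casmei:::iv(0L, 500L))
  expect_equal(nrow(mr$unmasked), 0L)

  ## 100M500I100M with both M blocks inside the feature: insertion unmasked
  aln2 <- data.frame(read_id = "r", read_len = 700L, read_start = 0L,
                     read_end = 700L, strand = "+", ref_name = "chrT",
                     ref_len = NA, ref_start = 1200L, ref_end = 1400L,
                     mapq = 60L, cigar = "100M500I100M")
  mr2 <- project_annotation_to_read(aln2, ann)
  expect_equal(mr2$masked, casmei:::iv(c(0L, 600L), c(100L, 700L)))
  expect_equal(mr2$unmasked, casmei:::iv(100L, 600L))

  ## mapping outside all features: nothing masked
  aln3 <- aln; aln3$ref_start <- 5000L; aln3$ref_end <- 5500L
  mr3 <- project_annotation_to_read(aln3, ann)
  expect_equal(nrow(mr3$masked), 0L)
  expect_equal(mr3$unmasked, casmei:::iv(0L, 500L))

  ## masked and unmasked intervals always partition [0, read_len)
  for (mr_i in list(mr, mr2, mr3)) {
    all_iv <- rbind(mr_i$masked, mr_i$unmasked)
    merged <- casmei:::iv_sort_merge(all_iv)
    expect_equal(merged, casmei:::iv(0L, mr_i$read_len))
    expect_equal(sum(all_iv[, 2] - all_iv[, 1]), mr_i$read_len)
  }

  bad <- aln; bad$cigar <- "400M"
  expect_error(project_annotation_to_read(bad, ann), "inconsistent")
})

test_that("per-read classification follows the precedence and family rules", {
  ann <- data.frame(ref_name = "chrT",
                    start = c(1000L, 5000L, 9000L, 13000L),
                    end = c(7000L, 11000L, 15000L, 19000L) - 4000L,
                    strand = "+", family = c("L1", "L1", "SVA", "Alu"),
                    subfamily = c("L1Hs", "L1PA4", "SVA_A", "AluSx"))
  base_aln <- data.frame(read_id = "r", read_len = 2000L, read_start = 0L,
                         read_end = 2000L, strand = "+", ref_name = "chrT",
                         ref_len = NA, ref_start = 1200L, ref_end = 3200L,
                         mapq = 60L, cigar = "2000M")
  sig_l1 <- list(family = "L1", subfamily_best = "L1Hs", location = "end5",
                 score = 200)
  sig_none <- list(family = NA, subfamily_best = NA, location = "none", score = 0)

  ## insertion signal from pre-masking wins over everything mapped
  expect_equal(classify_read(base_aln, sig_none, TRUE, "L1Hs", ann)$category,
               "on_target_nonreference")
  ## low MAPQ discards first
  low <- base_aln; low$mapq <- 5L
  expect_equal(classify_read(low, sig_l1, TRUE, "L1Hs", ann)$category,
               "discarded_mapq")
  expect_equal(classify_read(NULL, sig_l1, FALSE, "L1Hs", ann)$category,
               "discarded_mapq")
  ## mapped into the target subfamily element
  expect_equal(classify_read(base_aln, sig_l1, FALSE, "L1Hs", ann)$category,
               "on_target_reference")
  ## mapped into reference L1PA: close target for L1Hs experiments
  pa <- base_aln; pa$ref_start <- 5200L; pa$ref_end <- 7200L
  expect_equal(classify_read(pa, sig_l1, FALSE, "L1Hs", ann)$category,
               "close_target")
  ## SVA experiments define no off-target when an MEI signal is present
  sva <- base_aln; sva$ref_start <- 9200L; sva$ref_end <- 11200L
  sig_sva <- list(family = "SVA", subfamily_best = "SVA_F", location = "end3",
                  score = 150)
  expect_equal(classify_read(sva, sig_sva, FALSE, "SVA_F", ann)$category,
               "close_target")
  ## off-family element: off-target only without an MEI signal (SVA rule)
  alu <- base_aln; alu$ref_start <- 13200L; alu$ref_end <- 15200L
  expect_equal(classify_read(alu, sig_sva, FALSE, "SVA_F", ann)$category,
               "close_target")
  expect_equal(classify_read(alu, sig_none, FALSE, "SVA_F", ann)$category,
               "off_target")
  expect_equal(classify_read(alu, sig_none, FALSE, "L1Hs", ann)$category,
               "off_target")
  expect_error(classify_read(base_aln, sig_l1, FALSE, "HERVK", ann), "unknown")
})

test_that("rate table fractions are over passed reads and sum to one", {
  cls <- data.frame(read_id = paste0("r", 1:10),
                    category = c(rep("on_target_reference", 3),
                                 rep("on_target_nonreference", 3),
                                 rep("close_target", 2), "off_target",
                                 "discarded_quality"),
                    basis = "", read_len = 1000L)
  sig <- data.frame(read_id = paste0("r", 1:9), family = "L1",
                    subfamily_best = "L1Hs",
                    location = c(rep("end5", 4), rep("both", 3), "none", "none"),
                    score = 100)
  rates <- tally_target_rates(cls, sig)
  expect_equal(sum(rates$rates$fraction), 1, tolerance = 1e-9)
  expect_equal(rates$rates$n[rates$rates$category == "on_target_reference"], 3L)
  expect_equal(rates$wide$n_reads, 9L)     # discarded read excluded
  expect_true(all(c("end5", "both") %in% rates$by_location$location))
  single <- cls[1, , drop = FALSE]
  r1 <- tally_target_rates(single, sig[1, , drop = FALSE])
  expect_equal(r1$wide$on_ref_pct, 100)
  expect_error(tally_target_rates(cls[cls$category == "discarded_quality", ,
                                      drop = FALSE], sig), "non-discarded")
})
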