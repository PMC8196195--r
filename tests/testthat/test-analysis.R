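test_that("cleavage histogram concentrates at configured offsets and filters the rest", {
  fx <- cas9_fixture()
  lib <- fx$ref$consensus
  l1 <- lib$seq[lib$id == "L1Hs"]
  ch <- cleavage_site_histogram(fx$run$reads, l1, l1_guide()$pam)
  ## inclusion + exclusion partitions the input exactly
  expect_equal(ch$n_included + sum(ch$excluded$n), nrow(fx$run$reads))
  expect_setequal(unique(ch$per_read$reason),
                  c("included", "min_score", "not_first_base"))
  ## cut-origin reads (error-free, zero-divergence site) sit at 3/4 and 7
  m <- fx$run$manifest
  cut_l1hs <- m$read_id[m$origin == "cut" & m$site_kind %in% c("reference", "nonref")]
  pr <- ch$per_read[ch$per_read$read_id %in% cut_l1hs &
                    ch$per_read$reason == "included", ]
  fwd <- pr$distance[pr$strand == "forward"]
  rev <- pr$distance[pr$strand == "reverse"]
  expect_true(all(fwd %in% c(3L, 4L)))
  expect_true(all(rev == 7L))
  expect_gt(length(fwd), 0)
  expect_gt(length(rev), 0)
  expect_error(cleavage_site_histogram(fx$run$reads, l1, -1L), "PAM")
})

test_that("strand bias is the forward to reverse read ratio", {
  expect_equal(strand_bias(c(rep("fwd", 46), rep("rev", 10))), 4.6)
  expect_equal(strand_bias(c(rep("fwd", 10), rep("rev", 10))), 1)
  expect_equal(strand_bias(rep("fwd", 5)), Inf)
  fx <- cas9_fixture()
  b <- strand_bias(fx$run$manifest$direction)
  n <- sum(!is.na(fx$run$manifest$direction))
  p <- b / (1 + b)
  expect_lt(abs(p - 4.6 / 5.6), 3.3 * sqrt(0.821 * 0.179 / n))
})

test_that("saturation is monotone in merged reads and anti-monotone in cutoff", {
  fx <- cas9_fixture()
  aln_best <- casmei:::best_alignment_per_read(fx$run$alignments)
  mei_ann <- fx$ref$annotation
  sig <- casmei:::extract_run_signals(fx$run$reads, aln_best, mei_ann)
  ## split signals into three pseudo-runs of unequal size
  grp <- rep(1:3, length.out = nrow(sig))
  runs <- lapply(1:3, function(g) {
    list(signals = sig[grp == g, , drop = FALSE],
         on_target_reads = sum(grp == g))
  })
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    sat <- saturation_curve(runs[perm])
    for (cut in unique(sat$cutoff)) {
      expect_true(all(diff(sat$calls[sat$cutoff == cut]) >= 0))
    }
    by_step <- split(sat, sat$step)
    for (st in by_step) {
      expect_true(all(diff(st$calls[order(st$cutoff)]) <= 0))
    }
  }
  one <- saturation_curve(runs[1])
  expect_equal(nrow(one), 3L)
})

test_that("a locus below cutoff in one run appears only after merging", {
  sig_at <- function(ids, bp = 5000L) {
    data.frame(read_id = ids, ref_name = "chrT", strand = "+",
               source = "soft_clip", bk_type = "bp3",
               breakpoint = bp + seq_along(ids), ins_len = 300L,
               ins_seq = strrep("A", 300))
  }
  runs <- list(list(signals = sig_at(c("a1", "a2")), on_target_reads = 100),
               list(signals = sig_at(c("b1", "b2")), on_target_reads = 50))
  sat <- saturation_curve(runs, cutoffs = 4L)
  expect_equal(sat$calls, c(0L, 1L))       # support 2 then 4 after merging
})

test_that("trio transmission categories follow parental matching", {
  mk_calls <- function(pos, subfam = "L1Hs", support = 10L) {
    data.frame(ref_name = "chrT", position = pos, subfamily = subfam,
               strand = "+", length = 1000L, support = support,
               genotype = "het", tsd = NA, polya_len = 20L, en_matches = 4L,
               inverted5 = FALSE, transduction = NA, status = "non_reference",
               filter = "PASS")
  }
  child <- mk_calls(c(1000L, 5000L, 9000L, 13000L))
  p1 <- mk_calls(c(1020L, 9050L, 20000L), support = 15L)
  p2 <- mk_calls(c(9060L, 30000L))
  tr <- trio_transmission(child, p1, p2)
  ch <- tr$records[tr$records$role == "child", ]
  expect_equal(ch$category,
               c("from_parent1", "unmatched", "either_parent", "unmatched"))
  par <- tr$records[tr$records$role != "child", ]
  expect_equal(sum(par$category == "untransmitted_parent_call"), 2L)
  ## family must agree: an Alu parent call never matches an L1 child call
  p_alu <- mk_calls(1020L, subfam = "AluYb8")
  tr2 <- trio_transmission(child, p_alu, p2[0, ])
  expect_equal(tr2$records$category[1], "unmatched")
})

test_that("depth and enrichment ratios are plain means and folds", {
  a <- data.frame(support = c(10L, 10L))
  b <- data.frame(support = c(5L, 5L))
  expect_equal(depth_ratio(a, b), 2)
  expect_equal(depth_ratio(a, a), 1)
  expect_error(depth_ratio(a[0, , drop = FALSE], b), "non-empty")
  expect_equal(unname(fold_enrichment(26.8, 2.0)), 13.4)
  expect_equal(unname(fold_enrichment(c(x = 5), c(x = 5))), 1)
  expect_error(fold_enrichment(5, 0), "positive")
})

test_that("recurrence matrix equals the naive double loop and its geometry", {
  withr::with_seed(13, {
    s <- random_dna_str(100)
    rm1 <- recurrence_matrix(s, s, 10)
    expect_equal(nrow(rm1), 91L)
    expect_true(all(rm1$i == rm1$j))
    rm2 <- recurrence_matrix(s, revcomp(s), 10, "revcomp")
    expect_true(all(rm2$i + rm2$j == 90L))

    a <- random_dna_str(300)
    b <- paste0(random_dna_str(80), substr(a, 101, 180), random_dna_str(80))
    got <- recurrence_matrix(a, b, 10)
    want <- oracle_recurrence(a, b, 10)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)

    ## unrelated kilobase sequences share essentially no 10-mers
    x <- random_dna_str(1000); y <- random_dna_str(1000)
    expect_lt(nrow(recurrence_matrix(x, y, 10)), 5L)
  })
})
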