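## Non-reference MEI calling: insertion-signal extraction from CIGARs and
## soft clips (restricted to unmasked read intervals), breakpoint
## canonicalisation, subfamily/strand/5'-inversion assignment, TPRT hallmark
## detection (TSD, poly(A), endonuclease motif, empty site), single-linkage
## clustering of supporting reads, genotyping, and read-depth filtering.

EN_MOTIF <- c("T", "T", "T", "T", "A", "A")   # canonical L1 EN site TTTT/AA

#' Extract insertion signals from one alignment
#'
#' CIGAR `I` operations of at least `min_ins_len` bases and terminal soft
#' clips of at least `min_clip_len` bases become insertion signals; CIGAR
#' insertions must fall in unmasked read intervals (majority overlap) when a
#' mask is supplied. Sequences are reported in reference-forward
#' orientation. Clip signals are typed by the junction they evidence: a
#' leading (left) clip ends at the locus 3' breakpoint, a trailing (right)
#' clip at the 5' breakpoint.
#'
#' @param aln one-row alignment table.
#' @param read_seq the read sequence (original orientation).
#' @param masked optional [project_annotation_to_read()] result.
#' @param min_ins_len minimum CIGAR insertion length (default 100).
#' @param min_clip_len minimum terminal clip length (default 200).
#' @return data.frame of signals: `read_id`, `ref_name`, `strand`, `source`,
#'   `bk_type` (`bp3`/`bp5`/`both`), `breakpoint`, `ins_len`, `ins_seq`.
#' @export
extract_insertion_signals <- function(aln, read_seq, masked = NULL,
                                      min_ins_len = 100L, min_clip_len = 200L) {
  ops <- parse_cigar(aln$cigar)
  rseq <- if (aln$strand == "+") read_seq else revcomp(read_seq)
  q_off <- aln_q_offset(aln)
  rows <- list()
  bl <- cigar_blocks(ops, aln$ref_start)
  insb <- bl[bl$op == "I" & bl$len >= min_ins_len, , drop = FALSE]
  for (j in seq_len(nrow(insb))) {
    qs <- insb$q_start[j] + q_off; qe <- insb$q_end[j] + q_off
    if (!is.null(masked)) {
      if (iv_overlap_bp(qs, qe, masked$unmasked) < (qe - qs) / 2) next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = aln$read_id, ref_name = aln$ref_name, strand = aln$strand,
      source = "cigar_insertion", bk_type = "both", breakpoint = insb$r_start[j],
      ins_len = qe - qs, ins_seq = substr(rseq, qs + 1L, qe))
  }
  left_clip <- q_off
  right_clip <- aln$read_len - q_off - sum(bl$len[bl$op %in% c("M", "=", "X", "I")])
  if (left_clip >= min_clip_len) {
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = aln$read_id, ref_name = aln$ref_name, strand = aln$strand,
      source = "soft_clip", bk_type = "bp3", breakpoint = aln$ref_start,
      ins_len = left_clip, ins_seq = substr(rseq, 1L, left_clip))
  }
  if (right_clip >= min_clip_len) {
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = aln$read_id, ref_name = aln$ref_name, strand = aln$strand,
      source = "soft_clip", bk_type = "bp5", breakpoint = aln$ref_end,
      ins_len = right_clip,
      ins_seq = substr(rseq, aln$read_len - right_clip + 1L, aln$read_len))
  }
  do.call(rbind, rows) %||% empty_signals()
}

empty_signals <- function() {
  data.frame(read_id = character(0), ref_name = character(0),
             strand = character(0), source = character(0),
             bk_type = character(0), breakpoint = integer(0),
             ins_len = integer(0), ins_seq = character(0))
}

## all insertion signals of a run (pre-masking applied per read)
extract_run_signals <- function(reads, aln_best, mei_annotation,
                                min_ins_len = 100L, min_clip_len = 200L) {
  out <- list()
  seqs <- setNames(reads$seq, reads$id)
  for (i in seq_len(nrow(aln_best))) {
    aln <- aln_best[i, , drop = FALSE]
    rs <- seqs[[aln$read_id]]
    if (is.null(rs)) next
    masked <- project_annotation_to_read(aln, mei_annotation)
    sig <- extract_insertion_signals(aln, rs, masked, min_ins_len, min_clip_len)
    if (nrow(sig)) out[[length(out) + 1L]] <- sig
  }
  do.call(rbind, out) %||% empty_signals()
}

## Shift an insertion placement to its leftmost and rightmost equivalent
## positions (classic indel normalisation); applied to CIGAR insertions so
## both TSD junctions can be recovered from single-read evidence.
canonicalize_insertion <- function(genome_seq, breakpoint, ins_seq, max_shift = 60L) {
  b_left <- breakpoint; ins_left <- ins_seq
  for (s in seq_len(max_shift)) {
    last <- substr(ins_left, nchar(ins_left), nchar(ins_left))
    if (b_left <= 0L || substr(genome_seq, b_left, b_left) != last) break
    ins_left <- paste0(last, substr(ins_left, 1L, nchar(ins_left) - 1L))
    b_left <- b_left - 1L
  }
  b_right <- breakpoint; ins_right <- ins_seq
  n <- nchar(genome_seq)
  for (s in seq_len(max_shift)) {
    first <- substr(ins_right, 1L, 1L)
    if (b_right >= n || substr(genome_seq, b_right + 1L, b_right + 1L) != first) break
    ins_right <- paste0(substr(ins_right, 2L, nchar(ins_right)), first)
    b_right <- b_right + 1L
  }
  list(b_left = b_left, b_right = b_right, ins_left = ins_left)
}

## Extend the aligned part through junction micro-homology: a trailing
## (bp5) clip whose first bases equal the reference after the junction --
## e.g. the duplicated TSD word -- is realigned rightward; a leading (bp3)
## clip whose last bases equal the reference before the junction is
## realigned leftward. This reproduces the placement a score-maximising
## aligner reports and makes the two junction medians straddle the TSD.
canonicalize_clip <- function(genome_seq, breakpoint, clip_seq, bk_type,
                              max_shift = 60L) {
  b <- breakpoint; clip <- clip_seq
  n <- nchar(genome_seq)
  if (bk_type == "bp5") {
    for (s in seq_len(min(max_shift, nchar(clip) - 1L))) {
      first <- substr(clip, 1L, 1L)
      if (b >= n || substr(genome_seq, b + 1L, b + 1L) != first) break
      clip <- substr(clip, 2L, nchar(clip))
      b <- b + 1L
    }
  } else {
    for (s in seq_len(min(max_shift, nchar(clip) - 1L))) {
      last <- substr(clip, nchar(clip), nchar(clip))
      if (b <= 0L || substr(genome_seq, b, b) != last) break
      clip <- substr(clip, 1L, nchar(clip) - 1L)
      b <- b - 1L
    }
  }
  list(b = b, clip = clip)
}

#' Assign an insertion sequence to a consensus subfamily
#'
#' Exact 13-mer seeds vote for every consensus on both strands; the
#' subfamily is the top-voted consensus and the score is the number of
#' matched seed bases. The 5' and 3' halves are scored separately: when
#' their best strands disagree for an L1 the insertion carries the
#' twin-priming 5' inversion signature.
#'
#' @param ins_seq insertion sequence (reference-forward orientation).
#' @param consensus_lib consensus table with `family`.
#' @param min_seeds minimum seed votes before a call is made.
#' @return list: `family`, `subfamily`, `strand`, `inverted5`, `score`.
#' @export
assign_subfamily <- function(ins_seq, consensus_lib, min_seeds = 5L) {
  if (!nzchar(ins_seq)) stop("empty insertion sequence")
  k <- 13L
  votes <- subfamily_votes(ins_seq, consensus_lib, k)
  if (!nrow(votes) || max(votes$n) < min_seeds) {
    return(list(family = "unknown", subfamily = "unknown", strand = NA_character_,
                inverted5 = FALSE, score = 0))
  }
  top <- votes[which.max(votes$n), ]
  fam <- consensus_lib$family[match(top$id, consensus_lib$id)]
  inverted5 <- FALSE
  half <- nchar(ins_seq) %/% 2L
  if (identical(fam, "L1") && half >= 3L * k) {
    v5 <- subfamily_votes(substr(ins_seq, 1L, half), consensus_lib, k)
    v3 <- subfamily_votes(substr(ins_seq, half + 1L, nchar(ins_seq)), consensus_lib, k)
    v5 <- v5[v5$id == top$id, , drop = FALSE]
    v3 <- v3[v3$id == top$id, , drop = FALSE]
    if (nrow(v5) && nrow(v3)) {
      s5 <- v5$strand[which.max(v5$n)]; s3 <- v3$strand[which.max(v3$n)]
      if (max(v5$n) >= min_seeds && max(v3$n) >= min_seeds && s5 != s3) {
        inverted5 <- TRUE
      }
    }
  }
  ## strand of the element is the strand of its 3' (poly(A)-proximal) half
  strand <- top$strand
  if (inverted5) {
    v3 <- subfamily_votes(substr(ins_seq, half + 1L, nchar(ins_seq)), consensus_lib, k)
    v3 <- v3[v3$id == top$id, , drop = FALSE]
    if (nrow(v3)) strand <- v3$strand[which.max(v3$n)]
  }
  list(family = fam, subfamily = top$id, strand = strand,
       inverted5 = inverted5, score = as.integer(top$n) * k)
}

subfamily_votes <- function(seq, consensus_lib, k) {
  n <- nchar(seq)
  if (n < k) {
    return(data.frame(id = character(0), strand = character(0), n = integer(0)))
  }
  kms <- unique(substring(seq, 1:(n - k + 1L), k:n))
  rows <- list()
  for (i in seq_len(nrow(consensus_lib))) {
    for (strand in c("+", "-")) {
      cs <- if (strand == "+") consensus_lib$seq[i] else revcomp(consensus_lib$seq[i])
      m <- nchar(cs)
      if (m < k) next
      ck <- unique(substring(cs, 1:(m - k + 1L), k:m))
      rows[[length(rows) + 1L]] <- data.frame(
        id = consensus_lib$id[i], strand = strand, n = sum(kms %in% ck))
    }
  }
  do.call(rbind, rows)
}

#' Detect a target site duplication across the two insertion breakpoints
#'
#' The longest word (within `[min_tsd, max_tsd]`) that ends at the 5'
#' breakpoint (suffix of `flank5_ref`) and reappears starting at the 3'
#' breakpoint (prefix of `flank3_ref`) with at most `max_mismatch`
#' substitutions. Returns the reference word at the 3' breakpoint, or `NA`
#' when no word of at least `min_tsd` bases qualifies.
#'
#' @param flank5_ref reference window ending at the 5' breakpoint.
#' @param flank3_ref reference window starting at the 3' breakpoint.
#' @param min_tsd,max_tsd length bounds (default 5, 30).
#' @param max_mismatch substitution tolerance (default 1).
#' @return the TSD motif, or `NA_character_`.
#' @export
detect_tsd <- function(flank5_ref, flank3_ref, min_tsd = 5L, max_tsd = 30L,
                       max_mismatch = 1L) {
  lmax <- min(max_tsd, nchar(flank5_ref), nchar(flank3_ref))
  if (lmax < min_tsd) return(NA_character_)
  s5 <- strsplit(flank5_ref, "")[[1]]
  s3 <- strsplit(flank3_ref, "")[[1]]
  n5 <- length(s5)
  for (L in lmax:min_tsd) {
    a <- s5[(n5 - L + 1L):n5]
    b <- s3[1:L]
    mm <- sum(a != b | a == "N" | b == "N")
    if (mm <= max_mismatch) return(paste(b, collapse = ""))
  }
  NA_character_
}

#' Measure a terminal poly(A) tract
#'
#' Longest terminal run in which every sliding window of `window` bases
#' keeps an adenine fraction of at least `purity`; tracts shorter than
#' `min_len` report 0. For minus-strand insertions the poly(A) appears as a
#' 5' poly(T) tract on the reference-forward insertion sequence; passing
#' `strand = "-"` scans that tract and reports it as poly(A).
#'
#' @param ins_seq insertion sequence (reference-forward orientation).
#' @param strand `"+"` (3' A-tract) or `"-"` (5' T-tract).
#' @param min_len minimum reportable tract (default 10).
#' @param purity minimum A fraction per window (default 0.8).
#' @param window sliding window size (default 20).
#' @return tract length in bases (0 when absent).
#' @export
detect_polya <- function(ins_seq, strand = "+", min_len = 10L, purity = 0.8,
                         window = 20L) {
  seq <- if (strand == "-") revcomp(ins_seq) else ins_seq
  b <- rev(strsplit(seq, "")[[1]]) == "A"   # terminal-first
  n <- length(b)
  best <- 0L
  lmax <- min(n, 400L)
  for (L in seq_len(lmax)) {
    ## an impure window stays in the window set for every larger L
    if (!windows_pure(b[1:L], window, purity)) break
    if (b[L]) best <- L                     # the tract must start on an A
  }
  if (best >= min_len) best else 0L
}

windows_pure <- function(x, window, purity) {
  L <- length(x)
  w <- min(window, L)
  cs <- cumsum(c(0L, as.integer(x)))
  counts <- cs[(w + 1L):(L + 1L)] - cs[1:(L - w + 1L)]
  all(counts / w >= purity)
}

#' Score the endonuclease cleavage motif at a breakpoint
#'
#' Hamming matches (0-6) of the 6-mer spanning the insertion point against
#' the canonical L1 endonuclease consensus 5'-TTTT/AA (4 bases upstream of
#' the nick, 2 downstream).
#'
#' @param flank_ref_window reference window of at least 6 bases centred on
#'   the cleavage position.
#' @return integer match count 0-6.
#' @export
detect_en_motif <- function(flank_ref_window) {
  n <- nchar(flank_ref_window)
  if (n < 6L) stop("window must be at least 6 bases")
  mid <- (n - 6L) %/% 2L
  w <- strsplit(substr(flank_ref_window, mid + 1L, mid + 6L), "")[[1]]
  sum(w == EN_MOTIF)
}

#' Cluster supporting insertion signals into locus calls
#'
#' Signals sorted by reference position are chained by single linkage with
#' gap <= `cluster_window`; clusters with at least `min_support` distinct
#' supporting reads yield a call at the median 3'-junction breakpoint, with
#' subfamily by majority vote (when signals carry one) and length by median.
#'
#' @param signals signal table ([extract_insertion_signals()] shape; a
#'   `subfamily` column is honoured when present).
#' @param cluster_window maximum gap between neighbouring breakpoints
#'   (default 100 bp).
#' @param min_support minimum distinct supporting reads (default 4).
#' @return list of clusters; each has `signals`, `support`, `position`,
#'   `b_left`, `b_right`, `ins_len`, `subfamily`.
#' @export
cluster_supporting_reads <- function(signals, cluster_window = 100L,
                                     min_support = 4L) {
  if (!nrow(signals)) return(list())
  signals <- signals[order(signals$ref_name, signals$breakpoint), , drop = FALSE]
  newc <- c(TRUE, signals$ref_name[-1] != signals$ref_name[-nrow(signals)] |
                  diff(signals$breakpoint) > cluster_window)
  grp <- cumsum(newc)
  out <- list()
  for (g in unique(grp)) {
    s <- signals[grp == g, , drop = FALSE]
    support <- length(unique(s$read_id))
    if (support < min_support) next
    bp3 <- s$breakpoint[s$bk_type %in% c("bp3", "both")]
    bp5 <- s$breakpoint[s$bk_type == "bp5"]
    if ("b_right" %in% names(s)) bp5 <- c(bp5, s$b_right[!is.na(s$b_right)])
    b_left <- if (length(bp3)) as.integer(round(median(bp3)))
              else as.integer(round(median(s$breakpoint)))
    b_right <- if (length(bp5)) as.integer(round(median(bp5))) else b_left
    sf <- NA_character_
    if ("subfamily" %in% names(s) && any(!is.na(s$subfamily))) {
      tt <- sort(table(s$subfamily), decreasing = TRUE)
      sf <- names(tt)[1]
    }
    out[[length(out) + 1L]] <- list(
      signals = s, support = support, position = b_left,
      b_left = b_left, b_right = max(b_left, b_right),
      ins_len = as.integer(round(median(s$ins_len))),
      ref_name = s$ref_name[1], subfamily = sf)
  }
  out
}

#' Genotype a call from carrier and locus-spanning read counts
#'
#' Carrier fraction `f = support / span_reads_total`: `hom` for `f >= 0.8`,
#' `het` for `0.2 <= f < 0.8`, `unknown` below.
#'
#' @param support supporting (carrier) read count.
#' @param span_reads_total reads overlapping the locus.
#' @param hom_min,het_min genotype thresholds.
#' @return `"hom"`, `"het"` or `"unknown"`.
#' @export
genotype_call <- function(support, span_reads_total, hom_min = 0.8, het_min = 0.2) {
  if (span_reads_total == 0) stop("span_reads_total must be positive")
  if (span_reads_total < support) stop("span_reads_total below support")
  f <- support / span_reads_total
  if (f >= hom_min) "hom" else if (f >= het_min) "het" else "unknown"
}

#' Read-depth filter around an insertion site
#'
#' Compares mean coverage in the `bin_bp` bin centred on the call with the
#' median of the two flanking bins; the call fails when the ratio reaches
#' `max_fold` in either direction (the pass region is a strict < 2-fold
#' difference).
#'
#' @param position 0-based insertion point.
#' @param coverage per-base coverage vector over the reference contig.
#' @param bin_bp bin width (default 500).
#' @param max_fold fold-difference bound (default 2).
#' @return list with `pass` and `reason`.
#' @export
apply_depth_filter <- function(position, coverage, bin_bp = 500L, max_fold = 2.0) {
  n <- length(coverage)
  h <- bin_bp %/% 2L
  centre <- mean(coverage[clamp_idx(position - h, position + h, n)])
  left <- mean(coverage[clamp_idx(position - h - bin_bp, position - h, n)])
  right <- mean(coverage[clamp_idx(position + h, position + h + bin_bp, n)])
  flank <- median(c(left, right), na.rm = TRUE)
  if (!is.finite(flank) || flank == 0) {
    return(list(pass = FALSE, reason = "no_flank_coverage"))
  }
  ratio <- centre / flank
  if (ratio >= max_fold || ratio <= 1 / max_fold) {
    list(pass = FALSE, reason = sprintf("depth_ratio_%.2f", ratio))
  } else list(pass = TRUE, reason = "PASS")
}

clamp_idx <- function(s0, e0, n) {
  s <- max(0L, as.integer(s0)); e <- min(n, as.integer(e0))
  if (e <= s) integer(0) else (s + 1L):e
}

#' Per-base coverage from an alignment table
#' @param alns alignment table.
#' @param ref_len contig length.
#' @return numeric coverage vector of length `ref_len`.
#' @export
coverage_from_alignments <- function(alns, ref_len) {
  cov <- numeric(ref_len + 1L)
  for (i in seq_len(nrow(alns))) {
    cov[alns$ref_start[i] + 1L] <- cov[alns$ref_start[i] + 1L] + 1
    cov[alns$ref_end[i] + 1L] <- cov[alns$ref_end[i] + 1L] - 1
  }
  cumsum(cov)[seq_len(ref_len)]
}

#' Call non-reference MEIs from a simulated or real run
#'
#' Composition of the caller: pre-masking, insertion-signal extraction,
#' breakpoint canonicalisation, clustering, subfamily assignment, hallmark
#' detection, genotyping and optional depth filtering. Calls overlapping an
#' annotated element of the same subfamily are flagged `status =
#' "reference"` rather than emitted as non-reference.
#'
#' @param reads read table.
#' @param alns alignment table (reference coordinates).
#' @param annotation repeat annotation.
#' @param consensus_lib consensus library with `family`.
#' @param genome reference sequence table.
#' @param params overrides: `min_ins_len`, `min_clip_len`, `cluster_window`,
#'   `min_support`, `min_tsd`, `max_tsd`, `tsd_max_mismatch`, `span_slack`,
#'   `depth_filter` (logical), `min_q`.
#' @return call table in `CALL_COLS` order plus `b_right`, `span_reads` and
#'   `empty_site_ok` columns.
#' @export
call_nonreference <- function(reads, alns, annotation, consensus_lib, genome,
                              params = list()) {
  p <- modifyList(list(min_ins_len = 100L, min_clip_len = 200L,
                       cluster_window = 100L, min_support = 4L,
                       min_tsd = 5L, max_tsd = 30L, tsd_max_mismatch = 1L,
                       span_slack = 20L, depth_filter = FALSE, min_q = 7),
                  params)
  gseq <- genome$seq[1]
  flt <- filter_reads(reads, p$min_q)
  aln_best <- best_alignment_per_read(alns)
  aln_best <- aln_best[aln_best$read_id %in% flt$kept$id, , drop = FALSE]
  mei_ann <- annotation[annotation$family %in% unique(consensus_lib$family), , drop = FALSE]
  sig <- extract_run_signals(flt$kept, aln_best, mei_ann,
                             p$min_ins_len, p$min_clip_len)
  if (!nrow(sig)) return(empty_calls())
  ## canonicalise placements so both junctions are recoverable: CIGAR
  ## insertions are shifted to both extremes; clip junctions are extended
  ## the way a score-maximising aligner would place them
  sig$b_right <- NA_integer_
  for (i in which(sig$source == "cigar_insertion")) {
    cn <- canonicalize_insertion(gseq, sig$breakpoint[i], sig$ins_seq[i])
    sig$breakpoint[i] <- cn$b_left
    sig$ins_seq[i] <- cn$ins_left
    sig$b_right[i] <- cn$b_right
  }
  for (i in which(sig$source == "soft_clip")) {
    cn <- canonicalize_clip(gseq, sig$breakpoint[i], sig$ins_seq[i], sig$bk_type[i])
    sig$breakpoint[i] <- cn$b
    sig$ins_seq[i] <- cn$clip
  }
  clusters <- cluster_supporting_reads(sig, p$cluster_window, p$min_support)
  if (!length(clusters)) return(empty_calls())
  cov <- if (p$depth_filter) coverage_from_alignments(aln_best, nchar(gseq)) else NULL
  calls <- lapply(clusters, function(cl) {
    summarise_cluster(cl, aln_best, annotation, consensus_lib, gseq, p, cov)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  out <- data.frame(ref_name = character(0), position = integer(0),
                    subfamily = character(0), strand = character(0),
                    length = integer(0), support = integer(0),
                    genotype = character(0), tsd = character(0),
                    polya_len = integer(0), en_matches = integer(0),
                    inverted5 = logical(0), transduction = character(0),
                    status = character(0), filter = character(0),
                    b_right = integer(0), span_reads = integer(0),
                    empty_site_ok = logical(0))
  out
}

summarise_cluster <- function(cl, aln_best, annotation, consensus_lib, gseq, p, cov) {
  s <- cl$signals
  b_left <- cl$b_left
  b_right <- max(b_left, cl$b_right)
  rep_seq <- s$ins_seq[which.max(s$ins_len)]
  asg <- assign_subfamily(rep_seq, consensus_lib)
  ## TSD across the two junctions
  f5 <- substr(gseq, max(1L, b_right - p$max_tsd - 5L + 1L), b_right)
  f3 <- substr(gseq, b_left + 1L, min(nchar(gseq), b_left + p$max_tsd + 5L))
  tsd <- detect_tsd(f5, f3, p$min_tsd, p$max_tsd, p$tsd_max_mismatch)
  ## poly(A): strand-aware, on junction-appropriate evidence
  polya <- polya_from_signals(s, asg$strand %||% "+", tsd, p)
  en <- detect_en_motif(substr(gseq, max(1L, b_left - 3L), b_left + 2L))
  spans <- aln_best$ref_end > b_left - p$span_slack &
           aln_best$ref_start < b_right + p$span_slack &
           aln_best$ref_name == cl$ref_name
  span_reads <- sum(spans)
  genotype <- genotype_call(min(cl$support, span_reads), max(span_reads, cl$support))
  feats <- annotation[annotation$ref_name == cl$ref_name &
                      annotation$subfamily == asg$subfamily &
                      annotation$start <= b_right & annotation$end >= b_left, ,
                      drop = FALSE]
  status <- if (nrow(feats)) "reference" else "non_reference"
  transduction <- transduction_tail(s, asg$strand %||% "+", tsd, polya)
  filter <- "PASS"
  if (!is.null(cov)) {
    df <- apply_depth_filter(b_left, cov)
    if (!df$pass) filter <- df$reason
  }
  data.frame(ref_name = cl$ref_name, position = b_left,
             subfamily = asg$subfamily, strand = asg$strand %||% "+",
             length = cl$ins_len, support = cl$support, genotype = genotype,
             tsd = tsd, polya_len = polya, en_matches = en,
             inverted5 = asg$inverted5, transduction = transduction,
             status = status, filter = filter, b_right = b_right,
             span_reads = span_reads,
             empty_site_ok = span_reads - cl$support >= 1L)
}

## poly(A) evidence per strand: plus-strand tails live at the end of
## leading-clip sequences and of (TSD-trimmed) full insertion sequences;
## minus-strand poly(T) heads live at the start of trailing-clip sequences
## and of trimmed full insertions.
polya_from_signals <- function(s, strand, tsd, p) {
  tlen <- if (is.na(tsd)) 0L else nchar(tsd)
  cand <- character(0)
  full <- s$ins_seq[s$source == "cigar_insertion"]
  if (length(full)) cand <- substr(full, tlen + 1L, nchar(full))
  if (strand == "-") {
    cand <- c(cand, s$ins_seq[s$source == "soft_clip" & s$bk_type == "bp5"])
  } else {
    cand <- c(cand, s$ins_seq[s$source == "soft_clip" & s$bk_type == "bp3"])
  }
  cand <- cand[nzchar(cand)]
  if (!length(cand)) return(0L)
  vals <- vapply(cand, detect_polya, integer(1), strand = strand, USE.NAMES = FALSE)
  vals <- vals[vals > 0]
  if (!length(vals)) 0L else as.integer(round(median(vals)))
}

## unaligned tail beyond the poly(A): reported verbatim when >= 30 bp
transduction_tail <- function(s, strand, tsd, polya) {
  if (strand == "-" || polya <= 0) return(NA_character_)
  full <- s$ins_seq[s$source == "cigar_insertion"]
  rep_seq <- if (length(full)) full[which.max(nchar(full))] else {
    clips <- s$ins_seq[s$source == "soft_clip" & s$bk_type == "bp3"]
    if (!length(clips)) return(NA_character_)
    clips[which.max(nchar(clips))]
  }
  ## locate the last long A-run; anything 3' of it is candidate transduction
  ## (none is generated by the packaged simulator)
  m <- gregexpr("A{8,}", rep_seq)[[1]]
  if (m[1] < 0) return(NA_character_)
  last <- length(m)
  run_end <- m[last] + attr(m, "match.length")[last] - 1L
  tail_seq <- substr(rep_seq, run_end + 1L, nchar(rep_seq))
  if (nchar(tail_seq) >= 30L) tail_seq else NA_character_
}
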