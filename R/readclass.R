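## Read-level front end: quality filtering, MEI-signal end scan against the
## consensus library, projection of reference repeat annotation onto read
## coordinates (pre-masking), per-read on/close/off-target classification,
## and the run-level target-rate table.

#' Filter reads on mean quality
#'
#' A read is kept iff its probability-averaged mean Q-score is strictly
#' greater than `min_q`.
#'
#' @param reads read table from [read_fastq()] (needs `mean_q`).
#' @param min_q threshold (default 7).
#' @return list with `kept` and `dropped` read tables.
#' @export
filter_reads <- function(reads, min_q = 7) {
  keep <- reads$mean_q > min_q
  list(kept = reads[keep, , drop = FALSE], dropped = reads[!keep, , drop = FALSE])
}

## ---- end scan --------------------------------------------------------------

SCAN_K <- 11L          # exact-seed length for the BLAST-like prefilter
SCAN_DIAG_TOL <- 8L    # diagonal bandwidth when pooling seed votes

## k-mer position index over every consensus x strand, built once per scan
build_scan_index <- function(consensus_lib, k = SCAN_K) {
  idx <- list()
  for (i in seq_len(nrow(consensus_lib))) {
    id <- consensus_lib$id[i]
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") consensus_lib$seq[i] else revcomp(consensus_lib$seq[i])
      n <- nchar(seq)
      if (n < k) next
      kms <- substring(seq, 1:(n - k + 1L), k:n)
      e <- new.env(hash = TRUE, parent = emptyenv())
      sp <- split(seq_along(kms) - 1L, kms)
      for (km in names(sp)) assign(km, sp[[km]], envir = e)
      idx[[paste0(id, strand)]] <- list(id = id, strand = strand, seq = seq,
                                        len = n, env = e)
    }
  }
  if (!length(idx)) stop("empty consensus library")
  idx
}

## Best local-alignment score of one window against the library: exact
## 11-mer seeds vote on diagonals; the densest band is refined with a
## Smith-Waterman (match 2 / mismatch -3 / gap open 5 / extend 2) restricted
## to the seeded consensus region.
scan_window <- function(win, index, min_seeds = 2L) {
  n <- nchar(win)
  if (n < SCAN_K) return(list(score = 0, id = NA_character_))
  kms <- substring(win, 1:(n - SCAN_K + 1L), SCAN_K:n)
  best <- list(score = 0, id = NA_character_)
  for (entry in index) {
    hits_q <- integer(0); hits_r <- integer(0)
    for (qi in seq_along(kms)) {
      p <- get0(kms[qi], envir = entry$env, ifnotfound = NULL)
      if (!is.null(p)) { hits_q <- c(hits_q, rep(qi - 1L, length(p))); hits_r <- c(hits_r, p) }
    }
    if (length(hits_q) < min_seeds) next
    diag <- hits_r - hits_q
    dt <- sort(table(diag), decreasing = TRUE)
    d0 <- as.integer(names(dt)[1])
    votes <- sum(diag >= d0 - SCAN_DIAG_TOL & diag <= d0 + SCAN_DIAG_TOL)
    if (votes < min_seeds) next
    ws <- max(0L, d0 - 25L); we <- min(entry$len, d0 + n + 25L)
    sc <- cpp_local_score(win, substr(entry$seq, ws + 1L, we))
    if (sc > best$score) best <- list(score = sc, id = entry$id)
  }
  best
}

#' Scan a read for MEI signal at its ends
#'
#' The first and last `bin_bp` bases of the read are locally aligned against
#' every consensus on both strands (seeded Smith-Waterman, match 2 /
#' mismatch -3 / gap open 5 / extend 2); a terminal bin with score >=
#' `min_score` carries a signal. Optionally interior non-overlapping
#' `bin_bp` windows are scanned too, yielding `middle` when only they hit.
#'
#' @param read one-row read table (or list with `seq`).
#' @param consensus_lib consensus sequence table (with `family` column).
#' @param bin_bp terminal bin size (default 100).
#' @param min_score signal threshold (default 60, ~30 matched bases).
#' @param scan_interior also scan interior windows.
#' @param index prebuilt [build_scan_index()] (built on the fly if `NULL`).
#' @return list: `family`, `subfamily_best`, `location` (one of `end5`,
#'   `end3`, `both`, `middle`, `none`), `score`.
#' @export
scan_read_for_mei <- function(read, consensus_lib, bin_bp = 100L, min_score = 60,
                              scan_interior = FALSE, index = NULL) {
  if (is.null(index)) index <- build_scan_index(consensus_lib)
  seq <- read$seq[1]
  n <- nchar(seq)
  if (n <= bin_bp) {
    whole <- scan_window(seq, index)
    loc <- if (whole$score >= min_score) "both" else "none"
    return(signal_result(loc, whole, whole, consensus_lib))
  }
  s5 <- scan_window(substr(seq, 1L, bin_bp), index)
  s3 <- scan_window(substr(seq, n - bin_bp + 1L, n), index)
  hit5 <- s5$score >= min_score; hit3 <- s3$score >= min_score
  loc <- if (hit5 && hit3) "both" else if (hit5) "end5" else if (hit3) "end3" else "none"
  if (loc == "none" && scan_interior && n >= 3L * bin_bp) {
    starts <- seq(bin_bp, n - 2L * bin_bp, by = bin_bp)
    for (s in starts) {
      sm <- scan_window(substr(seq, s + 1L, s + bin_bp), index)
      if (sm$score >= min_score) return(signal_result("middle", sm, sm, consensus_lib))
    }
  }
  signal_result(loc, s5, s3, consensus_lib)
}

signal_result <- function(loc, s5, s3, consensus_lib) {
  pick <- if (s5$score >= s3$score) s5 else s3
  if (loc == "none") {
    return(list(family = NA_character_, subfamily_best = NA_character_,
                location = "none", score = max(s5$score, s3$score)))
  }
  fam <- consensus_lib$family[match(pick$id, consensus_lib$id)]
  list(family = fam, subfamily_best = pick$id, location = loc, score = pick$score)
}

## batch scan; returns a data.frame keyed by read_id
scan_reads <- function(reads, consensus_lib, bin_bp = 100L, min_score = 60,
                       index = NULL) {
  if (is.null(index)) index <- build_scan_index(consensus_lib)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    s <- scan_read_for_mei(reads[i, ], consensus_lib, bin_bp, min_score, index = index)
    data.frame(read_id = reads$id[i], family = s$family,
               subfamily_best = s$subfamily_best, location = s$location,
               score = s$score)
  })
  do.call(rbind, rows) %||%
    data.frame(read_id = character(0), family = character(0),
               subfamily_best = character(0), location = character(0),
               score = numeric(0))
}

## ---- pre-masking -----------------------------------------------------------

#' Project reference repeat annotation onto read coordinates
#'
#' Maps the reference intervals of annotated repeat features through the
#' alignment CIGAR onto the read (alignment orientation): deletions
#' collapse, read insertions inside a feature stay unmasked. The masked and
#' unmasked interval sets partition `[0, read_len)` exactly.
#'
#' @param aln one-row alignment table.
#' @param features repeat annotation (only rows on `aln$ref_name` are used).
#' @return list with `read_id`, `read_len`, `masked` and `unmasked`
#'   (0-based half-open interval matrices, alignment orientation).
#' @export
project_annotation_to_read <- function(aln, features) {
  ops <- parse_cigar(aln$cigar)
  if (cigar_read_bp(ops) != aln$read_end - aln$read_start ||
      cigar_ref_bp(ops) != aln$ref_end - aln$ref_start) {
    stop("CIGAR inconsistent with alignment spans for read ", aln$read_id)
  }
  feats <- features[features$ref_name == aln$ref_name &
                    features$end > aln$ref_start &
                    features$start < aln$ref_end, , drop = FALSE]
  masked <- if (nrow(feats)) {
    project_ref_intervals(ops, aln$ref_start, aln_q_offset(aln),
                          iv(feats$start, feats$end))
  } else iv()
  masked <- iv_sort_merge(masked)
  list(read_id = aln$read_id, read_len = aln$read_len, masked = masked,
       unmasked = iv_complement(masked, aln$read_len))
}

## ---- classification --------------------------------------------------------

READ_CATEGORIES <- c("on_target_reference", "on_target_nonreference",
                     "close_target", "off_target", "discarded_mapq",
                     "discarded_quality")

## target / close / off subfamily groups per experiment family
experiment_groups <- function(experiment_family) {
  switch(experiment_family,
    L1Hs = list(target = "L1Hs", close = "L1PA", sva_mode = FALSE),
    AluYb8 = ,
    AluYa5 = list(target = experiment_family, close = "AluY", sva_mode = FALSE),
    AluY = list(target = "AluY", close = "AluY", sva_mode = FALSE),
    SVA_F = ,
    SVA_E = list(target = experiment_family, close = "SVA", sva_mode = TRUE),
    stop("unknown experiment family: ", experiment_family))
}

#' Classify one read into the target-rate taxonomy
#'
#' Precedence: (1) unaligned or MAPQ < `min_mapq` -> `discarded_mapq`;
#' (2) a surviving insertion signal from pre-masking (`palmer_hit`) ->
#' `on_target_nonreference`; (3) aligned into a reference element of the
#' target subfamily (>= `min_element_overlap` bp) -> `on_target_reference`;
#' (4) per-family close/off rules on the overlapped element (L1Hs: L1PA
#' close, other L1 off; AluY experiments: other AluY close, other Alu off;
#' SVA: other SVA close and reads with MEI signal are never off-target);
#' (5) otherwise off_target when no MEI signal remains.
#'
#' @param aln one-row alignment table, or `NULL` when unaligned.
#' @param signal end-scan result for the read ([scan_read_for_mei()]).
#' @param palmer_hit does the read carry a surviving insertion signal?
#' @param experiment_family experiment target subfamily (e.g. `"L1Hs"`).
#' @param annotation repeat annotation table.
#' @param taxonomy taxonomy table ([mei_taxonomy()]).
#' @param min_mapq MAPQ threshold (default 10, strict less-than discards).
#' @param min_element_overlap minimum absolute overlap (bp) between the
#'   aligned span and a reference element for the read to count as mapped
#'   into it.
#' @return list with `category` and `basis` (text).
#' @export
classify_read <- function(aln, signal, palmer_hit, experiment_family,
                          annotation, taxonomy = mei_taxonomy(),
                          min_mapq = 10L, min_element_overlap = 100L) {
  grp <- experiment_groups(experiment_family)
  if (is.null(aln) || is.na(aln$mapq) || aln$mapq < min_mapq) {
    return(list(category = "discarded_mapq", basis = "unaligned or MAPQ below threshold"))
  }
  if (isTRUE(palmer_hit)) {
    return(list(category = "on_target_nonreference",
                basis = "insertion signal survived pre-masking"))
  }
  elem <- best_element_overlap(aln, annotation, min_element_overlap)
  has_signal <- !is.null(signal) && !identical(signal$location, "none")
  if (!is.null(elem)) {
    eg <- taxonomy_lookup(elem$subfamily, taxonomy)
    tg <- experiment_target_test(eg, grp, elem$subfamily)
    if (tg == "target") {
      return(list(category = "on_target_reference",
                  basis = paste0("mapped into reference ", elem$subfamily)))
    }
    if (tg == "close") {
      return(list(category = "close_target",
                  basis = paste0("mapped into reference ", elem$subfamily)))
    }
    if (grp$sva_mode && has_signal) {
      return(list(category = "close_target",
                  basis = paste0("SVA signal, mapped into reference ", elem$subfamily)))
    }
    return(list(category = "off_target",
                basis = paste0("mapped into reference ", elem$subfamily)))
  }
  if (has_signal && grp$sva_mode) {
    return(list(category = "close_target", basis = "SVA signal outside annotation"))
  }
  list(category = "off_target", basis = "no reference MEI and no surviving signal")
}

experiment_target_test <- function(elem_groups, grp, subfamily) {
  if (grp$target %in% c("L1Hs")) {
    if (elem_groups$group == "L1Hs") return("target")
    if (elem_groups$group == grp$close) return("close")
  } else {
    if (subfamily == grp$target) return("target")
    if (elem_groups$group == grp$close) return("close")
  }
  "other"
}

best_element_overlap <- function(aln, annotation, min_overlap) {
  feats <- annotation[annotation$ref_name == aln$ref_name &
                      annotation$end > aln$ref_start &
                      annotation$start < aln$ref_end, , drop = FALSE]
  if (!nrow(feats)) return(NULL)
  ov <- pmin(feats$end, aln$ref_end) - pmax(feats$start, aln$ref_start)
  j <- which.max(ov)
  if (ov[j] < min_overlap) return(NULL)
  list(subfamily = feats$subfamily[j], family = feats$family[j],
       overlap = ov[j], start = feats$start[j], end = feats$end[j])
}

#' Classify every read of a run
#'
#' End-to-end front end: quality filter, primary-alignment lookup, end scan,
#' pre-masking, insertion-signal check, per-read classification.
#'
#' @param reads read table ([read_fastq()] shape).
#' @param alns alignment table; only the best (highest MAPQ, then longest)
#'   record per read is used.
#' @param annotation repeat annotation.
#' @param consensus_lib consensus library with `family` column.
#' @param experiment_family experiment target subfamily.
#' @param params optional overrides: `min_q`, `min_mapq`, `bin_bp`,
#'   `min_score`, `min_element_overlap`, `min_ins_len`, `min_clip_len`.
#' @return list with `classifications` (per read), `signals` (end-scan
#'   table), `ins_signals` (insertion-signal table) and `rates`
#'   ([tally_target_rates()] output).
#' @export
classify_run <- function(reads, alns, annotation, consensus_lib,
                         experiment_family, params = list()) {
  p <- modifyList(list(min_q = 7, min_mapq = 10L, bin_bp = 100L, min_score = 60,
                       min_element_overlap = 100L, min_ins_len = 100L,
                       min_clip_len = 200L), params)
  flt <- filter_reads(reads, p$min_q)
  index <- build_scan_index(consensus_lib)
  signals <- scan_reads(flt$kept, consensus_lib, p$bin_bp, p$min_score, index)
  aln_best <- best_alignment_per_read(alns)
  mei_ann <- annotation[annotation$family %in% unique(consensus_lib$family), , drop = FALSE]
  ins_signals <- extract_run_signals(flt$kept, aln_best, mei_ann,
                                     min_ins_len = p$min_ins_len,
                                     min_clip_len = p$min_clip_len)
  palmer_reads <- unique(ins_signals$read_id)
  rows <- lapply(seq_len(nrow(flt$kept)), function(i) {
    id <- flt$kept$id[i]
    aln <- aln_best[aln_best$read_id == id, , drop = FALSE]
    aln <- if (nrow(aln)) aln[1, , drop = FALSE] else NULL
    sig <- as.list(signals[signals$read_id == id, ])
    cl <- classify_read(aln, sig, id %in% palmer_reads, experiment_family,
                        annotation, min_mapq = p$min_mapq,
                        min_element_overlap = p$min_element_overlap)
    data.frame(read_id = id, category = cl$category, basis = cl$basis,
               read_len = nchar(flt$kept$seq[i]))
  })
  cls <- do.call(rbind, rows)
  if (nrow(flt$dropped)) {
    cls <- rbind(cls, data.frame(read_id = flt$dropped$id,
                                 category = "discarded_quality",
                                 basis = "mean Q-score at or below threshold",
                                 read_len = nchar(flt$dropped$seq)))
  }
  rates <- tally_target_rates(cls, signals)
  list(classifications = cls, signals = signals, ins_signals = ins_signals,
       rates = rates)
}

best_alignment_per_read <- function(alns) {
  if (!nrow(alns)) return(alns)
  ord <- order(alns$read_id, -alns$mapq, -(alns$read_end - alns$read_start))
  alns <- alns[ord, , drop = FALSE]
  alns[!duplicated(alns$read_id), , drop = FALSE]
}

#' Tally per-category read counts and fractions
#'
#' Fractions are over non-discarded reads (the "passed reads" denominator of
#' run summary tables) and sum to 1. Read-length means are reported per
#' signal location so single-end and both-end signal reads can be compared.
#'
#' @param classifications per-read classification table.
#' @param signals end-scan table.
#' @return list with `rates` (category, n, fraction), `wide` (one-row
#'   percentage table) and `by_location` (location, n, mean read length).
#' @export
tally_target_rates <- function(classifications, signals) {
  if (!nrow(classifications)) stop("no reads to tally")
  live <- classifications[!classifications$category %in%
                            c("discarded_mapq", "discarded_quality"), , drop = FALSE]
  if (!nrow(live)) stop("zero non-discarded reads")
  n <- table(factor(live$category,
                    levels = c("on_target_reference", "on_target_nonreference",
                               "close_target", "off_target")))
  rates <- data.frame(category = names(n), n = as.integer(n),
                      fraction = as.numeric(n) / nrow(live))
  wide <- data.frame(n_reads = nrow(live),
                     on_ref_pct = 100 * rates$fraction[1],
                     on_nonref_pct = 100 * rates$fraction[2],
                     close_pct = 100 * rates$fraction[3],
                     off_pct = 100 * rates$fraction[4])
  merged <- merge(live, signals, by = "read_id", all.x = TRUE)
  merged$location[is.na(merged$location)] <- "none"
  by_loc <- aggregate(read_len ~ location, data = merged,
                      FUN = function(x) c(n = length(x), mean_len = mean(x)))
  by_loc <- data.frame(location = by_loc$location,
                       n = by_loc$read_len[, "n"],
                       mean_len = by_loc$read_len[, "mean_len"])
  list(rates = rates, wide = wide, by_location = by_loc)
}
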