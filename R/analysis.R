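## Downstream analyses: cleavage-site distributions, strand bias, saturation
## under cumulative run merging, trio transmission, support-depth ratios,
## fold enrichment, and recurrence (dot) plots.

#' Cleavage-site distribution of a guide from read head alignments
#'
#' The first `head_bp` bases of each read are aligned locally to the
#' consensus and its reverse complement (match +2 / mismatch -1; first gap
#' base costs `gap_open_first`, each further base `gap_extend`). A read is
#' included only when its best head alignment starts at the very first read
#' base and scores at least `min_score`; included reads contribute the base
#' distance of their 5' end from the PAM `N` to the strand-appropriate bin
#' (distance 1 = base adjacent to the PAM).
#'
#' @param reads read table.
#' @param consensus_seq consensus sequence (character scalar).
#' @param pam_n_pos 0-based consensus position of the `N` of the NGG PAM.
#' @param head_bp head length used for alignment (default 80).
#' @param min_score inclusion score threshold (default 100).
#' @param match,mismatch substitution scores.
#' @param gap_open_first,gap_extend gap penalties (positive costs; defaults
#'   10 and 5 for the first and each subsequent gap base).
#' @return list: `histogram` (strand, distance, count), `excluded` (reason,
#'   n), `n_included`, `per_read` (read-level detail).
#' @export
cleavage_site_histogram <- function(reads, consensus_seq, pam_n_pos,
                                    head_bp = 80L, min_score = 100,
                                    match = 2, mismatch = -1,
                                    gap_open_first = 10, gap_extend = 5) {
  if (pam_n_pos < 0 || pam_n_pos >= nchar(consensus_seq)) {
    stop("PAM position outside consensus")
  }
  if (!nrow(reads)) stop("no reads")
  heads <- substr(reads$seq, 1L, head_bp)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = FALSE)
  go <- gap_open_first - gap_extend    # Biostrings: gap costs opening + L*ext
  align_to <- function(subject) {
    Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(heads),
                                  Biostrings::DNAString(subject),
                                  type = "local", substitutionMatrix = submat,
                                  gapOpening = go, gapExtension = gap_extend)
  }
  L <- nchar(consensus_seq)
  fw <- align_to(consensus_seq)
  rv <- align_to(revcomp(consensus_seq))
  sc_fw <- BiocGenerics::score(fw); sc_rv <- BiocGenerics::score(rv)
  use_fw <- sc_fw >= sc_rv
  score <- ifelse(use_fw, sc_fw, sc_rv)
  pat_start <- ifelse(use_fw,
                      BiocGenerics::start(Biostrings::pattern(fw)),
                      BiocGenerics::start(Biostrings::pattern(rv)))
  subj_start0 <- ifelse(use_fw,
                        BiocGenerics::start(Biostrings::subject(fw)),
                        BiocGenerics::start(Biostrings::subject(rv))) - 1L
  first_base_pos <- ifelse(use_fw, subj_start0, L - 1L - subj_start0)
  distance <- pam_n_pos - first_base_pos
  strand <- ifelse(use_fw, "forward", "reverse")
  reason <- ifelse(score < min_score, "min_score",
            ifelse(pat_start != 1L, "not_first_base", "included"))
  per_read <- data.frame(read_id = reads$id, strand = strand, score = score,
                         distance = distance, reason = reason)
  inc <- per_read[per_read$reason == "included", , drop = FALSE]
  hist <- if (nrow(inc)) {
    agg <- aggregate(list(count = rep(1L, nrow(inc))),
                     by = list(strand = inc$strand, distance = inc$distance),
                     FUN = sum)
    agg[order(agg$strand, agg$distance), , drop = FALSE]
  } else data.frame(strand = character(0), distance = integer(0), count = integer(0))
  excl <- as.data.frame(table(reason = per_read$reason[per_read$reason != "included"]),
                        stringsAsFactors = FALSE)
  names(excl) <- c("reason", "n")
  list(histogram = hist, excluded = excl, n_included = nrow(inc),
       per_read = per_read)
}

#' Forward/reverse strand bias of sequenced reads
#'
#' @param direction character vector of per-read directions (`"fwd"` /
#'   `"rev"`), e.g. the `direction` column of a simulation manifest.
#' @return the forward:reverse ratio (Inf when no reverse reads).
#' @export
strand_bias <- function(direction) {
  direction <- direction[!is.na(direction)]
  nf <- sum(direction == "fwd"); nr <- sum(direction == "rev")
  if (nf + nr == 0) stop("no reads with a recorded direction")
  if (nr == 0) return(Inf)
  nf / nr
}

#' Saturation of call recovery under cumulative run merging
#'
#' Runs are ranked by on-target read count (descending) and merged one at a
#' time; after each merge the pooled insertion signals are re-clustered and
#' the number of loci reaching each supporting-read cutoff is recorded.
#'
#' @param runs list of runs, each a list with `signals` (insertion-signal
#'   table) and `on_target_reads` (count used for ranking).
#' @param cutoffs supporting-read cutoffs (default `c(1, 4, 15)`).
#' @param cluster_window clustering gap (bp).
#' @return data.frame with `step`, `cumulative_on_target_reads`, `cutoff`,
#'   `calls`.
#' @export
saturation_curve <- function(runs, cutoffs = c(1L, 4L, 15L),
                             cluster_window = 100L) {
  if (!length(runs)) stop("no runs")
  ord <- order(vapply(runs, function(r) r$on_target_reads, numeric(1)),
               decreasing = TRUE)
  runs <- runs[ord]
  pooled <- NULL
  out <- list()
  cum_reads <- 0
  for (step in seq_along(runs)) {
    pooled <- rbind(pooled, runs[[step]]$signals)
    cum_reads <- cum_reads + runs[[step]]$on_target_reads
    clusters <- cluster_supporting_reads(pooled, cluster_window, min_support = 1L)
    supports <- vapply(clusters, function(cl) cl$support, integer(1))
    for (cut in cutoffs) {
      out[[length(out) + 1L]] <- data.frame(
        step = step, cumulative_on_target_reads = cum_reads,
        cutoff = cut, calls = sum(supports >= cut))
    }
  }
  do.call(rbind, out)
}

#' Trio transmission of non-reference calls
#'
#' Child calls are matched to each parent's calls within `match_window` on
#' the same contig with family agreement, and categorised as
#' `from_parent1`, `from_parent2`, `either_parent` (both match; unknown
#' lineage) or `unmatched`. Parent calls without a child match are reported
#' as `untransmitted_parent_call`.
#'
#' @param child_calls,parent1_calls,parent2_calls call tables.
#' @param match_window positional tolerance (bp).
#' @return list with `records` (role, position, subfamily, support,
#'   category) and `summary` (mean support per category).
#' @export
trio_transmission <- function(child_calls, parent1_calls, parent2_calls,
                              match_window = 100L) {
  m1 <- match_calls(child_calls, parent1_calls, match_window)
  m2 <- match_calls(child_calls, parent2_calls, match_window)
  category <- ifelse(m1 & m2, "either_parent",
              ifelse(m1, "from_parent1",
              ifelse(m2, "from_parent2", "unmatched")))
  recs <- list()
  if (nrow(child_calls)) {
    recs[[1]] <- data.frame(role = "child", ref_name = child_calls$ref_name,
                            position = child_calls$position,
                            subfamily = child_calls$subfamily,
                            support = child_calls$support, category = category)
  }
  for (k in 1:2) {
    pc <- if (k == 1) parent1_calls else parent2_calls
    if (!nrow(pc)) next
    tr <- match_calls(pc, child_calls, match_window)
    recs[[length(recs) + 1L]] <- data.frame(
      role = paste0("parent", k), ref_name = pc$ref_name,
      position = pc$position, subfamily = pc$subfamily, support = pc$support,
      category = ifelse(tr, "transmitted_parent_call", "untransmitted_parent_call"))
  }
  records <- do.call(rbind, recs) %||%
    data.frame(role = character(0), ref_name = character(0),
               position = integer(0), subfamily = character(0),
               support = integer(0), category = character(0))
  summary <- if (nrow(records)) {
    aggregate(support ~ category, data = records, FUN = mean)
  } else data.frame(category = character(0), support = numeric(0))
  names(summary) <- c("category", "mean_support")
  list(records = records, summary = summary)
}

match_calls <- function(a, b, window) {
  if (!nrow(a)) return(logical(0))
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  fam_a <- taxonomy_lookup(a$subfamily)$family
  fam_b <- taxonomy_lookup(b$subfamily)$family
  vapply(seq_len(nrow(a)), function(i) {
    any(b$ref_name == a$ref_name[i] &
        abs(b$position - a$position[i]) <= window &
        fam_b == fam_a[i])
  }, logical(1))
}

#' Ratio of mean supporting-read depth between two call sets
#'
#' Typically reference (homozygous) versus non-reference (largely
#' heterozygous) loci, where equal per-haplotype capture predicts a 2:1
#' ratio.
#'
#' @param calls_reference,calls_nonreference call tables (need `support`).
#' @return mean support ratio.
#' @export
depth_ratio <- function(calls_reference, calls_nonreference) {
  if (!nrow(calls_reference) || !nrow(calls_nonreference)) {
    stop("both call sets must be non-empty")
  }
  mean(calls_reference$support) / mean(calls_nonreference$support)
}

#' Fold enrichment of reads per target versus a WGS baseline
#'
#' @param reads_per_target_capture,reads_per_target_wgs numeric vectors
#'   (per subfamily), matched by name when named.
#' @return elementwise capture/WGS fold.
#' @export
fold_enrichment <- function(reads_per_target_capture, reads_per_target_wgs) {
  if (!is.null(names(reads_per_target_capture)) &&
      !is.null(names(reads_per_target_wgs))) {
    reads_per_target_wgs <- reads_per_target_wgs[names(reads_per_target_capture)]
  }
  if (any(reads_per_target_wgs <= 0)) stop("WGS denominator must be positive")
  reads_per_target_capture / reads_per_target_wgs
}

#' Recurrence (dot plot) matrix of identical words
#'
#' All coordinate pairs `(i, j)` (0-based) where the `word`-mer of `seq_a`
#' at `i` equals the `word`-mer of `seq_b` at `j`; in `revcomp` mode the
#' comparison is against the reverse complement of `seq_b`, with `j`
#' reported on the original `seq_b` coordinates (anti-diagonal geometry).
#'
#' @param seq_a,seq_b DNA strings.
#' @param word word size (default 10).
#' @param mode `"forward"` or `"revcomp"`.
#' @return data.frame with columns `i`, `j`.
#' @export
recurrence_matrix <- function(seq_a, seq_b, word = 10L,
                              mode = c("forward", "revcomp")) {
  mode <- match.arg(mode)
  na <- nchar(seq_a); nb <- nchar(seq_b)
  if (na < word || nb < word) stop("sequences must be at least one word long")
  b_use <- if (mode == "revcomp") revcomp(seq_b) else seq_b
  wa <- substring(seq_a, 1:(na - word + 1L), word:na)
  wb <- substring(b_use, 1:(nb - word + 1L), word:nb)
  codes <- match(wb, wa)               # wa word index for each wb word, NA if absent
  ## expand all (i, j) pairs: group a-positions by word, join via codes
  ia <- split(seq_along(wa) - 1L, wa)
  rows_i <- integer(0); rows_j <- integer(0)
  hit <- which(!is.na(codes))
  if (length(hit)) {
    for (j in hit) {
      ii <- ia[[wb[j]]]
      rows_i <- c(rows_i, ii)
      rows_j <- c(rows_j, rep(j - 1L, length(ii)))
    }
  }
  if (mode == "revcomp") rows_j <- nb - word - rows_j
  out <- data.frame(i = rows_i, j = rows_j)
  out[order(out$i, out$j), , drop = FALSE]
}
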