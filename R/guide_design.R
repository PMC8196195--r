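## Subfamily-specific guide RNA design: diagnostic-column discovery on
## consensus alignments, 23-mer PAM candidate enumeration, genome-wide
## k-mer frequency screening, tier assignment, and theoretical capture
## bounds (lower / intermediate / upper) for a chosen guide.

#' Diagnostic positions of a target consensus against outgroup consensi
#'
#' A consensus column is diagnostic when the target base is a definite
#' nucleotide (A/C/G/T) and differs from the base of *every* outgroup at the
#' aligned column; a gap or `N` in any outgroup disqualifies the column.
#' Unaligned inputs are first anchored pairwise to the target with a global
#' alignment (match 1 / mismatch -1 / gap -2 per base).
#'
#' @param target single-row sequence table (or list with `id`, `seq`).
#' @param outgroups sequence table of one or more outgroup consensi.
#' @param aligned if `TRUE`, sequences are already columns of one alignment
#'   (equal lengths, `-` allowed); otherwise they are aligned here.
#' @return list with `target_id`, `outgroup_ids` and `positions` (0-based,
#'   strictly increasing, on the ungapped target).
#' @export
diagnostic_positions <- function(target, outgroups, aligned = FALSE) {
  if (NROW(outgroups) == 0) stop("diagnosticity undefined with zero outgroups")
  tseq <- target$seq[1]
  oseqs <- outgroups$seq
  if (aligned) {
    if (any(nchar(oseqs) != nchar(tseq))) {
      stop("aligned=TRUE requires equal-length gapped sequences")
    }
    tcols <- strsplit(tseq, "")[[1]]
    omat <- do.call(rbind, strsplit(oseqs, ""))
    keep <- tcols != "-"
    tb <- tcols[keep]
    ob <- omat[, keep, drop = FALSE]
  } else {
    tb <- strsplit(tseq, "")[[1]]
    ob <- do.call(rbind, lapply(oseqs, function(o) anchor_to_target(tseq, o)))
  }
  diag_ok <- tb %in% DNA_BASES
  for (r in seq_len(nrow(ob))) {
    diag_ok <- diag_ok & ob[r, ] %in% DNA_BASES & ob[r, ] != tb
  }
  list(target_id = target$id[1], outgroup_ids = outgroups$id,
       positions = which(diag_ok) - 1L)
}

## Global pairwise alignment of one outgroup to the target; returns the
## outgroup base (or "-") over each ungapped target position.
anchor_to_target <- function(target_seq, outgroup_seq) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(target_seq), Biostrings::DNAString(outgroup_seq),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  tg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  og <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  og[tg != "-"]
}

#' Enumerate 23-mer guide candidates with a valid PAM
#'
#' Every 23 bp window of the target consensus that ends in `GG` (PAM on the
#' 3' side, NGG) or starts with `CC` (5' CCN) and contains at least one
#' diagnostic position is a candidate. `diag_in_pam_GGCC` flags candidates
#' whose diagnostic base falls on the two G/C bases of the PAM.
#'
#' @param target single-row sequence table.
#' @param profile result of [diagnostic_positions()].
#' @param k window size; only `k = 23` is supported.
#' @return data.frame of candidates: `seq23`, `pam_side`, `consensus_pos`,
#'   `n_diag`, `diag_hits` (comma-separated window offsets),
#'   `diag_in_pam_GGCC`, `genome_freq` (NA until counted), `tier`.
#' @export
enumerate_guide_candidates <- function(target, profile, k = 23L) {
  if (k != 23L) stop("only k = 23 is supported")
  seq <- target$seq[1]
  n <- nchar(seq)
  if (n < k) return(empty_candidates())
  pos <- profile$positions
  starts <- 0:(n - k)
  rows <- list()
  for (s in starts) {
    win <- substr(seq, s + 1L, s + k)
    hits <- pos[pos >= s & pos < s + k] - s   # 0-based offsets in window
    if (!length(hits)) next
    if (substr(win, k - 1L, k) == "GG") {
      rows[[length(rows) + 1L]] <- candidate_row(win, "three_prime_NGG", s, hits,
                                                 any(hits %in% c(k - 2L, k - 1L)))
    }
    if (substr(win, 1L, 2L) == "CC") {
      rows[[length(rows) + 1L]] <- candidate_row(win, "five_prime_CCN", s, hits,
                                                 any(hits %in% c(0L, 1L)))
    }
  }
  if (!length(rows)) return(empty_candidates())
  do.call(rbind, rows)
}

candidate_row <- function(win, side, s, hits, in_pam) {
  data.frame(seq23 = win, pam_side = side, consensus_pos = as.integer(s),
             n_diag = length(hits), diag_hits = paste(hits, collapse = ","),
             diag_in_pam_GGCC = in_pam, genome_freq = NA_integer_,
             tier = NA_character_)
}

empty_candidates <- function() {
  data.frame(seq23 = character(0), pam_side = character(0),
             consensus_pos = integer(0), n_diag = integer(0),
             diag_hits = character(0), diag_in_pam_GGCC = logical(0),
             genome_freq = integer(0), tier = character(0))
}

#' Count k-mer occurrences in a genome
#'
#' Overlapping occurrences are counted on both strands (configurable). With
#' `pam_substitution = TRUE` the `N` position of the PAM (position 21 of an
#' NGG 23-mer, position 3 of a CCN 23-mer) is expanded to all four bases and
#' the counts summed, mirroring the frequency check applied to guide
#' candidates.
#'
#' @param genome sequence table (one or more reference sequences).
#' @param kmers character vector of equal-length k-mers (no `N`).
#' @param pam_substitution expand the PAM `N` position before counting.
#' @param pam_side `"three_prime_NGG"` or `"five_prime_CCN"`; used only when
#'   `pam_substitution` is `TRUE`. Recycled along `kmers`.
#' @param both_strands also count occurrences on the reverse strand.
#' @return integer vector of counts, named by k-mer.
#' @export
count_kmer_frequency <- function(genome, kmers, pam_substitution = FALSE,
                                 pam_side = "three_prime_NGG",
                                 both_strands = TRUE) {
  if (!NROW(genome)) stop("empty genome")
  if (!length(kmers)) return(integer(0))
  if (length(unique(nchar(kmers))) != 1) stop("k-mers must have equal length")
  if (any(grepl("N", kmers, fixed = TRUE))) stop("k-mers containing N are not countable")
  pam_side <- rep_len(pam_side, length(kmers))
  subj <- Biostrings::DNAStringSet(genome$seq)
  count_one <- function(km) {
    n <- sum(Biostrings::vcountPattern(km, subj))
    if (both_strands) n <- n + sum(Biostrings::vcountPattern(revcomp(km), subj))
    n
  }
  out <- integer(length(kmers))
  for (i in seq_along(kmers)) {
    km <- kmers[i]
    if (pam_substitution) {
      npos <- if (pam_side[i] == "three_prime_NGG") nchar(km) - 2L else 3L
      variants <- unique(vapply(DNA_BASES, function(b) {
        `substr<-`(km, npos, npos, value = b)
      }, character(1)))
      out[i] <- sum(vapply(variants, count_one, numeric(1)))
    } else {
      out[i] <- count_one(km)
    }
  }
  setNames(out, kmers)
}

#' Assign a guide candidate to a specificity tier
#'
#' Tier0: a subfamily-specific base falls on the GG/CC of the PAM.
#' Tier1: otherwise, the 23-mer genome frequency is within a reasonable
#' range (< 2-fold of the target subfamily copy number). Tier2: everything
#' else (diagnostic base only at the PAM N, or frequency out of range).
#'
#' @param cands candidate table with `genome_freq` populated.
#' @param target_copy_count number of target-subfamily copies in the genome.
#' @return the candidate table with `tier` filled in.
#' @export
assign_tier <- function(cands, target_copy_count) {
  if (target_copy_count <= 0) stop("target_copy_count must be positive")
  if (any(is.na(cands$genome_freq))) stop("genome_freq not populated")
  cands$tier <- ifelse(cands$diag_in_pam_GGCC, "Tier0",
                ifelse(cands$genome_freq < 2 * target_copy_count, "Tier1", "Tier2"))
  cands
}

#' Rank guide candidates
#'
#' Stable sort by tier (Tier0 first), then number of diagnostic bases
#' (descending), then proximity to the consensus 3' end (ascending distance),
#' with ties broken by consensus position.
#'
#' @param cands tiered candidate table.
#' @param consensus_len length of the target consensus.
#' @return the candidate table in rank order.
#' @export
rank_guides <- function(cands, consensus_len) {
  if (!nrow(cands)) stop("no candidates to rank")
  dist3 <- consensus_len - (cands$consensus_pos + 23L)
  ord <- order(cands$tier, -cands$n_diag, dist3, cands$consensus_pos)
  cands[ord, , drop = FALSE]
}

#' Classify how well a guide matches an element sequence
#'
#' Best semi-global placement of the 23 bp guide (both strands) inside the
#' element: `lower` for an exact 23/23 match, `intermediate` for total edit
#' distance (mismatches + gaps) <= 3, `upper` when the best-scoring placement
#' aligns >= 14 guide bases as matches (> 60%), `none` otherwise. The classes
#' nest; the most specific one is returned.
#'
#' @param guide 23 bp guide+PAM sequence.
#' @param element_seq element DNA (character scalar).
#' @param max_edit intermediate-bound edit budget.
#' @param min_match upper-bound matched-base floor.
#' @param both_strands also try the reverse complement of the guide.
#' @return one of `"lower"`, `"intermediate"`, `"upper"`, `"none"`.
#' @export
classify_guide_match <- function(guide, element_seq, max_edit = 3L,
                                 min_match = 14L, both_strands = TRUE) {
  if (nchar(guide) != 23L) stop("guide must be 23 bp")
  if (is.na(element_seq) || nchar(element_seq) < min_match) return("none")
  hit <- cpp_guide_match(guide, element_seq)
  if (both_strands) {
    hit2 <- cpp_guide_match(revcomp(guide), element_seq)
    hit <- c(min(hit[1], hit2[1]), max(hit[2], hit2[2]))
  }
  if (hit[1] == 0L) "lower"
  else if (hit[1] <= max_edit) "intermediate"
  else if (hit[2] >= min_match) "upper"
  else "none"
}

#' Theoretical capture bounds of a guide over reference and non-reference elements
#'
#' Extracts every annotated element from the genome, classifies it (and any
#' supplied non-reference element sequences) with [classify_guide_match()],
#' and tallies nested per-subfamily counts: every `lower` element is also
#' `intermediate` and `upper`.
#'
#' @param guide 23 bp guide+PAM sequence.
#' @param genome sequence table of reference sequences.
#' @param annotation repeat annotation (reference elements).
#' @param nonref_elements optional sequence table of non-reference element
#'   sequences; their subfamily is taken from the `subfamily` column when
#'   present, else `"nonref"`.
#' @return data.frame with columns `subfamily`, `status`, `n_lower`,
#'   `n_intermediate`, `n_upper`, `n_total`.
#' @export
compute_capture_bounds <- function(guide, genome, annotation,
                                   nonref_elements = NULL) {
  rows <- list()
  if (nrow(annotation)) {
    gmap <- setNames(genome$seq, genome$id)
    for (i in seq_len(nrow(annotation))) {
      g <- gmap[[annotation$ref_name[i]]]
      if (is.null(g) || annotation$end[i] > nchar(g) || annotation$start[i] < 0) {
        stop("feature outside genome bounds: ", annotation$ref_name[i], ":",
             annotation$start[i], "-", annotation$end[i])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subfamily = annotation$subfamily[i], status = "reference",
        class = classify_guide_match(guide, substr(g, annotation$start[i] + 1L,
                                                   annotation$end[i])))
    }
  }
  if (!is.null(nonref_elements) && NROW(nonref_elements)) {
    sf <- nonref_elements$subfamily %||% rep("nonref", nrow(nonref_elements))
    for (i in seq_len(nrow(nonref_elements))) {
      rows[[length(rows) + 1L]] <- data.frame(
        subfamily = sf[i], status = "non_reference",
        class = classify_guide_match(guide, nonref_elements$seq[i]))
    }
  }
  if (!length(rows)) {
    return(data.frame(subfamily = character(0), status = character(0),
                      n_lower = integer(0), n_intermediate = integer(0),
                      n_upper = integer(0), n_total = integer(0)))
  }
  x <- do.call(rbind, rows)
  agg <- aggregate(cbind(n_lower = x$class == "lower",
                         n_intermediate = x$class %in% c("lower", "intermediate"),
                         n_upper = x$class %in% c("lower", "intermediate", "upper"),
                         n_total = rep(1L, nrow(x))) ~ subfamily + status,
                   data = x, FUN = sum)
  agg[order(agg$status, agg$subfamily), , drop = FALSE]
}
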