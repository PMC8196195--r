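## Independent oracles used against the package implementations.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## naive sliding-window k-mer count (both-strand convention: forward hits of
## the k-mer plus forward hits of its reverse complement)
oracle_kmer_count <- function(seqs, kmer, both_strands = TRUE) {
  cnt <- function(s, k) {
    n <- nchar(s); w <- nchar(k)
    if (n < w) return(0L)
    sum(substring(s, 1:(n - w + 1L), w:n) == k)
  }
  tot <- sum(vapply(seqs, cnt, integer(1), k = kmer))
  if (both_strands) {
    tot <- tot + sum(vapply(seqs, cnt, integer(1), k = revcomp(kmer)))
  }
  tot
}

## Exhaustive semi-global DP over one strand: minimum edit distance, and the
## maximum number of matches among maximum-score alignments under
## match +1 / mismatch -1 / gap -1 (lexicographic objective encoded as
## score * BIG + matches). Row-wise vectorised; gap-left transitions use the
## linear-penalty running-extremum identity.
oracle_semiglobal <- function(guide, element) {
  g <- strsplit(guide, "")[[1]]
  e <- strsplit(element, "")[[1]]
  m <- length(g); n <- length(e)
  BIG <- 1000
  jj <- 0:n
  d <- rep(0L, n + 1L)
  v <- rep(0, n + 1L)
  for (i in seq_len(m)) {
    eq <- g[i] == e & g[i] != "N" & e != "N"
    ## edit distance
    diag <- d[1:n] + ifelse(eq, 0L, 1L)
    up <- d[2:(n + 1L)] + 1L
    w <- pmin(diag, up)
    u <- c(i, w) - jj
    d <- cummin(u) + jj
    ## lexicographic score/matches
    diag2 <- v[1:n] + ifelse(eq, BIG + 1, -BIG)
    up2 <- v[2:(n + 1L)] - BIG
    w2 <- pmax(diag2, up2)
    u2 <- c(-i * BIG, w2) + jj * BIG
    v <- cummax(u2) - jj * BIG
  }
  vbest <- max(v) + m * BIG
  list(edit = min(d), matches = vbest %% BIG, score = vbest %/% BIG - m)
}

## oracle version of the bound classification (both strands)
oracle_guide_class <- function(guide, element, max_edit = 3L, min_match = 14L) {
  if (nchar(element) < min_match) return("none")
  a <- oracle_semiglobal(guide, element)
  b <- oracle_semiglobal(revcomp(guide), element)
  edit <- min(a$edit, b$edit)
  matches <- max(a$matches, b$matches)
  if (edit == 0) "lower"
  else if (edit <= max_edit) "intermediate"
  else if (matches >= min_match) "upper"
  else "none"
}

## naive double-loop recurrence matrix
oracle_recurrence <- function(a, b, word) {
  na <- nchar(a); nb <- nchar(b)
  rows <- list()
  for (i in 0:(na - word)) {
    wa <- substr(a, i + 1L, i + word)
    for (j in 0:(nb - word)) {
      if (wa == substr(b, j + 1L, j + word)) {
        rows[[length(rows) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(rows)) return(data.frame(i = integer(0), j = integer(0)))
  m <- do.call(rbind, rows)
  out <- data.frame(i = m[, 1], j = m[, 2])
  out[order(out$i, out$j), , drop = FALSE]
}

## Biostrings local alignment score, the oracle for the Rcpp kernel
oracle_local_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_ext = 2) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = gap_open, gapExtension = gap_ext)
  BiocGenerics::score(pa)
}
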