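#' @useDynLib casmei, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rlnorm rpois runif setNames aggregate chisq.test
#' @importFrom utils read.table write.table head tail modifyList
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors. `N` is preserved.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## ---- tiny 0-based half-open interval helpers -------------------------------
## All internal coordinates in the package are 0-based half-open; these
## helpers keep interval algebra in that single convention (conversion to
## 1-based happens only inside I/O readers/writers and substring calls).

## intervals are integer matrices with columns start, end; zero rows allowed
iv <- function(start = integer(0), end = integer(0)) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (nrow(m) && any(m[, 2] < m[, 1])) stop("interval with end < start")
  m
}

iv_sort_merge <- function(m) {
  if (!nrow(m)) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out_s <- m[1, 1]; out_e <- m[1, 2]
  ss <- integer(0); ee <- integer(0)
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] <= out_e) out_e <- max(out_e, m[i, 2])
      else { ss <- c(ss, out_s); ee <- c(ee, out_e); out_s <- m[i, 1]; out_e <- m[i, 2] }
    }
  }
  iv(c(ss, out_s), c(ee, out_e))
}

## complement of merged intervals within [0, len)
iv_complement <- function(m, len) {
  m <- iv_sort_merge(m)
  m <- m[m[, 2] > 0 & m[, 1] < len, , drop = FALSE]
  if (!nrow(m)) return(iv(0L, len)[len > 0, , drop = FALSE])
  m[, 1] <- pmax(m[, 1], 0L); m[, 2] <- pmin(m[, 2], as.integer(len))
  ss <- c(0L, m[, 2]); ee <- c(m[, 1], as.integer(len))
  keep <- ee > ss
  iv(ss[keep], ee[keep])
}

## total overlap (bp) of a single interval [s,e) with an interval set
iv_overlap_bp <- function(s, e, m) {
  if (!nrow(m)) return(0L)
  sum(pmax(0L, pmin(m[, 2], as.integer(e)) - pmax(m[, 1], as.integer(s))))
}

## ---- seeded helpers --------------------------------------------------------

## Run code under a local, fully specified RNG state so the simulator is
## deterministic and never disturbs the caller's RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## mutate a DNA string with iid substitutions at the given rate
mutate_subs <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1L)
  paste(b, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
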