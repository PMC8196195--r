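## CIGAR handling. Alignment records store their CIGAR in reference-forward
## orientation, clips stripped (clip lengths are implicit in read_start /
## read_end), so a CIGAR always covers exactly the aligned part of the read.

CIGAR_READ_OPS <- c("M", "=", "X", "I", "S")
CIGAR_REF_OPS  <- c("M", "=", "X", "D")

#' Parse a CIGAR string
#'
#' @param cigar a single CIGAR string, e.g. `"100M2I50M"`.
#' @return data.frame with columns `op` (character) and `len` (integer).
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar) || cigar == "*") {
    return(data.frame(op = character(0), len = integer(0)))
  }
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]]
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) ||
      nchar(cigar) != sum(nchar(lens)) + length(ops)) {
    stop("malformed CIGAR: ", cigar)
  }
  data.frame(op = ops, len = as.integer(lens))
}

unparse_cigar <- function(ops) {
  if (!nrow(ops)) return("*")
  paste0(ops$len, ops$op, collapse = "")
}

cigar_read_bp <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
cigar_ref_bp  <- function(ops) sum(ops$len[ops$op %in% CIGAR_REF_OPS])
cigar_clip_bp <- function(ops) sum(ops$len[ops$op %in% c("S", "H")])

## run-length compress adjacent identical ops
cigar_canonical <- function(ops) {
  if (!nrow(ops)) return(ops)
  keep <- ops$len > 0L
  ops <- ops[keep, , drop = FALSE]
  if (!nrow(ops)) return(ops)
  grp <- cumsum(c(TRUE, ops$op[-1] != ops$op[-nrow(ops)]))
  data.frame(op = ops$op[!duplicated(grp)],
             len = as.integer(tapply(ops$len, grp, sum)))
}

## Walk a clip-free CIGAR and return per-op blocks with read offsets
## (alignment orientation, 0-based from the start of the aligned part) and
## reference positions (0-based, from ref_start).
cigar_blocks <- function(ops, ref_start = 0L) {
  n <- nrow(ops)
  q <- integer(n); r <- integer(n)
  qc <- as.integer(ops$op %in% c("M", "=", "X", "I")) * ops$len
  rc <- as.integer(ops$op %in% CIGAR_REF_OPS) * ops$len
  q <- cumsum(c(0L, qc))[seq_len(n)]
  r <- cumsum(c(0L, rc))[seq_len(n)] + as.integer(ref_start)
  data.frame(op = ops$op, len = ops$len,
             q_start = q, q_end = q + qc,
             r_start = r, r_end = r + rc)
}

## Project a set of reference intervals (0-based half-open) through one
## alignment onto read coordinates in alignment orientation, relative to the
## start of the read (not of the aligned part). Deletions collapse;
## insertions inside a projected interval are NOT included (they are read
## bases with no reference counterpart).
project_ref_intervals <- function(ops, ref_start, aln_q_offset, intervals) {
  bl <- cigar_blocks(ops, ref_start)
  bl <- bl[bl$op %in% CIGAR_REF_OPS & bl$op != "D", , drop = FALSE]
  out_s <- integer(0); out_e <- integer(0)
  for (k in seq_len(nrow(intervals))) {
    s <- intervals[k, 1]; e <- intervals[k, 2]
    hit <- bl[bl$r_end > s & bl$r_start < e, , drop = FALSE]
    if (!nrow(hit)) next
    qs <- hit$q_start + pmax(0L, s - hit$r_start)
    qe <- hit$q_end - pmax(0L, hit$r_end - e)
    out_s <- c(out_s, qs + aln_q_offset)
    out_e <- c(out_e, qe + aln_q_offset)
  }
  iv_sort_merge(iv(out_s, out_e))
}
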