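## Readers and writers for the on-disk formats the pipeline consumes, and
## the single internal coordinate convention: all positions are 0-based
## half-open; conversions happen only here, at the I/O boundary.

#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercased, `U` is mapped to `T`, and the alphabet is
#' restricted to A/C/G/T/N. Record ids (first whitespace-delimited token of
#' the header) must be unique within a file.
#'
#' @param path FASTA file.
#' @param role role tag attached to every record, one of
#'   `"target_consensus"`, `"outgroup_consensus"`, `"genome"`, `"read"`.
#' @return data.frame with columns `id`, `seq`, `role`.
#' @export
read_fasta <- function(path, role = "genome") {
  role <- match.arg(role, c("target_consensus", "outgroup_consensus", "genome", "read"))
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    return(data.frame(id = character(0), seq = character(0), role = character(0)))
  }
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- chartr("u", "t", toupper(as.character(x)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(id = ids, seq = unname(seqs), role = role)
}

#' Write a sequence table to FASTA
#'
#' @param seqs data.frame with columns `id` and `seq`.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read nanopore reads from FASTQ
#'
#' Per-base Phred qualities are retained and a mean quality is derived by
#' averaging error probabilities `10^(-Q/10)` and converting back to the
#' Phred scale, the usual base-caller summary semantics.
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual` (Phred+33 string) and
#'   `mean_q`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), mean_q = numeric(0)))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate read ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- toupper(as.character(x))
  if (any(nchar(quals) != nchar(seqs))) stop("quality/sequence length mismatch")
  data.frame(id = ids, seq = unname(seqs), qual = unname(quals),
             mean_q = vapply(quals, phred_mean_q, numeric(1), USE.NAMES = FALSE))
}

phred_mean_q <- function(qual_string) {
  q <- utf8ToInt(qual_string) - 33L
  -10 * log10(mean(10 ^ (-q / 10)))
}

#' Write reads to FASTQ
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  }
  invisible(path)
}

## ---- repeat taxonomy -------------------------------------------------------

#' Mobile element subfamily taxonomy
#'
#' Packaged lookup used to resolve a RepeatMasker subfamily name to its
#' family and to the targeting group used by read classification. Groups:
#' `L1Hs`, `L1PA`, `L1_other`, `AluY`, `Alu_other`, `SVA`, `other`.
#'
#' @return data.frame with columns `subfamily`, `family`, `group`.
#' @export
mei_taxonomy <- function() {
  rbind(
    data.frame(subfamily = c("L1Hs", "L1HS", "L1Ta", "L1PreTa"),
               family = "L1", group = "L1Hs"),
    data.frame(subfamily = paste0("L1PA", 2:17), family = "L1", group = "L1PA"),
    data.frame(subfamily = c("L1PB1", "L1PB2", "L1MA1", "L1MB3", "L1ME1"),
               family = "L1", group = "L1_other"),
    data.frame(subfamily = c("AluY", "AluYa5", "AluYa8", "AluYb8", "AluYb9",
                             "AluYc", "AluYd8", "AluYg6"),
               family = "Alu", group = "AluY"),
    data.frame(subfamily = c("AluSx", "AluSz", "AluSp", "AluSq", "AluJb", "AluJo"),
               family = "Alu", group = "Alu_other"),
    data.frame(subfamily = paste0("SVA_", LETTERS[1:6]), family = "SVA", group = "SVA")
  )
}

#' Resolve subfamily names to family and targeting group
#'
#' Unknown subfamilies fall back to their leading alphabetic prefix as the
#' family and group `"other"`.
#'
#' @param subfamily character vector of subfamily names.
#' @param taxonomy taxonomy table, see [mei_taxonomy()].
#' @return data.frame with `subfamily`, `family`, `group`.
#' @export
taxonomy_lookup <- function(subfamily, taxonomy = mei_taxonomy()) {
  i <- match(subfamily, taxonomy$subfamily)
  data.frame(subfamily = subfamily,
             family = ifelse(is.na(i), sub("^([A-Za-z]+).*$", "\\1", subfamily),
                             taxonomy$family[i]),
             group = ifelse(is.na(i), "other", taxonomy$group[i]))
}

## ---- repeat annotation -----------------------------------------------------

#' Read reference repeat annotation
#'
#' Supports RepeatMasker `.out` (1-based inclusive coordinates, converted to
#' the internal 0-based half-open convention; `C` strand mapped to `-`) and
#' BED6 (already 0-based half-open, passed through). The subfamily is taken
#' from the repeat name column and resolved to a family via the packaged
#' taxonomy.
#'
#' @param path annotation file.
#' @param dialect `"rmout"` or `"bed"`.
#' @return data.frame with columns `ref_name`, `start`, `end`, `strand`,
#'   `family`, `subfamily`.
#' @export
read_repeat_annotation <- function(path, dialect = c("rmout", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "rmout") {
    ## skip the standard header (starts with 'SW'/'score' banner + blank line)
    body <- grep("^\\s*[0-9]", lines, value = TRUE)
    if (!length(body)) {
      return(empty_annotation())
    }
    f <- strsplit(trimws(body), "\\s+")
    get <- function(i) vapply(f, `[`, character(1), i)
    ref_name <- get(5)
    start <- as.integer(get(6)) - 1L   # 1-based inclusive -> 0-based half-open
    end <- as.integer(get(7))
    strand <- ifelse(get(9) %in% c("C", "-"), "-", "+")
    subfam <- get(10)
  } else {
    body <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
    if (!length(body)) return(empty_annotation())
    f <- strsplit(trimws(body), "\\s+")
    if (any(lengths(f) < 4)) stop("BED rows need at least 4 columns")
    get <- function(i) vapply(f, function(x) if (length(x) >= i) x[i] else NA_character_, character(1))
    ref_name <- get(1)
    start <- as.integer(get(2))
    end <- as.integer(get(3))
    subfam <- get(4)
    strand <- ifelse(is.na(get(6)) | !get(6) %in% c("+", "-"), "+", get(6))
  }
  if (any(start >= end)) stop("annotation with start >= end after conversion")
  tx <- taxonomy_lookup(subfam)
  data.frame(ref_name = ref_name, start = start, end = end, strand = strand,
             family = tx$family, subfamily = subfam)
}

empty_annotation <- function() {
  data.frame(ref_name = character(0), start = integer(0), end = integer(0),
             strand = character(0), family = character(0), subfamily = character(0))
}

#' Write repeat annotation
#' @param ann annotation data.frame as from [read_repeat_annotation()].
#' @param path output file.
#' @param dialect `"bed"` (BED6) or `"rmout"`.
#' @export
write_repeat_annotation <- function(ann, path, dialect = c("bed", "rmout")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "bed") {
    if (nrow(ann)) {
      writeLines(paste(ann$ref_name, ann$start, ann$end, ann$subfamily, 0L,
                       ann$strand, sep = "\t"), con)
    }
  } else {
    writeLines(c(
      "   SW   perc perc perc  query      position in query      matching  repeat",
      "score   div. del. ins.  sequence   begin  end   (left)    repeat    class/family",
      ""), con)
    if (nrow(ann)) {
      fam <- paste0(ann$family, "/", ann$family)
      writeLines(sprintf("%5d %6.1f %4.1f %4.1f  %s %d %d (0) %s %s %s",
                         1000L, 0, 0, 0, ann$ref_name, ann$start + 1L, ann$end,
                         ifelse(ann$strand == "-", "C", "+"),
                         ann$subfamily, fam), con)
    }
  }
  invisible(path)
}

## ---- alignments ------------------------------------------------------------

ALN_COLS <- c("read_id", "read_len", "read_start", "read_end", "strand",
              "ref_name", "ref_len", "ref_start", "ref_end", "mapq", "cigar")

empty_alignments <- function() {
  out <- data.frame(read_id = character(0), read_len = integer(0),
                    read_start = integer(0), read_end = integer(0),
                    strand = character(0), ref_name = character(0),
                    ref_len = integer(0), ref_start = integer(0),
                    ref_end = integer(0), mapq = integer(0), cigar = character(0))
  out
}

#' Read read-to-reference alignments
#'
#' Accepts PAF (the `cg:Z:` CIGAR tag is required) or text SAM. Records are
#' normalised to one internal shape: `read_start`/`read_end` are 0-based
#' half-open on the *original* read orientation (PAF convention), the CIGAR
#' is reference-forward with clips stripped (clip lengths are implicit), and
#' hard clips contribute to `read_len`. Records whose CIGAR bookkeeping does
#' not reconcile with their coordinates are dropped with a warning count.
#'
#' @param path alignment file.
#' @param format `"paf"` or `"sam"`.
#' @return data.frame of alignment records (see `ALN_COLS`).
#' @export
read_alignments <- function(path, format = c("paf", "sam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  out <- if (format == "paf") parse_paf(lines) else parse_sam(lines)
  validate_alignments(out)
}

parse_paf <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_alignments())
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[`, character(1), i)
  cg <- vapply(f, function(x) {
    hit <- grep("^cg:Z:", x, value = TRUE)
    if (length(hit)) sub("^cg:Z:", "", hit[1]) else NA_character_
  }, character(1))
  if (anyNA(cg)) {
    stop("PAF records without cg:Z CIGAR tag: ",
         paste(get(1)[is.na(cg)], collapse = ", "))
  }
  data.frame(read_id = get(1), read_len = as.integer(get(2)),
             read_start = as.integer(get(3)), read_end = as.integer(get(4)),
             strand = get(5), ref_name = get(6), ref_len = as.integer(get(7)),
             ref_start = as.integer(get(8)), ref_end = as.integer(get(9)),
             mapq = as.integer(get(12)), cigar = cg)
}

parse_sam <- function(lines) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(lines)) return(empty_alignments())
  rows <- lapply(strsplit(lines, "\t", fixed = TRUE), function(x) {
    flag <- as.integer(x[2])
    if (bitwAnd(flag, 4L) > 0L || x[6] == "*") return(NULL)
    ops <- parse_cigar(x[6])
    read_len <- cigar_read_bp(ops) + sum(ops$len[ops$op %in% c("S", "H")])
    aligned <- ops[!ops$op %in% c("S", "H"), , drop = FALSE]
    lead <- 0L
    for (k in seq_len(nrow(ops))) {
      if (ops$op[k] %in% c("S", "H")) lead <- lead + ops$len[k] else break
    }
    aln_len <- cigar_read_bp(aligned)
    qs_aln <- lead                      # alignment orientation
    qe_aln <- lead + aln_len
    rev <- bitwAnd(flag, 16L) > 0L
    data.frame(read_id = x[1], read_len = read_len,
               read_start = if (rev) read_len - qe_aln else qs_aln,
               read_end = if (rev) read_len - qs_aln else qe_aln,
               strand = if (rev) "-" else "+",
               ref_name = x[3], ref_len = NA_integer_,
               ref_start = as.integer(x[4]) - 1L,
               ref_end = as.integer(x[4]) - 1L + cigar_ref_bp(aligned),
               mapq = as.integer(x[5]),
               cigar = unparse_cigar(cigar_canonical(aligned)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_alignments() else out
}

validate_alignments <- function(aln) {
  if (!nrow(aln)) return(aln)
  ok <- vapply(seq_len(nrow(aln)), function(i) {
    ops <- tryCatch(parse_cigar(aln$cigar[i]), error = function(e) NULL)
    if (is.null(ops) || !nrow(ops) || any(ops$op %in% c("S", "H"))) return(FALSE)
    cigar_read_bp(ops) == aln$read_end[i] - aln$read_start[i] &&
      cigar_ref_bp(ops) == aln$ref_end[i] - aln$ref_start[i] &&
      aln$read_start[i] >= 0 && aln$read_end[i] <= aln$read_len[i] &&
      aln$strand[i] %in% c("+", "-")
  }, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " alignment record(s) failed CIGAR bookkeeping and were dropped")
  }
  aln[ok, , drop = FALSE]
}

#' Write alignments as PAF (with cg:Z CIGAR tag)
#' @param aln alignment table.
#' @param path output file.
#' @export
write_paf <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(aln)) {
    nm <- aln$read_end - aln$read_start   # residue-match column, upper bound
    writeLines(paste(aln$read_id, aln$read_len, aln$read_start, aln$read_end,
                     aln$strand, aln$ref_name, aln$ref_len, aln$ref_start,
                     aln$ref_end, nm, pmax(nm, aln$ref_end - aln$ref_start),
                     aln$mapq, paste0("cg:Z:", aln$cigar), sep = "\t"), con)
  }
  invisible(path)
}

## offset of the aligned part within the alignment-oriented read
aln_q_offset <- function(aln_row) {
  if (aln_row$strand == "+") aln_row$read_start
  else aln_row$read_len - aln_row$read_end
}

## ---- callsets --------------------------------------------------------------

CALL_COLS <- c("ref_name", "position", "subfamily", "strand", "length",
               "support", "genotype", "tsd", "polya_len", "en_matches",
               "inverted5", "transduction", "status", "filter")

#' Read / write MEI call tables
#'
#' Tab-separated with a fixed header (`CALL_COLS` order); `position` is the
#' 0-based insertion point.
#'
#' @param path file path.
#' @rdname callset_io
#' @export
read_callset <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(position = "integer"), na.strings = ".")
  miss <- setdiff(CALL_COLS, names(x))
  if (length(miss)) stop("callset missing columns: ", paste(miss, collapse = ", "))
  x[, CALL_COLS]
}

#' @param calls call table.
#' @rdname callset_io
#' @export
write_callset <- function(calls, path) {
  out <- calls[, CALL_COLS]
  out$tsd[is.na(out$tsd) | out$tsd == ""] <- "."
  out$transduction[is.na(out$transduction) | out$transduction == ""] <- "."
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
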