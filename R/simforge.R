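## Synthetic-data generator. Produces every input the pipeline consumes --
## reference genome with implanted repeat copies and matching annotation,
## diploid donor with TPRT-hallmarked non-reference insertions, Cas9-cut or
## WGS-style nanopore-like reads with per-base errors -- together with
## complete ground truth (loci, hallmark strings, per-read provenance and
## exact reference alignments). All randomness is driven by one integer
## seed through an isolated Mersenne-Twister state.

#' Simulation configuration
#'
#' Defaults are the study conditions the package validates against: Cas9
#' cut-site offsets {3: 0.5, 4: 0.5} on the guide-forward side and {7: 1} on
#' the reverse side, a 4.6-fold forward-strand bias, per-base error rates
#' 3%/2%/2% (substitution/insertion/deletion), TSD lengths 5-20 bp, poly(A)
#' tails 10-40 bp. Read lengths follow a truncated log-normal tuned so the
#' base-weighted median equals `n50` (test default 5 kb; set 15000-32000 for
#' flow-cell-scale reads).
#'
#' @param ... overrides for any default listed below.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    genome_len = 300000L,
    ref_copies = c(L1Hs = 8L, L1PA4 = 4L, AluYb8 = 6L, AluSx = 4L),
    ref_divergence = c(L1Hs = 0.01, L1PA4 = 0.03, AluYb8 = 0.01, AluSx = 0.08),
    margin = 500L,                  # min spacing between implants (bp)
    ## non-reference insertions
    nonref_n = 10L,
    nonref_subfamily = "L1Hs",
    zygosity_mix = c(het = 0.5, hom = 0.5),
    full_length_prob = 0.5,         # else 5'-truncated
    truncation_frac = c(0.15, 0.6), # truncated copies keep this 3' fraction... range
    tsd_len = c(5L, 20L),
    polya_len = c(10L, 40L),
    inversion_prob = 0,
    nonref_divergence = 0.005,
    en_candidates = 50L,            # site draws per locus; the best EN match wins
    ## reads
    reads_per_cut = 10,             # Poisson mean per cut site per haplotype
    cut_offsets_fwd = c("3" = 0.5, "4" = 0.5),
    cut_offsets_rev = c("7" = 1),
    strand_bias = 4.6,
    error_sub = 0.03, error_ins = 0.02, error_del = 0.02,
    n50 = 5000, len_sdlog = 0.45, min_read_len = 300L,
    background_frac = 0.2,
    guide_max_mismatch = 3L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(abs(sum(cfg$cut_offsets_fwd) - 1) < 1e-9,
            abs(sum(cfg$cut_offsets_rev) - 1) < 1e-9,
            abs(sum(cfg$zygosity_mix) - 1) < 1e-9)
  structure(cfg, class = "sim_config")
}

#' Build a toy reference genome with implanted repeat copies
#'
#' A random background sequence receives per-copy-mutated implants of the
#' toy consensus subfamilies at non-overlapping positions; the returned
#' annotation matches the implants exactly. Close-family copies (L1PA4,
#' AluSx at higher divergence) are included so close/off-target
#' classification can be exercised.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `genome` (sequence table, one contig `chrT`),
#'   `annotation`, `consensus` (the toy library) and `config`.
#' @export
build_reference <- function(config = sim_config(), seed = 1L) {
  lib <- toy_consensus_library()
  with_seed(seed, {
    lens <- setNames(nchar(lib$seq), lib$id)
    need <- sum(lens[names(config$ref_copies)] * config$ref_copies) +
      (sum(config$ref_copies) + config$nonref_n + 2L) * 2L * config$margin
    if (need > 0.9 * config$genome_len) {
      stop("overcrowded config: ", need, " bp of implants for a ",
           config$genome_len, " bp genome")
    }
    genome <- random_dna(config$genome_len)
    occupied <- iv()
    ann <- empty_annotation()
    for (sf in names(config$ref_copies)) {
      cons <- lib$seq[lib$id == sf]
      dv <- config$ref_divergence[[sf]] %||% 0.02
      for (i in seq_len(config$ref_copies[[sf]])) {
        copy <- mutate_subs(cons, dv)
        w <- nchar(copy)
        s <- place_interval(w, config$genome_len, occupied, config$margin)
        occupied <- iv_sort_merge(rbind(occupied, iv(s, s + w)))
        genome <- seq_poke(genome, s, copy)
        ann <- rbind(ann, data.frame(ref_name = "chrT", start = s, end = s + w,
                                     strand = "+", family = taxonomy_lookup(sf)$family,
                                     subfamily = sf))
      }
    }
    ann <- ann[order(ann$start), , drop = FALSE]
    rownames(ann) <- NULL
    list(genome = data.frame(id = "chrT", seq = genome, role = "genome"),
         annotation = ann, consensus = lib, config = config)
  })
}

place_interval <- function(width, genome_len, occupied, margin) {
  for (try in 1:2000) {
    s <- sample.int(genome_len - width - 2L * margin, 1L) + margin
    if (iv_overlap_bp(s - margin, s + width + margin, occupied) == 0L) return(s)
  }
  stop("could not place implant of width ", width, "; genome too crowded")
}

#' Implant non-reference MEIs into a diploid donor
#'
#' Each locus inserts `TSD + element (possibly 5'-truncated and/or
#' 5'-inverted) + poly(A) + TSD` using the staggered-nick model: the donor
#' haplotype is `R[..pos+t) + element + polyA + R[pos..)`, so the reference
#' word `R[pos..pos+t)` flanks the insertion on both sides. Insertion sites
#' are biased toward the L1 endonuclease motif (best TTTT/AA match among
#' `en_candidates` random draws). Heterozygous loci touch haplotype 1 only,
#' homozygous loci touch both.
#'
#' @param reference result of [build_reference()].
#' @param config,seed as in [build_reference()].
#' @return list with `haplotypes` (per-haplotype sequence and block map) and
#'   `loci` (the truth table).
#' @export
implant_nonreference <- function(reference, config = reference$config, seed = 1L) {
  lib <- reference$consensus
  genome <- reference$genome$seq[1]
  with_seed(seed + 1000L, {
    n <- config$nonref_n
    ann_iv <- iv(reference$annotation$start, reference$annotation$end)
    occupied <- ann_iv
    loci <- list()
    for (i in seq_len(n)) {
      pos <- sample_en_biased_site(genome, occupied, config)
      occupied <- iv_sort_merge(rbind(occupied, iv(pos - config$margin, pos + config$margin)))
      sf <- if (length(config$nonref_subfamily) == 1L) config$nonref_subfamily
            else sample(config$nonref_subfamily, 1L)
      cons <- mutate_subs(lib$seq[lib$id == sf], config$nonref_divergence)
      full <- runif(1) < config$full_length_prob
      if (!full) {
        keep <- runif(1, config$truncation_frac[1], config$truncation_frac[2])
        cons <- substr(cons, nchar(cons) - max(50L, round(keep * nchar(cons))) + 1L,
                       nchar(cons))
      }
      inverted5 <- FALSE
      fam <- taxonomy_lookup(sf)$family
      if (fam == "L1" && runif(1) < config$inversion_prob) {
        split <- round(runif(1, 0.3, 0.6) * nchar(cons))
        cons <- paste0(revcomp(substr(cons, 1L, split)),
                       substr(cons, split + 1L, nchar(cons)))
        inverted5 <- TRUE
      }
      pa <- sample(config$polya_len[1]:config$polya_len[2], 1L)
      elem <- paste0(cons, strrep("A", pa))
      strand <- "+"
      tlen <- sample(config$tsd_len[1]:config$tsd_len[2], 1L)
      tsd <- substr(genome, pos + 1L, pos + tlen)
      zyg <- sample(names(config$zygosity_mix), 1L, prob = config$zygosity_mix)
      en <- en_motif_matches(substr(genome, pos - 3L, pos + 2L))
      loci[[i]] <- data.frame(
        locus_id = sprintf("nr%03d", i), ref_name = "chrT", position = pos,
        subfamily = sf, strand = strand, length = nchar(elem),
        zygosity = zyg, tsd = tsd, tsd_len = tlen, polya_len = pa,
        inverted5 = inverted5, en_matches = en, ins_seq = elem)
    }
    loci <- do.call(rbind, loci) %||% empty_loci()
    loci <- loci[order(loci$position), , drop = FALSE]
    rownames(loci) <- NULL
    if (nrow(loci)) {
      loci <- cbind(loci, canonical_hallmarks(genome, loci))
    } else {
      loci$canonical_position <- integer(0)
      loci$canonical_tsd <- character(0)
      loci$canonical_polya <- integer(0)
    }
    haps <- list(
      h1 = build_haplotype(genome, loci),
      h2 = build_haplotype(genome, loci[loci$zygosity == "hom", , drop = FALSE]))
    list(haplotypes = haps, loci = loci, reference = reference)
  })
}

empty_loci <- function() {
  data.frame(locus_id = character(0), ref_name = character(0),
             position = integer(0), subfamily = character(0),
             strand = character(0), length = integer(0),
             zygosity = character(0), tsd = character(0),
             tsd_len = integer(0), polya_len = integer(0),
             inverted5 = logical(0), en_matches = integer(0),
             ins_seq = character(0))
}

## Sequence-level (canonical) hallmark values of each implanted locus.
## Junction micro-homology makes the implanted TSD/poly(A) ambiguous at the
## sequence level: when the element happens to start with the same base as
## the reference just after the duplicated word (or the poly(A) matches the
## base just before the site), every placement-aware observer -- including
## an aligner -- reports the maximal duplication. The canonical values are
## the well-defined properties of the donor sequence itself and are what a
## correct caller recovers exactly.
canonical_hallmarks <- function(genome, loci) {
  n <- nchar(genome)
  out <- lapply(seq_len(nrow(loci)), function(i) {
    pos <- loci$position[i]; t <- loci$tsd_len[i]
    X <- paste0(loci$tsd[i], loci$ins_seq[i])           # leftmost-placement insert
    lx <- nchar(X)
    ## rightward extension: longest common prefix of X and R[pos..) beyond t
    r_ext <- 0L
    while (t + r_ext < lx && pos + t + r_ext < n &&
           substr(X, t + r_ext + 1L, t + r_ext + 1L) ==
           substr(genome, pos + t + r_ext + 1L, pos + t + r_ext + 1L)) {
      r_ext <- r_ext + 1L
    }
    ## leftward extension: common suffix of X and R[..pos)
    l_ext <- 0L
    while (l_ext < lx - 1L && pos - l_ext > 0L &&
           substr(X, lx - l_ext, lx - l_ext) ==
           substr(genome, pos - l_ext, pos - l_ext)) {
      l_ext <- l_ext + 1L
    }
    cpos <- pos - l_ext
    ctsd <- substr(genome, cpos + 1L, pos + t + r_ext)
    cins <- substr(loci$ins_seq[i], 1L, nchar(loci$ins_seq[i]) - l_ext)
    cpa <- detect_polya(cins, loci$strand[i])
    data.frame(canonical_position = cpos, canonical_tsd = ctsd,
               canonical_polya = cpa)
  })
  do.call(rbind, out)
}

en_motif_matches <- function(window6) {
  if (is.na(window6) || nchar(window6) != 6L) return(0L)
  sum(strsplit(window6, "")[[1]] == c("T", "T", "T", "T", "A", "A"))
}

sample_en_biased_site <- function(genome, occupied, config) {
  n <- nchar(genome)
  best_pos <- NA_integer_; best_en <- -1L
  tries <- 0L
  while (tries < 20L * config$en_candidates) {
    cand <- sample.int(n - 2L * config$margin, config$en_candidates) + config$margin
    for (p in cand) {
      tries <- tries + 1L
      if (iv_overlap_bp(p - config$margin, p + config$margin, occupied) > 0L) next
      en <- en_motif_matches(substr(genome, p - 3L, p + 2L))
      if (en > best_en) { best_en <- en; best_pos <- p }
    }
    if (!is.na(best_pos)) return(best_pos)
  }
  stop("could not place non-reference insertion; genome too crowded")
}

## Block map: alternating reference-backed and inserted blocks. The inserted
## block at a locus covers TSD + element + polyA (the duplicated reference
## word plus the inserted sequence), after which the reference resumes at
## pos + tsd_len.
build_haplotype <- function(genome, loci) {
  n <- nchar(genome)
  segs <- character(0)
  blocks <- list()
  hap_at <- 0L; ref_at <- 0L
  add_block <- function(width, ref_start, locus_id) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      hap_start = hap_at, hap_end = hap_at + width,
      ref_start = ref_start, locus_id = locus_id)
    hap_at <<- hap_at + width
  }
  if (nrow(loci)) {
    for (i in seq_len(nrow(loci))) {
      pos <- loci$position[i]; t <- loci$tsd_len[i]
      ref_seg <- substr(genome, ref_at + 1L, pos)
      segs <- c(segs, ref_seg)
      add_block(nchar(ref_seg), ref_at, NA_character_)
      ins <- paste0(loci$tsd[i], loci$ins_seq[i])
      segs <- c(segs, ins)
      add_block(nchar(ins), NA_integer_, loci$locus_id[i])
      ref_at <- pos
    }
  }
  segs <- c(segs, substr(genome, ref_at + 1L, n))
  add_block(n - ref_at, ref_at, NA_character_)
  blocks <- do.call(rbind, blocks)
  blocks <- blocks[blocks$hap_end > blocks$hap_start, , drop = FALSE]
  list(seq = paste(segs, collapse = ""), blocks = blocks)
}

#' Sample Cas9 cut-site offsets
#'
#' @param n number of draws.
#' @param dist named probability vector (names are base distances from the
#'   PAM `N`), e.g. `c("3" = 0.5, "4" = 0.5)`.
#' @return integer vector of offsets.
#' @export
sample_cut_offsets <- function(n, dist) {
  as.integer(sample(names(dist), n, replace = TRUE, prob = dist))
}

read_length_draw <- function(n, config) {
  meanlog <- log(config$n50) - config$len_sdlog^2
  len <- rlnorm(n, meanlog, config$len_sdlog)
  pmin(pmax(round(len), config$min_read_len), round(20 * config$n50))
}

#' Simulate a Cas9-targeted nanopore run
#'
#' Guide-matched sites on each haplotype (up to `guide_max_mismatch`
#' substitutions, both orientations) are cut; reads start at an offset drawn
#' from the configured cut-offset distributions and extend bi-directionally:
#' guide-forward reads (probability `strand_bias / (1 + strand_bias)`) run
#' 3'-ward out of the guide, reverse reads run the other way. Off-target
#' background reads are added at `background_frac` of the signal reads.
#' Errors are applied per base; the truth alignments are updated alongside,
#' so every emitted record satisfies the CIGAR bookkeeping invariants.
#'
#' @param donor result of [implant_nonreference()].
#' @param guide 23 bp guide (protospacer + PAM).
#' @param config,seed as elsewhere.
#' @return list with `reads`, `alignments` (truth, reference coordinates),
#'   `manifest` (per-read provenance) and `sites` (cut-site table).
#' @export
simulate_cas9_run <- function(donor, guide, config = sim_config(), seed = 1L) {
  with_seed(seed + 2000L, {
    sites <- do.call(rbind, lapply(names(donor$haplotypes), function(h) {
      s <- find_guide_sites(donor$haplotypes[[h]]$seq, guide,
                            config$guide_max_mismatch, h)
      if (is.null(s)) return(NULL)
      annotate_sites(s, donor$haplotypes[[h]]$blocks)
    }))
    if (is.null(sites) || !nrow(sites)) stop("guide matches no site in the donor")
    reads <- list(); alns <- list(); manifest <- list()
    rid <- 0L
    p_fwd <- config$strand_bias / (1 + config$strand_bias)
    for (i in seq_len(nrow(sites))) {
      h <- sites$haplotype[i]
      hap <- donor$haplotypes[[h]]
      nr <- rpois(1L, config$reads_per_cut)
      if (nr == 0L) next
      fwd <- runif(nr) < p_fwd
      offs <- ifelse(fwd,
                     sample_cut_offsets(nr, config$cut_offsets_fwd),
                     sample_cut_offsets(nr, config$cut_offsets_rev))
      lens <- read_length_draw(nr, config)
      for (k in seq_len(nr)) {
        rid <- rid + 1L
        rr <- cas9_read(hap, sites[i, ], fwd[k], offs[k], lens[k], config)
        if (is.null(rr)) next
        id <- sprintf("read%05d", rid)
        rr$read$id <- id
        reads[[id]] <- rr$read
        if (!is.null(rr$aln)) { rr$aln$read_id <- id; alns[[id]] <- rr$aln }
        manifest[[id]] <- data.frame(
          read_id = id, haplotype = h, origin = "cut",
          site_kind = sites$kind[i], locus_id = sites$locus_id[i],
          site_start = sites$site_start[i],
          direction = if (fwd[k]) "fwd" else "rev", offset = offs[k],
          strand = rr$strand, length = nchar(rr$read$seq),
          mapped = !is.null(rr$aln))
      }
    }
    n_bg <- round(config$background_frac * length(reads))
    bg <- simulate_background(donor, n_bg, config, rid)
    out_reads <- do.call(rbind, c(reads, bg$reads))
    out_alns <- do.call(rbind, c(alns, bg$alns))
    out_man <- do.call(rbind, c(manifest, bg$manifest))
    rownames(out_reads) <- rownames(out_man) <- NULL
    if (!is.null(out_alns)) rownames(out_alns) <- NULL
    list(reads = out_reads, alignments = out_alns %||% empty_alignments(),
         manifest = out_man, sites = sites)
  })
}

## all guide placements (<= max mismatches, both orientations) on a haplotype
find_guide_sites <- function(hap_seq, guide, max_mm, hap_name) {
  subj <- Biostrings::DNAString(hap_seq)
  fw <- Biostrings::matchPattern(guide, subj, max.mismatch = max_mm)
  rv <- Biostrings::matchPattern(revcomp(guide), subj, max.mismatch = max_mm)
  rows <- list()
  if (length(fw)) {
    s <- BiocGenerics::start(fw) - 1L
    rows[[1]] <- data.frame(haplotype = hap_name, site_start = s,
                            pam_n = s + 20L, orient = "+")
  }
  if (length(rv)) {
    s <- BiocGenerics::start(rv) - 1L
    rows[[2]] <- data.frame(haplotype = hap_name, site_start = s,
                            pam_n = s + 2L, orient = "-")
  }
  sites <- do.call(rbind, rows)
  if (is.null(sites)) return(NULL)
  sites$kind <- "reference"; sites$locus_id <- NA_character_
  sites
}

## annotate cut sites with the truth locus they fall in (insertion blocks)
annotate_sites <- function(sites, blocks) {
  for (i in seq_len(nrow(sites))) {
    j <- which(blocks$hap_start <= sites$site_start[i] &
               blocks$hap_end > sites$site_start[i])
    if (length(j) && !is.na(blocks$locus_id[j[1]])) {
      sites$kind[i] <- "nonref"; sites$locus_id[i] <- blocks$locus_id[j[1]]
    }
  }
  sites
}

## one Cas9 read: genomic interval on the haplotype, then sequence + truth
cas9_read <- function(hap, site, fwd, offset, len, config) {
  hap_len <- nchar(hap$seq)
  if (site$orient == "+") {
    ## guide-forward reads run 3'-ward (right); reverse reads run left
    if (fwd) { s <- site$pam_n - offset; e <- min(hap_len, s + len); strand <- "+" }
    else     { e <- site$pam_n - offset + 1L; s <- max(0L, e - len); strand <- "-" }
  } else {
    if (fwd) { e <- site$pam_n + offset + 1L; s <- max(0L, e - len); strand <- "-" }
    else     { s <- site$pam_n + offset; e <- min(hap_len, s + len); strand <- "+" }
  }
  if (e - s < config$min_read_len / 2) return(NULL)
  synth_read(hap, s, e, strand, config)
}

simulate_background <- function(donor, n_bg, config, rid0) {
  reads <- list(); alns <- list(); manifest <- list()
  if (n_bg <= 0) return(list(reads = reads, alns = alns, manifest = manifest))
  lens <- read_length_draw(n_bg, config)
  for (k in seq_len(n_bg)) {
    h <- sample(names(donor$haplotypes), 1L)
    hap <- donor$haplotypes[[h]]
    hap_len <- nchar(hap$seq)
    s <- sample.int(max(1L, hap_len - lens[k]), 1L) - 1L
    e <- min(hap_len, s + lens[k])
    strand <- sample(c("+", "-"), 1L)
    rr <- synth_read(hap, s, e, strand, config)
    id <- sprintf("read%05d", rid0 + k)
    rr$read$id <- id
    reads[[id]] <- rr$read
    if (!is.null(rr$aln)) { rr$aln$read_id <- id; alns[[id]] <- rr$aln }
    manifest[[id]] <- data.frame(
      read_id = id, haplotype = h, origin = "background",
      site_kind = "background", locus_id = NA_character_, site_start = NA_integer_,
      direction = NA_character_, offset = NA_integer_, strand = strand,
      length = nchar(rr$read$seq), mapped = !is.null(rr$aln))
  }
  list(reads = reads, alns = alns, manifest = manifest)
}

#' Simulate a WGS-like nanopore run over the donor
#'
#' Uniform random read starts over both haplotypes at the requested
#' per-haplotype depth; same error model and truth output as
#' [simulate_cas9_run()]. Useful for genotyping and spanning-read behaviour
#' that targeted runs cannot exercise.
#'
#' @param donor result of [implant_nonreference()].
#' @param depth expected per-haplotype coverage.
#' @param config,seed as elsewhere.
#' @return list with `reads`, `alignments`, `manifest`.
#' @export
simulate_wgs_run <- function(donor, depth = 10, config = sim_config(), seed = 1L) {
  with_seed(seed + 3000L, {
    reads <- list(); alns <- list(); manifest <- list()
    rid <- 0L
    for (h in names(donor$haplotypes)) {
      hap <- donor$haplotypes[[h]]
      hap_len <- nchar(hap$seq)
      n <- ceiling(depth * hap_len / (config$n50 * exp(-config$len_sdlog^2 / 2)))
      lens <- read_length_draw(n, config)
      starts <- sample.int(hap_len, n, replace = TRUE) - 1L
      for (k in seq_len(n)) {
        s <- starts[k]; e <- min(hap_len, s + lens[k])
        if (e - s < config$min_read_len) next
        rid <- rid + 1L
        strand <- sample(c("+", "-"), 1L)
        rr <- synth_read(hap, s, e, strand, config)
        id <- sprintf("wgs%05d", rid)
        rr$read$id <- id
        reads[[id]] <- rr$read
        if (!is.null(rr$aln)) { rr$aln$read_id <- id; alns[[id]] <- rr$aln }
        manifest[[id]] <- data.frame(read_id = id, haplotype = h, origin = "wgs",
                                     site_kind = "wgs", locus_id = NA_character_, site_start = NA_integer_,
                                     direction = NA_character_, offset = NA_integer_,
                                     strand = strand, length = nchar(rr$read$seq),
                                     mapped = !is.null(rr$aln))
      }
    }
    out_reads <- do.call(rbind, reads)
    rownames(out_reads) <- NULL
    list(reads = out_reads, alignments = do.call(rbind, alns) %||% empty_alignments(),
         manifest = do.call(rbind, manifest))
  })
}

## ---- read synthesis with truth alignment -----------------------------------

## Build the read covering haplotype interval [s, e), apply errors base by
## base while updating the alignment geometry, and emit the truth record in
## reference coordinates. `strand` is the genomic strand of the read.
synth_read <- function(hap, s, e, strand, config) {
  seg <- substr(hap$seq, s + 1L, e)
  bases <- strsplit(seg, "")[[1]]
  ## per-base type: M if the base is reference-backed, I if inserted
  bl <- hap$blocks
  hit <- bl[bl$hap_end > s & bl$hap_start < e, , drop = FALSE]
  type <- character(length(bases))
  refpos <- integer(length(bases))
  for (j in seq_len(nrow(hit))) {
    a <- max(hit$hap_start[j], s); b <- min(hit$hap_end[j], e)
    if (b <= a) next
    idx <- (a - s + 1L):(b - s)                 # 1-based read-local indices
    if (is.na(hit$ref_start[j])) {
      type[idx] <- "I"; refpos[idx] <- NA_integer_
    } else {
      type[idx] <- "M"
      refpos[idx] <- hit$ref_start[j] + (a - hit$hap_start[j]) + seq_along(idx) - 1L
    }
  }
  err <- apply_errors(bases, type, refpos, config)
  read_seq <- paste(err$bases[err$type != "D"], collapse = "")
  if (strand == "-") read_seq <- revcomp(read_seq)
  q <- error_phred(config)
  read <- data.frame(id = NA_character_, seq = read_seq,
                     qual = strrep(intToUtf8(33L + q), nchar(read_seq)),
                     mean_q = as.numeric(q))
  aln <- truth_alignment(err$type, err$refpos, strand, nchar(read_seq))
  list(read = read, aln = aln, strand = strand)
}

error_phred <- function(config) {
  p <- config$error_sub + config$error_ins + config$error_del
  if (p <= 0) 30L else max(2L, as.integer(round(-10 * log10(p))))
}

## iid per-base substitution / insertion / deletion errors applied to the
## (base, type) vectors; alignment columns are kept consistent (deleted M
## becomes D, deleted I disappears, inserted bases are I).
apply_errors <- function(bases, type, refpos, config) {
  n <- length(bases)
  if (config$error_sub + config$error_ins + config$error_del <= 0) {
    return(list(bases = bases, type = type, refpos = refpos))
  }
  u <- runif(n)
  sub <- u < config$error_sub
  del <- u >= config$error_sub & u < config$error_sub + config$error_del
  ins <- runif(n) < config$error_ins
  if (any(sub)) {
    for (i in which(sub & !del)) bases[i] <- sample(setdiff(DNA_BASES, bases[i]), 1L)
  }
  ## assemble: original columns (deleted I dropped, deleted M -> D) plus
  ## inserted I columns placed after their anchor
  keep <- !(del & type == "I")
  otype <- ifelse(del & type == "M", "D", type)
  key <- c(seq_len(n)[keep], which(ins) + 0.5)
  allb <- c(bases[keep], sample(DNA_BASES, sum(ins), replace = TRUE))
  allt <- c(otype[keep], rep("I", sum(ins)))
  allr <- c(refpos[keep], rep(NA_integer_, sum(ins)))
  ord <- order(key)
  list(bases = allb[ord], type = allt[ord], refpos = allr[ord])
}

## Collapse per-column types into an alignment record. Leading/trailing I
## runs become clips (implicit); if no reference-backed column remains the
## read is unmapped (NULL).
truth_alignment <- function(type, refpos, strand, read_len) {
  mcols <- which(type == "M")
  if (!length(mcols)) return(NULL)
  first_m <- mcols[1]; last_m <- mcols[length(mcols)]
  core <- seq(first_m, last_m)
  ctype <- type[core]
  r <- rle(ctype)
  ops <- data.frame(op = r$values, len = r$lengths)
  ops <- cigar_canonical(ops)
  ## read-coordinate extent of the aligned part, alignment orientation
  qs_aln <- sum(type[seq_len(first_m - 1L)] != "D")
  q_aligned <- sum(ctype != "D")
  qe_aln <- qs_aln + q_aligned
  ref_start <- refpos[first_m]
  ref_end <- refpos[last_m] + 1L
  data.frame(read_id = NA_character_, read_len = read_len,
             read_start = if (strand == "+") qs_aln else read_len - qe_aln,
             read_end = if (strand == "+") qe_aln else read_len - qs_aln,
             strand = strand, ref_name = "chrT", ref_len = NA_integer_,
             ref_start = ref_start, ref_end = ref_end, mapq = 60L,
             cigar = unparse_cigar(ops))
}

#' Write a simulated run to disk
#'
#' Emits `reference.fa`, `annotation.bed` and `annotation.out`,
#' `donor_h1.fa`/`donor_h2.fa`, `reads.fastq`, `truth.paf`,
#' `truth_loci.tsv` and `manifest.tsv` under `outdir`.
#'
#' @param reference result of [build_reference()].
#' @param donor result of [implant_nonreference()].
#' @param run result of [simulate_cas9_run()] or [simulate_wgs_run()].
#' @param outdir output directory (created if needed).
#' @export
write_sim_run <- function(reference, donor, run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(reference$genome, file.path(outdir, "reference.fa"))
  write_fasta(reference$consensus, file.path(outdir, "consensus.fa"))
  write_repeat_annotation(reference$annotation, file.path(outdir, "annotation.bed"), "bed")
  write_repeat_annotation(reference$annotation, file.path(outdir, "annotation.out"), "rmout")
  write_fasta(data.frame(id = "h1", seq = donor$haplotypes$h1$seq),
              file.path(outdir, "donor_h1.fa"))
  write_fasta(data.frame(id = "h2", seq = donor$haplotypes$h2$seq),
              file.path(outdir, "donor_h2.fa"))
  run$reads$id <- run$manifest$read_id
  write_fastq(run$reads, file.path(outdir, "reads.fastq"))
  aln <- run$alignments
  aln$ref_len <- nchar(reference$genome$seq[1])
  write_paf(aln, file.path(outdir, "truth.paf"))
  write.table(donor$loci[, setdiff(names(donor$loci), "ins_seq")],
              file.path(outdir, "truth_loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$manifest, file.path(outdir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
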