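## End-to-end simulated experiment: homozygous reference L1Hs copies versus
## heterozygous non-reference insertions under equal per-haplotype capture.
## Under that condition the mean supporting-read depth at reference loci is
## expected to be ~2x that at non-reference loci (two captured haplotypes
## versus one).

#' Simulation settings for the zygosity depth-ratio experiment
#'
#' A 4 Mb toy reference carrying `n_ref` homozygous L1Hs-like copies, a
#' diploid donor with `n_nonref` heterozygous non-reference L1Hs-like
#' insertions, and a Cas9 run with Poisson(`reads_per_cut`) reads per cut
#' site per haplotype (>= 20 expected reads per homozygous locus at the
#' default). Loci are spaced >= 40 kb apart and background reads are
#' disabled so that read depth at a locus reflects capture at that locus
#' alone; read lengths use a flow-cell-scale N50 of 15 kb.
#'
#' @param n_ref,n_nonref locus counts.
#' @param reads_per_cut Poisson mean per cut site per haplotype.
#' @return a [sim_config()].
#' @export
zygosity_sim_config <- function(n_ref = 30L, n_nonref = 30L, reads_per_cut = 10) {
  sim_config(
    genome_len = 4000000L,
    ref_copies = c(L1Hs = n_ref),
    ref_divergence = c(L1Hs = 0.01),
    margin = 20000L,
    nonref_n = n_nonref,
    nonref_subfamily = "L1Hs",
    zygosity_mix = c(het = 1),
    reads_per_cut = reads_per_cut,
    n50 = 15000,
    background_frac = 0)
}

#' Mean-support ratio of homozygous reference vs heterozygous non-reference loci
#'
#' Runs the full pipeline on one simulated Cas9 run: build reference,
#' implant heterozygous insertions, simulate reads, classify, call, then
#' divide the mean number of on-target reference reads per detected
#' reference element by the mean supporting-read count of the non-reference
#' calls.
#'
#' @param seed integer seed.
#' @param config a [zygosity_sim_config()].
#' @return list: `ratio`, `ref_mean`, `nonref_mean`, `n_ref_loci`,
#'   `n_nonref_calls`, `n_reads`.
#' @export
zygosity_depth_ratio_sim <- function(seed, config = zygosity_sim_config()) {
  ref <- build_reference(config, seed)
  donor <- implant_nonreference(ref, config, seed)
  guide <- toy_guides()
  guide <- guide$guide23[guide$subfamily == "L1Hs"]
  run <- simulate_cas9_run(donor, guide, config, seed)
  cls <- classify_run(run$reads, run$alignments, ref$annotation,
                      ref$consensus, "L1Hs")
  ## per-element on-target reference read counts
  aln_best <- best_alignment_per_read(run$alignments)
  ref_ids <- cls$classifications$read_id[
    cls$classifications$category == "on_target_reference"]
  counts <- count_reads_per_element(aln_best[aln_best$read_id %in% ref_ids, ,
                                             drop = FALSE],
                                    ref$annotation[ref$annotation$subfamily == "L1Hs", ,
                                                   drop = FALSE])
  counts <- counts[counts > 0]
  calls <- call_nonreference(run$reads, run$alignments, ref$annotation,
                             ref$consensus, ref$genome)
  nonref <- calls[calls$status == "non_reference", , drop = FALSE]
  if (!length(counts) || !nrow(nonref)) {
    stop("degenerate simulation: no reference or non-reference support")
  }
  ref_mean <- mean(counts)
  nonref_mean <- mean(nonref$support)
  list(ratio = ref_mean / nonref_mean, ref_mean = ref_mean,
       nonref_mean = nonref_mean, n_ref_loci = length(counts),
       n_nonref_calls = nrow(nonref), n_reads = nrow(run$reads))
}

## assign each alignment to its maximum-overlap element, return per-element counts
count_reads_per_element <- function(alns, elements) {
  counts <- integer(nrow(elements))
  for (i in seq_len(nrow(alns))) {
    ov <- pmin(elements$end, alns$ref_end[i]) - pmax(elements$start, alns$ref_start[i])
    ov[elements$ref_name != alns$ref_name[i]] <- -1L
    j <- which.max(ov)
    if (length(j) && ov[j] > 0) counts[j] <- counts[j] + 1L
  }
  counts
}

#' Average the zygosity depth ratio over several seeds
#'
#' @param seeds integer vector of seeds (>= 5 recommended).
#' @param config a [zygosity_sim_config()].
#' @return list: `mean_ratio`, `ratios` (per seed).
#' @export
zygosity_depth_ratio <- function(seeds, config = zygosity_sim_config()) {
  ratios <- vapply(seeds, function(s) zygosity_depth_ratio_sim(s, config)$ratio,
                   numeric(1))
  list(mean_ratio = mean(ratios), ratios = ratios)
}
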