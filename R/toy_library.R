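## Packaged toy consensus library. Six synthetic consensus sequences with
## realistic sizes and engineered subfamily-diagnostic differences, generated
## deterministically from a fixed internal seed so every session sees
## byte-identical sequences. Real Repbase-style consensus FASTA files are
## drop-in replacements.
##
##   L1Hs   ~6 kb; carries an engineered guide site (protospacer + TGG PAM)
##          ~300 bp from its 3' end, with an ACA->GTG diagnostic triplet
##          distinguishing it from L1PA4 inside the protospacer.
##   L1PA4  L1Hs at ~5% divergence; exactly 3 mismatches at the guide site,
##          so the guide binds L1PA copies only under the intermediate bound.
##   AluYb8 AluYa5 backbone with the 7 bp diagnostic insertion CAGTCCG; the
##          guide protospacer spans the insertion.
##   AluYa5 ~280 bp SINE-like backbone.
##   SVA_F  ~1.4 kb; guide site near the 3' end.
##   SVA_E  SVA_F at ~4% divergence with 3 engineered protospacer mismatches.

TOY_SEED <- 20240811L

#' Toy mobile element consensus library
#'
#' @param targets_only if `TRUE`, return only the five target subfamilies
#'   (drop the L1PA4 close-family outgroup).
#' @return sequence table (`id`, `seq`, `role`) with a `family` column.
#' @export
toy_consensus_library <- function(targets_only = FALSE) {
  lib <- toy_library_cache()
  out <- lib$consensus
  if (targets_only) out <- out[out$role != "outgroup_consensus", , drop = FALSE]
  out
}

#' Engineered guide sites of the toy library
#'
#' One row per target subfamily: the 23 bp guide (20 bp protospacer + NGG
#' PAM) lifted from the toy consensus, its 0-based start on the consensus,
#' and the consensus coordinate of the PAM `N` base.
#'
#' @return data.frame with columns `subfamily`, `guide23`, `consensus_pos`,
#'   `pam_n_pos`.
#' @export
toy_guides <- function() toy_library_cache()$guides

toy_library_env <- new.env(parent = emptyenv())

toy_library_cache <- function() {
  if (!is.null(toy_library_env$lib)) return(toy_library_env$lib)
  toy_library_env$lib <- with_seed(TOY_SEED, build_toy_library())
  toy_library_env$lib
}

## force a substring to a value, returning the modified sequence
seq_poke <- function(seq, at0, value) {
  substr(seq, at0 + 1L, at0 + nchar(value)) <- value
  seq
}

## mutate exactly the given 0-based positions to different random bases
seq_flip <- function(seq, at0) {
  b <- strsplit(seq, "")[[1]]
  for (p in at0) b[p + 1L] <- sample(setdiff(DNA_BASES, b[p + 1L]), 1L)
  paste(b, collapse = "")
}

build_toy_library <- function() {
  ## L1 pair -----------------------------------------------------------------
  l1hs <- random_dna(6000L)
  g_l1 <- 5675L                                   # protospacer start
  l1hs <- seq_poke(l1hs, g_l1 + 10L, "ACA")       # subfamily-diagnostic motif
  l1hs <- seq_poke(l1hs, g_l1 + 20L, "TGG")       # NGG PAM
  l1pa <- mutate_subs_sparing(l1hs, 0.05, spare = g_l1 + 0:22)
  l1pa <- seq_poke(l1pa, g_l1 + 10L, "GTG")       # 3 mismatches in protospacer

  ## Alu pair ----------------------------------------------------------------
  alu_ya <- random_dna(280L)
  ins_at <- 200L
  alu_yb <- paste0(substr(alu_ya, 1L, ins_at), "CAGTCCG",
                   substr(alu_ya, ins_at + 1L, nchar(alu_ya)))
  g_alu <- 193L                                   # spans the CAGTCCG insertion
  alu_yb <- seq_poke(alu_yb, g_alu + 20L, "AGG")
  alu_ya <- mutate_subs_sparing(alu_ya, 0.01, spare = integer(0))
  alu_sx <- mutate_subs(alu_ya, 0.15)             # older off-target SINE

  ## SVA pair ----------------------------------------------------------------
  sva_f <- random_dna(1400L)
  g_sva <- 1100L
  sva_f <- seq_poke(sva_f, g_sva + 20L, "CGG")
  sva_e <- mutate_subs_sparing(sva_f, 0.04, spare = g_sva + 0:22)
  sva_e <- seq_flip(sva_e, g_sva + c(4L, 9L, 15L))

  consensus <- data.frame(
    id = c("L1Hs", "L1PA4", "AluYb8", "AluYa5", "AluSx", "SVA_F", "SVA_E"),
    seq = c(l1hs, l1pa, alu_yb, alu_ya, alu_sx, sva_f, sva_e),
    role = c("target_consensus", "outgroup_consensus", "target_consensus",
             "target_consensus", "outgroup_consensus", "target_consensus",
             "target_consensus"))
  consensus$family <- taxonomy_lookup(consensus$id)$family

  guides <- data.frame(
    subfamily = c("L1Hs", "AluYb8", "SVA_F"),
    guide23 = c(substr(l1hs, g_l1 + 1L, g_l1 + 23L),
                substr(alu_yb, g_alu + 1L, g_alu + 23L),
                substr(sva_f, g_sva + 1L, g_sva + 23L)),
    consensus_pos = c(g_l1, g_alu, g_sva),
    pam_n_pos = c(g_l1, g_alu, g_sva) + 20L)

  list(consensus = consensus, guides = guides)
}

## substitution mutagenesis that never touches the spared positions
mutate_subs_sparing <- function(seq, rate, spare) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  hit <- setdiff(hit, spare + 1L)
  for (i in hit) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1L)
  paste(b, collapse = "")
}
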