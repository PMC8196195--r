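---
title: "Cas9-targeted nanopore enrichment of mobile element insertions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cas9-targeted nanopore enrichment of mobile element insertions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casmei)
```

## The problem

Active human mobile elements — the L1Hs LINE-1 subfamily, the young AluY
SINEs (AluYa5, AluYb8) and SVAs (SVA_E, SVA_F) — continue to produce new
insertions that are absent from the reference genome. Whole-genome long-read
sequencing finds them but is expensive; an alternative is to direct Cas9 to
a subfamily-specific sequence near the element 3' end, ligate sequencing
adapters at the cut, and read outward into unique flanking sequence. A read
anchored in unique flank identifies its locus unambiguously even though most
of its bases are repeat-derived.

`casmei` implements the computational stack around that protocol: guide
design from consensus differences, theoretical capture bounds for a chosen
guide, read classification into on/close/off-target categories,
non-reference MEI calling with hallmark detection, the downstream analyses
(cleavage-site distributions, strand bias, saturation, trio transmission,
recurrence plots), and a fully seeded synthetic-data generator that stands
in for real reference/FASTQ/alignment inputs with complete ground truth.

## Guide design

Guides are 20 bp protospacers followed by an NGG PAM, i.e. 23-mers that end
in `GG` (or begin with `CC` on the minus strand). A consensus column is
*diagnostic* for the target subfamily when its base differs from the aligned
base of every outgroup consensus; gaps and `N` disqualify a column. When
inputs are unaligned, each outgroup is anchored to the target by a global
pairwise alignment (match 1 / mismatch −1 / gap −2 per base) — a pairwise
anchor is sufficient here because consensus sequences within a family are
closely related, and it keeps the column bookkeeping on target coordinates.

Each candidate 23-mer containing at least one diagnostic position is scored
by its genome-wide frequency — overlapping occurrences, both strands, with
the PAM `N` expanded to all four bases — and assigned a tier:

* **Tier0** — a diagnostic base sits on the `GG`/`CC` of the PAM itself;
  mismatches there abolish cutting, so these are ideal candidates.
* **Tier1** — the 23-mer frequency is below 2× the target subfamily copy
  number (the guide is as specific as the subfamily is abundant).
* **Tier2** — diagnostic only at the PAM `N`, or frequency out of range.

Ranking is by tier, then number of diagnostic bases, then proximity to the
consensus 3' end (insertions are 5'-truncated by target-primed reverse
transcription, so 3'-proximal guides capture truncated copies too).

The both-strand, overlap-counting convention for k-mer frequency counts a
site once per matching orientation: the reverse-strand count is the
forward-strand count of the reverse complement.

## Capture bounds

For a chosen guide, each annotated (or candidate non-reference) element is
classified by the best semi-global placement of the 23-mer inside the
element, on either strand:

* **lower** — an exact 23/23 match exists;
* **intermediate** — minimum edit distance (substitutions + gaps, unit
  cost) ≤ 3;
* **upper** — the best-scoring placement (match +1 / mismatch −1 / gap −1)
  aligns ≥ 14 guide bases (>60%) as matches.

The classes nest by construction, so per-subfamily counts satisfy
`lower ≤ intermediate ≤ upper`. "≤3 mismatch or gap" is treated as one
joint edit budget because the two edit kinds are named without separate
allowances, and "≥14 bp matched" counts aligned identical bases rather than
the longest exact stretch, since a 60%-matched *alignment* is what the bound
describes. Among equal-scoring placements the match count is maximised, so
the classification is deterministic; the DP is implemented in C++ and
checked in the tests against an independent vectorised dynamic program and
against `Biostrings::pairwiseAlignment`.

## Read classification

Reads are kept when their mean quality exceeds Q7, with the mean taken on
the error-probability scale (`-10 log10(mean(10^(-Q/10)))`), matching how
base callers summarise per-read accuracy.

The **end scan** aligns the first and last 100 bp of each read against the
consensus library. The scoring is Smith–Waterman with match 2 / mismatch −3
/ gap open 5 / extend 2 and a signal threshold of 60 (≈30 matched bases per
bin). Rather than running the full quadratic alignment against every 6 kb
consensus, the scan first seeds exact 11-mers and pools them by diagonal —
the same seed-and-extend shape as the BLASTN search it models — then runs
the exact Smith–Waterman only on the seeded consensus window. Thresholds
are unchanged by the seeding; a bin with ≥30 matched bases essentially
cannot lack an exact 11-mer seed.

**Pre-masking** projects annotated reference repeats through the alignment
CIGAR onto read coordinates (deletions collapse; read insertions inside a
feature stay unmasked). Insertion signals — CIGAR `I` operations ≥ 100 bp
and terminal soft clips ≥ 200 bp — are then restricted to unmasked read
intervals, so residual signal indicates a non-reference insertion.

Classification precedence follows the enrichment taxonomy: reads unaligned
or below MAPQ 10 are discarded; reads with a surviving insertion signal are
*on-target non-reference*; reads mapped into a reference element of the
target subfamily are *on-target reference*; per-family rules then assign
*close* (L1PA for L1Hs experiments, other AluY for Alu experiments, other
SVA for SVA experiments — where reads with an MEI signal are never called
off-target) and *off*. A read counts as "mapped into" an element when the
aligned span overlaps it by at least 100 bp in absolute terms. A
fraction-of-span rule was considered and rejected: a Cas9 read cut near the
element 3' end legitimately spends most of its length in unique flank —
that anchoring is the point of the protocol — so a 50%-of-span requirement
would misclassify nearly all true on-target reference reads; a fixed
overlap floor instead filters incidental edge touches, mirroring
RepeatMasker-based pre-mask screening. Rate tables report category
fractions over passed (non-discarded) reads.

## Non-reference calling and TPRT hallmarks

Insertions integrate by target-primed reverse transcription (TPRT), which
leaves sequence hallmarks: a target site duplication (TSD) flanking the
insertion, a 3' poly(A) tract, and an L1 endonuclease nick site fitting the
consensus 5'-TTTT/AA.

Signals are clustered by single linkage with a 100 bp gap; clusters with at
least 4 distinct supporting reads (the default minimum; both thresholds are
configurable) become calls at the median 3'-junction breakpoint. Before
clustering, each signal's placement is canonicalised: CIGAR insertions are
shifted to their leftmost and rightmost equivalent placements, and clip
junctions are extended through junction micro-homology exactly as a
score-maximising aligner would place them. The left and right junction
medians then straddle the duplicated word, and the TSD is the longest word
(5–30 bp, ≤1 substitution) that ends at the 5' junction and reappears
starting at the 3' junction.

Junction micro-homology makes hallmark strings ambiguous at the sequence
level: when the element happens to begin with the same base as the
reference just after the duplicated word, an insertion with TSD length
*t* is literally indistinguishable from one with TSD *t*+1. The simulator
therefore records *canonical* hallmark values — the maximal duplication and
the poly(A) measured on the pure donor insertion sequence — alongside the
generator's internal values, and exactness is asserted against the
canonical truth, which is the well-defined property of the donor sequence.

Poly(A) tracts are measured as the longest terminal run in which every
20-base window keeps ≥80% adenine, reported from the strand-appropriate
junction (a minus-strand insertion shows its tail as a 5' poly(T)). The
endonuclease score is the Hamming match count (0–6) of the 6-mer spanning
the insertion point against TTTT/AA. Genotype uses the carrier fraction
*f* = support / spanning reads: `hom` ≥ 0.8, `het` ≥ 0.2, else `unknown`.
A read-depth filter fails calls whose 500 bp bin differs from the flanking
median by ≥2-fold in either direction (the pass region is a strict <2-fold
difference).

Two caller behaviours deserve note. First, in Cas9-targeted runs every read
at a non-reference locus starts at the cut inside the insertion, so no read
spans the empty allele; carrier fractions then approach 1 and genotypes
from targeted data alone are uninformative — the WGS-style simulation mode
exists to exercise genotyping with genuine spanning reads. Second, error
correction and assembly stages used by two-pass callers are replaced by a
single-pass caller: with exact simulated alignments they add nothing, and
externally corrected reads can be supplied through the same interface.
Subfamily assignment uses exact 13-mer seed voting against the consensus
library on both strands, with the 5' and 3' halves scored separately; an L1
whose halves prefer opposite strands carries the twin-priming 5'-inversion
signature. The transduction hook reports any ≥30 bp tail beyond the last
long adenine run verbatim, without source mapping.

## Downstream analyses

**Cleavage sites.** The first 80 bp of each read are aligned locally to the
consensus and its reverse complement with match +2 / mismatch −1; the first
gap base costs 10 and each further base 5. A read is included only when the
alignment starts at the very first read base and scores ≥100 (≈ at least 50
of 80 bases matched under these scores; the +2/−1 substitution scores are a
package choice — only the gap penalties and threshold are fixed by the
protocol). Included reads contribute the distance of their 5' end from the
PAM, with distance 1 the base adjacent to the `N`. Under the default cut
model, forward-strand mass sits at 3–4 and reverse-strand mass at 7.

**Saturation.** Runs are ranked by on-target read count and merged one at a
time; pooled signals are re-clustered after each merge and call counts
reported per supporting-read cutoff (1, 4, 15). Counts are non-decreasing
in merged reads and non-increasing in cutoff on well-separated loci.

**Trio transmission.** Child calls match parental calls within 100 bp on
the same contig with family agreement (family level, because subfamily
labels can disagree across callsets); matches to both parents are
`either_parent` (unknown lineage), and parental calls without a child match
are `untransmitted_parent_call`. Genotype is ignored in matching.

**Depth ratio.** Under equal per-haplotype capture, homozygous reference
loci are sequenced from two haplotypes and heterozygous non-reference loci
from one, so the ratio of mean supporting reads is expected near 2:1.

**Recurrence plots** report every coordinate pair sharing an identical
10 bp word (optionally against the reverse complement), the plain dot-plot
representation used for by-eye validation of insertion structure.

## The synthetic-data generator

The generator emulates the full input stack. A random background genome
receives per-copy-mutated implants of a packaged toy consensus library
(~6 kb L1Hs-like and L1PA4-like at ~5% divergence with an engineered
ACA/GTG diagnostic triplet in the guide protospacer; ~280 bp AluYa5-like
and AluYb8-like differing by the diagnostic 7 bp CAGTCCG insertion that the
AluYb8 guide spans; ~1.4 kb SVA_F/SVA_E-like), with annotation rows exactly
matching the implants. The toy sequences are generated once from a fixed
internal seed, so they are identical in every installation, and real
Repbase-style consensus FASTA files are drop-in replacements. Each toy
guide sits ~300 bp from the element 3' end so that guide-forward reads
retain a clip long enough (≥200 bp) to register as insertion evidence; for
~300 bp Alu-scale elements the clip threshold should be lowered accordingly.

Non-reference loci insert `TSD + element + poly(A)` by the staggered-nick
model (`R[..pos+t) + E + R[pos..)`), at sites chosen as the best TTTT/AA
match among 50 random draws — biased, not forced, toward the endonuclease
motif. Elements are 5'-truncated with probability 0.5 (keeping 15–60% of
the 3' end), optionally 5'-inverted, with TSDs of 5–20 bp and poly(A) of
10–40 bp. Heterozygous loci touch one haplotype.

Cas9 runs cut every guide placement within 3 mismatches on either strand of
each haplotype. Read counts per cut site are Poisson; guide-forward reads
(probability 4.6/5.6 under the default 4.6-fold strand bias) start 3 or 4
bases from the PAM and read outward 3', reverse reads start at base 7 and
read the other way. Read lengths are truncated log-normal with σ = 0.45 and
the mean log chosen so the base-weighted median equals the configured N50
(`μ = log N50 − σ²`), default 5 kb for fast tests, 15–32 kb for
flow-cell-scale geometry. Errors are iid per-base substitutions/insertions/
deletions (3%/2%/2% by default) — a deliberate simplification that ignores
homopolymer-conditioned nanopore error structure. Truth alignments are
updated base-by-base as errors are applied (a deleted matched base becomes
a deletion operation, inserted bases become insertions), so every truth PAF
record satisfies the CIGAR bookkeeping invariants at any error rate; the
truth alignment plays the role of the external aligner, which this package
deliberately does not reimplement. Background (off-target) reads default to
20% of the run. All randomness flows from one integer seed through an
isolated Mersenne–Twister state; identical (config, seed) gives
byte-identical output.

What the simulator does not model — real base-caller error spectra,
chimeras, adapter remnants, fragmentation-driven read-length differences
between single- and both-end signal reads, source-mapped transductions —
bounds what passing tests show: the pipeline's logic is validated
end-to-end, not its robustness to every artefact of real flow cells.

## The zygosity depth-ratio experiment

The packaged headline validation (`zygosity_depth_ratio()`) builds a 4 Mb
reference with 30 homozygous L1Hs-like copies, implants 30 heterozygous
non-reference L1Hs-like insertions, and simulates a Cas9 run with
Poisson(10) reads per cut site per haplotype (≥20 expected reads per
homozygous locus), N50 15 kb, no background reads. Loci are spaced ≥40 kb
apart. Those three choices are the study conditions, fixed from the
geometry of the experiment: flow-cell-scale read lengths are required for
reverse-strand reads to traverse a full-length ~6 kb element and anchor in
unique flank at non-reference loci (at a 5 kb N50 they cannot, and the
ratio would measure read-length censoring rather than capture); wide
spacing keeps reads from one locus from crossing another, so support
measures capture at a single locus; and background reads are excluded
because uniformly scattered long reads would otherwise land on reference
elements (which span kilobases) but almost never produce clip evidence at
non-reference points, inflating only the numerator. The reported value is
the mean per-element on-target reference read count divided by the mean
non-reference call support, averaged over ≥5 seeds; detected loci enter
each mean. Equal per-haplotype capture predicts ≈2.

```{r, eval = FALSE}
res <- zygosity_depth_ratio(seeds = 1:5)
res$mean_ratio     # ~2.0 (±15% band: 1.7-2.3)
```

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; conversions happen only
  in readers and writers (RepeatMasker `.out` is 1-based inclusive, BED and
  PAF are native). Hard clips contribute to read length but not stored
  sequence; truth and parsed CIGARs never store clip operations — clip
  lengths are implicit in the read start/end.
* `N` never matches anything in any comparison, including another `N`.
* k-mers containing `N` are rejected for counting; consensus windows
  shorter than 23 bp yield no candidates (not an error).
* Elements shorter than 14 bp classify as `none`; empty element sets give
  all-zero bound summaries.
* Cluster ties: call position is the median 3'-junction breakpoint
  (rounded); subfamily by majority vote; length by median signal length —
  for clip-only clusters this is a lower bound on the true insertion
  length, since no single read contains the whole insertion.
* Sort/rank ties in guide ranking break by consensus position ascending,
  keeping the order stable and reproducible.
* Zero reverse-strand reads make the strand-bias ratio infinite (reported
  as `Inf` rather than an error).
* The support-threshold default of 4 follows the validation convention for
  nanopore-specific calls; saturation analyses additionally report the
  stricter cutoff of 15.

## Problem sizes used by the test-suite

Unit fixtures use 0.2–1.5 Mb genomes with 6–10 implanted loci and a few
hundred to ~1,700 reads; the depth-ratio experiment uses 4 Mb genomes, 60
loci and ~900 reads per seed across 5 seeds. These sizes give every code
path multi-read, multi-locus coverage while keeping the full suite
desk-scale; all of them are generator parameters, and scaling up is a
matter of configuration, not code.

## Known limitations

* Genotypes from Cas9-targeted data alone are uninformative (see above);
  they are meaningful in WGS mode or with an external spanning-read source.
* TSDs are only recoverable when both junctions have read evidence; a
  full-length element locus reached by forward-strand reads alone reports
  `NA` rather than a guessed TSD.
* Transduction reporting is verbatim tail sequence without source mapping.
* The end-scan seeding can in principle miss a signal bin with no exact
  11-mer seed (≳35% divergence); such bins are far below the score
  threshold anyway.
* The simulator's error model and read-length distribution are idealised;
  parameters measured on real runs should be substituted when available.
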