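## Shared simulated fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

l1_guide <- function() {
  gd <- toy_guides()
  list(guide = gd$guide23[gd$subfamily == "L1Hs"],
       pam = gd$pam_n_pos[gd$subfamily == "L1Hs"])
}

## error-free Cas9-targeted run with 10 heterozygous/homozygous L1Hs implants
cas9_fixture <- function() fixture("cas9", {
  cfg <- sim_config(genome_len = 600000L, margin = 2000L, nonref_n = 10L,
                    reads_per_cut = 15, n50 = 8000,
                    error_sub = 0, error_ins = 0, error_del = 0)
  ref <- build_reference(cfg, 101)
  donor <- implant_nonreference(ref, cfg, 101)
  run <- simulate_cas9_run(donor, l1_guide()$guide, cfg, 101)
  list(cfg = cfg, ref = ref, donor = donor, run = run)
})

## same design with the default nanopore-like error rates
cas9_noisy_fixture <- function() fixture("cas9_noisy", {
  cfg <- sim_config(genome_len = 600000L, margin = 2000L, nonref_n = 10L,
                    reads_per_cut = 15, n50 = 8000)
  ref <- build_reference(cfg, 103)
  donor <- implant_nonreference(ref, cfg, 103)
  run <- simulate_cas9_run(donor, l1_guide()$guide, cfg, 103)
  list(cfg = cfg, ref = ref, donor = donor, run = run)
})

## error-free WGS-style run over truncated implants: spanning reads cover
## both insertion junctions, so hallmark recovery and genotyping are exact
wgs_fixture <- function() fixture("wgs", {
  cfg <- sim_config(genome_len = 600000L, margin = 2000L, nonref_n = 10L,
                    full_length_prob = 0, n50 = 8000, background_frac = 0,
                    error_sub = 0, error_ins = 0, error_del = 0)
  ref <- build_reference(cfg, 102)
  donor <- implant_nonreference(ref, cfg, 102)
  run <- simulate_wgs_run(donor, depth = 10, cfg, 102)
  list(cfg = cfg, ref = ref, donor = donor, run = run)
})

## sparse layout: loci far apart relative to read length, no background, so
## every read's expected category is determined by its originating cut site
sparse_cas9_fixture <- function() fixture("sparse", {
  cfg <- sim_config(genome_len = 1500000L, margin = 15000L,
                    ref_copies = c(L1Hs = 6L, L1PA4 = 3L),
                    ref_divergence = c(L1Hs = 0.01, L1PA4 = 0.03),
                    nonref_n = 6L, zygosity_mix = c(het = 1),
                    reads_per_cut = 8, n50 = 12000, background_frac = 0,
                    error_sub = 0, error_ins = 0, error_del = 0)
  ref <- build_reference(cfg, 104)
  donor <- implant_nonreference(ref, cfg, 104)
  run <- simulate_cas9_run(donor, l1_guide()$guide, cfg, 104)
  cls <- classify_run(run$reads, run$alignments, ref$annotation,
                      ref$consensus, "L1Hs")
  list(cfg = cfg, ref = ref, donor = donor, run = run, cls = cls)
})
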