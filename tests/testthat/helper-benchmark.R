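# Benchmark construction shared by the recovery tests: plant critical
# residues where the tiling library can in principle detect them
# (enough nearby cuts and a phase-aligned cut allowing an exact
# single-codon deletion), spread across the protein.

plant_critical <- function(ref, sgrnas, n = 5) {
  ar <- assayable_residues(ref, sgrnas)
  a <- ar$residue[ar$assayable]
  a[round(stats::quantile(seq_along(a), seq(0.1, 0.9, length.out = n)))]
}

# One full synthetic screen -> per-residue scores, at the default study
# conditions (200 residues, diploid recessive non-essential gene,
# depth 2e5 per condition).
run_benchmark <- function(seed, enrichment = 50, protein_length = 200L) {
  ref <- simulate_cds(protein_length, seed = seed)
  sgrnas <- design_sgrnas(ref)
  plant <- plant_critical(ref, sgrnas)
  cfg <- simulation_config(protein_length = protein_length,
                           critical_residues = plant,
                           enrichment = enrichment, seed = seed)
  sim <- simulate_screen(cfg, conditions = c("before", "after"))
  eff_b <- call_effects(sim$libraries$before, sim$ref)
  eff_a <- call_effects(sim$libraries$after, sim$ref)
  res <- score_screen(eff_b, eff_a, sim$ref)
  list(planted = plant, scores = res$scores,
       hits = res$scores$residue[res$scores$above_cutoff],
       planted_ranks = res$scores$rank[match(plant, res$scores$residue)])
}
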