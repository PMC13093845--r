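# small deterministic fixtures built in code

# 2 groups x 2 species x 2 replicates, 3 OTUs, hand-enterable numbers
toyExperiment <- function() {
  counts <- rbind(
    OTU1 = c(10, 0, 5, 5),
    OTU2 = c(2, 4, 0, 0),
    OTU3 = c(1, 1, 1, 1)
  )
  colnames(counts) <- c("a1", "a2", "b1", "b2")
  meta <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    species_id = c("spA", "spA", "spB", "spB"),
    group_id = c("G1", "G1", "G2", "G2"),
    replicate_index = c(1, 2, 1, 2)
  )
  EndophyteExperiment(counts, meta)
}

# trait table generator with valid defaults
makeTraits <- function(species, groups,
                       lma = 0.005, n_conc = 20, cn = 18, wc = 70,
                       abundance = 50) {
  n <- length(species)
  data.frame(
    species_id = species,
    group_id = rep_len(groups, n),
    lma = rep_len(lma, n),
    n_conc = rep_len(n_conc, n),
    cn_ratio = rep_len(cn, n),
    water_content = rep_len(wc, n),
    abundance = rep_len(abundance, n),
    stringsAsFactors = FALSE
  )
}

# small config for permutation-calibration studies
calibrationCfg <- function(seed) {
  simConfig(
    group_sizes = c(A = 3, B = 3), replicates_per_species = 2,
    n_background_otus = 40, n_marker_otus_per_group = 2,
    sequencing_depth = 2000, turnover_strength = 0, seed = seed
  )
}

# config for marker-recovery studies: trait-driven turnover off so the
# planted markers are the only group-specific ubiquitous OTUs
recoveryCfg <- function(seed, spec = 0.9, occ = 1.0, depth = 1e5) {
  simConfig(
    turnover_strength = 0,
    marker_specificity_target = spec,
    marker_occupancy_target = occ,
    sequencing_depth = depth,
    seed = seed
  )
}

sampleLabels <- function(ee) {
  info <- sampleInfo(ee)
  stats::setNames(info$group_id, info$sample_id)
}
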