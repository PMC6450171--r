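#!/usr/bin/env Rscript
# Generate the two synthetic trap-plant study designs and write their
# fixtures. Everything downstream (02-08) reads from results/data/.
#
# Design A ("genotype"): 4 host genotypes x 3 replicates in each of 2
# soils, plus uninoculated controls; library sizes 68-1950 reads.
# Design B ("soil_origin"): a single genotype, 8 soils x 4 replicates,
# library sizes 346-4065 reads; planted co-abundance communities, two of
# them tracking soil properties, plus planted differential and
# soil-specific OTUs as ground truth.

library(rhizonet)

seed <- 20190329L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genotype_cfg <- sim_config(
  n_soils = 2L, replicates_per_soil = 3L, n_genotypes = 4L,
  n_fungal_otus = 120L, n_bacterial_otus = 240L,
  n_planted_communities = 5L, community_size_range = c(8L, 15L),
  soil_effect_sd = 1.5, genotype_effect_sd = 1.0,
  genotype_effect_is_soil_conditional = TRUE,
  library_size_range = c(68L, 1950L), n_control_samples = 3L,
  n_differential = 0L, n_indicator_otus = 8L, seed = seed)

soil_cfg <- sim_config(seed = seed + 1L)  # defaults emulate this design

for (nm in c("genotype", "soil_origin")) {
  ds <- generate_dataset(if (nm == "genotype") genotype_cfg else soil_cfg)
  write_fixture(ds, file.path(out, nm), overwrite = TRUE)
  libs <- colSums(unclass(ds$table))
  cat(sprintf(
    "%-12s %3d OTUs x %2d samples; libraries %d-%d reads (mean %.0f)\n",
    nm, nrow(ds$table), ncol(ds$table), min(libs), max(libs), mean(libs)))
}
cat("fixtures written under", out, "\n")
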