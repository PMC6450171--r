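#!/usr/bin/env Rscript
# Alpha/beta-diversity descriptives: rank abundance, rarefaction, PCoA on
# Bray-Curtis of Hellinger-normalised tables, and PERMANOVA / PERMDISP on
# soil and (design A) genotype.

library(rhizonet)

dir.create("results", showWarnings = FALSE)
seed <- 20190329L

for (nm in c("genotype", "soil_origin")) {
  fx <- read_fixture(file.path("results/data", nm))
  meta <- fx$frame$samples[match(sample_ids(fx$table),
                                 fx$frame$samples$sample_id), ]
  tr <- !meta$is_control

  rank_ab <- relative_and_rank_abundance(fx$table, groups = meta$soil_id)
  write.table(rank_ab, file.path("results", paste0(nm, "_rank_abundance.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  depths <- c(50L, 100L, 200L, 346L)
  rare <- do.call(rbind, lapply(sample_ids(fx$table), function(s) {
    cc <- unclass(fx$table)[, s]
    ok <- depths[depths <= sum(cc)]
    data.frame(sample_id = s, depth = ok,
               expected_richness = rarefaction_expected_richness(cc, ok))
  }))
  write.table(rare, file.path("results", paste0(nm, "_rarefaction.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  h <- hellinger_transform(fx$table)[, tr]
  d <- bray_curtis_matrix(h)
  ord <- pcoa(d, k = 2L)
  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates,
                       soil = meta$soil_id[tr], genotype = meta$genotype_id[tr])
  write.table(coords, file.path("results", paste0(nm, "_pcoa.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  pa <- permanova(d, meta$soil_id[tr], n_permutations = 9999L, seed = seed)
  pd <- permdisp(d, meta$soil_id[tr], n_permutations = 999L, seed = seed)
  cat(sprintf("%-12s soil: PERMANOVA R2 = %.3f (p = %.4g); PERMDISP p = %.3g\n",
              nm, pa$R_squared, pa$p_value, pd$p_value))
  rows <- data.frame(design = nm, factor = "soil",
                     R2 = pa$R_squared, F = pa$pseudo_F,
                     p = pa$p_value, permdisp_p = pd$p_value)

  if (length(unique(meta$genotype_id[tr])) > 1L) {
    pg <- permanova(d, meta$genotype_id[tr], n_permutations = 9999L,
                    seed = seed)
    # the genotype effect is soil-conditional: test within each soil too
    for (soil in unique(meta$soil_id[tr])) {
      in_s <- meta$soil_id[tr] == soil
      ps <- permanova(bray_curtis_matrix(h[, in_s]),
                      meta$genotype_id[tr][in_s],
                      n_permutations = 9999L, seed = seed)
      cat(sprintf("%-12s genotype within %s: R2 = %.3f (p = %.4g)\n",
                  nm, soil, ps$R_squared, ps$p_value))
      rows <- rbind(rows, data.frame(design = nm,
                                     factor = paste0("genotype|", soil),
                                     R2 = ps$R_squared, F = ps$pseudo_F,
                                     p = ps$p_value, permdisp_p = NA))
    }
    cat(sprintf("%-12s genotype pooled: R2 = %.3f (p = %.4g)\n",
                nm, pg$R_squared, pg$p_value))
    rows <- rbind(rows, data.frame(design = nm, factor = "genotype",
                                   R2 = pg$R_squared, F = pg$pseudo_F,
                                   p = pg$p_value, permdisp_p = NA))
  }
  write.table(rows, file.path("results", paste0(nm, "_permanova.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
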