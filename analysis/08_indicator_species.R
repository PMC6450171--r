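#!/usr/bin/env Rscript
# Indicator-species analysis: IndVal with soil-group combinations,
# permutation p-values and BH FDR at 0.05, plus the chi-square test on
# OTU-detection counts per soil and per genotype. Recovery is checked
# against the planted soil-specific OTUs.

library(rhizonet)

seed <- 20190329L
for (nm in c("genotype", "soil_origin")) {
  fx <- read_fixture(file.path("results/data", nm))
  meta <- fx$frame$samples[match(sample_ids(fx$table),
                                 fx$frame$samples$sample_id), ]
  tr <- !meta$is_control
  ind <- indicator_analysis(fx$table[, tr], meta$soil_id[tr],
                            allow_combinations = TRUE, max_order = 3L,
                            n_permutations = 999L, alpha = 0.05,
                            seed = seed)
  write.table(ind, file.path("results", paste0(nm, "_indicators.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- ind[ind$significant, ]
  cat(sprintf("%-12s significant soil indicators: %d (top: %s)\n", nm,
              nrow(sig),
              paste(head(sig$otu_id[order(-sig$stat)], 3L), collapse = " ")))

  truth <- fx$truth_otu
  planted <- truth$otu_id[truth$indicator_soil != ""]
  hit <- vapply(planted, function(o) {
    row <- ind[ind$otu_id == o, ]
    nrow(row) == 1L && row$significant &&
      truth$indicator_soil[truth$otu_id == o] %in%
        strsplit(row$best_target, "+", fixed = TRUE)[[1L]]
  }, logical(1L))
  cat(sprintf("%-12s planted soil-specific OTUs recovered: %d of %d\n",
              nm, sum(hit), length(planted)))

  if (length(unique(meta$genotype_id[tr])) > 1L) {
    indg <- indicator_analysis(fx$table[, tr], meta$genotype_id[tr],
                               allow_combinations = FALSE,
                               n_permutations = 999L, alpha = 0.05,
                               seed = seed)
    cat(sprintf("%-12s significant genotype indicators: %d\n", nm,
                sum(indg$significant)))
  }

  det_soil <- detection_counts(fx$table[, tr], meta$soil_id[tr])
  chi <- chi_square_detection(matrix(det_soil, nrow = 1L))
  cat(sprintf("%-12s OTUs detected per soil: %s; chi-square p = %.3g\n",
              nm, paste(det_soil, collapse = "/"), chi$p_value))
  write.table(data.frame(group = names(det_soil),
                         otus_detected = as.integer(det_soil)),
              file.path("results", paste0(nm, "_detection.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
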