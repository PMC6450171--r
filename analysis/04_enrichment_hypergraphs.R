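#!/usr/bin/env Rscript
# OTU-sample enrichment hypergraphs (Fisher exact + BH FDR at 0.01), the
# genotype-binned variant computed separately within each soil, and the
# genotype-specificity quotient (selected: enriched in <= 2 genotypes with
# quotient >= 2).

library(rhizonet)

for (nm in c("genotype", "soil_origin")) {
  fx <- read_fixture(file.path("results/data", nm))
  enr <- build_enrichment_network(fx$table, fx$frame, mode = "per-sample",
                                  level = 0.01)
  write.table(enr$results,
              file.path("results", paste0(nm, "_enrichment.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(enr$network,
                 file.path("results", paste0(nm, "_enrichment.graphml")),
                 "graphml")
  cat(sprintf("%-12s per-sample enrichment: %d OTU-sample edges (%d tests)\n",
              nm, nrow(enr$network$edges), nrow(enr$results)))

  meta <- fx$frame$samples
  if (length(unique(meta$genotype_id[!meta$is_control])) > 1L) {
    binned <- build_enrichment_network(fx$table, fx$frame,
                                       mode = "binned-by-genotype",
                                       level = 0.01)
    write.table(binned$results,
                file.path("results", paste0(nm, "_enrichment_binned.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    quo <- genotype_quotient_selection(enr$network, fx$frame,
                                       max_genotypes = 2L,
                                       min_quotient = 2.0)
    write.table(quo, file.path("results", paste0(nm, "_quotient.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("%-12s genotype-specific OTUs by quotient rule: %d of %d enriched\n",
                nm, sum(quo$selected), nrow(quo)))
  }
}
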