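#!/usr/bin/env Rscript
# OTU co-occurrence communities: rare OTUs (< 3 positive samples) removed,
# pairwise Pearson on the Hellinger table thresholded at |r| >= 0.6, MCL
# clustering at inflation 2.5, node topology measures, and the
# fungal/bacterial composition of each community. Planted communities are
# compared against the simulation ground truth.

library(rhizonet)

for (nm in c("genotype", "soil_origin")) {
  fx <- read_fixture(file.path("results/data", nm))
  meta <- fx$frame$samples[match(sample_ids(fx$table),
                                 fx$frame$samples$sample_id), ]
  tr <- !meta$is_control

  net <- correlation_network(fx$table[, tr], threshold = 0.6,
                             min_nonzero = 3L)
  part <- mcl_cluster(net, inflation = 2.5)
  export_network(net, file.path("results", paste0(nm, "_correlation.tsv")),
                 "edge-tsv")
  write.table(data.frame(otu_id = names(part$membership),
                         community = part$membership),
              file.path("results", paste0(nm, "_communities.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  topo <- topology_measures(net)
  write.table(topo, file.path("results", paste0(nm, "_topology.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hubs <- head(topo[order(-topo$degree), "id"], 5L)

  taxonomy <- taxonomy_table(read.table(
    file.path("results/data", nm, "taxonomy.tsv"), sep = "\t",
    header = TRUE, colClasses = "character"))
  comp <- community_composition(part, taxonomy)
  write.table(comp$communities,
              file.path("results", paste0(nm, "_composition.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  multi <- comp$communities[comp$communities$size >= 2L, ]
  cat(sprintf(
    "%-12s %d communities of >= 2 OTUs (%d mixed, %d fungal-only, %d bacterial-only); hubs: %s\n",
    nm, nrow(multi), sum(multi$class == "mixed"),
    sum(multi$class == "fungal-only"), sum(multi$class == "bacterial-only"),
    paste(hubs, collapse = " ")))

  truth <- fx$truth_otu
  planted <- truth$otu_id[truth$community > 0]
  planted <- planted[planted %in% names(part$membership)]
  if (length(planted)) {
    ari <- mclust::adjustedRandIndex(
      part$membership[planted],
      truth$community[match(planted, truth$otu_id)])
    cat(sprintf("%-12s planted-community ARI: %.3f over %d OTUs\n",
                nm, ari, length(planted)))
  }
}
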