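#!/usr/bin/env Rscript
# Soil physicochemistry: property-property correlation network + MST, and
# the property-OTU map (|r| >= 0.6 at sample resolution) annotated with
# each OTU's co-occurrence community — the candidate environmental drivers
# of the communities. Checked against the property links planted in the
# simulation.

library(rhizonet)

nm <- "soil_origin"
fx <- read_fixture(file.path("results/data", nm))
meta <- fx$frame$samples[match(sample_ids(fx$table),
                               fx$frame$samples$sample_id), ]
tr <- !meta$is_control

spn <- soil_property_network(fx$frame, soils = unique(meta$soil_id[tr]))
write.table(spn$network$edges, "results/soil_property_correlations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
export_network(spn$mst, "results/soil_property_mst.tsv", "edge-tsv")
strong <- spn$network$edges[abs(spn$network$edges$weight) >= 0.8, ]
cat(sprintf("strongly correlated property pairs (|r| >= 0.8): %s\n",
            paste(paste0(strong$from, "~", strong$to), collapse = ", ")))

net <- correlation_network(fx$table[, tr], threshold = 0.6, min_nonzero = 3L)
part <- mcl_cluster(net, inflation = 2.5)
pm <- property_otu_community_map(fx$table[, tr], fx$frame, part,
                                 threshold = 0.6)
write.table(pm$edges, "results/property_otu_edges.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pm$community_properties, "results/community_properties.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("property-OTU edges at |r| >= 0.6: %d, touching %d communities\n",
            nrow(pm$edges), length(unique(pm$community_properties$community))))

# do the planted property-linked communities surface?
truth <- fx$truth_otu
for (cc in unique(truth$community[truth$community > 0])) {
  mem <- truth$otu_id[truth$community == cc]
  linked <- pm$edges[pm$edges$to %in% mem, ]
  if (nrow(linked))
    cat(sprintf("planted community %d linked to: %s\n", cc,
                paste(sort(unique(linked$from)), collapse = ", ")))
}
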