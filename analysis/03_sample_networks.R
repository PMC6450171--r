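#!/usr/bin/env Rscript
# Sample-similarity maximum spanning trees (Pearson and proportional
# similarity on the Hellinger table) and raw bipartite OTU-sample presence
# networks. The MSTs are the backbone views in which samples cluster by
# soil rather than genotype.

library(rhizonet)

for (nm in c("genotype", "soil_origin")) {
  fx <- read_fixture(file.path("results/data", nm))
  meta <- fx$frame$samples[match(sample_ids(fx$table),
                                 fx$frame$samples$sample_id), ]
  tr <- !meta$is_control
  h <- hellinger_transform(fx$table)[, tr]

  r <- pearson_similarity_matrix(h, axis = "samples")
  mst_r <- maximum_spanning_tree(r)
  export_network(mst_r, file.path("results", paste0(nm, "_mst_pearson.tsv")),
                 "edge-tsv")

  ps <- proportional_similarity_matrix(h)
  mst_ps <- maximum_spanning_tree(ps)
  export_network(mst_ps,
                 file.path("results", paste0(nm, "_mst_proportional.tsv")),
                 "edge-tsv")

  # how often does an MST edge join two samples of the same soil?
  same_soil <- function(net) {
    soil <- setNames(meta$soil_id, meta$sample_id)
    mean(soil[net$edges$from] == soil[net$edges$to])
  }
  cat(sprintf("%-12s MST same-soil edge fraction: pearson %.2f, PS %.2f\n",
              nm, same_soil(mst_r), same_soil(mst_ps)))

  bp <- bipartite_presence_network(fx$table)
  export_network(bp, file.path("results", paste0(nm, "_bipartite.graphml")),
                 "graphml")
  cat(sprintf("%-12s bipartite presence network: %d nodes, %d edges\n",
              nm, nrow(bp$nodes), nrow(bp$edges)))
}
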