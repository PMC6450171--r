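#' Soil-property correlation network and MST
#'
#' Pearson correlation between every pair of soil physicochemical
#' properties across soils, plus the maximum spanning tree of the resulting
#' similarity matrix (distance `1 - r`). Constant properties get r = 0 with
#' a warning.
#'
#' @param frame A [sample_frame()] with at least 3 soils.
#' @param soils Optional subset of soil ids to use.
#' @return List with `correlation` (property-by-property matrix), `mst`
#'   (a [rhizo_network()] over property nodes), and `network` (a
#'   [rhizo_network()] with one edge per property pair, weight `r`).
#' @export
soil_property_network <- function(frame, soils = NULL) {
  props <- frame$soils
  if (!is.null(soils)) props <- props[props$soil_id %in% soils, , drop = FALSE]
  pm <- as.matrix(props[, setdiff(colnames(props), "soil_id"), drop = FALSE])
  rownames(pm) <- props$soil_id
  if (nrow(pm) < 3L) stop("need at least 3 soils with property vectors")
  r <- pearson_similarity_matrix(pm, axis = "samples")  # columns = properties
  mst <- maximum_spanning_tree(r, role = "property")
  iu <- which(upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(from = rownames(r)[iu[, 1L]], to = rownames(r)[iu[, 2L]],
                      weight = r[iu], sign = ifelse(r[iu] < 0, "-", "+"))
  full <- rhizo_network(data.frame(id = colnames(pm), role = "property"),
                        edges)
  list(correlation = r, mst = mst, network = full)
}

#' Map soil properties onto OTU communities
#'
#' Correlates every soil property with every OTU abundance profile at
#' sample resolution (each soil's property value is broadcast to its
#' samples) and keeps pairs with `|Pearson| >= threshold`. Each surviving
#' property-OTU edge is annotated with the OTU's community label, giving a
#' per-community list of potentially driving properties. OTUs absent from
#' the partition get the background label 0.
#'
#' @param table An [otu_table()]; Hellinger-transformed first when on the
#'   counts scale (matching the co-occurrence analysis scale).
#' @param frame A [sample_frame()] resolving the table's samples to soils.
#' @param partition A `community_partition` or named membership vector.
#' @param threshold Absolute-correlation threshold (default 0.6).
#' @param transform Apply [hellinger_transform()] to counts input.
#' @return List with `network` (bipartite property-OTU [rhizo_network()],
#'   edges annotated with `community`), `edges` (the annotated edge table)
#'   and `community_properties` (data.frame community / property pairs).
#' @export
property_otu_community_map <- function(table, frame, partition,
                                       threshold = 0.6, transform = TRUE) {
  membership <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  if (transform && otu_scale(table) %in% c("counts", "relative"))
    table <- hellinger_transform(table)
  meta <- frame$samples[match(sample_ids(table), frame$samples$sample_id), ]
  if (anyNA(meta$sample_id)) stop("sample(s) missing from metadata")
  use <- !meta$is_control
  v <- unclass(table)[, use, drop = FALSE]
  prop_names <- setdiff(colnames(frame$soils), "soil_id")
  pm <- vapply(prop_names, function(p)
    sample_property(frame, colnames(v), p), numeric(ncol(v)))
  pm <- matrix(pm, ncol = length(prop_names),
               dimnames = list(colnames(v), prop_names))
  r <- suppressWarnings(stats::cor(t(v), pm))
  r[!is.finite(r)] <- 0
  hit <- which(abs(r) >= threshold, arr.ind = TRUE)
  comm <- membership[match(rownames(v), names(membership))]
  comm[is.na(comm)] <- 0L
  names(comm) <- rownames(v)
  edges <- data.frame(from = prop_names[hit[, 2L]],
                      to = rownames(v)[hit[, 1L]],
                      weight = abs(r[hit]),
                      sign = ifelse(r[hit] < 0, "-", "+"),
                      r = r[hit],
                      community = as.integer(comm[rownames(v)[hit[, 1L]]]))
  nodes <- data.frame(id = c(prop_names, rownames(v)),
                      role = rep(c("property", "otu"),
                                 c(length(prop_names), nrow(v))))
  cp <- unique(edges[edges$community > 0, c("community", "from")])
  colnames(cp) <- c("community", "property")
  cp <- cp[order(cp$community, cp$property, method = "radix"), , drop = FALSE]
  rownames(cp) <- NULL
  list(network = rhizo_network(nodes, edges, bipartite = TRUE),
       edges = edges, community_properties = cp)
}
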