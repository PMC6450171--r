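#' Deterministic per-stage random seed
#'
#' Expands one global seed into an independent substream per named stage by
#' mixing the stage name into the seed (multiplicative string hash, kept
#' below 2^31). Inserting or removing a stage therefore never perturbs the
#' randomness of the others.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

pipeline_stages <- c("transform", "sample_networks", "enrichment",
                     "communities", "envlinks", "differential",
                     "indicators", "stats")

default_thresholds <- list(correlation = 0.6, inflation = 2.5,
                           enrichment_fdr = 0.01, indicator_alpha = 0.05,
                           fcros_f = 0.9, fcros_p = 0.05, min_nonzero = 3L,
                           permutations = 999L)

#' Run the full rhizobiome network workflow
#'
#' Executes the analysis stages in dependency order over either a simulated
#' dataset (`simulate` block: arguments for [sim_config()]) or input files
#' (`input` block: `otu_table`, `samples`, `soils`, `taxonomy` paths), and
#' writes one or more TSV/GraphML artifacts per stage plus a JSON run
#' manifest (config hash, seed, package version, per-file checksums) into
#' `output_dir`. Identical config + seed gives byte-identical outputs.
#'
#' Stages: `transform` (Hellinger table, rank abundance),
#' `sample_networks` (Pearson and proportional-similarity MSTs, bipartite
#' presence network), `enrichment` (per-sample and, with genotypes,
#' genotype-binned hypergraphs and the quotient selection), `communities`
#' (correlation network, MCL partition, topology, composition), `envlinks`
#' (soil-property network/MST, property-OTU-community map), `differential`
#' (FCROS between `classes$a` and `classes$b`; defaults to the simulated
#' truth classes), `indicators` (indicator-species analysis over soils),
#' `stats` (PCoA, PERMANOVA, PERMDISP, detection chi-square).
#'
#' @param config Path to a YAML config file, or an equivalent named list
#'   with elements `seed`, `output_dir`, and `simulate` or `input`;
#'   optional `stages`, `thresholds`, `classes`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config needs a seed")
  if (is.null(config$output_dir)) stop("config needs an output_dir")
  stages <- config$stages %||% pipeline_stages
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "),
         "; valid: ", paste(pipeline_stages, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  thr <- utils::modifyList(default_thresholds, config$thresholds %||% list())
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  log_msg <- function(...) message(sprintf("[rhizonet] %s", sprintf(...)))

  ## load or simulate inputs
  state <- new.env(parent = emptyenv())
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (is.null(args$seed)) args$seed <- stage_seed(seed, "simulate")
    ds <- generate_dataset(do.call(sim_config, args))
    state$table <- ds$table; state$frame <- ds$frame
    state$taxonomy <- ds$taxonomy; state$truth <- ds$truth
    write_fixture(ds, file.path(out_dir, "fixture"), overwrite = TRUE)
    log_msg("simulated %d OTUs x %d samples", nrow(ds$table), ncol(ds$table))
  } else if (!is.null(config$input)) {
    inp <- config$input
    state$table <- read_otu_table(inp$otu_table)
    state$frame <- read_metadata(inp$samples, inp$soils)
    state$taxonomy <- if (!is.null(inp$taxonomy)) read_taxonomy(inp$taxonomy)
    state$truth <- NULL
  } else stop("config needs a simulate or input block")
  meta <- state$frame$samples[match(sample_ids(state$table),
                                    state$frame$samples$sample_id), ]
  state$treat <- !meta$is_control
  state$meta <- meta

  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_plain(df, path)
    files <<- c(files, path)
    path
  }
  for (st in stages) {
    t0 <- proc.time()[3L]
    switch(st,
      transform = {
        state$hellinger <- hellinger_transform(state$table)
        write_otu_table(state$hellinger, file.path(out_dir, "hellinger.tsv"))
        files <- c(files, file.path(out_dir, "hellinger.tsv"))
        emit(relative_and_rank_abundance(state$table,
                                         groups = state$meta$soil_id),
             "rank_abundance.tsv")
      },
      sample_networks = {
        h <- pipeline_need(state, "hellinger", "sample_networks", "transform")
        ht <- h[, state$treat]
        r <- pearson_similarity_matrix(ht, axis = "samples")
        ps <- proportional_similarity_matrix(ht)
        export_network(maximum_spanning_tree(r),
                       emit_path(files, out_dir, "mst_pearson.tsv"),
                       "edge-tsv")
        export_network(maximum_spanning_tree(ps),
                       emit_path(files, out_dir, "mst_proportional.tsv"),
                       "edge-tsv")
        files <- c(files, file.path(out_dir, c("mst_pearson.tsv",
                                               "mst_proportional.tsv")))
        bp <- bipartite_presence_network(state$table)
        export_network(bp, file.path(out_dir, "bipartite_presence.graphml"),
                       "graphml")
        files <- c(files, file.path(out_dir, "bipartite_presence.graphml"))
      },
      enrichment = {
        enr <- build_enrichment_network(state$table, state$frame,
                                        mode = "per-sample",
                                        level = thr$enrichment_fdr)
        state$enrichment <- enr
        emit(enr$results, "enrichment_per_sample.tsv")
        export_network(enr$network,
                       file.path(out_dir, "enrichment_network.graphml"),
                       "graphml")
        files <- c(files, file.path(out_dir, "enrichment_network.graphml"))
        if (length(unique(state$meta$genotype_id[state$treat])) > 1L) {
          binned <- suppressWarnings(
            build_enrichment_network(state$table, state$frame,
                                     mode = "binned-by-genotype",
                                     level = thr$enrichment_fdr))
          emit(binned$results, "enrichment_binned.tsv")
          emit(genotype_quotient_selection(enr$network, state$frame),
               "genotype_quotient.tsv")
        }
      },
      communities = {
        net <- correlation_network(state$table,
                                   threshold = thr$correlation,
                                   min_nonzero = thr$min_nonzero)
        part <- mcl_cluster(net, inflation = thr$inflation)
        state$correlation_net <- net
        state$partition <- part
        export_network(net, emit_path(files, out_dir,
                                      "correlation_network.tsv"), "edge-tsv")
        files <- c(files, file.path(out_dir, "correlation_network.tsv"))
        emit(data.frame(otu_id = names(part$membership),
                        community = part$membership),
             "communities.tsv")
        emit(topology_measures(net), "topology.tsv")
        if (!is.null(state$taxonomy)) {
          comp <- community_composition(part, state$taxonomy)
          emit(comp$communities, "community_composition.tsv")
        }
      },
      envlinks = {
        part <- pipeline_need(state, "partition", "envlinks", "communities")
        use_soils <- unique(state$meta$soil_id[state$treat])
        spn <- soil_property_network(state$frame, soils = use_soils)
        emit(spn$network$edges, "soil_property_correlations.tsv")
        export_network(spn$mst,
                       emit_path(files, out_dir, "soil_property_mst.tsv"),
                       "edge-tsv")
        files <- c(files, file.path(out_dir, "soil_property_mst.tsv"))
        pm <- property_otu_community_map(state$table, state$frame, part,
                                         threshold = thr$correlation)
        emit(pm$edges, "property_otu_edges.tsv")
        emit(pm$community_properties, "community_properties.tsv")
      },
      differential = {
        cls <- config$classes %||% state$truth$classes
        if (is.null(cls) || !length(cls$a) || !length(cls$b))
          stop("stage 'differential' needs classes$a and classes$b ",
               "(sample ids), or a simulated dataset providing them")
        res <- differential_abundance(state$table, cls$a, cls$b,
                                      alpha = thr$fcros_p,
                                      f_threshold = thr$fcros_f)
        state$differential <- res
        emit(res, "differential.tsv")
      },
      indicators = {
        tab <- state$table[, state$treat]
        grp <- state$meta$soil_id[state$treat]
        res <- indicator_analysis(tab, grp,
                                  n_permutations = thr$permutations,
                                  alpha = thr$indicator_alpha,
                                  seed = stage_seed(seed, "indicators"))
        state$indicators <- res
        emit(res, "indicators.tsv")
      },
      stats = {
        h <- pipeline_need(state, "hellinger", "stats", "transform")
        ht <- h[, state$treat]
        grp <- state$meta$soil_id[state$treat]
        d <- bray_curtis_matrix(ht)
        ord <- pcoa(d, k = 2L)
        emit(data.frame(sample_id = rownames(ord$coordinates),
                        ord$coordinates), "pcoa.tsv")
        rows <- list()
        pa <- permanova(d, grp, n_permutations = thr$permutations,
                        seed = stage_seed(seed, "permanova"))
        pd <- permdisp(d, grp, n_permutations = thr$permutations,
                       seed = stage_seed(seed, "permdisp"))
        rows$soil <- data.frame(factor = "soil", test = c("PERMANOVA",
                                                          "PERMDISP"),
                                statistic = c(pa$pseudo_F, pd$F),
                                R_squared = c(pa$R_squared, NA),
                                p_value = c(pa$p_value, pd$p_value))
        geno <- state$meta$genotype_id[state$treat]
        if (length(unique(geno)) > 1L) {
          pg <- permanova(d, geno, n_permutations = thr$permutations,
                          seed = stage_seed(seed, "permanova_genotype"))
          rows$geno <- data.frame(factor = "genotype", test = "PERMANOVA",
                                  statistic = pg$pseudo_F,
                                  R_squared = pg$R_squared,
                                  p_value = pg$p_value)
        }
        emit(do.call(rbind, rows), "permanova.tsv")
        det <- detection_counts(state$table[, state$treat], grp)
        chi <- chi_square_detection(det)
        emit(data.frame(group = names(det), otus_detected = as.integer(det)),
             "detection_counts.tsv")
        emit(data.frame(statistic = chi$statistic, df = chi$df,
                        p_value = chi$p_value), "detection_chisq.tsv")
        state$permanova <- pa
        state$permdisp <- pd
      })
    log_msg("stage %-15s done in %.1fs", st, proc.time()[3L] - t0)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rhizonet")),
    seed = seed,
    stages = stages,
    thresholds = thr,
    config_hash = config_hash(config),
    files = file_checksums(unique(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

emit_path <- function(files, out_dir, name) file.path(out_dir, name)

pipeline_need <- function(state, field, stage, upstream) {
  if (is.null(state[[field]]))
    stop("stage '", stage, "' needs the output of stage '", upstream,
         "' (not run)")
  state[[field]]
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  config <- config[setdiff(names(config), "output_dir")]
  writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

file_checksums <- function(paths) {
  sums <- tools::md5sum(paths)
  stats::setNames(as.list(unname(sums)), basename(paths))
}
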