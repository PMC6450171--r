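#' Simulation configuration
#'
#' Parameters of the synthetic rhizobiome generator. Defaults emulate the
#' soil-origin bioassay design: 8 soils x 4 replicate trap plants of a
#' single host genotype, ~300 joint fungal-bacterial OTUs, per-sample
#' library sizes uniform over the sequencing depth range 346-4065 reads,
#' soil-structured planted communities, a handful of low-diversity control
#' samples, and planted four-fold differential OTUs between two designated
#' soil classes. Set `n_genotypes > 0` for a genotype bioassay design
#' (every genotype is replicated in every soil).
#'
#' @param n_soils Number of field soils.
#' @param replicates_per_soil Replicate plants per soil (and per genotype
#'   when `n_genotypes > 0`).
#' @param n_genotypes Host genotypes; 0 means a single-genotype design.
#' @param n_fungal_otus,n_bacterial_otus OTU pool sizes per domain.
#' @param n_planted_communities Number of planted co-abundance communities.
#' @param community_size_range Inclusive size range of planted communities.
#' @param soil_effect_sd SD of the per-soil community mean shift (latent
#'   natural-log scale).
#' @param genotype_effect_sd SD of the genotype shift on community factors.
#' @param genotype_effect_is_soil_conditional Draw genotype shifts
#'   independently within each soil (the soil-conditional genotype effect
#'   the study reports) instead of once per genotype.
#' @param n_soil_properties Number of soil physicochemical properties.
#' @param n_property_linked_communities How many planted communities track
#'   a soil property (their soil shift is proportional to it).
#' @param base_log_abundance_sd SD of per-OTU baseline log abundance.
#' @param overdispersion SD of per-OTU per-sample latent noise (extra
#'   count dispersion beyond multinomial sampling).
#' @param sample_noise_sd SD of the per-sample noise on each community
#'   factor.
#' @param library_size_range Per-sample read depth range (uniform integer).
#' @param n_control_samples Uninoculated control plants.
#' @param control_taxa_count Size of the disjoint low-diversity control
#'   community.
#' @param n_differential Planted differential OTUs between the two
#'   designated sample classes.
#' @param differential_lfc Planted log2 fold change (default 2, i.e.
#'   four-fold).
#' @param n_indicator_otus Planted soil-specific OTUs: present (at solid
#'   abundance) in the samples of exactly one soil and absent elsewhere,
#'   spread round-robin over the soils. These emulate the
#'   presence-structured taxa (e.g. soil-restricted ectomycorrhizal fungi)
#'   that indicator-species analysis is designed to find.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_soils = 8L, replicates_per_soil = 4L,
                       n_genotypes = 0L, n_fungal_otus = 100L,
                       n_bacterial_otus = 200L, n_planted_communities = 5L,
                       community_size_range = c(8L, 15L),
                       soil_effect_sd = 2.0, genotype_effect_sd = 0.8,
                       genotype_effect_is_soil_conditional = TRUE,
                       n_soil_properties = 10L,
                       n_property_linked_communities = 2L,
                       base_log_abundance_sd = 1.0, overdispersion = 0.4,
                       sample_noise_sd = 0.5,
                       library_size_range = c(346L, 4065L),
                       n_control_samples = 3L, control_taxa_count = 12L,
                       n_differential = 20L, differential_lfc = 2.0,
                       n_indicator_otus = 16L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  counts <- c("n_soils", "replicates_per_soil", "n_genotypes",
              "n_fungal_otus", "n_bacterial_otus", "n_planted_communities",
              "n_soil_properties", "n_property_linked_communities",
              "n_control_samples", "control_taxa_count", "n_differential",
              "n_indicator_otus")
  for (nm in counts) if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  if (any(library_size_range <= 0) || diff(library_size_range) < 0)
    stop("library_size_range must be positive and ordered")
  if (cfg$n_property_linked_communities > cfg$n_planted_communities)
    stop("more property-linked communities than planted communities")
  if (cfg$n_property_linked_communities > cfg$n_soil_properties)
    stop("more property-linked communities than soil properties")
  pool <- cfg$n_fungal_otus + cfg$n_bacterial_otus
  if (sum(rep(mean(community_size_range), cfg$n_planted_communities)) +
      cfg$control_taxa_count + cfg$n_differential +
      cfg$n_indicator_otus > pool)
    stop("community sizes exceed the OTU pool")
  structure(cfg, class = "sim_config")
}

# uniform integer draw over an inclusive range (safe when lo == hi)
sample_int_range <- function(range, n) {
  vals <- seq.int(range[1L], range[2L])
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

soil_property_names <- c("Ca_ppm", "Mg_ppm", "P_ppm", "K_ppm", "pH",
                         "CEC_meq_100g", "sand_pct", "clay_pct",
                         "organic_pct", "dist_river_m")

#' Generate a synthetic rhizobiome dataset with planted ground truth
#'
#' Generative model: each planted community `c` carries one latent factor
#' per sample, `z[c, s] =` soil mean shift (per-soil, or proportional to a
#' generated soil property for property-linked communities) + genotype
#' shift (per soil-by-genotype cell when soil-conditional) + sample noise.
#' A member OTU's latent log abundance is its baseline plus a positive
#' loading times the factor; background OTUs get independent noise;
#' designated differential OTUs add their planted log fold change in the
#' second sample class. Counts are drawn multinomially per sample from the
#' softmax of the latent log abundances at a library size uniform over the
#' configured read-depth range. Control samples draw from a disjoint
#' low-diversity control community. Deterministic under a fixed seed.
#'
#' Community soil-shift profiles are mutually orthogonalised (and
#' orthogonal to the linked properties) so each planted community tracks
#' its own environmental axis; this keeps the planted partition
#' identifiable as ground truth.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset` with `table` ([otu_table()], counts),
#'   `frame` ([sample_frame()]), `taxonomy` ([taxonomy_table()]), `truth`
#'   (list: `otu` data.frame with community / lfc / is_control_taxon,
#'   `community_links`, `soil_shifts`, `classes`, `config`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_otu <- cfg$n_fungal_otus + cfg$n_bacterial_otus
  otu_id <- c(sprintf("f_otu%03d", seq_len(cfg$n_fungal_otus)),
              sprintf("b_otu%03d", seq_len(cfg$n_bacterial_otus)))
  domain <- rep(c("fungal", "bacterial"),
                c(cfg$n_fungal_otus, cfg$n_bacterial_otus))
  soils <- sprintf("S%d", seq_len(cfg$n_soils))

  ## soil properties: correlated Gaussians with two collinear pairs
  np <- cfg$n_soil_properties
  pnames <- if (np <= length(soil_property_names))
    soil_property_names[seq_len(np)] else
      c(soil_property_names, sprintf("prop_%02d",
                                     seq_len(np - length(soil_property_names))))
  z <- matrix(stats::rnorm(cfg$n_soils * np), cfg$n_soils, np)
  if (np >= 2L) z[, 2L] <- 0.95 * z[, 1L] + 0.31 * z[, 2L]   # Ca ~ Mg
  if (np >= 6L) z[, 6L] <- 0.9 * z[, 1L] + 0.44 * z[, 6L]    # CEC ~ Ca
  if (np >= 8L) z[, 8L] <- -0.85 * z[, 7L] + 0.53 * z[, 8L]  # clay ~ -sand
  prop_mean <- c(600, 150, 40, 120, 6.5, 12, 55, 20, 3, 150)
  prop_sd <- c(250, 60, 15, 40, 0.7, 4, 12, 8, 1.2, 90)
  if (np > 10L) { prop_mean <- c(prop_mean, rep(0, np - 10L))
                  prop_sd <- c(prop_sd, rep(1, np - 10L)) }
  props <- sweep(sweep(z, 2L, prop_sd[seq_len(np)], "*"), 2L,
                 prop_mean[seq_len(np)], "+")
  dimnames(props) <- list(soils, pnames)

  ## planted communities: disjoint, mixed fungal-bacterial membership
  ncomm <- cfg$n_planted_communities
  sizes <- if (ncomm) sample_int_range(cfg$community_size_range, ncomm)
           else integer()
  community <- integer(n_otu)
  free_f <- which(domain == "fungal")
  free_b <- which(domain == "bacterial")
  for (cc in seq_len(ncomm)) {
    nf <- max(2L, round(sizes[cc] * cfg$n_fungal_otus / n_otu))
    nb <- max(2L, sizes[cc] - nf)
    pick_f <- free_f[sample.int(length(free_f), nf)]
    pick_b <- free_b[sample.int(length(free_b), nb)]
    community[c(pick_f, pick_b)] <- cc
    free_f <- setdiff(free_f, pick_f)
    free_b <- setdiff(free_b, pick_b)
  }
  free <- which(community == 0L)
  ctl_taxa <- if (cfg$n_control_samples > 0)
    sort(free[sample.int(length(free), cfg$control_taxa_count)]) else integer()
  free <- setdiff(free, ctl_taxa)
  diff_otus <- if (cfg$n_differential > 0 && cfg$n_soils >= 2L)
    sort(free[sample.int(length(free), cfg$n_differential)]) else integer()
  free <- setdiff(free, diff_otus)
  ind_otus <- if (cfg$n_indicator_otus > 0)
    sort(free[sample.int(length(free), cfg$n_indicator_otus)]) else integer()
  ind_soil <- if (length(ind_otus))
    soils[rep_len(seq_len(cfg$n_soils), length(ind_otus))] else character()

  ## community soil-shift profiles, orthogonalised for identifiability
  linked <- seq_len(cfg$n_property_linked_communities)
  link_prop <- if (length(linked)) {
    # pick non-collinear properties: skip the constructed collinear partners
    cand <- setdiff(seq_len(np), c(2L, 6L, 8L))
    pnames[cand[seq_along(linked)]]
  } else character()
  alpha <- matrix(0, cfg$n_soils, max(ncomm, 1L))
  basis <- NULL
  for (cc in seq_len(ncomm)) {
    if (cc %in% linked) {
      vec <- scale(props[, link_prop[cc]])[, 1L]
    } else {
      vec <- stats::rnorm(cfg$n_soils)
      if (!is.null(basis) && ncol(basis) < cfg$n_soils - 1L) {
        proj <- basis %*% crossprod(basis, vec)
        vec <- vec - proj[, 1L]
      }
      if (stats::sd(vec) < 1e-8) vec <- stats::rnorm(cfg$n_soils)
      vec <- vec / stats::sd(vec)
    }
    alpha[, cc] <- vec * cfg$soil_effect_sd
    nrm <- sqrt(sum(vec^2))
    if (nrm > 1e-8) {
      qvec <- vec / nrm
      basis <- if (is.null(basis)) matrix(qvec, ncol = 1L) else {
        resid <- qvec - basis %*% crossprod(basis, qvec)
        rn <- sqrt(sum(resid^2))
        if (is.finite(rn) && rn > 1e-8) cbind(basis, resid / rn) else basis
      }
    }
  }
  rownames(alpha) <- soils

  ## sample layout
  genos <- if (cfg$n_genotypes > 0) sprintf("G%d", seq_len(cfg$n_genotypes))
           else "G1"
  lay <- expand.grid(rep = seq_len(cfg$replicates_per_soil),
                     genotype = genos, soil = soils,
                     stringsAsFactors = FALSE)
  sid <- if (cfg$n_genotypes > 0)
    sprintf("%s_%s_r%d", lay$soil, lay$genotype, lay$rep)
  else sprintf("%s_r%d", lay$soil, lay$rep)
  n_treat <- nrow(lay)
  ctl_ids <- if (cfg$n_control_samples > 0)
    sprintf("control_r%d", seq_len(cfg$n_control_samples)) else character()

  ## designated differential classes: first two soils vs next two
  cls <- list(a = character(), b = character())
  if (cfg$n_soils >= 4L) {
    cls$a <- sid[lay$soil %in% soils[1:2]]
    cls$b <- sid[lay$soil %in% soils[3:4]]
  } else if (cfg$n_soils >= 2L) {
    cls$a <- sid[lay$soil == soils[1L]]
    cls$b <- sid[lay$soil == soils[2L]]
  }

  ## latent log abundances; planted differential OTUs get baselines in the
  ## detectable range, since a fold change on a taxon the sequencing depth
  ## cannot observe is not measurable
  mu <- stats::rnorm(n_otu, 0, cfg$base_log_abundance_sd)
  if (length(diff_otus))
    mu[diff_otus] <- stats::rnorm(length(diff_otus), 0.5,
                                  cfg$base_log_abundance_sd / 2)
  lambda <- stats::runif(n_otu, 0.8, 1.2)
  x <- matrix(mu, n_otu, n_treat)
  if (ncomm) {
    gshift <- array(0, c(ncomm, length(genos), cfg$n_soils))
    if (cfg$n_genotypes > 0) {
      if (cfg$genotype_effect_is_soil_conditional) {
        gshift[] <- stats::rnorm(length(gshift), 0, cfg$genotype_effect_sd)
      } else {
        per_geno <- matrix(stats::rnorm(ncomm * length(genos), 0,
                                        cfg$genotype_effect_sd),
                           ncomm, length(genos))
        for (s in seq_len(cfg$n_soils)) gshift[, , s] <- per_geno
      }
    }
    soil_i <- match(lay$soil, soils)
    geno_i <- match(lay$genotype, genos)
    for (cc in seq_len(ncomm)) {
      zc <- alpha[soil_i, cc] +
        gshift[cbind(cc, geno_i, soil_i)] +
        stats::rnorm(n_treat, 0, cfg$sample_noise_sd)
      members <- which(community == cc)
      x[members, ] <- x[members, , drop = FALSE] +
        outer(lambda[members], zc)
    }
  }
  if (length(diff_otus) && length(cls$b)) {
    bcols <- sid %in% cls$b
    x[diff_otus, bcols] <- x[diff_otus, bcols] +
      cfg$differential_lfc * log(2)
  }
  if (length(ind_otus)) {
    x[ind_otus, ] <- -12   # absent outside the home soil
    for (ii in seq_along(ind_otus))
      x[ind_otus[ii], lay$soil == ind_soil[ii]] <- 1.5
  }
  x <- x + matrix(stats::rnorm(n_otu * n_treat, 0, cfg$overdispersion),
                  n_otu, n_treat)
  if (length(ctl_taxa)) x[ctl_taxa, ] <- -12   # control taxa absent in soil

  ## control samples: disjoint low-diversity community
  if (cfg$n_control_samples > 0) {
    xc <- matrix(-12, n_otu, cfg$n_control_samples)
    mu_ctl <- stats::rnorm(length(ctl_taxa), 2, cfg$base_log_abundance_sd)
    xc[ctl_taxa, ] <- mu_ctl +
      matrix(stats::rnorm(length(ctl_taxa) * cfg$n_control_samples, 0,
                          cfg$overdispersion),
             length(ctl_taxa), cfg$n_control_samples)
    x <- cbind(x, xc)
  }
  all_ids <- c(sid, ctl_ids)

  ## multinomial counts at uniform library sizes
  lib <- sample_int_range(cfg$library_size_range, ncol(x))
  counts <- vapply(seq_len(ncol(x)), function(s) {
    pr <- exp(x[, s] - max(x[, s]))
    as.numeric(stats::rmultinom(1L, lib[s], pr))
  }, numeric(n_otu))
  dimnames(counts) <- list(otu_id, all_ids)

  ## metadata
  samples <- data.frame(
    sample_id = all_ids,
    soil_id = c(lay$soil, rep("control", length(ctl_ids))),
    genotype_id = c(lay$genotype, rep(genos[1L], length(ctl_ids))),
    is_control = c(rep(FALSE, n_treat), rep(TRUE, length(ctl_ids))),
    experiment_id = if (cfg$n_genotypes > 0) "genotype" else "soil_origin")
  soil_df <- data.frame(soil_id = soils, as.data.frame(props),
                        check.names = FALSE)
  units <- stats::setNames(
    c("ppm", "ppm", "ppm", "ppm", "pH units", "meq/100g", "%", "%", "%",
      "m")[seq_len(min(np, 10L))], pnames[seq_len(min(np, 10L))])
  frame <- sample_frame(samples, soil_df, property_units = units)

  phyla_f <- c("Ascomycota", "Basidiomycota", "Mucoromycota")
  phyla_b <- c("Proteobacteria", "Bacteroidetes", "Actinobacteria",
               "Firmicutes")
  taxonomy <- taxonomy_table(data.frame(
    otu_id = otu_id,
    kingdom = ifelse(domain == "fungal", "Fungi", "Bacteria"),
    phylum = ifelse(domain == "fungal",
                    sample(phyla_f, n_otu, replace = TRUE),
                    sample(phyla_b, n_otu, replace = TRUE)),
    class = "", order = "", family = "", genus = "",
    species = otu_id, domain = domain))

  indicator_soil <- rep("", n_otu)
  indicator_soil[ind_otus] <- ind_soil
  truth_otu <- data.frame(
    otu_id = otu_id, community = community,
    lfc = ifelse(seq_len(n_otu) %in% diff_otus, cfg$differential_lfc, 0),
    is_control_taxon = seq_len(n_otu) %in% ctl_taxa,
    indicator_soil = indicator_soil)
  links <- data.frame(community = linked, property = link_prop)
  truth <- list(otu = truth_otu, community_links = links,
                soil_shifts = alpha[, seq_len(max(ncomm, 1L)), drop = FALSE],
                classes = cls, config = cfg)
  structure(list(table = otu_table(counts, marker = "ITS", scale = "counts"),
                 frame = frame, taxonomy = taxonomy, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d OTUs x %d samples, %d planted communities\n",
              nrow(x$table), ncol(x$table),
              max(x$truth$otu$community)))
  invisible(x)
}

#' Write a synthetic dataset to a fixture directory
#'
#' Emits the standard plain-text artifacts (`otu_table.tsv` dense dialect,
#' `samples.tsv`, `soils.tsv`, `taxonomy.tsv`) plus the ground-truth file
#' `truth.tsv` (`otu_id`, `community`, `lfc`, `is_control_taxon`); the set
#' round-trips through [read_otu_table()] / [read_metadata()] /
#' [read_taxonomy()].
#'
#' @param dataset A `sim_dataset` from [generate_dataset()].
#' @param directory Destination directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, the file paths written.
#' @export
write_fixture <- function(dataset, directory, overwrite = FALSE) {
  if (dir.exists(directory) && length(dir(directory)) && !overwrite)
    stop("directory exists and is not empty (use overwrite = TRUE): ",
         directory)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, c("otu_table.tsv", "samples.tsv", "soils.tsv",
                                  "taxonomy.tsv", "truth.tsv"))
  write_otu_table(dataset$table, paths[1L], dialect = "tsv-dense")
  write_metadata(dataset$frame, paths[2L], paths[3L])
  write_taxonomy(dataset$taxonomy, paths[4L])
  write_tsv_plain(dataset$truth$otu, paths[5L])
  invisible(paths)
}

#' Read a fixture directory back into memory
#'
#' @param directory Directory written by [write_fixture()].
#' @return List with `table`, `frame`, `taxonomy`, `truth_otu`.
#' @export
read_fixture <- function(directory) {
  list(table = read_otu_table(file.path(directory, "otu_table.tsv")),
       frame = read_metadata(file.path(directory, "samples.tsv"),
                             file.path(directory, "soils.tsv")),
       taxonomy = read_taxonomy(file.path(directory, "taxonomy.tsv")),
       truth_otu = utils::read.table(file.path(directory, "truth.tsv"),
                                     sep = "\t", header = TRUE))
}
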