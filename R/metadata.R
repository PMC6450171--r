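#' Sample and soil metadata
#'
#' Joins per-sample metadata (soil of origin, host genotype, control flag,
#' experiment id) with per-soil physicochemical property vectors. Control
#' samples (plants grown in sterilised sand) carry the reserved soil id
#' `"control"` and need no property vector.
#'
#' @param samples data.frame with columns `sample_id`, `soil_id`,
#'   `genotype_id`, `is_control`, `experiment_id`.
#' @param soils data.frame keyed by a `soil_id` column; remaining numeric
#'   columns are soil properties (Ca, Mg, pH, texture fractions, distance to
#'   river, ...).
#' @param property_units optional named character vector of units per
#'   property column (ppm, \%, cm, pH units).
#' @return Object of class `sample_frame`: list with elements `samples`,
#'   `soils`, `property_units`.
#' @export
sample_frame <- function(samples, soils, property_units = NULL) {
  req <- c("sample_id", "soil_id", "genotype_id", "is_control", "experiment_id")
  miss <- setdiff(req, colnames(samples))
  if (length(miss)) stop("missing sample metadata column(s): ",
                         paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)[, req]
  samples$sample_id <- as.character(samples$sample_id)
  samples$soil_id <- as.character(samples$soil_id)
  samples$genotype_id <- as.character(samples$genotype_id)
  samples$is_control <- as.logical(samples$is_control)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample metadata")
  if (!"soil_id" %in% colnames(soils)) stop("soil table lacks soil_id column")
  soils <- as.data.frame(soils)
  soils$soil_id <- as.character(soils$soil_id)
  if (anyDuplicated(soils$soil_id)) stop("duplicate soil_id in soil table")
  prop_cols <- setdiff(colnames(soils), "soil_id")
  for (p in prop_cols) {
    soils[[p]] <- as.numeric(soils[[p]])
    if (anyNA(soils[[p]]))
      stop("missing value in soil property '", p, "'")
  }
  need <- unique(samples$soil_id[!samples$is_control])
  unknown <- setdiff(need, soils$soil_id)
  if (length(unknown))
    stop("sample references undefined soil(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(property_units)) {
    property_units <- rep(NA_character_, length(prop_cols))
    names(property_units) <- prop_cols
  }
  rownames(samples) <- NULL
  rownames(soils) <- NULL
  structure(list(samples = samples, soils = soils,
                 property_units = property_units),
            class = "sample_frame")
}

#' @export
print.sample_frame <- function(x, ...) {
  cat(sprintf("sample_frame: %d samples (%d control), %d soils, %d properties\n",
              nrow(x$samples), sum(x$samples$is_control), nrow(x$soils),
              ncol(x$soils) - 1L))
  invisible(x)
}

#' Read sample and soil metadata from TSV files
#'
#' @param sample_path TSV with columns `sample_id`, `soil_id`, `genotype_id`,
#'   `is_control`, `experiment_id`.
#' @param soil_path TSV keyed by `soil_id`, other columns numeric properties.
#' @return A [sample_frame()].
#' @export
read_metadata <- function(sample_path, soil_path) {
  samples <- utils::read.table(sample_path, sep = "\t", header = TRUE,
                               check.names = FALSE, comment.char = "",
                               quote = "", colClasses = "character")
  soils <- utils::read.table(soil_path, sep = "\t", header = TRUE,
                             check.names = FALSE, comment.char = "",
                             quote = "")
  if ("is_control" %in% colnames(samples))
    samples$is_control <- toupper(samples$is_control) %in% c("TRUE", "T", "1")
  sample_frame(samples, soils)
}

#' Write sample and soil metadata to TSV files
#'
#' @param frame A [sample_frame()].
#' @param sample_path,soil_path Destination files.
#' @export
write_metadata <- function(frame, sample_path, soil_path) {
  write_tsv_plain(frame$samples, sample_path)
  write_tsv_plain(frame$soils, soil_path)
  invisible(c(sample_path, soil_path))
}

#' Soil property value for each sample
#'
#' Broadcasts the per-soil property vector to samples via soil membership.
#' Control samples get `NA`.
#'
#' @param frame A [sample_frame()].
#' @param sample_id Character vector of sample ids.
#' @param property Property column name.
#' @return Numeric vector aligned with `sample_id`.
#' @export
sample_property <- function(frame, sample_id, property) {
  if (!property %in% colnames(frame$soils))
    stop("unknown soil property: ", property)
  s <- frame$samples[match(sample_id, frame$samples$sample_id), ]
  if (anyNA(s$sample_id)) stop("unknown sample id(s)")
  out <- frame$soils[[property]][match(s$soil_id, frame$soils$soil_id)]
  out[s$is_control] <- NA_real_
  out
}

#' OTU taxonomy table
#'
#' Seven-rank lineage per OTU plus a binary domain tag separating fungi from
#' bacteria; the tag (not the amplicon marker) decides fungal/bacterial
#' identity in the joint networks. Empty strings are allowed below kingdom.
#'
#' @param df data.frame with columns `otu_id`, `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species`, `domain` (`"fungal"` or
#'   `"bacterial"`).
#' @return data.frame of class `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  req <- c("otu_id", "kingdom", "phylum", "class", "order", "family",
           "genus", "species", "domain")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("missing taxonomy column(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  for (cc in req) df[[cc]] <- as.character(df[[cc]])
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy")
  if (!all(df$domain %in% c("fungal", "bacterial")))
    stop("domain must be 'fungal' or 'bacterial'")
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' @rdname taxonomy_table
#' @param path TSV file with the taxonomy columns.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "", quote = "",
                          colClasses = "character")
  taxonomy_table(df)
}

#' @rdname taxonomy_table
#' @param taxonomy A `taxonomy_table`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write_tsv_plain(as.data.frame(taxonomy), path)
  invisible(path)
}

#' Domain tag lookup
#'
#' @param taxonomy A [taxonomy_table()].
#' @param otu Character vector of OTU ids.
#' @return `"fungal"`/`"bacterial"` per id; errors on an untagged OTU.
#' @export
otu_domain <- function(taxonomy, otu) {
  i <- match(otu, taxonomy$otu_id)
  if (anyNA(i))
    stop("OTU(s) missing from taxonomy: ",
         paste(otu[is.na(i)], collapse = ", "))
  taxonomy$domain[i]
}

write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cols <- vapply(df, function(col)
    if (is.numeric(col)) format_num(col) else as.character(col),
    character(nrow(df)))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(apply(cols, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
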