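#' OTU abundance table
#'
#' A dense OTU-by-sample abundance matrix with axis labels, the amplicon
#' marker it came from, and a record of the abundance scale currently held.
#' The study scale (a few hundred OTUs by a few dozen samples) never needs a
#' sparse representation, so the matrix is kept dense throughout.
#'
#' @param values Numeric matrix of non-negative abundances; rows are OTUs,
#'   columns are samples. Dimnames supply the ids unless `otu_ids` /
#'   `sample_ids` are given.
#' @param otu_ids,sample_ids Optional character vectors of axis labels.
#' @param marker Amplicon marker the table derives from: one of `"ITS"`,
#'   `"16S"`, `"28S"`, `"18S"`. Metadata only: fungal/bacterial identity is
#'   carried by the taxonomy table, because fungal (ITS) and bacterial (16S)
#'   OTUs are pooled into joint networks.
#' @param scale One of `"counts"`, `"relative"`, `"hellinger"`,
#'   `"normalized"`.
#' @return An object of class `otu_table`: the numeric matrix with attributes
#'   `marker` and `scale`.
#' @export
otu_table <- function(values, otu_ids = rownames(values),
                      sample_ids = colnames(values),
                      marker = "ITS", scale = "counts") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(otu_ids)) otu_ids <- paste0("otu", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (length(otu_ids) != nrow(values))
    stop("otu_ids length does not match row count")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match column count")
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite abundance values")
  if (any(values < 0))
    stop("negative abundance values")
  marker <- match.arg(marker, c("ITS", "16S", "28S", "18S"))
  scale <- match.arg(scale, c("counts", "relative", "hellinger", "normalized"))
  dimnames(values) <- list(otu_ids, sample_ids)
  check_scale(values, scale)
  structure(values, marker = marker, scale = scale, class = "otu_table")
}

check_scale <- function(values, scale) {
  nz <- colSums(values) > 0
  if (scale == "relative" && any(abs(colSums(values[, nz, drop = FALSE]) - 1) > 1e-9))
    stop("scale=relative but nonzero columns do not sum to 1")
  if (scale == "hellinger" &&
      any(abs(sqrt(colSums(values[, nz, drop = FALSE]^2)) - 1) > 1e-9))
    stop("scale=hellinger but nonzero columns do not have unit norm")
  invisible(TRUE)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (marker=%s, scale=%s)\n",
              nrow(x), ncol(x), otu_marker(x), otu_scale(x)))
  invisible(x)
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
otu_ids <- function(x) rownames(x)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname otu_table
#' @export
otu_marker <- function(x) attr(x, "marker")

#' @rdname otu_table
#' @export
otu_scale <- function(x) attr(x, "scale")

#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  v <- unclass(x)
  out <- v[i, j, drop = FALSE]
  otu_table(out, marker = attr(x, "marker"), scale = attr(x, "scale"))
}

#' Read an OTU table from disk
#'
#' Two plain-text dialects are supported. `tsv-dense`: UTF-8 TSV whose first
#' row holds sample ids and first column holds OTU ids. `triplet-sparse`:
#' three-column TSV `(otu_id, sample_id, count)` with a header line; absent
#' cells are zero.
#'
#' @param path File to read.
#' @param dialect `"tsv-dense"` or `"triplet-sparse"`.
#' @param marker Marker tag to attach (see [otu_table()]).
#' @return An [otu_table()] with `scale = "counts"`, preserving input order.
#' @export
read_otu_table <- function(path, dialect = c("tsv-dense", "triplet-sparse"),
                           marker = "ITS") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv-dense") {
    raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                             check.names = FALSE, colClasses = "character",
                             comment.char = "", quote = "")
    ids <- raw[[1L]]
    smp <- colnames(raw)[-1L]
    if (anyDuplicated(ids))
      stop("duplicate OTU ids in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (anyDuplicated(smp))
      stop("duplicate sample ids in ", path, ": ",
           paste(unique(smp[duplicated(smp)]), collapse = ", "))
    cells <- as.matrix(raw[, -1L, drop = FALSE])
    vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    if (any(is.na(vals))) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-numeric cell at OTU '%s', sample '%s' in %s",
                   ids[bad[1L]], smp[bad[2L]], path))
    }
    if (any(vals < 0)) {
      bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("negative cell at OTU '%s', sample '%s' in %s",
                   ids[bad[1L]], smp[bad[2L]], path))
    }
    dimnames(vals) <- list(ids, smp)
    return(otu_table(vals, marker = marker, scale = "counts"))
  }
  trip <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            comment.char = "", quote = "")
  if (ncol(trip) < 3L) stop("triplet-sparse file needs 3 columns: ", path)
  cnt <- suppressWarnings(as.numeric(trip[[3L]]))
  if (any(is.na(cnt)))
    stop(sprintf("non-numeric count at OTU '%s', sample '%s' in %s",
                 trip[[1L]][which(is.na(cnt))[1L]],
                 trip[[2L]][which(is.na(cnt))[1L]], path))
  if (any(cnt < 0))
    stop(sprintf("negative count at OTU '%s', sample '%s' in %s",
                 trip[[1L]][which(cnt < 0)[1L]],
                 trip[[2L]][which(cnt < 0)[1L]], path))
  key <- paste(trip[[1L]], trip[[2L]], sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (otu, sample) entries in ", path)
  ids <- unique(trip[[1L]])
  smp <- unique(trip[[2L]])
  vals <- matrix(0, length(ids), length(smp), dimnames = list(ids, smp))
  vals[cbind(match(trip[[1L]], ids), match(trip[[2L]], smp))] <- cnt
  otu_table(vals, marker = marker, scale = "counts")
}

#' Write an OTU table to disk
#'
#' Inverse of [read_otu_table()]; round-trips bit-identically for integer
#' count tables in both dialects.
#'
#' @param table An [otu_table()].
#' @param path Destination file.
#' @param dialect `"tsv-dense"` or `"triplet-sparse"` (nonzero cells only,
#'   row-major order).
#' @export
write_otu_table <- function(table, path,
                            dialect = c("tsv-dense", "triplet-sparse")) {
  dialect <- match.arg(dialect)
  v <- unclass(table)
  if (dialect == "tsv-dense") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(c("otu_id", colnames(v)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(v)), function(i)
      paste(c(rownames(v)[i], format_num(v[i, ])), collapse = "\t"), "")
    writeLines(body, con)
  } else {
    idx <- which(t(v) > 0)  # row-major over original matrix
    s_i <- ((idx - 1L) %% ncol(v)) + 1L
    o_i <- ((idx - 1L) %/% ncol(v)) + 1L
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines("otu_id\tsample_id\tcount", con)
    writeLines(paste(rownames(v)[o_i], colnames(v)[s_i],
                     format_num(t(v)[idx]), sep = "\t"), con)
  }
  invisible(path)
}

# Plain decimal formatting: integers stay integers, reals keep full precision.
format_num <- function(x) {
  out <- vapply(x, function(z) {
    if (is.finite(z) && z == round(z) && abs(z) < 2^53) sprintf("%.0f", z)
    else format(z, digits = 15, scientific = FALSE, trim = TRUE)
  }, "")
  out
}
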