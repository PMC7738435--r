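#' OTU count table
#'
#' Container for a 16S rRNA gene OTU-by-sample table of read counts with
#' per-OTU taxonomy lineage strings (SILVA-style, semicolon-delimited ranks).
#'
#' @param counts integer matrix of non-negative read counts, OTUs in rows,
#'   samples in columns; must carry unique rownames (OTU ids) and colnames
#'   (sample ids).
#' @param taxonomy character vector of lineage strings, one per OTU (empty
#'   string allowed). Recycled from `""` when omitted.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (character, named by OTU id).
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU ids as rownames and sample ids as colnames")
  if (is.null(taxonomy)) taxonomy <- rep("", nrow(counts))
  taxonomy <- as.character(taxonomy)
  names(taxonomy) <- rownames(counts)
  x <- structure(list(counts = counts, taxonomy = taxonomy),
                 class = "otu_table")
  validate_otu_table(x)
}

validate_otu_table <- function(x) {
  counts <- x$counts
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU id: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative count for OTU '", rownames(counts)[bad[1L, 1L]],
         "' in sample '", colnames(counts)[bad[1L, 2L]], "'")
  frac <- which(abs(counts - round(counts)) > 1e-9, arr.ind = TRUE)
  if (nrow(frac) > 0)
    stop("non-integer count for OTU '", rownames(counts)[frac[1L, 1L]],
         "' in sample '", colnames(counts)[frac[1L, 2L]], "'")
  storage.mode(x$counts) <- "double"  # counts can exceed .Machine$integer.max
  if (length(x$taxonomy) != nrow(counts))
    stop("taxonomy must have exactly one entry per OTU")
  x
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU count table: ", nrow(x$counts), " OTUs x ",
      ncol(x$counts), " samples, ", sum(x$counts), " reads total\n", sep = "")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Relative abundance table
#'
#' OTU-by-sample matrix of relative abundances (fractions in \[0, 1\]); every
#' sample column sums to 1 within 1e-9. Columns are whole-community fractions:
#' downstream mass-balance estimates depend on absolute relative abundance, so
#' subsetting operations never renormalize.
#'
#' @param p numeric matrix of fractions with OTU rownames and sample colnames.
#' @param taxonomy character vector of lineage strings, one per OTU.
#' @param normalized if `FALSE`, skip the column-sum check (used internally
#'   after filtering, which keeps original whole-community fractions).
#' @return An object of class `rel_abundance`: list with elements `p` and
#'   `taxonomy`.
#' @export
rel_abundance <- function(p, taxonomy = NULL, normalized = TRUE) {
  p <- as.matrix(p)
  if (is.null(rownames(p)) || is.null(colnames(p)))
    stop("p must have OTU ids as rownames and sample ids as colnames")
  if (any(p < 0) || any(p > 1)) stop("relative abundances must lie in [0, 1]")
  if (normalized) {
    s <- colSums(p)
    off <- which(abs(s - 1) > 1e-9)
    if (length(off) > 0)
      stop("sample column '", colnames(p)[off[1L]], "' sums to ",
           format(s[off[1L]]), ", not 1")
  }
  if (is.null(taxonomy)) taxonomy <- rep("", nrow(p))
  taxonomy <- as.character(taxonomy)
  names(taxonomy) <- rownames(p)
  structure(list(p = p, taxonomy = taxonomy), class = "rel_abundance")
}

#' @export
print.rel_abundance <- function(x, ...) {
  cat("Relative abundance table: ", nrow(x$p), " OTUs x ",
      ncol(x$p), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.rel_abundance <- function(x) dim(x$p)

#' Read an OTU table from disk
#'
#' Two dialects are supported. `tsv` is a tab-separated table whose header row
#' starts with an OTU-id column (conventionally `#OTU ID`), followed by one
#' column per sample, with taxonomy in the last column. `biom` is the JSON
#' BIOM 1.0 interchange format (read through the biomformat package).
#'
#' @param path file to read.
#' @param dialect `"tsv"` (default) or `"biom"`.
#' @param taxonomy_col name of the taxonomy column in the TSV dialect.
#' @return An [otu_table] with row/column order preserved from the file.
#' @export
read_otu_table <- function(path, dialect = c("tsv", "biom"),
                           taxonomy_col = "taxonomy") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, comment.char = "",
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2)
      stop("malformed header in '", path, "': need an OTU id column, ",
           "sample columns, and a '", taxonomy_col, "' column")
    has_tax <- names(df)[ncol(df)] == taxonomy_col
    if (has_tax) {
      taxonomy <- df[[ncol(df)]]
      df <- df[, -ncol(df), drop = FALSE]
    } else {
      taxonomy <- rep("", nrow(df))
    }
    if (ncol(df) < 2)
      stop("malformed header in '", path, "': no sample columns found")
    otu_ids <- df[[1L]]
    counts <- df[, -1L, drop = FALSE]
    num <- suppressWarnings(
      vapply(counts, as.numeric, numeric(nrow(counts))))
    num <- matrix(num, nrow = nrow(counts),
                  dimnames = list(otu_ids, names(counts)))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)
      stop("non-numeric count for OTU '", otu_ids[bad[1L, 1L]],
           "' in sample '", colnames(num)[bad[1L, 2L]], "'")
    }
    otu_table(num, taxonomy)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biom dialect requires the biomformat package")
    b <- biomformat::read_biom(path)
    counts <- as(biomformat::biom_data(b), "matrix")
    om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
    taxonomy <- rep("", nrow(counts))
    if (!is.null(om) && length(om) > 0) {
      om <- as.data.frame(om)
      tax <- apply(om, 1L, function(r) paste(r[!is.na(r) & r != ""],
                                             collapse = "; "))
      taxonomy <- unname(tax[rownames(counts)])
      taxonomy[is.na(taxonomy)] <- ""
    }
    otu_table(counts, taxonomy)
  }
}

#' Write an OTU table to disk
#'
#' @param x an [otu_table].
#' @param path output file.
#' @param dialect `"tsv"` or `"biom"` (JSON BIOM 1.0).
#' @param taxonomy_col taxonomy column name for the TSV dialect.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, dialect = c("tsv", "biom"),
                            taxonomy_col = "taxonomy") {
  stopifnot(inherits(x, "otu_table"))
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    hdr <- paste(c("#OTU ID", colnames(x$counts), taxonomy_col),
                 collapse = "\t")
    rows <- vapply(seq_len(nrow(x$counts)), function(i) {
      paste(c(rownames(x$counts)[i],
              format(x$counts[i, ], scientific = FALSE, trim = TRUE),
              x$taxonomy[i]), collapse = "\t")
    }, character(1L))
    writeLines(c(hdr, rows), path)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biom dialect requires the biomformat package")
    om <- data.frame(taxonomy = unname(x$taxonomy),
                     row.names = rownames(x$counts))
    b <- biomformat::make_biom(x$counts, observation_metadata = om)
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read per-sample metadata
#'
#' TSV with columns `sample_id`, `role` (one of inoculum/reactor/feed),
#' `day`, `replicate_group`, `condition`.
#'
#' @param path metadata file.
#' @return data.frame with validated columns.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(md)
}

validate_sample_metadata <- function(md) {
  need <- c("sample_id", "role", "day", "replicate_group", "condition")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1L])
  bad <- setdiff(unique(md$role), c("inoculum", "reactor", "feed"))
  if (length(bad) > 0)
    stop("unknown sample role(s): ", paste(bad, collapse = ", "))
  md$day <- as.numeric(md$day)
  md
}

#' Write per-sample metadata
#' @param md metadata data.frame (see [read_sample_metadata]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  md <- validate_sample_metadata(md)
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total read count.
#'
#' @param x an [otu_table].
#' @return A [rel_abundance] table; every column sums to 1 within 1e-9.
#' @export
to_relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  tot <- colSums(x$counts)
  zero <- which(tot == 0)
  if (length(zero) > 0)
    stop("sample '", colnames(x$counts)[zero[1L]],
         "' has zero total reads and cannot be normalized")
  p <- sweep(x$counts, 2L, tot, "/")
  rel_abundance(p, x$taxonomy)
}

#' Select dominant OTUs
#'
#' Keeps OTUs that pass either enabled criterion: maximum relative abundance
#' over samples above `any_sample_threshold`, or mean relative abundance over
#' samples (the pooled, equal-weight abundance) above `total_threshold`.
#' Setting a threshold to `NULL` disables that criterion. Retained fractions
#' are NOT renormalized: mass-balance growth rates need whole-community
#' fractions, and renormalizing after a subset would bias them.
#'
#' @param x a [rel_abundance] table.
#' @param any_sample_threshold fraction; OTU kept if `max(p) >` this in any
#'   sample. Default 0.02; `NULL` disables.
#' @param total_threshold fraction; OTU kept if `mean(p) >` this over all
#'   samples. Default 0.001; `NULL` disables.
#' @return A `rel_abundance` object holding the retained subset of the
#'   original fractions (columns generally sum to < 1).
#' @export
filter_dominant <- function(x, any_sample_threshold = 0.02,
                            total_threshold = 0.001) {
  stopifnot(inherits(x, "rel_abundance"))
  if (is.null(any_sample_threshold) && is.null(total_threshold))
    stop("enable at least one criterion")
  keep <- rep(FALSE, nrow(x$p))
  if (!is.null(any_sample_threshold)) {
    stopifnot(any_sample_threshold >= 0, any_sample_threshold <= 1)
    keep <- keep | apply(x$p, 1L, max) > any_sample_threshold
  }
  if (!is.null(total_threshold)) {
    stopifnot(total_threshold >= 0, total_threshold <= 1)
    keep <- keep | rowMeans(x$p) > total_threshold
  }
  rel_abundance(x$p[keep, , drop = FALSE], x$taxonomy[keep],
                normalized = FALSE)
}

#' Average replicate bottles
#'
#' Collapses the sample columns of each `replicate_group` to their arithmetic
#' mean. Averaging is done on relative abundances rather than raw counts so
#' that bottles with unequal sequencing depth contribute equally.
#'
#' @param x a [rel_abundance] table.
#' @param metadata metadata data.frame (see [read_sample_metadata]) covering
#'   every sample column of `x`.
#' @return A `rel_abundance` with one column per replicate group (named by
#'   group, first-appearance order); the per-column `role` is attached as
#'   attribute `"role"`.
#' @export
average_replicates <- function(x, metadata) {
  stopifnot(inherits(x, "rel_abundance"))
  metadata <- validate_sample_metadata(metadata)
  sids <- colnames(x$p)
  miss <- setdiff(sids, metadata$sample_id)
  if (length(miss) > 0)
    stop("sample(s) missing from metadata: ", paste(miss, collapse = ", "))
  md <- metadata[match(sids, metadata$sample_id), ]
  groups <- unique(md$replicate_group)
  cols <- matrix(0, nrow(x$p), length(groups),
                 dimnames = list(rownames(x$p), groups))
  roles <- character(length(groups))
  for (i in seq_along(groups)) {
    member <- md$replicate_group == groups[i]
    role <- unique(md$role[member])
    if (length(role) != 1L)
      stop("replicate group '", groups[i], "' mixes roles: ",
           paste(role, collapse = ", "))
    roles[i] <- role
    cols[, i] <- rowMeans(x$p[, member, drop = FALSE])
  }
  out <- rel_abundance(cols, x$taxonomy,
                       normalized = all(abs(colSums(x$p) - 1) <= 1e-9))
  attr(out, "role") <- stats::setNames(roles, groups)
  out
}
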