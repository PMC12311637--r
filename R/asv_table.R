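#' Construct an ASV table for one size fraction
#'
#' Bundles a samples x ASVs abundance matrix with per-sample metadata
#' (season, layer, station) and per-ASV annotation (taxonomy, trophic mode)
#' for one of the three size fractions.
#'
#' @param counts numeric matrix, samples in rows, ASVs in columns.
#'   Non-negative; integer counts or relative abundances.
#' @param fraction one of `"bacteria"`, `"pico"`, `"nano"`.
#' @param sample_data data.frame with one row per sample; typically columns
#'   `season`, `layer`, `station`. Row order must match `counts`.
#' @param asv_data data.frame with one row per ASV; typically columns
#'   `taxonomy` and (protists) `trophic_mode`. Row order matches columns of
#'   `counts`.
#' @param type `"counts"` or `"relative"`; set automatically by
#'   [relative_abundance()].
#'
#' @return An object of class `asv_table`: a list with elements `counts`,
#'   `fraction`, `sample_data`, `asv_data`, `type`, and `empty_samples`
#'   (ids of all-zero rows).
#' @export
asv_table <- function(counts, fraction = c("bacteria", "pico", "nano"),
                      sample_data = NULL, asv_data = NULL,
                      type = c("counts", "relative")) {
  fraction <- match.arg(fraction)
  type <- match.arg(type)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("abundances must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts))) stop("sample ids must be unique")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("ASV", seq_len(ncol(counts)))
  if (anyDuplicated(colnames(counts))) stop("ASV ids must be unique")
  if (!is.null(sample_data)) {
    sample_data <- as.data.frame(sample_data)
    if (nrow(sample_data) != nrow(counts))
      stop("sample_data rows must match count rows")
    rownames(sample_data) <- rownames(counts)
  }
  if (!is.null(asv_data)) {
    asv_data <- as.data.frame(asv_data)
    if (nrow(asv_data) != ncol(counts))
      stop("asv_data rows must match count columns")
    rownames(asv_data) <- colnames(counts)
  }
  structure(list(
    counts = counts, fraction = fraction,
    sample_data = sample_data, asv_data = asv_data, type = type,
    # per-sample totals at table creation; preserved through ASV filtering
    # so relative abundances always refer to the whole community
    row_totals = rowSums(counts),
    empty_samples = rownames(counts)[rowSums(counts) == 0]
  ), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table [%s]: %d samples x %d ASVs (%s)\n",
              x$fraction, nrow(x$counts), ncol(x$counts), x$type))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

# keep metadata (and original sample totals) consistent after subsetting
# columns (ASVs)
subset_asvs <- function(table, keep) {
  table$counts <- table$counts[, keep, drop = FALSE]
  if (!is.null(table$asv_data))
    table$asv_data <- table$asv_data[keep, , drop = FALSE]
  table
}

# totals to normalize against: the sample totals recorded when the table
# was created (before any ASV filtering), falling back to current row sums
sample_totals <- function(table) {
  if (!is.null(table$row_totals)) table$row_totals
  else rowSums(table$counts)
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each row by its sample total: the row sum recorded when the
#' table was created. For a freshly read table this is the plain row sum;
#' for a table that has been ASV-filtered it is the pre-filter total, so
#' relative abundances keep referring to the whole community. All-zero
#' samples are left as zero rows and recorded in `empty_samples`.
#'
#' @param table an [asv_table()].
#' @return The table with non-empty unfiltered rows summing to 1 and
#'   `type = "relative"`.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  if (table$type == "relative") return(table)
  rs <- sample_totals(table)
  out <- table$counts / ifelse(rs == 0, 1, rs)
  table$counts <- out
  table$type <- "relative"
  table$row_totals <- as.numeric(rs > 0)
  table$empty_samples <- rownames(out)[rs == 0]
  table
}

#' Hellinger transform of an abundance table
#'
#' Element-wise square root of relative abundances,
#' `sqrt(x_ij / rowsum_i)`; the standard pre-transform for Euclidean-based
#' ordination of community data. All-zero rows map to zero rows.
#'
#' @param table an [asv_table()] (counts or relative abundances).
#' @return A numeric matrix with the same dimnames; non-empty rows have
#'   unit Euclidean norm.
#' @export
hellinger_transform <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  rs <- rowSums(table$counts)
  sqrt(table$counts / ifelse(rs == 0, 1, rs))
}

#' Aggregate ASV columns by a shared label
#'
#' Sums abundance columns within a taxonomy rank or trophic-mode label,
#' preserving per-row totals, as used for stacked composition summaries.
#'
#' @param table an [asv_table()].
#' @param label column of `table$asv_data` to aggregate by (e.g. `"class"`,
#'   `"trophic_mode"`).
#' @param na_label label to use for ASVs with missing annotation.
#' @return An [asv_table()] whose columns are the unique labels.
#' @export
aggregate_by_label <- function(table, label, na_label = "unknown") {
  stopifnot(inherits(table, "asv_table"))
  if (is.null(table$asv_data) || !label %in% names(table$asv_data))
    stop("label column '", label, "' not present in asv_data")
  lab <- as.character(table$asv_data[[label]])
  lab[is.na(lab)] <- na_label
  groups <- unique(lab)
  agg <- sapply(groups, function(g)
    rowSums(table$counts[, lab == g, drop = FALSE]))
  agg <- matrix(agg, nrow = nrow(table$counts),
                dimnames = list(rownames(table$counts), groups))
  asv_table(agg, table$fraction, table$sample_data,
            asv_data = data.frame(label = groups), type = table$type)
}
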