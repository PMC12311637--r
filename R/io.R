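#' Write / read a numeric table as TSV
#'
#' Tab-separated with row names in the first column; lossless round trip
#' for counts and metadata tables.
#'
#' @param m matrix or data.frame.
#' @param path output file.
#' @export
write_tsv_matrix <- function(m, path) {
  df <- as.data.frame(m)
  df <- cbind(id = rownames(m), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @param as_matrix return a numeric matrix (default) or data.frame.
#' @export
read_tsv_matrix <- function(path, as_matrix = TRUE) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "id")
    stop("malformed header: expected first column 'id', found '",
         names(df)[1], "'")
  rn <- df$id
  df$id <- NULL
  if (as_matrix) {
    m <- as.matrix(df)
    rownames(m) <- rn
    m
  } else {
    rownames(df) <- rn
    df
  }
}

#' Read an ASV table and its annotation from TSV files
#'
#' @param counts_path samples x ASVs TSV (first column `id` = sample ids).
#' @param fraction size fraction label.
#' @param metadata_path optional per-sample metadata TSV.
#' @param taxonomy_path optional per-ASV annotation TSV.
#' @return an [asv_table()].
#' @export
read_asv_table <- function(counts_path, fraction, metadata_path = NULL,
                           taxonomy_path = NULL) {
  counts <- read_tsv_matrix(counts_path)
  meta <- if (!is.null(metadata_path))
    read_tsv_matrix(metadata_path, as_matrix = FALSE) else NULL
  tax <- if (!is.null(taxonomy_path))
    read_tsv_matrix(taxonomy_path, as_matrix = FALSE) else NULL
  if (!is.null(meta)) meta <- meta[rownames(counts), , drop = FALSE]
  if (!is.null(tax)) tax <- tax[colnames(counts), , drop = FALSE]
  asv_table(counts, fraction, sample_data = meta, asv_data = tax)
}

#' Write an ASV table (counts + metadata + annotation) as TSVs
#'
#' @param table an [asv_table()].
#' @param prefix path prefix; writes `<prefix>_counts.tsv` and, when
#'   present, `<prefix>_samples.tsv` and `<prefix>_asvs.tsv`.
#' @return character vector of written paths.
#' @export
write_asv_table <- function(table, prefix) {
  stopifnot(inherits(table, "asv_table"))
  paths <- paste0(prefix, "_counts.tsv")
  write_tsv_matrix(table$counts, paths)
  if (!is.null(table$sample_data)) {
    p <- paste0(prefix, "_samples.tsv")
    write_tsv_matrix(table$sample_data, p)
    paths <- c(paths, p)
  }
  if (!is.null(table$asv_data)) {
    p <- paste0(prefix, "_asvs.tsv")
    write_tsv_matrix(table$asv_data, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a network as GraphML and as a weighted edge-list TSV
#'
#' @param net a [cooccurrence_network()].
#' @param graphml_path output GraphML file (or `NULL` to skip).
#' @param edgelist_path output TSV file (or `NULL` to skip).
#' @return invisibly, the written paths.
#' @export
write_network <- function(net, graphml_path = NULL, edgelist_path = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  written <- character()
  if (!is.null(graphml_path)) {
    nodes <- net$nodes
    for (j in seq_along(nodes))
      if (!is.numeric(nodes[[j]])) {
        nodes[[j]] <- as.character(nodes[[j]])
        nodes[[j]][is.na(nodes[[j]])] <- "unknown"
      }
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(edgelist_path)) {
    write.table(net$edges, edgelist_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, edgelist_path)
  }
  invisible(written)
}

#' Read a network back from GraphML
#'
#' @param path GraphML file written by [write_network()].
#' @return a [cooccurrence_network()].
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as.data.frame(igraph::vertex_attr(g), stringsAsFactors = FALSE)
  names(nodes)[names(nodes) == "name"] <- "id"
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      weight = igraph::E(g)$weight,
                      abs_weight = igraph::E(g)$abs_weight,
                      stringsAsFactors = FALSE)
  cooccurrence_network(nodes[, c("id", setdiff(names(nodes), "id")),
                             drop = FALSE], edges)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
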