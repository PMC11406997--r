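# Plain-text interchange: TSV tables and long-format plate CSV. All files
# carry labels (cluster / genome / sample ids), never positional indices.

#' Read a clusters x genomes gene-cluster matrix from TSV
#'
#' Expects a header of genome ids and a first column of cluster ids.
#'
#' @param path TSV file path.
#' @return a [gene_cluster_matrix()].
#' @export
read_cluster_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  gene_cluster_matrix(m)
}

#' Write a gene-cluster matrix to TSV
#' @param matrix a [gene_cluster_matrix()] (or any matrix with dimnames).
#' @param path output path.
#' @export
write_cluster_matrix <- function(matrix, path) {
  df <- data.frame(cluster_id = rownames(matrix),
                   as.data.frame(unclass(matrix)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a gene-call count table with its design
#'
#' The count TSV holds gene calls in rows (first column ids) and samples
#' in columns; the design TSV has columns sample, condition, replicate.
#'
#' @param counts_path,design_path,lengths_path TSV paths; the lengths TSV
#'   has columns gene_call_id, length_bp.
#' @return list(counts, design, gene_lengths).
#' @export
read_count_table <- function(counts_path, design_path, lengths_path) {
  cdf <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf[[1]]
  storage.mode(counts) <- "integer"
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  stop_if_not(all(colnames(counts) %in% design$sample),
              "design is missing samples present in the count table")
  ldf <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  lengths <- stats::setNames(ldf$length_bp, ldf$gene_call_id)
  list(counts = counts, design = design, gene_lengths = lengths)
}

#' Write a generic data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read long-format plate-reader data
#'
#' CSV with columns well, time_h, channel, value, host, condition and
#' (for induction assays) inducer and inducer_conc.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_plate_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a hosts x clusters log2FC matrix to TSV
#' @param m matrix with host rownames and cluster colnames.
#' @param path output path.
#' @export
write_logfc_matrix <- function(m, path) {
  df <- data.frame(host = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a hosts x clusters log2FC matrix from TSV
#' @param path TSV path written by [write_logfc_matrix()].
#' @return numeric matrix.
#' @export
read_logfc_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
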