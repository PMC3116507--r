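# Reading and writing the standard formats the pipeline touches: FASTA
# (Biostrings), TSV tables, GFF3 exon records (rtracklayer when
# available), newick trees (ape), JSON reports (jsonlite).

#' Write protein or nucleotide sequences to FASTA
#'
#' @param seqs Named character vector, or tibble with `gene_id` and `seq`
#'   (protein) / `cds` (nucleotide) columns.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.data.frame(seqs)) {
    col <- if ("seq" %in% names(seqs)) "seq" else "cds"
    seqs <- stats::setNames(seqs[[col]], seqs$gene_id)
  }
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write the taxon table
#'
#' @param taxa Tibble `species_id`, `group`, `domain`.
#' @param path Output TSV path.
#' @export
write_taxa_tsv <- function(taxa, path) {
  utils::write.table(taxa, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a taxon table
#'
#' @param path TSV with `species_id`, `group`, `domain`.
#' @return Tibble.
#' @export
read_taxa_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write exon records as GFF3
#'
#' Uses rtracklayer when installed; records are `exon` features with
#' 1-based inclusive coordinates and `Parent` set to the gene id.
#'
#' @param gene_models Tibble from [implant_hgt()] (`seqid`, `start`,
#'   `end`, `strand`, `gene_id`, `exon_number`).
#' @param path Output path.
#' @export
write_gff3 <- function(gene_models, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to write GFF3")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = gene_models$seqid,
    ranges = IRanges::IRanges(gene_models$start, gene_models$end),
    strand = gene_models$strand, type = gene_models$type,
    source = gene_models$source, Parent = gene_models$gene_id,
    ID = paste0(gene_models$gene_id, ".exon", gene_models$exon_number))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read exon records from GFF3
#'
#' @param path GFF3 path.
#' @return Tibble in the same shape [write_gff3()] consumes.
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GFF3")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  m <- as.data.frame(gr)
  parent <- vapply(m$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  tibble::tibble(seqid = as.character(m$seqnames), source = m$source,
                 type = as.character(m$type), start = m$start, end = m$end,
                 strand = as.character(m$strand), gene_id = parent,
                 exon_number = seq_along(parent))
}

#' Write a hit table as TSV
#'
#' Columns follow the familiar tabular BLAST layout (query, subject,
#' percent identity, E-value, bit score, coverage) plus the species and
#' group labels the screen uses.
#'
#' @param hits Tibble from [best_hits()].
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a supported tree to newick
#'
#' Support percentages appear as internal-node labels.
#'
#' @param bs A [bootstrap_support()] result (or a `phylo`).
#' @param path Output path.
#' @export
write_tree <- function(bs, path) {
  tree <- if (inherits(bs, "phylo")) bs else bs$tree
  ape::write.tree(tree, path)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param expr Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expr_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with a `gene_id` column and one column per sample.
#' @return Numeric matrix.
#' @export
read_expr_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
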