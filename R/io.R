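# Readers and writers for the pipeline's on-disk formats: annotation TSV or
# GFF3, expression TSV + sample map, promoter FASTA, BED6 peak sets, binned
# tag tracks, and the bundled published worked-example tables.

#' Read a gene annotation table
#'
#' TSV input must have columns `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' GFF3 input (`format = "gff3"`) is converted on read: records of type
#' `gene` are used, the TSS is the 5' end of the gene (converted from
#' 1-based closed to 0-based), and for genes with several records the
#' 5'-most TSS per gene id is kept (with a message).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff3"`.
#' @return data.frame `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_annotation <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(ann)))
      stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
    return(ann[, need])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  plus <- as.character(GenomicRanges::strand(gr)) != "-"
  ann <- data.frame(
    gene_id = if (!is.null(gr$ID)) as.character(gr$ID)
              else as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(plus, GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr) - 1L),
    strand = ifelse(plus, "+", "-"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$gene_id)) {
    message("multiple records per gene id; keeping the 5'-most TSS")
    o <- order(ann$gene_id, ifelse(ann$strand == "+", 1, -1) * ann$tss)
    ann <- ann[o, ][!duplicated(ann$gene_id[o]), , drop = FALSE]
  }
  rownames(ann) <- NULL
  ann
}

#' Read a log2 expression matrix and its sample map
#'
#' @param expr_path TSV with gene ids in the first column and one column per
#'   sample.
#' @param map_path TSV with columns `sample_id`, `condition`.
#' @return list `matrix`, `sample_map`.
#' @export
read_expression <- function(expr_path, map_path) {
  df <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate gene ids in expression table")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (anyNA(mat)) stop("expression matrix contains missing values")
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(map)))
    stop("sample map needs columns sample_id, condition")
  list(matrix = mat, sample_map = map)
}

#' Read promoter sequences from FASTA
#' @param path FASTA file, one record per gene, id = gene id.
#' @return named character vector.
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", path)
  stats::setNames(as.character(ss), ids)
}

#' Write promoter sequences to FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_promoters <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a BED6 peak file
#' @param path BED file.
#' @return data.frame `chrom`, `start` (0-based), `end`, `name`, `score`,
#'   `strand`.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               sprintf("peak_%05d", seq_along(gr)),
             score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
             strand = {
               s <- as.character(GenomicRanges::strand(gr))
               ifelse(s == "*", ".", s)
             },
             stringsAsFactors = FALSE)
}

#' Write a BED6 peak file
#' @param peaks data.frame `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open).
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   if (!is.null(peaks$name)) peaks$name else ".",
                   if (!is.null(peaks$score)) peaks$score else 0,
                   if (!is.null(peaks$strand)) peaks$strand else ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete simulated dataset to a directory
#'
#' Emits annotation.tsv, expression.tsv, sample_map.tsv, promoters.fa,
#' peaks_<condition>.bed, truth.tsv, terms.tsv, term_labels.tsv and
#' pwms.jaspar.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_tsv(sim$annotation, fp("annotation.tsv"))
  expr <- data.frame(gene_id = rownames(sim$expression$matrix),
                     sim$expression$matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, fp("expression.tsv"))
  write_tsv(sim$expression$sample_map, fp("sample_map.tsv"))
  write_promoters(sim$promoters$sequences, fp("promoters.fa"))
  for (cond in names(sim$binding$peaks))
    write_peaks_bed(sim$binding$peaks[[cond]],
                    fp(sprintf("peaks_%s.bed", cond)))
  write_tsv(sim$truth, fp("truth.tsv"))
  write_tsv(sim$terms$annotations, fp("terms.tsv"))
  write_tsv(sim$terms$labels, fp("term_labels.tsv"))
  write_jaspar(sim$pwms, fp("pwms.jaspar"))
  invisible(dir)
}

#' Published worked-example panel: TNF-upregulated genes with kB motifs and
#' HSF1 binding sites
#'
#' The 27-gene panel reported in a published study of TNF-alpha/heat-shock
#' cross talk in human U-2 OS osteosarcoma cells: each TNF-upregulated gene
#' whose proximal promoter carries a kB motif and whose regulatory region
#' carries heat-shock-induced HSF1 binding, with its direction of regulation
#' by heat shock alone (`hs_call`), the printed HS_TNF/TNF signal ratio, and
#' the printed combined-effect label (O = antagonistic, A = co-activation,
#' blank = unaffected).
#'
#' @return data.frame `gene_id`, `hs_call`, `ratio_hstnf_vs_tnf`, `label`.
#' @export
published_panel <- function() {
  path <- system.file("extdata", "tnf_up_kb_hsf1_panel.tsv",
                      package = "stressxtalk", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
}

#' Published gene-category counts
#'
#' Genome-wide counts from the same published study (detected genes,
#' TNF- and HS-modulated genes, motif-positive and HSF1-bound subsets, and
#' the combined-effect mode counts among TNF-modulated genes), used as the
#' worked example for the percentage-reporting layer.
#'
#' @return data.frame `quantity`, `k`, `n`.
#' @export
published_counts <- function() {
  path <- system.file("extdata", "published_counts.tsv",
                      package = "stressxtalk", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
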