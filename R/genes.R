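#' Read gene annotation
#'
#' Accepts either a GTF file (gene_id-attribute dialect; coordinates
#' 1-based inclusive, converted on read) or a tab-separated gene table with
#' header `gene_id  contig  strand  start  end  [rpkm]` whose coordinates
#' are already 0-based half-open. Internally all coordinates are 0-based
#' half-open. The TSS of a `+` strand gene is `start`; for a `-` strand
#' gene it is `end - 1` (the last base of the interval); the TTS is the
#' symmetric opposite.
#'
#' When an expression table is supplied, genes without an entry get
#' `rpkm = 0` (and therefore land in the lowest expression quintile, where
#' silent and rarely expressed genes belong).
#'
#' @param path GTF file or TSV gene table.
#' @param expression optional expression table: a data.frame with columns
#'   `gene_id` and `rpkm`, or a path to a TSV with that header.
#' @param genome optional [genome] against which coordinates are validated.
#' @return data.frame with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end`, `rpkm`, in file order.
#' @export
read_genes <- function(path, expression = NULL, genome = NULL) {
  if (!file.exists(path)) stop("gene annotation file not found: ", path)
  first <- readLines(path, n = 1L)
  genes <- if (grepl("gene_id", first) && grepl("\t", first) &&
               !grepl("\t(gene|transcript|exon|CDS)\t", first)) {
    read_genes_tsv(path)
  } else {
    read_genes_gtf(path)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    bad <- which(!(genes$strand %in% c("+", "-")))[1L]
    stop("gene ", genes$gene_id[bad], ": strand must be '+' or '-'")
  }
  if (any(genes$start >= genes$end)) {
    bad <- which(genes$start >= genes$end)[1L]
    stop("gene ", genes$gene_id[bad], ": start must be < end")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  }
  if (!is.null(expression)) {
    if (is.character(expression)) {
      expression <- utils::read.delim(expression, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("gene_id", "rpkm") %in% names(expression)))
    idx <- match(genes$gene_id, expression$gene_id)
    genes$rpkm <- ifelse(is.na(idx), 0, expression$rpkm[idx])
  }
  if (any(genes$rpkm < 0)) stop("rpkm values must be non-negative")
  if (!is.null(genome)) {
    check_intervals(genes$contig, genes$start, genes$end, genome, "gene")
  }
  genes
}

read_genes_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  need <- c("gene_id", "contig", "strand", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$rpkm)) tab$rpkm <- 0
  bad <- which(is.na(tab$start) | is.na(tab$end))
  if (length(bad)) {
    stop("malformed gene table line ", bad[1L] + 1L, " in ", path)
  }
  data.frame(gene_id = as.character(tab$gene_id),
             contig = as.character(tab$contig),
             strand = as.character(tab$strand),
             start = as.integer(tab$start), end = as.integer(tab$end),
             rpkm = as.numeric(tab$rpkm), stringsAsFactors = FALSE)
}

read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) stop("GTF lacks gene_id attributes: ", path)
  # prefer explicit gene records; otherwise aggregate features per gene_id
  if (!is.null(md$type) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  id <- as.character(md$gene_id)
  first_idx <- !duplicated(id)
  ord_ids <- id[first_idx]
  start0 <- tapply(BiocGenerics::start(gr) - 1L, id, min)[ord_ids]
  end0 <- tapply(BiocGenerics::end(gr), id, max)[ord_ids]
  contig <- as.character(GenomicRanges::seqnames(gr))[first_idx]
  strand <- as.character(BiocGenerics::strand(gr))[first_idx]
  data.frame(gene_id = ord_ids, contig = contig, strand = strand,
             start = as.integer(start0), end = as.integer(end0),
             rpkm = 0, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a gene table to TSV
#'
#' Writes the 0-based half-open gene table format read back by
#' [read_genes()].
#'
#' @param genes gene data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(
    genes[, c("gene_id", "contig", "strand", "start", "end", "rpkm")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Anchor coordinates of genes
#'
#' Returns the 0-based genomic coordinate of the transcriptional start site
#' (TSS) or termination site (TTS) of each gene, respecting strand: a `-`
#' strand gene starts at `end - 1` and terminates at `start`.
#'
#' @param genes gene data.frame.
#' @param anchor `"TSS"` or `"TTS"`.
#' @return Integer vector of anchor positions, one per gene.
#' @export
gene_anchors <- function(genes, anchor = c("TSS", "TTS")) {
  anchor <- match.arg(anchor)
  plus <- genes$strand == "+"
  if (anchor == "TSS") {
    ifelse(plus, genes$start, genes$end - 1L)
  } else {
    ifelse(plus, genes$end - 1L, genes$start)
  }
}
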