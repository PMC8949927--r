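#' Construct a gene annotation table
#'
#' Minimal gene annotation: unique ids, 1-based closed coordinates and a
#' biotype from the interval census (protein-coding genes, predicted gene
#' models, miRNAs, Riken cDNA genes).
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome id.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param biotype One of `"coding"`, `"gene_model"`, `"miRNA"`, `"riken"`.
#' @return A `gene_annotation` data.frame.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, biotype) {
  n <- length(gene_id)
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = rep_len(as.character(chrom), n),
                    start = as.numeric(start), end = as.numeric(end),
                    biotype = rep_len(as.character(biotype), n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) stop("gene ids must be unique")
  if (any(out$start > out$end)) stop("gene start must be <= end")
  if (!all(out$biotype %in% c("coding", "gene_model", "miRNA", "riken")))
    stop("unknown biotype")
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' @keywords internal
annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(annotation$chrom,
                         IRanges::IRanges(annotation$start, annotation$end,
                                          names = annotation$gene_id))
}

#' Write a gene annotation as BED (coordinates converted to 0-based
#' half-open on write) or GFF3 (biotype kept in the `type`-level attributes)
#'
#' @param annotation A [gene_annotation()].
#' @param path Output path; format picked by extension unless `format` given.
#' @param format `"bed"` or `"gff3"`.
#' @export
write_annotation <- function(annotation, path,
                             format = tools::file_ext(path)) {
  gr <- annotation_granges(annotation)
  format <- tolower(format)
  if (format == "bed") {
    rtracklayer::export(gr, path, format = "BED")
  } else if (format %in% c("gff3", "gff")) {
    gr$type <- "gene"
    gr$ID <- annotation$gene_id
    gr$biotype <- annotation$biotype
    rtracklayer::export(gr, path, format = "GFF3")
  } else stop("unsupported annotation format: ", format)
  invisible(path)
}

#' Read a gene annotation written by [write_annotation()]
#'
#' BED files carry no biotype, so it is reported as `NA` there.
#'
#' @param path Input path.
#' @param format `"bed"` or `"gff3"`.
#' @return A [gene_annotation()] (biotype `"gene_model"` placeholder for BED).
#' @export
read_annotation <- function(path, format = tools::file_ext(path)) {
  format <- tolower(format)
  gr <- rtracklayer::import(path, format = ifelse(format == "bed",
                                                  "BED", "GFF3"))
  id <- if (!is.null(gr$ID)) gr$ID else gr$name
  biotype <- if (!is.null(gr$biotype)) gr$biotype else "gene_model"
  gene_annotation(id, as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr), GenomicRanges::end(gr), biotype)
}
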