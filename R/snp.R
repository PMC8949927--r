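#' Construct a two-strain SNP catalog
#'
#' A catalog of biallelic SNPs with the homozygous allele carried by each of
#' two inbred strains (A and B). A site is *discordant* when the two strain
#' alleles differ; discordant-SNP density is what the haplotype-window filter
#' consumes.
#'
#' @param chrom Chromosome id (recycled scalar or vector).
#' @param pos 1-based positions, strictly increasing within the catalog.
#' @param ref,alt Reference/alternate alleles (single nucleotides).
#' @param allele_a,allele_b Allele carried by strain A / strain B; each must
#'   equal `ref` or `alt` at that site.
#' @return A `snp_catalog` data.frame.
#' @export
snp_catalog <- function(chrom, pos, ref, alt, allele_a, allele_b) {
  n <- length(pos)
  out <- data.frame(chrom = rep_len(as.character(chrom), n),
                    pos = as.numeric(pos), ref = ref, alt = alt,
                    allele_a = allele_a, allele_b = allele_b,
                    stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  if (!all(unlist(out[c("ref", "alt", "allele_a", "allele_b")]) %in% bases))
    stop("alleles must be single nucleotides (A/C/G/T)")
  if (any(out$ref == out$alt)) stop("ref and alt must differ")
  if (is.unsorted(out$pos, strictly = TRUE))
    stop("positions must be strictly increasing")
  with(out, if (!all((allele_a == ref | allele_a == alt) &
                     (allele_b == ref | allele_b == alt)))
    stop("strain alleles must match ref or alt"))
  class(out) <- c("snp_catalog", "data.frame")
  out
}

#' Generate a SNP catalog with a declared block structure
#'
#' Places SNPs window by window over `[start, end)`. Windows inside a
#' declared layout block receive strictly more discordant SNPs than the
#' block's declared density; all other windows receive strictly fewer than
#' `background`. Trailing partial windows are scaled by their width. A
#' constant rate of concordant SNPs (both strains carry the alternate
#' allele) is added everywhere so total and discordant counts differ.
#'
#' Block boundaries must align to the window grid anchored at `start`; this
#' keeps the per-window guarantee exact rather than probabilistic.
#'
#' @param chrom Chromosome id.
#' @param start,end Region bounds in bp, half-open `[start, end)`.
#' @param blocks `data.frame(start, end, density)`: non-overlapping
#'   subintervals and the discordant-SNP density (per full window) each must
#'   strictly exceed. May have zero rows.
#' @param background Discordant density ceiling outside blocks (strict).
#' @param concordant Mean concordant SNPs per full window.
#' @param window_size Window width in bp (default 250 kb).
#' @param seed Integer seed.
#' @return A [snp_catalog()].
#' @export
make_snp_catalog <- function(chrom, start, end, blocks,
                             background = 40, concordant = 80,
                             window_size = 250000, seed = 1L) {
  stopifnot(end > start, window_size > 0)
  if (nrow(blocks) > 0) {
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    if (any(blocks$end[-nrow(blocks)] > blocks$start[-1]))
      stop("layout blocks overlap")
    if (any(blocks$start < start | blocks$end > end))
      stop("layout blocks outside region")
    if (any((blocks$start - start) %% window_size != 0) ||
        any(blocks$end != end & (blocks$end - start) %% window_size != 0))
      stop("block boundaries must align to the window grid")
  }
  set.seed(seed)
  n_win <- ceiling((end - start) / window_size)
  ws <- start + (seq_len(n_win) - 1) * window_size
  we <- pmin(ws + window_size, end)
  frac <- (we - ws) / window_size

  dens <- rep(NA_real_, n_win)
  for (i in seq_len(nrow(blocks)))
    dens[ws >= blocks$start[i] & we <= blocks$end[i]] <- blocks$density[i]

  pos <- integer(0); disc <- logical(0)
  for (k in seq_len(n_win)) {
    n_d <- if (is.na(dens[k])) {
      max(0L, floor(background * frac[k]) - 1L - stats::rpois(1, 2))
    } else {
      floor(dens[k] * frac[k]) + 1L + stats::rpois(1, 3)
    }
    n_c <- stats::rpois(1, concordant * frac[k])
    n_tot <- n_d + n_c
    if (n_tot == 0) next
    if (n_tot > we[k] - ws[k]) stop("window too small for requested density")
    p <- sort(sample.int(we[k] - ws[k], n_tot)) + ws[k] - 1L
    d <- rep(c(TRUE, FALSE), c(n_d, n_c))[sample.int(n_tot)]
    pos <- c(pos, p); disc <- c(disc, d)
  }
  n <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  # discordant: strain A keeps ref, strain B carries alt; concordant: both alt
  snp_catalog(chrom, pos, ref, alt,
              allele_a = ifelse(disc, ref, alt), allele_b = alt)
}

#' Write a SNP catalog as a minimal two-sample VCF 4.2
#'
#' One GT column per strain; discordant sites come out as `0/0` vs `1/1`.
#'
#' @param catalog A [snp_catalog()].
#' @param path Output file path.
#' @param strains Column names for strain A and strain B.
#' @export
write_snp_vcf <- function(catalog, path, strains = c("B6", "NZO")) {
  gt <- function(allele) ifelse(allele == catalog$ref, "0/0", "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(catalog$chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", strains), collapse = "\t"))
  body <- paste(catalog$chrom, format(catalog$pos, scientific = FALSE,
                                      trim = TRUE),
                sprintf("snp%06d", seq_len(nrow(catalog))),
                catalog$ref, catalog$alt, ".", "PASS", ".", "GT",
                gt(catalog$allele_a), gt(catalog$allele_b), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal two-sample VCF back into a SNP catalog
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @param strains Names of the two sample columns to use as strain A / B;
#'   defaults to the first two samples in the file.
#' @return A [snp_catalog()].
#' @export
read_snp_vcf <- function(path, strains = NULL) {
  v <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(v)$GT
  if (is.null(strains)) strains <- colnames(g)[1:2]
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(rr$REF)
  alt <- as.character(unlist(rr$ALT))
  pick <- function(s) ifelse(g[, s] %in% c("1/1", "1|1"), alt, ref)
  snp_catalog(as.character(GenomicRanges::seqnames(rr)),
              GenomicRanges::start(rr), ref, alt,
              pick(strains[1]), pick(strains[2]))
}
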