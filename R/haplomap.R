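#' Count SNPs in fixed windows over an interval
#'
#' Tiles `[start, end)` into half-open windows of `window_size` bp anchored
#' at `start` (the final window may be partial) and counts, per window, the
#' total SNPs and the strain-discordant SNPs of the catalog. A SNP sitting
#' exactly on a window boundary belongs to the right-hand window.
#'
#' @param catalog A [snp_catalog()].
#' @param chrom Chromosome of the interval.
#' @param start,end Interval bounds in bp, half-open.
#' @param window_size Window width in bp (default 250 kb).
#' @return A `snp_window_profile` data.frame with columns `window`,
#'   `start`, `end`, `n_total`, `n_discordant`, `polymorphic` (`NA` until
#'   [call_polymorphic()] is applied).
#' @export
window_counts <- function(catalog, chrom, start, end, window_size = 250000) {
  stopifnot(window_size > 0)
  if (end <= start)
    return(structure(data.frame(window = integer(), start = numeric(),
                                end = numeric(), n_total = integer(),
                                n_discordant = integer(),
                                polymorphic = logical()),
                     class = c("snp_window_profile", "data.frame")))
  n_win <- ceiling((end - start) / window_size)
  ws <- start + (seq_len(n_win) - 1) * window_size
  we <- pmin(ws + window_size, end)
  inside <- catalog$chrom == chrom & catalog$pos >= start & catalog$pos < end
  k <- floor((catalog$pos[inside] - start) / window_size) + 1
  disc <- catalog$allele_a[inside] != catalog$allele_b[inside]
  out <- data.frame(window = seq_len(n_win), start = ws, end = we,
                    n_total = tabulate(k, n_win),
                    n_discordant = tabulate(k[disc], n_win),
                    polymorphic = NA)
  class(out) <- c("snp_window_profile", "data.frame")
  out
}

#' Flag polymorphic windows and merge them into haplotype blocks
#'
#' A window is called polymorphic when its discordant-SNP count exceeds the
#' threshold (default 100 per 250 kb window, strict `>`; set `strict =
#' FALSE` for `>=`). Maximal runs of consecutive polymorphic windows are
#' merged into haplotype blocks.
#'
#' @param profiles Output of [window_counts()].
#' @param threshold Discordant-SNP count threshold (>= 0).
#' @param strict Use strict `>` (default) rather than `>=`.
#' @return A list with `profiles` (the input with `polymorphic` filled) and
#'   `blocks` (data.frame `start`, `end` in bp, `first_window`,
#'   `last_window`, `n_discordant`).
#' @export
call_polymorphic <- function(profiles, threshold = 100, strict = TRUE) {
  if (threshold < 0) stop("threshold must be >= 0")
  flag <- if (strict) profiles$n_discordant > threshold
          else profiles$n_discordant >= threshold
  profiles$polymorphic <- flag
  blocks <- data.frame(start = numeric(), end = numeric(),
                       first_window = integer(), last_window = integer(),
                       n_discordant = integer())
  if (any(flag)) {
    r <- rle(flag)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1
    for (i in which(r$values)) {
      idx <- lo[i]:hi[i]
      blocks[nrow(blocks) + 1, ] <-
        list(profiles$start[lo[i]], profiles$end[hi[i]],
             profiles$window[lo[i]], profiles$window[hi[i]],
             sum(profiles$n_discordant[idx]))
    }
  }
  list(profiles = profiles, blocks = blocks)
}

#' Filter genes to those overlapping a polymorphic window
#'
#' A gene is retained when its closed `[start, end]` span overlaps at least
#' one base of a polymorphic (flagged) window; windows are half-open, so a
#' window `[ws, we)` is treated as covering `ws .. we - 1`.
#'
#' @param annotation A [gene_annotation()].
#' @param profiles Flagged profiles from [call_polymorphic()] (either the
#'   returned list or its `profiles` element).
#' @return The retained subset of `annotation`.
#' @export
filter_genes <- function(annotation, profiles) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- profiles$profiles
  if (any(is.na(profiles$polymorphic)))
    stop("run call_polymorphic() before filter_genes()")
  poly <- profiles[profiles$polymorphic, , drop = FALSE]
  if (nrow(poly) == 0) return(annotation[integer(0), , drop = FALSE])
  hits <- IRanges::overlapsAny(
    IRanges::IRanges(annotation$start, annotation$end),
    IRanges::IRanges(poly$start, poly$end - 1))
  annotation[hits, , drop = FALSE]
}
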