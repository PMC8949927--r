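#' Construct a two-group expression set
#'
#' Genes x samples matrix of non-negative normalized intensities with a
#' two-level group label per sample (e.g. B6 vs NZO islets).
#'
#' @param mat Numeric matrix, rownames = gene ids (unique), colnames =
#'   sample ids.
#' @param groups Character/factor vector of length `ncol(mat)` with exactly
#'   two levels and at least two samples per level.
#' @param contrast Optional contrast name.
#' @return An `expression_set` list with `mat`, `groups`, `contrast`.
#' @export
expression_set <- function(mat, groups, contrast = "contrast") {
  stopifnot(is.matrix(mat), ncol(mat) == length(groups))
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("mat must have unique gene-id rownames")
  if (any(mat < 0)) stop("expression intensities must be non-negative")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  structure(list(mat = mat, groups = groups, contrast = contrast),
            class = "expression_set")
}

#' Per-gene log2 fold change and Welch p-value
#'
#' `LFC = mean(log2(x + c))` in group 1 minus group 2 (group 1 = first
#' factor level), with pseudocount `c = 1` by default; the p-value is a
#' Welch two-sided t-test on the same log2 values. A gene that is zero in
#' all samples gets LFC 0, p 1.
#'
#' @param expr An [expression_set()].
#' @param genes Genes to test (default: all).
#' @param pseudocount Pseudocount added before log2.
#' @param lfc_threshold Threshold used to fill the `pass` flag
#'   (`|LFC| > threshold`, strict).
#' @return A `de_result` data.frame: `gene_id`, `lfc`, `p`, `pass`.
#' @export
compute_lfc <- function(expr, genes = rownames(expr$mat), pseudocount = 1,
                        lfc_threshold = 1) {
  stopifnot(inherits(expr, "expression_set"))
  missing <- setdiff(genes, rownames(expr$mat))
  if (length(missing)) stop("genes not in matrix: ",
                            paste(missing, collapse = ", "))
  g1 <- expr$groups == levels(expr$groups)[1]
  lx <- log2(expr$mat[genes, , drop = FALSE] + pseudocount)
  lfc <- rowMeans(lx[, g1, drop = FALSE]) - rowMeans(lx[, !g1, drop = FALSE])
  p <- vapply(seq_along(genes), function(i) {
    a <- lx[i, g1]; b <- lx[i, !g1]
    if (all(c(a, b) == 0)) return(1)
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  lfc[vapply(seq_along(genes),
             function(i) all(lx[i, ] == 0), logical(1))] <- 0
  out <- data.frame(gene_id = genes, lfc = unname(lfc), p = p,
                    pass = abs(unname(lfc)) > lfc_threshold)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Filter genes by absolute log2 fold change
#'
#' Retains genes with `|LFC| > threshold` (strict by default, matching a
#' literal "LFC > +/-1" rule; set `strict = FALSE` for `>=`).
#'
#' @param results A `de_result` from [compute_lfc()].
#' @param threshold Positive LFC threshold (default 1).
#' @param strict Strict inequality (default TRUE).
#' @return Character vector of passing gene ids.
#' @export
de_filter <- function(results, threshold = 1, strict = TRUE) {
  if (threshold <= 0) stop("threshold must be > 0")
  keep <- if (strict) abs(results$lfc) > threshold
          else abs(results$lfc) >= threshold
  results$gene_id[keep]
}

#' qPCR relative expression by the 2^(-dCt) method
#'
#' Relative expression of a target gene versus a reference gene (e.g. Actb,
#' Eef2 or Tbp): `2^-(Ct_target - Ct_reference)` per sample. Samples with a
#' missing reference Ct are dropped with a warning.
#'
#' @param ct Data frame with columns `sample`, `ct_target`, `ct_reference`.
#' @return Data frame `sample`, `dct`, `rel_expr`.
#' @export
ddct <- function(ct) {
  stopifnot(all(c("sample", "ct_target", "ct_reference") %in% names(ct)))
  drop <- is.na(ct$ct_reference)
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) with missing reference Ct")
    ct <- ct[!drop, , drop = FALSE]
  }
  if (any(ct$ct_target <= 0 | ct$ct_reference <= 0, na.rm = TRUE))
    stop("Ct values must be positive")
  dct <- ct$ct_target - ct$ct_reference
  data.frame(sample = ct$sample, dct = dct, rel_expr = 2^(-dct))
}

#' Assemble the candidate-evidence cascade
#'
#' One row per annotated interval gene with the boolean filter cascade:
#' inside the critical interval, overlapping a polymorphic haplotype block,
#' differentially expressed in the parental contrast, differentially
#' expressed in the congenic contrast. Final candidates are the intersection
#' of all four. The ob/ob contrast flag and the single-cell top cluster are
#' attached as annotations, not filters.
#'
#' @param annotation [gene_annotation()] of the interval genes.
#' @param polymorphic_genes,de_parental,de_congenic,de_obob Character
#'   vectors of gene ids; each must be a subset of the annotation.
#' @param sc_top_cluster Optional named character vector gene -> cluster of
#'   maximal single-cell expression.
#' @return A `candidate_evidence` data.frame sorted by gene id.
#' @export
build_cascade <- function(annotation, polymorphic_genes, de_parental,
                          de_congenic, de_obob = character(),
                          sc_top_cluster = NULL) {
  ids <- annotation$gene_id
  for (nm in c("polymorphic_genes", "de_parental", "de_congenic",
               "de_obob")) {
    extra <- setdiff(get(nm), ids)
    if (length(extra))
      stop("genes in ", nm, " absent from the interval annotation: ",
           paste(extra, collapse = ", "))
  }
  out <- data.frame(
    gene_id = ids,
    in_interval = TRUE,
    in_polymorphic_block = ids %in% polymorphic_genes,
    de_parental = ids %in% de_parental,
    de_congenic = ids %in% de_congenic,
    de_obob = ids %in% de_obob,
    stringsAsFactors = FALSE)
  out$sc_top_cluster <- if (is.null(sc_top_cluster)) NA_character_
                        else unname(sc_top_cluster[ids])
  out$final_candidate <- out$in_interval & out$in_polymorphic_block &
    out$de_parental & out$de_congenic
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(!out$final_candidate |
                  (out$in_polymorphic_block & out$de_parental &
                     out$de_congenic)))
  class(out) <- c("candidate_evidence", "data.frame")
  out
}
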