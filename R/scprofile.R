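#' Canonical islet cluster labels
#'
#' Alpha, delta and gamma cells plus the six beta-cell clusters, including
#' the proliferating `BetaP` cluster defined by high Mki67.
#' @export
islet_clusters <- function() {
  c("Alpha", "Delta", "Gamma", "Beta1", "Beta2", "Beta3", "Beta4", "BetaP")
}

#' Construct a cell-by-gene count container
#'
#' @param counts Cells x genes matrix (base or `Matrix`) of non-negative
#'   integer counts; colnames = gene ids, rownames = cell barcodes.
#' @param clusters Cluster label per cell.
#' @return A `cell_matrix` list with `counts`, `clusters`, and `norm`
#'   (`NULL` until [normalize_cells()]).
#' @export
cell_matrix <- function(counts, clusters) {
  stopifnot(nrow(counts) == length(clusters))
  if (is.null(colnames(counts))) stop("counts must have gene colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(is.na(clusters))) stop("every cell must carry a cluster label")
  structure(list(counts = counts, clusters = as.character(clusters),
                 norm = NULL), class = "cell_matrix")
}

#' Total-count normalization with log transform
#'
#' Scales each cell to `target` total counts and applies `log1p`, the
#' standard library-size normalization of droplet scRNA toolchains. Cells
#' with zero total counts are dropped with a warning.
#'
#' @param cells A [cell_matrix()].
#' @param target Per-cell total after scaling (default 10 000).
#' @return The input with `norm` filled (and zero-total cells removed).
#' @export
normalize_cells <- function(cells, target = 1e4) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (nrow(cells$counts) == 0) stop("empty cell matrix")
  tot <- Matrix::rowSums(cells$counts)
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0), " cell(s) with zero total counts")
    cells$counts <- cells$counts[tot > 0, , drop = FALSE]
    cells$clusters <- cells$clusters[tot > 0]
    tot <- tot[tot > 0]
  }
  cells$norm <- log1p(as.matrix(cells$counts) * (target / tot))
  cells
}

#' Dot-plot statistics per cluster and gene
#'
#' For each requested (cluster, gene) pair: the fraction of cells with a
#' raw count > 0 and the mean normalized expression — the two quantities a
#' dot plot encodes as dot size and color.
#'
#' @param cells A normalized [cell_matrix()] (see [normalize_cells()]).
#' @param genes Genes to profile (must be present).
#' @param clusters Clusters to profile (default: all observed, in
#'   [islet_clusters()] order where applicable).
#' @return A `dotplot_table` data.frame: `cluster`, `gene`, `fraction`,
#'   `mean_norm`, `empty` (TRUE when the cluster has no cells; statistics
#'   reported as 0).
#' @export
dotplot_stats <- function(cells, genes, clusters = NULL) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (is.null(cells$norm)) cells <- normalize_cells(cells)
  missing <- setdiff(genes, colnames(cells$counts))
  if (length(missing)) stop("genes absent from matrix: ",
                            paste(missing, collapse = ", "))
  if (is.null(clusters)) {
    obs <- unique(cells$clusters)
    clusters <- c(intersect(islet_clusters(), obs),
                  sort(setdiff(obs, islet_clusters())))
  }
  out <- expand.grid(cluster = clusters, gene = genes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$fraction <- 0; out$mean_norm <- 0; out$empty <- FALSE
  for (i in seq_len(nrow(out))) {
    in_cl <- cells$clusters == out$cluster[i]
    if (!any(in_cl)) { out$empty[i] <- TRUE; next }
    cnt <- cells$counts[in_cl, out$gene[i]]
    out$fraction[i] <- mean(cnt > 0)
    out$mean_norm[i] <- mean(cells$norm[in_cl, out$gene[i]])
  }
  class(out) <- c("dotplot_table", "data.frame")
  out
}

#' Identify the proliferating cluster by a marker gene
#'
#' Returns the cluster with maximal mean normalized expression of the
#' proliferation marker (Mki67 by default). Ties are broken alphabetically
#' with a warning.
#'
#' @param stats A `dotplot_table` from [dotplot_stats()].
#' @param marker Marker gene (must be present in the table).
#' @return Cluster id (character scalar).
#' @export
label_proliferating <- function(stats, marker = "Mki67") {
  rows <- stats[stats$gene == marker, , drop = FALSE]
  if (nrow(rows) == 0) stop("marker ", marker, " absent from dot-plot table")
  best <- rows$cluster[rows$mean_norm == max(rows$mean_norm)]
  if (length(best) > 1) {
    warning("tie for maximal ", marker, " expression; ",
            "breaking alphabetically")
    best <- sort(best)
  }
  best[1]
}

#' Top-expressing cluster per gene
#'
#' @param stats A `dotplot_table`.
#' @return Named character vector gene -> cluster of maximal mean
#'   normalized expression (alphabetical tie-break).
#' @export
top_cluster <- function(stats) {
  vapply(unique(stats$gene), function(g) {
    rows <- stats[stats$gene == g, , drop = FALSE]
    sort(rows$cluster[rows$mean_norm == max(rows$mean_norm)])[1]
  }, "")
}

#' Simulate a clustered islet single-cell count matrix
#'
#' Draws counts from a negative binomial per gene x cluster mean (dispersion
#' 0.5 by default, i.e. size 2). The default mean profile emulates islet
#' cell types: hormone genes mark Alpha/Delta/Gamma/beta clusters, Mki67 is
#' strictly highest in BetaP, and the candidate genes S100z and Iqgap2 peak
#' in BetaP.
#'
#' @param clusters Cluster labels to simulate; must contain all of
#'   [islet_clusters()] and nothing else.
#' @param means Optional genes x clusters matrix of negative-binomial means
#'   (rownames = genes, colnames = clusters); defaults to the islet profile.
#' @param n_per_cluster Cells per cluster (recycled).
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param seed Integer seed.
#' @return A [cell_matrix()].
#' @export
make_single_cell <- function(clusters = islet_clusters(), means = NULL,
                             n_per_cluster = 50, dispersion = 0.5,
                             seed = 1L) {
  unknown <- setdiff(clusters, islet_clusters())
  if (length(unknown)) stop("unknown cluster name(s): ",
                            paste(unknown, collapse = ", "))
  if (!all(islet_clusters() %in% clusters))
    stop("clusters must include all of: ",
         paste(islet_clusters(), collapse = ", "))
  if (is.null(means)) means <- .default_sc_means()[, clusters, drop = FALSE]
  stopifnot(all(clusters %in% colnames(means)))
  set.seed(seed)
  n_per_cluster <- rep_len(n_per_cluster, length(clusters))
  lab <- rep(clusters, n_per_cluster)
  n_cells <- length(lab); genes <- rownames(means)
  counts <- matrix(0L, n_cells, length(genes),
                   dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                   genes))
  size <- 1 / dispersion
  for (g in genes) for (cl in clusters) {
    idx <- lab == cl
    mu <- means[g, cl]
    counts[idx, g] <- if (mu == 0) 0L
                      else stats::rnbinom(sum(idx), size = size, mu = mu)
  }
  cell_matrix(counts, lab)
}

# Islet-like NB means: hormones define cell types; Mki67/S100z/Iqgap2
# strictly maximal in BetaP.
.default_sc_means <- function() {
  cl <- islet_clusters()
  g <- c("Ins1", "Gcg", "Sst", "Ppy", "Mki67",
         "S100z", "Iqgap2", "Rnf180", "Ankrd55", "Acot12")
  m <- matrix(0.1, length(g), length(cl), dimnames = list(g, cl))
  beta <- c("Beta1", "Beta2", "Beta3", "Beta4", "BetaP")
  m["Ins1", beta] <- 60
  m["Gcg", "Alpha"] <- 50
  m["Sst", "Delta"] <- 45
  m["Ppy", "Gamma"] <- 40
  m["Mki67", ] <- 0.05; m["Mki67", "BetaP"] <- 5
  m["S100z", beta] <- 1.5; m["S100z", "BetaP"] <- 4
  m["Iqgap2", beta] <- 1.2; m["Iqgap2", "BetaP"] <- 3
  m["Rnf180", beta] <- 0.8
  m["Ankrd55", ] <- 0.4
  m["Acot12", ] <- 0.15
  m
}
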