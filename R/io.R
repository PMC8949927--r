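#' @keywords internal
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @keywords internal
.read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write / read a genotype matrix as TSV
#'
#' Rows are individuals (first column `id`), remaining columns markers with
#' codes `NN`/`NB`/`NA`.
#' @param geno Character matrix with rownames (ids) and colnames (markers).
#' @param path File path.
#' @export
write_genotypes <- function(geno, path) {
  .write_tsv(data.frame(id = rownames(geno), geno, check.names = FALSE),
             path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- .read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Write / read a phenotype table as TSV
#' @param pheno Data frame with `id` plus trait columns.
#' @param path File path.
#' @export
write_phenotypes <- function(pheno, path) .write_tsv(pheno, path)

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) .read_tsv(path)

#' Write / read a genetic map as TSV (marker, chrom, pos_bp, pos_cm)
#' @param map A [genetic_map()].
#' @param path File path.
#' @export
write_map <- function(map, path) .write_tsv(as.data.frame(map), path)

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- .read_tsv(path)
  genetic_map(as.character(df$chrom[1]), df$marker, df$pos_bp, df$pos_cm)
}

#' Write a LOD curve as TSV
#' @param curve A `lod_curve`.
#' @param path File path.
#' @export
write_lod_curve <- function(curve, path) .write_tsv(as.data.frame(curve),
                                                    path)

#' @rdname write_lod_curve
#' @export
read_lod_curve <- function(path) {
  out <- .read_tsv(path)
  class(out) <- c("lod_curve", "data.frame")
  out
}

#' Write / read window profiles, evidence tables, dot-plot tables
#' @param x The table to write.
#' @param path File path.
#' @export
write_table_tsv <- function(x, path) .write_tsv(as.data.frame(x), path)

#' @rdname write_table_tsv
#' @param class_ Class to prepend on read.
#' @export
read_table_tsv <- function(path, class_ = NULL) {
  out <- .read_tsv(path)
  if (!is.null(class_)) class(out) <- c(class_, "data.frame")
  out
}

#' Write / read a cell matrix as MatrixMarket + sidecar TSVs
#'
#' Writes `matrix.mtx` (genes x cells, the features-by-barcodes
#' orientation), `features.tsv`, `barcodes.tsv` and `clusters.tsv` into a
#' directory.
#'
#' @param cells A [cell_matrix()].
#' @param dir Output directory (created if needed).
#' @export
write_cell_matrix <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(cells$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(cells$counts), file.path(dir, "features.tsv"))
  writeLines(rownames(cells$counts), file.path(dir, "barcodes.tsv"))
  .write_tsv(data.frame(barcode = rownames(cells$counts),
                        cluster = cells$clusters),
             file.path(dir, "clusters.tsv"))
  invisible(dir)
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  features <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  counts <- t(m)
  dimnames(counts) <- list(barcodes, features)
  cl <- .read_tsv(file.path(dir, "clusters.tsv"))
  cell_matrix(counts, cl$cluster[match(barcodes, cl$barcode)])
}

#' Write / read a flat key-value config file
#'
#' One `key = value` pair per line; numeric-looking values are parsed as
#' numbers on read.
#'
#' @param config Named list of scalars.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, "")), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- regmatches(lines, regexpr(" *= *", lines), invert = TRUE)
  out <- lapply(kv, function(p) {
    v <- p[2]
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(out) <- trimws(vapply(kv, `[`, "", 1))
  out
}
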