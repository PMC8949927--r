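#' Write every input of the candidate cascade to a directory
#'
#' Materializes a [make_cascade_fixture()] plus a simulated backcross into
#' the on-disk formats the pipeline reads: genotype/phenotype/map TSVs, a
#' two-sample VCF, GFF3 and BED annotations, expression TSVs with group
#' maps, a MatrixMarket single-cell bundle, a Ct table, and a `config.txt`
#' manifest.
#'
#' @param dir Output directory.
#' @param seed Integer seed for fixture and cross.
#' @param n Backcross cohort size.
#' @param effect Planted additive QTL effect (SD units).
#' @param qtl_bp Planted QTL position (default: the rs4222065 map entry).
#' @return The config (named list) written to `config.txt`, invisibly.
#' @export
write_fixture_dir <- function(dir, seed = 7L, n = 600, effect = 0.4,
                              qtl_bp = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fix <- make_cascade_fixture(seed)
  map <- chr13_map()
  if (is.null(qtl_bp)) qtl_bp <- map$pos_bp[map$marker == "rs4222065"]
  sim <- simulate_backcross(map, cross_spec(n, qtl_bp, effect = effect,
                                            seed = seed + 10L))
  p <- function(f) file.path(dir, f)
  write_map(map, p("map.tsv"))
  write_genotypes(sim$geno, p("genotypes.tsv"))
  write_phenotypes(sim$pheno, p("phenotypes.tsv"))
  write_snp_vcf(fix$catalog, p("snps.vcf"))
  write_annotation(fix$annotation, p("genes.gff3"))
  write_annotation(fix$annotation, p("genes.bed"))
  for (ct in names(fix$expr)) {
    e <- fix$expr[[ct]]
    .write_tsv(data.frame(gene_id = rownames(e$mat), e$mat,
                          check.names = FALSE), p(paste0("expr_", ct,
                                                         ".tsv")))
    .write_tsv(data.frame(sample = colnames(e$mat),
                          group = as.character(e$groups)),
               p(paste0("groups_", ct, ".tsv")))
  }
  write_cell_matrix(fix$sc, p("sc"))
  .write_tsv(fix$ct, p("ct_table.tsv"))
  config <- list(
    dir = dir, map = "map.tsv", genotypes = "genotypes.tsv",
    phenotypes = "phenotypes.tsv", vcf = "snps.vcf",
    annotation = "genes.gff3", sc_dir = "sc", ct = "ct_table.tsv",
    chrom = fix$interval$chrom, interval_start = fix$interval$start,
    interval_end = fix$interval$end,
    window_size = fix$interval$window_size, snp_threshold = 100,
    lfc_threshold = 1, trait = "glucose", step_bp = 5e5,
    n_perm = 0, alpha = 0.01, seed = seed,
    candidate_genes = paste(c(.candidate_genes, "Mki67"), collapse = ","),
    marker_gene = "Mki67")
  write_config(config, p("config.txt"))
  invisible(config)
}

#' Read an expression contrast written by [write_fixture_dir()]
#' @param expr_path,groups_path Paths to the matrix and group-map TSVs.
#' @param contrast Contrast label.
#' @return An [expression_set()].
#' @export
read_expression_tsv <- function(expr_path, groups_path,
                                contrast = "contrast") {
  df <- .read_tsv(expr_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  gr <- .read_tsv(groups_path)
  # group 1 = first group listed in the map, preserving fixture order
  groups <- factor(gr$group[match(colnames(m), gr$sample)],
                   levels = unique(gr$group))
  expression_set(m, groups, contrast)
}

#' Run the full QTL-to-candidate pipeline from a fixture directory
#'
#' Stages: linkage scan (EM interval mapping, optional permutation
#' threshold), haplotype-window filter, differential-expression cascade over
#' the three contrasts, single-cell profiling, and the final evidence
#' table. Writes `lod.tsv`, `windows.tsv`, `dotplot.tsv`, `evidence.tsv`
#' and `summary.txt` into `outdir`. Any stage failure aborts with a
#' stage-tagged message and removes partial outputs. Identical config and
#' seeds give identical outputs.
#'
#' @param config Named list as produced by [write_fixture_dir()] /
#'   [read_config()]; relative paths resolve against `config$dir`.
#' @param outdir Output directory.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(outdir, c("lod.tsv", "windows.tsv", "dotplot.tsv",
                                 "evidence.tsv", "summary.txt"))
  stage <- "load"
  note <- function(...) message("[", stage, "] ", ...)
  res <- tryCatch({
    p <- function(f) if (startsWith(f, "/")) f else file.path(config$dir, f)
    map <- read_map(p(config$map))
    geno <- read_genotypes(p(config$genotypes))
    pheno <- read_phenotypes(p(config$phenotypes))
    catalog <- read_snp_vcf(p(config$vcf))
    annotation <- read_annotation(p(config$annotation))
    expr <- lapply(stats::setNames(nm = c("parental", "congenic", "obob")),
                   function(ct) read_expression_tsv(
                     p(paste0("expr_", ct, ".tsv")),
                     p(paste0("groups_", ct, ".tsv")), ct))
    sc <- read_cell_matrix(p(config$sc_dir))
    note("inputs parsed: ", nrow(geno), " individuals, ",
         nrow(annotation), " genes, ", nrow(catalog), " SNPs")

    stage <- "scan"
    note("trait = ", config$trait, ", step = ", config$step_bp, " bp, ",
         "seed = ", config$seed)
    curve <- em_scan(geno, pheno[[config$trait]], map,
                     step_bp = config$step_bp)
    peak <- peak_position(curve)
    perm <- NULL
    if (config$n_perm > 0) {
      perm <- permutation_threshold(geno, pheno[[config$trait]], map,
                                    n_perm = config$n_perm,
                                    alpha = config$alpha,
                                    seed = config$seed,
                                    step_bp = config$step_bp)
      note("permutation threshold (alpha = ", config$alpha, "): ",
           round(perm$threshold, 3))
    }
    effects <- peak_effects(geno, pheno, "rs4222065")

    stage <- "haplomap"
    prof <- window_counts(catalog, config$chrom, config$interval_start,
                          config$interval_end, config$window_size)
    called <- call_polymorphic(prof, config$snp_threshold)
    kept <- filter_genes(annotation, called)
    note(nrow(annotation), " genes -> ", nrow(kept),
         " in polymorphic windows (", nrow(called$blocks), " blocks)")

    stage <- "deg"
    de <- lapply(expr, compute_lfc,
                 lfc_threshold = config$lfc_threshold)
    de_parental <- intersect(de_filter(de$parental, config$lfc_threshold),
                             kept$gene_id)
    de_congenic <- intersect(de_filter(de$congenic, config$lfc_threshold),
                             de_parental)
    de_obob <- intersect(de_filter(de$obob, config$lfc_threshold),
                         annotation$gene_id)
    note("parental DE in block genes: ", length(de_parental),
         "; congenic intersection: ", length(de_congenic))

    stage <- "sc"
    genes <- strsplit(config$candidate_genes, ",")[[1]]
    stats <- dotplot_stats(normalize_cells(sc), genes)
    prolif <- label_proliferating(stats, config$marker_gene)
    note("proliferating cluster by ", config$marker_gene, ": ", prolif)

    stage <- "prioritize"
    tops <- top_cluster(stats)
    evidence <- build_cascade(annotation, kept$gene_id, de_parental,
                              de_congenic, de_obob,
                              sc_top_cluster = tops)
    final <- evidence$gene_id[evidence$final_candidate]
    # cascade nestedness along the filter chain
    stopifnot(all(final %in% de_parental),
              all(de_parental %in% kept$gene_id),
              all(kept$gene_id %in% annotation$gene_id))
    note("final candidates: ", paste(final, collapse = ", "))

    stage <- "write"
    write_lod_curve(curve, outputs[1])
    write_table_tsv(called$profiles, outputs[2])
    write_table_tsv(stats, outputs[3])
    write_table_tsv(evidence, outputs[4])
    writeLines(c(
      sprintf("peak: %.1f Mbp (LOD %.2f)", peak$pos_bp / 1e6, peak$lod),
      if (!is.null(perm))
        sprintf("genome-wide LOD threshold (alpha %.2g, %d perms): %.3f",
                config$alpha, perm$n_perm, perm$threshold),
      sprintf("interval genes: %d", nrow(annotation)),
      sprintf("in polymorphic blocks: %d", nrow(kept)),
      sprintf("parental DE (|LFC| > %g): %d", config$lfc_threshold,
              length(de_parental)),
      sprintf("congenic intersection: %d", length(de_congenic)),
      sprintf("proliferating cluster: %s", prolif),
      sprintf("final candidates: %s", paste(final, collapse = ", "))),
      outputs[5])
    list(curve = curve, peak = peak, perm = perm, effects = effects,
         profiles = called$profiles, blocks = called$blocks,
         kept = kept, de = de, evidence = evidence, final = final,
         dotplot = stats, proliferating = prolif)
  }, error = function(e) {
    unlink(outputs)
    stop("pipeline failed at stage [", stage, "]: ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
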