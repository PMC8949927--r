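#' Simulate a two-group expression fixture with planted log2 effects
#'
#' Generates intensities so that `log2(x + 1)` is exactly
#' `base + effect/2` in group 1 and `base - effect/2` in group 2 plus
#' Normal noise, i.e. the planted effect is recovered (up to noise) by
#' [compute_lfc()] with its default pseudocount.
#'
#' @param genes Gene ids.
#' @param effects Named numeric vector of planted log2 effects (genes not
#'   named get 0).
#' @param n_per_group Samples per group (>= 2).
#' @param sd Within-group SD on the log2 scale (> 0).
#' @param base Baseline log2 intensity.
#' @param group_names Length-2 character vector (group 1 first).
#' @param contrast Contrast label.
#' @param seed Integer seed.
#' @return An [expression_set()] with attribute `planted` (the full effect
#'   vector).
#' @export
make_expression_fixture <- function(genes, effects = numeric(),
                                    n_per_group = 5, sd = 0.1, base = 7,
                                    group_names = c("B6", "NZO"),
                                    contrast = "contrast", seed = 1L) {
  if (n_per_group < 2) stop("need >= 2 samples per group")
  if (sd <= 0) stop("within-group SD must be > 0")
  set.seed(seed)
  eff <- stats::setNames(rep(0, length(genes)), genes)
  eff[names(effects)] <- effects
  groups <- rep(group_names, each = n_per_group)
  shift <- ifelse(groups == group_names[1], 1, -1) / 2
  lmat <- outer(eff, shift) + base +
    matrix(stats::rnorm(length(genes) * 2 * n_per_group, 0, sd),
           length(genes))
  mat <- pmax(2^lmat - 1, 0)
  dimnames(mat) <- list(genes,
                        sprintf("%s_%d", groups,
                                rep(seq_len(n_per_group), 2)))
  out <- expression_set(mat, groups, contrast)
  attr(out, "planted") <- eff
  out
}

# Candidate genes fixed by the congenic contrast, plus parental-only
# fillers; Acot12 is the one candidate not differential in the ob/ob set.
.candidate_genes <- c("Acot12", "S100z", "Ankrd55", "Rnf180", "Iqgap2")
.filler_genes <- c("Gm40810", "Gm41234", "Gm42561")

#' Full synthetic candidate-cascade fixture
#'
#' One seeded preset producing every input of the prioritization cascade
#' over the chromosome 13 critical interval (78.0-120.4 Mbp):
#' \itemize{
#'   \item a 644-gene annotation (208 coding, 377 gene models, 8 miRNAs,
#'     51 Riken genes) tiled over the interval;
#'   \item a two-strain SNP catalog whose three polymorphic blocks (windows
#'     exceeding 100 discordant SNPs per 250 kb) overlap exactly 111 of the
#'     644 genes;
#'   \item three bulk islet expression fixtures: the parental B6-vs-NZO
#'     contrast plants |log2 effects| in [1.5, 3] for exactly 8 of the 111
#'     block genes (the five candidates Acot12, S100z, Ankrd55, Rnf180,
#'     Iqgap2 plus three fillers), the congenic B/B-vs-N/N contrast for
#'     exactly the five candidates, and the B6-ob/ob-vs-NZO contrast for
#'     the four candidates other than Acot12;
#'   \item a clustered single-cell count matrix ([make_single_cell()]);
#'   \item a qPCR Ct table for S100z against Actb.
#' }
#' The block/gene geometry is deterministic, so the 644 -> 111 -> 8 -> 5
#' cascade counts hold at any seed; noise SD 0.1 with n = 5 per group keeps
#' the empirical LFC filter aligned with the planted truth.
#'
#' @param seed Integer seed (default 7).
#' @return List with `annotation`, `catalog`, `expr` (list `parental`,
#'   `congenic`, `obob`), `sc` (a [cell_matrix()]), `ct` (Ct table),
#'   `interval` (chrom/start/end), and `truth` (planted gene sets).
#' @export
make_cascade_fixture <- function(seed = 7L) {
  chrom <- "13"; start <- 78e6; end <- 120.4e6
  w <- 250000
  spacing <- 65838; glen <- 30000; n_genes <- 644

  gs <- start + (seq_len(n_genes) - 1) * spacing
  ge <- gs + glen - 1

  # polymorphic blocks on the window grid; chosen so that exactly 111 genes
  # overlap (38 + 42 + 31); the third block spans the 112.5 Mbp peak
  blocks <- data.frame(start = start + c(10, 60, 134) * w,
                       end = start + c(20, 71, 142) * w,
                       density = 150)

  # candidate + filler slots inside the third block (genes 510..540)
  slots <- c(Acot12 = 512L, S100z = 516L, Ankrd55 = 520L, Rnf180 = 524L,
             Iqgap2 = 528L, Gm40810 = 532L, Gm41234 = 535L, Gm42561 = 538L)
  ids <- sprintf("C13g%04d", seq_len(n_genes))
  ids[slots] <- names(slots)

  biotype <- rep("gene_model", n_genes)
  plain <- setdiff(seq_len(n_genes), slots)
  biotype[slots[.candidate_genes]] <- "coding"
  biotype[plain[1:203]] <- "coding"          # 203 + 5 candidates = 208
  biotype[plain[204:211]] <- "miRNA"         # 8
  biotype[plain[212:262]] <- "riken"         # 51; remaining 377 gene models
  annotation <- gene_annotation(ids, chrom, gs, ge, biotype)

  catalog <- make_snp_catalog(chrom, start, end, blocks, background = 40,
                              seed = seed)

  planted_parental <- c(Acot12 = -2.2, S100z = 2.6, Ankrd55 = -1.8,
                        Rnf180 = 1.6, Iqgap2 = 2.9,
                        Gm40810 = 1.7, Gm41234 = -2.4, Gm42561 = 2.0)
  planted_congenic <- planted_parental[.candidate_genes] * 0.8
  planted_obob <- planted_parental[setdiff(.candidate_genes, "Acot12")]

  expr <- list(
    parental = make_expression_fixture(ids, planted_parental,
                                       group_names = c("B6", "NZO"),
                                       contrast = "parental",
                                       seed = seed + 1L),
    congenic = make_expression_fixture(ids, planted_congenic,
                                       group_names = c("BB", "NN"),
                                       contrast = "congenic",
                                       seed = seed + 2L),
    obob = make_expression_fixture(ids, planted_obob,
                                   group_names = c("B6ob", "NZO"),
                                   contrast = "obob", seed = seed + 3L))

  sc <- make_single_cell(seed = seed + 4L)
  ct <- make_ct_fixture(seed = seed + 5L)

  list(annotation = annotation, catalog = catalog, expr = expr, sc = sc,
       ct = ct,
       interval = list(chrom = chrom, start = start, end = end,
                       window_size = w),
       truth = list(blocks = blocks,
                    de_parental = names(planted_parental),
                    de_congenic = names(planted_congenic),
                    de_obob = names(planted_obob),
                    candidates = .candidate_genes))
}

#' qPCR Ct fixture for S100z against Actb
#'
#' Six samples (three per strain) with a planted ~2 cycle strain difference
#' in the target Ct, mirroring low endogenous S100z expression in NZO
#' islets.
#'
#' @param seed Integer seed.
#' @return Data frame `sample`, `group`, `ct_target`, `ct_reference`.
#' @export
make_ct_fixture <- function(seed = 1L) {
  set.seed(seed)
  group <- rep(c("B6", "NZO"), each = 3)
  data.frame(sample = sprintf("%s_%d", group, rep(1:3, 2)),
             group = group,
             ct_target = ifelse(group == "B6", 26, 28) +
               stats::rnorm(6, 0, 0.2),
             ct_reference = 18 + stats::rnorm(6, 0, 0.2))
}
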