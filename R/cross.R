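#' Specify a backcross simulation
#'
#' Describes an (NZOxB6)N2-style backcross cohort: `n` offspring, a single
#' additive QTL planted at `qtl_bp`, and a residual standard deviation. The
#' two genotype classes are homozygous `NN` and heterozygous `NB`, expected in
#' a 1:1 ratio. The additive effect is given in phenotype-SD units; for the
#' default traits the planted direction mirrors the diabetes phenotype of
#' NZO-allele carriers (glucose up in `NN`, pancreatic insulin and body
#' weight down).
#'
#' @param n Cohort size (>= 2).
#' @param qtl_bp Physical position of the planted QTL (bp); must lie within
#'   the map passed to [simulate_backcross()].
#' @param effect Additive effect `a` in units of the residual SD: the `NN`
#'   class mean is shifted by `a * sigma` relative to `NB`.
#' @param sigma Residual standard deviation (> 0), applied per trait in that
#'   trait's units.
#' @param traits Named numeric vector of per-trait effect signs/relative
#'   sizes; the planted effect for trait t is `effect * traits[t] * sigma`.
#' @param missing_rate Fraction of genotype calls set to missing at random.
#' @param seed Integer seed driving all randomness of the simulation.
#' @return A `cross_spec` list.
#' @export
cross_spec <- function(n, qtl_bp, effect = 0.4, sigma = 1,
                       traits = c(glucose = 1, insulin = -1, weight = -1),
                       missing_rate = 0, seed = 1L) {
  if (n < 2) stop("cohort size n must be >= 2")
  if (sigma <= 0) stop("residual SD sigma must be > 0")
  if (is.null(names(traits)) || any(names(traits) == ""))
    stop("traits must be a named numeric vector")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  structure(list(n = as.integer(n), qtl_bp = as.numeric(qtl_bp),
                 effect = effect, sigma = sigma, traits = traits,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cross_spec")
}

# Baseline trait means, in the units of each default trait
.trait_means <- c(glucose = 10, insulin = 80, weight = 25)

#' Simulate an N2 backcross cohort
#'
#' Each individual's chromosome is simulated as a two-state Markov chain
#' (states `NN`, `NB`) along the ordered loci, with transition probability
#' given by the Haldane recombination fraction of the inter-locus map
#' distance — i.e. crossovers are Poisson with no interference. The planted
#' QTL is inserted as a hidden locus: its true genotype drives the phenotypes
#' but is not reported in the marker matrix. Phenotypes are
#' `y = mu + a * sigma * 1[g = NN] + Normal(0, sigma^2)` per trait.
#'
#' @param map A [genetic_map()].
#' @param spec A [cross_spec()].
#' @return A list of class `backcross_sim` with elements `geno` (n x markers
#'   character matrix, codes `"NN"`/`"NB"`/`NA`), `map`, `pheno` (data.frame
#'   with `id` and one column per trait), and `qtl_geno` (the hidden truth at
#'   the QTL, for validation).
#' @export
simulate_backcross <- function(map, spec) {
  stopifnot(inherits(map, "genetic_map"), inherits(spec, "cross_spec"))
  span <- map_span_bp(map)
  if (spec$qtl_bp < span[1] || spec$qtl_bp > span[2])
    stop("QTL position lies outside the map span")
  set.seed(spec$seed)
  n <- spec$n

  # insert the QTL as an extra (hidden) locus; cM by linear interpolation
  loci_bp <- sort(unique(c(map$pos_bp, spec$qtl_bp)))
  loci_cm <- stats::approx(map$pos_bp, map$pos_cm, xout = loci_bp)$y
  qtl_idx <- match(spec$qtl_bp, loci_bp)
  n_loci <- length(loci_bp)

  # two-state chain: 0 = NN, 1 = NB; switch with prob r(d) between loci
  g <- matrix(0L, n, n_loci)
  g[, 1] <- stats::rbinom(n, 1L, 0.5)
  if (n_loci > 1) {
    r <- haldane(diff(loci_cm) / 100)
    for (j in 2:n_loci) {
      sw <- stats::rbinom(n, 1L, r[j - 1])
      g[, j] <- bitwXor(g[, j - 1], sw)
    }
  }

  qtl_g <- g[, qtl_idx]
  pheno <- data.frame(id = sprintf("N2_%04d", seq_len(n)))
  for (tr in names(spec$traits)) {
    mu <- if (tr %in% names(.trait_means)) .trait_means[[tr]] else 0
    a_units <- spec$effect * spec$traits[[tr]] * spec$sigma
    pheno[[tr]] <- mu + a_units * (qtl_g == 0L) +
      stats::rnorm(n, 0, spec$sigma)
  }

  keep <- match(map$pos_bp, loci_bp)
  geno <- matrix(c("NN", "NB")[g[, keep, drop = FALSE] + 1L], n,
                 length(keep), dimnames = list(pheno$id, map$marker))
  if (spec$missing_rate > 0) {
    drop <- matrix(stats::runif(length(geno)) < spec$missing_rate,
                   nrow = nrow(geno))
    # keep at least one informative genotype per individual
    full_row <- rowSums(!drop) == 0
    drop[full_row, 1] <- FALSE
    geno[drop] <- NA_character_
  }

  structure(list(geno = geno, map = map, pheno = pheno,
                 qtl_geno = c("NN", "NB")[qtl_g + 1L]),
            class = "backcross_sim")
}
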