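#' Conditional genotype probabilities at arbitrary positions
#'
#' For an N2 backcross (states `NN`, `NB`) computes, per individual and per
#' queried position, the probability of each genotype given the nearest
#' informative flanking markers, assuming no crossover interference
#' (Haldane). The chromosome is a two-state Markov chain, so conditioning on
#' the nearest informative marker on each side is exact. At a typed marker
#' the probabilities collapse to 0/1; an individual with no informative
#' marker on either side gets the (0.5, 0.5) prior.
#'
#' @param geno Character matrix individuals x markers (`"NN"`/`"NB"`/`NA`),
#'   columns ordered as in `map`.
#' @param map The [genetic_map()] the columns refer to.
#' @param pos_bp Positions (bp) to evaluate; must lie within the map span.
#' @return Array `n x length(pos_bp) x 2`; third dimension named
#'   `c("NN", "NB")`. Rows sum to 1.
#' @export
genotype_probabilities <- function(geno, map, pos_bp) {
  stopifnot(ncol(geno) == nrow(map))
  span <- map_span_bp(map)
  if (any(pos_bp < span[1] | pos_bp > span[2]))
    stop("position outside map span")
  n <- nrow(geno); M <- ncol(geno)
  g01 <- matrix(match(geno, c("NN", "NB")) - 1L, n, M)  # 0/1/NA
  pos_cm <- stats::approx(map$pos_bp, map$pos_cm, xout = pos_bp)$y

  idx <- matrix(rep(seq_len(M), each = n), n, M)
  idx[is.na(g01)] <- 0L
  left_inf <- t(apply(idx, 1, cummax))                  # 0 = none
  idx[idx == 0L] <- M + 1L
  right_inf <- t(apply(idx[, M:1, drop = FALSE], 1, cummin))[, M:1,
                                                             drop = FALSE]

  out <- array(NA_real_, c(n, length(pos_bp), 2),
               dimnames = list(rownames(geno), NULL, c("NN", "NB")))
  for (j in seq_along(pos_bp)) {
    jl <- findInterval(pos_cm[j], map$pos_cm)           # last marker <= pos
    jr <- findInterval(pos_cm[j], c(map$pos_cm, Inf),
                       left.open = TRUE) + 1L           # first marker >= pos
    L <- if (jl >= 1) left_inf[, jl] else rep(0L, n)
    R <- if (jr <= M) right_inf[, jr] else rep(M + 1L, n)
    # factor per side: P(transition) over the cM gap; 1 when uninformative
    fac <- function(midx, valid) {
      r <- rep(NA_real_, n)
      r[valid] <- haldane(abs(map$pos_cm[midx[valid]] - pos_cm[j]) / 100)
      g <- rep(NA_integer_, n)
      g[valid] <- g01[cbind(which(valid), midx[valid])]
      w0 <- ifelse(valid, ifelse(g == 0L, 1 - r, r), 1)  # toward state NN
      w1 <- ifelse(valid, ifelse(g == 1L, 1 - r, r), 1)  # toward state NB
      cbind(w0, w1)
    }
    fl <- fac(L, L >= 1L); fr <- fac(R, R <= M)
    w0 <- fl[, 1] * fr[, 1]; w1 <- fl[, 2] * fr[, 2]
    out[, j, 1] <- w0 / (w0 + w1)
    out[, j, 2] <- 1 - out[, j, 1]
  }
  out
}

# EM mixture fit vectorized across grid positions.
# P: n x npos prior P(NN); y: phenotype vector. Returns list of per-position
# vectors: lod, mu_nn, mu_nb, sigma, plus convergence/monotonicity info.
.em_core <- function(P, y, tol = 1e-8, maxit = 1000L) {
  n <- length(y); npos <- ncol(P)
  s0 <- sqrt(mean((y - mean(y))^2))
  if (s0 == 0) stop("phenotype has zero variance")
  ll0 <- sum(stats::dnorm(y, mean(y), s0, log = TRUE))

  bcast <- function(v) matrix(v, n, npos, byrow = TRUE)
  Q <- 1 - P
  mu1 <- colSums(P * y) / pmax(colSums(P), 1e-12)
  mu2 <- colSums(Q * y) / pmax(colSums(Q), 1e-12)
  sig <- rep(s0, npos)
  ll <- rep(-Inf, npos); monotone <- TRUE; converged <- FALSE
  for (it in seq_len(maxit)) {
    D1 <- stats::dnorm(y, bcast(mu1), bcast(sig))
    D2 <- stats::dnorm(y, bcast(mu2), bcast(sig))
    mix <- P * D1 + Q * D2
    ll_new <- colSums(log(pmax(mix, 1e-300)))
    if (it > 1 && any(ll_new < ll - 1e-6)) monotone <- FALSE
    done <- it > 1 && max(abs(ll_new - ll)) < tol
    ll <- ll_new
    if (done) { converged <- TRUE; break }
    W <- P * D1 / pmax(mix, 1e-300)
    V <- 1 - W
    sw <- pmax(colSums(W), 1e-12); sv <- pmax(colSums(V), 1e-12)
    mu1 <- colSums(W * y) / sw
    mu2 <- colSums(V * y) / sv
    rss <- colSums(W * (y - bcast(mu1))^2) + colSums(V * (y - bcast(mu2))^2)
    sig <- sqrt(pmax(rss / n, 1e-12))
  }
  list(lod = (ll - ll0) / log(10), mu_nn = mu1, mu_nb = mu2, sigma = sig,
       ll0 = ll0, converged = converged, monotone = monotone)
}

#' Single-QTL EM genome scan
#'
#' Interval mapping over a pseudomarker grid: at each position the phenotype
#' is modeled as a two-component normal mixture with mixing proportions
#' given by the conditional genotype probabilities, fitted by EM (posterior
#' weights in the E-step; weighted class means and a pooled common sigma in
#' the M-step). `LOD = log10 L1 - log10 L0` against the single-normal MLE.
#'
#' @param geno Genotype matrix (see [genotype_probabilities()]).
#' @param pheno Numeric phenotype vector, one value per row of `geno`;
#'   missing values are dropped pairwise.
#' @param map The [genetic_map()].
#' @param step_bp Pseudomarker grid spacing in bp (default 0.5 Mbp); marker
#'   positions are always included in the grid.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param maxit Maximum EM iterations (warns on non-convergence).
#' @return A `lod_curve` data.frame with columns `pos_bp`, `pos_cm`, `lod`,
#'   `mu_nn`, `mu_nb`, `sigma`; attribute `n` is the analyzed cohort size.
#' @export
em_scan <- function(geno, pheno, map, step_bp = 5e5, tol = 1e-8,
                    maxit = 1000L) {
  stopifnot(length(pheno) == nrow(geno))
  keep <- !is.na(pheno)
  if (sum(keep) < 2) stop("need >= 2 individuals with non-missing phenotype")
  geno <- geno[keep, , drop = FALSE]; y <- pheno[keep]
  span <- map_span_bp(map)
  grid <- sort(unique(c(map$pos_bp, seq(span[1], span[2], by = step_bp))))
  P <- genotype_probabilities(geno, map, grid)[, , "NN", drop = TRUE]
  P <- matrix(P, nrow = length(y))
  fit <- .em_core(P, y, tol, maxit)
  if (!fit$converged)
    warning("EM did not converge at tol in ", maxit, " iterations")
  out <- data.frame(pos_bp = grid,
                    pos_cm = stats::approx(map$pos_bp, map$pos_cm,
                                           xout = grid)$y,
                    lod = fit$lod, mu_nn = fit$mu_nn, mu_nb = fit$mu_nb,
                    sigma = fit$sigma)
  attr(out, "n") <- length(y)
  attr(out, "monotone") <- fit$monotone
  class(out) <- c("lod_curve", "data.frame")
  out
}

#' Position of the maximum-LOD pseudomarker
#'
#' Ties are broken toward the leftmost (smallest bp) grid position.
#'
#' @param curve A `lod_curve` from [em_scan()].
#' @return Named list with `pos_bp` and `lod`.
#' @export
peak_position <- function(curve) {
  i <- which(curve$lod == max(curve$lod))[1]
  list(pos_bp = curve$pos_bp[i], lod = curve$lod[i])
}

#' Permutation-based genome-wide LOD threshold
#'
#' Permutes the phenotype vector against the genotype rows, reruns the full
#' EM scan per permutation, and records the genome-wide maximum LOD. The
#' threshold is the empirical `1 - alpha` quantile (type-7 linear
#' interpolation) of the max-LOD distribution.
#'
#' @inheritParams em_scan
#' @param n_perm Number of permutations (>= 100; the conventional choice is
#'   1000 at `alpha = 0.01`).
#' @param alpha Genome-wide significance level in (0, 1).
#' @param seed Integer seed for the permutations.
#' @param .permutations Optional list of explicit permutation index vectors
#'   (overrides `n_perm`; intended for testing).
#' @return A `permutation_null` list: `max_lod`, `n_perm`, `alpha`,
#'   `threshold`.
#' @export
permutation_threshold <- function(geno, pheno, map, n_perm = 1000,
                                  alpha = 0.01, seed = 1L, step_bp = 5e5,
                                  .permutations = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  keep <- !is.na(pheno)
  geno <- geno[keep, , drop = FALSE]; y <- pheno[keep]
  span <- map_span_bp(map)
  grid <- sort(unique(c(map$pos_bp, seq(span[1], span[2], by = step_bp))))
  P <- genotype_probabilities(geno, map, grid)[, , "NN", drop = TRUE]
  P <- matrix(P, nrow = length(y))
  if (is.null(.permutations)) {
    if (n_perm < 100) stop("n_perm must be >= 100")
    set.seed(seed)
    .permutations <- replicate(n_perm, sample.int(length(y)),
                               simplify = FALSE)
  }
  max_lod <- vapply(.permutations, function(p)
    max(.em_core(P, y[p])$lod), numeric(1))
  thr <- unname(stats::quantile(max_lod, 1 - alpha, type = 7))
  structure(list(max_lod = max_lod, n_perm = length(.permutations),
                 alpha = alpha, threshold = thr),
            class = "permutation_null")
}

# t-test that tolerates zero-variance groups (identical values give a
# defined zero-difference result instead of an error)
.safe_t <- function(a, b, var.equal = FALSE) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    d <- mean(a) - mean(b)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p.value = as.numeric(d == 0)))
  }
  stats::t.test(a, b, var.equal = var.equal)
}

#' Per-genotype-class effect summary at a marker
#'
#' Splits each trait by the genotype classes observed at the given marker
#' and reports class sizes, means and SEMs. Two classes are compared by a
#' Welch two-sided t-test; three or more by one-way ANOVA followed by
#' pairwise Bonferroni-adjusted t-tests. Classes with fewer than two
#' non-missing members are excluded with a warning.
#'
#' @param geno Genotype matrix.
#' @param pheno Data frame of traits (plus an optional `id` column, ignored).
#' @param marker Marker name (a column of `geno`).
#' @return List with `marker`, `summary` (trait, class, n, mean, sem) and
#'   `tests` (trait, comparison, method, statistic, p, p_adj).
#' @export
peak_effects <- function(geno, pheno, marker) {
  if (!marker %in% colnames(geno)) stop("marker not in genotype matrix")
  g <- geno[, marker]
  traits <- setdiff(names(pheno), "id")
  summ <- NULL; tests <- NULL
  for (tr in traits) {
    y <- pheno[[tr]]
    ok <- !is.na(g) & !is.na(y)
    cls <- sort(unique(g[ok]))
    sizes <- vapply(cls, function(cl) sum(ok & g == cl), 0L)
    if (any(sizes < 2)) {
      warning("excluding class(es) with < 2 members: ",
              paste(cls[sizes < 2], collapse = ", "))
      cls <- cls[sizes >= 2]
    }
    ok <- ok & g %in% cls
    for (cl in cls) {
      v <- y[ok & g == cl]
      summ <- rbind(summ, data.frame(trait = tr, class = cl,
                                     n = length(v), mean = mean(v),
                                     sem = stats::sd(v) / sqrt(length(v))))
    }
    if (length(cls) == 2) {
      tt <- .safe_t(y[ok & g == cls[1]], y[ok & g == cls[2]])
      tests <- rbind(tests, data.frame(
        trait = tr, comparison = paste(cls, collapse = " vs "),
        method = "Welch t", statistic = unname(tt$statistic),
        p = tt$p.value, p_adj = tt$p.value))
    } else if (length(cls) > 2) {
      an <- stats::oneway.test(y[ok] ~ factor(g[ok]), var.equal = TRUE)
      tests <- rbind(tests, data.frame(
        trait = tr, comparison = "omnibus", method = "one-way ANOVA",
        statistic = unname(an$statistic), p = an$p.value,
        p_adj = an$p.value))
      k <- choose(length(cls), 2)
      for (a in seq_along(cls)) for (b in seq_along(cls)) if (a < b) {
        tt <- .safe_t(y[ok & g == cls[a]], y[ok & g == cls[b]],
                      var.equal = TRUE)
        tests <- rbind(tests, data.frame(
          trait = tr, comparison = paste(cls[a], "vs", cls[b]),
          method = "t + Bonferroni", statistic = unname(tt$statistic),
          p = tt$p.value, p_adj = min(1, k * tt$p.value)))
      }
    }
  }
  list(marker = marker, summary = summ, tests = tests)
}
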