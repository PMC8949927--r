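test_that("haldane map function matches its closed form and bounds", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(0.5), (1 - exp(-1)) / 2)
  expect_lt(haldane(5), 0.5)
  expect_equal(haldane(1e3), 0.5, tolerance = 1e-12)
  expect_error(haldane(-0.1), "non-negative")
})

test_that("genotype probabilities: typed marker, midpoint, missing flanks", {
  map <- tiny_map(nm = 3)                 # markers at 10, 12, 14 Mbp; 1 cM
  geno <- rbind(a = c("NN", "NN", "NN"),
                b = c("NB", NA, "NB"),
                c = c(NA, NA, "NB"),
                d = c(NA, NA, NA))
  colnames(geno) <- map$marker
  expect_error(genotype_probabilities(geno, map, 9e6), "outside")
  # on a typed marker: 0/1
  p <- genotype_probabilities(geno, map, 10e6)
  expect_equal(p["a", 1, ], c(NN = 1, NB = 0))
  expect_equal(p["b", 1, ], c(NN = 0, NB = 1))
  # no informative marker anywhere: prior
  expect_equal(p["d", 1, ], c(NN = 0.5, NB = 0.5))
  # midpoint between two NN markers: enumerate two-recombination outcomes
  r <- haldane(0.005)                     # 0.5 cM to each side
  p_mid <- genotype_probabilities(geno, map, 11e6)
  expect_equal(unname(p_mid["a", 1, "NN"]),
               (1 - r)^2 / ((1 - r)^2 + r^2), tolerance = 1e-12)
  # only a right marker informative: single-transition probability
  r2 <- haldane(0.015)                    # 10.5 -> 14 Mbp = 1.75 cM? no:
  r2 <- haldane((14 - 10.5) * 0.5 / 100)
  p_c <- genotype_probabilities(geno, map, 10.5e6)
  expect_equal(unname(p_c["c", 1, "NB"]), 1 - r2, tolerance = 1e-12)
  # rows sum to one
  expect_true(all(abs(apply(p_mid, 1, sum) - 1) < 1e-12))
})

test_that("EM scan equals the closed-form regression LOD at complete
           markers and is invariant to affine phenotype rescaling", {
  map <- tiny_map()
  sim <- simulate_backcross(map, cross_spec(200, 14e6, effect = 0.8,
                                            seed = 2))
  y <- sim$pheno$glucose
  curve <- em_scan(sim$geno, y, map, step_bp = 1e6)
  expect_true(attr(curve, "monotone"))
  expect_true(all(curve$lod > -1e-8))
  for (m in map$marker) {
    i <- which(curve$pos_bp == map$pos_bp[map$marker == m])
    expect_equal(curve$lod[i], lod_closed_form(y, sim$geno[, m]),
                 tolerance = 1e-6)
  }
  curve2 <- em_scan(sim$geno, 3.5 * y - 11, map, step_bp = 1e6)
  expect_equal(curve2$lod, curve$lod, tolerance = 1e-6)
  expect_error(em_scan(sim$geno, rep(1, 200), map), "zero variance")
})

test_that("null phenotype gives a flat low LOD curve", {
  map <- tiny_map()
  sim <- simulate_backcross(map, cross_spec(2000, 14e6, effect = 0,
                                            seed = 4))
  curve <- em_scan(sim$geno, sim$pheno$glucose, map, step_bp = 1e6)
  expect_lt(max(curve$lod), 3)    # genome-wide null at n = 2000
})

test_that("QTL recovery: peak near planted position, class-mean difference
           within 3 SE of the planted effect", {
  map <- tiny_map(nm = 11)                # 10-30 Mbp
  rec <- vapply(1:8, function(s) {
    sim <- simulate_backcross(map, cross_spec(600, 20e6, effect = 0.8,
                                              seed = s))
    curve <- em_scan(sim$geno, sim$pheno$glucose, map, step_bp = 1e6)
    pk <- peak_position(curve)
    c(err = abs(pk$pos_bp - 20e6) / 1e6,
      excess = pk$lod - curve$lod[curve$pos_bp == 20e6])
  }, numeric(2))
  # localization: Darvasi-Soller CI ~ 530/(600 * 0.64) = 1.4 cM at 0.5
  # cM/Mbp; LOD tops can be near-flat over several Mbp, so require a tight
  # median, a majority within 3 Mbp, and never a peak that beats the LOD
  # at the true position by a meaningful margin
  expect_lte(median(rec["err", ]), 2)
  expect_gte(mean(rec["err", ] <= 3), 0.75)
  expect_lt(max(rec["excess", ]), 2)
  # effect recovery at the true QTL position (fitted mixture means)
  sim <- simulate_backcross(map, cross_spec(600, 20e6, effect = 0.8,
                                            seed = 1))
  curve <- em_scan(sim$geno, sim$pheno$glucose, map, step_bp = 1e6)
  i <- which(curve$pos_bp == 20e6)
  d <- curve$mu_nn[i] - curve$mu_nb[i]
  se <- 2 * curve$sigma[i] / sqrt(attr(curve, "n"))
  expect_lt(abs(d - 0.8), 3 * se)
})

test_that("permutation threshold follows the type-7 quantile rule", {
  map <- tiny_map(nm = 4)
  sim <- simulate_backcross(map, cross_spec(60, 12e6, effect = 0.5,
                                            seed = 6))
  y <- sim$pheno$glucose
  expect_error(permutation_threshold(sim$geno, y, map, n_perm = 10),
               "n_perm")
  expect_error(permutation_threshold(sim$geno, y, map, alpha = 0),
               "alpha")
  # identity permutation only: threshold equals the observed max LOD
  obs <- max(em_scan(sim$geno, y, map, step_bp = 1e6)$lod)
  pn <- permutation_threshold(sim$geno, y, map, step_bp = 1e6,
                              .permutations = list(seq_along(y)))
  expect_equal(pn$threshold, obs, tolerance = 1e-9)
  # order-statistics oracle at n_perm = 100, alpha = 0.01 (type-7)
  set.seed(8)
  perms <- replicate(100, sample(seq_along(y)), simplify = FALSE)
  pn100 <- permutation_threshold(sim$geno, y, map, step_bp = 1e6,
                                 .permutations = perms, alpha = 0.01)
  expect_equal(pn100$threshold,
               unname(quantile(pn100$max_lod, 0.99, type = 7)))
  s <- sort(pn100$max_lod)
  expect_equal(pn100$threshold, s[100] * 0.01 + s[99] * 0.99,
               tolerance = 1e-9)
})

test_that("peak_effects: hand-computed Welch t, Bonferroni rule,
           degenerate classes", {
  geno <- cbind(mk = c("NN", "NN", "NN", "NB", "NB", "NB"))
  rownames(geno) <- paste0("i", 1:6)
  pheno <- data.frame(id = rownames(geno),
                      glucose = c(10, 12, 14, 7, 8, 9))
  pe <- peak_effects(geno, pheno, "mk")
  # hand calculation: means 12 and 8, s1^2 = 4, s2^2 = 1, n = 3 each
  expect_equal(pe$summary$mean, c(8, 12))
  t_hand <- (12 - 8) / sqrt(4 / 3 + 1 / 3)
  expect_equal(abs(pe$tests$statistic), t_hand, tolerance = 1e-12)
  expect_equal(pe$tests$p, t.test(c(10, 12, 14), c(7, 8, 9))$p.value)
  # identical class values -> zero difference
  ph0 <- data.frame(id = rownames(geno), glucose = rep(5, 6))
  pe0 <- peak_effects(geno, ph0, "mk")
  expect_equal(diff(pe0$summary$mean), 0)
  # three classes: omnibus ANOVA + pairwise Bonferroni p = min(1, 3 raw)
  g3 <- cbind(mk = rep(c("BB", "NB", "NN"), each = 4))
  rownames(g3) <- paste0("j", 1:12)
  set.seed(1)
  ph3 <- data.frame(id = rownames(g3), glucose = rnorm(12))
  pe3 <- peak_effects(g3, ph3, "mk")
  pair <- pe3$tests[pe3$tests$comparison != "omnibus", ]
  expect_equal(nrow(pair), 3)
  expect_equal(pair$p_adj, pmin(1, 3 * pair$p))
  # class with < 2 members excluded with a warning
  g2 <- cbind(mk = c("NN", "NN", "NN", "NB"))
  rownames(g2) <- paste0("k", 1:4)
  ph2 <- data.frame(id = rownames(g2), glucose = c(1, 2, 3, 4))
  expect_warning(pe2 <- peak_effects(g2, ph2, "mk"), "excluding")
  expect_equal(pe2$summary$class, "NN")
})
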