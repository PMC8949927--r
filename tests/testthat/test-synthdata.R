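test_that("genetic_map and cross_spec enforce their invariants", {
  expect_error(genetic_map("1", c("a", "a"), c(1, 2), c(0, 1)), "unique")
  expect_error(genetic_map("1", c("a", "b"), c(2, 1), c(0, 1)),
               "increasing")
  expect_error(genetic_map("1", c("a", "b"), c(1, 2), c(1, 0)),
               "increasing")
  expect_error(cross_spec(1, 1e6), "n must be >= 2")
  expect_error(cross_spec(10, 1e6, sigma = 0), "sigma")
  map <- tiny_map()
  expect_error(simulate_backcross(map, cross_spec(10, 1e9)),
               "outside the map span")
})

test_that("backcross genotype classes converge to 1:1", {
  map <- tiny_map()
  sim <- simulate_backcross(map, cross_spec(10000, 14e6, effect = 0,
                                            seed = 3))
  p_nn <- mean(sim$geno == "NN")
  # binomial CI at n = 10000 x 6 markers; use 4 SE of the marker-wise mean
  expect_lt(abs(p_nn - 0.5), 4 * sqrt(0.25 / 10000))
})

test_that("adjacent-marker recombination matches Haldane r(d)", {
  map <- tiny_map(nm = 4, by = 4e6)     # 2 cM gaps
  sim <- simulate_backcross(map, cross_spec(10000, 12e6, effect = 0,
                                            seed = 5))
  r_exp <- haldane(0.02)
  # pooled over the three equal 2 cM gaps: 30 000 Bernoulli draws
  r_obs <- mean(sim$geno[, 1:3] != sim$geno[, 2:4])
  expect_lt(abs(r_obs - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / 30000))
})

test_that("zero cM distance gives identical genotype columns", {
  map <- genetic_map("1", c("a", "b"), c(1e6, 1e6 + 1), c(0, 1e-9))
  sim <- simulate_backcross(map, cross_spec(500, 1e6, seed = 1))
  expect_equal(sim$geno[, 1], sim$geno[, 2])
})

test_that("null cross gives a central t statistic and planted effect is
           recovered at a marker on the QTL", {
  map <- tiny_map()
  # a = 0: marker association null
  sim0 <- simulate_backcross(map, cross_spec(2000, 14e6, effect = 0,
                                             seed = 7))
  t0 <- t.test(sim0$pheno$glucose ~ sim0$geno[, "m03"])$statistic
  expect_lt(abs(t0), 4)
  # a = 1, sigma = 1, marker at the QTL: group mean difference within 3 SE
  sim1 <- simulate_backcross(map, cross_spec(10000, 14e6, effect = 1,
                                             sigma = 1, seed = 7))
  g <- sim1$geno[, "m03"]; y <- sim1$pheno$glucose
  d <- mean(y[g == "NN"]) - mean(y[g == "NB"])
  se <- sqrt(var(y[g == "NN"]) / sum(g == "NN") +
               var(y[g == "NB"]) / sum(g == "NB"))
  expect_lt(abs(d - 1), 3 * se)
})

test_that("make_snp_catalog honors the declared block layout", {
  blk <- data.frame(start = 10.25e6, end = 10.75e6, density = 150)
  cat1 <- make_snp_catalog("1", 10e6, 11e6, blk, background = 40,
                           seed = 2)
  prof <- window_counts(cat1, "1", 10e6, 11e6)
  inside <- prof$start >= 10.25e6 & prof$end <= 10.75e6
  expect_true(all(prof$n_discordant[inside] > 150))
  expect_true(all(prof$n_discordant[!inside] < 40))
  # [PAPER] downstream 100/window threshold: density 150 -> all polymorphic
  called <- call_polymorphic(prof, 100)
  expect_equal(called$profiles$polymorphic, inside)
  # density 40 -> no window polymorphic (brute-force window scan oracle)
  cat2 <- make_snp_catalog("1", 10e6, 11e6,
                           data.frame(start = numeric(), end = numeric(),
                                      density = numeric()),
                           background = 40, seed = 2)
  br <- window_counts_brute(cat2, "1", 10e6, 11e6, 250000)
  expect_true(all(br$n_discordant < 100))
  expect_false(any(call_polymorphic(
    window_counts(cat2, "1", 10e6, 11e6), 100)$profiles$polymorphic))
  # empty layout => no discordant SNPs requires background 0
  cat3 <- make_snp_catalog("1", 10e6, 11e6,
                           data.frame(start = numeric(), end = numeric(),
                                      density = numeric()),
                           background = 0, concordant = 10, seed = 2)
  expect_equal(sum(cat3$allele_a != cat3$allele_b), 0)
  expect_error(make_snp_catalog("1", 10e6, 11e6,
                                data.frame(start = c(10e6, 10.25e6),
                                           end = c(10.5e6, 10.75e6),
                                           density = 150)),
               "overlap")
})

test_that("cascade fixture embodies the planted counts at any seed", {
  for (s in c(7L, 23L)) {
    fix <- make_cascade_fixture(s)
    expect_equal(nrow(fix$annotation), 644)
    expect_equal(as.vector(table(fix$annotation$biotype)[
      c("coding", "gene_model", "miRNA", "riken")]),
      c(208, 377, 8, 51))
    prof <- window_counts(fix$catalog, "13", 78e6, 120.4e6)
    kept <- filter_genes(fix$annotation, call_polymorphic(prof, 100))
    expect_equal(nrow(kept), 111)
    de_par <- de_filter(compute_lfc(fix$expr$parental))
    expect_setequal(intersect(de_par, kept$gene_id), fix$truth$de_parental)
    de_con <- intersect(de_filter(compute_lfc(fix$expr$congenic)), de_par)
    expect_setequal(de_con, fix$truth$candidates)
  }
})

test_that("single-cell generator is deterministic and marker means peak in
           BetaP", {
  sc1 <- make_single_cell(seed = 9)
  sc2 <- make_single_cell(seed = 9)
  expect_identical(sc1$counts, sc2$counts)
  for (g in c("Mki67", "S100z", "Iqgap2")) {
    mu <- tapply(sc1$counts[, g], sc1$clusters, mean)
    expect_equal(names(which.max(mu)), "BetaP")
    expect_true(all(mu["BetaP"] > mu[names(mu) != "BetaP"]))
  }
  expect_error(make_single_cell(clusters = c(islet_clusters(), "BetaX")),
               "unknown cluster")
  # all-zero means -> all-zero matrix
  m0 <- matrix(0, 2, 8, dimnames = list(c("a", "b"), islet_clusters()))
  sc0 <- make_single_cell(means = m0, n_per_cluster = 3, seed = 1)
  expect_true(all(sc0$counts == 0))
})
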