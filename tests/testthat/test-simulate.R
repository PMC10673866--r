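test_that("ancestral pools diverge to the configured Fst", {
  cfg <- sim_config(n_snp = 1500, seed = 5)
  pools <- simulate_ancestral_pools(cfg)
  expect_true(all(pools$freq_bi >= 0 & pools$freq_bi <= 1))
  expect_true(all(pools$freq_bt >= 0 & pools$freq_bt <= 1))
  # draw 200 + 200 haplotypes SNP-wise from the pool frequencies and
  # estimate Fst with an independent Hudson-style estimator
  set.seed(1)
  h1 <- matrix(rbinom(200 * cfg$n_snp, 1, rep(pools$freq_bi, each = 200)), 200)
  h2 <- matrix(rbinom(200 * cfg$n_snp, 1, rep(pools$freq_bt, each = 200)), 200)
  expect_lt(abs(fst_hudson(h1, h2) - 0.3), 0.05)
  # near-zero divergence limit
  cfg0 <- sim_config(n_snp = 1500, divergence_fst = 0.005, seed = 5)
  pools0 <- simulate_ancestral_pools(cfg0)
  set.seed(2)
  h1 <- matrix(rbinom(200 * cfg$n_snp, 1, rep(pools0$freq_bi, each = 200)), 200)
  h2 <- matrix(rbinom(200 * cfg$n_snp, 1, rep(pools0$freq_bt, each = 200)), 200)
  expect_lt(abs(fst_hudson(h1, h2)), 0.03)
})

test_that("the reference panel matches pool frequencies and is reproducible", {
  cfg <- sim_config(n_snp = 800, n_ref_bi = 60, n_ref_bt = 60,
                    founder_pool_size = 40, seed = 9)
  pools <- simulate_ancestral_pools(cfg)
  panel <- simulate_reference_panel(cfg, pools)
  g <- panel$genotypes
  expect_equal(length(g$animal_ids), 120)
  # labels partition the panel
  expect_setequal(panel$labels$animal_id, g$animal_ids)
  expect_equal(sum(panel$labels$subspecies == "indicus"), 60)
  # observed allele frequencies track the pool frequencies (binomial error
  # plus founder-pool sampling noise at K = 40 founders)
  bi <- panel$labels$animal_id[panel$labels$subspecies == "indicus"]
  rows <- match(bi, g$animal_ids)
  obs <- (colSums(g$hap0[rows, ]) + colSums(g$hap1[rows, ])) / (2 * length(bi))
  expect_lt(mean(abs(obs - pools$freq_bi)), 0.08)
  expect_gt(cor(obs, pools$freq_bi), 0.9)
  # same seed: identical; different seed: different
  panel2 <- simulate_reference_panel(cfg, pools)
  expect_identical(panel2$genotypes$hap0, g$hap0)
  cfg2 <- sim_config(n_snp = 800, n_ref_bi = 60, n_ref_bt = 60,
                     founder_pool_size = 40, seed = 10)
  pools2 <- simulate_ancestral_pools(cfg2)
  panel3 <- simulate_reference_panel(cfg2, pools2)
  expect_false(identical(panel3$genotypes$hap0, g$hap0))
})

test_that("hybrid ancestry tracts realise the profile's indicus fraction", {
  cfg <- sim_config(n_snp = 1000, n_target_per_breed = 200,
                    breed_profiles = tibble::tibble(name = "half",
                                                    indicus_fraction = 0.5,
                                                    generations = 8),
                    seed = 13)
  pools <- simulate_ancestral_pools(cfg)
  hyb <- simulate_hybrids(cfg, pools)
  tr <- hyb$truth
  frac <- mean(c(tr$ancestry0, tr$ancestry1) == "Bi")
  expect_lt(abs(100 * frac - 50), 3)
  # truth covers every animal x window and diplotype is consistent
  expect_equal(nrow(tr), 200 * nrow(pools$windows))
  expect_identical(tr$diplotype, classify_diplotype(tr$ancestry0, tr$ancestry1))
  # a strongly graded profile still carries rare taurus tracts
  cfg9 <- sim_config(n_snp = 600, n_target_per_breed = 60,
                     breed_profiles = tibble::tibble(name = "graded",
                                                     indicus_fraction = 0.9,
                                                     generations = 10),
                     seed = 14)
  pools9 <- simulate_ancestral_pools(cfg9)
  hyb9 <- simulate_hybrids(cfg9, pools9)
  anc9 <- c(hyb9$truth$ancestry0, hyb9$truth$ancestry1)
  expect_gt(mean(anc9 == "Bi"), 0.85)
  expect_gt(sum(anc9 == "Bt"), 0)
})

test_that("QTL effect triples follow the configured cross-origin correlation", {
  cfg0 <- sim_config(n_snp = 4000, n_chrom = 4, n_qtl = 150,
                     effect_correlation = 0, qtl_variance_fraction = NA, seed = 21)
  pools0 <- simulate_ancestral_pools(cfg0)
  q0 <- assign_qtl_effects(cfg0, pools0)
  expect_equal(nrow(q0), 150)
  expect_false(anyDuplicated(q0$window) > 0)
  expect_lt(abs(cor(q0$beta_bi, q0$beta_bt)), 0.17)
  cfg1 <- sim_config(n_snp = 1000, n_qtl = 50, effect_correlation = 1, seed = 22)
  pools1 <- simulate_ancestral_pools(cfg1)
  q1 <- assign_qtl_effects(cfg1, pools1)
  expect_equal(q1$beta_bi, q1$beta_bt)
  expect_equal(q1$beta_bi, q1$beta_bx)
  # QTL land on SNP common in both ancestral pools
  maf <- function(f) pmin(f, 1 - f)
  expect_true(all(maf(pools1$freq_bi[q1$snp_index]) >= cfg1$qtl_min_maf))
  expect_true(all(maf(pools1$freq_bt[q1$snp_index]) >= cfg1$qtl_min_maf))
  # no QTL: empty table
  cfgz <- sim_config(n_qtl = 0, seed = 23)
  expect_equal(nrow(assign_qtl_effects(cfgz, simulate_ancestral_pools(cfgz))), 0)
})

test_that("phenotypes realise the configured heritability and equal QTL shares", {
  cfg <- sim_config(n_snp = 500, n_chrom = 1, n_target_per_breed = 334,
                    n_qtl = 8, h2 = 0.20, seed = 31)
  pools <- simulate_ancestral_pools(cfg)
  hyb <- simulate_hybrids(cfg, pools)
  qtl <- assign_qtl_effects(cfg, pools)
  phe <- simulate_phenotypes(hyb$genotypes, hyb$truth, qtl, cfg, hyb$breeds)
  # realised h2: var(TBV) over var(phenotype - fixed effects)
  resid_pheno <- phe$tbv + (phe$phenotypes$trait - phe$tbv -
    phe$fixed$cg_eff[as.character(phe$phenotypes$cg)] -
    phe$fixed$age_slope * (phe$phenotypes$age - mean(cfg$age_range)) - 2.5)
  h2_real <- var(phe$tbv) / var(resid_pheno)
  expect_lt(abs(h2_real - 0.20), 0.03)
  # each QTL contributes an equal share of the genetic variance
  D <- dosage(hyb$genotypes)
  shares <- sapply(seq_len(nrow(phe$qtl)), function(qi) {
    w <- phe$qtl$window[qi]
    tw <- hyb$truth[hyb$truth$window == w, ]
    cls <- tw$diplotype[match(hyb$genotypes$animal_ids, tw$animal_id)]
    beta <- c(Bi = phe$qtl$beta_bi[qi], Bt = phe$qtl$beta_bt[qi],
              Bx = phe$qtl$beta_bx[qi])[cls]
    var(D[, phe$qtl$snp_index[qi]] * beta)
  })
  expect_equal(shares / sum(shares), rep(1 / 8, 8), tolerance = 1e-6)
  # regression of phenotype on TBV is ~1 (fixed effects are independent)
  expect_equal(unname(coef(lm(phe$phenotypes$trait ~ phe$tbv))[2]), 1,
               tolerance = 0.15)
  # h2 = 1: phenotype equals TBV plus fixed effects exactly
  cfg1 <- sim_config(n_snp = 300, n_chrom = 1, n_target_per_breed = 30,
                     n_qtl = 4, h2 = 1, seed = 32)
  pools1 <- simulate_ancestral_pools(cfg1)
  hyb1 <- simulate_hybrids(cfg1, pools1)
  qtl1 <- assign_qtl_effects(cfg1, pools1)
  phe1 <- simulate_phenotypes(hyb1$genotypes, hyb1$truth, qtl1, cfg1, hyb1$breeds)
  fx <- phe1$fixed$cg_eff[as.character(phe1$phenotypes$cg)] +
    phe1$fixed$age_slope * (phe1$phenotypes$age - mean(cfg1$age_range)) + 2.5
  expect_equal(phe1$phenotypes$trait, unname(phe1$tbv + fx), tolerance = 1e-12)
  # no QTL: pure-noise trait with unit residual scale
  cfgz <- sim_config(n_snp = 300, n_chrom = 1, n_target_per_breed = 30,
                     n_qtl = 0, seed = 33)
  poolsz <- simulate_ancestral_pools(cfgz)
  hybz <- simulate_hybrids(cfgz, poolsz)
  phez <- simulate_phenotypes(hybz$genotypes, hybz$truth,
                              assign_qtl_effects(cfgz, poolsz), cfgz, hybz$breeds)
  expect_equal(phez$tbv, setNames(rep(0, length(hybz$genotypes$animal_ids)),
                                  hybz$genotypes$animal_ids))
})

test_that("the one-shot study wires all components together deterministically", {
  cfg <- sim_config(n_snp = 400, n_chrom = 2, n_ref_bi = 20, n_ref_bt = 20,
                    n_target_per_breed = 10, n_qtl = 3, seed = 51)
  s1 <- simulate_hybrid_study(cfg)
  s2 <- simulate_hybrid_study(cfg)
  expect_identical(s1$target$hap0, s2$target$hap0)
  expect_identical(s1$phenotypes$trait, s2$phenotypes$trait)
  expect_identical(s1$qtl, s2$qtl)
  expect_setequal(names(s1), c("pools", "ref", "labels", "target", "breeds",
                               "truth", "qtl", "phenotypes", "tbv", "sigma_e2",
                               "windows", "map", "cfg"))
  # breeds cover the three default profiles
  expect_equal(length(unique(s1$breeds$breed)), 3)
})
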