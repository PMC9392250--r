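test_that("pedigree simulation respects ordering, founders and determinism", {
  cfg <- sim_config(n_founders = 10, n_generations = 0, seed = 4)
  ped <- sim_pedigree(cfg)
  expect_equal(nrow(ped), 10L)
  expect_true(all(ped$sire == 0L & ped$dam == 0L))

  cfg2 <- sim_config(n_founders = 4, n_generations = 2,
                     n_per_generation = 8, prop_sires = 0.5, seed = 9)
  ped2 <- sim_pedigree(cfg2)
  pos <- match(ped2$animal, ped2$animal)
  for (col in c("sire", "dam")) {
    known <- ped2[[col]] != 0L
    expect_true(all(match(ped2[[col]][known], ped2$animal) <
                      which(known)))
  }
  expect_true(all(ped2$generation[ped2$sire != 0L] >= 1L))

  expect_identical(sim_pedigree(cfg2), sim_pedigree(cfg2))
  expect_error(sim_config(n_founders = 0), "founders")
  expect_error(sim_config(n_founders = 10, n_generations = -1),
               "n_generations")
})

test_that("gene dropping transmits alleles and matches founder frequencies", {
  ## monomorphic transmission: parents 0/0 at a SNP -> offspring 0
  cfg <- sim_config(n_founders = 20, n_generations = 2,
                    n_per_generation = 40, n_chromosomes = 1,
                    snps_per_chromosome = 30, seed = 21)
  sim <- sim_dataset(cfg)
  X <- sim$genotypes$X
  ped <- sim$pedigree
  off <- which(ped$sire != 0L & ped$dam != 0L)
  for (i in off[1:10]) {
    s <- as.character(ped$sire[i]); d <- as.character(ped$dam[i])
    zero_both <- X[s, ] == 0L & X[d, ] == 0L
    expect_true(all(X[as.character(ped$animal[i]), zero_both] == 0L))
    two_both <- X[s, ] == 2L & X[d, ] == 2L
    expect_true(all(X[as.character(ped$animal[i]), two_both] == 2L))
  }

  ## founder allele frequency concentrates at the configured p
  cfg_f <- sim_config(n_founders = 10000, n_generations = 0,
                      n_chromosomes = 1, snps_per_chromosome = 12,
                      maf_low = 0.499999, maf_high = 0.5, seed = 2)
  simf <- sim_dataset(cfg_f)
  pf <- allele_freq(simf$genotypes)
  expect_true(all(abs(pf - 0.5) < 0.02))
})

test_that("parent-offspring genomic relationship is about one half", {
  cfg <- sim_config(n_founders = 100, n_generations = 2,
                    n_per_generation = 200, n_chromosomes = 4,
                    snps_per_chromosome = 150, maf_low = 0.1, seed = 31)
  sim <- sim_dataset(cfg)
  geno <- sim$genotypes
  ## centre at founder frequencies so G is on the base-population scale
  G <- build_G(geno, p = geno$map$founder_freq)
  ped <- sim$pedigree
  off <- ped[ped$sire != 0L, ]
  po <- mapply(function(a, s) G[as.character(a), as.character(s)],
               off$animal, off$sire)
  expect_lt(abs(mean(po) - 0.5), 0.05)
})

test_that("phenotype variance structure matches the requested components", {
  ## pure-noise limit: only residual variance remains
  cfg0 <- sim_config(n_founders = 4000, n_generations = 0,
                     n_chromosomes = 1, snps_per_chromosome = 5,
                     sigma2_a = 0, sigma2_pe = 0, sigma2_e = 0.25,
                     thi_beta = 0, fixed_effect_sd = 0, n_farmyear = 1,
                     n_parity = 1, n_stage = 1, n_milkstatus = 1,
                     records_per_animal = c(3, 3), seed = 5)
  ped0 <- sim_pedigree(cfg0)
  phe0 <- sim_phenotypes(ped0, NULL, cfg0)
  expect_gt(nrow(phe0), 10000)
  expect_lt(abs(var(phe0$y) / 0.25 - 1), 0.05)

  ## within-animal correlation of repeated records approximates t
  cfg <- sim_config(n_founders = 3000, n_generations = 0,
                    n_chromosomes = 1, snps_per_chromosome = 5,
                    sigma2_a = 0.3, sigma2_pe = 0.3, sigma2_e = 0.4,
                    thi_beta = 0, fixed_effect_sd = 0, n_farmyear = 1,
                    n_parity = 1, n_stage = 1, n_milkstatus = 1,
                    records_per_animal = c(2, 2), seed = 6)
  ped <- sim_pedigree(cfg)
  phe <- sim_phenotypes(ped, NULL, cfg)
  first <- phe[!duplicated(phe$animal), ]
  second <- phe[duplicated(phe$animal), ]
  second <- second[match(first$animal, second$animal), ]
  t_hat <- cor(first$y, second$y)
  expect_lt(abs(t_hat - 0.6), 0.05)

  expect_error(sim_config(sigma2_e = -1), "non-negative")
})

test_that("the THI regression coefficient is recoverable by OLS", {
  cfg <- sim_config(n_founders = 2500, n_generations = 0,
                    n_chromosomes = 1, snps_per_chromosome = 5,
                    sigma2_a = 0.015, sigma2_pe = 0.03, sigma2_e = 0.2,
                    thi_beta = 0.05, fixed_effect_sd = 0, n_farmyear = 1,
                    n_parity = 1, n_stage = 1, n_milkstatus = 1,
                    records_per_animal = c(2, 2), seed = 8)
  ped <- sim_pedigree(cfg)
  phe <- sim_phenotypes(ped, NULL, cfg)
  beta <- coef(lm(y ~ thi, phe))["thi"]
  expect_lt(abs(beta - 0.05), 0.01)
})

test_that("QTL effects are scaled to the requested variance share", {
  cfg <- sim_config(n_founders = 2000, n_generations = 0,
                    n_chromosomes = 2, snps_per_chromosome = 50,
                    n_qtl = 5, qtl_var_frac = 0.4, sigma2_a = 0.2,
                    seed = 13)
  sim <- sim_dataset(cfg)
  qtl <- sim$qtl
  expect_equal(nrow(qtl), 5L)
  expect_equal(sum(2 * qtl$founder_freq * (1 - qtl$founder_freq) *
                     qtl$effect^2), 0.4 * 0.2, tolerance = 1e-12)
  ## realised TBV variance close to sigma2_a
  tbv <- attr(sim$phenotypes, "tbv")
  expect_lt(abs(var(tbv) / 0.2 - 1), 0.15)
})
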