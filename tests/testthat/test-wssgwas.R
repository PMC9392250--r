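## a founder panel whose G (at founder frequencies) is full rank
founder_panel <- function(seed = 7, n = 40, m = 120) {
  cfg <- sim_config(n_founders = n, n_generations = 0, n_chromosomes = 2,
                    snps_per_chromosome = m / 2, maf_low = 0.2, seed = seed)
  sim <- sim_dataset(cfg)
  list(geno = sim$genotypes, p = sim$map$founder_freq, sim = sim)
}

test_that("backsolved SNP effects match hand arithmetic and the projection identity", {
  ## hand fixture: 2 individuals, 1 SNP, genotypes {0, 2}, p = 0.5
  X <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("i1", "i2"), "s1"))
  g <- genotypes(X, data.frame(snp = "s1", chrom = 1L, pos = 50L))
  ## G = [[2,-2],[-2,2]] (singular), blended with A22 = I at alpha = 0.5:
  ## G* = [[1.5,-1],[-1,1.5]], G*^-1 = [[1.2,0.8],[0.8,1.2]]
  G_star_inv <- matrix(c(1.2, 0.8, 0.8, 1.2), 2)
  a_hat <- c(i1 = -1, i2 = 1)
  ## u = (1/k) Zc' G*^-1 a = 2 * ((-1)(-0.4) + (1)(0.4)) = 1.6
  u <- backsolve_snp_effects(a_hat, g, G_star_inv, p = 0.5)
  expect_equal(unname(u), 1.6, tolerance = 1e-10)
  ## zero GEBV give zero effects
  expect_equal(unname(backsolve_snp_effects(c(i1 = 0, i2 = 0), g,
                                            G_star_inv, p = 0.5)), 0)

  ## projection identity: alpha = 0, full-rank G (founder frequencies,
  ## M >= n) -> Z_c u reproduces the GEBV
  fp <- founder_panel()
  G <- build_G(fp$geno, p = fp$p)
  Gi <- solve(G)
  set.seed(12)
  a_g <- setNames(rnorm(nrow(fp$geno$X)), rownames(fp$geno$X))
  u2 <- backsolve_snp_effects(a_g, fp$geno, Gi, p = fp$p)
  Zc <- fp$geno$X - matrix(2 * fp$p, nrow(fp$geno$X), ncol(fp$geno$X),
                           byrow = TRUE)
  expect_lt(max(abs(drop(Zc %*% u2) - a_g)), 1e-6)
})

test_that("the SNP weight rule has the documented fixed points", {
  ## construct effects with known |u|/sd ratios: sd computed from the data
  u <- c(2, -2, 0, 7, 2, -2, 2, -2)
  s <- sd(u)
  w <- snp_weights(u)
  ## pre-rescaling values via the rule, then the same rescaling
  raw <- 1.125 ^ (pmin(abs(u) / s, 5) - 2)
  expect_equal(unname(w), raw * length(u) / sum(raw), tolerance = 1e-12)
  ## canonical fixed points of the rule before rescaling
  expect_equal(1.125 ^ ((2 * s) / s - 2), 1)
  expect_equal(1.125 ^ (0 / s - 2), 0.79012345679, tolerance = 1e-10)
  expect_equal(1.125 ^ (5 - 2), 1.423828125)     # cap at 5 sd
  ## rescaling conserves the SNP count
  expect_equal(sum(w), length(u), tolerance = 1e-8)
  ## degenerate all-equal effects
  expect_warning(w0 <- snp_weights(rep(0, 5)), "identity")
  expect_equal(unname(w0), rep(1, 5))
})

test_that("window scan matches brute-force and linkage-equilibrium oracles", {
  fp <- founder_panel(seed = 17, n = 1000, m = 60)
  geno <- fp$geno
  set.seed(18)
  u <- rnorm(ncol(geno$X), 0, 0.01)
  s2a <- 0.015
  scan <- window_variance_scan(u, geno, s2a, window_size = 10, step = 1,
                               p = fp$p)
  ## brute-force per-individual loop on one chromosome of windows
  map <- geno$map
  idx1 <- which(map$chrom == 1)
  Zc <- geno$X - matrix(2 * fp$p, nrow(geno$X), ncol(geno$X), byrow = TRUE)
  for (w in c(1, 7, 15)) {
    cols <- idx1[w:(w + 9)]
    av <- numeric(nrow(Zc))
    for (i in seq_len(nrow(Zc))) av[i] <- sum(Zc[i, cols] * u[cols])
    v_brute <- mean((av - mean(av))^2)           # population variance
    row <- scan[scan$chrom == 1 & scan$start_index == cols[1], ]
    expect_equal(row$var_window, v_brute, tolerance = 1e-8)
    expect_equal(row$pct_var, 100 * v_brute / s2a, tolerance = 1e-8)
  }
  ## under linkage equilibrium the window variance approximates
  ## sum 2 p (1-p) u^2 over member SNPs; individual windows carry
  ## Monte-Carlo LD noise, so the mean deviation carries the check
  obs <- scan$var_window[scan$chrom == 1][1:21]
  expct <- vapply(1:21, function(w) {
    cols <- idx1[w:(w + 9)]
    sum(2 * fp$p[cols] * (1 - fp$p[cols]) * u[cols]^2)
  }, 0)
  expect_lt(mean(abs(obs / expct - 1)), 0.10)
  expect_lt(max(abs(obs / expct - 1)), 0.30)
  ## zero effects give a zero scan
  scan0 <- window_variance_scan(rep(0, ncol(geno$X)), geno, s2a)
  expect_true(all(scan0$pct_var == 0))
  ## individual permutation invariance
  perm <- sample(nrow(geno$X))
  scan_p <- window_variance_scan(u, geno[perm, ], s2a, p = fp$p)
  expect_equal(scan_p$var_window, scan$var_window, tolerance = 1e-10)
  ## disjoint windows with step = size
  scan10 <- window_variance_scan(u, geno, s2a, window_size = 10, step = 10)
  expect_true(all(table(scan10$chrom) == 3))
  ## short chromosome flagged
  g5 <- geno[, 1:5]
  scan5 <- window_variance_scan(u[1:5], g5, s2a)
  expect_true(scan5$short && scan5$n_snps == 5)
})

test_that("significant windows merge into regions correctly", {
  scan <- data.frame(chrom = c(1, 1, 1, 1, 2),
                     start_bp = c(100, 200, 5000, 5100, 100),
                     end_bp = c(1000, 1100, 6000, 6100, 900),
                     start_index = c(1, 2, 30, 31, 61),
                     n_snps = 10L,
                     var_window = 1,
                     pct_var = c(0.3, 0.2, 0.1, 0.25, 0.5),
                     short = FALSE)
  class(scan) <- c("window_scan", "data.frame")
  reg <- significant_regions(scan, 0.15)
  ## windows 1+2 overlap (share 9 SNPs) -> one region spanning 11 SNPs;
  ## window 4 stands alone; chromosome 2 separate
  expect_equal(nrow(reg), 3L)
  r1 <- reg[reg$chrom == 1 & reg$start_bp == 100, ]
  expect_equal(r1$end_bp, 1100)
  expect_equal(r1$n_windows, 2L)
  expect_equal(r1$pct_var, 0.3)          # max member window
  expect_equal(r1$pct_sum, 0.5)          # summed member windows
  ## nothing significant -> empty table
  expect_equal(nrow(significant_regions(scan, 10)), 0L)
})

test_that("iterative weighting is a fixed point under symmetric effects and improves QTL rank", {
  d <- small_dataset(seed = 121, n_founders = 50, n_per_generation = 70,
                     n_chromosomes = 2, snps_per_chromosome = 50,
                     n_qtl = 1, qtl_var_frac = 0.6)
  s2 <- c(a = 0.015, pe = 0.03, e = 0.2)
  fml <- y ~ farmyear + thi
  ## one iteration with D = I is the plain unweighted ssGWAS
  f1 <- wssgwas(fml, d$phenotypes, d$pedigree, d$geno_qc, varcomp = s2,
                iterations = 1)
  expect_true(all(f1$iterations[[1]]$weights_in == 1))
  ## three iterations conserve the weight sum each round
  f3 <- wssgwas(fml, d$phenotypes, d$pedigree, d$geno_qc, varcomp = s2,
                iterations = 3)
  for (it in f3$iterations)
    expect_equal(sum(it$weights_out), ncol(d$geno_qc$X), tolerance = 1e-8)
  ## iteration 1 of the 3-run equals the 1-iteration run exactly
  expect_equal(f3$iterations[[1]]$effects, f1$effects, tolerance = 1e-12)
  ## scan/regions reproducible
  f3b <- wssgwas(fml, d$phenotypes, d$pedigree, d$geno_qc, varcomp = s2,
                 iterations = 3)
  expect_identical(f3$scan$pct_var, f3b$scan$pct_var)
})
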