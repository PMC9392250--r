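make_geno <- function(X) {
  m <- ncol(X)
  rownames(X) <- as.character(seq_len(nrow(X)))
  genotypes(X, data.frame(snp = paste0("s", seq_len(m)), chrom = 1L,
                          pos = seq_len(m) * 1000L))
}

test_that("individual call-rate filter counts missingness strictly", {
  set.seed(1)
  X <- matrix(rbinom(5 * 100, 2, 0.4), 5, 100)
  X[2, 1:15] <- NA            # call rate 0.85 -> removed at 0.9
  X[3, 1:10] <- NA            # call rate 0.90 exactly -> removed (strict >)
  g <- make_geno(X)
  out <- filter_individual_call_rate(g, 0.9)
  expect_setequal(attr(out, "removed"), c("2", "3"))
  expect_equal(nrow(out$X), 3L)
  ## vacuous threshold keeps everyone
  expect_equal(nrow(filter_individual_call_rate(g, 0)$X), 5L)
})

test_that("MAF filter uses strict inequality on the minor allele", {
  ## column 1: one het in 5 diploids -> p = 0.1, retained at 0.05
  ## column 2: monomorphic -> removed
  ## column 3: p = 0.05 exactly in 10 diploids -> removed (strict >)
  X10 <- rbind(matrix(0L, 9, 3), c(1L, 0L, 1L))
  X10[1, 1] <- 1L
  g <- make_geno(X10)
  p <- allele_freq(g)
  expect_equal(unname(p), c(0.1, 0, 0.05))
  out <- filter_maf(g, 0.05)
  expect_equal(colnames(out$X), "s1")
  expect_setequal(attr(out, "removed"), c("s2", "s3"))
})

test_that("Hardy-Weinberg exact test matches enumeration", {
  ## independent oracle: multinomial enumeration over all genotype splits
  ## with the observed allele count
  hwe_oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    na <- 2 * naa + nAa
    if (na > n) na <- 2 * n - na
    if (na == 0) return(1)
    hs <- seq(na %% 2, na, by = 2)
    lp <- vapply(hs, function(h) {
      n2 <- (na - h) / 2          # minor homozygotes
      n0 <- n - h - n2            # major homozygotes
      lfactorial(n) - lfactorial(n0) - lfactorial(h) - lfactorial(n2) +
        h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
        lfactorial(2 * n)
    }, 0)
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(nAa, hs)] + 1e-12])
  }
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(3, 14, 83), c(10, 1, 0),
                c(40, 20, 40), c(7, 0, 1))
  for (k in cases)
    expect_equal(hwe_exact_test(k[1], k[2], k[3]),
                 hwe_oracle(k[1], k[2], k[3]), tolerance = 1e-10)
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-9)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_equal(hwe_exact_test(0, 0, 100), 1)   # monomorphic convention
  ## allele-relabelling symmetry
  expect_equal(hwe_exact_test(3, 14, 83), hwe_exact_test(83, 14, 3))
  expect_error(hwe_exact_test(-1, 2, 3), "negative")
})

test_that("the QC chain filters in order and its report reconciles", {
  ## 6-SNP panel: s2 monomorphic (MAF), s3 p=0.05 (MAF), s4 extreme HWE,
  ## s5 on a non-autosome, s1 and s6 clean
  set.seed(42)
  n <- 100
  X <- cbind(rbinom(n, 2, 0.3),                       # s1 clean
             rep(0L, n),                              # s2 MAF 0
             c(rep(0L, 90), rep(1L, 10)),             # s3 p = 0.05
             c(rep(0L, 50), rep(2L, 50)),             # s4 HWE catastrophic
             rbinom(n, 2, 0.4),                       # s5 chrom X
             rbinom(n, 2, 0.45))                      # s6 clean
  rownames(X) <- as.character(seq_len(n))
  g <- genotypes(X, data.frame(snp = paste0("s", 1:6),
                               chrom = c(1, 1, 1, 1, 30, 2),
                               pos = c(1e3, 2e3, 3e3, 4e3, 5e3, 6e3)))
  qc <- run_qc(g, autosomes = 1:29)
  expect_setequal(colnames(qc$genotypes$X), c("s1", "s6"))
  steps <- qc$report$steps
  expect_equal(steps$autosome_position$removed, "s5")
  expect_setequal(steps$maf$removed, c("s2", "s3"))
  expect_equal(steps$hwe$removed, "s4")
  ## counts reconcile at every step
  rep_df <- as.data.frame(qc$report)
  snp_path <- c(6L, rep_df$n_snp)
  removed_snps <- c(0L, ifelse(rep_df$kind == "snps", rep_df$n_removed, 0L))
  expect_true(all(diff(snp_path) == -removed_snps[-1]))
  ## idempotence: QC of QC'd output changes nothing
  qc2 <- run_qc(qc$genotypes)
  expect_identical(qc2$genotypes$X, qc$genotypes$X)
  ## no thresholds violated -> passthrough
  clean <- qc$genotypes
  expect_identical(run_qc(clean)$genotypes$X, clean$X)
})

test_that("genotype PCA separates simulated founder groups", {
  set.seed(3)
  n <- 40; m <- 200
  p1 <- runif(m, 0.1, 0.9)
  p2 <- pmin(pmax(p1 + sample(c(-0.35, 0.35), m, TRUE), 0.05), 0.95)
  X <- rbind(matrix(rbinom(n / 2 * m, 2, rep(p1, each = n / 2)), n / 2, m),
             matrix(rbinom(n / 2 * m, 2, rep(p2, each = n / 2)), n / 2, m))
  g <- make_geno(X)
  pc <- genotype_pca(g, 4)
  expect_true(all(pc$var_explained >= 0) && sum(pc$var_explained) <= 1)
  grp <- rep(c(1, 2), each = n / 2)
  ## PC1 separates the groups: between-group gap exceeds within-group spread
  expect_gt(abs(mean(pc$scores[grp == 1, 1]) - mean(pc$scores[grp == 2, 1])),
            2 * max(sd(pc$scores[grp == 1, 1]), sd(pc$scores[grp == 2, 1])))
  ## identical individuals get identical scores
  X2 <- X; X2[2, ] <- X2[1, ]
  pc2 <- genotype_pca(make_geno(X2), 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-10)
  expect_warning(genotype_pca(make_geno(X[1:3, ]), 10), "rank")
})
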