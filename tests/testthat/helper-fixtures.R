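## shared fixtures, all generated in code

## a small three-generation dataset with genotyped subset already QC'd
small_dataset <- function(seed = 11, n_founders = 60, n_per_generation = 80,
                          n_chromosomes = 3, snps_per_chromosome = 60, ...) {
  cfg <- sim_config(n_founders = n_founders, n_generations = 2,
                    n_per_generation = n_per_generation,
                    n_chromosomes = n_chromosomes,
                    snps_per_chromosome = snps_per_chromosome,
                    prop_genotyped = 0.8, seed = seed, ...)
  sim <- sim_dataset(cfg)
  gids <- as.character(sim$pedigree$animal[sim$pedigree$genotyped])
  geno <- suppressWarnings(run_qc(sim$genotypes[gids, ]))$genotypes
  c(sim, list(geno_qc = geno, gids = rownames(geno$X)))
}

## 5-animal pedigree with a full-sib mating (offspring F = 0.25)
fullsib_pedigree <- function() {
  data.frame(animal = 1:5,
             sire = c(0L, 0L, 1L, 1L, 3L),
             dam = c(0L, 0L, 2L, 2L, 4L))
}

## joint H built the conditional (Legarra-style) way: brute-force oracle
joint_H <- function(A, G, idx_g) {
  idx_n <- setdiff(seq_len(nrow(A)), idx_g)
  A11 <- A[idx_n, idx_n, drop = FALSE]
  A12 <- A[idx_n, idx_g, drop = FALSE]
  A22 <- A[idx_g, idx_g, drop = FALSE]
  A22i <- solve(A22)
  H <- A
  H[idx_n, idx_n] <- A11 + A12 %*% A22i %*% (G - A22) %*% A22i %*% t(A12)
  H[idx_n, idx_g] <- A12 %*% A22i %*% G
  H[idx_g, idx_n] <- t(H[idx_n, idx_g])
  H[idx_g, idx_g] <- G
  H
}

## dense GLS/BLUP oracle from the phenotypic covariance V
gls_blup <- function(y, X, Za, W, A, s2a, s2pe, s2e) {
  Za <- as.matrix(Za); W <- as.matrix(W)
  V <- Za %*% A %*% t(Za) * s2a + W %*% t(W) * s2pe + diag(length(y)) * s2e
  Vi <- solve(V)
  XVX <- solve(t(X) %*% Vi %*% X)
  b <- XVX %*% t(X) %*% Vi %*% y
  r <- y - X %*% b
  a <- s2a * A %*% t(Za) %*% Vi %*% r
  pe <- s2pe * t(W) %*% Vi %*% r
  list(b = drop(b), a = drop(a), pe = drop(pe))
}
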