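test_that("design matrices follow the reference-coding contract", {
  d <- small_dataset(seed = 15)
  phe <- d$phenotypes
  des <- build_design(phe, y ~ parity + thi, d$pedigree$animal)
  ## intercept + 2 non-reference parity levels + 1 covariate
  expect_equal(ncol(des$X), 4L)
  expect_equal(unname(des$X[, "thi"]), phe$thi)  # covariate passthrough
  ## an animal's Za column has one 1 per record
  counts <- table(as.character(phe$animal))
  a <- names(counts)[counts == max(counts)][1]
  expect_equal(sum(des$Za[, a]), unname(max(counts)))
  expect_error(build_design(transform(phe, animal = animal + 10000),
                            y ~ thi, d$pedigree$animal), "absent")
})

test_that("MME-based restricted likelihood equals the dense GLS evaluation", {
  d <- small_dataset(seed = 33, n_founders = 20, n_per_generation = 25)
  des <- build_design(d$phenotypes, y ~ farmyear + thi, d$pedigree$animal)
  Ainv <- build_A_inverse(d$pedigree)
  A <- build_A(d$pedigree)
  theta <- c(a = 0.02, pe = 0.04, e = 0.18)
  l_mme <- reml_loglik(des, Ainv, theta)
  V <- as.matrix(des$Za %*% A %*% Matrix::t(des$Za)) * theta["a"] +
    as.matrix(des$W %*% Matrix::t(des$W)) * theta["pe"] +
    diag(length(des$y)) * theta["e"]
  Vi <- solve(V)
  X <- des$X; y <- des$y
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  l_gls <- -0.5 * (determinant(V)$modulus[1] +
                     determinant(XVX)$modulus[1] +
                     drop(t(y) %*% P %*% y) +
                     (length(y) - ncol(X)) * log(2 * pi))
  expect_equal(l_mme, as.numeric(l_gls), tolerance = 1e-8)
})

test_that("REML agrees with lme4 on a model both can fit", {
  set.seed(5)
  n_an <- 80
  an <- rep(seq_len(n_an), rep(2:4, length.out = n_an))
  N <- length(an)
  x <- rnorm(N)
  u <- rnorm(n_an, 0, sqrt(0.4))
  d <- data.frame(animal = an, x = x,
                  y = 1 + 0.5 * x + u[an] + rnorm(N, 0, sqrt(0.6)))
  ped <- data.frame(animal = seq_len(n_an), sire = 0L, dam = 0L)
  des <- build_design(d, y ~ x, ped$animal)
  fit <- reml_estimate(des, Matrix::Diagonal(n_an), include_pe = FALSE)
  lf <- lme4::lmer(y ~ x + (1 | animal), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(unname(fit$sigma2), vc, tolerance = 1e-4)
  ## likelihood evaluated at the reference implementation's estimates
  expect_equal(reml_loglik(des, Matrix::Diagonal(n_an),
                           c(a = vc[1], e = vc[2])),
               as.numeric(logLik(lf, REML = TRUE)), tolerance = 1e-4)
})

test_that("AI and EM converge to the same maximum and logL never decreases", {
  d <- small_dataset(seed = 41, n_founders = 30, n_per_generation = 45)
  des <- build_design(d$phenotypes, y ~ farmyear + parity + thi,
                      d$pedigree$animal)
  Ainv <- build_A_inverse(d$pedigree)
  fit_ai <- reml_estimate(des, Ainv, method = "ai", tol = 1e-8)
  fit_em <- reml_estimate(des, Ainv, method = "em", max_iter = 2000,
                          tol = 1e-8)
  expect_true(fit_ai$converged)
  expect_equal(fit_ai$sigma2, fit_em$sigma2, tolerance = 1e-3)
  expect_equal(fit_ai$logLik, fit_em$logLik, tolerance = 1e-6)
  expect_true(all(fit_ai$se[!fit_ai$boundary] > 0))
})

test_that("REML estimates are invariant to record order and location shift", {
  d <- small_dataset(seed = 51, n_founders = 25, n_per_generation = 35)
  phe <- d$phenotypes
  des <- build_design(phe, y ~ farmyear + thi, d$pedigree$animal)
  Ainv <- build_A_inverse(d$pedigree)
  fit <- reml_estimate(des, Ainv, tol = 1e-8)
  ## permuted records
  set.seed(1); perm <- sample(nrow(phe))
  des_p <- build_design(phe[perm, ], y ~ farmyear + thi, d$pedigree$animal)
  fit_p <- reml_estimate(des_p, Ainv, tol = 1e-8)
  expect_equal(fit$sigma2, fit_p$sigma2, tolerance = 1e-6)
  ## constant shift absorbed by the intercept
  phe_s <- transform(phe, y = y + 100)
  des_s <- build_design(phe_s, y ~ farmyear + thi, d$pedigree$animal)
  fit_s <- reml_estimate(des_s, Ainv, tol = 1e-8)
  expect_equal(fit$sigma2, fit_s$sigma2, tolerance = 1e-5)
})

test_that("a noise-only trait drives genetic components to the boundary", {
  cfg <- sim_config(n_founders = 120, n_generations = 2,
                    n_per_generation = 220, sigma2_a = 0, sigma2_pe = 0,
                    sigma2_e = 0.25, thi_beta = 0, fixed_effect_sd = 0,
                    n_farmyear = 1, n_parity = 1, n_stage = 1,
                    n_milkstatus = 1, records_per_animal = c(3, 4),
                    seed = 61)
  ped <- sim_pedigree(cfg)
  phe <- sim_phenotypes(ped, NULL, cfg)
  expect_gt(nrow(phe), 1500)
  des <- build_design(phe, y ~ 1, ped$animal)
  fit <- reml_estimate(des, build_A_inverse(ped), tol = 1e-7)
  expect_lt(abs(fit$sigma2["e"] / 0.25 - 1), 0.05)
  expect_lt(fit$sigma2["a"], 0.01)
  expect_lt(fit$sigma2["pe"], 0.01)
})

test_that("heritability and repeatability ratios reproduce printed values", {
  ## rectal temperature components
  expect_equal(round(heritability(c(a = 0.015, pe = 0.03, e = 0.20)), 2),
               0.06)
  ## respiratory rate score
  expect_equal(round(heritability(c(a = 0.016, pe = 0.03, e = 0.31)), 2),
               0.04)
  expect_equal(round(repeatability(c(a = 0.016, pe = 0.03, e = 0.31)), 2),
               0.13)
  ## drooling score
  expect_equal(round(repeatability(c(a = 0.011, pe = 0.03, e = 0.29)), 2),
               0.12)
  ## degenerate limits
  expect_equal(heritability(c(a = 2, pe = 0, e = 0)), 1)
  expect_equal(repeatability(c(a = 1, pe = 1, e = 0)), 1)
  expect_error(heritability(c(a = 0, pe = 0, e = 0)), "zero")
})

test_that("bivariate REML recovers a strong genetic correlation", {
  ## two traits sharing genetics (r_a = 0.7), simulated on one pedigree
  cfg <- sim_config(n_founders = 50, n_generations = 2,
                    n_per_generation = 85, seed = 71, thi_beta = 0,
                    fixed_effect_sd = 0, n_farmyear = 1, n_parity = 1,
                    n_stage = 1, n_milkstatus = 1,
                    sigma2_a = 0.3, sigma2_pe = 0.15, sigma2_e = 0.55,
                    records_per_animal = c(2, 3))
  ped <- sim_pedigree(cfg)
  phe <- sim_phenotypes(ped, NULL, cfg)
  set.seed(72)
  r_a <- 0.7
  n_an <- nrow(ped)
  tbv1 <- attr(phe, "tbv")
  ## second trait's TBV = r * tbv1 + sqrt(1-r^2) * independent polygene
  cfg2 <- cfg; cfg2$seed <- 720L
  tbv2 <- r_a * tbv1 + sqrt(1 - r_a^2) *
    attr(sim_phenotypes(ped, NULL, cfg2), "tbv")
  idx <- match(as.character(phe$animal), names(tbv2))
  y2 <- 10 + tbv2[idx] + rnorm(n_an, 0, sqrt(0.15))[match(
    as.character(phe$animal), as.character(ped$animal))] +
    rnorm(nrow(phe), 0, sqrt(0.55))
  des <- build_design(phe, y ~ 1, ped$animal)
  fit2 <- reml_bivariate(des, cbind(phe$y, y2), build_A_inverse(ped),
                         max_eval = 800)
  r_hat <- genetic_correlation(fit2)
  expect_gt(r_hat, 0.35)
  expect_lte(abs(r_hat), 1)
  ## duplicated trait has correlation 1; zero covariance gives 0
  expect_equal(genetic_correlation(matrix(c(1, 0, 0, 2), 2)), 0)
  expect_equal(genetic_correlation(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_error(genetic_correlation(matrix(c(0, 0, 0, 1), 2)), "zero")
})
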