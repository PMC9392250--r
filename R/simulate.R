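#' Simulation configuration
#'
#' Builds the configuration list driving the pedigree / gene-dropping /
#' phenotype simulator. Defaults emulate a dairy heat-stress study at desk
#' scale: a multi-generation pedigree with a small proportion of sires, a
#' biallelic autosomal SNP panel, and repeated records per cow carrying
#' farm-year, parity (1/2/3+), lactation-stage, milking-status and a linear
#' temperature-humidity-index (THI) covariate on top of additive,
#' permanent-environmental and residual variation. Default variance
#' components (0.015 / 0.03 / 0.20, trait squared units) give heritability
#' 0.06 and repeatability 0.18, the magnitudes typical of physiological
#' heat-tolerance indicators such as rectal temperature.
#'
#' @param n_founders number of founder animals (generation 0).
#' @param n_generations number of offspring generations bred beyond the
#'   founders; 0 gives a founders-only pedigree.
#' @param n_per_generation offspring born into each generation.
#' @param prop_sires proportion of males among founders/parents; mating is a
#'   random union of a sire and a distinct dam from the previous generation.
#' @param prop_genotyped proportion of animals (sampled from the last two
#'   generations) flagged as genotyped.
#' @param n_chromosomes,snps_per_chromosome marker panel dimensions.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param maf_low,maf_high bounds of the founder minor-allele-frequency
#'   spectrum (uniform draw per SNP).
#' @param n_qtl number of marker QTL; 0 gives a purely polygenic trait.
#' @param qtl_var_frac fraction of `sigma2_a` explained by the marker QTL
#'   jointly (remainder is polygenic).
#' @param qtl_effects optional vector of per-QTL allele substitution effects;
#'   when `NULL` effects are drawn standard normal and rescaled to
#'   `qtl_var_frac * sigma2_a`.
#' @param qtl_var_shares optional vector (length `n_qtl`, summing to 1) of
#'   each QTL's share of the marker-linked variance; effects are then scaled
#'   per QTL so QTL `q` explains exactly `qtl_var_shares[q] * qtl_var_frac *
#'   sigma2_a` at founder frequencies. Overrides the joint rescaling.
#' @param sigma2_a,sigma2_pe,sigma2_e additive, permanent-environmental and
#'   residual variances (trait squared units).
#' @param n_farmyear,n_parity,n_stage,n_milkstatus numbers of levels of the
#'   cross-classified fixed effects.
#' @param fixed_effect_sd standard deviation of the simulated level effects
#'   (trait units).
#' @param trait_mean overall mean (default resembles rectal temperature, deg C).
#' @param thi_range range of the uniform per-record THI draw (index units).
#' @param thi_beta linear THI regression coefficient (trait units per THI unit).
#' @param records_per_animal integer range `c(min, max)` of repeated records.
#' @param recombination if `TRUE` gametes recombine under a Haldane model at
#'   `morgan_per_bp` Morgans per base pair; the default drops every SNP
#'   independently (no linkage), which suffices for relationship-matrix and
#'   window-variance work.
#' @param morgan_per_bp map length density used when `recombination = TRUE`.
#' @param seed integer seed from which every stochastic stage derives its RNG
#'   state; identical configs give bit-identical simulations.
#' @return a classed list (`sim_config`) of validated settings.
#' @export
sim_config <- function(n_founders = 100, n_generations = 2,
                       n_per_generation = 150, prop_sires = 0.1,
                       prop_genotyped = 0.5,
                       n_chromosomes = 5, snps_per_chromosome = 100,
                       chrom_length_bp = 1e8,
                       maf_low = 0.05, maf_high = 0.5,
                       n_qtl = 0, qtl_var_frac = 0.5, qtl_effects = NULL,
                       qtl_var_shares = NULL,
                       sigma2_a = 0.015, sigma2_pe = 0.03, sigma2_e = 0.20,
                       n_farmyear = 10, n_parity = 3, n_stage = 7,
                       n_milkstatus = 3, fixed_effect_sd = 0.2,
                       trait_mean = 38.8,
                       thi_range = c(70.5, 90.2), thi_beta = 0.02,
                       records_per_animal = c(2, 4),
                       recombination = FALSE, morgan_per_bp = 1e-8,
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              n_per_generation = as.integer(n_per_generation),
              prop_sires = prop_sires, prop_genotyped = prop_genotyped,
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chrom_length_bp = chrom_length_bp,
              maf_low = maf_low, maf_high = maf_high,
              n_qtl = as.integer(n_qtl), qtl_var_frac = qtl_var_frac,
              qtl_effects = qtl_effects, qtl_var_shares = qtl_var_shares,
              sigma2_a = sigma2_a, sigma2_pe = sigma2_pe, sigma2_e = sigma2_e,
              n_farmyear = as.integer(n_farmyear),
              n_parity = as.integer(n_parity),
              n_stage = as.integer(n_stage),
              n_milkstatus = as.integer(n_milkstatus),
              fixed_effect_sd = fixed_effect_sd, trait_mean = trait_mean,
              thi_range = thi_range, thi_beta = thi_beta,
              records_per_animal = as.integer(records_per_animal),
              recombination = isTRUE(recombination),
              morgan_per_bp = morgan_per_bp,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_founders < 2L)
    stop("invalid config: need at least 2 founders", call. = FALSE)
  if (cfg$n_generations < 0L)
    stop("invalid config: n_generations must be >= 0", call. = FALSE)
  if (any(c(cfg$sigma2_a, cfg$sigma2_pe, cfg$sigma2_e) < 0))
    stop("invalid config: variance components must be non-negative",
         call. = FALSE)
  if (!(cfg$maf_low > 0 && cfg$maf_low <= cfg$maf_high && cfg$maf_high <= 0.5))
    stop("invalid config: need 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  if (cfg$n_qtl > cfg$n_chromosomes * cfg$snps_per_chromosome)
    stop("invalid config: n_qtl exceeds the number of SNPs", call. = FALSE)
  if (cfg$qtl_var_frac < 0 || cfg$qtl_var_frac > 1)
    stop("invalid config: qtl_var_frac must lie in [0, 1]", call. = FALSE)
  if (!is.null(cfg$qtl_var_shares)) {
    if (length(cfg$qtl_var_shares) != cfg$n_qtl ||
        any(cfg$qtl_var_shares < 0) ||
        abs(sum(cfg$qtl_var_shares) - 1) > 1e-8)
      stop("invalid config: qtl_var_shares must have length n_qtl and sum",
           " to 1", call. = FALSE)
  }
  if (length(cfg$records_per_animal) != 2L ||
      cfg$records_per_animal[1] < 1L ||
      cfg$records_per_animal[1] > cfg$records_per_animal[2])
    stop("invalid config: records_per_animal must be c(min, max), min >= 1",
         call. = FALSE)
  invisible(cfg)
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents (coded 0). Each later
#' generation is produced by random union of a sire and a distinct dam drawn
#' from the previous generation, so parents always precede offspring and the
#' pedigree is topologically ordered by construction. A subset of animals in
#' the last two generations is flagged as genotyped.
#'
#' @param config a [sim_config()] list.
#' @return data.frame with columns `animal`, `sire`, `dam` (0 = unknown),
#'   `generation`, `sex` (`"M"`/`"F"`) and logical `genotyped`.
#' @export
sim_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 101L)
  n0 <- config$n_founders
  sex0 <- rep("F", n0)
  n_m <- max(1L, round(config$prop_sires * n0))
  sex0[sample.int(n0, n_m)] <- "M"
  ped <- data.frame(animal = seq_len(n0), sire = 0L, dam = 0L,
                    generation = 0L, sex = sex0,
                    stringsAsFactors = FALSE)
  nxt <- n0 + 1L
  for (g in seq_len(config$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    sires <- prev$animal[prev$sex == "M"]
    dams <- prev$animal[prev$sex == "F"]
    if (length(sires) < 1L || length(dams) < 1L)
      stop("mating impossible: a generation lacks sires or dams", call. = FALSE)
    n_off <- config$n_per_generation
    off_sex <- ifelse(runif(n_off) < config$prop_sires, "M", "F")
    off <- data.frame(animal = seq.int(nxt, nxt + n_off - 1L),
                      sire = sample(sires, n_off, replace = TRUE),
                      dam = sample(dams, n_off, replace = TRUE),
                      generation = g, sex = off_sex,
                      stringsAsFactors = FALSE)
    ped <- rbind(ped, off)
    nxt <- nxt + n_off
  }
  gen_cut <- max(0L, config$n_generations - 1L)
  candidates <- which(ped$generation >= gen_cut)
  n_g <- round(config$prop_genotyped * length(candidates))
  ped$genotyped <- FALSE
  if (n_g > 0)
    ped$genotyped[sample(candidates, n_g)] <- TRUE
  ped
}

#' Simulate a marker map with founder allele frequencies
#'
#' SNP positions are drawn without replacement per chromosome and sorted, so
#' positions are strictly increasing within chromosome. Each SNP gets a
#' founder frequency whose minor-allele frequency is uniform on
#' `[maf_low, maf_high]`.
#'
#' @param config a [sim_config()] list.
#' @return data.frame with `snp`, `chrom`, `pos`, `a1`, `a2`, `founder_freq`
#'   (frequency of the counted `a1` allele).
#' @export
sim_map <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 202L)
  m <- config$snps_per_chromosome
  maps <- lapply(seq_len(config$n_chromosomes), function(chr) {
    pos <- sort(sample.int(config$chrom_length_bp, m))
    data.frame(snp = sprintf("snp%d_%d", chr, seq_len(m)),
               chrom = chr, pos = pos, a1 = "A", a2 = "B",
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  maf <- runif(nrow(map), config$maf_low, config$maf_high)
  flip <- runif(nrow(map)) < 0.5
  map$founder_freq <- ifelse(flip, 1 - maf, maf)
  map
}

## one gamete from a phased parent (h1/h2 are 0/1 allele vectors over all SNPs)
draw_gamete <- function(h1, h2, map, config) {
  m <- length(h1)
  if (!config$recombination) {
    pick <- runif(m) < 0.5
  } else {
    pick <- logical(m)
    for (chr in unique(map$chrom)) {
      idx <- which(map$chrom == chr)
      d_bp <- diff(map$pos[idx])
      ## Haldane: recombination fraction r = 0.5 (1 - exp(-2d)) for d Morgans
      r <- 0.5 * (1 - exp(-2 * d_bp * config$morgan_per_bp))
      state <- runif(1) < 0.5
      sw <- runif(length(r)) < r
      pick[idx] <- cumsum(c(state, sw)) %% 2 == 1
    }
  }
  ifelse(pick, h1, h2)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotype alleles are Bernoulli draws at each SNP's founder
#' frequency; every offspring receives one gamete from each parent. With the
#' default independent-segregation model each SNP segregates independently;
#' with `recombination = TRUE` in the config, crossovers follow a Haldane
#' model along each chromosome. Genotypes are complete (no missingness) and
#' coded 0/1/2 counts of the `a1` allele.
#'
#' @param ped pedigree from [sim_pedigree()] (topologically ordered).
#' @param map marker map from [sim_map()].
#' @param config a [sim_config()] list.
#' @return a [genotypes()] object covering every pedigree animal.
#' @export
sim_genotypes <- function(ped, map, config) {
  validate_sim_config(config)
  set.seed(config$seed + 303L)
  n <- nrow(ped)
  m <- nrow(map)
  row_of <- integer(max(ped$animal))
  row_of[ped$animal] <- seq_len(n)
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  p <- map$founder_freq
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (s == 0L) H1[i, ] <- as.integer(runif(m) < p)
    else {
      if (row_of[s] == 0L || row_of[s] >= i)
        stop("pedigree not ordered: parent ", s, " missing before animal ",
             ped$animal[i], call. = FALSE)
      H1[i, ] <- draw_gamete(H1[row_of[s], ], H2[row_of[s], ], map, config)
    }
    if (d == 0L) H2[i, ] <- as.integer(runif(m) < p)
    else {
      if (row_of[d] == 0L || row_of[d] >= i)
        stop("pedigree not ordered: parent ", d, " missing before animal ",
             ped$animal[i], call. = FALSE)
      H2[i, ] <- draw_gamete(H1[row_of[d], ], H2[row_of[d], ], map, config)
    }
  }
  X <- H1 + H2
  rownames(X) <- as.character(ped$animal)
  colnames(X) <- map$snp
  genotypes(X, map)
}

#' Simulate repeated phenotypic records
#'
#' The record model is `y = mean + farmyear + parity + stage + milkstatus +
#' thi_beta * THI + a + pe + e`. The true breeding value of animal `i` is the
#' sum of a marker part (QTL allele counts times substitution effects, scaled
#' so the QTL jointly explain `qtl_var_frac * sigma2_a` at founder
#' frequencies) and a polygenic part flowed through the pedigree (founder
#' polygenes `N(0, s2)`, Mendelian sampling `N(0, s2/2)`, with
#' `s2 = (1 - qtl_var_frac) * sigma2_a`). Permanent-environment deviations are
#' one draw per animal, residuals one per record. True values are attached as
#' attributes for recovery tests.
#'
#' @param ped pedigree from [sim_pedigree()].
#' @param geno [genotypes()] for all pedigree animals (only needed when
#'   `n_qtl > 0`; may be `NULL` otherwise).
#' @param config a [sim_config()] list.
#' @return data.frame of records (`animal`, factor covariates, `thi`, `y`)
#'   with attributes `tbv`, `pe` (named by animal), `qtl` (data.frame of QTL
#'   snp/effect) and `true_effects`.
#' @export
sim_phenotypes <- function(ped, geno = NULL, config) {
  validate_sim_config(config)
  set.seed(config$seed + 404L)
  n <- nrow(ped)
  ids <- as.character(ped$animal)

  ## --- true breeding values -------------------------------------------
  qtl <- NULL
  m_part <- numeric(n)
  s2_poly <- config$sigma2_a
  if (config$n_qtl > 0L) {
    stopifnot(!is.null(geno))
    map <- geno$map
    qtl_idx <- sort(sample.int(nrow(map), config$n_qtl))
    alpha <- config$qtl_effects
    if (is.null(alpha)) alpha <- rnorm(config$n_qtl)
    p <- map$founder_freq[qtl_idx]
    target <- config$qtl_var_frac * config$sigma2_a
    if (!is.null(config$qtl_var_shares)) {
      ## per-QTL exact variance shares at founder frequencies
      alpha <- sign(alpha) *
        sqrt(config$qtl_var_shares * target / (2 * p * (1 - p)))
    } else {
      raw_var <- sum(2 * p * (1 - p) * alpha^2)
      if (raw_var > 0) alpha <- alpha * sqrt(target / raw_var)
    }
    Zq <- geno$X[ids, qtl_idx, drop = FALSE]
    m_part <- drop(Zq %*% alpha) - drop(2 * p %*% alpha)
    s2_poly <- config$sigma2_a - sum(2 * p * (1 - p) * alpha^2)
    qtl <- data.frame(snp = map$snp[qtl_idx], index = qtl_idx,
                      effect = alpha, founder_freq = p,
                      stringsAsFactors = FALSE)
  }
  u <- numeric(n)
  row_of <- integer(max(ped$animal))
  row_of[ped$animal] <- seq_len(n)
  mend_sd <- sqrt(pmax(s2_poly, 0) / 2)
  founder_sd <- sqrt(pmax(s2_poly, 0))
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (s == 0L && d == 0L) u[i] <- rnorm(1, 0, founder_sd)
    else {
      pa <- 0.5 * ((if (s > 0L) u[row_of[s]] else 0) +
                   (if (d > 0L) u[row_of[d]] else 0))
      u[i] <- pa + rnorm(1, 0, mend_sd)
    }
  }
  tbv <- setNames(m_part + u, ids)
  pe <- setNames(rnorm(n, 0, sqrt(config$sigma2_pe)), ids)

  ## --- fixed-effect level values --------------------------------------
  eff <- list(farmyear = rnorm(config$n_farmyear, 0, config$fixed_effect_sd),
              parity = rnorm(config$n_parity, 0, config$fixed_effect_sd),
              stage = rnorm(config$n_stage, 0, config$fixed_effect_sd),
              milkstatus = rnorm(config$n_milkstatus, 0, config$fixed_effect_sd))

  ## --- records ---------------------------------------------------------
  rec_range <- seq.int(config$records_per_animal[1],
                       config$records_per_animal[2])
  n_rec <- if (length(rec_range) == 1L) rep(rec_range, n)
           else sample(rec_range, n, replace = TRUE)
  idx <- rep(seq_len(n), n_rec)
  N <- length(idx)
  fy <- sample.int(config$n_farmyear, N, replace = TRUE)
  par <- sample.int(config$n_parity, N, replace = TRUE)
  stg <- sample.int(config$n_stage, N, replace = TRUE)
  mlk <- sample.int(config$n_milkstatus, N, replace = TRUE)
  thi <- runif(N, config$thi_range[1], config$thi_range[2])
  e <- rnorm(N, 0, sqrt(config$sigma2_e))
  y <- config$trait_mean + eff$farmyear[fy] + eff$parity[par] +
    eff$stage[stg] + eff$milkstatus[mlk] + config$thi_beta * thi +
    tbv[idx] + pe[idx] + e
  rec <- data.frame(animal = ped$animal[idx],
                    farmyear = factor(fy, levels = seq_len(config$n_farmyear)),
                    parity = factor(par, levels = seq_len(config$n_parity)),
                    stage = factor(stg, levels = seq_len(config$n_stage)),
                    milkstatus = factor(mlk,
                                        levels = seq_len(config$n_milkstatus)),
                    thi = thi, y = unname(y),
                    stringsAsFactors = FALSE)
  attr(rec, "tbv") <- tbv
  attr(rec, "pe") <- pe
  attr(rec, "qtl") <- qtl
  attr(rec, "true_effects") <- eff
  rec
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [sim_pedigree()], [sim_map()],
#' [sim_genotypes()] and [sim_phenotypes()] from one config.
#'
#' @param config a [sim_config()] list.
#' @return list with `pedigree`, `map`, `genotypes` (all animals),
#'   `phenotypes`, `qtl` and the `config`, classed `"wssg_sim"`.
#' @export
sim_dataset <- function(config) {
  ped <- sim_pedigree(config)
  map <- sim_map(config)
  geno <- sim_genotypes(ped, map, config)
  phe <- sim_phenotypes(ped, geno, config)
  out <- list(pedigree = ped, map = map, genotypes = geno,
              phenotypes = phe, qtl = attr(phe, "qtl"), config = config)
  class(out) <- "wssg_sim"
  out
}

#' @export
print.wssg_sim <- function(x, ...) {
  cat("Simulated single-step dataset\n")
  cat(sprintf("  pedigree: %d animals over %d generations (%d genotyped)\n",
              nrow(x$pedigree), max(x$pedigree$generation) + 1L,
              sum(x$pedigree$genotyped)))
  cat(sprintf("  markers:  %d SNPs on %d chromosomes\n",
              nrow(x$map), length(unique(x$map$chrom))))
  cat(sprintf("  records:  %d phenotypic records on %d animals\n",
              nrow(x$phenotypes), length(unique(x$phenotypes$animal))))
  if (!is.null(x$qtl))
    cat(sprintf("  QTL:      %d marker QTL\n", nrow(x$qtl)))
  invisible(x)
}
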