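#' Backsolve SNP effects from genomic breeding values
#'
#' Converts the GEBV of the genotyped animals into per-SNP allele
#' substitution effects: `u_hat = D Z_c' G*^-1 a_hat / k` with `Z_c` the
#' centred gene-content matrix, `D` the current diagonal SNP weights and
#' `k = sum 2 p (1 - p)` the VanRaden denominator used to build G. With an
#' unblended, full-rank G this inverts the linear map exactly, so
#' `Z_c u_hat` reproduces the genotyped GEBV.
#'
#' @param gebv_g named vector of GEBV for the genotyped animals, in the row
#'   order of `geno`.
#' @param geno [genotypes()] of the genotyped animals (post QC).
#' @param G_star_inv inverse of the (possibly blended) genomic matrix used
#'   in the evaluation, same ordering.
#' @param weights per-SNP weights `d_i` (default 1).
#' @param p allele frequencies used for centring (default observed).
#' @return numeric vector of SNP effects named by SNP id.
#' @export
backsolve_snp_effects <- function(gebv_g, geno, G_star_inv, weights = NULL,
                                  p = NULL) {
  if (is.null(p)) p <- allele_freq(geno)
  m <- ncol(geno$X)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(gebv_g) != nrow(geno$X))
    stop("GEBV length does not match the number of genotyped individuals",
         call. = FALSE)
  if (!all(dim(G_star_inv) == nrow(geno$X)))
    stop("G_star_inv dimension mismatch", call. = FALSE)
  if (!is.null(names(gebv_g)) &&
      !identical(names(gebv_g), rownames(geno$X)))
    stop("GEBV ids not in genotype row order", call. = FALSE)
  Zc <- center_genotypes(geno, p)
  k <- sum(2 * p * (1 - p))
  u <- weights * as.numeric(crossprod(Zc, as.numeric(G_star_inv %*%
                                                       gebv_g))) / k
  setNames(u, geno$map$snp)
}

#' SNP variance weights from backsolved effects
#'
#' The weighting rule `d_i = 1.125 ^ (|u_i| / sd(u) - 2)`: a SNP whose
#' effect sits two standard deviations out keeps weight 1, smaller effects
#' are shrunk, larger ones amplified. The standardised effect is capped at
#' `cap_sd` standard deviations before the shift, preventing single-marker
#' weight explosions, and the weights are rescaled to sum to the number of
#' SNPs so total genomic variance is preserved across iterations.
#'
#' @param effects numeric vector of SNP effects (one trait).
#' @param cap_sd cap on `|u| / sd(u)` (default 5).
#' @param base exponent base (default 1.125).
#' @return positive weight vector summing to `length(effects)`.
#' @export
snp_weights <- function(effects, cap_sd = 5, base = 1.125) {
  m <- length(effects)
  s <- sd(effects)
  if (!is.finite(s) || s == 0) {
    warning("all SNP effects equal; returning identity weights",
            call. = FALSE)
    return(setNames(rep(1, m), names(effects)))
  }
  x <- pmin(abs(effects) / s, cap_sd) - 2
  d <- base ^ x
  d * (m / sum(d))
}

#' Sliding-window scan of additive genetic variance
#'
#' For every window of `window_size` consecutive SNPs within a chromosome,
#' computes the genomic value `a_w(ind) = sum_j z_c,ij u_j` of each
#' genotyped individual, its population variance (divide by n) across
#' individuals, and that variance as a percentage of the total additive
#' genetic variance. Chromosomes with fewer SNPs than `window_size` yield a
#' single short window, flagged.
#'
#' @param effects per-SNP effects (order must match `geno`).
#' @param geno [genotypes()] of the genotyped individuals.
#' @param sigma2_a total additive genetic variance of the trait.
#' @param window_size SNPs per window (default 10).
#' @param step slide step in SNPs; 1 (default) slides SNP by SNP, 10 gives
#'   disjoint contiguous windows.
#' @param p allele frequencies for centring (default observed).
#' @return data.frame of class `"window_scan"`: `chrom`, `start_bp`,
#'   `end_bp` (positions of the first/last member SNP), `start_index`,
#'   `n_snps`, `var_window`, `pct_var`, `short` flag.
#' @export
window_variance_scan <- function(effects, geno, sigma2_a, window_size = 10,
                                 step = 1, p = NULL) {
  stopifnot(window_size >= 1, step >= 1, sigma2_a > 0)
  map <- geno$map
  if (length(effects) != nrow(map))
    stop("effects length does not match the SNP panel", call. = FALSE)
  if (is.null(p)) p <- allele_freq(geno)
  Zc <- center_genotypes(geno, p)
  Q <- sweep(Zc, 2L, as.numeric(effects), "*")
  ## cumulative sums over columns give O(1) window sums
  CS <- cbind(0, t(apply(Q, 1L, cumsum)))
  n <- nrow(Zc)
  rows <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    m_c <- length(idx)
    if (m_c < window_size) {
      starts <- idx[1]; ends <- idx[m_c]; short <- TRUE
    } else {
      starts <- idx[seq.int(1L, m_c - window_size + 1L, by = step)]
      ends <- starts + window_size - 1L
      short <- FALSE
    }
    S <- CS[, ends + 1L, drop = FALSE] - CS[, starts, drop = FALSE]
    vw <- colSums(sweep(S, 2L, colMeans(S))^2) / n
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = chr, start_bp = map$pos[starts],
                 end_bp = map$pos[ends], start_index = starts,
                 n_snps = ends - starts + 1L, var_window = vw,
                 pct_var = 100 * vw / sigma2_a, short = short)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sigma2_a") <- sigma2_a
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  class(out) <- c("window_scan", "data.frame")
  out
}

#' Significant genomic regions from a window scan
#'
#' Selects windows explaining at least `threshold_pct` percent of the
#' additive genetic variance and merges overlapping or adjacent significant
#' windows on the same chromosome into regions. A region reports the
#' maximum member-window percentage (`pct_var`) and the sum over its member
#' windows (`pct_sum`).
#'
#' @param scan a `"window_scan"` data.frame.
#' @param threshold_pct significance threshold in percent (default 0.15).
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `n_windows`,
#'   `pct_var`, `pct_sum`; zero rows when nothing exceeds the threshold.
#' @export
significant_regions <- function(scan, threshold_pct = 0.15) {
  sig <- scan[scan$pct_var >= threshold_pct, , drop = FALSE]
  out <- data.frame(chrom = integer(0), start_bp = integer(0),
                    end_bp = integer(0), n_windows = integer(0),
                    pct_var = numeric(0), pct_sum = numeric(0))
  if (nrow(sig) == 0L) {
    attr(out, "threshold_pct") <- threshold_pct
    return(out)
  }
  sig <- sig[order(sig$chrom, sig$start_index), , drop = FALSE]
  sig$end_index <- sig$start_index + sig$n_snps - 1L
  cur <- sig[1, ]
  regions <- list()
  flush <- function(cur, members) {
    data.frame(chrom = cur$chrom, start_bp = cur$start_bp,
               end_bp = cur$end_bp, n_windows = length(members),
               pct_var = max(members), pct_sum = sum(members))
  }
  members <- cur$pct_var
  for (i in seq_len(nrow(sig))[-1]) {
    w <- sig[i, ]
    if (w$chrom == cur$chrom && w$start_index <= cur$end_index + 1L) {
      cur$end_index <- max(cur$end_index, w$end_index)
      cur$end_bp <- max(cur$end_bp, w$end_bp)
      members <- c(members, w$pct_var)
    } else {
      regions[[length(regions) + 1L]] <- flush(cur, members)
      cur <- w
      members <- w$pct_var
    }
  }
  regions[[length(regions) + 1L]] <- flush(cur, members)
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  attr(out, "threshold_pct") <- threshold_pct
  out
}

#' Weighted single-step GWAS
#'
#' The iterative weighting procedure: fit ssGBLUP with identity SNP weights,
#' backsolve SNP effects from the genotyped animals' GEBV, convert effects
#' to variance weights, rebuild the weighted G (and H-inverse), re-solve the
#' evaluation and repeat — three iterations by default, with variance
#' components held fixed across iterations. The final effects drive a
#' sliding 10-SNP window scan of the percentage of additive genetic
#' variance, and windows at or above the threshold are merged into candidate
#' regions.
#'
#' @inheritParams ssgblup
#' @param iterations number of weighting iterations (1 = unweighted ssGWAS).
#' @param window_size,step,threshold_pct window-scan settings.
#' @param cap_sd cap (in sd units) on the standardised effect in the weight
#'   rule.
#' @param scan_each_iteration keep a window scan for every iteration, not
#'   just the last.
#' @return object of class `"wssgwas"`: per-iteration `effects`, `weights`
#'   and models, the final `scan` and `regions`, plus the variance
#'   components used.
#' @export
wssgwas <- function(fixed, data, pedigree, genotypes, varcomp = NULL,
                    iterations = 3, window_size = 10, step = 1,
                    threshold_pct = 0.15, cap_sd = 5, blend_alpha = 0.05,
                    include_pe = TRUE, scan_each_iteration = FALSE, ...) {
  stopifnot(iterations >= 1)
  check_pedigree(pedigree)
  gids <- rownames(genotypes$X)
  if (!all(gids %in% as.character(pedigree$animal)))
    stop("genotyped ids missing from pedigree", call. = FALSE)
  design <- build_design(data, fixed, pedigree$animal)
  A_inv <- build_A_inverse(pedigree)
  A22 <- build_A22(pedigree, gids)
  p_freq <- allele_freq(genotypes)
  m <- ncol(genotypes$X)

  weights <- rep(1, m)
  iters <- vector("list", iterations)
  vc_used <- varcomp
  for (it in seq_len(iterations)) {
    G <- build_G(genotypes, weights = weights, p = p_freq)
    G_star <- blend_G(G, A22, alpha = blend_alpha)
    K_inv <- build_H_inverse(A_inv, A22, G_star, gids)
    if (is.null(vc_used))
      vc_used <- reml_estimate(design, K_inv, include_pe = include_pe, ...)
    sys <- assemble_mme(design, K_inv, vc_used)
    sol <- solve_mme(sys)
    a_g <- sol$animal[gids]
    G_star_inv <- solve(G_star)
    u <- backsolve_snp_effects(a_g, genotypes, G_star_inv,
                               weights = weights, p = p_freq)
    new_w <- snp_weights(u, cap_sd = cap_sd)
    if (max(new_w) / min(new_w) > 1e6)
      stop("divergent SNP weights (max/min > 1e6) at iteration ", it,
           call. = FALSE)
    iters[[it]] <- list(iteration = it, effects = u,
                        weights_in = weights, weights_out = new_w,
                        gebv = sol$animal, fixed = sol$fixed,
                        scan = if (scan_each_iteration)
                          window_variance_scan(u, genotypes,
                                               sigma2_a(vc_used),
                                               window_size, step, p_freq))
    weights <- new_w
  }
  u_final <- iters[[iterations]]$effects
  scan <- window_variance_scan(u_final, genotypes, sigma2_a(vc_used),
                               window_size, step, p_freq)
  regions <- significant_regions(scan, threshold_pct)
  out <- list(call = match.call(), iterations = iters,
              effects = u_final,
              weights = iters[[iterations]]$weights_out,
              gebv = iters[[iterations]]$gebv,
              scan = scan, regions = regions, varcomp = vc_used,
              settings = list(iterations = iterations,
                              window_size = window_size, step = step,
                              threshold_pct = threshold_pct,
                              cap_sd = cap_sd, blend_alpha = blend_alpha),
              map = genotypes$map)
  class(out) <- "wssgwas"
  out
}

sigma2_a <- function(vc) unname(vc_sigma2(vc)["a"])

#' @export
print.wssgwas <- function(x, ...) {
  s <- x$settings
  cat("Weighted single-step GWAS\n")
  cat(sprintf("  %d SNPs, %d weighting iteration(s)\n",
              length(x$effects), s$iterations))
  cat(sprintf("  window scan: %d windows of %d SNPs (step %d)\n",
              nrow(x$scan), s$window_size, s$step))
  cat(sprintf("  %d region(s) at or above %.2f%% of additive variance\n",
              nrow(x$regions), s$threshold_pct))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.wssgwas <- function(object, ...) {
  top <- object$scan[order(-object$scan$pct_var), ][
    seq_len(min(10L, nrow(object$scan))), ]
  structure(list(object = object, top_windows = top,
                 regions = object$regions), class = "summary.wssgwas")
}

#' @export
print.summary.wssgwas <- function(x, ...) {
  print(x$object)
  cat("\nTop windows by % additive variance:\n")
  print(x$top_windows, row.names = FALSE, digits = 4)
  if (nrow(x$regions)) {
    cat("\nSignificant regions:\n")
    print(x$regions, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Manhattan-style plot of a window scan
#'
#' @param x a `"wssgwas"` object.
#' @param threshold_pct horizontal reference line (defaults to the scan
#'   threshold).
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.wssgwas <- function(x, threshold_pct = x$settings$threshold_pct, ...) {
  scan <- x$scan
  chroms <- unique(scan$chrom)
  offset <- setNames(cumsum(c(0, sapply(chroms, function(ch)
    max(scan$end_bp[scan$chrom == ch]))))[seq_along(chroms)],
    as.character(chroms))
  pos <- scan$start_bp + offset[as.character(scan$chrom)]
  cols <- 1L + scan$chrom %% 2L
  plot(pos, scan$pct_var, pch = 20, cex = 0.6,
       col = c("grey40", "steelblue")[cols],
       xlab = "genome position", ylab = "% additive genetic variance", ...)
  abline(h = threshold_pct, col = "red", lty = 2)
  invisible(x)
}
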