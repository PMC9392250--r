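#' Filter individuals on genotype call rate
#'
#' Keeps individuals whose fraction of non-missing genotypes is strictly
#' greater than `threshold` (default 0.9).
#'
#' @param geno a [genotypes()] object.
#' @param threshold call-rate threshold in `[0, 1]`.
#' @return a [genotypes()] object with the retained individuals; attribute
#'   `"removed"` lists the discarded ids.
#' @export
filter_individual_call_rate <- function(geno, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (nrow(geno$X) == 0L || ncol(geno$X) == 0L)
    stop("empty genotype matrix", call. = FALSE)
  cr <- rowMeans(!is.na(geno$X))
  keep <- cr > threshold
  out <- geno[which(keep), ]
  attr(out, "removed") <- rownames(geno$X)[!keep]
  out
}

#' Filter SNPs on minor allele frequency
#'
#' Keeps SNPs whose minor allele frequency, computed on the current
#' individuals, is strictly greater than `min_maf` (default 0.05).
#'
#' @param geno a [genotypes()] object.
#' @param min_maf MAF threshold.
#' @return filtered [genotypes()]; attribute `"removed"` lists dropped SNPs.
#' @export
filter_maf <- function(geno, min_maf = 0.05) {
  if (nrow(geno$X) == 0L || ncol(geno$X) == 0L)
    stop("empty genotype matrix", call. = FALSE)
  p <- allele_freq(geno)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > min_maf
  out <- geno[, which(keep)]
  attr(out, "removed") <- geno$map$snp[!keep]
  out
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: all
#' heterozygote counts compatible with the minor-allele total are enumerated,
#' their probabilities under random union of gametes computed, and the
#' p-value is the summed probability of configurations no more probable than
#' the observed one. Monomorphic SNPs return p = 1 (no departure computable).
#' The mid-p variant is not used.
#'
#' @param n_AA,n_Aa,n_aa genotype counts at one SNP.
#' @return exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype count",
                                         call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotyped individual", call. = FALSE)
  n_a <- 2 * n_aa + n_Aa          # minor allele copies (relabel if needed)
  if (n_a > n) n_a <- 2 * n - n_a
  if (n_a == 0) return(1)
  ## heterozygote counts share the parity of the minor-allele total
  hets <- seq.int(n_a %% 2, n_a, by = 2L)
  ## log P(het = h | allele counts) up to a constant:
  ## P proportional to n_a! n_A! n! 2^h / ( ((n_a-h)/2)! h! ((n_A-h)/2)! N! )
  n_A <- 2 * n - n_a
  logp <- h_log_prob(hets, n, n_a, n_A)
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, hets)]
  sum(prob[prob <= p_obs + 1e-12])
}

h_log_prob <- function(h, n, n_a, n_A) {
  h * log(2) - lfactorial((n_a - h) / 2) - lfactorial(h) -
    lfactorial((n_A - h) / 2)
}

#' Run the genotype quality-control chain
#'
#' Applies, in order: individual call rate, autosome/known-position filter,
#' minor allele frequency, and the exact Hardy-Weinberg test. Allele
#' frequencies are recomputed after the individual filter, before the SNP
#' filters, and a SNP removed by an earlier filter is never re-examined by a
#' later one. Remaining missing genotypes are left in place (downstream
#' matrix construction mean-imputes at 2p).
#'
#' @param geno a [genotypes()] object.
#' @param call_rate individual call-rate threshold (strict `>`).
#' @param min_maf MAF threshold (strict `>`).
#' @param hwe_p Hardy-Weinberg p-value threshold (keep `p > hwe_p`).
#' @param autosomes integer vector of admissible chromosome codes (default
#'   1-29, the cattle autosomes).
#' @return list with `genotypes` (filtered) and `report` (a `qc_report`).
#' @export
run_qc <- function(geno, call_rate = 0.9, min_maf = 0.05, hwe_p = 1e-6,
                   autosomes = 1:29) {
  steps <- list()
  n0 <- nrow(geno$X); m0 <- ncol(geno$X)

  g1 <- filter_individual_call_rate(geno, call_rate)
  steps$individual_call_rate <- list(
    kind = "individuals", removed = attr(g1, "removed"),
    n_ind = nrow(g1$X), n_snp = ncol(g1$X))

  keep_chr <- g1$map$chrom %in% autosomes & !is.na(g1$map$pos) & g1$map$pos >= 1
  g2 <- g1[, which(keep_chr)]
  steps$autosome_position <- list(
    kind = "snps", removed = g1$map$snp[!keep_chr],
    n_ind = nrow(g2$X), n_snp = ncol(g2$X))

  if (ncol(g2$X) == 0L) stop("empty panel: no SNPs survive QC", call. = FALSE)
  g3 <- filter_maf(g2, min_maf)
  steps$maf <- list(kind = "snps", removed = attr(g3, "removed"),
                    n_ind = nrow(g3$X), n_snp = ncol(g3$X))

  if (ncol(g3$X) == 0L) stop("empty panel: no SNPs survive QC", call. = FALSE)
  counts <- apply(g3$X, 2L, function(g) {
    g <- g[!is.na(g)]
    c(sum(g == 2), sum(g == 1), sum(g == 0))
  })
  pvals <- apply(counts, 2L, function(k) hwe_exact_test(k[1], k[2], k[3]))
  keep_hwe <- pvals > hwe_p
  g4 <- g3[, which(keep_hwe)]
  steps$hwe <- list(kind = "snps", removed = g3$map$snp[!keep_hwe],
                    n_ind = nrow(g4$X), n_snp = ncol(g4$X))
  if (ncol(g4$X) == 0L) stop("empty panel: no SNPs survive QC", call. = FALSE)

  report <- structure(list(input = c(n_ind = n0, n_snp = m0), steps = steps,
                           thresholds = list(call_rate = call_rate,
                                             min_maf = min_maf, hwe_p = hwe_p,
                                             autosomes = autosomes)),
                      class = "qc_report")
  list(genotypes = g4, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Genotype QC: %d individuals x %d SNPs in\n",
              x$input["n_ind"], x$input["n_snp"]))
  for (nm in names(x$steps)) {
    s <- x$steps[[nm]]
    cat(sprintf("  %-22s removed %4d %-11s -> %d x %d\n",
                nm, length(s$removed), s$kind, s$n_ind, s$n_snp))
  }
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(step = names(x$steps),
             kind = vapply(x$steps, `[[`, "", "kind"),
             n_removed = vapply(x$steps, function(s) length(s$removed), 0L),
             n_ind = vapply(x$steps, `[[`, 0L, "n_ind"),
             n_snp = vapply(x$steps, `[[`, 0L, "n_snp"),
             stringsAsFactors = FALSE)
}

#' Principal component analysis of genotypes
#'
#' PCA of the column-centred (optionally column-standardised) genotype
#' matrix, the usual population-structure diagnostic. Missing genotypes are
#' mean-imputed before decomposition.
#'
#' @param geno a [genotypes()] object with at least 2 individuals.
#' @param n_components number of PCs to return (truncated to the matrix rank
#'   with a warning if too large).
#' @param standardize divide each centred column by `sqrt(2 p (1-p))`.
#' @return list with `scores` (individuals x PCs), `var_explained`
#'   (fractions) and `sdev`.
#' @export
genotype_pca <- function(geno, n_components = 10, standardize = FALSE) {
  if (nrow(geno$X) < 2L) stop("need at least two individuals", call. = FALSE)
  Zc <- center_genotypes(geno)
  if (standardize) {
    p <- allele_freq(geno)
    s <- sqrt(2 * p * (1 - p))
    s[s == 0] <- 1
    Zc <- sweep(Zc, 2L, s, "/")
  }
  pc <- prcomp(Zc, center = FALSE, scale. = FALSE)
  r <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (n_components > r) {
    warning("requested ", n_components, " components but rank is ", r,
            "; truncating", call. = FALSE)
    n_components <- r
  }
  k <- seq_len(n_components)
  list(scores = pc$x[, k, drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[k],
       sdev = pc$sdev[k])
}
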