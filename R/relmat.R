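## pedigree utilities ----------------------------------------------------

check_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("animal", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  pos <- match(ped$animal, ped$animal)
  if (any(pos != seq_len(n))) stop("duplicated animal ids", call. = FALSE)
  row_of <- integer(max(ped$animal, 1L))
  row_of[ped$animal] <- seq_len(n)
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- which(p != 0L)
    if (any(p[known] > length(row_of)) || any(row_of[p[known]] == 0L))
      stop(col, " references an animal absent from the pedigree",
           call. = FALSE)
    if (any(row_of[p[known]] >= known))
      stop("pedigree not topologically ordered (a ", col,
           " appears at or after its offspring); reorder so parents precede",
           " offspring", call. = FALSE)
  }
  invisible(row_of)
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the pedigree relationship matrix A by the tabular recursion:
#' `a_ii = 1 + 0.5 a_{sire,dam}` and, for j before i,
#' `a_ij = 0.5 (a_{j,sire(i)} + a_{j,dam(i)})`, an unknown parent
#' contributing zero. Requires a topologically ordered pedigree; intended for
#' pedigrees up to a few thousand animals (dense storage).
#'
#' @param ped data.frame with `animal`, `sire`, `dam` (0 = unknown), parents
#'   before offspring.
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  row_of <- check_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  s <- ifelse(ped$sire > 0L, row_of[pmax(ped$sire, 1L)], 0L)
  d <- ifelse(ped$dam > 0L, row_of[pmax(ped$dam, 1L)], 0L)
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (s[i] > 0L) A[j, s[i]] else 0) +
                   (if (d[i] > 0L) A[j, d[i]] else 0))
      A[j, i] <- aj
      A[i, j] <- aj
    }
  }
  dimnames(A) <- list(as.character(ped$animal), as.character(ped$animal))
  A
}

#' Inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes F for every animal by the Meuwissen & Luo algorithm: for each
#' animal the generalized Cholesky row of A is accumulated over its ancestor
#' list, giving `F_i = sum L_ij^2 d_j - 1` without forming A. Linear memory;
#' suitable for large pedigrees.
#'
#' @param ped ordered pedigree data.frame (`animal`, `sire`, `dam`).
#' @return numeric vector of inbreeding coefficients named by animal id.
#' @export
inbreeding <- function(ped) {
  row_of <- check_pedigree(ped)
  n <- nrow(ped)
  s <- ifelse(ped$sire > 0L, row_of[pmax(ped$sire, 1L)], 0L)
  d <- ifelse(ped$dam > 0L, row_of[pmax(ped$dam, 1L)], 0L)
  F <- numeric(n)
  Dv <- numeric(n)   # Mendelian sampling variance d_j, filled in order
  for (i in seq_len(n)) {
    Fs <- if (s[i] > 0L) F[s[i]] else -1
    Fd <- if (d[i] > 0L) F[d[i]] else -1
    Dv[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (s[i] == 0L && d[i] == 0L) { F[i] <- 0; next }
    ## accumulate L row over ancestors of i
    L <- numeric(i)
    L[i] <- 1
    f <- 0
    for (j in seq.int(i, 1L)) {
      if (L[j] == 0) next
      lj <- L[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      f <- f + lj * lj * Dv[j]
    }
    F[i] <- f - 1
  }
  setNames(F, as.character(ped$animal))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly by Henderson's rules with inbreeding
#' accounted for via Meuwissen-Luo coefficients: each animal contributes
#' `1/m_i` to its diagonal, `-1/(2 m_i)` to animal-parent entries and
#' `1/(4 m_i)` to parent-parent entries, where
#' `m_i = 0.5 - 0.25 (F_s + F_d)` is the Mendelian sampling variance (an
#' unknown parent enters with F = -1). Never forms or inverts dense A.
#'
#' @param ped ordered pedigree data.frame.
#' @return sparse symmetric `Matrix` (class `dsCMatrix`) with id dimnames.
#' @export
build_A_inverse <- function(ped) {
  row_of <- check_pedigree(ped)
  n <- nrow(ped)
  s <- ifelse(ped$sire > 0L, row_of[pmax(ped$sire, 1L)], 0L)
  d <- ifelse(ped$dam > 0L, row_of[pmax(ped$dam, 1L)], 0L)
  F <- unname(inbreeding(ped))
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], -1)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], -1)
  alpha <- 1 / (0.5 - 0.25 * (Fs + Fd))
  ks <- which(s > 0L)
  kd <- which(d > 0L)
  kb <- which(s > 0L & d > 0L)
  ti <- c(seq_len(n),                       # diagonal
          ks, s[ks], kd, d[kd],             # animal-parent (both directions)
          s[ks], d[kd],                     # parent diagonals
          s[kb], d[kb])                     # sire-dam (both directions)
  tj <- c(seq_len(n),
          s[ks], ks, d[kd], kd,
          s[ks], d[kd],
          d[kb], s[kb])
  tx <- c(alpha,
          -0.5 * alpha[ks], -0.5 * alpha[ks],
          -0.5 * alpha[kd], -0.5 * alpha[kd],
          0.25 * alpha[ks], 0.25 * alpha[kd],
          0.25 * alpha[kb], 0.25 * alpha[kb])
  Ainv <- sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n),
                       dimnames = list(as.character(ped$animal),
                                       as.character(ped$animal)))
  forceSymmetric(drop0(Ainv))
}

#' Genomic relationship matrix (weighted VanRaden)
#'
#' `G = Z_c D Z_c' / sum_i 2 p_i (1 - p_i)` where `Z_c` is the gene-content
#' matrix column-centred at twice the observed allele frequency, `D` a
#' diagonal matrix of per-SNP variance weights (identity gives the
#' unweighted VanRaden method 1 matrix), and the denominator the expected
#' heterozygosity sum over retained SNPs. Missing genotypes are mean-imputed
#' at `2 p_i` (centring them to zero).
#'
#' @param geno a [genotypes()] object after QC (all frequencies strictly
#'   inside (0, 1)).
#' @param weights optional positive per-SNP weight vector `d_i` (default 1).
#' @param p optional allele frequencies (default observed).
#' @return dense symmetric matrix with individual ids as dimnames; attribute
#'   `"denominator"` carries `sum 2 p (1 - p)`.
#' @export
build_G <- function(geno, weights = NULL, p = NULL) {
  if (is.null(p)) p <- allele_freq(geno)
  if (any(p <= 0 | p >= 1))
    stop("allele frequency 0 or 1 found; remove monomorphic SNPs in QC",
         call. = FALSE)
  m <- ncol(geno$X)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("weights length != number of SNPs",
                                 call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  Zc <- center_genotypes(geno, p)
  k <- sum(2 * p * (1 - p))
  G <- tcrossprod(sweep(Zc, 2L, weights, "*"), Zc) / k
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(geno$X), rownames(geno$X))
  attr(G, "denominator") <- k
  G
}

#' Blend G towards the pedigree submatrix
#'
#' `G* = (1 - alpha) G + alpha A22`, the usual numerical stabilisation making
#' G invertible and on the pedigree scale. `alpha = 0` returns G unchanged.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship matrix of the same (identically ordered)
#'   genotyped animals.
#' @param alpha blending weight in `[0, 1)`, default 0.05.
#' @return blended matrix; attribute `"blend_alpha"` records alpha.
#' @export
blend_G <- function(G, A22, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha < 1)
  if (!is.null(dimnames(G)[[1]]) && !is.null(dimnames(A22)[[1]]) &&
      !identical(dimnames(G)[[1]], dimnames(A22)[[1]]))
    stop("G and A22 id orderings differ", call. = FALSE)
  if (!all(dim(G) == dim(A22))) stop("G and A22 dimensions differ",
                                     call. = FALSE)
  Gs <- (1 - alpha) * G + alpha * A22
  attr(Gs, "blend_alpha") <- alpha
  attr(Gs, "denominator") <- attr(G, "denominator")
  Gs
}

#' Inverse of the single-step H matrix
#'
#' `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]`: the pedigree inverse with the
#' genotyped block incremented by the difference between the inverted
#' (blended) genomic matrix and the inverted pedigree submatrix of the
#' genotyped animals.
#'
#' @param A_inv sparse inverse of A over all animals (from
#'   [build_A_inverse()]).
#' @param A22 pedigree relationship matrix of the genotyped animals, in the
#'   order given by `genotyped_ids`.
#' @param G_star blended genomic matrix, same order.
#' @param genotyped_ids character ids of genotyped animals (must exist in
#'   `A_inv`'s dimnames).
#' @return sparse symmetric H-inverse over all animals, ordered as `A_inv`.
#' @export
build_H_inverse <- function(A_inv, A22, G_star, genotyped_ids) {
  ids <- rownames(A_inv)
  idx <- match(genotyped_ids, ids)
  if (anyNA(idx)) stop("genotyped ids absent from A_inv: ",
                       paste(genotyped_ids[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  Gi <- tryCatch(solve(as.matrix(G_star)), error = function(e)
    stop("G* is not invertible; blend towards A22 (blend_G with alpha > 0)",
         call. = FALSE))
  A22i <- solve(as.matrix(A22))
  corr <- (Gi + t(Gi)) / 2 - (A22i + t(A22i)) / 2
  H_inv <- as(A_inv, "CsparseMatrix")
  H_inv[idx, idx] <- H_inv[idx, idx] + corr
  forceSymmetric((H_inv + Matrix::t(H_inv)) / 2)
}

#' Pedigree relationship submatrix of the genotyped animals
#'
#' Dense tabular A restricted to `ids` (order preserved). Convenience for
#' desk-scale pedigrees; the full matrix is built once and subset.
#'
#' @param ped ordered pedigree data.frame.
#' @param ids animal ids (character or integer) to retain, in target order.
#' @return dense symmetric matrix.
#' @export
build_A22 <- function(ped, ids) {
  A <- build_A(ped)
  ids <- as.character(ids)
  if (!all(ids %in% rownames(A)))
    stop("ids absent from pedigree", call. = FALSE)
  A[ids, ids, drop = FALSE]
}
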