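#' Genotype matrix with marker map
#'
#' Container for an individuals x SNPs allele-count matrix (entries 0/1/2 or
#' NA for missing) and its marker map. Row names of `X` are animal ids;
#' columns follow the map order (sorted by chromosome then position).
#'
#' @param X integer matrix, individuals x SNPs, entries in \{0, 1, 2, NA\}.
#' @param map data.frame with at least `snp`, `chrom`, `pos` (1-based bp);
#'   rows must match the columns of `X`.
#' @return an object of class `"genotypes"`: list with `X` and `map`.
#' @export
genotypes <- function(X, map) {
  X <- as.matrix(X)
  stopifnot(is.data.frame(map), all(c("snp", "chrom", "pos") %in% names(map)))
  if (ncol(X) != nrow(map))
    stop("genotype matrix has ", ncol(X), " columns but map has ",
         nrow(map), " SNPs", call. = FALSE)
  if (is.null(rownames(X)))
    stop("genotype matrix must carry animal ids as row names", call. = FALSE)
  bad <- X[!is.na(X)]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    stop("genotype entries must be allele counts in {0, 1, 2} or NA",
         call. = FALSE)
  ord <- order(map$chrom, map$pos)
  if (any(ord != seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    X <- X[, ord, drop = FALSE]
  }
  if (anyDuplicated(map[c("chrom", "pos")]))
    stop("duplicated chromosome/position in marker map", call. = FALSE)
  rownames(map) <- NULL
  colnames(X) <- map$snp
  structure(list(X = X, map = map), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  miss <- mean(is.na(x$X))
  cat(sprintf("genotypes: %d individuals x %d SNPs on %d chromosome(s)",
              nrow(x$X), ncol(x$X), length(unique(x$map$chrom))))
  if (miss > 0) cat(sprintf(" (%.2f%% missing)", 100 * miss))
  cat("\n")
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$X)

#' Observed allele frequencies
#'
#' Frequency of the counted allele at each SNP, computed on non-missing
#' genotypes of the individuals currently in the object.
#'
#' @param geno a [genotypes()] object.
#' @return numeric vector named by SNP id.
#' @export
allele_freq <- function(geno) {
  colMeans(geno$X, na.rm = TRUE) / 2
}

#' Subset a genotypes object
#'
#' @param x a [genotypes()] object.
#' @param i individual ids (character) or row indices.
#' @param j SNP ids (character) or column indices.
#' @param ... unused.
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  X <- x$X
  map <- x$map
  if (!missing(i)) X <- X[i, , drop = FALSE]
  if (!missing(j)) {
    if (is.character(j)) j <- match(j, map$snp)
    X <- X[, j, drop = FALSE]
    map <- map[j, , drop = FALSE]
  }
  genotypes(X, map)
}

## centered gene-content matrix Z_c = X - 2p (columnwise), missing -> 0
## (mean imputation 2p then centering); p defaults to observed frequencies
center_genotypes <- function(geno, p = NULL) {
  if (is.null(p)) p <- allele_freq(geno)
  X <- geno$X
  X[is.na(X)] <- 0            # overwritten below via centering with 2p
  Zc <- sweep(X, 2L, 2 * p)
  if (anyNA(geno$X)) {
    na <- which(is.na(geno$X))
    Zc[na] <- 0               # mean-imputed entries centre to exactly 0
  }
  Zc
}
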