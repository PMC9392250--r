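#' Read and write PLINK binary genotype files
#'
#' Minimal reader/writer for the PLINK 1 binary triplet (.bed/.bim/.fam) in
#' SNP-major layout. Genotypes are returned as counts of the .bim A1 allele
#' (0/1/2, NA for missing). `.bim` positions are 1-based base pairs.
#'
#' @param prefix path prefix (files `<prefix>.bed`, `.bim`, `.fam`).
#' @return a [genotypes()] object.
#' @export
read_plink <- function(prefix) {
  bim <- read.delim(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chrom", "snp", "cm", "pos", "a1", "a2"),
                    stringsAsFactors = FALSE)
  fam <- read.delim(paste0(prefix, ".fam"), header = FALSE, sep = "",
                    stringsAsFactors = FALSE)
  ids <- as.character(fam[[2]])
  n <- length(ids); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file", call. = FALSE)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * m)
  codes <- matrix(0L, 4L, length(raw))
  v <- as.integer(raw)
  codes[1, ] <- v %% 4L
  codes[2, ] <- (v %/% 4L) %% 4L
  codes[3, ] <- (v %/% 16L) %% 4L
  codes[4, ] <- (v %/% 64L) %% 4L
  ## 2-bit codes: 00 = 2 copies of A1, 10 = het, 11 = 0 copies, 01 = missing
  lookup <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  G <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    col <- codes[, ((j - 1L) * bytes_per_snp + 1L):(j * bytes_per_snp)]
    G[, j] <- lookup[as.character(col[seq_len(n)])]
  }
  rownames(G) <- ids
  map <- data.frame(snp = bim$snp, chrom = bim$chrom, pos = bim$pos,
                    a1 = as.character(bim$a1), a2 = as.character(bim$a2),
                    stringsAsFactors = FALSE)
  genotypes(G, map)
}

#' @rdname read_plink
#' @param geno a [genotypes()] object to write.
#' @export
write_plink <- function(geno, prefix) {
  X <- geno$X; map <- geno$map
  n <- nrow(X); m <- ncol(X)
  a1 <- if ("a1" %in% names(map)) map$a1 else rep("A", m)
  a2 <- if ("a2" %in% names(map)) map$a2 else rep("B", m)
  write.table(data.frame(map$chrom, map$snp, 0, map$pos, a1, a2),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(rownames(X), rownames(X), 0, 0, 0, -9),
              paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  ## genotype count -> 2-bit code (see read_plink)
  code_of <- function(g) ifelse(is.na(g), 1L,
                                ifelse(g == 2L, 0L, ifelse(g == 1L, 2L, 3L)))
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4L - n
  for (j in seq_len(m)) {
    cj <- c(code_of(X[, j]), rep(0L, pad))
    dim(cj) <- c(4L, bytes_per_snp)
    writeBin(as.raw(cj[1, ] + 4L * cj[2, ] + 16L * cj[3, ] + 64L * cj[4, ]),
             con)
  }
  invisible(prefix)
}

#' Read and write genotypes as a plain TSV matrix
#'
#' The matrix file has individuals in rows (first column `id`) and SNPs in
#' columns; the companion map file carries `snp`, `chrom`, `pos`.
#'
#' @param matrix_path,map_path file paths.
#' @return a [genotypes()] object.
#' @export
read_genotypes_tsv <- function(matrix_path, map_path) {
  d <- read.delim(matrix_path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- read.delim(map_path, stringsAsFactors = FALSE)
  X <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(X) <- "integer"
  rownames(X) <- as.character(d[[1]])
  genotypes(X, map)
}

#' @rdname read_genotypes_tsv
#' @param geno a [genotypes()] object.
#' @export
write_genotypes_tsv <- function(geno, matrix_path, map_path) {
  out <- data.frame(id = rownames(geno$X), geno$X, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(geno$map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}

#' Read a pedigree CSV
#'
#' Comma-separated columns `animal`, `sire`, `dam` (0 = unknown parent),
#' optional `generation` and `genotyped`. Rows must be topologically
#' ordered (parents before offspring).
#'
#' @param path CSV file path.
#' @return pedigree data.frame.
#' @export
read_pedigree_csv <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  check_pedigree(ped)
  ped
}

#' Read a phenotype CSV
#'
#' Comma-separated records with an `animal` column, the factor covariates
#' (converted to factors), numeric covariates and the trait column(s).
#'
#' @param path CSV file path.
#' @param factors character vector of columns to convert to factors.
#' @return record data.frame.
#' @export
read_phenotypes_csv <- function(path,
                                factors = c("farmyear", "parity", "stage",
                                            "milkstatus")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"animal" %in% names(d))
    stop("phenotype CSV needs an `animal` column", call. = FALSE)
  for (f in intersect(factors, names(d))) d[[f]] <- factor(d[[f]])
  d
}
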