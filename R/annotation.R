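#' Read gene annotation from GFF3 or BED
#'
#' Thin wrappers over `rtracklayer::import()` returning a plain gene table
#' with 1-based inclusive coordinates (BED's half-open intervals are
#' converted on read by rtracklayer). GFF3 rows are restricted to `feature`
#' records (default `"gene"`).
#'
#' @param path file path.
#' @param feature GFF3 `type` to keep.
#' @return data.frame with `gene_id`, `gene_name`, `chrom`, `start_bp`,
#'   `end_bp`, `strand`.
#' @export
read_gff3_genes <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature]
  md <- S4Vectors::mcols(gr)
  nm <- if ("Name" %in% names(md)) as.character(md$Name)
        else if ("gene_name" %in% names(md)) as.character(md$gene_name)
        else NA_character_
  id <- if ("ID" %in% names(md)) as.character(md$ID)
        else if ("gene_id" %in% names(md)) as.character(md$gene_id)
        else paste0("gene", seq_along(gr))
  out <- data.frame(gene_id = id,
                    gene_name = ifelse(is.na(nm) | nm == "", id, nm),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start_bp = GenomicRanges::start(gr),
                    end_bp = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname read_gff3_genes
#' @export
read_bed_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else paste0("gene", seq_along(gr))
  data.frame(gene_id = nm, gene_name = nm,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Genes overlapping significant regions
#'
#' Assigns a gene to a region when their closed 1-based intervals share at
#' least one base pair. Genes may be assigned to several regions.
#'
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp` (as produced
#'   by [significant_regions()]).
#' @param annotation gene table as from [read_gff3_genes()].
#' @return data.frame pairing each region (`region`, `chrom`, `start_bp`,
#'   `end_bp`) with its overlapping `gene_id` / `gene_name`; regions with no
#'   genes are absent.
#' @export
genes_in_regions <- function(regions, annotation) {
  stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(regions)),
            all(c("gene_name", "chrom", "start_bp", "end_bp") %in%
                  names(annotation)))
  if (nrow(regions) == 0L)
    return(data.frame(region = integer(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      gene_id = character(0), gene_name = character(0)))
  unknown <- setdiff(as.character(regions$chrom),
                     as.character(annotation$chrom))
  if (length(unknown))
    stop("region chromosome(s) absent from annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rg <- GenomicRanges::GRanges(as.character(regions$chrom),
                               IRanges::IRanges(regions$start_bp,
                                                regions$end_bp))
  gg <- GenomicRanges::GRanges(as.character(annotation$chrom),
                               IRanges::IRanges(annotation$start_bp,
                                                annotation$end_bp))
  hits <- GenomicRanges::findOverlaps(rg, gg)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(region = qi,
                    chrom = as.character(regions$chrom)[qi],
                    start_bp = regions$start_bp[qi],
                    end_bp = regions$end_bp[qi],
                    gene_id = if ("gene_id" %in% names(annotation))
                      annotation$gene_id[si] else annotation$gene_name[si],
                    gene_name = annotation$gene_name[si],
                    stringsAsFactors = FALSE)
  out[order(out$region, out$start_bp), , drop = FALSE]
}

#' Read a differential-expression results table
#'
#' Tab-separated table with columns for the gene name, the log2 expression
#' ratio and the FDR (column names are matched case-insensitively against
#' `gene`/`gene_name`/`symbol`, `log2`/`logfc`/`log2ratio`, `fdr`/`padj`).
#'
#' @param path TSV file path.
#' @return data.frame with `gene_name`, `log2_ratio`, `fdr`.
#' @export
read_deg_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  ln <- tolower(names(d))
  pick <- function(cands) {
    i <- which(ln %in% cands)[1]
    if (is.na(i)) stop("DEG table lacks a column among: ",
                       paste(cands, collapse = ", "), call. = FALSE)
    d[[i]]
  }
  out <- data.frame(gene_name = as.character(pick(c("gene", "gene_name",
                                                    "symbol"))),
                    log2_ratio = as.numeric(pick(c("log2_ratio", "log2ratio",
                                                   "log2fc", "logfc",
                                                   "log2"))),
                    fdr = as.numeric(pick(c("fdr", "padj", "qvalue"))),
                    stringsAsFactors = FALSE)
  if (any(out$fdr < 0 | out$fdr > 1, na.rm = TRUE))
    stop("FDR values outside [0, 1]", call. = FALSE)
  out
}

#' Intersect region genes with differentially expressed genes
#'
#' Filters the DEG table at the given FDR and absolute log2-ratio
#' thresholds, then intersects by gene name (case-insensitive exact match)
#' with the genes found in significant regions. The sign of the log2 ratio
#' is passed through verbatim; its orientation (which group is the
#' numerator) is the caller's contract.
#'
#' @param region_genes output of [genes_in_regions()] (or any data.frame
#'   with a `gene_name` column).
#' @param deg DEG table as from [read_deg_table()].
#' @param fdr_threshold keep DEG rows with `fdr < fdr_threshold`.
#' @param min_abs_log2fc keep DEG rows with `|log2_ratio| >= min_abs_log2fc`
#'   (1 corresponds to a twofold change).
#' @param trait optional trait label carried into the output.
#' @return data.frame with `trait`, `gene_name`, `log2_ratio`, `fdr`,
#'   `direction` (`"up"`/`"down"` by the sign of the ratio).
#' @export
overlap_with_deg <- function(region_genes, deg, fdr_threshold = 0.05,
                             min_abs_log2fc = 1, trait = NA_character_) {
  if (nrow(deg) == 0L) {
    warning("empty DEG table", call. = FALSE)
    return(data.frame(trait = character(0), gene_name = character(0),
                      log2_ratio = numeric(0), fdr = numeric(0),
                      direction = character(0)))
  }
  pass <- !is.na(deg$fdr) & deg$fdr < fdr_threshold &
    abs(deg$log2_ratio) >= min_abs_log2fc
  deg <- deg[pass, , drop = FALSE]
  hit <- tolower(deg$gene_name) %in%
    unique(tolower(region_genes$gene_name))
  deg <- deg[hit, , drop = FALSE]
  deg <- deg[!duplicated(tolower(deg$gene_name)), , drop = FALSE]
  data.frame(trait = trait, gene_name = deg$gene_name,
             log2_ratio = deg$log2_ratio, fdr = deg$fdr,
             direction = ifelse(deg$log2_ratio >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}
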