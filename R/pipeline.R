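#' Run the full analysis pipeline from one configuration
#'
#' Sequences the whole analysis: simulate (or read) pedigree, genotypes and
#' phenotypes; genotype QC; variance-component estimation; iterative
#' weighted single-step GWAS; window scan and significant regions; optional
#' gene annotation and DEG intersection. All stage outputs are written as
#' TSVs under `outdir` together with a JSON manifest (settings, seed,
#' package version), so a rerun with the same config reproduces the same
#' files.
#'
#' @param config a named list or the path of a YAML file. Recognised blocks:
#'   `simulate` (arguments of [sim_config()]) *or* `paths` (with `pedigree`,
#'   `phenotypes`, `genotypes_matrix`, `genotypes_map` or `plink_prefix`);
#'   `qc` (`call_rate`, `min_maf`, `hwe_p`, `autosomes`); `model` (`fixed`
#'   formula as character, `include_pe`); `varcomp` (optional fixed values
#'   `a`, `pe`, `e` to skip REML); `wssgwas` (`iterations`, `window_size`,
#'   `step`, `threshold_pct`, `cap_sd`, `blend_alpha`); `annotation`
#'   (`gff3` or `bed` path); `deg` (`path`, `fdr_threshold`,
#'   `min_abs_log2fc`); `outdir`; `seed`.
#' @param outdir overrides `config$outdir`.
#' @param seed overrides `config$seed` (and the simulate block's seed).
#' @return the run manifest (list, invisibly also written as JSON).
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  seed <- seed %||% config$seed %||% 1L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message(sprintf("[%s] %s",
                                            format(Sys.time(), "%H:%M:%S"),
                                            sprintf(...)))
  tsv <- function(d, name) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  artifacts <- list()

  ## ---- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    log_line("simulating dataset (seed %d)", seed)
    sim <- sim_dataset(cfg)
    ped <- sim$pedigree
    phe <- sim$phenotypes
    geno_all <- sim$genotypes
    gids <- as.character(ped$animal[ped$genotyped])
    geno <- geno_all[gids, ]
    artifacts$pedigree <- tsv(ped, "pedigree")
    artifacts$phenotypes <- tsv(phe, "phenotypes")
    if (!is.null(sim$qtl)) artifacts$qtl <- tsv(sim$qtl, "qtl_truth")
  } else if (!is.null(config$paths)) {
    p <- config$paths
    ped <- read_pedigree_csv(p$pedigree)
    phe <- read_phenotypes_csv(p$phenotypes)
    geno <- if (!is.null(p$plink_prefix)) read_plink(p$plink_prefix)
            else read_genotypes_tsv(p$genotypes_matrix, p$genotypes_map)
  } else stop("config needs a `simulate` block or a `paths` block",
              call. = FALSE)

  ## ---- QC -------------------------------------------------------------
  qc_args <- config$qc %||% list()
  qc <- do.call(run_qc, c(list(geno), qc_args))
  geno <- qc$genotypes
  log_line("QC: %d individuals x %d SNPs retained",
           nrow(geno$X), ncol(geno$X))
  artifacts$qc_report <- tsv(as.data.frame(qc$report), "qc_report")

  ## ---- model ----------------------------------------------------------
  model <- config$model %||% list()
  fixed <- stats::as.formula(model$fixed %||%
    "y ~ farmyear + parity + stage + milkstatus + thi")
  include_pe <- model$include_pe %||% TRUE
  w <- config$wssgwas %||% list()
  vc <- if (!is.null(config$varcomp)) unlist(config$varcomp) else NULL
  log_line("running WssGWAS (%d iterations)", w$iterations %||% 3)
  fit <- wssgwas(fixed, phe, ped, geno, varcomp = vc,
                 iterations = w$iterations %||% 3,
                 window_size = w$window_size %||% 10,
                 step = w$step %||% 1,
                 threshold_pct = w$threshold_pct %||% 0.15,
                 cap_sd = w$cap_sd %||% 5,
                 blend_alpha = w$blend_alpha %||% 0.05,
                 include_pe = include_pe)
  s <- vc_sigma2(fit$varcomp)
  artifacts$varcomp <- tsv(data.frame(component = names(s),
                                      estimate = unname(s)), "varcomp")
  artifacts$gebv <- tsv(data.frame(animal = names(fit$gebv),
                                   gebv = unname(fit$gebv)), "gebv")
  for (it in fit$iterations) {
    artifacts[[paste0("snp_effects_iter", it$iteration)]] <-
      tsv(data.frame(snp = names(it$effects), effect = unname(it$effects),
                     weight = unname(it$weights_out)),
          paste0("snp_effects_iter", it$iteration))
  }
  artifacts$window_scan <- tsv(as.data.frame(fit$scan), "window_scan")
  artifacts$regions <- tsv(fit$regions, "significant_regions")
  log_line("%d significant region(s)", nrow(fit$regions))

  ## ---- annotation -----------------------------------------------------
  if (!is.null(config$annotation) && nrow(fit$regions) > 0L) {
    ann <- if (!is.null(config$annotation$gff3))
      read_gff3_genes(config$annotation$gff3)
    else read_bed_genes(config$annotation$bed)
    rg <- genes_in_regions(fit$regions, ann)
    artifacts$region_genes <- tsv(rg, "region_genes")
    if (!is.null(config$deg)) {
      deg <- read_deg_table(config$deg$path)
      ov <- overlap_with_deg(rg, deg,
                             fdr_threshold = config$deg$fdr_threshold %||%
                               0.05,
                             min_abs_log2fc = config$deg$min_abs_log2fc %||%
                               1)
      artifacts$deg_overlap <- tsv(ov, "deg_overlap")
    }
  }

  manifest <- list(package_version = as.character(utils::packageVersion(
    "wssgblup")), seed = seed, settings = fit$settings,
    varcomp = as.list(s), n_records = nrow(phe),
    n_animals = nrow(ped), n_snps = ncol(geno$X),
    n_regions = nrow(fit$regions), artifacts = artifacts,
    config = config)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  log_line("done; manifest written to %s", file.path(outdir,
                                                     "manifest.json"))
  invisible(manifest)
}
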