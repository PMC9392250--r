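#' Build design matrices for the repeatability animal model
#'
#' Constructs `y`, the full-rank fixed-effect matrix `X` (reference coding,
#' one column dropped per factor), the sparse record-to-animal incidence
#' `Z_a` over *all* pedigree animals (in pedigree order, the same ordering as
#' H-inverse) and the sparse permanent-environment incidence `W` over the
#' recorded animals only.
#'
#' @param phenos record data.frame; must contain the response, the model
#'   covariates and an `animal` column.
#' @param fixed one-sided or two-sided formula for the fixed effects, e.g.
#'   `y ~ farmyear + parity + stage + milkstatus + thi`.
#' @param animal_ids ordered vector of all pedigree animal ids (defines the
#'   `Z_a` column space; typically `pedigree$animal`).
#' @param response name of the response column when `fixed` is one-sided.
#' @return list with `y`, `X`, `Za`, `W`, `animal_ids` (character),
#'   `recorded_ids` (character, pedigree order) and `formula`.
#' @export
build_design <- function(phenos, fixed, animal_ids, response = NULL) {
  stopifnot(is.data.frame(phenos), "animal" %in% names(phenos))
  if (!all(phenos$animal %in% animal_ids))
    stop("records refer to animals absent from the pedigree", call. = FALSE)
  if (length(fixed) == 3L) {
    response <- deparse(fixed[[2]])
    rhs <- fixed
  } else {
    if (is.null(response)) stop("one-sided formula needs `response`",
                                call. = FALSE)
    rhs <- fixed
  }
  y <- phenos[[response]]
  if (is.null(y)) stop("response column `", response, "` not found",
                       call. = FALSE)

  ## drop factor levels with zero records so X stays full rank
  mf_vars <- all.vars(fixed)
  for (v in setdiff(mf_vars, response)) {
    if (is.factor(phenos[[v]]) && any(table(phenos[[v]]) == 0L)) {
      warning("dropping empty level(s) of factor `", v, "`", call. = FALSE)
      phenos[[v]] <- droplevels(phenos[[v]])
    }
  }
  X <- model.matrix(stats::as.formula(paste(
    "~", paste(deparse(rhs[[length(rhs)]]), collapse = ""))), data = phenos)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
  }

  animal_ids <- as.character(animal_ids)
  rec_animal <- as.character(phenos$animal)
  a_idx <- match(rec_animal, animal_ids)
  n <- nrow(phenos)
  Za <- sparseMatrix(i = seq_len(n), j = a_idx,
                     dims = c(n, length(animal_ids)),
                     dimnames = list(NULL, animal_ids))
  recorded_ids <- animal_ids[sort(unique(a_idx))]
  W <- sparseMatrix(i = seq_len(n), j = match(rec_animal, recorded_ids),
                    dims = c(n, length(recorded_ids)),
                    dimnames = list(NULL, recorded_ids))
  list(y = as.numeric(y), X = X,
       Za = as(Za, "dMatrix"), W = as(W, "dMatrix"),
       animal_ids = animal_ids, recorded_ids = recorded_ids,
       formula = fixed)
}
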