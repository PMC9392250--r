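#' Assemble Henderson's mixed model equations
#'
#' Builds the lambda-scaled coefficient matrix
#' `[X'X  X'Z  X'W;  Z'X  Z'Z + K^-1 lambda_a  Z'W;  W'X  W'Z  W'W + I
#' lambda_pe]` and right-hand side `[X'y; Z'y; W'y]`, with
#' `lambda_a = sigma2_e / sigma2_a` and `lambda_pe = sigma2_e / sigma2_pe`.
#' With `K^-1 = H^-1` the solutions are single-step GEBV; with `A^-1` they
#' are pedigree BLUP.
#'
#' @param design output of [build_design()].
#' @param K_inv sparse inverse relationship matrix ordered as
#'   `design$animal_ids`.
#' @param vc variance components: a `varcomp` object or named vector
#'   `c(a =, pe =, e =)` (omit `pe` for a model without the
#'   permanent-environment term).
#' @return object of class `"mme"`: `C` (sparse symmetric), `rhs`,
#'   partition sizes and the variance ratios.
#' @export
assemble_mme <- function(design, K_inv, vc) {
  s <- vc_sigma2(vc)
  if (any(s <= 0)) stop("variance components must be positive", call. = FALSE)
  include_pe <- "pe" %in% names(s)
  if (nrow(K_inv) != ncol(design$Za))
    stop("K_inv dimension does not match the animal ordering of the design",
         call. = FALSE)
  if (!is.null(rownames(K_inv)) &&
      !identical(rownames(K_inv), design$animal_ids))
    stop("K_inv id ordering differs from design$animal_ids", call. = FALSE)
  theta <- c(a = unname(s["a"]),
             pe = if (include_pe) unname(s["pe"]) else NULL,
             e = unname(s["e"]))
  parts <- mme_parts(design, forceSymmetric(as(K_inv, "CsparseMatrix")),
                     theta, include_pe)
  out <- list(C = parts$C, rhs = parts$rhs,
              p = ncol(design$X), q = ncol(design$Za),
              q_r = if (include_pe) ncol(design$W) else 0L,
              lambda_a = unname(s["e"] / s["a"]),
              lambda_pe = if (include_pe) unname(s["e"] / s["pe"]) else NA,
              effect_names = list(fixed = colnames(design$X),
                                  animal = design$animal_ids,
                                  pe = if (include_pe) design$recorded_ids),
              include_pe = include_pe)
  class(out) <- "mme"
  out
}

#' @export
print.mme <- function(x, ...) {
  cat(sprintf("mixed model equations: %d equations (%d fixed, %d animal, %d pe)\n",
              length(x$rhs), x$p, x$q, x$q_r))
  cat(sprintf("lambda_a = %.4f  lambda_pe = %.4f\n", x$lambda_a, x$lambda_pe))
  invisible(x)
}

#' Solve mixed model equations
#'
#' Direct sparse Cholesky solution, or preconditioned conjugate gradients
#' with a Jacobi (diagonal) preconditioner for large systems.
#'
#' @param sys an `"mme"` object from [assemble_mme()].
#' @param method `"direct"` (default) or `"pcg"`.
#' @param tol relative-residual convergence tolerance for PCG.
#' @param max_iter PCG iteration cap.
#' @return list with `fixed`, `animal` (GEBV for every pedigree animal),
#'   `pe` (recorded animals), the full `solution` vector, and the achieved
#'   `relative_residual`.
#' @export
solve_mme <- function(sys, method = c("direct", "pcg"), tol = 1e-8,
                      max_iter = 5000L) {
  method <- match.arg(method)
  C <- sys$C; r <- sys$rhs
  if (method == "direct") {
    x <- as.numeric(solve(Cholesky(C, LDL = FALSE, perm = TRUE), r))
  } else {
    d <- Matrix::diag(C)
    d[d <= 0] <- 1
    x <- numeric(length(r))
    res <- r - as.numeric(C %*% x)
    z <- res / d
    pvec <- z
    rz <- sum(res * z)
    rnorm0 <- sqrt(sum(r * r))
    for (i in seq_len(max_iter)) {
      Cp <- as.numeric(C %*% pvec)
      alpha <- rz / sum(pvec * Cp)
      x <- x + alpha * pvec
      res <- res - alpha * Cp
      if (sqrt(sum(res * res)) / rnorm0 < tol) break
      z <- res / d
      rz_new <- sum(res * z)
      pvec <- z + (rz_new / rz) * pvec
      rz <- rz_new
    }
    if (sqrt(sum(res * res)) / rnorm0 >= tol)
      stop(sprintf(
        "PCG did not converge in %d iterations (relative residual %.3e)",
        max_iter, sqrt(sum(res * res)) / rnorm0), call. = FALSE)
  }
  rel <- sqrt(sum((r - as.numeric(C %*% x))^2)) / sqrt(sum(r * r))
  p <- sys$p; q <- sys$q
  out <- list(fixed = setNames(x[seq_len(p)], sys$effect_names$fixed),
              animal = setNames(x[(p + 1L):(p + q)],
                                sys$effect_names$animal),
              pe = if (sys$include_pe)
                setNames(x[(p + q + 1L):length(x)], sys$effect_names$pe),
              solution = x, relative_residual = rel, method = method)
  out
}

#' Fit a single-step GBLUP repeatability animal model
#'
#' The front door of the package: fits `y = Xb + Z a + W pe + e` with
#' `a ~ N(0, H sigma2_a)` where H combines pedigree and genomic
#' relationships. Variance components are estimated by AI-REML unless
#' supplied. With `genotypes = NULL` the model is ordinary pedigree BLUP
#' (H = A).
#'
#' @param fixed model formula for the fixed effects, response on the left,
#'   e.g. `y ~ farmyear + parity + stage + milkstatus + thi`.
#' @param data record data.frame with an `animal` column.
#' @param pedigree ordered pedigree data.frame (`animal`, `sire`, `dam`).
#' @param genotypes optional [genotypes()] object for the genotyped animals
#'   (ids must appear in the pedigree).
#' @param varcomp optional known variance components (named vector or
#'   `varcomp` object); when `NULL` they are estimated by [reml_estimate()].
#' @param snp_weights optional per-SNP variance weights used to build G.
#' @param blend_alpha weight of A22 blended into G for invertibility.
#' @param include_pe fit the permanent-environment term.
#' @param solver `"direct"` or `"pcg"` for the final solve.
#' @param ... passed on to [reml_estimate()].
#' @return an object of class `"ssgblup"`.
#' @export
ssgblup <- function(fixed, data, pedigree, genotypes = NULL, varcomp = NULL,
                    snp_weights = NULL, blend_alpha = 0.05,
                    include_pe = TRUE, solver = c("direct", "pcg"), ...) {
  solver <- match.arg(solver)
  check_pedigree(pedigree)
  design <- build_design(data, fixed, pedigree$animal)
  A_inv <- build_A_inverse(pedigree)
  H_parts <- NULL
  if (!is.null(genotypes)) {
    gids <- rownames(genotypes$X)
    if (!all(gids %in% as.character(pedigree$animal)))
      stop("genotyped ids missing from pedigree", call. = FALSE)
    G <- build_G(genotypes, weights = snp_weights)
    A22 <- build_A22(pedigree, gids)
    G_star <- blend_G(G, A22, alpha = blend_alpha)
    K_inv <- build_H_inverse(A_inv, A22, G_star, gids)
    H_parts <- list(G = G, G_star = G_star, A22 = A22,
                    genotyped_ids = gids, blend_alpha = blend_alpha,
                    denominator = attr(G, "denominator"))
  } else {
    K_inv <- A_inv
  }
  if (is.null(varcomp)) {
    varcomp <- reml_estimate(design, K_inv, include_pe = include_pe, ...)
  }
  sys <- assemble_mme(design, K_inv, varcomp)
  sol <- solve_mme(sys, method = solver)
  fitted <- as.numeric(design$X %*% sol$fixed) +
    as.numeric(design$Za %*% sol$animal) +
    (if (sys$include_pe) as.numeric(design$W %*% sol$pe) else 0)
  out <- list(call = match.call(), formula = fixed, design = design,
              K_inv = K_inv, H_parts = H_parts, varcomp = varcomp,
              mme = sys, solutions = sol,
              fitted_values = fitted, residuals = design$y - fitted,
              pedigree = pedigree, genotypes = genotypes)
  class(out) <- "ssgblup"
  out
}

#' @export
print.ssgblup <- function(x, ...) {
  cat("Single-step GBLUP repeatability animal model\n")
  cat("  formula: ", deparse(x$formula), "\n")
  cat(sprintf("  %d records, %d animals (%d genotyped)\n",
              length(x$design$y), x$mme$q,
              if (is.null(x$H_parts)) 0L
              else length(x$H_parts$genotyped_ids)))
  s <- vc_sigma2(x$varcomp)
  cat("  variance components:",
      paste(sprintf("%s=%.4g", names(s), s), collapse = "  "), "\n")
  if (all(c("a", "pe", "e") %in% names(s)))
    cat(sprintf("  h2 = %.4f, repeatability = %.4f\n",
                heritability(s), repeatability(s)))
  invisible(x)
}

#' @export
summary.ssgblup <- function(object, ...) {
  g <- gebv(object)
  structure(list(model = object,
                 fixed = object$solutions$fixed,
                 gebv_summary = summary(g$gebv),
                 varcomp = object$varcomp,
                 relative_residual = object$solutions$relative_residual),
            class = "summary.ssgblup")
}

#' @export
print.summary.ssgblup <- function(x, ...) {
  print(x$model)
  cat("\nFixed-effect solutions (reference coding):\n")
  print(round(x$fixed, 5))
  cat("\nGEBV distribution:\n")
  print(x$gebv_summary)
  invisible(x)
}

#' @export
coef.ssgblup <- function(object, ...) object$solutions$fixed

#' @export
fitted.ssgblup <- function(object, ...) object$fitted_values

#' @export
residuals.ssgblup <- function(object, ...) object$residuals

#' Genomic estimated breeding values
#'
#' @param object a fitted [ssgblup()] model.
#' @return data.frame with `animal`, `gebv`, and flags `phenotyped` /
#'   `genotyped`.
#' @export
gebv <- function(object) {
  stopifnot(inherits(object, "ssgblup"))
  a <- object$solutions$animal
  data.frame(animal = names(a), gebv = unname(a),
             phenotyped = names(a) %in% object$design$recorded_ids,
             genotyped = if (is.null(object$H_parts)) FALSE
                         else names(a) %in% object$H_parts$genotyped_ids,
             stringsAsFactors = FALSE)
}

#' @export
predict.ssgblup <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  ## breeding values for named animals (e.g. candidates without records)
  if (is.data.frame(newdata) && "animal" %in% names(newdata))
    newdata <- newdata$animal
  a <- object$solutions$animal
  idx <- match(as.character(newdata), names(a))
  if (anyNA(idx)) stop("unknown animal id(s): ",
                       paste(newdata[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  setNames(unname(a[idx]), as.character(newdata))
}
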