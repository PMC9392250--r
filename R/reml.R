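## ----------------------------------------------------------------------
## REML for the repeatability animal model
##   y = X b + Z_a a + W pe + e,   a ~ N(0, H sigma2_a),
##   pe ~ N(0, I sigma2_pe),       e ~ N(0, I sigma2_e)
## H enters through its inverse (K_inv), so the same code serves pedigree
## BLUP (K_inv = A^-1) and single-step (K_inv = H^-1).
## ----------------------------------------------------------------------

## assemble the lambda-scaled MME coefficient matrix and RHS
mme_parts <- function(design, K_inv, theta, include_pe = TRUE) {
  X <- design$X; Za <- design$Za; W <- design$W; y <- design$y
  lam_a <- theta["e"] / theta["a"]
  XtX <- crossprod(X)
  XtZ <- crossprod(X, Za)
  ZtZ <- crossprod(Za)
  if (include_pe) {
    lam_pe <- theta["e"] / theta["pe"]
    XtW <- crossprod(X, W)
    ZtW <- crossprod(Za, W)
    WtW <- crossprod(W)
    C <- rbind(
      cbind(as(XtX, "CsparseMatrix"), XtZ, XtW),
      cbind(Matrix::t(XtZ), ZtZ + K_inv * lam_a, ZtW),
      cbind(Matrix::t(XtW), Matrix::t(ZtW),
            WtW + Diagonal(ncol(W)) * lam_pe))
    rhs <- c(crossprod(X, y), as.numeric(crossprod(Za, y)),
             as.numeric(crossprod(W, y)))
  } else {
    C <- rbind(cbind(as(XtX, "CsparseMatrix"), XtZ),
               cbind(Matrix::t(XtZ), ZtZ + K_inv * lam_a))
    rhs <- c(crossprod(X, y), as.numeric(crossprod(Za, y)))
  }
  list(C = forceSymmetric(C), rhs = as.numeric(rhs))
}

## restricted log-likelihood via the mixed-model log-determinant identity:
## -2 logL = (n-p) log 2pi + n log s2e + q log s2a + log|H| + q_r log s2pe
##           + log|C_lambda| - n_eq log s2e + y'Py
reml_loglik_parts <- function(design, K_inv, theta, include_pe = TRUE,
                              logdet_H = 0) {
  parts <- mme_parts(design, K_inv, theta, include_pe)
  ch <- Cholesky(parts$C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(solve(ch, parts$rhs))
  y <- design$y
  n <- length(y); p <- ncol(design$X); q <- ncol(design$Za)
  q_r <- if (include_pe) ncol(design$W) else 0L
  n_eq <- length(parts$rhs)
  ypy <- (sum(y * y) - sum(sol * parts$rhs)) / theta["e"]
  ldC <- 2 * determinant(ch, sqrt = TRUE)$modulus[1]
  m2l <- (n - p) * log(2 * pi) + n * log(theta["e"]) +
    q * log(theta["a"]) + logdet_H +
    (if (include_pe) q_r * log(theta["pe"]) else 0) +
    ldC - n_eq * log(theta["e"]) + ypy
  list(logLik = -0.5 * as.numeric(m2l), sol = sol, chol = ch,
       parts = parts, ypy = ypy)
}

#' Restricted log-likelihood of the repeatability model
#'
#' Evaluates the REML log-likelihood (all constants included) at given
#' variance components, using the sparse mixed-model-equation
#' log-determinant identity.
#'
#' @param design output of [build_design()].
#' @param K_inv sparse inverse relationship matrix over `design$animal_ids`
#'   (A-inverse or H-inverse).
#' @param sigma2 named numeric vector `c(a =, pe =, e =)`; omit `pe` to fit
#'   the model without a permanent-environment term.
#' @return the restricted log-likelihood (numeric scalar).
#' @export
reml_loglik <- function(design, K_inv, sigma2) {
  include_pe <- "pe" %in% names(sigma2)
  theta <- c(a = unname(sigma2["a"]), pe = unname(sigma2["pe"]),
             e = unname(sigma2["e"]))
  ldH <- -as.numeric(2 * determinant(Cholesky(forceSymmetric(
    as(K_inv, "CsparseMatrix")), LDL = FALSE, perm = TRUE),
    sqrt = TRUE)$modulus[1])
  reml_loglik_parts(design, K_inv, theta, include_pe, ldH)$logLik
}

## exact trace terms tr(K_inv Caa) and tr(Cpp) from the factored MME,
## via a multi-RHS solve on the random-effect columns
mme_traces <- function(ch, K_inv, p, q, q_r, include_pe) {
  n_eq <- p + q + q_r
  cols_a <- (p + 1L):(p + q)
  Ba <- sparseMatrix(i = cols_a, j = seq_len(q), x = 1,
                     dims = c(n_eq, q))
  Ca <- solve(ch, Ba)               # n_eq x q, columns of C^-1
  Caa <- Ca[cols_a, , drop = FALSE]
  tr_KCaa <- sum(K_inv * Caa)       # K_inv sparse: elementwise product sum
  tr_Cpp <- 0
  if (include_pe && q_r > 0L) {
    cols_p <- (p + q + 1L):n_eq
    Bp <- sparseMatrix(i = cols_p, j = seq_len(q_r), x = 1,
                       dims = c(n_eq, q_r))
    Cp <- solve(ch, Bp)
    tr_Cpp <- sum(Cp[cbind(cols_p, seq_len(q_r))])
  }
  list(tr_KCaa = as.numeric(tr_KCaa), tr_Cpp = as.numeric(tr_Cpp))
}

## apply the projection P to a vector: Pv = (v - X b_v - Za a_v - W p_v)/s2e
apply_P <- function(v, design, ch, theta, include_pe) {
  X <- design$X; Za <- design$Za; W <- design$W
  rhs <- c(crossprod(X, v), as.numeric(crossprod(Za, v)),
           if (include_pe) as.numeric(crossprod(W, v)))
  sol <- as.numeric(solve(ch, rhs))
  p <- ncol(X); q <- ncol(Za)
  fit <- as.numeric(X %*% sol[seq_len(p)]) +
    as.numeric(Za %*% sol[(p + 1L):(p + q)])
  if (include_pe)
    fit <- fit + as.numeric(W %*% sol[(p + q + 1L):length(sol)])
  (v - fit) / theta["e"]
}

#' Estimate variance components by REML
#'
#' Average-information REML with EM fallback for the repeatability animal
#' model. Each iteration factorises the sparse mixed-model equations, forms
#' the exact first derivatives (trace terms from MME-inverse blocks) and the
#' average-information matrix, and takes a Newton step; when the AI step
#' proposes an inadmissible component or decreases the restricted
#' likelihood, an EM step (guaranteed non-decreasing) is taken instead.
#' Standard errors come from the inverse AI matrix at convergence.
#'
#' @param design output of [build_design()].
#' @param K_inv sparse inverse relationship matrix (A-inverse or H-inverse)
#'   over `design$animal_ids`.
#' @param start optional named start values `c(a =, pe =, e =)`; defaults to
#'   an equal split of the phenotypic variance.
#' @param method `"ai"` (AI with EM fallback, default) or `"em"` (pure EM).
#' @param include_pe fit the permanent-environment term (default `TRUE`;
#'   meaningless with one record per animal).
#' @param max_iter,tol iteration cap and relative-change convergence
#'   tolerance.
#' @param verbose print the iteration trail.
#' @return an object of class `"varcomp"`: estimated `sigma2` (named vector),
#'   `se`, `logLik`, `converged`, `iterations`, `boundary` flags, and the
#'   derived `h2` and `repeatability`.
#' @export
reml_estimate <- function(design, K_inv, start = NULL,
                          method = c("ai", "em"), include_pe = TRUE,
                          max_iter = 100L, tol = 1e-8, verbose = FALSE) {
  method <- match.arg(method)
  y <- design$y
  n <- length(y); p <- ncol(design$X); q <- ncol(design$Za)
  q_r <- if (include_pe) ncol(design$W) else 0L
  vy <- var(y)
  floor_v <- 1e-8 * vy
  if (is.null(start)) {
    start <- if (include_pe) c(a = 0.3, pe = 0.2, e = 0.5) * vy
             else c(a = 0.4, e = 0.6) * vy
  }
  theta <- c(a = unname(start["a"]),
             pe = if (include_pe) unname(start["pe"]) else NA_real_,
             e = unname(start["e"]))
  theta <- theta[!is.na(theta)]
  if (any(theta <= 0)) stop("start values must be positive", call. = FALSE)
  K_inv <- forceSymmetric(as(K_inv, "CsparseMatrix"))
  ldH <- -as.numeric(2 * determinant(Cholesky(K_inv, LDL = FALSE, perm = TRUE),
                              sqrt = TRUE)$modulus[1])

  em_step <- function(theta, ev, tr = NULL) {
    sol <- ev$sol
    a_hat <- sol[(p + 1L):(p + q)]
    if (is.null(tr)) tr <- mme_traces(ev$chol, K_inv, p, q, q_r, include_pe)
    new <- theta
    new["a"] <- (sum(a_hat * as.numeric(K_inv %*% a_hat)) +
                   tr$tr_KCaa * theta["e"]) / q
    if (include_pe) {
      pe_hat <- sol[(p + q + 1L):(p + q + q_r)]
      new["pe"] <- (sum(pe_hat^2) + tr$tr_Cpp * theta["e"]) / q_r
    }
    new["e"] <- (sum(y * y) - sum(sol * ev$parts$rhs)) / (n - p)
    new
  }

  ai_step <- function(theta, ev) {
    nms <- names(theta)
    theta <- setNames(as.numeric(theta), nms)   # strip carried-over names
    sol <- ev$sol
    a_hat <- sol[(p + 1L):(p + q)]
    e_hat <- y - as.numeric(design$X %*% sol[seq_len(p)]) -
      as.numeric(design$Za %*% a_hat)
    if (include_pe) {
      pe_hat <- sol[(p + q + 1L):(p + q + q_r)]
      e_hat <- e_hat - as.numeric(design$W %*% pe_hat)
    }
    Py <- e_hat / theta["e"]
    tr <- mme_traces(ev$chol, K_inv, p, q, q_r, include_pe)
    lam_a <- theta["e"] / theta["a"]
    f <- list(a = as.numeric(design$Za %*% a_hat) / theta["a"])
    score <- c(a = unname(-0.5 * ((q - lam_a * tr$tr_KCaa) / theta["a"] -
                                    sum(as.numeric(crossprod(design$Za, Py)) *
                                          a_hat) / theta["a"])))
    if (include_pe) {
      lam_pe <- theta["e"] / theta["pe"]
      f$pe <- as.numeric(design$W %*% pe_hat) / theta["pe"]
      score["pe"] <- -0.5 * ((q_r - lam_pe * tr$tr_Cpp) / theta["pe"] -
                               sum(as.numeric(crossprod(design$W, Py)) *
                                     pe_hat) / theta["pe"])
    }
    f$e <- Py
    tr_P <- (n - p - q - q_r +
               (theta["e"] / theta["a"]) * tr$tr_KCaa +
               (if (include_pe) (theta["e"] / theta["pe"]) * tr$tr_Cpp
                else 0)) / theta["e"]
    score["e"] <- -0.5 * (tr_P - sum(Py * Py))
    k <- length(theta)
    AI <- matrix(0, k, k, dimnames = list(names(theta), names(theta)))
    Pf <- lapply(f, apply_P, design = design, ch = ev$chol, theta = theta,
                 include_pe = include_pe)
    for (i in seq_len(k)) for (j in i:k) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(f[[names(theta)[i]]] *
                                          Pf[[names(theta)[j]]])
    }
    list(score = score[names(theta)], AI = AI, tr = tr)
  }

  ev <- reml_loglik_parts(design, K_inv, theta, include_pe, ldH)
  logL <- ev$logLik
  AI_last <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (method == "ai") {
      st <- ai_step(theta, ev)
      AI_last <- st$AI
      delta <- tryCatch(solve(st$AI, st$score), error = function(e) NULL)
      cand <- NULL
      if (!is.null(delta)) {
        ## AI Newton step with step-halving before falling back to EM
        for (sfac in c(1, 0.5, 0.25, 0.1)) {
          cnd <- theta + sfac * delta
          if (any(cnd < floor_v)) next
          evc <- reml_loglik_parts(design, K_inv, cnd, include_pe, ldH)
          if (evc$logLik + 1e-10 >= logL) {
            cand <- cnd; ev_cand <- evc; break
          }
        }
      }
      if (is.null(cand)) {
        cand <- pmax(em_step(theta, ev, st$tr), floor_v)
        ev_cand <- reml_loglik_parts(design, K_inv, cand, include_pe, ldH)
      }
    } else {
      cand <- pmax(em_step(theta, ev), floor_v)
      ev_cand <- reml_loglik_parts(design, K_inv, cand, include_pe, ldH)
    }
    rel <- max(abs(cand - theta) / pmax(theta, floor_v))
    if (verbose)
      message(sprintf("it %3d  logL %.6f  %s", it, ev_cand$logLik,
                      paste(sprintf("%s=%.6g", names(cand), cand),
                            collapse = "  ")))
    theta <- cand
    ev <- ev_cand
    logL <- ev$logLik
    if (rel < tol) { converged <- TRUE; break }
  }
  if (method == "ai" && is.null(AI_last)) AI_last <- ai_step(theta, ev)$AI
  se <- if (method == "ai") {
    ## SEs from the inverse AI matrix at (or just before) convergence
    sqrt(pmax(diag(tryCatch(solve(AI_last),
                            error = function(e)
                              matrix(NA_real_, length(theta),
                                     length(theta)))), 0))
  } else rep(NA_real_, length(theta))
  names(se) <- names(theta)
  boundary <- theta <= floor_v * (1 + 1e-6)
  sigma2 <- theta
  out <- list(sigma2 = sigma2, se = se, logLik = logL,
              converged = converged, iterations = it, method = method,
              boundary = boundary, include_pe = include_pe,
              n_records = n, n_animals = q,
              solutions = ev$sol, design_dims = c(p = p, q = q, q_r = q_r))
  class(out) <- "varcomp"
  out
}

#' @export
print.varcomp <- function(x, ...) {
  cat("REML variance components (", x$method, ")\n", sep = "")
  tab <- data.frame(component = names(x$sigma2),
                    estimate = round(unname(x$sigma2), 6),
                    se = round(unname(x$se), 6))
  print(tab, row.names = FALSE)
  cat(sprintf("logLik %.4f  %s after %d iterations\n", x$logLik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (any(x$boundary))
    cat("components at boundary:",
        paste(names(x$sigma2)[x$boundary], collapse = ", "), "\n")
  if (x$include_pe)
    cat(sprintf("h2 = %.4f   repeatability = %.4f\n",
                heritability(x), repeatability(x)))
  invisible(x)
}

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)`.
#'
#' @param vc a `varcomp` object, or a named vector/list with elements `a`,
#'   `pe` (optional) and `e`.
#' @return narrow-sense heritability.
#' @export
heritability <- function(vc) {
  s <- vc_sigma2(vc)
  tot <- sum(s)
  if (tot <= 0) stop("total variance is zero", call. = FALSE)
  unname(s["a"] / tot)
}

#' Repeatability from variance components
#'
#' `t = (sigma2_a + sigma2_pe) / (sigma2_a + sigma2_pe + sigma2_e)`.
#'
#' @inheritParams heritability
#' @return repeatability.
#' @export
repeatability <- function(vc) {
  s <- vc_sigma2(vc)
  if (!"pe" %in% names(s))
    stop("repeatability needs a permanent-environment component",
         call. = FALSE)
  tot <- sum(s)
  if (tot <= 0) stop("total variance is zero", call. = FALSE)
  unname((s["a"] + s["pe"]) / tot)
}

vc_sigma2 <- function(vc) {
  if (inherits(vc, "varcomp")) return(vc$sigma2)
  s <- unlist(vc)
  if (!all(c("a", "e") %in% names(s)))
    stop("need named components `a` and `e` (and optionally `pe`)",
         call. = FALSE)
  s[names(s) %in% c("a", "pe", "e")]
}

## ----------------------------------------------------------------------
## bivariate REML (dense, desk scale) for genetic correlations
## ----------------------------------------------------------------------

chol2cov <- function(par) {
  L <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2, 2)
  tcrossprod(L)
}
cov2par <- function(S) {
  L <- t(chol(S))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

bivariate_m2l <- function(par, MtM, Mty, yy, K_inv, n, p, q, q_r, ldH) {
  Sa <- chol2cov(par[1:3]); Spe <- chol2cov(par[4:6])
  Se <- chol2cov(par[7:9])
  Sei <- solve(Se); Sai <- solve(Sa); Spei <- solve(Spe)
  n_eq <- p + q + q_r
  C <- kronecker(Sei, MtM)
  ia <- p + seq_len(q)
  ip <- p + q + seq_len(q_r)
  Kd <- as.matrix(K_inv)
  for (i in 1:2) for (j in 1:2) {
    bi <- (i - 1L) * n_eq; bj <- (j - 1L) * n_eq
    C[bi + ia, bj + ia] <- C[bi + ia, bj + ia] + Sai[i, j] * Kd
    idx <- cbind(bi + ip, bj + ip)
    C[idx] <- C[idx] + Spei[i, j]
  }
  rhs <- as.numeric(Mty %*% Sei)        # (n_eq x 2) %*% Sei, stacked
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  ypy <- sum(Sei * yy) - sum(sol * rhs)
  ldC <- 2 * sum(log(diag(ch)))
  n * determinant(Se)$modulus[1] + q * determinant(Sa)$modulus[1] +
    2 * ldH + q_r * determinant(Spe)$modulus[1] + ldC + ypy
}

#' Bivariate REML for two repeated traits
#'
#' Estimates 2x2 additive, permanent-environmental and residual
#' (co)variance matrices for two traits recorded on the same records, by
#' direct maximisation of the restricted likelihood (dense mixed-model
#' log-determinant identity, log-Cholesky parameterisation). Intended for
#' desk-scale data; the per-trait pipeline remains univariate.
#'
#' @param design output of [build_design()] (its response is ignored).
#' @param y2 numeric matrix with two columns, the two traits record by
#'   record.
#' @param K_inv sparse inverse relationship matrix.
#' @param start optional list with `Sa`, `Spe`, `Se` 2x2 start matrices.
#' @param max_eval optimiser evaluation budget.
#' @return object of class `"varcomp2"` with `Sa`, `Spe`, `Se`, `logLik`,
#'   `convergence`.
#' @export
reml_bivariate <- function(design, y2, K_inv, start = NULL,
                           max_eval = 2000L) {
  y2 <- as.matrix(y2)
  stopifnot(ncol(y2) == 2L, nrow(y2) == nrow(design$X))
  X <- design$X; Za <- design$Za; W <- design$W
  M <- cbind(as(X, "CsparseMatrix"), Za, W)
  MtM <- as.matrix(crossprod(M))
  Mty <- as.matrix(crossprod(M, y2))
  yy <- crossprod(y2)
  n <- nrow(y2); p <- ncol(X); q <- ncol(Za); q_r <- ncol(W)
  K_inv <- forceSymmetric(as(K_inv, "CsparseMatrix"))
  ldH <- -as.numeric(2 * determinant(Cholesky(K_inv, LDL = FALSE, perm = TRUE),
                              sqrt = TRUE)$modulus[1])
  if (is.null(start)) {
    vy <- diag(var(y2))
    r0 <- 0.1 * sqrt(vy[1] * vy[2])
    start <- list(Sa = matrix(c(0.3 * vy[1], r0 * 0.3, r0 * 0.3,
                                0.3 * vy[2]), 2),
                  Spe = matrix(c(0.2 * vy[1], 0, 0, 0.2 * vy[2]), 2),
                  Se = matrix(c(0.5 * vy[1], 0, 0, 0.5 * vy[2]), 2))
  }
  par0 <- c(cov2par(start$Sa), cov2par(start$Spe), cov2par(start$Se))
  obj <- function(par) bivariate_m2l(par, MtM, Mty, yy, K_inv,
                                     n, p, q, q_r, ldH)
  opt <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = max_eval, reltol = 1e-10))
  out <- list(Sa = chol2cov(opt$par[1:3]), Spe = chol2cov(opt$par[4:6]),
              Se = chol2cov(opt$par[7:9]),
              logLik = -0.5 * (opt$value + (n - p) * log(2 * pi)),
              convergence = opt$convergence, evaluations = opt$counts[1])
  class(out) <- "varcomp2"
  out
}

#' @export
print.varcomp2 <- function(x, ...) {
  cat("Bivariate REML (co)variance matrices\n")
  for (nm in c("Sa", "Spe", "Se")) {
    cat(nm, ":\n"); print(round(x[[nm]], 6))
  }
  cat(sprintf("genetic correlation %.4f   logLik %.4f\n",
              genetic_correlation(x), x$logLik))
  invisible(x)
}

#' Genetic correlation between two traits
#'
#' `r = sigma_a(1,2) / sqrt(sigma2_a(1) sigma2_a(2))` from a bivariate fit
#' (or any 2x2 additive covariance matrix). Estimates outside `[-1, 1]`
#' are reported clipped with a warning.
#'
#' @param vc a `varcomp2` object or a 2x2 additive covariance matrix.
#' @param component which covariance matrix to use (`"a"`, `"pe"`, `"e"`).
#' @return the correlation.
#' @export
genetic_correlation <- function(vc, component = "a") {
  S <- if (inherits(vc, "varcomp2"))
    vc[[c(a = "Sa", pe = "Spe", e = "Se")[component]]] else as.matrix(vc)
  v1 <- S[1, 1]; v2 <- S[2, 2]
  if (v1 <= 0 || v2 <= 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- S[1, 2] / sqrt(v1 * v2)
  if (abs(r) > 1) {
    warning("correlation estimate outside [-1, 1]; clipped", call. = FALSE)
    r <- sign(r)
  }
  r
}
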