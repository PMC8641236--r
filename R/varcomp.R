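#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = Z Z' / (2 sum_j p_j (1 - p_j)), where Z is the dosage matrix with
#' missing entries mean-imputed and columns centered at 2 p_j. Monomorphic
#' markers are excluded with a warning.
#'
#' @param ds a post-QC [genotype_dataset()].
#' @return a list of class \code{grm}: \code{G} (n x n symmetric matrix with
#'   sample ids as dimnames), \code{p} (allele frequencies used),
#'   \code{n_markers}.
#' @export
compute_grm <- function(ds) {
  g <- ds$geno
  p <- counted_allele_freq(ds)
  poly <- !is.nan(p) & p > 0 & p < 1
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic marker(s) excluded from the GRM")
    g <- g[, poly, drop = FALSE]
    p <- p[poly]
  }
  if (!length(p)) stop("no polymorphic markers left for the GRM")
  z <- sweep(g, 2L, 2 * p, "-")
  z[is.na(z)] <- 0  # mean imputation: dosage 2p centers to 0
  G <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(ds$samples$id, ds$samples$id)
  structure(list(G = G, p = p, n_markers = length(p)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("Genomic relationship matrix:", nrow(x$G), "samples,", x$n_markers,
      "markers\n")
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(x$G)),
              mean(x$G[upper.tri(x$G)])))
  invisible(x)
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of G; variance proportions are eigenvalues divided by
#' the trace. Scores (eigenvectors scaled by the square root of their
#' eigenvalue) are returned for use as fixed covariates.
#'
#' @param g a [compute_grm()] result or a symmetric matrix.
#' @param k number of components to return (default 3).
#' @return list of class \code{grm_pca}: \code{scores} (n x k),
#'   \code{vectors}, \code{values} (all eigenvalues), \code{proportions}.
#' @export
pca_grm <- function(g, k = 3L) {
  G <- if (inherits(g, "grm")) g$G else g
  if (!isSymmetric(unname(G), tol = 1e-8)) stop("GRM must be symmetric")
  k <- min(as.integer(k), nrow(G))
  e <- eigen(G, symmetric = TRUE)
  prop <- e$values / sum(diag(G))
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 vectors = e$vectors[, seq_len(k), drop = FALSE],
                 values = e$values, proportions = prop),
            class = "grm_pca")
}

#' Specify a single-trait mixed model
#'
#' Bundles a response with its fixed-effect design matrix. Aliased columns
#' are detected here so downstream solvers always see a full-rank design.
#'
#' @param y numeric response vector.
#' @param W fixed-effect design matrix (an intercept column is prepended
#'   when absent); defaults to intercept only.
#' @param ids optional sample ids aligned with \code{y}.
#' @return list of class \code{mixed_model_spec} with full-rank \code{W}.
#' @export
mixed_model_spec <- function(y, W = NULL, ids = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  W <- as.matrix(W)
  if (nrow(W) != n) stop("W has ", nrow(W), " rows but y has length ", n)
  if (!any(apply(W, 2L, function(c) all(c == c[1L] & c[1L] != 0))))
    W <- cbind(`(Intercept)` = 1, W)
  qr_w <- qr(W)
  if (qr_w$rank < ncol(W)) {
    drop <- colnames(W)[qr_w$pivot[-seq_len(qr_w$rank)]]
    stop("fixed-effect design is singular; aliased columns: ",
         paste(drop, collapse = ", "))
  }
  structure(list(y = y, W = W, ids = ids), class = "mixed_model_spec")
}

## REML log-likelihood constant convention used throughout the package:
## ll = -1/2 [ (n-p) log 2*pi + log|V| + log|W' V^-1 W| + y' P y ].

## Generic average-information REML for V = sum_k theta_k K_k + theta_e I.
## Klist: list of n x n covariance structure matrices (residual appended
## internally). Returns estimates, inverse-AI covariance, log-likelihood.
reml_ai <- function(y, W, Klist, init = NULL, max_iter = 200L, tol = 1e-8,
                    verbose = FALSE) {
  n <- length(y)
  W <- as.matrix(W)
  p <- ncol(W)
  nk <- length(Klist) + 1L  # + residual
  vp <- stats::var(stats::lm.fit(W, y)$residuals) * (n - 1) / max(n - p, 1)
  floor_v <- 1e-10 * vp
  theta <- if (is.null(init)) rep(vp / nk, nk) else init
  theta <- pmax(theta, floor_v)

  eval_state <- function(theta) {
    V <- diag(theta[nk], n)
    for (k in seq_along(Klist)) V <- V + theta[k] * Klist[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViW <- Vi %*% W
    WViW <- crossprod(W, ViW)
    chw <- tryCatch(chol(WViW), error = function(e) NULL)
    if (is.null(chw)) return(NULL)
    WViW_inv <- chol2inv(chw)
    ViWy <- crossprod(ViW, y)
    beta <- WViW_inv %*% ViWy
    Py <- Vi %*% y - ViW %*% beta
    yPy <- sum(y * Py)
    ll <- -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                    2 * sum(log(diag(chw))) + yPy)
    list(V = V, Vi = Vi, ViW = ViW, WViW_inv = WViW_inv, beta = beta,
         Py = Py, ll = ll)
  }

  st <- eval_state(theta)
  if (is.null(st)) stop("initial covariance matrix is not positive definite")
  converged <- FALSE
  AI <- NULL
  it <- 0L
  floor_hits <- integer(nk)  # consecutive iterations a component sat at floor
  while (it < max_iter) {
    it <- it + 1L
    # score and AI matrix at current theta
    Kt <- c(Klist, list(NULL))  # NULL sentinel = identity (residual)
    tvec <- vector("list", nk)
    score <- numeric(nk)
    for (k in seq_len(nk)) {
      Kk <- Kt[[k]]
      t_k <- if (is.null(Kk)) st$Py else Kk %*% st$Py
      tvec[[k]] <- t_k
      if (is.null(Kk)) {
        trPK <- sum(diag(st$Vi)) -
          sum(st$WViW_inv * crossprod(st$ViW))
      } else {
        trPK <- sum(st$Vi * Kk) -
          sum(st$WViW_inv * crossprod(st$ViW, Kk %*% st$ViW))
      }
      score[k] <- -0.5 * (trPK - sum(st$Py * t_k))
    }
    AI <- matrix(0, nk, nk)
    Pt <- vector("list", nk)
    for (k in seq_len(nk))
      Pt[[k]] <- st$Vi %*% tvec[[k]] -
        st$ViW %*% (st$WViW_inv %*% crossprod(st$ViW, tvec[[k]]))
    for (k in seq_len(nk)) for (l in k:nk) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(tvec[[k]] * Pt[[l]])
    }
    # freeze components that keep sitting at the floor with negative score
    frozen <- floor_hits >= 3L & score < 0
    active <- which(!frozen)
    step <- NULL
    if (length(active)) {
      step_a <- tryCatch(solve(AI[active, active, drop = FALSE],
                               score[active]), error = function(e) NULL)
      if (!is.null(step_a)) {
        step <- numeric(nk)
        step[active] <- step_a
      }
    }
    new_st <- NULL
    new_theta <- NULL
    if (!is.null(step)) {
      frac <- 1
      for (try in 1:8) {  # clamped AI step with step-halving
        cand <- pmax(theta + frac * step, floor_v)
        cand_st <- eval_state(cand)
        if (!is.null(cand_st) && cand_st$ll >= st$ll - 1e-10) {
          new_theta <- cand
          new_st <- cand_st
          break
        }
        frac <- frac / 2
      }
    }
    if (is.null(new_st)) {
      # boundary probe: a small component whose removal does not lower the
      # likelihood is pinned at the floor outright (the surface can be
      # extremely flat near a zero variance)
      for (k in which(theta < 1e-2 * vp & theta > floor_v * 1.001)) {
        cand <- theta
        cand[k] <- floor_v
        cand_st <- eval_state(cand)
        if (!is.null(cand_st) && cand_st$ll >= st$ll - 1e-10) {
          new_theta <- cand
          new_st <- cand_st
          break
        }
      }
    }
    if (is.null(new_st)) {
      # EM fallback step (always uphill, slower)
      new_theta <- theta
      for (k in seq_len(nk))
        new_theta[k] <- theta[k] +
          theta[k]^2 * (sum(st$Py * tvec[[k]]) -
                          (if (is.null(Kt[[k]]))
                            sum(diag(st$Vi)) -
                             sum(st$WViW_inv * crossprod(st$ViW))
                           else
                            sum(st$Vi * Kt[[k]]) -
                             sum(st$WViW_inv *
                                   crossprod(st$ViW, Kt[[k]] %*% st$ViW)))) / n
      new_theta <- pmax(new_theta, floor_v)
      new_st <- eval_state(new_theta)
      if (is.null(new_st)) {
        warning("REML covariance became non-positive-definite; stopping early")
        break
      }
    }
    dll <- new_st$ll - st$ll
    dth <- max(abs(pmax(new_theta, floor_v) - theta))
    theta <- pmax(new_theta, floor_v)
    st <- new_st
    floor_hits <- ifelse(theta <= floor_v * 1.001, floor_hits + 1L, 0L)
    if (verbose) message(sprintf("iter %d  ll = %.6f", it, st$ll))
    if (abs(dll) < tol || dth < 1e-10 * vp) {
      converged <- TRUE
      break
    }
  }
  if (!converged && it >= max_iter)
    warning("REML did not converge in ", max_iter, " iterations (last ",
            "log-likelihood change above tolerance)")
  ai_inv <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, nk, nk))
  list(theta = theta, se = sqrt(pmax(diag(ai_inv), 0)), ai_inv = ai_inv,
       loglik = st$ll, converged = converged, iterations = it,
       boundary = theta <= floor_v * 1.001, floor = floor_v,
       beta = st$beta, Py = st$Py, Vi = st$Vi, ViW = st$ViW,
       WViW_inv = st$WViW_inv, n = n, rank_W = p)
}

## REML log-likelihood of the fixed-effects-only model (V = Ve I), on the
## same constant convention, with Ve at its analytical optimum.
reml_null_loglik <- function(y, W) {
  n <- length(y)
  W <- as.matrix(W)
  p <- ncol(W)
  fit <- stats::lm.fit(W, y)
  rss <- sum(fit$residuals^2)
  ve <- rss / (n - p)
  ldWW <- as.numeric(determinant(crossprod(W), logarithm = TRUE)$modulus)
  -0.5 * ((n - p) * log(2 * pi) + n * log(ve) + (ldWW - p * log(ve)) +
            (n - p))
}

#' Univariate REML variance components on a genomic relationship matrix
#'
#' Fits y = W alpha + u + e with u ~ N(0, Vg G), e ~ N(0, Ve I), by
#' average-information REML with expectation-maximization fallback steps.
#' Heritability is Vg / (Vg + Ve); its standard error comes from the
#' inverse average-information matrix by the delta method.
#'
#' @param spec a [mixed_model_spec()].
#' @param g a [compute_grm()] result (or symmetric matrix).
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   change in REML log-likelihood.
#' @return object of class \code{reml_fit}: \code{vg}, \code{ve}, \code{h2}
#'   with standard errors, \code{loglik}, \code{loglik_null} (no-genetics
#'   model), \code{converged}, \code{boundary} flags, and solver internals
#'   used by [gebv()].
#' @export
reml_univariate <- function(spec, g, max_iter = 200L, tol = 1e-8) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  G <- if (inherits(g, "grm")) g$G else g
  n <- length(spec$y)
  if (nrow(G) != n) stop("GRM dimension does not match the phenotype vector")
  if (n < ncol(spec$W) + 2L) stop("too few samples for REML")
  fit <- reml_ai(spec$y, spec$W, list(G), max_iter = max_iter, tol = tol)
  vg <- fit$theta[1L]; ve <- fit$theta[2L]
  h2 <- vg / (vg + ve)
  grad <- c(ve, -vg) / (vg + ve)^2
  se_h2 <- if (all(is.finite(fit$ai_inv))) {
    sqrt(max(drop(t(grad) %*% fit$ai_inv %*% grad), 0))
  } else NA_real_
  # a variance is "at the boundary" when pinned at its floor or when the
  # heritability sits at either end of [0, 1]
  boundary <- fit$boundary | c(h2 <= 1e-3, h2 >= 1 - 1e-3)
  structure(list(vg = vg, ve = ve, h2 = h2,
                 se_vg = fit$se[1L], se_ve = fit$se[2L], se_h2 = se_h2,
                 loglik = fit$loglik,
                 loglik_null = reml_null_loglik(spec$y, spec$W),
                 converged = fit$converged, iterations = fit$iterations,
                 boundary = boundary, spec = spec, G = G,
                 engine = fit),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("Univariate REML fit\n")
  cat(sprintf("  Vg = %.5g (SE %.3g), Ve = %.5g (SE %.3g)\n",
              x$vg, x$se_vg, x$ve, x$se_ve))
  cat(sprintf("  h2 = %.4f (SE %.3g)%s\n", x$h2, x$se_h2,
              if (any(x$boundary)) "  [variance at boundary]" else ""))
  cat(sprintf("  REML logL = %.4f (null %.4f), converged: %s in %d iter\n",
              x$loglik, x$loglik_null, x$converged, x$iterations))
  invisible(x)
}

## ---- bivariate REML ----
## Fast path: rotate both traits by the eigenvectors of G; the stacked
## covariance G0 x G + R0 x I becomes n independent 2x2 blocks
## Sigma_i = G0 d_i + R0.
bivar_loglik <- function(par6, d, y1r, y2r, W1r, W2r) {
  g11 <- par6[1L]; g12 <- par6[2L]; g22 <- par6[3L]
  e11 <- par6[4L]; e12 <- par6[5L]; e22 <- par6[6L]
  a <- g11 * d + e11
  b <- g22 * d + e22
  cc <- g12 * d + e12
  det_i <- a * b - cc^2
  if (any(det_i <= 0) || any(a <= 0) || any(b <= 0)) return(-Inf)
  i11 <- b / det_i; i22 <- a / det_i; i12 <- -cc / det_i
  p1 <- ncol(W1r); p2 <- ncol(W2r)
  # W' V^-1 W for block-diagonal fixed design diag(W1, W2)
  A11 <- crossprod(W1r * i11, W1r)
  A22 <- crossprod(W2r * i22, W2r)
  A12 <- crossprod(W1r * i12, W2r)
  WViW <- rbind(cbind(A11, A12), cbind(t(A12), A22))
  b1 <- crossprod(W1r, i11 * y1r + i12 * y2r)
  b2 <- crossprod(W2r, i12 * y1r + i22 * y2r)
  WViy <- rbind(b1, b2)
  chw <- tryCatch(chol(WViW), error = function(e) NULL)
  if (is.null(chw)) return(-Inf)
  beta <- backsolve(chw, forwardsolve(t(chw), WViy))
  yViy <- sum(y1r * (i11 * y1r + i12 * y2r)) +
    sum(y2r * (i12 * y1r + i22 * y2r))
  yPy <- yViy - sum(WViy * beta)
  n2 <- 2L * length(d)
  -0.5 * ((n2 - p1 - p2) * log(2 * pi) + sum(log(det_i)) +
            2 * sum(log(diag(chw))) + yPy)
}

chol_to_cov <- function(l3) {
  L <- matrix(c(l3[1L], l3[2L], 0, l3[3L]), 2L, 2L)
  tcrossprod(L)
}

#' Bivariate REML: genetic and residual covariances for two traits
#'
#' Fits the two-trait genomic mixed model with unstructured 2 x 2 genetic
#' and residual covariance matrices (Cholesky-parameterized, so both stay
#' positive semi-definite) on the same samples, maximizing the exact REML
#' likelihood after rotating both traits by the eigenvectors of G. The
#' genetic correlation's standard error comes from the observed information
#' at the optimum by the delta method; significance uses a two-tailed t with
#' n - rank(W1) - 1 degrees of freedom.
#'
#' When the estimate sits on the correlation boundary the Wald SE does not
#' exist; \code{profile_rg} evaluates the profile REML likelihood at chosen
#' correlation values (all other parameters re-optimized), giving
#' likelihood-ratio statistics that remain valid at the boundary.
#'
#' @param spec1,spec2 [mixed_model_spec()] objects for the two traits,
#'   sample-aligned with \code{g}.
#' @param g a [compute_grm()] result or symmetric matrix.
#' @param profile_rg optional numeric vector of genetic-correlation values at
#'   which to evaluate the profile likelihood.
#' @return object of class \code{reml_bivar}: \code{G0}, \code{R0}, per-trait
#'   \code{h2}, \code{rg} with \code{se_rg}, \code{p_rg}, \code{loglik},
#'   boundary flag, and (when requested) \code{rg_profile} with columns
#'   \code{rg}, \code{loglik}, \code{lrt}.
#' @export
reml_bivariate <- function(spec1, spec2, g, profile_rg = NULL) {
  stopifnot(inherits(spec1, "mixed_model_spec"),
            inherits(spec2, "mixed_model_spec"))
  G <- if (inherits(g, "grm")) g$G else g
  n <- length(spec1$y)
  if (length(spec2$y) != n || nrow(G) != n)
    stop("both traits and the GRM must cover the same samples")
  e <- eigen(G, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  y1r <- drop(crossprod(U, spec1$y))
  y2r <- drop(crossprod(U, spec2$y))
  W1r <- crossprod(U, spec1$W)
  W2r <- crossprod(U, spec2$W)

  f1 <- reml_univariate(spec1, G)
  f2 <- reml_univariate(spec2, G)
  init <- c(sqrt(f1$vg), 0, sqrt(f2$vg), sqrt(f1$ve), 0, sqrt(f2$ve))
  negll <- function(par) {
    G0 <- chol_to_cov(par[1:3]); R0 <- chol_to_cov(par[4:6])
    -bivar_loglik(c(G0[1, 1], G0[1, 2], G0[2, 2],
                    R0[1, 1], R0[1, 2], R0[2, 2]),
                  d, y1r, y2r, W1r, W2r)
  }
  opt <- stats::optim(init, negll, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  opt <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-13))
  G0 <- chol_to_cov(opt$par[1:3])
  R0 <- chol_to_cov(opt$par[4:6])
  ll <- -opt$value

  vg1 <- G0[1, 1]; vg2 <- G0[2, 2]; cg <- G0[1, 2]
  rg <- if (vg1 > 0 && vg2 > 0) cg / sqrt(vg1 * vg2) else NA_real_
  boundary <- is.na(rg) || abs(rg) > 0.999

  # observed information in the covariance parameterization
  th <- c(G0[1, 1], G0[1, 2], G0[2, 2], R0[1, 1], R0[1, 2], R0[2, 2])
  f_cov <- function(t6) -bivar_loglik(t6, d, y1r, y2r, W1r, W2r)
  H <- num_hessian(f_cov, th)
  cov_th <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, 6L, 6L))
  se_rg <- NA_real_
  if (!boundary && all(is.finite(cov_th[1:3, 1:3]))) {
    grad <- c(-rg / (2 * vg1), 1 / sqrt(vg1 * vg2), -rg / (2 * vg2))
    v <- drop(t(grad) %*% cov_th[1:3, 1:3] %*% grad)
    if (is.finite(v) && v > 0) se_rg <- sqrt(v)
  }
  df <- n - ncol(spec1$W) - 1L
  p_rg <- if (is.finite(se_rg))
    2 * stats::pt(abs(rg / se_rg), df = df, lower.tail = FALSE)
  else NA_real_
  h2 <- c(vg1 / (vg1 + R0[1, 1]), vg2 / (vg2 + R0[2, 2]))

  rg_profile <- NULL
  if (!is.null(profile_rg)) {
    prof_one <- function(rg0) {
      # 5 free parameters: log genetic SDs, residual Cholesky
      neg5 <- function(par) {
        s1 <- exp(par[1L]); s2 <- exp(par[2L])
        R0c <- chol_to_cov(par[3:5])
        -bivar_loglik(c(s1^2, rg0 * s1 * s2, s2^2,
                        R0c[1, 1], R0c[1, 2], R0c[2, 2]),
                      d, y1r, y2r, W1r, W2r)
      }
      ini <- c(log(max(sqrt(vg1), 1e-4)), log(max(sqrt(vg2), 1e-4)),
               opt$par[4:6])
      op <- stats::optim(ini, neg5, method = "Nelder-Mead",
                         control = list(maxit = 3000, reltol = 1e-12))
      -op$value
    }
    pll <- vapply(profile_rg, prof_one, 0)
    rg_profile <- data.frame(rg = profile_rg, loglik = pll,
                             lrt = pmax(2 * (ll - pll), 0))
  }
  structure(list(G0 = G0, R0 = R0, h2 = h2, rg = rg, se_rg = se_rg,
                 p_rg = p_rg, df = df, loglik = ll, boundary = boundary,
                 rg_profile = rg_profile, univariate = list(f1, f2)),
            class = "reml_bivar")
}

#' @export
print.reml_bivar <- function(x, ...) {
  cat("Bivariate REML fit\n")
  cat(sprintf("  h2: %.4f, %.4f\n", x$h2[1L], x$h2[2L]))
  cat(sprintf("  genetic correlation rg = %.4f (SE %.3g, P = %.3g)%s\n",
              x$rg, x$se_rg, x$p_rg,
              if (x$boundary) "  [at boundary]" else ""))
  invisible(x)
}

## Central-difference Hessian (small, dense problems only).
num_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- pmax(abs(x) * 1e-4, 1e-7)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Genomic breeding values with prediction-error variances
#'
#' BLUP solutions of the mixed-model equations at the REML estimates:
#' u_hat = Vg G P y, with prediction error variance
#' PEV_i = (Vg G - Vg G P G Vg)_(ii) and accuracy
#' sqrt(1 - PEV_i / Vg). PEV is clamped to [0, Vg] before the square root;
#' clamped individuals are flagged.
#'
#' @param spec a [mixed_model_spec()] (only used for dimension checks; the
#'   phenotype and design are taken from \code{vc}).
#' @param g a [compute_grm()] result or matrix.
#' @param vc a converged [reml_univariate()] fit on the same data.
#' @return data.frame (id, gebv, pev, accuracy).
#' @export
gebv <- function(spec, g, vc) {
  stopifnot(inherits(vc, "reml_fit"))
  if (!vc$converged) stop("variance-component fit did not converge")
  G <- if (inherits(g, "grm")) g$G else g
  en <- vc$engine
  vg <- vc$vg
  GPy <- G %*% en$Py
  u_hat <- vg * GPy
  # PEV = Vg G - Vg G P G Vg (diagonal); P G = Vi G - ViW WViW_inv (ViW' G)
  ViG <- en$Vi %*% G
  PG <- ViG - en$ViW %*% (en$WViW_inv %*% crossprod(en$ViW, G))
  pev <- vg * diag(G) - vg^2 * colSums(t(G) * PG)
  clamped <- pev < 0 | pev > vg
  pev_c <- pmin(pmax(pev, 0), vg)
  acc <- sqrt(1 - pev_c / vg)
  ids <- if (!is.null(vc$spec$ids)) vc$spec$ids else rownames(G)
  if (is.null(ids)) ids <- seq_along(u_hat)
  data.frame(id = ids, gebv = drop(u_hat), pev = pev_c, accuracy = acc,
             clamped = clamped, stringsAsFactors = FALSE)
}
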