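# Spectral REML for the two-component model
#   y = X beta + a + e,  a ~ N(0, sg2 * K),  e ~ N(0, se2 * diag(1/w))
#
# With S = diag(sqrt(w)) the rotated model  S y = S X beta + S a + S e  has
# covariance  sg2 * (S K S) + se2 * I.  One eigendecomposition
# S K S = U L U'  diagonalises the covariance for every variance ratio
# delta = sg2/se2, so the restricted likelihood profiles to a 1-D function
# of delta that is optimised exactly.  The same decomposition is reused by
# the fast per-SNP GLS scan.

#' @keywords internal
reml_prep <- function(K, X, weights) {
  n <- nrow(K)
  stopifnot(ncol(K) == n, nrow(X) == n, length(weights) == n)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design matrix is rank deficient")
  sw <- sqrt(weights)
  Ks <- K * tcrossprod(sw)
  eg <- eigen(Ks, symmetric = TRUE)
  list(U = eg$vectors, lambda = pmax(eg$values, 0), sw = sw,
       Xt = crossprod(eg$vectors, X * sw), n = n, p = ncol(X))
}

# Rotate a vector/matrix into the spectral basis.
#' @keywords internal
reml_rotate <- function(prep, M) {
  crossprod(prep$U, M * prep$sw)
}

# Profile restricted log-likelihood at variance ratio delta, plus the
# implied estimates.  Xt/yt are rotated design and response.
#' @keywords internal
reml_eval <- function(delta, lambda, Xt, yt) {
  n <- length(yt); p <- ncol(Xt)
  v <- delta * lambda + 1
  wv <- 1 / v
  XtW <- Xt * wv
  A0 <- crossprod(Xt, XtW)
  ch <- tryCatch(chol(A0), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(XtW, yt)))
  r <- yt - Xt %*% beta
  ss <- sum(r^2 * wv)
  if (ss <= 0) return(list(loglik = -Inf))
  ll <- 0.5 * ((n - p) * (log(n - p) - log(2 * pi) - 1) -
                 (n - p) * log(ss) - sum(log(v)) -
                 2 * sum(log(diag(ch))))
  list(loglik = ll, sigma_e2 = ss / (n - p), beta = drop(beta),
       v = v, resid = drop(r))
}

# Maximise the profile restricted likelihood over delta >= 0 by a log-grid
# scan refined with optimize(); the delta = 0 boundary is always a
# candidate.
#' @keywords internal
reml_profile <- function(lambda, Xt, yt, grid_n = 81L) {
  f <- function(ld) reml_eval(exp(ld), lambda, Xt, yt)$loglik
  grid <- seq(-14, 14, length.out = grid_n)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  ll0 <- reml_eval(0, lambda, Xt, yt)
  if (ll0$loglik >= opt$objective) {
    delta <- 0; best <- ll0
  } else {
    delta <- exp(opt$maximum); best <- reml_eval(delta, lambda, Xt, yt)
  }
  list(delta = delta, loglik = best$loglik,
       sigma_e2 = best$sigma_e2, sigma_g2 = delta * best$sigma_e2,
       beta = best$beta)
}

# Restricted log-likelihood at explicit (sg2, se2); used for curvature.
#' @keywords internal
reml_loglik_at <- function(sg2, se2, lambda, Xt, yt) {
  n <- length(yt); p <- ncol(Xt)
  v <- sg2 * lambda + se2
  if (any(v <= 0)) return(-Inf)
  wv <- 1 / v
  XtW <- Xt * wv
  A0 <- crossprod(Xt, XtW)
  ch <- tryCatch(chol(A0), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(XtW, yt)))
  r <- drop(yt - Xt %*% beta)
  -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + sum(r^2 * wv)) -
    0.5 * (n - p) * log(2 * pi)
}

# Approximate SE of prop_g = sg2/(sg2+se2) from the numerical Hessian of
# the restricted log-likelihood in (log sg2, log se2); NA near boundaries.
#' @keywords internal
prop_g_se <- function(sg2, se2, lambda, Xt, yt) {
  if (sg2 <= 1e-8 || se2 <= 1e-8) return(NA_real_)
  th <- log(c(sg2, se2))
  f <- function(t) reml_loglik_at(exp(t[1]), exp(t[2]), lambda, Xt, yt)
  h <- 1e-4
  H <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    e1 <- e2 <- numeric(2); e1[i] <- h; e2[j] <- h
    H[i, j] <- (f(th + e1 + e2) - f(th + e1 - e2) -
                  f(th - e1 + e2) + f(th - e1 - e2)) / (4 * h^2)
  }
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || any(diag(V) < 0)) return(NA_real_)
  # prop on log scale: d prop / d log sg2 = prop*(1-prop), symmetric in se2
  pr <- sg2 / (sg2 + se2)
  gr <- c(pr * (1 - pr), -pr * (1 - pr))
  se2p <- drop(t(gr) %*% V %*% gr)
  if (!is.finite(se2p) || se2p < 0) return(NA_real_)
  sqrt(se2p)
}

#' Fit the polygenic null model by REML
#'
#' Restricted maximum likelihood for
#' `y = X beta + u + e`, `u ~ N(0, A sigma_a2)`,
#' `Var(e_i) = sigma_e2 / w_i`, via a single spectral decomposition of the
#' weighted relationship matrix and exact 1-D optimisation of the
#' variance ratio.
#'
#' When the (weighted) relationship matrix is proportional to the
#' identity the two variances are not separately identifiable; the fitter
#' detects the flat likelihood direction, warns, and reports the total
#' variance instead of failing.
#'
#' @param y Numeric response (one record per animal, e.g. standardised
#'   trait deviations).
#' @param X Fixed-effect design matrix (mean, breed, sex).
#' @param A Relationship matrix aligned with `y`.
#' @param weights Positive residual weights `w` (record reliabilities);
#'   `Var(e_i) = sigma_e2 / w_i`.  Default all 1.
#' @param prep Optional spectral preparation from a previous fit with the
#'   same `A`, `X` and `weights` (the `prep` element of an `lmm_fit`);
#'   reusing it across traits on one population skips the
#'   eigendecomposition.
#' @return An object of class `lmm_fit`: `sigma_a2`, `sigma_e2`, `delta`
#'   (ratio), `beta`, `loglik`, `identifiable`, `total_var`, and the
#'   spectral preparation reused by [snp_association()].
#' @export
fit_null_model <- function(y, X, A, weights = rep(1, length(y)),
                           prep = NULL) {
  y <- as.numeric(y)
  if (stats::var(y) == 0) stop("response has zero variance")
  if (is.null(prep)) prep <- reml_prep(A, X, weights)
  yt <- drop(reml_rotate(prep, y))
  lam <- prep$lambda
  spread <- max(lam) - min(lam)
  if (spread < 1e-8 * max(1, max(abs(lam)))) {
    ll0 <- reml_eval(0, lam, prep$Xt, yt)
    warning("relationship matrix is proportional to the identity under ",
            "these weights; polygenic and residual variances are not ",
            "separately identifiable - reporting total variance only")
    return(structure(list(sigma_a2 = NA_real_, sigma_e2 = NA_real_,
                          delta = 0, beta = ll0$beta,
                          loglik = ll0$loglik,
                          total_var = ll0$sigma_e2,
                          identifiable = FALSE,
                          prep = prep, yt = yt, weights = weights),
                     class = "lmm_fit"))
  }
  fit <- reml_profile(lam, prep$Xt, yt)
  structure(list(sigma_a2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                 delta = fit$delta, beta = fit$beta, loglik = fit$loglik,
                 total_var = fit$sigma_g2 + fit$sigma_e2,
                 identifiable = TRUE,
                 prep = prep, yt = yt, weights = weights),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> sigma_a2 =", format(x$sigma_a2, digits = 4),
      " sigma_e2 =", format(x$sigma_e2, digits = 4),
      " logLik =", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Single-SNP association scan under the polygenic model
#'
#' Tests each SNP as a fixed additive covariate (`b` = effect of the
#' counted allele) in the weighted polygenic model.  Two modes:
#' \describe{
#'   \item{fast}{generalised least squares with the null model's variance
#'     components, via the null fit's spectral decomposition (one rotation
#'     of the genotype matrix, then O(n) per SNP).}
#'   \item{exact}{a full REML refit of the variance ratio per SNP with
#'     the SNP in the fixed part; the reference implementation the fast
#'     mode is tested against.}
#' }
#' Monomorphic SNPs and SNPs collinear with the fixed effects are flagged
#' in `status` and get `NA` estimates rather than being dropped.
#'
#' @param genotypes Animals x SNPs dosage matrix (0/1/2 or imputed
#'   dosages), column names = SNP ids, rows aligned with the null fit.
#' @param null_fit An `lmm_fit` from [fit_null_model()].
#' @param mode `"fast"` (default) or `"exact"`.
#' @param rotated Optional pre-rotated genotype matrix from
#'   [rotate_genotypes()]; lets multi-trait scans on one population pay
#'   the genotype rotation once.
#' @return A `data.frame`: `snp_id`, `beta`, `se`, `pvalue`, `status`
#'   (`"ok"`, `"monomorphic"` or `"collinear"`).  P-values are two-sided
#'   from the standard normal reference for the Wald ratio.
#' @export
snp_association <- function(genotypes, null_fit, mode = c("fast", "exact"),
                            rotated = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(null_fit, "lmm_fit"),
            nrow(genotypes) == null_fit$prep$n)
  prep <- null_fit$prep
  yt <- null_fit$yt
  m <- ncol(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  mono <- apply(genotypes, 2L, function(g) stats::var(g) == 0)
  Gt <- if (is.null(rotated)) reml_rotate(prep, genotypes) else rotated
  beta <- se <- rep(NA_real_, m)
  status <- ifelse(mono, "monomorphic", "ok")

  if (mode == "fast") {
    v <- null_fit$delta * prep$lambda + 1
    wv <- 1 / v
    Xt <- prep$Xt
    XtW <- Xt * wv
    A0 <- crossprod(Xt, XtW)
    XtWy <- crossprod(XtW, yt)
    beta0 <- solve(A0, XtWy)
    ss_y <- sum((yt - Xt %*% beta0)^2 * wv)   # for collinearity scaling
    WG <- Gt * wv
    CB <- crossprod(Xt, WG)          # p x m
    B <- solve(A0, CB)
    num <- drop(crossprod(WG, yt)) - colSums(B * drop(XtWy))
    den <- colSums(Gt * WG) - colSums(CB * B)
    raw <- colSums(Gt * WG)
    coll <- !mono & (den <= 1e-10 * pmax(raw, 1e-300))
    status[coll] <- "collinear"
    ok <- !mono & !coll
    beta[ok] <- num[ok] / den[ok]
    # residual variance re-estimated per SNP at the null variance ratio
    # (REML denominator n - p - 1), matching the exact refit closely
    s2 <- (ss_y - num[ok]^2 / den[ok]) / (prep$n - prep$p - 1L)
    se[ok] <- sqrt(s2 / den[ok])
  } else {
    lam <- prep$lambda
    for (j in seq_len(m)) {
      if (mono[j]) next
      Xt2 <- cbind(prep$Xt, Gt[, j])
      if (qr(Xt2)$rank < ncol(Xt2)) { status[j] <- "collinear"; next }
      fit <- reml_profile(lam, Xt2, yt)
      v <- fit$delta * lam + 1
      wv <- 1 / v
      A0 <- crossprod(Xt2, Xt2 * wv)
      Vb <- tryCatch(solve(A0), error = function(e) NULL)
      if (is.null(Vb)) { status[j] <- "collinear"; next }
      k <- ncol(Xt2)
      beta[j] <- fit$beta[k]
      se[j] <- sqrt(fit$sigma_e2 * Vb[k, k])
    }
  }
  p <- ifelse(is.na(beta), NA_real_, 2 * stats::pnorm(-abs(beta / se)))
  data.frame(snp_id = ids, beta = beta, se = se, pvalue = p,
             status = status, stringsAsFactors = FALSE)
}

#' Fit the genomic (GRM) variance-component model by REML
#'
#' REML for `y = X beta + g + e`, `g ~ N(0, G sigma_g2)`,
#' `Var(e_i) = sigma_e2 / w_i`, where `G` is a genomic relationship
#' matrix built from a SNP set.  Reports the proportion of (random-part)
#' variance captured by the SNPs, `prop_g = sigma_g2 / (sigma_g2 +
#' sigma_e2)`, with an approximate standard error from the curvature of
#' the restricted likelihood.
#'
#' @param y Numeric response.
#' @param X Fixed-effect design matrix.
#' @param grm A `grm` object from [build_grm()] (or a plain symmetric
#'   matrix).
#' @param weights Positive residual weights (default all 1).
#' @param prep Optional spectral preparation from a previous fit with the
#'   same GRM, design and weights.
#' @return An object of class `varcomp_fit`: `sigma_g2`, `sigma_e2`,
#'   `prop_g`, `se_prop`, `loglik`, `converged`, `snp_ids`, `prep`.
#' @export
fit_grm_model <- function(y, X, grm, weights = rep(1, length(y)),
                          prep = NULL) {
  G <- if (inherits(grm, "grm")) grm$G else grm
  snp_ids <- if (inherits(grm, "grm")) grm$snp_ids else NULL
  y <- as.numeric(y)
  if (stats::var(y) == 0) stop("response has zero variance")
  if (is.null(prep)) prep <- reml_prep(G, X, weights)
  yt <- drop(reml_rotate(prep, y))
  lam <- prep$lambda
  spread <- max(lam) - min(lam)
  if (spread < 1e-8 * max(1, max(abs(lam))))
    warning("GRM is proportional to the identity under these weights; ",
            "genomic and residual variances are not separately identifiable")
  fit <- reml_profile(lam, prep$Xt, yt)
  prop <- fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2)
  sep <- prop_g_se(fit$sigma_g2, fit$sigma_e2, lam, prep$Xt, yt)
  structure(list(sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                 prop_g = prop, se_prop = sep, beta = fit$beta,
                 loglik = fit$loglik, converged = is.finite(fit$loglik),
                 snp_ids = snp_ids, prep = prep),
            class = "varcomp_fit")
}

#' Rotate a genotype matrix into a null fit's spectral basis
#'
#' @param null_fit An `lmm_fit` (or its `prep` element).
#' @param genotypes Animals x SNPs dosage matrix aligned with the fit.
#' @return The rotated matrix, usable as the `rotated` argument of
#'   [snp_association()].
#' @export
rotate_genotypes <- function(null_fit, genotypes) {
  prep <- if (inherits(null_fit, "lmm_fit")) null_fit$prep else null_fit
  reml_rotate(prep, genotypes)
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("<varcomp_fit> prop_g =", format(x$prop_g, digits = 4),
      "( sigma_g2 =", format(x$sigma_g2, digits = 4),
      ", sigma_e2 =", format(x$sigma_e2, digits = 4), ")\n")
  invisible(x)
}

#' Genomic-control inflation factor
#'
#' Lambda = median observed Wald chi-square / median of the 1-df
#' chi-square reference; values near 1 indicate a well-calibrated scan.
#'
#' @param assoc Association results from [snp_association()] (or a vector
#'   of p-values).
#' @return The genomic-control lambda.
#' @export
gc_lambda <- function(assoc) {
  p <- if (is.data.frame(assoc)) assoc$pvalue else as.numeric(assoc)
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no p-values available")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}
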