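test_that("with identity A and unit weights the scan collapses to OLS", {
  set.seed(11)
  n <- 80
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + rnorm(n)
  geno <- matrix(rbinom(n * 5, 2, 0.4), n,
                 dimnames = list(NULL, paste0("s", 1:5)))
  expect_warning(nf <- fit_null_model(y, X, diag(n)),
                 "not.*separately identifiable")
  expect_false(nf$identifiable)
  # total variance equals the null-model residual variance
  r0 <- resid(lm(y ~ X - 1))
  expect_equal(nf$total_var, sum(r0^2) / (n - 2))
  res <- snp_association(geno, nf, mode = "fast")
  for (j in 1:5) {
    g <- geno[, j]
    sm <- summary(lm(y ~ X - 1 + g))$coefficients["g", ]
    expect_equal(res$beta[j], unname(sm["Estimate"]))
    expect_equal(res$se[j], unname(sm["Std. Error"]))
    # normal rather than t reference for the Wald ratio
    expect_equal(res$pvalue[j],
                 2 * pnorm(-abs(sm["Estimate"] / sm["Std. Error"])),
                 ignore_attr = TRUE)
  }
})

test_that("fast mode on a diagonal A with unit weights is textbook GLS", {
  set.seed(12)
  n <- 60
  d <- runif(n, 0.5, 3)           # heteroscedastic 'relationship' diagonal
  A <- diag(d)
  X <- cbind(1, rbinom(n, 1, 0.5))
  u <- rnorm(n, 0, sqrt(0.5 * d))
  y <- drop(X %*% c(0, 1)) + u + rnorm(n, 0, sqrt(0.5))
  nf <- fit_null_model(y, X, A)
  geno <- matrix(rbinom(n * 4, 2, 0.3), n,
                 dimnames = list(NULL, paste0("s", 1:4)))
  res <- snp_association(geno, nf, mode = "fast")
  Sig <- nf$delta * A + diag(n)   # relative covariance at the null fit
  Si <- solve(Sig)
  for (j in 1:4) {
    C <- cbind(X, geno[, j])
    V <- solve(t(C) %*% Si %*% C)
    b <- drop(V %*% t(C) %*% Si %*% y)
    expect_equal(res$beta[j], b[3])
    r <- y - drop(C %*% b)
    s2 <- drop(t(r) %*% Si %*% r) / (n - 3)
    expect_equal(res$se[j], sqrt(s2 * V[3, 3]))
  }
})

test_that("p-values are invariant to allele flipping", {
  sim <- small_sim(seed = 31, n_animals = 200, n_snps = 300)
  ph <- sim$phenotypes$t
  geno <- sim$genotypes[ph$animal, 1:40]
  A <- build_a_matrix(sim$pedigree)[ph$animal, ph$animal]
  w <- record_weights(ph, 0.33, 0.56)
  nf <- fit_null_model(ph$value, make_design(ph), A, w)
  res <- snp_association(geno, nf)
  resf <- snp_association(2 - geno, nf)
  ok <- res$status == "ok"
  expect_equal(resf$beta[ok], -res$beta[ok])
  expect_equal(resf$pvalue[ok], res$pvalue[ok])
})

test_that("exact per-SNP REML and fast GLS agree at scan scale", {
  sim <- small_sim(seed = 32, n_animals = 200, n_snps = 300, h2 = 0.33)
  ph <- sim$phenotypes$t
  geno <- sim$genotypes[ph$animal, seq(1, 300, by = 10)]
  A <- build_a_matrix(sim$pedigree)[ph$animal, ph$animal]
  w <- record_weights(ph, 0.33, 0.56)
  nf <- fit_null_model(ph$value, make_design(ph), A, w)
  fast <- snp_association(geno, nf, mode = "fast")
  exact <- snp_association(geno, nf, mode = "exact")
  ok <- fast$status == "ok" & exact$status == "ok"
  dlp <- abs(log10(fast$pvalue[ok]) - log10(exact$pvalue[ok]))
  expect_lte(max(dlp), 0.05)
})

test_that("degenerate and malformed inputs fail loudly", {
  n <- 30
  A <- diag(n)
  expect_error(fit_null_model(rep(1, n), cbind(1, rnorm(n)), A),
               "zero variance")
  Xbad <- cbind(1, 1:n, 2 * (1:n))
  expect_error(fit_null_model(rnorm(n), Xbad, A), "rank deficient")
  expect_error(fit_null_model(rnorm(n), cbind(1, rnorm(n)), A,
                              weights = rep(-1, n)), "positive")
})

test_that("monomorphic and collinear SNPs are flagged, not dropped", {
  set.seed(13)
  n <- 50
  sex <- rbinom(n, 1, 0.5)
  X <- cbind(1, sex)
  y <- rnorm(n)
  geno <- cbind(mono = rep(2, n), coll = 2 * sex,
                ok = rbinom(n, 2, 0.4))
  A <- diag(runif(n, 0.9, 1.5))
  nf <- fit_null_model(y, X, A)
  for (mode in c("fast", "exact")) {
    res <- snp_association(geno, nf, mode = mode)
    expect_equal(res$status, c("monomorphic", "collinear", "ok"))
    expect_true(all(is.na(res$beta[1:2])))
    expect_false(is.na(res$pvalue[3]))
    expect_equal(nrow(res), 3L)
  }
})

test_that("REML null fit recovers variance components in simulation", {
  # moderate-size sanity version of the recovery experiment
  set.seed(14)
  ped <- make_test_pedigree(n = 300, n_founders = 60, seed = 15)
  A <- build_a_matrix(ped)
  L <- t(chol(A))
  X <- cbind(1, rbinom(300, 1, 0.5))
  ests <- replicate(10, {
    y <- drop(X %*% c(0, 0.3)) + drop(L %*% rnorm(300, 0, sqrt(0.4))) +
      rnorm(300, 0, sqrt(0.6))
    f <- fit_null_model(y, X, A)
    c(f$sigma_a2, f$sigma_e2)
  })
  expect_equal(mean(ests[1, ]), 0.4,
               tolerance = 3 * sd(ests[1, ]) / sqrt(10) / 0.4 + 0.05)
  expect_equal(mean(ests[1, ] + ests[2, ]), 1.0, tolerance = 0.15)
})

test_that("rotated-genotype reuse reproduces the direct scan", {
  sim <- small_sim(seed = 33, n_animals = 150, n_snps = 200)
  ph <- sim$phenotypes$t
  geno <- sim$genotypes[ph$animal, ]
  A <- build_a_matrix(sim$pedigree)[ph$animal, ph$animal]
  w <- record_weights(ph, 0.33, 0.56)
  nf <- fit_null_model(ph$value, make_design(ph), A, w)
  rot <- rotate_genotypes(nf, geno)
  expect_equal(snp_association(geno, nf, rotated = rot),
               snp_association(geno, nf))
  # prep reuse across traits gives identical fits
  nf2 <- fit_null_model(ph$value, make_design(ph), A, w, prep = nf$prep)
  expect_equal(nf2$sigma_a2, nf$sigma_a2)
  expect_equal(nf2$loglik, nf$loglik)
})
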