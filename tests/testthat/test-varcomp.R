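test_that("REML criterion equals an independent error-contrast evaluation", {
  set.seed(601)
  N <- 40; q <- 15
  Z <- matrix(rbinom(N * q, 1, 0.3), N, q)
  K <- crossprod(matrix(rnorm(q * q), q)) / q
  X <- cbind(1, rnorm(N))
  y <- rnorm(N)
  theta <- c(1.3, 0.7)
  # independent route: project onto an orthonormal basis of the null
  # space of X' and evaluate the Gaussian -2 loglik of the contrasts;
  # the two parameterizations differ by the constant log|X'X|
  V <- theta[1] * Z %*% K %*% t(Z) + theta[2] * diag(N)
  A <- qr.Q(qr(X), complete = TRUE)[, -(1:2)]
  AVA <- t(A) %*% V %*% A
  w <- t(A) %*% y
  oracle <- as.numeric(determinant(AVA)$modulus) +
    drop(t(w) %*% solve(AVA, w)) +
    as.numeric(determinant(crossprod(X))$modulus)
  impl <- neg2_restricted_loglik(y, list(g = list(Z = Z, K = K)), theta, X = X)
  expect_equal(impl, oracle, tolerance = 1e-10)
})

test_that("REML criterion obeys the location-scale identity", {
  set.seed(602)
  N <- 60; q <- 12
  Z <- matrix(rbinom(N * q, 1, 0.4), N, q)
  random <- list(g = list(Z = Z, K = NULL))
  y <- rnorm(N, mean = 5)
  theta <- c(0.8, 1.2)
  cc <- 3.7
  base <- neg2_restricted_loglik(y, random, theta)
  scaled <- neg2_restricted_loglik(cc * y, random, cc^2 * theta)
  expect_equal(scaled, base + (N - 1) * log(cc^2), tolerance = 1e-8)
})

test_that("residual-only REML recovers the unbiased variance estimate", {
  set.seed(603)
  N <- 50
  X <- cbind(1, rnorm(N), runif(N))
  y <- drop(X %*% c(2, 1, -1)) + rnorm(N, sd = 2)
  fit <- reml_fit(y, random = list(), X = X)
  s2 <- sum(stats::lm.fit(X, y)$residuals^2) / (N - ncol(X))
  expect_true(fit$converged)
  expect_equal(unname(fit$theta[["residual"]]), s2, tolerance = 1e-6)
})

test_that("variance estimates match lme4 on a random-intercept model", {
  set.seed(604)
  ng <- 40; nper <- 6
  grp <- factor(rep(seq_len(ng), each = nper))
  y <- 3 + rnorm(ng, sd = 1.6)[grp] + rnorm(ng * nper, sd = 1.2)
  fit <- reml_fit(y, list(grp = list(Z = stats::model.matrix(~ grp - 1),
                                     K = NULL)))
  lf <- lme4::lmer(y ~ 1 + (1 | grp))
  ref <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_true(fit$converged)
  expect_equal(unname(fit$theta), ref, tolerance = 1e-5)
  # BLUPs of the group effects agree too
  expect_equal(unname(fit$blup$grp),
               lme4::ranef(lf)$grp[["(Intercept)"]], tolerance = 1e-4)
})

test_that("grouped-data simulation is recovered within 3 SE", {
  set.seed(605)
  ng <- 200; nper <- 4
  grp <- factor(rep(seq_len(ng), each = nper))
  truth <- c(2, 1)
  y <- rnorm(ng, sd = sqrt(truth[1]))[grp] +
    rnorm(ng * nper, sd = sqrt(truth[2]))
  fit <- reml_fit(y, list(grp = list(Z = stats::model.matrix(~ grp - 1),
                                     K = NULL)))
  expect_true(fit$converged)
  expect_true(all(abs(fit$theta - truth) < 3 * fit$se))
})

test_that("AI-REML optimum matches a derivative-free optimizer", {
  set.seed(606)
  n <- 150
  g <- hwe_genotypes(n, runif(400, 0.1, 0.9))
  G <- grm_additive(g)$K
  y <- drop(crossprod(chol(G + diag(1e-8, n)), rnorm(n))) * sqrt(2) +
    rnorm(n, sd = 1)
  random <- list(a = list(Z = NULL, K = G))
  fit <- reml_fit(y, random)
  nm <- optim(log(c(1, 1)),
              function(lt) neg2_restricted_loglik(y, random, exp(lt)),
              method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta - exp(nm$par)) / exp(nm$par)), 1e-4)
  expect_lt(abs(fit$minus2logL - nm$value), 1e-6)
})

test_that("constant response pins every component and zeroes the BLUPs", {
  g <- hwe_genotypes(30, runif(50, 0.2, 0.8))
  G <- grm_additive(g)$K
  y <- rep(7, 30)
  fit <- reml_fit(y, list(a = list(Z = NULL, K = G)))
  expect_true(all(fit$pinned))
  expect_lt(max(abs(fit$blup$a)), 1e-10)
})

test_that("-2logL never increases on EM fallback steps", {
  set.seed(607)
  n <- 80
  g <- hwe_genotypes(n, runif(200, 0.1, 0.9))
  G <- grm_additive(g)$K
  y <- drop(crossprod(chol(G + diag(1e-8, n)), rnorm(n))) + rnorm(n, 3)
  # a wild start makes early AI proposals fail, exercising the fallback
  fit <- reml_fit(y, list(a = list(Z = NULL, K = G)),
                  start = c(1e3 * var(y), 1e-5 * var(y)))
  tr <- fit$trace
  em <- which(tr$step == "EM")
  for (i in em)
    expect_lte(tr$minus2logL[i], tr$minus2logL[i - 1] + 1e-8)
  expect_true(fit$converged)
})

test_that("GBLUP predictions equal SNP-BLUP ridge predictions", {
  set.seed(608)
  n_ref <- 200; n_test <- 40; m <- 500
  g <- hwe_genotypes(n_ref + n_test, runif(m, 0.1, 0.9))
  f <- allele_frequencies(g)
  ca <- additive_coding(g, f)
  G <- grm_additive(ca)
  s2a <- 2; s2e <- 1.5
  y_all <- drop(crossprod(chol_tol(G$K), rnorm(n_ref + n_test))) * sqrt(s2a) +
    rnorm(n_ref + n_test, sd = sqrt(s2e)) + 10
  pheno <- tibble::tibble(id = rownames(g), y = y_all,
                          test = seq_len(n_ref + n_test) > n_ref)
  # BLUP at fixed variance components (no iteration)
  fit <- gblup(pheno, list(additive = G), litter = NULL,
               start = c(s2a, s2e), max_iter = 0)
  pred <- predict(fit)
  oracle <- snp_blup_oracle(ca$coef[1:n_ref, ], y_all[1:n_ref], ca$coef,
                            s2a, s2e, ca$scale)
  expect_lt(max(abs(pred$gbv - oracle)), 1e-6)
})

test_that("test-set solutions equal the covariance projection of reference
           solutions, and duplicated individuals get identical values", {
  set.seed(609)
  n_ref <- 80; m <- 300
  g_ref <- hwe_genotypes(n_ref, runif(m, 0.1, 0.9))
  dos <- rbind(unclass(g_ref), unclass(g_ref)[c(3, 17), ])
  rownames(dos) <- c(rownames(g_ref), "copy3", "copy17")
  g <- genotype_matrix(dos)
  G <- grm_additive(g)
  y <- rnorm(n_ref, 5, 2)
  pheno <- tibble::tibble(id = rownames(g),
                          y = c(y, NA, NA),
                          test = c(rep(FALSE, n_ref), TRUE, TRUE))
  fit <- gblup(pheno, list(additive = G), litter = NULL)
  pred <- predict(fit)
  # identical relationship rows -> identical predictions
  expect_equal(pred$gbv[pred$id == "copy3"], pred$gbv[pred$id == "id3"],
               tolerance = 1e-10)
  expect_equal(pred$gbv[pred$id == "copy17"], pred$gbv[pred$id == "id17"],
               tolerance = 1e-10)
  # projection route: u_test = K_tr K_rr^{-1} u_ref
  Krr <- G$K[1:n_ref, 1:n_ref]
  Ktr <- G$K[n_ref + (1:2), 1:n_ref]
  u_ref <- pred$gbv[1:n_ref]
  proj <- unname(drop(Ktr %*% solve(Krr + diag(1e-10, n_ref), u_ref)))
  expect_equal(pred$gbv[n_ref + (1:2)], proj, tolerance = 1e-6)
})

test_that("model family is nested, comparable and internally consistent", {
  set.seed(610)
  sim <- simulate_gblup_data(n_ref = 250, n_test = 50, m = 400,
                             vc = truth_vc, mode = "mvn", seed = 610)
  g <- qc_filter(sim$genotypes)$genotypes
  G <- grm_additive(g)
  D <- grm_dominance(g)
  fam <- fit_model_family(sim$pheno, G, D)
  m2 <- vapply(fam, function(f) f$minus2logL, numeric(1))
  tol <- 1e-6 * (1 + abs(m2[["MA"]]))
  expect_lte(m2[["MAED"]], m2[["MAD"]] + tol)
  expect_lte(m2[["MAD"]], m2[["MA"]] + tol)
  expect_lte(m2[["MAED"]], m2[["MAE"]] + tol)
  expect_lte(m2[["MAE"]], m2[["MA"]] + tol)
  # proportions sum to one by construction, per fit
  for (f in fam) expect_equal(sum(tidy(f)$proportion), 1)
  # GTV is the exact sum of the genetic-term solutions
  pred <- predict(fam$MAED)
  expect_equal(pred$gtv, pred$additive + pred$epistatic + pred$dominance)
})

test_that("heritability is invariant to rescaling the response", {
  set.seed(611)
  sim <- simulate_gblup_data(n_ref = 200, n_test = 0, m = 300,
                             vc = c(a = 2, aa = 0, d = 0, litter = 0.5, e = 2),
                             mode = "mvn", seed = 611)
  g <- qc_filter(sim$genotypes)$genotypes
  G <- grm_additive(g)
  f1 <- gblup(sim$pheno, list(additive = G))
  pheno2 <- sim$pheno
  pheno2$y <- 100 * pheno2$y
  f2 <- gblup(pheno2, list(additive = G))
  h2 <- function(f) attr(variance_proportions(f), "h2_narrow")
  expect_equal(h2(f1), h2(f2), tolerance = 1e-4)
  expect_equal(unname(f2$theta / f1$theta), rep(1e4, 3), tolerance = 1e-3)
})
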