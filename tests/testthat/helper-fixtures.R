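# Shared fixtures and independent oracles for the test suite.

# small genotype matrix with explicit values
tiny_genotypes <- function(dosages, ids = NULL, loci = NULL) {
  m <- as.matrix(dosages)
  rownames(m) <- ids %||% paste0("id", seq_len(nrow(m)))
  colnames(m) <- loci %||% paste0("snp", seq_len(ncol(m)))
  genotype_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# HWE genotypes at given allele frequencies, no family structure
hwe_genotypes <- function(n, p) {
  m <- length(p)
  g <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  tiny_genotypes(g)
}

# brute-force double-sum oracle for the additive relationship matrix:
# G_kl = sum_i m_ki m_li / (2 sum p q), coefficients computed entry by entry
bruteforce_G <- function(g, freqs = allele_frequencies(g)) {
  n <- nrow(g); m <- ncol(g)
  p <- freqs$p
  K <- matrix(0, n, n)
  scale <- 2 * sum(p * (1 - p))
  for (k in seq_len(n)) for (l in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) {
      xk <- g[k, i]; xl <- g[l, i]
      mk <- if (is.na(xk)) 0 else xk - 2 * p[i]
      ml <- if (is.na(xl)) 0 else xl - 2 * p[i]
      s <- s + mk * ml
    }
    K[k, l] <- s / scale
  }
  K
}

# same for the dominance matrix with the heterozygosity coding
bruteforce_D <- function(g, freqs = allele_frequencies(g)) {
  n <- nrow(g); m <- ncol(g)
  p <- freqs$p; q <- 1 - p
  K <- matrix(0, n, n)
  scale <- sum(2 * p * q * (1 - 2 * p * q))
  for (k in seq_len(n)) for (l in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) {
      hk <- if (is.na(g[k, i])) 0 else (g[k, i] == 1) - 2 * p[i] * q[i]
      hl <- if (is.na(g[l, i])) 0 else (g[l, i] == 1) - 2 * p[i] * q[i]
      s <- s + hk * hl
    }
    K[k, l] <- s / scale
  }
  K
}

# SNP-BLUP ridge oracle: marker effects b = M'(MM' + lambda I)^{-1} (y - Xb)
# with lambda = sigma2_e / sigma2_marker, sigma2_marker = sigma2_a / scale.
# Predictions for any coded individual are M_new %*% b.  Solved directly
# from its own normal equations, independent of the package's MME route.
snp_blup_oracle <- function(M_ref, y_ref, M_all, sigma2_a, sigma2_e, scale) {
  N <- nrow(M_ref)
  lambda <- sigma2_e / (sigma2_a / scale)
  # joint normal equations for (mu, marker effects)
  W <- cbind(1, M_ref)
  lhs <- crossprod(W)
  diag(lhs)[-1] <- diag(lhs)[-1] + lambda
  sol <- solve(lhs, crossprod(W, y_ref))
  drop(M_all %*% sol[-1])
}

# default simulation truth used across recovery tests (magnitudes of a
# growth trait measured in g/day)
truth_vc <- c(a = 2000, aa = 500, d = 300, litter = 500, e = 2200)

expect_symmetric <- function(K, tol = 1e-12) {
  expect_lt(max(abs(K - t(K))), tol)
}

# Cholesky with a fixed small ridge, for drawing from near-singular K
chol_tol <- function(K) chol(K + diag(1e-8, nrow(K)))
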