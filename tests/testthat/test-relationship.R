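test_that("additive coding substitutes the centred coefficients", {
  # p = 0.5: dosages (0,1,2) -> (-1, 0, 1)
  g <- tiny_genotypes(matrix(c(0L, 1L, 2L), 3, 1))
  ca <- additive_coding(g)
  expect_equal(unname(drop(ca$coef)), c(-1, 0, 1))
  # p = 0.8, dosage 2 -> 2 - 1.6 = 0.4 (external frequencies)
  g2 <- tiny_genotypes(matrix(2L, 1, 1))
  f <- tibble::tibble(locus_id = "snp1", p = 0.8, q = 0.2)
  expect_equal(unname(drop(additive_coding(g2, f)$coef)), 0.4)
  # two loci at p = 0.5 -> scale 2 * (0.25 + 0.25) = 1
  g3 <- tiny_genotypes(rbind(c(0L, 2L), c(2L, 0L)))
  expect_equal(additive_coding(g3)$scale, 1.0)
  # missing entries contribute their expectation, 0 on the centred scale
  g4 <- tiny_genotypes(rbind(c(0L, NA), c(2L, 1L), c(1L, 1L)))
  expect_equal(additive_coding(g4)$coef[1, 2], 0)
})

test_that("dominance coding uses the centred heterozygosity coefficients", {
  # p = 0.5: heterozygote 1 - 0.5 = 0.5, homozygote -0.5
  g <- tiny_genotypes(matrix(c(0L, 1L, 2L), 3, 1))
  cd <- dominance_coding(g)
  expect_equal(unname(drop(cd$coef)), c(-0.5, 0.5, -0.5))
  # p = 0.9: heterozygote 1 - 2*0.9*0.1 = 0.82
  g2 <- tiny_genotypes(matrix(1L, 1, 1))
  f <- tibble::tibble(locus_id = "snp1", p = 0.9, q = 0.1)
  expect_equal(unname(drop(dominance_coding(g2, f)$coef)), 0.82)
  # two loci at p = 0.5: per-locus 2pq(1-2pq) = 0.5*0.5 = 0.25, summed 0.5
  g3 <- tiny_genotypes(rbind(c(0L, 2L), c(2L, 0L)))
  expect_equal(dominance_coding(g3)$scale, 0.5)
  # missing entries contribute 0
  g4 <- tiny_genotypes(rbind(c(1L, NA), c(0L, 1L), c(2L, 1L), c(1L, 0L)))
  expect_equal(dominance_coding(g4)$coef[1, 2], 0)
  # fixed loci are rejected by name
  g5 <- tiny_genotypes(cbind(c(0L, 1L), c(2L, 2L)), loci = c("ok", "fixed1"))
  expect_error(additive_coding(g5), "fixed1")
  expect_error(dominance_coding(g5), "fixed1")
})

test_that("worked 2x2 example: G, its Hadamard square, identical rows", {
  # individuals A = (0,2), B = (2,0) at two loci with p = 0.5:
  # M rows (-1, 1) and (1, -1), scale 1 -> G = [[2,-2],[-2,2]]
  g <- tiny_genotypes(rbind(A = c(0L, 2L), B = c(2L, 0L)),
                      ids = c("A", "B"))
  G <- grm_additive(g)
  expect_equal(unname(G$K), rbind(c(2, -2), c(-2, 2)))
  # G # G = elementwise square
  GG <- grm_epistatic(G, G)
  expect_equal(unname(GG$K), rbind(c(4, 4), c(4, 4)))
  expect_identical(GG$kind, "epistatic")
  expect_identical(GG$recipe, "AxA")

  # identical genotype rows give identical G rows/entries
  g2 <- tiny_genotypes(rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(2L, 0L, 1L)))
  G2 <- grm_additive(g2)$K
  expect_equal(G2[1, 1], G2[1, 2])
  expect_equal(G2[1, 1], G2[2, 2])
})

test_that("dominance matrix worked examples", {
  # an individual heterozygous at every locus, all p = 0.5:
  # per-locus h = 0.5, per-locus scale 0.25 -> D_kk = m*0.25 / (m*0.25) = 1
  g <- tiny_genotypes(rbind(c(1L, 1L, 1L, 1L),
                            c(0L, 2L, 0L, 2L),
                            c(2L, 0L, 2L, 0L),
                            c(1L, 1L, 0L, 2L)))
  f <- tibble::tibble(locus_id = colnames(g), p = rep(0.5, 4), q = rep(0.5, 4))
  D <- grm_dominance(g, f)
  expect_equal(D$K[1, 1], 1.0)
  # identical heterozygosity patterns -> equal entries
  expect_equal(D$K[2, 3], D$K[2, 2])  # rows 2 and 3 have the same h pattern
})

test_that("matrix formula equals the brute-force double sum", {
  set.seed(501)
  g <- hwe_genotypes(12, runif(40, 0.15, 0.85))
  dos <- unclass(g)
  dos[sample(length(dos), 10)] <- NA   # exercise missing handling too
  g <- genotype_matrix(dos)
  f <- allele_frequencies(g)
  expect_lt(max(abs(grm_additive(g, f)$K - bruteforce_G(g, f))), 1e-10)
  expect_lt(max(abs(grm_dominance(g, f)$K - bruteforce_D(g, f))), 1e-10)
})

test_that("G and D are invariant to allele relabelling", {
  set.seed(502)
  g <- hwe_genotypes(15, runif(30, 0.1, 0.9))
  flip <- sample(ncol(g), 12)
  dos2 <- unclass(g)
  dos2[, flip] <- 2L - dos2[, flip]
  g2 <- genotype_matrix(dos2)
  expect_equal(grm_additive(g)$K, grm_additive(g2)$K, tolerance = 1e-12)
  expect_equal(grm_dominance(g)$K, grm_dominance(g2)$K, tolerance = 1e-12)
})

test_that("built matrices are symmetric and PSD after tiny jitter", {
  set.seed(503)
  g <- hwe_genotypes(30, runif(100, 0.1, 0.9))
  for (K in list(grm_additive(g)$K, grm_dominance(g)$K,
                 grm_epistatic(grm_additive(g), grm_additive(g))$K)) {
    expect_symmetric(K)
    ev <- eigen(K + diag(1e-8, nrow(K)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("expectation properties hold on a large HWE population", {
  set.seed(504)
  g <- hwe_genotypes(500, runif(5000, 0.05, 0.95))
  G <- grm_additive(g)$K
  D <- grm_dominance(g)$K
  expect_lt(abs(mean(diag(G)) - 1), 0.02)
  expect_lt(abs(mean(diag(D)) - 1), 0.02)
  off <- upper.tri(G)
  expect_lt(abs(mean(G[off])), 0.01)
  expect_lt(abs(mean(D[off])), 0.01)
})

test_that("Hadamard with a matrix of ones is an identity operation", {
  set.seed(505)
  g <- hwe_genotypes(8, runif(20, 0.2, 0.8))
  G <- grm_additive(g)
  ones <- G; ones$K[] <- 1
  expect_equal(grm_epistatic(G, ones)$K, G$K)
  # diagonal of G # G is the squared diagonal of G
  expect_equal(diag(grm_epistatic(G, G)$K), diag(G$K)^2)
  # three-way recipes record their composition
  D <- grm_dominance(g)
  expect_identical(grm_epistatic(G, G, D)$recipe, "AxAxD")
  # mismatched individuals error
  g2 <- tiny_genotypes(unclass(hwe_genotypes(8, runif(20, 0.2, 0.8))),
                       ids = paste0("other", 1:8))
  expect_error(grm_epistatic(G, grm_additive(g2)), "individuals")
})

test_that("GRM file round-trips: exact for tsv, float32 for gcta binary", {
  set.seed(506)
  g <- hwe_genotypes(12, runif(25, 0.3, 0.7))
  G <- grm_additive(g)
  tsv <- withr::local_tempfile(fileext = ".grm.tsv")
  write_grm(G, tsv, "tsv")
  G2 <- read_grm(tsv, "tsv")
  expect_identical(G2$K, G$K)
  expect_identical(G2$kind, "additive")
  expect_equal(G2$scale, G$scale)

  prefix <- file.path(withr::local_tempdir(), "test")
  write_grm(G, prefix, "gcta_bin", n_markers = ncol(g))
  # n(n+1)/2 float32 values stored for the lower triangle
  expect_identical(file.size(paste0(prefix, ".grm.bin")), 4 * 12 * 13 / 2)
  G3 <- read_grm(prefix, "gcta_bin")
  expect_identical(rownames(G3$K), rownames(G$K))
  expect_lt(max(abs(G3$K - G$K)), 1e-6)
  # truncated id file is caught
  ids <- readLines(paste0(prefix, ".grm.id"))
  writeLines(ids[-1], paste0(prefix, ".grm.id"))
  expect_error(read_grm(prefix, "gcta_bin"), "inconsistent")
})

test_that("column means of centred codings shrink with sample size", {
  set.seed(507)
  g <- hwe_genotypes(800, runif(50, 0.2, 0.8))
  f <- allele_frequencies(g)
  # centring on the realized sample frequencies zeroes the additive
  # column sums exactly; the dominance columns are zero in expectation
  # only, so their means shrink like 1/sqrt(n)
  expect_lt(max(abs(colMeans(additive_coding(g, f)$coef))), 1e-12)
  expect_lt(max(abs(colMeans(dominance_coding(g, f)$coef))), 4 / sqrt(nrow(g)))
})
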