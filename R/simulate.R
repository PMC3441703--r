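#' Simulate SNP genotypes with litter (full-sib) family structure
#'
#' Generates a pedigree-free population with genuine genomic relatedness:
#' unrelated founders are drawn in Hardy-Weinberg equilibrium at allele
#' frequencies sampled uniformly from `freq_range`; reference-generation
#' individuals are produced by Mendelian gamete sampling from randomly
#' mated founder pairs and grouped into full-sib litters; a second,
#' unphenotyped test generation is bred the same way from
#' reference-generation parents.  The generational split mirrors the
#' usual practice of validating genomic predictions on the youngest
#' animals.
#'
#' @param n_ref,n_test Number of reference- and test-generation
#'   individuals.
#' @param m Number of biallelic loci.
#' @param n_founders Size of the founder parent pool (default 80).
#' @param litter_size Full-sib litter size (default 8, the scale of a
#'   pig litter); the last litter of a generation may be smaller.
#' @param freq_range Range of the uniform allele-frequency law for the
#'   founders (default `c(0.05, 0.95)`, i.e. all loci start above the
#'   usual 5% MAF editing threshold).
#' @param seed Optional integer seed; the generator is fully
#'   reproducible given the same configuration and seed.
#' @return A list with `genotypes` (a [genotype_matrix()] of the
#'   reference + test individuals; founders are not returned) and `meta`
#'   (tibble `id`, `litter`, `generation`, `test`).
#' @export
simulate_genotypes <- function(n_ref, n_test, m, n_founders = 80,
                               litter_size = 8,
                               freq_range = c(0.05, 0.95), seed = NULL) {
  stopifnot(n_ref >= 1, n_test >= 0, m >= 1, n_founders >= 2,
            litter_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(m, freq_range[1L], freq_range[2L])
  founders <- matrix(stats::rbinom(n_founders * m, 2L, rep(p, each = n_founders)),
                     nrow = n_founders)

  breed <- function(parents, n_off, litter_prefix) {
    n_litters <- ceiling(n_off / litter_size)
    if (nrow(parents) < 2L) stop("parent pool too small to mate", call. = FALSE)
    dosages <- matrix(0L, n_off, m)
    litter <- character(n_off)
    row <- 1L
    for (l in seq_len(n_litters)) {
      pair <- sample.int(nrow(parents), 2L)
      size <- min(litter_size, n_off - row + 1L)
      sire <- parents[pair[1L], ]
      dam <- parents[pair[2L], ]
      for (k in seq_len(size)) {
        dosages[row, ] <- stats::rbinom(m, 1L, sire / 2) +
          stats::rbinom(m, 1L, dam / 2)
        litter[row] <- paste0(litter_prefix, l)
        row <- row + 1L
      }
    }
    list(dosages = dosages, litter = litter)
  }

  ref <- breed(founders, n_ref, "L1_")
  ids_ref <- sprintf("ref%04d", seq_len(n_ref))
  if (n_test > 0L) {
    tst <- breed(ref$dosages, n_test, "L2_")
    ids_test <- sprintf("tst%04d", seq_len(n_test))
    dosages <- rbind(ref$dosages, tst$dosages)
    meta <- tibble::tibble(
      id = c(ids_ref, ids_test),
      litter = c(ref$litter, tst$litter),
      generation = rep(1:2, c(n_ref, n_test)),
      test = rep(c(FALSE, TRUE), c(n_ref, n_test)))
  } else {
    dosages <- ref$dosages
    meta <- tibble::tibble(id = ids_ref, litter = ref$litter,
                           generation = 1L, test = FALSE)
  }
  rownames(dosages) <- meta$id
  colnames(dosages) <- sprintf("snp%05d", seq_len(m))
  list(genotypes = genotype_matrix(dosages), meta = meta,
       founder_freq = p)
}

#' Simulate phenotypes with additive, epistatic, dominance and litter
#' components
#'
#' Builds a phenotype `y = mu + a + i + d + litter + e` on top of
#' simulated (or real) genotypes, with every component's true value
#' recorded so that variance-component estimation and prediction can be
#' checked against the truth.
#'
#' Two generating modes:
#' * `"mvn"` — the genetic components are drawn multivariate normal with
#'   covariances proportional to the realized relationship matrices
#'   (`a ~ N(0, G s2_a)`, `i ~ N(0, (G#G) s2_aa)`, `d ~ N(0, D s2_d)`),
#'   i.e. exactly the covariance structure the GBLUP model assumes.
#' * `"locus"` — per-locus additive effects and dominance values are
#'   drawn iid normal and summed over the genotype codings, with
#'   variances scaled so the expected component variances hit the
#'   targets (additive effect variance `s2_a / (2*sum(p*q))`, dominance
#'   value variance `s2_d / sum(2pq(1-2pq))`); additive-by-additive
#'   effects act on a random subset of locus pairs through the product
#'   of the centred additive codings, scaled analogously.
#'
#' Litter effects are iid normal per litter (a purely environmental
#' common-litter effect) and residuals iid normal.
#'
#' @param genotypes A [genotype_matrix()].
#' @param meta Tibble with columns `id`, `litter`, `test` matching the
#'   genotype rows (as produced by [simulate_genotypes()]).
#' @param vc Named numeric vector of true variances
#'   `c(a=, aa=, d=, litter=, e=)`; any component may be 0.
#' @param mu Overall mean (default 0).
#' @param mode `"mvn"` or `"locus"`.
#' @param n_pairs Number of interacting locus pairs in `"locus"` mode.
#' @param seed Optional integer seed.
#' @return A list of class `sim_truth`: `pheno` (tibble `id`, `litter`,
#'   `test`, `y` — the input to [gblup()]), `truth` (tibble of the true
#'   per-individual components), `realized_vc` (sample variances of the
#'   realized components), `vc`, `mode`, `mu`, `seed`.
#' @export
simulate_phenotypes <- function(genotypes, meta,
                                vc = c(a = 2000, aa = 500, d = 300,
                                       litter = 500, e = 2200),
                                mu = 0, mode = c("mvn", "locus"),
                                n_pairs = 2000, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  need <- c("a", "aa", "d", "litter", "e")
  if (!all(need %in% names(vc)))
    stop("vc must name components ", paste(need, collapse = ", "), call. = FALSE)
  if (any(vc < 0)) stop("variances must be >= 0", call. = FALSE)
  meta <- as.data.frame(meta)
  if (!identical(as.character(meta$id), rownames(genotypes)))
    stop("meta$id must match genotype rows in order", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(genotypes)
  freqs <- allele_frequencies(genotypes)
  # loci fixed by drift carry no genetic variance; build the generating
  # covariances on the polymorphic ones
  poly <- freqs$p > 0 & freqs$p < 1
  if (!any(poly)) stop("all loci are fixed; no genetic variance possible",
                       call. = FALSE)
  genotypes <- genotype_matrix(unclass(genotypes)[, poly, drop = FALSE])
  freqs <- freqs[poly, ]

  draw_mvn <- function(K, s2) {
    if (s2 == 0) return(numeric(n))
    U <- chol_jitter(K, "relationship matrix")
    unname(drop(crossprod(U, stats::rnorm(n)))) * sqrt(s2)
  }

  if (mode == "mvn") {
    G <- grm_additive(genotypes, freqs)
    a <- draw_mvn(G$K, vc[["a"]])
    i <- if (vc[["aa"]] > 0) draw_mvn(grm_epistatic(G, G)$K, vc[["aa"]])
         else numeric(n)
    d <- if (vc[["d"]] > 0) draw_mvn(grm_dominance(genotypes, freqs)$K,
                                     vc[["d"]]) else numeric(n)
  } else {
    ca <- additive_coding(genotypes, freqs)
    a <- if (vc[["a"]] > 0)
      unname(drop(ca$coef %*% stats::rnorm(ncol(genotypes),
                                           sd = sqrt(vc[["a"]] / ca$scale))))
      else numeric(n)
    d <- if (vc[["d"]] > 0) {
      cd <- dominance_coding(genotypes, freqs)
      unname(drop(cd$coef %*% stats::rnorm(ncol(genotypes),
                                           sd = sqrt(vc[["d"]] / cd$scale))))
    } else numeric(n)
    i <- numeric(n)
    if (vc[["aa"]] > 0) {
      mloc <- ncol(genotypes)
      pairs <- cbind(sample.int(mloc, n_pairs, replace = TRUE),
                     sample.int(mloc, n_pairs, replace = TRUE))
      pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
      tpq <- 2 * freqs$p * freqs$q
      # Var(m_i * m_j) = 2p_i q_i * 2p_j q_j for independent HWE loci
      pair_var <- tpq[pairs[, 1L]] * tpq[pairs[, 2L]]
      gam <- stats::rnorm(nrow(pairs), sd = sqrt(vc[["aa"]] / sum(pair_var)))
      W <- ca$coef[, pairs[, 1L], drop = FALSE] *
        ca$coef[, pairs[, 2L], drop = FALSE]
      i <- unname(drop(W %*% gam))
    }
  }

  lf <- factor(meta$litter)
  litter_eff <- if (vc[["litter"]] > 0)
    stats::rnorm(nlevels(lf), sd = sqrt(vc[["litter"]]))[as.integer(lf)]
    else numeric(n)
  e <- if (vc[["e"]] > 0) stats::rnorm(n, sd = sqrt(vc[["e"]]))
       else numeric(n)
  y <- mu + a + i + d + litter_eff + e

  truth <- tibble::tibble(id = meta$id, a = a, i = i, d = d,
                          litter_eff = litter_eff, e = e, y = y)
  pheno <- tibble::tibble(id = meta$id, litter = as.character(meta$litter),
                          test = meta$test, y = y)
  structure(list(pheno = pheno, truth = truth,
                 realized_vc = c(a = stats::var(a), aa = stats::var(i),
                                 d = stats::var(d),
                                 litter = stats::var(litter_eff),
                                 e = stats::var(e)),
                 vc = vc, mode = mode, mu = mu, seed = seed),
            class = "sim_truth")
}

#' One-call simulation of a complete GBLUP dataset
#'
#' Convenience wrapper chaining [simulate_genotypes()] and
#' [simulate_phenotypes()] under a single seed.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams simulate_phenotypes
#' @param ... Passed on to [simulate_genotypes()].
#' @return A list with `genotypes`, `meta`, `pheno`, `truth`,
#'   `realized_vc`, `vc`, `mode`, `seed`.
#' @export
simulate_gblup_data <- function(n_ref, n_test, m,
                                vc = c(a = 2000, aa = 500, d = 300,
                                       litter = 500, e = 2200),
                                mode = c("mvn", "locus"), seed = NULL, ...) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  geno <- simulate_genotypes(n_ref, n_test, m, ...)
  tr <- simulate_phenotypes(geno$genotypes, geno$meta, vc = vc, mode = mode)
  list(genotypes = geno$genotypes, meta = geno$meta,
       pheno = tr$pheno, truth = tr$truth, realized_vc = tr$realized_vc,
       vc = vc, mode = mode, seed = seed)
}

#' Write a complete benchmark bundle to disk
#'
#' Materializes a simulated dataset as plain-text files exercising the
#' whole pipeline end to end: `genotypes.tsv` (dosage matrix),
#' `pheno.tsv` (id, litter, test flag, phenotype), `truth.tsv` (true
#' genetic components) and `manifest.yaml` (configuration, seed, true
#' and realized variances).
#'
#' @param dir Output directory (created if absent).
#' @inheritParams simulate_gblup_data
#' @return The simulated dataset (as [simulate_gblup_data()]),
#'   invisibly; side effect: files under `dir`.
#' @export
make_benchmark <- function(dir, n_ref = 1000, n_test = 200, m = 2000,
                           vc = c(a = 2000, aa = 500, d = 300,
                                  litter = 500, e = 2200),
                           mode = "mvn", seed = 1, ...) {
  sim <- simulate_gblup_data(n_ref, n_test, m, vc = vc, mode = mode,
                             seed = seed, ...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_tsv(sim$genotypes, file.path(dir, "genotypes.tsv"))
  utils::write.table(sim$pheno, file.path(dir, "pheno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    n_ref = n_ref, n_test = n_test, m = m, mode = mode, seed = seed,
    true_variances = as.list(vc),
    realized_variances = lapply(as.list(sim$realized_vc), unname),
    files = c("genotypes.tsv", "pheno.tsv", "truth.tsv")),
    file.path(dir, "manifest.yaml"))
  invisible(sim)
}
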