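#' Centred additive genotype coding
#'
#' Builds the centred additive coefficient matrix `M` underlying the
#' additive genomic relationship matrix.  Column `i` of `M` takes the
#' value `0 - 2*p_i` for genotype A1A1, `1 - 2*p_i` for A1A2 and
#' `2 - 2*p_i` for A2A2, where `p_i` is the allele-2 frequency at locus
#' `i`.  A missing genotype contributes its expectation, i.e. 0 on the
#' centred scale.  The associated scale factor is `2 * sum(p_i * q_i)`.
#'
#' @param g A [genotype_matrix()] with no fixed loci (enforce with
#'   [qc_filter()]).
#' @param freqs Allele frequencies as returned by [allele_frequencies()];
#'   defaults to frequencies computed from `g` itself.  Supply external
#'   frequencies (e.g. from a base population) to centre on them instead.
#' @return A list of class `genomic_coding` with elements `coef` (the
#'   n x m centred matrix), `scale` (the denominator of the relationship
#'   matrix) and `kind` (`"additive"`).
#' @export
additive_coding <- function(g, freqs = NULL) {
  freqs <- check_coding_freqs(g, freqs)
  p <- freqs$p
  M <- sweep(unclass(g), 2L, 2 * p, `-`)
  M[is.na(M)] <- 0
  new_coding(M, scale = 2 * sum(p * (1 - p)), kind = "additive")
}

#' Centred dominance (heterozygosity) coding
#'
#' Builds the centred heterozygosity matrix `H` underlying the dominance
#' genomic relationship matrix.  At locus `i` a homozygote codes as
#' `-2*p_i*q_i` and a heterozygote as `1 - 2*p_i*q_i` (the raw 0/1
#' heterozygosity indicator centred by its Hardy-Weinberg expectation
#' `2*p_i*q_i`); a missing genotype contributes 0.  The scale factor is
#' `sum(2*p_i*q_i * (1 - 2*p_i*q_i))`, the unique constant for which, in
#' a Hardy-Weinberg population, the expected diagonal of `HH'/scale` is 1
#' for a non-inbred individual and the expected off-diagonal is 0 for two
#' unrelated individuals.
#'
#' @inheritParams additive_coding
#' @return A `genomic_coding` list with `kind = "dominance"`.
#' @export
dominance_coding <- function(g, freqs = NULL) {
  freqs <- check_coding_freqs(g, freqs)
  tpq <- 2 * freqs$p * freqs$q
  het <- (unclass(g) == 1L) * 1
  H <- sweep(het, 2L, tpq, `-`)
  H[is.na(H)] <- 0
  new_coding(H, scale = sum(tpq * (1 - tpq)), kind = "dominance")
}

check_coding_freqs <- function(g, freqs) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  if (!all(c("locus_id", "p") %in% names(freqs)))
    stop("`freqs` must have columns locus_id and p (see allele_frequencies())",
         call. = FALSE)
  freqs <- freqs[match(colnames(g), freqs$locus_id), ]
  if (anyNA(freqs$p))
    stop("`freqs` is missing loci present in `g`", call. = FALSE)
  fixed <- freqs$p <= 0 | freqs$p >= 1
  if (any(fixed))
    stop("fixed locus (p = 0 or 1): ",
         paste(utils::head(freqs$locus_id[fixed], 5L), collapse = ", "),
         call. = FALSE)
  if (!"q" %in% names(freqs)) freqs$q <- 1 - freqs$p
  freqs
}

new_coding <- function(coef, scale, kind) {
  if (scale <= 0) stop("coding scale factor must be positive", call. = FALSE)
  structure(list(coef = coef, scale = scale, kind = kind),
            class = "genomic_coding")
}

#' @export
print.genomic_coding <- function(x, ...) {
  cat(sprintf("<genomic_coding> %s, %d x %d, scale = %.4g\n",
              x$kind, nrow(x$coef), ncol(x$coef), x$scale))
  invisible(x)
}

new_grm <- function(K, kind, recipe, scale = NA_real_) {
  K <- (K + t(K)) / 2  # exact symmetry against rounding in BLAS products
  structure(list(K = K, kind = kind, recipe = recipe, scale = scale),
            class = "grm")
}

#' Genomic relationship matrices
#'
#' `grm_additive()` computes the additive (VanRaden) genomic relationship
#' matrix `G = MM' / (2 * sum(p*q))`; `grm_dominance()` computes the
#' dominance relationship matrix `D = HH' / sum(2pq(1-2pq))`;
#' `grm_epistatic()` forms an epistatic relationship matrix as the
#' Hadamard (elementwise) product of lower-order matrices, e.g. `G # G`
#' for additive-by-additive, `G # G # D` for
#' additive-by-additive-by-dominance.  No rescaling is applied after the
#' Hadamard product.
#'
#' @param x A [genotype_matrix()] or a `genomic_coding` from
#'   [additive_coding()] / [dominance_coding()].
#' @param freqs Optional allele frequencies (used only when `x` is a
#'   genotype matrix); see [additive_coding()].
#' @return An object of class `grm`: a list with `K` (the symmetric
#'   n x n matrix, individual ids as dimnames), `kind`
#'   (`additive`/`dominance`/`epistatic`), `recipe` (e.g. `"A"`, `"D"`,
#'   `"AxA"`) and `scale` (the denominator used, `NA` for epistatic).
#' @export
grm_additive <- function(x, freqs = NULL) {
  c <- if (inherits(x, "genomic_coding")) x else additive_coding(x, freqs)
  if (c$kind != "additive") stop("need an additive coding", call. = FALSE)
  new_grm(tcrossprod(c$coef) / c$scale, "additive", "A", c$scale)
}

#' @rdname grm_additive
#' @export
grm_dominance <- function(x, freqs = NULL) {
  c <- if (inherits(x, "genomic_coding")) x else dominance_coding(x, freqs)
  if (c$kind != "dominance") stop("need a dominance coding", call. = FALSE)
  new_grm(tcrossprod(c$coef) / c$scale, "dominance", "D", c$scale)
}

#' @rdname grm_additive
#' @param ... For `grm_epistatic()`: two or more `grm` objects sharing the
#'   same individuals in the same order.
#' @export
grm_epistatic <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !inherits(parts[[1L]], "grm"))
    parts <- parts[[1L]]
  if (length(parts) < 2L)
    stop("grm_epistatic() needs at least two relationship matrices", call. = FALSE)
  if (!all(vapply(parts, inherits, logical(1L), "grm")))
    stop("all arguments must be grm objects", call. = FALSE)
  ids <- rownames(parts[[1L]]$K)
  for (p in parts[-1L]) {
    if (!identical(dim(p$K), dim(parts[[1L]]$K)) ||
        !identical(rownames(p$K), ids))
      stop("relationship matrices differ in individuals or order", call. = FALSE)
  }
  K <- Reduce(`*`, lapply(parts, `[[`, "K"))
  recipe <- paste(vapply(parts, function(p) {
    switch(p$kind, additive = "A", dominance = "D", p$recipe)
  }, character(1L)), collapse = "x")
  new_grm(K, "epistatic", recipe)
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %s (%s), %d individuals, mean diag = %.3f\n",
              x$kind, x$recipe, nrow(x$K), mean(diag(x$K))))
  invisible(x)
}

#' @export
dim.grm <- function(x) dim(x$K)

#' Write / read a genomic relationship matrix
#'
#' `format = "tsv"` writes the full symmetric matrix with a header of
#' individual ids (exact round-trip).  `format = "gcta_bin"` writes the
#' GCTA GRM binary triplet: `<prefix>.grm.bin` (lower triangle including
#' the diagonal, row-wise, little-endian 4-byte floats),
#' `<prefix>.grm.id` (two tab-separated columns FID IID) and
#' `<prefix>.grm.N.bin` (float32 per-pair marker counts); the round-trip
#' is exact to float32 precision.
#'
#' @param x A `grm`.
#' @param prefix Output path (a file path for `tsv`, a prefix for
#'   `gcta_bin`).
#' @param format `"tsv"` or `"gcta_bin"`.
#' @param n_markers Marker count written to `.grm.N.bin` (gcta_bin only).
#' @return `write_grm()` returns `prefix` invisibly; `read_grm()` returns
#'   a `grm` (with `kind` as recorded in the TSV comment or
#'   `"unknown"` for gcta_bin).
#' @export
write_grm <- function(x, prefix, format = c("tsv", "gcta_bin"),
                      n_markers = NA_integer_) {
  stopifnot(inherits(x, "grm"))
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(prefix, "w")
    on.exit(close(con))
    writeLines(sprintf("# grm kind=%s recipe=%s scale=%.17g",
                       x$kind, x$recipe, x$scale), con)
    # 17 significant digits make the text round-trip exact for doubles
    txt <- matrix(sprintf("%.17g", x$K), nrow(x$K))
    utils::write.table(
      data.frame(id = rownames(x$K), txt, check.names = FALSE),
      con, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = c("id", colnames(x$K)))
  } else {
    n <- nrow(x$K)
    lower <- x$K[upper.tri(x$K, diag = TRUE)]  # column-wise upper == row-wise lower
    writeBin(as.numeric(lower), paste0(prefix, ".grm.bin"),
             size = 4L, endian = "little")
    utils::write.table(
      data.frame(fid = rownames(x$K), iid = rownames(x$K)),
      paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    nm <- if (is.na(n_markers)) 0 else n_markers
    writeBin(rep(as.numeric(nm), n * (n + 1) / 2),
             paste0(prefix, ".grm.N.bin"), size = 4L, endian = "little")
  }
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix, format = c("tsv", "gcta_bin")) {
  format <- match.arg(format)
  if (format == "tsv") {
    first <- readLines(prefix, n = 1L)
    kind <- "unknown"; recipe <- NA_character_; scale <- NA_real_
    skip <- 0L
    if (startsWith(first, "#")) {
      skip <- 1L
      kv <- regmatches(first, gregexpr("\\w+=[^ ]+", first))[[1L]]
      kvs <- strsplit(kv, "=", fixed = TRUE)
      for (p in kvs) {
        if (p[1L] == "kind") kind <- p[2L]
        if (p[1L] == "recipe") recipe <- p[2L]
        if (p[1L] == "scale") scale <- as.numeric(p[2L])
      }
    }
    dat <- utils::read.table(prefix, header = TRUE, sep = "\t", skip = skip,
                             check.names = FALSE, row.names = 1L)
    K <- as.matrix(dat)
    if (nrow(K) != ncol(K) || !identical(rownames(K), colnames(K)))
      stop("TSV GRM is not a symmetric id-labelled matrix", call. = FALSE)
    new_grm(K, kind, recipe, scale)
  } else {
    ids <- utils::read.table(paste0(prefix, ".grm.id"),
                             stringsAsFactors = FALSE)
    n <- nrow(ids)
    bin <- paste0(prefix, ".grm.bin")
    if (file.size(bin) != 4 * n * (n + 1) / 2)
      stop(".grm.bin size inconsistent with .grm.id (expected ",
           n * (n + 1) / 2, " float32 values)", call. = FALSE)
    vals <- readBin(bin, "numeric", n = n * (n + 1) / 2, size = 4L,
                    endian = "little")
    K <- matrix(0, n, n, dimnames = list(ids[[2L]], ids[[2L]]))
    K[upper.tri(K, diag = TRUE)] <- vals
    K <- K + t(K) - diag(diag(K))
    new_grm(K, "unknown", NA_character_)
  }
}
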