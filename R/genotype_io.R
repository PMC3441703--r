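#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds biallelic SNP genotypes as allele-2 dosages
#' (0, 1 or 2 copies of the second allele, `NA` when the call is missing),
#' one row per individual and one column per locus.  All downstream
#' machinery — allele frequencies, quality filtering and the centred
#' codings behind the genomic relationship matrices — starts from this
#' container.
#'
#' @param dosages Integer or numeric matrix of allele-2 counts in
#'   `{0, 1, 2}` with `NA` for missing calls.  Row names are individual
#'   ids, column names locus ids; both must be unique and non-empty.
#' @return An object of class `genotype_matrix` (a dosage matrix with
#'   validated dimnames).
#' @examples
#' m <- matrix(c(0L, 1L, 2L, 2L, NA, 0L), nrow = 3,
#'             dimnames = list(paste0("id", 1:3), c("snp1", "snp2")))
#' g <- genotype_matrix(m)
#' dim(g)
#' @export
genotype_matrix <- function(dosages) {
  if (!is.matrix(dosages)) stop("`dosages` must be a matrix", call. = FALSE)
  if (nrow(dosages) < 1L || ncol(dosages) < 1L)
    stop("genotype matrix must have at least one individual and one locus",
         call. = FALSE)
  storage.mode(dosages) <- "integer"
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("dosage at individual %d, locus %d is not in {0,1,2} or NA",
                 idx[1L], idx[2L]), call. = FALSE)
  }
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("individual ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(dosages)))
    stop("locus ids must be unique", call. = FALSE)
  structure(dosages, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d loci (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Individual and locus ids of a genotype matrix
#' @param g A [genotype_matrix()].
#' @return Character vector of ids.
#' @export
individual_ids <- function(g) rownames(g)

#' @rdname individual_ids
#' @export
locus_ids <- function(g) colnames(g)

#' Read SNP genotypes from disk
#'
#' Supported dialects:
#' * `plink_raw` — PLINK `--recode A` output: header
#'   `FID IID PAT MAT SEX PHENOTYPE <SNP>_<counted allele> ...`,
#'   whitespace separated, `NA` for missing.  The counting allele of the
#'   `.raw` file is taken as allele 2.
#' * `tsv` — first column individual id, header row of locus ids, cells
#'   `0/1/2/NA`.  Values are taken literally as allele-2 dosages.
#' * `vcf` — VCF v4.x; the ALT allele is allele 2, `./.` is missing.
#'   Records that are not biallelic SNPs are skipped with a warning.
#'
#' @param path Path to the genotype file.
#' @param format One of `"plink_raw"`, `"tsv"`, `"vcf"`.
#' @return A [genotype_matrix()].  For VCF input the number of skipped
#'   non-biallelic records is attached as attribute `"n_skipped"`.
#' @export
read_genotypes <- function(path, format = c("plink_raw", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         plink_raw = read_plink_raw(path),
         tsv       = read_genotype_tsv(path),
         vcf       = read_genotype_vcf(path))
}

read_plink_raw <- function(path) {
  dat <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           na.strings = "NA", stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(dat)))
    stop("not a PLINK .raw file: missing header columns ",
         paste(setdiff(meta, names(dat)), collapse = ", "), call. = FALSE)
  snp_cols <- setdiff(names(dat), meta)
  if (length(snp_cols) == 0L) stop("PLINK .raw file has no SNP columns", call. = FALSE)
  m <- as.matrix(dat[, snp_cols, drop = FALSE])
  # strip the "_<allele>" suffix PLINK appends to each SNP id
  colnames(m) <- sub("_[ACGT0-9]+$", "", snp_cols)
  rownames(m) <- as.character(dat$IID)
  genotype_matrix(m)
}

read_genotype_tsv <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           na.strings = "NA", stringsAsFactors = FALSE,
                           row.names = 1L)
  if (ncol(dat) == 0L) stop("TSV genotype file has no locus columns", call. = FALSE)
  genotype_matrix(as.matrix(dat))
}

read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!snp)
  if (n_skipped > 0L)
    warning(sprintf("skipped %d non-biallelic-SNP record(s)", n_skipped),
            call. = FALSE)
  if (!any(snp)) stop("no biallelic SNP records in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  })
  ids <- fix[snp, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[snp, "CHROM"], ":", fix[snp, "POS"])[no_id]
  rownames(dos) <- ids
  g <- genotype_matrix(t(dos))
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Allele frequencies per locus
#'
#' Computes, for every locus, the frequency `p` of allele 2 (the counted /
#' ALT allele) from the non-missing dosages:
#' `p = sum(dosages) / (2 * n_called)`.  `q = 1 - p` is the allele-1
#' frequency.
#'
#' @param g A [genotype_matrix()].
#' @return A tibble with columns `locus_id`, `p`, `q`, `n_called`
#'   (non-missing genotypes at the locus) and `call_rate`.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_called <- colSums(!is.na(g))
  if (any(n_called == 0L))
    stop("locus entirely missing: ",
         paste(colnames(g)[n_called == 0L], collapse = ", "), call. = FALSE)
  p <- colSums(g, na.rm = TRUE) / (2 * n_called)
  tibble::tibble(locus_id = colnames(g), p = as.numeric(p),
                 q = 1 - as.numeric(p),
                 n_called = as.integer(n_called),
                 call_rate = as.numeric(n_called) / nrow(g))
}

#' Quality-filter a genotype matrix
#'
#' Applies the standard SNP-chip editing rules, in this fixed order:
#' 1. drop loci whose minor allele frequency is not strictly above
#'    `maf_min` (computed on the input matrix);
#' 2. drop loci whose call rate is not strictly above `locus_call_min`;
#' 3. drop individuals whose call rate, over the retained loci, is not
#'    strictly above `indiv_call_min`.
#'
#' All thresholds are strict (`>`), so e.g. a locus at MAF exactly 0.05 is
#' removed under the default.  Allele frequencies used downstream should be
#' recomputed on the filtered matrix.
#'
#' @param g A [genotype_matrix()].
#' @param maf_min Minimum (exclusive) minor allele frequency. Default 0.05.
#' @param locus_call_min Minimum (exclusive) locus call rate. Default 0.95.
#' @param indiv_call_min Minimum (exclusive) individual call rate. Default 0.95.
#' @return A list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report`, a one-row tibble of class
#'   `qc_report` with removal counts and the thresholds used.
#' @export
qc_filter <- function(g, maf_min = 0.05, locus_call_min = 0.95,
                      indiv_call_min = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"))
  f <- allele_frequencies(g)
  maf <- pmin(f$p, f$q)
  keep_maf <- maf > maf_min
  keep_call <- f$call_rate > locus_call_min
  keep_locus <- keep_maf & keep_call
  n_maf <- sum(!keep_maf)
  # loci failing both rules are attributed to the MAF rule (applied first)
  n_lcall <- sum(!keep_call & keep_maf)
  if (!any(keep_locus))
    stop("all loci removed by QC (maf_min = ", maf_min,
         ", locus_call_min = ", locus_call_min, ")", call. = FALSE)
  g2 <- g[, keep_locus, drop = FALSE]
  ind_call <- rowMeans(!is.na(g2))
  keep_ind <- ind_call > indiv_call_min
  n_ind <- sum(!keep_ind)
  if (!any(keep_ind))
    stop("all individuals removed by QC (indiv_call_min = ",
         indiv_call_min, ")", call. = FALSE)
  out <- genotype_matrix(unclass(g2)[keep_ind, , drop = FALSE])
  report <- tibble::tibble(
    loci_in = ncol(g), individuals_in = nrow(g),
    loci_removed_maf = n_maf, loci_removed_callrate = n_lcall,
    individuals_removed_callrate = n_ind,
    loci_out = ncol(out), individuals_out = nrow(out),
    maf_min = maf_min, locus_call_min = locus_call_min,
    indiv_call_min = indiv_call_min)
  class(report) <- c("qc_report", class(report))
  list(genotypes = out, report = report)
}

#' Write genotypes as TSV
#'
#' Writes the dosage matrix in the package's TSV dialect (first column
#' `id`, header row of locus ids, `NA` for missing), the inverse of
#' `read_genotypes(format = "tsv")`.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  dat <- data.frame(id = rownames(g), unclass(g), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(dat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
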