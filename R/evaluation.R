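#' Variance components as proportions of phenotypic variance
#'
#' Expresses each variance component as a proportion of the total
#' phenotypic variance, defined as the sum of all variance components in
#' the model (including litter and residual).  The proportion of the
#' additive component is the narrow-sense heritability `h2_a`; when
#' dominance and/or epistatic components are present, the broad-sense
#' heritability `H2` is the summed proportion of all genetic components.
#'
#' @param x Either a [reml_fit()] / [gblup()] fit, or a named numeric
#'   vector of variance components (e.g.
#'   `c(additive = 2176, litter = 604, residual = 2707)`).
#' @param genetic Names of the genetic components.  For a `gblup_fit`
#'   this defaults to its genetic terms; for a plain vector, to every
#'   name except `litter` and `residual`.
#' @param additive Name of the additive component (default: first
#'   genetic component).
#' @return A tibble of class `variance_proportions` with columns `term`,
#'   `variance`, `proportion`, and attributes `h2_narrow`, `H2_broad`
#'   and `total_variance`.
#' @examples
#' vp <- variance_proportions(c(additive = 2176, litter = 604,
#'                              residual = 2707))
#' attr(vp, "h2_narrow")
#' @export
variance_proportions <- function(x, genetic = NULL, additive = NULL) {
  if (inherits(x, "reml_fit")) {
    vc <- x$theta
    if (is.null(genetic))
      genetic <- if (!is.null(x$genetic_terms)) x$genetic_terms
                 else setdiff(names(vc), c("litter", "residual"))
  } else {
    vc <- x
    if (is.null(names(vc)) || any(names(vc) == ""))
      stop("variance components must be named", call. = FALSE)
    if (is.null(genetic))
      genetic <- setdiff(names(vc), c("litter", "residual"))
  }
  if (any(vc < 0)) stop("variance components must be non-negative", call. = FALSE)
  total <- sum(vc)
  if (total <= 0) stop("total variance is zero", call. = FALSE)
  if (is.null(additive)) additive <- genetic[1L]
  out <- tibble::tibble(term = names(vc), variance = as.numeric(vc),
                        proportion = as.numeric(vc) / total)
  attr(out, "total_variance") <- total
  attr(out, "h2_narrow") <- out$proportion[out$term == additive]
  attr(out, "H2_broad") <- sum(out$proportion[out$term %in% genetic])
  class(out) <- c("variance_proportions", class(out))
  out
}

#' Likelihood-ratio test between nested variance-component models
#'
#' Compares two nested models fitted on identical data by the difference
#' of their `-2 log L` values, referred to a central chi-squared
#' distribution whose degrees of freedom equal the number of added
#' variance components.  No boundary (50:50 mixture) correction is
#' applied by default; set `boundary_mixture = TRUE` for the mixture
#' `0.5 * chi2_{df-1} + 0.5 * chi2_df` alternative appropriate when the
#' added components lie on the boundary of the parameter space.
#'
#' @param minus2logL_null,minus2logL_alt `-2 log L` of the null (smaller)
#'   and alternative (larger) model.
#' @param df Number of variance components added by the alternative.
#' @param boundary_mixture Use the 50:50 chi-squared mixture reference
#'   distribution instead of the plain central chi-squared.
#' @return A one-row tibble with `chisq`, `df`, `p_value`.
#' @examples
#' likelihood_ratio_test(18019.6, 18015.9, df = 1)
#' @export
likelihood_ratio_test <- function(minus2logL_null, minus2logL_alt, df,
                                  boundary_mixture = FALSE) {
  stopifnot(df >= 1, length(df) == 1L)
  chisq <- minus2logL_null - minus2logL_alt
  # a component pinned at the variance lower bound can leave the larger
  # model a sliver above the null; only a material reversal is an error
  if (chisq < -1e-6 * (1 + abs(minus2logL_null)))
    stop("alternative model has higher -2logL than the null: ",
         "models are not nested or did not converge", call. = FALSE)
  chisq <- max(chisq, 0)
  p <- if (boundary_mixture) {
    lower <- if (df == 1L) (chisq <= 0) * 1 else
      stats::pchisq(chisq, df - 1L, lower.tail = FALSE)
    0.5 * lower + 0.5 * stats::pchisq(chisq, df, lower.tail = FALSE)
  } else {
    stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  tibble::tibble(chisq = chisq, df = as.integer(df), p_value = p)
}

#' Reliability of predicted breeding values
#'
#' The reliability of genomic breeding values validated against a
#' phenotype is the squared correlation between predictions and the
#' (corrected) phenotype divided by the trait heritability:
#' `r^2 / h2`.  Dividing by `h2` rescales the phenotype-anchored
#' correlation to the accuracy with which the unobservable true breeding
#' value is predicted.
#'
#' @param r Correlation between predicted breeding values and the
#'   validation phenotype.
#' @param h2 Narrow-sense heritability of the validation phenotype,
#'   in (0, 1].
#' @return The scalar reliability `r^2 / h2`.
#' @examples
#' reliability(0.319, 0.357)
#' @export
reliability <- function(r, h2) {
  if (any(h2 <= 0)) stop("heritability must be > 0", call. = FALSE)
  if (any(h2 > 1)) stop("heritability must be <= 1", call. = FALSE)
  r^2 / h2
}

#' Regression test of prediction unbiasedness
#'
#' Regresses the validation phenotype on the predictions by ordinary
#' least squares.  Unbiased predictions have expectation slope 1; the
#' standardized deviation `|b - 1| / SE(b)` measures how far the
#' realized slope is from that.
#'
#' @param y Validation phenotypes.
#' @param predictions Predicted genetic values, same length.
#' @return A one-row tibble with `slope`, `se`, `z_bias`
#'   (`abs(slope - 1) / se`) and `n`.
#' @export
regression_unbiasedness <- function(y, predictions) {
  ok <- stats::complete.cases(y, predictions)
  y <- y[ok]; predictions <- predictions[ok]
  if (length(y) < 3L) stop("need at least 3 validation records", call. = FALSE)
  if (stats::var(predictions) <= 0)
    stop("predictions have zero variance", call. = FALSE)
  n <- length(y)
  x <- predictions
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss <- sum((y - mean(y) - b * (x - mean(x)))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tibble::tibble(slope = b, se = se, z_bias = abs(b - 1) / se, n = n)
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests whether two correlations that share a variable differ: with
#' `r13 = cor(x1, x3)`, `r23 = cor(x2, x3)` and `r12 = cor(x1, x2)`
#' measured on the same `n` subjects, Williams' statistic
#' \deqn{t = (r_{13} - r_{23}) \sqrt{\frac{(n-1)(1+r_{12})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{12})^3}}}
#' with \eqn{|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 +
#' 2 r_{12} r_{13} r_{23}} and \eqn{\bar r = (r_{13}+r_{23})/2} is
#' referred to a t distribution with `n - 3` degrees of freedom
#' (two-sided).  Typical use: comparing the validation accuracies of two
#' prediction models evaluated against the same phenotypes.
#'
#' @param r13,r23 The two correlations being compared (each with the
#'   shared variable 3).
#' @param r12 Correlation between the two non-shared variables.
#' @param n Number of subjects (at least 4).
#' @return A one-row tibble with `t`, `df` and `p_value`.
#' @export
hotelling_williams_test <- function(r13, r23, r12, n) {
  stopifnot(n >= 4)
  if (any(abs(c(r13, r23, r12)) >= 1))
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-10)
    stop("correlation matrix is not positive semidefinite", call. = FALSE)
  detR <- max(detR, 0)
  rbar <- (r13 + r23) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3
  t_stat <- (r13 - r23) * sqrt((n - 1) * (1 + r12) / denom)
  tibble::tibble(t = t_stat, df = as.integer(n - 3),
                 p_value = 2 * stats::pt(abs(t_stat), n - 3,
                                         lower.tail = FALSE))
}

#' Validate genomic predictions on a test set
#'
#' Assembles, for each fitted model, the standard validation report of a
#' reference/test genomic-prediction study: accuracy (Pearson
#' correlation of predicted total genetic value and of predicted
#' breeding value with the test phenotype), reliability of the breeding
#' values, and the unbiasedness regressions — plus pairwise
#' Hotelling-Williams comparisons of the breeding-value accuracies and,
#' when a baseline model is named, a likelihood-ratio-test table.
#'
#' @param fits A `gblup_family` (or named list of `gblup_fit` objects)
#'   fitted on the same reference records.
#' @param test_pheno Data frame of test individuals with the id and
#'   response columns (individuals must be absent from the training
#'   records).
#' @param h2 Narrow-sense heritability used for the reliability
#'   denominator.  Default: the estimate from the last (fullest) fitted
#'   model.
#' @param baseline Model name used as the LRT null (default `"MA"` when
#'   present).
#' @inheritParams gblup
#' @return A list of class `validation_report`: `accuracy` (per-model
#'   tibble), `pairwise` (Hotelling-Williams tibble), `lrt` (tibble or
#'   `NULL`) and `h2`.
#' @export
validate_predictions <- function(fits, test_pheno, response = "y", id = "id",
                                 h2 = NULL, baseline = NULL) {
  if (inherits(fits, "gblup_fit")) fits <- list(fit = fits)
  stopifnot(length(fits) >= 1L)
  test_pheno <- as.data.frame(test_pheno)
  for (nm in names(fits)) {
    overlap <- intersect(as.character(test_pheno[[id]]), fits[[nm]]$record_ids)
    if (length(overlap) > 0L)
      stop("test individuals were used to fit model ", nm, ": ",
           paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  }
  if (is.null(h2)) {
    last <- fits[[length(fits)]]
    h2 <- attr(variance_proportions(last), "h2_narrow")
  }
  y <- test_pheno[[response]]
  ids <- as.character(test_pheno[[id]])

  preds <- lapply(fits, function(f) {
    p <- stats::predict(f)
    p[match(ids, p$id), , drop = FALSE]
  })
  acc <- purrr::imap_dfr(preds, function(p, nm) {
    r_gtv <- stats::cor(p$gtv, y)
    r_gbv <- stats::cor(p$gbv, y)
    reg_gtv <- regression_unbiasedness(y, p$gtv)
    reg_gbv <- regression_unbiasedness(y, p$gbv)
    tibble::tibble(model = nm, n_test = length(y),
                   cor_gtv = r_gtv, cor_gbv = r_gbv,
                   reliability = reliability(r_gbv, h2),
                   slope_gtv = reg_gtv$slope, se_slope_gtv = reg_gtv$se,
                   slope_gbv = reg_gbv$slope, se_slope_gbv = reg_gbv$se)
  })

  pairwise <- NULL
  if (length(fits) >= 2L) {
    combs <- utils::combn(names(fits), 2L)
    pairwise <- purrr::map_dfr(seq_len(ncol(combs)), function(k) {
      m1 <- combs[1L, k]; m2 <- combs[2L, k]
      hw <- hotelling_williams_test(
        r13 = stats::cor(preds[[m1]]$gbv, y),
        r23 = stats::cor(preds[[m2]]$gbv, y),
        r12 = stats::cor(preds[[m1]]$gbv, preds[[m2]]$gbv),
        n = length(y))
      tibble::tibble(model_1 = m1, model_2 = m2, t = hw$t, df = hw$df,
                     p_value = hw$p_value)
    })
  }

  lrt <- NULL
  if (is.null(baseline) && "MA" %in% names(fits)) baseline <- "MA"
  if (!is.null(baseline) && baseline %in% names(fits) && length(fits) >= 2L) {
    null_fit <- fits[[baseline]]
    alts <- setdiff(names(fits), baseline)
    lrt <- purrr::map_dfr(alts, function(nm) {
      df <- fits[[nm]]$n_terms - null_fit$n_terms
      if (df < 1L) return(NULL)
      lt <- likelihood_ratio_test(null_fit$minus2logL,
                                  fits[[nm]]$minus2logL, df)
      tibble::tibble(model = nm, null = baseline,
                     minus2logL = fits[[nm]]$minus2logL,
                     chisq = lt$chisq, df = lt$df, p_value = lt$p_value)
    })
  }

  structure(list(accuracy = acc, pairwise = pairwise, lrt = lrt, h2 = h2),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>  (reliability uses h2 =",
      format(round(x$h2, 3)), ")\n\nAccuracy and unbiasedness:\n")
  print(as.data.frame(x$accuracy), digits = 3, row.names = FALSE)
  if (!is.null(x$lrt)) {
    cat("\nLikelihood-ratio tests vs", x$lrt$null[1L], ":\n")
    print(as.data.frame(x$lrt), digits = 4, row.names = FALSE)
  }
  if (!is.null(x$pairwise)) {
    cat("\nHotelling-Williams pairwise accuracy comparisons (GBV):\n")
    print(as.data.frame(x$pairwise), digits = 3, row.names = FALSE)
  }
  invisible(x)
}
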