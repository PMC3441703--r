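#' Restricted likelihood criterion for a variance-component model
#'
#' Evaluates the REML criterion
#' `-2 l_R = log|V| + log|X'V^{-1}X| + y'Py` for the linear mixed model
#' `y = Xb + sum_j Z_j u_j + e`, `u_j ~ N(0, K_j sigma2_j)`,
#' `e ~ N(0, I sigma2_e)`, at a fixed vector of variance components
#' (the constant `(N - p) log(2 pi)` is omitted, as is conventional).
#' `P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}` is the REML projection
#' matrix.
#'
#' @param y Numeric response vector of length N.
#' @param random Named list of random terms.  Each element is a list with
#'   `K` (q x q covariance/relationship matrix, `NULL` for identity) and
#'   `Z` (N x q incidence matrix, `NULL` for identity, requiring q = N).
#' @param theta Numeric vector of variance components, one per random
#'   term followed by the residual variance; all strictly positive.
#' @param X Fixed-effect design matrix (default: intercept only).
#' @return The scalar value of `-2 l_R`.
#' @export
neg2_restricted_loglik <- function(y, random, theta, X = NULL) {
  spec <- build_mixed_spec(y, random, X)
  if (length(theta) != length(spec$VZ) + 1L)
    stop("theta must have one entry per random term plus the residual",
         call. = FALSE)
  if (any(theta <= 0)) stop("all variance components must be > 0", call. = FALSE)
  reml_pieces(spec, theta)$m2ll
}

# Precompute the n x n covariance contribution Z K Z' of every random term.
build_mixed_spec <- function(y, random, X = NULL) {
  y <- as.numeric(y)
  N <- length(y)
  if (N < 2L) stop("need at least two records", call. = FALSE)
  if (is.null(X)) X <- matrix(1, N, 1L, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != N) stop("X and y disagree in length", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient", call. = FALSE)
  if (length(random) > 0L &&
      (is.null(names(random)) || any(names(random) == "")))
    names(random) <- paste0("term", seq_along(random))
  VZ <- lapply(seq_along(random), function(j) {
    tm <- random[[j]]
    lbl <- names(random)[j]
    K <- tm$K; Z <- tm$Z
    if (is.null(Z) && is.null(K)) return(list(VZ = diag(N), q = N))
    if (is.null(Z)) {
      if (nrow(K) != N)
        stop("term '", lbl, "': K must be N x N when Z is NULL", call. = FALSE)
      return(list(VZ = (K + t(K)) / 2, q = N))
    }
    Z <- as.matrix(Z)
    if (nrow(Z) != N) stop("term '", lbl, "': Z must have N rows", call. = FALSE)
    if (is.null(K)) return(list(VZ = tcrossprod(Z), q = ncol(Z)))
    if (nrow(K) != ncol(Z))
      stop("term '", lbl, "': K and Z are not conformable", call. = FALSE)
    list(VZ = Z %*% ((K + t(K)) / 2) %*% t(Z), q = ncol(Z))
  })
  list(y = y, X = X, N = N, p = ncol(X),
       VZ = lapply(VZ, `[[`, "VZ"),
       q = vapply(VZ, `[[`, numeric(1L), "q"),
       labels = names(random))
}

# Cholesky with escalating diagonal jitter; errors only if 1e-6 fails.
chol_jitter <- function(A, label = "matrix") {
  for (j in c(0, 1e-10, 1e-8, 1e-6)) {
    ch <- tryCatch(chol(A + diag(j, nrow(A))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop(label, " is not positive definite even after jitter", call. = FALSE)
}

# One evaluation of the REML criterion and the pieces AI-REML needs.
reml_pieces <- function(spec, theta, need_P = TRUE) {
  nt <- length(spec$VZ)
  V <- diag(theta[nt + 1L], spec$N)
  for (j in seq_len(nt)) V <- V + theta[j] * spec$VZ[[j]]
  chV <- chol_jitter(V, "V")
  Vi <- chol2inv(chV)
  ViX <- Vi %*% spec$X
  XtViX <- crossprod(spec$X, ViX)
  chX <- chol_jitter(XtViX, "X'V^{-1}X")
  XtViX_inv <- chol2inv(chX)
  Py <- Vi %*% spec$y - ViX %*% (XtViX_inv %*% crossprod(ViX, spec$y))
  m2ll <- 2 * sum(log(diag(chV))) + 2 * sum(log(diag(chX))) +
    drop(crossprod(spec$y, Py))
  out <- list(m2ll = m2ll, Vi = Vi, Py = drop(Py),
              XtViX_inv = XtViX_inv, ViX = ViX)
  if (need_P) out$P <- Vi - ViX %*% XtViX_inv %*% t(ViX)
  out
}

#' Fit a variance-component model by AI-REML
#'
#' Estimates the variance components of
#' `y = Xb + sum_j Z_j u_j + e` by restricted maximum likelihood using
#' average-information (AI) updates with step halving; whenever an AI
#' step leaves the feasible region or worsens the criterion after 10
#' halvings, a single EM-REML step (which cannot decrease the restricted
#' likelihood) is taken instead.  Components that hit the lower bound
#' `1e-6 * var(y)` are pinned there, flagged, and excluded from the AI
#' matrix when standard errors are computed.
#'
#' @inheritParams neg2_restricted_loglik
#' @param start Optional numeric vector of starting values (terms then
#'   residual).  Default: residual `0.5 * var(y)`, each other term
#'   `0.5 * var(y) / n_terms`.
#' @param max_iter Maximum number of iterations (default 200).
#' @param tol Convergence tolerance: relative change in `-2 l_R` below
#'   `tol` and maximum relative parameter change below `1e-6`.
#' @param verbose Print the iteration trace as it happens.
#' @return An object of class `reml_fit`: variance estimates `theta`
#'   (named, residual last), asymptotic standard errors `se` from the
#'   inverse AI matrix, `minus2logL`, `converged`, `pinned` flags, the
#'   per-iteration `trace` tibble, fixed-effect estimates `beta`, BLUP
#'   solutions `blup` (one numeric vector per random term) and the model
#'   dimensions.
#' @seealso [tidy.reml_fit()], [glance.reml_fit()], [gblup()]
#' @export
reml_fit <- function(y, random, X = NULL, start = NULL,
                     max_iter = 200L, tol = 1e-8, verbose = FALSE) {
  spec <- build_mixed_spec(y, random, X)
  nt <- length(spec$VZ)
  np <- nt + 1L
  vy <- stats::var(spec$y)
  if (!is.finite(vy) || vy <= .Machine$double.eps) vy <- 1
  lb <- 1e-6 * vy
  theta <- if (is.null(start)) c(rep(0.5 * vy / nt, nt), 0.5 * vy)
           else as.numeric(start)
  if (length(theta) != np) stop("start has wrong length", call. = FALSE)
  theta <- pmax(theta, lb)

  cur <- reml_pieces(spec, theta)
  trace <- list(record_iter(0L, theta, cur$m2ll, "start", spec$labels))
  converged <- FALSE
  AI <- NULL

  for (iter in seq_len(max_iter)) {
    # score (gradient of l_R) and AI matrix at current theta
    PVj <- vector("list", np)
    for (j in seq_len(nt)) PVj[[j]] <- spec$VZ[[j]] %*% cur$Py
    PVj[[np]] <- cur$Py
    trPV <- numeric(np)
    for (j in seq_len(nt)) trPV[j] <- sum(cur$P * spec$VZ[[j]])
    trPV[np] <- sum(diag(cur$P))
    # PVj[[j]] = V_j P y, so crossprod(Py, PVj[[j]]) = y'P V_j P y
    PtVj <- lapply(PVj, function(v) cur$P %*% v)
    yPVPy <- vapply(PVj, function(v) drop(crossprod(cur$Py, v)), numeric(1L))
    score <- -0.5 * (trPV - yPVPy)
    AI <- matrix(0, np, np)
    for (j in seq_len(np)) for (k in j:np) {
      AI[j, k] <- AI[k, j] <- 0.5 * drop(crossprod(PVj[[j]], PtVj[[k]]))
    }

    free <- theta > lb * (1 + 1e-12) | score > 0
    if (!any(free)) break
    delta <- numeric(np)
    ok <- TRUE
    d_free <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                       error = function(e) NULL)
    if (is.null(d_free)) ok <- FALSE else delta[free] <- d_free

    step_type <- "AI"
    new_theta <- NULL; new_fit <- NULL
    if (ok) {
      step <- 1
      for (h in seq_len(11L)) {
        cand <- pmax(theta + step * delta, lb)
        fit <- tryCatch(reml_pieces(spec, cand), error = function(e) NULL)
        if (!is.null(fit) && is.finite(fit$m2ll) &&
            fit$m2ll <= cur$m2ll + 1e-10 * abs(cur$m2ll) + 1e-8) {
          new_theta <- cand; new_fit <- fit
          if (h > 1L) step_type <- "AI-halved"
          break
        }
        step <- step / 2
      }
    }
    if (is.null(new_theta)) {
      # EM-REML fallback: sigma2_new = sigma2 + sigma2^2 (y'PV_jPy - tr(PV_j)) / q_j
      qj <- c(spec$q, spec$N)
      cand <- pmax(theta + theta^2 * (yPVPy - trPV) / qj, lb)
      new_fit <- reml_pieces(spec, cand)
      new_theta <- cand
      step_type <- "EM"
    }

    rel_ll <- abs(new_fit$m2ll - cur$m2ll) / (abs(cur$m2ll) + 1e-10)
    rel_th <- max(abs(new_theta - theta) / pmax(abs(theta), lb))
    theta <- new_theta
    cur <- new_fit
    trace[[length(trace) + 1L]] <-
      record_iter(iter, theta, cur$m2ll, step_type, spec$labels)
    if (verbose)
      message(sprintf("iter %3d  -2logL = %.6f  (%s)", iter, cur$m2ll, step_type))
    if (rel_ll < tol && rel_th < 1e-6) { converged <- TRUE; break }
  }

  pinned <- theta <= lb * (1 + 1e-8)
  labels <- c(spec$labels, "residual")
  names(theta) <- names(pinned) <- labels

  # standard errors from the inverse AI matrix at the optimum, pinned
  # components excluded
  se <- rep(NA_real_, np)
  free <- !pinned
  if (any(free) && !is.null(AI)) {
    cov_free <- tryCatch(solve(AI[free, free, drop = FALSE]),
                         error = function(e) NULL)
    if (!is.null(cov_free)) {
      d <- diag(cov_free)
      se[free] <- sqrt(pmax(d, 0))
    }
  }
  names(se) <- labels

  beta <- drop(cur$XtViX_inv %*% crossprod(cur$ViX, spec$y))
  names(beta) <- colnames(spec$X)
  blup <- vector("list", nt)
  names(blup) <- spec$labels
  for (j in seq_len(nt)) {
    tm <- random[[j]]
    K <- tm$K; Z <- tm$Z
    KtZ_Py <- if (is.null(Z) && is.null(K)) cur$Py
      else if (is.null(Z)) drop(K %*% cur$Py)
      else if (is.null(K)) drop(crossprod(Z, cur$Py))
      else drop(K %*% crossprod(Z, cur$Py))
    u <- theta[j] * KtZ_Py
    if (!is.null(K) && !is.null(rownames(K))) names(u) <- rownames(K)
    blup[[j]] <- u
  }

  structure(list(theta = theta, se = se, minus2logL = cur$m2ll,
                 converged = converged, pinned = pinned,
                 trace = dplyr::bind_rows(trace),
                 beta = beta, blup = blup,
                 n = spec$N, n_terms = nt, lower_bound = lb,
                 Py = cur$Py, labels = spec$labels),
            class = "reml_fit")
}

record_iter <- function(iter, theta, m2ll, step, labels) {
  th <- as.list(theta)
  names(th) <- c(labels, "residual")
  tibble::tibble(iteration = iter, !!!th, minus2logL = m2ll, step = step)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> %d records, %d random term(s) + residual\n",
              x$n, x$n_terms))
  cat(sprintf("  -2logL = %.4f  (%s after %d iterations)\n", x$minus2logL,
              if (x$converged) "converged" else "NOT converged",
              max(x$trace$iteration)))
  est <- format(signif(x$theta, 6))
  se <- ifelse(is.na(x$se), "--", format(signif(x$se, 4)))
  for (i in seq_along(x$theta))
    cat(sprintf("  %-10s %s +- %s%s\n", names(x$theta)[i], est[i], se[i],
                if (x$pinned[i]) "  [at lower bound]" else ""))
  invisible(x)
}

#' Fit a GBLUP model from a phenotype table and relationship matrices
#'
#' High-level interface for genomic prediction: takes a phenotype table
#' (one row per individual) and a named list of genomic relationship
#' matrices, fits the variance components by [reml_fit()], and carries
#' enough structure to predict genetic values for individuals that are in
#' the relationship matrices but have no phenotype (the test set).
#'
#' Records used for fitting are the rows with a non-missing response and,
#' if a `test` column is present, `test == FALSE`.  An optional litter
#' column adds an iid random litter (common-environment) effect.
#'
#' @param pheno Data frame with at least an id column and a response
#'   column; optionally a litter column and a logical `test` column.
#' @param grms Named list of `grm` objects (e.g.
#'   `list(additive = G, epistatic = Gaa, dominance = D)`), all spanning
#'   the same individuals.  Every phenotyped individual must appear in
#'   them.
#' @param response,id,litter,test Column names in `pheno`.  Set
#'   `litter = NULL` to omit the litter effect.
#' @param ... Passed to [reml_fit()] (`start`, `max_iter`, `tol`,
#'   `verbose`).
#' @return An object of class `gblup_fit` (inherits `reml_fit`) with the
#'   genetic-term labels in `$genetic_terms` and per-individual solutions
#'   retrievable with [predict.gblup_fit()].
#' @examples
#' sim <- simulate_gblup_data(n_ref = 150, n_test = 30, m = 300,
#'                            vc = c(a = 1, aa = 0, d = 0, litter = 0.3,
#'                                   e = 1), seed = 1)
#' G <- grm_additive(sim$genotypes)
#' fit <- gblup(sim$pheno, list(additive = G))
#' tidy(fit)
#' @export
gblup <- function(pheno, grms, response = "y", id = "id", litter = "litter",
                  test = "test", ...) {
  pheno <- as.data.frame(pheno)
  if (!id %in% names(pheno)) stop("no id column '", id, "' in pheno", call. = FALSE)
  if (!response %in% names(pheno))
    stop("no response column '", response, "' in pheno", call. = FALSE)
  if (!is.list(grms) || length(grms) == 0L ||
      !all(vapply(grms, inherits, logical(1L), "grm")))
    stop("`grms` must be a non-empty named list of grm objects", call. = FALSE)
  if (is.null(names(grms)) || any(names(grms) == ""))
    stop("`grms` must be named", call. = FALSE)

  all_ids <- rownames(grms[[1L]]$K)
  for (g in grms[-1L])
    if (!identical(rownames(g$K), all_ids))
      stop("relationship matrices differ in individuals or order", call. = FALSE)

  is_test <- if (test %in% names(pheno)) isTRUE_vec(pheno[[test]]) else
    rep(FALSE, nrow(pheno))
  use <- !is.na(pheno[[response]]) & !is_test
  if (sum(use) < 3L) stop("fewer than 3 phenotyped records", call. = FALSE)
  rec <- pheno[use, , drop = FALSE]
  pos <- match(as.character(rec[[id]]), all_ids)
  if (anyNA(pos))
    stop("phenotyped individual(s) absent from the relationship matrices: ",
         paste(utils::head(rec[[id]][is.na(pos)], 5L), collapse = ", "),
         call. = FALSE)

  N <- nrow(rec)
  random <- list()
  for (nm in names(grms)) {
    Z <- matrix(0, N, length(all_ids))
    Z[cbind(seq_len(N), pos)] <- 1
    random[[nm]] <- list(Z = Z, K = grms[[nm]]$K)
  }
  use_litter <- !is.null(litter) && litter %in% names(pheno)
  if (use_litter) {
    lf <- factor(rec[[litter]])
    Zl <- stats::model.matrix(~ lf - 1)
    colnames(Zl) <- levels(lf)
    random$litter <- list(Z = Zl, K = NULL)
  }

  fit <- reml_fit(rec[[response]], random, ...)
  fit$genetic_terms <- names(grms)
  fit$individual_ids <- all_ids
  fit$record_ids <- as.character(rec[[id]])
  fit$test_ids <- as.character(pheno[[id]][is_test |
                                           !pheno[[id]] %in% rec[[id]]])
  class(fit) <- c("gblup_fit", class(fit))
  fit
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Genetic-value predictions from a GBLUP fit
#'
#' Returns the BLUP solutions for every individual spanned by the
#' relationship matrices — phenotyped (reference) and unphenotyped (test)
#' alike.  The genomic breeding value `gbv` is the additive-term
#' solution; the total genetic value `gtv` is the sum of all genetic-term
#' solutions (the litter effect is environmental and excluded).
#'
#' @param object A `gblup_fit`.
#' @param additive Name of the additive term among the genetic terms
#'   (default: the first term).
#' @param ... Ignored.
#' @return A tibble with `id`, one column per genetic term, `gbv`, `gtv`
#'   and a logical `test` flag (individuals without a fitting record).
#' @export
predict.gblup_fit <- function(object, additive = NULL, ...) {
  gt <- object$genetic_terms
  if (is.null(additive)) additive <- gt[1L]
  if (!additive %in% gt) stop("no genetic term '", additive, "'", call. = FALSE)
  sol <- lapply(object$blup[gt],
                function(u) unname(u[object$individual_ids]))
  out <- tibble::tibble(id = object$individual_ids, !!!sol)
  out$gbv <- sol[[additive]]
  out$gtv <- Reduce(`+`, sol)
  out$test <- !(out$id %in% object$record_ids)
  out
}

#' Fit the additive / non-additive GBLUP model family
#'
#' Fits, on identical records and with identical conventions (so that
#' `-2logL` values are directly comparable), the four nested models
#' routinely compared in non-additive genomic evaluation:
#' * `MA`   — additive + litter,
#' * `MAE`  — additive + additive-by-additive epistatic + litter,
#' * `MAD`  — additive + dominance + litter,
#' * `MAED` — all three genetic components + litter.
#'
#' The epistatic relationship matrix defaults to the Hadamard square
#' `G # G` of the supplied additive matrix.
#'
#' @param pheno Phenotype table, see [gblup()].
#' @param G Additive `grm`.
#' @param D Dominance `grm` (required for `MAD`/`MAED`).
#' @param G_aa Epistatic `grm`; default `grm_epistatic(G, G)`.
#' @param models Character vector of models to fit.
#' @inheritParams gblup
#' @return A named list of `gblup_fit` objects of class `gblup_family`.
#' @export
fit_model_family <- function(pheno, G, D = NULL, G_aa = NULL,
                             models = c("MA", "MAE", "MAD", "MAED"),
                             response = "y", id = "id", litter = "litter",
                             test = "test", ...) {
  models <- match.arg(models, several.ok = TRUE)
  needs_aa <- any(models %in% c("MAE", "MAED"))
  needs_d <- any(models %in% c("MAD", "MAED"))
  if (needs_aa && is.null(G_aa)) G_aa <- grm_epistatic(G, G)
  if (needs_d && is.null(D))
    stop("models with dominance need a dominance relationship matrix D",
         call. = FALSE)
  terms_of <- list(
    MA   = function() list(additive = G),
    MAE  = function() list(additive = G, epistatic = G_aa),
    MAD  = function() list(additive = G, dominance = D),
    MAED = function() list(additive = G, epistatic = G_aa, dominance = D))
  fits <- lapply(models, function(m)
    gblup(pheno, terms_of[[m]](), response = response, id = id,
          litter = litter, test = test, ...))
  names(fits) <- models
  structure(fits, class = "gblup_family")
}

#' @export
print.gblup_family <- function(x, ...) {
  cat("<gblup_family>\n")
  for (nm in names(x))
    cat(sprintf("  %-5s -2logL = %.4f%s\n", nm, x[[nm]]$minus2logL,
                if (x[[nm]]$converged) "" else "  (not converged)"))
  invisible(x)
}
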