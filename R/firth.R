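# Firth bias-corrected logistic regression and the penalized likelihood-ratio
# burden test.
#
# The penalized log-likelihood is l*(beta) = l(beta) + 0.5 * log det I(beta),
# where l is the binomial log-likelihood with pi_i = plogis(x_i' beta) and
# I(beta) = X'WX, W = diag(pi_i (1 - pi_i)). Maximization uses Newton steps on
# the modified score
#   U*_j(beta) = sum_i (y_i - pi_i + h_i (1/2 - pi_i)) x_ij,
# where h_i are the diagonals of the hat matrix
# H = W^{1/2} X (X'WX)^{-1} X' W^{1/2}, with step-halving whenever a step
# would decrease l*. The penalty (Jeffreys prior) keeps estimates finite even
# under complete separation, which is what makes the test usable for genes
# with zero carriers among cases or among controls.

binom_loglik <- function(eta, y) {
  # sum(y*eta - log(1 + exp(eta))), stable for large |eta|
  sum(y * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
}

firth_parts <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pi * (1 - pi)
  XW <- X * sqrt(w)
  info <- crossprod(XW)
  R <- tryCatch(chol(info), error = function(e) NULL)
  if (is.null(R)) {
    stop("design matrix is rank deficient (singular Fisher information); ",
         "check for collinear columns: ",
         paste(colnames(X) %||% seq_len(ncol(X)), collapse = ", "),
         call. = FALSE)
  }
  Rinv <- backsolve(R, diag(ncol(X)))
  h <- rowSums((XW %*% Rinv)^2)
  list(eta = eta, pi = pi, w = w, R = R, Rinv = Rinv, h = h,
       loglik = binom_loglik(eta, y),
       logdet = 2 * sum(log(diag(R))))
}

#' Penalized log-likelihood of a Firth logistic model
#'
#' Evaluates `l(beta) + 0.5 * log det(X'WX)` where `l` is the binomial
#' log-likelihood and `W = diag(pi (1-pi))`. The log-determinant is computed
#' from a Cholesky factorization; the binomial term is evaluated in log space
#' so fitted probabilities numerically equal to 0 or 1 do not overflow.
#'
#' @param beta coefficient vector (length `ncol(X)`).
#' @param X numeric design matrix (rows = samples).
#' @param y binary outcome vector (1 = case).
#' @return The penalized log-likelihood, a single finite number.
#' @export
penalized_loglik <- function(beta, X, y) {
  X <- as.matrix(X)
  stopifnot(length(beta) == ncol(X), length(y) == nrow(X))
  if (any(!is.finite(beta))) stop("beta must be finite", call. = FALSE)
  p <- firth_parts(beta, X, y)
  p$loglik + 0.5 * p$logdet
}

#' Fit a Firth penalized logistic regression
#'
#' Newton iteration on the modified score with step-halving; initialized at
#' `beta = 0`. Convergence requires both the largest modified-score component
#' and the Newton step norm to fall below `tol`.
#'
#' @param X design matrix, full column rank (include an intercept column).
#' @param y binary outcome vector.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100).
#' @param max_halving maximum step-halvings per iteration (default 25).
#' @param constrain optional column names/indices held fixed at zero while the
#'   remaining coefficients are maximized; the penalty is still computed from
#'   the full design's information, which is what a profile penalized
#'   likelihood-ratio test needs.
#' @return An object of class `firth_fit`: coefficients, `loglik` (penalized,
#'   at the maximum), `loglik_unpenalized`, fitted probabilities, hat
#'   diagonals, iteration count and a `converged` flag.
#' @examples
#' X <- cbind(intercept = 1, carrier = c(1, 1, 0, 0, 0, 0))
#' y <- c(1, 1, 1, 0, 0, 0)
#' fit <- fit_firth(X, y)
#' coef(fit)
#' @export
fit_firth <- function(X, y, tol = 1e-8, max_iter = 100, max_halving = 25,
                      constrain = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient; collinear columns among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  free <- seq_len(ncol(X))
  if (!is.null(constrain)) {
    jfix <- if (is.character(constrain)) match(constrain, colnames(X))
            else as.integer(constrain)
    if (anyNA(jfix)) stop("constrained column not found", call. = FALSE)
    free <- setdiff(free, jfix)
  }

  beta <- rep(0, ncol(X))
  parts <- firth_parts(beta, X, y)
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter && length(free) > 0) {
    U <- drop(crossprod(X[, free, drop = FALSE],
                        y - parts$pi + parts$h * (0.5 - parts$pi)))
    if (max(abs(U)) < tol) {
      converged <- TRUE
      break
    }
    # Newton direction restricted to the free coordinates (I_FF^{-1} U_F),
    # halved until the penalized log-likelihood does not decrease (strict
    # monotone ascent)
    Rf <- if (length(free) == ncol(X)) parts$R
          else chol(crossprod(X[, free, drop = FALSE] * sqrt(parts$w)))
    step <- backsolve(Rf, forwardsolve(t(Rf), U))
    ll_cur <- parts$loglik + 0.5 * parts$logdet
    halvings <- 0L
    repeat {
      cand <- beta
      cand[free] <- cand[free] + step
      parts_new <- firth_parts(cand, X, y)
      ll_new <- parts_new$loglik + 0.5 * parts_new$logdet
      if (ll_new >= ll_cur || halvings >= max_halving) break
      step <- step / 2
      halvings <- halvings + 1L
    }
    beta[free] <- beta[free] + step
    parts <- parts_new
    iter <- iter + 1L
    # converged when the accepted update is below tolerance in every
    # coordinate: at the numerical optimum halving collapses the step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (length(free) == 0) converged <- TRUE

  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta,
    loglik = parts$loglik + 0.5 * parts$logdet,
    loglik_unpenalized = parts$loglik,
    fitted = parts$pi,
    hat_diagonals = parts$h,
    iterations = iter,
    converged = converged,
    tol = tol
  ), class = "firth_fit")
}

#' @export
coef.firth_fit <- function(object, ...) object$coefficients

#' @export
logLik.firth_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth penalized logistic fit\n")
  print(x$coefficients)
  cat(sprintf("penalized logLik: %.6f  iterations: %d  converged: %s\n",
              x$loglik, x$iterations, x$converged))
  invisible(x)
}

#' Penalized likelihood-ratio test for one coefficient
#'
#' Fits the full model, then the null model, and refers twice the difference
#' of maximized penalized log-likelihoods to a chi-square with one degree of
#' freedom. The default null model (`null_penalty = "full"`) is the same
#' design with the tested coefficient constrained to zero, so both models
#' share the full design's Jeffreys penalty (the profile construction used by
#' established Firth implementations); this keeps the statistic calibrated.
#' `null_penalty = "reduced"` instead refits the reduced design under its own
#' penalty — the penalty term is then dimension-dependent and the statistic
#' runs anti-conservative for sparse predictors, so it is offered for
#' comparison only.
#'
#' @param X full design matrix including the tested column.
#' @param y binary outcome.
#' @param test_col name or index of the tested column.
#' @param null_penalty `"full"` (profile, default) or `"reduced"`.
#' @param ... passed to [fit_firth()].
#' @return List with `statistic` (clipped at 0), `p`, `beta` (tested
#'   coefficient), both fits, and a `converged` flag covering both fits.
#' @export
firth_lrt <- function(X, y, test_col = "carrier",
                      null_penalty = c("full", "reduced"), ...) {
  null_penalty <- match.arg(null_penalty)
  X <- as.matrix(X)
  if (is.character(test_col)) {
    j <- match(test_col, colnames(X))
    if (is.na(j)) stop("tested column '", test_col, "' not found", call. = FALSE)
  } else j <- as.integer(test_col)
  if (length(unique(X[, j])) < 2L) {
    # constant tested column: the nested models coincide
    null <- fit_firth(X[, -j, drop = FALSE], y, ...)
    return(list(statistic = 0, p = 1, beta = NA_real_,
                full = null, null = null, converged = null$converged))
  }
  full <- fit_firth(X, y, ...)
  null <- if (null_penalty == "full") {
    fit_firth(X, y, constrain = j, ...)
  } else {
    fit_firth(X[, -j, drop = FALSE], y, ...)
  }
  stat <- max(0, 2 * (full$loglik - null$loglik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  ok <- full$converged && null$converged
  if (!ok) warning("Firth fit did not converge; p-value flagged", call. = FALSE)
  list(statistic = stat, p = p, beta = unname(full$coefficients[j]),
       full = full, null = null, converged = ok)
}

#' Per-gene Firth burden tests
#'
#' For every gene in a carrier matrix, tests the collapsed carrier indicator
#' against case/control status by the profile penalized likelihood-ratio test
#' of [firth_lrt()], adjusting for the supplied covariates (typically
#' ancestry PCs and age in years). Genes whose carrier indicator is constant
#' (no carriers, or everyone a carrier) get statistic 0 and p = 1.
#'
#' @param carriers a `carrier_matrix` from [collapse_carriers()], or a plain
#'   binary matrix (genes x samples) with dimnames.
#' @param covariates numeric matrix (samples x covariates) or NULL.
#' @param y binary outcome vector aligned with the carrier-matrix columns.
#' @param min_case_carriers eligibility threshold forwarded to
#'   [gene_test_eligibility()] (default 5 case carriers).
#' @param alpha family-wise error rate for [bonferroni_correct()].
#' @param ... passed to [fit_firth()].
#' @return A data frame (one row per gene, sorted by p): gene, carrier counts
#'   by phenotype, `beta_carrier`, `lrt_stat`, `p_value`, `eligible`,
#'   `p_corrected`, `converged`. The Bonferroni threshold is attached as
#'   attribute `"threshold"`.
#' @export
test_all_genes <- function(carriers, covariates, y, min_case_carriers = 5,
                           alpha = 0.05, ...) {
  M <- if (inherits(carriers, "carrier_matrix")) carriers$matrix else as.matrix(carriers)
  if (is.null(rownames(M))) stop("carrier matrix must have gene rownames", call. = FALSE)
  y <- as.numeric(y)
  n <- ncol(M)
  if (length(y) != n) stop("y must match the carrier-matrix columns", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per sample", call. = FALSE)
    if (anyNA(covariates)) stop("covariates must be complete (no missing values)", call. = FALSE)
  }
  X0 <- cbind(intercept = rep(1, n), covariates)

  genes <- rownames(M)
  res <- lapply(genes, function(g) {
    carrier <- M[g, ]
    cc <- sum(carrier == 1 & y == 1)
    ctl <- sum(carrier == 1 & y == 0)
    if (length(unique(carrier)) < 2L) {
      return(data.frame(gene = g, case_carriers = cc, control_carriers = ctl,
                        beta_carrier = NA_real_, lrt_stat = 0,
                        p_value = 1, converged = TRUE))
    }
    lrt <- suppressWarnings(
      firth_lrt(cbind(X0, carrier = carrier), y, test_col = "carrier", ...)
    )
    data.frame(gene = g, case_carriers = cc, control_carriers = ctl,
               beta_carrier = lrt$beta,
               lrt_stat = lrt$statistic,
               p_value = lrt$p,
               converged = lrt$converged)
  })
  res <- do.call(rbind, res)
  res$eligible <- res$case_carriers >= min_case_carriers
  if (any(res$eligible)) {
    out <- bonferroni_correct(res, alpha = alpha)
    res <- out$results
    threshold <- out$threshold
  } else {
    res$p_corrected <- NA_real_
    threshold <- NA_real_
  }
  sorted <- res[order(res$p_value), , drop = FALSE]
  rownames(sorted) <- NULL
  attr(sorted, "threshold") <- threshold
  sorted
}

#' Bonferroni correction over eligible genes
#'
#' The family-wise significance threshold is `alpha / n_eligible`, where
#' eligibility is carried on the results (genes with enough case carriers).
#' Corrected p-values are `min(1, p * n_eligible)` for eligible genes;
#' ineligible genes keep their raw p but are annotated untested (`NA`
#' corrected p).
#'
#' @param results data frame with columns `p_value` and `eligible`.
#' @param alpha family-wise error rate (default 0.05).
#' @return List with `threshold`, `n_eligible`, and the annotated `results`.
#' @examples
#' res <- data.frame(gene = "G", p_value = 1e-5, eligible = TRUE)
#' bonferroni_correct(res)$threshold  # 0.05
#' @export
bonferroni_correct <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), all(c("p_value", "eligible") %in% names(results)))
  n_eligible <- sum(results$eligible)
  if (n_eligible == 0L) {
    stop("no eligible genes: Bonferroni denominator would be zero", call. = FALSE)
  }
  results$p_corrected <- ifelse(results$eligible,
                                pmin(1, results$p_value * n_eligible),
                                NA_real_)
  list(threshold = alpha / n_eligible, n_eligible = n_eligible,
       results = results)
}
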