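# Independent oracles for the Firth machinery. These deliberately share no
# code with the package: the penalized log-likelihood is written from its
# definition with a dense determinant, and maximization uses generic
# quasi-Newton / exhaustive lattice search rather than the modified-score
# Newton iteration the package implements.

oracle_pll <- function(beta, X, y) {
  eta <- as.vector(X %*% beta)
  pi <- 1 / (1 + exp(-eta))
  ll <- sum(y * log(pi) + (1 - y) * log(1 - pi))
  W <- diag(pi * (1 - pi), nrow(X))
  ll + 0.5 * log(det(t(X) %*% W %*% X))
}

oracle_fit_optim <- function(X, y) {
  fn <- function(b) -oracle_pll(b, X, y)
  fit <- stats::optim(rep(0, ncol(X)), fn, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
  # polish with a second start from the found optimum
  fit <- stats::optim(fit$par, fn, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
  fit$par
}

# exhaustive local lattice search: returns the lattice point with the highest
# penalized log-likelihood in a box of +/- half-width around `center`
oracle_grid_max <- function(X, y, center, halfwidth = 0.02, spacing = 1e-3) {
  p <- length(center)
  axes <- lapply(seq_len(p), function(j) {
    seq(center[j] - halfwidth, center[j] + halfwidth, by = spacing)
  })
  grid <- as.matrix(expand.grid(axes))
  eta <- grid %*% t(X)                         # n_grid x n
  pi <- 1 / (1 + exp(-eta))
  ll <- pi
  ll[] <- log(ifelse(rep(y, each = nrow(grid)) == 1, pi, 1 - pi))
  ll_sum <- rowSums(ll)
  w <- pi * (1 - pi)
  # vectorized log-determinant of X'WX for every lattice point
  pairs <- which(upper.tri(matrix(0, ncol(X), ncol(X)), diag = TRUE),
                 arr.ind = TRUE)
  XX <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  S <- w %*% XX                                # n_grid x n_pairs
  logdet <- apply(S, 1, function(s) {
    M <- matrix(0, ncol(X), ncol(X))
    M[cbind(pairs[, 1], pairs[, 2])] <- s
    M[cbind(pairs[, 2], pairs[, 1])] <- s
    determinant(M, logarithm = TRUE)$modulus
  })
  grid[which.max(ll_sum + 0.5 * logdet), ]
}

# random small logistic datasets with a binary and optionally a continuous
# covariate; guaranteed non-degenerate outcome
random_logit_data <- function(n, p_extra = 1, seed) {
  withr::with_seed(seed, {
    repeat {
      X <- cbind(intercept = 1,
                 carrier = rbinom(n, 1, runif(1, 0.2, 0.5)))
      if (p_extra > 0) {
        X <- cbind(X, matrix(rnorm(n * p_extra), n,
                             dimnames = list(NULL, paste0("z", seq_len(p_extra)))))
      }
      beta <- c(runif(1, -1, 1), runif(1, -1.5, 1.5), rep(0.5, p_extra))
      y <- rbinom(n, 1, 1 / (1 + exp(-X %*% beta)))
      if (var(y) > 0 && var(X[, "carrier"]) > 0 &&
          qr(X)$rank == ncol(X)) return(list(X = X, y = y))
    }
  })
}
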