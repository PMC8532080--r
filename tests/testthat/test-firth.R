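# Firth penalized logistic regression: closed forms, oracles, separation.

expand_2x2 <- function(a, b, c, d) {
  # a = case carriers, b = case non-carriers, c = control carriers,
  # d = control non-carriers
  list(X = cbind(intercept = 1,
                 carrier = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))),
       y = c(rep(1, a + b), rep(0, c + d)))
}

test_that("carrier coefficient equals the 0.5-corrected 2x2 log odds ratio", {
  tables <- list(c(21, 1181, 0, 331),   # the separated carrier table
                 c(5, 95, 2, 98),
                 c(10, 40, 10, 40),     # balanced: log OR 0
                 c(0, 50, 0, 60),       # no carriers anywhere... skip (constant)
                 c(3, 7, 9, 1))
  for (tb in tables) {
    a <- tb[1]; b <- tb[2]; c <- tb[3]; d <- tb[4]
    if (a + c == 0) next
    dat <- expand_2x2(a, b, c, d)
    fit <- fit_firth(dat$X, dat$y)
    expected <- log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)["carrier"]), expected, tolerance = 1e-6)
  }
})

test_that("balanced table gives a zero carrier coefficient", {
  dat <- expand_2x2(10, 40, 10, 40)
  fit <- fit_firth(dat$X, dat$y)
  expect_lt(abs(coef(fit)["carrier"]), 1e-7)
})

test_that("penalized log-likelihood matches its closed form at beta = 0", {
  for (n in c(4, 10, 25)) {
    X <- matrix(1, n, 1)
    y <- rep_len(c(0, 1), n)
    expect_equal(penalized_loglik(0, X, y),
                 n * log(0.5) + 0.5 * log(n / 4), tolerance = 1e-12)
  }
})

test_that("penalized log-likelihood matches a dense-determinant oracle", {
  withr::with_seed(11, {
    X <- cbind(1, matrix(rnorm(40), 20, 2))
    y <- rbinom(20, 1, 0.5)
    for (i in 1:5) {
      beta <- rnorm(3, sd = 0.7)
      expect_equal(penalized_loglik(beta, X, y), oracle_pll(beta, X, y),
                   tolerance = 1e-10)
    }
  })
})

test_that("fitted maximum dominates perturbed evaluations", {
  dat <- random_logit_data(40, p_extra = 1, seed = 3)
  fit <- fit_firth(dat$X, dat$y)
  ll_hat <- penalized_loglik(coef(fit), dat$X, dat$y)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-10)
  withr::with_seed(4, {
    for (i in 1:20) {
      expect_gte(ll_hat,
                 penalized_loglik(coef(fit) + rnorm(3, sd = 0.05),
                                  dat$X, dat$y))
    }
  })
})

test_that("hat diagonals sum to the number of columns", {
  dat <- random_logit_data(60, p_extra = 2, seed = 8)
  fit <- fit_firth(dat$X, dat$y)
  expect_equal(sum(fit$hat_diagonals), ncol(dat$X), tolerance = 1e-6)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("fit agrees with an independent quasi-Newton maximizer", {
  for (seed in 1:20) {
    dat <- random_logit_data(sample(30:60, 1), p_extra = sample(0:1, 1),
                             seed = seed)
    fit <- fit_firth(dat$X, dat$y)
    ref <- oracle_fit_optim(dat$X, dat$y)
    expect_true(fit$converged)
    expect_lt(max(abs(coef(fit) - ref)), 1e-4)
  }
})

test_that("fit matches exhaustive lattice search on a 3-parameter problem", {
  # n = 8 with one continuous covariate: small enough for a dense lattice
  X <- cbind(intercept = 1,
             carrier = c(1, 1, 1, 0, 0, 0, 0, 1),
             z = c(0.3, -1.2, 0.5, 0.1, -0.4, 1.7, -0.9, 0.8))
  y <- c(1, 1, 0, 0, 1, 0, 0, 1)
  fit <- fit_firth(X, y)
  best <- oracle_grid_max(X, y, center = coef(fit),
                          halfwidth = 0.02, spacing = 1e-3)
  expect_lt(max(abs(coef(fit) - best)), 2e-3)
})

test_that("complete separation still yields finite estimates and valid p", {
  # zero carriers among controls (the enriched-gene situation) and the
  # reverse; also a perfectly separating covariate
  for (tb in list(c(21, 1181, 0, 331), c(0, 50, 8, 42))) {
    dat <- expand_2x2(tb[1], tb[2], tb[3], tb[4])
    lrt <- firth_lrt(dat$X, dat$y)
    expect_true(all(is.finite(coef(lrt$full))))
    expect_true(lrt$converged)
    expect_gt(lrt$p, 0)
    expect_lt(lrt$p, 1)
    expect_gte(lrt$statistic, 0)
  }
  X <- cbind(intercept = 1, z = c(-3, -2, -1, 1, 2, 3))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_firth(X, y)
  expect_true(fit$converged)
  expect_true(all(is.finite(coef(fit))))
})

test_that("LRT is invariant under affine rescaling of covariates", {
  dat <- random_logit_data(80, p_extra = 1, seed = 21)
  lrt1 <- firth_lrt(dat$X, dat$y)
  X2 <- dat$X
  X2[, "z1"] <- 1000 * X2[, "z1"] + 57
  lrt2 <- firth_lrt(X2, dat$y)
  expect_equal(lrt1$statistic, lrt2$statistic, tolerance = 1e-8)
})

test_that("LRT self-consistency: statistic recomputable via penalized_loglik", {
  dat <- expand_2x2(21, 1181, 0, 331)
  lrt <- firth_lrt(dat$X, dat$y)
  b_full <- coef(lrt$full)
  b_null <- coef(lrt$null)      # same design, carrier constrained to zero
  stat <- 2 * (penalized_loglik(b_full, dat$X, dat$y) -
                 penalized_loglik(b_null, dat$X, dat$y))
  expect_equal(lrt$statistic, stat, tolerance = 1e-6)
  expect_equal(lrt$p, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-9)
})

test_that("constant carrier column gives a null test, not an error", {
  X <- cbind(intercept = 1, carrier = rep(0, 30))
  y <- rep_len(c(1, 0), 30)
  lrt <- firth_lrt(X, y)
  expect_lte(lrt$statistic, 1e-8)
  expect_equal(lrt$p, 1)
})

test_that("rank-deficient designs raise an informative error", {
  X <- cbind(intercept = 1, a = 1:10, b = 2 * (1:10))
  y <- rep_len(c(0, 1), 10)
  expect_error(fit_firth(X, y), "rank deficient")
})

test_that("reduced-penalty null is available and differs from the profile", {
  dat <- expand_2x2(15, 85, 3, 97)
  prof <- firth_lrt(dat$X, dat$y, null_penalty = "full")
  red <- firth_lrt(dat$X, dat$y, null_penalty = "reduced")
  expect_gt(red$statistic, prof$statistic)
})

test_that("test_all_genes ranks genes, flags eligibility, corrects p", {
  withr::with_seed(31, {
    n <- 400
    y <- rep(c(1, 0), c(300, 100))
    M <- rbind(
      strong = c(rbinom(300, 1, 0.08), rep(0, 100)),
      nullg  = rbinom(n, 1, 0.05),
      empty  = rep(0, n)
    )
    colnames(M) <- paste0("s", 1:n)
    covars <- cbind(age = rnorm(n, 50, 15))
    res <- test_all_genes(M, covars, y, min_case_carriers = 5)
  })
  expect_equal(nrow(res), 3)
  expect_equal(res$gene[1], "strong")
  expect_true(all(diff(res$p_value) >= 0))
  expect_equal(res$p_value[res$gene == "empty"], 1)
  expect_true(all(res$p_corrected >= res$p_value, na.rm = TRUE))
  n_el <- sum(res$eligible)
  expect_equal(attr(res, "threshold"), 0.05 / n_el)
  expect_true(all(is.na(res$p_corrected[!res$eligible])))
})

test_that("single-gene carrier matrix yields a single result", {
  y <- rep(c(1, 0), c(30, 20))
  M <- matrix(rep(c(1, 0), c(6, 44)), nrow = 1,
              dimnames = list("only", paste0("s", 1:50)))
  res <- test_all_genes(M, NULL, y, min_case_carriers = 5)
  expect_equal(nrow(res), 1)
  expect_true(res$eligible)
})

test_that("bonferroni correction reproduces the published threshold and clips", {
  res226 <- data.frame(p_value = runif(226, 1e-6, 1), eligible = TRUE)
  out <- bonferroni_correct(res226, alpha = 0.05)
  expect_equal(out$threshold, 0.05 / 226)
  expect_equal(signif(out$threshold, 2), 2.2e-4)

  res1 <- data.frame(p_value = 0.01, eligible = TRUE)
  out1 <- bonferroni_correct(res1, alpha = 0.05)
  expect_equal(out1$threshold, 0.05)
  expect_equal(out1$results$p_corrected, 0.01)

  resc <- data.frame(p_value = c(0.5, 0.2), eligible = c(TRUE, FALSE))
  outc <- bonferroni_correct(rbind(resc, resc[rep(1, 9), ]), alpha = 0.05)
  expect_equal(max(outc$results$p_corrected, na.rm = TRUE), 1)

  expect_error(bonferroni_correct(data.frame(p_value = 0.1, eligible = FALSE)),
               "no eligible genes")
})
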