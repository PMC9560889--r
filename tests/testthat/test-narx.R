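# Candidate dictionaries, design matrices, FROLS selection, estimation.

test_that("candidate counts follow the combinatorial formulas", {
  # oracle: p + q + p(p+1)/2 + q(q+1)/2 + pq, independently enumerated
  count_nar <- function(p) p + p * (p + 1) / 2
  count_narx <- function(p, q) p + q + p * (p + 1) / 2 + q * (q + 1) / 2 + p * q
  expect_equal(build_candidates(5, 0, 2)$M, count_nar(5))          # 20
  expect_equal(build_candidates(5, 5, 2)$M, count_narx(5, 5))      # 65
  expect_equal(build_candidates(3, 2, 2)$M, count_narx(3, 2))
  cs1 <- build_candidates(1, 0, 1)
  expect_equal(cs1$M, 1L)
  expect_equal(cs1$labels, "y(t-1)")
  # canonical ordering: product terms are sorted, no duplicates
  cs <- build_candidates(4, 4, 2)
  expect_equal(anyDuplicated(cs$labels), 0L)
  expect_error(build_candidates(2, 2, 3), "unsupported degree")
  expect_error(build_candidates(0, 1), "p must be")
})

test_that("build_design evaluates lagged products (hand oracle)", {
  cs1 <- build_candidates(1, 0, 1)
  d1 <- build_design(c(1, 2, 3, 4), NULL, cs1)
  expect_equal(unname(d1$Phi[, 1]), c(1, 2, 3))
  expect_equal(d1$target, c(2, 3, 4))
  cs2 <- build_candidates(2, 0, 2)
  d2 <- build_design(c(1, 2, 3, 4), NULL, cs2)
  expect_equal(unname(d2$Phi[, "y(t-1)*y(t-2)"]), c(2 * 1, 3 * 2))
  expect_equal(d2$target, c(3, 4))
  expect_true(all(build_design(numeric(10), NULL, cs2)$Phi == 0))
  expect_error(build_design(c(1, 2), NULL, cs2), "too short")
  csx <- build_candidates(2, 2, 2)
  expect_error(build_design(1:10, NULL, csx), "x is NULL")
  dx <- build_design(c(1, 2, 3, 4), c(10, 20, 30, 40), csx)
  expect_equal(unname(dx$Phi[, "y(t-1)*x(t-2)"]), c(2 * 10, 3 * 20))
})

test_that("err_score matches the normalized squared inner product", {
  expect_equal(err_score(c(1, 2, 3), c(1, 1, 1)), 36 / 42)
  expect_equal(err_score(c(1, 0), c(0, 1)), 0)
  expect_equal(err_score(c(1, 2, -1), 2 * c(1, 2, -1)), 1)
  expect_error(err_score(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("frols picks a perfect regressor first and stops", {
  set.seed(2)
  Phi <- matrix(rnorm(300), 100, 3)
  y <- Phi[, 3]
  fr <- frols(y, Phi)
  expect_equal(fr$selected[1], 3L)
  expect_equal(fr$err[1], 1, tolerance = 1e-12)
  expect_equal(fr$n, 1L)
  expect_equal(fr$theta, 1, tolerance = 1e-10)
})

test_that("frols ERR sequence attains the max among remaining candidates", {
  # recompute each step's score by explicit Gram-Schmidt over all candidates
  set.seed(9)
  y <- ar2_series(300, seed = 9)
  des <- build_design(y, NULL, build_candidates(4, 0, 2))
  fr <- frols(des$target, des$Phi, n_max = 4)
  yv <- des$target
  Q <- NULL
  for (s in seq_len(fr$n)) {
    scores <- rep(NA_real_, ncol(des$Phi))
    for (m in setdiff(seq_len(ncol(des$Phi)), fr$selected[seq_len(s - 1)])) {
      q <- des$Phi[, m]
      if (!is.null(Q)) for (r in seq_len(ncol(Q))) {
        q <- q - sum(des$Phi[, m] * Q[, r]) / sum(Q[, r]^2) * Q[, r]
      }
      if (sum(q^2) > 1e-20) scores[m] <- sum(yv * q)^2 / (sum(yv^2) * sum(q^2))
    }
    expect_equal(fr$selected[s], which.max(scores))
    expect_equal(fr$err[s], max(scores, na.rm = TRUE), tolerance = 1e-10)
    q_sel <- des$Phi[, fr$selected[s]]
    if (!is.null(Q)) for (r in seq_len(ncol(Q))) {
      q_sel <- q_sel - sum(des$Phi[, fr$selected[s]] * Q[, r]) / sum(Q[, r]^2) * Q[, r]
    }
    Q <- cbind(Q, q_sel)
  }
  # selected q vectors are mutually orthogonal
  G <- crossprod(fr$q_vectors)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / min(diag(G)), 1e-8)
  # ERR values lie in [0, 1] and sum below 1
  expect_true(all(fr$err >= 0 & fr$err <= 1))
  expect_lte(sum(fr$err), 1 + 1e-10)
})

test_that("AR(2) structure is identified and parameters recovered", {
  y <- ar2_series(2000, seed = 31)
  m <- fit_nar(y, p = 5)
  expect_setequal(m$selected_labels[1:2], c("y(t-1)", "y(t-2)"))
  th <- m$theta[match(c("y(t-1)", "y(t-2)"), m$selected_labels)]
  expect_lt(max(abs(th - c(0.5, -0.3))), 0.05)
})

test_that("back-substitution equals restricted least squares", {
  y <- ar2_series(500, seed = 4)
  des <- build_design(y, NULL, build_candidates(5, 0, 2))
  fr <- frols(des$target, des$Phi, err_min_frac = 0, n_max = 6)
  theta_bs <- solve_parameters(fr)
  # normal-equation oracle on the selected columns
  X <- des$Phi[, fr$selected, drop = FALSE]
  theta_ls <- solve(crossprod(X), crossprod(X, des$target))
  expect_equal(theta_bs, as.numeric(theta_ls), tolerance = 1e-8)
  # single selected term: projection formula
  fr1 <- frols(des$target, des$Phi, n_max = 1)
  phi <- des$Phi[, fr1$selected]
  expect_equal(fr1$theta, sum(des$target * phi) / sum(phi^2), tolerance = 1e-10)
})

test_that("FROLS equals exhaustive best subset on noiseless data", {
  # noiseless 3-term model inside a 12-candidate dictionary
  set.seed(14)
  N <- 400
  Phi <- matrix(rnorm(N * 12), N)
  y <- 0.7 * Phi[, 2] - 1.2 * Phi[, 7] + 0.4 * Phi[, 11]
  fr <- frols(y, Phi, n_max = 3)
  rss_frols <- {
    X <- Phi[, fr$selected, drop = FALSE]
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  combs <- utils::combn(12, 3)
  rss_best <- min(apply(combs, 2, function(cc) {
    sum(stats::lm.fit(Phi[, cc, drop = FALSE], y)$residuals^2)
  }))
  expect_equal(rss_frols, rss_best, tolerance = 1e-16)
  expect_lt(rss_frols, 1e-20)
})

test_that("noiseless quadratic coupling is identified exactly", {
  set.seed(6)
  N <- 1000
  x <- rnorm(N)
  y <- numeric(N)
  for (t in 2:N) y[t] <- 0.4 * x[t - 1]^2
  m <- fit_narx(y, x, 5, 5)
  expect_equal(m$selected_labels[1], "x(t-1)*x(t-1)")
  expect_equal(m$theta[1], 0.4, tolerance = 1e-6)
  expect_lt(m$residual_variance, 1e-20)
})

test_that("residual variances behave like innovation variances", {
  # white noise: no structure survives selection; variance ~ sample variance
  set.seed(18)
  w <- rnorm(3000)
  mw <- fit_nar(w, p = 5)
  expect_equal(mw$residual_variance, stats::var(w), tolerance = 0.1 * stats::var(w))
  # strong AR(1): residual variance is the innovation variance, << var(y)
  y <- as.numeric(stats::filter(rnorm(5000), 0.9, method = "recursive"))
  my <- fit_nar(y, p = 5)
  expect_lt(my$residual_variance, 0.3 * stats::var(y))
  expect_equal(my$residual_variance, 1, tolerance = 0.1)
  # irrelevant input: matched stop keeps the NARX variance close to NAR
  set.seed(19)
  y2 <- ar2_series(3000, sd = 1, seed = 19)
  x2 <- rnorm(3000)
  expect_equal(fit_narx(y2, x2, 5, 5)$residual_variance,
               fit_nar(y2, 5)$residual_variance,
               tolerance = 0.05 * fit_nar(y2, 5)$residual_variance)
  # known NARX: innovation variance recovered
  set.seed(20)
  N <- 10000
  x3 <- rnorm(N); e <- rnorm(N); y3 <- numeric(N)
  for (t in 2:N) y3[t] <- 0.8 * y3[t - 1] + 0.5 * x3[t - 1] + e[t]
  expect_equal(fit_narx(y3, x3, 5, 5)$residual_variance, 1, tolerance = 0.05)
})

test_that("nested full model never predicts worse than the restricted one", {
  for (s in 1:10) {
    set.seed(400 + s)
    y <- rnorm(400); x <- rnorm(400)
    r <- fit_nar(y, 5)
    cs <- build_candidates(5, 5, 2)
    f <- fit_narx(y, x, 5, 5,
                  force_in = match(r$selected_labels, cs$labels),
                  n_max = 10 + r$frols$n)
    expect_lte(f$residual_variance, r$residual_variance + 1e-12)
  }
})

test_that("parameter recovery on simulated NARX data (100 seeds)", {
  errs <- vapply(1:100, function(s) {
    set.seed(600 + s)
    N <- 2000
    x <- rnorm(N); e <- rnorm(N, 0, 0.1); y <- numeric(N)
    for (t in 3:N) y[t] <- 0.5 * y[t - 1] - 0.3 * y[t - 2] + 0.4 * x[t - 1] + e[t]
    m <- fit_narx(y, x, 5, 5)
    idx <- match(c("y(t-1)", "y(t-2)", "x(t-1)"), m$selected_labels)
    if (anyNA(idx)) return(1)
    mean(abs(m$theta[idx] - c(0.5, -0.3, 0.4)))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("predict matches manual term evaluation", {
  y <- c(0.1, 0.5, -0.2, 0.8, 0.3, -0.1, 0.6, 0.2, -0.4, 0.7)
  x <- c(1, -1, 2, 0.5, -0.5, 1.5, -2, 0.3, 0.9, -1.1)
  m <- fit_narx(ar2_series(500, seed = 44), rnorm(500), 2, 2, n_max = 3,
                err_min_frac = 0)
  p <- predict(m, y, x)
  manual <- vapply(3:10, function(t) {
    sum(vapply(seq_along(m$selected_terms), function(i) {
      tm <- m$selected_terms[[i]]
      v <- m$theta[i]
      for (k in tm$y_lags) v <- v * y[t - k]
      for (k in tm$x_lags) v <- v * x[t - k]
      v
    }, numeric(1)))
  }, numeric(1))
  expect_equal(p, manual, tolerance = 1e-12)
  # on training data, target - predictions == residuals
  ytr <- ar2_series(300, seed = 45)
  mtr <- fit_nar(ytr, 3)
  expect_equal(ytr[4:300] - predict(mtr, ytr), mtr$residuals, tolerance = 1e-10)
})
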