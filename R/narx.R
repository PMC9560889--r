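# Polynomial NAR/NARX modeling with forward-regression orthogonal least
# squares (FROLS) structure detection. The candidate dictionary holds all
# lagged linear terms and all degree-2 lag products; FROLS greedily selects
# terms by the error-reduction ratio computed on Gram-Schmidt-orthogonalized
# regressors, and parameters come from the unit-upper-triangular
# back-substitution (optionally refit by least squares on the selected
# columns, which is the default).

#' Build the polynomial candidate-term dictionary
#'
#' For output lags `1..p` and (optionally) input lags `1..q` with a degree
#' cap of 2, the dictionary holds all linear lags plus all unordered lag
#' pairs: `y` lags, `y*y` products, and -- when `include_input` -- `x` lags,
#' `x*x` products, and `y*x` cross products. Counts are
#' `p + p(p+1)/2` for the output-only (NAR) dictionary and
#' `p + q + p(p+1)/2 + q(q+1)/2 + p*q` for the full (NARX) dictionary.
#' No intercept term is included: signals are z-normalized upstream.
#'
#' @param p Maximum output lag, `>= 1`.
#' @param q Maximum input lag (`0` for none).
#' @param degree Polynomial degree cap, 1 or 2.
#' @param include_input Include input-bearing terms (requires `q >= 1`).
#' @return A `candidate_set`: list of terms (each with `y_lags`, `x_lags`),
#'   `M`, `p`, `q`, `degree`, plus canonical labels.
#' @export
build_candidates <- function(p, q = 0L, degree = 2L, include_input = q > 0L) {
  p <- as.integer(p); q <- as.integer(q)
  if (p < 1L) stop("p must be >= 1")
  if (q < 0L) stop("q must be >= 0")
  if (!degree %in% c(1L, 2L)) stop("unsupported degree ", degree,
                                   ": the model is at most quadratic")
  if (include_input && q < 1L) stop("include_input requires q >= 1")
  terms <- list()
  add <- function(y_lags, x_lags) {
    terms[[length(terms) + 1L]] <<- list(y_lags = sort(y_lags),
                                         x_lags = sort(x_lags))
  }
  for (k in seq_len(p)) add(k, integer(0))
  if (include_input) for (k in seq_len(q)) add(integer(0), k)
  if (degree >= 2L) {
    for (k in seq_len(p)) for (j in k:p) add(c(k, j), integer(0))
    if (include_input) {
      for (k in seq_len(q)) for (j in k:q) add(integer(0), c(k, j))
      for (k in seq_len(p)) for (j in seq_len(q)) add(k, j)
    }
  }
  structure(
    list(terms = terms, M = length(terms), p = p,
         q = if (include_input) q else 0L, degree = degree,
         labels = vapply(terms, term_label, character(1))),
    class = "candidate_set"
  )
}

#' Human-readable label of a model term
#' @param term A term (list with `y_lags`, `x_lags`).
#' @return Character like `"y(t-1)*x(t-2)"`.
#' @export
term_label <- function(term) {
  paste(c(sprintf("y(t-%d)", term$y_lags), sprintf("x(t-%d)", term$x_lags)),
        collapse = "*")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: M = %d terms (p = %d, q = %d, degree <= %d)\n",
              x$M, x$p, x$q, x$degree))
  invisible(x)
}

#' Evaluate the candidate dictionary into a regressor matrix
#'
#' Rows are time points `t = maxlag+1 .. N`; column `m` is the lagged
#' product defining term `m`; the target is `y(t)` over the same rows.
#'
#' @param y Output series.
#' @param x Input series (or `NULL` for output-only dictionaries).
#' @param cs A `candidate_set`.
#' @return List with matrix `Phi` (`(N - maxlag) x M`), vector `target`,
#'   and `maxlag`.
#' @export
build_design <- function(y, x = NULL, cs) {
  stopifnot(inherits(cs, "candidate_set"))
  y <- as.numeric(y)
  N <- length(y)
  maxlag <- max(cs$p, cs$q)
  if (N < maxlag + 2L) stop("series too short: need at least maxlag + 2 = ",
                            maxlag + 2L, " samples, got ", N)
  if (cs$q > 0L) {
    if (is.null(x)) stop("dictionary contains input terms but x is NULL")
    x <- as.numeric(x)
    if (length(x) != N) stop("x and y must have equal length")
  }
  rows <- (maxlag + 1L):N
  lag_col <- function(v, k) v[rows - k]
  Phi <- matrix(1, nrow = length(rows), ncol = cs$M)
  for (m in seq_len(cs$M)) {
    tm <- cs$terms[[m]]
    for (k in tm$y_lags) Phi[, m] <- Phi[, m] * lag_col(y, k)
    for (k in tm$x_lags) Phi[, m] <- Phi[, m] * lag_col(x, k)
  }
  colnames(Phi) <- cs$labels
  list(Phi = Phi, target = y[rows], maxlag = maxlag)
}

#' Error reduction ratio of one regressor
#'
#' Squared normalized inner product
#' `(y'phi)^2 / ((y'y)(phi'phi))`, the fraction of target energy a single
#' (orthogonalized) regressor explains; always in `[0, 1]`.
#'
#' @param y Target vector.
#' @param phi Regressor vector.
#' @return Scalar ERR.
#' @export
err_score <- function(y, phi) {
  yty <- sum(y * y); ptp <- sum(phi * phi)
  if (yty == 0 || ptp == 0) stop("err_score: zero-norm vector")
  sum(y * phi)^2 / (yty * ptp)
}

#' Forward-regression orthogonal least squares
#'
#' Greedy term selection: at each step every remaining candidate is
#' orthogonalized (classical Gram-Schmidt) against the already-selected
#' orthogonal vectors and the candidate with the largest ERR on its
#' orthogonalized version is selected. Parameters solve the unit
#' upper-triangular system `A theta = g` by back-substitution. Candidates
#' whose orthogonalized norm collapses below `1e-12` of their original norm
#' are skipped as degenerate.
#'
#' Selection stops when any of three rules fires: (i) `n_max` terms are
#' reached; (ii) the unexplained energy fraction `1 - sum(ERR)` drops below
#' `rho` (disabled by default); (iii) the best remaining candidate's ERR
#' falls below `err_min_frac * (1 - sum(ERR))`, i.e. the term fails to
#' explain a minimum fraction of the energy still unexplained. The default
#' `err_min_frac = (log(N) + 2 log(M)) / N` is a BIC-type penalty inflated
#' for best-of-`M` selection: a pure-noise candidate's maximum ERR is about
#' `2 log(M) / N` of the remaining energy, so accepted terms must beat the
#' expected noise maximum. An absolute threshold (`rho` alone) cannot work
#' across the dynamic range seen here: narrowband signals are >99%
#' self-predictable, and a fixed unexplained-energy target either freezes
#' out genuinely informative input terms or lets noise terms pile up.
#'
#' @param y Target vector.
#' @param Phi Regressor matrix (columns = candidates).
#' @param rho Unexplained-energy stopping tolerance; `0` (default) disables
#'   this rule.
#' @param n_max Maximum number of selected terms, default 10.
#' @param err_min_frac Minimum ERR of an accepted term as a fraction of the
#'   currently unexplained energy; `NULL` (default) uses
#'   `(log(N) + 2 log(M)) / N`. The first term (or any forced term) is
#'   always accepted.
#' @param force_in Integer column indices selected unconditionally, in
#'   order, before greedy selection starts (used to nest a restricted
#'   model's terms inside a full model).
#' @return A `frols_result`: `selected` (column indices in selection
#'   order), `err` per step, `A`, `g`, `theta` (back-substitution
#'   estimates), `q_vectors`, and `n`.
#' @export
frols <- function(y, Phi, rho = 0, n_max = 10L, err_min_frac = NULL,
                  force_in = integer(0)) {
  Phi <- as.matrix(Phi)
  M <- ncol(Phi)
  if (M < 1L) stop("Phi must have at least one column")
  yty <- sum(y * y)
  if (yty == 0) stop("target has zero energy")
  n_max <- min(n_max, M, nrow(Phi))
  if (is.null(err_min_frac)) {
    err_min_frac <- (log(nrow(Phi)) + 2 * log(M)) / nrow(Phi)
  }
  force_in <- as.integer(force_in)
  n_max <- max(n_max, length(force_in))

  orig_norm2 <- unname(colSums(Phi^2))
  W <- Phi                      # running orthogonalized copies
  alive <- orig_norm2 > 0
  selected <- integer(0)
  err <- numeric(0)
  Q <- matrix(0, nrow(Phi), 0L)
  qnorm2 <- numeric(0)
  A <- matrix(0, 0L, 0L)
  g <- numeric(0)
  queue <- force_in

  while (length(selected) < n_max) {
    forced <- length(queue) > 0L
    if (forced) {
      l_s <- queue[1L]
      queue <- queue[-1L]
      if (!alive[l_s]) next
      if (sum(W[, l_s]^2) < (1e-12)^2 * orig_norm2[l_s]) {
        alive[l_s] <- FALSE     # degenerate forced term: skip
        next
      }
    } else {
      cand <- which(alive)
      if (length(cand) == 0L) break
      w_norm2 <- colSums(W[, cand, drop = FALSE]^2)
      degen <- w_norm2 < (1e-12)^2 * orig_norm2[cand]
      if (any(degen)) {
        alive[cand[degen]] <- FALSE
        cand <- cand[!degen]
        if (length(cand) == 0L) break
        w_norm2 <- w_norm2[!degen]
      }
      num <- as.vector(crossprod(W[, cand, drop = FALSE], y))^2
      scores <- num / (yty * w_norm2)
      pick <- which.max(scores)
      remaining <- max(0, 1 - sum(err))
      if (length(selected) > 0L &&
          (remaining < 1e-12 || scores[pick] < err_min_frac * remaining)) break
      l_s <- cand[pick]
    }
    q_s <- W[, l_s]
    # classical GS already applied incrementally; re-orthogonalize once if
    # accumulated loss of orthogonality against earlier q vectors is visible
    if (ncol(Q) > 0L) {
      ip <- as.vector(crossprod(Q, q_s)) / sqrt(qnorm2 * sum(q_s^2))
      if (max(abs(ip)) > 1e-8) {
        q_s <- q_s - Q %*% (as.vector(crossprod(Q, q_s)) / qnorm2)
        q_s <- as.vector(q_s)
      }
    }
    qn2 <- sum(q_s^2)
    s <- length(selected) + 1L
    # triangular bookkeeping against the ORIGINAL selected column
    A <- if (s == 1L) matrix(0, 1L, 1L) else cbind(rbind(A, rep(0, s - 1L)), 0)
    A[s, s] <- 1
    if (s > 1L) {
      A[seq_len(s - 1L), s] <- as.vector(crossprod(Q, Phi[, l_s])) / qnorm2
    }
    g <- c(g, sum(y * q_s) / qn2)
    err <- c(err, g[s]^2 * qn2 / yty)
    selected <- c(selected, l_s)
    Q <- cbind(Q, q_s)
    qnorm2 <- c(qnorm2, qn2)
    alive[l_s] <- FALSE
    if (rho > 0 && length(queue) == 0L && 1 - sum(err) < rho) break
    # deflate all remaining candidates against the new orthogonal vector
    cand <- which(alive)
    if (length(cand) > 0L) {
      proj <- as.vector(crossprod(q_s, W[, cand, drop = FALSE])) / qn2
      W[, cand] <- W[, cand, drop = FALSE] - outer(q_s, proj)
    }
  }

  theta <- if (length(selected) > 0L) backsolve(A, g) else numeric(0)
  structure(
    list(selected = selected, err = err, A = A, g = g, theta = theta,
         q_vectors = Q, q_norm2 = qnorm2, n = length(selected), yty = yty),
    class = "frols_result"
  )
}

#' @export
print.frols_result <- function(x, ...) {
  cat(sprintf("FROLS: %d term(s) selected, sum ERR = %.4f\n", x$n, sum(x$err)))
  if (x$n > 0L) {
    print(data.frame(index = x$selected, err = x$err, theta = x$theta))
  }
  invisible(x)
}

#' Solve the triangular parameter system of a FROLS result
#'
#' Back-substitution of `A theta = g` where `A` is unit upper-triangular.
#' Equals direct least squares restricted to the selected terms.
#'
#' @param fr A `frols_result`.
#' @return Parameter vector `theta` in selection order.
#' @export
solve_parameters <- function(fr) {
  stopifnot(inherits(fr, "frols_result"))
  if (fr$n == 0L) return(numeric(0))
  if (any(abs(diag(fr$A)) < .Machine$double.eps)) {
    stop("singular triangular system")
  }
  backsolve(fr$A, fr$g)
}

# Least-squares refit of theta on a fixed set of original columns.
.refit_theta <- function(target, Phi, cols) {
  fit <- stats::lm.fit(Phi[, cols, drop = FALSE], target)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  list(theta = unname(coef), residuals = fit$residuals)
}

# Shared model assembly for fit_nar / fit_narx.
.fit_polynomial <- function(y, x, cs, rho, n_max, refit, err_min_frac = NULL,
                            force_in = integer(0)) {
  des <- build_design(y, x, cs)
  fr <- frols(des$target, des$Phi, rho = rho, n_max = n_max,
              err_min_frac = err_min_frac, force_in = force_in)
  if (fr$n == 0L) stop("no term selected: target may be degenerate")
  if (refit) {
    rf <- .refit_theta(des$target, des$Phi, fr$selected)
    theta <- rf$theta
    residuals <- rf$residuals
  } else {
    theta <- fr$theta
    residuals <- des$target - des$Phi[, fr$selected, drop = FALSE] %*% fr$theta
  }
  structure(
    list(
      candidate_set = cs,
      frols = fr,
      theta = as.numeric(theta),
      selected_terms = cs$terms[fr$selected],
      selected_labels = cs$labels[fr$selected],
      residuals = as.numeric(residuals),
      residual_variance = mean(residuals^2),
      valid_range = c(first = des$maxlag + 1L, last = length(y)),
      refit = refit
    ),
    class = "narx_model"
  )
}

#' Fit a univariate polynomial NAR model
#'
#' Output-only quadratic autoregression identified by FROLS. The residual
#' variance is the restricted-model prediction-error variance
#' `var(Y|Y-)`, averaged over the `N - p` predictable samples.
#'
#' @param y Series.
#' @param p Maximum lag, default 5.
#' @param degree Polynomial degree cap, default 2.
#' @param rho,n_max,err_min_frac FROLS stopping rule; see [frols()].
#' @param refit Re-estimate `theta` by least squares on the selected terms
#'   (default) instead of keeping the orthogonal-stage estimates.
#' @return A `narx_model`.
#' @export
fit_nar <- function(y, p = 5L, degree = 2L, rho = 0, n_max = 10L,
                    err_min_frac = NULL, refit = TRUE) {
  cs <- build_candidates(p, 0L, degree, include_input = FALSE)
  .fit_polynomial(y, NULL, cs, rho, n_max, refit, err_min_frac)
}

#' Fit a bivariate polynomial NARX model
#'
#' Quadratic model of `y` on its own past and the past of the input `x`.
#' The candidate dictionary is a strict superset of the NAR dictionary of
#' [fit_nar()], which keeps restricted/full model comparisons meaningful.
#' The residual variance is the full-model `var(Y|Y-,X-)`.
#'
#' @param y Output series.
#' @param x Input series of equal length.
#' @param p,q Maximum output/input lags, defaults 5.
#' @inheritParams fit_nar
#' @return A `narx_model`.
#' @export
fit_narx <- function(y, x, p = 5L, q = 5L, degree = 2L, rho = 0,
                     n_max = 10L, err_min_frac = NULL, refit = TRUE,
                     force_in = integer(0)) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  cs <- build_candidates(p, q, degree, include_input = TRUE)
  .fit_polynomial(y, x, cs, rho, n_max, refit, err_min_frac, force_in)
}

#' @export
print.narx_model <- function(x, ...) {
  kind <- if (x$candidate_set$q > 0L) "NARX" else "NAR"
  cat(sprintf("%s model: %d term(s), residual variance %.6g\n",
              kind, x$frols$n, x$residual_variance))
  print(data.frame(term = x$selected_labels, theta = x$theta,
                   err = x$frols$err))
  invisible(x)
}

#' One-step-ahead prediction from a fitted model
#'
#' Evaluates the selected terms on measured lagged values of the supplied
#' series and combines them with the fitted coefficients.
#'
#' @param object A `narx_model`.
#' @param y Output series.
#' @param x Input series (required iff the model has input terms).
#' @param ... Unused.
#' @return Numeric vector of predictions for `t = maxlag+1 .. N`.
#' @export
predict.narx_model <- function(object, y, x = NULL, ...) {
  cs <- object$candidate_set
  des <- build_design(y, x, cs)
  as.numeric(des$Phi[, object$frols$selected, drop = FALSE] %*% object$theta)
}
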