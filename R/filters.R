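# Minimal IIR filtering toolbox: Butterworth design via the bilinear
# transform and zero-phase forward-backward application. Kept deliberately
# small -- just what the preprocessing chain needs.

# Analog Butterworth lowpass prototype poles (unit cutoff), order n.
.butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Polynomial coefficients (descending powers) from roots; drops the
# negligible imaginary part left by conjugate-pair arithmetic.
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0i) - c(0i, p * ri)
  Re(p)
}

#' Digital Butterworth filter design
#'
#' Designs lowpass, highpass or bandpass Butterworth filters by analog
#' prototype, frequency transformation and bilinear transform with edge
#' prewarping (the standard scipy/Matlab construction).
#'
#' @param n Prototype order (a bandpass of prototype order `n` has `2n` poles).
#' @param fc Cutoff in Hz: scalar for low/highpass, length-2 `c(low, high)`
#'   for bandpass.
#' @param fs Sampling rate in Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(n, fc, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (any(fc <= 0) || any(fc >= fs / 2)) {
    stop("cutoff frequencies must lie strictly inside (0, fs/2) = (0, ",
         fs / 2, ") Hz")
  }
  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)
  proto <- .butter_prototype(n)

  if (type == "low") {
    wc <- warp(fc)
    poles <- proto * wc
    zeros <- complex(0)
    gain <- wc^n
  } else if (type == "high") {
    wc <- warp(fc)
    poles <- wc / proto
    zeros <- rep(0 + 0i, n)
    gain <- 1
  } else {
    if (length(fc) != 2L || fc[1] >= fc[2]) {
      stop("bandpass needs fc = c(low, high) with low < high")
    }
    w1 <- warp(fc[1]); w2 <- warp(fc[2])
    bw <- w2 - w1
    w0 <- sqrt(w1 * w2)
    s <- proto * bw / 2
    poles <- c(s + sqrt(s^2 - w0^2), s - sqrt(s^2 - w0^2))
    zeros <- rep(0 + 0i, n)
    gain <- bw^n
  }

  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  kd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  # zeros at infinity map to z = -1
  zd <- c(zd, rep(-1 + 0i, length(poles) - length(zeros)))
  b <- kd * .poly_from_roots(zd)
  a <- .poly_from_roots(pd)
  list(b = b, a = a, zeros = zd, poles = pd, gain = kd,
       sos = .zpk2sos(zd, pd, kd))
}

# Pair digital zeros/poles into second-order sections. Sections are ordered
# with poles farthest from the unit circle first; the overall gain is folded
# into the first section. Narrowband filters are numerically unusable in
# expanded polynomial form, so all filtering below runs on sections.
.zpk2sos <- function(z, p, k) {
  stopifnot(length(z) <= length(p))
  z <- c(z, rep(0 + 0i, length(p) - length(z)))   # pad with origin zeros
  if (length(p) %% 2L == 1L) { p <- c(p, 0 + 0i); z <- c(z, 0 + 0i) }
  take_pair <- function(pool, anchor = NULL) {
    # pick an element (closest to unit circle, or to `anchor`) plus its
    # conjugate partner; returns list(pair, rest)
    if (is.null(anchor)) {
      i <- which.min(abs(1 - abs(pool)))
    } else {
      i <- which.min(abs(pool - anchor))
    }
    first <- pool[i]; pool <- pool[-i]
    if (abs(Im(first)) > 1e-12) {
      j <- which.min(abs(pool - Conj(first)))
    } else {
      reals <- which(abs(Im(pool)) <= 1e-12)
      j <- if (is.null(anchor)) reals[which.min(abs(1 - abs(pool[reals])))]
           else reals[which.min(abs(pool[reals] - anchor))]
    }
    list(pair = c(first, pool[j]), rest = pool[-j])
  }
  n_sec <- length(p) %/% 2L
  sos <- matrix(0, n_sec, 6L)
  for (s in seq_len(n_sec)) {
    pp <- take_pair(p); p <- pp$rest
    zz <- take_pair(z, anchor = pp$pair[1]); z <- zz$rest
    bs <- .poly_from_roots(zz$pair)
    as <- .poly_from_roots(pp$pair)
    sos[s, ] <- c(bs, as)
  }
  # worst-conditioned (closest to circle) section last
  sos <- sos[rev(seq_len(n_sec)), , drop = FALSE]
  sos[1L, 1:3] <- sos[1L, 1:3] * k
  sos
}

# Steady-state section states for sosfiltfilt, scaled for input level x0.
.sos_zi <- function(sos, x0) {
  n_sec <- nrow(sos)
  zi <- matrix(0, n_sec, 2L)
  scale <- x0
  for (s in seq_len(n_sec)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    zi[s, ] <- .lfilter_zi(b, a) * scale
    scale <- scale * sum(b) / sum(a)
  }
  zi
}

.sosfilt <- function(sos, x, zi = NULL) {
  for (s in seq_len(nrow(sos))) {
    z <- if (is.null(zi)) NULL else zi[s, ]
    x <- .lfilter(sos[s, 1:3], sos[s, 4:6], x, z)
  }
  x
}

#' Zero-phase filtering through second-order sections
#'
#' Forward-backward application of a cascade of biquad sections with odd
#' reflection padding and steady-state initial conditions per section.
#' This is the numerically robust form of [filtfilt()] and the one the
#' preprocessing chain uses.
#'
#' @param sos Section matrix (rows `b0 b1 b2 a0 a1 a2`), e.g.
#'   `butter_design(...)$sos`.
#' @param x Signal.
#' @param pad Reflection padding length; default `3 * fs`-independent
#'   `6 * nrow(sos) + 1`, capped at `length(x) - 1`. Increase for very
#'   low cutoff frequencies relative to `fs`.
#' @return Filtered signal, same length as `x`.
#' @export
sosfiltfilt <- function(sos, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- 6L * nrow(sos) + 1L
  pad <- min(pad, n - 1L)
  if (pad < 1L) stop("signal too short for sosfiltfilt")
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- .sosfilt(sos, ext, .sos_zi(sos, ext[1]))
  y <- rev(.sosfilt(sos, rev(y), .sos_zi(sos, y[length(y)])))
  y[(pad + 1L):(pad + n)]
}

# Direct-form II transposed linear filter with initial state zi.
.lfilter <- function(b, a, x, zi = NULL) {
  nf <- max(length(b), length(a))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) numeric(nf - 1L) else zi
  y <- numeric(length(x))
  for (t in seq_along(x)) {
    xt <- x[t]
    yt <- b[1] * xt + z[1]
    if (nf > 2L) {
      z[seq_len(nf - 2L)] <- b[2:(nf - 1L)] * xt + z[2:(nf - 1L)] - a[2:(nf - 1L)] * yt
    }
    z[nf - 1L] <- b[nf] * xt - a[nf] * yt
    y[t] <- yt
  }
  y
}

# Steady-state initial state for a unit-step input (scipy lfilter_zi).
.lfilter_zi <- function(b, a) {
  nf <- max(length(b), length(a))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  b <- b / a[1]; a <- a / a[1]
  n <- nf - 1L
  IminusA <- diag(n)
  IminusA[, 1] <- IminusA[, 1] + a[-1]
  if (n > 1L) for (i in seq_len(n - 1L)) IminusA[i, i + 1L] <- IminusA[i, i + 1L] - 1
  B <- b[-1] - b[1] * a[-1]
  # stiff narrowband filters make this system ill-conditioned; LAPACK still
  # produces the usable steady state, so skip R's rcond gate
  solve(IminusA, B, tol = 0)
}

#' Zero-phase forward-backward filtering
#'
#' Applies an IIR filter forward and then backward, cancelling phase
#' distortion (important here because directed-lag inference downstream is
#' sensitive to phase shifts). Edge transients are controlled by odd
#' reflection padding and steady-state initial conditions, following the
#' usual filtfilt construction.
#'
#' @param b,a Filter coefficients.
#' @param x Signal.
#' @param pad Padding length; default `3 * (max(length(a), length(b)) - 1)`,
#'   capped at `length(x) - 1`.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x, pad = NULL) {
  n <- length(x)
  nf <- max(length(a), length(b))
  if (is.null(pad)) pad <- 3L * (nf - 1L)
  pad <- min(pad, n - 1L)
  if (pad < 1L) stop("signal too short for filtfilt")
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- .lfilter_zi(b, a)
  y <- .lfilter(b, a, ext, zi * ext[1])
  y <- rev(.lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}
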