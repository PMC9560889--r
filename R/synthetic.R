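# Ground-truth generators: coupled polynomial NARX pairs with optional
# time-varying coupling, narrowband oscillatory pairs emulating preprocessed
# band-limited physiological signals, and a registry of canonical fixtures.

#' Specify a coupled NARX simulation
#'
#' Describes a pair of difference equations driven by Gaussian innovations.
#' Each term is a lagged product of the "own" series (`y_lags`, i.e. lags
#' of the equation's own output) and the other series (`x_lags`); cross
#' terms (non-empty `x_lags`) in the `y` equation are multiplied by the
#' time-indexed coupling profile, which realizes time-varying coupling as a
#' constant, a step at `t_switch`, or a linear ramp.
#'
#' @param n_samples Samples to return after burn-in.
#' @param fs Sampling rate in Hz (metadata), default 250.
#' @param y_terms,x_terms Lists of `list(y_lags=, x_lags=, coef=)`; in
#'   `x_terms`, `y_lags` refers to lags of `x` itself and `x_lags` to lags
#'   of `y` (the "other" series).
#' @param coupling_profile `list(type = "constant"|"step"|"ramp",
#'   t_switch = index)`; multiplier applied to cross terms of the `y`
#'   equation (0 before `t_switch`, 1 after, for `"step"`).
#' @param noise_sd Length-2 numeric `c(y, x)` innovation standard deviations.
#' @param burn_in Samples discarded; must be `>= 10 * max lag`.
#' @param seed Integer seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_samples, fs = 250,
                     y_terms = list(), x_terms = list(),
                     coupling_profile = list(type = "constant"),
                     noise_sd = c(y = 1, x = 1),
                     burn_in = 500L, seed = 1L) {
  lags <- function(tl) vapply(tl, function(tm) {
    max(c(tm$y_lags, tm$x_lags, 0L))
  }, numeric(1))
  maxlag <- max(c(lags(y_terms), lags(x_terms), 1))
  if (burn_in < 10L * maxlag) stop("burn_in must be >= 10 * max lag = ",
                                   10L * maxlag)
  if (length(noise_sd) == 1L) noise_sd <- c(y = noise_sd, x = noise_sd)
  structure(
    list(n_samples = as.integer(n_samples), fs = fs, y_terms = y_terms,
         x_terms = x_terms, coupling_profile = coupling_profile,
         noise_sd = noise_sd, burn_in = as.integer(burn_in),
         seed = as.integer(seed), max_lag = as.integer(maxlag)),
    class = "sim_spec"
  )
}

.profile_value <- function(profile, t, n_total) {
  switch(profile$type,
         constant = 1,
         step = if (t >= profile$t_switch) 1 else 0,
         ramp = min(1, max(0, (t - profile$t_switch) /
                                max(1, n_total - profile$t_switch))),
         stop("unknown coupling profile type '", profile$type, "'"))
}

#' Simulate a coupled polynomial NARX pair
#'
#' Iterates the difference equations of a [sim_spec()] with Gaussian
#' innovations. Generation aborts if any sample exceeds `1e6` in magnitude
#' (declared system unstable). Deterministic given the spec's seed.
#'
#' @param spec A `sim_spec`.
#' @return List with `x`, `y` (length `n_samples`) and `truth` (active
#'   terms with coefficients, coupling directions, `t_switch` if any, and
#'   the seed).
#' @export
simulate_narx_pair <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n_total <- spec$n_samples + spec$burn_in
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  ey <- stats::rnorm(n_total, 0, spec$noise_sd[["y"]])
  ex <- stats::rnorm(n_total, 0, spec$noise_sd[["x"]])
  y <- numeric(n_total); x <- numeric(n_total)
  ml <- spec$max_lag
  eval_terms <- function(terms, own, other, t, profile_mult) {
    v <- 0
    for (tm in terms) {
      term_val <- tm$coef
      for (k in tm$y_lags) term_val <- term_val * own[t - k]
      for (k in tm$x_lags) term_val <- term_val * other[t - k]
      if (length(tm$x_lags) > 0L) term_val <- term_val * profile_mult
      v <- v + term_val
    }
    v
  }
  # switch index is relative to the returned (post burn-in) series
  profile <- spec$coupling_profile
  if (!is.null(profile$t_switch)) {
    profile$t_switch <- profile$t_switch + spec$burn_in
  }
  for (t in (ml + 1L):n_total) {
    mult <- .profile_value(profile, t, n_total)
    x[t] <- eval_terms(spec$x_terms, x, y, t, 1) + ex[t]
    y[t] <- eval_terms(spec$y_terms, y, x, t, mult) + ey[t]
    if (!is.finite(y[t]) || !is.finite(x[t]) ||
        abs(y[t]) > 1e6 || abs(x[t]) > 1e6) {
      stop("simulation unstable: sample ", t - spec$burn_in,
           " diverged (|value| > 1e6)")
    }
  }
  keep <- (spec$burn_in + 1L):n_total
  truth <- list(
    y_terms = spec$y_terms, x_terms = spec$x_terms,
    coupling_x_to_y = any(vapply(spec$y_terms,
                                 function(tm) length(tm$x_lags) > 0L, logical(1))),
    coupling_y_to_x = any(vapply(spec$x_terms,
                                 function(tm) length(tm$x_lags) > 0L, logical(1))),
    coupling_profile = spec$coupling_profile,
    noise_sd = spec$noise_sd, seed = spec$seed
  )
  list(x = x[keep], y = y[keep], truth = truth)
}

#' Simulate a narrowband-coupled oscillatory pair
#'
#' `x` is a stochastic narrowband oscillation at `f_c` (an AR(2) resonator
#' with pole radius `r` driven by white noise) riding on a broadband noise
#' floor; `y` is its own narrowband rhythm at `y_own_f` plus
#' `coupling * x_nb(t - lag)`, where `x_nb` is the narrowband component of
#' `x`, plus broadband noise. `snr` is the ratio of narrowband to broadband
#' power in `x`. Both outputs are z-normalized, mirroring the scale of
#' preprocessed recordings.
#'
#' Note the broadband floors set a hard ceiling on band-level causality:
#' within a ~1 Hz analysis band a signal is almost perfectly predictable
#' from its own past, so the detectable directed effect is of order
#' `ln(1 + band innovation / broadband in-band power)` -- keep `y_broad_sd`
#' small if the coupled band is meant to stand out.
#'
#' @param f_c Center frequency in Hz (`< fs/2`).
#' @param lag Coupling delay in samples.
#' @param coupling Coupling gain applied to the unit-variance narrowband
#'   component.
#' @param snr Narrowband-to-broadband power ratio in `x` (> 0), default 10.
#' @param n Number of samples.
#' @param fs Sampling rate in Hz, default 250.
#' @param r Resonator pole radius, default 0.97 (bandwidth of a few Hz).
#' @param y_own_f Center frequency of y's intrinsic rhythm in Hz, default 10.
#' @param y_broad_sd Broadband noise sd in `y` (relative to the
#'   unit-variance rhythms), default 0.2.
#' @param seed Integer seed.
#' @return List with `x`, `y`, and `truth` (parameters incl. direction).
#' @export
simulate_banded_pair <- function(f_c = 20, lag = 2L, coupling = 0.8, snr = 10,
                                 n = 10000L, fs = 250, r = 0.97,
                                 y_own_f = 10, y_broad_sd = 0.2, seed = 1L) {
  if (f_c >= fs / 2) stop("f_c must be below Nyquist = ", fs / 2, " Hz")
  if (snr <= 0) stop("snr must be > 0")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  burn <- 500L
  n_tot <- n + burn + lag
  resonator <- function(f) {
    a1 <- 2 * r * cos(2 * pi * f / fs); a2 <- -r^2
    v <- numeric(n_tot)
    e <- stats::rnorm(n_tot)
    for (t in 3:n_tot) v[t] <- a1 * v[t - 1] + a2 * v[t - 2] + e[t]
    v / stats::sd(v[(burn + 1):n_tot])
  }
  nb <- resonator(f_c)
  idx <- (burn + lag + 1L):n_tot
  x <- nb[idx] + stats::rnorm(length(idx)) / sqrt(snr)
  y_own <- resonator(y_own_f)[idx]
  y <- y_own + coupling * nb[idx - lag] + y_broad_sd * stats::rnorm(length(idx))
  list(
    x = as.numeric(scale(x)), y = as.numeric(scale(y)),
    truth = list(f_c = f_c, lag = lag, coupling = coupling, snr = snr,
                 fs = fs, r = r, y_own_f = y_own_f, y_broad_sd = y_broad_sd,
                 seed = seed, direction = "x->y")
  )
}

#' Canonical test fixtures
#'
#' Registry of frozen simulation designs used across the test surface:
#' \describe{
#'   \item{null_pair}{Two independent AR(1) (0.3) series, unit noise.}
#'   \item{linear_unidirectional}{`y(t) = 0.8 y(t-1) + 0.5 x(t-1) + e`,
#'     `x` unit white noise: restricted innovation variance `1 + 0.25`,
#'     so the true GC is `ln 1.25 ~ 0.223` in the X->Y direction only.}
#'   \item{quadratic_unidirectional}{`y(t) = 0.5 y(t-1) + 0.6 x(t-1)^2 + e`:
#'     invisible to a degree-1 dictionary (odd moments vanish), detectable
#'     at degree 2.}
#'   \item{bidirectional}{Linear coupling both ways at different lags.}
#'   \item{step_coupling}{Coupling `0 -> 0.5 x(t-1)` switched on at the
#'     midpoint of a 10 s segment at 250 Hz.}
#'   \item{banded_20hz}{Narrowband 20 Hz coupling via
#'     [simulate_banded_pair()].}
#' }
#'
#' @param name Fixture name.
#' @param n Override the sample count (optional).
#' @param seed Override the frozen seed (optional).
#' @return A `sim_spec`, or for `banded_20hz` a list of arguments for
#'   [simulate_banded_pair()] (attribute `generator` names the generator).
#' @export
make_fixture <- function(name, n = NULL, seed = NULL) {
  term <- function(y_lags, x_lags, coef) {
    list(y_lags = as.integer(y_lags), x_lags = as.integer(x_lags), coef = coef)
  }
  registry <- list(
    null_pair = function(n, seed) sim_spec(
      n_samples = n %||% 5000L, seed = seed %||% 101L,
      y_terms = list(term(1, integer(0), 0.3)),
      x_terms = list(term(1, integer(0), 0.3))
    ),
    linear_unidirectional = function(n, seed) sim_spec(
      n_samples = n %||% 10000L, seed = seed %||% 102L,
      y_terms = list(term(1, integer(0), 0.8), term(integer(0), 1, 0.5)),
      x_terms = list()
    ),
    quadratic_unidirectional = function(n, seed) sim_spec(
      n_samples = n %||% 2000L, seed = seed %||% 103L,
      y_terms = list(term(1, integer(0), 0.5), term(integer(0), c(1, 1), 0.6)),
      x_terms = list()
    ),
    bidirectional = function(n, seed) sim_spec(
      n_samples = n %||% 5000L, seed = seed %||% 104L,
      y_terms = list(term(1, integer(0), 0.5), term(integer(0), 1, 0.4)),
      x_terms = list(term(1, integer(0), 0.5), term(integer(0), 2, 0.4))
    ),
    step_coupling = function(n, seed) {
      n <- n %||% 2500L
      sim_spec(
        n_samples = n, seed = seed %||% 105L,
        y_terms = list(term(1, integer(0), 0.5), term(integer(0), 1, 0.5)),
        x_terms = list(),
        coupling_profile = list(type = "step", t_switch = n %/% 2L)
      )
    },
    banded_20hz = function(n, seed) {
      structure(list(f_c = 20, lag = 2L, coupling = 0.8, snr = 5,
                     n = n %||% 10000L, fs = 250, seed = seed %||% 106L),
                generator = "simulate_banded_pair")
    }
  )
  if (!name %in% names(registry)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(registry), collapse = ", "))
  }
  registry[[name]](n, seed)
}

#' Generate the signal pair of a named fixture
#'
#' Convenience wrapper dispatching [make_fixture()] output to the right
#' generator.
#' @inheritParams make_fixture
#' @return List with `x`, `y`, `truth`.
#' @export
simulate_fixture <- function(name, n = NULL, seed = NULL) {
  spec <- make_fixture(name, n = n, seed = seed)
  if (identical(attr(spec, "generator"), "simulate_banded_pair")) {
    do.call(simulate_banded_pair, spec)
  } else {
    simulate_narx_pair(spec)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
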