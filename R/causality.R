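# Directed Granger causality from polynomial NAR/NARX fits, sliding-window
# time-varying GC, time-frequency map assembly over wavelet packet bands,
# band/period summaries, group statistics and surrogate thresholds.

#' Bidirectional nonlinear Granger causality of a signal pair
#'
#' Fits four models -- restricted NAR and full NARX for each direction --
#' and returns the log variance ratios
#' `G_{X->Y} = ln( var(Y|Y-) / var(Y|Y-,X-) )` and vice versa, clamped at 0
#' (the population quantity is non-negative; small negative estimates are
#' finite-sample noise and are kept as `raw_*`).
#'
#' To guarantee the restricted model is genuinely nested in the full one,
#' the full-model FROLS run starts from the restricted model's selected
#' terms (forced in, re-expressed in the full dictionary) and continues
#' selection over the full dictionary; the final least-squares refit over
#' that superset makes `var(Y|Y-,X-) <= var(Y|Y-)` up to rounding and
#' prevents spurious negative causality from independent selections. It
#' also lets input terms be judged against the energy the restricted terms
#' leave unexplained, which matters for highly self-predictable narrowband
#' signals.
#'
#' @param y,x Numeric series of equal length.
#' @param p,q Maximum output/input lags, defaults 5.
#' @param degree Polynomial degree cap (2 = quadratic, the default).
#' @param rho,n_max,err_min_frac FROLS stopping rule; see [frols()].
#'   `n_max` bounds the restricted selection and the number of additional
#'   full-model terms. Setting `err_min_frac = 0` forces both models to
#'   their full `n_max` budget, which yields a continuous (tie-free) GC
#'   statistic at the cost of more overfitting noise.
#' @return A `gc_pair` object: `g_xy`, `g_yx` (clamped, nats), `raw_xy`,
#'   `raw_yx`, and the four fitted models.
#' @export
gc_pair <- function(y, x, p = 5L, q = 5L, degree = 2L, rho = 0,
                    n_max = 10L, err_min_frac = NULL) {
  y <- as.numeric(y); x <- as.numeric(x)
  if (length(y) != length(x)) stop("x and y must have equal length")
  if (length(y) <= 10L * max(p, q)) {
    stop("series too short for reliable GC: need > ", 10L * max(p, q),
         " samples, got ", length(y))
  }
  one_direction <- function(out, inp) {
    restricted <- fit_nar(out, p = p, degree = degree, rho = rho,
                          n_max = n_max, err_min_frac = err_min_frac)
    # the full model nests the restricted one: the restricted selection is
    # forced in first and FROLS continues over the full dictionary, so
    # informative input terms are judged against the energy the restricted
    # terms leave unexplained
    cs_full <- build_candidates(p, q, degree, include_input = TRUE)
    restricted_in_full <- match(restricted$selected_labels, cs_full$labels)
    full <- fit_narx(out, inp, p = p, q = q, degree = degree, rho = rho,
                     n_max = n_max + restricted$frols$n,
                     err_min_frac = err_min_frac,
                     force_in = restricted_in_full)
    var_full <- full$residual_variance
    var_restricted <- restricted$residual_variance
    if (var_full < 1e-15) {
      stop("full-model residual variance ", var_full,
           " is numerically zero: log variance ratio unstable")
    }
    list(raw = log(var_restricted / var_full),
         restricted = restricted, full = full,
         var_restricted = var_restricted, var_full = var_full)
  }
  xy <- one_direction(y, x)
  yx <- one_direction(x, y)
  structure(
    list(
      g_xy = max(0, xy$raw), g_yx = max(0, yx$raw),
      raw_xy = xy$raw, raw_yx = yx$raw,
      models = list(y_restricted = xy$restricted, y_full = xy$full,
                    x_restricted = yx$restricted, x_full = yx$full),
      variances = c(y_restricted = xy$var_restricted, y_full = xy$var_full,
                    x_restricted = yx$var_restricted, x_full = yx$var_full)
    ),
    class = "gc_pair"
  )
}

#' @export
print.gc_pair <- function(x, ...) {
  cat(sprintf("Granger causality: X->Y %.4f, Y->X %.4f (raw %.4f / %.4f)\n",
              x$g_xy, x$g_yx, x$raw_xy, x$raw_yx))
  invisible(x)
}

#' Time-varying Granger causality by sliding windows
#'
#' Under the short-time-invariance assumption, the time-varying model
#' coefficients are treated as constants within each window of length
#' `window` seconds; [gc_pair()] is re-estimated (including term selection)
#' on the samples in `[t_n - window/2, t_n + window/2]` for window centers
#' advancing by `step` seconds.
#'
#' @param y,x Series of equal length.
#' @param fs Sampling rate in Hz.
#' @param window Window length in seconds, default 1.
#' @param step Window advance in seconds, default 0.1.
#' @param ... Passed to [gc_pair()] (`p`, `q`, `degree`, `rho`, `n_max`).
#' @return A `tvgc_series`: `window_centers` (s), `g_xy`, `g_yx`,
#'   `raw_xy`, `raw_yx`, plus the window geometry.
#' @export
tv_gc <- function(y, x, fs, window = 1, step = 0.1, p = 5L, q = 5L, ...) {
  n <- length(y)
  if (length(x) != n) stop("x and y must have equal length")
  w_samp <- round(window * fs)
  min_samp <- 10L * max(p, q) + 1L
  if (w_samp < min_samp) {
    stop("window of ", w_samp, " samples too short: need >= ", min_samp,
         " (", min_samp / fs, " s at fs = ", fs, ")")
  }
  step_samp <- max(1L, round(step * fs))
  half <- w_samp %/% 2L
  centers <- seq.int(half + 1L, n - (w_samp - half) + 1L, by = step_samp)
  if (length(centers) == 0L) centers <- (n %/% 2L)
  res <- lapply(centers, function(c0) {
    idx <- (c0 - half):(c0 - half + w_samp - 1L)
    gp <- gc_pair(y[idx], x[idx], p = p, q = q, ...)
    c(g_xy = gp$g_xy, g_yx = gp$g_yx, raw_xy = gp$raw_xy, raw_yx = gp$raw_yx)
  })
  res <- do.call(rbind, res)
  structure(
    list(window_centers = (centers - 1L) / fs, window_length = w_samp / fs,
         step = step_samp / fs, fs = fs,
         g_xy = res[, "g_xy"], g_yx = res[, "g_yx"],
         raw_xy = res[, "raw_xy"], raw_yx = res[, "raw_yx"]),
    class = "tvgc_series"
  )
}

#' @export
print.tvgc_series <- function(x, ...) {
  cat(sprintf("Time-varying GC: %d windows of %.3g s (step %.3g s)\n",
              length(x$window_centers), x$window_length, x$step))
  cat(sprintf("  mean X->Y %.4f, mean Y->X %.4f\n",
              mean(x$g_xy), mean(x$g_yx)))
  invisible(x)
}

#' Time-frequency Granger causality maps over wavelet packet bands
#'
#' For each requested center frequency, extracts the matching narrowband
#' components of both signals with [wpt_decompose()] / [extract_band()] and
#' runs [tv_gc()] on the band-limited pair; rows (ascending frequency) are
#' stacked into one map per direction.
#'
#' @param y,x Series of equal length (e.g. preprocessed EEG and EMG).
#' @param fs Sampling rate in Hz.
#' @param freqs Center frequencies in Hz, default `1:50`.
#' @param wavelet_name,levels Wavelet packet configuration (default
#'   `coif5`, 7 levels).
#' @param window,step Sliding-window geometry in seconds.
#' @param ... Further arguments to [gc_pair()].
#' @return A list of two `tfgc_map` objects (`xy`, `yx`), each with
#'   `freqs`, `times`, a frequency x time `values` matrix and `direction`.
#'   A band whose fit fails is recorded as a row of `NA` (and listed in
#'   `failed_bands`), never silently zeroed.
#' @export
tf_gc_map <- function(y, x, fs, freqs = 1:50, wavelet_name = "coif5",
                      levels = 7L, window = 1, step = 0.1, ...) {
  freqs <- sort(as.numeric(freqs))
  if (any(freqs <= 0 | freqs >= fs / 2)) {
    stop("freqs must lie in (0, fs/2) = (0, ", fs / 2, ") Hz")
  }
  dy <- wpt_decompose(y, wavelet_name, levels, fs)
  dx <- wpt_decompose(x, wavelet_name, levels, fs)
  rows_xy <- list(); rows_yx <- list()
  times <- NULL
  failed <- character(0)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    band_res <- tryCatch({
      by <- extract_band(dy, f)$w
      bx <- extract_band(dx, f)$w
      tv_gc(by, bx, fs, window = window, step = step, ...)
    }, error = function(e) e)
    if (inherits(band_res, "error")) {
      failed <- c(failed, sprintf("%g Hz: %s", f, conditionMessage(band_res)))
      rows_xy[[i]] <- NULL; rows_yx[[i]] <- NULL
    } else {
      if (is.null(times)) times <- band_res$window_centers
      rows_xy[[i]] <- band_res$g_xy
      rows_yx[[i]] <- band_res$g_yx
    }
  }
  if (is.null(times)) stop("all bands failed: ", paste(failed, collapse = "; "))
  n_t <- length(times)
  to_map <- function(rows, direction) {
    vals <- matrix(vapply(seq_along(freqs), function(i) {
      if (is.null(rows[[i]])) rep(NA_real_, n_t) else as.numeric(rows[[i]])
    }, numeric(n_t)), nrow = n_t)
    vals <- t(vals)
    dimnames(vals) <- list(paste0(freqs, "Hz"), sprintf("%.3fs", times))
    structure(list(freqs = freqs, times = times, values = vals,
                   direction = direction, failed_bands = failed),
              class = "tfgc_map")
  }
  list(xy = to_map(rows_xy, "X->Y"), yx = to_map(rows_yx, "Y->X"))
}

#' @export
print.tfgc_map <- function(x, ...) {
  cat(sprintf("TF-GC map %s: %d frequencies x %d windows, mean %.4f\n",
              x$direction, length(x$freqs), length(x$times),
              mean(x$values, na.rm = TRUE)))
  if (length(x$failed_bands) > 0L) {
    cat("  failed bands:", paste(x$failed_bands, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Canonical EEG band definitions
#'
#' Delta 0.5-4, theta 4-8, alpha 9-12, beta 13-35, gamma 35-50 Hz. The
#' gamma upper edge is capped at 50 Hz, the top of the default extraction
#' grid (`edge_inferred` notes this cap is a convention, not a datum).
#' @return Named list of `c(lo, hi)` pairs (half-open intervals).
#' @export
default_bands <- function() {
  structure(list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(9, 12),
                 beta = c(13, 35), gamma = c(35, 50)),
            edge_inferred = "gamma upper edge capped at extraction limit 50 Hz")
}

#' Default analysis periods
#'
#' Movement preparation = first 3 s, execution = following 4 s of the 7 s
#' segment.
#' @return Named list of `c(lo, hi)` pairs in seconds.
#' @export
default_periods <- function() {
  list(preparation = c(0, 3), execution = c(3, 7))
}

#' Band-by-period summary of a TF-GC map
#'
#' Arithmetic mean of the map cells whose center frequency falls inside
#' each band (half-open `[lo, hi)`) and whose window center falls inside
#' each period.
#'
#' @param map A `tfgc_map`.
#' @param bands Named list of `c(lo, hi)` Hz pairs, default [default_bands()].
#' @param periods Named list of `c(lo, hi)` second pairs, default
#'   [default_periods()].
#' @return A data frame with columns `band`, `period`, `direction`,
#'   `mean_gc`, `n_cells`.
#' @export
band_average <- function(map, bands = default_bands(),
                         periods = default_periods()) {
  stopifnot(inherits(map, "tfgc_map"))
  out <- list()
  for (b in names(bands)) {
    f_in <- map$freqs >= bands[[b]][1] & map$freqs < bands[[b]][2]
    if (!any(f_in)) stop("band '", b, "' contains no map frequencies")
    for (pd in names(periods)) {
      t_in <- map$times >= periods[[pd]][1] & map$times < periods[[pd]][2]
      if (!any(t_in)) stop("period '", pd, "' contains no map windows")
      cells <- map$values[f_in, t_in, drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        band = b, period = pd, direction = map$direction,
        mean_gc = mean(cells, na.rm = TRUE),
        n_cells = sum(!is.na(cells))
      )
    }
  }
  do.call(rbind, out)
}

#' Compare GC values across groups with a normality/homogeneity gate
#'
#' Runs a Shapiro-Wilk normality check per group and a Brown-Forsythe
#' (median-centered Levene) homogeneity-of-variance check at the 0.05
#' level. If every group is compatible with normality and variances are
#' homogeneous, a one-way ANOVA is used; otherwise the Kruskal-Wallis rank
#' test.
#'
#' @param samples Named list: group -> numeric vector (>= 2 groups with
#'   >= 3 values each).
#' @param gate_alpha Significance level of the routing checks, default 0.05.
#' @return A `group_test` list: `route` ("anova" or "kruskal"),
#'   `statistic`, `p_value`, `gate` (per-group normality p-values and the
#'   homogeneity p-value), `df`.
#' @export
compare_groups <- function(samples, gate_alpha = 0.05) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("need at least 2 groups")
  }
  if (is.null(names(samples))) names(samples) <- paste0("group", seq_along(samples))
  sizes <- vapply(samples, length, integer(1))
  if (any(sizes < 3L)) stop("every group needs at least 3 values")
  values <- unlist(samples, use.names = FALSE)
  group <- factor(rep(names(samples), sizes))

  normal_p <- vapply(samples, function(v) {
    if (stats::sd(v) == 0) return(0)   # degenerate: not testably normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  # Brown-Forsythe: ANOVA on absolute deviations from group medians
  adev <- abs(values - stats::ave(values, group, FUN = stats::median))
  homo_p <- stats::anova(stats::lm(adev ~ group))[["Pr(>F)"]][1]

  if (all(normal_p > gate_alpha) && homo_p > gate_alpha) {
    fit <- stats::oneway.test(values ~ group, var.equal = TRUE)
    route <- "anova"
    statistic <- unname(fit$statistic)
    p_value <- fit$p.value
    df <- unname(fit$parameter)
  } else {
    fit <- stats::kruskal.test(values, group)
    route <- "kruskal"
    statistic <- unname(fit$statistic)
    p_value <- fit$p.value
    df <- unname(fit$parameter)
  }
  structure(
    list(route = route, statistic = statistic, p_value = p_value,
         df = df, gate = list(normality_p = normal_p, homogeneity_p = homo_p,
                              gate_alpha = gate_alpha),
         group_sizes = sizes),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  lab <- if (x$route == "anova") "one-way ANOVA F" else "Kruskal-Wallis chi-squared"
  cat(sprintf("Group comparison via %s: statistic %.4g, p = %.4g\n",
              lab, x$statistic, x$p_value))
  cat(sprintf("  gate: min normality p %.3g, homogeneity p %.3g (alpha %.2g)\n",
              min(x$gate$normality_p), x$gate$homogeneity_p, x$gate$gate_alpha))
  invisible(x)
}

#' Surrogate significance threshold for directed GC
#'
#' Destroys the putative causal alignment by circularly time-shifting the
#' candidate cause by a random offset (preserving its marginal and spectral
#' structure), recomputes the directed GC for each surrogate, and returns
#' the empirical `(1 - alpha)` threshold as the `ceiling((1-alpha) *
#' (n_surr + 1))`-th order statistic. With `n_surr = 19` and `alpha = 0.05`
#' this is the surrogate maximum. Deterministic given `seed`.
#'
#' @param y,x Series of equal length.
#' @param n_surr Number of surrogates; must satisfy
#'   `ceiling((1-alpha)(n_surr+1)) <= n_surr` (>= 19 for alpha 0.05).
#' @param alpha Significance level, default 0.05.
#' @param seed Integer seed.
#' @param min_shift Minimum circular shift in samples, default
#'   `max(50, 10 * max(p, q))`.
#' @param statistic `"clamped"` (default) thresholds the non-negative GC
#'   used in maps; `"raw"` thresholds the unclamped log variance ratio,
#'   which avoids ties at zero and gives exact `alpha`-level calibration.
#' @param ... Passed to [gc_pair()].
#' @return Named vector `c(xy = , yx = )` of thresholds, with the surrogate
#'   statistics attached as attribute `"surrogates"`.
#' @export
surrogate_threshold <- function(y, x, n_surr = 19L, alpha = 0.05, seed = 1L,
                                min_shift = NULL, statistic = c("clamped", "raw"),
                                p = 5L, q = 5L, ...) {
  statistic <- match.arg(statistic)
  n <- length(y)
  kth <- ceiling((1 - alpha) * (n_surr + 1L))
  if (kth > n_surr) {
    stop("n_surr = ", n_surr, " too small for alpha = ", alpha,
         ": need at least ", ceiling((1 - alpha) / alpha))
  }
  if (is.null(min_shift)) min_shift <- max(50L, 10L * max(p, q))
  if (2L * min_shift >= n) stop("series too short for circular-shift surrogates")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  shifts <- sample.int(n - 2L * min_shift, n_surr, replace = TRUE) + min_shift
  roll <- function(v, k) c(v[(k + 1L):n], v[1L:k])
  g_surr <- vapply(shifts, function(k) {
    gp <- gc_pair(y, roll(x, k), p = p, q = q, ...)
    # shifting x breaks alignment for BOTH directions
    if (statistic == "clamped") c(xy = gp$g_xy, yx = gp$g_yx)
    else c(xy = gp$raw_xy, yx = gp$raw_yx)
  }, numeric(2))
  structure(c(xy = sort(g_surr["xy", ])[kth], yx = sort(g_surr["yx", ])[kth]),
            surrogates = g_surr)
}
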