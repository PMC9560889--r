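# Directed GC, sliding windows, maps, summaries, group statistics,
# surrogate thresholds.

test_that("gc_pair recovers the closed-form linear coupling", {
  sim <- simulate_fixture("linear_unidirectional", seed = 71)
  gp <- gc_pair(sim$y, sim$x)
  expect_equal(gp$g_xy, log(1.25), tolerance = 0.03 / log(1.25))
  expect_lt(gp$g_yx, 0.02)
  expect_gte(gp$g_xy, 0); expect_gte(gp$g_yx, 0)
  expect_lte(gp$variances[["y_full"]], gp$variances[["y_restricted"]] + 1e-12)
})

test_that("independent pairs give near-zero clamped GC", {
  sim <- simulate_fixture("null_pair", seed = 72)
  gp <- gc_pair(sim$y, sim$x)
  expect_lt(gp$g_xy, 0.02)
  expect_lt(gp$g_yx, 0.02)
  # clamped-to-zero cells come from small raw magnitudes
  expect_lt(abs(gp$raw_xy), 0.05)
  expect_lt(abs(gp$raw_yx), 0.05)
})

test_that("quadratic coupling needs the degree-2 dictionary", {
  sim <- simulate_fixture("quadratic_unidirectional", seed = 73)
  y <- as.numeric(scale(sim$y)); x <- as.numeric(scale(sim$x))
  expect_gt(gc_pair(y, x, degree = 2)$g_xy, 0.1)
  expect_lt(gc_pair(y, x, degree = 1)$g_xy, 0.02)
})

test_that("direction separation holds across seeds", {
  gs <- vapply(1:12, function(s) {
    sim <- simulate_fixture("linear_unidirectional", n = 3000, seed = 900 + s)
    gp <- gc_pair(sim$y, sim$x)
    c(gp$g_xy, gp$g_yx)
  }, numeric(2))
  expect_gt(stats::median(gs[1, ]), 5 * stats::median(gs[2, ]))
  expect_gt(stats::median(gs[1, ]), 0.15)
})

test_that("tv_gc with one full-length window reduces to gc_pair", {
  sim <- simulate_fixture("linear_unidirectional", n = 1000, seed = 74)
  tv <- tv_gc(sim$y, sim$x, fs = 250, window = 4, step = 10)
  gp <- gc_pair(sim$y, sim$x)
  expect_length(tv$g_xy, 1L)
  expect_equal(unname(tv$g_xy), gp$g_xy)
  expect_equal(unname(tv$g_yx), gp$g_yx)
  expect_error(tv_gc(sim$y, sim$x, fs = 250, window = 0.1), "too short")
})

test_that("stationary coupling is consistent across windows", {
  sim <- simulate_fixture("linear_unidirectional", n = 4000, seed = 75)
  tv <- tv_gc(sim$y, sim$x, fs = 250, window = 4, step = 1)
  whole <- gc_pair(sim$y, sim$x)$g_xy
  frac_close <- mean(abs(tv$g_xy - whole) < 0.5 * whole)
  expect_gte(frac_close, 0.8)
})

test_that("step-change coupling is tracked and localized", {
  sim <- simulate_fixture("step_coupling", seed = 105)   # frozen fixture seed
  tv <- tv_gc(sim$y, sim$x, fs = 250, window = 1, step = 0.1)
  t_true <- (sim$truth$coupling_profile$t_switch - 1) / 250
  first <- tv$window_centers < t_true
  expect_gt(mean(tv$g_xy[!first]) - mean(tv$g_xy[first]), 0.1)
  # change point: best two-segment mean split of the g_xy series
  g <- tv$g_xy; n <- length(g)
  sse <- vapply(2:(n - 1), function(k) {
    sum((g[1:k] - mean(g[1:k]))^2) + sum((g[(k + 1):n] - mean(g[(k + 1):n]))^2)
  }, numeric(1))
  t_est <- tv$window_centers[which.min(sse) + 1]
  expect_lt(abs(t_est - t_true), tv$window_length + 1e-9)
})

test_that("band_average partitions map cells correctly", {
  freqs <- 1:50
  times <- seq(0.5, 6.5, by = 0.5)
  vals <- matrix(0, length(freqs), length(times))
  vals[freqs >= 13 & freqs < 35, ] <- 1
  map <- structure(list(freqs = freqs, times = times, values = vals,
                        direction = "X->Y", failed_bands = character(0)),
                   class = "tfgc_map")
  ba <- band_average(map)
  expect_equal(ba$mean_gc[ba$band == "beta"], c(1, 1))
  for (b in c("delta", "theta", "alpha", "gamma")) {
    expect_equal(ba$mean_gc[ba$band == b], c(0, 0))
  }
  expect_equal(sort(unique(ba$period)), c("execution", "preparation"))
  # constant map: every summary entry equals the constant
  mapc <- map; mapc$values[] <- 0.37
  expect_true(all(abs(band_average(mapc)$mean_gc - 0.37) < 1e-12))
  expect_error(band_average(map, bands = list(hf = c(60, 80))), "hf")
  expect_error(band_average(map, periods = list(late = c(10, 20))), "late")
})

test_that("compare_groups gates normality/homogeneity and routes correctly", {
  set.seed(81)
  same <- lapply(1:3, function(i) rnorm(15))
  # identical groups: F ~ 0, p ~ 1
  ident <- list(a = c(1.1, 2.2, 3.0, 2.5), b = c(1.1, 2.2, 3.0, 2.5),
                c = c(1.1, 2.2, 3.0, 2.5))
  gt0 <- compare_groups(ident)
  expect_lt(gt0$statistic, 1e-10)
  expect_gt(gt0$p_value, 0.99)
  # normal groups with a 3-sd shift: ANOVA route, p < 0.01
  shift <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15) + 3)
  gts <- compare_groups(shift)
  expect_equal(gts$route, "anova")
  expect_lt(gts$p_value, 0.01)
  # heavy-tailed groups: Kruskal-Wallis route
  heavy <- lapply(1:3, function(i) rt(30, df = 1))
  gth <- compare_groups(heavy)
  expect_equal(gth$route, "kruskal")
  expect_error(compare_groups(list(a = 1:5)), "2 groups")
  expect_error(compare_groups(list(a = 1:2, b = 1:5)), "at least 3 values")
})

test_that("surrogate thresholds are deterministic and detect real coupling", {
  sim <- simulate_fixture("linear_unidirectional", n = 1500, seed = 82)
  th1 <- surrogate_threshold(sim$y, sim$x, n_surr = 19, seed = 5)
  th2 <- surrogate_threshold(sim$y, sim$x, n_surr = 19, seed = 5)
  expect_identical(th1, th2)
  gp <- gc_pair(sim$y, sim$x)
  expect_gt(gp$g_xy, th1[["xy"]])
  expect_error(surrogate_threshold(sim$y, sim$x, n_surr = 10, alpha = 0.05),
               "too small")
})

test_that("tf_gc_map localizes narrowband coupling in frequency", {
  sim <- simulate_fixture("banded_20hz", n = 5000, seed = 83)
  n_s <- length(sim$y)
  maps <- tf_gc_map(sim$y, sim$x, fs = 250, freqs = c(12, 20, 28),
                    window = n_s / 250, step = n_s / 250)
  avg <- rowMeans(maps$xy$values)
  expect_equal(maps$xy$freqs[which.max(avg)], 20)
  expect_true(all(maps$xy$values >= 0, na.rm = TRUE))
  expect_equal(dim(maps$yx$values), dim(maps$xy$values))
  expect_equal(maps$xy$direction, "X->Y")
  expect_equal(maps$yx$direction, "Y->X")
})
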