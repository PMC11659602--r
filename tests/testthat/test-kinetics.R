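# Covalent inhibition kinetics: kobs, progress curves, the implicit
# IC50(t) relation and its fit, and the second-order constant.

ctx_padi4 <- substrate_context(S = 10, K_M = 1.36)

test_that("kobs follows saturation kinetics in the apparent K_I", {
  m <- krippendorff_model(covalent_params(0.78, 0.17), ctx_padi4)
  A <- apparent_KI(m)
  expect_equal(A, 0.78 * (1 + 10 / 1.36))
  expect_identical(kobs_covalent(0, m), 0)
  expect_equal(kobs_covalent(A, m), 0.17 / 2)
  expect_equal(kobs_covalent(1e6 * A, m), 0.17, tolerance = 1e-4)
  # monotone nondecreasing, bounded by k_inact
  I <- sort(10^runif(50, -3, 3))
  ko <- kobs_covalent(I, m)
  expect_true(all(diff(ko) >= 0))
  expect_true(all(ko <= 0.17))
  expect_error(kobs_covalent(-1, m), "non-negative")
})

test_that("progress curves match the independent RK4 ODE oracle", {
  times <- c(5, 15, 30, 60, 90)
  for (K_I in c(0.3, 2, 10)) {
    for (k in c(0.05, 0.2, 0.5)) {
      m <- krippendorff_model(covalent_params(K_I, k), ctx_padi4)
      for (I in c(0.5, 5, 50)) {
        got <- progress_curve(I, m, v0_uninhibited = 1, times = times)
        want <- ode_progress_oracle(I, K_I, k, 10, 1.36, 1, times)
        expect_equal(got, want, tolerance = 1e-6)
      }
    }
  }
})

test_that("progress curve limits: linear when uninhibited, plateau when covalent", {
  m <- krippendorff_model(covalent_params(1, 0.2), ctx_padi4)
  times <- c(0, 10, 50)
  expect_identical(progress_curve(0, m, 2.5, times), 2.5 * times)
  # t -> infinity plateau at v0/kobs
  A <- apparent_KI(m)
  I <- 5
  v0 <- 1 / (1 + I / A)
  kobs <- kobs_covalent(I, m)
  expect_equal(progress_curve(I, m, 1, 1e7), v0 / kobs, tolerance = 1e-9)
  expect_error(progress_curve(1, m, -1, times), "non-negative")
  expect_error(progress_curve(1, m, 1, c(-1, 2)), "non-negative")
})

test_that("implicit IC50(t) solver: limits, residual, and agreement with a damped fixed-point oracle", {
  m <- krippendorff_model(covalent_params(0.78, 0.17), ctx_padi4)
  A <- apparent_KI(m)
  # t -> 0 limit is the apparent K_I
  expect_equal(krippendorff_ic50(1e-9, m), A, tolerance = 1e-6)
  # k_inact = 0: purely reversible, IC50 = apparent K_I at any time
  m0 <- krippendorff_model(covalent_params(0.78, 0), ctx_padi4)
  expect_equal(krippendorff_ic50(c(1, 100), m0), c(A, A))
  # solution satisfies the printed implicit equation to < 1e-9 relative
  ts <- c(1, 5, 15, 30, 60, 120, 600)
  x <- krippendorff_ic50(ts, m)
  eta <- x / (A + x)
  u <- eta * 0.17 * ts
  rhs <- A * ((2 - 2 * exp(-u)) / u - 1)
  expect_true(all(abs(x - rhs) / x < 1e-9))
  expect_true(all(x > 0 & x <= A))
  # two independent root-finders agree (bisection+Newton vs fixed point)
  x60 <- krippendorff_ic50(60, m)
  fp <- fixed_point_ic50_oracle(60, 0.78, 0.17, 10, 1.36)
  expect_equal(x60, fp, tolerance = 1e-6)
  expect_error(krippendorff_ic50(0, m), "positive")
})

test_that("IC50(t) is strictly decreasing in incubation time across random models", {
  set.seed(42)
  for (i in 1:100) {
    K_I <- 10^runif(1, -1, 1)
    k <- 10^runif(1, log10(0.05), log10(0.5))
    m <- krippendorff_model(covalent_params(K_I, k), ctx_padi4)
    A <- apparent_KI(m)
    t1 <- 10^runif(1, 0, 2)
    expect_lt(krippendorff_ic50(2 * t1, m), krippendorff_ic50(t1, m))
    # residual and t->0 limit across the random draw
    x <- krippendorff_ic50(t1, m)
    u <- x / (A + x) * k * t1
    rhs <- A * ((2 - 2 * exp(-u)) / u - 1)
    expect_lt(abs(x - rhs) / x, 1e-9)
    expect_equal(krippendorff_ic50(1e-9, m), A, tolerance = 1e-6)
  }
})

test_that("Krippendorff fit recovers noise-free truth across a parameter grid", {
  ts <- c(15, 30, 45, 60, 75)
  for (K_I in c(0.1, 1, 10)) {
    for (k in c(0.05, 0.15, 0.5)) {
      m <- krippendorff_model(covalent_params(K_I, k), ctx_padi4)
      ser <- data.frame(t = ts, ic50 = krippendorff_ic50(ts, m),
                        usable = TRUE)
      f <- fit_krippendorff(ser, ctx_padi4)
      expect_equal(f$params$K_I, K_I, tolerance = 1e-3)
      expect_equal(f$params$k_inact, k, tolerance = 1e-3)
    }
  }
})

test_that("Krippendorff fit under lognormal noise: median recovery within 10%, no worse than a grid-search oracle", {
  ts <- c(15, 30, 45, 60, 75)
  truth <- krippendorff_model(covalent_params(0.78, 0.17), ctx_padi4)
  clean <- krippendorff_ic50(ts, truth)
  set.seed(7)
  KI_hat <- numeric(200)
  k_hat <- numeric(200)
  for (s in 1:200) {
    y <- clean * exp(rnorm(length(ts), 0, 0.1))
    f <- fit_krippendorff(data.frame(t = ts, ic50 = y, usable = TRUE),
                          ctx_padi4)
    KI_hat[s] <- f$params$K_I
    k_hat[s] <- f$params$k_inact
  }
  expect_lt(abs(median(KI_hat) - 0.78) / 0.78, 0.10)
  expect_lt(abs(median(k_hat) - 0.17) / 0.17, 0.10)
  # optimizer at least matches a 1%-resolution brute-force grid search
  set.seed(11)
  y <- clean * exp(rnorm(length(ts), 0, 0.1))
  f <- fit_krippendorff(data.frame(t = ts, ic50 = y, usable = TRUE),
                        ctx_padi4)
  gs <- grid_search_krippendorff_oracle(ts, y, 10, 1.36,
                                        KI_range = 0.78 * c(0.5, 2),
                                        k_range = 0.17 * c(0.5, 2))
  expect_lte(f$rss, gs$rss + 1e-12)
  expect_equal(f$params$K_I, gs$K_I, tolerance = 0.02)
  expect_equal(f$params$k_inact, gs$k_inact, tolerance = 0.02)
})

test_that("second-order efficiency constant reproduces printed kinetics-table entries", {
  # chloroacetimidoyl variant: exactly the printed value
  expect_equal(kinact_over_KI(covalent_params(4.0, 0.28)), 70000)
  # printed constants were computed from unrounded fits, so printed
  # K_I/k_inact pairs reproduce them to within ~1%
  expect_equal(kinact_over_KI(covalent_params(1.6, 0.55)), 343000,
               tolerance = 0.01)
  expect_equal(kinact_over_KI(covalent_params(1.3, 0.12)), 92000,
               tolerance = 0.01)
  expect_equal(kinact_over_KI(covalent_params(1, 0)), 0)
  expect_error(kinact_over_KI(0, 0.2), "non-zero")
})

test_that("parameter containers enforce their invariants", {
  expect_error(covalent_params(-1, 0.1), "positive")
  expect_error(covalent_params(1, -0.1), "non-negative")
  expect_error(substrate_context(-1, 1), "non-negative")
  expect_error(substrate_context(10, 0), "positive")
  expect_gte(apparent_KI(krippendorff_model(covalent_params(2, 0.1),
                                            substrate_context(0, 1))), 2)
})
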