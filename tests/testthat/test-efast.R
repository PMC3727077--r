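test_that("search curves span their ranges and are reproducible", {
  d <- efast_design(list(a = c(2, 10), b = c(-1, 1), c = c(0, 100)),
                    M = 4, omega_max = 32, Nr = 2)
  X <- sample_search_curve(d, 1, phase = c(0.3, 1.1, 2.9))
  for (j in 1:3) {
    r <- d$ranges[[j]]
    expect_lt(min(X[, j]), r[1] + 0.02 * diff(r))
    expect_gt(max(X[, j]), r[2] - 0.02 * diff(r))
    expect_true(all(X[, j] >= r[1] & X[, j] <= r[2]))
  }
  # identical phases give identical curves
  expect_identical(X, sample_search_curve(d, 1, phase = c(0.3, 1.1, 2.9)))
  # Nyquist violation rejected
  expect_error(efast_design(list(a = c(0, 1)), M = 4, omega_max = 32,
                            Ns = 100), "Nyquist")
})

test_that("output spectrum concentrates at the driving frequency", {
  d <- efast_design(list(a = c(0, 1)), M = 4, omega_max = 16, Nr = 1)
  X <- sample_search_curve(d, 1, phase = 0.7)
  y <- X[, 1]                      # identity model
  p <- vegftrap:::.spectrum_power(y - mean(y))
  om <- attr(X, "omega")[1]
  at_harmonics <- sum(p[seq_len(4) * om])
  expect_gt(at_harmonics / sum(p), 0.99)
})

test_that("partial variance matches the closed-form Fourier oracle", {
  d <- efast_design(list(a = c(0, 1)), M = 4, omega_max = 16, Nr = 1)
  s <- attr(sample_search_curve(d, 1), "s")
  a <- 3.2
  y <- a * cos(16 * s)
  # a pure cosine of amplitude a carries variance a^2/2
  expect_equal(partial_variance(y, 16, M = 4), a^2 / 2, tolerance = 1e-10)
  # constant output has zero partial variance everywhere
  expect_equal(partial_variance(rep(2, length(s)), 16, 4), 0)
  expect_error(partial_variance(y[1:10], 16, 4), "too few samples")
  # constant model: indices reported as undefined
  idx <- efast_indices(0, 0, 0)
  expect_true(is.na(idx$S_i) && is.na(idx$S_Ti))
})

test_that("an additive linear model recovers analytic Sobol indices", {
  cc <- c(a = 1, b = 2, d = 3)
  fn <- function(x) sum(cc * x[names(cc)])
  res <- efast(fn, list(a = c(0, 1), b = c(0, 1), d = c(0, 1)),
               M = 4, omega_max = 64, Nr = 5, seed = 2)
  analytic <- cc^2 / sum(cc^2)
  got <- res$indices
  expect_lt(max(abs(got$S_i - analytic[got$parameter])), 0.02)
  # additive model: total indices equal first-order indices
  expect_lt(max(abs(got$S_Ti - analytic[got$parameter])), 0.02)
  expect_lte(sum(got$S_i), 1 + 0.02)
})

test_that("the Ishigami benchmark matches its closed forms", {
  a <- 7; b <- 0.1
  fn <- function(x) sin(x[["x1"]]) + a * sin(x[["x2"]])^2 +
    b * x[["x3"]]^4 * sin(x[["x1"]])
  rng <- list(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi))
  res <- efast(fn, rng, M = 4, omega_max = 64, Nr = 5, seed = 3)
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  VT3 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + VT3
  S <- c(x1 = V1 / V, x2 = V2 / V, x3 = 0)
  ST <- c(x1 = (V1 + VT3) / V, x2 = V2 / V, x3 = VT3 / V)
  got <- res$indices
  expect_lt(max(abs(got$S_i - S[got$parameter])), 0.03)
  expect_lt(max(abs(got$S_Ti - ST[got$parameter])), 0.03)
  # definitional ordering, asserted numerically
  expect_true(all(got$S_Ti >= got$S_i - 0.01))
})

test_that("a pure interaction is seen by total but not first-order indices", {
  # y = x1 x2 on [-1,1]^2: E[y|x_i] = 0 so S_i = 0, S_Ti = 1
  fn <- function(x) x[["x1"]] * x[["x2"]]
  res <- efast(fn, list(x1 = c(-1, 1), x2 = c(-1, 1)),
               M = 4, omega_max = 64, Nr = 5, seed = 4)
  expect_lt(max(res$indices$S_i), 0.05)
  expect_gt(min(res$indices$S_Ti - res$indices$S_i), 0.3)
})

test_that("resample averaging reduces estimator variance", {
  fn <- function(x) sin(2 * pi * x[["a"]]) + 0.5 * x[["b"]]
  rng <- list(a = c(0, 1), b = c(0, 1))
  est <- function(Nr, seed)
    efast(fn, rng, M = 4, omega_max = 32, Nr = Nr,
          seed = seed)$indices$S_i[1]
  v1 <- stats::var(vapply(1:12, function(s) est(1, s), numeric(1)))
  v4 <- stats::var(vapply(1:12, function(s) est(4, 100 + s), numeric(1)))
  expect_lt(v4, v1)
})

test_that("indices are invariant to affine rescaling of the output", {
  fn <- function(x) x[["a"]]^2 + x[["b"]]
  rng <- list(a = c(0, 1), b = c(0, 1))
  r1 <- efast(fn, rng, M = 4, omega_max = 32, Nr = 2, seed = 5)
  r2 <- efast(function(x) 100 * fn(x) - 7, rng, M = 4, omega_max = 32,
              Nr = 2, seed = 5)
  expect_equal(r1$indices$S_i, r2$indices$S_i, tolerance = 1e-10)
  expect_equal(r1$indices$S_Ti, r2$indices$S_Ti, tolerance = 1e-10)
})

test_that("modular analysis flags an inert model input as insensitive", {
  cfg <- default_config(tumor = FALSE)
  paths <- list(kp_normal_V = c("transport", "k_p", "normal", "V"),
                body_weight = c("dosing", "body_weight_g"))
  res <- run_module_analysis(cfg, module = paths,
                             outputs = "mVEGF_blood",
                             M = 4, Nr = 1, omega_max = 8, seed = 1,
                             v_tumor = 0)
  tab <- res$indices
  expect_lt(tab$S_i[tab$parameter == "body_weight"], 0.02)
  expect_gt(tab$S_i[tab$parameter == "kp_normal_V"], 0.1)
  expect_true(all(tab$S_Ti >= tab$S_i - 0.05))
  expect_error(run_module_analysis(cfg, module = list()), "empty")
})
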