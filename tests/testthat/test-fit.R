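test_that("the objective is the weighted sum of squared residuals", {
  theta <- c(q_EC = 0.009)
  data <- generate_plasma_dataset(theta, normal_config(), doses = 2.5,
                                  times_days = c(1, 3, 7),
                                  schedule_times_days = 0, seed = 1)
  problem <- vegf_fit_problem(data, normal_config(), free = "q_EC",
                              schedule_times_days = 0)
  # brute-force oracle: recompute the sum from the predictions
  theta2 <- c(q_EC = 0.015)
  pred <- predict_observables(problem, theta2)
  manual <- sum((1 / data$value_pM) * (data$value_pM - pred)^2)
  expect_equal(wssr(theta2, problem), manual, tolerance = 1e-8)
  # at the generating truth the objective vanishes
  expect_lt(wssr(theta, problem) / sum(1 / data$value_pM * data$value_pM^2),
            1e-8)
  # weights are 1/C: a single point C_exp = 2 predicted at 1 gives 0.5
  expect_equal((1 / 2) * (2 - 1)^2, 0.5)
})

test_that("the objective is invariant to data-point order", {
  theta <- c(q_EC = 0.012)
  data <- generate_plasma_dataset(c(q_EC = 0.009), normal_config(),
                                  doses = 2.5, times_days = c(1, 3, 7),
                                  schedule_times_days = 0, seed = 2)
  p1 <- vegf_fit_problem(data, normal_config(), free = "q_EC",
                         schedule_times_days = 0)
  p2 <- vegf_fit_problem(data[rev(seq_len(nrow(data))), ],
                         normal_config(), free = "q_EC",
                         schedule_times_days = 0)
  expect_equal(wssr(theta, p1), wssr(theta, p2), tolerance = 1e-10)
})

test_that("problem construction rejects non-positive measurements", {
  bad <- data.frame(time_days = 1, dose_mg_per_kg = 2.5,
                    observable = "trap_free", value_pM = 0)
  expect_error(vegf_fit_problem(bad), "positive")
  expect_error(vegf_fit_problem(data.frame(time_days = 1)), "columns")
})

test_that("bounded multi-start fitting recovers an identifiable rate", {
  truth <- c(q_EC = 0.009)
  data <- generate_plasma_dataset(truth, normal_config(), doses = 2.5,
                                  times_days = c(0.5, 1, 2, 3, 5, 7),
                                  schedule_times_days = 0, seed = 3)
  problem <- vegf_fit_problem(data, normal_config(), free = "q_EC",
                              schedule_times_days = 0)
  fit <- vegf_fit(problem, n_starts = 2, seed = 4)
  expect_gte(fit$n_converged, 1)
  expect_lt(abs(fit$mean[["q_EC"]] - truth[["q_EC"]]) / truth[["q_EC"]],
            0.05)
  # descent contract: optimum never worse than its start
  set.seed(4)
  lb <- log10(problem$bounds$lower); ub <- log10(problem$bounds$upper)
  starts <- 10^matrix(stats::runif(2, lb, ub), nrow = 2)
  for (s in 1:2) {
    w0 <- wssr(stats::setNames(starts[s], "q_EC"), problem)
    expect_lte(fit$runs$wssr[s], w0 + 1e-9)
  }
  # a truth on the bound is recovered at the bound
  expect_true(all(fit$runs$q_EC >= problem$bounds$lower - 1e-12))
})

test_that("parameter sweeps degenerate gracefully", {
  data <- generate_plasma_dataset(c(q_EC = 0.009), normal_config(),
                                  doses = 2.5, times_days = c(1, 3),
                                  schedule_times_days = 0, seed = 5)
  problem <- vegf_fit_problem(data, normal_config(), free = "q_EC",
                              schedule_times_days = 0)
  empty <- sweep_parameter("q_EC", numeric(0), problem)
  expect_equal(nrow(empty), 0L)
  one <- sweep_parameter("q_EC", 0.009, problem)
  expect_equal(one$wssr, wssr(c(q_EC = 0.009), problem), tolerance = 1e-8)
})

test_that("tumor secretion sweeps move the human complex monotonically", {
  m <- xeno_model()
  ss <- xeno_ss()
  peak_hv <- function(q_tumor) {
    cfg <- apply_params(default_config(), c(q_tumor = q_tumor))
    mm <- vegf_model(cfg)
    sim <- simulate(mm, schedule = dose_schedule(2.5, 0), days = 7,
                    rtol = 1e-6)
    max(plasma_observables(sim)$trap_hVEGF)
  }
  peaks <- vapply(c(0.003, 0.009, 0.027), peak_hv, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
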