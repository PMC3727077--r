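#' Free-parameter catalogue for fitting
#'
#' Known free parameters, their configuration targets and default
#' bounds: secretion rates between 1.5e-6 (the ELISA detection floor)
#' and 2 molecules/cell/s; VEGF Trap clearance within one order of
#' magnitude of the 72 h half-life equivalent (1.6e-4/min); the Trap
#' dissociation constant between 0.25 and 5 pM; permeability of normal
#' or tumor tissue to the drug within one order of magnitude of its
#' baseline.
#'
#' @return data.frame with columns `name`, `lower`, `upper`.
#' @export
fit_parameter_table <- function() {
  cl <- half_life_to_clearance(72, "h", "min") / 60   # 1/s
  data.frame(
    name = c("q_muscle", "q_EC", "q_tumor", "c_A", "c_VA",
             "Kd_trap_pM", "kp_trap_normal", "kp_trap_tumor"),
    lower = c(1.5e-6, 1.5e-6, 1.5e-6, cl / 10, cl / 10,
              0.25, 3e-9, 3e-8),
    upper = c(2, 2, 2, cl * 10, cl * 10, 5, 3e-7, 3e-6),
    stringsAsFactors = FALSE)
}

#' Apply free-parameter values to a configuration
#'
#' @param config a `vegf_config`.
#' @param theta named numeric vector; names from [fit_parameter_table()].
#' @return the modified configuration.
#' @export
apply_params <- function(config, theta) {
  for (nm in names(theta)) {
    v <- theta[[nm]]
    if (nm %in% c("q_muscle", "q_EC", "q_tumor")) {
      config$secretion[[nm]] <- v
    } else if (nm == "c_A") {
      config$transport$clearance[["Trap"]] <- v
    } else if (nm == "c_VA") {
      config$transport$clearance[["TrapV"]] <- v
    } else if (nm == "Kd_trap_pM") {
      i <- match("V-Trap", config$kinetics$class)
      config$kinetics$koff[i] <- v * 1e-12 * config$kinetics$kon[i]
    } else if (nm == "kp_trap_normal") {
      config$transport$k_p$normal[c("Trap", "TrapV")] <- v
    } else if (nm == "kp_trap_tumor") {
      config$transport$k_p$tumor[c("Trap", "TrapV")] <- v
    } else stop("unknown free parameter '", nm, "'", call. = FALSE)
  }
  config
}

#' Define a weighted least-squares fitting problem
#'
#' @param data data.frame with columns `time_days`, `dose_mg_per_kg`,
#'   `observable` (one of `trap_free`, `trap_mVEGF`, `trap_hVEGF`) and
#'   `value_pM` (strictly positive: weights are 1/value).
#' @param config base model configuration.
#' @param free character vector of free parameter names.
#' @param bounds optional data.frame (`name`, `lower`, `upper`)
#'   overriding the defaults of [fit_parameter_table()].
#' @param schedule_times_days injection times of the experiment.
#' @param rtol,atol solver tolerances used during fitting.
#' @return object of class `vegf_fit_problem`.
#' @export
vegf_fit_problem <- function(data, config = default_config(),
                             free = c("q_muscle", "q_EC", "q_tumor"),
                             bounds = NULL,
                             schedule_times_days = c(0, 3.5, 7, 10.5),
                             rtol = 1e-6, atol = 1e-22) {
  need <- c("time_days", "dose_mg_per_kg", "observable", "value_pM")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(data$value_pM <= 0))
    stop("all experimental values must be positive (weights are 1/C)",
         call. = FALSE)
  tab <- fit_parameter_table()
  if (!is.null(bounds)) {
    i <- match(bounds$name, tab$name)
    tab$lower[i] <- bounds$lower; tab$upper[i] <- bounds$upper
  }
  tab <- tab[match(free, tab$name), ]
  if (anyNA(tab$name))
    stop("unknown free parameter(s): ",
         paste(setdiff(free, fit_parameter_table()$name), collapse = ", "),
         call. = FALSE)
  stopifnot(all(is.finite(tab$lower)), all(is.finite(tab$upper)),
            all(tab$lower < tab$upper))
  structure(list(data = data, config = config, free = free, bounds = tab,
                 schedule_times_days = schedule_times_days,
                 weights = 1 / data$value_pM,
                 rtol = rtol, atol = atol),
            class = "vegf_fit_problem")
}

#' Simulated observables at the data design points
#'
#' Builds the model at `theta`, settles the steady state, runs the
#' dosing protocol once per dose level, and returns predictions aligned
#' with the problem's data rows.
#'
#' @param problem a `vegf_fit_problem`.
#' @param theta named parameter vector (subset of the free parameters).
#' @return numeric vector of predicted concentrations (pM).
#' @export
predict_observables <- function(problem, theta) {
  cfg <- apply_params(problem$config, theta)
  model <- vegf_model(cfg)
  ss <- suppressWarnings(steady_state(model, tol = 1e-10))
  d <- problem$data
  pred <- numeric(nrow(d))
  for (dose in unique(d$dose_mg_per_kg)) {
    rows <- which(d$dose_mg_per_kg == dose)
    tt <- sort(unique(d$time_days[rows])) * 86400
    sim <- simulate(model,
                    schedule = dose_schedule(dose,
                                             problem$schedule_times_days),
                    days = max(d$time_days[rows]),
                    t_out = tt, init = ss,
                    rtol = problem$rtol, atol = problem$atol)
    obs <- plasma_observables(sim)
    for (r in rows) {
      i <- which.min(abs(obs$time_days - d$time_days[r]))
      pred[r] <- obs[[d$observable[r]]][i]
    }
  }
  pred
}

#' Weighted sum of squared residuals
#'
#' The fitting objective: `sum_i W_i (C_exp,i - C_sim,i(theta))^2` with
#' weights `W_i = 1/C_exp,i`.  A failed simulation yields a large
#' finite penalty and a warning.
#'
#' @param theta named parameter vector.
#' @param problem a `vegf_fit_problem`.
#' @return scalar objective value.
#' @export
wssr <- function(theta, problem) {
  pred <- tryCatch(predict_observables(problem, theta),
                   error = function(e) {
                     warning("simulation failed at theta (",
                             conditionMessage(e), "); penalized")
                     NULL
                   })
  if (is.null(pred)) return(1e12)
  sum(problem$weights * (problem$data$value_pM - pred)^2)
}

#' Multi-start bounded least-squares fit
#'
#' Runs `n_starts` bounded Levenberg-Marquardt least-squares
#' minimizations (trust-region-style steps with box constraints,
#' [minpack.lm::nls.lm()]) from starting points drawn log-uniformly
#' within the parameter bounds, in log10 parameter space.  The optimum
#' of each converged run is collected and the estimate is reported as
#' the mean and standard deviation over converged runs.
#'
#' @param problem a `vegf_fit_problem`.
#' @param n_starts number of optimization runs (default 20).
#' @param seed integer seed for the start-point draws.
#' @param maxiter per-run iteration cap.
#' @return object of class `vegf_fit`: per-run table, summary mean/SD,
#'   convergence counts.
#' @export
vegf_fit <- function(problem, n_starts = 20, seed = 1L, maxiter = 40) {
  stopifnot(inherits(problem, "vegf_fit_problem"))
  lb <- log10(problem$bounds$lower); ub <- log10(problem$bounds$upper)
  k <- length(lb)
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * k, rep(lb, each = n_starts),
                                rep(ub, each = n_starts)),
                   nrow = n_starts)
  resid_fn <- function(lt) {
    theta <- stats::setNames(10^lt, problem$free)
    pred <- tryCatch(predict_observables(problem, theta),
                     error = function(e) NULL)
    if (is.null(pred))
      return(rep(1e6, nrow(problem$data)))
    sqrt(problem$weights) * (problem$data$value_pM - pred)
  }
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    t0 <- Sys.time()
    ans <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = lb, upper = ub,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-10, ftol = 1e-10,
                           # forward-difference steps of ~1% in log10
                           # space: far above the ODE solver noise
                           # floor, and wide enough to sense curvature
                           # across the low-secretion plateau
                           epsfcn = 1e-4)),
      error = function(e) e)
    if (inherits(ans, "error")) {
      runs[[s]] <- data.frame(run = s, converged = FALSE, wssr = NA,
                              message = conditionMessage(ans),
                              t(stats::setNames(rep(NA_real_, k),
                                                problem$free)))
    } else {
      theta <- stats::setNames(10^ans$par, problem$free)
      runs[[s]] <- data.frame(run = s,
                              converged = ans$info %in% 1:4,
                              wssr = ans$deviance,
                              message = ans$message, t(theta))
    }
    attr(runs[[s]], "elapsed") <- as.numeric(Sys.time() - t0, units = "secs")
  }
  runs <- do.call(rbind, runs)
  ok <- runs$converged & !is.na(runs$wssr)
  est <- runs[ok, problem$free, drop = FALSE]
  structure(list(
    runs = runs,
    mean = colMeans(est),
    sd = apply(est, 2, stats::sd),
    n_converged = sum(ok),
    n_starts = n_starts,
    best = if (any(ok)) runs[ok, ][which.min(runs$wssr[ok]), ] else NULL,
    problem = problem, seed = seed),
    class = "vegf_fit")
}

#' @export
print.vegf_fit <- function(x, ...) {
  cat(sprintf("Multi-start weighted least-squares fit: %d/%d runs converged\n",
              x$n_converged, x$n_starts))
  tab <- data.frame(parameter = names(x$mean), mean = x$mean, sd = x$sd)
  print(tab, row.names = FALSE, digits = 4)
  if (!is.null(x$best))
    cat(sprintf("best WSSR: %.6g\n", x$best$wssr))
  invisible(x)
}

#' @export
summary.vegf_fit <- function(object, ...) {
  print(object)
  cat("\nPer-run optima:\n")
  print(object$runs[, c("run", "converged", "wssr", object$problem$free)],
        row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.vegf_fit <- function(object, ...) object$mean

#' Weighted residuals of a fit at its mean estimate
#'
#' Re-simulates the model at the mean of the converged optima and
#' returns `sqrt(W_i) (C_exp,i - C_sim,i)`.
#'
#' @param object a `vegf_fit`.
#' @param ... unused.
#' @return numeric vector, one entry per data row.
#' @export
residuals.vegf_fit <- function(object, ...) {
  pred <- predict_observables(object$problem, object$mean)
  sqrt(object$problem$weights) * (object$problem$data$value_pM - pred)
}

#' One-dimensional parameter sweep of fit quality
#'
#' Varies a single model input over the given values and records the
#' objective and the predicted observables at each value, the design
#' used to probe identifiability (e.g. muscle secretion from 0 to
#' 0.02 molecules/cell/s).
#'
#' @param parameter free-parameter name.
#' @param values numeric vector of values to scan.
#' @param problem a `vegf_fit_problem`.
#' @param theta named vector of the remaining parameters (optional).
#' @return data.frame of class `vegf_sweep` with columns `value`,
#'   `wssr`; predicted observables in `attr(, "predictions")`.
#' @export
sweep_parameter <- function(parameter, values, problem, theta = NULL) {
  preds <- list()
  ws <- numeric(length(values))
  for (i in seq_along(values)) {
    th <- c(stats::setNames(values[i], parameter), theta)
    preds[[i]] <- tryCatch(predict_observables(problem, th),
                           error = function(e) rep(NA_real_,
                                                   nrow(problem$data)))
    ws[i] <- sum(problem$weights * (problem$data$value_pM - preds[[i]])^2)
  }
  out <- data.frame(value = values, wssr = ws)
  attr(out, "predictions") <- preds
  class(out) <- c("vegf_sweep", "data.frame")
  out
}
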