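#' Design of an extended-FAST sensitivity analysis
#'
#' Fixes the sampling frequencies of the extended Fourier Amplitude
#' Sensitivity Test.  The parameter of interest is driven at the high
#' frequency `omega_max`; the complementary set shares low frequencies
#' no larger than `omega_max / (2 M)`, so that the first `M` harmonics
#' of the interest frequency do not interfere with complementary power.
#' The sample count obeys the Nyquist requirement
#' `Ns >= 4 M omega_max + 1`.
#'
#' @param ranges named list of length-2 numeric ranges, one per
#'   parameter.
#' @param M number of harmonics summed into the partial variance.
#' @param omega_max frequency assigned to the parameter of interest.
#' @param Ns samples per search curve (default the Nyquist minimum).
#' @param Nr number of resampling curves (random phase shifts).
#' @param log_scale logical (scalar or per parameter): sample the
#'   range on a log scale.
#' @return object of class `efast_design`.
#' @export
efast_design <- function(ranges, M = 4, omega_max = 64, Ns = NULL, Nr = 5,
                         log_scale = FALSE) {
  k <- length(ranges)
  stopifnot(k >= 1, M >= 1, omega_max >= 2 * M)
  if (is.null(Ns)) Ns <- 4 * M * omega_max + 1
  if (Ns < 4 * M * omega_max + 1)
    stop(sprintf(
      "Ns = %d violates the Nyquist requirement 4*M*omega_max + 1 = %d",
      Ns, 4 * M * omega_max + 1), call. = FALSE)
  # Complementary frequencies are spread over [1, omega_max/(4M)]:
  # this keeps not only their M harmonics but also their low-order
  # combination tones below omega_max/2, so complementary power does
  # not leak into the band attributed to the parameter of interest.
  max_c <- max(1, floor(omega_max / (4 * M)))
  omega_c <- if (k == 1) integer(0)
             else if (k == 2) 1L
             else as.integer(round(seq(1, max_c, length.out = k - 1)))
  structure(list(ranges = ranges, names = names(ranges), k = k, M = M,
                 omega_max = omega_max, omega_c = omega_c, Ns = Ns,
                 Nr = Nr,
                 log_scale = rep_len(log_scale, k)),
            class = "efast_design")
}

#' Sample one eFAST search curve
#'
#' @param design an [efast_design()].
#' @param i index of the parameter of interest (driven at `omega_max`).
#' @param phase numeric vector of phase shifts (length k), or `NULL`
#'   for zero phases.
#' @return `Ns x k` matrix of parameter values; the underlying
#'   frequencies are attached as `attr(, "omega")`.
#' @export
sample_search_curve <- function(design, i, phase = NULL) {
  k <- design$k; Ns <- design$Ns
  stopifnot(i >= 1, i <= k)
  if (is.null(phase)) phase <- rep(0, k)
  omega <- numeric(k)
  omega[i] <- design$omega_max
  omega[-i] <- design$omega_c
  s <- -pi + pi * (2 * seq_len(Ns) - 1) / Ns
  X <- matrix(NA_real_, Ns, k, dimnames = list(NULL, design$names))
  for (j in seq_len(k)) {
    u <- 0.5 + asin(sin(omega[j] * s + phase[j])) / pi
    r <- design$ranges[[j]]
    X[, j] <- if (design$log_scale[j])
      exp(log(r[1]) + u * (log(r[2]) - log(r[1])))
    else r[1] + u * (r[2] - r[1])
  }
  attr(X, "omega") <- omega
  attr(X, "s") <- s
  X
}

# Spectral power |c_f|^2 at integer frequencies 1..(Ns-1)/2, with the
# normalization for which the total variance is 2 * sum(power).
.spectrum_power <- function(y) {
  Ns <- length(y)
  F <- stats::fft(y)
  nf <- floor((Ns - 1) / 2)
  (Mod(F[2:(nf + 1)])^2) / Ns^2
}

#' Partial variance at a driving frequency
#'
#' Sums the squared Fourier coefficients (cosine and sine series) over
#' the first `M` harmonics of `omega`, doubled:
#' `D = 2 * sum_p (A_{p w}^2 + B_{p w}^2)`.
#'
#' @param y model output sampled along a search curve.
#' @param omega integer driving frequency.
#' @param M number of harmonics.
#' @return scalar partial variance.
#' @export
partial_variance <- function(y, omega, M = 4) {
  Ns <- length(y)
  if (Ns < 4 * M * omega + 1)
    stop("too few samples for ", M, " harmonics of frequency ", omega,
         call. = FALSE)
  p <- .spectrum_power(y)
  2 * sum(p[seq_len(M) * omega])
}

#' First-order and total sensitivity indices from variances
#'
#' `S_i = D_i / D_total`; `S_Ti = 1 - D_ci / D_total`, where `D_ci`
#' is the partial variance of the complementary set.
#'
#' @param D_i partial variance at the interest frequency.
#' @param D_ci complementary partial variance.
#' @param D_total total variance (`2 * sum` over the full spectrum).
#' @return list with `S_i` and `S_Ti`; both `NA` when `D_total` is 0
#'   (constant model output).
#' @export
efast_indices <- function(D_i, D_ci, D_total) {
  if (!is.finite(D_total) || D_total <= 0)
    return(list(S_i = NA_real_, S_Ti = NA_real_))
  list(S_i = D_i / D_total, S_Ti = 1 - D_ci / D_total)
}

#' Extended Fourier Amplitude Sensitivity Test
#'
#' Variance-based global sensitivity analysis.  For each parameter the
#' model is evaluated along `Nr` space-filling search curves (random
#' phase shifts, seeded); the first-order index is the share of output
#' variance at the interest frequency and its harmonics, the total
#' index is one minus the share below `omega_max / 2`, which contains
#' all complementary power.  Indices are averaged over the resample
#' curves.
#'
#' @param fn model: function of a named numeric vector returning a
#'   numeric (possibly named, possibly multi-output) vector.
#' @param ranges named list of parameter ranges.
#' @param design optional [efast_design()]; built from `...` otherwise.
#' @param seed integer seed for the phase draws.
#' @param ... passed to [efast_design()].
#' @return object of class `efast_result`: data.frame with columns
#'   `parameter`, `output`, `S_i`, `S_Ti` plus the design.
#' @examples
#' r <- efast(function(x) x[["a"]] + 2 * x[["b"]],
#'            list(a = c(0, 1), b = c(0, 1)), Nr = 2, seed = 1)
#' @export
efast <- function(fn, ranges, design = NULL, seed = 1L, ...) {
  if (is.null(design)) design <- efast_design(ranges, ...)
  k <- design$k
  set.seed(seed)
  phases <- array(stats::runif(design$Nr * k * k, 0, 2 * pi),
                  c(design$Nr, k, k))
  rows <- list()
  for (i in seq_len(k)) {
    acc <- NULL
    for (r in seq_len(design$Nr)) {
      X <- sample_search_curve(design, i, phase = phases[r, i, ])
      y1 <- fn(X[1, ])
      Y <- matrix(NA_real_, design$Ns, length(y1))
      Y[1, ] <- y1
      for (j in 2:design$Ns) Y[j, ] <- fn(X[j, ])
      outs <- if (!is.null(names(y1))) names(y1)
              else paste0("y", seq_along(y1))
      for (q in seq_along(y1)) {
        p <- .spectrum_power(Y[, q])
        D_total <- 2 * sum(p)
        D_i <- 2 * sum(p[seq_len(design$M) * design$omega_max])
        D_ci <- 2 * sum(p[seq_len(floor(design$omega_max / 2))])
        idx <- efast_indices(D_i, D_ci, D_total)
        acc <- rbind(acc, data.frame(parameter = design$names[i],
                                     output = outs[q],
                                     S_i = idx$S_i, S_Ti = idx$S_Ti))
      }
    }
    agg <- stats::aggregate(acc[, c("S_i", "S_Ti")],
                            by = acc[, c("parameter", "output")], mean)
    rows[[i]] <- agg
  }
  out <- do.call(rbind, rows)
  structure(list(indices = out, design = design, seed = seed),
            class = "efast_result")
}

#' @export
print.efast_result <- function(x, ...) {
  cat(sprintf(
    "eFAST sensitivity indices (M = %d, Ns = %d, Nr = %d, omega = %d)\n",
    x$design$M, x$design$Ns, x$design$Nr, x$design$omega_max))
  print(x$indices, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Default parameter groupings for the modular sensitivity analysis
#'
#' Editable grouping of model inputs into the receptor-expression,
#' transport and kinetic modules.  Each entry gives the configuration
#' path of a scalar parameter; ranges default to one order of
#' magnitude either side of the baseline on a log scale.
#'
#' @param config a `vegf_config`.
#' @return named list of modules; each module is a named list of
#'   configuration paths (character vectors).
#' @export
efast_modules <- function(config) {
  list(
    receptor = list(
      tumor_VEGFR1 = c("network", "compartments", "tumor", "surfaces",
                       "tumor_cell", "densities", "VEGFR1"),
      tumor_VEGFR2 = c("network", "compartments", "tumor", "surfaces",
                       "tumor_cell", "densities", "VEGFR2"),
      tumor_NRP1 = c("network", "compartments", "tumor", "surfaces",
                     "tumor_cell", "densities", "NRP1"),
      tumor_NRP2 = c("network", "compartments", "tumor", "surfaces",
                     "tumor_cell", "densities", "NRP2")),
    transport = list(
      kp_normal_V = c("transport", "k_p", "normal", "V"),
      kp_tumor_V = c("transport", "k_p", "tumor", "V"),
      kp_normal_sR1 = c("transport", "k_p", "normal", "sR1"),
      kL_normal = c("transport", "k_L", "normal")),
    kinetic = list(
      kon_V_R1 = c("kinetics_kon", "V-R1"),
      kon_V_R2 = c("kinetics_kon", "V-R2"),
      kon_V_N = c("kinetics_kon", "V-N"),
      kon_V_GAG = c("kinetics_kon", "V-GAG"),
      kon_V_sR1 = c("kinetics_kon", "V-sR1")))
}

.config_set_path <- function(config, path, value) {
  if (path[1] == "kinetics_kon") {
    i <- match(path[2], config$kinetics$class)
    config$kinetics$kon[i] <- value
    return(config)
  }
  expr <- Reduce(function(acc, p) call("[[", acc, p), path,
                 accumulate = FALSE, init = quote(config))
  eval(call("<-", expr, value), envir = environment())
  config
}

#' Modular eFAST analysis of the compartment model
#'
#' Runs the eFAST estimator over one parameter module against the
#' steady-state VEGF and soluble VEGFR1 concentrations in the three
#' compartments (the tumor volume is held at the dosing trigger
#' volume).  Defaults are reduced relative to toy-function use because
#' each sample is a full steady-state solve; all settings are
#' configurable.
#'
#' @param config a `vegf_config`.
#' @param module `"receptor"`, `"transport"` or `"kinetic"`, or a
#'   named list of configuration paths.
#' @param outputs subset of the nine steady-state observables (default
#'   all): `mVEGF_normal`, `mVEGF_blood`, `mVEGF_tumor`, `hVEGF_*`,
#'   `sR1_*`.
#' @param span multiplicative half-range of each parameter (default
#'   one order of magnitude each side).
#' @param M,Nr,omega_max,seed eFAST settings (see [efast_design()]).
#' @param v_tumor tumor volume at which the steady state is evaluated.
#' @return an `efast_result`.
#' @export
run_module_analysis <- function(config, module = "transport",
                                outputs = NULL, span = 10,
                                M = 4, Nr = 1, omega_max = 8, seed = 1L,
                                v_tumor = config$growth$trigger_volume) {
  paths <- if (is.character(module)) efast_modules(config)[[module]]
           else module
  if (is.null(paths) || length(paths) == 0)
    stop("empty or unknown parameter module", call. = FALSE)
  base <- vapply(paths, function(p) {
    if (p[1] == "kinetics_kon")
      config$kinetics$kon[match(p[2], config$kinetics$class)]
    else Reduce(`[[`, p, init = config)
  }, numeric(1))
  ranges <- lapply(base, function(b) c(b / span, b * span))
  fn <- function(x) {
    cfg <- config
    for (nm in names(paths))
      cfg <- .config_set_path(cfg, paths[[nm]], x[[nm]])
    m <- vegf_model(cfg)
    ss <- suppressWarnings(steady_state(m, tol = 1e-10, v_tumor = v_tumor))
    g <- function(ids, kav) {
      ids <- ids[ids %in% names(ss)]
      if (!length(ids)) return(NA_real_)
      1e15 * sum(ss[ids]) / kav
    }
    iso <- cfg$network$isoforms
    kavn <- cfg$geometry$normal$K_av
    kavt <- if (!is.null(cfg$geometry$tumor)) cfg$geometry$tumor$K_av else 1
    y <- c(
      mVEGF_normal = g(paste0("normal.fluid.", iso$mouse), kavn),
      mVEGF_blood = g(paste0("blood.fluid.", iso$mouse), 1),
      mVEGF_tumor = g(paste0("tumor.fluid.", iso$mouse), kavt),
      hVEGF_normal = g(paste0("normal.fluid.", iso$human), kavn),
      hVEGF_blood = g(paste0("blood.fluid.", iso$human), 1),
      hVEGF_tumor = g(paste0("tumor.fluid.", iso$human), kavt),
      sR1_normal = g("normal.fluid.sR1", kavn),
      sR1_blood = g("blood.fluid.sR1", 1),
      sR1_tumor = g("tumor.fluid.sR1", kavt))
    if (!is.null(outputs)) y <- y[outputs]
    y
  }
  design <- efast_design(ranges, M = M, omega_max = omega_max, Nr = Nr,
                         log_scale = TRUE)
  efast(fn, ranges, design = design, seed = seed)
}
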